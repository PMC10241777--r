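#' driftline: dispersal simulation meets clonal population genetics
#'
#' Tools to (i) simulate passive surface drift of propagules over gridded
#' daily ocean-current fields and summarise it as site-to-site connectivity,
#' (ii) analyse clonal multilocus genotype data (Psex clone discrimination,
#' clonal richness, rarefied allelic richness, heterozygosities, FIS,
#' Weir-Cockerham FST), and (iii) compare the two through permutation tests.
#'
#' @keywords internal
"_PACKAGE"

# Mean Earth radius, km. Shared by advection (metres-to-degrees conversion)
# and all great-circle distances so the two sides of the pipeline agree.
EARTH_RADIUS_KM <- 6371

#' Great-circle (haversine) distance in kilometres
#'
#' Vectorised over all four coordinate arguments (usual recycling rules).
#' Uses the mean Earth radius of 6371 km, the same constant the advection
#' integrator uses to convert velocities to angular displacement.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' haversine_km(0, 0, 1, 0)  # one degree of longitude at the equator
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Cross-distance matrix (n x m) between two coordinate sets, km.
cross_dist_km <- function(lon1, lat1, lon2, lat2) {
  n <- length(lon1)
  m <- length(lon2)
  haversine_km(rep(lon1, times = m), rep(lat1, times = m),
               rep(lon2, each = n), rep(lat2, each = n)) |>
    matrix(nrow = n, ncol = m)
}

stop_spec <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

is_fraction <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1

# Population (divisor n) standard deviation, optionally weighted.
sd_pop <- function(x, w = NULL) {
  if (length(x) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(x))
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}
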