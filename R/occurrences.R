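#' Generate clustered species occurrence records
#'
#' Emulates a compilation of species occurrence records (literature plus
#' biodiversity databases) as jittered clusters around known centres, for
#' testing the site-aggregation and simulation stages without downloads.
#'
#' @param centers Data frame or matrix with columns `lon`, `lat` (degrees).
#' @param n_per_center Records per centre.
#' @param jitter_km Isotropic jitter scale in km; each record is displaced
#'   by a truncated normal (|z| <= 3) in each axis, so every record lies
#'   within `3 * jitter_km` of its centre.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param landmask Optional `velocity_field` (or logical-mask holder) used
#'   to reject centres that fall on land.
#' @return Data frame of class `occurrence_table` with columns `lon`,
#'   `lat`, `source` (the centre index, as text).
#' @export
make_occurrences <- function(centers, n_per_center, jitter_km = 0.1,
                             seed = 1L, landmask = NULL) {
  centers <- as.data.frame(centers)
  if (!all(c("lon", "lat") %in% names(centers)))
    stop_spec("make_occurrences: centers needs lon and lat columns")
  if (!is_count(n_per_center))
    stop_spec("make_occurrences: n_per_center must be a positive integer")
  if (!is.null(landmask)) {
    on_land <- is_land(landmask, centers$lon, centers$lat)
    if (any(on_land))
      stop_spec("make_occurrences: centers on land: ",
                paste(which(on_land), collapse = ", "))
  }
  n <- nrow(centers)
  rng <- local_rng(seed)
  km_per_deg <- EARTH_RADIUS_KM * pi / 180
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    dx <- rtruncnorm3(n_per_center, rng) * jitter_km / km_per_deg /
      cos(centers$lat[i] * pi / 180)
    dy <- rtruncnorm3(n_per_center, rng) * jitter_km / km_per_deg
    data.frame(lon = centers$lon[i] + dx, lat = centers$lat[i] + dy,
               source = sprintf("center_%d", i))
  }))
  class(out) <- c("occurrence_table", "data.frame")
  out
}

# Standard normal truncated at |z| <= 3, drawn from an isolated RNG stream.
rtruncnorm3 <- function(n, rng) {
  z <- rng$rnorm(n)
  while (any(bad <- abs(z) > 3)) z[bad] <- rng$rnorm(sum(bad))
  z
}

# A private RNG stream: isolates generator randomness from the global seed
# state so all synthetic generators are reproducible and independent.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = with_state(stats::rnorm),
       runif = with_state(stats::runif),
       rgamma = with_state(stats::rgamma),
       sample_int = with_state(function(n, size, replace = FALSE, prob = NULL)
         sample.int(n, size, replace = replace, prob = prob)))
}

# TRUE where (lon, lat) falls on a land node of the mask grid
# (nearest-node lookup; points outside the grid count as land).
is_land <- function(field, lon, lat) {
  ix <- round(stats::approx(field$lon, seq_along(field$lon), lon,
                            rule = 2)$y)
  iy <- round(stats::approx(field$lat, seq_along(field$lat), lat,
                            rule = 2)$y)
  out <- field$land[cbind(ix, iy)]
  out | lon < min(field$lon) | lon > max(field$lon) |
    lat < min(field$lat) | lat > max(field$lat)
}

#' Write / read occurrence records as CSV (`lon`, `lat`, `source`)
#' @param occ An `occurrence_table` (any data frame with those columns).
#' @param path File path.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[c("lon", "lat", "source")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) {
  out <- utils::read.csv(path, colClasses = c(lon = "numeric",
                                              lat = "numeric",
                                              source = "character"))
  class(out) <- c("occurrence_table", "data.frame")
  out
}
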