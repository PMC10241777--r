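#' Aggregate occurrence records into source/sink habitat sites
#'
#' Snaps records onto a fixed equal-angle grid and keeps one site per
#' occupied cell. The latitudinal step is `resolution_km / 111.32` degrees;
#' the longitudinal step is that divided by `cos(lat)` at the domain centre
#' (constant over the domain), giving near-square cells of about
#' `resolution_km` on a side. Cells are indexed 0-based, half-open, from a
#' fixed global origin at (-180, -90); a cell owns its lower/left edge.
#' Site coordinates are cell centres.
#'
#' Records that fall on land (per `landmask`) are snapped to the nearest
#' ocean cell within 2 cells (Chebyshev), else dropped with a warning.
#'
#' @param occ Occurrence table (columns `lon`, `lat`).
#' @param resolution_km Aggregation resolution in km (> 0).
#' @param landmask Optional `velocity_field` providing the land raster.
#' @param ref_lat Latitude (degrees) at which the longitudinal step is
#'   scaled; defaults to the mid-range of the input latitudes. Pass it
#'   explicitly to reuse one grid across datasets (e.g. when re-aggregating
#'   site centres, use the `ref_lat` attribute of the original `site_set`).
#' @return A `site_set` data frame: `site_id` (contiguous from 0), `lon`,
#'   `lat` (cell centres), `cell_i`, `cell_j`, `n_occ`. Attributes:
#'   `resolution_km`, `n_dropped`, grid steps.
#' @export
#' @examples
#' occ <- data.frame(lon = c(0, 0.001, 1), lat = c(0, 0.001, 0),
#'                   source = "x")
#' aggregate_occurrences(occ, resolution_km = 1)
aggregate_occurrences <- function(occ, resolution_km = 1, landmask = NULL,
                                  ref_lat = NULL) {
  occ <- as.data.frame(occ)
  if (nrow(occ) == 0) stop_spec("aggregate_occurrences: empty table")
  if (!is.numeric(resolution_km) || resolution_km <= 0)
    stop_spec("aggregate_occurrences: resolution_km must be > 0")
  if (any(occ$lon < -180 | occ$lon > 180 | occ$lat < -90 | occ$lat > 90))
    stop_spec("aggregate_occurrences: coordinates outside WGS84 bounds")

  step_lat <- resolution_km / 111.32
  lat0 <- if (is.null(ref_lat)) mean(range(occ$lat)) else ref_lat
  step_lon <- step_lat / cos(lat0 * pi / 180)

  cell_of <- function(lon, lat)
    cbind(i = floor((lon - (-180)) / step_lon),
          j = floor((lat - (-90)) / step_lat))
  center_of <- function(ij)
    cbind(lon = -180 + (ij[, 1] + 0.5) * step_lon,
          lat = -90 + (ij[, 2] + 0.5) * step_lat)

  ij <- cell_of(occ$lon, occ$lat)
  keep <- rep(TRUE, nrow(occ))

  if (!is.null(landmask)) {
    ctr <- center_of(ij)
    land <- is_land(landmask, ctr[, 1], ctr[, 2])
    if (any(land)) {
      # snap to nearest ocean cell within a 2-cell Chebyshev neighbourhood
      offs <- expand.grid(di = -2:2, dj = -2:2)
      offs <- offs[order(pmax(abs(offs$di), abs(offs$dj)),
                         abs(offs$di) + abs(offs$dj), offs$di, offs$dj), ]
      for (r in which(land)) {
        cand <- cbind(ij[r, 1] + offs$di, ij[r, 2] + offs$dj)
        cc <- center_of(cand)
        ok <- !is_land(landmask, cc[, 1], cc[, 2])
        if (any(ok)) ij[r, ] <- cand[which(ok)[1], ] else keep[r] <- FALSE
      }
      n_drop <- sum(!keep)
      if (n_drop > 0)
        warning(sprintf("aggregate_occurrences: dropped %d record(s) on land beyond snap range", n_drop))
      if (all(!keep))
        stop_spec("aggregate_occurrences: all occurrences on land beyond snap range")
    }
  }

  ij <- ij[keep, , drop = FALSE]
  key <- paste(ij[, 1], ij[, 2])
  tab <- table(key)
  uk <- names(tab)
  first <- match(uk, key)
  cells <- ij[first, , drop = FALSE]
  ord <- order(cells[, 1], cells[, 2])
  cells <- cells[ord, , drop = FALSE]
  ctr <- center_of(cells)
  out <- data.frame(site_id = seq_len(nrow(cells)) - 1L,
                    lon = ctr[, 1], lat = ctr[, 2],
                    cell_i = cells[, 1], cell_j = cells[, 2],
                    n_occ = as.integer(tab[uk][ord]))
  rownames(out) <- NULL
  structure(out, resolution_km = resolution_km,
            step_lon = step_lon, step_lat = step_lat, ref_lat = lat0,
            n_dropped = sum(!keep),
            class = c("site_set", "data.frame"))
}

#' Write / read a site set as CSV
#' @param sites A `site_set`.
#' @param path File path.
#' @export
write_sites_csv <- function(sites, path) {
  df <- as.data.frame(sites)
  df$resolution_km <- attr(sites, "resolution_km")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path)
  res <- if ("resolution_km" %in% names(df)) df$resolution_km[1] else NA_real_
  df$resolution_km <- NULL
  structure(df, resolution_km = res, class = c("site_set", "data.frame"))
}
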