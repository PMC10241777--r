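#' Build an asymmetric connectivity matrix from trajectories
#'
#' Pairwise probability of connectivity: the number of particles released
#' from site i that produced a connectivity event at site j (retention
#' i = j included), divided by the number released from i.
#'
#' @param traj A `trajectory_set` (from [run_year()] or equivalent, with
#'   columns `site_id`, `fate`, `event_site`).
#' @param sites The `site_set` the trajectories reference.
#' @param year Optional label (year or `"mean"`).
#' @return A `connectivity_matrix`: list with `site_id`, `n_released`
#'   (per source), `n_events` (matrix), `p` (matrix `n_events / n_released`),
#'   `year`.
#' @export
build_matrix <- function(traj, sites, year = attr(traj, "year")) {
  ids <- sites$site_id
  if (!all(traj$site_id %in% ids))
    stop_spec("build_matrix: trajectory references unknown source site id")
  ev <- traj[traj$fate == "event", ]
  if (nrow(ev) > 0 && !all(ev$event_site %in% ids))
    stop_spec("build_matrix: trajectory references unknown event site id")
  n <- length(ids)
  n_released <- as.integer(table(factor(traj$site_id, levels = ids)))
  n_events <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(ev) > 0) {
    tab <- table(factor(ev$site_id, levels = ids),
                 factor(ev$event_site, levels = ids))
    n_events <- matrix(as.integer(tab), n, n, dimnames = list(ids, ids))
  }
  p <- n_events / ifelse(n_released == 0, 1, n_released)
  structure(list(site_id = ids, n_released = n_released,
                 n_events = n_events, p = p,
                 year = if (is.null(year)) NA else year),
            class = "connectivity_matrix")
}

#' Construct a connectivity matrix from explicit counts or probabilities
#'
#' @param p Square probability matrix (entries in `[0, 1]`).
#' @param n_released Releases per source; with `n_events`, `p` may be
#'   omitted and is computed exactly as `n_events / n_released`.
#' @param n_events Integer event-count matrix.
#' @param site_id Site ids; default `0:(n-1)`.
#' @param year Label.
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(p = NULL, n_released = NULL, n_events = NULL,
                                site_id = NULL, year = NA) {
  if (is.null(p)) {
    stopifnot(!is.null(n_events), !is.null(n_released))
    p <- n_events / ifelse(n_released == 0, 1, n_released)
  }
  p <- as.matrix(p)
  n <- nrow(p)
  if (ncol(p) != n) stop_spec("connectivity_matrix: p must be square")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_spec("connectivity_matrix: probabilities must lie in [0, 1]")
  if (is.null(site_id)) site_id <- seq_len(n) - 1L
  if (is.null(n_events)) n_events <- matrix(NA_integer_, n, n)
  if (is.null(n_released)) n_released <- rep(NA_integer_, n)
  structure(list(site_id = site_id, n_released = n_released,
                 n_events = n_events, p = p, year = year),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d sites, year %s, %d event(s)\n",
              length(x$site_id), as.character(x$year),
              sum(x$n_events, na.rm = TRUE)))
  invisible(x)
}

#' Element-wise mean of per-year connectivity matrices
#'
#' Interannual averaging: the probability matrix is the arithmetic mean of
#' the yearly probabilities; releases and event counts are summed for
#' bookkeeping.
#'
#' @param per_year List of `connectivity_matrix` objects over an identical
#'   site set.
#' @return A `connectivity_matrix` labelled `"mean"`.
#' @export
mean_matrix <- function(per_year) {
  stopifnot(length(per_year) >= 1)
  ids <- per_year[[1]]$site_id
  for (m in per_year)
    if (!identical(m$site_id, ids))
      stop_spec("mean_matrix: site sets differ between years")
  p <- Reduce(`+`, lapply(per_year, `[[`, "p")) / length(per_year)
  n_events <- Reduce(`+`, lapply(per_year, `[[`, "n_events"))
  n_released <- Reduce(`+`, lapply(per_year, `[[`, "n_released"))
  structure(list(site_id = ids, n_released = n_released,
                 n_events = n_events, p = p, year = "mean"),
            class = "connectivity_matrix")
}

#' Summary statistics of connectivity events
#'
#' Distances are great-circle (haversine, R = 6371 km) between site cell
#' centres. By default (mirroring the conditioning implied by reporting a
#' mean probability alongside "few events") the probability and event-count
#' means are over ordered pairs with at least one event, diagonal included;
#' `connected_only = FALSE` averages over all ordered pairs instead. The
#' distance mean/SD weight each pair by its event count (the event
#' multiset); SDs are population SDs.
#'
#' @param mat A `connectivity_matrix` with event counts.
#' @param sites The matching `site_set`.
#' @param connected_only Condition the P and event-count means on pairs
#'   with >= 1 event (default `TRUE`).
#' @param include_diagonal Include retention pairs (default `TRUE`).
#' @return An `event_stats` list: `defined`, `n_events_total`,
#'   `mean_distance_km`, `sd_distance_km`, `max_distance_km`, `mean_p`,
#'   `sd_p`, `mean_events`, `sd_events`, `n_pairs_connected`.
#' @export
event_statistics <- function(mat, sites, connected_only = TRUE,
                             include_diagonal = TRUE) {
  stopifnot(inherits(mat, "connectivity_matrix"))
  n <- length(mat$site_id)
  idx <- match(mat$site_id, sites$site_id)
  if (anyNA(idx)) stop_spec("event_statistics: site mismatch")
  D <- cross_dist_km(sites$lon[idx], sites$lat[idx],
                     sites$lon[idx], sites$lat[idx])
  keep <- matrix(TRUE, n, n)
  if (!include_diagonal) diag(keep) <- FALSE
  ev <- mat$n_events
  total <- sum(ev[keep])
  if (is.na(total) || total == 0) {
    return(structure(list(defined = FALSE, n_events_total = 0,
                          mean_distance_km = NA_real_, sd_distance_km = NA_real_,
                          max_distance_km = NA_real_, mean_p = NA_real_,
                          sd_p = NA_real_, mean_events = NA_real_,
                          sd_events = NA_real_, n_pairs_connected = 0L),
                     class = "event_stats"))
  }
  con <- keep & ev > 0
  pairs <- if (connected_only) con else keep
  structure(list(
    defined = TRUE,
    n_events_total = total,
    mean_distance_km = sum(D[con] * ev[con]) / total,
    sd_distance_km = sd_pop(D[con], ev[con]),
    max_distance_km = max(D[con]),
    mean_p = mean(mat$p[pairs]),
    sd_p = sd_pop(mat$p[pairs]),
    mean_events = mean(ev[pairs]),
    sd_events = sd_pop(ev[pairs]),
    n_pairs_connected = sum(con)), class = "event_stats")
}

#' @export
print.event_stats <- function(x, ...) {
  if (!x$defined) { cat("<event_stats> no events\n"); return(invisible(x)) }
  cat(sprintf(paste0("<event_stats> %d events over %d connected pairs\n",
                     "  distance %.2f +/- %.2f km (max %.2f)\n",
                     "  probability %.3f +/- %.3f; events/pair %.2f +/- %.2f\n"),
              x$n_events_total, x$n_pairs_connected,
              x$mean_distance_km, x$sd_distance_km, x$max_distance_km,
              x$mean_p, x$sd_p, x$mean_events, x$sd_events))
  invisible(x)
}

#' Release ledger for a multi-year daily-release design
#'
#' Desk arithmetic of the release scheme: one row per calendar year with
#' its day count and particle releases (`n_sites * days * per_day`), plus
#' the grand total.
#'
#' @param n_sites Number of source sites.
#' @param years Integer vector of calendar years.
#' @param particles_per_day Particles per site per day (default 1).
#' @return List with `per_year` data frame and `total`.
#' @export
#' @examples
#' release_ledger(183, 2008:2017)$total
release_ledger <- function(n_sites, years, particles_per_day = 1L) {
  days <- vapply(years, function(y)
    as.integer(as.Date(sprintf("%d-12-31", y)) -
               as.Date(sprintf("%d-01-01", y))) + 1L, integer(1))
  per_year <- data.frame(year = years, days = days,
                         released = n_sites * days * particles_per_day)
  list(per_year = per_year, total = sum(per_year$released))
}

#' Write a connectivity matrix as long-format CSV
#'
#' Columns `source_id`, `sink_id`, `n_events`, `n_released`, `probability`.
#' @param mat A `connectivity_matrix`.
#' @param path File path.
#' @param square Write the square probability matrix instead.
#' @export
write_connectivity_csv <- function(mat, path, square = FALSE) {
  if (square) {
    m <- as.data.frame(mat$p)
    names(m) <- mat$site_id
    utils::write.csv(cbind(site_id = mat$site_id, m), path, row.names = FALSE)
  } else {
    n <- length(mat$site_id)
    df <- data.frame(source_id = rep(mat$site_id, times = n),
                     sink_id = rep(mat$site_id, each = n),
                     n_events = as.vector(mat$n_events),
                     n_released = rep(mat$n_released, times = n),
                     probability = as.vector(mat$p))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  df <- utils::read.csv(path)
  ids <- sort(unique(df$source_id))
  n <- length(ids)
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  ev <- matrix(0L, n, n, dimnames = list(ids, ids))
  i <- match(df$source_id, ids); j <- match(df$sink_id, ids)
  p[cbind(i, j)] <- df$probability
  ev[cbind(i, j)] <- df$n_events
  rel <- df$n_released[match(ids, df$source_id)]
  connectivity_matrix(p = p, n_released = rel, n_events = ev, site_id = ids)
}
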