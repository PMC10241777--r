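#' Map genotyped populations to their nearest simulation sites
#'
#' @param sites A `site_set`.
#' @param pops Data frame with columns `pop`, `lon`, `lat`.
#' @param max_km Maximum tolerated population-to-site distance (km).
#' @return Data frame `pop`, `site_id`, `distance_km`.
#' @export
site_to_population_map <- function(sites, pops, max_km = 50) {
  stopifnot(all(c("pop", "lon", "lat") %in% names(pops)))
  D <- cross_dist_km(pops$lon, pops$lat, sites$lon, sites$lat)
  nearest <- max.col(-D, ties.method = "first")
  dist <- D[cbind(seq_len(nrow(pops)), nearest)]
  far <- dist > max_km
  if (any(far))
    stop_spec("site_to_population_map: population(s) farther than ", max_km,
              " km from any site: ", paste(pops$pop[far], collapse = ", "))
  data.frame(pop = pops$pop, site_id = sites$site_id[nearest],
             distance_km = dist)
}

#' Symmetrise a directional stepping-stone matrix
#'
#' Stepping-stone connectivity is directional while genetic differentiation
#' is not; the comparison uses the element-wise `max` (default) or `mean`
#' of the two directions.
#'
#' @param ss A `stepping_stone` object or square numeric matrix.
#' @param mode `"max"` or `"mean"`.
#' @return Symmetric numeric matrix.
#' @export
symmetrize_connectivity <- function(ss, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  m <- if (inherits(ss, "stepping_stone")) ss$ss else as.matrix(ss)
  if (mode == "max") pmax(m, t(m)) else (m + t(m)) / 2
}

#' Mantel permutation test between two distance-like matrices
#'
#' Pearson correlation over the (optionally masked) upper-triangle entries,
#' with significance from simultaneous row/column permutation of `B`:
#' `p = (1 + #{|r*| >= |r|}) / (1 + n_perm)` (two-sided; one-sided
#' alternatives available).
#'
#' @param A,B Square symmetric matrices of equal dimension (>= 4 rows
#'   after masking).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed recorded in the result.
#' @param mask Optional logical matrix; only pairs with `mask = TRUE` enter
#'   the correlation (e.g. reachable pairs).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `mantel_test` list: `r`, `p`, `n_perm`, `n_pairs_used`,
#'   `alternative`, `seed`, `undefined` (`TRUE` when a matrix has zero
#'   variance over the used pairs).
#' @export
mantel <- function(A, B, n_perm = 9999, seed = NULL, mask = NULL,
                   alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (!all(dim(A) == c(n, n)) || !all(dim(B) == c(n, n)))
    stop_spec("mantel: matrices must be square and of equal dimension")
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  mask <- mask & t(mask)
  ut <- upper.tri(A) & mask
  used_rows <- unique(c(row(A)[ut], col(A)[ut]))
  if (length(used_rows) < 4)
    stop_spec("mantel: need >= 4 populations after masking")
  iu <- row(A)[ut]; ju <- col(A)[ut]
  x <- A[ut]; y <- B[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          n_pairs_used = sum(ut), alternative = alternative,
                          seed = seed, undefined = TRUE),
                     class = "mantel_test"))
  }
  r_obs <- stats::cor(x, y)
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    perm_fun <- function() rng$sample_int(n, n)
  } else perm_fun <- function() sample.int(n, n)
  # Precompute x moments; per permutation only y changes. Masked pairs of B
  # can resurface under permutation as NA: those pairs drop out of that
  # permutation's correlation (complete-pair Mantel).
  xc <- x - mean(x)
  sxx <- sqrt(sum(xc^2))
  b_has_na <- anyNA(B[upper.tri(B)])
  r_perm <- vapply(seq_len(n_perm), function(k) {
    pr <- perm_fun()
    yp <- B[cbind(pr[iu], pr[ju])]
    if (b_has_na) {
      ok <- !is.na(yp)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(yp[ok]) == 0)
        return(0)
      return(stats::cor(x[ok], yp[ok]))
    }
    yc <- yp - mean(yp)
    s <- sqrt(sum(yc^2))
    if (s == 0) return(0)
    sum(xc * yc) / (sxx * s)
  }, numeric(1))
  p <- switch(alternative,
              two.sided = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm),
              greater = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
              less = (1 + sum(r_perm <= r_obs)) / (1 + n_perm))
  structure(list(r = r_obs, p = p, n_perm = n_perm, n_pairs_used = sum(ut),
                 alternative = alternative, seed = seed, undefined = FALSE),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  if (x$undefined) { cat("<mantel_test> undefined (zero variance)\n"); return(invisible(x)) }
  cat(sprintf("<mantel_test> r = %.4f, p = %.4g (%s, %d permutations, %d pairs)\n",
              x$r, x$p, x$alternative, x$n_perm, x$n_pairs_used))
  invisible(x)
}

#' Compare genetic differentiation with modelled connectivity
#'
#' The package's operationalisation of the genetics-versus-currents
#' comparison: Mantel correlation between linearised FST
#' (`theta / (1 - theta)`) and `-log` symmetrised stepping-stone
#' probability over the populations' matched sites. Pairs with zero
#' symmetrised connectivity (unreachable in both directions) are excluded
#' via the mask and reported as a count rather than imputed.
#'
#' @param fst An `fst_matrix` over populations.
#' @param ss A `stepping_stone` object over sites.
#' @param pop_sites Data frame `pop`, `site_id` (e.g. from
#'   [site_to_population_map()]); row order defines the population order.
#' @param mode Symmetrisation mode, see [symmetrize_connectivity()].
#' @param n_perm,seed Passed to [mantel()].
#' @return A `concordance_report` list: `mantel` (the test), `r`, `p`,
#'   `n_pairs_used`, `n_pairs_unreachable`, `settings`.
#' @export
compare_genetics_currents <- function(fst, ss, pop_sites, mode = "max",
                                      n_perm = 9999, seed = NULL) {
  stopifnot(inherits(fst, "fst_matrix"), inherits(ss, "stepping_stone"))
  idx <- match(pop_sites$site_id, ss$site_id)
  if (anyNA(idx)) stop_spec("compare_genetics_currents: unknown site id")
  pidx <- match(pop_sites$pop, fst$pop)
  if (anyNA(pidx)) stop_spec("compare_genetics_currents: unknown population")
  sym <- symmetrize_connectivity(ss, mode)[idx, idx, drop = FALSE]
  gen <- linearize_fst(fst)[pidx, pidx, drop = FALSE]
  mask <- sym > 0
  n_unreach <- sum(!mask[upper.tri(mask)])
  ocean <- -log(sym)
  ocean[!mask] <- NA
  mt <- mantel(gen, ocean, n_perm = n_perm, seed = seed, mask = mask)
  structure(list(mantel = mt, r = mt$r, p = mt$p,
                 n_pairs_used = mt$n_pairs_used,
                 n_pairs_unreachable = n_unreach,
                 settings = list(mode = mode, n_perm = n_perm, seed = seed,
                                 genetic = "theta/(1-theta)",
                                 oceanographic = "-log symmetrised stepping-stone")),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> Mantel r = %.4f, p = %.4g; %d pairs used, %d unreachable pair(s) excluded\n",
              x$r, x$p, x$n_pairs_used, x$n_pairs_unreachable))
  invisible(x)
}

#' Write a concordance report as JSON
#' @param report A `concordance_report`.
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(r = report$r, p = report$p, n_pairs_used = report$n_pairs_used,
         n_pairs_unreachable = report$n_pairs_unreachable,
         settings = report$settings),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
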