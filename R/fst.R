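#' Weir-Cockerham variance components and multilocus theta
#'
#' The 1984 variance-components estimator of FST for diploid data. Per
#' locus and allele, with `r` populations, `n_i` individuals scored in
#' population i, allele frequency `p_i` and heterozygote frequency `h_i`
#' (individuals carrying exactly one copy of the allele):
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals). The multilocus estimate is
#' `theta = sum(a) / sum(a + b + c)` over all loci and alleles. Negative
#' estimates are reported as computed, never truncated.
#'
#' @param g_table A `genotype_table` (conventionally genet level) with at
#'   least two populations.
#' @param pops Optional subset of population labels.
#' @return A `wc_fst` list: `theta` (multilocus), `per_locus` data frame
#'   (`locus`, `a`, `b`, `c`, `theta`), `undefined` flag (`TRUE` when no
#'   locus is polymorphic).
#' @export
wc_fst <- function(g_table, pops = NULL) {
  stopifnot(inherits(g_table, "genotype_table"))
  if (is.null(pops)) pops <- unique(g_table$pop)
  if (length(pops) < 2) stop_spec("wc_fst: need >= 2 populations")
  rows_by_pop <- lapply(pops, function(p) which(g_table$pop == p))

  per_locus <- do.call(rbind, lapply(seq_along(g_table$loci), function(l) {
    n_i <- numeric(0); p_mat <- NULL; h_mat <- NULL
    alleles <- sort(unique(c(g_table$a1[unlist(rows_by_pop), l],
                             g_table$a2[unlist(rows_by_pop), l])))
    alleles <- alleles[alleles != 0]
    if (length(alleles) < 2)
      return(data.frame(locus = g_table$loci[l], a = 0, b = 0, c = 0,
                        theta = NA_real_))
    stats_i <- lapply(rows_by_pop, function(rows) {
      a1 <- g_table$a1[rows, l]; a2 <- g_table$a2[rows, l]
      scored <- a1 != 0
      a1 <- a1[scored]; a2 <- a2[scored]
      n <- length(a1)
      p <- vapply(alleles, function(al) sum(a1 == al) + sum(a2 == al),
                  numeric(1)) / max(1, 2 * n)
      h <- vapply(alleles, function(al) sum(xor(a1 == al, a2 == al)),
                  numeric(1)) / max(1, n)
      list(n = n, p = p, h = h)
    })
    n_i <- vapply(stats_i, `[[`, numeric(1), "n")
    use <- n_i > 0
    if (sum(use) < 2)
      return(data.frame(locus = g_table$loci[l], a = 0, b = 0, c = 0,
                        theta = NA_real_))
    n_i <- n_i[use]
    p_mat <- do.call(cbind, lapply(stats_i[use], `[[`, "p"))  # alleles x pops
    h_mat <- do.call(cbind, lapply(stats_i[use], `[[`, "h"))
    r <- length(n_i)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    abc <- vapply(seq_along(alleles), function(k) {
      p_i <- p_mat[k, ]; h_i <- h_mat[k, ]
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      if (nbar <= 1 || nc <= 0) return(c(0, 0, 0))
      a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      c(a, b, cc)
    }, numeric(3))
    a <- sum(abc[1, ]); b <- sum(abc[2, ]); cc <- sum(abc[3, ])
    tot <- a + b + cc
    data.frame(locus = g_table$loci[l], a = a, b = b, c = cc,
               theta = if (tot != 0) a / tot else NA_real_)
  }))
  rownames(per_locus) <- NULL
  denom <- sum(per_locus$a + per_locus$b + per_locus$c)
  theta <- if (denom != 0) sum(per_locus$a) / denom else NA_real_
  structure(list(theta = theta, per_locus = per_locus,
                 undefined = denom == 0, pops = pops),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("<wc_fst> %d populations, multilocus theta = %s\n",
              length(x$pops),
              if (x$undefined) "undefined" else sprintf("%.4f", x$theta)))
  invisible(x)
}

#' Pairwise Weir-Cockerham FST matrix
#'
#' Multilocus theta for every pair of populations; symmetric with a zero
#' diagonal. Pairs where every shared locus is monomorphic are undefined
#' (`NA`, flagged).
#'
#' @param g_table A `genotype_table` at genet level.
#' @return An `fst_matrix`: `pop` (labels), `theta` (matrix), `undefined`
#'   (logical matrix).
#' @export
pairwise_fst <- function(g_table) {
  pops <- unique(g_table$pop)
  if (length(pops) < 2) stop_spec("pairwise_fst: need >= 2 populations")
  n <- length(pops)
  th <- matrix(0, n, n, dimnames = list(pops, pops))
  und <- matrix(FALSE, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    f <- wc_fst(g_table, pops = c(pops[i], pops[j]))
    th[i, j] <- th[j, i] <- f$theta
    und[i, j] <- und[j, i] <- f$undefined
  }
  structure(list(pop = pops, theta = th, undefined = und),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("<fst_matrix> %d populations\n", length(x$pop)))
  print(round(x$theta, 4))
  invisible(x)
}

#' Linearised FST for distance-matrix comparisons
#'
#' `theta / (1 - theta)`, the standard linearisation for regressions of
#' differentiation on distance or connectivity.
#'
#' @param fst An `fst_matrix` or numeric matrix of theta values.
#' @return Numeric matrix.
#' @export
linearize_fst <- function(fst) {
  th <- if (inherits(fst, "fst_matrix")) fst$theta else fst
  th / (1 - th)
}

#' Write an FST matrix as CSV
#' @param fst An `fst_matrix`.
#' @param path File path.
#' @export
write_fst_csv <- function(fst, path) {
  m <- as.data.frame(fst$theta)
  utils::write.csv(cbind(pop = fst$pop, m), path, row.names = FALSE)
  invisible(path)
}
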