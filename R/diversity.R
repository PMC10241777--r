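#' Expected allele count in a rarefied subsample (one locus)
#'
#' Hurlbert-style rarefaction: for allele counts `N_a` summing to `N` gene
#' copies, the expected number of distinct alleles in a subsample of `g`
#' copies drawn without replacement is
#' `sum_a [1 - C(N - N_a, g) / C(N, g)]`.
#'
#' @param counts Integer vector of allele counts at the locus.
#' @param g Standardised number of gene copies, `1 <= g <= sum(counts)`.
#' @return Expected allele count (exact).
#' @export
#' @examples
#' rarefy_alleles(c(A = 3, B = 1), 2)  # 1.5
rarefy_alleles <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (!is_count(g) || g > N)
    stop_spec("rarefy_alleles: need 1 <= g <= total gene copies (", N, ")")
  sum(1 - choose(N - counts, g) / choose(N, g))
}

#' Rarefied allelic richness per population
#'
#' Mean over loci of the expected allele count in a standardised subsample
#' of `g` gene copies. `g` defaults to the smallest number of copies scored
#' at any locus in any population (the largest size valid everywhere);
#' the conventional choice of twice the minimum genet sample size is
#' `g = 2 * min(N_pop)` when data are complete.
#'
#' @param g_table A `genotype_table` (genet level for standardised
#'   comparisons).
#' @param g Standardised gene-copy count; see Details for the default.
#' @return Data frame `pop`, `A_hat` (mean rarefied allele count per
#'   locus), with attribute `g`.
#' @export
allelic_richness <- function(g_table, g = NULL) {
  fr <- allele_freqs(g_table)
  copies <- vapply(fr, function(pl) vapply(pl, attr, numeric(1), "n_copies"),
                   numeric(length(g_table$loci)))
  if (is.null(g)) g <- min(copies)
  if (g > min(copies))
    stop_spec("allelic_richness: g exceeds copies scored at some locus (min ",
              min(copies), ")")
  out <- data.frame(
    pop = names(fr),
    A_hat = vapply(fr, function(pl)
      mean(vapply(pl, function(f) rarefy_alleles(attr(f, "counts"), g),
                  numeric(1))), numeric(1)))
  rownames(out) <- NULL
  structure(out, g = g)
}

#' Rarefied private allelic richness per population
#'
#' Like [allelic_richness()] but restricted, per population, to alleles
#' absent from every other population's full sample: the expected number
#' of private alleles seen in a subsample of `g` copies.
#'
#' @inheritParams allelic_richness
#' @return Data frame `pop`, `PA_hat`, with attribute `g`.
#' @export
private_allelic_richness <- function(g_table, g = NULL) {
  fr <- allele_freqs(g_table)
  pops <- names(fr)
  L <- length(g_table$loci)
  copies <- vapply(fr, function(pl) vapply(pl, attr, numeric(1), "n_copies"),
                   numeric(L))
  if (is.null(g)) g <- min(copies)
  if (g > min(copies))
    stop_spec("private_allelic_richness: g exceeds copies scored at some locus")
  pa <- vapply(pops, function(p) {
    per_locus <- vapply(seq_len(L), function(l) {
      cnt <- attr(fr[[p]][[l]], "counts")
      others <- unlist(lapply(setdiff(pops, p), function(q)
        names(attr(fr[[q]][[l]], "counts"))))
      priv <- setdiff(names(cnt), others)
      if (length(priv) == 0) return(0)
      N <- sum(cnt)
      sum(1 - choose(N - cnt[priv], g) / choose(N, g))
    }, numeric(1))
    mean(per_locus)
  }, numeric(1))
  out <- data.frame(pop = pops, PA_hat = unname(pa))
  rownames(out) <- NULL
  structure(out, g = g)
}

#' Per-population diversity statistics (HO, HE, FIS)
#'
#' Per locus: `HO` = fraction of heterozygous scored individuals; `HE` =
#' Nei's unbiased gene diversity `n/(n-1) * (1 - sum p_k^2)` with `n` the
#' gene copies scored; `FIS = 1 - HO / HE` (undefined and `NA` at
#' monomorphic loci, where `HE = 0`). Multilocus values: mean `HO`, mean
#' `HE` over loci, and `FIS = 1 - mean(HO) / mean(HE)`. The full per-locus
#' FIS distribution is retained for inspecting heterozygote excess or
#' deficit locus by locus.
#'
#' @param g_table A `genotype_table`, conventionally at genet level.
#' @return A `diversity_table`: `pops` data frame (`pop`, `n`, `HO`, `HE`,
#'   `FIS`) and `per_locus` data frame (`pop`, `locus`, `n_copies`, `HO`,
#'   `HE`, `FIS`, `monomorphic`).
#' @export
diversity <- function(g_table) {
  stopifnot(inherits(g_table, "genotype_table"))
  pops <- unique(g_table$pop)
  per_locus <- do.call(rbind, lapply(pops, function(p) {
    rows <- which(g_table$pop == p)
    do.call(rbind, lapply(seq_along(g_table$loci), function(l) {
      a1 <- g_table$a1[rows, l]; a2 <- g_table$a2[rows, l]
      scored <- a1 != 0
      n_ind <- sum(scored)
      nn <- 2 * n_ind
      if (n_ind == 0)
        return(data.frame(pop = p, locus = g_table$loci[l], n_copies = 0L,
                          HO = NA_real_, HE = NA_real_, FIS = NA_real_,
                          monomorphic = NA))
      ho <- mean(a1[scored] != a2[scored])
      pfreq <- table(c(a1[scored], a2[scored])) / nn
      he_raw <- 1 - sum(pfreq^2)
      he <- if (nn > 1) nn / (nn - 1) * he_raw else 0
      mono <- he == 0
      fis <- if (mono) NA_real_ else 1 - ho / he
      data.frame(pop = p, locus = g_table$loci[l], n_copies = nn,
                 HO = ho, HE = he, FIS = fis, monomorphic = mono)
    }))
  }))
  pops_df <- do.call(rbind, lapply(pops, function(p) {
    sub <- per_locus[per_locus$pop == p & per_locus$n_copies > 0, ]
    mho <- mean(sub$HO); mhe <- mean(sub$HE)
    data.frame(pop = p, n = sum(g_table$pop == p), HO = mho, HE = mhe,
               FIS = if (mhe > 0) 1 - mho / mhe else NA_real_)
  }))
  rownames(per_locus) <- rownames(pops_df) <- NULL
  structure(list(pops = pops_df, per_locus = per_locus),
            class = "diversity_table")
}

#' @export
print.diversity_table <- function(x, ...) {
  cat("<diversity_table>\n")
  print(x$pops, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-call population-genetic summary of a ramet-level dataset
#'
#' Runs the clonal pipeline ([assign_genets()]), collapses to genet level,
#' and assembles the per-population summary table: N, G, R, rarefied
#' allelic richness and private alleles, HO, HE and FIS.
#'
#' @param g Ramet-level `genotype_table`.
#' @param threshold Psex threshold (default 0.01).
#' @param g_copies Standardised gene copies for rarefaction; default as in
#'   [allelic_richness()].
#' @param min_genets Populations with fewer genets are flagged (not
#'   dropped); default 5.
#' @return List: `assignment`, `genets` (genotype table), `summary` (data
#'   frame `pop`, `N`, `G`, `R`, `A_hat`, `PA_hat`, `HO`, `HE`, `FIS`,
#'   `flag_small`), `diversity` (full `diversity_table`).
#' @export
popgen_summary <- function(g, threshold = 0.01, g_copies = NULL,
                           min_genets = 5L) {
  asg <- assign_genets(g, threshold = threshold)
  gl <- genet_table(g, asg)
  div <- diversity(gl)
  ar <- allelic_richness(gl, g_copies)
  pa <- private_allelic_richness(gl, attr(ar, "g"))
  s <- merge(asg$pops, merge(ar, pa, by = "pop"), by = "pop")
  s <- merge(s, div$pops[c("pop", "HO", "HE", "FIS")], by = "pop")
  s$flag_small <- s$G < min_genets
  list(assignment = asg, genets = gl, summary = s, diversity = div,
       rarefaction_g = attr(ar, "g"))
}
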