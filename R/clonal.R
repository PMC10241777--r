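#' Group ramets into multilocus genotypes (MLGs)
#'
#' Grouping is within populations. Two ramets share an MLG iff their
#' genotypes match at every locus where both are scored (missing entries
#' act as wildcards unless `match_missing = FALSE`, in which case exact
#' equality including the missingness pattern is required). Ramets with
#' more than `max_missing` of their loci missing are kept but never merged
#' (forced singletons); ramets missing all loci are excluded with a
#' warning. Matching against existing MLGs uses each MLG's first member as
#' representative and assigns to the first match, so the grouping is
#' deterministic in input order.
#'
#' @param g A `genotype_table`.
#' @param max_missing Maximum tolerated missing-locus fraction for a ramet
#'   to take part in wildcard merging (default 0.5).
#' @param match_missing Treat missing loci as wildcards (default `TRUE`).
#' @return A data frame (`id`, `pop`, `mlg`) plus attribute `mlg_table`
#'   (`mlg`, `pop`, `n`, `representative`).
#' @export
find_mlgs <- function(g, max_missing = 0.5, match_missing = TRUE) {
  stopifnot(inherits(g, "genotype_table"))
  L <- ncol(g$a1)
  n_miss <- rowSums(g$a1 == 0)
  excluded <- n_miss == L
  if (any(excluded))
    warning(sprintf("find_mlgs: excluded %d individual(s) with no scored loci",
                    sum(excluded)))
  keep <- which(!excluded)
  mlg <- rep(NA_integer_, length(g$id))
  next_id <- 0L
  reps <- list()   # per MLG: list(a1, a2, pop, high_missing)
  for (i in keep) {
    hm <- n_miss[i] / L > max_missing
    assigned <- NA_integer_
    if (!hm) {
      for (m in seq_along(reps)) {
        r <- reps[[m]]
        if (r$pop != g$pop[i] || r$high_missing) next
        if (match_missing) {
          both <- g$a1[i, ] != 0 & r$a1 != 0
          ok <- all(g$a1[i, both] == r$a1[both] & g$a2[i, both] == r$a2[both])
        } else {
          ok <- all(g$a1[i, ] == r$a1 & g$a2[i, ] == r$a2)
        }
        if (ok) { assigned <- m; break }
      }
    }
    if (is.na(assigned)) {
      next_id <- next_id + 1L
      reps[[next_id]] <- list(a1 = g$a1[i, ], a2 = g$a2[i, ],
                              pop = g$pop[i], high_missing = hm)
      assigned <- next_id
    }
    mlg[i] <- assigned
  }
  out <- data.frame(id = g$id[keep], pop = g$pop[keep], mlg = mlg[keep])
  tab <- as.data.frame(table(mlg = out$mlg), stringsAsFactors = FALSE)
  tab$mlg <- as.integer(tab$mlg)
  mlg_table <- data.frame(
    mlg = tab$mlg,
    pop = vapply(tab$mlg, function(m) reps[[m]]$pop, character(1)),
    n = as.integer(tab$Freq),
    representative = vapply(tab$mlg, function(m)
      g$id[!excluded & mlg == m][1], character(1)))
  structure(out, mlg_table = mlg_table, class = c("mlg_assignment",
                                                  "data.frame"))
}

#' Per-population allele frequencies and counts
#'
#' @param g A `genotype_table`.
#' @return Nested list `[[pop]][[locus]]`: named numeric vector of allele
#'   frequencies, with attributes `counts` (allele counts) and `n_copies`
#'   (gene copies scored).
#' @export
allele_freqs <- function(g) {
  out <- lapply(unique(g$pop), function(p) {
    rows <- g$pop == p
    lapply(seq_along(g$loci), function(l) {
      al <- c(g$a1[rows, l], g$a2[rows, l])
      al <- al[al != 0]
      cnt <- table(al)
      fr <- as.numeric(cnt) / max(1, sum(cnt))
      names(fr) <- names(cnt)
      attr(fr, "counts") <- stats::setNames(as.integer(cnt), names(cnt))
      attr(fr, "n_copies") <- sum(cnt)
      fr
    })
  })
  stats::setNames(out, unique(g$pop))
}

#' Probability of a multilocus genotype under Hardy-Weinberg (pgen)
#'
#' Product over non-missing loci of `p_a^2` for homozygotes and
#' `2 p_a p_b` for heterozygotes, with allele frequencies from the
#' population the ramet belongs to (genet-level frequencies in the
#' standard pipeline).
#'
#' @param a1,a2 Integer allele vectors (one per locus, 0 = missing).
#' @param freqs List over loci of named frequency vectors (names = allele
#'   codes), as one element of [allele_freqs()].
#' @return The genotype probability.
#' @export
pgen <- function(a1, a2, freqs) {
  stopifnot(length(a1) == length(a2), length(a1) == length(freqs))
  pr <- 1
  for (l in seq_along(a1)) {
    if (a1[l] == 0) next
    f <- freqs[[l]]
    pa <- f[as.character(a1[l])]
    pb <- f[as.character(a2[l])]
    if (is.na(pa) || is.na(pb))
      stop_spec("pgen: allele absent from frequency table at locus ", l)
    pr <- pr * if (a1[l] == a2[l]) pa * pa else 2 * pa * pb
  }
  unname(pr)
}

#' Probability of repeated sexual origin of an MLG (Psex)
#'
#' Unconditional binomial upper tail: the probability that an MLG with
#' genotype probability `pgen` is observed `n` or more times among `N`
#' sampled ramets if every ramet were an independent sexual recruit,
#' `Psex = sum_{i=n}^{N} C(N, i) pgen^i (1 - pgen)^(N - i)`. Below the
#' discrimination threshold (0.01 in the standard pipeline) the copies are
#' taken to be one clone.
#'
#' @param pgen Genotype probability in `[0, 1]`.
#' @param n Observed copies of the MLG (>= 2; Psex is undefined for
#'   singletons).
#' @param N Sample size (ramets in the population), `n <= N`.
#' @return The tail probability.
#' @export
#' @examples
#' psex(0.1, 2, 3)  # 3 * 0.01 * 0.9 + 0.001 = 0.028
psex <- function(pgen, n, N) {
  if (!is_fraction(pgen)) stop_spec("psex: pgen must lie in [0, 1]")
  if (!is_count(n) || n < 2) stop_spec("psex: n must be >= 2 (undefined for singletons)")
  if (!is_count(N) || n > N) stop_spec("psex: need 2 <= n <= N")
  stats::pbinom(n - 1, N, pgen, lower.tail = FALSE)
}

#' Clonal (genotypic) richness R
#'
#' `R = (G - 1) / (N - 1)`: 0 for a monoclonal stand (one genet), 1 when
#' every sampled ramet is a distinct genet.
#'
#' @param N Ramets sampled (>= 2 for a defined value).
#' @param G Genets found, `1 <= G <= N`.
#' @return `R`, or `NA` (with attribute `undefined = TRUE`) when `N = 1`.
#' @export
clonal_richness <- function(N, G) {
  if (!is_count(N) || !is_count(G) || G > N || G < 1)
    stop_spec("clonal_richness: need 1 <= G <= N")
  if (N == 1) return(structure(NA_real_, undefined = TRUE))
  (G - 1) / (N - 1)
}

#' Full clonal discrimination pipeline
#'
#' Groups ramets into MLGs, computes genet-level allele frequencies (one
#' representative ramet per MLG), evaluates pgen and Psex for every
#' repeated MLG, and merges copies into a single genet where
#' `Psex < threshold` (otherwise the copies count as distinct genets that
#' happen to share a genotype). Frequencies can instead be taken from the
#' ramet level via `freq_level = "ramet"`.
#'
#' @param g A `genotype_table` (ramet level).
#' @param threshold Psex discrimination threshold (default 0.01).
#' @param freq_level `"genet"` (default) or `"ramet"`: data level for the
#'   allele frequencies entering pgen.
#' @param max_missing,match_missing Passed to [find_mlgs()].
#' @return A `clonal_assignment`: `ramets` (`id`, `pop`, `mlg`, `genet`),
#'   `mlgs` (`mlg`, `pop`, `n`, `pgen`, `psex`, `merged`), `pops` (`pop`,
#'   `N`, `G`, `R`).
#' @export
assign_genets <- function(g, threshold = 0.01,
                          freq_level = c("genet", "ramet"),
                          max_missing = 0.5, match_missing = TRUE) {
  freq_level <- match.arg(freq_level)
  ml <- find_mlgs(g, max_missing = max_missing, match_missing = match_missing)
  tab <- attr(ml, "mlg_table")
  freq_g <- if (freq_level == "genet")
    allele_freqs(subset_genotypes(g, match(tab$representative, g$id)))
  else allele_freqs(g)

  pop_N <- table(ml$pop)
  tab$pgen <- NA_real_; tab$psex <- NA_real_; tab$merged <- FALSE
  for (k in seq_len(nrow(tab))) {
    i <- match(tab$representative[k], g$id)
    tab$pgen[k] <- pgen(g$a1[i, ], g$a2[i, ], freq_g[[tab$pop[k]]])
    if (tab$n[k] >= 2) {
      tab$psex[k] <- psex(tab$pgen[k], tab$n[k], as.integer(pop_N[tab$pop[k]]))
      tab$merged[k] <- tab$psex[k] < threshold
    }
  }

  # genet labels: merged MLG -> one genet; otherwise one genet per ramet
  genet <- character(nrow(ml))
  for (k in seq_len(nrow(tab))) {
    rows <- which(ml$mlg == tab$mlg[k])
    if (tab$n[k] >= 2 && tab$merged[k]) {
      genet[rows] <- sprintf("%s_g%d", tab$pop[k], tab$mlg[k])
    } else {
      genet[rows] <- sprintf("%s_g%d_%s", tab$pop[k], tab$mlg[k], ml$id[rows])
    }
  }
  ramets <- data.frame(id = ml$id, pop = ml$pop, mlg = ml$mlg, genet = genet)
  pops <- do.call(rbind, lapply(sort(unique(ml$pop)), function(p) {
    N <- sum(ml$pop == p)
    G <- length(unique(genet[ml$pop == p]))
    data.frame(pop = p, N = N, G = G,
               R = as.numeric(clonal_richness(N, G)))
  }))
  structure(list(ramets = ramets, mlgs = tab, pops = pops,
                 threshold = threshold, freq_level = freq_level),
            class = "clonal_assignment")
}

#' @export
print.clonal_assignment <- function(x, ...) {
  cat(sprintf("<clonal_assignment> %d ramets -> %d genets in %d population(s); Psex < %.3g merges %d MLG(s)\n",
              nrow(x$ramets), length(unique(x$ramets$genet)),
              nrow(x$pops), x$threshold, sum(x$mlgs$merged)))
  print(x$pops, row.names = FALSE)
  invisible(x)
}

#' Collapse a genotype table to genet level
#'
#' Keeps the first-sampled ramet of every genet, the dataset on which
#' diversity and differentiation statistics are computed.
#'
#' @param g The ramet-level `genotype_table`.
#' @param assignment A `clonal_assignment` from [assign_genets()].
#' @return A `genotype_table` with one row per genet.
#' @export
genet_table <- function(g, assignment) {
  first <- !duplicated(assignment$ramets$genet)
  subset_genotypes(g, match(assignment$ramets$id[first], g$id))
}
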