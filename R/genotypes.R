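#' Construct a multilocus genotype table
#'
#' Ramet-by-locus diploid genotypes with integer allele codes, 0 = missing.
#' Allele pairs are unordered and stored normalised (`a1 <= a2`); an entry
#' is either fully scored or fully missing at a locus.
#'
#' @param a1,a2 Integer matrices (individuals x loci) of allele codes.
#' @param pop Population label per individual (character or factor).
#' @param id Individual (ramet) identifiers; default `ind_1 ...`.
#' @param loci Locus names; default `loc_1 ...`.
#' @return A `genotype_table`: list with `a1`, `a2`, `pop`, `id`, `loci`.
#' @export
genotype_table <- function(a1, a2, pop, id = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(all(dim(a1) == dim(a2)), nrow(a1) == length(pop))
  if ((nrow(a1) > 0) && (any(a1 < 0) || any(a2 < 0)))
    stop_spec("genotype_table: allele codes must be non-negative")
  if (any(xor(a1 == 0, a2 == 0)))
    stop_spec("genotype_table: half-missing entries (one allele 0) not allowed")
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  if (is.null(id)) id <- sprintf("ind_%d", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- sprintf("loc_%d", seq_len(ncol(a1)))
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  structure(list(a1 = a1, a2 = a2, pop = as.character(pop), id = id,
                 loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals, %d loci, %d population(s), %.1f%% missing\n",
              nrow(x$a1), ncol(x$a1), length(unique(x$pop)),
              100 * mean(x$a1 == 0)))
  invisible(x)
}

#' Subset a genotype table by individuals
#' @param g A `genotype_table`.
#' @param keep Logical or integer index over individuals.
#' @export
subset_genotypes <- function(g, keep) {
  genotype_table(g$a1[keep, , drop = FALSE], g$a2[keep, , drop = FALSE],
                 g$pop[keep], g$id[keep], g$loci)
}

#' Simulation design for clonal multilocus genotype data
#'
#' Island-model design with a clonality knob. Each population's allele
#' frequencies are drawn from a Dirichlet centred on a global frequency
#' vector with concentration `(1 - d) / d` (`d` = `differentiation`), so
#' the expected FST is approximately `d`. Each population hosts
#' `genets_per_pop` resident founder genets; each ramet is, with
#' probability `clonality`, a copy of a uniformly chosen founder and
#' otherwise a fresh Hardy-Weinberg draw. With a single founder
#' (`genets_per_pop = 1`, the default) `clonality = 1` collapses every
#' population to one genet and `clonality = 0` makes every ramet a
#' distinct genet (up to vanishing genotype-collision probability).
#'
#' @param n_pops Number of populations.
#' @param genets_per_pop Resident founder genets per population (>= 1).
#' @param ramets_per_pop Sampled ramets per population
#'   (>= `genets_per_pop`).
#' @param n_loci Number of microsatellite loci.
#' @param alleles_per_locus Alleles segregating per locus.
#' @param differentiation Island-model differentiation `d` in `[0, 1]`.
#' @param clonality Fraction of ramets that are clonal copies, in `[0, 1]`.
#' @param missing_rate Per-entry missing-data probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `geno_sim_spec`.
#' @export
geno_sim_spec <- function(n_pops = 19L, genets_per_pop = 1L,
                          ramets_per_pop = 25L, n_loci = 8L,
                          alleles_per_locus = 6L, differentiation = 0.25,
                          clonality = 0.6, missing_rate = 0.02, seed = 1L) {
  if (!is_count(n_pops) || !is_count(genets_per_pop) ||
      !is_count(ramets_per_pop) || !is_count(n_loci) ||
      !is_count(alleles_per_locus))
    stop_spec("geno_sim_spec: counts must be positive integers")
  if (ramets_per_pop < genets_per_pop)
    stop_spec("geno_sim_spec: ramets_per_pop must be >= genets_per_pop")
  if (!is_fraction(differentiation) || !is_fraction(clonality) ||
      !is_fraction(missing_rate))
    stop_spec("geno_sim_spec: differentiation, clonality, missing_rate must lie in [0, 1]")
  structure(list(n_pops = as.integer(n_pops),
                 genets_per_pop = as.integer(genets_per_pop),
                 ramets_per_pop = as.integer(ramets_per_pop),
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 differentiation = differentiation, clonality = clonality,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "geno_sim_spec")
}

# Dirichlet draw via normalised gammas; guards the degenerate all-zero case.
rdirichlet1 <- function(alpha, rng) {
  x <- rng$rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a clonal multilocus genotype sample with known ground truth
#'
#' @param spec A [geno_sim_spec()].
#' @return List with `genotypes` (a `genotype_table`), `truth` (data frame
#'   `id`, `pop`, `genet`: the ground-truth genet label per ramet, by draw
#'   event), `freq_global` and `freq_pop` (allele-frequency parameters,
#'   lists over loci).
#' @export
make_genotypes <- function(spec) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  rng <- local_rng(spec$seed)
  L <- spec$n_loci; A <- spec$alleles_per_locus
  d <- spec$differentiation

  freq_global <- lapply(seq_len(L), function(l) rdirichlet1(rep(1, A), rng))
  freq_pop <- lapply(seq_len(spec$n_pops), function(p) {
    lapply(seq_len(L), function(l) {
      if (d == 0) freq_global[[l]]
      else if (d == 1) rdirichlet1(freq_global[[l]] * 1e-6, rng)
      else rdirichlet1(freq_global[[l]] * (1 - d) / d, rng)
    })
  })

  draw_genets <- function(p, m) {
    # draw m independent Hardy-Weinberg genotypes (rows) for population p
    g1 <- matrix(0L, m, L); g2 <- matrix(0L, m, L)
    if (m > 0) for (l in seq_len(L)) {
      g1[, l] <- rng$sample_int(A, m, replace = TRUE, prob = freq_pop[[p]][[l]])
      g2[, l] <- rng$sample_int(A, m, replace = TRUE, prob = freq_pop[[p]][[l]])
    }
    list(g1 = g1, g2 = g2)
  }

  n <- spec$n_pops * spec$ramets_per_pop
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  pop <- character(n); genet <- character(n)
  for (p in seq_len(spec$n_pops)) {
    pname <- sprintf("pop_%02d", p)
    founders <- draw_genets(p, spec$genets_per_pop)
    clonal <- rng$runif(spec$ramets_per_pop) < spec$clonality
    pick <- rng$sample_int(spec$genets_per_pop, spec$ramets_per_pop,
                           replace = TRUE)
    fresh <- draw_genets(p, sum(!clonal))
    rows <- (p - 1L) * spec$ramets_per_pop + seq_len(spec$ramets_per_pop)
    fi <- 0L
    for (r in seq_len(spec$ramets_per_pop)) {
      row <- rows[r]
      if (clonal[r]) {
        a1[row, ] <- founders$g1[pick[r], ]; a2[row, ] <- founders$g2[pick[r], ]
        genet[row] <- sprintf("%s_founder_%d", pname, pick[r])
      } else {
        fi <- fi + 1L
        a1[row, ] <- fresh$g1[fi, ]; a2[row, ] <- fresh$g2[fi, ]
        genet[row] <- sprintf("%s_ramet_%d", pname, r)
      }
      pop[row] <- pname
    }
  }

  if (spec$missing_rate > 0) {
    miss <- matrix(rng$runif(n * L) < spec$missing_rate, n, L)
    a1[miss] <- 0L; a2[miss] <- 0L
  }

  gt <- genotype_table(a1, a2, pop)
  list(genotypes = gt,
       truth = data.frame(id = gt$id, pop = pop, genet = genet),
       freq_global = freq_global, freq_pop = freq_pop)
}

#' Write a genotype table in GENEPOP format
#'
#' Alleles coded with `digits` digits (3 by default, `000` = missing),
#' diploid entries concatenated, one `pop` block per population.
#'
#' @param g A `genotype_table`.
#' @param path File path.
#' @param digits Allele code width, 2 or 3.
#' @param title Header line.
#' @export
write_genepop <- function(g, path, digits = 3, title = "driftline genotypes") {
  stopifnot(inherits(g, "genotype_table"), digits %in% c(2, 3))
  if (max(g$a1, g$a2) >= 10^digits)
    stop_spec("write_genepop: allele code too wide for ", digits, " digits")
  fmt <- sprintf("%%0%dd%%0%dd", digits, digits)
  lines <- c(title, g$loci)
  for (p in unique(g$pop)) {
    lines <- c(lines, "pop")
    for (i in which(g$pop == p)) {
      codes <- sprintf(fmt, g$a1[i, ], g$a2[i, ])
      lines <- c(lines, paste0(g$id[i], " ,  ", paste(codes, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GENEPOP file into a genotype table
#'
#' Accepts 2- or 3-digit allele codes (detected from token width), comma
#' after the individual name, `pop`/`POP` block separators, and locus names
#' given one per line or comma-separated on one line.
#'
#' @param path File path.
#' @return A `genotype_table`; populations are labelled `pop_1 ...` in file
#'   order.
#' @export
read_genepop <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  is_pop <- toupper(lines) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop_spec("read_genepop: no pop block found")
  loci <- lines[2:(first_pop - 1)]
  if (length(loci) == 1 && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  body <- lines[first_pop:length(lines)]
  pop_idx <- cumsum(toupper(body) == "POP")
  ind <- body[toupper(body) != "POP"]
  ind_pop <- pop_idx[toupper(body) != "POP"]
  n <- length(ind); L <- length(loci)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  id <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(ind[i], ",")[[1]]
    if (length(parts) < 2) stop_spec("read_genepop: malformed line: ", ind[i])
    id[i] <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(toks) != L)
      stop_spec("read_genepop: expected ", L, " loci, got ", length(toks),
                " for ", id[i])
    w <- nchar(toks[1]) / 2
    if (!w %in% c(2, 3)) stop_spec("read_genepop: unsupported allele width")
    a1[i, ] <- as.integer(substr(toks, 1, w))
    a2[i, ] <- as.integer(substr(toks, w + 1, 2 * w))
  }
  genotype_table(a1, a2, sprintf("pop_%d", ind_pop), id = id, loci = loci)
}
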