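# Shared fixtures and independent oracles. Oracles here deliberately use a
# different computational route than the package (enumeration, sums of
# squares, recursion) so agreement is evidence, not tautology.

# --- site fixtures -----------------------------------------------------------

# Hand-built site set: n sites in a zonal line at `lat`, `spacing_km` apart.
line_sites <- function(n, spacing_km, lat = 0, lon0 = 1, resolution_km = 1) {
  km_per_deg <- 6371 * pi / 180
  lon <- lon0 + (seq_len(n) - 1) * spacing_km / (km_per_deg * cos(lat * pi / 180))
  structure(data.frame(site_id = seq_len(n) - 1L, lon = lon, lat = lat,
                       cell_i = seq_len(n), cell_j = 1L, n_occ = 1L),
            resolution_km = resolution_km,
            class = c("site_set", "data.frame"))
}

# Minimal trajectory_set builder for connectivity tests.
traj_df <- function(site_id, fate, event_site = NA_integer_) {
  structure(data.frame(particle_id = seq_along(site_id) - 1L,
                       site_id = site_id,
                       release_date = as.Date("2008-01-01"),
                       fate = fate, event_site = event_site,
                       arrival_step = ifelse(fate == "event", 1L, NA_integer_)),
            class = c("trajectory_set", "data.frame"))
}

# A still-water field big enough for multi-day runs.
zero_field <- function(n_days = 70, lon = c(0, 20), lat = c(-5, 5), step = 1) {
  make_velocity_field(field_spec("zero", lon = lon, lat = lat, step = step,
                                 n_days = n_days,
                                 start_date = as.Date("2008-01-01")))
}

# --- stepping-stone oracle ---------------------------------------------------

# Exhaustive simple-path enumeration: best (max product) path probability
# between every ordered pair, accumulated as a sum of logs. Exponential-time
# recursion, valid for small n only.
oracle_ss_log <- function(p) {
  n <- nrow(p)
  best <- matrix(-Inf, n, n)
  diag(best) <- 0
  lp <- suppressWarnings(log(p))
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    rec <- function(v, acc) {
      for (w in seq_len(n)) {
        if (visited[w] || p[v, w] <= 0) next
        nacc <- acc + lp[v, w]
        if (nacc > best[s, w]) best[s, w] <<- nacc
        visited[w] <<- TRUE
        rec(w, nacc)
        visited[w] <<- FALSE
      }
    }
    rec(s, 0)
  }
  best
}

# Random sparse digraph probabilities in (0, 1).
random_p_matrix <- function(n, density = 0.35) {
  p <- matrix(0, n, n)
  edges <- matrix(stats::runif(n * n) < density, n, n)
  diag(edges) <- FALSE
  p[edges] <- stats::runif(sum(edges), 0.01, 0.99)
  p
}

# --- popgen oracles ----------------------------------------------------------

# Expected distinct alleles in a g-subsample by exhaustive enumeration of
# all C(N, g) subsets of the individual gene copies.
oracle_rarefaction <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# Binomial upper tail by explicit term-by-term summation.
oracle_psex <- function(pg, n, N) {
  i <- n:N
  sum(choose(N, i) * pg^i * (1 - pg)^(N - i))
}

# Weir-Cockerham theta via nested sums of squares (ANOVA route):
# per locus and allele, mean squares among populations / among individuals /
# within individuals, converted to variance components.
oracle_wc_theta <- function(gt, pops = unique(gt$pop)) {
  num <- 0; den <- 0
  for (l in seq_along(gt$loci)) {
    alleles <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    alleles <- setdiff(alleles, 0)
    if (length(alleles) < 2) next
    rows_by_pop <- lapply(pops, function(p)
      which(gt$pop == p & gt$a1[, l] != 0))
    n_i <- lengths(rows_by_pop)
    keep <- n_i > 0
    rows_by_pop <- rows_by_pop[keep]; n_i <- n_i[keep]
    r <- length(n_i)
    if (r < 2) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      # y: 2 gene-copy indicators per individual
      y_by_pop <- lapply(rows_by_pop, function(rows)
        cbind(gt$a1[rows, l] == al, gt$a2[rows, l] == al) * 1)
      ybar_i <- vapply(y_by_pop, mean, numeric(1))
      ybar <- sum(n_i * ybar_i) / sum(n_i)
      ssg <- sum(vapply(y_by_pop, function(y)
        sum((y - rowMeans(y))^2), numeric(1)))
      ssi <- 2 * sum(vapply(seq_len(r), function(i)
        sum((rowMeans(y_by_pop[[i]]) - ybar_i[i])^2), numeric(1)))
      ssp <- 2 * sum(n_i * (ybar_i - ybar)^2)
      msg <- ssg / sum(n_i)
      msi <- if (sum(n_i - 1) > 0) ssi / sum(n_i - 1) else 0
      msp <- ssp / (r - 1)
      sig_g <- msg
      sig_i <- (msi - msg) / 2
      sig_p <- (msp - msi) / (2 * nc)
      num <- num + sig_p
      den <- den + sig_p + sig_i + sig_g
    }
  }
  num / den
}

# Two populations fixed for alternative alleles at every locus.
fixed_diff_table <- function(n_per_pop = 10, n_loci = 3) {
  a <- matrix(1L, 2 * n_per_pop, n_loci)
  a[(n_per_pop + 1):(2 * n_per_pop), ] <- 2L
  genotype_table(a, a, rep(c("A", "B"), each = n_per_pop))
}
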