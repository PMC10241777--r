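test_that("zero and uniform fields take their closed-form values everywhere", {
  fz <- make_velocity_field(field_spec("zero", lon = c(0, 4), lat = c(0, 4),
                                       step = 1, n_days = 2))
  expect_true(all(fz$u == 0) && all(fz$v == 0))
  fu <- make_velocity_field(field_spec("uniform", lon = c(0, 4), lat = c(0, 4),
                                       step = 1, n_days = 2, amplitude = 0.3))
  expect_true(all(fu$u == 0.3) && all(fu$v == 0))
})

test_that("solid rotation has speed omega * r at every node", {
  omega <- 1e-5
  fs <- field_spec("solid_rotation", lon = c(-2, 2), lat = c(-2, 2),
                   step = 0.5, center = c(0, 0), omega = omega)
  f <- make_velocity_field(fs)
  r_m <- 6371e3
  for (i in seq_along(f$lon)) for (j in seq_along(f$lat)) {
    x <- r_m * cos(0) * f$lon[i] * pi / 180
    y <- r_m * f$lat[j] * pi / 180
    expect_equal(sqrt(f$u[i, j, 1]^2 + f$v[i, j, 1]^2),
                 omega * sqrt(x^2 + y^2), tolerance = 1e-10)
  }
})

test_that("double gyre has vanishing discrete divergence at interior nodes", {
  # 2:1 domain with equal steps: the central-difference phase factors match
  f <- make_velocity_field(field_spec("double_gyre", lon = c(0, 20),
                                      lat = c(0, 10), step = 0.5,
                                      amplitude = 0.5))
  u <- f$u[, , 1]; v <- f$v[, , 1]
  nx <- length(f$lon); ny <- length(f$lat)
  h <- 0.5
  div <- (u[3:nx, 2:(ny - 1)] - u[1:(nx - 2), 2:(ny - 1)]) / (2 * h) +
    (v[2:(nx - 1), 3:ny] - v[2:(nx - 1), 1:(ny - 2)]) / (2 * h)
  expect_lt(max(abs(div)), 1e-6 * 0.5 / h)
  expect_equal(max(abs(c(u, v))), 0.5, tolerance = 1e-12)
})

test_that("field specification errors are caught", {
  expect_error(field_spec("zero", lon = c(5, 5)), "rectangle")
  expect_error(field_spec("zero", step = -1), "step")
  expect_error(field_spec("zero", n_days = 0), "n_days")
})

test_that("velocity field round-trips through CSV", {
  f <- make_velocity_field(field_spec("double_gyre", lon = c(0, 4),
                                      lat = c(0, 2), step = 1, n_days = 3),
                           land = function(lon, lat) lon == 0 & lat == 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, path)
  f2 <- read_field_csv(path)
  expect_equal(f2$lon, f$lon)
  expect_equal(f2$days, f$days)
  expect_equal(f2$u, f$u, ignore_attr = TRUE)
  expect_equal(f2$land, f$land, ignore_attr = TRUE)
})

test_that("occurrence generator is deterministic, jitter-bounded, and rejects land centres", {
  centers <- data.frame(lon = c(1, 2), lat = c(0.5, -0.5))
  o1 <- make_occurrences(centers, 50, jitter_km = 0.2, seed = 11)
  o2 <- make_occurrences(centers, 50, jitter_km = 0.2, seed = 11)
  expect_identical(o1, o2)
  o3 <- make_occurrences(centers, 50, jitter_km = 0.2, seed = 12)
  expect_false(identical(o1, o3))
  expect_equal(nrow(o1), 100)
  d <- haversine_km(o1$lon, o1$lat,
                    rep(centers$lon, each = 50), rep(centers$lat, each = 50))
  expect_lt(max(d), 3 * 0.2 * sqrt(2) + 1e-9)

  o0 <- make_occurrences(centers[1, ], 5, jitter_km = 0, seed = 1)
  expect_equal(unique(o0$lon), centers$lon[1])
  expect_equal(nrow(unique(o0[c("lon", "lat")])), 1)

  f <- make_velocity_field(field_spec("zero", lon = c(0, 4), lat = c(-2, 2),
                                      step = 1),
                           land = function(lon, lat) lon >= 2)
  expect_error(make_occurrences(centers, 5, seed = 1, landmask = f), "2")
})

test_that("genotype simulator hits its frequency targets and clonality endpoints", {
  # law of large numbers: sample allele frequencies near the Dirichlet draw
  spec <- geno_sim_spec(n_pops = 2, ramets_per_pop = 400, clonality = 0,
                        missing_rate = 0, differentiation = 0.2,
                        alleles_per_locus = 4, n_loci = 3, seed = 42)
  sim <- make_genotypes(spec)
  fr <- allele_freqs(sim$genotypes)
  for (p in 1:2) for (l in 1:3) {
    target <- sim$freq_pop[[p]][[l]]
    obs <- rep(0, 4)
    got <- fr[[sprintf("pop_%02d", p)]][[l]]
    obs[as.integer(names(got))] <- as.numeric(got)
    se <- sqrt(target * (1 - target) / (2 * 400))
    expect_true(all(abs(obs - target) <= 3 * se + 1e-12))
  }

  # clonality endpoints under the single-resident model
  s1 <- make_genotypes(geno_sim_spec(n_pops = 3, ramets_per_pop = 20,
                                     clonality = 1, missing_rate = 0, seed = 7))
  expect_equal(unname(tapply(s1$truth$genet, s1$truth$pop,
                             function(x) length(unique(x)))),
               c(1L, 1L, 1L), ignore_attr = TRUE)
  s0 <- make_genotypes(geno_sim_spec(n_pops = 3, ramets_per_pop = 20,
                                     clonality = 0, missing_rate = 0, seed = 7))
  expect_equal(length(unique(s0$truth$genet)), 60)
})

test_that("fresh-draw genotype collisions match the enumeration probability", {
  # 1 locus, 2 alleles: P(two independent HW draws give the same genotype)
  # = sum over unordered genotypes of P(genotype)^2
  reps <- 400
  hits <- 0
  probs <- numeric(reps)
  for (k in seq_len(reps)) {
    sim <- make_genotypes(geno_sim_spec(n_pops = 1, ramets_per_pop = 2,
                                        n_loci = 1, alleles_per_locus = 2,
                                        clonality = 0, missing_rate = 0,
                                        differentiation = 0, seed = 1000 + k))
    g <- sim$genotypes
    hits <- hits + (g$a1[1, 1] == g$a1[2, 1] && g$a2[1, 1] == g$a2[2, 1])
    p <- sim$freq_pop[[1]][[1]]
    probs[k] <- (p[1]^2)^2 + (p[2]^2)^2 + (2 * p[1] * p[2])^2
  }
  expected <- mean(probs)
  se <- sqrt(expected * (1 - expected) / reps)
  expect_lt(abs(hits / reps - expected), 3.5 * se + 0.02)
})

test_that("no-differentiation fixtures centre multilocus theta on zero", {
  thetas <- vapply(1:30, function(k) {
    sim <- make_genotypes(geno_sim_spec(n_pops = 4, ramets_per_pop = 30,
                                        clonality = 0, missing_rate = 0,
                                        differentiation = 0, seed = 500 + k))
    wc_fst(sim$genotypes)$theta
  }, numeric(1))
  se <- stats::sd(thetas) / sqrt(length(thetas))
  expect_lt(abs(mean(thetas)), 3 * se)
})

test_that("genotype simulator is reproducible and validates its spec", {
  s1 <- make_genotypes(geno_sim_spec(seed = 3))
  s2 <- make_genotypes(geno_sim_spec(seed = 3))
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth, s2$truth)
  expect_error(geno_sim_spec(ramets_per_pop = 2, genets_per_pop = 5), ">=")
  expect_error(geno_sim_spec(clonality = 1.2), "\\[0, 1\\]")
})
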