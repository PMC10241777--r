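test_that("connectivity probabilities are exact event/release ratios", {
  sites <- line_sites(2, spacing_km = 100)
  tr <- traj_df(site_id = c(rep(0L, 10), rep(1L, 4)),
                fate = c(rep("event", 3), rep("expired", 7),
                         rep("beached_no_site", 4)),
                event_site = c(rep(1L, 3), rep(NA_integer_, 11)))
  m <- build_matrix(tr, sites)
  expect_equal(m$p[1, 2], 0.3)
  expect_equal(m$n_released, c(10L, 4L))
  expect_equal(sum(m$n_events), 3)
  expect_error(build_matrix(traj_df(5L, "expired"), sites), "unknown")
})

test_that("pure retention gives the identity probability matrix", {
  sites <- line_sites(3, spacing_km = 400)
  ts <- run_year(zero_field(366), sites, 2008,
                 sim_config(dt = 8, max_days = 1, capture_km = 1))
  m <- build_matrix(ts, sites)
  expect_equal(m$p, diag(3), ignore_attr = TRUE)
  # conservation: per-source fates partition releases
  for (s in sites$site_id) {
    sub <- ts[ts$site_id == s, ]
    expect_equal(sum(sub$fate == "event") + sum(sub$fate == "beached_no_site") +
                   sum(sub$fate == "lost_domain") + sum(sub$fate == "expired"),
                 m$n_released[s + 1])
  }
})

test_that("uniform eastward flow connects only to eastern neighbours", {
  f <- make_velocity_field(field_spec("uniform", lon = c(0, 8), lat = c(-2, 2),
                                      step = 0.25, n_days = 40,
                                      amplitude = 0.3,
                                      start_date = as.Date("2008-01-01")))
  sites <- line_sites(3, spacing_km = 60, lat = 0, lon0 = 1,
                      resolution_km = 2)
  cfg <- sim_config(dt = 1, max_days = 5, capture_km = 2)
  for (k in 1:3) {
    tr <- advect_particle(f, c(sites$lon[k], sites$lat[k]), f$days[1], cfg,
                          sites, source_id = k - 1L)
    if (k < 3) {
      expect_equal(tr$fate, "event")
      expect_equal(tr$event_site, k)  # the next site east
    } else {
      expect_true(tr$fate %in% c("expired", "lost_domain"))
    }
  }
})

test_that("mean_matrix is an element-wise mean with the expected algebra", {
  sites <- line_sites(2, spacing_km = 100)
  m0 <- connectivity_matrix(p = matrix(c(0, 0, 0, 0), 2), site_id = 0:1,
                            n_released = c(10L, 10L),
                            n_events = matrix(0L, 2, 2))
  m1 <- connectivity_matrix(p = matrix(c(1, 0, 1, 0), 2), site_id = 0:1,
                            n_released = c(10L, 10L),
                            n_events = matrix(c(10L, 0L, 10L, 0L), 2))
  expect_equal(mean_matrix(list(m1, m1))$p, m1$p)
  avg <- mean_matrix(list(m0, m1))
  expect_equal(avg$p[1, 2], 0.5)
  expect_equal(avg$p[2, 2], 0)
  expect_equal(mean_matrix(list(m0, m1))$p, mean_matrix(list(m1, m0))$p)
  expect_equal(avg$n_released, c(20L, 20L))
  # bounded element-wise between min and max
  expect_true(all(avg$p >= pmin(m0$p, m1$p) & avg$p <= pmax(m0$p, m1$p)))
  m_bad <- connectivity_matrix(p = matrix(0, 3, 3))
  expect_error(mean_matrix(list(m0, m_bad)), "site sets")
})

test_that("event statistics match hand values and a brute-force event list", {
  # single connected pair 100 km apart
  s2 <- line_sites(2, spacing_km = 100)
  ev <- matrix(c(0L, 0L, 7L, 0L), 2)  # 7 events 0 -> 1
  m <- connectivity_matrix(n_events = ev, n_released = c(10L, 10L),
                           site_id = 0:1)
  st <- event_statistics(m, s2)
  expect_equal(st$mean_distance_km, 100, tolerance = 1e-6)
  expect_equal(st$sd_distance_km, 0)
  expect_equal(st$max_distance_km, 100, tolerance = 1e-6)
  expect_equal(st$mean_p, 0.7)

  # two pairs at 100 and 300 km with equal counts
  s4 <- line_sites(4, spacing_km = 100)
  ev <- matrix(0L, 4, 4)
  ev[1, 2] <- 5L  # 100 km
  ev[1, 4] <- 5L  # 300 km
  m <- connectivity_matrix(n_events = ev, n_released = rep(10L, 4),
                           site_id = 0:3)
  st <- event_statistics(m, s4)
  expect_equal(st$mean_distance_km, 200, tolerance = 1e-6)
  expect_equal(st$max_distance_km, 300, tolerance = 1e-6)

  # brute force over the flat event multiset on a random fixture
  withr::local_seed(77)
  n <- 5
  sites <- line_sites(n, spacing_km = 137, lat = 12)
  ev <- matrix(rpois(n * n, 1.2), n)
  m <- connectivity_matrix(n_events = ev, n_released = rep(50L, n),
                           site_id = sites$site_id)
  st <- event_statistics(m, sites)
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(sites$lon[i], sites$lat[i], sites$lon[j], sites$lat[j]))
  flat <- rep(D[ev > 0], ev[ev > 0])          # one distance per event
  expect_equal(st$n_events_total, length(flat))
  expect_equal(st$mean_distance_km, mean(flat))
  expect_equal(st$sd_distance_km, sqrt(mean((flat - mean(flat))^2)))
  expect_equal(st$max_distance_km, max(flat))
  expect_equal(st$mean_p, mean(m$p[ev > 0]))
  expect_equal(st$mean_events, mean(ev[ev > 0]))

  # no events: undefined with flag, not a crash
  m0 <- connectivity_matrix(n_events = matrix(0L, 2, 2),
                            n_released = c(5L, 5L))
  st0 <- event_statistics(m0, s2)
  expect_false(st0$defined)
  expect_true(is.na(st0$mean_distance_km))
})

test_that("the release ledger reproduces calendar arithmetic", {
  led <- release_ledger(2, 2011:2012)
  expect_equal(led$per_year$days, c(365L, 366L))
  expect_equal(led$total, 2 * 731)
})

test_that("connectivity matrices round-trip through long CSV", {
  ev <- matrix(c(2L, 0L, 3L, 1L), 2)
  m <- connectivity_matrix(n_events = ev, n_released = c(8L, 9L),
                           site_id = c(4L, 9L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_csv(m, path)
  m2 <- read_connectivity_csv(path)
  expect_equal(m2$p, m$p, ignore_attr = TRUE)
  expect_equal(m2$n_events, m$n_events, ignore_attr = TRUE)
  expect_equal(m2$site_id, m$site_id)
})
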