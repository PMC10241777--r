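test_that("bilinear sampling is exact at nodes, at cell midpoints, and for bilinear fields", {
  withr::local_seed(101)
  f <- zero_field(n_days = 1, lon = c(0, 5), lat = c(0, 5), step = 1)
  # plant a random bilinear function u = a*lon + b*lat + c + d*lon*lat
  co <- runif(8, -1, 1)
  LON <- matrix(f$lon, 6, 6); LAT <- matrix(f$lat, 6, 6, byrow = TRUE)
  f$u[, , 1] <- co[1] * LON + co[2] * LAT + co[3] + co[4] * LON * LAT
  f$v[, , 1] <- co[5] * LON + co[6] * LAT + co[7] + co[8] * LON * LAT

  # node identity
  s <- sample_velocity(f, f$lon[3], f$lat[4], f$days[1])
  expect_identical(s$u, f$u[3, 4, 1])
  # cell midpoint = mean of the 4 corners
  s <- sample_velocity(f, 2.5, 3.5, f$days[1])
  expect_equal(s$u, mean(f$u[3:4, 4:5, 1]), tolerance = 1e-14)
  # bilinearity: exact reproduction anywhere in the hull
  q <- cbind(runif(1000, 0, 5), runif(1000, 0, 5))
  s <- sample_velocity(f, q[, 1], q[, 2], f$days[1])
  tru <- co[1] * q[, 1] + co[2] * q[, 2] + co[3] + co[4] * q[, 1] * q[, 2]
  trv <- co[5] * q[, 1] + co[6] * q[, 2] + co[7] + co[8] * q[, 1] * q[, 2]
  expect_lt(max(abs(s$u - tru)), 1e-10)
  expect_lt(max(abs(s$v - trv)), 1e-10)
})

test_that("land nodes are renormalised out of the interpolation", {
  f <- zero_field(n_days = 1, lon = c(0, 2), lat = c(0, 2), step = 1)
  f$land[1, 1] <- TRUE
  f$u[, , 1] <- matrix(c(NA, 2, 4, 6, 8, 10, 12, 14, 16), 3, 3)
  s <- sample_velocity(f, 0.5, 0.5, f$days[1])
  # corners (0,0)=land, (1,0)=2, (0,1)=6, (1,1)=8, equal weights 1/4 -> renorm
  expect_equal(s$u, (2 + 6 + 8) / 3)
  expect_false(s$all_land)

  f$land[] <- TRUE
  s <- sample_velocity(f, 0.5, 0.5, f$days[1])
  expect_identical(s$u, 0)
  expect_true(s$all_land)

  s <- sample_velocity(f, 10, 0.5, f$days[1])
  expect_false(s$in_domain)
  expect_true(is.na(s$u))
})

test_that("still water yields pure retention at the source", {
  f <- zero_field(n_days = 70)
  sites <- line_sites(4, spacing_km = 300, resolution_km = 1)
  cfg <- sim_config(dt = 1, max_days = 60, capture_km = 1)
  for (k in 1:4) {
    tr <- advect_particle(f, c(sites$lon[k], sites$lat[k]), f$days[1], cfg,
                          sites)
    expect_equal(tr$fate, "event")
    expect_equal(tr$event_site, sites$site_id[k])
    expect_equal(tr$arrival_step, 60 * 24)
    expect_equal(nrow(unique(tr$positions)), 1)
  }
})

test_that("uniform flow matches the constant-velocity closed form to 1e-9 relative", {
  f <- make_velocity_field(field_spec("uniform", lon = c(0, 10), lat = c(-5, 5),
                                      step = 1, n_days = 3, amplitude = 0.1,
                                      start_date = as.Date("2008-01-01")))
  sites <- line_sites(1, 1, lat = 0, lon0 = 1)
  cfg <- sim_config(dt = 1, max_days = 1, capture_km = 0.5)
  tr <- advect_particle(f, c(1, 0), f$days[1], cfg, sites)
  end <- tr$positions[nrow(tr$positions), ]
  # 0.1 m/s for 24 h = 8.64 km east at the equator
  dist_km <- 0.1 * 86400 / 1000
  expected_lon <- 1 + dist_km / 6371 * 180 / pi
  expect_equal(unname(end["lat"]), 0)
  expect_equal(unname(end["lon"]), expected_lon, tolerance = 1e-9)
  expect_equal(haversine_km(1, 0, end["lon"], end["lat"]), dist_km,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("solid-rotation trajectories stay within the first-order Euler bound", {
  # circle of radius 50 km at the equator, period 20 days
  omega <- 2 * pi / (20 * 86400)
  f <- make_velocity_field(field_spec("solid_rotation", lon = c(-2, 2),
                                      lat = c(-2, 2), step = 0.1,
                                      center = c(0, 0), omega = omega,
                                      n_days = 12))
  r0_km <- 50
  start_lat <- r0_km / (6371 * pi / 180)
  sites <- line_sites(1, 1, lat = -1.9, lon0 = -1.9)  # far away, no captures
  run_one <- function(integ, dt) {
    cfg <- sim_config(dt = dt, max_days = 10, capture_km = 0.5,
                      integrator = integ)
    advect_particle(f, c(0, start_lat), f$days[1], cfg, sites)
  }
  analytic <- function(t_s) {
    ang <- pi / 2 + omega * t_s   # starts due north of centre
    c(lon = r0_km * cos(ang) / (6371 * pi / 180),
      lat = r0_km * sin(ang) / (6371 * pi / 180))
  }
  tr <- run_one("euler", 1)
  T_s <- 10 * 86400
  end <- tr$positions[nrow(tr$positions), ]
  ref <- analytic(T_s)
  err_km <- haversine_km(end["lon"], end["lat"], ref["lon"], ref["lat"])
  # Gronwall bound for Euler: dt * omega * r0 / 2 * (e^(omega T) - 1)
  bound_km <- 3600 * omega * r0_km / 2 * (exp(omega * T_s) - 1)
  expect_lt(err_km, bound_km)

  # halving dt roughly halves the error (first order); rk2 is far better
  tr2 <- run_one("euler", 0.5)
  end2 <- tr2$positions[nrow(tr2$positions), ]
  err2 <- haversine_km(end2["lon"], end2["lat"], ref["lon"], ref["lat"])
  expect_lt(err2, 0.65 * err_km)
  trk <- run_one("rk2", 1)
  endk <- trk$positions[nrow(trk$positions), ]
  errk <- haversine_km(endk["lon"], endk["lat"], ref["lon"], ref["lat"])
  expect_lt(errk, 0.05 * err_km)
})

test_that("fates partition releases and non-terminal positions avoid land", {
  # eastward flow into a land wall: particles either beach or hit the far site
  f <- make_velocity_field(field_spec("uniform", lon = c(0, 6), lat = c(-2, 2),
                                      step = 0.25, n_days = 40,
                                      amplitude = 0.4,
                                      start_date = as.Date("2008-01-01")),
                           land = function(lon, lat) lon >= 4)
  sites <- line_sites(2, spacing_km = 150, lat = 0, lon0 = 0.5,
                      resolution_km = 5)
  cfg <- sim_config(dt = 1, max_days = 8, capture_km = 5)
  tr <- advect_particle(f, c(sites$lon[1], sites$lat[1]), f$days[1], cfg,
                        sites, source_id = 0)
  expect_equal(tr$fate, "event")
  expect_equal(tr$event_site, 1)
  tr2 <- advect_particle(f, c(sites$lon[2], sites$lat[2]), f$days[1], cfg,
                         sites, source_id = 1)
  expect_equal(tr2$fate, "beached_no_site")
  # all but the terminal position are on ocean
  pos <- tr2$positions
  if (nrow(pos) > 1) {
    non_term <- pos[-nrow(pos), , drop = FALSE]
    expect_true(all(!driftline:::is_land(f, non_term[, 1], non_term[, 2])))
  }

  # a particle in unbounded eastward flow with no land leaves the domain
  f2 <- make_velocity_field(field_spec("uniform", lon = c(0, 3), lat = c(-2, 2),
                                       step = 0.25, n_days = 40,
                                       amplitude = 0.4,
                                       start_date = as.Date("2008-01-01")))
  tr3 <- advect_particle(f2, c(2.5, 0.4), f2$days[1],
                         sim_config(dt = 1, max_days = 3, capture_km = 1),
                         line_sites(1, 1, lat = -1.5, lon0 = 0.3))
  expect_equal(tr3$fate, "lost_domain")

  expect_error(advect_particle(f, c(5, 0), f$days[1], cfg, sites), "land")
})

test_that("run_year produces the exact release ledger and is deterministic", {
  f <- zero_field(n_days = 366)
  sites <- line_sites(3, spacing_km = 400)
  cfg <- sim_config(dt = 8, max_days = 1, capture_km = 1)
  ts <- run_year(f, sites, 2008, cfg)          # leap year
  expect_equal(nrow(ts), 3 * 366)
  expect_true(all(table(ts$site_id) == 366))
  expect_identical(ts, run_year(f, sites, 2008, cfg))

  f2 <- zero_field(n_days = 365)
  f2$days <- seq(as.Date("2009-01-01"), by = "day", length.out = 365)
  ts2 <- run_year(f2, line_sites(1, 1), 2009, cfg)
  expect_equal(nrow(ts2), 365)
  expect_error(run_year(f2, sites, 2008, cfg), "cover")

  # fates always partition releases
  expect_true(all(ts$fate %in% c("event", "beached_no_site", "lost_domain",
                                 "expired")))
  expect_equal(sum(table(ts$fate)), nrow(ts))
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(dt = 7), "divide 24")
  expect_error(sim_config(max_days = 0), "max_days")
  expect_s3_class(sim_config(dt = 1, integrator = "rk2"), "sim_config")
})
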