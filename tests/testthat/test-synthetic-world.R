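test_that("landscape generation enforces sizing and is seed-deterministic", {
  expect_error(generate_landscape(extent_km = 80), "120 km")

  L1 <- generate_landscape(extent_km = 120, res_terrain_m = 600,
                           res_ndvi_m = 1000, rng_seed = 3)
  L2 <- generate_landscape(extent_km = 120, res_terrain_m = 600,
                           res_ndvi_m = 1000, rng_seed = 3)
  expect_identical(L1$elevation$values, L2$elevation$values)
  expect_identical(L1$dist_roads$values, L2$dist_roads$values)
  expect_identical(L1$ndvi[[7]]$values, L2$ndvi[[7]]$values)

  # layers are finite everywhere and ruggedness nonnegative
  expect_true(all(is.finite(L1$ruggedness$values)))
  expect_true(all(L1$ruggedness$values >= 0))
  expect_true(all(L1$dist_roads$values >= 0))
  expect_true(all(L1$canopy$values >= 0 & L1$canopy$values <= 100))
  expect_true(all(abs(unlist(lapply(L1$ndvi, function(l) l$values))) <= 1))

  # green-up: July greener than January across the extent
  expect_gt(mean(L1$ndvi[[7]]$values), mean(L1$ndvi[[1]]$values))

  # ruggedness is exactly the TRI of the elevation layer
  expect_equal(L1$ruggedness$values,
               terrain_ruggedness(L1$elevation)$values)
})

test_that("landscape round-trips through ASCII-grid persistence", {
  L <- generate_landscape(extent_km = 120, res_terrain_m = 1500,
                          res_ndvi_m = 2000, rng_seed = 4)
  d <- tempfile()
  write_landscape(L, d)
  L2 <- read_landscape(d)
  expect_equal(L2$ruggedness$values, L$ruggedness$values, tolerance = 1e-6)
  expect_equal(L2$ndvi[[6]]$values, L$ndvi[[6]]$values, tolerance = 1e-6)
  expect_equal(unname(L2$extent), unname(L$extent))
  expect_equal(L2$scaling, L$scaling, tolerance = 1e-5)
  unlink(d, recursive = TRUE)
})

test_that("same config reproduces a trajectory bit-identically", {
  L <- test_world()
  cfg <- simulation_config(rng_seed = 21)
  t1 <- suppressWarnings(simulate_trajectory(L, "disperser", cfg, seed = 21))
  t2 <- suppressWarnings(simulate_trajectory(L, "disperser", cfg, seed = 21))
  expect_identical(t1$x, t2$x)
  expect_identical(t1$timestamp, t2$timestamp)
})

test_that("null selection chooses uniformly among candidates", {
  L <- test_world()
  cfg <- simulation_config(true_betas = zero_betas, outlier_prob = 0,
                           rng_seed = 31)
  tr <- suppressWarnings(simulate_trajectory(L, "resident", cfg, seed = 31))
  st <- build_steps(tr)
  # under zero betas and wide-angle proposals the chosen-step covariates
  # match plain availability: compare chosen-endpoint ruggedness to the
  # landscape around the home range (one-sample scale check)
  pts <- attach_covariates(data.frame(x = tr$x, y = tr$y,
                                      timestamp = tr$timestamp), L)
  # draw matched availability: same endpoints jittered by the step kernel
  set.seed(31)
  n <- nrow(tr)
  len <- rgamma(n, shape = 1.2, scale = 150)
  ang <- runif(n, -pi, pi)
  av <- data.frame(x = pmin(pmax(tr$x + len * cos(ang), 1), 119999),
                   y = pmin(pmax(tr$y + len * sin(ang), 1), 119999),
                   timestamp = tr$timestamp)
  av <- attach_covariates(av, L)
  expect_lt(abs(mean(pts$ruggedness) - mean(av$ruggedness)),
            2 * sd(av$ruggedness) / sqrt(n) * 3)
})

test_that("strong avoidance shows up as lower covariate values at chosen endpoints", {
  L <- test_world()
  beta <- zero_betas; beta["ruggedness"] <- -2
  d <- simulate_ssf_strata(L, n_animals = 2, n_strata_per_animal = 600,
                           beta = beta, seed = 41)
  chosen <- d$ruggedness[d$case == 1]
  rejected <- d$ruggedness[d$case == 0]
  tt <- t.test(chosen, rejected, alternative = "less")
  expect_lt(tt$p.value, 1e-6)
})

test_that("resident NSD stays at home-range scale; disperser hits its target", {
  L <- test_world()
  cfg <- simulation_config(rng_seed = 51)
  tr <- suppressWarnings(simulate_trajectory(L, "resident", cfg, seed = 51))
  nsd <- compute_nsd(screen_outliers(tr)$trajectory)
  expect_lt(max(nsd$nsd_km2), 100)  # well under the (10 km)^2 residency scale

  cfg2 <- simulation_config(
    dispersal_displacement_km = c(98.01, 98.01), rng_seed = 52)
  ok <- 0
  for (s in c(52, 53, 54)) {
    tr2 <- suppressWarnings(simulate_trajectory(L, "disperser", cfg2, seed = s))
    tru <- attr(tr2, "truth")
    ed <- as.numeric(tr2$timestamp - tr2$timestamp[1], units = "days")
    d <- tr2[ed >= tru$dispersal_start_day - 1e-9 &
               ed <= tru$dispersal_end_day + 1e-9, ]
    sl <- sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2) / 1000
    ok <- ok + (abs(sl - 98.01) / 98.01 < 0.10)
  }
  expect_equal(ok, 3)
})

test_that("exploratory animals return to within 5 km of the origin", {
  L <- test_world()
  cfg <- simulation_config(dispersal_duration_days = c(12, 25), rng_seed = 61)
  tr <- suppressWarnings(simulate_trajectory(L, "exploratory", cfg, seed = 61))
  tru <- attr(tr, "truth")
  last <- c(tr$x[nrow(tr)], tr$y[nrow(tr)])
  # settled back near the origin by the end of the year (within the home
  # ranging scale of the 5-km return tolerance)
  expect_lt(sqrt(sum((last - tru$start_xy)^2)), 8000)
})

test_that("directly simulated strata have conserved structure", {
  L <- test_world()
  d <- simulate_ssf_strata(L, n_animals = 3, n_strata_per_animal = 20,
                           beta = zero_betas, seed = 71)
  sizes <- table(d$stratum_id)
  expect_true(all(sizes == 11))
  cases <- tapply(d$case, d$stratum_id, sum)
  expect_true(all(cases == 1))
})
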