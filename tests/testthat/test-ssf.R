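library(survival)  # independent conditional-logistic implementation

make_steps_df <- function(lengths, turns, animal = "a1") {
  n <- length(lengths)
  data.frame(
    animal_id = animal,
    t_start = as.POSIXct("2008-06-01", tz = "UTC") + (1:n) * 7200,
    t_end = as.POSIXct("2008-06-01", tz = "UTC") + (1:n + 1) * 7200,
    x0 = 0, y0 = 0, x1 = lengths, y1 = 0,
    length_m = lengths, duration_min = 120,
    rate_m_hr = lengths / 2, rate_m_min = lengths / 120,
    heading_deg = 0, turning_angle_deg = turns, regular = TRUE,
    stringsAsFactors = FALSE
  )
}

test_that("leave-one-out kernels exclude the focal animal and sum to one", {
  steps <- list(
    a1 = make_steps_df(c(10, 60, 110), c(0, 5, -5), "a1"),
    a2 = make_steps_df(c(9000, 9100), c(100, -100), "a2")
  )
  k <- build_kernels(steps, focal_animal = "a2")
  # lengths 10, 60, 110 fall in three 50-m bins with mass 1/3 each
  expect_equal(nrow(k$length), 3)
  expect_equal(k$length$mass, rep(1 / 3, 3))
  expect_equal(sum(k$turn$mass), 1)
  # the focal animal's extreme steps are absent from its own kernel
  expect_lt(max(k$length$hi), 9000)
  expect_identical(k$source_animal_ids, "a1")

  expect_error(build_kernels(steps["a1"], "a1"), "at least 2")

  # mass sums to 1 for every focal animal in a multi-animal set
  set.seed(8)
  many <- lapply(1:6, function(i) {
    make_steps_df(rgamma(40, 2, 0.01), runif(40, -179, 179), paste0("m", i))
  })
  names(many) <- paste0("m", 1:6)
  for (a in names(many)) {
    k <- build_kernels(many, a)
    expect_equal(sum(k$length$mass), 1)
    expect_equal(sum(k$turn$mass), 1)
  }
})

test_that("random steps respect the kernel support and are seed-reproducible", {
  # degenerate kernel: one length bin (100-150 m), one turn bin (0-10 deg)
  kern <- structure(list(
    length = data.frame(lo = 100, hi = 150, mass = 1),
    turn = data.frame(lo = 0, hi = 10, mass = 1),
    source_animal_ids = "x"
  ), class = "step_kernel")
  set.seed(1)
  rs <- draw_random_steps(0, 0, prior_heading_deg = 0, kern, n = 10)
  d <- sqrt(rs$x1^2 + rs$y1^2)
  ang <- atan2(rs$y1, rs$x1) * 180 / pi
  expect_true(all(d >= 100 & d < 150))
  expect_true(all(ang >= 0 & ang < 10))

  set.seed(42); a <- draw_random_steps(0, 0, 30, kern, n = 10)
  set.seed(42); b <- draw_random_steps(0, 0, 30, kern, n = 10)
  expect_identical(a, b)

  # bin masses are respected: chi-square on many draws
  kern2 <- structure(list(
    length = data.frame(lo = c(0, 50, 100), hi = c(50, 100, 150),
                        mass = c(0.2, 0.5, 0.3)),
    turn = data.frame(lo = -180, hi = 180, mass = 1),
    source_animal_ids = "x"
  ), class = "step_kernel")
  set.seed(2)
  rs2 <- draw_random_steps(0, 0, 0, kern2, n = 20000)
  bin <- cut(rs2$length_m, c(0, 50, 100, 150), labels = FALSE)
  p <- chisq.test(tabulate(bin, 3), p = c(0.2, 0.5, 0.3))$p.value
  expect_gt(p, 0.01)

  # impossible extent: error after the redraw budget
  tiny <- c(xmin = 0, xmax = 1, ymin = 0, ymax = 1)
  expect_error(draw_random_steps(500, 500, 0, kern, n = 5, extent = tiny),
               "could not place")
})

test_that("Newton conditional logistic matches grid search and survival::clogit", {
  L <- test_world()
  # grid oracle on a tiny problem: 6 strata, 2 covariates
  d <- simulate_ssf_strata(L, n_animals = 1, n_strata_per_animal = 6,
                           beta = c(ruggedness = -0.5, ndvi = 1.0),
                           seed = 31)
  X <- as.matrix(d[c("ruggedness", "ndvi")])
  f <- fit_conditional_logistic(X, d$case, d$stratum_id)
  cll <- function(b) {
    eta <- X %*% b
    sum(tapply(seq_len(nrow(X)), d$stratum_id, function(i) {
      eta[i][d$case[i] == 1] - log(sum(exp(eta[i])))
    }))
  }
  # exhaustive grid around the optimum
  g <- expand.grid(b1 = seq(-4, 4, by = 0.01), b2 = seq(-4, 4, by = 0.25))
  ll <- apply(g, 1, cll)
  best <- g[which.max(ll), ]
  g2 <- expand.grid(b1 = seq(best$b1 - 0.3, best$b1 + 0.3, by = 0.002),
                    b2 = seq(best$b2 - 0.3, best$b2 + 0.3, by = 0.002))
  ll2 <- apply(g2, 1, cll)
  best2 <- g2[which.max(ll2), ]
  expect_lt(abs(f$coef[1] - best2$b1), 1e-2)
  expect_lt(abs(f$coef[2] - best2$b2), 1e-2)
  expect_gte(f$loglik, max(ll2) - 1e-6)

  # independent implementation cross-check on a larger problem
  d2 <- simulate_ssf_strata(L, n_animals = 2, n_strata_per_animal = 150,
                            beta = c(ruggedness = -0.5, ndvi = 1.0),
                            seed = 32)
  X2 <- as.matrix(d2[c("ruggedness", "ndvi")])
  f2 <- fit_conditional_logistic(X2, d2$case, d2$stratum_id)
  sid <- as.integer(factor(d2$stratum_id))
  cf <- survival::clogit(case ~ rug + nd + survival::strata(sid),
                         data = data.frame(case = d2$case,
                                           rug = X2[, 1], nd = X2[, 2],
                                           sid = sid))
  expect_equal(unname(f2$coef), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(unname(f2$se), unname(sqrt(diag(vcov(cf)))), tolerance = 1e-4)
})

test_that("separation is flagged with infinite SEs, not silently returned", {
  X <- matrix(c(rep(c(1, rep(0, 10)), 5)), ncol = 1)
  case <- rep(c(1L, rep(0L, 10)), 5)
  strata <- rep(1:5, each = 11)
  f <- fit_conditional_logistic(X, case, strata)
  expect_true(f$separation)
  expect_true(all(is.infinite(f$se)))
})

test_that("simulated strata recover the generating coefficients within 2 SE", {
  L <- test_world()
  beta <- c(ruggedness = -0.5, ndvi = 1.0)
  d <- simulate_ssf_strata(L, n_animals = 1, n_strata_per_animal = 200,
                           beta = beta, seed = 33)
  X <- as.matrix(d[names(beta)])
  f <- fit_conditional_logistic(X, d$case, d$stratum_id)
  expect_true(all(abs(f$coef - beta) < 2 * f$se))
})

test_that("two-stage pooling matches a brute-force REML profile", {
  fits <- list(
    a = structure(list(coef = c(b = 1.0), se = c(b = 0.5),
                       converged = TRUE, separation = FALSE), class = "ssf_fit"),
    b = structure(list(coef = c(b = 3.0), se = c(b = 0.5),
                       converged = TRUE, separation = FALSE), class = "ssf_fit"),
    c = structure(list(coef = c(b = 2.0), se = c(b = 0.5),
                       converged = TRUE, separation = FALSE), class = "ssf_fit")
  )
  p <- pool_two_stage(fits)
  # REML profile oracle over tau^2: restricted log-likelihood maximised on a
  # fine grid, with the weighted mean at each tau^2
  yi <- c(1, 3, 2); vi <- rep(0.25, 3)
  reml_ll <- function(tau2) {
    w <- 1 / (vi + tau2)
    mu <- sum(w * yi) / sum(w)
    -0.5 * sum(log(vi + tau2)) - 0.5 * log(sum(w)) -
      0.5 * sum(w * (yi - mu)^2)
  }
  tg <- seq(0, 10, by = 1e-4)
  tau2_hat <- tg[which.max(vapply(tg, reml_ll, numeric(1)))]
  w <- 1 / (vi + tau2_hat)
  expect_equal(p$table$beta, sum(w * yi) / sum(w), tolerance = 1e-3)
  expect_equal(p$table$tau^2, tau2_hat, tolerance = 2e-3)
  expect_equal(p$table$se, sqrt(1 / sum(w)), tolerance = 1e-3)

  # identical inputs pool to themselves with zero between-variance
  same <- lapply(1:3, function(i) {
    structure(list(coef = c(b = 0.5), se = c(b = 0.2),
                   converged = TRUE, separation = FALSE), class = "ssf_fit")
  })
  names(same) <- letters[1:3]
  p2 <- pool_two_stage(same)
  expect_equal(p2$table$beta, 0.5, tolerance = 1e-8)
  expect_equal(p2$table$tau, 0, tolerance = 1e-6)

  expect_error(pool_two_stage(fits["a"]), "at least 2")
})

test_that("pooling recovers a population mean across individuals", {
  L <- test_world()
  beta <- c(ruggedness = -0.2, ndvi = 0.8)
  d <- simulate_ssf_strata(L, n_animals = 10, n_strata_per_animal = 150,
                           beta = beta, between_sd = 0.1, seed = 34)
  fits <- lapply(split(d, d$animal_id), function(x) {
    fit_conditional_logistic(as.matrix(x[names(beta)]), x$case, x$stratum_id)
  })
  p <- pool_two_stage(fits)
  for (j in seq_along(beta)) {
    row <- p$table[p$table$coef == names(beta)[j], ]
    expect_lt(abs(row$beta - beta[j]), 2 * row$se + 0.05)
  }
})

test_that("k-fold validation separates signal from noise and handles degeneracy", {
  L <- test_world()
  strong <- c(ruggedness = -1.5, ndvi = 2.5)
  d <- simulate_ssf_strata(L, n_animals = 4, n_strata_per_animal = 60,
                           beta = strong, seed = 35)
  X <- as.matrix(d[names(strong)])
  v <- kfold_validate(X, d$case, d$stratum_id, n_perm = 100, seed = 35)
  expect_true(v$useful)
  expect_gt(v$mean_rs, 0.65)

  null <- c(ruggedness = 0, ndvi = 0)
  d0 <- simulate_ssf_strata(L, n_animals = 4, n_strata_per_animal = 60,
                            beta = null, seed = 36)
  v0 <- kfold_validate(as.matrix(d0[names(null)]), d0$case, d0$stratum_id,
                       n_perm = 100, seed = 36)
  expect_false(v0$useful)
  expect_lt(abs(v0$mean_rs), 0.5)

  # perfect knowledge: the observed step is always the unique top score
  n_strata <- 40
  Xp <- matrix(rep(c(5, rep(0, 10)), n_strata), ncol = 1)
  casep <- rep(c(1L, rep(0L, 10)), n_strata)
  stratap <- rep(seq_len(n_strata), each = 11)
  vp <- kfold_validate(Xp, casep, stratap, n_perm = 50, seed = 37)
  expect_equal(vp$mean_rs, 1)

  expect_error(kfold_validate(Xp, casep, stratap, k = 1000), "folds")
})

test_that("strata built from trajectories conserve the matched structure", {
  L <- test_world()
  cfg <- simulation_config(rng_seed = 15)
  steps <- list()
  for (i in 1:3) {
    tr <- suppressWarnings(simulate_trajectory(L, "resident", cfg,
                                               animal_id = paste0("r", i),
                                               seed = 600 + i))
    st <- build_steps(screen_outliers(tr)$trajectory)
    steps[[paste0("r", i)]] <- st[1:80, ]
  }
  strata <- build_strata(steps, L, n_random = 10, seed = 15)
  sizes <- table(strata$stratum_id)
  expect_true(all(sizes == 11))
  expect_true(all(tapply(strata$case, strata$stratum_id, sum) == 1))
  # covariates are attached everywhere
  expect_true(all(is.finite(strata$ruggedness)))
  expect_true(all(is.finite(strata$ndvi)))

  # the full suite runs and reports non-estimable models gracefully
  suite <- run_model_suite(list(
    m1 = strata, empty = strata[0, ], single = strata[strata$animal_id == "r1", ]
  ), k = 3, n_perm = 30, seed = 15, min_strata_per_animal = 10)
  expect_true(isTRUE(suite$models$m1$estimable))
  expect_false(isTRUE(suite$models$empty$estimable))
  expect_false(isTRUE(suite$models$single$estimable))
  expect_true(all(c("beta", "se", "tau", "strong") %in% names(suite$table)))
})
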