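test_that("segmented regression recovers exact and noisy breakpoints", {
  # exact piecewise-linear bins: psi = 5, perfect fit
  mk_rates <- function(psi, b0, s1, s2, noise_sd, seed, bw = 0.5) {
    # build rates whose binned log-frequency is the target broken line
    set.seed(seed)
    mids <- seq(bw / 2, 15, by = bw)
    logf <- b0 + s1 * mids + (s2 - s1) * pmax(mids - psi, 0)
    if (noise_sd > 0) logf <- logf + rnorm(length(mids), 0, noise_sd)
    counts <- round(exp(logf))
    rep(mids, counts)
  }
  # exactly piecewise-linear bins (integer geometric counts, so the binned
  # log frequencies are exact): quartering left segment, halving right; the
  # two lines meet exactly at the junction bin
  counts_exact <- c(1024, 256, 64, 32, 16, 8, 4, 2)
  mids_exact <- seq(0.25, by = 0.5, length.out = length(counts_exact))
  rates <- rep(mids_exact, counts_exact)
  f <- fit_segmented(rates, bin_width = 0.5)
  expect_true(f$breakpoint_found)
  expect_equal(f$psi, 1.25, tolerance = 0.05)  # junction of the two lines
  expect_gt(f$r2_segmented, 0.9999)
  expect_equal(f$slope_left, -2 * log(2) / 0.5, tolerance = 0.05)
  expect_equal(f$slope_right, -log(2) / 0.5, tolerance = 0.05)

  # noisy two-segment input: psi recovered within 2 SE, segmented beats null
  rates2 <- mk_rates(psi = 7.0, b0 = 7, s1 = -0.15, s2 = -0.55,
                     noise_sd = 0.15, seed = 2)
  f2 <- fit_segmented(rates2, bin_width = 0.5)
  expect_true(f2$breakpoint_found)
  expect_lt(abs(f2$psi - 7.0), 2 * f2$psi_se)
  expect_gt(f2$r2_segmented, f2$r2_null)

  # pure single line (exact geometric counts): the null wins
  rates3 <- rep(seq(0.25, by = 0.5, length.out = 12), 2^(12:1))
  f3 <- fit_segmented(rates3, bin_width = 0.5)
  expect_false(f3$breakpoint_found)
  expect_true(is.na(f3$psi))
})

test_that("segmented fit beats the null whenever the slope change clears the noise", {
  set.seed(10)
  for (rep in 1:5) {
    noise <- 0.1
    s1 <- -0.1; s2 <- s1 - 3 * noise - runif(1, 0.1, 0.4)
    mids <- seq(0.25, 14.75, by = 0.5)
    logf <- 7 + s1 * mids + (s2 - s1) * pmax(mids - 6, 0) +
      rnorm(length(mids), 0, noise)
    rates <- rep(mids, pmax(round(exp(logf)), 0))
    f <- fit_segmented(rates, bin_width = 0.5)
    expect_true(f$breakpoint_found)
    expect_gt(f$r2_segmented, f$r2_null)
  }
})

test_that("step splitting uses the psi-by-interval threshold (854 m rule)", {
  st <- data.frame(length_m = c(300, 853, 854, 900, 2000),
                   turning_angle_deg = c(10, -120, 5, 0, -3),
                   regular = TRUE)
  sp <- split_steps(st, psi = 7.118, interval_min = 120)
  expect_equal(sp$threshold_m, 854)
  expect_equal(nrow(sp$short), 2)   # 300, 853
  expect_equal(nrow(sp$long), 3)    # 854 (boundary goes long), 900, 2000
  expect_equal(nrow(sp$short) + nrow(sp$long), nrow(st))
  expect_equal(sum(sp$turn_hist$short), 2)
  expect_equal(sum(sp$turn_hist$long), 3)

  sp2 <- split_steps(st, psi = 2.5, interval_min = 120)
  expect_equal(sp2$threshold_m, 300)
  expect_equal(nrow(sp2$short), 0)
})

test_that("long travelling steps are more directional than short foraging steps", {
  L <- test_world()
  cfg <- simulation_config(dispersal_duration_days = c(15, 30), rng_seed = 12)
  long_t <- c(); short_t <- c()
  for (s in c(301, 302)) {
    tr <- suppressWarnings(simulate_trajectory(L, "disperser", cfg, seed = s))
    tru <- attr(tr, "truth")
    st <- build_steps(screen_outliers(tr)$trajectory)
    ed <- as.numeric(st$t_start - st$t_start[1], units = "days")
    dur <- st[ed >= tru$dispersal_start_day & ed <= tru$dispersal_end_day &
                st$regular, ]
    sp <- split_steps(dur, psi = 7.118)
    long_t <- c(long_t, sp$long$turning_angle_deg)
    short_t <- c(short_t, sp$short$turning_angle_deg)
  }
  expect_lt(circular_sd_deg(long_t), circular_sd_deg(short_t))
})

test_that("movement-rate mixed model recovers period offsets and the reference zero", {
  # synthetic rates: known offsets on a per-animal random intercept
  set.seed(20)
  n_an <- 8
  truth <- c(rest_of_year = 0, before = 55, during = 175, after = 0)
  base <- 90
  rows <- list()
  w <- make_period_windows(structure(list(
    start_date = as.Date("2008-06-10"), end_date = as.Date("2008-07-05")
  ), class = "dispersal_event"))
  windows <- list()
  for (a in 1:n_an) {
    aid <- sprintf("a%02d", a)
    windows[[aid]] <- w
    u <- rnorm(1, 0, 20)
    ts <- seq(as.POSIXct("2008-04-01", tz = "UTC"),
              as.POSIXct("2008-10-31", tz = "UTC"), by = "2 hours")
    per <- as.character(assign_period(ts, w))
    rows[[aid]] <- data.frame(
      animal_id = aid, t_start = ts,
      rate_m_hr = base + u + truth[per] + rnorm(length(ts), 0, 60)
    )
  }
  steps <- do.call(rbind, rows)
  m <- fit_rate_period_model(steps, windows)
  co <- m$coefficients
  expect_equal(co$beta[co$period == "rest_of_year"], 0)
  for (p in c("before", "during", "after")) {
    i <- which(co$period == p)
    expect_lt(abs(co$beta[i] - truth[[p]]), 2 * (co$ci_hi[i] - co$beta[i]))
  }
  # during does not overlap the reference; after does
  expect_false(m$overlap["during", "rest_of_year"])
  expect_true(m$overlap["after", "rest_of_year"])

  # a period with no steps is refused by name
  steps2 <- steps[as.character(assign_period(steps$t_start, w)) != "during", ]
  expect_error(fit_rate_period_model(steps2, windows), "during")
})

test_that("simulated dispersers move faster during dispersal; residents stay flat", {
  L <- test_world()
  cfg <- simulation_config(dispersal_duration_days = c(15, 30), rng_seed = 13)
  # dispersers with their own windows
  steps <- list(); windows <- list()
  for (i in 1:4) {
    aid <- sprintf("d%d", i)
    tr <- suppressWarnings(simulate_trajectory(L, "disperser", cfg,
                                               animal_id = aid,
                                               seed = 400 + i))
    tru <- attr(tr, "truth")
    anchor <- as.Date(tr$timestamp[1])
    ev <- structure(list(
      start_date = anchor + round(tru$dispersal_start_day),
      end_date = anchor + round(tru$dispersal_end_day)
    ), class = "dispersal_event")
    windows[[aid]] <- make_period_windows(ev)
    steps[[aid]] <- build_steps(screen_outliers(tr)$trajectory)
  }
  m <- fit_rate_period_model(do.call(rbind, steps), windows)
  co <- m$coefficients
  expect_gt(co$beta[co$period == "during"], co$beta[co$period == "before"])
  expect_false(m$overlap["during", "rest_of_year"])

  # residents matched to the same windows show no during elevation
  steps_r <- list()
  for (i in 1:4) {
    aid <- sprintf("r%d", i)
    tr <- suppressWarnings(simulate_trajectory(L, "resident", cfg,
                                               animal_id = aid,
                                               seed = 500 + i))
    steps_r[[aid]] <- build_steps(screen_outliers(tr)$trajectory)
  }
  windows_r <- setNames(windows, names(steps_r))
  m2 <- fit_rate_period_model(do.call(rbind, steps_r), windows_r)
  co2 <- m2$coefficients
  expect_lt(abs(co2$beta[co2$period == "during"]), 20)
})
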