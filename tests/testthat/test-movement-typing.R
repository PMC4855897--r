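test_that("NSD model family recovers its generating shapes", {
  # constant profile -> resident wins
  p <- sigmoid_profile(delta = 0, theta = 100, phi = 5)
  p$nsd_km2 <- 4 + 0.5 * sin(p$elapsed_days / 9)   # flat with wiggle
  fits <- fit_movement_models(p)
  expect_equal(fits[[1]]$model_name, "resident")

  # single sigmoid with delta = 9604 km^2 -> dispersal wins, sqrt(delta) ~ 98 km
  p2 <- sigmoid_profile(delta = 9604, theta = 100, phi = 4)
  set.seed(1)
  p2$nsd_km2 <- pmax(p2$nsd_km2 + rnorm(nrow(p2), 0, 50), 0)
  fits2 <- fit_movement_models(p2)
  expect_equal(fits2[[1]]$model_name, "dispersal")
  expect_equal(sqrt(fits2[[1]]$parameters[["delta"]]), 98, tolerance = 0.02)

  # mirrored double sigmoid -> migration wins
  t <- seq(0, 214, by = 0.25)
  nsd <- 2500 * (1 / (1 + exp((60 - t) / 3)) - 1 / (1 + exp((170 - t) / 3)))
  set.seed(2)
  p3 <- data.frame(
    timestamp = as.POSIXct("2008-04-01", tz = "UTC") + t * 86400,
    elapsed_days = t, nsd_km2 = pmax(nsd + rnorm(length(t), 0, 30), 0),
    x = sqrt(pmax(nsd, 0)) * 1000, y = 0
  )
  fits3 <- fit_movement_models(p3)
  expect_equal(fits3[[1]]$model_name, "migration")
  expect_gt(fits3[[1]]$parameters[["theta_ret"]],
            fits3[[1]]$parameters[["theta_dep"]])

  # a series not covering April-October is refused
  expect_error(fit_movement_models(sigmoid_profile(100, 50, 3, days = 90)),
               "refused")
})

test_that("classification separates the four movement signatures and truncation", {
  # out-and-back with a short dwell is exploratory, not migrant
  t <- seq(0, 214, by = 0.25)
  nsd <- 3600 * (1 / (1 + exp((95 - t) / 2)) - 1 / (1 + exp((115 - t) / 2)))
  set.seed(3)
  prof <- data.frame(
    timestamp = as.POSIXct("2008-04-01", tz = "UTC") + t * 86400,
    elapsed_days = t, nsd_km2 = pmax(nsd + rnorm(length(t), 0, 20), 0),
    x = sqrt(pmax(nsd, 0)) * 1000, y = 0
  )
  cl <- classify(fit_movement_models(prof), prof)
  expect_equal(cl$assigned_type, "exploratory")

  # same shape with a months-long dwell is a migrant
  nsd2 <- 3600 * (1 / (1 + exp((50 - t) / 2)) - 1 / (1 + exp((175 - t) / 2)))
  prof2 <- prof
  set.seed(4)
  prof2$nsd_km2 <- pmax(nsd2 + rnorm(length(t), 0, 20), 0)
  cl2 <- classify(fit_movement_models(prof2), prof2)
  expect_equal(cl2$assigned_type, "migrant")

  # a series ending mid-rise (hunter-kill truncation) is other/not classified
  nsd3 <- 6400 / (1 + exp((200 - t) / 12))
  prof3 <- prof
  set.seed(5)
  prof3$nsd_km2 <- pmax(nsd3 + rnorm(length(t), 0, 20), 0)
  cl3 <- classify(fit_movement_models(prof3), prof3)
  expect_equal(cl3$assigned_type, "other")
  expect_true("truncated_rise" %in% cl3$rationale)
})

test_that("classification is invariant to rigid motions of the coordinates", {
  L <- test_world()
  cfg <- simulation_config(rng_seed = 81)
  tr <- suppressWarnings(simulate_trajectory(L, "disperser", cfg, seed = 81))
  tr <- screen_outliers(tr)$trajectory
  cl0 <- classify(fit_movement_models(compute_nsd(tr)), compute_nsd(tr))

  th <- 0.7
  rot <- tr
  rot$x <- cos(th) * tr$x - sin(th) * tr$y + 5000
  rot$y <- sin(th) * tr$x + cos(th) * tr$y - 2000
  nsd_r <- compute_nsd(rot)
  cl1 <- classify(fit_movement_models(nsd_r), nsd_r)
  expect_equal(cl1$assigned_type, cl0$assigned_type)
})

test_that("dispersal window inverts the fitted sigmoid at 2.5%/97.5% of the asymptote", {
  # closed-form oracle: start = theta - phi log 39, end = theta + phi log 39
  prof <- sigmoid_profile(delta = 2500, theta = 170, phi = 4, days = 214)
  set.seed(6)
  prof$nsd_km2 <- pmax(prof$nsd_km2 + rnorm(nrow(prof), 0, 10), 0)
  prof$x <- sqrt(prof$nsd_km2) * 1000
  fits <- fit_movement_models(prof)
  cl <- classify(fits, prof)
  expect_equal(cl$assigned_type, "disperser")
  ev <- extract_dispersal_event(prof, cl)
  expect_equal(ev$start_day, round(170 - 4 * log(39)))   # ~155.3 -> 155
  expect_equal(ev$end_day, round(170 + 4 * log(39)))     # ~184.7 -> 185
  expect_equal(ev$duration_days, ev$end_day - ev$start_day)
  expect_true(ev$completed)

  # a fit whose rise is not completed inside the series errors out
  prof_inc <- sigmoid_profile(delta = 2500, theta = 205, phi = 10, days = 214)
  fake_fit <- structure(list(model_name = "dispersal",
                             parameters = c(delta = 2500, theta = 205, phi = 10),
                             converged = TRUE, rss = 1, aicc = 1),
                        class = "movement_model_fit")
  fake_cl <- structure(list(assigned_type = "disperser", winning_fit = fake_fit),
                       class = "movement_classification")
  expect_error(extract_dispersal_event(prof_inc, fake_cl), "not completed")
})

test_that("extracted duration tracks the simulated dispersal to about two days", {
  L <- test_world()
  cfg <- simulation_config(dispersal_duration_days = c(12, 12), rng_seed = 91)
  devs <- sapply(c(201, 202, 203, 204), function(s) {
    tr <- suppressWarnings(simulate_trajectory(L, "disperser", cfg, seed = s))
    tru <- attr(tr, "truth")
    nsd <- compute_nsd(screen_outliers(tr)$trajectory)
    cl <- classify(fit_movement_models(nsd), nsd)
    ev <- extract_dispersal_event(nsd, cl)
    # truth on the same event definition: the true path's own NSD rise
    abs(ev$duration_days - (tru$event_end_day - tru$event_start_day))
  })
  expect_lte(mean(devs), 2)
})

test_that("period windows and resident matching follow the date arithmetic", {
  ev <- structure(list(
    start_day = 70, end_day = 95,
    start_date = as.Date("2008-06-10"), end_date = as.Date("2008-07-05"),
    duration_days = 25, straight_line_km = 50, completed = TRUE
  ), class = "dispersal_event")
  w <- make_period_windows(ev, window_days = 26)
  expect_equal(w$before, as.Date(c("2008-05-15", "2008-06-09")))
  expect_equal(w$during, as.Date(c("2008-06-10", "2008-07-05")))
  expect_equal(w$after, as.Date(c("2008-07-06", "2008-07-31")))

  per <- assign_period(as.POSIXct(c("2008-05-20", "2008-06-15", "2008-07-10",
                                    "2008-09-01"), tz = "UTC"), w)
  expect_equal(as.character(per), c("before", "during", "after", "rest_of_year"))

  # 10 dispersers, 10 all-year residents: perfect matching of size 10
  dw <- setNames(rep(list(w), 10), paste0("d", 1:10))
  spans <- setNames(rep(list(as.Date(c("2008-01-01", "2008-12-31"))), 10),
                    paste0("r", 1:10))
  m <- match_residents(dw, spans)
  expect_true(all(!is.na(m$resident)))
  expect_equal(length(unique(m$resident)), 10)

  # no coverage-complete resident -> reported unmatched
  short <- list(r1 = as.Date(c("2008-06-01", "2008-06-20")))
  expect_warning(m2 <- match_residents(dw[1], short), "no coverage-complete")
  expect_true(is.na(m2$resident[1]))
})

test_that("classification report reproduces printed-count arithmetic", {
  # the published tallies: 38 males / 94 females; 97 migratory, 17 resident,
  # 18 other; 15 male dispersal events of which 6 exploratory
  expect_equal(unname(tally_percentages(c(15, 9, 6), 38)), c(39, 24, 16))
  expect_equal(unname(tally_percentages(c(97, 17, 18), 132)), c(73, 13, 14))

  # the report's percentages recompute from its own counts (row-sum identity)
  df <- data.frame(
    animal_id = sprintf("a%03d", 1:132),
    sex = c(rep("M", 38), rep("F", 94)),
    mode = c(rep("disperser", 9), rep("exploratory", 6), rep("migrant", 20),
             rep("resident", 2), rep("other", 1),
             rep("migrant", 71), rep("resident", 15), rep("other", 7),
             rep("exploratory", 1))
  )
  rep1 <- classification_report(df)
  expect_equal(rep1$type_table$percentage,
               unname(round(100 * rep1$type_table$total /
                              sum(rep1$type_table$total))))
  expect_equal(unname(rep1$male_dispersal),
               c(39, 24, 16))
})
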