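#' Fit the candidate NSD movement models
#'
#' Nonlinear least-squares fits of the four classical net-squared-
#' displacement shapes to an animal-year profile, ranked by AICc:
#' \describe{
#'   \item{resident}{constant NSD, `nsd = c`.}
#'   \item{dispersal}{single logistic rise to an asymptote,
#'     `nsd = delta / (1 + exp((theta - t) / phi))` with asymptote `delta`
#'     (km^2), midpoint `theta` (days) and time scale `phi` (days).}
#'   \item{migration}{two mirrored logistics sharing `delta`: a departure
#'     sigmoid minus a return sigmoid with its own midpoint/scale.}
#'   \item{nomadism}{linear drift through the origin, `nsd = b * t`.}
#' }
#' Sigmoid fits use multi-start initialisation over a midpoint grid to avoid
#' local minima; non-convergence of a candidate is reported as a failed fit,
#' not an error.  Classification requires the profile to cover at least the
#' 1 April - 31 October span (shorter series are refused, mirroring field
#' practice of excluding animals whose dispersal window is not covered).
#'
#' @param nsd_profile data.frame from [compute_nsd()]
#' @param require_span logical; enforce the April-October coverage rule
#' @param span_slack_days tolerated shortfall at either end, days
#' @return list of fits (class `movement_model_fit`: `model_name`,
#'   `parameters`, `rss`, `aicc`, `converged`), sorted by AICc with failed
#'   fits last
#' @export
fit_movement_models <- function(nsd_profile, require_span = TRUE,
                                span_slack_days = 7) {
  t <- nsd_profile$elapsed_days
  y <- nsd_profile$nsd_km2
  n <- length(t)
  if (require_span) {
    dates <- as.Date(nsd_profile$timestamp)
    yr <- as.integer(format(dates[1], "%Y"))
    need_start <- as.Date(sprintf("%d-04-01", yr))
    need_end <- as.Date(sprintf("%d-10-31", yr))
    if (dates[1] > need_start + span_slack_days ||
        dates[n] < need_end - span_slack_days) {
      stop("series does not cover 1 April - 31 October; classification refused",
           call. = FALSE)
    }
  }
  if (n < 20) stop("too few fixes for NSD model fitting", call. = FALSE)

  aicc <- function(rss, k) {
    # gaussian profile likelihood; k counts model parameters + sigma
    k <- k + 1
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  fits <- list()

  # resident: constant
  c_hat <- mean(y)
  rss <- sum((y - c_hat)^2)
  fits$resident <- structure(list(
    model_name = "resident", parameters = c(c = c_hat),
    rss = rss, aicc = aicc(rss, 1), converged = TRUE,
    fitted_fun = local({ ch <- c_hat; function(tt) rep(ch, length(tt)) })
  ), class = "movement_model_fit")

  # nomadism: linear through the origin
  b_hat <- sum(t * y) / sum(t^2)
  rss <- sum((y - b_hat * t)^2)
  fits$nomadism <- structure(list(
    model_name = "nomadism", parameters = c(b = b_hat),
    rss = rss, aicc = aicc(rss, 1), converged = TRUE,
    fitted_fun = local({ bh <- b_hat; function(tt) bh * tt })
  ), class = "movement_model_fit")

  dat <- data.frame(t = t, y = y)
  delta0 <- max(stats::quantile(y, 0.95), 1e-3)
  t_grid <- stats::quantile(t, c(0.2, 0.35, 0.5, 0.65, 0.8), names = FALSE)

  # dispersal: single sigmoid
  best <- NULL
  for (th0 in t_grid) for (ph0 in c(2, 8)) {
    f <- try(minpack.lm::nlsLM(
      y ~ delta / (1 + exp((theta - t) / phi)), data = dat,
      start = list(delta = delta0, theta = th0, phi = ph0),
      lower = c(delta = 1e-6, theta = min(t) - 50, phi = 0.25),
      upper = c(delta = Inf, theta = max(t) + 50, phi = 200),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(f, "try-error")) next
    rssf <- sum(stats::resid(f)^2)
    if (is.null(best) || rssf < best$rss) best <- list(fit = f, rss = rssf)
  }
  fits$dispersal <- if (is.null(best)) {
    failed_fit("dispersal")
  } else {
    p <- stats::coef(best$fit)
    structure(list(
      model_name = "dispersal", parameters = p,
      rss = best$rss, aicc = aicc(best$rss, 3), converged = TRUE,
      fitted_fun = local({ pp <- p; function(tt) {
        pp["delta"] / (1 + exp((pp["theta"] - tt) / pp["phi"]))
      } })
    ), class = "movement_model_fit")
  }

  # migration: mirrored double sigmoid sharing delta
  best <- NULL
  th_pairs <- expand.grid(
    thd = stats::quantile(t, c(0.2, 0.35), names = FALSE),
    thr = stats::quantile(t, c(0.65, 0.85), names = FALSE)
  )
  for (i in seq_len(nrow(th_pairs))) for (ph0 in c(3, 10)) {
    f <- try(minpack.lm::nlsLM(
      y ~ delta * (1 / (1 + exp((theta_dep - t) / phi_dep)) -
                     1 / (1 + exp((theta_ret - t) / phi_ret))),
      data = dat,
      start = list(delta = delta0, theta_dep = th_pairs$thd[i],
                   phi_dep = ph0, theta_ret = th_pairs$thr[i], phi_ret = ph0),
      lower = c(delta = 1e-6, theta_dep = min(t) - 50, phi_dep = 0.25,
                theta_ret = min(t), phi_ret = 0.25),
      upper = c(delta = Inf, theta_dep = max(t) + 50, phi_dep = 200,
                theta_ret = max(t) + 150, phi_ret = 200),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(f, "try-error")) next
    p <- stats::coef(f)
    if (p["theta_ret"] <= p["theta_dep"]) next   # return must follow departure
    rssf <- sum(stats::resid(f)^2)
    if (is.null(best) || rssf < best$rss) best <- list(fit = f, rss = rssf)
  }
  fits$migration <- if (is.null(best)) {
    failed_fit("migration")
  } else {
    p <- stats::coef(best$fit)
    structure(list(
      model_name = "migration", parameters = p,
      rss = best$rss, aicc = aicc(best$rss, 5), converged = TRUE,
      fitted_fun = local({ pp <- p; function(tt) {
        pp["delta"] * (1 / (1 + exp((pp["theta_dep"] - tt) / pp["phi_dep"])) -
                         1 / (1 + exp((pp["theta_ret"] - tt) / pp["phi_ret"])))
      } })
    ), class = "movement_model_fit")
  }

  ok <- vapply(fits, `[[`, logical(1), "converged")
  ord <- order(!ok, vapply(fits, function(f) {
    if (f$converged) f$aicc else Inf
  }, numeric(1)))
  fits[ord]
}

failed_fit <- function(name) {
  structure(list(model_name = name, parameters = NULL, rss = NA_real_,
                 aicc = Inf, converged = FALSE, fitted_fun = NULL),
            class = "movement_model_fit")
}

#' @export
print.movement_model_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<movement_model_fit> %s (failed to converge)\n", x$model_name))
  } else {
    cat(sprintf("<movement_model_fit> %s  AICc = %.1f\n", x$model_name, x$aicc))
    print(round(x$parameters, 3))
  }
  invisible(x)
}

#' Classify an animal-year from its NSD model fits
#'
#' Codifies the visual inspection of NSD graphs: the AICc-winning model
#' assigns the type, with decision rules for the shapes a single winner
#' cannot distinguish:
#' \itemize{
#'   \item dispersal winner with the fitted rise completed inside the series
#'     and a sustained terminal plateau: \emph{disperser}; if the series ends
#'     mid-rise (e.g. the animal was shot during the autumn hunt):
#'     \emph{other} (code `truncated_rise`); if NSD later falls back below a
#'     quarter of its peak: \emph{exploratory}.
#'   \item migration winner: out-and-back.  A dwell above half the asymptote
#'     shorter than `explore_dwell_days` is an exploration on a timescale of
#'     weeks, not a migration: \emph{exploratory}; otherwise \emph{migrant}.
#'   \item resident winner: \emph{resident}.
#'   \item nomadism winner, all-sigmoid failure, or a winning non-resident
#'     fit with pseudo-R^2 below `min_pseudo_r2}: \emph{other}.
#' }
#'
#' @param fits list from [fit_movement_models()]
#' @param nsd_profile the profile the fits were computed from
#' @param min_pseudo_r2 minimum 1 - RSS/TSS for a non-resident winner
#' @param return_frac NSD fraction of peak under which the animal counts as
#'   returned to its origin range
#' @param explore_dwell_days dwell threshold separating exploration from
#'   migration (days between the departure and return midpoints)
#' @param resident_scale_km2 fitted displacement scale (km^2) under which any
#'   winning model describes within-home-range wandering, hence residency
#'   (default 100 km^2, i.e. a 10-km displacement scale, far below any
#'   migration or dispersal in this system)
#' @return object of class `movement_classification`: `assigned_type`,
#'   `winning_fit`, `rationale` (character codes), `fits`
#' @export
classify <- function(fits, nsd_profile, min_pseudo_r2 = 0.5,
                     return_frac = 0.25, explore_dwell_days = 56,
                     resident_scale_km2 = 100) {
  t <- nsd_profile$elapsed_days
  y <- nsd_profile$nsd_km2
  tss <- sum((y - mean(y))^2)
  conv <- Filter(function(f) f$converged, fits)
  codes <- character(0)
  if (!length(conv)) {
    return(new_classification("other", NULL, "no_convergent_fit", fits))
  }
  win <- conv[[1]]
  if (win$model_name == "resident") {
    return(new_classification("resident", win, "resident_wins", fits))
  }
  # a "winning" sigmoid or drift whose fitted displacement never leaves the
  # home-range scale is still residency, whatever its shape
  fitted_scale <- max(win$fitted_fun(t))
  if (fitted_scale < resident_scale_km2) {
    return(new_classification("resident", win,
                              c("home_range_scale",
                                sprintf("fitted_max=%.0fkm2", fitted_scale)),
                              fits))
  }
  pr2 <- 1 - win$rss / tss
  if (pr2 < min_pseudo_r2) {
    return(new_classification("other", win, c("poor_fit",
      sprintf("pseudo_r2=%.2f", pr2)), fits))
  }
  type <- "other"
  if (win$model_name == "dispersal") {
    p <- win$parameters
    end_day <- p[["theta"]] + p[["phi"]] * log(39)   # 97.5% of asymptote
    peak <- max(y)
    tail_y <- y[t >= max(t) - 0.1 * diff(range(t))]
    if (end_day > max(t)) {
      type <- "other"; codes <- "truncated_rise"
    } else if (stats::median(tail_y) < return_frac * peak) {
      type <- "exploratory"; codes <- "dispersal_shape_with_return"
    } else {
      type <- "disperser"; codes <- "sigmoid_plateau"
    }
  } else if (win$model_name == "migration") {
    p <- win$parameters
    dwell <- p[["theta_ret"]] - p[["theta_dep"]]
    ret_end <- p[["theta_ret"]] + p[["phi_ret"]] * log(39)
    rise_end <- p[["theta_dep"]] + p[["phi_dep"]] * log(39)
    if (ret_end > max(t)) {
      # the return leg never happens inside the data: a one-way relocation
      if (rise_end > max(t)) {
        type <- "other"; codes <- "truncated_rise"
      } else {
        type <- "disperser"; codes <- "plateau_no_return"
      }
    } else if (dwell < explore_dwell_days) {
      type <- "exploratory"; codes <- sprintf("out_and_back_dwell=%.0fd", dwell)
    } else {
      type <- "migrant"; codes <- sprintf("out_and_back_dwell=%.0fd", dwell)
    }
  } else {
    type <- "other"; codes <- "nomadic_drift"
  }
  new_classification(type, win, codes, fits)
}

new_classification <- function(type, win, codes, fits) {
  structure(list(assigned_type = type, winning_fit = win,
                 rationale = codes, fits = fits),
            class = "movement_classification")
}

#' @export
print.movement_classification <- function(x, ...) {
  cat(sprintf("<movement_classification> %s (%s)\n", x$assigned_type,
              paste(x$rationale, collapse = ", ")))
  invisible(x)
}

#' Extract the dispersal event window
#'
#' Operationalises "steep NSD increase" / "NSD plateauing": the event starts
#' on the day the fitted sigmoid first exceeds 2.5% of its asymptote and ends
#' when it first exceeds 97.5% (`theta -+ phi * log(39)` for a logistic),
#' snapped to the nearest calendar day.  For exploratory animals the
#' departure sigmoid of the out-and-back fit bounds the outbound leg.  Any
#' small displacement followed by a month or more of stationary behaviour
#' before the main rise sits below the 2.5% threshold and is excluded by
#' construction.  The straight-line displacement is recomputed from the
#' actual first and last fixes inside the window.
#'
#' @param nsd_profile the animal's NSD profile
#' @param classification a [classify()] result of type disperser/exploratory
#' @return object of class `dispersal_event`: `start_day`, `end_day`
#'   (elapsed days, nearest day), `start_date`, `end_date`,
#'   `duration_days`, `straight_line_km`, `completed`
#' @export
extract_dispersal_event <- function(nsd_profile, classification) {
  type <- classification$assigned_type
  if (!type %in% c("disperser", "exploratory")) {
    stop("dispersal event extraction requires a disperser or exploratory animal",
         call. = FALSE)
  }
  win <- classification$winning_fit
  # for a completed (one-way) dispersal the single logistic is the event
  # model; use its converged fit even when an out-and-back fit with a
  # never-realised return limb edges it on AICc
  if (type == "disperser" && win$model_name != "dispersal") {
    alt <- classification$fits[["dispersal"]]
    if (!is.null(alt) && isTRUE(alt$converged)) win <- alt
  }
  p <- win$parameters
  t <- nsd_profile$elapsed_days
  if (win$model_name == "dispersal") {
    theta <- p[["theta"]]; phi <- p[["phi"]]
    start_day <- theta - phi * log(39)
    end_day <- theta + phi * log(39)
  } else if (win$model_name == "migration") {
    # out-and-back fits can inflate the shared asymptote; bound the rise by
    # the observed peak so the 2.5%/97.5% thresholds stay on the data scale
    theta <- p[["theta_dep"]]; phi <- p[["phi_dep"]]
    delta <- p[["delta"]]
    delta_eff <- min(delta, max(nsd_profile$nsd_km2))
    start_day <- theta - phi * log(delta / (0.025 * delta_eff) - 1)
    end_day <- theta - phi * log(pmax(delta / (0.975 * delta_eff) - 1, 1e-9))
  } else {
    stop("winning fit has no dispersal-shaped rise", call. = FALSE)
  }
  if (start_day < min(t) - 1 || end_day > max(t) + 1) {
    stop("dispersal not completed in series", call. = FALSE)
  }
  start_day <- round(start_day); end_day <- round(end_day)
  if (end_day <= start_day) end_day <- start_day + 1
  inside <- which(t >= start_day & t <= end_day)
  if (!length(inside)) stop("no fixes inside the dispersal window", call. = FALSE)
  i0 <- inside[1]; i1 <- inside[length(inside)]
  # displacement between the first and last fix of the window, from raw NSD
  # geometry: reconstruct via the profile's anchored coordinates
  sl_km <- straight_line_km(nsd_profile, i0, i1)
  anchor <- as.Date(nsd_profile$timestamp[1])
  structure(list(
    start_day = start_day, end_day = end_day,
    start_date = anchor + start_day, end_date = anchor + end_day,
    duration_days = end_day - start_day,
    straight_line_km = sl_km,
    completed = type == "disperser"
  ), class = "dispersal_event")
}

# straight-line km between fixes i0 and i1; uses raw coordinates when the
# profile carries them, otherwise the law of cosines on anchored NSD
straight_line_km <- function(nsd_profile, i0, i1) {
  if (all(c("x", "y") %in% names(nsd_profile))) {
    return(sqrt((nsd_profile$x[i1] - nsd_profile$x[i0])^2 +
                  (nsd_profile$y[i1] - nsd_profile$y[i0])^2) / 1000)
  }
  stop("profile lacks coordinates; attach x/y columns to compute displacement",
       call. = FALSE)
}

#' @export
print.dispersal_event <- function(x, ...) {
  cat(sprintf(
    "<dispersal_event> day %d to %d (%s to %s), %.1f km straight line, %s\n",
    x$start_day, x$end_day, format(x$start_date), format(x$end_date),
    x$straight_line_km,
    if (x$completed) "completed" else "exploratory"
  ))
  invisible(x)
}

#' Period windows around a dispersal event
#'
#' Four disjoint intervals: `before` and `after` span exactly `window_days`
#' (default 26, the average dispersal duration) immediately adjacent to the
#' event; `during` is the event itself; `rest_of_year` is everything else in
#' the animal-year.
#'
#' @param event a [extract_dispersal_event()] result
#' @param window_days width of the before/after windows in days
#' @return object of class `period_windows` with `Date` interval rows
#' @export
make_period_windows <- function(event, window_days = 26) {
  before <- c(event$start_date - window_days, event$start_date - 1)
  during <- c(event$start_date, event$end_date)
  after <- c(event$end_date + 1, event$end_date + window_days)
  structure(list(
    before = before, during = during, after = after,
    window_days = window_days
  ), class = "period_windows")
}

#' Assign a period label to timestamps
#' @param timestamps POSIXct vector
#' @param windows a [make_period_windows()] result (or NULL: everything is
#'   rest_of_year)
#' @return factor with levels rest_of_year, before, during, after
#' @export
assign_period <- function(timestamps, windows) {
  d <- as.Date(timestamps)
  lab <- rep("rest_of_year", length(d))
  if (!is.null(windows)) {
    lab[d >= windows$before[1] & d <= windows$before[2]] <- "before"
    lab[d >= windows$during[1] & d <= windows$during[2]] <- "during"
    lab[d >= windows$after[1] & d <= windows$after[2]] <- "after"
  }
  factor(lab, levels = c("rest_of_year", "before", "during", "after"))
}

#' Pair dispersers with residents covering the same timeframe
#'
#' Greedy matching: each disperser is paired with a distinct resident whose
#' data fully cover the disperser's four period windows, so the pair shares
#' the season (controlling seasonal effects on movement).  Unmatched
#' dispersers are reported.
#'
#' @param disperser_windows named list of [make_period_windows()] per
#'   disperser
#' @param resident_spans named list of `Date` length-2 vectors (first, last
#'   day of data) per resident
#' @return data.frame `disperser`, `resident` (NA when unmatched)
#' @export
match_residents <- function(disperser_windows, resident_spans) {
  used <- character(0)
  res <- data.frame(disperser = names(disperser_windows),
                    resident = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(disperser_windows)) {
    w <- disperser_windows[[i]]
    need <- c(w$before[1], w$after[2])
    for (r in setdiff(names(resident_spans), used)) {
      sp <- resident_spans[[r]]
      if (sp[1] <= need[1] && sp[2] >= need[2]) {
        res$resident[i] <- r
        used <- c(used, r)
        break
      }
    }
  }
  if (anyNA(res$resident)) {
    miss <- res$disperser[is.na(res$resident)]
    warning(sprintf("no coverage-complete resident for: %s",
                    paste(miss, collapse = ", ")), call. = FALSE)
  }
  res
}

#' Movement-type report (counts and percentages by sex)
#'
#' Tabulates assigned movement types by sex and adds integer percentages of
#' the total, plus dispersal-rate percentages among males (share with any
#' dispersal period, share completing, share exploratory), reproducing the
#' arithmetic of a classification summary table.
#'
#' @param truth_or_class data.frame with columns `animal_id`, `sex` and
#'   either `assigned_type` or `mode`
#' @return list with `type_table` (counts by sex, totals, integer
#'   percentages) and `male_dispersal` (percentages among males)
#' @export
classification_report <- function(truth_or_class) {
  df <- truth_or_class
  type <- if ("assigned_type" %in% names(df)) df$assigned_type else df$mode
  # dispersal events are tallied separately; dispersing animals without a
  # post-settlement year fall under other/not classified for the type rows
  main <- ifelse(type %in% c("disperser", "exploratory"), "other", type)
  main <- factor(main, levels = c("migrant", "resident", "other"))
  tab <- table(main, factor(df$sex, levels = c("M", "F")))
  total <- rowSums(tab)
  pct <- round(100 * total / sum(total))
  n_male <- sum(df$sex == "M")
  disp_m <- sum(df$sex == "M" & type %in% c("disperser", "exploratory"))
  comp_m <- sum(df$sex == "M" & type == "disperser")
  expl_m <- sum(df$sex == "M" & type == "exploratory")
  list(
    type_table = data.frame(
      type = rownames(tab), male = tab[, "M"], female = tab[, "F"],
      total = total, percentage = pct, row.names = NULL
    ),
    male_dispersal = c(
      pct_dispersing = round(100 * disp_m / n_male),
      pct_completing = round(100 * comp_m / n_male),
      pct_exploratory = round(100 * expl_m / n_male)
    )
  )
}

#' Percentage arithmetic for a classification tally
#'
#' Integer percentages (nearest whole percent) of counts over a total, the
#' presentation rule used by classification summary tables.
#'
#' @param counts named numeric vector of counts
#' @param total denominator (default `sum(counts)`)
#' @return named numeric vector of rounded percentages
#' @export
tally_percentages <- function(counts, total = sum(counts)) {
  round(100 * counts / total)
}
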