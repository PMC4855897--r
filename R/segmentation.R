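#' Mixed-model comparison of movement rates across dispersal periods
#'
#' Linear mixed model of step movement rate (m/h) on the period factor
#' (rest-of-year reference; before / during / after the dispersal event) with
#' a per-animal random intercept, fitted by REML.  Significance between
#' periods follows the 95% CI overlap rule: two periods differ when their
#' Wald 95% confidence intervals do not overlap.
#'
#' @param steps data.frame of steps (from [build_steps()], any regularity)
#'   with columns `animal_id`, `t_start`, `rate_m_hr`
#' @param windows_by_animal named list of [make_period_windows()] per animal
#'   (a disperser's own windows, or the matched disperser's windows for a
#'   resident)
#' @return object of class `rate_period_model`: `coefficients` (period
#'   offsets in m/h with SE and 95% CI; reference row is exactly 0),
#'   `overlap` (logical matrix of pairwise CI overlap), `n_steps` per period,
#'   `model` (the lme4 fit)
#' @export
fit_rate_period_model <- function(steps, windows_by_animal) {
  per <- assign_period(steps$t_start,
                       windows = NULL)  # placeholder; filled per animal below
  per <- unlist(lapply(split(seq_len(nrow(steps)), steps$animal_id), function(i) {
    w <- windows_by_animal[[steps$animal_id[i[1]]]]
    as.character(assign_period(steps$t_start[i], w))
  }), use.names = FALSE)
  ord <- order(steps$animal_id)   # split() regroups by animal; restore rows
  dat <- steps[ord, , drop = FALSE]
  dat$period <- factor(per, levels = c("rest_of_year", "before", "during", "after"))
  counts <- table(dat$period)
  if (any(counts == 0)) {
    stop(sprintf("no steps in period(s): %s",
                 paste(names(counts)[counts == 0], collapse = ", ")),
         call. = FALSE)
  }
  fit <- lme4::lmer(rate_m_hr ~ period + (1 | animal_id), data = dat, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  periods <- c("rest_of_year", "before", "during", "after")
  beta <- c(0, fe[paste0("period", periods[-1])])
  sev <- c(0, se[paste0("period", periods[-1])])
  co <- data.frame(
    period = periods, beta = unname(beta), se = unname(sev),
    ci_lo = unname(beta - 1.96 * sev), ci_hi = unname(beta + 1.96 * sev)
  )
  ov <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
    co$ci_lo[i] <= co$ci_hi[j] && co$ci_lo[j] <= co$ci_hi[i]
  }))
  dimnames(ov) <- list(periods, periods)
  structure(list(
    coefficients = co, overlap = ov,
    n_steps = as.vector(counts), model = fit,
    ranef_var = as.data.frame(lme4::VarCorr(fit))$vcov[1]
  ), class = "rate_period_model")
}

#' @export
print.rate_period_model <- function(x, ...) {
  cat("<rate_period_model> movement rate (m/h) by period, rest-of-year reference\n")
  print(transform(x$coefficients, beta = round(beta, 1),
                  se = round(se, 2), ci_lo = round(ci_lo, 1),
                  ci_hi = round(ci_hi, 1)))
  invisible(x)
}

#' Segmented (broken-stick) regression of the log-binned rate distribution
#'
#' Bins movement rates (m/min), takes the natural log of each occupied bin's
#' frequency, and fits a continuous two-segment line to (bin midpoint,
#' log frequency) by Muggeo-style iterative linearisation with a grid-search
#' fallback.  The breakpoint `psi` separates the short (foraging/resting) and
#' long (travelling) movement regimes; its SE comes from the final linear
#' fit by the delta method.  A single-line null model is fitted alongside;
#' when no interior breakpoint improves on the null beyond the convergence
#' tolerance the null is returned with `breakpoint_found = FALSE`.
#'
#' @param rates_m_per_min numeric vector of movement rates (m/min)
#' @param bin_width histogram bin width in m/min
#' @param tol relative RSS improvement under which the null wins
#' @return object of class `segmented_fit`: `psi`, `psi_se`, `intercept`,
#'   `slope_left`, `slope_right`, `r2_segmented`, `r2_null`,
#'   `breakpoint_found`, `bins` (the binned table)
#' @export
fit_segmented <- function(rates_m_per_min, bin_width = 0.5, tol = 1e-6) {
  br <- seq(0, max(rates_m_per_min) + bin_width, by = bin_width)
  cnt <- graphics::hist(rates_m_per_min, breaks = br, plot = FALSE)$counts
  keep <- cnt > 0
  x <- (br[-length(br)] + bin_width / 2)[keep]
  y <- log(cnt[keep])
  bins <- data.frame(rate_mid = x, count = cnt[keep], log_freq = y)
  if (length(x) < 5) stop("too few occupied bins for segmented regression",
                          call. = FALSE)
  null_fit <- stats::lm(y ~ x)
  rss_null <- sum(stats::resid(null_fit)^2)
  tss <- sum((y - mean(y))^2)

  seg_rss <- function(psi) {
    u <- pmax(x - psi, 0)
    sum(stats::resid(stats::lm(y ~ x + u))^2)
  }
  # admissible interior breakpoints: at least 2 occupied bins on each side,
  # and at least max(5, 1% of n) observations on each side -- a behavioural
  # breakpoint separates two populated movement classes, so a handful of
  # straggler steps in the far tail cannot anchor it
  xo <- sort(unique(x))
  n_obs <- sum(bins$count)
  min_tail <- max(5, ceiling(0.01 * n_obs))
  cnt_below <- cumsum(bins$count)
  ok_tail <- cnt_below >= min_tail & (n_obs - cnt_below) >= min_tail
  lo <- max(xo[2], if (any(ok_tail)) min(x[ok_tail]) else Inf)
  hi <- min(xo[length(xo) - 1], if (any(ok_tail)) max(x[ok_tail]) else -Inf)
  if (hi <= lo) stop("no admissible interior breakpoint", call. = FALSE)

  # Muggeo iteration from the median, then grid fallback
  linearise <- function(psi0) {
    for (it in 1:50) {
      u <- pmax(x - psi0, 0)
      w <- as.numeric(x > psi0)
      f <- stats::lm(y ~ x + u + w)
      cf <- stats::coef(f)
      if (anyNA(cf)) return(NULL)
      step <- -cf[["w"]] / cf[["u"]]
      psi1 <- psi0 + step
      if (!is.finite(psi1)) return(NULL)
      psi1 <- min(max(psi1, lo), hi)
      if (abs(psi1 - psi0) < 1e-8) { psi0 <- psi1; break }
      psi0 <- psi1
    }
    psi0
  }
  grid <- seq(lo, hi, length.out = 60)
  grid_best <- grid[which.min(vapply(grid, seg_rss, numeric(1)))]
  cand <- c(linearise(stats::median(x)), linearise(grid_best), grid_best)
  # boundary solutions are not breakpoints; keep interior candidates only
  cand <- unique(cand[is.finite(cand) & cand > lo & cand < hi])
  if (length(cand)) {
    psi_hat <- cand[which.min(vapply(cand, seg_rss, numeric(1)))]
    rss_seg <- seg_rss(psi_hat)
    improvement <- (rss_null - rss_seg) / max(rss_null, .Machine$double.eps)
    found <- improvement > tol
  } else {
    psi_hat <- NA_real_
    found <- FALSE
  }

  if (!found) {
    cf <- stats::coef(null_fit)
    return(structure(list(
      psi = NA_real_, psi_se = NA_real_,
      intercept = cf[[1]], slope_left = cf[[2]], slope_right = cf[[2]],
      r2_segmented = 1 - rss_null / tss, r2_null = 1 - rss_null / tss,
      breakpoint_found = FALSE, bins = bins
    ), class = "segmented_fit"))
  }

  u <- pmax(x - psi_hat, 0)
  w <- as.numeric(x > psi_hat)
  f <- stats::lm(y ~ x + u + w)
  cf <- stats::coef(f)
  # summary() warns on an exactly-interpolating fit; the SE is still the
  # right delta-method quantity (zero in that case)
  vc <- suppressWarnings(stats::vcov(f))
  # at convergence gamma ~ 0: SE(psi) = SE(gamma) / |slope difference|
  psi_se <- sqrt(vc["w", "w"]) / abs(cf[["u"]])
  final <- stats::lm(y ~ x + u)
  cff <- stats::coef(final)
  structure(list(
    psi = psi_hat, psi_se = psi_se,
    intercept = cff[[1]], slope_left = cff[["x"]],
    slope_right = cff[["x"]] + cff[["u"]],
    r2_segmented = 1 - rss_seg / tss,
    r2_null = 1 - rss_null / tss,
    breakpoint_found = TRUE, bins = bins
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  if (x$breakpoint_found) {
    cat(sprintf(
      "<segmented_fit> psi = %.3f m/min (SE %.3f), slopes %.3f / %.3f, r2 %.3f (null %.3f)\n",
      x$psi, x$psi_se, x$slope_left, x$slope_right, x$r2_segmented, x$r2_null))
  } else {
    cat(sprintf("<segmented_fit> no breakpoint; single line r2 = %.3f\n", x$r2_null))
  }
  invisible(x)
}

#' Split steps into short and long behavioural classes
#'
#' The breakpoint rate times the nominal interval gives a step-length
#' threshold (rounded to the nearest metre; e.g. 7.118 m/min over 120 min is
#' 854 m).  Regular steps below it form the short (foraging/resting) class;
#' steps at or above it the long (travelling) class.  Per-class turn-angle
#' histograms (10-degree bins) are attached for directionality comparison.
#'
#' @param steps data.frame of regular steps with `length_m` and
#'   `turning_angle_deg`
#' @param psi breakpoint movement rate, m/min
#' @param interval_min nominal step duration, minutes
#' @return list: `short`, `long` (step subsets), `threshold_m`,
#'   `turn_hist` (data.frame of per-class 10-degree bin counts)
#' @export
split_steps <- function(steps, psi, interval_min = 120) {
  threshold_m <- round(psi * interval_min)
  short <- steps[steps$length_m < threshold_m, , drop = FALSE]
  long <- steps[steps$length_m >= threshold_m, , drop = FALSE]
  brks <- seq(-180, 180, by = 10)
  hist_of <- function(s) {
    a <- s$turning_angle_deg
    a <- a[is.finite(a)]
    graphics::hist(a, breaks = brks, plot = FALSE)$counts
  }
  turn_hist <- data.frame(
    bin_lo = brks[-length(brks)], bin_hi = brks[-1],
    short = hist_of(short), long = hist_of(long)
  )
  list(short = short, long = long, threshold_m = threshold_m,
       turn_hist = turn_hist)
}

#' Circular standard deviation of angles
#'
#' Mardia's circular SD `sqrt(-2 log Rbar)` in degrees; used to compare the
#' directionality of turn-angle distributions between step classes.
#'
#' @param angles_deg angles in degrees
#' @return circular SD in degrees
#' @export
circular_sd_deg <- function(angles_deg) {
  a <- angles_deg[is.finite(angles_deg)] * pi / 180
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  sqrt(-2 * log(rbar)) * 180 / pi
}
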