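#' Leave-one-individual-out empirical step kernel
#'
#' Step-length (50-m bins) and turn-angle (10-degree bins) probability masses
#' built from the regular steps of every animal except the focal one, so an
#' individual's availability sample never reuses its own movements.  Length
#' and angle are drawn independently (their observed correlation is low in
#' ungulate steps).
#'
#' @param steps_by_animal named list of step data.frames (from
#'   [build_steps()]); regular steps with finite turn angles are used
#' @param focal_animal name of the animal to exclude
#' @param len_bin,turn_bin bin widths (m, degrees)
#' @return object of class `step_kernel`: `length` and `turn` data.frames
#'   (`lo`, `hi`, `mass`) and `source_animal_ids`
#' @export
build_kernels <- function(steps_by_animal, focal_animal,
                          len_bin = 50, turn_bin = 10) {
  others <- setdiff(names(steps_by_animal), focal_animal)
  if (length(others) < 1) {
    stop("leave-one-out kernel needs at least 2 animals", call. = FALSE)
  }
  pool <- do.call(rbind, steps_by_animal[others])
  pool <- pool[pool$regular & is.finite(pool$turning_angle_deg), , drop = FALSE]
  if (nrow(pool) == 0) stop("no regular steps available for the kernel",
                            call. = FALSE)
  lbr <- seq(0, max(pool$length_m) + len_bin, by = len_bin)
  lcnt <- graphics::hist(pool$length_m, breaks = lbr, plot = FALSE)$counts
  keep <- lcnt > 0
  len_tab <- data.frame(lo = lbr[-length(lbr)][keep], hi = lbr[-1][keep],
                        mass = lcnt[keep] / sum(lcnt))
  tbr <- seq(-180, 180, by = turn_bin)
  tcnt <- graphics::hist(pool$turning_angle_deg, breaks = tbr,
                         plot = FALSE)$counts
  keep <- tcnt > 0
  turn_tab <- data.frame(lo = tbr[-length(tbr)][keep], hi = tbr[-1][keep],
                         mass = tcnt[keep] / sum(tcnt))
  structure(list(length = len_tab, turn = turn_tab,
                 source_animal_ids = others),
            class = "step_kernel")
}

# draw n values from a binned mass table, uniform within the half-open bin
draw_from_bins <- function(tab, n) {
  i <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$mass)
  stats::runif(n, tab$lo[i], tab$hi[i])
}

#' Draw random (available) steps for one observed step
#'
#' Each random step shares the observed step's start point and prior
#' heading: a length bin and a turn bin are drawn by kernel mass, the value
#' uniformly within the bin, and the endpoint placed at
#' `start + length * (cos, sin)(prior_heading + turn)`.  Endpoints falling
#' outside the landscape extent are redrawn (up to `max_attempts`).
#'
#' @param x0,y0 start coordinates of the observed step (metres)
#' @param prior_heading_deg heading of the preceding step, degrees
#' @param kernel a [build_kernels()] result
#' @param n number of random steps
#' @param extent named vector (xmin, xmax, ymin, ymax) or NULL for unbounded
#' @param max_attempts redraw budget per batch
#' @return data.frame `x1`, `y1`, `length_m`, `turn_deg`
#' @export
draw_random_steps <- function(x0, y0, prior_heading_deg, kernel, n = 10,
                              extent = NULL, max_attempts = 100) {
  need <- n
  out <- matrix(NA_real_, n, 4)
  filled <- 0
  for (attempt in seq_len(max_attempts)) {
    len <- draw_from_bins(kernel$length, need)
    trn <- draw_from_bins(kernel$turn, need)
    hd <- (prior_heading_deg + trn) * pi / 180
    x1 <- x0 + len * cos(hd)
    y1 <- y0 + len * sin(hd)
    ok <- if (is.null(extent)) rep(TRUE, need) else {
      x1 >= extent["xmin"] & x1 < extent["xmax"] &
        y1 >= extent["ymin"] & y1 < extent["ymax"]
    }
    k <- sum(ok)
    if (k > 0) {
      rows <- filled + seq_len(k)
      out[rows, ] <- cbind(x1[ok], y1[ok], len[ok], trn[ok])
      filled <- filled + k
      need <- n - filled
    }
    if (need == 0) break
  }
  if (need > 0) {
    stop("could not place random steps inside the extent", call. = FALSE)
  }
  data.frame(x1 = out[, 1], y1 = out[, 2], length_m = out[, 3],
             turn_deg = out[, 4])
}

#' Build matched used/available strata for a set of animals
#'
#' For every regular observed step with a defined prior heading, a stratum of
#' the observed step plus `n_random` kernel-drawn available steps is built,
#' and raw covariates are attached at all step endpoints (NDVI month from
#' the step's end timestamp).
#'
#' @param steps_by_animal named list of step data.frames
#' @param landscape a `landscape_stack`
#' @param n_random available steps per stratum
#' @param seed integer seed for the availability draws
#' @return data.frame: `animal_id`, `stratum_id`, `case`, `x`, `y`,
#'   `timestamp`, `obs_length_m` (the stratum's observed step length, for
#'   long/short splitting), raw covariates (`ruggedness`, `ndvi`,
#'   `dist_roads`, `canopy`)
#' @export
build_strata <- function(steps_by_animal, landscape, n_random = 10, seed = 1L) {
  set.seed(as.integer(seed))
  ext <- landscape$extent
  rows <- list()
  for (a in names(steps_by_animal)) {
    st <- steps_by_animal[[a]]
    usable <- which(st$regular & is.finite(st$turning_angle_deg))
    if (!length(usable)) next
    kern <- build_kernels(steps_by_animal, a)
    prior_heading <- st$heading_deg - st$turning_angle_deg
    for (i in usable) {
      rnd <- draw_random_steps(st$x0[i], st$y0[i], prior_heading[i], kern,
                               n = n_random, extent = ext)
      sid <- sprintf("%s_%05d", a, i)
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = a, stratum_id = sid,
        case = c(1L, rep(0L, n_random)),
        x = c(st$x1[i], rnd$x1), y = c(st$y1[i], rnd$y1),
        timestamp = st$t_end[i],
        obs_length_m = st$length_m[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no usable strata", call. = FALSE)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  attach_covariates(df, landscape)
}

#' Conditional logistic regression by Newton-Raphson
#'
#' Maximises the stratified (matched used/available) conditional
#' log-likelihood `sum_s log( exp(b'x_obs) / sum_j exp(b'x_j) )` with exact
#' gradient and observed information, step-halving on any likelihood
#' decrease.  This is the estimator behind the exponential step selection
#' function `w(x) = exp(b'x)`.  Complete separation (the likelihood
#' increasing without bound) is detected and flagged; such coefficients are
#' reported with infinite SEs rather than silently returned.
#'
#' @param X numeric design matrix (rows = steps, cols = covariates)
#' @param case 0/1 vector, exactly one 1 per stratum
#' @param strata stratum identifier per row
#' @param max_iter,tol Newton controls
#' @return object of class `ssf_fit`: `coef`, `se`, `vcov`, `loglik`,
#'   `converged`, `separation`, `n_strata`, `iterations`
#' @export
fit_conditional_logistic <- function(X, case, strata, max_iter = 60,
                                     tol = 1e-9) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  sid <- as.integer(factor(strata))
  p <- ncol(X)
  stopifnot(length(case) == nrow(X), length(sid) == nrow(X))
  if (any(tapply(case, sid, sum) != 1)) {
    stop("each stratum must contain exactly one observed (case) step",
         call. = FALSE)
  }
  beta <- rep(0, p)
  x_obs_sum <- colSums(X[case == 1, , drop = FALSE])

  loglik_parts <- function(beta) {
    eta <- as.vector(X %*% beta)
    mx <- as.vector(tapply(eta, sid, max))
    w <- exp(eta - mx[sid])
    denom <- rowsum(w, sid)[, 1]
    pr <- as.vector(w / denom[sid])
    ll <- sum(eta[case == 1]) - sum(log(denom) + mx)
    list(ll = ll, pr = pr)
  }
  lp <- loglik_parts(beta)
  separation <- FALSE
  iterations <- 0
  for (it in seq_len(max_iter)) {
    iterations <- it
    pr <- lp$pr
    G <- x_obs_sum - colSums(pr * X)
    A <- crossprod(X, pr * X)
    M <- rowsum(pr * X, sid)
    H <- A - crossprod(M)               # observed information
    step <- tryCatch(solve(H, G), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    # step halving
    new_beta <- beta + step
    lp_new <- loglik_parts(new_beta)
    halvings <- 0
    while (lp_new$ll < lp$ll - 1e-12 && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      lp_new <- loglik_parts(new_beta)
      halvings <- halvings + 1
    }
    delta_ll <- lp_new$ll - lp$ll
    beta <- new_beta; lp <- lp_new
    if (max(abs(beta)) > 15) { separation <- TRUE; break }
    if (abs(delta_ll) < tol && sqrt(sum(G^2)) < 1e-5) break
  }
  pr <- lp$pr
  A <- crossprod(X, pr * X)
  M <- rowsum(pr * X, sid)
  H <- A - crossprod(M)
  vc <- tryCatch(solve(H), error = function(e) matrix(Inf, p, p))
  if (separation || any(!is.finite(vc))) {
    vc <- matrix(Inf, p, p)
  }
  se <- sqrt(pmax(diag(vc), 0))
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    coef = beta, se = se, vcov = vc, loglik = lp$ll,
    converged = !separation && iterations < max_iter,
    separation = separation,
    n_strata = max(sid), iterations = iterations
  ), class = "ssf_fit")
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("<ssf_fit> %d strata, loglik %.3f%s\n", x$n_strata, x$loglik,
              if (x$separation) " [SEPARATION]" else ""))
  print(round(rbind(coef = x$coef, se = x$se), 4))
  invisible(x)
}

#' Two-stage population pooling of per-individual SSF coefficients
#'
#' Per coefficient, a random-effects combination of the individual estimates:
#' the population mean and its SE are estimated by restricted maximum
#' likelihood with a between-individual variance component (normal
#' approximation to the per-individual likelihoods).  A coefficient is
#' flagged `strong` when it exceeds twice its pooled SE in magnitude.
#' Individuals whose fits are non-convergent or separated are excluded with a
#' report.
#'
#' @param fits named list of [fit_conditional_logistic()] results (one per
#'   individual)
#' @return object of class `pooled_ssf`: `table` (coef, pooled beta, se,
#'   between-individual SD tau, strong flag, n individuals), `excluded`,
#'   `individual` (matrix of per-individual coefficients)
#' @export
pool_two_stage <- function(fits) {
  ok <- vapply(fits, function(f) f$converged && !f$separation &&
                 all(is.finite(f$se)), logical(1))
  excluded <- names(fits)[!ok]
  fits <- fits[ok]
  if (length(fits) < 2) {
    stop("two-stage pooling needs at least 2 usable individual fits",
         call. = FALSE)
  }
  cn <- names(fits[[1]]$coef)
  B <- matrix(unlist(lapply(fits, `[[`, "coef")), ncol = length(cn),
              byrow = TRUE, dimnames = list(names(fits), cn))
  S <- matrix(unlist(lapply(fits, `[[`, "se")), ncol = length(cn),
              byrow = TRUE, dimnames = list(names(fits), cn))
  tab <- do.call(rbind, lapply(seq_along(cn), function(j) {
    rm <- suppressWarnings(
      metafor::rma.uni(yi = B[, j], sei = S[, j], method = "REML",
                       control = list(maxiter = 500))
    )
    data.frame(
      coef = cn[j], beta = as.numeric(rm$beta), se = rm$se,
      tau = sqrt(rm$tau2), n = nrow(B),
      strong = abs(as.numeric(rm$beta)) > 2 * rm$se
    )
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, excluded = excluded, individual = B,
                 individual_se = S),
            class = "pooled_ssf")
}

#' @export
print.pooled_ssf <- function(x, ...) {
  cat(sprintf("<pooled_ssf> %d individuals pooled (%d excluded)\n",
              x$table$n[1], length(x$excluded)))
  print(transform(x$table, beta = round(beta, 3), se = round(se, 3),
                  tau = round(tau, 3)))
  invisible(x)
}

#' k-fold cross-validation of an SSF
#'
#' Strata are shuffled into `k` folds; for each fold the model is refitted
#' on the remainder and the held-out steps scored with `w(x) = exp(b'x)`.
#' Scores are cut into `n_bins` quantile bins and the Spearman correlation
#' between bin rank and the count of *observed* steps per bin measures
#' whether high-score habitat is where the animals actually stepped.  The
#' chance distribution comes from re-labelling one random step per stratum
#' as "observed" (`n_perm` permutations).  The model is declared useful when
#' the mean observed r_S exceeds `rs_threshold` and the null's 95th
#' percentile.
#'
#' @param X,case,strata as in [fit_conditional_logistic()]
#' @param k number of folds
#' @param n_bins quantile bins for the scores
#' @param n_perm within-stratum label permutations for the null
#' @param rs_threshold usefulness bar on mean r_S
#' @param seed integer seed (fold shuffle + permutations)
#' @return object of class `ssf_validation`: `fold_rs`, `mean_rs`,
#'   `null_rs`, `null_q95`, `useful`
#' @export
kfold_validate <- function(X, case, strata, k = 5, n_bins = 10, n_perm = 200,
                           rs_threshold = 0.65, seed = 1L) {
  set.seed(as.integer(seed))
  X <- as.matrix(X)
  ids <- unique(strata)
  if (k > length(ids)) stop("more folds than strata", call. = FALSE)
  fold_of <- sample(rep(seq_len(k), length.out = length(ids)))
  names(fold_of) <- ids
  fold_rs <- numeric(k)
  null_rs <- numeric(0)
  for (f in seq_len(k)) {
    hold <- strata %in% ids[fold_of[ids] == f]
    fit <- fit_conditional_logistic(X[!hold, , drop = FALSE], case[!hold],
                                    strata[!hold])
    sc <- as.vector(X[hold, , drop = FALSE] %*% fit$coef)
    hold_strata <- strata[hold]
    hold_case <- case[hold]
    qs <- stats::quantile(sc, probs = seq(0, 1, length.out = n_bins + 1))
    qs <- unique(qs)
    if (length(qs) - 1 < 2) {
      # near-constant scores: quantiles collapse; bin by distinct values
      vals <- sort(unique(sc))
      qs <- c(vals[1], (vals[-1] + vals[-length(vals)]) / 2,
              vals[length(vals)])
      qs <- unique(qs)
    }
    bin <- cut(sc, breaks = qs, include.lowest = TRUE, labels = FALSE)
    nb <- length(qs) - 1
    obs_count <- tabulate(bin[hold_case == 1], nbins = nb)
    fold_rs[f] <- suppressWarnings(
      stats::cor(seq_len(nb), obs_count, method = "spearman"))
    # chance: a uniformly chosen member of each stratum is the "observed"
    sizes <- as.numeric(table(hold_strata)[unique(hold_strata)])
    start_of <- c(0, cumsum(sizes))[seq_along(sizes)]
    ord <- order(match(hold_strata, unique(hold_strata)))
    bin_ord <- bin[ord]
    for (pp in seq_len(n_perm)) {
      pick <- start_of + ceiling(stats::runif(length(sizes)) * sizes)
      cnt <- tabulate(bin_ord[pick], nbins = nb)
      null_rs <- c(null_rs, suppressWarnings(
        stats::cor(seq_len(nb), cnt, method = "spearman")))
    }
  }
  mean_rs <- mean(fold_rs, na.rm = TRUE)
  null_rs <- null_rs[is.finite(null_rs)]
  q95 <- stats::quantile(null_rs, 0.95, names = FALSE)
  structure(list(
    fold_rs = fold_rs, mean_rs = mean_rs, null_rs = null_rs,
    null_q95 = q95,
    useful = is.finite(mean_rs) && mean_rs > rs_threshold && mean_rs > q95
  ), class = "ssf_validation")
}

#' @export
print.ssf_validation <- function(x, ...) {
  cat(sprintf("<ssf_validation> mean r_S = %.3f (null q95 = %.3f): %s\n",
              x$mean_rs, x$null_q95,
              if (x$useful) "useful" else "not useful"))
  invisible(x)
}

#' Fit the eight-model SSF suite
#'
#' Fits the full battery with one shared covariate structure (ruggedness +
#' squared, NDVI, distance to roads, canopy + squared): dispersers and
#' matched residents in the before / during / after windows, plus the
#' during-dispersal strata split into long and short observed steps at the
#' segmented-regression threshold.  Each model is scaled on its own data,
#' fitted per individual, pooled in two stages and cross-validated.  Models
#' with fewer than two usable individuals are reported not-estimable and the
#' suite continues.
#'
#' @param strata_by_model named list of stratum data.frames (raw covariates,
#'   as from [build_strata()]); names become model ids
#' @param k,n_perm,seed validation controls (see [kfold_validate()])
#' @param min_strata_per_animal individuals contributing fewer strata are
#'   dropped from that model
#' @return object of class `ssf_suite`: `models` (per-model list with
#'   `pooled`, `validation`, `screen`, or `reason` when not estimable) and
#'   `table` (coefficient table across models with the 2-SE strong flag)
#' @export
run_model_suite <- function(strata_by_model, k = 5, n_perm = 200, seed = 1L,
                            min_strata_per_animal = 20) {
  model_cols <- c("ruggedness", "ruggedness_sq", "ndvi", "dist_roads",
                  "canopy", "canopy_sq")
  models <- list()
  for (mid in names(strata_by_model)) {
    df <- strata_by_model[[mid]]
    if (is.null(df) || !nrow(df)) {
      models[[mid]] <- list(estimable = FALSE, reason = "no strata")
      next
    }
    sc <- try(scale_and_screen(df), silent = TRUE)
    if (inherits(sc, "try-error")) {
      models[[mid]] <- list(estimable = FALSE,
                            reason = "degenerate covariates")
      next
    }
    d <- sc$scaled
    per_animal <- split(d, d$animal_id)
    per_animal <- per_animal[vapply(per_animal, function(x) {
      length(unique(x$stratum_id)) >= min_strata_per_animal
    }, logical(1))]
    if (length(per_animal) < 2) {
      models[[mid]] <- list(estimable = FALSE,
                            reason = "fewer than 2 usable individuals")
      next
    }
    fits <- lapply(per_animal, function(x) {
      fit_conditional_logistic(as.matrix(x[model_cols]), x$case, x$stratum_id)
    })
    pooled <- try(pool_two_stage(fits), silent = TRUE)
    if (inherits(pooled, "try-error")) {
      models[[mid]] <- list(estimable = FALSE, reason = "pooling failed")
      next
    }
    dd <- do.call(rbind, per_animal)
    val <- kfold_validate(as.matrix(dd[model_cols]), dd$case, dd$stratum_id,
                          k = k, n_perm = n_perm, seed = seed)
    models[[mid]] <- list(estimable = TRUE, pooled = pooled, validation = val,
                          screen = sc$screen, n_individuals = length(fits))
  }
  tabs <- lapply(names(models), function(mid) {
    m <- models[[mid]]
    if (!isTRUE(m$estimable)) return(NULL)
    cbind(model = mid, m$pooled$table)
  })
  structure(list(models = models, table = do.call(rbind, tabs)),
            class = "ssf_suite")
}

#' @export
print.ssf_suite <- function(x, ...) {
  est <- vapply(x$models, function(m) isTRUE(m$estimable), logical(1))
  cat(sprintf("<ssf_suite> %d/%d models estimable\n", sum(est), length(est)))
  if (!is.null(x$table)) {
    print(transform(x$table, beta = round(beta, 3), se = round(se, 3),
                    tau = round(tau, 3)))
  }
  invisible(x)
}
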