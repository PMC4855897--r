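#' Correlated-random-walk null paths for a dispersal route
#'
#' Builds the whole-route null set: `n_paths` correlated random walks with
#' as many steps as the individual's observed long movement steps, drawing
#' step lengths and turn angles from that individual's own long-step
#' histograms (50-m / 10-degree bins, uniform within bin), sharing the
#' observed start point and initial heading.  Paths are kept inside the
#' landscape extent by redrawing any step whose endpoint would leave it.
#'
#' @param observed_long_steps the individual's long steps during dispersal
#'   (data.frame from [build_steps()], already filtered to the long class);
#'   at least 5 are required
#' @param n_paths number of null paths
#' @param extent named vector (xmin, xmax, ymin, ymax) or NULL
#' @param seed integer seed
#' @param max_attempts redraw budget per step
#' @return object of class `crw_null_set`: `paths` (list of (n+1)-point
#'   coordinate data.frames), `observed` (endpoint coordinates of the
#'   observed long steps with timestamps), `start`, `init_heading_deg`
#' @export
simulate_crw <- function(observed_long_steps, n_paths = 10, extent = NULL,
                         seed = 1L, max_attempts = 100) {
  st <- observed_long_steps
  if (nrow(st) < 5) {
    stop("fewer than 5 observed long steps; individual excluded from the broad-scale test",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  lbr <- seq(0, max(st$length_m) + 50, by = 50)
  lcnt <- graphics::hist(st$length_m, breaks = lbr, plot = FALSE)$counts
  keep <- lcnt > 0
  len_tab <- data.frame(lo = lbr[-length(lbr)][keep], hi = lbr[-1][keep],
                        mass = lcnt[keep] / sum(lcnt))
  ta <- st$turning_angle_deg[is.finite(st$turning_angle_deg)]
  tbr <- seq(-180, 180, by = 10)
  tcnt <- graphics::hist(ta, breaks = tbr, plot = FALSE)$counts
  keep <- tcnt > 0
  turn_tab <- data.frame(lo = tbr[-length(tbr)][keep], hi = tbr[-1][keep],
                         mass = tcnt[keep] / sum(tcnt))
  n_steps <- nrow(st)
  start <- c(st$x0[1], st$y0[1])
  init_heading <- st$heading_deg[1]
  paths <- vector("list", n_paths)
  for (p in seq_len(n_paths)) {
    xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
    xs[1] <- start[1]; ys[1] <- start[2]
    heading <- init_heading
    for (i in seq_len(n_steps)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        len <- draw_from_bins(len_tab, 1)
        trn <- draw_from_bins(turn_tab, 1)
        hd <- heading + trn
        x1 <- xs[i] + len * cos(hd * pi / 180)
        y1 <- ys[i] + len * sin(hd * pi / 180)
        if (is.null(extent) ||
            (x1 >= extent["xmin"] && x1 < extent["xmax"] &&
             y1 >= extent["ymin"] && y1 < extent["ymax"])) {
          xs[i + 1] <- x1; ys[i + 1] <- y1; heading <- hd
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("CRW path could not stay inside the extent",
                        call. = FALSE)
    }
    paths[[p]] <- data.frame(x = xs, y = ys)
  }
  structure(list(
    paths = paths,
    observed = data.frame(x = st$x1, y = st$y1, timestamp = st$t_end),
    start = start, init_heading_deg = init_heading,
    n_steps = n_steps
  ), class = "crw_null_set")
}

#' @export
print.crw_null_set <- function(x, ...) {
  cat(sprintf("<crw_null_set> %d null paths of %d steps\n",
              length(x$paths), x$n_steps))
  invisible(x)
}

#' Observed-vs-null binomial comparison of one dispersal route
#'
#' Labels the observed long-step endpoints 1 and the null-path vertices 0,
#' attaches the four covariates (NDVI month taken from the temporally
#' corresponding observed step), z-scales them over the combined point set,
#' and fits a binomial GLM of label on ruggedness, NDVI, distance to roads
#' and canopy.  Positive coefficients mean the real route over-uses that
#' covariate relative to where a correlated random walker would have gone.
#' Perfect separation is flagged so the individual can be excluded from
#' population averaging.
#'
#' @param null_set a [simulate_crw()] result
#' @param landscape a `landscape_stack`
#' @return list: `coef` (named vector over the 4 covariates), `separation`
#'   flag, `model` (the glm fit)
#' @export
compare_route <- function(null_set, landscape) {
  obs <- null_set$observed
  n <- nrow(obs)
  months <- as.POSIXlt(obs$timestamp)$mon + 1L
  pts <- list(data.frame(x = obs$x, y = obs$y, month = months, label = 1L))
  for (p in null_set$paths) {
    # drop the shared start vertex; remaining n vertices pair with the
    # observed steps in time
    pts[[length(pts) + 1]] <- data.frame(
      x = p$x[-1], y = p$y[-1], month = months, label = 0L
    )
  }
  df <- do.call(rbind, pts)
  df <- attach_covariates(df, landscape, month = df$month)
  vars <- c("ruggedness", "ndvi", "dist_roads", "canopy")
  for (v in vars) {
    s <- stats::sd(df[[v]])
    df[[v]] <- if (s > 0) (df[[v]] - mean(df[[v]])) / s else df[[v]] * 0
  }
  fit <- suppressWarnings(stats::glm(
    label ~ ruggedness + ndvi + dist_roads + canopy,
    data = df, family = stats::binomial()
  ))
  co <- stats::coef(fit)[vars]
  separation <- !fit$converged || any(abs(co) > 10, na.rm = TRUE) || anyNA(co)
  list(coef = co, separation = separation, model = fit)
}

#' Population-level broad-scale selection test
#'
#' Per covariate: the arithmetic mean of the per-individual binomial
#' coefficients, an exact two-sided one-sample Wilcoxon signed-rank test
#' against zero (exact for n <= 25; zero differences dropped), and the count
#' of individuals selecting (+) versus avoiding (-).
#'
#' @param coef_by_individual matrix/data.frame of per-individual
#'   coefficients (rows = individuals, cols = covariates); at least 5 rows
#' @return object of class `broad_scale_result`: data.frame with `covariate`,
#'   `mean_beta`, `p_wilcoxon`, `n_positive`, `n_negative`, `n`
#' @export
aggregate_population <- function(coef_by_individual) {
  B <- as.matrix(coef_by_individual)
  if (nrow(B) < 5) stop("broad-scale aggregation needs at least 5 individuals",
                        call. = FALSE)
  tab <- do.call(rbind, lapply(colnames(B), function(v) {
    b <- B[, v]
    b <- b[is.finite(b)]
    wt <- suppressWarnings(
      stats::wilcox.test(b, mu = 0, exact = length(b) <= 25)
    )
    data.frame(
      covariate = v, mean_beta = mean(b), p_wilcoxon = wt$p.value,
      n_positive = sum(b > 0), n_negative = sum(b < 0), n = length(b)
    )
  }))
  rownames(tab) <- NULL
  structure(list(table = tab), class = "broad_scale_result")
}

#' @export
print.broad_scale_result <- function(x, ...) {
  cat("<broad_scale_result> route selection vs correlated-random-walk nulls\n")
  print(transform(x$table, mean_beta = round(mean_beta, 3),
                  p_wilcoxon = round(p_wilcoxon, 4)))
  invisible(x)
}

#' Run the broad-scale CRW test for a set of dispersers
#'
#' Convenience wrapper: per disperser, long during-dispersal steps feed
#' [simulate_crw()] and [compare_route()]; individuals with too few long
#' steps or separated fits are excluded with a report, and the remainder is
#' aggregated with [aggregate_population()].
#'
#' @param long_steps_by_animal named list of long-step data.frames
#' @param landscape a `landscape_stack`
#' @param n_paths null paths per individual
#' @param seed integer seed
#' @return list: `result` (a `broad_scale_result` or NULL), `coefs`
#'   (per-individual matrix), `excluded` (named reasons)
#' @export
broad_scale_test <- function(long_steps_by_animal, landscape, n_paths = 10,
                             seed = 1L) {
  coefs <- list()
  excluded <- character(0)
  i <- 0
  for (a in names(long_steps_by_animal)) {
    i <- i + 1
    ns <- try(simulate_crw(long_steps_by_animal[[a]], n_paths = n_paths,
                           extent = landscape$extent,
                           seed = seed + 31L * i),
              silent = TRUE)
    if (inherits(ns, "try-error")) {
      excluded[a] <- "insufficient long steps"
      next
    }
    cmp <- compare_route(ns, landscape)
    if (cmp$separation) {
      excluded[a] <- "separated fit"
      next
    }
    coefs[[a]] <- cmp$coef
  }
  B <- do.call(rbind, coefs)
  res <- if (!is.null(B) && nrow(B) >= 5) aggregate_population(B) else NULL
  list(result = res, coefs = B, excluded = excluded)
}
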