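#' Attach landscape covariates to points
#'
#' Nearest-cell sampling of ruggedness, distance-to-roads, canopy cover and
#' the NDVI layer of each point's calendar month.  Out-of-extent points are
#' an error naming the point, never a silent missing value.
#'
#' @param points data.frame with `x`, `y` (projected metres) and either a
#'   `timestamp` column or an explicit `month`
#' @param landscape a `landscape_stack`
#' @param month optional integer (1-12) overriding the timestamp month
#' @return `points` with raw covariate columns `ruggedness`, `ndvi`,
#'   `dist_roads`, `canopy` appended
#' @export
attach_covariates <- function(points, landscape, month = NULL) {
  if (is.null(month)) {
    if (!"timestamp" %in% names(points)) {
      stop("points need a timestamp column (or pass month=)", call. = FALSE)
    }
    month <- as.POSIXlt(points$timestamp)$mon + 1L
  } else {
    month <- rep(as.integer(month), length.out = nrow(points))
  }
  out <- points
  out$ruggedness <- grid_sample(landscape$ruggedness, points$x, points$y)
  out$dist_roads <- grid_sample(landscape$dist_roads, points$x, points$y)
  out$canopy <- grid_sample(landscape$canopy, points$x, points$y)
  nd <- numeric(nrow(points))
  for (m in unique(month)) {
    sel <- month == m
    nd[sel] <- grid_sample(landscape$ndvi[[m]], points$x[sel], points$y[sel])
  }
  out$ndvi <- nd
  out
}

#' Scale a design table and screen it for collinearity
#'
#' z-scales each named column with the analysis set's own mean/SD (models
#' fitted to different period/group subsets each get their own scaling),
#' appends squared terms as squares of the scaled linear terms, and reports
#' pairwise Pearson correlations and variance inflation factors against the
#' conventional thresholds r < 0.3 and VIF < 2.
#'
#' @param design data.frame containing the raw covariate columns
#' @param vars columns to scale (linear terms)
#' @param sq_vars subset of `vars` that also get a squared term
#'   (`<name>_sq`)
#' @param r_max,vif_max screening thresholds
#' @return list: `scaled` (design with `<var>` replaced by its z-score and
#'   squared columns appended; raw columns kept as `<var>_raw`), `centers`,
#'   `scales`, `screen` (pairwise r, VIF and pass flags)
#' @export
scale_and_screen <- function(design,
                             vars = c("ruggedness", "ndvi", "dist_roads", "canopy"),
                             sq_vars = c("ruggedness", "canopy"),
                             r_max = 0.3, vif_max = 2) {
  stopifnot(all(vars %in% names(design)))
  centers <- vapply(design[vars], mean, numeric(1))
  scales <- vapply(design[vars], stats::sd, numeric(1))
  if (any(scales == 0)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(vars[scales == 0], collapse = ", ")), call. = FALSE)
  }
  out <- design
  for (v in vars) {
    out[[paste0(v, "_raw")]] <- design[[v]]
    out[[v]] <- (design[[v]] - centers[[v]]) / scales[[v]]
  }
  for (v in sq_vars) out[[paste0(v, "_sq")]] <- out[[v]]^2
  model_cols <- c(vars, paste0(sq_vars, "_sq"))
  X <- as.matrix(out[model_cols])
  r <- stats::cor(X)
  vif <- vapply(seq_along(model_cols), function(j) {
    # summary() warns when a column is perfectly collinear; VIF is then Inf
    r2 <- suppressWarnings(summary(stats::lm(X[, j] ~ X[, -j]))$r.squared)
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- model_cols
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  screen <- list(
    pairwise_r = data.frame(
      var1 = model_cols[pairs[, 1]], var2 = model_cols[pairs[, 2]],
      r = r[pairs], pass = abs(r[pairs]) < r_max
    ),
    vif = data.frame(var = model_cols, vif = unname(vif),
                     pass = unname(vif) < vif_max),
    all_pass = all(abs(r[pairs]) < r_max) && all(vif < vif_max)
  )
  list(scaled = out, centers = centers, scales = scales, screen = screen,
       model_cols = model_cols)
}

#' Undo z-scaling
#'
#' Inverse of the scaling in [scale_and_screen()]; scaling then unscaling is
#' the identity to machine tolerance.
#'
#' @param scaled_values numeric vector of z-scores
#' @param center,scale the statistics used to scale
#' @return values on the raw scale
#' @export
unscale <- function(scaled_values, center, scale) {
  scaled_values * scale + center
}
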