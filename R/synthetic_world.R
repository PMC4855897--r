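#' Simulation configuration
#'
#' Bundles every tunable of the synthetic world: cohort composition, the true
#' step-selection coefficients, the GPS sampling process and the dispersal
#' geometry.  Defaults follow the telemetry regime the package targets:
#' 2-h fixes, collar-specific fix success of 81.7% (store-on-board collars on
#' females) and 66.2% (satellite collars on males), dispersal displacements of
#' 29.16-98.01 km lasting 12-47 days, and rare single-fix position outliers
#' 10-40 km off the true path.
#'
#' `true_betas` are selection coefficients on z-scaled covariates, in the
#' order (ruggedness, ruggedness^2, NDVI, distance-to-roads, canopy,
#' canopy^2); squared terms are squares of the scaled linear term.  Scaling
#' uses landscape-wide means/SDs so the generator's coefficients live on the
#' same scale the estimators report.
#'
#' @param n_residents,n_dispersers,n_exploratory,n_migrants cohort counts
#' @param true_betas named numeric vector of length 6 (see Details)
#' @param fix_interval_min nominal fix interval, minutes
#' @param fix_success_prob named vector of per-collar fix success in (0, 1]
#' @param outlier_prob per-fix probability of a gross position outlier
#' @param outlier_offset_km range (km) of the single-fix outlier offset
#' @param dispersal_displacement_km range of straight-line dispersal distance
#' @param dispersal_duration_days range of dispersal duration
#' @param start_date first day of the simulated animal-year (UTC)
#' @param days length of the simulated series in days (default covers
#'   1 April - 31 October)
#' @param n_candidates candidate steps proposed per 2-h tick (discrete-choice
#'   set size of the generating process)
#' @param rng_seed integer seed; identical configs reproduce trajectories
#'   bit-identically
#' @return an object of class `sim_config`
#' @export
simulation_config <- function(n_residents = 10,
                              n_dispersers = 5,
                              n_exploratory = 3,
                              n_migrants = 10,
                              true_betas = c(
                                ruggedness = -0.1, ruggedness_sq = -0.3,
                                ndvi = 0.8, dist_roads = 0.1,
                                canopy = 0.2, canopy_sq = -0.25
                              ),
                              fix_interval_min = 120,
                              fix_success_prob = c(lotek = 0.817, argos = 0.662),
                              outlier_prob = 0.005,
                              outlier_offset_km = c(10, 40),
                              dispersal_displacement_km = c(29.16, 98.01),
                              dispersal_duration_days = c(12, 47),
                              start_date = "2008-04-01",
                              days = 214,
                              n_candidates = 50,
                              rng_seed = 1L) {
  stopifnot(
    all(fix_success_prob > 0), all(fix_success_prob <= 1),
    length(true_betas) == 6,
    outlier_prob >= 0, outlier_prob < 1,
    diff(outlier_offset_km) >= 0,
    diff(dispersal_displacement_km) >= 0,
    diff(dispersal_duration_days) >= 0,
    n_candidates >= 2, days >= 1
  )
  names(true_betas) <- c("ruggedness", "ruggedness_sq", "ndvi",
                         "dist_roads", "canopy", "canopy_sq")
  structure(list(
    n_residents = n_residents, n_dispersers = n_dispersers,
    n_exploratory = n_exploratory, n_migrants = n_migrants,
    true_betas = true_betas,
    fix_interval_min = fix_interval_min,
    fix_success_prob = fix_success_prob,
    outlier_prob = outlier_prob, outlier_offset_km = outlier_offset_km,
    dispersal_displacement_km = dispersal_displacement_km,
    dispersal_duration_days = dispersal_duration_days,
    start_date = start_date, days = days,
    n_candidates = n_candidates,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("%d residents, %d dispersers, %d exploratory, %d migrants",
              x$n_residents, x$n_dispersers, x$n_exploratory, x$n_migrants),
      sprintf("seed %d, %d days from %s", x$rng_seed, x$days, x$start_date),
      sep = "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# smooth random fields

# Gaussian-ish random field on an nr x nc grid: spectral cosine sum on a
# coarse lattice, bilinearly resampled.  range_frac is the correlation length
# as a fraction of the grid's larger side.  Values roughly N(0, 1).
smooth_field <- function(nr, nc, range_frac = 0.15, n_comp = 40,
                         coarse_max = NULL) {
  # the coarse lattice must resolve the requested correlation length
  if (is.null(coarse_max)) {
    coarse_max <- min(max(160, ceiling(4 / range_frac)), 480)
  }
  cr <- min(nr, coarse_max); cc <- min(nc, coarse_max)
  u <- seq(0, 1, length.out = cc)
  v <- seq(0, 1, length.out = cr)
  f <- matrix(0, cr, cc)
  for (k in seq_len(n_comp)) {
    w <- stats::rnorm(2, sd = 1 / (2 * pi * range_frac))
    phi <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1, sd = sqrt(2 / n_comp))
    f <- f + a * cos(2 * pi * (outer(v * w[2], u * w[1], "+")) + phi)
  }
  if (cr == nr && cc == nc) return(f)
  bilinear_resample(f, nr, nc)
}

# resample matrix to nr x nc by bilinear interpolation of cell-centre values
bilinear_resample <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  ri <- (seq_len(nr) - 0.5) / nr * (sr - 1) + 1
  ci <- (seq_len(nc) - 0.5) / nc * (sc - 1) + 1
  r0 <- pmin(floor(ri), sr - 1); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), sc - 1); c1 <- c0 + 1; fc <- ci - c0
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}

# ---------------------------------------------------------------------------
# landscape generation

#' Generate a synthetic landscape stack
#'
#' Builds aligned covariate grids over one planar projected frame: a smooth
#' elevation surface with a mountainous west grading into plains east,
#' terrain ruggedness derived from it by the 8-neighbour TRI rule, percent
#' canopy cover, a sparse rasterised road network with its distance
#' transform, and 12 monthly NDVI layers following a green-up curve that
#' peaks in mid-summer.
#'
#' @param extent_km numeric length-2, landscape width/height in km; at least
#'   120 x 120 so that ~100-km dispersal paths fit inside
#' @param res_terrain_m cell size for elevation / ruggedness / canopy /
#'   distance-to-roads layers (native design: 30 m; coarser grids are useful
#'   for fast simulation studies)
#' @param res_ndvi_m cell size of NDVI layers (native design: 250 m)
#' @param n_roads number of road polylines crossing the extent
#' @param rng_seed integer seed; the same seed reproduces the landscape
#'   bit-identically
#' @return an object of class `landscape_stack` with elements `elevation`,
#'   `ruggedness`, `canopy`, `dist_roads` (each a [grid_layer()]), `ndvi`
#'   (list of 12 [grid_layer()]s), `scaling` (landscape-wide means/SDs used
#'   to put selection coefficients on the z-scale) and `extent`.
#' @export
generate_landscape <- function(extent_km = c(120, 120),
                               res_terrain_m = 30,
                               res_ndvi_m = 250,
                               n_roads = 16,
                               rng_seed = 1L) {
  if (length(extent_km) == 1) extent_km <- rep(extent_km, 2)
  if (any(extent_km < 120)) {
    stop("extent must be at least 120 km x 120 km so long dispersal paths fit",
         call. = FALSE)
  }
  set.seed(as.integer(rng_seed))
  ex_m <- extent_km * 1000
  nc <- round(ex_m[1] / res_terrain_m); nr <- round(ex_m[2] / res_terrain_m)

  westness <- matrix(rep(1 - (seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  elev <- 800 + 1200 * westness +
    300 * smooth_field(nr, nc, range_frac = 0.15) +
    (30 + 90 * westness) * smooth_field(nr, nc, range_frac = 0.02)
  elevation <- grid_layer(elev, 0, 0, res_terrain_m)
  ruggedness <- terrain_ruggedness(elevation)

  # canopy mosaic: broad forest blocks plus stand-scale (~1 km) patchiness
  canopy <- 45 + 20 * smooth_field(nr, nc, range_frac = 0.08) +
    16 * smooth_field(nr, nc, range_frac = 0.008)
  canopy <- pmin(pmax(canopy, 0), 100)
  canopy <- grid_layer(matrix(canopy, nr, nc), 0, 0, res_terrain_m)

  # sparse polyline road network rasterised to a cell mask, then distance
  road_mask <- matrix(0, nr, nc)
  for (r in seq_len(n_roads)) {
    # a road enters on one edge and leaves on another
    p0 <- stats::runif(2) * ex_m
    ang <- stats::runif(1, 0, pi)
    len <- sqrt(sum(ex_m^2))
    t_seq <- seq(-len, len, by = res_terrain_m / 2)
    xs <- p0[1] + cos(ang) * t_seq
    ys <- p0[2] + sin(ang) * t_seq
    keep <- xs >= 0 & xs < ex_m[1] & ys >= 0 & ys < ex_m[2]
    if (!any(keep)) next
    idx <- grid_cell_index(elevation, xs[keep], ys[keep])
    road_mask[idx] <- 1
  }
  dist_roads <- grid_distance_transform(grid_layer(road_mask, 0, 0, res_terrain_m))

  # NDVI: spatial greenness base modulated by a seasonal curve peaking
  # mid-July (month 7)
  ncn <- round(ex_m[1] / res_ndvi_m); nrn <- round(ex_m[2] / res_ndvi_m)
  base <- stats::pnorm(
    0.8 * smooth_field(nrn, ncn, range_frac = 0.2) +
      0.7 * smooth_field(nrn, ncn, range_frac = 0.01)
  )  # in (0,1); broad gradients plus meadow-scale patches
  ndvi <- vector("list", 12)
  for (m in 1:12) {
    s <- ndvi_seasonal_weight(m)
    v <- -0.1 + (0.2 + 0.7 * base) * s
    ndvi[[m]] <- grid_layer(pmin(pmax(v, -1), 1), 0, 0, res_ndvi_m)
  }

  stack <- structure(list(
    elevation = elevation, ruggedness = ruggedness, canopy = canopy,
    dist_roads = dist_roads, ndvi = ndvi,
    extent = c(xmin = 0, xmax = ex_m[1], ymin = 0, ymax = ex_m[2]),
    rng_seed = as.integer(rng_seed)
  ), class = "landscape_stack")
  stack$scaling <- landscape_scaling(stack)
  stack
}

# seasonal NDVI multiplier by calendar month; Gaussian green-up peaking
# in mid-July with a non-zero winter floor
ndvi_seasonal_weight <- function(month) {
  0.15 + 0.85 * exp(-0.5 * ((month - 7.2) / 1.9)^2)
}

#' @export
print.landscape_stack <- function(x, ...) {
  e <- x$extent
  cat(sprintf(
    "<landscape_stack> %.0f x %.0f km, terrain cell %g m, NDVI cell %g m, seed %d\n",
    (e["xmax"] - e["xmin"]) / 1000, (e["ymax"] - e["ymin"]) / 1000,
    x$ruggedness$cell, x$ndvi[[1]]$cell, x$rng_seed
  ))
  invisible(x)
}

# landscape-wide mean/SD of each covariate; NDVI pooled across 12 months
landscape_scaling <- function(stack) {
  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  nd <- unlist(lapply(stack$ndvi, function(l) as.vector(l$values)),
               use.names = FALSE)
  out <- rbind(
    ruggedness = msd(as.vector(stack$ruggedness$values)),
    ndvi = msd(nd),
    dist_roads = msd(as.vector(stack$dist_roads$values)),
    canopy = msd(as.vector(stack$canopy$values))
  )
  out
}

# fast lookup environment for repeated covariate sampling: pre-z-scaled
# matrices plus grid geometry
prepare_selection_surface <- function(stack) {
  sc <- stack$scaling
  zs <- function(layer, nm) (layer$values - sc[nm, "mean"]) / sc[nm, "sd"]
  list(
    rug = zs(stack$ruggedness, "ruggedness"),
    droads = zs(stack$dist_roads, "dist_roads"),
    canopy = zs(stack$canopy, "canopy"),
    ndvi = lapply(stack$ndvi, function(l) zs(l, "ndvi")),
    cell_t = stack$ruggedness$cell,
    nr_t = nrow(stack$ruggedness$values), nc_t = ncol(stack$ruggedness$values),
    cell_n = stack$ndvi[[1]]$cell,
    nr_n = nrow(stack$ndvi[[1]]$values), nc_n = ncol(stack$ndvi[[1]]$values),
    extent = stack$extent
  )
}

# scaled 6-column design (rug, rug^2, ndvi, droads, canopy, canopy^2) at
# points assumed inside the extent; month is scalar or per-point vector
surface_design <- function(surf, x, y, month) {
  ct <- pmin(floor(x / surf$cell_t) + 1L, surf$nc_t)
  rt <- pmin(floor(y / surf$cell_t) + 1L, surf$nr_t)
  it <- (ct - 1L) * surf$nr_t + rt
  cn <- pmin(floor(x / surf$cell_n) + 1L, surf$nc_n)
  rn <- pmin(floor(y / surf$cell_n) + 1L, surf$nr_n)
  inn <- (cn - 1L) * surf$nr_n + rn
  if (length(month) == 1) {
    nd <- surf$ndvi[[month]][inn]
  } else {
    nd <- numeric(length(x))
    for (m in unique(month)) {
      sel <- month == m
      nd[sel] <- surf$ndvi[[m]][inn[sel]]
    }
  }
  r <- surf$rug[it]; cp <- surf$canopy[it]
  cbind(ruggedness = r, ruggedness_sq = r^2, ndvi = nd,
        dist_roads = surf$droads[it], canopy = cp, canopy_sq = cp^2)
}

# reflect coordinates into [lo, hi) (triangle fold)
reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  v <- ifelse(v > span, 2 * span - v, v)
  # keep strictly inside the half-open extent
  pmin(lo + v, hi - 1e-6)
}

wrap_deg <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

# ---------------------------------------------------------------------------
# trajectory simulation

#' Simulate one GPS trajectory under a known step-selection function
#'
#' A discrete-choice simulator: at every 2-h tick the animal proposes
#' `n_candidates` steps from a phase-specific step-length/turn kernel and
#' chooses one with probability proportional to
#' `exp(true_betas %*% x(endpoint))`, where `x` is the z-scaled covariate
#' vector.  Behavioural phases give the four NSD signatures:
#' \describe{
#'   \item{resident}{short, wide-angle steps with a soft attraction to the
#'     home-range centre all year.}
#'   \item{disperser}{resident behaviour until a departure day, then a travel
#'     phase (a mix of long, directional "burst" steps steered towards a
#'     target drawn at the configured displacement, and short foraging
#'     steps), then settlement at the new range.}
#'   \item{exploratory}{as disperser, followed after a short dwell by a
#'     return leg to within 5 km of the origin.}
#'   \item{migrant}{spring travel to a summer range 15-40 km away, a long
#'     summer residency, and an autumn return.}
#' }
#' Fixes are then thinned by the collar's fix-success probability and, with
#' probability `outlier_prob`, displaced 10-40 km for a single fix (the
#' classic out-and-back GPS error signature).
#'
#' @param landscape a [generate_landscape()] stack
#' @param mode one of `"resident"`, `"migrant"`, `"disperser"`,
#'   `"exploratory"`
#' @param config a [simulation_config()]
#' @param animal_id identifier recorded in the output
#' @param collar_type `"lotek"` or `"argos"`; defaults to argos for
#'   dispersing/exploratory (male) animals and lotek otherwise
#' @param seed integer seed for this animal (defaults to the config seed)
#' @return a data.frame with columns `animal_id`, `collar_type`, `timestamp`
#'   (POSIXct UTC), `x`, `y`, plus a `"truth"` attribute (mode, true phase
#'   boundaries in days, target displacement, injected outlier timestamps and
#'   the true betas).
#' @export
simulate_trajectory <- function(landscape, mode, config = simulation_config(),
                                animal_id = "A1", collar_type = NULL,
                                seed = config$rng_seed) {
  mode <- match.arg(mode, c("resident", "migrant", "disperser", "exploratory"))
  if (is.null(collar_type)) {
    collar_type <- if (mode %in% c("disperser", "exploratory")) "argos" else "lotek"
  }
  set.seed(as.integer(seed))
  surf <- prepare_selection_surface(landscape)
  beta <- config$true_betas
  K <- config$n_candidates
  ticks_per_day <- round(1440 / config$fix_interval_min)
  n_ticks <- config$days * ticks_per_day + 1
  ex <- surf$extent

  # start well inside the extent so ~100-km dispersals fit
  margin_frac <- 0.12
  draw_start <- function() c(
    stats::runif(1, ex["xmin"] + margin_frac * (ex["xmax"] - ex["xmin"]),
                 ex["xmax"] - margin_frac * (ex["xmax"] - ex["xmin"])),
    stats::runif(1, ex["ymin"] + margin_frac * (ex["ymax"] - ex["ymin"]),
                 ex["ymax"] - margin_frac * (ex["ymax"] - ex["ymin"]))
  )
  # a target dist_m away whose endpoint stays inside the extent, or NULL if
  # no direction from this origin fits.  Among feasible directions the animal
  # prefers rays with better habitat (a broad assessment of the route under
  # the same selection coefficients); with zero betas this is uniform.
  draw_target <- function(origin, dist_m, month = 6L) {
    pad <- 2000
    ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = 720)
    tx <- origin[1] + dist_m * cos(ang)
    ty <- origin[2] + dist_m * sin(ang)
    ok <- tx > ex["xmin"] + pad & tx < ex["xmax"] - pad &
      ty > ex["ymin"] + pad & ty < ex["ymax"] - pad
    if (!any(ok)) return(NULL)
    idx <- which(ok)
    frac <- seq(0.1, 1, length.out = 24)
    # route-integrated utility: the per-step selection kernel summed over the
    # ~dist/burst_len travel steps the route would take
    n_route_steps <- dist_m / 1600
    u <- vapply(idx, function(i) {
      px <- origin[1] + frac * (tx[i] - origin[1])
      py <- origin[2] + frac * (ty[i] - origin[2])
      mean(surface_design(surf, px, py, month) %*% beta) * n_route_steps
    }, numeric(1))
    w <- exp(u - max(u))
    i <- idx[sample.int(length(idx), 1, prob = w)]
    c(tx[i], ty[i])
  }
  start <- draw_start()

  # mode schedule -----------------------------------------------------------
  legs <- list()   # each: list(depart_tick, target, speed_len)
  # travel bursts have a fixed characteristic length; the burst frequency is
  # set so the drawn displacement is covered in the drawn duration
  burst_len_m <- 1600
  travel_p <- function(dist_m, dur_days) {
    min(0.8, max(0.05,
                 1.25 * dist_m / (dur_days * ticks_per_day * burst_len_m * 0.96)))
  }
  if (mode %in% c("disperser", "exploratory")) {
    depart_day <- stats::runif(1, 47, 95)   # mid-May to early July departure
    disp_m <- stats::runif(1, config$dispersal_displacement_km[1],
                           config$dispersal_displacement_km[2]) * 1000
    dur <- stats::runif(1, config$dispersal_duration_days[1],
                        config$dispersal_duration_days[2])
    # long displacements only fit from some origins; redraw the start until a
    # target direction exists
    tg <- draw_target(start, disp_m)
    tries <- 0
    while (is.null(tg) && tries < 500) {
      start <- draw_start()
      tg <- draw_target(start, disp_m)
      tries <- tries + 1
    }
    if (is.null(tg)) stop("no feasible dispersal target inside the extent",
                          call. = FALSE)
    legs[[1]] <- list(depart = round(depart_day * ticks_per_day),
                      target = tg, len = burst_len_m, p = travel_p(disp_m, dur),
                      leg_dist = disp_m,
                      max_ticks = round(dur * ticks_per_day * 1.6))
    if (mode == "exploratory") {
      dwell_days <- stats::runif(1, 3, 10)
      legs[[2]] <- list(after_dwell = round(dwell_days * ticks_per_day),
                        target = start, len = burst_len_m,
                        p = travel_p(disp_m, dur), leg_dist = disp_m,
                        max_ticks = round(dur * ticks_per_day * 1.6))
    }
  } else if (mode == "migrant") {
    depart_day <- stats::runif(1, 20, 50)        # late April / May
    mig_m <- stats::runif(1, 15, 40) * 1000
    dur <- stats::runif(1, 6, 14)
    tg <- draw_target(start, mig_m)
    while (is.null(tg)) {
      start <- draw_start()
      tg <- draw_target(start, mig_m)
    }
    return_day <- stats::runif(1, 165, 190)      # mid-September onwards
    legs[[1]] <- list(depart = round(depart_day * ticks_per_day),
                      target = tg, len = burst_len_m, p = travel_p(mig_m, dur),
                      leg_dist = mig_m,
                      max_ticks = round(dur * ticks_per_day * 1.6))
    legs[[2]] <- list(depart = round(return_day * ticks_per_day),
                      target = start, len = burst_len_m,
                      p = travel_p(mig_m, dur), leg_dist = mig_m,
                      max_ticks = round(dur * ticks_per_day * 1.6))
  }

  # main loop ---------------------------------------------------------------
  xs <- numeric(n_ticks); ys <- numeric(n_ticks)
  phase <- character(n_ticks)
  xs[1] <- start[1]; ys[1] <- start[2]
  pos <- start
  heading <- stats::runif(1, -180, 180)
  anchor <- start
  state <- "range"
  leg_i <- 0
  cur <- NULL
  arrive_tol <- 1500
  travel_elapsed <- 0
  dwell_left <- NA_real_
  reflected <- 0L
  home_sd_m <- 1000
  months <- as.POSIXlt(
    as.POSIXct(config$start_date, tz = "UTC") +
      (seq_len(n_ticks) - 1) * config$fix_interval_min * 60
  )$mon + 1L
  phase[1] <- "range"

  for (t in 2:n_ticks) {
    # phase transitions
    if (state == "range") {
      nxt <- leg_i + 1
      if (nxt <= length(legs)) {
        lg <- legs[[nxt]]
        trigger <- if (!is.null(lg$depart)) (t - 1) >= lg$depart else {
          if (is.na(dwell_left)) FALSE else dwell_left <= 0
        }
        if (trigger) {
          leg_i <- nxt; cur <- lg; state <- "travel"; travel_elapsed <- 0
        }
      }
      if (!is.na(dwell_left)) dwell_left <- dwell_left - 1
    }
    if (state == "travel") {
      d_to <- sqrt(sum((pos - cur$target)^2))
      travel_elapsed <- travel_elapsed + 1
      if (d_to < arrive_tol || travel_elapsed > cur$max_ticks) {
        state <- "range"; anchor <- pos
        # arm a dwell countdown if the next leg waits on one
        if (leg_i + 1 <= length(legs) && !is.null(legs[[leg_i + 1]]$after_dwell)) {
          dwell_left <- legs[[leg_i + 1]]$after_dwell
        } else dwell_left <- NA_real_
      }
    }

    # propose K candidates from the phase kernel; during travel the tick is
    # either a directional burst or a foraging pause (the kernel schedule),
    # so habitat choice stays a pure exp(beta'x) draw within the set
    if (state == "travel") {
      # slow-fast-slow displacement schedule: a hesitant departure, sustained
      # mid-dispersal travel, and deceleration while the new range forms
      d_to_now <- sqrt(sum((pos - cur$target)^2))
      frac <- 1 - min(1, d_to_now / cur$leg_dist)
      # speed proportional to f(1-f^2) (f = fraction of displacement
      # covered) makes the squared displacement rise as a logistic -- the
      # canonical dispersal NSD shape -- with a floor so departure and
      # settlement still complete
      speed_mult <- 0.35 + 2.6 * (frac - frac^3)
      burst_tick <- stats::runif(1) < min(0.85, cur$p * speed_mult)
      if (burst_tick) {
        len <- stats::rgamma(K, shape = 1, scale = cur$len)
        # on final approach the animal settles rather than overshooting
        len <- pmin(len, pmax(1.1 * d_to_now, 400))
        bearing <- atan2(cur$target[2] - pos[2], cur$target[1] - pos[1]) * 180 / pi
        hd <- bearing + stats::rnorm(K, 0, 25)
      } else {
        len <- stats::rgamma(K, shape = 1.2, scale = 200 / 1.2)
        hd <- stats::runif(K, -180, 180)
      }
    } else {
      len <- stats::rgamma(K, shape = 1.2, scale = 180 / 1.2)
      hd <- stats::runif(K, -180, 180)
    }
    cx <- pos[1] + len * cos(hd * pi / 180)
    cy <- pos[2] + len * sin(hd * pi / 180)
    out <- cx < ex["xmin"] | cx >= ex["xmax"] | cy < ex["ymin"] | cy >= ex["ymax"]
    if (any(out)) {
      reflected <- reflected + sum(out)
      cx <- reflect_into(cx, ex["xmin"], ex["xmax"])
      cy <- reflect_into(cy, ex["ymin"], ex["ymax"])
    }

    X <- surface_design(surf, cx, cy, months[t])
    u <- as.vector(X %*% beta)
    if (state == "range") {
      d_home2 <- (cx - anchor[1])^2 + (cy - anchor[2])^2
      u <- u - 0.5 * d_home2 / home_sd_m^2
    }
    w <- exp(u - max(u))
    pick <- sample.int(K, 1L, prob = w)
    heading <- hd[pick]
    pos <- c(cx[pick], cy[pick])
    xs[t] <- pos[1]; ys[t] <- pos[2]
    phase[t] <- state
  }
  if (reflected > 0) {
    warning(sprintf("%s: %d candidate endpoints reflected at the landscape boundary",
                    animal_id, reflected), call. = FALSE)
  }

  # corrupt: single-fix outliers, then thin by fix success -------------------
  ts <- as.POSIXct(config$start_date, tz = "UTC") +
    (seq_len(n_ticks) - 1) * config$fix_interval_min * 60
  ox <- xs; oy <- ys
  is_outlier <- rep(FALSE, n_ticks)
  cand_idx <- 2:(n_ticks - 1)
  hit <- cand_idx[stats::runif(length(cand_idx)) < config$outlier_prob]
  # never corrupt two adjacent fixes: the round-trip signature needs clean
  # neighbours
  hit <- hit[c(TRUE, diff(hit) > 1)]
  for (i in hit) {
    r <- stats::runif(1, config$outlier_offset_km[1],
                      config$outlier_offset_km[2]) * 1000
    a <- stats::runif(1, 0, 2 * pi)
    ox[i] <- reflect_into(xs[i] + r * cos(a), ex["xmin"], ex["xmax"])
    oy[i] <- reflect_into(ys[i] + r * sin(a), ex["ymin"], ex["ymax"])
    is_outlier[i] <- TRUE
  }
  p_fix <- config$fix_success_prob[[collar_type]]
  keep <- stats::runif(n_ticks) < p_fix
  keep[1] <- TRUE

  traj <- data.frame(
    animal_id = animal_id, collar_type = collar_type,
    timestamp = ts[keep], x = ox[keep], y = oy[keep],
    stringsAsFactors = FALSE
  )
  # truth in days from the series start
  tick_day <- function(tk) (tk - 1) / ticks_per_day
  travel_ticks <- which(phase == "travel")
  truth <- list(
    mode = mode, true_betas = beta,
    start_xy = start,
    outlier_timestamps = ts[is_outlier & keep],
    n_outliers_injected = sum(is_outlier & keep),
    phase_days = if (length(travel_ticks)) {
      range(tick_day(travel_ticks))
    } else c(NA_real_, NA_real_)
  )
  if (mode %in% c("disperser", "exploratory")) {
    out_travel <- travel_ticks[travel_ticks <= which.max(
      (xs - start[1])^2 + (ys - start[2])^2)]
    truth$dispersal_start_day <- tick_day(min(travel_ticks))
    truth$dispersal_end_day <- if (length(out_travel)) tick_day(max(out_travel)) else NA
    truth$target_displacement_km <- sqrt(sum((legs[[1]]$target - start)^2)) / 1000
    # the NSD-defined event truth: days when the true (uncorrupted) squared
    # displacement first crosses 2.5% and 97.5% of its settled plateau --
    # the same event definition the extractor estimates, but computed on the
    # noiseless path, so estimator accuracy can be scored against it
    if (length(out_travel)) {
      nsd_true <- (xs - start[1])^2 + (ys - start[2])^2
      arrive <- max(out_travel)
      plateau <- nsd_true[arrive]
      win <- seq(min(travel_ticks), arrive)
      truth$event_start_day <-
        tick_day(win[which(nsd_true[win] >= 0.025 * plateau)[1]])
      truth$event_end_day <-
        tick_day(win[which(nsd_true[win] >= 0.975 * plateau)[1]])
    }
  }
  attr(traj, "truth") <- truth
  traj
}

#' Simulate a cohort of animals
#'
#' Draws the per-mode counts in `config`, assigning satellite (argos) collars
#' and male sex to dispersing/exploratory animals and store-on-board (lotek)
#' collars to residents/migrants (mostly female), mirroring the strongly
#' male-biased dispersal the method targets.  Per-animal seeds derive from
#' `config$rng_seed`, so the whole cohort is reproducible.
#'
#' @inheritParams simulate_trajectory
#' @return list with `trajectories` (list of per-animal data.frames) and
#'   `truth` (data.frame of animal id, sex, collar and true mode)
#' @export
simulate_cohort <- function(landscape, config = simulation_config()) {
  modes <- c(
    rep("resident", config$n_residents),
    rep("migrant", config$n_migrants),
    rep("disperser", config$n_dispersers),
    rep("exploratory", config$n_exploratory)
  )
  n <- length(modes)
  ids <- sprintf("elk%03d", seq_len(n))
  sex <- ifelse(modes %in% c("disperser", "exploratory"), "M", "F")
  collar <- ifelse(sex == "M", "argos", "lotek")
  trajectories <- vector("list", n)
  for (i in seq_len(n)) {
    trajectories[[i]] <- simulate_trajectory(
      landscape, modes[i], config,
      animal_id = ids[i], collar_type = collar[i],
      seed = config$rng_seed + 7919L * i
    )
  }
  names(trajectories) <- ids
  list(
    trajectories = trajectories,
    truth = data.frame(animal_id = ids, sex = sex, collar_type = collar,
                       mode = modes, stringsAsFactors = FALSE)
  )
}

#' Directly simulate matched step-selection strata under known coefficients
#'
#' Bypasses full trajectory simulation: for each stratum a start point and
#' prior heading are drawn, `n_avail + 1` candidate endpoints are proposed
#' from one availability kernel, covariates are attached on the landscape
#' z-scale, and the "observed" member is chosen with probability proportional
#' to `exp(beta %*% x)`.  Because chosen and available candidates share the
#' proposal kernel, conditional logistic regression on these strata is a
#' consistent estimator of `beta`; this makes the generator the ground truth
#' for parameter-recovery and validation-calibration studies.
#'
#' @param landscape a [generate_landscape()] stack
#' @param n_animals number of simulated individuals
#' @param n_strata_per_animal strata (observed steps) per individual
#' @param beta true selection coefficients, length 6 as in
#'   [simulation_config()] (or fewer: named subset of the design columns)
#' @param n_avail available (random) steps per stratum
#' @param between_sd SD of per-animal coefficient deviations (all
#'   coefficients) for two-stage pooling studies
#' @param month calendar month used for NDVI lookup
#' @param seed integer seed
#' @param len_mean_m,len_shape gamma step-length kernel of the candidate
#'   proposals (the scale over which availability is contrasted)
#' @return data.frame: `animal_id`, `stratum_id`, `case` (1 = chosen),
#'   plus the six scaled covariate columns; true per-animal coefficients in
#'   attribute `"animal_betas"`.
#' @export
simulate_ssf_strata <- function(landscape, n_animals = 10,
                                n_strata_per_animal = 300,
                                beta = c(ruggedness = -0.1, ruggedness_sq = -0.3,
                                         ndvi = 0.8, dist_roads = 0.1,
                                         canopy = 0.2, canopy_sq = -0.25),
                                n_avail = 10, between_sd = 0,
                                month = 6L, seed = 1L,
                                len_mean_m = 800, len_shape = 2) {
  set.seed(as.integer(seed))
  surf <- prepare_selection_surface(landscape)
  ex <- surf$extent
  cols <- c("ruggedness", "ruggedness_sq", "ndvi", "dist_roads",
            "canopy", "canopy_sq")
  if (is.null(names(beta))) names(beta) <- cols[seq_along(beta)]
  stopifnot(all(names(beta) %in% cols))
  K <- n_avail + 1
  res <- vector("list", n_animals)
  animal_betas <- matrix(NA_real_, n_animals, length(beta),
                         dimnames = list(NULL, names(beta)))
  pad <- 0.05 * c(ex["xmax"] - ex["xmin"], ex["ymax"] - ex["ymin"])
  for (a in seq_len(n_animals)) {
    b <- beta + stats::rnorm(length(beta), 0, between_sd)
    animal_betas[a, ] <- b
    n <- n_strata_per_animal
    sx <- stats::runif(n, ex["xmin"] + pad[1], ex["xmax"] - pad[1])
    sy <- stats::runif(n, ex["ymin"] + pad[2], ex["ymax"] - pad[2])
    len <- stats::rgamma(n * K, shape = len_shape, scale = len_mean_m / len_shape)
    ang <- stats::runif(n * K, -pi, pi)
    cx <- rep(sx, each = K) + len * cos(ang)
    cy <- rep(sy, each = K) + len * sin(ang)
    cx <- reflect_into(cx, ex["xmin"], ex["xmax"])
    cy <- reflect_into(cy, ex["ymin"], ex["ymax"])
    X <- surface_design(surf, cx, cy, month)
    u <- as.vector(X[, names(beta), drop = FALSE] %*% b)
    grp <- rep(seq_len(n), each = K)
    case <- integer(n * K)
    um <- matrix(u, nrow = K)
    w <- exp(sweep(um, 2, apply(um, 2, max)))
    pickcol <- function(j) sample.int(K, 1L, prob = w[, j])
    picks <- vapply(seq_len(n), pickcol, integer(1))
    case[(seq_len(n) - 1) * K + picks] <- 1L
    res[[a]] <- data.frame(
      animal_id = sprintf("sim%02d", a),
      stratum_id = sprintf("sim%02d_%04d", a, grp),
      case = case, X, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "animal_betas") <- animal_betas
  out
}

# ---------------------------------------------------------------------------
# landscape persistence (plain-text ASCII grids + a yaml sidecar)

#' Write / read a landscape stack to a directory of ASCII grids
#'
#' One `.asc` file per layer (`elevation`, `ruggedness`, `canopy`,
#' `dist_roads`, `ndvi_01` ... `ndvi_12`) plus `landscape.yml` recording the
#' generator seed and extent.
#'
#' @param stack a `landscape_stack`
#' @param dir output directory (created if missing)
#' @return `write_landscape` returns `dir` invisibly; `read_landscape`
#'   returns a `landscape_stack`.
#' @export
write_landscape <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("elevation", "ruggedness", "canopy", "dist_roads")) {
    write_ascii_grid(stack[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  for (m in 1:12) {
    write_ascii_grid(stack$ndvi[[m]], file.path(dir, sprintf("ndvi_%02d.asc", m)))
  }
  yaml::write_yaml(
    list(rng_seed = stack$rng_seed, extent = as.list(stack$extent)),
    file.path(dir, "landscape.yml")
  )
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "landscape.yml"))
  stack <- structure(list(
    elevation = read_ascii_grid(file.path(dir, "elevation.asc")),
    ruggedness = read_ascii_grid(file.path(dir, "ruggedness.asc")),
    canopy = read_ascii_grid(file.path(dir, "canopy.asc")),
    dist_roads = read_ascii_grid(file.path(dir, "dist_roads.asc")),
    ndvi = lapply(1:12, function(m) {
      read_ascii_grid(file.path(dir, sprintf("ndvi_%02d.asc", m)))
    }),
    extent = unlist(meta$extent),
    rng_seed = meta$rng_seed
  ), class = "landscape_stack")
  names(stack$extent) <- c("xmin", "xmax", "ymin", "ymax")
  stack$scaling <- landscape_scaling(stack)
  stack
}
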