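#' Read / write trajectory CSV
#'
#' The trajectory interchange dialect: columns `animal_id`, `collar_type`,
#' `timestamp` (ISO-8601 UTC), `x`, `y` (projected metres).
#'
#' @param trajectories a single trajectory data.frame or a list of them
#' @param path CSV file path
#' @return `write_trajectories` returns `path` invisibly; `read_trajectories`
#'   returns one data.frame with POSIXct timestamps.
#' @export
write_trajectories <- function(trajectories, path) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(
      animal_id = tr$animal_id, collar_type = tr$collar_type,
      timestamp = format(tr$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      x = tr$x, y = tr$y, stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  df
}

#' Screen gross position outliers from a trajectory
#'
#' Removes fixes that imply an out-and-back excursion: a fix is dropped when
#' the legs to both its temporal neighbours exceed a rate-implied threshold
#' (default 5,000 m per 2-h interval, scaled by the actual gap) while the
#' direct neighbour-to-neighbour distance stays ordinary — operationalised
#' as a round-trip excess (leg out + leg back - direct distance) beyond
#' `round_trip_excess_m`.  The rule captures the "tens of km round trip
#' within 4 h" signature of GPS gross errors and is iterated until stable;
#' removed fixes are reported, never silently dropped.
#'
#' @param trajectory data.frame with `timestamp`, `x`, `y` (one animal,
#'   sorted by time)
#' @param max_leg_m_per_interval threshold leg length per nominal interval
#' @param interval_min nominal fix interval in minutes
#' @param round_trip_excess_m minimum implied detour (metres) beyond the
#'   direct neighbour-to-neighbour path
#' @return list with `trajectory` (screened) and `removed` (data.frame of
#'   removed fixes with a `reason` code)
#' @export
screen_outliers <- function(trajectory, max_leg_m_per_interval = 5000,
                            interval_min = 120,
                            round_trip_excess_m = 10000) {
  removed <- trajectory[0, , drop = FALSE]
  if (nrow(trajectory) < 3) {
    warning("fewer than 3 fixes; outlier screening skipped", call. = FALSE)
    removed$reason <- character(0)
    return(list(trajectory = trajectory, removed = removed))
  }
  tr <- trajectory
  repeat {
    n <- nrow(tr)
    if (n < 3) break
    dt_min <- as.numeric(diff(tr$timestamp), units = "mins")
    leg <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    thr <- max_leg_m_per_interval * dt_min / interval_min
    # for interior fix i: legs i-1 (in) and i (out)
    i <- 2:(n - 1)
    d_skip <- sqrt((tr$x[i + 1] - tr$x[i - 1])^2 + (tr$y[i + 1] - tr$y[i - 1])^2)
    excess <- leg[i - 1] + leg[i] - d_skip
    bad <- leg[i - 1] > thr[i - 1] & leg[i] > thr[i] &
      excess > round_trip_excess_m
    if (!any(bad)) break
    # remove one at a time (the worst) so neighbours re-evaluate cleanly
    excess <- pmin(leg[i - 1] / thr[i - 1], leg[i] / thr[i])
    worst <- i[bad][which.max(excess[bad])]
    rem <- tr[worst, , drop = FALSE]
    rem$reason <- "round_trip_outlier"
    removed <- rbind(removed, rem)
    tr <- tr[-worst, , drop = FALSE]
  }
  rownames(tr) <- NULL
  rownames(removed) <- NULL
  list(trajectory = tr, removed = removed)
}

#' Build steps from a screened trajectory
#'
#' One step per consecutive fix pair, with length (m), duration (min),
#' movement rates (m/h and m/min), and the turning angle relative to the
#' previous step's heading (degrees, counter-clockwise positive, in
#' (-180, 180]).  A step is `regular` when its duration is within 10 minutes
#' of the nominal interval; irregular steps are retained (they still carry
#' movement rates) but flagged for exclusion from step-length analyses.
#'
#' @inheritParams screen_outliers
#' @return data.frame of steps: `animal_id`, `t_start`, `t_end`, `x0`, `y0`,
#'   `x1`, `y1`, `length_m`, `duration_min`, `rate_m_hr`, `rate_m_min`,
#'   `heading_deg`, `turning_angle_deg` (NA for the first step), `regular`
#' @export
build_steps <- function(trajectory, interval_min = 120, tolerance_min = 10) {
  n <- nrow(trajectory)
  if (n < 2) {
    stop("need at least 2 fixes to build steps", call. = FALSE)
  }
  dup <- which(diff(as.numeric(trajectory$timestamp)) == 0)
  if (length(dup)) {
    stop(sprintf("duplicate timestamp at fix %d (%s, animal %s)",
                 dup[1] + 1, format(trajectory$timestamp[dup[1] + 1]),
                 trajectory$animal_id[dup[1] + 1]), call. = FALSE)
  }
  dx <- diff(trajectory$x); dy <- diff(trajectory$y)
  len <- sqrt(dx^2 + dy^2)
  dur <- as.numeric(diff(trajectory$timestamp), units = "mins")
  heading <- atan2(dy, dx) * 180 / pi
  turn <- c(NA_real_, wrap_deg(diff(heading)))
  data.frame(
    animal_id = trajectory$animal_id[-n],
    t_start = trajectory$timestamp[-n],
    t_end = trajectory$timestamp[-1],
    x0 = trajectory$x[-n], y0 = trajectory$y[-n],
    x1 = trajectory$x[-1], y1 = trajectory$y[-1],
    length_m = len, duration_min = dur,
    rate_m_hr = len / (dur / 60),
    rate_m_min = len / dur,
    heading_deg = heading,
    turning_angle_deg = turn,
    regular = abs(dur - interval_min) <= tolerance_min,
    stringsAsFactors = FALSE
  )
}

#' Net squared displacement profile
#'
#' Squared straight-line distance (km^2) from the first retained fix to every
#' fix, with elapsed time in days.  The time profile of this statistic
#' separates residency (flat), migration (rise and return) and dispersal
#' (single rise to a plateau).
#'
#' @inheritParams screen_outliers
#' @return data.frame: `timestamp`, `elapsed_days`, `nsd_km2`, plus the
#'   anchoring `x`, `y` coordinates (kept so event windows can recompute
#'   straight-line displacement from raw fixes)
#' @export
compute_nsd <- function(trajectory) {
  if (nrow(trajectory) == 0) stop("empty trajectory", call. = FALSE)
  dx <- (trajectory$x - trajectory$x[1]) / 1000
  dy <- (trajectory$y - trajectory$y[1]) / 1000
  data.frame(
    timestamp = trajectory$timestamp,
    elapsed_days = as.numeric(trajectory$timestamp - trajectory$timestamp[1],
                              units = "days"),
    nsd_km2 = dx^2 + dy^2,
    x = trajectory$x, y = trajectory$y
  )
}

#' Trim a trajectory's capture-affected start
#'
#' Drops the leading hours of a series (default 48 h) where behaviour may
#' reflect capture handling; trimming at the end for mortality/collar failure
#' is the caller's responsibility since it needs fate information.
#'
#' @inheritParams screen_outliers
#' @param trim_start_hr hours to drop from the start
#' @return the trimmed trajectory
#' @export
trim_trajectory <- function(trajectory, trim_start_hr = 48) {
  if (nrow(trajectory) == 0) return(trajectory)
  cutoff <- trajectory$timestamp[1] + trim_start_hr * 3600
  out <- trajectory[trajectory$timestamp >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
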