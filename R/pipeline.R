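#' Default pipeline configuration
#'
#' The single structured config driving [run_pipeline()].  Every default
#' named in the module documentation appears here so a run is fully
#' described by one file.
#'
#' @param out_dir output directory
#' @param rng_seed master seed; all stage seeds derive from it
#' @param extent_km,res_terrain_m,res_ndvi_m,n_roads landscape controls
#' @param n_residents,n_dispersers,n_exploratory,n_migrants cohort counts
#' @param true_betas generating selection coefficients (see
#'   [simulation_config()])
#' @param window_days before/after window width, days
#' @param bin_width_m_min rate histogram bin width for segmented regression
#' @param n_random available steps per stratum
#' @param k_folds,n_perm validation controls
#' @param n_crw_paths null paths per disperser
#' @param trim_start_hr capture-effect trim at the series start
#' @return a named list (class `pipeline_config`)
#' @export
pipeline_config <- function(out_dir = "pipeline_out",
                            rng_seed = 1L,
                            extent_km = 120, res_terrain_m = 250,
                            res_ndvi_m = 500, n_roads = 16,
                            n_residents = 6, n_dispersers = 4,
                            n_exploratory = 2, n_migrants = 4,
                            true_betas = NULL,
                            window_days = 26,
                            bin_width_m_min = 0.5,
                            n_random = 10, k_folds = 5, n_perm = 200,
                            n_crw_paths = 10,
                            trim_start_hr = 48) {
  cfg <- as.list(environment())
  if (is.null(cfg$true_betas)) {
    cfg$true_betas <- simulation_config()$true_betas
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline config file (YAML)
#' @param config a [pipeline_config()]
#' @param path file path
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  # yaml serialises named atomic vectors as bare sequences; keep the names
  cfg$true_betas <- as.list(cfg$true_betas)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, list())
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$true_betas <- unlist(cfg$true_betas)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate, screen, classify, segment, SSF and CRW in
#' dependency order and writes structured reports plus a reproducibility
#' manifest: `trajectories.csv`, `screening_report.csv`,
#' `classification_report.csv`, `nsd_fit_parameters.csv`,
#' `movement_rate_model.csv`, `segmented_fit.csv`, `binned_rates.csv`,
#' `turn_angle_histograms.csv`, `ssf_table.csv`, `ssf_validation.csv`,
#' `broad_scale.csv` and `manifest.json`.  Re-running with the same config
#' reproduces every output bit-identically.
#'
#' @param config a [pipeline_config()] or a path to a YAML config file
#' @param quiet suppress per-stage log lines
#' @return (invisibly) a list with all in-memory stage results and
#'   `out_dir`
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t_all <- proc.time()[3]
  log_stage <- function(stage, n_in, n_out) {
    if (!quiet) {
      message(sprintf("[%s] seed=%d n_in=%s n_out=%s elapsed=%.1fs",
                      stage, config$rng_seed, n_in, n_out,
                      proc.time()[3] - t_all))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$out_dir, f)

  # --- simulate -----------------------------------------------------------
  landscape <- generate_landscape(
    extent_km = config$extent_km, res_terrain_m = config$res_terrain_m,
    res_ndvi_m = config$res_ndvi_m, n_roads = config$n_roads,
    rng_seed = config$rng_seed
  )
  sim_cfg <- simulation_config(
    n_residents = config$n_residents, n_dispersers = config$n_dispersers,
    n_exploratory = config$n_exploratory, n_migrants = config$n_migrants,
    true_betas = config$true_betas, rng_seed = config$rng_seed
  )
  cohort <- suppressWarnings(simulate_cohort(landscape, sim_cfg))
  write_trajectories(cohort$trajectories, outfile("trajectories.csv"))
  log_stage("simulate", length(cohort$trajectories),
            sum(vapply(cohort$trajectories, nrow, integer(1))))

  # --- screen + steps -----------------------------------------------------
  screened <- list(); removed <- list()
  for (a in names(cohort$trajectories)) {
    tr <- trim_trajectory(cohort$trajectories[[a]], config$trim_start_hr)
    sc <- screen_outliers(tr)
    screened[[a]] <- sc$trajectory
    if (nrow(sc$removed)) removed[[a]] <- sc$removed
  }
  rem_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(animal_id = character(0), timestamp = character(0),
               reason = character(0))
  utils::write.csv(rem_df, outfile("screening_report.csv"), row.names = FALSE)
  steps <- lapply(screened, build_steps)
  log_stage("screen", sum(vapply(cohort$trajectories, nrow, integer(1))),
            sum(vapply(screened, nrow, integer(1))))

  # --- classify -----------------------------------------------------------
  nsd <- lapply(screened, compute_nsd)
  classifications <- lapply(names(screened), function(a) {
    out <- try({
      fits <- fit_movement_models(nsd[[a]])
      classify(fits, nsd[[a]])
    }, silent = TRUE)
    if (inherits(out, "try-error")) {
      out <- new_classification("other", NULL, "classification_refused", list())
    }
    out
  })
  names(classifications) <- names(screened)
  class_df <- data.frame(
    animal_id = names(classifications),
    sex = cohort$truth$sex[match(names(classifications),
                                 cohort$truth$animal_id)],
    assigned_type = vapply(classifications, `[[`, character(1),
                           "assigned_type"),
    true_mode = cohort$truth$mode[match(names(classifications),
                                        cohort$truth$animal_id)],
    stringsAsFactors = FALSE
  )
  report <- classification_report(class_df)
  utils::write.csv(report$type_table, outfile("classification_report.csv"),
                   row.names = FALSE)
  fit_rows <- do.call(rbind, lapply(names(classifications), function(a) {
    w <- classifications[[a]]$winning_fit
    if (is.null(w)) return(NULL)
    data.frame(animal_id = a, model = w$model_name,
               parameter = names(w$parameters),
               value = unname(w$parameters), aicc = w$aicc)
  }))
  utils::write.csv(fit_rows, outfile("nsd_fit_parameters.csv"),
                   row.names = FALSE)
  log_stage("classify", length(classifications), nrow(class_df))

  # --- dispersal events, windows, matching --------------------------------
  disp_ids <- names(classifications)[class_df$assigned_type %in%
                                       c("disperser", "exploratory")]
  events <- list(); windows <- list()
  for (a in disp_ids) {
    ev <- try(extract_dispersal_event(nsd[[a]], classifications[[a]]),
              silent = TRUE)
    if (inherits(ev, "try-error")) next
    events[[a]] <- ev
    windows[[a]] <- make_period_windows(ev, config$window_days)
  }
  resident_ids <- names(classifications)[class_df$assigned_type == "resident"]
  spans <- lapply(screened[resident_ids], function(tr) {
    range(as.Date(tr$timestamp))
  })
  pairing <- suppressWarnings(match_residents(windows, spans))
  matched <- pairing[!is.na(pairing$resident), , drop = FALSE]
  log_stage("windows", length(disp_ids), nrow(matched))

  # --- movement-rate mixed models -----------------------------------------
  rate_models <- list()
  disp_steps <- do.call(rbind, steps[names(windows)])
  if (length(windows) >= 2) {
    rate_models$dispersers <- try(
      fit_rate_period_model(disp_steps, windows), silent = TRUE)
  }
  if (nrow(matched) >= 2) {
    res_windows <- windows[matched$disperser]
    names(res_windows) <- matched$resident
    res_steps <- do.call(rbind, steps[matched$resident])
    rate_models$residents <- try(
      fit_rate_period_model(res_steps, res_windows), silent = TRUE)
  }
  rate_rows <- do.call(rbind, lapply(names(rate_models), function(g) {
    m <- rate_models[[g]]
    if (inherits(m, "try-error")) return(NULL)
    cbind(group = g, m$coefficients)
  }))
  utils::write.csv(rate_rows, outfile("movement_rate_model.csv"),
                   row.names = FALSE)
  log_stage("rates", length(rate_models), NROW(rate_rows))

  # --- segmented regression on during-dispersal rates ---------------------
  during_steps <- do.call(rbind, lapply(names(windows), function(a) {
    st <- steps[[a]]
    st[st$regular &
         as.character(assign_period(st$t_start, windows[[a]])) == "during", ,
       drop = FALSE]
  }))
  seg <- fit_segmented(during_steps$rate_m_min, config$bin_width_m_min)
  split <- if (seg$breakpoint_found) {
    split_steps(during_steps, seg$psi)
  } else NULL
  utils::write.csv(
    data.frame(psi_m_min = seg$psi, psi_se = seg$psi_se,
               threshold_m = if (!is.null(split)) split$threshold_m else NA,
               r2_segmented = seg$r2_segmented, r2_null = seg$r2_null,
               n_short = if (!is.null(split)) nrow(split$short) else NA,
               n_long = if (!is.null(split)) nrow(split$long) else NA),
    outfile("segmented_fit.csv"), row.names = FALSE)
  utils::write.csv(seg$bins, outfile("binned_rates.csv"), row.names = FALSE)
  if (!is.null(split)) {
    utils::write.csv(split$turn_hist, outfile("turn_angle_histograms.csv"),
                     row.names = FALSE)
  }
  log_stage("segment", nrow(during_steps),
            if (is.null(split)) 0 else nrow(split$long))

  # --- SSF suite ----------------------------------------------------------
  period_steps <- function(ids, win_of) {
    lapply(stats::setNames(ids, ids), function(a) {
      st <- steps[[a]]
      lab <- as.character(assign_period(st$t_start, win_of[[a]]))
      split(st, lab)
    })
  }
  disp_by_period <- period_steps(names(windows), windows)
  res_win <- windows[matched$disperser]
  names(res_win) <- matched$resident
  res_by_period <- period_steps(matched$resident, res_win)
  strata_for <- function(by_period, period, seed_off) {
    sl <- lapply(by_period, function(x) x[[period]])
    sl <- Filter(function(x) !is.null(x) && nrow(x) > 2, sl)
    if (length(sl) < 2) return(NULL)
    try(build_strata(sl, landscape, n_random = config$n_random,
                     seed = config$rng_seed + seed_off), silent = TRUE)
  }
  strata_by_model <- list(
    dispersers_before = strata_for(disp_by_period, "before", 11L),
    dispersers_during = strata_for(disp_by_period, "during", 12L),
    dispersers_after = strata_for(disp_by_period, "after", 13L),
    residents_before = strata_for(res_by_period, "before", 21L),
    residents_during = strata_for(res_by_period, "during", 22L),
    residents_after = strata_for(res_by_period, "after", 23L)
  )
  strata_by_model <- lapply(strata_by_model, function(x) {
    if (inherits(x, "try-error")) NULL else x
  })
  du <- strata_by_model$dispersers_during
  if (!is.null(du) && !is.null(split)) {
    strata_by_model$during_long <- du[du$obs_length_m >= split$threshold_m, ]
    strata_by_model$during_short <- du[du$obs_length_m < split$threshold_m, ]
  } else {
    strata_by_model$during_long <- NULL
    strata_by_model$during_short <- NULL
  }
  suite <- run_model_suite(strata_by_model, k = config$k_folds,
                           n_perm = config$n_perm, seed = config$rng_seed,
                           min_strata_per_animal = 20)
  if (!is.null(suite$table)) {
    utils::write.csv(suite$table, outfile("ssf_table.csv"), row.names = FALSE)
  }
  val_rows <- do.call(rbind, lapply(names(suite$models), function(mid) {
    m <- suite$models[[mid]]
    if (!isTRUE(m$estimable)) {
      return(data.frame(model = mid, mean_rs = NA, null_q95 = NA,
                        useful = NA, note = m$reason))
    }
    data.frame(model = mid, mean_rs = m$validation$mean_rs,
               null_q95 = m$validation$null_q95,
               useful = m$validation$useful, note = "")
  }))
  utils::write.csv(val_rows, outfile("ssf_validation.csv"), row.names = FALSE)
  log_stage("ssf", length(strata_by_model),
            sum(vapply(suite$models, function(m) isTRUE(m$estimable),
                       logical(1))))

  # --- broad scale --------------------------------------------------------
  broad <- NULL
  if (!is.null(split) && length(windows) >= 2) {
    long_by_animal <- lapply(stats::setNames(names(windows), names(windows)),
                             function(a) {
      st <- disp_by_period[[a]][["during"]]
      if (is.null(st)) return(st)
      st <- st[st$regular, , drop = FALSE]
      st[st$length_m >= split$threshold_m, , drop = FALSE]
    })
    long_by_animal <- Filter(Negate(is.null), long_by_animal)
    broad <- broad_scale_test(long_by_animal, landscape,
                              n_paths = config$n_crw_paths,
                              seed = config$rng_seed + 41L)
    if (!is.null(broad$result)) {
      utils::write.csv(broad$result$table, outfile("broad_scale.csv"),
                       row.names = FALSE)
    }
  }
  log_stage("crw", length(windows),
            if (is.null(broad) || is.null(broad$coefs)) 0 else
              nrow(broad$coefs))

  # --- manifest -----------------------------------------------------------
  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    config = unclass(config),
    seed = config$rng_seed,
    package_version = as.character(utils::packageVersion("dispersalSSF")),
    n_animals = length(cohort$trajectories),
    n_fixes = sum(vapply(screened, nrow, integer(1))),
    n_removed_fixes = nrow(rem_df),
    n_dispersal_events = length(events),
    n_matched_pairs = nrow(matched),
    file_digests = as.list(tools::md5sum(sort(outputs)))
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    landscape = landscape, cohort = cohort, screened = screened,
    steps = steps, classifications = classifications, report = report,
    events = events, windows = windows, pairing = pairing,
    rate_models = rate_models, segmented = seg, split = split,
    suite = suite, broad = broad, out_dir = config$out_dir
  ))
}
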