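# Shared fixtures: one small-but-valid landscape, built once per test run.
# 120 km extent (the minimum that fits long dispersals) at coarse grid
# resolution so the whole suite stays fast.

test_world <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$L)) {
      cache$L <- generate_landscape(
        extent_km = 120, res_terrain_m = 300, res_ndvi_m = 500,
        n_roads = 16, rng_seed = 11
      )
    }
    cache$L
  }
})

# covariate column order used throughout
ssf_cols <- c("ruggedness", "ruggedness_sq", "ndvi", "dist_roads",
              "canopy", "canopy_sq")

zero_betas <- stats::setNames(rep(0, 6), ssf_cols)

# a toy trajectory data.frame from coordinate/time vectors
make_traj <- function(x, y, t0 = as.POSIXct("2008-04-01", tz = "UTC"),
                      step_min = 120, animal_id = "t1") {
  data.frame(
    animal_id = animal_id, collar_type = "lotek",
    timestamp = t0 + (seq_along(x) - 1) * step_min * 60,
    x = x, y = y, stringsAsFactors = FALSE
  )
}

# noiseless logistic NSD profile sampled daily, with planar coordinates
# consistent with the displacement (movement along the x axis)
sigmoid_profile <- function(delta, theta, phi, days = 214, per_day = 4) {
  t <- seq(0, days, by = 1 / per_day)
  nsd <- delta / (1 + exp((theta - t) / phi))
  data.frame(
    timestamp = as.POSIXct("2008-04-01", tz = "UTC") + t * 86400,
    elapsed_days = t, nsd_km2 = nsd,
    x = sqrt(nsd) * 1000, y = 0
  )
}
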