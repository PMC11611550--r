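# Shared fixtures, built once per test run and cached in-process.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a small symmetric phantom with simulated dose arms
small_phantom <- function() fixture("small_phantom", function() {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size_mm = c(4, 4, 4),
                       total_counts_standard = 2e6, seed = 42L)
  ph <- build_phantom(spec)
  sd <- simulate_standard_dose(ph$activity, spec)
  ld <- simulate_low_dose(sd, spec)
  list(spec = spec, activity = ph$activity, labels = ph$labels,
       sd = sd, ld = ld)
})

# the same phantom with one hypometabolic (0.6x) left-hemisphere lesion
lesion_phantom <- function() fixture("lesion_phantom", function() {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), voxel_size_mm = c(3, 3, 3),
                       lesions = list(list(center = c(16, 24, 22),
                                           radius_mm = 9, multiplier = 0.6)),
                       seed = 43L)
  ph <- build_phantom(spec)
  list(spec = spec, activity = ph$activity, labels = ph$labels)
})

# tiny attention configuration usable at narrow channel widths
tiny_ssab_cfg <- function(...) {
  ssab_config(sa_reduction = 2L, ca_reduction = 2L, spatial_kernel = 3L,
              window_size = 3L, ...)
}

# finite-difference gradient checker for tape graphs: `fun(tape, pnodes)`
# must return a scalar node
fd_gradient_check <- function(fun, params, n_probe = 3L, eps = 1e-6,
                              tol = 1e-4) {
  tape <- petgan:::tg_tape()
  pn <- lapply(params, function(p) petgan:::tg_param(tape, p))
  loss <- fun(tape, pn)
  petgan:::tg_backward(loss)
  worst <- 0
  for (nm in names(params)) {
    g <- pn[[nm]]$grad
    if (is.null(g)) next
    idx <- sample(length(params[[nm]]), min(n_probe, length(params[[nm]])))
    for (i in idx) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      t2 <- petgan:::tg_tape()
      l2 <- fun(t2, lapply(pp, function(p) petgan:::tg_param(t2, p)))
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      t3 <- petgan:::tg_tape()
      l3 <- fun(t3, lapply(pp, function(p) petgan:::tg_param(t3, p)))
      num <- (l2$value - l3$value) / (2 * eps)
      worst <- max(worst, abs(num - g[i]) / (1 + abs(num)))
    }
  }
  worst
}
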