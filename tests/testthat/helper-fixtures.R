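# Shared fixtures. Expensive simulations are cached per test session so
# several test files can interrogate the same run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a small, fast parameter set for kernel-level tests (not the calibrated
# excitable regime): few nodes, cheap steps
tiny_params <- function() {
  geom <- hf_geometry(grid_spacing = 0.1, length_min = 0.6, length_max = 1.2,
                      region1 = c(0.1, 0.3), region2_width = 0.2)
  act <- pathway_params(0.1, 0.05, list(telogen = 1, anagen = 2),
                        bind_on = 1, bind_off = 0.2, degradation = 0.1,
                        receptor_total = 1)
  inh <- pathway_params(0.1, 0.05, list(telogen = 0.1, anagen = 1),
                        bind_on = 1, bind_off = 0.2, degradation = 0.1,
                        receptor_total = 1)
  list(geometry = geom, act = act, inh = inh,
       thresholds = phase_thresholds(0.4, 0.05, 1))
}

# pathway with all sources, sinks and binding off: pure diffusion
closed_pathway <- function(D = 0.1) {
  pathway_params(D, 0, list(telogen = 0, anagen = 0),
                 bind_on = 0, bind_off = 0, degradation = 0,
                 receptor_total = 1)
}

trapz <- function(v, dx) dx * (sum(v) - 0.5 * (v[1] + v[length(v)]))

# the calibrated default single-follicle trajectory, shared across files
default_traj <- function() {
  cached("default_traj", {
    p <- hf_defaults()
    simulate_hf(p$act, p$inh, p$geometry, p$thresholds,
                horizon = 450, dt = p$numerics$dt)
  })
}

# the homogeneous-sheet scenario (asynchrony persistence), reduced lattice
persistence_record <- function() {
  cached("persistence_record", {
    cfg <- preset_config("homogeneous_sheet")
    cfg$lattice$nrow <- 12
    cfg$lattice$ncol <- 12
    cfg$numerics$horizon <- 1050
    run_scenario(cfg, file.path(tempdir(), "t1_test"))$result
  })
}

# the two-domain scenario, as configured by the preset
two_domain_record <- function() {
  cached("two_domain_record", {
    cfg <- preset_config("two_domain")
    run_scenario(cfg, file.path(tempdir(), "t2_test"))$result
  })
}

# established-wave scenarios shared by the wave and acceptance tests
feature_record <- function(key, features = list()) {
  cached(paste0("wave_", key), {
    lat <- build_lattice(16, 16, coupling_strength = 0.05,
                         features = features)
    init <- initial_conditions(head_tail_span = 8, jitter_sd = 0)
    simulate_population(lat, init, horizon = 250,
                        dt = hf_defaults()$numerics$dt, seed = 2)
  })
}
open_record <- function() feature_record("open")
barrier_record <- function()
  feature_record("barrier", list(barrier = cbind(8, 4:13)))
aperture_record <- function()
  feature_record("aperture", list(barrier = cbind(8, c(1:6, 11:16))))
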