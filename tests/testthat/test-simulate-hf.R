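# Whole-trajectory behavior of the single follicle.

test_that("horizon 0 returns only the initial state", {
  p <- hf_defaults()
  traj <- simulate_hf(p$act, p$inh, p$geometry, p$thresholds,
                      horizon = 0, dt = p$numerics$dt)
  expect_equal(length(traj$time), 1)
  expect_equal(traj$time, 0)
  expect_equal(traj$phase, "telogen")
  expect_equal(nrow(traj$transitions), 0)
})

test_that("the default regime cycles stably: >= 5 cycles, period CV < 1%", {
  traj <- default_traj()
  pd <- phase_durations(traj)
  expect_gte(nrow(pd), 5)
  after <- pd[pd$cycle > 2, ]
  expect_lt(sd(after$period) / mean(after$period), 0.01)
  # concentrations stay in range throughout
  expect_true(all(is.finite(traj$signal)))
  expect_true(all(traj$length >= hf_defaults()$geometry$length_min - 1e-9))
  expect_true(all(traj$length <= hf_defaults()$geometry$length_max + 1e-9))
  expect_identical(traj$clip_events, 0L)
})

test_that("bound receptor levels never exceed receptor_total", {
  traj <- default_traj()
  expect_true(all(traj$mean_bound_act <= hf_defaults()$act$receptor_total + 1e-12))
  expect_true(all(traj$mean_bound_act >= 0))
  expect_true(all(traj$mean_bound_inh >= 0))
})

test_that("strong inhibitor production leads to an extended telogen", {
  p <- hf_defaults()
  inh <- haircycle:::scale_inhibitor(p$inh, 3)
  traj <- simulate_hf(p$act, inh, p$geometry, p$thresholds,
                      horizon = 300, dt = p$numerics$dt)
  ana <- traj$transitions[traj$transitions$to == "anagen", ]
  expect_lte(nrow(ana), 1)  # at most the initial poised entry
  expect_equal(traj$phase[length(traj$phase)], "telogen")
})

test_that("a fixed seed gives a bit-identical noisy trajectory", {
  p <- hf_defaults()
  p$act$noise_amplitude <- 0.02
  p$inh$noise_amplitude <- 0.02
  run <- function(seed) simulate_hf(p$act, p$inh, p$geometry, p$thresholds,
                                    horizon = 60, dt = p$numerics$dt,
                                    seed = seed)
  a <- run(11); b <- run(11); c <- run(12)
  expect_identical(a$signal, b$signal)
  expect_identical(a$transitions, b$transitions)
  expect_false(identical(a$signal, c$signal))
})

test_that("noise perturbs but does not destroy cycling, with few clips", {
  p <- hf_defaults()
  p$act$noise_amplitude <- 0.02
  p$inh$noise_amplitude <- 0.02
  traj <- simulate_hf(p$act, p$inh, p$geometry, p$thresholds,
                      horizon = 300, dt = p$numerics$dt, seed = 5)
  pd <- suppressWarnings(phase_durations(traj))
  expect_gte(nrow(pd), 2)
  # clip events are rare relative to node-steps
  node_steps <- 4 * 7 * 300 / p$numerics$dt
  expect_lt(traj$clip_events / node_steps, 0.001)
})

test_that("phase_durations extracts scripted transitions exactly", {
  tr <- data.frame(
    time = c(0, 10, 25, 37, 50),
    from = c("telogen", "anagen", "telogen", "anagen", "telogen"),
    to = c("anagen", "telogen", "anagen", "telogen", "anagen"),
    cycle_index = c(1L, 1L, 2L, 2L, 3L))
  pd <- phase_durations(tr)
  expect_equal(pd$anagen, c(10, 12))
  expect_equal(pd$telogen, c(15, 13))
  expect_equal(pd$period, c(25, 25))
  expect_warning(phase_durations(tr[1:2, ]), "no complete cycle")
})

test_that("noise-free periodic trajectories have identical rows after transient", {
  pd <- phase_durations(default_traj())
  after <- pd[pd$cycle > 2, ]
  expect_lt(max(after$anagen) - min(after$anagen), 0.1)
  expect_lt(max(after$telogen) - min(after$telogen), 0.1)
})

test_that("halving dt and grid spacing changes the period by < 2%", {
  p <- hf_defaults()
  per <- function(geom, dt) {
    tr <- simulate_hf(p$act, p$inh, geom, p$thresholds, horizon = 250,
                      dt = dt)
    d <- suppressWarnings(phase_durations(tr))
    mean(d$period[d$cycle > 1])
  }
  p_base <- cached("per_base", per(p$geometry, p$numerics$dt))
  p_fine <- cached("per_fine",
                   per(hf_geometry(grid_spacing = p$geometry$grid_spacing / 2),
                       p$numerics$dt / 4))
  expect_lt(abs(p_fine - p_base) / p_base, 0.02)
})

test_that("inhibitor scan: anagen shortens, telogen lengthens, extremes stall", {
  sc <- cached("scan_table", {
    inhibitor_strength_scan(hf_defaults(),
                            levels = c(0.5, 0.7, 0.85, 1, 1.1, 1.2, 1.5),
                            horizon = 420)
  })
  mid <- sc[sc$cycling, ]
  expect_gte(nrow(mid), 3)
  expect_true(all(diff(mid$anagen) <= 1e-9))
  expect_true(all(diff(mid$telogen) >= -1e-9))
  # low extreme: equilibrates in extended anagen
  expect_false(sc$cycling[1])
  expect_equal(sc$terminal_phase[1], "anagen")
  # high extreme: equilibrates in extended telogen
  expect_false(sc$cycling[nrow(sc)])
  expect_equal(sc$terminal_phase[nrow(sc)], "telogen")
})
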