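# Single-follicle step operations: reaction-diffusion kernel, growth signal,
# geometry update, phase checkpoints.

test_that("closed-system ligand mass is conserved by the diffusion kernel", {
  p <- tiny_params()
  act <- closed_pathway(0.1)
  inh <- closed_pathway(0.05)
  st <- new_hf_state(p$geometry, act, inh, init = "zero")
  # uneven initial profile
  n <- length(st$ligand_act)
  st$ligand_act <- exp(-seq_len(n))
  st$ligand_inh <- seq_len(n) / n
  dx <- p$geometry$grid_spacing
  m0a <- trapz(st$ligand_act, dx)
  m0i <- trapz(st$ligand_inh, dx)
  for (i in 1:1000) st <- reaction_diffusion_step(st, act, inh, dt = 0.04)
  expect_lt(abs(trapz(st$ligand_act, dx) - m0a) / m0a, 1e-10)
  expect_lt(abs(trapz(st$ligand_inh, dx) - m0i) / m0i, 1e-10)
  expect_identical(st$clip_events, 0L)
})

test_that("a uniform ligand field is a fixed point of pure diffusion", {
  p <- tiny_params()
  act <- closed_pathway(0.1)
  st <- new_hf_state(p$geometry, act, act, init = "zero")
  st$ligand_act <- rep(0.7, length(st$ligand_act))
  st2 <- reaction_diffusion_step(st, act, act, dt = 0.04)
  expect_equal(st2$ligand_act, st$ligand_act, tolerance = 1e-14)
})

test_that("one coarse step matches a fine-step reference within O(dt)", {
  p <- tiny_params()
  st0 <- new_hf_state(p$geometry, p$act, p$inh, signal0 = 0.2)
  dt <- 0.02
  coarse <- reaction_diffusion_step(st0, p$act, p$inh, dt)
  fine <- st0
  for (i in 1:1000)
    fine <- reaction_diffusion_step(fine, p$act, p$inh, dt / 1000)
  for (f in c("ligand_act", "ligand_inh", "bound_act", "bound_inh")) {
    err <- max(abs(coarse[[f]] - fine[[f]]))
    # explicit Euler local error: O(dt^2) per step with an O(1) constant
    expect_lt(err, 5 * dt^2)
  }
})

test_that("growth_signal is the bulge mean of bound differences", {
  p <- tiny_params()
  st <- new_hf_state(p$geometry, p$act, p$inh, init = "zero")
  expect_equal(growth_signal(st), 0)

  # constant fields on the receptor support: weights cancel
  ctx <- haircycle:::make_ctx(p$geometry)
  st$bound_act[ctx$phirows] <- 2 * ctx$phi[ctx$phirows]
  st$bound_inh[ctx$phirows] <- 0.5 * ctx$phi[ctx$phirows]
  expect_equal(growth_signal(st), 1.5)

  # piecewise-linear profile: direct summation oracle
  prof_a <- 0.1 * seq_along(st$bound_act)
  prof_i <- rev(prof_a) / 2
  st$bound_act <- prof_a * 0
  st$bound_inh <- prof_i * 0
  st$bound_act[ctx$phirows] <- prof_a[ctx$phirows]
  st$bound_inh[ctx$phirows] <- prof_i[ctx$phirows]
  oracle <- sum(prof_a[ctx$phirows] - prof_i[ctx$phirows]) / sum(ctx$phi)
  expect_equal(growth_signal(st), oracle)
})

test_that("geometry_step clamps length and preserves re-gridded field mass", {
  p <- tiny_params()
  st <- new_hf_state(p$geometry, p$act, p$inh, signal0 = 0.2)
  n0 <- length(st$ligand_act)
  st$ligand_act <- seq(1, 0.2, length.out = n0)

  # zero velocity: nothing changes
  same <- geometry_step(st, 0.5, function(s, a) 0, dt = 1)
  expect_equal(same$geometry$length0, st$geometry$length0)
  expect_equal(same$ligand_act, st$ligand_act)

  # clamp at length_max
  st_max <- st
  st_max$geometry$length0 <- p$geometry$length_max
  clamped <- geometry_step(st_max, 0.5, function(s, a) 1, dt = 1)
  expect_equal(clamped$geometry$length0, p$geometry$length_max)

  # elongation by exactly one grid cell: trapezoidal mass preserved
  dx <- p$geometry$grid_spacing
  st$phase <- "anagen"
  m0 <- trapz(st$ligand_act, dx)
  grown <- geometry_step(st, 0.5, function(s, a) dx, dt = 1)
  expect_equal(length(grown$ligand_act), n0 + 1)
  expect_lt(abs(trapz(grown$ligand_act, dx) - m0) / m0, 1e-8)

  # retraction by one cell: mass carried upward, also preserved
  shrunk <- geometry_step(grown, 0, function(s, a) -dx, dt = 1)
  expect_equal(length(shrunk$ligand_act), n0)
  expect_lt(abs(trapz(shrunk$ligand_act, dx) - m0) / m0, 1e-8)
})

test_that("checkpoints gate on thresholds and the dwell guard", {
  p <- tiny_params()
  thr <- p$thresholds
  st <- new_hf_state(p$geometry, p$act, p$inh, init = "zero")
  st$phase_elapsed <- 10

  # below both thresholds in telogen: nothing
  st2 <- checkpoint_update(st, 0.1, thr)
  expect_equal(st2$phase, "telogen")
  expect_equal(nrow(st2$transitions), 0)

  # crossing during the dwell window: guarded
  st$phase_elapsed <- 0.5
  st3 <- checkpoint_update(st, 0.9, thr)
  expect_equal(st3$phase, "telogen")

  # crossing after the dwell window: transition logged with time
  st$phase_elapsed <- 2
  st$time <- 12.5
  st4 <- checkpoint_update(st, 0.9, thr)
  expect_equal(st4$phase, "anagen")
  expect_equal(st4$transitions$time, 12.5)
  expect_equal(st4$transitions$cycle_index, 1L)
})

test_that("a sinusoidal signal produces exactly two transitions per period", {
  p <- tiny_params()
  thr <- phase_thresholds(0.3, -0.3, refractory_min = 1)
  st <- new_hf_state(p$geometry, p$act, p$inh, init = "zero")
  dt <- 0.05
  period <- 20
  n_per <- 5
  for (k in seq_len(n_per * period / dt)) {
    st$time <- k * dt
    st$phase_elapsed <- st$phase_elapsed + dt
    sig <- 0.8 * sin(2 * pi * st$time / period)
    st <- checkpoint_update(st, sig, thr)
  }
  expect_equal(nrow(st$transitions), 2 * n_per)
  expect_equal(sum(st$transitions$to == "anagen"), n_per)
})
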