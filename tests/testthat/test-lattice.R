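# Lattice construction, the exchange operator, and population simulation
# invariants.

test_that("build_lattice counts sites and resolves domains exactly", {
  lat <- build_lattice(10, 10, coupling_strength = 0.1)
  expect_equal(length(lat$sites), 100)
  expect_true(all(lat$domain[lat$sites] == "base"))

  # striped two-domain layout: site counts match mask areas
  vmask <- matrix(FALSE, 10, 12)
  vmask[, c(1:3, 10:12)] <- TRUE
  lat2 <- build_lattice(10, 12, domains = list(
    domain_spec("Ventral", vmask), domain_spec("Dorsal", !vmask)))
  expect_equal(sum(lat2$domain == "Ventral", na.rm = TRUE), 60)
  expect_equal(sum(lat2$domain == "Dorsal", na.rm = TRUE), 60)

  # aperture hole: follicle count = total - k
  hole <- cbind(rep(4:5, each = 3), rep(2:4, 2))
  lat3 <- build_lattice(8, 8, features = list(aperture = hole))
  expect_equal(length(lat3$sites), 64 - 6)

  # overlapping domain masks are rejected
  expect_error(build_lattice(4, 4, domains = list(
    domain_spec("A", matrix(TRUE, 4, 4)),
    domain_spec("B", matrix(TRUE, 4, 4)))), "overlap")
})

test_that("exchange conserves mass, is antisymmetric, and matches the stencil", {
  p <- tiny_params()
  mk_state <- function(la) {
    st <- new_hf_state(p$geometry, p$act, p$inh, init = "zero")
    st$ligand_act[] <- la
    st
  }
  # two-site array with L = (1, 0): symmetric mass transfer
  lat <- build_lattice(2, 1, coupling_strength = 0.2)
  sts <- list(mk_state(1), mk_state(0))
  out <- coupling_step(sts, lat, dt = 0.1)
  band <- haircycle:::make_ctx(p$geometry)$r1rows
  d1 <- sts[[1]]$ligand_act[band] - out[[1]]$ligand_act[band]
  d2 <- out[[2]]$ligand_act[band] - sts[[2]]$ligand_act[band]
  expect_equal(d1, d2)                       # antisymmetry
  expect_equal(d1, rep(0.2 * 0.1 * 1, length(band)))

  # identical states: exchange is a no-op
  same <- coupling_step(list(mk_state(0.5), mk_state(0.5)), lat, dt = 0.1)
  expect_equal(same[[1]]$ligand_act, mk_state(0.5)$ligand_act)

  # 3x3 lattice, center site loaded: one step matches the 4-neighbor
  # Laplacian computed by hand
  lat9 <- build_lattice(3, 3, coupling_strength = 0.1)
  sts9 <- c(rep(list(mk_state(0)), 4), list(mk_state(1)),
            rep(list(mk_state(0)), 4))
  out9 <- coupling_step(sts9, lat9, dt = 0.1)
  got <- vapply(out9, function(s) s$ligand_act[band[1]], numeric(1))
  lap <- c(0, 0.01, 0, 0.01, 1 - 4 * 0.01, 0.01, 0, 0.01, 0)
  expect_equal(got, lap)
  # lattice-total band mass conserved exactly
  expect_equal(sum(vapply(out9, function(s) sum(s$ligand_act[band]),
                          numeric(1))),
               sum(vapply(sts9, function(s) sum(s$ligand_act[band]),
                          numeric(1))))
})

test_that("zero coupling factorizes into independent single-follicle runs", {
  p <- hf_defaults()
  p$act$noise_amplitude <- 0.02   # noise makes the check non-trivial
  lat <- build_lattice(2, 2, coupling_strength = 0)
  init <- initial_conditions(head_tail_span = 0, lateral_span = 0,
                             jitter_sd = 0)
  rec <- simulate_population(lat, init, horizon = 40, dt = p$numerics$dt,
                             seed = 9, base = p)
  for (s in 1:4) {
    solo <- simulate_hf(p$act, p$inh, p$geometry, p$thresholds,
                        horizon = 40, dt = p$numerics$dt, seed = 9,
                        stream = s - 1L,
                        signal0 = p$thresholds$activation + 0.02)
    expect_identical(rec$signal[, s], solo$signal)
    expect_identical(rec$length[, s], solo$length)
  }
})

test_that("population runs are bit-identical under a fixed seed", {
  p <- hf_defaults()
  p$act$noise_amplitude <- 0.01
  lat <- build_lattice(3, 3, coupling_strength = 0.02)
  init <- initial_conditions(head_tail_span = 2, jitter_sd = 0.5)
  r1 <- simulate_population(lat, init, 30, p$numerics$dt, seed = 4, base = p)
  r2 <- simulate_population(lat, init, 30, p$numerics$dt, seed = 4, base = p)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$transitions, r2$transitions)
})

test_that("identical uncoupled noise-free sites stay exactly synchronized", {
  p <- hf_defaults()
  lat <- build_lattice(2, 3, coupling_strength = 0)
  init <- initial_conditions(head_tail_span = 0, jitter_sd = 0)
  rec <- simulate_population(lat, init, horizon = 120, dt = p$numerics$dt,
                             base = p)
  expect_true(all(apply(rec$signal, 1, function(r) max(r) - min(r)) == 0))
  expect_true(all(apply(rec$phase, 1, function(r) length(unique(r))) == 1))
})

test_that("make_hyper_refractory elevates inhibitor sources multiplicatively", {
  d <- domain_spec("Ear")
  expect_identical(make_hyper_refractory(d, 1), d)
  d2 <- make_hyper_refractory(d, 3)
  expect_equal(d2$overrides$inhibitor_scale, 3)
  d3 <- make_hyper_refractory(d2, 2)
  expect_equal(d3$overrides$inhibitor_scale, 6)
  expect_error(make_hyper_refractory(d, 0.5), ">= 1")
})

test_that("an isolated hyper-refractory follicle stops after its first cycle", {
  p <- hf_defaults()
  inh <- haircycle:::scale_inhibitor(p$inh, 2)
  traj <- simulate_hf(p$act, inh, p$geometry, p$thresholds, horizon = 250,
                      dt = p$numerics$dt)
  ana <- traj$transitions[traj$transitions$to == "anagen", ]
  expect_lte(nrow(ana), 1)
  expect_true(all(ana$time < 50))
})
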