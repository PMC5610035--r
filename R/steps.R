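#' Advance the reaction-diffusion signaling of one follicle by one step
#'
#' One explicit (Euler, central-difference) step of the coupled ligand and
#' bound-receptor dynamics on the follicle axis. Free ligand diffuses with
#' no-flux ends, is produced at a constant rate in region I and at a
#' phase-scheduled rate in region II, binds free receptors in region I at
#' `bind_on * L * (receptor_total - LR)`, receives `bind_off * LR` back from
#' the complex, and decays. The bound complex gains the binding flux, loses
#' dissociation and degradation, and receives the deterministic extra source
#' plus, when `noise_amplitude > 0`, additive Gaussian increments scaled by
#' `noise_amplitude * sqrt(dt)` drawn from the follicle's counter-based
#' stream. Negative values are clipped to zero and counted in
#' `$clip_events`; geometry and phase are not touched.
#'
#' @param state An [new_hf_state()] object.
#' @param act,inh [pathway_params()] for the two pathways.
#' @param dt Time step (days); must satisfy the explicit stability bound
#'   `dt <= grid_spacing^2 / (2 max diffusion_coeff)`.
#' @return The advanced `hf_state` (time and rng step incremented).
#' @export
reaction_diffusion_step <- function(state, act, inh, dt) {
  check_stability(dt, state$geometry, act, inh)
  ctx <- make_ctx(state$geometry)
  n <- active_node_count(state$geometry$length0, ctx$dx)
  masks <- make_masks(ctx, n)
  fields <- state_as_fields(state, ctx)
  w2m <- region2_weights(ctx, n, masks$a)
  par <- list(act = site_pathway(act), inh = site_pathway(inh))
  n1 <- length(ctx$phirows)
  z_act <- z_inh <- NULL
  if (act$noise_amplitude > 0 || inh$noise_amplitude > 0) {
    z_act <- .ct_normals(state$rng$seed, state$rng$stream, state$rng$step, n1, 0)
    z_inh <- .ct_normals(state$rng$seed, state$rng$stream, state$rng$step, n1, n1)
  }
  upd <- rd_update(fields, ctx, par, masks, w2m,
                   phase_anagen = state$phase == "anagen", dt = dt,
                   z_act = z_act, z_inh = z_inh)
  upd$clips <- upd$clips_ligand + upd$clips_bound
  for (nm in names(upd$fields)) {
    v <- upd$fields[[nm]][seq_len(n), 1]
    if (any(!is.finite(v)))
      stop("integration failure: non-finite values in field ", nm)
  }
  state <- fields_into_state(state, upd$fields, n)
  state$clip_events <- state$clip_events + upd$clips
  state$time <- state$time + dt
  state$phase_elapsed <- state$phase_elapsed + dt
  state$rng$step <- state$rng$step + 1
  state
}

#' Growth signal of a follicle
#'
#' The scalar C driving growth and the phase checkpoints: the mean over
#' region I (bulge) grid nodes of bound activator minus bound inhibitor.
#' Positive values favor growth.
#'
#' @param state An `hf_state`.
#' @return A single number.
#' @export
growth_signal <- function(state) {
  ctx <- make_ctx(state$geometry)
  n <- active_node_count(state$geometry$length0, ctx$dx)
  rows <- ctx$phirows[ctx$phirows <= n]
  if (length(rows) == 0)
    stop("geometry error: region I contains no grid node")
  sum(state$bound_act[rows] - state$bound_inh[rows]) / ctx$phi_sum
}

#' Advance follicle geometry under a growth law
#'
#' Updates the follicle length by `velocity * dt`, where the velocity comes
#' from `growth_law(signal, anagen)`, clamps to `[length_min, length_max]`,
#' keeps region II attached to the distal tip, and re-grids the ligand fields:
#' nodes are inserted (constant distal extrapolation) or removed at the tip
#' and the fields rescaled so the trapezoidal mass of each is preserved.
#'
#' @param state An `hf_state`.
#' @param signal Growth signal value (see [growth_signal()]).
#' @param growth_law A function `f(signal, anagen)` returning a signed
#'   velocity, e.g. [default_growth_law()].
#' @param dt Time step (days).
#' @return The updated `hf_state`.
#' @export
geometry_step <- function(state, signal, growth_law, dt) {
  g <- state$geometry
  ctx <- make_ctx(g)
  v <- growth_law(signal, state$phase == "anagen")
  len_new <- min(max(g$length0 + v * dt, g$length_min), g$length_max)
  n_old <- active_node_count(g$length0, ctx$dx)
  n_new <- active_node_count(len_new, ctx$dx)
  if (n_new != n_old) {
    fields <- state_as_fields(state, ctx)
    fields <- regrid_fields(fields, ctx, n_old, n_new, 1L)
    state <- fields_into_state(state, fields, n_new)
  }
  state$geometry$length0 <- len_new
  state
}

#' Apply the phase checkpoints to a follicle
#'
#' Implements the two hair cycle checkpoints: a telogen follicle whose signal
#' exceeds the activation threshold enters anagen, and an anagen follicle
#' whose signal drops below the termination threshold enters telogen, in both
#' cases only after at least `refractory_min` days in the current phase.
#' Transitions are appended to `state$transitions` with the current time.
#'
#' @param state An `hf_state`.
#' @param signal Growth signal value.
#' @param thresholds A [phase_thresholds()] object.
#' @return The updated `hf_state`.
#' @export
checkpoint_update <- function(state, signal, thresholds) {
  if (state$phase_elapsed < thresholds$refractory_min) return(state)
  new_phase <- NULL
  if (state$phase == "telogen" && signal > thresholds$activation) {
    new_phase <- "anagen"
  } else if (state$phase == "anagen" && signal < thresholds$termination) {
    new_phase <- "telogen"
  }
  if (!is.null(new_phase)) {
    cyc <- sum(state$transitions$to == "anagen") +
      as.integer(new_phase == "anagen")
    state$transitions <- rbind(
      state$transitions,
      data.frame(time = state$time, from = state$phase, to = new_phase,
                 cycle_index = cyc, stringsAsFactors = FALSE))
    state$phase <- new_phase
    state$phase_elapsed <- 0
  }
  state
}
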