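#' Simulate one follicle over a time horizon
#'
#' Integrates the coupled signaling-growth-checkpoint dynamics of a single
#' follicle with the explicit scheme and returns the sampled trajectory. The
#' follicle starts in late competent telogen with the growth signal poised
#' just above the activation threshold, so the first anagen entry occurs at
#' (or just after) `gate` days. A fixed `seed` gives a bit-identical
#' trajectory.
#'
#' @param act,inh [pathway_params()] for the activator and inhibitor.
#' @param geometry An [hf_geometry()].
#' @param thresholds A [phase_thresholds()].
#' @param horizon Simulated time (days); `horizon = 0` returns only the
#'   initial state.
#' @param dt Time step (days); checked against the stability bound.
#' @param seed Master seed for the follicle's noise stream.
#' @param stream Stream index within the master seed (used by lattice runs to
#'   address per-site streams; default 0).
#' @param growth_law Velocity law, see [default_growth_law()]; defaults to the
#'   calibrated law from [hf_defaults()].
#' @param output_stride Sampling interval of the returned trajectory (days).
#' @param signal0 Initial growth-signal level; defaults to just above the
#'   activation threshold.
#' @param gate Earliest allowed time of the first anagen entry (days).
#' @return An object of class `hf_trajectory`: a list with `time`, `phase`,
#'   `length`, `signal`, `mean_bound_act`, `mean_bound_inh` vectors, the
#'   transition log `transitions` (time, from, to, cycle_index), the total
#'   count of negativity `clip_events`, and the parameter echo `params`.
#' @examples
#' p <- hf_defaults()
#' traj <- simulate_hf(p$act, p$inh, p$geometry, p$thresholds,
#'                     horizon = 5, dt = 0.025)
#' @export
simulate_hf <- function(act, inh, geometry, thresholds,
                        horizon, dt, seed = 1, stream = 0L,
                        growth_law = NULL, output_stride = 0.25,
                        signal0 = NULL, gate = 0) {
  check_stability(dt, geometry, act, inh)
  if (horizon < 0) stop("horizon must be >= 0")
  if (is.null(growth_law)) {
    d <- hf_defaults()
    growth_law <- default_growth_law(d$growth$v_max, d$growth$C_half,
                                     d$growth$v_catagen,
                                     thresholds$termination)
  }
  if (is.null(signal0)) signal0 <- thresholds$activation + 0.02
  ctx <- make_ctx(geometry)
  spec <- list(
    ctx = ctx, s = 1L,
    par = list(act = site_pathway(act), inh = site_pathway(inh)),
    thr = list(activation = thresholds$activation,
               termination = thresholds$termination,
               refractory = thresholds$refractory_min),
    growth = growth_law, kmat = NULL,
    len0 = geometry$length0, phase0 = 0L, c0 = signal0, gates = gate,
    dt = dt, nsteps = as.integer(round(horizon / dt)),
    stride_steps = max(1L, as.integer(round(output_stride / dt))),
    seed = seed, streams = as.integer(stream)
  )
  res <- sim_core(spec)
  traj <- list(
    time = res$times,
    phase = c("telogen", "anagen")[res$phase[, 1] + 1L],
    length = res$length[, 1],
    signal = res$signal[, 1],
    mean_bound_act = res$mean_bound_act[, 1],
    mean_bound_inh = res$mean_bound_inh[, 1],
    transitions = res$transitions[, c("time", "from", "to", "cycle_index")],
    clip_events = res$clip_events,
    params = list(act = act, inh = inh, geometry = geometry,
                  thresholds = thresholds, dt = dt, horizon = horizon,
                  seed = seed, stream = stream,
                  output_stride = output_stride)
  )
  class(traj) <- "hf_trajectory"
  traj
}

#' @export
print.hf_trajectory <- function(x, ...) {
  n_cyc <- sum(x$transitions$to == "anagen")
  cat(sprintf("<hf_trajectory> %g days, %d samples, %d anagen entries\n",
              max(x$time), length(x$time), n_cyc))
  invisible(x)
}

#' @export
as.data.frame.hf_trajectory <- function(x, ...) {
  data.frame(time = x$time, phase = x$phase, length = x$length,
             signal_C = x$signal, mean_bound_act_region1 = x$mean_bound_act,
             mean_bound_inh_region1 = x$mean_bound_inh,
             stringsAsFactors = FALSE)
}

#' Per-cycle phase durations of a trajectory
#'
#' Extracts, from the logged transitions, one row per complete cycle: the
#' anagen-phase duration, the telogen-phase duration, and the total period
#' (anagen entry to next anagen entry).
#'
#' @param traj An `hf_trajectory`, or a transition log data frame with
#'   columns `time` and `to`.
#' @return A data frame with columns `cycle`, `anagen`, `telogen`, `period`.
#'   Empty (with a warning) when no complete cycle exists.
#' @export
phase_durations <- function(traj) {
  tr <- if (is.data.frame(traj)) traj else traj$transitions
  a_t <- tr$time[tr$to == "anagen"]
  t_t <- tr$time[tr$to == "telogen"]
  empty <- data.frame(cycle = integer(0), anagen = numeric(0),
                      telogen = numeric(0), period = numeric(0))
  if (length(a_t) < 2) {
    warning("no complete cycle in trajectory")
    return(empty)
  }
  k <- length(a_t) - 1  # complete cycles
  rows <- lapply(seq_len(k), function(i) {
    t_end <- t_t[t_t > a_t[i] & t_t < a_t[i + 1]]
    if (length(t_end) != 1) return(NULL)
    data.frame(cycle = i, anagen = t_end - a_t[i],
               telogen = a_t[i + 1] - t_end, period = a_t[i + 1] - a_t[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    warning("no complete cycle in trajectory")
    return(empty)
  }
  rownames(out) <- NULL
  out
}

#' Scan phase durations against inhibitor signaling strength
#'
#' Scales the inhibitor pathway's production rates (regions I and II, both
#' phase schedules, and any extra source) by each level and simulates a
#' single follicle per level. Within the excitable range the anagen phase
#' shortens and the telogen phase lengthens as the inhibitor strengthens;
#' outside it the follicle stops cycling, equilibrating in extended telogen
#' (strong inhibitor) or extended anagen (weak inhibitor).
#'
#' @param base Parameter set as returned by [hf_defaults()].
#' @param levels Ordered multiplicative scaling factors; 1 is the baseline.
#' @param horizon Simulated days per level.
#' @param dt Time step; defaults to `base$numerics$dt`.
#' @param drop_cycles Leading cycles discarded as transient (default 1).
#' @return A data frame with one row per level: mean `anagen` and `telogen`
#'   durations (NA when not cycling), `period`, the `cycling` flag (FALSE
#'   when no transition occurs in the final half of the horizon) and the
#'   `terminal_phase`.
#' @export
inhibitor_strength_scan <- function(base = hf_defaults(), levels,
                                    horizon = 300, dt = NULL,
                                    drop_cycles = 1) {
  if (is.null(dt)) dt <- base$numerics$dt
  rows <- lapply(levels, function(f) {
    inh <- scale_inhibitor(base$inh, f)
    traj <- simulate_hf(base$act, inh, base$geometry, base$thresholds,
                        horizon = horizon, dt = dt,
                        growth_law = growth_law_from(base))
    cycling <- any(traj$transitions$time > horizon / 2)
    dur <- suppressWarnings(phase_durations(traj))
    dur <- dur[dur$cycle > drop_cycles, , drop = FALSE]
    data.frame(
      level = f,
      anagen = if (cycling && nrow(dur) > 0) mean(dur$anagen) else NA_real_,
      telogen = if (cycling && nrow(dur) > 0) mean(dur$telogen) else NA_real_,
      period = if (cycling && nrow(dur) > 0) mean(dur$period) else NA_real_,
      cycling = cycling,
      terminal_phase = traj$phase[length(traj$phase)],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# multiply all inhibitor sources by a factor
scale_inhibitor <- function(inh, f) {
  inh$production_region1 <- inh$production_region1 * f
  inh$production_region2 <- lapply(inh$production_region2, function(v) v * f)
  inh$extra_source_region1 <- inh$extra_source_region1 * f
  inh
}
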