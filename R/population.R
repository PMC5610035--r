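# per-site parameter resolution: expand the base parameter set to per-site
# vectors wherever a domain override differs from the base
resolve_sites <- function(lat, base) {
  s <- length(lat$sites)
  par <- list(act = site_pathway(base$act), inh = site_pathway(base$inh))
  thr <- list(activation = base$thresholds$activation,
              termination = base$thresholds$termination,
              refractory = base$thresholds$refractory_min)
  site_dom <- lat$domain[lat$sites]
  pf_map <- c(diffusion = "diffusion_coeff",
              production1 = "production_region1",
              bind_on = "bind_on", bind_off = "bind_off",
              degradation = "degradation", receptor_total = "receptor_total",
              noise = "noise_amplitude", extra = "extra_source_region1")
  th_map <- c(activation = "activation", termination = "termination",
              refractory = "refractory_min")
  set_sites <- function(vec, hit, value) {
    if (length(vec) == 1L) vec <- rep(vec, s)
    vec[hit] <- value
    vec
  }
  for (d in lat$domains) {
    ov <- d$overrides
    if (length(ov) == 0) next
    hit <- !is.na(site_dom) & site_dom == d$name
    if (!any(hit)) next
    for (p in c("act", "inh")) {
      repl <- ov[[p]]
      if (is.null(repl)) next
      for (nm in names(repl)) {
        if (nm == "production_region2") {
          for (ph in names(repl[[nm]])) {
            key <- paste0("production2_", ph)
            par[[p]][[key]] <- set_sites(par[[p]][[key]], hit,
                                         repl[[nm]][[ph]])
          }
        } else {
          key <- names(pf_map)[pf_map == nm]
          if (length(key) != 1) stop("unknown pathway override field: ", nm)
          par[[p]][[key]] <- set_sites(par[[p]][[key]], hit, repl[[nm]])
        }
      }
    }
    if (!is.null(ov$receptor_scale)) {
      for (p in c("act", "inh"))
        par[[p]]$receptor_total <-
          set_sites(par[[p]]$receptor_total, hit,
                    rep_len(par[[p]]$receptor_total, s)[hit] *
                      ov$receptor_scale)
    }
    if (!is.null(ov$inhibitor_scale)) {
      f <- ov$inhibitor_scale
      for (key in c("production1", "production2_telogen",
                    "production2_anagen", "extra"))
        par$inh[[key]] <- set_sites(par$inh[[key]], hit,
                                    rep_len(par$inh[[key]], s)[hit] * f)
    }
    if (!is.null(ov$thresholds)) {
      for (nm in names(ov$thresholds)) {
        key <- names(th_map)[th_map == nm]
        if (length(key) != 1) stop("unknown threshold override: ", nm)
        thr[[key]] <- set_sites(thr[[key]], hit, ov$thresholds[[nm]])
      }
    }
  }
  list(par = par, thr = thr)
}

#' Simulate a coupled follicle population
#'
#' Integrates every follicle of a lattice simultaneously: each site runs the
#' full single-follicle dynamics on its own axis, and neighboring follicles
#' exchange free ligand over the bulge depth band at the lattice's
#' `coupling_strength`. Domain overrides (ventral receptor elevation,
#' hyper-refractory inhibitor elevation, ...) are resolved per site. Per-site
#' noise streams are split from the master seed by a counter-based scheme, so
#' a site's stream does not depend on the lattice size, and with
#' `coupling_strength = 0` each site's trajectory is bit-identical to the
#' corresponding [simulate_hf()] run.
#'
#' @param lattice An [build_lattice()] object.
#' @param init An [initial_conditions()] object.
#' @param horizon Simulated days.
#' @param dt Time step (days).
#' @param seed Master seed; fixes the jitter and all noise streams.
#' @param base Baseline parameter set, see [hf_defaults()].
#' @param growth_law Velocity law; defaults to the calibrated law.
#' @param output_stride Sampling interval (days).
#' @return An object of class `pattern_record`: sampled `times`, per-site
#'   `phase`/`length`/`signal` matrices (time x site), the transition log
#'   (site, time, from, to, cycle_index), per-site coordinates, and the
#'   lattice/init/seed metadata.
#' @export
simulate_population <- function(lattice, init, horizon, dt, seed = 1,
                                base = hf_defaults(), growth_law = NULL,
                                output_stride = 0.25) {
  if (!inherits(lattice, "hf_lattice")) stop("lattice must be an hf_lattice")
  if (!inherits(init, "hf_init")) stop("init must be initial_conditions()")
  check_stability(dt, base$geometry, base$act, base$inh)
  nb_max <- if (length(lattice$sites) > 1) max(rowSums(lattice$adjacency)) else 0
  if (nb_max > 0 && dt * lattice$coupling_strength * nb_max >= 1)
    stop(sprintf(
      "exchange stability violated: dt * coupling_strength * neighbors = %g >= 1",
      dt * lattice$coupling_strength * nb_max))
  if (is.null(growth_law)) growth_law <- growth_law_from(base)

  s <- length(lattice$sites)
  res <- resolve_sites(lattice, base)
  act_thr <- rep_len(res$thr$activation, s)

  li0 <- rep(0, s)
  if (init$mode == "phase_gradient") {
    gates <- site_gates(init, lattice, seed)
    c0 <- act_thr + 0.02
  } else {
    src <- as_mask(init$source, lattice$nrow, lattice$ncol)
    is_src <- src[lattice$sites]
    if (!any(is_src)) stop("no source site falls on a follicle site")
    gates <- rep(0, s)
    # non-source sites start in competent telogen held below threshold by a
    # free-inhibitor reservoir; they fire autonomously once it degrades, and
    # an arriving activator pulse recruits them earlier (propagating-anagen
    # to competent-telogen recruitment)
    c0 <- act_thr + 0.02
    li0 <- ifelse(is_src, 0, init$refractory_level)
  }

  kmat <- NULL
  if (s > 1 && lattice$coupling_strength > 0) {
    a <- lattice$adjacency
    kmat <- lattice$coupling_strength * (a - diag(rowSums(a)))
  }

  ctx <- make_ctx(base$geometry)
  spec <- list(
    ctx = ctx, s = s, par = res$par, thr = res$thr,
    growth = growth_law, kmat = kmat,
    len0 = base$geometry$length0, phase0 = rep(0L, s), c0 = c0, li0 = li0,
    gates = gates,
    dt = dt, nsteps = as.integer(round(horizon / dt)),
    stride_steps = max(1L, as.integer(round(output_stride / dt))),
    seed = seed, streams = as.integer(seq_len(s) - 1L)
  )
  out <- sim_core(spec)
  rec <- list(
    times = out$times, phase = out$phase, length = out$length,
    signal = out$signal, mean_bound_act = out$mean_bound_act,
    mean_bound_inh = out$mean_bound_inh,
    transitions = out$transitions, clip_events = out$clip_events,
    lattice = lattice, init = init, seed = seed, dt = dt,
    horizon = horizon, site_row = lattice$site_row,
    site_col = lattice$site_col
  )
  class(rec) <- "pattern_record"
  rec
}

#' @export
print.pattern_record <- function(x, ...) {
  cat(sprintf(
    "<pattern_record> %d x %d lattice (%d sites), %g days, %d transitions\n",
    x$lattice$nrow, x$lattice$ncol, ncol(x$phase),
    max(x$times), nrow(x$transitions)))
  invisible(x)
}

#' Apply one inter-follicular exchange step to a set of follicle states
#'
#' The exchange operator of the population model, exposed on plain follicle
#' states: for every pathway, the free-ligand field of each follicle gains
#' `coupling_strength * sum_neighbors(L_nbr - L_self) * dt`, applied on the
#' grid nodes of the bulge depth band (shared by all follicles). The operator
#' is symmetric, so the lattice-total ligand mass in the band is conserved to
#' round-off; barrier and aperture sites carry no state and no flux.
#'
#' @param states List of [new_hf_state()] objects, one per follicle site of
#'   `lattice` (in site order: column-major over follicle sites).
#' @param lattice An [build_lattice()] object.
#' @param dt Time step (days).
#' @return The list of updated states.
#' @export
coupling_step <- function(states, lattice, dt) {
  s <- length(lattice$sites)
  if (length(states) != s)
    stop("coupling_step: need one state per follicle site (", s, ")")
  if (s < 2 || lattice$coupling_strength == 0) return(states)
  ctx <- make_ctx(states[[1]]$geometry)
  band <- ctx$r1rows
  a <- lattice$adjacency
  kmat <- lattice$coupling_strength * (a - diag(rowSums(a)))
  for (fld in c("ligand_act", "ligand_inh")) {
    m <- vapply(states, function(st) st[[fld]][band], numeric(length(band)))
    m <- matrix(m, nrow = length(band))
    m2 <- m + dt * (m %*% kmat)
    for (k in seq_len(s)) states[[k]][[fld]][band] <- m2[, k]
  }
  states
}
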