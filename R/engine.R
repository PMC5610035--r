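# The shared integration engine. All simulators (single follicle and lattice)
# run through sim_core(), which integrates S follicles side by side as
# nodes x sites matrices. Every kernel except the explicit inter-follicle
# exchange is column-local, so with coupling off a site's trajectory is
# bit-identical to a single-follicle run on the same stream.

# spec: list with
#   ctx          geometry context (make_ctx)
#   s            number of follicle sites
#   par          list(act, inh) of site_pathway() bundles (length 1 or S)
#   thr          list(activation, termination, refractory) (length 1 or S)
#   growth       function(signal, anagen) -> velocity, vectorized
#   kmat         S x S exchange operator (adjacency - degree) * strength, or NULL
#   len0, phase0 (0 telogen / 1 anagen), c0, bi0, gates   per-site vectors
#   dt, nsteps, stride_steps
#   seed, streams
sim_core <- function(spec) {
  ctx <- spec$ctx
  s <- spec$s
  dt <- spec$dt
  par <- spec$par
  thr <- spec$thr
  nmx <- ctx$n_max
  r1 <- ctx$r1rows
  n1 <- length(r1)

  len <- rep_len(spec$len0, s)
  n_nodes <- active_node_count(len, ctx$dx)
  phase <- rep_len(as.integer(spec$phase0), s)
  gates <- rep_len(spec$gates, s)
  first_done <- rep_len(FALSE, s)
  elapsed <- rep_len(Inf, s)
  act_thr <- rep_len(thr$activation, s)
  term_thr <- rep_len(thr$termination, s)
  refr <- rep_len(thr$refractory, s)

  masks <- make_masks(ctx, n_nodes)
  fields <- init_fields(ctx, s, par, masks, rep_len(spec$c0, s),
                        rep_len(spec$li0 %||% 0, s))
  cache <- list(
    act = list(src1 = outer(ctx$w1, rep_len(par$act$production1, s)),
               rtot_m = outer(ctx$phi, rep_len(par$act$receptor_total, s))),
    inh = list(src1 = outer(ctx$w1, rep_len(par$inh$production1, s)),
               rtot_m = outer(ctx$phi, rep_len(par$inh$receptor_total, s)))
  )
  use_noise <- any(par$act$noise > 0) || any(par$inh$noise > 0)
  kmat <- spec$kmat
  if (!is.null(kmat) && all(kmat == 0)) kmat <- NULL

  n_out <- spec$nsteps %/% spec$stride_steps + 1L
  rec <- list(
    times = numeric(n_out),
    phase = matrix(NA_integer_, n_out, s),
    length = matrix(NA_real_, n_out, s),
    signal = matrix(NA_real_, n_out, s),
    mean_bound_act = matrix(NA_real_, n_out, s),
    mean_bound_inh = matrix(NA_real_, n_out, s)
  )
  tr_site <- integer(0); tr_time <- numeric(0)
  tr_from <- integer(0); tr_to <- integer(0)

  sig <- signal_mean(fields$bound_act, fields$bound_inh, ctx)
  record <- function(row, t) {
    rec$times[row] <<- t
    rec$phase[row, ] <<- phase
    rec$length[row, ] <<- len
    rec$signal[row, ] <<- sig
    pr <- ctx$phirows
    rec$mean_bound_act[row, ] <<-
      colSums(fields$bound_act[pr, , drop = FALSE]) / ctx$phi_sum
    rec$mean_bound_inh[row, ] <<-
      colSums(fields$bound_inh[pr, , drop = FALSE]) / ctx$phi_sum
  }
  record(1L, 0)

  total_clips <- 0L
  out_row <- 1L
  nsteps <- spec$nsteps
  if (nsteps > 0) for (k in seq_len(nsteps)) {
    t_k <- k * dt
    w2m <- region2_weights(ctx, n_nodes, masks$a)
    z_act <- z_inh <- NULL
    if (use_noise) {
      nphi <- length(ctx$phirows)
      z_act <- .ct_normals(spec$seed, spec$streams, k - 1, nphi, 0)
      z_inh <- .ct_normals(spec$seed, spec$streams, k - 1, nphi, nphi)
    }
    upd <- rd_update(fields, ctx, par, masks, w2m, phase == 1L, dt,
                     z_act, z_inh, cache)
    fields <- upd$fields
    if (upd$clips_ligand > 0 || upd$clips_bound > 0) {
      total_clips <- total_clips + upd$clips_ligand + upd$clips_bound
      # ligand undershoot signals a deterministic instability; bound-field
      # clips at near-zero levels are routine under additive noise
      if (upd$clips_ligand > 0.01 * 2 * sum(n_nodes))
        stop(sprintf(
          "integration failure at t = %g: clipped %d negative ligand values in one step (> 1%% of nodes); reduce dt",
          t_k, upd$clips_ligand))
    }
    if (!is.null(kmat)) {
      fields$ligand_act[r1, ] <- fields$ligand_act[r1, , drop = FALSE] +
        dt * (fields$ligand_act[r1, , drop = FALSE] %*% kmat)
      fields$ligand_inh[r1, ] <- fields$ligand_inh[r1, , drop = FALSE] +
        dt * (fields$ligand_inh[r1, , drop = FALSE] %*% kmat)
    }
    sig <- signal_mean(fields$bound_act, fields$bound_inh, ctx)
    if (k %% 50L == 0L && any(!is.finite(sig)))
      stop("integration failure: non-finite growth signal at t = ", t_k)

    v <- spec$growth(sig, phase == 1L)
    len <- pmin(pmax(len + v * dt, ctx$lmin), ctx$lmax)
    n_new <- active_node_count(len, ctx$dx)
    changed <- which(n_new != n_nodes)
    if (length(changed) > 0) {
      fields <- regrid_fields(fields, ctx, n_nodes, n_new, changed)
      n_nodes <- n_new
      masks <- make_masks(ctx, n_nodes)
    }

    elapsed <- elapsed + dt
    ok_dwell <- elapsed >= refr
    up <- phase == 0L & ok_dwell & sig > act_thr &
      (first_done | t_k >= gates - 1e-9)
    down <- phase == 1L & ok_dwell & sig < term_thr
    if (any(up) || any(down)) {
      iu <- which(up); idn <- which(down)
      tr_site <- c(tr_site, iu, idn)
      tr_time <- c(tr_time, rep(t_k, length(iu) + length(idn)))
      tr_from <- c(tr_from, rep(0L, length(iu)), rep(1L, length(idn)))
      tr_to <- c(tr_to, rep(1L, length(iu)), rep(0L, length(idn)))
      phase[iu] <- 1L
      phase[idn] <- 0L
      elapsed[iu] <- 0
      elapsed[idn] <- 0
      first_done[iu] <- TRUE
    }

    if (k %% spec$stride_steps == 0L) {
      out_row <- out_row + 1L
      record(out_row, t_k)
    }
  }

  lab <- c("telogen", "anagen")
  transitions <- data.frame(
    site = tr_site, time = tr_time,
    from = lab[tr_from + 1L], to = lab[tr_to + 1L],
    stringsAsFactors = FALSE)
  transitions <- transitions[order(transitions$time, transitions$site), ,
                             drop = FALSE]
  rownames(transitions) <- NULL
  cyc <- integer(nrow(transitions))
  if (nrow(transitions) > 0) {
    # anagen entries open cycle k; the following telogen entry belongs to it
    ana <- transitions$to == "anagen"
    for (s_i in unique(transitions$site)) {
      sel <- transitions$site == s_i
      cyc[sel] <- cumsum(ana[sel])
    }
  }
  transitions$cycle_index <- cyc

  list(times = rec$times, phase = rec$phase, length = rec$length,
       signal = rec$signal, mean_bound_act = rec$mean_bound_act,
       mean_bound_inh = rec$mean_bound_inh, transitions = transitions,
       clip_events = total_clips, final_phase = phase, final_length = len)
}

# warm competent-telogen initial fields: bulge-bound activator poised so the
# signal from the activator alone starts at c0, free activator at the
# corresponding binding equilibrium. li0 is a free inhibitor ligand load
# (the post-catagen refractory reservoir concentrated into the short
# follicle); bound inhibitor starts at its binding equilibrium with li0 and
# both clear on the ligand degradation timescale
init_fields <- function(ctx, s, par, masks, c0, li0 = 0) {
  # bound profile proportional to the receptor profile, so the
  # capacity-normalized signal mean equals c0 exactly
  rtot <- rep_len(par$act$receptor_total, s)
  if (any(c0 >= rtot))
    stop("initial signal c0 must be below receptor_total")
  kon <- rep_len(par$act$bind_on, s)
  koff <- rep_len(par$act$bind_off, s)
  deg <- rep_len(par$act$degradation, s)
  la0 <- ifelse(c0 > 0, (koff + deg) * c0 / (kon * (rtot - c0)), 0)
  zero <- matrix(0, ctx$n_max, s)
  la <- matrix(la0, ctx$n_max, s, byrow = TRUE) * masks$a
  ba <- outer(ctx$phi, c0)
  li <- zero
  bi <- zero
  if (any(li0 > 0)) {
    li0 <- rep_len(li0, s)
    li <- matrix(li0, ctx$n_max, s, byrow = TRUE) * masks$a
    kon_i <- rep_len(par$inh$bind_on, s)
    koff_i <- rep_len(par$inh$bind_off, s)
    deg_i <- rep_len(par$inh$degradation, s)
    rtot_i <- rep_len(par$inh$receptor_total, s)
    occ <- kon_i * li0 / (kon_i * li0 + koff_i + deg_i)
    bi <- outer(ctx$phi, rtot_i * occ)
  }
  list(ligand_act = la, ligand_inh = li, bound_act = ba, bound_inh = bi)
}
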