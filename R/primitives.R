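# Internal matrix kernels shared by the single-follicle step operations and
# the lattice engine. Fields are n_max x S matrices (nodes x sites); sites
# with shorter follicles simply have zero rows beyond their active node count.
# All kernels are column-local (except the explicit inter-follicle exchange),
# so a one-column run is bit-identical to the same column of a lattice run.

# static per-geometry context
make_ctx <- function(geometry) {
  nd <- node_depths(geometry)
  dx <- geometry$grid_spacing
  # cell-overlap production weights for the fixed region I
  w1 <- cell_overlap(nd$x, dx, geometry$region1[1], geometry$region1[2])
  # receptor expression profile: 1 inside region I, linear taper over a fixed
  # physical margin on both sides (keeps every kernel smooth in x, so spatial
  # discretization errors are second order)
  taper <- geometry$region1[1]
  d_out <- pmax(pmax(geometry$region1[1] - nd$x, nd$x - geometry$region1[2]), 0)
  phi <- pmax(1 - d_out / taper, 0)
  phirows <- which(phi > 0)
  list(
    dx = dx, n_max = nd$n_max, x = nd$x,
    r1rows = which(nd$in_region1),
    r1ind = as.numeric(nd$in_region1),
    w1 = w1,
    phi = phi, phirows = phirows,
    phi_sum = sum(phi), phi2_sum = sum(phi^2),
    lmin = geometry$length_min, lmax = geometry$length_max,
    w2 = geometry$region2_width
  )
}

# fraction of each node's cell [x - dx/2, x + dx/2] covered by [lo, hi]
cell_overlap <- function(x, dx, lo, hi) {
  pmax(pmin(x + dx / 2, hi) - pmax(x - dx / 2, lo), 0) / dx
}

# nearest-node tip: keeps the discrete domain end centered on the true
# length, so the tip error oscillates around zero instead of biasing short
active_node_count <- function(len, dx) as.integer(floor(len / dx + 0.5)) + 1L

# 0/1 active mask and distal-boundary mask for per-site node counts
make_masks <- function(ctx, n_nodes) {
  rows <- seq_len(ctx$n_max)
  a <- outer(rows, n_nodes, "<=")
  bnd <- outer(rows, n_nodes, "==")
  storage.mode(a) <- "double"
  list(a = a, bnd = bnd)
}

# region II production weights: overlap of the moving interval
# [tip - w2, tip] with each node's trapezoidal cell, normalized by the cell
# width so that the trapezoid-integrated source is exactly rate * w2.
# The interval is anchored at the discrete domain end (nearest node to the
# true length), per site (n_max x S).
region2_weights <- function(ctx, n_nodes, a) {
  s <- length(n_nodes)
  dx <- ctx$dx
  tip <- matrix((n_nodes - 1L) * dx, ctx$n_max, s, byrow = TRUE)
  cell_lo <- pmax(ctx$x - dx / 2, 0)
  cell_hi <- pmin(ctx$x + dx / 2, tip)
  width <- pmax(cell_hi - cell_lo, 0)
  ov <- pmax(pmin(cell_hi, tip) - pmax(cell_lo, tip - ctx$w2), 0)
  w <- ov / ifelse(width > 0, width, 1)
  w * a
}

# no-flux Laplacian with symmetric ghosts: the boundary rows use
# 2*(neighbor - self)/dx^2, which conserves the trapezoidal mass exactly
laplacian <- function(f, ctx, a, bnd) {
  n <- ctx$n_max
  up <- f[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- f[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  up[1L, ] <- dn[1L, ]      # ghost above the surface mirrors node 2
  dn[bnd] <- up[bnd]        # ghost below the tip mirrors the node above it
  ((up + dn - 2 * f) / ctx$dx^2) * a
}

# broadcast a per-site parameter down the node dimension (scalars stay scalar)
bc <- function(v, n_max) if (length(v) == 1L) v else rep(v, each = n_max)

# one explicit Euler update of the four fields; all right-hand sides are
# evaluated at the current state. z_act / z_inh are n(region I) x S standard
# normal draws or NULL.
rd_update <- function(fields, ctx, par, masks, w2m, phase_anagen, dt,
                      z_act = NULL, z_inh = NULL, cache = NULL) {
  nmx <- ctx$n_max
  clips_ligand <- 0L
  clips_bound <- 0L
  out <- fields
  for (p in c("act", "inh")) {
    pp <- par[[p]]
    ch <- cache[[p]]
    l <- fields[[paste0("ligand_", p)]]
    b <- fields[[paste0("bound_", p)]]
    lap <- laplacian(l, ctx, masks$a, masks$bnd)
    prod2 <- ifelse(phase_anagen, pp$production2_anagen, pp$production2_telogen)
    src1 <- if (is.null(ch)) outer(ctx$w1, rep_len(pp$production1, ncol(l)))
            else ch$src1
    src <- src1 + w2m * bc(prod2, nmx)
    rtot_m <- if (is.null(ch)) outer(ctx$phi, rep_len(pp$receptor_total, ncol(l)))
              else ch$rtot_m
    bind <- bc(pp$bind_on, nmx) * l * (rtot_m - b)
    dl <- bc(pp$diffusion, nmx) * lap + src - bind +
      bc(pp$bind_off, nmx) * b - bc(pp$degradation, nmx) * l
    l2 <- l + dt * dl
    db <- bind - bc(pp$bind_off, nmx) * b - bc(pp$degradation, nmx) * b
    if (any(pp$extra > 0))
      db <- db + outer(ctx$phi, rep_len(pp$extra, ncol(l)))
    b2 <- b + dt * db
    z <- if (p == "act") z_act else z_inh
    if (!is.null(z))
      b2[ctx$phirows, ] <- b2[ctx$phirows, ] +
        (sqrt(dt) * ctx$phi[ctx$phirows]) * bc(pp$noise, length(ctx$phirows)) * z
    neg_l <- l2 < 0
    neg_b <- b2 < 0
    clips_ligand <- clips_ligand + sum(neg_l)
    clips_bound <- clips_bound + sum(neg_b)
    if (any(neg_l)) l2[neg_l] <- 0
    if (any(neg_b)) b2[neg_b] <- 0
    over <- b2 > rtot_m
    if (any(over)) b2[over] <- rtot_m[over]
    out[[paste0("ligand_", p)]] <- l2 * masks$a
    out[[paste0("bound_", p)]] <- b2 * masks$a
  }
  list(fields = out, clips_ligand = clips_ligand, clips_bound = clips_bound)
}

# capacity-normalized spatial average over region I: the growth signal.
# Dividing the summed bound concentration by the summed receptor profile
# cancels the taper structure exactly (for bound fields proportional to the
# profile), so the statistic is the mean bound level per unit receptor
# capacity across the bulge.
signal_mean <- function(ba, bi, ctx) {
  pr <- ctx$phirows
  (colSums(ba[pr, , drop = FALSE]) - colSums(bi[pr, , drop = FALSE])) /
    ctx$phi_sum
}

# trapezoidal mass of the first n nodes of column v
trapz_mass <- function(v, n, dx) {
  if (n == 1L) return(v[1L] * dx)
  dx * (sum(v[seq_len(n)]) - 0.5 * (v[1L] + v[n]))
}

# re-grid the ligand fields of the sites whose node count changed.
# Elongation: new distal nodes take the previous boundary value (constant
# extrapolation); retraction: distal nodes are dropped. In both cases the
# column is then rescaled so the trapezoidal mass matches the pre-step mass.
regrid_fields <- function(fields, ctx, n_old, n_new, changed) {
  for (s in changed) {
    no <- n_old[s]; nn <- n_new[s]
    for (nm in c("ligand_act", "ligand_inh")) {
      col <- fields[[nm]][, s]
      m_old <- trapz_mass(col, no, ctx$dx)
      if (nn > no) {
        col[(no + 1L):nn] <- col[no]
      } else {
        col[(nn + 1L):no] <- 0
      }
      m_new <- trapz_mass(col, nn, ctx$dx)
      if (m_new > 1e-300) col[seq_len(nn)] <- col[seq_len(nn)] * (m_old / m_new)
      fields[[nm]][, s] <- col
    }
  }
  fields
}

# per-site parameter bundle (vectors of length 1 or S) from pathway_params
site_pathway <- function(p, s = 1L) {
  list(diffusion = p$diffusion_coeff,
       production1 = rep_len(p$production_region1, 1L),
       production2_telogen = p$production_region2$telogen,
       production2_anagen = p$production_region2$anagen,
       bind_on = p$bind_on, bind_off = p$bind_off,
       degradation = p$degradation,
       receptor_total = p$receptor_total,
       noise = p$noise_amplitude,
       extra = p$extra_source_region1)
}

state_as_fields <- function(st, ctx) {
  n <- active_node_count(st$geometry$length0, ctx$dx)
  f <- list()
  for (nm in c("ligand_act", "ligand_inh", "bound_act", "bound_inh")) {
    col <- numeric(ctx$n_max)
    col[seq_len(n)] <- st[[nm]]
    f[[nm]] <- matrix(col, ncol = 1)
  }
  f
}

fields_into_state <- function(st, fields, n) {
  for (nm in c("ligand_act", "ligand_inh", "bound_act", "bound_inh"))
    st[[nm]] <- fields[[nm]][seq_len(n), 1]
  st
}
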