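#' Kinetic parameters for one signaling pathway
#'
#' Describes the ligand-receptor kinetics of a single diffusible signaling
#' pathway (an activator such as WNT, or an inhibitor such as BMP) acting
#' along the follicle axis. Free ligand diffuses, is produced in the bulge
#' (region I, at a constant rate) and in the dermal papilla compartment
#' (region II, at a phase-dependent rate), binds receptors expressed in the
#' bulge, and decays. The bound complex is released at `bind_off`, degraded at
#' `degradation`, and can receive a deterministic extra source and stochastic
#' fluctuations confined to the bulge.
#'
#' @param diffusion_coeff Ligand diffusion coefficient (length^2/day).
#' @param production_region1 Constant ligand production rate in region I
#'   (concentration/day).
#' @param production_region2 Named list with elements `telogen` and `anagen`:
#'   ligand production rate in region II during each model phase
#'   (concentration/day).
#' @param bind_on Receptor binding rate constant (1/(concentration x day)).
#' @param bind_off Complex dissociation rate constant (1/day).
#' @param degradation First-order decay rate applied to free ligand and to the
#'   bound complex (1/day).
#' @param receptor_total Maximum bindable receptor density in the bulge
#'   (concentration); bound levels never exceed it.
#' @param noise_amplitude Amplitude of additive Gaussian fluctuations on the
#'   bound-receptor dynamics in region I (concentration/day^(1/2) scaling,
#'   applied as `noise_amplitude * sqrt(dt)` per step).
#' @param extra_source_region1 Deterministic extra source on the bound complex
#'   in region I (concentration/day). Default 0.
#'
#' @return An object of class `pathway_params`.
#' @examples
#' act <- pathway_params(0.15, 0.02, list(telogen = 2, anagen = 1),
#'                       bind_on = 2, bind_off = 0.3, degradation = 0.15,
#'                       receptor_total = 1)
#' @export
pathway_params <- function(diffusion_coeff,
                           production_region1,
                           production_region2,
                           bind_on,
                           bind_off,
                           degradation,
                           receptor_total,
                           noise_amplitude = 0,
                           extra_source_region1 = 0) {
  p <- list(
    diffusion_coeff = diffusion_coeff,
    production_region1 = production_region1,
    production_region2 = production_region2,
    bind_on = bind_on,
    bind_off = bind_off,
    degradation = degradation,
    receptor_total = receptor_total,
    noise_amplitude = noise_amplitude,
    extra_source_region1 = extra_source_region1
  )
  class(p) <- "pathway_params"
  validate_pathway_params(p)
  p
}

validate_pathway_params <- function(p) {
  rates <- c(
    diffusion_coeff = p$diffusion_coeff,
    production_region1 = p$production_region1,
    bind_on = p$bind_on, bind_off = p$bind_off,
    degradation = p$degradation,
    noise_amplitude = p$noise_amplitude,
    extra_source_region1 = p$extra_source_region1
  )
  bad <- names(rates)[!is.finite(rates) | rates < 0]
  if (length(bad) > 0)
    stop("pathway_params: non-negative finite values required for: ",
         paste(bad, collapse = ", "))
  if (!is.list(p$production_region2) ||
      !all(c("telogen", "anagen") %in% names(p$production_region2)))
    stop("pathway_params: production_region2 must be a named list with ",
         "entries for every phase label ('telogen', 'anagen')")
  p2 <- unlist(p$production_region2[c("telogen", "anagen")])
  if (any(!is.finite(p2) | p2 < 0))
    stop("pathway_params: production_region2 rates must be non-negative")
  if (!is.finite(p$receptor_total) || p$receptor_total <= 0)
    stop("pathway_params: receptor_total must be > 0")
  invisible(p)
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("<pathway_params>\n")
  cat(sprintf("  D = %g, degradation = %g, bind on/off = %g/%g\n",
              x$diffusion_coeff, x$degradation, x$bind_on, x$bind_off))
  cat(sprintf("  production: region I %g; region II telogen %g / anagen %g\n",
              x$production_region1, x$production_region2$telogen,
              x$production_region2$anagen))
  cat(sprintf("  receptor_total = %g, noise = %g, extra source = %g\n",
              x$receptor_total, x$noise_amplitude, x$extra_source_region1))
  invisible(x)
}

#' Follicle geometry on a one-dimensional axis
#'
#' The follicle is a 1D segment with depth 0 at the skin surface. Region I
#' (the bulge) is a fixed interval near the top; region II (dermal papilla
#' plus hair germ or matrix) is a moving interval of fixed width abutting the
#' distal tip at `length_current`. The grid has fixed spacing; nodes are
#' inserted or removed at the distal end as the follicle grows or retracts.
#'
#' @param grid_spacing Node spacing (length units).
#' @param length_min,length_max Bounds on follicle length; telogen rest length
#'   and full anagen length.
#' @param region1 Numeric length-2: depth interval of the bulge.
#' @param region2_width Width of the distal signaling compartment.
#' @param length0 Initial length; defaults to `length_min`.
#'
#' @return An object of class `hf_geometry`.
#' @export
hf_geometry <- function(grid_spacing = 0.1,
                        length_min = 0.6,
                        length_max = 2.4,
                        region1 = c(0.1, 0.3),
                        region2_width = 0.2,
                        length0 = length_min) {
  g <- list(grid_spacing = grid_spacing, length_min = length_min,
            length_max = length_max, region1 = region1,
            region2_width = region2_width, length0 = length0)
  class(g) <- "hf_geometry"
  validate_hf_geometry(g)
  g
}

validate_hf_geometry <- function(g) {
  if (g$grid_spacing <= 0) stop("hf_geometry: grid_spacing must be > 0")
  if (!(g$length_min <= g$length0 && g$length0 <= g$length_max))
    stop("hf_geometry: need length_min <= length0 <= length_max")
  if (length(g$region1) != 2 || g$region1[1] < 0 || diff(g$region1) <= 0)
    stop("hf_geometry: region1 must be an increasing interval within [0, length)")
  if (g$region2_width <= 0)
    stop("hf_geometry: region2_width must be > 0")
  # regions must stay disjoint even at the resting length
  if (g$region1[2] >= g$length_min - g$region2_width)
    stop("hf_geometry: region1 and region2 overlap at length_min; ",
         "require region1[2] < length_min - region2_width")
  n1 <- sum(node_depths(g)$in_region1)
  if (n1 < 1) stop("hf_geometry: region1 contains no grid node")
  invisible(g)
}

# node positions and region-I bookkeeping for a geometry
node_depths <- function(g) {
  n_max <- floor(g$length_max / g$grid_spacing + 1e-9) + 1
  x <- (seq_len(n_max) - 1) * g$grid_spacing
  list(x = x,
       n_max = n_max,
       in_region1 = x >= g$region1[1] - 1e-9 & x <= g$region1[2] + 1e-9)
}

#' @export
print.hf_geometry <- function(x, ...) {
  cat("<hf_geometry>\n")
  cat(sprintf("  dx = %g, length in [%g, %g] (now %g)\n",
              x$grid_spacing, x$length_min, x$length_max, x$length0))
  cat(sprintf("  region I (bulge): [%g, %g]; region II width %g at distal tip\n",
              x$region1[1], x$region1[2], x$region2_width))
  invisible(x)
}

#' Phase checkpoint thresholds
#'
#' The two hair cycle checkpoints are driven by the growth signal C, the bulge
#' mean of bound activator minus bound inhibitor. A telogen follicle enters
#' anagen when C crosses `activation` upward; an anagen follicle enters
#' telogen when C crosses `termination` downward. A minimum dwell time in each
#' phase prevents chattering under noise.
#'
#' @param activation Activation threshold (concentration).
#' @param termination Termination threshold (concentration);
#'   must satisfy `activation >= termination`.
#' @param refractory_min Minimum dwell time per phase (days). Default 1.
#' @return An object of class `phase_thresholds`.
#' @export
phase_thresholds <- function(activation = 0.5, termination = 0.08,
                             refractory_min = 1) {
  t <- list(activation = activation, termination = termination,
            refractory_min = refractory_min)
  class(t) <- "phase_thresholds"
  if (t$activation < t$termination)
    stop("phase_thresholds: activation must be >= termination")
  if (t$refractory_min < 0)
    stop("phase_thresholds: refractory_min must be >= 0")
  t
}

#' Phase-gated saturating growth law
#'
#' Returns the default velocity law coupling the growth signal to follicle
#' elongation: during anagen the elongation velocity is
#' `v_max * max(C - termination, 0) / (C_half + |C|)` (saturating in C, zero
#' at the termination threshold); during telogen the follicle retracts at the
#' constant catagen velocity until it reaches its resting length. The law is
#' injected into the simulators and can be replaced by any function with the
#' same signature.
#'
#' @param v_max Maximum elongation velocity (length/day).
#' @param C_half Half-saturation constant for the growth signal.
#' @param v_catagen Constant retraction speed during catagen (length/day).
#' @param termination Signal level at which elongation stops; should match
#'   `phase_thresholds()$termination`.
#' @return A function `f(signal, anagen)` mapping a signal vector and a
#'   logical vector (in anagen?) to signed velocities.
#' @export
default_growth_law <- function(v_max = 0.3, C_half = 0.3, v_catagen = 0.6,
                               termination = 0.08) {
  force(v_max); force(C_half); force(v_catagen); force(termination)
  function(signal, anagen) {
    ifelse(anagen,
           v_max * pmax(signal - termination, 0) / (C_half + abs(signal)),
           -v_catagen)
  }
}

#' Calibrated default parameter set
#'
#' A single parameter set for which the noise-free follicle is excitable:
#' it cycles autonomously with a stable period, telogen lengthens and anagen
#' shortens as inhibitor signaling is scaled up, and the system equilibrates
#' in extended telogen (high inhibitor) or extended anagen (low inhibitor)
#' outside the excitable range. Values are the package's own calibration in
#' simulated days and arbitrary concentration units.
#'
#' @return A list with elements `act`, `inh` (`pathway_params`), `geometry`
#'   (`hf_geometry`), `thresholds` (`phase_thresholds`), `growth` (list
#'   `v_max`, `C_half`, `v_catagen`) and `numerics` (list `dt`,
#'   `output_stride`).
#' @export
hf_defaults <- function() {
  list(
    act = pathway_params(
      diffusion_coeff = 0.15,
      production_region1 = 0.02,
      production_region2 = list(telogen = 1.8, anagen = 5),
      bind_on = 2, bind_off = 0.3, degradation = 0.15,
      receptor_total = 1, noise_amplitude = 0, extra_source_region1 = 0
    ),
    inh = pathway_params(
      diffusion_coeff = 0.15,
      production_region1 = 0.02,
      production_region2 = list(telogen = 0.05, anagen = 1.8),
      bind_on = 0.5, bind_off = 0.08, degradation = 0.07,
      receptor_total = 1, noise_amplitude = 0, extra_source_region1 = 0
    ),
    geometry = hf_geometry(),
    thresholds = phase_thresholds(),
    growth = list(v_max = 0.3, C_half = 0.3, v_catagen = 0.6),
    numerics = list(dt = 0.025, output_stride = 0.25)
  )
}

# growth law from a defaults-style list
growth_law_from <- function(base) {
  default_growth_law(base$growth$v_max, base$growth$C_half,
                     base$growth$v_catagen, base$thresholds$termination)
}

#' Maximum stable time step for the explicit scheme
#'
#' @param geometry An `hf_geometry`.
#' @param act,inh `pathway_params` for the two pathways.
#' @return The stability bound `grid_spacing^2 / (2 * max D)`.
#' @export
stability_dt <- function(geometry, act, inh) {
  dmax <- max(act$diffusion_coeff, inh$diffusion_coeff)
  if (dmax == 0) return(Inf)
  geometry$grid_spacing^2 / (2 * dmax)
}

check_stability <- function(dt, geometry, act, inh) {
  bound <- stability_dt(geometry, act, inh)
  if (dt > bound + 1e-12)
    stop(sprintf(
      "explicit-scheme stability bound violated: dt = %g exceeds the maximum admissible dt = %g (grid_spacing^2 / (2 max diffusion_coeff))",
      dt, bound))
  invisible(bound)
}
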