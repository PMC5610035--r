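#' Construct the state of a single follicle
#'
#' Holds the per-follicle fields on the axis grid: free ligand and bound
#' receptor concentrations for both pathways, the current geometry, the phase
#' label and per-phase clock, and the identifiers of the follicle's random
#' stream. Fields are stored on the active grid (`floor(length/dx) + 1`
#' nodes).
#'
#' @param geometry An [hf_geometry()].
#' @param act,inh [pathway_params()] for the activator and inhibitor.
#' @param init Initial condition: `"zero"` (all fields zero),
#'   `"competent"` (late competent telogen: bulge-bound activator poised at
#'   `signal0`, free activator at its binding equilibrium), the default.
#' @param signal0 Initial growth-signal level used by `init = "competent"`.
#' @param phase Initial phase label, `"telogen"` or `"anagen"`.
#' @param seed,stream Master seed and stream index of the follicle's
#'   counter-based noise stream.
#' @return An object of class `hf_state`.
#' @export
new_hf_state <- function(geometry, act, inh,
                         init = c("competent", "zero"),
                         signal0 = NULL, phase = "telogen",
                         seed = 1, stream = 0L) {
  init <- match.arg(init)
  nd <- node_depths(geometry)
  n <- floor(geometry$length0 / geometry$grid_spacing + 1e-9) + 1
  zero <- numeric(n)
  la <- ba <- zero
  if (init == "competent") {
    if (is.null(signal0)) signal0 <- 0.1
    if (signal0 >= act$receptor_total)
      stop("hf_state: signal0 must be below the activator receptor_total")
    ba[nd$in_region1[seq_len(n)]] <- signal0
    la[] <- (act$bind_off + act$degradation) * signal0 /
      (act$bind_on * (act$receptor_total - signal0))
  }
  st <- list(
    geometry = geometry,
    ligand_act = la, ligand_inh = zero,
    bound_act = ba, bound_inh = zero,
    phase = match.arg(phase, c("telogen", "anagen")),
    phase_elapsed = Inf,  # no transition yet; dwell guard starts satisfied
    time = 0,
    transitions = empty_transitions(),
    clip_events = 0L,
    rng = list(seed = seed, stream = as.integer(stream), step = 0)
  )
  class(st) <- "hf_state"
  validate_hf_state(st, act, inh)
  st
}

empty_transitions <- function() {
  data.frame(time = numeric(0), from = character(0), to = character(0),
             cycle_index = integer(0), stringsAsFactors = FALSE)
}

validate_hf_state <- function(st, act = NULL, inh = NULL) {
  g <- st$geometry
  n <- floor(length_of(st) / g$grid_spacing + 1e-9) + 1
  flds <- list(ligand_act = st$ligand_act, ligand_inh = st$ligand_inh,
               bound_act = st$bound_act, bound_inh = st$bound_inh)
  for (nm in names(flds)) {
    f <- flds[[nm]]
    if (length(f) != n)
      stop("hf_state: field ", nm, " has ", length(f),
           " nodes; geometry implies ", n)
    if (any(!is.finite(f)))
      stop("hf_state: non-finite values in field ", nm)
    if (any(f < 0))
      stop("hf_state: negative concentrations in field ", nm)
  }
  if (!is.null(act) && any(st$bound_act > act$receptor_total + 1e-12))
    stop("hf_state: bound_act exceeds activator receptor_total")
  if (!is.null(inh) && any(st$bound_inh > inh$receptor_total + 1e-12))
    stop("hf_state: bound_inh exceeds inhibitor receptor_total")
  if (!st$phase %in% c("telogen", "anagen"))
    stop("hf_state: phase must be 'telogen' or 'anagen'")
  invisible(st)
}

length_of <- function(st) st$geometry$length0

#' @export
print.hf_state <- function(x, ...) {
  cat("<hf_state>\n")
  cat(sprintf("  t = %g d, phase = %s (elapsed %g d), length = %g\n",
              x$time, x$phase, x$phase_elapsed, x$geometry$length0))
  cat(sprintf("  %d grid nodes, signal C = %.4f\n",
              length(x$ligand_act), growth_signal(x)))
  invisible(x)
}
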