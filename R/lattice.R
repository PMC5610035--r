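#' Define a named skin domain
#'
#' A domain is a named set of lattice sites sharing parameter overrides, used
#' to model anatomical skin regions with distinct cycling dynamics (e.g. a
#' fast-cycling ventral region, or a hyper-refractory ear-like region).
#'
#' Supported overrides:
#' * `receptor_scale`: multiplies `receptor_total` of both pathways (the
#'   ventral parameterization; larger means faster cycling),
#' * `inhibitor_scale`: multiplies all inhibitor sources (production in both
#'   regions and schedules, and the extra source),
#' * `act`, `inh`: named lists of `pathway_params` fields to replace,
#' * `thresholds`: named list of `phase_thresholds` fields to replace.
#'
#' @param name Domain label, e.g. `"Dorsal"`.
#' @param mask Logical matrix (lattice shape) or 2-column matrix/data frame of
#'   (row, col) coordinates selecting the domain's sites.
#' @param overrides Named list of overrides (see Details).
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(name, mask = NULL, overrides = list()) {
  known <- c("receptor_scale", "inhibitor_scale", "act", "inh", "thresholds")
  bad <- setdiff(names(overrides), known)
  if (length(bad) > 0)
    stop("domain_spec: unknown overrides: ", paste(bad, collapse = ", "))
  d <- list(name = name, mask = mask, overrides = overrides)
  class(d) <- "domain_spec"
  d
}

#' Make a domain hyper-refractory
#'
#' Elevates all inhibitor sources of a domain by a common factor. With a
#' sufficiently large elevation the domain's follicles equilibrate in an
#' extended telogen after their first cycle and anagen waves arriving from
#' neighboring domains stop at the domain boundary (ear-like behavior).
#'
#' @param domain A [domain_spec()].
#' @param elevation Multiplicative inhibitor elevation, `>= 1`; `1` returns
#'   the domain unchanged.
#' @return The modified `domain_spec`.
#' @export
make_hyper_refractory <- function(domain, elevation = 4) {
  if (elevation < 1)
    stop("make_hyper_refractory: elevation must be >= 1")
  if (elevation == 1) return(domain)
  prior <- domain$overrides$inhibitor_scale
  if (is.null(prior)) prior <- 1
  domain$overrides$inhibitor_scale <- prior * elevation
  domain
}

#' Build a follicle lattice
#'
#' Arranges follicles on a 1D array or 2D grid with von Neumann (4-neighbor)
#' connectivity, optional periodic wrap in the lateral (column) direction
#' (the skin modeled as an unrolled cylinder), named parameter domains, and
#' wave-breaking geometry: `barrier` and `aperture` sites host no follicle
#' and carry no exchange flux.
#'
#' @param nrow,ncol Lattice dimensions (head-to-tail rows, lateral columns);
#'   use `ncol = 1` (or `nrow = 1`) for a linear array.
#' @param coupling_strength Inter-follicular ligand exchange rate (1/day)
#'   between neighboring follicles, applied over the bulge depth band.
#' @param wrap_lateral Periodic boundary in the column direction.
#' @param domains List of [domain_spec()]; their masks must be disjoint.
#'   Sites in no listed domain fall into the base domain `"base"` (no
#'   overrides).
#' @param features Named list of site features: each of `barrier`, `aperture`
#'   may be a logical matrix or a 2-column (row, col) coordinate set. Feature
#'   sites host no follicle.
#' @param spacing Lattice spacing (site units; metadata only).
#' @return An object of class `hf_lattice` with per-site domain assignment,
#'   site kinds, and the exchange adjacency among follicle sites.
#' @examples
#' lat <- build_lattice(8, 8, coupling_strength = 0.5)
#' @export
build_lattice <- function(nrow, ncol = 1, coupling_strength = 0,
                          wrap_lateral = FALSE, domains = list(),
                          features = list(), spacing = 1) {
  if (nrow < 1 || ncol < 1) stop("build_lattice: nrow, ncol must be >= 1")
  if (coupling_strength < 0)
    stop("build_lattice: coupling_strength must be >= 0")
  kind <- matrix("follicle", nrow, ncol)
  for (f in c("barrier", "aperture")) {
    m <- features[[f]]
    if (!is.null(m)) kind[as_mask(m, nrow, ncol)] <- f
  }
  unknown <- setdiff(names(features), c("barrier", "aperture"))
  if (length(unknown) > 0)
    stop("build_lattice: unknown features: ", paste(unknown, collapse = ", "))

  domain <- matrix(NA_character_, nrow, ncol)
  specs <- list()
  for (d in domains) {
    if (!inherits(d, "domain_spec")) stop("domains must be domain_spec objects")
    m <- as_mask(d$mask, nrow, ncol)
    if (any(!is.na(domain[m])))
      stop("build_lattice: domain masks overlap (", d$name, ")")
    domain[m] <- d$name
    specs[[d$name]] <- d
  }
  if (any(is.na(domain))) {
    domain[is.na(domain)] <- "base"
    if (is.null(specs[["base"]]))
      specs[["base"]] <- domain_spec("base")
  }
  domain[kind != "follicle"] <- NA_character_

  lat <- list(nrow = nrow, ncol = ncol, spacing = spacing,
              coupling_strength = coupling_strength,
              wrap_lateral = wrap_lateral,
              site_kind = kind, domain = domain, domains = specs)
  lat$sites <- which(kind == "follicle")          # linear indices, col-major
  lat$site_row <- row(kind)[lat$sites]
  lat$site_col <- col(kind)[lat$sites]
  lat$adjacency <- lattice_adjacency(lat)
  class(lat) <- "hf_lattice"
  lat
}

# coerce a logical matrix or (row, col) coordinate set to a logical matrix
as_mask <- function(m, nrow, ncol) {
  if (is.null(m)) return(matrix(TRUE, nrow, ncol))
  if (is.logical(m) && is.matrix(m)) {
    if (!all(dim(m) == c(nrow, ncol)))
      stop("mask dimensions do not match the lattice")
    return(m)
  }
  m <- as.matrix(m)
  if (ncol(m) != 2) stop("coordinate masks need two columns (row, col)")
  out <- matrix(FALSE, nrow, ncol)
  if (any(m[, 1] < 1 | m[, 1] > nrow | m[, 2] < 1 | m[, 2] > ncol))
    stop("mask coordinates outside the lattice")
  out[m] <- TRUE
  out
}

# symmetric 0/1 adjacency among follicle sites (4-neighbor; optional lateral
# wrap); exchange through barrier/aperture sites is impossible by construction
# because those sites are simply absent from the graph
lattice_adjacency <- function(lat) {
  nr <- lat$nrow; nc <- lat$ncol
  idx <- matrix(0L, nr, nc)
  idx[cbind(lat$site_row, lat$site_col)] <- seq_along(lat$sites)
  s <- length(lat$sites)
  a <- matrix(0, s, s)
  for (k in seq_len(s)) {
    r <- lat$site_row[k]; cc <- lat$site_col[k]
    nbr <- list(c(r - 1L, cc), c(r + 1L, cc), c(r, cc - 1L), c(r, cc + 1L))
    for (n in nbr) {
      rr <- n[1]; ccn <- n[2]
      if (lat$wrap_lateral && nc > 1) {
        if (ccn == 0L) ccn <- nc
        if (ccn == nc + 1L) ccn <- 1L
      }
      if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
      j <- idx[rr, ccn]
      if (j > 0L) a[k, j] <- a[k, j] + 1
    }
  }
  a
}

#' @export
print.hf_lattice <- function(x, ...) {
  cat(sprintf("<hf_lattice> %d x %d (%d follicle sites), coupling = %g%s\n",
              x$nrow, x$ncol, length(x$sites), x$coupling_strength,
              if (x$wrap_lateral) ", lateral wrap" else ""))
  tab <- table(x$domain[!is.na(x$domain)])
  cat("  domains:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  nb <- sum(x$site_kind == "barrier"); na_ <- sum(x$site_kind == "aperture")
  if (nb + na_ > 0)
    cat(sprintf("  features: %d barrier, %d aperture sites\n", nb, na_))
  invisible(x)
}

#' Initial conditions for a lattice simulation
#'
#' Describes the first-cycle anagen onset pattern. Every follicle starts in
#' late competent telogen; its first anagen entry is gated to occur no
#' earlier than its onset offset. Offsets combine a linear head-to-tail
#' gradient (rows), a linear lateral gradient (columns), per-domain onset
#' delays, and a seeded per-site developmental jitter that breaks exact
#' lattice symmetries (realized from the simulation master seed at run time).
#'
#' With `mode = "point_source"` all sites instead start just below the
#' activation threshold (competent but not yet firing) and only `source`
#' sites are poised above it, so a single anagen wave propagates from the
#' sources; offsets and jitter are ignored.
#'
#' @param head_tail_span Offset difference (days) between first and last row.
#' @param lateral_span Offset difference (days) between first and last column.
#' @param domain_delays Named numeric: additional onset delay (days) per
#'   domain name.
#' @param jitter_sd Standard deviation (days) of the per-site jitter;
#'   negative jitter is truncated at 0.
#' @param mode `"phase_gradient"` (default) or `"point_source"`.
#' @param source Coordinate set or logical matrix of wave source sites
#'   (required for `"point_source"`).
#' @param competent_depth How far below the activation threshold non-source
#'   sites start in `"point_source"` mode (signal units).
#' @param refractory_level Initial free inhibitor ligand concentration of
#'   non-source sites in `"point_source"` mode. Mimics the post-catagen
#'   refractory reservoir: the site becomes competent, and then fires
#'   autonomously, only as this inhibitor degrades, which gives an arriving
#'   wave a wide window to recruit the site first.
#' @return An object of class `hf_init`.
#' @export
initial_conditions <- function(head_tail_span = 8, lateral_span = 0,
                               domain_delays = c(), jitter_sd = 1,
                               mode = c("phase_gradient", "point_source"),
                               source = NULL, competent_depth = 0.15,
                               refractory_level = 0.12) {
  mode <- match.arg(mode)
  if (mode == "point_source" && is.null(source))
    stop("initial_conditions: point_source mode needs source sites")
  init <- list(head_tail_span = head_tail_span, lateral_span = lateral_span,
               domain_delays = domain_delays, jitter_sd = jitter_sd,
               mode = mode, source = source,
               competent_depth = competent_depth,
               refractory_level = refractory_level)
  class(init) <- "hf_init"
  init
}

# realize per-site onset gates (days) from an hf_init; jitter is drawn from
# the counter-based stream of the master seed (stream offset 2^20 keeps it
# clear of the per-site noise streams)
site_gates <- function(init, lat, seed) {
  nr <- lat$nrow; nc <- lat$ncol
  g <- numeric(length(lat$sites))
  if (nr > 1)
    g <- g + init$head_tail_span * (lat$site_row - 1) / (nr - 1)
  if (nc > 1)
    g <- g + init$lateral_span * (lat$site_col - 1) / (nc - 1)
  for (nm in names(init$domain_delays)) {
    hit <- !is.na(lat$domain[lat$sites]) & lat$domain[lat$sites] == nm
    g[hit] <- g[hit] + init$domain_delays[[nm]]
  }
  if (init$jitter_sd > 0) {
    z <- .ct_normals(seed, as.integer(seq_along(lat$sites) - 1L + 2^20),
                     0, 1, 0)
    g <- g + init$jitter_sd * as.numeric(z)
  }
  pmax(g, 0)
}
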