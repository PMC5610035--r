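#' Default scenario configuration
#'
#' The full set of tunable quantities of a simulation scenario as a nested
#' list, JSON-serializable: pathway kinetics, geometry, thresholds, growth
#' law constants, numerics (dt, stride, horizon, seed), and optionally a
#' lattice block (dimensions, coupling, domains, features) and an
#' initial-conditions block. `load_config()` fills unspecified values from
#' these defaults.
#'
#' @return A nested list of class `scenario_config`.
#' @export
default_config <- function() {
  d <- hf_defaults()
  cfg <- list(
    pathways = list(act = unclass_params(d$act), inh = unclass_params(d$inh)),
    geometry = unclass(d$geometry),
    thresholds = unclass(d$thresholds),
    growth = d$growth,
    numerics = list(dt = d$numerics$dt, output_stride = d$numerics$output_stride,
                    horizon = 300, seed = 1),
    lattice = NULL,
    init = NULL,
    scan = NULL,
    preset = NULL
  )
  class(cfg) <- "scenario_config"
  cfg
}

unclass_params <- function(p) unclass(p)

#' Load and validate a scenario configuration
#'
#' Reads a JSON configuration file, fills every unspecified value from
#' [default_config()], records the provenance of each top-level section
#' (`"user"` vs `"default"`), and validates the result: unknown keys, type
#' errors and numerics violating the explicit-scheme stability bound are all
#' collected and reported together. An empty file (or empty JSON object)
#' yields the all-defaults configuration.
#'
#' @param path Path to a JSON file.
#' @return A validated `scenario_config` with attribute `provenance`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (grepl("^\\s*$", txt)) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  as_config(user)
}

#' Build a validated configuration from a nested list
#'
#' @param user Nested list of overrides on [default_config()].
#' @return A validated `scenario_config`.
#' @export
as_config <- function(user = list()) {
  cfg <- default_config()
  known <- names(cfg)
  bad <- setdiff(names(user), known)
  errors <- character(0)
  if (length(bad) > 0)
    errors <- c(errors, paste0("unknown keys: ", paste(bad, collapse = ", ")))
  for (nm in intersect(names(user), known)) {
    cfg[[nm]] <- merge_into(cfg[[nm]], user[[nm]],
                            path = nm, errors = environment())
  }
  prov <- stats::setNames(
    ifelse(known %in% names(user), "user", "default"), known)
  errors <- c(errors, validate_config(cfg))
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  attr(cfg, "provenance") <- prov
  class(cfg) <- "scenario_config"
  cfg
}

# recursive merge of user values into defaults; unknown nested keys are
# collected into the caller's error vector. Sections that default to NULL
# (lattice, init, scan) are taken as-is.
merge_into <- function(def, usr, path, errors) {
  if (is.null(def)) return(usr)
  if (!is.list(def) || !is.list(usr)) return(usr)
  bad <- setdiff(names(usr), names(def))
  if (length(bad) > 0)
    assign("errors", c(get("errors", errors),
                       paste0("unknown keys under ", path, ": ",
                              paste(bad, collapse = ", "))), errors)
  for (nm in intersect(names(usr), names(def)))
    def[[nm]] <- merge_into(def[[nm]], usr[[nm]],
                            paste0(path, ".", nm), errors)
  def
}

validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(expr, msg) if (!isTRUE(expr)) errs <<- c(errs, msg)
  p <- try(config_params(cfg), silent = TRUE)
  if (inherits(p, "try-error")) {
    errs <- c(errs, paste("parameter block invalid:",
                          attr(p, "condition")$message))
    return(errs)
  }
  bound <- stability_dt(p$geometry, p$act, p$inh)
  chk(cfg$numerics$dt > 0, "numerics.dt must be > 0")
  chk(cfg$numerics$dt <= bound + 1e-12,
      sprintf("numerics.dt = %g violates the stability bound %g (grid_spacing^2 / (2 max diffusion_coeff))",
              cfg$numerics$dt, bound))
  chk(cfg$numerics$horizon >= 0, "numerics.horizon must be >= 0")
  chk(cfg$numerics$output_stride >= cfg$numerics$dt,
      "numerics.output_stride must be >= dt")
  if (!is.null(cfg$lattice)) {
    lt <- cfg$lattice
    chk(isTRUE(lt$nrow >= 1) && isTRUE(lt$ncol >= 1),
        "lattice.nrow/ncol must be >= 1")
    if (isTRUE(lt$coupling_strength > 0)) {
      chk(cfg$numerics$dt * lt$coupling_strength * 4 < 1,
          "lattice coupling violates dt * coupling * 4 < 1")
    }
  }
  errs
}

# materialize pathway_params / geometry / thresholds objects from a config
config_params <- function(cfg) {
  pw <- cfg$pathways
  mk <- function(x) pathway_params(
    x$diffusion_coeff, x$production_region1, x$production_region2,
    x$bind_on, x$bind_off, x$degradation, x$receptor_total,
    x$noise_amplitude, x$extra_source_region1)
  g <- cfg$geometry
  th <- cfg$thresholds
  list(
    act = mk(pw$act), inh = mk(pw$inh),
    geometry = hf_geometry(g$grid_spacing, g$length_min, g$length_max,
                           unlist(g$region1), g$region2_width, g$length0),
    thresholds = phase_thresholds(th$activation, th$termination,
                                  th$refractory_min),
    growth = cfg$growth,
    numerics = cfg$numerics
  )
}

#' Save a configuration as JSON
#'
#' Inverse of [load_config()]: `load_config(save_config(x, f))` reproduces
#' `x`.
#'
#' @param cfg A `scenario_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(drop_null(unclass(cfg)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

drop_null <- function(x) {
  if (!is.list(x)) return(x)
  x[!vapply(x, is.null, logical(1))] <- lapply(
    x[!vapply(x, is.null, logical(1))], drop_null)
  x
}

#' Named scenario presets
#'
#' Ready-made configurations for the package's canonical simulation
#' scenarios:
#' * `single_follicle`: one noise-free follicle cycling autonomously.
#' * `inhibitor_scan`: single-follicle scan over inhibitor signaling
#'   strength (durations vs level; non-cycling equilibria at both extremes).
#' * `homogeneous_sheet`: homogeneous 2D grid seeded with a head-to-tail
#'   onset gradient (asynchrony persistence scenario).
#' * `two_domain`: Ventral|Dorsal|Ventral stripes with elevated ventral
#'   receptor totals, dorsal head-to-tail asynchrony and delayed ventral
#'   onset (bilateral-symmetry scenario).
#' * `barrier`: anagen wave launched against a lateral barrier segment.
#' * `aperture`: anagen wave passing through a hole in a barrier row.
#' * `ear_hyper_refractory`: a normal stripe coupled to a hyper-refractory
#'   stripe (waves stop at the boundary).
#'
#' @param name Preset name.
#' @return A `scenario_config`.
#' @export
preset_config <- function(name = c("single_follicle", "inhibitor_scan",
                                   "homogeneous_sheet", "two_domain",
                                   "barrier", "aperture",
                                   "ear_hyper_refractory")) {
  name <- match.arg(name)
  cfg <- default_config()
  cfg$preset <- NULL
  if (name == "single_follicle") {
    cfg$numerics$horizon <- 500
  } else if (name == "inhibitor_scan") {
    cfg$numerics$horizon <- 500
    cfg$scan <- list(levels = c(0.5, 0.7, 0.85, 1, 1.1, 1.2, 1.5))
  } else if (name == "homogeneous_sheet") {
    cfg$numerics$horizon <- 1200
    cfg$lattice <- list(nrow = 16, ncol = 16, coupling_strength = 0.05,
                        wrap_lateral = TRUE, domains = NULL, features = NULL)
    cfg$init <- list(mode = "phase_gradient", head_tail_span = 8,
                     lateral_span = 0, jitter_sd = 1, domain_delays = NULL)
  } else if (name == "two_domain") {
    cfg$numerics$horizon <- 480
    cfg$lattice <- list(
      nrow = 16, ncol = 20, coupling_strength = 0.015, wrap_lateral = TRUE,
      domains = list(
        list(name = "Ventral", columns = c(1:5, 16:20),
             overrides = list(receptor_scale = 1.5)),
        list(name = "Dorsal", columns = 6:15, overrides = NULL)),
      features = NULL)
    cfg$init <- list(mode = "phase_gradient", head_tail_span = 8,
                     lateral_span = 0, jitter_sd = 1,
                     domain_delays = list(Ventral = 3.5))
  } else if (name == "barrier") {
    # established head-to-tail anagen wave against a lateral barrier segment;
    # the front detours around the ends and bows behind the feature
    cfg$numerics$horizon <- 250
    cfg$lattice <- list(nrow = 16, ncol = 16, coupling_strength = 0.05,
                        wrap_lateral = FALSE, domains = NULL,
                        features = list(barrier = list(rows = 8,
                                                       columns = 4:13)))
    cfg$init <- list(mode = "phase_gradient", head_tail_span = 8,
                     lateral_span = 0, jitter_sd = 0, domain_delays = NULL)
  } else if (name == "aperture") {
    # same wave forced through a hole in an otherwise blocking row
    cfg$numerics$horizon <- 250
    cfg$lattice <- list(nrow = 16, ncol = 16, coupling_strength = 0.05,
                        wrap_lateral = FALSE, domains = NULL,
                        features = list(barrier = list(rows = 8,
                                                       columns = c(1:6, 11:16))))
    cfg$init <- list(mode = "phase_gradient", head_tail_span = 8,
                     lateral_span = 0, jitter_sd = 0, domain_delays = NULL)
  } else if (name == "ear_hyper_refractory") {
    cfg$numerics$horizon <- 260
    cfg$lattice <- list(
      nrow = 12, ncol = 16, coupling_strength = 0.05, wrap_lateral = FALSE,
      domains = list(
        list(name = "Cranial", columns = 1:8, overrides = NULL),
        list(name = "Ear", columns = 9:16,
             overrides = list(inhibitor_scale = 2))),
      features = NULL)
    # a deep, slowly degrading inhibitor hold keeps the field refractory
    # long enough for the question (can the wave recruit the ear?) to be
    # about propagation rather than autonomous recovery
    cfg$init <- list(mode = "point_source", source = list(columns = 1),
                     refractory_level = 0.4)
  }
  cfg$preset <- name
  class(cfg) <- "scenario_config"
  cfg
}

# build an hf_lattice from a config lattice block
config_lattice <- function(cfg) {
  lt <- cfg$lattice
  if (is.null(lt)) return(NULL)
  doms <- list()
  for (d in lt$domains %||% list()) {
    mask <- block_mask(d, lt$nrow, lt$ncol)
    ov <- d$overrides %||% list()
    doms[[length(doms) + 1L]] <- domain_spec(d$name, mask, ov)
  }
  feats <- list()
  for (f in names(lt$features %||% list()))
    feats[[f]] <- block_mask(lt$features[[f]], lt$nrow, lt$ncol)
  build_lattice(lt$nrow, lt$ncol,
                coupling_strength = lt$coupling_strength %||% 0,
                wrap_lateral = isTRUE(lt$wrap_lateral),
                domains = doms, features = feats)
}

# rows/columns block selector from a config entry
block_mask <- function(d, nrow, ncol) {
  m <- matrix(FALSE, nrow, ncol)
  rows <- if (is.null(d$rows)) seq_len(nrow) else unlist(d$rows)
  cols <- if (is.null(d$columns)) seq_len(ncol) else unlist(d$columns)
  m[rows, cols] <- TRUE
  m
}

config_init <- function(cfg) {
  ic <- cfg$init
  if (is.null(ic)) return(initial_conditions())
  if (identical(ic$mode, "point_source")) {
    src <- block_mask(ic$source, cfg$lattice$nrow, cfg$lattice$ncol)
    initial_conditions(mode = "point_source", source = src,
                       competent_depth = ic$competent_depth %||% 0.15,
                       refractory_level = ic$refractory_level %||% 0.12)
  } else {
    initial_conditions(
      head_tail_span = ic$head_tail_span %||% 8,
      lateral_span = ic$lateral_span %||% 0,
      domain_delays = unlist(ic$domain_delays %||% list()),
      jitter_sd = ic$jitter_sd %||% 1)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario and write its output bundle
#'
#' Executes the scenario described by a configuration — a single-follicle
#' run, an inhibitor-strength scan, or a lattice simulation — and writes a
#' reproducible output bundle to `out_dir`: trajectory or pattern CSVs, the
#' transition log, metric tables for lattice runs (per-cycle asynchrony and
#' symmetry statistics), and a `metadata.json` echoing the fully resolved
#' configuration, seed and package version. Rerunning the same configuration
#' and seed reproduces the outputs bit-identically.
#'
#' @param cfg A `scenario_config` (see [load_config()], [preset_config()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of `cfg$numerics$seed`.
#' @return Invisibly, a list with the result object and the written paths.
#' @export
run_scenario <- function(cfg, out_dir, seed = NULL) {
  if (!inherits(cfg, "scenario_config")) stop("cfg must be a scenario_config")
  if (!is.null(seed)) cfg$numerics$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config_params(cfg)
  gl <- default_growth_law(p$growth$v_max, p$growth$C_half,
                           p$growth$v_catagen, p$thresholds$termination)
  paths <- character(0)
  result <- NULL

  write_meta <- function(extra = list()) {
    meta <- c(list(config = drop_null(unclass(cfg)),
                   seed = cfg$numerics$seed,
                   package_version = as.character(packageVersion("haircycle"))),
              extra)
    mp <- file.path(out_dir, "metadata.json")
    jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    mp
  }

  if (!is.null(cfg$scan)) {
    base <- list(act = p$act, inh = p$inh, geometry = p$geometry,
                 thresholds = p$thresholds, growth = p$growth,
                 numerics = cfg$numerics)
    tab <- inhibitor_strength_scan(base, unlist(cfg$scan$levels),
                                   horizon = cfg$numerics$horizon,
                                   dt = cfg$numerics$dt)
    fp <- file.path(out_dir, "scan.csv")
    write.csv(tab, fp, row.names = FALSE)
    paths <- c(paths, fp, write_meta())
    result <- tab
  } else if (is.null(cfg$lattice)) {
    traj <- simulate_hf(p$act, p$inh, p$geometry, p$thresholds,
                        horizon = cfg$numerics$horizon, dt = cfg$numerics$dt,
                        seed = cfg$numerics$seed, growth_law = gl,
                        output_stride = cfg$numerics$output_stride)
    fp <- file.path(out_dir, "trajectory.csv")
    write.csv(as.data.frame(traj), fp, row.names = FALSE)
    tp <- file.path(out_dir, "transitions.csv")
    write.csv(traj$transitions, tp, row.names = FALSE)
    paths <- c(paths, fp, tp,
               write_meta(list(clip_events = traj$clip_events)))
    result <- traj
  } else {
    lat <- config_lattice(cfg)
    init <- config_init(cfg)
    base <- list(act = p$act, inh = p$inh, geometry = p$geometry,
                 thresholds = p$thresholds, growth = p$growth,
                 numerics = cfg$numerics)
    rec <- simulate_population(lat, init,
                               horizon = cfg$numerics$horizon,
                               dt = cfg$numerics$dt,
                               seed = cfg$numerics$seed, base = base,
                               growth_law = gl,
                               output_stride = cfg$numerics$output_stride)
    paths <- c(paths, write_record(rec, out_dir))
    metrics <- record_metrics(rec)
    mp <- file.path(out_dir, "metrics.csv")
    write.csv(metrics, mp, row.names = FALSE)
    paths <- c(paths, mp, write_meta(list(clip_events = rec$clip_events)))
    result <- rec
  }
  invisible(list(result = result, paths = paths, out_dir = out_dir))
}

#' Write a pattern record as wide CSV tables
#'
#' One wide CSV per variable (phase, length, signal) with a time column and
#' one column per follicle site (named `s<row>_<col>`), plus the transition
#' log.
#'
#' @param record A `pattern_record`.
#' @param out_dir Output directory.
#' @return The written file paths.
#' @export
write_record <- function(record, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  site_names <- sprintf("s%d_%d", record$site_row, record$site_col)
  paths <- character(0)
  for (v in c("phase", "length", "signal")) {
    m <- record[[v]]
    df <- data.frame(time = record$times, m)
    names(df) <- c("time", site_names)
    fp <- file.path(out_dir, paste0(v, ".csv"))
    write.csv(df, fp, row.names = FALSE)
    paths <- c(paths, fp)
  }
  tp <- file.path(out_dir, "transitions.csv")
  write.csv(record$transitions, tp, row.names = FALSE)
  c(paths, tp)
}

# tidy per-cycle metric table for a lattice record
record_metrics <- function(record) {
  out <- data.frame(cycle = integer(0), metric = character(0),
                    value = numeric(0))
  k <- try(suppressWarnings(asynchrony_persistence(record)), silent = TRUE)
  if (!inherits(k, "try-error")) {
    tab <- attr(k, "table")
    if (nrow(tab) > 0)
      out <- rbind(out, data.frame(cycle = tab$cycle,
                                   metric = "head_tail_spearman",
                                   value = tab$rho))
    out <- rbind(out, data.frame(cycle = NA_integer_,
                                 metric = "asynchrony_persistence",
                                 value = as.numeric(k)))
  }
  if (record$lattice$ncol >= 2) {
    bs <- try(bilateral_symmetry(record), silent = TRUE)
    if (!inherits(bs, "try-error") && nrow(bs) > 0) {
      out <- rbind(out, data.frame(cycle = bs$cycle,
                                   metric = "bilateral_symmetry",
                                   value = bs$score))
    }
  }
  out
}
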