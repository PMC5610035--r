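#' Per-site anagen onset times for one cycle
#'
#' Extracts, for every follicle site, the time of its k-th anagen entry from
#' the transition log. Cycles are counted per site from the site's own first
#' anagen entry, since sites drift out of phase. Sites with fewer than k
#' entries (e.g. hyper-refractory follicles) are masked with `NA`.
#'
#' @param record A [simulate_population()] `pattern_record`.
#' @param cycle Cycle index, `>= 1`.
#' @return An `onset_map`: a `nrow x ncol` numeric matrix of onset times with
#'   `NA` at masked and non-follicle sites, with attributes `cycle` and
#'   `n_sites` (number of unmasked sites).
#' @export
onset_map <- function(record, cycle) {
  if (cycle < 1) stop("cycle must be >= 1")
  tr <- record$transitions
  ana <- tr[tr$to == "anagen", , drop = FALSE]
  hit <- ana[ana$cycle_index == cycle, , drop = FALSE]
  if (max(c(0, ana$cycle_index)) < cycle)
    stop("range error: record spans no cycle ", cycle, " onsets")
  lat <- record$lattice
  m <- matrix(NA_real_, lat$nrow, lat$ncol)
  m[cbind(record$site_row[hit$site], record$site_col[hit$site])] <- hit$time
  structure(m, cycle = cycle, n_sites = nrow(hit), class = "onset_map")
}

#' @export
print.onset_map <- function(x, ...) {
  cat(sprintf("<onset_map> cycle %d, %d/%d sites, t in [%.2f, %.2f]\n",
              attr(x, "cycle"), attr(x, "n_sites"), length(x),
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

# per-cycle onset maps as a list, up to the last cycle with >= min_frac of
# the reference sites present
cycle_maps <- function(record, sites = NULL, min_frac = 0.9) {
  tr <- record$transitions
  ana <- tr[tr$to == "anagen", , drop = FALSE]
  if (nrow(ana) == 0) return(list())
  kmax <- max(ana$cycle_index)
  sel <- site_selector(record, sites)
  n_ref <- sum(sel)
  maps <- list()
  for (k in seq_len(kmax)) {
    m <- onset_map(record, k)
    if (sum(!is.na(m[sel])) < min_frac * n_ref) break
    maps[[k]] <- m
  }
  maps
}

# logical nrow x ncol selector from NULL (all follicle sites), a domain name,
# or a logical matrix
site_selector <- function(record, sites) {
  lat <- record$lattice
  sel <- matrix(FALSE, lat$nrow, lat$ncol)
  sel[cbind(record$site_row, record$site_col)] <- TRUE
  if (is.null(sites)) return(sel)
  if (is.character(sites)) {
    dom <- !is.na(lat$domain) & lat$domain == sites
    if (!any(dom)) stop("no sites in domain '", sites, "'")
    return(sel & dom)
  }
  sel & as_mask(sites, lat$nrow, lat$ncol)
}

#' Persistence of head-to-tail onset asynchrony
#'
#' For each cycle, computes the Spearman rank correlation between per-site
#' anagen onset times and the head-to-tail coordinate (row index by
#' default), and returns the largest k such that the correlation exceeds the
#' persistence threshold for all cycles 1..k. This operationalizes how long
#' an initial head-to-tail onset ordering survives the coupled dynamics.
#'
#' @param record A `pattern_record`.
#' @param axis Optional per-site coordinate matrix (defaults to row index).
#' @param threshold Persistence threshold on the rank correlation
#'   (default 0.5).
#' @param sites Optional site restriction: domain name or logical matrix.
#' @return Integer: the number of consecutive initial cycles with rank
#'   correlation above the threshold. Attribute `table` holds the per-cycle
#'   statistics (cycle, rho, n).
#' @export
asynchrony_persistence <- function(record, axis = NULL, threshold = 0.5,
                                   sites = NULL) {
  lat <- record$lattice
  if (is.null(axis)) axis <- row(matrix(0, lat$nrow, lat$ncol))
  sel <- site_selector(record, sites)
  maps <- cycle_maps(record, sites = sites)
  tab <- data.frame(cycle = integer(0), rho = numeric(0), n = integer(0))
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    ok <- sel & !is.na(m)
    n <- sum(ok)
    rho <- if (n >= 3 && sd(m[ok]) > 0 && sd(axis[ok]) > 0)
      cor(m[ok], axis[ok], method = "spearman") else NA_real_
    tab <- rbind(tab, data.frame(cycle = k, rho = rho, n = n))
  }
  keep <- !is.na(tab$rho) & tab$rho > threshold
  k <- if (nrow(tab) == 0 || !keep[1]) 0L else {
    runs <- rle(keep)
    as.integer(runs$lengths[1])
  }
  structure(k, table = tab, threshold = threshold)
}

#' Bilateral symmetry of onset maps
#'
#' Scores, per cycle, how mirror-symmetric the anagen onset pattern is about
#' a lateral midline. The onset map is first centered per row (the
#' head-to-tail trend removed, since a purely front-to-back gradient is
#' trivially mirror symmetric) and the score is the Pearson correlation
#' between the centered map and its column-mirrored image over jointly
#' unmasked sites: 1 for a perfectly mirror-symmetric lateral pattern, -1
#' for an antisymmetric one, near 0 for unrelated lateral structure. If the
#' centered map is degenerate (no lateral variation), the score is 1 exactly
#' when the raw map equals its mirror and 0 otherwise.
#'
#' @param record A `pattern_record`.
#' @param midline Mirror axis; default the lattice's vertical center
#'   (`(ncol + 1) / 2`). Columns map to `2 * midline - col`.
#' @param threshold Emergence threshold on the score (default 0.7).
#' @param sites Optional site restriction: domain name or logical matrix.
#' @param detrend Remove per-row means before correlating (default TRUE).
#' @return Data frame with columns `cycle`, `score`, `n`; attribute
#'   `emergence` is the first cycle whose score exceeds the threshold
#'   (`NA` if none).
#' @export
bilateral_symmetry <- function(record, midline = NULL, threshold = 0.7,
                               sites = NULL, detrend = TRUE) {
  lat <- record$lattice
  if (lat$ncol < 2) stop("bilateral symmetry needs >= 2 columns")
  if (is.null(midline)) midline <- (lat$ncol + 1) / 2
  mir_col <- round(2 * midline) - seq_len(lat$ncol)
  if (any(mir_col < 1 | mir_col > lat$ncol))
    stop("midline does not map every column onto the lattice")
  sel <- site_selector(record, sites)
  maps <- cycle_maps(record, sites = sites)
  out <- data.frame(cycle = integer(0), score = numeric(0), n = integer(0))
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    m[!sel] <- NA
    mm <- m[, mir_col, drop = FALSE]
    ok <- !is.na(m) & !is.na(mm)
    score <- symmetry_score(m, mm, ok, detrend)
    out <- rbind(out, data.frame(cycle = k, score = score, n = sum(ok)))
  }
  emergence <- out$cycle[!is.na(out$score) & out$score > threshold][1]
  structure(out, emergence = emergence, threshold = threshold)
}

symmetry_score <- function(m, mm, ok, detrend) {
  if (sum(ok) < 4) return(NA_real_)
  a <- m; b <- mm
  a[!ok] <- NA; b[!ok] <- NA
  if (detrend) {
    rmeans <- rowMeans(a, na.rm = TRUE)   # == rowMeans of b on joint sites
    a <- a - rmeans
    b <- b - rmeans
  }
  av <- a[ok]; bv <- b[ok]
  if (sd(av) == 0 || sd(bv) == 0) {
    return(if (max(abs(m[ok] - mm[ok])) == 0) 1 else 0)
  }
  cor(av, bv)
}

#' Anagen wavefront arrival field, contours and distortion
#'
#' Treats a cycle's onset map as a wavefront arrival-time field. Iso-arrival
#' contours are extracted at fixed time levels, and a distortion metric
#' quantifies how much the front deviates behind a barrier or aperture from
#' the unobstructed planar front: a plane `t(row)` is fit to the arrival
#' times over reference (feature-free) columns, and the distortion is the
#' maximum arrival delay behind the feature converted into site units via
#' the fitted front speed.
#'
#' @param record A `pattern_record`.
#' @param cycle Cycle index.
#' @param reference_cols Columns used to fit the planar reference front;
#'   defaults to all columns free of barrier/aperture sites (all columns if
#'   the lattice has no features).
#' @param levels Number of iso-arrival contour levels (default 8).
#' @return A list with the arrival matrix (relative to the earliest onset),
#'   `contours` (list of iso-arrival polylines), `distortion` (site units),
#'   and the planar `fit` (intercept, slope per row, speed in sites/day).
#' @export
wavefront_arrival <- function(record, cycle, reference_cols = NULL,
                              levels = 8) {
  m <- onset_map(record, cycle)
  arr <- unclass(m) - min(m, na.rm = TRUE)
  rng <- range(arr, na.rm = TRUE)
  if (diff(rng) < 1e-9) {
    warning("no propagation detected: flat arrival field")
    return(list(arrival = arr, contours = list(), distortion = 0,
                fit = NULL))
  }
  lat <- record$lattice
  feat <- lat$site_kind != "follicle"
  if (is.null(reference_cols)) {
    reference_cols <- which(colSums(feat) == 0)
    if (length(reference_cols) == 0) reference_cols <- seq_len(lat$ncol)
  }
  ref <- arr[, reference_cols, drop = FALSE]
  rows <- row(ref)[!is.na(ref)]
  vals <- ref[!is.na(ref)]
  fit <- stats::lm.fit(cbind(1, rows), vals)
  slope <- fit$coefficients[2]
  speed <- if (abs(slope) > 1e-9) 1 / abs(slope) else NA_real_

  pred <- fit$coefficients[1] + slope * row(arr)
  resid <- arr - pred
  if (any(feat)) {
    # sites behind the feature: rows beyond the feature's last row, in the
    # feature's column span
    frows <- row(feat)[feat]; fcols <- col(feat)[feat]
    behind <- row(arr) > max(frows) &
      col(arr) >= min(fcols) & col(arr) <= max(fcols)
    dist_resid <- resid[behind & !is.na(arr)]
  } else {
    dist_resid <- resid[!is.na(arr)]
  }
  distortion <- if (length(dist_resid) == 0 || is.na(speed)) NA_real_
                else max(dist_resid) * speed

  lv <- pretty(rng, levels)
  lv <- lv[lv > rng[1] & lv < rng[2]]
  z <- arr
  z[is.na(z)] <- max(arr, na.rm = TRUE) + diff(rng)  # features arrive "late"
  contours <- grDevices::contourLines(
    x = seq_len(nrow(arr)), y = seq_len(ncol(arr)), z = z, levels = lv)
  list(arrival = arr, contours = contours, distortion = distortion,
       fit = c(intercept = unname(fit$coefficients[1]),
               slope = unname(slope), speed = unname(speed)))
}
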