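#' Equal-area zone boundaries of the nuclear cross-section
#'
#' The zoning assay divides the circular nuclear cross-section into three
#' concentric rings of equal area.  Zone 1 is the outermost ring (the nuclear
#' periphery, where the nuclear pore complexes sit), zone 3 the central disc.
#' Equal areas give boundary radii \eqn{\sqrt{1/3}\,R} and \eqn{\sqrt{2/3}\,R}.
#'
#' @param radius Nuclear cross-section radius in micrometres (> 0).
#' @return Named numeric vector `c(r_inner, r_outer)`: the zone-3/zone-2 and
#'   zone-2/zone-1 boundary radii in micrometres.
#' @examples
#' zone_boundaries(1)   # 0.5774, 0.8165
#' @export
zone_boundaries <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("'radius' must be a single positive number", call. = FALSE)
  }
  c(r_inner = sqrt(1 / 3) * radius, r_outer = sqrt(2 / 3) * radius)
}

#' Nuclear geometry of one scored cell
#'
#' Centre and radius of the nuclear cross-section in the focal plane of the
#' scored focus, as fitted from the Nup49 ring signal.
#'
#' @param center Numeric length-2, (x, y) centre in micrometres.
#' @param radius Cross-section radius in micrometres (> 0).
#' @param plane_index 0-based index of the focal plane within the stack.
#' @param n_planes Total number of z planes in the stack.
#' @return An object of class `NucleusGeometry`.
#' @export
nucleus_geometry <- function(center, radius, plane_index = 0L, n_planes = 1L) {
  stopifnot(length(center) == 2L, is.numeric(center), all(is.finite(center)))
  if (radius <= 0) stop("nuclear radius must be positive", call. = FALSE)
  plane_index <- as.integer(plane_index)
  n_planes <- as.integer(n_planes)
  if (plane_index < 0L || plane_index >= n_planes) {
    stop("'plane_index' must lie in [0, n_planes)", call. = FALSE)
  }
  structure(
    list(center = as.numeric(center), radius = as.numeric(radius),
         plane_index = plane_index, n_planes = n_planes),
    class = "NucleusGeometry"
  )
}

#' @export
print.NucleusGeometry <- function(x, ...) {
  cat(sprintf("<NucleusGeometry> center (%.3f, %.3f) um, radius %.3f um, plane %d/%d\n",
              x$center[1], x$center[2], x$radius, x$plane_index, x$n_planes))
  invisible(x)
}

#' Classify a focus into one of three equal-area nuclear zones
#'
#' Zone is assigned from the normalised radial coordinate
#' \eqn{\rho = |focus - center| / R}: zone 1 for \eqn{\rho \ge \sqrt{2/3}}
#' (ties assign outward), zone 2 for \eqn{\sqrt{1/3} \le \rho < \sqrt{2/3}},
#' zone 3 below that.  Foci slightly outside the fitted circle
#' (\eqn{1 < \rho \le} `tol`) clamp to zone 1 — tolerance for ring-fit and
#' localisation error; beyond the tolerance the cell is rejected.
#'
#' @param focus_xy Numeric length-2, focus (x, y) in micrometres.
#' @param nucleus A [nucleus_geometry()] object.
#' @param tol Rejection threshold on \eqn{\rho} (default 1.2).
#' @return Integer zone in `{1, 2, 3}`.
#' @export
classify_zone <- function(focus_xy, nucleus, tol = 1.2) {
  stopifnot(inherits(nucleus, "NucleusGeometry"), length(focus_xy) == 2L)
  rho <- sqrt(sum((as.numeric(focus_xy) - nucleus$center)^2)) / nucleus$radius
  if (rho > tol) {
    stop(sprintf("focus outside nucleus (rho = %.2f > %.2f): cell rejected",
                 rho, tol), call. = FALSE)
  }
  if (rho >= sqrt(2 / 3)) 1L else if (rho >= sqrt(1 / 3)) 2L else 3L
}

#' Mid-stack gate
#'
#' Only the middle two-thirds of the z stack is scored; the top and bottom
#' sixths are excluded (poor axial resolution and out-of-focus ring signal).
#' The excluded sixth is rounded up so the rule is bit-reproducible.
#'
#' @param plane_index 0-based plane index (vectorised).
#' @param n_planes Total planes in the stack.
#' @return Logical: `TRUE` for planes that are kept.
#' @examples
#' sum(midstack_gate(0:23, 24))  # 16 planes kept
#' @export
midstack_gate <- function(plane_index, n_planes) {
  plane_index <- as.integer(plane_index)
  n_planes <- as.integer(n_planes)
  stopifnot(all(plane_index >= 0L), all(plane_index < n_planes))
  cut <- as.integer(ceiling(n_planes / 6))
  plane_index >= cut & plane_index <= n_planes - cut - 1L
}

#' Cell-cycle stage from bud size
#'
#' Mid-to-late S-phase cells are identified by bud morphology: a bud of at
#' least 15% and at most two-thirds of the mother cell's area.  Unbudded
#' cells are G1; smaller buds early S; larger buds (post-S) are "other".
#'
#' @param bud_area,mother_area Cell areas in square micrometres (vectorised).
#' @return Character vector in `{"G1","earlyS","midlateS","other"}`.
#' @export
cell_cycle_gate <- function(bud_area, mother_area) {
  stopifnot(all(bud_area >= 0), all(mother_area >= 0))
  if (any(mother_area == 0)) stop("mother_area must be positive", call. = FALSE)
  ratio <- bud_area / mother_area
  out <- rep("other", length(ratio))
  out[ratio == 0] <- "G1"
  out[ratio > 0 & ratio < 0.15] <- "earlyS"
  out[ratio >= 0.15 & ratio <= 2 / 3] <- "midlateS"
  out
}

#' Tally zone calls per condition and time point
#'
#' @param records Data frame with columns `zone` (integer in 1..3),
#'   `condition`, and optionally `timepoint`.
#' @return Data frame of class `ZoneTally`, one row per (condition, timepoint):
#'   columns `condition`, `timepoint`, `n1`, `n2`, `n3`, `n_total`.
#' @export
zone_tally <- function(records) {
  stopifnot(is.data.frame(records), all(c("zone", "condition") %in% names(records)))
  if (nrow(records) == 0L) {
    out <- data.frame(condition = character(), timepoint = character(),
                      n1 = integer(), n2 = integer(), n3 = integer(),
                      n_total = integer(), stringsAsFactors = FALSE)
    class(out) <- c("ZoneTally", "data.frame")
    return(out)
  }
  if (!all(records$zone %in% 1:3)) {
    stop("unknown zone label: zones must be 1, 2 or 3", call. = FALSE)
  }
  tp <- if ("timepoint" %in% names(records)) as.character(records$timepoint)
        else rep(NA_character_, nrow(records))
  key <- data.frame(condition = as.character(records$condition), timepoint = tp,
                    stringsAsFactors = FALSE)
  groups <- unique(key)
  groups <- groups[order(groups$condition, groups$timepoint, na.last = TRUE), ,
                   drop = FALSE]
  counts <- t(vapply(seq_len(nrow(groups)), function(i) {
    sel <- key$condition == groups$condition[i] &
      (key$timepoint == groups$timepoint[i] |
         (is.na(key$timepoint) & is.na(groups$timepoint[i])))
    tabulate(records$zone[sel], nbins = 3L)
  }, integer(3)))
  out <- data.frame(groups, n1 = counts[, 1], n2 = counts[, 2], n3 = counts[, 3],
                    n_total = as.integer(rowSums(counts)), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("ZoneTally", "data.frame")
  out
}
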