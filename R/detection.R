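## --- low-level imaging helpers ------------------------------------------

## separable Gaussian smoothing of a 3D array; sigma per dimension in voxels.
## Band-matrix product per axis with per-row renormalised truncated kernels
## (no edge dimming).
gauss_smooth3 <- function(a, sigma) {
  smooth1 <- function(m, n, sig) {
    if (sig <= 0) return(m)
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) stats::dnorm(i - j, sd = sig))
    K[K < stats::dnorm(ceiling(4 * sig), sd = sig)] <- 0
    K <- K / rowSums(K)
    K %*% m
  }
  d <- dim(a)
  a <- array(smooth1(matrix(a, d[1]), d[1], sigma[1]), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(smooth1(matrix(a, d[2]), d[2], sigma[2]), dim(a))
  a <- aperm(a, c(3, 2, 1))          # now (z, x, y)
  a <- array(smooth1(matrix(a, d[3]), d[3], sigma[3]), dim(a))
  aperm(a, c(2, 3, 1))
}

## robust background statistics (median / MAD-as-SD); signal occupies a small
## fraction of the voxels so the medians see background only
bg_stats <- function(a) {
  med <- stats::median(a)
  list(med = med, sd = max(stats::mad(a, center = med), 1e-12))
}

## above-threshold mask at the standard policy: background median + k * SD
#' Threshold mask of a channel
#'
#' Voxels above `median + k * MAD-SD` of the channel, the mask policy used
#' for overlap-based colocalization scoring.
#'
#' @param img 3D array (one channel of an [render()] stack).
#' @param k Threshold multiplier (default 3).
#' @return Logical array of the same dimensions.
#' @export
threshold_mask <- function(img, k = 3) {
  s <- bg_stats(img)
  img > s$med + k * s$sd
}

## --- periphery ------------------------------------------------------------

#' Fit the nuclear periphery from a ring-channel plane
#'
#' Thresholds the Nup49 ring signal in one z plane and fits a circle to the
#' ring pixels by linear (algebraic) least squares, with two rounds of
#' outlier rejection at 2.5 robust SDs of the radial residual — isolated
#' bright pixels far from the ring do not pull the fit.
#'
#' @param ring_plane Numeric matrix: one z plane of the ring channel,
#'   dims (x, y).
#' @param pixel_size Lateral calibration, um/px.
#' @param plane_index,n_planes Stack bookkeeping carried into the result.
#' @param k Threshold multiplier for ring pixels (default 3).
#' @return A [nucleus_geometry()] (centre and radius in um).
#' @export
fit_periphery <- function(ring_plane, pixel_size, plane_index = 0L,
                          n_planes = 1L, k = 3) {
  stopifnot(is.matrix(ring_plane), pixel_size > 0)
  s <- bg_stats(ring_plane)
  if (max(ring_plane) < 2 * max(s$med, 1e-12)) {
    stop("no ring signal: max / background < 2", call. = FALSE)
  }
  thr <- s$med + k * s$sd
  mask <- ring_plane > thr
  pix <- which(mask, arr.ind = TRUE) - 1  # 0-based voxel indices
  if (nrow(pix) < 20L) stop("no nucleus: fewer than 20 ring pixels", call. = FALSE)
  xy <- pix * pixel_size
  ## intensity weights: the radial ring profile is symmetric about the true
  ## radius, so weighting by excess intensity centres the fit on it instead
  ## of on the (asymmetric) thresholded annulus
  w <- ring_plane[mask] - thr
  ## first pass unweighted (intensity weights would hand isolated hot pixels
  ## maximal leverage before any rejection has happened), then iterate
  ## weighted fits with outlier rejection on the radial residual
  fit <- circle_fit(xy)
  for (it in 1:5) {
    res <- abs(sqrt((xy[, 1] - fit$cx)^2 + (xy[, 2] - fit$cy)^2) - fit$r)
    keep <- res <= 2.5 * max(stats::mad(res), 1e-9) + 1e-12
    if (sum(keep) < 20L) break
    xy <- xy[keep, , drop = FALSE]
    w <- w[keep]
    fit <- circle_fit(xy, w)
    if (all(keep)) break
  }
  ## curvature correction: the mean radius of an annulus of radial spread
  ## sigma about a circle of radius R is R + sigma^2/R (area element grows
  ## with r), so the fitted radius is pulled back by v/r
  rr <- sqrt((xy[, 1] - fit$cx)^2 + (xy[, 2] - fit$cy)^2)
  v <- sum(w * (rr - fit$r)^2) / sum(w)
  r_corr <- fit$r - v / fit$r
  nucleus_geometry(center = c(fit$cx, fit$cy), radius = r_corr,
                   plane_index = plane_index, n_planes = n_planes)
}

## Kasa algebraic circle fit: solve x^2 + y^2 = 2 a x + 2 b y + c
circle_fit <- function(xy, w = NULL) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  sol <- if (is.null(w)) stats::lm.fit(A, b)$coefficients
         else stats::lm.wfit(A, b, w)$coefficients
  list(cx = sol[1], cy = sol[2], r = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

## --- foci ------------------------------------------------------------------

#' Detect diffraction-limited foci in one channel
#'
#' Matched-filter blob detection: the channel is smoothed with a Gaussian at
#' the diffraction-limited scale (the preset PSF), 26-connected local maxima
#' above `median + k_detect * MAD-SD` of the smoothed stack are selected, and
#' each is refined to sub-voxel precision by a background-subtracted
#' intensity-weighted centroid in a small window.  Deterministic given the
#' stack and the policy.
#'
#' @param stack An [render()] `ImageStack` (or any object with `channels`,
#'   `pixel_size`, `z_step`).
#' @param channel Channel name.
#' @param psf_sigma,psf_sigma_z Smoothing scale, um (defaults match the
#'   renderer defaults).
#' @param k_detect Detection threshold in smoothed-background SDs
#'   (default 8; smoothing suppresses photon noise strongly, so genuine foci
#'   sit far above this).
#' @return List of `FocusObservation`: each a list with `channel`,
#'   `position` (xyz um), `peak` (smoothed peak height above background) and
#'   `sigma` (the detection scale); brightest first.
#' @export
detect_foci <- function(stack, channel, psf_sigma = 0.11, psf_sigma_z = 0.27,
                        k_detect = 8) {
  img <- stack$channels[[channel]]
  if (is.null(img)) stop("no such channel: ", channel, call. = FALSE)
  sig_vox <- c(psf_sigma / stack$pixel_size, psf_sigma / stack$pixel_size,
               psf_sigma_z / stack$z_step)
  sm <- gauss_smooth3(img, sig_vox)
  s <- bg_stats(sm)
  thr <- s$med + k_detect * s$sd
  peaks <- local_maxima3(sm, thr)
  if (nrow(peaks) == 0L) return(list())
  ## sub-voxel refinement on the raw image
  obs <- lapply(seq_len(nrow(peaks)), function(i) {
    ctr <- refine_centroid(img, peaks[i, 1:3], stack$pixel_size, stack$z_step)
    list(channel = channel, position = ctr,
         peak = peaks[i, 4] - s$med, sigma = psf_sigma)
  })
  obs[order(vapply(obs, `[[`, numeric(1), "peak"), decreasing = TRUE)]
}

## 26-connected local maxima above thr; returns (ix, iy, iz, value), 1-based
local_maxima3 <- function(a, thr) {
  d <- dim(a)
  cand <- which(a > thr)
  if (!length(cand)) return(matrix(0, 0, 4))
  idx <- arrayInd(cand, d)
  keep <- vapply(seq_along(cand), function(i) {
    p <- idx[i, ]
    xr <- max(1, p[1] - 1):min(d[1], p[1] + 1)
    yr <- max(1, p[2] - 1):min(d[2], p[2] + 1)
    zr <- max(1, p[3] - 1):min(d[3], p[3] + 1)
    a[p[1], p[2], p[3]] >= max(a[xr, yr, zr])
  }, logical(1))
  cbind(idx[keep, , drop = FALSE], a[cand[keep]])
}

## intensity-weighted centroid in a +-2 px (xy) / +-1 plane (z) window
refine_centroid <- function(img, p, pixel_size, z_step) {
  d <- dim(img)
  xr <- max(1, p[1] - 2):min(d[1], p[1] + 2)
  yr <- max(1, p[2] - 2):min(d[2], p[2] + 2)
  zr <- max(1, p[3] - 1):min(d[3], p[3] + 1)
  w <- img[xr, yr, zr, drop = FALSE]
  w <- pmax(w - stats::median(img), 0)
  tot <- sum(w)
  if (tot <= 0) return(c((p[1] - 1) * pixel_size, (p[2] - 1) * pixel_size,
                         (p[3] - 1) * z_step))
  wx <- apply(w, 1, sum); wy <- apply(w, 2, sum); wz <- apply(w, 3, sum)
  c(sum((xr - 1) * wx) / tot * pixel_size,
    sum((yr - 1) * wy) / tot * pixel_size,
    sum((zr - 1) * wz) / tot * z_step)
}

#' Detect the spindle pole body
#'
#' The brightest compact focus in the tubulin channel.  If two maxima tie in
#' (smoothed) peak height, the one nearer `centre_hint` (the nucleus centre,
#' when supplied) is taken — a fixed, documented tie-break.
#'
#' @inheritParams detect_foci
#' @param centre_hint Optional xyz um used only to break exact ties.
#' @return A single `FocusObservation`.
#' @export
detect_spb <- function(stack, channel = "tubulin", psf_sigma = 0.11,
                       psf_sigma_z = 0.27, k_detect = 8, centre_hint = NULL) {
  foci <- detect_foci(stack, channel, psf_sigma, psf_sigma_z, k_detect)
  if (!length(foci)) stop("no SPB focus above threshold", call. = FALSE)
  peaks <- vapply(foci, `[[`, numeric(1), "peak")
  top <- which(peaks >= max(peaks) * (1 - 1e-9))
  if (length(top) > 1L && !is.null(centre_hint)) {
    dd <- vapply(foci[top], function(f) sum((f$position - centre_hint)^2),
                 numeric(1))
    top <- top[which.min(dd)]
  }
  foci[[top[1]]]
}

## --- DIMs ------------------------------------------------------------------

#' Detect a damage-induced microtubule (DIM)
#'
#' A DIM is a monopolar linear tubulin structure emanating from the SPB.
#' Above-threshold voxels of the (smoothed) tubulin channel are projected
#' onto directions from the SPB; the dominant direction is that of the
#' farthest above-threshold voxel, and voxels within a 30 degree cone of it
#' form the candidate structure.  A DIM is reported iff that structure is a
#' gap-free chain starting within `anchor_radius` of the SPB and extending at
#' least `min_length`, with no comparable chain in the opposite cone (which
#' would indicate a bipolar spindle, not a DIM).
#'
#' @inheritParams detect_foci
#' @param spb A `FocusObservation` for the SPB (from [detect_spb()]).
#' @param min_length Minimum DIM length, um (default 0.5).
#' @param anchor_radius Maximum gap between the SPB and the chain start, um
#'   (default 0.25).
#' @param cone_deg Half-angle of the direction cone, degrees (default 30).
#' @param gap_tol Maximum along-axis gap between chain voxels, um
#'   (default 0.25; spans the axial voxel pitch).
#' @param k_mask Mask threshold in smoothed-background SDs (default 8).
#' @return A `DimObservation`: list with `present`, `length` (um),
#'   `endpoints` (2x3 matrix, um) and `anchored_at_spb`; absent DIMs have
#'   `length = 0` and `NULL` endpoints.
#' @export
detect_dim <- function(stack, spb, channel = "tubulin",
                       psf_sigma = 0.11, psf_sigma_z = 0.27,
                       min_length = 0.5, anchor_radius = 0.25,
                       cone_deg = 30, gap_tol = 0.25, k_mask = 8) {
  img <- stack$channels[[channel]]
  if (is.null(img)) stop("no such channel: ", channel, call. = FALSE)
  sig_vox <- c(psf_sigma / stack$pixel_size, psf_sigma / stack$pixel_size,
               psf_sigma_z / stack$z_step)
  sm <- gauss_smooth3(img, sig_vox)
  s <- bg_stats(sm)
  ## matched subtraction of the SPB's own point-spread blob: the axially
  ## elongated PSF otherwise reads as a z-oriented "structure" that masks
  ## z-tilted DIMs and trips the monopolarity veto.  The blob amplitude is
  ## the directional median at a fixed scaled radius, so a DIM arm (which
  ## brightens only a narrow cone of directions) does not inflate it.
  sig_eff <- sqrt(2) * c(psf_sigma, psf_sigma, psf_sigma_z)
  resid <- subtract_spb_blob(sm - s$med, spb$position, sig_eff,
                             stack$pixel_size, stack$z_step)
  mask <- resid > k_mask * s$sd
  vox <- which(mask, arr.ind = TRUE) - 1
  absent <- list(present = FALSE, length = 0, endpoints = NULL,
                 anchored_at_spb = FALSE)
  if (nrow(vox) == 0L) return(absent)
  pos <- cbind(vox[, 1] * stack$pixel_size, vox[, 2] * stack$pixel_size,
               vox[, 3] * stack$z_step)
  rel <- sweep(pos, 2, spb$position)
  r <- sqrt(rowSums(rel^2))
  far <- r > 0.12                      # outside the SPB blob core
  if (!any(far)) return(absent)
  ## axis: farthest residual voxel, refined once by the principal axis of
  ## the voxels within the tube around it
  dir <- rel[which.max(r), ] / max(r)
  perp_tol <- 0.35                     # half-width of the blurred tube, um
  for (it in 1:2) {
    proj <- as.vector(rel %*% dir)
    perp <- sqrt(pmax(r^2 - proj^2, 0))
    memb <- proj > 0 & perp <= perp_tol
    if (sum(memb) < 3L) break
    ev <- eigen(crossprod(rel[memb, , drop = FALSE]), symmetric = TRUE)
    ax <- ev$vectors[, 1]
    if (sum(ax * dir) < 0) ax <- -ax
    dir <- ax
  }
  proj <- as.vector(rel %*% dir)
  perp <- sqrt(pmax(r^2 - proj^2, 0))
  fwd <- chain_extent(proj[proj > 0 & perp <= perp_tol],
                      anchor_radius, gap_tol)
  if (is.null(fwd)) return(absent)
  ## deblurred length: the above-threshold chain extends past the physical
  ## tip by the axis-projected PSF scale
  sig_axis <- sqrt(sig_eff[1]^2 * (dir[1]^2 + dir[2]^2) +
                     sig_eff[3]^2 * dir[3]^2)
  len <- max(fwd - 1.5 * sig_axis, 0)
  if (len < min_length) return(absent)
  ## monopolarity: a comparable chain within the opposite cone is a spindle
  cos_min <- cos(cone_deg * pi / 180)
  opp <- -proj > 0 & (-proj / pmax(r, 1e-12)) >= cos_min
  bwd <- chain_extent(-proj[opp], anchor_radius, gap_tol)
  if (!is.null(bwd) && bwd >= min_length) return(absent)  # bipolar spindle
  list(present = TRUE, length = len,
       endpoints = rbind(spb$position, spb$position + len * dir),
       anchored_at_spb = TRUE)
}

## subtract an anisotropic Gaussian blob centred at p from a
## background-subtracted smoothed stack.  Coordinates are scaled so the blob
## is isotropic (radius sig_eff[1]); amplitude is the median over 26
## directions of the value at scaled radius 2*sigma, back-projected to the
## peak.
subtract_spb_blob <- function(sm0, p, sig_eff, pixel_size, z_step) {
  d <- dim(sm0)
  xs <- (seq_len(d[1]) - 1) * pixel_size
  ys <- (seq_len(d[2]) - 1) * pixel_size
  zs <- (seq_len(d[3]) - 1) * z_step
  zscale <- sig_eff[1] / sig_eff[3]
  e2 <- outer(outer((xs - p[1])^2, (ys - p[2])^2, `+`),
              ((zs - p[3]) * zscale)^2, `+`)
  e0 <- 2 * sig_eff[1]
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  vals <- apply(dirs, 1, function(u) {
    q <- p + e0 * c(u[1], u[2], u[3] / zscale)
    i <- pmin(pmax(round(c(q[1] / pixel_size, q[2] / pixel_size,
                           q[3] / z_step)) + 1, 1), d)
    sm0[i[1], i[2], i[3]]
  })
  amp <- max(stats::median(vals) / exp(-(e0^2) / (2 * sig_eff[1]^2)), 0)
  sm0 - amp * exp(-e2 / (2 * sig_eff[1]^2))
}

## gap-free extent along the axis of the supplied member projections,
## anchored at the SPB: the first member must lie within
## anchor_radius + gap_tol of the SPB (the anchor window absorbs the
## blob-subtraction shadow), then the chain is walked outward until the
## first along-axis gap exceeding gap_tol; the tip projection (distance
## from the SPB) is returned.
chain_extent <- function(proj, anchor_radius, gap_tol) {
  t <- sort(proj)
  if (!length(t)) return(NULL)
  if (t[1] > anchor_radius + gap_tol) return(NULL)
  gaps <- diff(t)
  brk <- which(gaps > gap_tol)
  if (length(brk)) t[brk[1]] else t[length(t)]
}

## --- colocalization and distances -----------------------------------------

#' Overlap-based colocalization of two binary masks
#'
#' `TRUE` iff the masks share at least one voxel.  Edge- or corner-adjacent
#' masks with no shared voxel ("touching") score `FALSE`.
#'
#' @param mask_a,mask_b Logical arrays of identical dimensions (e.g. from
#'   [threshold_mask()]).
#' @return Logical scalar.
#' @export
colocalize <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  any(mask_a & mask_b)
}

#' Calibrated 3D distance between two observations
#'
#' Euclidean distance between two focus positions already expressed in
#' micrometres (anisotropic voxel calibration applied at detection time).
#'
#' @param spb,locus `FocusObservation`s, or bare xyz um vectors.
#' @return Distance in um.
#' @export
spb_locus_distance <- function(spb, locus) {
  p <- if (is.list(spb)) spb$position else spb
  q <- if (is.list(locus)) locus$position else locus
  stopifnot(length(p) == 3L, length(q) == 3L)
  sqrt(sum((p - q)^2))
}
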