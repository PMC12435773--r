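#' Render a synthetic cell into a multi-channel image stack
#'
#' Channels (all sharing one voxel grid; array dims are x, y, z with 0-based
#' voxel indices and pixel-centre calibration: voxel `i` sits at `i * pixel_size`):
#' \describe{
#'   \item{ring}{the nuclear envelope: a spherical shell through the
#'     nucleus surface with a Gaussian radial profile (the Nup49 signal).}
#'   \item{locus}{a diffraction-limited point source at the locus.}
#'   \item{tubulin}{a bright point source at the SPB plus, when present, DIM
#'     line sources anchored there (the Tub1 signal).}
#'   \item{spb}{optional: the SPB point source alone.}
#' }
#' Point and line sources carry the anisotropic Gaussian optics of the preset
#' (`psf_sigma` lateral, `psf_sigma_z` axial).  Photon noise is Poisson about
#' a constant background, scaled so that peak signal over background-noise SD
#' equals the preset's `snr`; `snr = Inf` renders noise free.
#'
#' @param scene A [make_cell()] scene.
#' @param preset The [scene_preset()] used to generate it.
#' @param channels Channels to render (default all four).
#' @param rng_seed Integer seed for the photon noise.
#' @return Object of class `ImageStack`: list with `channels` (named list of
#'   3D arrays), `pixel_size`, `z_step`, `dim`.
#' @export
render <- function(scene, preset,
                   channels = c("ring", "locus", "tubulin", "spb"),
                   rng_seed = NULL) {
  stopifnot(inherits(scene, "CellScene"), inherits(preset, "ScenePreset"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_xy <- field_npix(preset)
  dims <- c(n_xy, n_xy, preset$n_planes)
  fov <- (dims - 1) * c(preset$pixel_size, preset$pixel_size, preset$z_step)
  for (p in list(scene$locus_true, scene$spb_true)) {
    if (any(p < -1e-9) || any(p > fov + 1e-9)) {
      stop("scene geometry outside the field of view", call. = FALSE)
    }
  }
  bg <- 10
  amp <- if (is.finite(preset$snr)) preset$snr * sqrt(bg) else 1000
  grids <- voxel_grids(dims, preset$pixel_size, preset$z_step)
  out <- list()
  for (ch in channels) {
    img <- array(0, dims)
    if (ch == "ring") {
      img <- amp * shell_intensity(grids, scene$nucleus_centre,
                                   scene$nucleus_radius,
                                   preset$psf_sigma, preset$psf_sigma_z)
    } else if (ch == "locus") {
      img <- add_point_source(img, grids, scene$locus_true, amp,
                              preset$psf_sigma, preset$psf_sigma_z)
    } else if (ch == "spb") {
      img <- add_point_source(img, grids, scene$spb_true, amp,
                              preset$psf_sigma, preset$psf_sigma_z)
    } else if (ch == "tubulin") {
      img <- add_point_source(img, grids, scene$spb_true, amp,
                              preset$psf_sigma, preset$psf_sigma_z)
      for (seg in scene$dim_segments) {
        img <- add_line_source(img, grids, seg[1, ], seg[2, ], 0.6 * amp,
                               preset$psf_sigma, preset$psf_sigma_z)
      }
    } else stop("unknown channel: ", ch, call. = FALSE)
    img <- img + bg
    if (is.finite(preset$snr)) {
      img <- array(stats::rpois(length(img), img), dims)
    }
    out[[ch]] <- img
  }
  structure(list(channels = out, pixel_size = preset$pixel_size,
                 z_step = preset$z_step, dim = dims),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  cat(sprintf("<ImageStack> %dx%dx%d voxels (%.3f um/px, %.3f um/z), channels: %s\n",
              x$dim[1], x$dim[2], x$dim[3], x$pixel_size, x$z_step,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

## voxel-centre coordinate vectors and full coordinate arrays (um)
voxel_grids <- function(dims, pixel_size, z_step) {
  xs <- (seq_len(dims[1]) - 1) * pixel_size
  ys <- (seq_len(dims[2]) - 1) * pixel_size
  zs <- (seq_len(dims[3]) - 1) * z_step
  list(xs = xs, ys = ys, zs = zs, dims = dims)
}

## spherical shell with Gaussian radial profile.  The profile uses the true
## (unscaled) distance to the sphere surface so that in any z plane the ring
## peaks at the geometric cross-section radius sqrt(R^2 - dz^2) — the radius
## the zoning protocol measures; sigma_z is not applied to the shell, a
## deliberate simplification that keeps the in-plane ring geometry exact.
shell_intensity <- function(g, centre, radius, sigma, sigma_z) {
  dx2 <- (g$xs - centre[1])^2
  dy2 <- (g$ys - centre[2])^2
  dz2 <- (g$zs - centre[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  exp(-(sqrt(r2) - radius)^2 / (2 * sigma^2))
}

add_point_source <- function(img, g, p, amp, sigma, sigma_z) {
  kx <- exp(-(g$xs - p[1])^2 / (2 * sigma^2))
  ky <- exp(-(g$ys - p[2])^2 / (2 * sigma^2))
  kz <- exp(-(g$zs - p[3])^2 / (2 * sigma_z^2))
  img + amp * outer(outer(kx, ky), kz)
}

## Gaussian tube around segment a-b, restricted to a bounding box for speed;
## axial coordinate scaled by sigma/sigma_z as for the shell
add_line_source <- function(img, g, a, b, amp, sigma, sigma_z) {
  pad_xy <- 4 * sigma; pad_z <- 4 * sigma_z
  ix <- which(g$xs >= min(a[1], b[1]) - pad_xy & g$xs <= max(a[1], b[1]) + pad_xy)
  iy <- which(g$ys >= min(a[2], b[2]) - pad_xy & g$ys <= max(a[2], b[2]) + pad_xy)
  iz <- which(g$zs >= min(a[3], b[3]) - pad_z & g$zs <= max(a[3], b[3]) + pad_z)
  if (!length(ix) || !length(iy) || !length(iz)) return(img)
  sc <- c(1, 1, sigma / sigma_z)
  as_ <- a * sc; bs_ <- b * sc
  ab <- bs_ - as_; ab2 <- sum(ab^2)
  crd <- expand.grid(x = g$xs[ix], y = g$ys[iy] , z = g$zs[iz])
  v <- cbind(crd$x * sc[1], crd$y * sc[2], crd$z * sc[3])
  vrel <- sweep(v, 2, as_)
  tt <- if (ab2 > 0) pmin(pmax((vrel %*% ab) / ab2, 0), 1) else rep(0, nrow(v))
  d2 <- rowSums((vrel - tt %*% t(ab))^2)
  add <- amp * exp(-d2 / (2 * sigma^2))
  sub <- img[ix, iy, iz, drop = FALSE]
  img[ix, iy, iz] <- sub + array(add, dim(sub))
  img
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are z planes, channel blocks concatenated in channel order; the
#' sidecar records dimensions, calibration, channel names, the intensity
#' scale used for 16-bit encoding and, optionally, scene ground truth.
#'
#' @param stack An [render()] result.
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param scene Optional `CellScene` whose ground truth is embedded in the
#'   sidecar.
#' @return `write_stack` returns `path` invisibly; `read_stack` an
#'   `ImageStack` (with `ground_truth` attribute when present).
#' @export
write_stack <- function(stack, path, scene = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  scale <- max(1, max(vapply(stack$channels, max, numeric(1))))
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]] / scale
    for (k in seq_len(stack$dim[3])) {
      ## writeTIFF consumes row-major matrices: rows = y
      pages[[length(pages) + 1L]] <- t(a[, , k])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(dim = stack$dim, pixel_size = stack$pixel_size,
               z_step = stack$z_step, channels = names(stack$channels),
               scale = scale)
  if (!is.null(scene)) {
    meta$ground_truth <- list(
      cell_id = scene$cell_id, stage = scene$stage,
      nucleus_centre = scene$nucleus_centre,
      nucleus_radius = scene$nucleus_radius,
      locus_true = scene$locus_true, spb_true = scene$spb_true,
      zone_true = scene$zone_true,
      dim_segments = lapply(scene$dim_segments, function(s) as.vector(t(s))))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- meta$dim
  chans <- list()
  idx <- 0L
  for (ch in meta$channels) {
    a <- array(0, dims)
    for (k in seq_len(dims[3])) {
      idx <- idx + 1L
      a[, , k] <- t(pages[[idx]])
    }
    chans[[ch]] <- a * meta$scale
  }
  out <- structure(list(channels = chans, pixel_size = meta$pixel_size,
                        z_step = meta$z_step, dim = dims),
                   class = "ImageStack")
  if (!is.null(meta$ground_truth)) attr(out, "ground_truth") <- meta$ground_truth
  out
}
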