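#' Generate one ground-truthed synthetic cell
#'
#' Draws a cell-cycle stage from the preset's stage mix, places the nucleus
#' at the centre of the field, plants the locus according to the preset's
#' zone-1 weight, embeds the spindle pole body (SPB) in the nuclear envelope
#' at the preset's SPB-locus distance, and with the preset's prevalence
#' attaches a damage-induced microtubule (DIM): a line segment anchored at
#' the SPB, aimed through the locus with probability `dim_colocal_prob` and
#' otherwise into a random inward direction.
#'
#' Zone-1 planting samples the axial coordinate with the uniform-in-sphere
#' marginal and the in-plane radius uniformly over the zone-1 annulus of that
#' cross-section, so planted and uniform components mix exactly as the
#' zoning geometry scores them.
#'
#' @param preset A [scene_preset()].
#' @param rng_seed Integer seed; identical seeds give identical scenes.
#' @return Object of class `CellScene`: nucleus geometry (3D centre + radius,
#'   um, in stack coordinates), `locus_true`, `spb_true` (xyz um),
#'   `dim_segments` (list of 2x3 matrices, rows = endpoints), `zone_true`,
#'   `stage`, `cell_id`.
#' @export
make_cell <- function(preset, rng_seed = NULL) {
  stopifnot(inherits(preset, "ScenePreset"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  R <- preset$nucleus_radius
  centre <- field_centre(preset)

  stage <- sample(names(preset$stage_mix), 1L, prob = preset$stage_mix)

  ## --- locus placement (nucleus-centred coordinates) ---
  w <- preset$zone1_weight
  u <- stats::runif(1)
  mode <- if (w >= 0 && u < w) "zone1" else if (w < 0 && u < -w) "inner" else "uniform"
  ## axial coordinate: uniform-in-sphere marginal, density prop. to (R^2 - z^2)
  repeat {
    z <- stats::runif(1, -R, R)
    if (stats::runif(1) < 1 - (z / R)^2) break
  }
  rz <- sqrt(R^2 - z^2)               # cross-section radius at this plane
  rho2 <- switch(mode,
                 zone1   = stats::runif(1, 2 / 3, 1),
                 inner   = stats::runif(1, 0, 2 / 3),
                 uniform = stats::runif(1))
  phi <- stats::runif(1, 0, 2 * pi)
  r_xy <- sqrt(rho2) * rz
  locus <- c(r_xy * cos(phi), r_xy * sin(phi), z)
  zone_true <- if (rho2 >= 2 / 3) 1L else if (rho2 >= 1 / 3) 2L else 3L

  ## --- SPB on the nuclear envelope at the preset's distance from the locus ---
  a <- sqrt(sum(locus^2))
  d <- truncnorm1(preset$spb_locus_mean_dist, preset$spb_locus_sd_dist,
                  lo = max(R - a, 0) + 0.02, hi = R + a - 0.02)
  spb <- envelope_point_at_distance(locus, R, d)

  ## --- DIM segments ---
  dim_segments <- list()
  if (stats::runif(1) < preset$dim_prevalence) {
    if (stats::runif(1) < preset$dim_colocal_prob && sum((locus - spb)^2) > 1e-6) {
      dir <- (locus - spb) / sqrt(sum((locus - spb)^2))
      len <- min(sqrt(sum((locus - spb)^2)) + stats::runif(1, 0.1, 0.4), 1.8)
    } else {
      ## random direction on the inward hemisphere (DIMs extend into the
      ## nucleoplasm from the envelope-embedded SPB)
      inward <- -spb / sqrt(sum(spb^2))
      repeat {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        if (sum(dir * inward) > 0.2) break
      }
      len <- stats::runif(1, 0.8, 1.5)
    }
    dim_segments <- list(rbind(spb + centre, spb + centre + len * dir))
  }

  structure(
    list(cell_id = sprintf("cell_%08x", sample.int(.Machine$integer.max, 1L)),
         stage = stage,
         nucleus_centre = centre, nucleus_radius = R,
         locus_true = locus + centre,
         spb_true = spb + centre,
         dim_segments = dim_segments,
         zone_true = zone_true),
    class = "CellScene"
  )
}

#' @export
print.CellScene <- function(x, ...) {
  cat(sprintf("<CellScene> %s stage %s, zone %d, %d DIM segment(s)\n",
              x$cell_id, x$stage, x$zone_true, length(x$dim_segments)))
  invisible(x)
}

## centre of the rendered field in um (nucleus is centred in the stack)
field_centre <- function(preset) {
  n_xy <- field_npix(preset)
  c((n_xy - 1) / 2 * preset$pixel_size,
    (n_xy - 1) / 2 * preset$pixel_size,
    (preset$n_planes - 1) / 2 * preset$z_step)
}

## lateral field size: nucleus plus a 0.6 um margin each side
field_npix <- function(preset) {
  2L * as.integer(ceiling((preset$nucleus_radius + 0.6) / preset$pixel_size)) + 1L
}

## one draw from N(mean, sd) truncated to [lo, hi] (rejection; narrow use)
truncnorm1 <- function(mean, sd, lo, hi) {
  if (lo >= hi) return((lo + hi) / 2)
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

## point on the sphere of radius R at Euclidean distance d from an interior
## point p: polar angle fixed by the law of cosines, azimuth uniform
envelope_point_at_distance <- function(p, R, d) {
  a <- sqrt(sum(p^2))
  if (a < 1e-9) {                     # locus at dead centre: any direction
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    return(R * dir)
  }
  cos_theta <- (R^2 + a^2 - d^2) / (2 * R * a)
  cos_theta <- min(max(cos_theta, -1), 1)
  e1 <- p / a
  ## orthonormal basis completing e1
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  phi <- stats::runif(1, 0, 2 * pi)
  sin_theta <- sqrt(1 - cos_theta^2)
  R * (cos_theta * e1 + sin_theta * (cos(phi) * e2 + sin(phi) * e3))
}

#' Simulate a confined-diffusion locus trajectory with nuclear drift
#'
#' The locus performs reflecting Brownian motion (Euler steps of SD
#' `sqrt(2 D dt)` per axis) inside a sphere of radius `rc_true` about the
#' nucleus centre, started from the uniform stationary distribution; the
#' nucleus centre translates rigidly by `drift` per frame.  Both the
#' projected (x, y) locus track and the nucleus-centre track are emitted, as
#' a tracking pipeline would deliver them.
#'
#' @param rc_true Confinement radius, um (> 0).
#' @param diffusion Diffusion coefficient, um^2/s (default 0.005, typical of
#'   interphase yeast chromatin).
#' @param dt Frame interval, s (default 1.5).
#' @param n_frames Number of frames (default 200, i.e. 5 min at 1.5 s).
#' @param drift Nucleus-centre translation per frame: scalar (applied along
#'   x) or length-2 (x, y) in um/frame.
#' @param rng_seed Integer seed.
#' @return A [trajectory()].
#' @export
simulate_trajectory <- function(rc_true, diffusion = 0.005, dt = 1.5,
                                n_frames = 200, drift = 0, rng_seed = NULL) {
  stopifnot(rc_true > 0, dt > 0, diffusion >= 0, n_frames >= 2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (length(drift) == 1L) drift <- c(drift, 0)
  step_sd <- sqrt(2 * diffusion * dt)
  pos <- matrix(NA_real_, n_frames, 3L)
  ## stationary start: uniform in the confinement sphere
  p <- stats::rnorm(3)
  p <- p / sqrt(sum(p^2)) * rc_true * stats::runif(1)^(1 / 3)
  for (i in seq_len(n_frames)) {
    pos[i, ] <- p
    if (i == n_frames) break
    p <- p + stats::rnorm(3, sd = step_sd)
    ## radial reflection at the confinement boundary
    r <- sqrt(sum(p^2))
    while (r > rc_true) {
      p <- p * (2 * rc_true - r) / r
      r <- abs(2 * rc_true - r)
    }
  }
  nuc <- cbind(seq_len(n_frames) - 1, seq_len(n_frames) - 1) *
    rep(drift, each = n_frames)
  trajectory(t_s = (seq_len(n_frames) - 1) * dt,
             locus = pos[, 1:2] + nuc,
             nucleus = nuc,
             meta = list(rc_true = rc_true, diffusion = diffusion))
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Per culture the number of mutation events is Poisson(`m_true`); each event
#' founds a clone whose final size follows the Lea-Coulson law
#' \eqn{P(j) = 1/(j(j+1))}, sampled as `floor(1/U)` with U uniform; the
#' culture's mutant count is the sum of clone sizes.  Clone sizes are
#' truncated at 1e6 (tail mass < `m_true` * 1e-6).
#'
#' @param m_true Expected mutation events per culture (>= 0).
#' @param n_cultures Number of parallel cultures.
#' @param N_t Viable cells plated per culture (carried as metadata).
#' @param rng_seed Integer seed.
#' @return Object of class `FluctuationSim`: list with `counts`, `m_true`,
#'   `n_cultures`, `N_t`.
#' @export
simulate_fluctuation <- function(m_true, n_cultures, N_t = 1e7, rng_seed = NULL) {
  stopifnot(m_true >= 0, n_cultures >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  counts <- vapply(seq_len(n_cultures), function(i) {
    k <- stats::rpois(1, m_true)
    if (k == 0L) return(0)
    sum(pmin(floor(1 / stats::runif(k)), 1e6))
  }, numeric(1))
  structure(list(counts = as.integer(counts), m_true = m_true,
                 n_cultures = as.integer(n_cultures), N_t = N_t),
            class = "FluctuationSim")
}

#' @export
print.FluctuationSim <- function(x, ...) {
  cat(sprintf("<FluctuationSim> %d cultures, m_true %.3g, median count %g\n",
              x$n_cultures, x$m_true, stats::median(x$counts)))
  invisible(x)
}
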