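#' Experimental-condition preset for the synthetic-scene generator
#'
#' A preset bundles the condition-dependent parameters of the generator: where
#' the locus sits relative to the nuclear periphery, how often the cell
#' carries a damage-induced microtubule (DIM), imaging geometry and noise.
#'
#' `zone1_weight` controls peripheral enrichment of the locus.  For
#' `w` in `[0, 1]` the locus is planted uniformly in the zone-1 annulus of its
#' cross-section with probability `w` and uniformly in the nuclear sphere
#' otherwise, giving an expected zone-1 occupancy of `w + (1 - w)/3`.
#' Negative `w` in `[-1, 0)` models peripheral *depletion*: with probability
#' `|w|` the locus is planted uniformly in zones 2-3, giving occupancy
#' `(1 - |w|)/3` — occupancies below the uniform null of 1/3 (as in
#' repeat-free control strains) are unreachable by the nonnegative mixture.
#'
#' @param name Condition label.
#' @param zone1_weight Zone-1 planting weight in `[-1, 1]` (see Details).
#' @param dim_prevalence Probability a cell carries at least one DIM.
#' @param dim_colocal_prob Probability a DIM is aimed through the locus.
#' @param spb_locus_mean_dist Mean SPB-to-locus 3D distance, um.
#' @param spb_locus_sd_dist SD of the SPB-to-locus distance, um.
#' @param nucleus_radius Nuclear radius, um.
#' @param pixel_size Lateral pixel size, um/px.
#' @param z_step Axial step, um/plane.
#' @param n_planes Number of z planes per stack.
#' @param psf_sigma Lateral PSF sigma, um.
#' @param psf_sigma_z Axial PSF sigma, um.
#' @param snr Peak signal over background-noise SD (may be `Inf` for
#'   noise-free rendering).
#' @param stage_mix Named proportions over `c(G1, earlyS, midlateS)`.
#' @return Object of class `ScenePreset`.
#' @export
scene_preset <- function(name,
                         zone1_weight = 0,
                         dim_prevalence = 0,
                         dim_colocal_prob = 0,
                         spb_locus_mean_dist = 0.8,
                         spb_locus_sd_dist = 0.15,
                         nucleus_radius = 1.0,
                         pixel_size = 0.065,
                         z_step = 0.175,
                         n_planes = 25L,
                         psf_sigma = 0.11,
                         psf_sigma_z = 0.27,
                         snr = 10,
                         stage_mix = c(G1 = 0.25, earlyS = 0.15, midlateS = 0.6)) {
  stopifnot(zone1_weight >= -1, zone1_weight <= 1,
            dim_prevalence >= 0, dim_prevalence <= 1,
            dim_colocal_prob >= 0, dim_colocal_prob <= 1,
            nucleus_radius > 0, pixel_size > 0, z_step > 0,
            psf_sigma > 0, psf_sigma_z > 0, snr > 0,
            spb_locus_mean_dist > 0, n_planes >= 3L)
  stage_mix <- stage_mix / sum(stage_mix)
  if (is.null(names(stage_mix))) names(stage_mix) <- c("G1", "earlyS", "midlateS")
  structure(
    list(name = name, zone1_weight = zone1_weight,
         dim_prevalence = dim_prevalence, dim_colocal_prob = dim_colocal_prob,
         spb_locus_mean_dist = spb_locus_mean_dist,
         spb_locus_sd_dist = spb_locus_sd_dist,
         nucleus_radius = nucleus_radius, pixel_size = pixel_size,
         z_step = z_step, n_planes = as.integer(n_planes),
         psf_sigma = psf_sigma, psf_sigma_z = psf_sigma_z, snr = snr,
         stage_mix = stage_mix),
    class = "ScenePreset"
  )
}

#' @export
print.ScenePreset <- function(x, ...) {
  cat(sprintf("<ScenePreset> '%s': zone1_weight %.2f, DIM prevalence %.2f, SPB-locus %.2f um, SNR %g\n",
              x$name, x$zone1_weight, x$dim_prevalence,
              x$spb_locus_mean_dist, x$snr))
  invisible(x)
}

#' Built-in condition presets
#'
#' Presets encoding the experimental conditions the pipeline is exercised
#' against:
#' \describe{
#'   \item{`wt_cag0`}{repeat-free control; 31% expected zone-1 occupancy,
#'     rare DIMs.}
#'   \item{`wt_cag130`}{expanded-repeat strain; 48% zone-1 occupancy,
#'     repeat-induced DIMs that mostly colocalize with the locus.}
#'   \item{`mms`}{alkylation damage (0.03% MMS): DIMs in 62% of S-phase
#'     cells.}
#'   \item{`mms_hu`}{fork-collapsing treatment (MMS + 0.2 M HU): DIMs in 87%
#'     of mid-to-late S cells.}
#'   \item{`spb_offset`}{peripheral locus with SPB placed 0.6 um away on
#'     average, for distance-recovery runs.}
#' }
#'
#' @param name Preset name, one of the above.
#' @return A [scene_preset()].
#' @export
preset <- function(name = c("wt_cag0", "wt_cag130", "mms", "mms_hu", "spb_offset")) {
  name <- match.arg(name)
  switch(name,
    wt_cag0 = scene_preset("wt_cag0", zone1_weight = -0.07,
                           dim_prevalence = 0.10, dim_colocal_prob = 0.2,
                           spb_locus_mean_dist = 0.8),
    wt_cag130 = scene_preset("wt_cag130", zone1_weight = 0.22,
                             dim_prevalence = 0.30, dim_colocal_prob = 0.7,
                             spb_locus_mean_dist = 0.7),
    mms = scene_preset("mms", zone1_weight = 0.22,
                       dim_prevalence = 0.62, dim_colocal_prob = 0.5,
                       stage_mix = c(G1 = 0, earlyS = 0.3, midlateS = 0.7)),
    mms_hu = scene_preset("mms_hu", zone1_weight = 0.22,
                          dim_prevalence = 0.87, dim_colocal_prob = 0.5,
                          stage_mix = c(G1 = 0, earlyS = 0, midlateS = 1)),
    spb_offset = scene_preset("spb_offset", zone1_weight = 1,
                              dim_prevalence = 0, spb_locus_mean_dist = 0.6,
                              spb_locus_sd_dist = 0.15)
  )
}

#' Read / write presets as JSON
#'
#' One file per experimental condition; all fields of [scene_preset()].
#'
#' @param x A `ScenePreset`.
#' @param path File path.
#' @return `read_preset` returns a `ScenePreset`; `write_preset` returns
#'   `path` invisibly.
#' @export
write_preset <- function(x, path) {
  stopifnot(inherits(x, "ScenePreset"))
  obj <- unclass(x)
  obj$stage_mix <- as.list(obj$stage_mix)  # keep stage names in the JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_preset
#' @export
read_preset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$stage_mix <- unlist(obj$stage_mix)
  do.call(scene_preset, obj)
}
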