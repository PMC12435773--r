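#' Score one rendered cell through the zoning pipeline
#'
#' The measurement chain applied to every cell: detect the locus focus,
#' gate its plane to the middle two-thirds of the stack, fit the nuclear
#' periphery from the ring channel in the locus's focal plane, and classify
#' the locus into a zone.  Cells failing any gate are returned with a
#' status instead of a zone.
#'
#' @param stack An [render()] `ImageStack` with `ring` and `locus` channels.
#' @param psf_sigma,psf_sigma_z Detection scale, um.
#' @return List with `status` (`"ok"`, `"no_locus"`, `"midstack_excluded"`,
#'   `"no_nucleus"`, `"rejected"`), and when ok: `zone`, `nucleus`
#'   ([nucleus_geometry()]), `locus` (FocusObservation), `plane_index`.
#' @export
score_cell <- function(stack, psf_sigma = 0.11, psf_sigma_z = 0.27) {
  n_planes <- stack$dim[3]
  foci <- detect_foci(stack, "locus", psf_sigma, psf_sigma_z)
  if (!length(foci)) return(list(status = "no_locus"))
  locus <- foci[[1]]
  plane_index <- as.integer(round(locus$position[3] / stack$z_step))
  plane_index <- min(max(plane_index, 0L), n_planes - 1L)
  if (!midstack_gate(plane_index, n_planes)) {
    return(list(status = "midstack_excluded", plane_index = plane_index))
  }
  nucleus <- tryCatch(
    fit_periphery(stack$channels$ring[, , plane_index + 1L],
                  stack$pixel_size, plane_index, n_planes),
    error = function(e) NULL
  )
  if (is.null(nucleus)) return(list(status = "no_nucleus", plane_index = plane_index))
  zone <- tryCatch(classify_zone(locus$position[1:2], nucleus),
                   error = function(e) NULL)
  if (is.null(zone)) return(list(status = "rejected", plane_index = plane_index))
  list(status = "ok", zone = zone, nucleus = nucleus, locus = locus,
       plane_index = plane_index)
}

#' Simulate, render and score a batch of cells under one preset
#'
#' Convenience driver for preset-recovery runs: generates `n` cells, renders
#' the requested channels, and applies the zoning and/or DIM measurement
#' chains.
#'
#' @param preset A [scene_preset()].
#' @param n Number of cells.
#' @param rng_seed Integer seed for the whole batch.
#' @param measure Character subset of `c("zone", "dim", "spb_locus")`.
#' @return Data frame, one row per cell: ground truth (`zone_true`,
#'   `dim_true`, `dist_true`, `stage`) and measurements (`zone`, `status`,
#'   `dim_detected`, `spb_locus_dist`), NA where not measured or not scored.
#' @export
simulate_batch <- function(preset, n, rng_seed = 1L,
                           measure = c("zone")) {
  set.seed(rng_seed)
  seeds <- sample.int(2^30, 2L * n)
  channels <- character()
  if ("zone" %in% measure) channels <- c(channels, "ring", "locus")
  if ("dim" %in% measure) channels <- union(channels, "tubulin")
  if ("spb_locus" %in% measure) channels <- union(channels, c("tubulin", "locus"))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    scene <- make_cell(preset, rng_seed = seeds[i])
    stack <- render(scene, preset, channels = channels,
                    rng_seed = seeds[n + i])
    row <- list(cell = i, stage = scene$stage, zone_true = scene$zone_true,
                dim_true = length(scene$dim_segments) > 0L,
                dist_true = spb_locus_distance(scene$spb_true, scene$locus_true),
                zone = NA_integer_, status = NA_character_,
                dim_detected = NA, spb_locus_dist = NA_real_)
    if ("zone" %in% measure) {
      sc <- score_cell(stack, preset$psf_sigma, preset$psf_sigma_z)
      row$status <- sc$status
      if (sc$status == "ok") row$zone <- sc$zone
    }
    if (any(c("dim", "spb_locus") %in% measure)) {
      spb <- tryCatch(detect_spb(stack, "tubulin", preset$psf_sigma,
                                 preset$psf_sigma_z,
                                 centre_hint = scene$nucleus_centre),
                      error = function(e) NULL)
      if (!is.null(spb)) {
        if ("dim" %in% measure) {
          dd <- detect_dim(stack, spb, "tubulin",
                           preset$psf_sigma, preset$psf_sigma_z)
          row$dim_detected <- dd$present
        }
        if ("spb_locus" %in% measure) {
          loci <- detect_foci(stack, "locus", preset$psf_sigma, preset$psf_sigma_z)
          if (length(loci)) {
            row$spb_locus_dist <- spb_locus_distance(spb, loci[[1]])
          }
        }
      } else if ("dim" %in% measure) row$dim_detected <- FALSE
    }
    rows[[i]] <- row
  }
  do.call(rbind.data.frame, rows)
}

#' Run a configured end-to-end analysis
#'
#' Executes the stages named in a JSON-style config (a file path or a list)
#' and writes a reproducible report.  Supported stages:
#' \describe{
#'   \item{zoning}{`preset`, `n`, optionally `condition`: simulate, render,
#'     score, tally.}
#'   \item{mobility}{`rc_true`, `n_traj`, `n_frames`: simulate confined
#'     trajectories, drift-correct, fit the radius of constraint.}
#'   \item{fluctuation}{`m_true`, `n_cultures`, `N_t`: simulate counts and
#'     estimate the rate.}
#' }
#' All randomness derives from the config's `seed`; re-running the same
#' config reproduces the report exactly.
#'
#' @param config List or path to a JSON file.
#' @param out_dir Output directory for the report and stage tables
#'   (created if missing); `NULL` to skip writing.
#' @return The report, invisibly when written: a list with one entry per
#'   configured stage plus `seed` and package version.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed)) stop("config must name a 'seed'", call. = FALSE)
  seed <- as.integer(config$seed)
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("nucleozone")))
  if (!is.null(config$zoning)) {
    zc <- config$zoning
    pre <- if (is.character(zc$preset)) preset(zc$preset)
           else do.call(scene_preset, zc$preset)
    batch <- simulate_batch(pre, as.integer(zc$n), rng_seed = seed,
                            measure = "zone")
    scored <- batch[!is.na(batch$zone), , drop = FALSE]
    scored$condition <- if (!is.null(zc$condition)) zc$condition else pre$name
    tal <- zone_tally(scored)
    report$zoning <- list(preset = pre$name, n = nrow(batch),
                          n_scored = nrow(scored),
                          tally = as.list(tal[1, c("n1", "n2", "n3", "n_total")]),
                          zone1_percent = 100 * tal$n1[1] / tal$n_total[1])
  }
  if (!is.null(config$mobility)) {
    mc <- config$mobility
    trajs <- lapply(seq_len(as.integer(mc$n_traj)), function(i) {
      drift_correct(simulate_trajectory(mc$rc_true,
                                        n_frames = as.integer(mc$n_frames),
                                        rng_seed = seed + i))
    })
    curve <- ensemble_msd(trajs, max_lag = min(100L, as.integer(mc$n_frames) - 1L))
    fit <- fit_plateau(curve, n_lags = min(100L, as.integer(mc$n_frames) - 1L))
    report$mobility <- list(rc_true = mc$rc_true, n_traj = mc$n_traj,
                            plateau = fit$plateau, rc = fit$rc, tau = fit$tau)
  }
  if (!is.null(config$fluctuation)) {
    fc <- config$fluctuation
    sim <- simulate_fluctuation(fc$m_true, as.integer(fc$n_cultures),
                                N_t = fc$N_t, rng_seed = seed)
    est <- rate_estimate(sim$counts, N_t = sim$N_t)
    report$fluctuation <- list(m_true = fc$m_true, m_hat = est$m_hat,
                               rate = est$rate, ci95_m = est$ci95_m,
                               n_cultures = sim$n_cultures)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
  } else report
}
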