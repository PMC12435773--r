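#' Locus trajectory with matched nucleus-centre track
#'
#' @param t_s Frame times in seconds (uniform spacing).
#' @param locus Two-column matrix (x, y) of projected locus positions, um.
#' @param nucleus Two-column matrix of nucleus-centre positions, um (the
#'   Nup49 track used for drift correction).  Rows may be NA for dropped
#'   frames; lag pairs spanning gaps are excluded downstream.
#' @param cell_id,meta Optional identifiers carried through the analysis.
#' @return Object of class `Trajectory`.
#' @export
trajectory <- function(t_s, locus, nucleus, cell_id = NA_character_, meta = list()) {
  locus <- as.matrix(locus); nucleus <- as.matrix(nucleus)
  stopifnot(ncol(locus) == 2L, ncol(nucleus) == 2L,
            nrow(locus) == length(t_s), nrow(nucleus) == length(t_s))
  dt <- unique(round(diff(t_s), 9))
  if (length(t_s) > 1L && (length(dt) != 1L || dt <= 0)) {
    stop("frame times must be uniformly spaced with dt > 0", call. = FALSE)
  }
  structure(list(t_s = as.numeric(t_s), locus = locus, nucleus = nucleus,
                 dt = if (length(t_s) > 1L) dt else NA_real_,
                 cell_id = cell_id, meta = meta),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames, dt = %.3g s, cell %s\n",
              length(x$t_s), x$dt, x$cell_id))
  invisible(x)
}

#' Remove rigid nuclear translation from a locus track
#'
#' Replaces each locus position by its offset from the simultaneous nucleus
#' centre (the Nup49 reference track), so that whole-nucleus motion does not
#' inflate the MSD; the nucleus series is zeroed.
#'
#' @param traj A [trajectory()].
#' @return A drift-corrected `Trajectory`.
#' @export
drift_correct <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  traj$locus <- traj$locus - traj$nucleus
  traj$nucleus <- matrix(0, nrow(traj$nucleus), 2L)
  traj
}

#' Time-averaged mean-squared displacement
#'
#' \deqn{MSD(k\,\Delta t) = \langle |x(t + k\Delta t) - x(t)|^2 \rangle_t}
#' averaged over all overlapping frame pairs, summed over the two projected
#' axes.  Pairs with an NA endpoint (trajectory gaps) are dropped; the number
#' of contributing pairs is recorded per lag.
#'
#' @param traj A [trajectory()] (drift-correct first if a nucleus track exists).
#' @param max_lag Largest lag in frames (must be < trajectory length).
#' @return Object of class `MSDCurve`: data frame with columns `lag_s`,
#'   `msd`, `n_pairs` (lag 0 row included with MSD 0).
#' @export
compute_msd <- function(traj, max_lag) {
  stopifnot(inherits(traj, "Trajectory"))
  n <- nrow(traj$locus)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("'max_lag' must be smaller than trajectory length",
                         call. = FALSE)
  msd <- numeric(max_lag)
  npairs <- integer(max_lag)
  xy <- traj$locus
  for (k in seq_len(max_lag)) {
    d <- xy[(k + 1):n, , drop = FALSE] - xy[1:(n - k), , drop = FALSE]
    sq <- rowSums(d^2)
    ok <- !is.na(sq)
    npairs[k] <- sum(ok)
    msd[k] <- if (npairs[k] > 0L) mean(sq[ok]) else NA_real_
  }
  out <- data.frame(lag_s = c(0, seq_len(max_lag) * traj$dt),
                    msd = c(0, msd), n_pairs = c(n, npairs))
  class(out) <- c("MSDCurve", "data.frame")
  out
}

#' Plateau fit and radius of constraint
#'
#' Fits the saturating model \eqn{MSD(\Delta t) = P (1 - e^{-\Delta t/\tau})}
#' to the first `n_lags` lags of the curve by nonlinear least squares and
#' converts the plateau to a radius of constraint
#' \deqn{R_c = \sqrt{\tfrac{5}{4} P},}
#' the standard conversion from a 2D-projected MSD plateau to the radius of
#' the spherical volume a confined locus explores (uniform occupancy of a
#' sphere of radius Rc has a projected-MSD plateau of \eqn{(4/5) R_c^2}).
#' If the nonlinear fit fails to converge the plateau falls back to the mean
#' of the last quartile of the fit window and the result is flagged.
#'
#' @param curve An [compute_msd()] result.
#' @param n_lags Number of leading lags used for the regression (default 100,
#'   i.e. the first 100 time intervals).
#' @param min_pairs Lags averaged over fewer pairs than this are excluded
#'   from the fit (default 10).
#' @return Object of class `MobilityResult`: list with `plateau` (um^2),
#'   `tau` (s), `rc` (um), `n_lags`, `residual` (RMS), `fallback` (logical).
#' @export
fit_plateau <- function(curve, n_lags = 100, min_pairs = 10) {
  stopifnot(inherits(curve, "MSDCurve"))
  lags <- curve[curve$lag_s > 0, , drop = FALSE]
  if (nrow(lags) < n_lags) stop("curve has fewer than 'n_lags' lags", call. = FALSE)
  win <- lags[seq_len(n_lags), , drop = FALSE]
  win <- win[!is.na(win$msd) & win$n_pairs >= min_pairs, , drop = FALSE]
  tail_mean <- mean(win$msd[win$lag_s >= stats::quantile(win$lag_s, 0.75)])
  p0 <- max(tail_mean, .Machine$double.eps)
  tau0 <- max(win$lag_s[which.min(abs(win$msd - p0 * (1 - exp(-1))))], win$lag_s[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(msd ~ P * (1 - exp(-lag_s / tau)), data = win,
                      start = list(P = p0, tau = tau0),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    plateau <- tail_mean; tau <- NA_real_; resid <- NA_real_; fb <- TRUE
  } else {
    cf <- stats::coef(fit)
    plateau <- unname(cf["P"]); tau <- unname(cf["tau"])
    resid <- sqrt(mean(stats::residuals(fit)^2)); fb <- FALSE
  }
  structure(list(plateau = plateau, tau = tau,
                 rc = sqrt(5 / 4 * max(plateau, 0)),
                 n_lags = n_lags, residual = resid, fallback = fb,
                 tail_mean = tail_mean),
            class = "MobilityResult")
}

#' @export
print.MobilityResult <- function(x, ...) {
  cat(sprintf("<MobilityResult> plateau %.4g um^2, tau %.3g s, Rc %.3g um%s\n",
              x$plateau, x$tau, x$rc,
              if (x$fallback) " (tail-mean fallback)" else ""))
  invisible(x)
}

#' Ensemble MSD over several trajectories
#'
#' Pools lag pairs across cells (pair-count-weighted average of per-cell
#' curves), the usual estimator when single 200-frame tracks are too noisy at
#' large lags.
#'
#' @param trajs List of [trajectory()] objects with identical `dt`.
#' @param max_lag Largest lag in frames.
#' @return An `MSDCurve`.
#' @export
ensemble_msd <- function(trajs, max_lag) {
  stopifnot(length(trajs) >= 1L)
  curves <- lapply(trajs, compute_msd, max_lag = max_lag)
  lag_s <- curves[[1]]$lag_s
  wsum <- Reduce(`+`, lapply(curves, function(cv) {
    v <- cv$msd * cv$n_pairs; v[is.na(v)] <- 0; v
  }))
  ntot <- Reduce(`+`, lapply(curves, function(cv) cv$n_pairs))
  out <- data.frame(lag_s = lag_s, msd = ifelse(ntot > 0, wsum / ntot, NA_real_),
                    n_pairs = ntot)
  out$msd[1] <- 0
  class(out) <- c("MSDCurve", "data.frame")
  out
}
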