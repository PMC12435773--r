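#' Luria-Delbruck probability mass function (Ma-Sandri-Sarkar recursion)
#'
#' Probability of observing r mutant colonies in a culture in which mutation
#' events arise as a Poisson process with mean `m` and each mutation founds a
#' clone whose final size j follows the Lea-Coulson law
#' \eqn{q_j = 1/(j(j+1))}.  The count is compound Poisson, so the MSS
#' recursion (the Panjer recursion with kernel \eqn{j q_j = 1/(j+1)}) gives
#' \deqn{p_0 = e^{-m}, \qquad
#'       p_r = \frac{m}{r} \sum_{i=0}^{r-1} \frac{p_i}{r-i+1}.}
#' The distribution is heavy tailed (\eqn{p_r \sim m/(r(r+1))}); probabilities
#' are returned for r = 0..n_max and the remaining tail mass is
#' `1 - sum(p)`.
#'
#' @param m Expected number of mutation events per culture (>= 0).
#' @param n_max Largest count for which a probability is returned.
#' @return Numeric vector of length `n_max + 1`: `p[r + 1]` is P(count = r).
#' @examples
#' ld_pmf(1, 2)  # exp(-1), exp(-1)/2, ...
#' @export
ld_pmf <- function(m, n_max) {
  if (m < 0) stop("'m' must be nonnegative", call. = FALSE)
  n_max <- as.integer(n_max)
  if (n_max < 0L) stop("'n_max' must be nonnegative", call. = FALSE)
  p <- numeric(n_max + 1L)
  p[1] <- exp(-m)
  if (n_max >= 1L && m > 0) {
    # Panjer kernel k[d] = d * q_d = 1 / (d + 1) for lag d = r - i
    d <- seq_len(n_max)
    kern <- 1 / (d + 1)
    for (r in seq_len(n_max)) {
      i <- 0:(r - 1L)
      p[r + 1L] <- (m / r) * sum(p[i + 1L] * kern[r - i])
    }
  }
  p
}

## Log-likelihood of counts under the MSS pmf.  The recursion is exact up to
## n_cap; the far tail of the Lea-Coulson distribution is p_r ~ m/(r(r+1)),
## so rare extreme counts (jackpot cultures) use the analytic tail instead
## of an O(n^2) recursion out to the jackpot size.
ld_loglik <- function(m, counts, n_cap = 1000L) {
  if (m < 0) return(-Inf)
  if (m == 0) return(if (all(counts == 0)) 0 else -Inf)
  n_eval <- min(max(counts), n_cap)
  p <- pmax(ld_pmf(m, n_eval), .Machine$double.xmin)
  small <- counts <= n_eval
  ll <- sum(log(p[counts[small] + 1L]))
  if (any(!small)) {
    big <- as.numeric(counts[!small])
    ll <- ll + sum(log(m) - log(big) - log1p(big))
  }
  ll
}

#' Maximum-likelihood estimate of mutations per culture (MSS method)
#'
#' Maximises the Luria-Delbruck log-likelihood over m by bracketed 1D search
#' ([stats::optimize()] on log m, refined by the derivative-free golden
#' bracket it uses internally).  All-zero counts give the boundary solution
#' m = 0.
#'
#' @param counts Integer vector of per-culture mutant colony counts.
#' @param tol Convergence tolerance in m (default 1e-6).
#' @return The MLE `m_hat` (single number).
#' @export
mss_mle <- function(counts, tol = 1e-6) {
  counts <- check_counts(counts)
  if (all(counts == 0)) return(0)
  # Lea-Coulson moment-style start: m / (mean zeros) brackets; the likelihood
  # is unimodal in m, so a generous bracket around a crude P0/mean start is safe.
  m0 <- max(mean(counts > 0), 0.05)
  lo <- m0 / 50
  hi <- max(10 * m0, mean(counts) + 5, 10)
  opt <- stats::optimize(function(lm) ld_loglik(exp(lm), counts),
                         lower = log(lo), upper = log(hi),
                         maximum = TRUE, tol = tol / 10)
  m_hat <- exp(opt$maximum)
  # widen once if the optimum sits on the bracket edge
  if (m_hat / lo < 1.05 || hi / m_hat < 1.05) {
    opt <- stats::optimize(function(lm) ld_loglik(exp(lm), counts),
                           lower = log(lo / 100), upper = log(hi * 100),
                           maximum = TRUE, tol = tol / 10)
    m_hat <- exp(opt$maximum)
  }
  m_hat
}

#' Profile-likelihood confidence interval for m
#'
#' Endpoints are the values of m at which the log-likelihood drops by
#' \eqn{\chi^2_1(level)/2} from its maximum (likelihood-ratio inversion).
#' With all-zero counts the lower endpoint is 0 and the interval is flagged
#' as boundary-limited.
#'
#' @param counts Per-culture mutant counts.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)`, with attribute `boundary = TRUE` when
#'   the MLE is on the m = 0 boundary.
#' @export
profile_ci <- function(counts, level = 0.95) {
  counts <- check_counts(counts)
  m_hat <- mss_mle(counts)
  drop <- stats::qchisq(level, df = 1) / 2
  if (m_hat == 0) {
    # likelihood is exp(-m)^C; solve C * m = drop
    hi <- drop / length(counts)
    out <- c(lo = 0, hi = hi)
    attr(out, "boundary") <- TRUE
    return(out)
  }
  ll_max <- ld_loglik(m_hat, counts)
  f <- function(m) ld_loglik(m, counts) - (ll_max - drop)
  lo_bracket <- m_hat * 1e-4
  lo <- if (f(lo_bracket) > 0) 0
        else stats::uniroot(f, c(lo_bracket, m_hat), tol = 1e-8)$root
  hi_bracket <- m_hat
  repeat {
    hi_bracket <- hi_bracket * 4
    if (f(hi_bracket) < 0 || hi_bracket > m_hat * 1e6) break
  }
  hi <- stats::uniroot(f, c(m_hat, hi_bracket), tol = 1e-8)$root
  out <- c(lo = lo, hi = hi)
  attr(out, "boundary") <- lo == 0
  out
}

#' Likelihood-ratio test for equality of mutation parameters
#'
#' Tests m_a = m_b between two fluctuation experiments: twice the gap between
#' the sum of the separately maximised log-likelihoods and the pooled
#' log-likelihood is referred to chi-squared with 1 degree of freedom.
#'
#' @param counts_a,counts_b Per-culture mutant counts for the two experiments.
#' @return List with `statistic`, `p_value`, `m_a`, `m_b`, `m_pooled`.
#' @export
lrt_compare <- function(counts_a, counts_b) {
  counts_a <- check_counts(counts_a)
  counts_b <- check_counts(counts_b)
  if (all(counts_a == 0) && all(counts_b == 0)) {
    return(list(statistic = 0, p_value = 1, m_a = 0, m_b = 0, m_pooled = 0))
  }
  m_a <- mss_mle(counts_a)
  m_b <- mss_mle(counts_b)
  m_pool <- mss_mle(c(counts_a, counts_b))
  stat <- 2 * (ld_loglik(m_a, counts_a) + ld_loglik(m_b, counts_b) -
                 ld_loglik(m_pool, c(counts_a, counts_b)))
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       m_a = m_a, m_b = m_b, m_pooled = m_pool)
}

#' Mutation rate per cell per division
#'
#' @param m_hat Expected mutations per culture (MLE).
#' @param N_t Viable cells per culture at plating.
#' @param dilution Fold dilution applied before selective plating: a count
#'   from a 10x-diluted aliquot represents 10x the events, so the effective
#'   denominator is `N_t / dilution`.
#' @param plating_efficiency Optional multiplier on the denominator
#'   (default 1; the estimator itself makes no plating-efficiency correction).
#' @return Rate = `m_hat / (N_t / dilution * plating_efficiency)`.
#' @export
rate_per_cell <- function(m_hat, N_t, dilution = 1, plating_efficiency = 1) {
  if (N_t <= 0) stop("'N_t' must be positive", call. = FALSE)
  if (dilution <= 0) stop("'dilution' must be positive", call. = FALSE)
  m_hat / (N_t / dilution * plating_efficiency)
}

#' Full rate estimate for one fluctuation experiment
#'
#' Convenience wrapper: MSS MLE, per-cell rate and 95% profile CI (both m and
#' rate scales).
#'
#' @inheritParams rate_per_cell
#' @param counts Per-culture mutant counts.
#' @param level Confidence level for the profile interval.
#' @return Object of class `RateEstimate`: list with `m_hat`, `rate`, `ci95_m`,
#'   `ci95_rate`, `loglik`, `n_cultures`.
#' @export
rate_estimate <- function(counts, N_t, dilution = 1, level = 0.95) {
  counts <- check_counts(counts)
  m_hat <- mss_mle(counts)
  ci <- profile_ci(counts, level)
  denom <- N_t / dilution
  structure(
    list(m_hat = m_hat,
         rate = m_hat / denom,
         ci95_m = unname(ci),
         ci95_rate = unname(ci) / denom,
         loglik = ld_loglik(m_hat, counts),
         n_cultures = length(counts)),
    class = "RateEstimate"
  )
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("<RateEstimate> m_hat = %.4g (95%% CI %.4g-%.4g), rate = %.3g per cell, %d cultures\n",
              x$m_hat, x$ci95_m[1], x$ci95_m[2], x$rate, x$n_cultures))
  invisible(x)
}

check_counts <- function(counts) {
  if (length(counts) < 1L) stop("need at least one culture", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  as.integer(counts)
}
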