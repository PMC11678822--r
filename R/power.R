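# Exact TOST power and sample size for ln-scale average bioequivalence in
# a 2x2x2 crossover, plus a fast metric-level crossover Monte Carlo used
# to validate the exact computation.

#' Exact power of the two one-sided tests procedure
#'
#' Probability that both one-sided t-tests at level `alpha` reject, i.e.
#' that the `100(1-2*alpha)%` CI for the geometric mean ratio falls inside
#' the acceptance limits, for a 2x2x2 crossover on the ln scale with
#' within-subject standard deviation `s = sqrt(ln(1 + CV^2))`, standard
#' error `s*sqrt(2/n)` and `df = n - 2`. Evaluated exactly as the
#' bivariate noncentral-t rejection probability, integrating the
#' conditional (normal) rejection probability over the scaled-chi
#' distribution of the residual standard deviation — the Owen's Q
#' construction in quadrature form.
#'
#' @param n_total Total number of subjects (even, >= 4).
#' @param iscv_pct Assumed intra-subject CV in percent.
#' @param gmr_pct Assumed true Test/Reference ratio in percent.
#' @param alpha One-sided significance level (default 0.05, the 90% CI).
#' @param limits_pct Acceptance limits in percent, default c(80, 125).
#' @return Power as a fraction in \[0, 1\].
#' @export
tost_power <- function(n_total, iscv_pct, gmr_pct, alpha = 0.05,
                       limits_pct = c(80, 125)) {
  stopifnot(is.numeric(n_total), length(n_total) == 1L)
  if (n_total < 4) stop("design error: n_total must be at least 4")
  if (n_total %% 2 != 0) stop("design error: n_total must be even")
  stopifnot(alpha > 0, alpha < 0.5, iscv_pct >= 0,
            length(limits_pct) == 2L, limits_pct[1L] < limits_pct[2L])

  s <- sqrt(iscv_to_variance(iscv_pct))
  se <- s * sqrt(2 / n_total)
  df <- n_total - 2
  d <- log(gmr_pct / 100)
  th1 <- log(limits_pct[1L] / 100)
  th2 <- log(limits_pct[2L] / 100)
  if (se == 0) return(as.numeric(d > th1 && d < th2))

  tcrit <- stats::qt(1 - alpha, df)
  # u = S/sigma; both tests reject iff
  #   th1 + tcrit*se*u <= dhat <= th2 - tcrit*se*u,
  # possible only while u < (th2 - th1)/(2*tcrit*se).
  umax <- (th2 - th1) / (2 * tcrit * se)
  upper <- min(umax, sqrt(stats::qchisq(1e-14, df, lower.tail = FALSE) / df))
  if (upper <= 0) return(0)
  integrand <- function(u) {
    p <- stats::pnorm((th2 - d) / se - tcrit * u) -
      stats::pnorm((th1 - d) / se + tcrit * u)
    pmax(p, 0) * 2 * u * df * stats::dchisq(df * u^2, df)
  }
  stats::integrate(integrand, 0, upper, rel.tol = 1e-11,
                   subdivisions = 500L)$value
}

#' Smallest balanced sample size reaching a target TOST power
#'
#' Searches the even total sample sizes upward for the smallest `n` whose
#' exact [tost_power()] reaches `target_power`. A GMR given as a range
#' (length 2) is evaluated at its worst-case endpoint at every `n`.
#'
#' @param iscv_pct Assumed intra-subject CV in percent.
#' @param gmr_pct Assumed true ratio in percent, or a length-2 range.
#' @param target_power Target power fraction (default 0.80).
#' @param alpha One-sided significance level.
#' @param limits_pct Acceptance limits in percent.
#' @param n_max Search ceiling (error beyond it).
#' @return The smallest even total `n` with power >= `target_power`.
#' @export
sample_size <- function(iscv_pct, gmr_pct, target_power = 0.80,
                        alpha = 0.05, limits_pct = c(80, 125),
                        n_max = 10000L) {
  stopifnot(target_power >= 0, target_power < 1)
  if (any(gmr_pct <= limits_pct[1L]) || any(gmr_pct >= limits_pct[2L]))
    stop("unattainable: true GMR must lie strictly inside the limits")
  pow <- function(n) min(vapply(gmr_pct, function(g)
    tost_power(n, iscv_pct, g, alpha, limits_pct), numeric(1L)))
  n <- 4L
  while (n <= n_max) {
    if (pow(n) >= target_power) return(n)
    n <- n + 2L
  }
  stop("sample size exceeds n_max = ", n_max)
}

#' Metric-level Monte Carlo of balanced 2x2x2 crossover BE outcomes
#'
#' Simulates the bioequivalence analysis directly at the ln-metric level:
#' for each replicate the within-subject Test-minus-Reference ln
#' differences are drawn as `N(ln GMR, 2*sigma^2)` per subject, and the
#' closed-form balanced crossover ANOVA (sequence-mean average for the
#' formulation effect, pooled within-sequence variance of the differences
#' for the residual) yields the GMR estimate and its CI. Algebraically
#' identical to [run_abe()] on balanced complete data (verified in the
#' test suite), but vectorised over replicates, so large operating
#' characteristic checks of [tost_power()] run in seconds.
#'
#' @param n_reps Number of simulated studies.
#' @param n_subjects Total subjects per study (even).
#' @param iscv_pct True intra-subject CV in percent.
#' @param gmr_true_pct True GMR in percent.
#' @param alpha One-sided level for the CI.
#' @param limits_pct Acceptance limits in percent.
#' @param seed Integer seed.
#' @return Data frame with one row per replicate: `gmr_pct`, `lower_pct`,
#'   `upper_pct`, `pass` (CI inside the closed limits), `covers_true`.
#' @export
simulate_be_outcomes <- function(n_reps, n_subjects, iscv_pct,
                                 gmr_true_pct = 100, alpha = 0.05,
                                 limits_pct = c(80, 125), seed = 1L) {
  stopifnot(n_subjects >= 4, n_subjects %% 2 == 0, n_reps >= 1)
  set.seed(as.integer(seed))
  sigma <- sqrt(iscv_to_variance(iscv_pct))
  mu <- log(gmr_true_pct / 100)
  n <- as.integer(n_subjects)
  half <- n %/% 2L
  dmat <- matrix(stats::rnorm(n * n_reps, mu, sqrt(2) * sigma),
                 nrow = n, ncol = n_reps)
  m1 <- colMeans(dmat[seq_len(half), , drop = FALSE])
  m2 <- colMeans(dmat[half + seq_len(half), , drop = FALSE])
  est <- (m1 + m2) / 2
  ssq <- colSums((dmat[seq_len(half), , drop = FALSE] -
                    rep(m1, each = half))^2) +
    colSums((dmat[half + seq_len(half), , drop = FALSE] -
               rep(m2, each = half))^2)
  s2 <- ssq / (n - 2L) / 2      # residual (within-subject) mean square
  se <- sqrt(2 * s2 / n)
  tcrit <- stats::qt(1 - alpha, n - 2L)
  lo <- est - tcrit * se
  hi <- est + tcrit * se
  data.frame(gmr_pct = 100 * exp(est),
             lower_pct = 100 * exp(lo),
             upper_pct = 100 * exp(hi),
             pass = 100 * exp(lo) >= limits_pct[1L] &
               100 * exp(hi) <= limits_pct[2L],
             covers_true = lo <= mu & mu <= hi)
}
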