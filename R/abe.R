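# Average bioequivalence on ln-transformed metrics: all-fixed-effects
# crossover ANOVA (Sequence, Subject nested within Sequence, Period,
# Formulation), geometric least-square means, GMR with 90% CI, and the
# intra-subject CV from the residual mean square.

#' Intra-subject coefficient of variation from the ANOVA residual
#'
#' \deqn{ISCV = 100\sqrt{e^{s^2} - 1}}
#' where \eqn{s^2} is the residual mean square of the ANOVA on the
#' ln-transformed metric.
#'
#' @param mse Residual mean square on the ln scale (>= 0).
#' @return ISCV in percent.
#' @export
iscv_from_mse <- function(mse) {
  if (!is.numeric(mse) || anyNA(mse) || any(mse < 0))
    stop("numeric error: mse must be non-negative")
  100 * sqrt(exp(mse) - 1)
}

# Inverse map: ln-scale variance implied by an intra-subject CV in percent.
iscv_to_variance <- function(iscv_pct) log(1 + (iscv_pct / 100)^2)

#' Average-bioequivalence ANOVA for one metric
#'
#' Fits the fixed-effects linear model
#' `ln(metric) ~ Sequence + Subject(Sequence) + Period + Formulation` by
#' least squares on completers with both periods evaluable, and derives the
#' geometric least-square means (equal weight over subjects and periods),
#' the Test/Reference geometric mean ratio with its two-sided
#' `100(1-2*alpha)%` confidence interval on the residual t distribution,
#' the residual mean square and the intra-subject CV. Because the subject
#' term absorbs all between-subject variation, the residual is the
#' within-subject mean square error.
#'
#' The per-term ANOVA table (sequential sums of squares in the model order
#' above) tests Sequence against the Subject-within-Sequence mean square
#' and the remaining terms against the residual, the convention for
#' crossover bioequivalence.
#'
#' @param nca An `nca_table` from [run_nca()] (or any data frame with
#'   columns `subject`, `sequence`, `period`, `formulation` and the metric
#'   column).
#' @param metric `"cmax"` or `"auc0_72"`.
#' @param alpha One-sided significance level; 0.05 gives the conventional
#'   90% CI.
#' @param anova_table Compute the per-term ANOVA table (default TRUE; skip
#'   for speed in simulations).
#' @return An object of class `abe_result`: `metric`, `n_subjects`,
#'   `lsm_test`, `lsm_ref` (original scale), `gmr_pct`, `ci90_pct`,
#'   `mse`, `df_resid`, `iscv_pct`, `anova_table`, `alpha`.
#' @export
run_abe <- function(nca, metric = c("cmax", "auc0_72"), alpha = 0.05,
                    anova_table = TRUE) {
  metric <- match.arg(metric)
  col <- switch(metric, cmax = "cmax_ng_ml", auc0_72 = "auc0_72_ng_h_ml")
  if (!col %in% names(nca)) col <- metric  # plain metric column
  d <- data.frame(subject = as.character(nca$subject),
                  sequence = as.character(nca$sequence),
                  period = as.integer(nca$period),
                  formulation = as.character(nca$formulation),
                  value = as.numeric(nca[[col]]),
                  stringsAsFactors = FALSE)
  d <- d[!is.na(d$value), ]
  if (any(d$value <= 0))
    stop("data error: metric values must be strictly positive for ",
         "ln-transformation")
  both <- names(which(table(unique(d[c("subject", "period")])$subject) == 2L))
  d <- d[d$subject %in% both, ]
  n <- length(unique(d$subject))
  if (n < 2L || length(unique(d$sequence)) < 2L)
    stop("design error: need completers in both sequences")
  n_by_seq <- table(unique(d[c("subject", "sequence")])$sequence)
  if (any(n_by_seq < 3L))
    warning("fewer than 3 completers in a sequence; estimates unstable")
  if (n < 12L)
    warning(sprintf("only %d completers; below the customary minimum of 12",
                    n))

  d$seq_f <- factor(d$sequence, levels = c("TR", "RT"))
  d$subj_f <- factor(d$subject)
  d$per_f <- factor(d$period, levels = c(1L, 2L))
  d$form_f <- factor(d$formulation, levels = c("Reference", "Test"))
  d$lny <- log(d$value)

  # Sequence is confounded with subjects; lm() drops the aliased subject
  # columns, leaving the usual n - 2 residual df for complete data.
  fit <- stats::lm(lny ~ seq_f + subj_f + per_f + form_f, data = d)
  df_resid <- fit$df.residual
  if (df_resid < 1L) stop("design error: no residual degrees of freedom")
  mse <- sum(stats::residuals(fit)^2) / df_resid

  cf <- stats::coef(fit)
  est <- cf[["form_fTest"]]
  se <- sqrt(diag(stats::vcov(fit))[["form_fTest"]])
  if (!is.finite(se)) se <- 0
  tcrit <- stats::qt(1 - alpha, df_resid)
  ci <- exp(est + c(-1, 1) * tcrit * se)

  # Least-square means: equal-weight average of the model prediction over
  # every subject x period cell with the formulation forced to each level.
  grid <- expand.grid(subj_f = levels(d$subj_f), per_f = levels(d$per_f),
                      stringsAsFactors = FALSE)
  grid$seq_f <- d$seq_f[match(grid$subj_f, d$subj_f)]
  lsm_ln <- vapply(levels(d$form_f), function(f) {
    g <- grid
    g$form_f <- factor(f, levels = levels(d$form_f))
    mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)), g,
                              xlev = fit$xlevels,
                              contrasts.arg = fit$contrasts)
    beta <- ifelse(is.na(cf), 0, cf)
    mean(drop(mm %*% beta))
  }, numeric(1L))

  tab <- NULL
  if (anova_table) tab <- abe_anova_table(d, mse, df_resid)

  structure(list(metric = metric, n_subjects = n,
                 lsm_test = exp(lsm_ln[["Test"]]),
                 lsm_ref = exp(lsm_ln[["Reference"]]),
                 gmr_pct = 100 * exp(est),
                 ci90_pct = 100 * ci,
                 mse = mse, df_resid = df_resid,
                 iscv_pct = iscv_from_mse(mse),
                 anova_table = tab, alpha = alpha),
            class = "abe_result")
}

# Sequential decomposition in the stated model order; Sequence is tested
# against the Subject(Sequence) mean square.
abe_anova_table <- function(d, mse, df_resid) {
  rss <- function(formula) sum(stats::residuals(stats::lm(formula, d))^2)
  rss0 <- rss(lny ~ 1)
  rss_seq <- rss(lny ~ seq_f)
  rss_subj <- rss(lny ~ subj_f)          # subjects absorb sequence
  rss_per <- rss(lny ~ subj_f + per_f)
  rss_form <- rss(lny ~ subj_f + per_f + form_f)
  n_subj <- nlevels(d$subj_f)
  ss <- c(Sequence = rss0 - rss_seq,
          `Subject(Sequence)` = rss_seq - rss_subj,
          Period = rss_subj - rss_per,
          Formulation = rss_per - rss_form,
          Residual = rss_form)
  df <- c(1L, n_subj - 2L, 1L, 1L, df_resid)
  ms <- ss / df
  fval <- c(ms[1L] / ms[2L], ms[2L:4L] / ms[5L], NA)
  fdf2 <- c(df[2L], rep(df_resid, 3L), NA)
  p <- stats::pf(fval, df, fdf2, lower.tail = FALSE)
  data.frame(term = names(ss), df = df, ss = unname(ss), ms = unname(ms),
             f_value = unname(fval), p_value = unname(p))
}

#' @export
print.abe_result <- function(x, ...) {
  cat(sprintf("Average bioequivalence, ln(%s), n = %d completers\n",
              x$metric, x$n_subjects))
  cat(sprintf("  geometric LSM  Test %.2f  Reference %.2f\n",
              x$lsm_test, x$lsm_ref))
  cat(sprintf("  GMR %.2f%%  [%.2f-%.2f]%% (%.0f%% CI)\n", x$gmr_pct,
              x$ci90_pct[1L], x$ci90_pct[2L], 100 * (1 - 2 * x$alpha)))
  cat(sprintf("  ISCV %.1f%%  (MSE %.5f, %d residual df)\n",
              x$iscv_pct, x$mse, x$df_resid))
  invisible(x)
}

#' Geometric mean ratio from least-square means
#'
#' Worked-example helper: the GMR in percent implied by a pair of
#' geometric least-square means, as printed in bioequivalence reports.
#'
#' @param lsm_test,lsm_ref Geometric least-square means (original scale).
#' @return `100 * lsm_test / lsm_ref`.
#' @export
gmr_from_lsm <- function(lsm_test, lsm_ref) {
  stopifnot(lsm_test > 0, lsm_ref > 0)
  100 * lsm_test / lsm_ref
}

#' Bioequivalence decision on the 90% confidence interval
#'
#' Bioequivalent if and only if both CI bounds fall inside the closed
#' acceptance interval (default \[80.00, 125.00\]%). The decision is taken
#' on unrounded values; bounds exactly on a limit pass.
#'
#' @param result An `abe_result`.
#' @param limits_pct Acceptance limits in percent.
#' @return List of class `be_decision` with `bioequivalent`,
#'   `interval_pct` and the CI assessed.
#' @export
be_decision <- function(result, limits_pct = c(80, 125)) {
  stopifnot(inherits(result, "abe_result"), length(limits_pct) == 2L,
            limits_pct[1L] < 100, limits_pct[2L] > 100)
  ci <- result$ci90_pct
  structure(list(bioequivalent = ci[1L] >= limits_pct[1L] &&
                   ci[2L] <= limits_pct[2L],
                 interval_pct = limits_pct, ci90_pct = ci),
            class = "be_decision")
}

#' @export
print.be_decision <- function(x, ...) {
  cat(sprintf("90%% CI [%.2f-%.2f]%% vs [%.2f-%.2f]%%: %s\n",
              x$ci90_pct[1L], x$ci90_pct[2L], x$interval_pct[1L],
              x$interval_pct[2L],
              if (x$bioequivalent) "bioequivalent"
              else "bioequivalence not shown"))
  invisible(x)
}
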