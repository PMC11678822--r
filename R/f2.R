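# Cmax f2 similarity factor: mean profiles, normalisation to the Reference
# mean Cmax truncated at the Reference mean tmax, the f2 statistic, and the
# decision bands for proceeding to a pivotal study.

#' Mean concentration-time profile of one formulation
#'
#' Arithmetic mean concentration at each nominal time across completers.
#' A BLQ observation before a subject's first quantifiable concentration
#' contributes 0 (nothing absorbed yet); embedded or trailing BLQ are
#' excluded from the mean at that time.
#'
#' @param dataset A [study_dataset()].
#' @param formulation `"Test"` or `"Reference"`.
#' @return Object of class `mean_profile` with `times_h`, `mean_conc`,
#'   `n_subjects` (completer count) and `formulation`.
#' @export
mean_profile <- function(dataset, formulation = c("Reference", "Test")) {
  formulation <- match.arg(formulation)
  stopifnot(inherits(dataset, "study_dataset"))
  comp <- completers(dataset)
  if (length(comp) == 0L) stop("data error: no completers")
  rec <- dataset$records
  rec <- rec[rec$subject %in% comp & rec$formulation == formulation, ]
  grid <- dataset$nominal_times_h
  acc <- matrix(NA_real_, nrow = length(comp), ncol = length(grid),
                dimnames = list(comp, NULL))
  for (s in comp) {
    sel <- rec$subject == s
    prof <- clean_profile(rec$time_h[sel], rec$conc_ng_ml[sel],
                          rec$blq[sel])
    acc[s, match(prof$time_h, grid)] <- prof$conc
  }
  structure(list(times_h = grid,
                 mean_conc = colMeans(acc, na.rm = TRUE),
                 n_subjects = length(comp),
                 formulation = formulation),
            class = "mean_profile")
}

#' Normalise a Test/Reference pair of mean profiles
#'
#' Both mean curves are scaled to the maximum of the mean Reference profile
#' (\eqn{C_{maxR}}) and truncated at the time that maximum is observed
#' (\eqn{t_{maxR}}, earliest grid point on ties):
#' \deqn{C_t^N = 100\, \bar{C}_t / C_{maxR}, \quad 0 \le t \le t_{maxR}.}
#' The normalised Reference curve therefore equals 100 at \eqn{t_{maxR}}.
#'
#' @param ref,test `mean_profile` objects on the same time grid.
#' @return Object of class `normalized_pair`: `times_h`, `ref_norm`,
#'   `test_norm`, `cmax_ref`, `tmax_ref_h`, `n_points` (post-dose points,
#'   `0 < t <= tmax_ref_h`).
#' @export
normalize_pair <- function(ref, test) {
  stopifnot(inherits(ref, "mean_profile"), inherits(test, "mean_profile"),
            identical(ref$times_h, test$times_h))
  mu <- ref$mean_conc
  if (!any(is.finite(mu)) || max(mu, na.rm = TRUE) <= 0)
    stop("normalization error: reference mean profile has no positive ",
         "maximum")
  i_max <- which.max(mu)  # earliest tie by which.max
  cmax_ref <- mu[i_max]
  tmax_ref <- ref$times_h[i_max]
  keep <- ref$times_h <= tmax_ref
  structure(list(times_h = ref$times_h[keep],
                 ref_norm = 100 * ref$mean_conc[keep] / cmax_ref,
                 test_norm = 100 * test$mean_conc[keep] / cmax_ref,
                 cmax_ref = cmax_ref,
                 tmax_ref_h = tmax_ref,
                 n_points = sum(ref$times_h[keep] > 0)),
            class = "normalized_pair")
}

#' The Cmax f2 similarity factor
#'
#' \deqn{f_2 = 50 \log_{10}\!\left[100\left(1 + \tfrac{1}{n}\sum_{t=1}^{n}
#'   (R_t^N - T_t^N)^2\right)^{-0.5}\right]}
#' summed over the post-dose points of the normalised pair
#' (\eqn{0 < t \le t_{maxR}}; the pre-dose point, identically zero on both
#' curves, is excluded so that it cannot inflate similarity). Identical
#' curves give exactly 100.
#'
#' @param pair A [normalize_pair()] result.
#' @return Object of class `f2_result` with `f2`, `n_points`, `cutoff`
#'   (35) and the `pair`.
#' @export
f2_factor <- function(pair) {
  stopifnot(inherits(pair, "normalized_pair"))
  post <- pair$times_h > 0
  r <- pair$ref_norm[post]; t <- pair$test_norm[post]
  if (length(r) == 0L || anyNA(r) || anyNA(t))
    stop("data error: empty or incomplete normalised pair")
  msd <- mean((r - t)^2)
  structure(list(f2 = 50 * log10(100 * (1 + msd)^(-0.5)),
                 n_points = length(r), cutoff = 35, pair = pair),
            class = "f2_result")
}

#' @export
print.f2_result <- function(x, ...) {
  cat(sprintf(paste0("Cmax f2 similarity: f2 = %.2f over %d points ",
                     "(CmaxR %.2f at %.2f h)\n"),
              x$f2, x$n_points, x$pair$cmax_ref, x$pair$tmax_ref_h))
  invisible(x)
}

#' Decision band for proceeding to a pivotal study
#'
#' For a highly variable drug the f2 value, together with the intra-subject
#' CV estimated by the average-bioequivalence ANOVA, maps to a confidence
#' level of proceeding to a pivotal study:
#' f2 >= 50 gives > 90% confidence regardless of ISCV; f2 >= 41 with
#' ISCV >= 50% gives > 80%; f2 >= 35 with ISCV > 40% gives > 60%; f2 below
#' the cut-off of 35 shows no similarity. Combinations not covered by these
#' rules (e.g. f2 in \[35, 50) with ISCV <= 40%) are flagged as outside the
#' tabulated scenarios and reported at the weakest band.
#'
#' @param f2 The f2 value (unrounded).
#' @param iscv_pct ANOVA intra-subject CV in percent.
#' @return List of class `f2_band`: `band` (one of `below_cutoff`,
#'   `conf_gt60`, `conf_gt80`, `conf_gt90`), `outside_tabulated`,
#'   `recommendation`.
#' @export
confidence_band <- function(f2, iscv_pct) {
  stopifnot(is.finite(f2), is.finite(iscv_pct))
  outside <- FALSE
  if (f2 < 35) {
    band <- "below_cutoff"
    rec <- "Cmax similarity not shown (f2 below the cut-off of 35)."
  } else if (f2 >= 50) {
    band <- "conf_gt90"
    rec <- paste("High (>90%) confidence in proceeding to a pivotal",
                 "study, regardless of ISCV.")
  } else if (f2 >= 41 && iscv_pct >= 50) {
    band <- "conf_gt80"
    rec <- ">80% confidence in proceeding to a pivotal study."
  } else if (iscv_pct > 40) {
    band <- "conf_gt60"
    rec <- ">60% confidence in proceeding to a pivotal study."
  } else {
    band <- "conf_gt60"
    outside <- TRUE
    rec <- paste("f2 >= 35 but ISCV <= 40%: outside tabulated scenarios;",
                 "weakest stated band reported.")
  }
  structure(list(band = band, outside_tabulated = outside,
                 recommendation = rec),
            class = "f2_band")
}

#' Full Cmax f2 analysis of a study
#'
#' Convenience wrapper: mean profiles of both formulations, normalisation
#' to the Reference mean Cmax, and the f2 statistic.
#'
#' @param dataset A [study_dataset()].
#' @return An `f2_result`.
#' @export
run_f2 <- function(dataset) {
  ref <- mean_profile(dataset, "Reference")
  test <- mean_profile(dataset, "Test")
  f2_factor(normalize_pair(ref, test))
}
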