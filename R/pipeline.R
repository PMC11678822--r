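# End-to-end study analysis: NCA -> average bioequivalence -> f2 (pilot
# mode) -> decision report.

#' Run the full pilot/pivotal bioequivalence analysis
#'
#' Orchestrates the analysis of one 2x2x2 crossover study on its
#' completers: non-compartmental metrics with arithmetic-mean/CV%
#' summaries (median and range for tmax), the average-bioequivalence ANOVA
#' on ln-Cmax and ln-AUC0-72, the \[80.00-125.00\]% decision and, in pilot
#' mode, the Cmax f2 similarity factor with its confidence band. Pivotal
#' mode marks the f2 analysis as not calculated, as is conventional for
#' fully powered studies. Deterministic given the input dataset.
#'
#' @param study A [study_dataset()].
#' @param mode `"pilot"` (computes f2) or `"pivotal"` (f2 not calculated).
#' @param alpha One-sided significance level for the ABE CI.
#' @return Object of class `study_report` with elements `label`, `mode`,
#'   `n_completers`, `nca_summary`, `abe_cmax`, `abe_auc`, `decision_cmax`,
#'   `decision_auc`, `f2` (`NULL` in pivotal mode), `f2_band`,
#'   `recommendation` and `provenance`.
#' @export
run_pipeline <- function(study, mode = c("pilot", "pivotal"),
                         alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(study, "study_dataset"))
  if (nrow(study$records) == 0L)
    stop("pipeline [input]: empty dataset")
  comp <- completers(study)
  if (length(comp) < 2L)
    stop("pipeline [input]: fewer than 2 completers")

  nca <- withCallingHandlers(
    run_nca(study),
    warning = function(w) {
      message("pipeline [nca]: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  ncac <- nca[nca$subject %in% comp, ]
  summ <- nca_summary(ncac)

  abe_cmax <- run_abe(ncac, "cmax", alpha = alpha)
  abe_auc <- run_abe(ncac, "auc0_72", alpha = alpha)
  dec_cmax <- be_decision(abe_cmax)
  dec_auc <- be_decision(abe_auc)

  f2 <- NULL; band <- NULL
  if (mode == "pilot") {
    f2 <- run_f2(study)
    band <- confidence_band(f2$f2, abe_cmax$iscv_pct)
  }

  rec <- if (dec_cmax$bioequivalent && dec_auc$bioequivalent) {
    "Bioequivalence shown for Cmax and AUC0-72."
  } else if (mode == "pilot" && !is.null(band)) {
    paste("Average bioequivalence not shown on the 90% CI.",
          band$recommendation)
  } else {
    "Bioequivalence not shown."
  }

  structure(list(label = study$label, mode = mode,
                 n_completers = length(comp),
                 nca_summary = summ,
                 abe_cmax = abe_cmax, abe_auc = abe_auc,
                 decision_cmax = dec_cmax, decision_auc = dec_auc,
                 f2 = f2, f2_band = band,
                 recommendation = rec,
                 provenance = report_provenance(study)),
            class = "study_report")
}

# Version and an input fingerprint so a report can be traced back to the
# exact dataset that produced it.
report_provenance <- function(study) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_study(study, tmp)
  list(package_version =
         as.character(utils::packageVersion("bepilot")),
       input_md5 = unname(tools::md5sum(tmp)),
       n_records = nrow(study$records))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("== %s study report%s ==\n", x$mode,
              if (nzchar(x$label)) paste0(": ", x$label) else ""))
  cat(sprintf("completers: n = %d\n\n", x$n_completers))
  s <- x$nca_summary
  cat("PK metrics (arithmetic mean (CV%); tmax median [range]):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s Cmax %.2f (%.1f%%)  tmax %.2f [%.2f-%.2f] h\n",
                s$formulation[i], s$cmax_mean[i], s$cmax_cv_pct[i],
                s$tmax_median[i], s$tmax_min[i], s$tmax_max[i]))
    cat(sprintf("            AUC0-72 %.2f (%.1f%%)  t1/2 %.2f h (%.1f%%)\n",
                s$auc_mean[i], s$auc_cv_pct[i], s$t_half_mean[i],
                s$t_half_cv_pct[i]))
  }
  cat("\n")
  print(x$abe_cmax)
  print(x$decision_cmax)
  if (!is.null(x$f2)) {
    print(x$f2)
    cat(sprintf("f2 band: %s\n", x$f2_band$band))
  } else {
    cat("f2 factor: NC (not calculated in pivotal mode)\n")
  }
  cat("\n", x$recommendation, "\n", sep = "")
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' @param report A `study_report`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "study_report"))
  x <- list(
    label = report$label, mode = report$mode,
    n_completers = report$n_completers,
    nca_summary = report$nca_summary,
    abe = lapply(list(cmax = report$abe_cmax, auc0_72 = report$abe_auc),
                 function(a) list(n_subjects = a$n_subjects,
                                  lsm_test = a$lsm_test,
                                  lsm_ref = a$lsm_ref,
                                  gmr_pct = a$gmr_pct,
                                  ci90_pct = a$ci90_pct,
                                  mse = a$mse, df_resid = a$df_resid,
                                  iscv_pct = a$iscv_pct,
                                  anova_table = a$anova_table)),
    bioequivalent = list(cmax = report$decision_cmax$bioequivalent,
                         auc0_72 = report$decision_auc$bioequivalent),
    f2 = if (is.null(report$f2)) "NC" else
      list(f2 = report$f2$f2, n_points = report$f2$n_points,
           cmax_ref = report$f2$pair$cmax_ref,
           tmax_ref_h = report$f2$pair$tmax_ref_h,
           band = report$f2_band$band,
           outside_tabulated = report$f2_band$outside_tabulated),
    recommendation = report$recommendation,
    provenance = report$provenance)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
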