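# Non-compartmental analysis: Cmax/tmax, truncated AUC by the
# linear-up/log-down trapezoid, and terminal-phase ln-linear regression.

# BLQ handling for a single profile: observations below the LLOQ before the
# first quantifiable concentration are taken as 0 (single-dose study,
# nothing on board yet); embedded or trailing BLQ are treated as missing so
# that AUC intervals bridge across them and the lambda_z fit ignores them.
clean_profile <- function(time_h, conc_ng_ml, blq) {
  stopifnot(length(time_h) == length(conc_ng_ml),
            length(time_h) == length(blq))
  o <- order(time_h)
  time_h <- time_h[o]; conc <- conc_ng_ml[o]; blq <- blq[o]
  used <- conc
  used[blq] <- NA_real_
  quant <- !blq & !is.na(conc)
  if (any(quant)) {
    lead <- seq_len(min(which(quant)) - 1L)
    used[lead][blq[lead]] <- 0
  }
  data.frame(time_h = time_h, conc = used)
}

#' Maximum observed concentration and its time
#'
#' @param time_h Sampling times in hours.
#' @param conc Observed concentrations (NA = not usable).
#' @return List with `cmax` and `tmax_h` (earliest time attaining the
#'   maximum), or `NULL` when no positive concentration is available (NCA
#'   failure for that occasion).
#' @export
cmax_tmax <- function(time_h, conc) {
  keep <- !is.na(conc)
  time_h <- time_h[keep]; conc <- conc[keep]
  if (length(conc) == 0L || max(conc) <= 0) return(NULL)
  i <- which.max(conc)  # which.max returns the first (earliest) maximum
  list(cmax = conc[i], tmax_h = time_h[i])
}

# One trapezoid segment. Log-down rule when the concentration falls between
# two positive values; linear otherwise (rise, equal values, or a zero
# endpoint, where the log rule degenerates).
auc_segment <- function(t1, t2, c1, c2, method) {
  dt <- t2 - t1
  if (method == "linlog" && c1 > c2 && c2 > 0) {
    dt * (c1 - c2) / log(c1 / c2)
  } else {
    dt * (c1 + c2) / 2
  }
}

#' Area under the curve truncated at 72 h
#'
#' Linear-up/log-down trapezoidal area from dosing to `end_h`. Missing
#' concentrations are bridged (the interval spans them). When the last
#' usable observation falls short of `end_h` the area is truncated there
#' with a warning and flagged non-evaluable for bioequivalence.
#'
#' @param time_h Sampling times (hours).
#' @param conc Usable concentrations (NA = missing).
#' @param end_h Truncation time, default 72.
#' @param method `"linlog"` (default) or `"linear"` for the all-linear
#'   trapezoid.
#' @return List with `auc` (ng·h/mL), `end_used_h` and `evaluable`, or
#'   `NULL` with fewer than two usable points.
#' @export
auc_0_72 <- function(time_h, conc, end_h = 72, method = c("linlog", "linear")) {
  method <- match.arg(method)
  keep <- !is.na(conc) & time_h <= end_h + 1e-9
  t <- time_h[keep]; c <- conc[keep]
  if (length(t) < 2L) return(NULL)
  evaluable <- TRUE
  if (max(t) < end_h) {
    warning(sprintf("no usable sample at %g h; AUC truncated at %g h",
                    end_h, max(t)))
    evaluable <- FALSE
  }
  auc <- 0
  for (i in seq_len(length(t) - 1L))
    auc <- auc + auc_segment(t[i], t[i + 1L], c[i], c[i + 1L], method)
  list(auc = auc, end_used_h = max(t), evaluable = evaluable)
}

# Closed-form OLS of ln(conc) on time for one candidate point set.
lnlinear_fit <- function(t, lnc) {
  n <- length(t)
  mx <- mean(t); my <- mean(lnc)
  sxx <- sum((t - mx)^2)
  sxy <- sum((t - mx) * (lnc - my))
  syy <- sum((lnc - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(slope = slope, r2adj = r2adj)
}

#' Terminal elimination rate constant by best-fit ln-linear regression
#'
#' Candidate point sets are the trailing `k >= 3` quantifiable positive
#' concentrations strictly after `tmax`; the set maximising the adjusted
#' R-squared is selected (ties within 1e-4 go to the larger set). The fit
#' must give a positive rate constant, otherwise lambda_z is reported
#' absent.
#'
#' @param time_h Sampling times (hours).
#' @param conc Usable concentrations (NA = missing).
#' @param tmax_h Time of the observed maximum (excluded from the fit).
#' @return List with `lambda_z` (1/h), `t_half_h`, `n_points`, `r2adj`;
#'   all `NA` when no admissible fit exists.
#' @export
lambda_z <- function(time_h, conc, tmax_h) {
  absent <- list(lambda_z = NA_real_, t_half_h = NA_real_,
                 n_points = NA_integer_, r2adj = NA_real_)
  keep <- !is.na(conc) & conc > 0 & time_h > tmax_h
  t <- time_h[keep]; lnc <- log(conc[keep])
  m <- length(t)
  if (m < 3L) return(absent)
  best <- NULL
  for (k in 3:m) {
    idx <- (m - k + 1L):m
    fit <- lnlinear_fit(t[idx], lnc[idx])
    if (fit$slope >= 0) next
    if (is.null(best) || fit$r2adj > best$r2adj + 1e-4 ||
        (abs(fit$r2adj - best$r2adj) <= 1e-4 && k > best$k))
      best <- list(slope = fit$slope, r2adj = fit$r2adj, k = k)
  }
  if (is.null(best)) return(absent)
  lz <- -best$slope
  list(lambda_z = lz, t_half_h = log(2) / lz,
       n_points = best$k, r2adj = best$r2adj)
}

#' Non-compartmental analysis of a crossover study
#'
#' Derives Cmax, tmax, AUC truncated at 72 h, lambda_z and the terminal
#' half-life for every subject-by-period profile, applying the BLQ rules
#' described in [auc_0_72()] and [lambda_z()]. Occasions with no
#' quantifiable concentration, or without a usable 72 h sample, are flagged
#' non-evaluable.
#'
#' @param dataset A [study_dataset()].
#' @param end_h AUC truncation time (default 72 h).
#' @param auc_method `"linlog"` (default) or `"linear"`.
#' @return Data frame of class `nca_table`, one row per subject-by-period,
#'   with columns `subject`, `sequence`, `period`, `formulation`,
#'   `cmax_ng_ml`, `tmax_h`, `auc0_72_ng_h_ml`, `lambda_z_per_h`,
#'   `t_half_h`, `lambda_z_points`, `lambda_z_r2adj`, `evaluable`.
#' @export
run_nca <- function(dataset, end_h = 72, auc_method = "linlog") {
  stopifnot(inherits(dataset, "study_dataset"))
  rec <- dataset$records
  occ <- unique(rec[c("subject", "sequence", "period", "formulation")])
  occ <- occ[order(occ$subject, occ$period), , drop = FALSE]
  out <- vector("list", nrow(occ))
  for (i in seq_len(nrow(occ))) {
    sel <- rec$subject == occ$subject[i] & rec$period == occ$period[i]
    prof <- clean_profile(rec$time_h[sel], rec$conc_ng_ml[sel],
                          rec$blq[sel])
    ct <- cmax_tmax(prof$time_h, prof$conc)
    if (is.null(ct)) {
      out[[i]] <- data.frame(occ[i, ], cmax_ng_ml = NA_real_,
                             tmax_h = NA_real_, auc0_72_ng_h_ml = NA_real_,
                             lambda_z_per_h = NA_real_, t_half_h = NA_real_,
                             lambda_z_points = NA_integer_,
                             lambda_z_r2adj = NA_real_, evaluable = FALSE)
      next
    }
    auc <- auc_0_72(prof$time_h, prof$conc, end_h = end_h,
                    method = auc_method)
    lz <- lambda_z(prof$time_h, prof$conc, ct$tmax_h)
    out[[i]] <- data.frame(occ[i, ],
                           cmax_ng_ml = ct$cmax,
                           tmax_h = ct$tmax_h,
                           auc0_72_ng_h_ml = if (is.null(auc)) NA_real_
                                             else auc$auc,
                           lambda_z_per_h = lz$lambda_z,
                           t_half_h = lz$t_half_h,
                           lambda_z_points = lz$n_points,
                           lambda_z_r2adj = lz$r2adj,
                           evaluable = !is.null(auc) && auc$evaluable)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("nca_table", "data.frame")
  res
}

#' Summary statistics of NCA metrics by formulation
#'
#' Arithmetic mean with CV% (100·sd/mean) for Cmax, AUC0-72, lambda_z and
#' t1/2; median with range for tmax — the conventional presentation of
#' single-dose bioequivalence PK tables.
#'
#' @param nca An `nca_table` from [run_nca()].
#' @param subjects Optional subject subset (e.g. [completers()]).
#' @return Data frame, one row per formulation.
#' @export
nca_summary <- function(nca, subjects = NULL) {
  if (!is.null(subjects)) nca <- nca[nca$subject %in% subjects, ]
  mean_cv <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), cv_pct = 100 * stats::sd(x) / mean(x))
  }
  do.call(rbind, lapply(split(nca, nca$formulation), function(d) {
    cm <- mean_cv(d$cmax_ng_ml); au <- mean_cv(d$auc0_72_ng_h_ml)
    lz <- mean_cv(d$lambda_z_per_h); th <- mean_cv(d$t_half_h)
    tm <- d$tmax_h[!is.na(d$tmax_h)]
    data.frame(formulation = d$formulation[1L], n = nrow(d),
               cmax_mean = cm["mean"], cmax_cv_pct = cm["cv_pct"],
               tmax_median = stats::median(tm), tmax_min = min(tm),
               tmax_max = max(tm),
               auc_mean = au["mean"], auc_cv_pct = au["cv_pct"],
               lambda_z_mean = lz["mean"], lambda_z_cv_pct = lz["cv_pct"],
               t_half_mean = th["mean"], t_half_cv_pct = th["cv_pct"],
               row.names = NULL)
  }))
}
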