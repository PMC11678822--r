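# Fixture builders and the independent least-squares oracle used across
# the suite. All fixtures are generated in code.

# A tiny hand-built crossover dataset on a 4-point grid. `profiles` is a
# list keyed by subject id, each a list with `sequence` and two numeric
# concentration vectors `p1`, `p2` (NA = BLQ).
make_dataset <- function(profiles, times = c(0, 1, 2, 3), lloq = 1,
                         dose = 100, label = "fixture") {
  rows <- list()
  for (id in names(profiles)) {
    p <- profiles[[id]]
    for (period in 1:2) {
      conc <- p[[paste0("p", period)]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = id, sequence = p$sequence, period = period,
        formulation = bepilot:::expected_formulation(p$sequence, period),
        time_h = times, conc_ng_ml = conc, blq = is.na(conc),
        stringsAsFactors = FALSE)
    }
  }
  study_dataset(do.call(rbind, rows),
                study_config(lloq_ng_ml = lloq, dose_mg = dose,
                             nominal_times_h = times, label = label))
}

# Metric-level NCA-shaped table for the ABE model: one Cmax value per
# subject x period, formulation implied by the sequence.
make_metric_table <- function(subject, sequence, p1, p2) {
  do.call(rbind, lapply(seq_along(subject), function(i) {
    data.frame(subject = subject[i], sequence = sequence[i],
               period = 1:2,
               formulation = bepilot:::expected_formulation(sequence[i], 1:2),
               cmax_ng_ml = c(p1[i], p2[i]),
               auc0_72_ng_h_ml = c(p1[i], p2[i]),
               stringsAsFactors = FALSE)
  }))
}

# Independent average-bioequivalence oracle: generalised-inverse normal
# equations on the over-parameterised design matrix (intercept plus full
# dummy blocks for sequence, subject, period, formulation), with the
# Test/Reference least-square means taken as estimable equal-weight
# averages over the subject x period grid. Shares no code with run_abe().
oracle_abe <- function(tab, metric_col = "cmax_ng_ml", alpha = 0.05) {
  y <- log(tab[[metric_col]])
  subj <- factor(tab$subject)
  seqf <- factor(tab$sequence)
  perf <- factor(tab$period)
  formf <- factor(tab$formulation, levels = c("Reference", "Test"))
  dummies <- function(f) sapply(levels(f), function(l) as.numeric(f == l))
  X <- cbind(1, dummies(seqf), dummies(subj), dummies(perf), dummies(formf))
  XtX <- crossprod(X)
  b <- MASS::ginv(XtX) %*% crossprod(X, y)
  fitted <- X %*% b
  r <- qr(X)$rank
  df <- length(y) - r
  mse <- sum((y - fitted)^2) / df

  # Equal-weight LSM contrast vectors over all (subject, period) cells.
  subj_levels <- levels(subj)
  seq_of_subj <- tab$sequence[match(subj_levels, tab$subject)]
  lsm_vec <- function(form_level) {
    rows <- list()
    for (i in seq_along(subj_levels)) {
      for (p in levels(perf)) {
        rows[[length(rows) + 1L]] <-
          c(1, as.numeric(levels(seqf) == seq_of_subj[i]),
            as.numeric(subj_levels == subj_levels[i]),
            as.numeric(levels(perf) == p),
            as.numeric(levels(formf) == form_level))
      }
    }
    colMeans(do.call(rbind, rows))
  }
  ct <- lsm_vec("Test")
  cr <- lsm_vec("Reference")
  contrast <- ct - cr
  est <- drop(contrast %*% b)
  se <- sqrt(mse * drop(t(contrast) %*% MASS::ginv(XtX) %*% contrast))
  tcrit <- stats::qt(1 - alpha, df)
  list(lsm_test = exp(drop(ct %*% b)), lsm_ref = exp(drop(cr %*% b)),
       gmr_pct = 100 * exp(est),
       ci90_pct = 100 * exp(est + c(-1, 1) * tcrit * se),
       mse = mse, df_resid = df)
}

# Random small crossover metric table (possibly unbalanced sequences).
random_metric_table <- function(n_tr, n_rt, sigma_w = 0.3, gmr = 1) {
  n <- n_tr + n_rt
  subject <- sprintf("R%02d", seq_len(n))
  sequence <- c(rep("TR", n_tr), rep("RT", n_rt))
  subj_eff <- stats::rnorm(n, log(1000), 0.5)
  per_eff <- c(0, stats::rnorm(1, 0, 0.1))
  vals <- function(i, period) {
    form <- bepilot:::expected_formulation(sequence[i], period)
    exp(subj_eff[i] + per_eff[period] +
          log(gmr) * (form == "Test") + stats::rnorm(1, 0, sigma_w))
  }
  p1 <- vapply(seq_len(n), vals, numeric(1), period = 1L)
  p2 <- vapply(seq_len(n), vals, numeric(1), period = 2L)
  make_metric_table(subject, sequence, p1, p2)
}
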