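test_that("ISCV maps the residual mean square as 100*sqrt(exp(s2)-1)", {
  expect_equal(iscv_from_mse(0), 0)
  expect_equal(iscv_from_mse(log(1.25)), 50, tolerance = 1e-9)
  expect_equal(iscv_from_mse(0.25), 53.294, tolerance = 1e-3)
  expect_error(iscv_from_mse(-0.1), "numeric error")
  # inverse map round-trips
  expect_equal(iscv_from_mse(bepilot:::iscv_to_variance(50)), 50,
               tolerance = 1e-12)
})

test_that("crossover ANOVA matches the normal-equations oracle", {
  skip_if_not_installed("MASS")
  set.seed(2024)
  for (sizes in list(c(2, 2), c(3, 3), c(3, 2), c(5, 4))) {
    tab <- random_metric_table(sizes[1L], sizes[2L])
    got <- suppressWarnings(run_abe(tab, "cmax"))
    want <- oracle_abe(tab)
    expect_equal(got$gmr_pct, want$gmr_pct, tolerance = 1e-9)
    expect_equal(got$ci90_pct, want$ci90_pct, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(got$mse, want$mse, tolerance = 1e-9)
    expect_equal(got$df_resid, want$df_resid)
    expect_equal(got$lsm_test, want$lsm_test, tolerance = 1e-9)
    expect_equal(got$lsm_ref, want$lsm_ref, tolerance = 1e-9)
    # internal consistency: GMR = 100 * LSM_T / LSM_R, CI contains GMR
    expect_equal(got$gmr_pct, 100 * got$lsm_test / got$lsm_ref,
                 tolerance = 1e-12)
    expect_true(got$ci90_pct[1L] <= got$gmr_pct &&
                  got$gmr_pct <= got$ci90_pct[2L])
    expect_equal(got$iscv_pct, iscv_from_mse(got$mse))
  }
})

test_that("balanced complete data reduce to within-subject differences", {
  set.seed(7)
  tab <- random_metric_table(6, 6, sigma_w = 0.4, gmr = 1.1)
  got <- suppressWarnings(run_abe(tab, "cmax", anova_table = TRUE))

  # closed form: formulation effect is the average over sequences of the
  # mean within-subject (Test - Reference) ln difference
  w <- reshape(tab[c("subject", "sequence", "formulation", "cmax_ng_ml")],
               direction = "wide", idvar = c("subject", "sequence"),
               timevar = "formulation")
  d <- log(w$cmax_ng_ml.Test) - log(w$cmax_ng_ml.Reference)
  m_tr <- mean(d[w$sequence == "TR"]); m_rt <- mean(d[w$sequence == "RT"])
  expect_equal(got$gmr_pct, 100 * exp((m_tr + m_rt) / 2),
               tolerance = 1e-12)
  s2 <- (sum((d[w$sequence == "TR"] - m_tr)^2) +
           sum((d[w$sequence == "RT"] - m_rt)^2)) / (nrow(w) - 2) / 2
  expect_equal(got$mse, s2, tolerance = 1e-12)
  expect_equal(got$df_resid, nrow(w) - 2L)

  # ANOVA table bookkeeping: df and SS decompose the total
  at <- got$anova_table
  expect_equal(sum(at$df), nrow(tab) - 1L)
  total_ss <- sum((log(tab$cmax_ng_ml) - mean(log(tab$cmax_ng_ml)))^2)
  expect_equal(sum(at$ss), total_ss, tolerance = 1e-12)
  expect_identical(at$term, c("Sequence", "Subject(Sequence)", "Period",
                              "Formulation", "Residual"))
})

test_that("GMR is invariant to period relabeling without a period effect", {
  set.seed(12)
  n <- 8
  subj <- rnorm(n, log(500), 0.4)
  eT <- rnorm(n, 0, 0.3); eR <- rnorm(n, 0, 0.3)
  sequence <- rep(c("TR", "RT"), each = n / 2)
  val <- function(i, period) {
    form <- bepilot:::expected_formulation(sequence[i], period)
    exp(subj[i] + if (form == "Test") eT[i] else eR[i])
  }
  p1 <- vapply(1:n, val, numeric(1), period = 1L)
  p2 <- vapply(1:n, val, numeric(1), period = 2L)
  tab <- make_metric_table(sprintf("P%02d", 1:n), sequence, p1, p2)
  # relabel: flip each subject's sequence and swap its periods; every
  # subject keeps the same Test and Reference values
  flipped <- make_metric_table(sprintf("P%02d", 1:n),
                               ifelse(sequence == "TR", "RT", "TR"),
                               p2, p1)
  g1 <- suppressWarnings(run_abe(tab, "cmax"))
  g2 <- suppressWarnings(run_abe(flipped, "cmax"))
  expect_equal(g1$gmr_pct, g2$gmr_pct, tolerance = 1e-9)
})

test_that("degenerate identical Test/Reference data give GMR 100, MSE 0", {
  vals <- exp(rnorm(6, log(1000), 0.5))
  tab <- make_metric_table(sprintf("D%d", 1:6),
                           rep(c("TR", "RT"), each = 3), vals, vals)
  got <- suppressWarnings(run_abe(tab, "cmax"))
  expect_equal(got$gmr_pct, 100, tolerance = 1e-9)
  expect_equal(got$mse, 0, tolerance = 1e-12)
  expect_equal(diff(got$ci90_pct), 0, tolerance = 1e-9)
})

test_that("data and design errors are reported", {
  tab <- random_metric_table(3, 3)
  tab$cmax_ng_ml[1L] <- -1
  expect_error(suppressWarnings(run_abe(tab, "cmax")), "data error")
  one_seq <- random_metric_table(4, 3)
  one_seq <- one_seq[one_seq$sequence == "TR", ]
  expect_error(suppressWarnings(run_abe(one_seq, "cmax")), "design error")
})

test_that("bioequivalence decision uses the closed 80.00-125.00 interval", {
  mk <- function(lo, hi) structure(list(ci90_pct = c(lo, hi)),
                                   class = "abe_result")
  expect_true(be_decision(mk(89.04, 114.60))$bioequivalent)
  expect_false(be_decision(mk(81.76, 132.21))$bioequivalent)
  expect_true(be_decision(mk(80.00, 125.00))$bioequivalent)
  expect_false(be_decision(mk(79.999, 124))$bioequivalent)
})
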