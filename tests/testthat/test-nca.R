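test_that("Cmax and tmax follow the earliest-maximum convention", {
  expect_equal(cmax_tmax(c(0, 1, 2, 3), c(0, 5, 10, 8)),
               list(cmax = 10, tmax_h = 2))
  expect_equal(cmax_tmax(c(0, 1, 2, 3), c(0, 5, 10, 10))$tmax_h, 2)
  expect_equal(cmax_tmax(1, 7), list(cmax = 7, tmax_h = 1))
  expect_null(cmax_tmax(c(0, 1), c(NA, NA)))
  expect_null(cmax_tmax(c(0, 1), c(0, 0)))
})

test_that("AUC applies linear-up / log-down segment rules", {
  # rise then flat: both segments linear -> 5 + 10
  expect_equal(auc_0_72(c(0, 1, 2), c(0, 10, 10), end_h = 2)$auc, 15)
  # falling segment uses the log trapezoid: 5 + 5/ln(2)
  expect_equal(auc_0_72(c(0, 1, 2), c(0, 10, 5), end_h = 2)$auc,
               5 + 5 / log(2), tolerance = 1e-12)
  expect_equal(auc_0_72(c(0, 1, 2), c(0, 10, 5), end_h = 2)$auc,
               12.2135, tolerance = 1e-4)
  # all-linear option
  expect_equal(auc_0_72(c(0, 1, 2), c(0, 10, 5), end_h = 2,
                        method = "linear")$auc, 12.5)
  # all-zero profile integrates to zero
  expect_equal(auc_0_72(c(0, 1, 2), c(0, 0, 0), end_h = 2)$auc, 0)
  expect_null(auc_0_72(c(0, 1), c(0, NA)))
  # truncation short of 72 h is flagged non-evaluable
  expect_warning(a <- auc_0_72(c(0, 24, 48), c(0, 10, 5)), "truncated")
  expect_false(a$evaluable)
  expect_equal(a$end_used_h, 48)
})

test_that("AUC is additive and invariant to on-interpolant points", {
  t <- c(0, 1, 2, 4, 8)
  c0 <- c(0, 8, 10, 6, 2)
  full <- auc_0_72(t, c0, end_h = 8)$auc
  left <- auc_0_72(t[1:3], c0[1:3], end_h = 2)$auc
  right <- auc_0_72(t[3:5], c0[3:5], end_h = 8)$auc
  expect_equal(full, left + right, tolerance = 1e-12)

  # inserting the linear midpoint of a rising segment changes nothing
  t2 <- c(0, 0.5, 1, 2, 4, 8); c2 <- c(0, 4, 8, 10, 6, 2)
  expect_equal(auc_0_72(t2, c2, end_h = 8)$auc, full, tolerance = 1e-12)
  # inserting the log-interpolant point of a falling segment too
  c_mid <- exp((log(10) + log(6)) / 2)  # at t = 3, geometric midpoint
  t3 <- c(0, 1, 2, 3, 4, 8); c3 <- c(0, 8, 10, c_mid, 6, 2)
  expect_equal(auc_0_72(t3, c3, end_h = 8)$auc, full, tolerance = 1e-12)
})

test_that("terminal slope regression recovers exact exponentials", {
  t <- c(0, 1, 2, 24, 48, 72)
  conc <- c(0, 50, 100, 100 * exp(-0.1 * 24), 100 * exp(-0.1 * 48),
            100 * exp(-0.1 * 72))
  lz <- lambda_z(t, conc, tmax_h = 2)
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(lz$t_half_h, log(2) / 0.1, tolerance = 1e-12)
  expect_equal(lz$n_points, 3L)

  # flat tail: zero slope is not an admissible terminal phase
  flat <- lambda_z(c(0, 1, 2, 4, 8, 12), c(0, 5, 10, 7, 7, 7), tmax_h = 2)
  expect_true(is.na(flat$lambda_z))
  # fewer than 3 points after tmax
  expect_true(is.na(lambda_z(c(0, 1, 2, 4), c(0, 5, 10, 7), 2)$lambda_z))
})

test_that("NCA on noiseless model curves recovers the model constants", {
  ps <- study_preset("pazopanib_200", n_subjects = 4L)
  st <- simulate_study(ps$params, variability_spec(), ps$design, seed = 2)
  nca <- run_nca(st)
  expect_true(all(nca$evaluable))
  # lambda_z within 2% of ke, tmax within one grid step of closed form
  expect_equal(nca$lambda_z_per_h, rep(ps$params$ke, nrow(nca)),
               tolerance = 0.02)
  t_star <- tmax_closed_form(ps$params$ka, ps$params$ke)
  grid <- ps$design$nominal_times_h
  step <- max(diff(grid[grid <= 5]))
  expect_true(all(abs(nca$tmax_h - t_star) <= step + 1e-9))
})

test_that("BLQ rules: leading zeros, bridged gaps, lost 72 h sample", {
  st <- make_dataset(list(
    A = list(sequence = "TR", p1 = c(NA, 10, NA, 6), p2 = c(NA, 8, 12, 9)),
    B = list(sequence = "RT", p1 = c(NA, 4, 8, 6), p2 = c(NA, 5, 7, NA))),
    times = c(0, 1, 2, 3))
  nca <- suppressWarnings(run_nca(st, end_h = 3))
  a1 <- nca[nca$subject == "A" & nca$period == 1L, ]
  # leading BLQ -> 0; embedded BLQ bridged: linear 0->10 (5), then the
  # interval 1->3 h spans the missing point: log-down 10->6
  expect_equal(a1$auc0_72_ng_h_ml, 5 + 2 * (10 - 6) / log(10 / 6),
               tolerance = 1e-12)
  expect_true(a1$evaluable)
  # trailing BLQ drops the 3 h sample -> truncated, non-evaluable
  b2 <- nca[nca$subject == "B" & nca$period == 2L, ]
  expect_false(b2$evaluable)

  # a fully BLQ occasion fails NCA
  allblq <- make_dataset(list(
    A = list(sequence = "TR", p1 = c(NA, NA, NA, NA),
             p2 = c(NA, 8, 12, 9)),
    B = list(sequence = "RT", p1 = c(NA, 4, 8, 6), p2 = c(NA, 5, 7, 5))))
  nb <- run_nca(allblq, end_h = 3)
  expect_true(is.na(nb$cmax_ng_ml[nb$subject == "A" & nb$period == 1L]))
  expect_identical(completers(allblq), "B")
})

test_that("simulated terminal half-life sits at the studied scale", {
  ps <- study_preset("pazopanib_200", n_subjects = 200L)
  st <- simulate_study(ps$params, ps$var, ps$design, seed = 17)
  nca <- run_nca(st)
  # observed single-dose half-life for this drug is in the 40-45 h range;
  # order-of-magnitude agreement for the simulated preset
  expect_gt(mean(nca$t_half_h, na.rm = TRUE), 30)
  expect_lt(mean(nca$t_half_h, na.rm = TRUE), 55)
})
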