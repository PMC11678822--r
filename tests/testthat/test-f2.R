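test_that("mean profiles average completers with the leading-BLQ rule", {
  st <- make_dataset(list(
    A = list(sequence = "TR", p1 = c(NA, 10, 20, 15), p2 = c(NA, 8, 16, 12)),
    B = list(sequence = "RT", p1 = c(NA, 20, 30, 25), p2 = c(NA, 16, 26, 21))))
  ref <- mean_profile(st, "Reference")
  # Reference occasions: A period 2 and B period 1
  expect_equal(ref$mean_conc, c(0, (8 + 20) / 2, (16 + 30) / 2,
                                (12 + 25) / 2))
  expect_equal(ref$n_subjects, 2L)

  # identical subjects: the mean equals the common profile
  same <- make_dataset(list(
    A = list(sequence = "TR", p1 = c(NA, 5, 9, 7), p2 = c(NA, 5, 9, 7)),
    B = list(sequence = "RT", p1 = c(NA, 5, 9, 7), p2 = c(NA, 5, 9, 7))))
  expect_equal(mean_profile(same, "Test")$mean_conc, c(0, 5, 9, 7))
})

test_that("normalisation scales to the Reference mean Cmax at its tmax", {
  st <- make_dataset(list(
    A = list(sequence = "TR", p1 = c(NA, 10, 20, 15), p2 = c(NA, 8, 16, 12)),
    B = list(sequence = "RT", p1 = c(NA, 20, 30, 25), p2 = c(NA, 16, 26, 21))))
  pair <- normalize_pair(mean_profile(st, "Reference"),
                         mean_profile(st, "Test"))
  expect_equal(pair$cmax_ref, 23)       # max of (0, 14, 23, 18.5)
  expect_equal(pair$tmax_ref_h, 2)      # truncated at the reference peak
  expect_equal(max(pair$times_h), 2)
  expect_equal(pair$ref_norm[pair$times_h == pair$tmax_ref_h], 100)
  expect_equal(pair$n_points, 2L)       # post-dose points only
  # worked scaling: a mean of half the normalising constant maps to 50.00
  expect_equal(100 * 6188.51 / 12377.02, 50, tolerance = 1e-4)
})

test_that("f2 arithmetic matches its closed forms", {
  mk_pair <- function(r, t, times = seq_along(r)) {
    structure(list(times_h = times, ref_norm = r, test_norm = t,
                   cmax_ref = 100, tmax_ref_h = max(times),
                   n_points = sum(times > 0)),
              class = "normalized_pair")
  }
  expect_equal(f2_factor(mk_pair(c(20, 60, 100), c(20, 60, 100)))$f2, 100)
  # constant 10-unit offset: 50*log10(100/sqrt(101)), independent of n
  for (n in c(3, 5, 9)) {
    got <- f2_factor(mk_pair(seq(40, 100, length.out = n),
                             seq(40, 100, length.out = n) - 10))$f2
    expect_equal(got, 50 * log10(100 / sqrt(101)), tolerance = 1e-9)
  }
  expect_equal(f2_factor(mk_pair(c(20, 60, 100), c(10, 50, 90)))$f2,
               49.89, tolerance = 1e-2)
  # single point at maximal disagreement
  expect_equal(f2_factor(mk_pair(100, 50, times = 1))$f2,
               50 * log10(100 / sqrt(2501)), tolerance = 1e-9)
  expect_equal(f2_factor(mk_pair(100, 50, times = 1))$f2, 15.05,
               tolerance = 1e-2)
  # symmetry in Test/Reference and monotone decay in the offset
  expect_equal(f2_factor(mk_pair(c(50, 100), c(40, 80)))$f2,
               f2_factor(mk_pair(c(40, 80), c(50, 100)))$f2)
  offs <- vapply(c(2, 5, 10, 20, 40), function(o)
    f2_factor(mk_pair(c(50, 100), c(50, 100) - o))$f2, numeric(1))
  expect_true(all(diff(offs) < 0))
  # the pre-dose point is excluded from the summation
  with0 <- mk_pair(c(0, 50, 100), c(0, 40, 90), times = c(0, 1, 2))
  no0 <- mk_pair(c(50, 100), c(40, 90), times = c(1, 2))
  expect_equal(f2_factor(with0)$f2, f2_factor(no0)$f2)
  expect_equal(f2_factor(with0)$n_points, 2L)
})

test_that("f2 is invariant to a common scaling of the raw profiles", {
  st <- make_dataset(list(
    A = list(sequence = "TR", p1 = c(NA, 10, 20, 15), p2 = c(NA, 8, 16, 12)),
    B = list(sequence = "RT", p1 = c(NA, 20, 30, 25), p2 = c(NA, 16, 26, 21))))
  base <- run_f2(st)$f2
  scaled_rec <- st$records
  scaled_rec$conc_ng_ml <- scaled_rec$conc_ng_ml * 7.3
  scaled <- study_dataset(scaled_rec,
                          study_config(st$lloq_ng_ml, st$dose_mg,
                                       st$nominal_times_h))
  expect_equal(run_f2(scaled)$f2, base, tolerance = 1e-12)
})

test_that("with no noise, f2 decreases as the true GMR leaves unity", {
  grid <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 12, 24, 48, 72)
  f2_at <- function(g) {
    p <- pk_params(ka = 1.25, t_half_h = 42, v_l = 25, dose_mg = 200,
                   gmr_true = g)
    st <- simulate_study(p, variability_spec(),
                         design_spec(4, grid, lloq_ng_ml = 1), seed = 1)
    run_f2(st)$f2
  }
  f2s <- vapply(c(1, 0.9, 0.8, 0.6, 0.45), f2_at, numeric(1))
  expect_equal(f2s[1L], 100)
  expect_true(all(diff(f2s) < 0))
  expect_gt(f2_at(1.0), 50)  # identical formulations are clearly similar
})

test_that("decision bands follow the highly-variable-drug rules", {
  expect_equal(confidence_band(79.00, 50.1)$band, "conf_gt90")
  expect_equal(confidence_band(53.51, 41.7)$band, "conf_gt90")
  expect_equal(confidence_band(34.9, 55)$band, "below_cutoff")
  expect_equal(confidence_band(43, 55)$band, "conf_gt80")
  expect_equal(confidence_band(43, 45)$band, "conf_gt60")
  expect_equal(confidence_band(36, 45)$band, "conf_gt60")
  expect_false(confidence_band(43, 45)$outside_tabulated)
  # gap in the tabulated scenarios: f2 in [35, 50) with ISCV <= 40
  gap <- confidence_band(43, 35)
  expect_true(gap$outside_tabulated)
  expect_equal(gap$band, "conf_gt60")
  # band thresholds are closed where stated
  expect_equal(confidence_band(50, 10)$band, "conf_gt90")
  expect_equal(confidence_band(41, 50)$band, "conf_gt80")
  expect_equal(confidence_band(35, 40.01)$band, "conf_gt60")
})
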