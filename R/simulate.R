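# Synthetic 2x2x2 crossover study generator: one-compartment oral model
# with lognormal between-subject and inter-occasion variability.

#' One-compartment oral-absorption model parameters
#'
#' First-order absorption and elimination:
#' \deqn{C(t) = \frac{F D k_a}{V (k_a - k_e)} (e^{-k_e t} - e^{-k_a t})}
#' with a single interior maximum at \eqn{t^* = \ln(k_a/k_e)/(k_a-k_e)}.
#' `v_l` is the apparent volume of distribution (V/F scale), so `f_ref`
#' defaults to 1 and acts as the relative-bioavailability handle: Test
#' occasions multiply it by `gmr_true`.
#'
#' @param ka Absorption rate constant (1/h).
#' @param v_l Apparent volume of distribution (L).
#' @param dose_mg Dose (mg).
#' @param ke Elimination rate constant (1/h); give either `ke` or
#'   `t_half_h`.
#' @param t_half_h Elimination half-life (h); `ke = ln(2)/t_half_h`.
#' @param f_ref Reference-product relative bioavailability (0 < F <= 1).
#' @param gmr_true True Test/Reference exposure ratio, applied
#'   multiplicatively to F for Test occasions.
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(ka, v_l, dose_mg, ke = NULL, t_half_h = NULL,
                      f_ref = 1, gmr_true = 1) {
  if (is.null(ke) == is.null(t_half_h))
    stop("give exactly one of ke or t_half_h")
  if (is.null(ke)) {
    stopifnot(is.numeric(t_half_h), t_half_h > 0)
    ke <- log(2) / t_half_h
  }
  stopifnot(ka > 0, ke > 0, v_l > 0, dose_mg > 0,
            f_ref > 0, f_ref <= 1, gmr_true > 0)
  if (ka == ke)
    stop("parameter error: ka must differ from ke ",
         "(flip-flop degenerate case refused)")
  structure(list(ka = ka, ke = ke, v_l = v_l, dose_mg = dose_mg,
                 f_ref = f_ref, gmr_true = gmr_true),
            class = "pk_params")
}

#' Variability specification for the study simulator
#'
#' All random deviates are lognormal with `sdlog = sqrt(ln(1 + CV^2))`.
#' Between-subject variability (BSV) applies to `ka`, `ke` and `V` once per
#' subject; within-subject (inter-occasion) variability applies to the
#' bioavailability fraction `F` and optionally to `ka` once per
#' subject-by-period occasion. Because `F` scales every concentration of an
#' occasion, the occasion-level CV on `F` is exactly the intra-subject CV
#' the downstream ANOVA estimates on ln-Cmax and ln-AUC (calibration
#' constant 1); occasion-level `ka` variability adds Cmax-specific noise on
#' top and defaults to 0.
#'
#' @param bsv_cv Named numeric vector of between-subject CV fractions for
#'   `ka`, `ke`, `v`.
#' @param wsv_cv Named numeric vector of within-subject CV fractions for
#'   `f`, `ka`.
#' @param period_effect Multiplicative shift applied to period-2
#'   concentrations (1 = no period effect).
#' @return An object of class `variability_spec`.
#' @export
variability_spec <- function(bsv_cv = c(ka = 0, ke = 0, v = 0),
                             wsv_cv = c(f = 0, ka = 0),
                             period_effect = 1) {
  bsv <- c(ka = 0, ke = 0, v = 0)
  bsv[names(bsv_cv)] <- bsv_cv
  wsv <- c(f = 0, ka = 0)
  wsv[names(wsv_cv)] <- wsv_cv
  stopifnot(all(bsv >= 0), all(wsv >= 0), period_effect > 0)
  structure(list(bsv_cv = bsv, wsv_cv = wsv, period_effect = period_effect),
            class = "variability_spec")
}

#' Crossover design specification
#'
#' @param n_subjects Even number of subjects, allocated n/2 per sequence
#'   (TR, RT).
#' @param nominal_times_h Sampling grid in hours (starts at 0, strictly
#'   increasing).
#' @param lloq_ng_ml Lower limit of quantification; simulated
#'   concentrations below it are censored to BLQ.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_subjects, nominal_times_h, lloq_ng_ml) {
  stopifnot(is.numeric(n_subjects), n_subjects >= 2)
  if (n_subjects %% 2 != 0)
    stop("design error: n_subjects must be even (balanced sequences)")
  check_time_grid(nominal_times_h)
  stopifnot(lloq_ng_ml > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 nominal_times_h = as.numeric(nominal_times_h),
                 lloq_ng_ml = lloq_ng_ml),
            class = "design_spec")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Concentration predicted by the one-compartment oral model
#'
#' @param params A [pk_params()] object.
#' @param t Time(s) post dose in hours (>= 0). Vectorised.
#' @param f Bioavailability fraction to use (defaults to `params$f_ref`).
#' @param ka,ke,v_l Optional overrides of the corresponding parameters
#'   (used internally for per-subject deviates).
#' @return Concentration(s) in ng/mL; `C(0) = 0`.
#' @export
concentration_curve <- function(params, t, f = params$f_ref,
                                ka = params$ka, ke = params$ke,
                                v_l = params$v_l) {
  stopifnot(inherits(params, "pk_params"), all(t >= 0))
  if (any(ka == ke))
    stop("parameter error: ka must differ from ke")
  dose_ng <- params$dose_mg * 1e6
  v_ml <- v_l * 1e3
  f * dose_ng * ka / (v_ml * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Time of the model's concentration maximum
#' @param ka,ke Absorption and elimination rate constants (1/h).
#' @return `ln(ka/ke) / (ka - ke)` in hours.
#' @export
tmax_closed_form <- function(ka, ke) log(ka / ke) / (ka - ke)

#' Simulate a 2x2x2 crossover study
#'
#' Draws per-subject parameter deviates and per-occasion bioavailability
#' (and optionally absorption-rate) deviates, samples each occasion's
#' concentration curve on the nominal grid, censors values below the LLOQ
#' to BLQ, and returns a validated [study_dataset()]. Sequences are
#' allocated deterministically (first half TR) and then shuffled under the
#' seed, so the design is balanced by construction. Bit-reproducible given
#' `seed`.
#'
#' @param params A [pk_params()] object.
#' @param var A [variability_spec()] object.
#' @param design A [design_spec()] object.
#' @param seed Integer seed for all randomness.
#' @param label Study label stored in the dataset.
#' @return A [study_dataset()].
#' @export
simulate_study <- function(params, var, design, seed, label = "simulated") {
  stopifnot(inherits(params, "pk_params"),
            inherits(var, "variability_spec"),
            inherits(design, "design_spec"),
            is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))

  n <- design$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  sequences <- sample(rep(c("TR", "RT"), each = n %/% 2L))

  bsd <- cv_to_sdlog(var$bsv_cv)
  wsd <- cv_to_sdlog(var$wsv_cv)
  ka_i <- params$ka * exp(stats::rnorm(n, 0, bsd[["ka"]]))
  ke_i <- params$ke * exp(stats::rnorm(n, 0, bsd[["ke"]]))
  v_i <- params$v_l * exp(stats::rnorm(n, 0, bsd[["v"]]))

  grid <- design$nominal_times_h
  rows <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (period in 1:2) {
      form <- expected_formulation(sequences[i], period)
      f_occ <- params$f_ref * exp(stats::rnorm(1L, 0, wsd[["f"]]))
      if (form == "Test") f_occ <- f_occ * params$gmr_true
      if (period == 2L) f_occ <- f_occ * var$period_effect
      ka_occ <- ka_i[i] * exp(stats::rnorm(1L, 0, wsd[["ka"]]))
      conc <- concentration_curve(params, grid, f = f_occ,
                                  ka = ka_occ, ke = ke_i[i], v_l = v_i[i])
      blq <- conc < design$lloq_ng_ml
      conc[blq] <- NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(subject = ids[i], sequence = sequences[i],
                              period = period, formulation = form,
                              time_h = grid, conc_ng_ml = conc, blq = blq,
                              stringsAsFactors = FALSE)
    }
  }
  cfg <- study_config(lloq_ng_ml = design$lloq_ng_ml,
                      dose_mg = params$dose_mg,
                      nominal_times_h = grid, label = label)
  study_dataset(do.call(rbind, rows), cfg)
}

# Sampling schedule used across all four pazopanib studies: 20 venous
# samples per period, pre-dose through 72 h.
PAZOPANIB_GRID <- c(0, 0.50, 1.00, 1.50, 2.00, 2.50, 2.75, 3.00, 3.25,
                    3.50, 4.00, 4.50, 5.00, 6.00, 8.00, 10.00, 12.00,
                    24.00, 48.00, 72.00)

#' Built-in simulation presets
#'
#' `pazopanib_200` / `pazopanib_400` emulate the single-dose pilot studies
#' of a highly variable BCS class 2 drug: apparent V = 25 L, terminal
#' half-life 42 h, tmax about 3.5 h, intra-subject CV 50% on Cmax/AUC,
#' n = 24 on the 20-point 0-72 h grid, LLOQ 50 (200 mg) or 100 (400 mg)
#' ng/mL. `validation` mirrors the short-half-life setting under which the
#' Cmax f2 decision bands were originally calibrated: t1/2 = 4.6 h,
#' V = 60 L, intra-subject CV 30%.
#'
#' @param name One of `"pazopanib_200"`, `"pazopanib_400"`, `"validation"`.
#' @param n_subjects Number of subjects (default 24, the pilot design).
#' @param iscv_pct Target intra-subject CV in percent on Cmax/AUC
#'   (occasion-level CV on F).
#' @param gmr_true True Test/Reference ratio.
#' @return A list with elements `params`, `var`, `design`.
#' @export
study_preset <- function(name = c("pazopanib_200", "pazopanib_400",
                                  "validation"),
                         n_subjects = 24L, iscv_pct = NULL, gmr_true = 1) {
  name <- match.arg(name)
  base <- switch(name,
    pazopanib_200 = list(ka = 1.25, t_half_h = 42, v_l = 25, dose_mg = 200,
                         lloq = 50, iscv = 50),
    pazopanib_400 = list(ka = 1.25, t_half_h = 42, v_l = 25, dose_mg = 400,
                         lloq = 100, iscv = 50),
    validation = list(ka = 1.0, t_half_h = 4.6, v_l = 60, dose_mg = 200,
                      lloq = 50, iscv = 30))
  iscv <- (iscv_pct %||% base$iscv) / 100
  list(params = pk_params(ka = base$ka, t_half_h = base$t_half_h,
                          v_l = base$v_l, dose_mg = base$dose_mg,
                          gmr_true = gmr_true),
       var = variability_spec(bsv_cv = c(ka = 0.30, ke = 0.25, v = 0.25),
                              wsv_cv = c(f = iscv, ka = 0)),
       design = design_spec(n_subjects = n_subjects,
                            nominal_times_h = PAZOPANIB_GRID,
                            lloq_ng_ml = base$lloq))
}
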