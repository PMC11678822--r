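# Crossover study container, validation and CSV I/O.

STUDY_COLUMNS <- c("subject", "sequence", "period", "formulation",
                   "time_h", "conc_ng_ml", "blq")

#' Study configuration
#'
#' Bundles the assay and design constants attached to a concentration-time
#' dataset: the lower limit of quantification of the bioanalytical method,
#' the administered dose, and (optionally) the nominal sampling grid.
#'
#' @param lloq_ng_ml Lower limit of quantification in ng/mL (> 0).
#' @param dose_mg Administered dose in mg (> 0).
#' @param nominal_times_h Optional strictly increasing nominal sampling grid
#'   in hours, starting at 0. When `NULL`, [read_study()] infers the grid
#'   from the observed times.
#' @param label Free-text study label.
#' @return An object of class `study_config`.
#' @export
study_config <- function(lloq_ng_ml, dose_mg, nominal_times_h = NULL,
                         label = "") {
  stopifnot(is.numeric(lloq_ng_ml), length(lloq_ng_ml) == 1L,
            is.finite(lloq_ng_ml), lloq_ng_ml > 0,
            is.numeric(dose_mg), length(dose_mg) == 1L,
            is.finite(dose_mg), dose_mg > 0)
  if (!is.null(nominal_times_h)) check_time_grid(nominal_times_h)
  structure(list(lloq_ng_ml = lloq_ng_ml, dose_mg = dose_mg,
                 nominal_times_h = nominal_times_h,
                 label = as.character(label)),
            class = "study_config")
}

#' Read a study configuration from a YAML key-value file
#'
#' Recognised keys: `lloq_ng_ml`, `dose_mg`, `nominal_times_h`, `label`.
#'
#' @param path Path to a YAML file.
#' @return A [study_config()] object.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg),
                     c("lloq_ng_ml", "dose_mg", "nominal_times_h", "label"))
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  study_config(lloq_ng_ml = cfg$lloq_ng_ml, dose_mg = cfg$dose_mg,
               nominal_times_h = unlist(cfg$nominal_times_h),
               label = cfg$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2L || anyNA(times))
    stop("nominal time grid must be a numeric vector of length >= 2")
  if (times[1L] != 0)
    stop("nominal time grid must start at 0 (pre-dose)")
  if (any(diff(times) <= 0))
    stop("nominal time grid must be strictly increasing")
  invisible(times)
}

# Formulation implied by the 2x2x2 design: sequence TR doses Test in
# period 1, Reference in period 2; RT the reverse.
expected_formulation <- function(sequence, period) {
  ifelse((sequence == "TR") == (period == 1L), "Test", "Reference")
}

#' Construct a crossover concentration-time dataset
#'
#' Validates and normalises one 2x2x2 crossover study. `records` holds one
#' row per observed concentration with columns `subject`, `sequence`
#' (`"TR"`/`"RT"`), `period` (1/2), `formulation` (`"Test"`/`"Reference"`),
#' `time_h`, `conc_ng_ml` and `blq`. Below-quantification observations are
#' stored with a missing concentration and `blq = TRUE`; a measurement below
#' the LLOQ that is not flagged is an integrity error. A missing pre-dose
#' record is added as BLQ with a warning (single-dose study).
#'
#' @param records Data frame of observations (see Details).
#' @param config A [study_config()] object.
#' @return An object of class `study_dataset` with elements `records`,
#'   `nominal_times_h`, `lloq_ng_ml`, `dose_mg` and `label`.
#' @export
study_dataset <- function(records, config) {
  stopifnot(inherits(config, "study_config"), is.data.frame(records))
  missing_cols <- setdiff(STUDY_COLUMNS, names(records))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(records), STUDY_COLUMNS)
  if (length(unknown) > 0L)
    stop("unknown columns: ", paste(unknown, collapse = ", "))

  rec <- data.frame(subject = as.character(records$subject),
                    sequence = as.character(records$sequence),
                    period = as.integer(records$period),
                    formulation = as.character(records$formulation),
                    time_h = as.numeric(records$time_h),
                    conc_ng_ml = as.numeric(records$conc_ng_ml),
                    blq = as.logical(records$blq),
                    stringsAsFactors = FALSE)

  if (!all(rec$sequence %in% c("TR", "RT")))
    stop("sequence must be 'TR' or 'RT'")
  if (!all(rec$period %in% c(1L, 2L)))
    stop("period must be 1 or 2")
  if (anyNA(rec$blq)) stop("blq flag must be TRUE/FALSE (or 0/1)")
  bad_form <- rec$formulation != expected_formulation(rec$sequence, rec$period)
  if (any(bad_form))
    stop("integrity error: formulation inconsistent with sequence/period ",
         "for subject(s) ",
         paste(unique(rec$subject[bad_form]), collapse = ", "))

  seq_by_subj <- tapply(rec$sequence, rec$subject,
                        function(s) length(unique(s)))
  if (any(seq_by_subj > 1L))
    stop("integrity error: a subject is listed under two sequences")

  grid <- config$nominal_times_h %||% sort(unique(rec$time_h))
  check_time_grid(grid)
  if (!all(rec$time_h %in% grid))
    stop("integrity error: observation times outside the nominal grid: ",
         paste(utils::head(setdiff(unique(rec$time_h), grid)), collapse = ", "))

  key <- paste(rec$subject, rec$period, format(rec$time_h, digits = 15L))
  if (anyDuplicated(key))
    stop("integrity error: duplicate (subject, period, time) records")

  # BLQ convention: concentration absent; unflagged values must be
  # quantifiable (0 allowed only as an explicit pre-dose zero).
  if (any(!rec$blq & is.na(rec$conc_ng_ml)))
    stop("integrity error: missing concentration without BLQ flag")
  quant <- !rec$blq
  if (any(quant & !is.finite(rec$conc_ng_ml)))
    stop("integrity error: non-finite concentration")
  if (any(quant & rec$conc_ng_ml < 0))
    stop("integrity error: negative concentration")
  below <- quant & rec$conc_ng_ml > 0 & rec$conc_ng_ml < config$lloq_ng_ml
  if (any(below))
    stop("integrity error: quantifiable concentration below LLOQ; ",
         "flag such observations as BLQ")
  rec$conc_ng_ml[rec$blq] <- NA_real_

  # Require a pre-dose observation per subject x period.
  occ <- unique(rec[c("subject", "sequence", "period", "formulation")])
  has_t0 <- mapply(function(s, p) any(rec$subject == s & rec$period == p &
                                        rec$time_h == 0),
                   occ$subject, occ$period)
  if (!all(has_t0)) {
    warning("missing pre-dose sample(s); adding BLQ records at t = 0")
    add <- occ[!has_t0, , drop = FALSE]
    add$time_h <- 0
    add$conc_ng_ml <- NA_real_
    add$blq <- TRUE
    rec <- rbind(rec, add[STUDY_COLUMNS])
  }

  rec <- rec[order(rec$subject, rec$period, rec$time_h), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec,
                 nominal_times_h = as.numeric(grid),
                 lloq_ng_ml = config$lloq_ng_ml,
                 dose_mg = config$dose_mg,
                 label = config$label),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("2x2x2 crossover concentration-time dataset",
      if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  cat(sprintf("  subjects: %d enrolled, %d completers\n",
              length(subjects(x)), length(completers(x))))
  cat(sprintf("  nominal grid: %d timepoints, 0-%g h\n",
              length(x$nominal_times_h), max(x$nominal_times_h)))
  cat(sprintf("  LLOQ %g ng/mL, dose %g mg, %d records (%d BLQ)\n",
              x$lloq_ng_ml, x$dose_mg, nrow(x$records), sum(x$records$blq)))
  invisible(x)
}

#' Subjects present in a dataset
#' @param dataset A `study_dataset`.
#' @return Character vector of subject identifiers.
#' @export
subjects <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  sort(unique(dataset$records$subject))
}

#' Completers of a crossover study
#'
#' A completer provided evaluable pharmacokinetic data for both the Test and
#' the Reference product: both periods are present and each contains at
#' least one quantifiable concentration. All downstream statistics
#' (non-compartmental summaries, the bioequivalence ANOVA, mean profiles for
#' the f2 factor) are computed on completers only.
#'
#' @param dataset A `study_dataset`.
#' @return Character vector of completer subject identifiers (possibly
#'   empty).
#' @export
completers <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0L) return(character(0L))
  ok <- rec[!rec$blq & !is.na(rec$conc_ng_ml) & rec$conc_ng_ml > 0, ]
  tab <- unique(ok[c("subject", "period")])
  counts <- table(tab$subject)
  sort(names(counts)[counts == 2L])
}

#' Read a crossover study from CSV
#'
#' Expects the long layout written by [write_study()]: one row per observed
#' concentration with columns
#' `subject,sequence,period,formulation,time_h,conc_ng_ml,blq`; BLQ rows
#' carry an empty concentration cell and `blq = 1`.
#'
#' @param path CSV file path.
#' @param config A [study_config()] object.
#' @return A validated [study_dataset()].
#' @export
read_study <- function(path, config) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject = "character"))
  if (!setequal(names(raw), STUDY_COLUMNS))
    stop("schema error: expected columns ",
         paste(STUDY_COLUMNS, collapse = ","), "; found ",
         paste(names(raw), collapse = ","))
  study_dataset(raw[STUDY_COLUMNS], config)
}

#' Write a crossover study to CSV
#'
#' Emits the long CSV dialect read by [read_study()]. Concentrations are
#' written with 17 significant digits so that a read of the written file
#' reproduces the dataset exactly; BLQ observations are written with an
#' empty concentration cell and flag `1`.
#'
#' @param dataset A `study_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_study <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  rec <- dataset$records
  quant <- !rec$blq
  if (any(quant & !is.finite(rec$conc_ng_ml)))
    stop("refusing to write non-finite concentrations")
  out <- data.frame(subject = rec$subject,
                    sequence = rec$sequence,
                    period = rec$period,
                    formulation = rec$formulation,
                    time_h = sprintf("%.17g", rec$time_h),
                    conc_ng_ml = ifelse(rec$blq, "",
                                        sprintf("%.17g", rec$conc_ng_ml)),
                    blq = as.integer(rec$blq),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
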