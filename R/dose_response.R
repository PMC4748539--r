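#' @title FAC dilution series and sensitivity classification
#' @name dose_response
#' @description The fixed-ratio FAC concentration ladder, per-readout
#'   effect flags, threshold-dilution calling, and the
#'   sensitive/intermediate/resistant classification with cohort
#'   aggregation.
NULL

#' Build the FAC dilution table
#'
#' Eleven rows: dilutions 1 (strongest) to 10 (weakest) plus the untreated
#' control (11, all zero). The three components 5-fluorouracil, doxorubicin
#' and 4-hydroperoxycyclophosphamide are held at the clinical molar ratio
#' 46:1:22 in every row; successive dilutions follow the repeating
#' divide-by-2, 2, 2.5 pattern, so concentrations fall one decade every
#' three steps.
#'
#' @param top_c_dox Doxorubicin concentration (uM) of dilution 1.
#' @param ratio Molar ratio (5-FU, doxorubicin, 4-HC).
#' @return Data frame of class `dilution_series` with columns `dilution`,
#'   `c_5fu_um`, `c_dox_um`, `c_4hc_um`; the ratio is kept as an attribute.
#' @export
#' @examples
#' build_dilution_table()[4, ]   # 46, 1, 22 uM
build_dilution_table <- function(top_c_dox = 10, ratio = c(46, 1, 22)) {
  if (top_c_dox <= 0) stop("top_c_dox must be > 0", call. = FALSE)
  if (length(ratio) != 3 || any(ratio <= 0))
    stop("ratio must be three positive numbers", call. = FALSE)
  steps <- rep(c(2, 2, 2.5), length.out = 9)
  c_dox <- top_c_dox / cumprod(c(1, steps))
  c_dox <- c(c_dox, 0)                       # dilution 11 = control
  out <- data.frame(dilution = 1:11,
                    c_5fu_um = c_dox * ratio[1] / ratio[2],
                    c_dox_um = c_dox,
                    c_4hc_um = c_dox * ratio[3] / ratio[2])
  attr(out, "molar_ratio") <- ratio
  class(out) <- c("dilution_series", "data.frame")
  out
}

#' Per-dilution readout series
#'
#' Bundles the per-dilution slice statistics of one tumor for one readout
#' together with its untreated-control statistics. For the morphology
#' readout the values are manual binary calls (aberrant nuclear morphology
#' present/absent, scored by a pathologist); for EdU and TUNEL they are the
#' slice medians, and the control summary is required.
#'
#' @param readout One of `"morphology"`, `"edu"`, `"tunel"`.
#' @param dilutions Integer dilution indices (unique, control excluded).
#' @param values Per-dilution values: logical calls for morphology, numeric
#'   medians otherwise.
#' @param control_median,control_iqr Untreated-control (dilution 11)
#'   statistics; required for edu/tunel.
#' @return An object of class `readout_series`.
#' @export
readout_series <- function(readout = c("morphology", "edu", "tunel"),
                           dilutions, values,
                           control_median = NULL, control_iqr = NULL) {
  readout <- match.arg(readout)
  dilutions <- as.integer(dilutions)
  if (anyDuplicated(dilutions)) stop("dilution indices must be unique",
                                     call. = FALSE)
  if (any(dilutions < 1 | dilutions > 10))
    stop("tested dilutions must lie in 1..10", call. = FALSE)
  if (length(values) != length(dilutions))
    stop("values and dilutions must have equal length", call. = FALSE)
  if (readout != "morphology" && is.null(control_median))
    stop("missing control: ", readout,
         " series requires the dilution-11 summary", call. = FALSE)
  structure(list(readout = readout, dilutions = dilutions, values = values,
                 control_median = control_median, control_iqr = control_iqr),
            class = "readout_series")
}

#' Flag dilutions with inhibited proliferation
#'
#' A dilution is flagged inhibited when its slice-median proliferation
#' index falls below `criterion_fraction` times the untreated-control
#' median (default one half).
#'
#' @param series An EdU [readout_series()].
#' @param criterion_fraction Fraction of the control median below which
#'   proliferation counts as inhibited.
#' @return Named logical vector over the tested dilutions.
#' @export
edu_effect_flags <- function(series, criterion_fraction = 0.5) {
  stopifnot(inherits(series, "readout_series"))
  if (series$readout != "edu") stop("series readout must be 'edu'",
                                    call. = FALSE)
  if (is.null(series$control_median)) stop("missing control", call. = FALSE)
  flags <- series$values < criterion_fraction * series$control_median
  setNames(as.logical(flags), series$dilutions)
}

#' Flag dilutions with induced cell death
#'
#' A dilution is flagged when its slice-median TUNEL percentage exceeds the
#' control median by more than `k` control interquartile ranges (default
#' 1.5) — an outlier-style criterion against the control's own field-to-
#' field dispersion.
#'
#' @param series A TUNEL [readout_series()].
#' @param k Multiplier of the control IQR.
#' @return Named logical vector over the tested dilutions.
#' @export
tunel_effect_flags <- function(series, k = 1.5) {
  stopifnot(inherits(series, "readout_series"))
  if (series$readout != "tunel") stop("series readout must be 'tunel'",
                                      call. = FALSE)
  if (is.null(series$control_median) || is.null(series$control_iqr))
    stop("missing control", call. = FALSE)
  flags <- series$values > series$control_median + k * series$control_iqr
  setNames(as.logical(flags), series$dilutions)
}

#' Call the threshold dilution from per-dilution flags
#'
#' The threshold is the weakest (most dilute, largest index) dilution `d*`
#' such that the effect is flagged at `d*` and at every tested dilution
#' stronger than it — an unbroken run starting at the strongest tested
#' dilution. With no flagged dilution the threshold is `NA`. Flags at
#' weaker dilutions that are separated from the run (a non-monotone series,
#' which the assay's dose-effect logic does not expect) are ignored with a
#' warning.
#'
#' @param flags Named logical vector; names are tested dilution indices
#'   (control excluded).
#' @return Integer threshold dilution, or `NA_integer_`.
#' @export
#' @examples
#' call_threshold(c(`2` = TRUE, `3` = TRUE, `4` = FALSE, `5` = FALSE,
#'                  `6` = FALSE, `7` = FALSE))  # 3
call_threshold <- function(flags) {
  if (!length(flags)) stop("empty flag set", call. = FALSE)
  if (is.null(names(flags))) stop("flags must be named by dilution index",
                                  call. = FALSE)
  d <- as.integer(names(flags))
  ord <- order(d)                # strongest (lowest index) first
  d <- d[ord]; fl <- as.logical(flags[ord])
  if (anyNA(fl)) stop("flags must be TRUE/FALSE", call. = FALSE)
  run_len <- match(FALSE, fl, nomatch = length(fl) + 1L) - 1L
  if (any(fl[seq_along(fl) > run_len]))
    warning("non-monotone flag series: isolated flags at weaker dilutions ",
            "ignored", call. = FALSE)
  if (run_len == 0L) return(NA_integer_)
  d[run_len]
}

#' Classify tumors from threshold dilutions
#'
#' A tumor is sensitive when its threshold dilution is at least
#' `sensitive_min` (the effect already appears at very dilute drug),
#' resistant when the threshold is at most `resistant_max` or absent (the
#' effect appears only at the strongest concentrations, or never), and
#' intermediate otherwise. Applied per readout; vectorized.
#'
#' @param threshold Integer vector of threshold dilutions (`NA` = none).
#' @param sensitive_min Minimum threshold called sensitive (default 7).
#' @param resistant_max Maximum threshold called resistant (default 2).
#' @return Character vector: `"sensitive"`, `"intermediate"`,
#'   `"resistant"`.
#' @export
classify_tumor <- function(threshold, sensitive_min = 7L,
                           resistant_max = 2L) {
  out <- ifelse(is.na(threshold) | threshold <= resistant_max, "resistant",
                ifelse(threshold >= sensitive_min, "sensitive",
                       "intermediate"))
  if (!is.null(names(threshold))) names(out) <- names(threshold)
  out
}

#' Per-tumor response profile
#'
#' @param tumor_id Character id.
#' @param thresholds Named integer vector of threshold dilutions per
#'   readout (e.g. `c(morphology = 5, edu = 5, tunel = 5)`; `NA` = none).
#' @param ... Passed to [classify_tumor()].
#' @return Object of class `tumor_response_profile` with per-readout
#'   `threshold` and `response_class`.
#' @export
tumor_response_profile <- function(tumor_id, thresholds, ...) {
  if (is.null(names(thresholds)))
    stop("thresholds must be named by readout", call. = FALSE)
  structure(list(tumor_id = as.character(tumor_id),
                 threshold = thresholds,
                 response_class = classify_tumor(thresholds, ...)),
            class = "tumor_response_profile")
}

#' Cohort histogram of threshold dilutions
#'
#' Counts, per threshold dilution, the tumors whose chosen readout reached
#' its threshold there; tumors with a missing threshold are reported
#' separately, so counts always sum to the number of non-missing profiles.
#'
#' @param profiles List of [tumor_response_profile()] objects, or a data
#'   frame with a `tumor_id` column and one column per readout.
#' @param readout Readout to tabulate.
#' @return List with `counts` (named integer vector by dilution),
#'   `n_missing`, `n_total`.
#' @export
#' @examples
#' cohort_counts(fac_reference_cohort(), "morphology")$counts
cohort_counts <- function(profiles, readout = "morphology") {
  if (is.data.frame(profiles)) {
    if (!readout %in% names(profiles))
      stop("readout column `", readout, "` not found", call. = FALSE)
    thr <- profiles[[readout]]
  } else {
    if (!length(profiles)) stop("profiles must be non-empty", call. = FALSE)
    thr <- vapply(profiles, function(p) {
      v <- p$threshold[[readout]]
      if (is.null(v)) NA_integer_ else as.integer(v)
    }, integer(1))
  }
  present <- thr[!is.na(thr)]
  counts <- table(factor(present, levels = sort(unique(present))))
  list(counts = setNames(as.integer(counts), names(counts)),
       n_missing = sum(is.na(thr)), n_total = length(thr))
}

#' Reference breast-tumor cohort: FAC response thresholds
#'
#' Threshold dilutions of the 15-tumor reference cohort for the three
#' readouts (manual nuclear-morphology scoring on H&E, EdU proliferation,
#' TUNEL cell death), as published for the assay. One tumor lacks an EdU
#' threshold (not available). These values serve as printed inputs for
#' cohort aggregation and as ground-truth thresholds for simulation-based
#' validation.
#'
#' @return Data frame with columns `sample`, `histology`, `morphology`,
#'   `edu`, `tunel`.
#' @export
fac_reference_cohort <- function() {
  path <- system.file("extdata", "fac_cohort_thresholds.csv",
                      package = "slicetox", mustWork = TRUE)
  read.csv(path, colClasses = c(sample = "character"))
}

#' Call per-tumor thresholds from a table of quantified fields
#'
#' Groups quantified fields by tumor and dilution, summarizes each slice,
#' builds the per-tumor readout series against the dilution-11 control,
#' flags effects and calls the threshold dilution — the full
#' dose-response half of the pipeline downstream of image quantification.
#'
#' @param quants Data frame of [quantify_field()] rows with `tumor_id` and
#'   `dilution` columns, including control (dilution 11) fields.
#' @param readout `"edu"` or `"tunel"`.
#' @param criterion Criterion parameter passed to the flagger
#'   (`criterion_fraction` for EdU, `k` for TUNEL).
#' @return Data frame: `tumor_id`, `threshold`, `response_class`.
#' @export
call_cohort_thresholds <- function(quants, readout = c("edu", "tunel"),
                                   criterion = NULL) {
  readout <- match.arg(readout)
  stopifnot(is.data.frame(quants))
  col <- if (readout == "edu") "pi" else "tunel"
  tumors <- unique(quants$tumor_id)
  rows <- lapply(tumors, function(tid) {
    sub <- quants[quants$tumor_id == tid, , drop = FALSE]
    dils <- sort(unique(sub$dilution))
    if (!11L %in% dils)
      stop("missing control (dilution 11) for tumor ", tid, call. = FALSE)
    summ <- do.call(rbind, lapply(dils, function(d)
      summarize_slice(sub[sub$dilution == d, , drop = FALSE])))
    ctrl <- summ[summ$dilution == 11L, ]
    tested <- summ[summ$dilution != 11L, ]
    series <- readout_series(readout, tested$dilution,
                             tested[[paste0(col, "_median")]],
                             control_median = ctrl[[paste0(col, "_median")]],
                             control_iqr = ctrl[[paste0(col, "_iqr")]])
    flags <- if (readout == "edu") {
      if (is.null(criterion)) edu_effect_flags(series)
      else edu_effect_flags(series, criterion)
    } else {
      if (is.null(criterion)) tunel_effect_flags(series)
      else tunel_effect_flags(series, criterion)
    }
    thr <- withCallingHandlers(call_threshold(flags),
                               warning = function(w) invokeRestart("muffleWarning"))
    data.frame(tumor_id = tid, threshold = thr,
               response_class = classify_tumor(thr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
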