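#' Simulate a dose-response experiment and quantify every field
#'
#' The streaming counterpart of [generate_cohort()] + [quantify_field()]:
#' for each tumor, dilution and field it renders the synthetic field under
#' a derived sub-seed, quantifies it immediately and discards the rasters,
#' so cohort-scale sweeps run in constant memory. Ground-truth fractions
#' and member counts are carried into the output table.
#'
#' @inheritParams generate_cohort
#' @param n_fields Fields per slice.
#' @param params A [segmentation_params()] object.
#' @return Data frame, one row per field: quantification columns from
#'   [quantify_field()] plus `expected_*`/`realized_*` fractions and truth
#'   member counts.
#' @export
simulate_response_experiment <- function(profiles, dilutions = c(2:7, 11L),
                                         n_fields = 10L,
                                         spec = field_spec(),
                                         day = 3L,
                                         series = build_dilution_table(),
                                         seed = 1L,
                                         params = segmentation_params()) {
  if (!length(profiles)) stop("profiles must be a non-empty list",
                              call. = FALSE)
  if (inherits(profiles, "tumor_sim_profile")) profiles <- list(profiles)
  rows <- vector("list", length(profiles) * length(dilutions) * n_fields)
  counter <- 0L
  idx <- 0L
  for (p in profiles) {
    for (d in dilutions) {
      expected <- dose_effect_model(p, d, series)
      counter <- counter + 1L
      fracs <- with_seed(sub_seed(seed, counter * 1000L), {
        cbind(edu = rbeta_meansd(n_fields, expected[["edu_fraction"]],
                                 p$heterogeneity_sd),
              tunel = rbeta_meansd(n_fields, expected[["tunel_fraction"]],
                                   p$heterogeneity_sd))
      })
      for (f in seq_len(n_fields)) {
        counter <- counter + 1L
        fs <- spec
        fs$edu_fraction <- fracs[f, "edu"]
        fs$tunel_fraction <- fracs[f, "tunel"]
        fs$seed <- as.integer(sub_seed(seed, counter) %% .Machine$integer.max)
        gen <- generate_field(fs)
        gen$field$meta <- list(tumor_id = p$tumor_id, dilution = d, day = day,
                               field_id = sprintf("%s_d%02d_f%02d",
                                                  p$tumor_id, d, f),
                               seed = fs$seed)
        q <- quantify_field(gen$field, params)
        q$expected_edu_fraction <- unname(expected["edu_fraction"])
        q$expected_tunel_fraction <- unname(expected["tunel_fraction"])
        q$realized_edu_fraction <- unname(fracs[f, "edu"])
        q$realized_tunel_fraction <- unname(fracs[f, "tunel"])
        q$n_edu_members <- length(gen$truth$edu_members)
        q$n_tunel_members <- length(gen$truth$tunel_members)
        q$true_keratin_px <- sum(gen$truth$keratin_mask)
        idx <- idx + 1L
        rows[[idx]] <- q
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(idx)])
  rownames(out) <- NULL
  out
}

#' Quantify all fields of a cohort held in memory
#'
#' @param cohort A `slice_cohort` from [generate_cohort()] with
#'   `keep_images = TRUE`.
#' @param params A [segmentation_params()] object.
#' @return Data frame of [quantify_field()] rows.
#' @export
quantify_cohort <- function(cohort, params = segmentation_params()) {
  stopifnot(inherits(cohort, "slice_cohort"))
  rows <- lapply(cohort$records, function(rec) {
    if (is.null(rec$field))
      stop("cohort was generated with keep_images = FALSE", call. = FALSE)
    rec$field$meta <- list(tumor_id = rec$tumor_id, dilution = rec$dilution,
                           day = rec$day, field_id = rec$field_id,
                           seed = rec$sub_seed)
    quantify_field(rec$field, params)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Thresholds from manual per-dilution morphology calls.
morphology_thresholds <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("tumor_id", "dilution", "call") %in% names(calls)))
  tumors <- unique(calls$tumor_id)
  rows <- lapply(tumors, function(tid) {
    sub <- calls[calls$tumor_id == tid, , drop = FALSE]
    flags <- setNames(as.logical(sub$call), sub$dilution)
    thr <- withCallingHandlers(call_threshold(flags),
                               warning = function(w) invokeRestart("muffleWarning"))
    data.frame(tumor_id = tid, threshold = thr,
               response_class = classify_tumor(thr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages: obtain fields (simulate from profiles, or read
#' the TIFFs of a manifest), quantify every field, summarize slices, call
#' per-readout thresholds against the untreated control, classify tumors
#' and aggregate cohort counts. Writes per-field and per-slice CSVs,
#' per-tumor profile JSON, cohort counts, and a provenance record
#' (parameters, seeds, package version) into `config$output_dir`. The run
#' is deterministic given identical inputs and configuration; inputs are
#' never mutated.
#'
#' If only the untreated control is present, summaries are still produced
#' and threshold calling is skipped with a notice.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fields`, `slices`, `thresholds`,
#'   `cohort`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$profiles)) {
    fields <- simulate_response_experiment(
      config$profiles, dilutions = config$dilutions,
      n_fields = config$n_fields_per_slice, spec = config$field,
      seed = config$seed, params = config$segmentation)
  } else if (!is.null(config$manifest)) {
    man <- read.csv(config$manifest, stringsAsFactors = FALSE)
    need <- c("tumor_id", "dilution", "day", "field_path")
    if (!all(need %in% names(man)))
      stop("manifest must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    rows <- lapply(seq_len(nrow(man)), function(i) {
      fld <- read_field(man$field_path[i], channel_map = config$channel_map)
      fld$meta <- list(tumor_id = man$tumor_id[i], dilution = man$dilution[i],
                       day = man$day[i],
                       field_id = sub("\\.tiff?$", "", basename(man$field_path[i])))
      quantify_field(fld, config$segmentation)
    })
    fields <- do.call(rbind, rows)
  } else if (is.null(config$morphology_calls)) {
    stop("config must provide profiles, a manifest, or morphology calls",
         call. = FALSE)
  } else {
    fields <- NULL
  }

  slices <- NULL
  thresholds <- list()
  if (!is.null(fields)) {
    keys <- unique(fields[, c("tumor_id", "dilution", "day")])
    slices <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
      sel <- fields$tumor_id == keys$tumor_id[k] &
        fields$dilution == keys$dilution[k] & fields$day == keys$day[k]
      summarize_slice(fields[sel, , drop = FALSE])
    }))
    rownames(slices) <- NULL
    tested <- setdiff(unique(fields$dilution), 11L)
    if (length(tested) == 0) {
      message("only the untreated control present: threshold calling skipped")
    } else {
      thresholds$edu <- call_cohort_thresholds(
        fields, "edu", config$edu_criterion_fraction)
      if (any(!is.na(fields$tunel_pct)))
        thresholds$tunel <- call_cohort_thresholds(
          fields, "tunel", config$tunel_k)
    }
  }
  if (!is.null(config$morphology_calls))
    thresholds$morphology <- morphology_thresholds(config$morphology_calls)

  cohort <- lapply(thresholds, function(tab) {
    cohort_counts(data.frame(tumor_id = tab$tumor_id,
                             readout = tab$threshold),
                  "readout")
  })

  provenance <- list(package = "slicetox",
                     version = as.character(packageVersion("slicetox")),
                     seed = config$seed,
                     dilutions = config$dilutions,
                     n_fields_per_slice = config$n_fields_per_slice,
                     segmentation = unclass(config$segmentation),
                     edu_criterion_fraction = config$edu_criterion_fraction,
                     tunel_k = config$tunel_k)

  out <- config$output_dir
  if (!is.null(fields))
    write.csv(format_float_df(fields), file.path(out, "fields.csv"),
              row.names = FALSE)
  if (!is.null(slices))
    write.csv(format_float_df(slices), file.path(out, "slices.csv"),
              row.names = FALSE)
  if (length(thresholds)) {
    profs <- lapply(names(thresholds), function(r) {
      tab <- thresholds[[r]]
      lapply(seq_len(nrow(tab)), function(i)
        list(tumor_id = tab$tumor_id[i], readout = r,
             threshold = tab$threshold[i],
             response_class = tab$response_class[i]))
    })
    jsonlite::write_json(unlist(profs, recursive = FALSE),
                         file.path(out, "profiles.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(
      lapply(cohort, function(cc) {
        cc$counts <- as.list(cc$counts)  # keep dilution names in the JSON
        cc
      }),
      file.path(out, "cohort_counts.json"), auto_unbox = TRUE, digits = NA)
    concordance <- Reduce(function(a, b) merge(a, b, by = "tumor_id"),
                          lapply(names(thresholds), function(r) {
                            tab <- thresholds[[r]][, c("tumor_id", "threshold")]
                            names(tab)[2] <- r
                            tab
                          }))
    write.csv(concordance, file.path(out, "threshold_concordance.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(fields = fields, slices = slices, thresholds = thresholds,
                 cohort = cohort, provenance = provenance))
}

# CSVs carry floats at 6 significant digits.
format_float_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}
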