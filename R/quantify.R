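#' Quantify one image field
#'
#' Runs the keratin-area and EdU-count operators and, when TUNEL and DAPI
#' channels are present, the TUNEL/DAPI overlap fraction. The proliferation
#' index is expressed as EdU-positive cells per 10^4 um^2 of
#' keratin-positive area. A field without detectable keratin area is
#' flagged `"no tumor tissue in field"` and its index left undefined —
#' flagged fields are excluded (and counted) by [summarize_slice()], never
#' imputed.
#'
#' @param field An [image_field()] with at least `keratin` and `edu`
#'   channels.
#' @param params A [segmentation_params()] object.
#' @return One-row data frame (a `FieldQuantification` record): `field_id`,
#'   `tumor_id`, `day`, `dilution`, `keratin_area_px`, `keratin_area_um2`,
#'   `edu_count`, `proliferation_index`, `tunel_pct`, `flagged`,
#'   `flag_reason`.
#' @export
#' @examples
#' gen <- generate_field(field_spec(width = 128, height = 128,
#'                                  n_nuclei = 12, seed = 7))
#' quantify_field(gen$field)
quantify_field <- function(field, params = segmentation_params()) {
  stopifnot(inherits(field, "image_field"))
  ch <- field$channels
  if (is.null(ch$keratin) || is.null(ch$edu))
    stop("field must have keratin and edu channels", call. = FALSE)
  meta <- field$meta
  ka <- keratin_area(ch$keratin, params)
  ec <- count_edu(ch$edu, params)
  area_um2 <- ka$area_px * field$pixel_size^2
  flagged <- ka$area_px == 0L
  tunel_pct <- NA_real_
  if (!is.null(ch$tunel) && !is.null(ch$dapi))
    tunel_pct <- tryCatch(tunel_fraction(ch$tunel, ch$dapi),
                          error = function(e) NA_real_)
  data.frame(
    field_id = meta$field_id %||% NA_character_,
    tumor_id = meta$tumor_id %||% NA_character_,
    day = meta$day %||% NA_integer_,
    dilution = meta$dilution %||% NA_integer_,
    keratin_area_px = ka$area_px,
    keratin_area_um2 = area_um2,
    edu_count = ec$count,
    proliferation_index = if (flagged) NA_real_ else
      ec$count / area_um2 * 1e4,
    tunel_pct = tunel_pct,
    flagged = flagged,
    flag_reason = if (flagged) "no tumor tissue in field" else NA_character_,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quartile_summary <- function(x, prefix) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    out <- rep(NA_real_, 4)
  } else {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    out <- c(q[2], q[1], q[3], q[3] - q[1])
  }
  setNames(as.list(out), paste0(prefix, c("_median", "_q1", "_q3", "_iqr")))
}

#' Summarize the fields of one slice
#'
#' Median and quartiles (linear-interpolation convention) of the
#' proliferation index and TUNEL percentage across the unflagged fields of
#' a slice. Field-to-field heterogeneity is deliberately summarized by the
#' interquartile range rather than a variance, mirroring how slice assays
#' report dispersion.
#'
#' @param quants Data frame of [quantify_field()] rows belonging to one
#'   slice.
#' @return One-row data frame with `tumor_id`, `day`, `dilution`,
#'   `n_fields`, `n_flagged`, and `{pi,tunel}_{median,q1,q3,iqr}` columns.
#' @export
summarize_slice <- function(quants) {
  stopifnot(is.data.frame(quants))
  ok <- !quants$flagged
  if (!any(ok)) stop("slice unquantifiable: all fields flagged",
                     call. = FALSE)
  used <- quants[ok, , drop = FALSE]
  out <- data.frame(
    tumor_id = used$tumor_id[1], day = used$day[1],
    dilution = used$dilution[1],
    n_fields = sum(ok), n_flagged = sum(!ok),
    stringsAsFactors = FALSE)
  cbind(out,
        as.data.frame(quartile_summary(used$proliferation_index, "pi")),
        as.data.frame(quartile_summary(used$tunel_pct, "tunel")))
}

#' Longitudinal summary table
#'
#' Pools all fields per tumor and culture day (duplicate slices at one day
#' are pooled, so re-summarizing is idempotent) and reports the median and
#' interquartile range of each readout — the per-tumor time-course table
#' used to check that proliferation stays near constant over prolonged
#' culture.
#'
#' @param quants Data frame of [quantify_field()] rows with `tumor_id` and
#'   `day` columns.
#' @return Data frame, one row per tumor x day; empty input gives an empty
#'   table.
#' @export
longitudinal_table <- function(quants) {
  stopifnot(is.data.frame(quants))
  if (!nrow(quants)) return(quants[0, c("tumor_id", "day"), drop = FALSE])
  keys <- unique(quants[, c("tumor_id", "day")])
  keys <- keys[order(keys$tumor_id, keys$day), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- quants$tumor_id == keys$tumor_id[k] & quants$day == keys$day[k] &
      !quants$flagged
    used <- quants[sel, , drop = FALSE]
    cbind(data.frame(tumor_id = keys$tumor_id[k], day = keys$day[k],
                     n_fields = nrow(used), stringsAsFactors = FALSE),
          as.data.frame(quartile_summary(used$proliferation_index, "pi")),
          as.data.frame(quartile_summary(used$tunel_pct, "tunel")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
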