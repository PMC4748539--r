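#' Write an image field as a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit page per channel, in the field's channel order. Channel
#' names, pixel size, bit depth and (optionally) the ground truth's
#' non-raster content (nucleus centers, radii, member indices, seed) go
#' into `<path>.json`; pixel masks are not serialized because the field is
#' fully regenerable from its spec and seed.
#'
#' @param field An [image_field()].
#' @param path Output TIFF path.
#' @param truth Optional `ground_truth` object.
#' @param spec Optional [field_spec()] recorded for regeneration.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, truth = NULL, spec = NULL) {
  stopifnot(inherits(field, "image_field"))
  tiff::writeTIFF(unname(field$channels), path,
                  bits.per.sample = field$bit_depth, compression = "none")
  sidecar <- list(channels = names(field$channels),
                  pixel_size = field$pixel_size,
                  bit_depth = field$bit_depth,
                  meta = field$meta)
  if (!is.null(truth))
    sidecar$truth <- list(
      nucleus_centers = truth$nucleus_centers,
      nucleus_radii = truth$nucleus_radii,
      edu_members = truth$edu_members,
      tunel_members = truth$tunel_members,
      seed = truth$seed)
  if (!is.null(spec)) sidecar$spec <- unclass(spec)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image field from a multi-page TIFF
#'
#' Channel names and pixel size come from the `<path>.json` sidecar when
#' present; otherwise `channel_map` must name the pages in order. Explicit
#' arguments override sidecar values.
#'
#' @param path TIFF path.
#' @param channel_map Character vector naming the pages in order (e.g.
#'   `c("dapi", "keratin", "edu", "tunel")`).
#' @param pixel_size Pixel size override (um).
#' @return An [image_field()].
#' @export
read_field <- function(path, channel_map = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("cannot read TIFF: ", path, " (", conditionMessage(e),
                           ")", call. = FALSE))
  if (!length(pages)) stop("cannot read TIFF: ", path, " (no pages)",
                           call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  nm <- channel_map %||% sidecar$channels
  if (is.null(nm))
    stop("unknown channel names: supply channel_map or a sidecar for ", path,
         call. = FALSE)
  if (length(nm) != length(pages))
    stop("channel_map names ", length(nm), " channels but ", path, " has ",
         length(pages), " pages", call. = FALSE)
  dims <- lapply(pages, dim)
  if (length(unique(dims)) != 1)
    stop("mixed page shapes in ", path, call. = FALSE)
  bits <- attr(pages[[1]], "bits.per.sample") %||% sidecar$bit_depth %||% 16L
  ps <- pixel_size %||% sidecar$pixel_size %||% 0.7
  meta <- sidecar$meta %||% list()
  image_field(setNames(lapply(pages, function(p) {
    attributes(p)[setdiff(names(attributes(p)), "dim")] <- NULL
    as.matrix(p)
  }), nm), pixel_size = ps, bit_depth = as.integer(bits),
  meta = as.list(meta))
}

#' Run configuration for the analysis pipeline
#'
#' @param output_dir Directory for report files (created if needed).
#' @param seed Master seed for any simulation stage.
#' @param segmentation A [segmentation_params()] object.
#' @param edu_criterion_fraction,tunel_k Dose-response criteria.
#' @param dilutions Tested dilution indices including the control (11).
#' @param n_fields_per_slice Fields per slice for the simulate stage.
#' @param field Base [field_spec()] for the simulate stage.
#' @param profiles Optional list of [tumor_sim_profile()] (simulate mode).
#' @param manifest Optional path to a cohort manifest CSV with columns
#'   `tumor_id`, `dilution`, `day`, `field_path` (quantify mode).
#' @param channel_map Channel names for manifest TIFFs without sidecars.
#' @param morphology_calls Optional data frame of manual per-dilution
#'   morphology calls: `tumor_id`, `dilution`, `call` (logical).
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir = "slicetox-out", seed = 1L,
                       segmentation = segmentation_params(),
                       edu_criterion_fraction = 0.5, tunel_k = 1.5,
                       dilutions = c(2:7, 11L), n_fields_per_slice = 10L,
                       field = field_spec(), profiles = NULL,
                       manifest = NULL, channel_map = NULL,
                       morphology_calls = NULL) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 segmentation = segmentation,
                 edu_criterion_fraction = edu_criterion_fraction,
                 tunel_k = tunel_k, dilutions = as.integer(dilutions),
                 n_fields_per_slice = as.integer(n_fields_per_slice),
                 field = field, profiles = profiles, manifest = manifest,
                 channel_map = channel_map,
                 morphology_calls = morphology_calls),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields of the YAML override the [run_config()] defaults;
#' `segmentation:` and `field:` blocks override the corresponding parameter
#' objects field-wise.
#'
#' @param path YAML file.
#' @return List of class `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, y$segmentation %||% list())
  fld <- do.call(field_spec, y$field %||% list())
  args <- y[setdiff(names(y), c("segmentation", "field", "profiles"))]
  args$segmentation <- seg
  args$field <- fld
  if (!is.null(y$profiles))
    args$profiles <- lapply(y$profiles, function(p)
      do.call(tumor_sim_profile, p))
  do.call(run_config, args)
}
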