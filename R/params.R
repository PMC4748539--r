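#' Specification of one synthetic microscopy field
#'
#' Collects the geometry, staining composition and noise model of a single
#' simulated multi-channel field. Defaults follow the acquisition geometry of
#' the assay (512 x 512 pixels at ~0.7 um/pixel).
#'
#' @param width,height Field size in pixels.
#' @param pixel_size Pixel edge length in micrometers.
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param nucleus_radius_range Length-2 numeric, min/max nucleus radius in
#'   pixels.
#' @param edu_fraction Fraction of nuclei rendered EdU-positive, in `[0,1]`.
#' @param tunel_fraction Fraction of nuclei rendered TUNEL-positive, in
#'   `[0,1]`.
#' @param keratin_coverage Fraction of the frame covered by the cytokeratin
#'   (tumor) mask, in `[0,1]`.
#' @param background_level,foreground_level Background and stained-object
#'   intensities on the normalized `[0,1]` scale; `foreground_level` must
#'   exceed `background_level`.
#' @param noise_sd Standard deviation of the additive Gaussian sensor noise.
#' @param psf_sigma Standard deviation (pixels) of the Gaussian optical blur
#'   applied to rendered structures before noise; kept well below half the
#'   nucleus separation so objects never merge.
#' @param seed Integer seed; a field spec is fully deterministic given its
#'   seed.
#'
#' @return An object of class `field_spec`.
#' @seealso [generate_field()]
#' @export
field_spec <- function(width = 512L, height = 512L, pixel_size = 0.7,
                       n_nuclei = 50L, nucleus_radius_range = c(4, 6),
                       edu_fraction = 0.2, tunel_fraction = 0.05,
                       keratin_coverage = 0.5,
                       background_level = 0.05, foreground_level = 0.7,
                       noise_sd = 0.02, psf_sigma = 0.6, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               pixel_size = pixel_size, n_nuclei = as.integer(n_nuclei),
               nucleus_radius_range = as.numeric(nucleus_radius_range),
               edu_fraction = edu_fraction, tunel_fraction = tunel_fraction,
               keratin_coverage = keratin_coverage,
               background_level = background_level,
               foreground_level = foreground_level,
               noise_sd = noise_sd, psf_sigma = psf_sigma,
               seed = as.integer(seed))
  class(spec) <- "field_spec"
  validate_field_spec(spec)
}

validate_field_spec <- function(spec) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid field spec: `", field, "` ", msg, call. = FALSE)
  }
  chk(spec$width >= 1 && spec$height >= 1, "width/height",
      "must be positive")
  chk(spec$pixel_size > 0, "pixel_size", "must be > 0")
  chk(spec$n_nuclei >= 0, "n_nuclei", "must be >= 0")
  chk(length(spec$nucleus_radius_range) == 2 &&
        all(spec$nucleus_radius_range >= 1) &&
        diff(spec$nucleus_radius_range) >= 0,
      "nucleus_radius_range", "must be an increasing pair >= 1")
  for (f in c("edu_fraction", "tunel_fraction", "keratin_coverage"))
    chk(spec[[f]] >= 0 && spec[[f]] <= 1, f, "must be in [0,1]")
  chk(spec$foreground_level > spec$background_level, "foreground_level",
      "must exceed background_level")
  chk(spec$background_level >= 0 && spec$foreground_level <= 1,
      "background_level/foreground_level", "must lie in [0,1]")
  chk(spec$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(spec$psf_sigma >= 0, "psf_sigma", "must be >= 0")
  chk(length(spec$seed) == 1 && !is.na(spec$seed), "seed",
      "must be a single integer")
  spec
}

#' Segmentation parameters for the image-quantification operators
#'
#' Thresholds are expressed on the normalized `[0,1]` intensity scale so they
#' are independent of bit depth. The size filters follow the assay's counting
#' rules: objects smaller than `min_object_px` (strictly) are removed before
#' filling, and only post-erosion objects larger than `count_min_px`
#' (strictly) are counted.
#'
#' @param sobel_edge_threshold Normalized Sobel gradient magnitude cut, in
#'   `[0,1]`.
#' @param edu_intensity_threshold Normalized intensity cut for the EdU
#'   channel, in `[0,1]`.
#' @param min_object_px Minimum object size (pixels) kept before filling.
#' @param count_min_px Objects must exceed this size (pixels) after erosion
#'   to be counted.
#' @param opening_radius,closing_radius,erosion_radius Disc structuring
#'   element radii in pixels (a radius-1 disc is the 3x3 neighborhood under
#'   this discretization).
#' @param keratin_erosion_radius Radius of the post-fill erosion that
#'   compensates the outward offset of the filled edge contour (the Sobel
#'   ridge straddles the true boundary, so the filled region is dilated by
#'   about the ridge half-width; eroding by it re-centers the mask on the
#'   boundary).
#' @param connectivity Pixel connectivity for components and reconstruction,
#'   4 or 8.
#' @param keratin_order Order of the post-edge-detection cleanup of the
#'   keratin mask; recorded in pipeline provenance.
#'
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(sobel_edge_threshold = 0.1,
                                edu_intensity_threshold = 0.3,
                                min_object_px = 10L, count_min_px = 10L,
                                opening_radius = 2L, closing_radius = 2L,
                                erosion_radius = 1L,
                                keratin_erosion_radius = 2L,
                                connectivity = 8L,
                                keratin_order = c("closing", "fill",
                                                  "erosion", "opening")) {
  p <- list(sobel_edge_threshold = sobel_edge_threshold,
            edu_intensity_threshold = edu_intensity_threshold,
            min_object_px = as.integer(min_object_px),
            count_min_px = as.integer(count_min_px),
            opening_radius = as.integer(opening_radius),
            closing_radius = as.integer(closing_radius),
            erosion_radius = as.integer(erosion_radius),
            keratin_erosion_radius = as.integer(keratin_erosion_radius),
            connectivity = as.integer(connectivity),
            keratin_order = match.arg(keratin_order,
                                      c("closing", "fill", "erosion",
                                        "opening"),
                                      several.ok = TRUE))
  stopifnot(p$min_object_px > 0, p$count_min_px > 0,
            p$opening_radius >= 1, p$closing_radius >= 1,
            p$erosion_radius >= 1, p$keratin_erosion_radius >= 0)
  if (!p$connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  for (f in c("sobel_edge_threshold", "edu_intensity_threshold"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop("`", f, "` must be in [0,1]", call. = FALSE)
  class(p) <- "segmentation_params"
  p
}

check_threshold <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop("`", what, "` must be a single value in [0,1]", call. = FALSE)
  x
}
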