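#' @title Image-quantification operators
#' @name segmentation
#' @description The three readout operators of the slice assay: keratin
#'   positive area, EdU positive cell count, and TUNEL/DAPI overlap fraction,
#'   plus the Otsu threshold they rely on.
NULL

# Disc structuring element of the given radius (radius 1 = 3x3 under this
# discretization).
disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Connected components at the configured connectivity; returns the label
# matrix (integers, 0 = background).
label_components <- function(mask, connectivity = 8L) {
  label_components_cpp(mask, as.integer(connectivity))
}

#' Normalized Sobel gradient magnitude
#'
#' Euclidean norm of the horizontal and vertical Sobel responses, divided by
#' the maximum attainable response for intensities in `[0,1]` (a unit step
#' yields magnitude `4 * sqrt(2)`), so the result lies in `[0,1]`.
#'
#' @param raster 2D numeric matrix with intensities in `[0,1]`.
#' @return Gradient-magnitude matrix in `[0,1]`.
#' @export
sobel_magnitude <- function(raster) {
  stop_if_not_raster(raster)
  sobel_cpp(raster) / (4 * sqrt(2))
}

#' Otsu threshold of a grayscale raster
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' `[0,1]` intensity range. Candidate thresholds are the 255 interior bin
#' boundaries; when several candidates tie (flat plateaus of the criterion,
#' e.g. a two-valued image), the mean of the tied candidates is returned, so
#' a `{0, 1}` image thresholds at 0.5.
#'
#' @param raster 2D numeric matrix with intensities in `[0,1]`.
#' @param n_bins Number of histogram bins (default 256).
#' @return A single threshold in `(0,1)`; pixels strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(raster, n_bins = 256L) {
  stop_if_not_raster(raster)
  if (any(raster < 0 | raster > 1)) stop("intensities must lie in [0,1]",
                                         call. = FALSE)
  n_bins <- as.integer(n_bins)
  bin <- pmin(floor(raster * n_bins), n_bins - 1L)  # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = n_bins)
  if (sum(counts > 0) < 2) stop("degenerate histogram", call. = FALSE)
  n <- sum(counts)
  levels <- seq_len(n_bins) - 1L
  w0 <- cumsum(counts)                 # pixels in bins 0..k
  m0 <- cumsum(counts * levels)        # first moment
  mt <- m0[n_bins]
  # candidate k: class 0 = bins 0..k-1, class 1 = bins k..255, k = 1..255
  k <- seq_len(n_bins - 1L)
  n0 <- w0[k]
  n1 <- n - n0
  valid <- n0 > 0 & n1 > 0
  mu0 <- m0[k] / n0
  mu1 <- (mt - m0[k]) / n1
  sigma_b <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
  sigma_b[!valid] <- -Inf
  best <- max(sigma_b)
  ties <- k[sigma_b >= best - 1e-12 * max(1, best)]
  mean(ties) / n_bins
}

#' Cytokeratin-positive tumor area
#'
#' Segments the keratin channel by the assay's edge-based pipeline: dark
#' holes are filled by morphological reconstruction, the Sobel gradient
#' magnitude is thresholded, the edge mask is cleaned by morphological
#' closing, enclosed regions are filled, a small erosion re-centers the
#' filled contour on the true boundary, and an opening removes residual
#' specks (order configurable via `keratin_order`). The area is the pixel
#' count of the final mask.
#'
#' If no gradient pixel exceeds the threshold (e.g. a uniformly bright
#' frame), an empty mask with `no_edges = TRUE` is returned.
#'
#' @param keratin_raster Normalized keratin-channel matrix in `[0,1]`.
#' @param params A [segmentation_params()] object.
#' @return A list with `mask` (logical matrix), `area_px` (integer), and
#'   `no_edges` (logical flag).
#' @export
keratin_area <- function(keratin_raster, params = segmentation_params()) {
  stop_if_not_raster(keratin_raster)
  check_threshold(params$sobel_edge_threshold, "sobel_edge_threshold")
  filled <- fill_dark_holes(keratin_raster, params$connectivity)
  g <- sobel_magnitude(filled)
  mask <- g > params$sobel_edge_threshold
  if (!any(mask)) {
    return(list(mask = mask, area_px = 0L, no_edges = TRUE))
  }
  for (step in params$keratin_order) {
    mask <- switch(step,
      closing = as_raster(EBImage::closing(mask * 1,
                                           disc_brush(params$closing_radius))) > 0.5,
      opening = as_raster(EBImage::opening(mask * 1,
                                           disc_brush(params$opening_radius))) > 0.5,
      erosion = if (params$keratin_erosion_radius > 0)
        as_raster(EBImage::erode(mask * 1,
                                 disc_brush(params$keratin_erosion_radius))) > 0.5
        else mask,
      fill = fill_binary(mask, params$connectivity))
  }
  list(mask = mask, area_px = as.integer(sum(mask)), no_edges = FALSE)
}

#' Count EdU-positive cells
#'
#' Binarizes the EdU channel at a user-defined threshold, removes objects
#' smaller than `min_object_px` pixels (strictly), fills the remaining
#' objects by morphological reconstruction, erodes with a flat disc, and
#' counts the objects whose post-erosion area exceeds `count_min_px` pixels
#' (strictly). Objects of exactly `min_object_px` pixels survive removal but
#' are not counted if erosion leaves them at or below `count_min_px` — the
#' two size rules are applied literally.
#'
#' @param edu_raster Normalized EdU-channel matrix in `[0,1]`.
#' @param params A [segmentation_params()] object.
#' @return A list with `count` (integer), `labels` (integer label matrix of
#'   the counted, post-erosion objects), and `pre_erosion_mask` (logical).
#' @export
count_edu <- function(edu_raster, params = segmentation_params()) {
  stop_if_not_raster(edu_raster)
  check_threshold(params$edu_intensity_threshold, "edu_intensity_threshold")
  bw <- edu_raster > params$edu_intensity_threshold
  lab <- label_components(bw, params$connectivity)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(areas >= params$min_object_px)   # remove strictly < 10 px
    bw <- matrix(lab %in% keep, nrow(bw), ncol(bw))
  }
  bw <- fill_binary(bw, params$connectivity)
  eroded <- as_raster(EBImage::erode(bw * 1,
                                     disc_brush(params$erosion_radius))) > 0.5
  lab2 <- label_components(eroded, params$connectivity)
  count <- 0L
  if (max(lab2) > 0) {
    areas2 <- tabulate(lab2[lab2 > 0L], nbins = max(lab2))
    counted <- which(areas2 > params$count_min_px)  # count strictly > 10 px
    count <- length(counted)
    lab2[!(lab2 %in% counted)] <- 0L
  }
  list(count = count, labels = lab2, pre_erosion_mask = bw)
}

#' TUNEL-positive fraction of DAPI pixels
#'
#' Otsu-binarizes the TUNEL and DAPI channels independently and returns the
#' percentage of DAPI-positive pixels that are also TUNEL-positive (a binary
#' Manders-style overlap fraction with DAPI as the reference mask). Counting
#' pixels rather than nuclei sidesteps the overlapping-nuclei problem of
#' dense tumor tissue.
#'
#' A TUNEL channel with a degenerate (single-level) histogram is treated as
#' having no positive pixels; a degenerate or empty DAPI mask is an error
#' because the reference denominator is undefined.
#'
#' @param tunel_raster,dapi_raster Normalized channel matrices in `[0,1]`,
#'   identical dimensions.
#' @return Percentage in `[0,100]`.
#' @export
tunel_fraction <- function(tunel_raster, dapi_raster) {
  stop_if_not_raster(tunel_raster, "tunel_raster")
  stop_if_not_raster(dapi_raster, "dapi_raster")
  if (!identical(dim(tunel_raster), dim(dapi_raster)))
    stop("TUNEL and DAPI rasters must have identical dimensions",
         call. = FALSE)
  dapi_thr <- tryCatch(otsu_threshold(dapi_raster),
                       error = function(e) NULL)
  if (is.null(dapi_thr)) stop("no nuclei detected", call. = FALSE)
  dapi_mask <- dapi_raster > dapi_thr
  if (!any(dapi_mask)) stop("no nuclei detected", call. = FALSE)
  tunel_mask <- tryCatch(tunel_raster > otsu_threshold(tunel_raster),
                         error = function(e) matrix(FALSE, nrow(tunel_raster),
                                                    ncol(tunel_raster)))
  100 * sum(tunel_mask & dapi_mask) / sum(dapi_mask)
}
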