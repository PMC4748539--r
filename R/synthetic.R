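#' @title Synthetic microscopy with ground truth
#' @name synthetic_microscopy
#' @description Seeded generator of multi-channel fluorescence fields
#'   (DAPI, cytokeratin, EdU, TUNEL) with known nucleus positions, channel
#'   memberships and masks, plus a dose-effect model and cohort generator
#'   that emulate the statistical structure of the slice assay.
NULL

#' Construct an image field
#'
#' @param channels Named list of 2D numeric matrices (any subset of
#'   `dapi`, `keratin`, `edu`, `tunel`), all with identical dimensions and
#'   intensities in `[0,1]`.
#' @param pixel_size Pixel edge length in micrometers.
#' @param bit_depth Source bit depth, 8 or 16.
#' @param meta Optional named list of provenance (tumor id, dilution, day,
#'   field id, seed).
#' @return An object of class `image_field`.
#' @export
image_field <- function(channels, pixel_size = 0.7, bit_depth = 16L,
                        meta = list()) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a non-empty named list", call. = FALSE)
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1)
    stop("all channels must share one shape", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16",
                                       call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth), meta = meta),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_field> %dx%d px, %.2f um/px, channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Stamp filled discs onto a logical canvas; centers is an n x 2 matrix of
# (row, col), radii a length-n vector. Returns the updated canvas.
stamp_discs <- function(canvas, centers, radii) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  for (k in seq_len(nrow(centers))) {
    r <- radii[k]
    ci <- centers[k, 1]; cj <- centers[k, 2]
    i0 <- max(1L, floor(ci - r)); i1 <- min(nr, ceiling(ci + r))
    j0 <- max(1L, floor(cj - r)); j1 <- min(nc, ceiling(cj + r))
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - ci)^2, (jj - cj)^2, `+`)
    canvas[ii, jj] <- canvas[ii, jj] | (d2 <= r^2)
  }
  canvas
}

# Smooth random tumor region covering ~coverage of the frame. A Gaussian
# random field is tapered to zero at the border (so no blob touches the
# frame edge, a guarantee the edge-fill segmentation relies on) and
# thresholded at the coverage quantile.
keratin_region <- function(h, w, coverage) {
  if (coverage <= 0) return(matrix(FALSE, h, w))
  field <- matrix(rnorm(h * w), h, w)
  field <- gauss_blur_cpp(field, max(2, min(h, w) / 8))
  field <- field - min(field) + 1e-6          # strictly positive
  m <- max(4L, round(0.04 * min(h, w)))
  ramp <- function(n) {
    r <- rep(1, n)
    edge <- seq_len(m)
    r[edge] <- (1 - cos(pi * edge / (m + 1))) / 2
    r[n + 1 - edge] <- r[edge]
    r
  }
  field <- field * outer(ramp(h), ramp(w))
  if (coverage >= 1) return(matrix(TRUE, h, w))
  q <- quantile(field, probs = 1 - coverage, names = FALSE)
  field >= q
}

# Rejection-sample nucleus centers with pairwise separation >= min_sep and
# a border margin. Errors if the packing cannot be achieved.
place_nuclei <- function(n, h, w, r_max, min_sep) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  margin <- r_max + 2
  if (h - 2 * margin < 1 || w - 2 * margin < 1)
    stop("field too small to place nuclei", call. = FALSE)
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * n + 500L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    ci <- runif(1, margin, h - margin)
    cj <- runif(1, margin, w - margin)
    ok <- placed == 0L ||
      all((centers[seq_len(placed), 1] - ci)^2 +
            (centers[seq_len(placed), 2] - cj)^2 >= min_sep^2)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- c(ci, cj)
    }
  }
  if (placed < n)
    stop("cannot place ", n, " nuclei with separation guarantee ",
         round(min_sep, 1), " px in a ", h, "x", w, " field", call. = FALSE)
  centers
}

#' Generate one synthetic multi-channel field
#'
#' Renders DAPI (all nuclei), cytokeratin (tumor region), EdU (a subset of
#' nuclei) and TUNEL (another subset) channels with a small optical blur,
#' additive Gaussian noise clipped to `[0,1]`, and quantization to the
#' target bit depth (so TIFF round trips are bit exact). Nuclei are placed
#' by rejection sampling with pairwise center separation at least
#' `2 * max radius + 3` pixels — a generator guarantee that makes exact
#' object counting well defined downstream, not a biological claim.
#'
#' EdU members are drawn preferentially from nuclei inside the keratin
#' region (proliferating tumor cells); membership counts are exactly
#' `round(fraction * n_nuclei)`. Identical spec (including seed) yields bit
#' identical output.
#'
#' @param spec A [field_spec()].
#' @return A list with `field` (an [image_field()]) and `truth` (class
#'   `ground_truth`: `nucleus_centers` (n x 2, row/col), `nucleus_radii`,
#'   `nucleus_mask`, `keratin_mask`, `edu_members`, `tunel_members`,
#'   `seed`).
#' @export
generate_field <- function(spec = field_spec()) {
  spec <- validate_field_spec(spec)
  h <- spec$height; w <- spec$width
  r_rng <- spec$nucleus_radius_range
  with_seed(spec$seed, {
    kmask <- keratin_region(h, w, spec$keratin_coverage)
    min_sep <- 2 * r_rng[2] + 3
    centers <- place_nuclei(spec$n_nuclei, h, w, r_rng[2], min_sep)
    radii <- if (spec$n_nuclei > 0) runif(spec$n_nuclei, r_rng[1], r_rng[2])
             else numeric(0)

    nmask <- matrix(FALSE, h, w)
    if (spec$n_nuclei > 0) nmask <- stamp_discs(nmask, centers, radii)

    inside <- if (spec$n_nuclei > 0)
      which(kmask[cbind(pmin(h, pmax(1, round(centers[, 1]))),
                        pmin(w, pmax(1, round(centers[, 2]))))])
      else integer(0)
    safe_sample <- function(x, k) x[sample.int(length(x), k)]
    pick_members <- function(k, pool_first, exclude = integer(0)) {
      if (k == 0) return(integer(0))
      pool1 <- setdiff(pool_first, exclude)
      pool2 <- setdiff(seq_len(spec$n_nuclei), c(pool1, exclude))
      take1 <- min(k, length(pool1))
      m <- if (take1 > 0) safe_sample(pool1, take1) else integer(0)
      if (take1 < k) {
        extra <- min(k - take1, length(pool2))
        if (extra > 0) m <- c(m, safe_sample(pool2, extra))
      }
      sort(m)
    }
    n_edu <- round(spec$edu_fraction * spec$n_nuclei)
    n_tunel <- round(spec$tunel_fraction * spec$n_nuclei)
    edu_members <- pick_members(n_edu, inside)
    tunel_members <- pick_members(n_tunel, setdiff(seq_len(spec$n_nuclei),
                                                   edu_members))

    member_mask <- function(members) {
      m <- matrix(FALSE, h, w)
      if (length(members))
        m <- stamp_discs(m, centers[members, , drop = FALSE], radii[members])
      m
    }
    render <- function(mask) {
      x <- spec$background_level +
        (spec$foreground_level - spec$background_level) * (mask * 1)
      if (spec$psf_sigma > 0)
        x <- gauss_blur_cpp(x, spec$psf_sigma)
      if (spec$noise_sd > 0) x <- x + rnorm(h * w, 0, spec$noise_sd)
      quantize(clamp01(as_raster(x)), 16L)
    }
    channels <- list(dapi = render(nmask), keratin = render(kmask),
                     edu = render(member_mask(edu_members)),
                     tunel = render(member_mask(tunel_members)))
    truth <- structure(list(nucleus_centers = centers, nucleus_radii = radii,
                            nucleus_mask = nmask, keratin_mask = kmask,
                            edu_members = edu_members,
                            tunel_members = tunel_members, seed = spec$seed),
                       class = "ground_truth")
    list(field = image_field(channels, pixel_size = spec$pixel_size,
                             bit_depth = 16L, meta = list(seed = spec$seed)),
         truth = truth)
  })
}

#' Simulation profile of one tumor
#'
#' Describes how a simulated tumor responds to the FAC ladder: the dilution
#' index at which its response threshold sits (`NA` for a tumor with no
#' detectable response), baseline per-field EdU/TUNEL fractions at the
#' untreated control, the field-to-field dispersion, and the steepness of
#' the dose-effect curve.
#'
#' @param tumor_id Character id.
#' @param true_threshold Dilution index in `1..10`, or `NA` for no response.
#' @param baseline_edu_fraction Mean EdU-positive fraction of nuclei in
#'   untreated slices.
#' @param baseline_tunel_fraction Mean TUNEL-positive fraction in untreated
#'   slices.
#' @param max_tunel_fraction TUNEL fraction approached at saturating drug
#'   concentration.
#' @param heterogeneity_sd Standard deviation of the per-field realized
#'   fractions around the dose-effect mean (beta-distributed).
#' @param hill_slope Hill coefficient of the logistic dose-effect curve.
#' @return An object of class `tumor_sim_profile`.
#' @export
tumor_sim_profile <- function(tumor_id, true_threshold = NA_integer_,
                              baseline_edu_fraction = 0.2,
                              baseline_tunel_fraction = 0.05,
                              max_tunel_fraction = 0.4,
                              heterogeneity_sd = 0.05, hill_slope = 4) {
  if (!is.na(true_threshold) &&
      (!true_threshold %in% 1:10))
    stop("true_threshold must be in 1..10 or NA", call. = FALSE)
  for (f in c(baseline_edu_fraction, baseline_tunel_fraction,
              max_tunel_fraction))
    if (f < 0 || f > 1) stop("baseline fractions must be in [0,1]",
                             call. = FALSE)
  if (heterogeneity_sd < 0) stop("heterogeneity_sd must be >= 0",
                                 call. = FALSE)
  structure(list(tumor_id = as.character(tumor_id),
                 true_threshold = as.integer(true_threshold),
                 baseline_edu_fraction = baseline_edu_fraction,
                 baseline_tunel_fraction = baseline_tunel_fraction,
                 max_tunel_fraction = max_tunel_fraction,
                 heterogeneity_sd = heterogeneity_sd,
                 hill_slope = hill_slope),
            class = "tumor_sim_profile")
}

#' Expected EdU and TUNEL fractions under FAC treatment
#'
#' Four-parameter logistic in log drug concentration (doxorubicin is the
#' reference component of the fixed-ratio mixture), floored at zero effect
#' for the untreated control. The curve midpoint sits at the geometric mean
#' of the concentrations of `true_threshold` and the next weaker dilution,
#' so the threshold dilution lies clearly on the affected side of the curve
#' and the next weaker dilution clearly on the unaffected side. EdU is
#' non-increasing and TUNEL non-decreasing in concentration; dilution 11
#' (control) returns the baselines exactly, as does a profile with no
#' threshold.
#'
#' @param profile A [tumor_sim_profile()].
#' @param dilution Dilution index in `1..11` (11 = untreated control).
#' @param series Dilution table from [build_dilution_table()].
#' @return Named numeric: `edu_fraction`, `tunel_fraction`.
#' @export
dose_effect_model <- function(profile, dilution,
                              series = build_dilution_table()) {
  stopifnot(inherits(profile, "tumor_sim_profile"))
  if (length(dilution) != 1 || is.na(dilution) || !dilution %in% 1:11)
    stop("dilution must be in 1..11", call. = FALSE)
  base <- c(edu_fraction = profile$baseline_edu_fraction,
            tunel_fraction = profile$baseline_tunel_fraction)
  if (dilution == 11L || is.na(profile$true_threshold)) return(base)
  cd <- series$c_dox_um
  conc <- cd[dilution]
  thr <- profile$true_threshold
  c_next <- if (thr < 10) cd[thr + 1] else cd[10] / 2
  c50 <- sqrt(cd[thr] * c_next)
  f <- 1 / (1 + (conc / c50)^profile$hill_slope)   # survival-like factor
  c(edu_fraction = profile$baseline_edu_fraction * f,
    tunel_fraction = profile$baseline_tunel_fraction +
      (profile$max_tunel_fraction - profile$baseline_tunel_fraction) * (1 - f))
}

#' Generate a dose-response cohort with ground truth
#'
#' For every tumor profile and dilution, draws `n_fields_per_slice` fields
#' whose realized EdU/TUNEL fractions are beta-distributed around the
#' [dose_effect_model()] expectations with the profile's
#' `heterogeneity_sd` (zero dispersion reproduces the expectation exactly),
#' then renders each field with [generate_field()] under a per-field
#' sub-seed derived from `seed`. All truths are retained.
#'
#' @param profiles List of [tumor_sim_profile()] objects.
#' @param dilutions Integer dilution indices to simulate (default the
#'   assay's tested set `{2..7}` plus control 11).
#' @param n_fields_per_slice Fields imaged per slice (>= 1).
#' @param spec Base [field_spec()]; its fractions are overridden per field.
#' @param day Culture day recorded in the manifest.
#' @param series Dilution table.
#' @param seed Master seed; per-field sub-seeds are derived from it and
#'   recorded in the manifest.
#' @param keep_images Retain rendered fields and pixel-level truth (set
#'   `FALSE` for large sweeps; realized fractions and member counts are
#'   always kept).
#' @return A list of class `slice_cohort` with `records` (one entry per
#'   field) and `manifest` (data frame).
#' @export
generate_cohort <- function(profiles, dilutions = c(2:7, 11L),
                            n_fields_per_slice = 10L, spec = field_spec(),
                            day = 3L, series = build_dilution_table(),
                            seed = spec$seed, keep_images = TRUE) {
  if (!length(profiles)) stop("profiles must be a non-empty list",
                              call. = FALSE)
  if (n_fields_per_slice < 1) stop("n_fields_per_slice must be >= 1",
                                   call. = FALSE)
  if (inherits(profiles, "tumor_sim_profile")) profiles <- list(profiles)
  records <- list()
  rows <- list()
  counter <- 0L
  for (p in profiles) {
    for (d in dilutions) {
      expected <- dose_effect_model(p, d, series)
      counter <- counter + 1L
      fracs <- with_seed(sub_seed(seed, counter * 1000L), {
        cbind(edu = rbeta_meansd(n_fields_per_slice,
                                 expected[["edu_fraction"]],
                                 p$heterogeneity_sd),
              tunel = rbeta_meansd(n_fields_per_slice,
                                   expected[["tunel_fraction"]],
                                   p$heterogeneity_sd))
      })
      for (f in seq_len(n_fields_per_slice)) {
        counter <- counter + 1L
        fs <- spec
        fs$edu_fraction <- fracs[f, "edu"]
        fs$tunel_fraction <- fracs[f, "tunel"]
        fs$seed <- as.integer(sub_seed(seed, counter) %% .Machine$integer.max)
        gen <- generate_field(fs)
        field_id <- sprintf("%s_d%02d_f%02d", p$tumor_id, d, f)
        rec <- list(tumor_id = p$tumor_id, dilution = d, day = day,
                    field_id = field_id, sub_seed = fs$seed,
                    expected_edu_fraction = unname(expected["edu_fraction"]),
                    expected_tunel_fraction = unname(expected["tunel_fraction"]),
                    realized_edu_fraction = fracs[f, "edu"],
                    realized_tunel_fraction = fracs[f, "tunel"],
                    n_edu_members = length(gen$truth$edu_members),
                    n_tunel_members = length(gen$truth$tunel_members))
        if (keep_images) {
          rec$field <- gen$field
          rec$truth <- gen$truth
        }
        records[[length(records) + 1L]] <- rec
        rows[[length(rows) + 1L]] <-
          data.frame(tumor_id = p$tumor_id, dilution = d, day = day,
                     field_id = field_id, sub_seed = fs$seed,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(records = records, manifest = do.call(rbind, rows),
                 master_seed = seed),
            class = "slice_cohort")
}
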