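# Independent reference implementations used as test oracles. They are
# deliberately naive (iterative, brute-force) and share no code with the
# package internals they check.

# Reconstruction by repeated geodesic dilation: dilate the marker, clamp
# under the mask, repeat to a fixed point. EBImage::dilate provides the
# elementary dilation (grayscale, flat 3x3 or cross structuring element).
oracle_reconstruct <- function(marker, mask, connectivity = 8) {
  kern <- if (connectivity == 8) matrix(1, 3, 3)
          else matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  j <- pmin(marker, mask)
  repeat {
    d <- EBImage::imageData(EBImage::dilate(j, kern))
    j2 <- matrix(pmin(as.numeric(d), as.numeric(mask)),
                 nrow(mask), ncol(mask))
    if (isTRUE(all.equal(j2, j, tolerance = 0))) return(j2)
    j <- j2
  }
}

oracle_fill_holes <- function(x, connectivity = 8) {
  m <- max(x)
  comp <- m - x
  marker <- matrix(0, nrow(x), ncol(x))
  b <- c(1, nrow(x)); marker[b, ] <- comp[b, ]
  marker[, c(1, ncol(x))] <- comp[, c(1, ncol(x))]
  m - oracle_reconstruct(marker, comp, connectivity)
}

# Exhaustive Otsu: every candidate split of the 256-bin histogram scored by
# explicitly computed class weights and means.
oracle_otsu <- function(values, n_bins = 256L) {
  bin <- pmin(floor(values * n_bins), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  lev <- 0:(n_bins - 1L)
  best <- -Inf
  best_k <- integer(0)
  for (k in 1:(n_bins - 1L)) {
    c0 <- counts[1:k]; c1 <- counts[(k + 1):n_bins]
    n0 <- sum(c0); n1 <- sum(c1)
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(c0 * lev[1:k]) / n0
    mu1 <- sum(c1 * lev[(k + 1):n_bins]) / n1
    sb <- (n0 / (n0 + n1)) * (n1 / (n0 + n1)) * (mu0 - mu1)^2
    if (sb > best + 1e-12 * max(1, best)) {
      best <- sb; best_k <- k
    } else if (sb >= best - 1e-12 * max(1, best)) {
      best_k <- c(best_k, k)
    }
  }
  mean(best_k) / n_bins
}

# Flood-fill connected components (plain R, stack-based), for counting
# objects on a binary mask.
oracle_component_sizes <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  sizes <- integer(0)
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE; size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        ii <- p[1] + offs[k, 1]; jj <- p[2] + offs[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

clamp_values <- function(x) pmin(1, pmax(0, x))

# Small raster with bright discs at given centers/radii on a dark
# background (no noise) — a controlled input for the counting operator.
disc_raster <- function(nr, nc, centers, radius, fg = 0.8, bg = 0.02) {
  x <- matrix(bg, nr, nc)
  for (k in seq_len(nrow(centers))) {
    ci <- centers[k, 1]; cj <- centers[k, 2]
    ii <- max(1, ci - radius):min(nr, ci + radius)
    jj <- max(1, cj - radius):min(nc, cj + radius)
    d2 <- outer((ii - ci)^2, (jj - cj)^2, `+`)
    x[ii, jj][d2 <= radius^2] <- fg
  }
  x
}

# Reference cohort simulation profiles (true thresholds = the printed
# morphology column), shared by recovery tests.
reference_profiles <- function() {
  ref <- fac_reference_cohort()
  lapply(seq_len(nrow(ref)), function(i)
    tumor_sim_profile(ref$sample[i], true_threshold = ref$morphology[i]))
}

# Compact field spec used for cohort-scale simulation tests.
small_field_spec <- function(seed = 1L)
  field_spec(width = 96, height = 96, n_nuclei = 25,
             nucleus_radius_range = c(4, 5), seed = seed)
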