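# Keratin area ---------------------------------------------------------

test_that("keratin_area of an empty frame is zero with the no-edges flag", {
  z <- keratin_area(matrix(0, 64, 64))
  expect_identical(z$area_px, 0L)
  expect_true(z$no_edges)

  bright <- keratin_area(matrix(1, 64, 64))  # no gradient anywhere
  expect_identical(bright$area_px, 0L)
  expect_true(bright$no_edges)
})

test_that("keratin_area recovers a sharp uniform square within 5%", {
  sq <- matrix(0, 256, 256)
  sq[79:178, 79:178] <- 1
  res <- keratin_area(sq)
  expect_false(res$no_edges)
  expect_lt(abs(res$area_px - 10000) / 10000, 0.05)
  expect_lte(res$area_px, 256 * 256)
})

test_that("keratin_area tracks the generator's ground-truth mask", {
  for (seed in c(2, 3, 4)) {
    gen <- generate_field(field_spec(width = 128, height = 128,
                                     n_nuclei = 15, seed = seed))
    res <- keratin_area(gen$field$channels$keratin)
    truth <- sum(gen$truth$keratin_mask)
    expect_lt(abs(res$area_px - truth) / truth, 0.10)
  }
})

test_that("keratin_area validates its threshold", {
  p <- segmentation_params()
  p$sobel_edge_threshold <- 1.5
  expect_error(keratin_area(matrix(0, 8, 8), p), "\\[0,1\\]")
})

# EdU counting ----------------------------------------------------------

test_that("count_edu applies both size rules literally", {
  expect_identical(count_edu(matrix(0, 64, 64))$count, 0L)

  # 3x3 block = 9 px: removed by the strict < 10 px filter
  x <- matrix(0, 64, 64)
  x[30:32, 30:32] <- 0.9
  expect_identical(count_edu(x)$count, 0L)

  # 12 well-separated discs of radius 4 survive erosion and are counted
  centers <- as.matrix(expand.grid(i = c(15, 40, 65, 90),
                                   j = c(15, 45, 75)))
  x <- disc_raster(104, 90, centers, radius = 4)
  res <- count_edu(x)
  expect_identical(res$count, 12L)
  # pre-erosion mask agrees with the flood-fill component oracle
  expect_identical(length(oracle_component_sizes(res$pre_erosion_mask)), 12L)
})

test_that("count_edu is translation invariant", {
  base <- disc_raster(60, 60, cbind(c(20, 40), c(20, 40)), radius = 4)
  shifted <- disc_raster(60, 60, cbind(c(25, 45), c(23, 43)), radius = 4)
  expect_identical(count_edu(base)$count, count_edu(shifted)$count)
})

test_that("count_edu equals the truth on separation-guaranteed fields", {
  for (seed in 11:20) {
    gen <- generate_field(field_spec(width = 96, height = 96, n_nuclei = 20,
                                     nucleus_radius_range = c(4, 5),
                                     edu_fraction = 0.4, seed = seed))
    res <- count_edu(gen$field$channels$edu)
    expect_identical(res$count, length(gen$truth$edu_members))
    expect_identical(length(oracle_component_sizes(res$pre_erosion_mask)),
                     length(gen$truth$edu_members))
  }
})

# Otsu ------------------------------------------------------------------

test_that("otsu_threshold splits a two-valued raster strictly between", {
  x <- matrix(rep(c(0, 1), each = 50), 10, 10)
  t <- otsu_threshold(x)
  expect_gt(t, 0)
  expect_lt(t, 1)
  expect_equal(t, 0.5)              # midpoint of the tied plateau
  expect_true(any(x > t) && any(x <= t))
})

test_that("otsu_threshold matches exhaustive between-class-variance search", {
  set.seed(42)
  for (rep in 1:50) {
    # bimodal mixtures with random separations and weights
    n1 <- sample(50:200, 1)
    n2 <- sample(50:200, 1)
    v <- c(rbeta(n1, 2, 8), rbeta(n2, 8, 2))
    x <- matrix(v, nrow = 1)
    expect_equal(otsu_threshold(x), oracle_otsu(v), tolerance = 1e-12)
  }
  # the spec'd three-level histogram: 100 @ 10/255, 50 @ 128/255, 100 @ 240/255
  v <- c(rep(10.4 / 256, 100), rep(128.4 / 256, 50), rep(240.4 / 256, 100))
  expect_equal(otsu_threshold(matrix(v, 1)), oracle_otsu(v), tolerance = 1e-12)
})

test_that("otsu partitions of an image and its inversion are complements", {
  set.seed(7)
  v <- c(rbeta(150, 2, 6), rbeta(150, 6, 2))
  x <- matrix(v, 20, 15)
  t1 <- otsu_threshold(x)
  t2 <- otsu_threshold(1 - x)
  expect_identical(x > t1, !((1 - x) > t2))
})

test_that("constant rasters give a degenerate-histogram error", {
  expect_error(otsu_threshold(matrix(0.5, 10, 10)), "degenerate histogram")
})

# TUNEL fraction --------------------------------------------------------

test_that("tunel_fraction handles full, empty and partial overlap", {
  dapi <- matrix(0.05, 40, 40)
  dapi[5:20, 5:20] <- 0.9            # 256 px of nuclei
  expect_equal(tunel_fraction(dapi, dapi), 100)

  tunel_disjoint <- matrix(0.05, 40, 40)
  tunel_disjoint[25:39, 25:39] <- 0.9
  expect_equal(tunel_fraction(tunel_disjoint, dapi), 0)

  # DAPI mask 200 px, overlap 50 px -> 25%
  dapi2 <- matrix(0.05, 40, 40)
  dapi2[1:20, 1:10] <- 0.9           # 200 px
  tunel2 <- matrix(0.05, 40, 40)
  tunel2[1:10, 1:5] <- 0.9           # 50 px inside the DAPI mask
  tunel2[30:39, 30:34] <- 0.9        # 50 px outside (ignored)
  expect_equal(tunel_fraction(tunel2, dapi2), 25)
})

test_that("tunel_fraction is bounded and monotone under TUNEL mask growth", {
  dapi <- matrix(0.05, 50, 50)
  dapi[10:40, 10:40] <- 0.9
  prev <- -1
  for (k in c(0, 5, 10, 20, 30)) {
    tunel <- matrix(0.05, 50, 50)
    if (k > 0) tunel[10:(10 + k), 10:(10 + k)] <- 0.9
    val <- tunel_fraction(tunel, dapi)
    expect_gte(val, 0)
    expect_lte(val, 100)
    expect_gte(val, prev)
    prev <- val
  }
})

test_that("tunel_fraction requires nuclei and matching shapes", {
  expect_error(tunel_fraction(matrix(0.5, 5, 5), matrix(0.5, 5, 5)),
               "no nuclei detected")
  expect_error(tunel_fraction(matrix(0.5, 5, 5), matrix(0.5, 6, 6)),
               "dimensions")
})
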