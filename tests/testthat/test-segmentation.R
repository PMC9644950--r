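# Segmentation: Li thresholding, cortex closing, pore extraction/partition.

test_that("two-level images are separated exactly by the Li threshold", {
  for (frac in c(0.1, 0.5, 0.9)) {
    n <- 4000
    v <- c(rep(10, round(n * frac)), rep(200, n - round(n * frac)))
    arr <- array(sample(v), c(20, 20, 10))
    vol <- grayscale_volume(arr, 2)
    mask <- threshold_min_cross_entropy(vol)
    expect_identical(mask$data, arr > 100 | arr == 200)
    expect_identical(mask$data, arr == 200)
  }
})

test_that("constant images raise a degenerate-input error", {
  vol <- grayscale_volume(array(7, c(5, 5, 5)), 2)
  expect_error(threshold_min_cross_entropy(vol), "constant")
})

test_that("Li threshold equals the exhaustive cross-entropy oracle", {
  set.seed(41)
  # bimodal Gaussian mixture
  v <- c(rnorm(5e5, 50, 10), rnorm(5e5, 180, 10))
  expect_equal(li_threshold(v), li_oracle(v), tolerance = 1e-9)
  # assorted random mixtures
  for (i in 1:10) {
    mu <- sort(runif(2, 10, 240))
    if (diff(mu) < 40) mu[2] <- mu[1] + 40
    v <- c(rnorm(2e4, mu[1], runif(1, 3, 12)),
           rnorm(3e4, mu[2], runif(1, 3, 12)))
    expect_equal(li_threshold(v), li_oracle(v), tolerance = 1e-9)
  }
})

test_that("closing is idempotent on a solid block", {
  a <- array(FALSE, c(30, 30, 30))
  a[6:25, 6:25, 6:25] <- TRUE
  closed <- close_cortex(binary_volume(a, 2), closing_radius = 4)
  expect_identical(closed$data, a)
})

test_that("closing fills an axial tunnel and matches the brute-force oracle", {
  # blind tunnel fully inside the block: pure Minkowski closing fills it,
  # so implementation and oracle must agree voxel for voxel
  a <- array(FALSE, c(50, 50, 50))
  a[6:45, 6:45, 6:45] <- TRUE
  tunnel <- outer((seq_len(50) - 25)^2, (seq_len(50) - 25)^2, "+") <= 9
  for (z in 10:40) a[, , z][tunnel] <- FALSE
  closed <- close_cortex(binary_volume(a, 2), closing_radius = 5)
  inside <- array(FALSE, dim(a))
  for (z in 10:40) inside[, , z][tunnel] <- TRUE
  expect_true(all(closed$data[inside]))
  expect_identical(closed$data, closing_oracle(a, 5))

  # through-tunnel: the interior is filled; only the mouths keep
  # closing-radius smoothing, and the result contains the oracle closing
  b <- array(FALSE, c(50, 50, 50))
  b[6:45, 6:45, 6:45] <- TRUE
  for (z in 1:50) b[, , z][tunnel] <- FALSE
  closedb <- close_cortex(binary_volume(b, 2), closing_radius = 5)
  interior <- array(FALSE, dim(b))
  for (z in 11:40) interior[, , z][tunnel] <- TRUE
  expect_true(all(closedb$data[interior]))
  orac <- closing_oracle(b, 5)
  expect_true(all(closedb$data[orac]))  # superset of the plain closing
})

test_that("closing preserves a wide lumen", {
  hollow <- make_hollow_cylinder_z(20, 10, 30, voxel_size = 2)
  closed <- close_cortex(hollow, closing_radius = 3)
  expect_identical(closed$data, closing_oracle(hollow$data, 3))
  # lumen (radius 10 > 2 * closing radius) remains background
  d <- dim(hollow$data)
  ctr <- (d[1] + 1) / 2
  lumen <- outer((seq_len(d[1]) - ctr)^2, (seq_len(d[2]) - ctr)^2, "+") <= 6^2
  for (z in c(5, 15, 25))
    expect_false(any(closed$data[, , z][lumen]))
})

test_that("invalid closing radii are rejected", {
  a <- binary_volume(array(TRUE, c(4, 4, 4)), 2)
  expect_error(close_cortex(a, 0), "positive")
  expect_error(close_cortex(a, -2), "positive")
})

test_that("pore extraction counts disjoint canals and lacunae exactly", {
  solid <- array(TRUE, c(40, 40, 60))
  mineral <- solid
  # 2 tubes (canals) and 3 small blobs (lacunae)
  mineral[10:12, 10:12, 5:55] <- FALSE
  mineral[30:32, 30:32, 5:55] <- FALSE
  mineral[20:21, 8:9, 10:11] <- FALSE
  mineral[8:9, 30:31, 20:21] <- FALSE
  mineral[33:34, 12:13, 40:41] <- FALSE
  pores <- extract_pores(binary_volume(solid, 2),
                         binary_volume(mineral, 2))
  expect_identical(nrow(pores$components), 5L)
  part <- partition_pores(pores, lacuna_threshold = 1000)
  expect_identical(sum(part$components$class == "canal"), 2L)
  expect_identical(sum(part$components$class == "lacuna"), 3L)
})

test_that("identical masks give zero pore components", {
  solid <- binary_volume(array(TRUE, c(10, 10, 10)), 2)
  pores <- extract_pores(solid, solid)
  expect_identical(nrow(pores$components), 0L)
})

test_that("excluded regions are removed from the pore set", {
  solid <- array(TRUE, c(30, 30, 30))
  mineral <- solid
  mineral[5:7, 5:7, 5:25] <- FALSE
  mineral[20:22, 20:22, 5:25] <- FALSE
  excl <- array(FALSE, c(30, 30, 30))
  excl[4:8, 4:8, 4:26] <- TRUE
  pores <- extract_pores(binary_volume(solid, 2), binary_volume(mineral, 2),
                         binary_volume(excl, 2, "exclusion"))
  expect_identical(nrow(pores$components), 1L)
})

test_that("shape mismatches are invalid arguments", {
  a <- binary_volume(array(TRUE, c(5, 5, 5)), 2)
  b <- binary_volume(array(TRUE, c(6, 5, 5)), 2)
  expect_error(extract_pores(a, b), "dimensions")
})

test_that("the 1000 um^3 partition boundary is strict", {
  # components of exactly 999, 1000 and 1001 voxels at 1 um voxels
  solid <- array(TRUE, c(30, 30, 130))
  mineral <- solid
  mineral[2:4, 2:4, 2:112] <- FALSE      # 3 x 3 x 111 = 999
  mineral[15:24, 15:24, 5:14] <- FALSE   # 10 x 10 x 10 = 1000
  mineral[2:8, 15:25, 60:72] <- FALSE    # 7 x 11 x 13 = 1001
  pores <- extract_pores(binary_volume(solid, 1), binary_volume(mineral, 1))
  part <- partition_pores(pores, lacuna_threshold = 1000)
  comp <- part$components[order(part$components$volume_um3), ]
  expect_identical(comp$volume_um3, c(999, 1000, 1001))
  expect_identical(comp$class, c("lacuna", "lacuna", "canal"))
  expect_error(partition_pores(pores, -1), "non-negative")
})

test_that("canal and lacuna masks partition the pore set", {
  ph <- small_phantom()
  seg <- segment_cortex(ph$grayscale, closing_radius = 6)
  pores <- seg$canals$data | seg$lacunae$data
  expect_false(any(seg$canals$data & seg$lacunae$data))
  recomputed <- extract_pores(seg$solid_cortex, seg$mineralised)
  expect_identical(pores, recomputed$pores$data)
  expect_true(all(seg$components$volume_um3[seg$components$class == "canal"] >
                    1000))
  expect_true(all(seg$components$volume_um3[seg$components$class == "lacuna"] <=
                    1000))
})

test_that("noise-free phantoms are thresholded exactly and noisy ones nearly", {
  ph <- small_phantom()
  seg <- segment_cortex(ph$grayscale, closing_radius = 6)
  expect_identical(seg$mineralised$data, ph$bone_mask$data)

  spec <- small_phantom_spec(noise_sd = 14)  # 10% of the 140 grey contrast
  phn <- suppressWarnings(
    build_phantom(60, mixture = c(0.4, 0.3, 0.2, 0.1), n_lacunae = 40,
                  spec = spec, seed = 7))
  segn <- segment_cortex(phn$grayscale, closing_radius = 6)
  gt <- phn$canal_mask$data
  rec <- segn$canals$data
  recall <- sum(rec & gt) / sum(gt)
  jaccard <- sum(rec & gt) / sum(rec | gt)
  expect_gte(recall, 0.98)
  expect_gte(jaccard, 0.9)
})
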