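# Orientation: skeletonisation, segment decomposition, angles, indices.

test_that("longitudinal angle follows the arcsin(|v_z|) convention", {
  expect_equal(longitudinal_angle(c(0, 0, 1)), 90)
  expect_equal(longitudinal_angle(c(1, 0, 0)), 0)
  expect_equal(longitudinal_angle(c(1, 0, 1) / sqrt(2)), 45)
  expect_equal(longitudinal_angle(c(0, 0, -1)), 90)  # sign-free
  expect_error(longitudinal_angle(c(0, 0, 0)), "zero")
})

test_that("radial angle measures deviation from the tangent plane", {
  frame <- bone_frame(c(0, 0))
  mid <- c(100, 0, 50)
  expect_equal(radial_angle(mid, c(0, 1, 0), frame), 0)   # circumferential
  expect_equal(radial_angle(mid, c(1, 0, 0), frame), 90)  # radial spoke
  expect_equal(radial_angle(mid, c(0, 0, 1), frame), 0)   # axial
  expect_equal(radial_angle(mid, c(-1, 0, 0), frame), 90) # sign-free
  expect_error(radial_angle(c(0, 0, 10), c(1, 0, 0), frame), "axis")
})

test_that("classification matches the brute-force truth table on a fine grid", {
  grid <- expand.grid(tl = seq(0, 90, by = 0.5), tr = seq(0, 90, by = 0.5))
  expect_identical(classify_segment(grid$tl, grid$tr),
                   classify_oracle(grid$tl, grid$tr))
})

test_that("category boundaries resolve as documented", {
  expect_identical(classify_segment(70, 50), "longitudinal")
  expect_identical(classify_segment(30, 80), "radial")
  expect_identical(classify_segment(30, 10), "laminar")
  expect_identical(classify_segment(30, 45), "oblique")
  expect_identical(classify_segment(67.5, 10), "longitudinal")
  expect_identical(classify_segment(60, 67.5), "radial")
  expect_identical(classify_segment(60, 22.5), "laminar")
  expect_error(classify_segment(95, 10), "0, 90")
  expect_error(classify_segment(10, -1), "0, 90")
})

test_that("a straight cylinder yields one full-length axial segment", {
  cyl <- make_cylinder_z(5, 100, voxel_size = 2)
  skel <- skeletonize(cyl)
  d <- dim(cyl$data)
  ctr <- (d[1] + 1) / 2
  idx <- which(skel$data, arr.ind = TRUE)
  # skeleton on the true centreline
  expect_lte(max(sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)), 1)
  # endpoints within 2 voxels of the cylinder ends (z slabs 5..104)
  expect_lte(abs(min(idx[, 3]) - 5), 2)
  expect_lte(abs(max(idx[, 3]) - 104), 2)
  segs <- extract_segments(skel, bone_frame(c(1e6, 1e6)))
  expect_identical(nrow(segs), 1L)
  expect_lt(abs(segs$chord_length_um - 200) / 200, 0.05)
  expect_gt(segs$theta_long_deg, 85)
})

test_that("a single voxel skeletonises to itself", {
  a <- array(FALSE, c(7, 7, 7)); a[4, 4, 4] <- TRUE
  skel <- skeletonize(binary_volume(a, 2))
  expect_identical(skel$data, a)
  expect_error(skeletonize(binary_volume(a & FALSE, 2)), "empty")
})

test_that("a Y-shaped union decomposes into three segments", {
  a <- array(FALSE, c(40, 40, 40))
  paint <- function(a, p0, p1, r) {
    array(bonevasc:::cpp_paint_canals(a, dim(a), list(rbind(p0, p1)), r),
          dim(a))
  }
  a <- paint(a, c(20, 20, 2), c(20, 20, 20), 3)
  a <- paint(a, c(20, 20, 20), c(8, 30, 38), 3)
  a <- paint(a, c(20, 20, 20), c(32, 30, 38), 3)
  skel <- skeletonize(binary_volume(a, 1))
  segs <- extract_segments(skel, bone_frame(c(500, 500)))
  expect_identical(nrow(segs), 3L)
})

test_that("a closed ring decomposes into at least two chords", {
  a <- array(FALSE, c(60, 60, 20))
  for (z in 1:20) for (y in 1:60) {
    rr <- sqrt((seq_len(60) - 30.5)^2 + (y - 30.5)^2)
    a[, y, z] <- (rr - 20)^2 + (z - 10.5)^2 <= 16
  }
  skel <- skeletonize(binary_volume(a, 1))
  segs <- extract_segments(skel, bone_frame(c(30.5, 30.5)))
  expect_gte(nrow(segs), 2L)
})

test_that("orientation indices are length-weighted proportions", {
  segs <- data.frame(category = c("longitudinal", "laminar"),
                     chord_length_um = c(2, 1))
  idx <- orientation_indices(segs)
  expect_equal(idx$longitudinal_index, 2 / 3)
  expect_equal(idx$laminar_index, 1 / 3)
  expect_equal(idx$radial_index, 0)
  expect_equal(idx$laminar_index + idx$longitudinal_index +
                 idx$radial_index + idx$oblique_index, 1)
  expect_error(orientation_indices(segs[0, ]), "undefined")
})

test_that("removing one category renormalises the remaining indices", {
  set.seed(4)
  segs <- data.frame(
    category = sample(c("laminar", "longitudinal", "radial", "oblique"),
                      60, replace = TRUE),
    chord_length_um = runif(60, 5, 50))
  idx <- orientation_indices(segs)
  kept <- segs[segs$category != "radial", ]
  idx2 <- orientation_indices(kept)
  expect_equal(idx2$radial_index, 0)
  rest <- 1 - idx$radial_index
  expect_equal(idx2$laminar_index, idx$laminar_index / rest)
  expect_equal(idx2$oblique_index, idx$oblique_index / rest)
})

test_that("indices are invariant under rotation about the bone axis", {
  ph <- small_phantom()
  frame <- bone_frame(ph$spec$center)
  segs <- extract_segments(skeletonize(ph$canal_mask), frame)
  idx <- orientation_indices(segs)
  rot90 <- function(a) {
    b <- aperm(a, c(2, 1, 3))
    b[, rev(seq_len(dim(b)[2])), , drop = FALSE]
  }
  mask_r <- binary_volume(rot90(ph$canal_mask$data), 2, "canals")
  segs_r <- extract_segments(skeletonize(mask_r), frame)
  idx_r <- orientation_indices(segs_r)
  for (k in c("laminar_index", "longitudinal_index", "radial_index",
              "oblique_index"))
    expect_lt(abs(idx[[k]] - idx_r[[k]]), 0.02)
})

test_that("recovered segment angles track ground truth within 5 degrees", {
  spec <- small_phantom_spec()
  canals <- suppressWarnings(
    generate_canal_population(25, c(0.25, 0.25, 0.25, 0.25), spec,
                              seed = 13))
  spec$canals <- canals
  ph <- render_phantom(spec)
  frame <- bone_frame(spec$center)
  segs <- extract_segments(skeletonize(ph$canal_mask), frame)
  # match each long segment to its nearest ground-truth canal midpoint
  long <- segs[segs$chord_length_um >= 40, ]
  errs <- t(vapply(seq_len(nrow(long)), function(i) {
    d <- sqrt((canals$mid_x - long$mid_x[i])^2 +
                (canals$mid_y - long$mid_y[i])^2 +
                (canals$mid_z - long$mid_z[i])^2)
    j <- which.min(d)
    c(abs(long$theta_long_deg[i] - canals$theta_long[j]),
      abs(long$theta_rad_deg[i] - canals$theta_rad[j]))
  }, numeric(2)))
  expect_lte(mean(errs[, 1]), 5)
  expect_lte(mean(errs[, 2]), 5)
})

test_that("bone centre estimation works on rings and quadrants, not slabs", {
  spec <- phantom_spec(outer_radius = 300, cortical_thickness = 120,
                       height = 60, voxel_size = 2)
  f <- estimate_center(render_phantom(spec)$cortex_mask)
  expect_lt(max(abs(f$center - spec$center)), 2)  # within 1 voxel
  expect_lt(abs(attr(f, "radius_um") - 300), 4)

  specq <- phantom_spec(outer_radius = 300, cortical_thickness = 120,
                        height = 60, voxel_size = 2, sector = c(0, 90))
  fq <- estimate_center(render_phantom(specq)$cortex_mask)
  expect_lt(max(abs(fq$center - specq$center)), 6)  # within 3 voxels

  slab <- array(FALSE, c(60, 60, 10)); slab[, 25:35, ] <- TRUE
  expect_error(estimate_center(binary_volume(slab, 2)), "fit failure")
})
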