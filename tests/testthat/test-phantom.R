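# Synthetic phantom generator: canal populations, rendering, ground truth.

test_that("canal category draw follows the multinomial law", {
  spec <- small_phantom_spec()
  mix <- c(0.25, 0.25, 0.25, 0.25)
  canals <- suppressWarnings(
    generate_canal_population(2000, mix, spec, seed = 3))
  counts <- table(factor(canals$category,
                         levels = c("laminar", "longitudinal", "radial",
                                    "oblique")))
  n <- nrow(canals)
  for (k in seq_along(mix)) {
    expected <- n * mix[k]
    sigma <- sqrt(n * mix[k] * (1 - mix[k]))
    expect_lt(abs(counts[k] - expected), 3 * sigma)
  }
})

test_that("degenerate draws and invalid mixtures are handled", {
  spec <- small_phantom_spec()
  expect_identical(nrow(generate_canal_population(0, spec = spec)), 0L)
  expect_error(generate_canal_population(10, c(0.5, 0.5, 0.5, 0.5), spec),
               "sum")
  expect_error(generate_canal_population(10, c(1, 0, 0), spec), "4")
})

test_that("pure laminar populations respect the laminar angle box", {
  spec <- small_phantom_spec()
  canals <- generate_canal_population(50, c(1, 0, 0, 0), spec, seed = 5)
  expect_true(all(canals$theta_rad <= 22.5))
  expect_true(all(canals$theta_long < 67.5))
})

test_that("every generated canal's true angles match its category box", {
  spec <- small_phantom_spec()
  canals <- suppressWarnings(
    generate_canal_population(400, c(0.25, 0.25, 0.25, 0.25), spec,
                              seed = 9))
  expect_identical(classify_segment(canals$theta_long, canals$theta_rad),
                   canals$category)
})

test_that("voxelised cylinder volume matches the analytic volume", {
  # one axial canal: radius 10 um, length 500 um, voxel 2 um
  spec <- phantom_spec(outer_radius = 120, cortical_thickness = 100,
                      height = 560, voxel_size = 2)
  mid <- c(spec$center[1] + 60, spec$center[2], 280)
  canal <- data.frame(category = "longitudinal", radius_um = 10,
                      length_um = 500, theta_long = 90, theta_rad = 0,
                      mid_x = mid[1], mid_y = mid[2], mid_z = mid[3],
                      dir_x = 0, dir_y = 0, dir_z = 1)
  canal$centerline <- list(rbind(mid - c(0, 0, 250), mid + c(0, 0, 250)))
  spec$canals <- canal
  ph <- render_phantom(spec)
  vol <- sum(ph$canal_mask$data) * spec$voxel_size^3
  expect_lt(abs(vol - pi * 10^2 * 500) / (pi * 10^2 * 500), 0.05)
})

test_that("noise-free rendering is two-level with disjoint ground truth", {
  ph <- small_phantom()
  expect_identical(sort(unique(as.numeric(ph$grayscale$data))), c(40, 180))
  expect_false(any(ph$canal_mask$data & ph$lacuna_mask$data))
  expect_false(any(ph$canal_mask$data & ph$bone_mask$data))
  expect_false(any(ph$lacuna_mask$data & ph$bone_mask$data))
})

test_that("phantom with no pores has empty pore ground truth", {
  ph <- render_phantom(phantom_spec(outer_radius = 100,
                                    cortical_thickness = 50, height = 60,
                                    voxel_size = 2))
  expect_identical(sum(ph$canal_mask$data), 0L)
  expect_identical(sum(ph$lacuna_mask$data), 0L)
  expect_identical(sort(unique(as.numeric(ph$grayscale$data))), c(40, 180))
})

test_that("sector crops contain no foreground outside the sector", {
  spec <- phantom_spec(outer_radius = 150, cortical_thickness = 80,
                       height = 60, voxel_size = 2, sector = c(0, 90))
  ph <- render_phantom(spec)
  idx <- which(ph$bone_mask$data, arr.ind = TRUE)
  ang <- atan2((idx[, 2] - 0.5) * 2 - spec$center[2],
               (idx[, 1] - 0.5) * 2 - spec$center[1]) * 180 / pi
  expect_true(all(ang %% 360 <= 90 + 1e-9))
})

test_that("rendering is bit-reproducible for a fixed seed", {
  spec <- phantom_spec(outer_radius = 120, cortical_thickness = 60,
                       height = 60, voxel_size = 2, noise_sd = 8, seed = 21)
  a <- suppressWarnings(build_phantom(10, spec = spec, seed = 21,
                                      n_lacunae = 5))
  b <- suppressWarnings(build_phantom(10, spec = spec, seed = 21,
                                      n_lacunae = 5))
  expect_identical(a$grayscale$data, b$grayscale$data)
  expect_identical(a$canal_mask$data, b$canal_mask$data)
})

test_that("all generated lacunae fall below the size-filter boundary", {
  ph <- small_phantom()
  expect_true(all(ph$lacunae$volume_um3 <= 1000))
})

test_that("ground-truth orientation indices sum to one", {
  ph <- small_phantom()
  gt <- ground_truth_indices(ph$canals)
  expect_equal(gt$laminar_index + gt$longitudinal_index + gt$radial_index +
                 gt$oblique_index, 1, tolerance = 1e-9)
  expect_error(ground_truth_indices(NULL), "undefined")
})

test_that("oversized phantoms are refused", {
  expect_error(render_phantom(phantom_spec(), max_voxels = 1e6), "budget")
})

test_that("phantom artefacts round-trip through disk formats", {
  ph <- small_phantom()
  dir <- tempfile("phantom")
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "grayscale.tif", "canal_mask.tif", "canals.csv", "manifest.json")))))
  back <- read_volume_tiff(file.path(dir, "grayscale.tif"), voxel_size = 2)
  expect_equal(dim(back$data), dim(ph$grayscale$data))
  mask <- read_mask_tiff(file.path(dir, "canal_mask.tif"), voxel_size = 2)
  expect_identical(mask$data, ph$canal_mask$data)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$seed, 7L)
  unlink(dir, recursive = TRUE)
})
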