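# Fixtures are generated in code; heavyweight phantom products are cached
# once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# solid ball of given radius (voxels), lattice-aligned on a voxel centre
make_ball <- function(radius_vox, voxel_size = 2, margin = 4) {
  n <- 2 * (radius_vox + margin) + 1
  ctr <- (n + 1) / 2  # voxel index of the centre voxel
  coords <- seq_len(n) - ctr
  arr <- array(FALSE, c(n, n, n))
  for (z in seq_len(n))
    arr[, , z] <- outer(coords^2, coords^2, "+") + coords[z]^2 <=
      radius_vox^2 + 1e-9
  binary_volume(arr, voxel_size)
}

# solid z-cylinder, lattice-aligned axis
make_cylinder_z <- function(radius_vox, length_vox, voxel_size = 2,
                            margin = 4) {
  n <- 2 * (radius_vox + margin) + 1
  ctr <- (n + 1) / 2
  coords <- seq_len(n) - ctr
  nz <- length_vox + 2 * margin
  disk <- outer(coords^2, coords^2, "+") <= radius_vox^2 + 1e-9
  arr <- array(FALSE, c(n, n, nz))
  for (z in seq_len(length_vox)) arr[, , margin + z] <- disk
  binary_volume(arr, voxel_size)
}

# hollow z-cylinder (annulus wall)
make_hollow_cylinder_z <- function(outer_vox, inner_vox, length_vox,
                                   voxel_size = 2, margin = 4) {
  n <- 2 * (outer_vox + margin) + 1
  ctr <- (n + 1) / 2
  coords <- seq_len(n) - ctr
  rr <- outer(coords^2, coords^2, "+")
  wall <- rr <= outer_vox^2 + 1e-9 & rr >= inner_vox^2 - 1e-9
  arr <- array(FALSE, c(n, n, length_vox))
  for (z in seq_len(length_vox)) arr[, , z] <- wall
  binary_volume(arr, voxel_size)
}

# standard small study phantom used by the pipeline tests
small_phantom_spec <- function(noise_sd = 0) {
  phantom_spec(outer_radius = 300, cortical_thickness = 150, height = 300,
               voxel_size = 2, noise_sd = noise_sd)
}

small_phantom <- function() {
  cached("small_phantom", suppressWarnings(
    build_phantom(60, mixture = c(0.4, 0.3, 0.2, 0.1), n_lacunae = 40,
                  spec = small_phantom_spec(), seed = 7)))
}

# validation-scale study phantom (200 canals in a 0.8-mm cortex ring),
# reduced to the summary quantities the acceptance checks need
validation_phantom_spec <- function(noise_sd = 0) {
  phantom_spec(noise_sd = noise_sd)  # default 0.6-mm study geometry
}

acceptance_phantom_results <- function() {
  cached("acceptance_phantom_results", {
    spec <- validation_phantom_spec()
    ph <- suppressWarnings(
      build_phantom(200, mixture = c(0.4, 0.3, 0.2, 0.1), n_lacunae = 100,
                    spec = spec, seed = 11))
    gt_idx <- ground_truth_indices(ph$canals)
    gt_poro <- sum(ph$canal_mask$data) / sum(ph$cortex_mask$data)
    gray <- ph$grayscale
    n_canals <- nrow(ph$canals)
    rm(ph); gc(FALSE)
    seg <- segment_cortex(gray, closing_radius = 8)
    rm(gray); gc(FALSE)
    poro <- porosity(seg$canals, seg$solid_cortex)
    canals <- seg$canals
    rm(seg); gc(FALSE)
    skel <- skeletonize(canals)
    rm(canals); gc(FALSE)
    segs <- extract_segments(skel, bone_frame(spec$center))
    idx <- orientation_indices(segs)
    list(gt_idx = gt_idx, idx = idx, gt_porosity = gt_poro,
         porosity = poro, n_canals = n_canals,
         n_segments = nrow(segs))
  })
}
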