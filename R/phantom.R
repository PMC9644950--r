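#' Specification of a synthetic cortical-bone phantom
#'
#' Describes a hollow-cylinder (optionally quadrant-sector) mineralised cortex
#' containing tubular vascular canals and small ellipsoidal osteocyte
#' lacunae, rendered as a two-level grayscale volume plus additive Gaussian
#' noise. The phantom provides voxel-exact ground truth (masks and per-canal
#' orientation records) for validating every downstream stage.
#'
#' The cylinder axis is the stack (z) axis; its centre lies at
#' `(outer_radius, outer_radius)` in world micrometres. A voxel belongs to a
#' solid if its centre lies inside the solid (centre-of-voxel inclusion).
#'
#' @param outer_radius periosteal radius of the cortex, um.
#' @param cortical_thickness wall thickness, um (endosteal radius is
#'   `outer_radius - cortical_thickness`).
#' @param height stack height, um.
#' @param sector angular range in degrees kept as cortex, e.g. `c(0, 360)`
#'   for a full ring or `c(0, 90)` for a quadrant.
#' @param voxel_size isotropic voxel size, um.
#' @param canals canal ground-truth table from [generate_canal_population()]
#'   (may be empty).
#' @param lacunae lacuna ground-truth table from [generate_lacunae()].
#' @param foreground_intensity,background_intensity grey values of
#'   mineralised tissue and of pores/background; foreground must exceed
#'   background.
#' @param noise_sd standard deviation of additive Gaussian grey-value noise.
#' @param seed integer seed controlling noise; stored in the manifest.
#' @param padding background margin between the periosteal surface and the
#'   volume faces, um; frames the specimen inside the field of view the way
#'   a scan would, so that morphological operations see real background all
#'   around the cortex.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(outer_radius = 200, cortical_thickness = 100,
#'                      height = 120, voxel_size = 2)
#' @export
phantom_spec <- function(outer_radius = 600, cortical_thickness = 300,
                         height = 400, sector = c(0, 360), voxel_size = 2,
                         canals = NULL, lacunae = NULL,
                         foreground_intensity = 180,
                         background_intensity = 40,
                         noise_sd = 0, seed = 1L,
                         padding = 12 * voxel_size) {
  if (!(outer_radius > cortical_thickness && cortical_thickness > 0))
    stop("need outer_radius > cortical_thickness > 0")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (height <= 0) stop("height must be positive")
  if (foreground_intensity <= background_intensity)
    stop("foreground_intensity must exceed background_intensity")
  if (length(sector) != 2 || any(sector < 0) || any(sector > 360) ||
      sector[2] <= sector[1])
    stop("sector must be an increasing pair of angles within [0, 360]")
  structure(list(
    outer_radius = outer_radius, cortical_thickness = cortical_thickness,
    inner_radius = outer_radius - cortical_thickness,
    height = height, sector = sector, voxel_size = voxel_size,
    canals = canals, lacunae = lacunae,
    foreground_intensity = foreground_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, seed = as.integer(seed), padding = padding,
    center = c(outer_radius + padding, outer_radius + padding)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> shell %g/%g um (wall %g), height %g um, sector %g-%g deg, voxel %g um\n",
    x$inner_radius, x$outer_radius, x$cortical_thickness, x$height,
    x$sector[1], x$sector[2], x$voxel_size))
  cat(sprintf("  %d canals, %d lacunae, contrast %g/%g, noise sd %g, seed %d\n",
              if (is.null(x$canals)) 0L else nrow(x$canals),
              if (is.null(x$lacunae)) 0L else nrow(x$lacunae),
              x$foreground_intensity, x$background_intensity,
              x$noise_sd, x$seed))
  invisible(x)
}

canal_categories <- c("laminar", "longitudinal", "radial", "oblique")

# run `expr` with a private RNG stream, restoring the caller's RNG state
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# angles of a sign-free direction vector at a midpoint, degrees
direction_angles <- function(v, mid, center) {
  v <- v / sqrt(sum(v^2))
  rhat <- c(mid[1] - center[1], mid[2] - center[2], 0)
  rhat <- rhat / sqrt(sum(rhat^2))
  c(theta_long = rad2deg(asin(min(1, abs(v[3])))),
    theta_rad = rad2deg(asin(min(1, abs(sum(v * rhat))))))
}

#' Generate a ground-truthed vascular canal population
#'
#' Draws `n` canals from a mixture over the four orientation categories and
#' places them inside the cortical shell of `spec`. Longitudinal canals run
#' along z, radial canals along the local radial direction, oblique canals
#' inside the oblique angle region, each with uniform angular jitter inside
#' its category box; laminar canals are circular arcs at fixed radius
#' (a true circumferential course) with an optional helical pitch, whose
#' ground-truth angles are those of the end-to-end chord. Each record stores
#' its analytically computed longitudinal and radial angles.
#'
#' @param n number of canals (>= 0).
#' @param mixture proportions over `c("laminar", "longitudinal", "radial",
#'   "oblique")`; must sum to 1 (tolerance 1e-9).
#' @param spec a [phantom_spec()] providing the shell geometry.
#' @param seed integer seed for the draw.
#' @param radius canal radius in um (recycled over canals).
#' @param length_range target canal length range in um (before clipping to
#'   the shell).
#' @param angle_jitter half-width in degrees of the angular jitter around
#'   each category's canonical orientation.
#' @return A data.frame with one row per canal: `category`, `radius_um`,
#'   `length_um` (chord), `theta_long`, `theta_rad`, midpoint and direction
#'   columns, and a `centerline` list column of world-um polylines. Canals
#'   that cannot be fitted into the shell are skipped with a warning.
#' @export
generate_canal_population <- function(n, mixture = c(0.25, 0.25, 0.25, 0.25),
                                      spec = phantom_spec(), seed = 1L,
                                      radius = 8, length_range = c(150, 300),
                                      angle_jitter = 10) {
  if (length(mixture) != 4 || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-9)
    stop("mixture must be 4 non-negative proportions summing to 1")
  if (n < 0) stop("n must be >= 0")
  empty <- data.frame(category = character(), radius_um = numeric(),
                      length_um = numeric(), theta_long = numeric(),
                      theta_rad = numeric(), mid_x = numeric(),
                      mid_y = numeric(), mid_z = numeric(),
                      dir_x = numeric(), dir_y = numeric(),
                      dir_z = numeric(), stringsAsFactors = FALSE)
  empty$centerline <- list()
  if (n == 0) return(empty)

  radius <- rep_len(radius, n)
  with_private_seed(seed, {
    cats <- sample(canal_categories, n, replace = TRUE, prob = mixture)
    rows <- vector("list", n)
    skipped <- 0L
    for (i in seq_len(n)) {
      rec <- tryCatch(
        make_canal(cats[i], spec, radius[i], length_range, angle_jitter),
        error = function(e) NULL)
      if (is.null(rec)) skipped <- skipped + 1L else rows[[i]] <- rec
    }
    if (skipped > 0)
      warning(sprintf("%d canal(s) could not be fitted into the shell and were skipped",
                      skipped))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) return(empty)
    out <- do.call(rbind, lapply(rows, function(r) r$row))
    out$centerline <- lapply(rows, function(r) r$centerline)
    rownames(out) <- NULL
    out
  })
}

# one canal record, or error if it cannot fit
make_canal <- function(category, spec, radius, length_range, angle_jitter) {
  vox <- spec$voxel_size
  margin <- radius + 2 * vox
  r_lo <- spec$inner_radius + margin
  r_hi <- spec$outer_radius - margin
  if (r_lo >= r_hi) stop("shell too thin for canal radius")
  if (spec$height <= 2 * margin) stop("shell too short for canal radius")
  full_ring <- (spec$sector[2] - spec$sector[1]) >= 360

  rho <- runif(1, r_lo, r_hi)
  ang_margin <- if (full_ring) 0 else rad2deg(margin / rho)
  s_lo <- spec$sector[1] + ang_margin
  s_hi <- spec$sector[2] - ang_margin
  if (s_lo >= s_hi) stop("sector too narrow")
  phi0 <- deg2rad(runif(1, s_lo, s_hi))
  z0 <- runif(1, margin, spec$height - margin)
  l_target <- runif(1, length_range[1], length_range[2])

  if (category == "laminar")
    make_laminar_arc(spec, radius, margin, rho, phi0, z0, l_target,
                     angle_jitter, full_ring)
  else
    make_straight_canal(category, spec, radius, margin, rho, phi0, z0,
                        l_target, angle_jitter, full_ring)
}

sample_category_angles <- function(category, jitter) {
  if (category == "longitudinal") {
    tl <- runif(1, max(67.5, 90 - jitter), 90)
    tr <- runif(1, 0, min(jitter, 90 - tl))
  } else if (category == "radial") {
    tr <- runif(1, max(67.5, 90 - jitter), 90)
    tl <- runif(1, 0, min(jitter, 90 - tr))
  } else if (category == "oblique") {
    tr <- runif(1, max(22.6, 45 - jitter), min(67.4, 45 + jitter))
    tl <- runif(1, max(0, 45 - jitter), min(c(67.4, 45 + jitter, 90 - tr)))
  } else stop("unknown category")
  c(tl, tr)
}

make_straight_canal <- function(category, spec, radius, margin, rho, phi0,
                                z0, l_target, angle_jitter, full_ring) {
  ang <- sample_category_angles(category, angle_jitter)
  a <- sin(deg2rad(ang[2])) * sample(c(-1, 1), 1)   # radial component
  cz <- sin(deg2rad(ang[1])) * sample(c(-1, 1), 1)  # axial component
  b2 <- 1 - a^2 - cz^2
  b <- sqrt(max(0, b2)) * sample(c(-1, 1), 1)       # circumferential
  rhat <- c(cos(phi0), sin(phi0), 0)
  phat <- c(-sin(phi0), cos(phi0), 0)
  v <- a * rhat + b * phat + cz * c(0, 0, 1)
  v <- v / sqrt(sum(v^2))
  mid <- c(spec$center[1] + rho * cos(phi0),
           spec$center[2] + rho * sin(phi0), z0)

  ok_inside <- function(p) {
    rr <- sqrt((p[1] - spec$center[1])^2 + (p[2] - spec$center[2])^2)
    if (rr < spec$inner_radius + radius || rr > spec$outer_radius - radius)
      return(FALSE)
    if (p[3] < radius || p[3] > spec$height - radius) return(FALSE)
    if (!full_ring) {
      aa <- rad2deg(atan2(p[2] - spec$center[2], p[1] - spec$center[1])) %% 360
      amar <- rad2deg(radius / rr)
      if (aa < spec$sector[1] + amar || aa > spec$sector[2] - amar)
        return(FALSE)
    }
    TRUE
  }
  L <- l_target
  for (try in 1:25) {
    p1 <- mid - (L / 2) * v
    p2 <- mid + (L / 2) * v
    if (ok_inside(p1) && ok_inside(p2)) break
    L <- L * 0.8
  }
  if (!(ok_inside(mid - (L / 2) * v) && ok_inside(mid + (L / 2) * v)) ||
      L < 12 * spec$voxel_size)
    stop("cannot fit canal")
  if (pi * radius^2 * L <= 1200) stop("canal too small to survive lacuna filter")
  p1 <- mid - (L / 2) * v
  p2 <- mid + (L / 2) * v
  angs <- direction_angles(v, mid, spec$center)
  list(row = data.frame(category = category, radius_um = radius,
                        length_um = L, theta_long = angs[["theta_long"]],
                        theta_rad = angs[["theta_rad"]],
                        mid_x = mid[1], mid_y = mid[2], mid_z = mid[3],
                        dir_x = v[1], dir_y = v[2], dir_z = v[3],
                        stringsAsFactors = FALSE),
       centerline = rbind(p1, p2))
}

make_laminar_arc <- function(spec, radius, margin, rho, phi0, z0, l_target,
                             angle_jitter, full_ring) {
  # arc at fixed radius rho; half-angle from the target chord length
  alpha <- 2 * asin(min(0.45, l_target / (2 * rho)))
  alpha <- min(alpha, deg2rad(60))
  if (!full_ring) {
    span_lo <- deg2rad(spec$sector[1]) + margin / rho
    span_hi <- deg2rad(spec$sector[2]) - margin / rho
    alpha <- min(alpha, 2 * min(phi0 - span_lo, span_hi - phi0))
  }
  if (alpha <= 0) stop("cannot fit laminar arc")
  tl <- runif(1, 0, min(angle_jitter, 60))          # pitch -> chord z-angle
  chord_xy <- 2 * rho * sin(alpha / 2)
  dz_total <- chord_xy * tan(deg2rad(tl)) * sample(c(-1, 1), 1)
  # clip pitch to the axial margins
  max_dz <- 2 * min(z0 - margin, spec$height - margin - z0)
  if (abs(dz_total) > max_dz) dz_total <- sign(dz_total) * max_dz
  sweep_dir <- sample(c(-1, 1), 1)

  npts <- max(5L, ceiling(alpha * rho / (2 * spec$voxel_size)))
  tt <- seq(-alpha / 2, alpha / 2, length.out = npts) * sweep_dir
  pts <- cbind(spec$center[1] + rho * cos(phi0 + tt),
               spec$center[2] + rho * sin(phi0 + tt),
               z0 + dz_total * (tt * sweep_dir + alpha / 2) / alpha -
                 dz_total / 2)
  chord <- pts[npts, ] - pts[1, ]
  L <- sqrt(sum(chord^2))
  if (L < 12 * spec$voxel_size) stop("cannot fit laminar arc")
  if (pi * radius^2 * rho * alpha <= 1200)
    stop("canal too small to survive lacuna filter")
  v <- chord / L
  mid <- (pts[npts, ] + pts[1, ]) / 2
  angs <- direction_angles(v, mid, spec$center)
  list(row = data.frame(category = "laminar", radius_um = radius,
                        length_um = L, theta_long = angs[["theta_long"]],
                        theta_rad = angs[["theta_rad"]],
                        mid_x = mid[1], mid_y = mid[2], mid_z = mid[3],
                        dir_x = v[1], dir_y = v[2], dir_z = v[3],
                        stringsAsFactors = FALSE),
       centerline = pts)
}

#' Generate ground-truthed osteocyte lacunae
#'
#' Places `n` axis-aligned ellipsoidal lacunae in the cortical shell, away
#' from the canal network so that lacunae and canals remain disjoint pore
#' components. All generated lacunae have volumes at or below the canal /
#' lacuna partition boundary (1000 um^3), so the size filter must remove
#' every one of them.
#'
#' @inheritParams generate_canal_population
#' @param canals canal table used for overlap rejection (may be `NULL`).
#' @param semiaxis_range range of ellipsoid semi-axes, um.
#' @return data.frame with `center_x/y/z` (um), `semi_a/b/c` (um),
#'   `volume_um3`.
#' @export
generate_lacunae <- function(n, spec = phantom_spec(), canals = NULL,
                             seed = 2L, semiaxis_range = c(2, 5)) {
  empty <- data.frame(center_x = numeric(), center_y = numeric(),
                      center_z = numeric(), semi_a = numeric(),
                      semi_b = numeric(), semi_c = numeric(),
                      volume_um3 = numeric())
  if (n == 0) return(empty)
  vox <- spec$voxel_size
  with_private_seed(seed, {
    rows <- vector("list", n)
    kept <- 0L
    for (i in seq_len(n)) {
      for (try in 1:50) {
        ax <- runif(3, semiaxis_range[1], semiaxis_range[2])
        m <- max(ax) + 2 * vox
        rho <- runif(1, spec$inner_radius + m, spec$outer_radius - m)
        full_ring <- (spec$sector[2] - spec$sector[1]) >= 360
        amar <- if (full_ring) 0 else rad2deg(m / rho)
        phi <- deg2rad(runif(1, spec$sector[1] + amar, spec$sector[2] - amar))
        z <- runif(1, m, spec$height - m)
        ctr <- c(spec$center[1] + rho * cos(phi),
                 spec$center[2] + rho * sin(phi), z)
        clearance <- max(ax) + 3 * vox
        if (!is.null(canals) && nrow(canals) > 0) {
          dmin <- min(vapply(seq_len(nrow(canals)), function(k) {
            dist_point_polyline(ctr, canals$centerline[[k]]) -
              canals$radius_um[k]
          }, numeric(1)))
          if (dmin < clearance) next
        }
        vol <- 4 / 3 * pi * prod(ax)
        stopifnot(vol <= 1000)
        kept <- kept + 1L
        rows[[kept]] <- data.frame(center_x = ctr[1], center_y = ctr[2],
                                   center_z = ctr[3], semi_a = ax[1],
                                   semi_b = ax[2], semi_c = ax[3],
                                   volume_um3 = vol)
        break
      }
    }
    if (kept < n)
      warning(sprintf("placed %d of %d lacunae (crowded shell)", kept, n))
    if (kept == 0) return(empty)
    out <- do.call(rbind, rows[seq_len(kept)])
    rownames(out) <- NULL
    out
  })
}

# minimum distance from point p to a polyline (rows are vertices)
dist_point_polyline <- function(p, pts) {
  if (nrow(pts) == 1) return(sqrt(sum((p - pts[1, ])^2)))
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  pm <- matrix(p, nrow(a), 3, byrow = TRUE)
  ap <- pm - a
  len2 <- pmax(rowSums(ab^2), 1e-12)
  t <- pmin(1, pmax(0, rowSums(ap * ab) / len2))
  cl <- a + ab * t
  sqrt(min(rowSums((pm - cl)^2)))
}

#' Render a phantom specification into voxel volumes
#'
#' Produces the noisy grayscale stack plus noise-free ground-truth masks of
#' the vascular canals, the mineralised bone, and the lacunae. The grayscale
#' equals `foreground_intensity` on mineralised voxels (shell minus pores),
#' `background_intensity` elsewhere, with optional additive Gaussian noise
#' seeded from `spec$seed`; the three ground-truth masks are pairwise
#' disjoint by construction.
#'
#' @param spec a [phantom_spec()]; its `canals` / `lacunae` tables define the
#'   pore ground truth.
#' @param max_voxels refuse to render volumes above this voxel budget.
#' @return A list of class `bone_phantom`: `grayscale`
#'   ([grayscale_volume()]), `canal_mask`, `lacuna_mask`, `bone_mask`,
#'   `cortex_mask` (filled shell) ([binary_volume()]s), the ground-truth
#'   tables, and a `manifest` (spec parameters + seed).
#' @export
render_phantom <- function(spec, max_voxels = 2.5e8) {
  vox <- spec$voxel_size
  nx <- as.integer(ceiling(2 * (spec$outer_radius + spec$padding) / vox))
  ny <- nx
  nz <- as.integer(ceiling(spec$height / vox))
  if (as.double(nx) * ny * nz > max_voxels)
    stop(sprintf("phantom of %d x %d x %d voxels exceeds the voxel budget (%g)",
                 nx, ny, nz, max_voxels))
  dims <- c(nx, ny, nz)

  # shell cross-section (identical for every slice)
  xs <- (seq_len(nx) - 0.5) * vox - spec$center[1]
  ys <- (seq_len(ny) - 0.5) * vox - spec$center[2]
  rr <- sqrt(outer(xs^2, ys^2, "+"))
  shell2d <- rr >= spec$inner_radius & rr <= spec$outer_radius
  if ((spec$sector[2] - spec$sector[1]) < 360) {
    ang <- outer(xs, ys, function(x, y) atan2(y, x)) * 180 / pi
    ang <- ang %% 360
    shell2d <- shell2d & ang >= spec$sector[1] & ang <= spec$sector[2]
  }
  shell <- array(shell2d, dim = dims)

  canal <- array(FALSE, dim = dims)
  if (!is.null(spec$canals) && nrow(spec$canals) > 0) {
    polys <- lapply(spec$canals$centerline, function(p) p / vox)
    canal <- array(cpp_paint_canals(canal, dims, polys,
                                    spec$canals$radius_um / vox), dim = dims)
    canal <- canal & shell
  }
  lacuna <- array(FALSE, dim = dims)
  if (!is.null(spec$lacunae) && nrow(spec$lacunae) > 0) {
    ctr <- as.matrix(spec$lacunae[, c("center_x", "center_y", "center_z")]) / vox
    ax <- as.matrix(spec$lacunae[, c("semi_a", "semi_b", "semi_c")]) / vox
    lacuna <- array(cpp_paint_ellipsoids(lacuna, dims, ctr, ax), dim = dims)
    lacuna <- lacuna & shell & !canal
  }
  bone <- shell & !canal & !lacuna

  int_levels <- spec$noise_sd == 0 &&
    spec$foreground_intensity == round(spec$foreground_intensity) &&
    spec$background_intensity == round(spec$background_intensity)
  if (int_levels) {
    # two-level integer images at half the memory footprint
    grey <- array(as.integer(spec$background_intensity), dim = dims)
    grey[bone] <- as.integer(spec$foreground_intensity)
  } else {
    grey <- array(spec$background_intensity, dim = dims)
    grey[bone] <- spec$foreground_intensity
    if (spec$noise_sd > 0)
      grey <- with_private_seed(spec$seed,
        grey + array(rnorm(length(grey), 0, spec$noise_sd), dim = dims))
  }

  structure(list(
    grayscale = grayscale_volume(grey, vox),
    canal_mask = binary_volume(canal, vox, "canals"),
    lacuna_mask = binary_volume(lacuna, vox, "lacunae"),
    bone_mask = binary_volume(bone, vox, "mineralised"),
    cortex_mask = binary_volume(shell, vox, "solid_cortex"),
    canals = spec$canals, lacunae = spec$lacunae, spec = spec,
    manifest = list(
      generator = "bonevasc::render_phantom",
      seed = spec$seed, voxel_size = vox, dims = dims,
      outer_radius = spec$outer_radius,
      cortical_thickness = spec$cortical_thickness,
      height = spec$height, sector = spec$sector,
      foreground_intensity = spec$foreground_intensity,
      background_intensity = spec$background_intensity,
      noise_sd = spec$noise_sd,
      n_canals = if (is.null(spec$canals)) 0L else nrow(spec$canals),
      n_lacunae = if (is.null(spec$lacunae)) 0L else nrow(spec$lacunae))
  ), class = "bone_phantom")
}

#' @export
print.bone_phantom <- function(x, ...) {
  d <- dim(x$grayscale$data)
  cat(sprintf("<bone_phantom> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$grayscale$voxel_size))
  cat(sprintf("  canal voxels %d, lacuna voxels %d, bone voxels %d\n",
              sum(x$canal_mask$data), sum(x$lacuna_mask$data),
              sum(x$bone_mask$data)))
  invisible(x)
}

#' Build and render a phantom in one call
#'
#' Convenience wrapper: draws a canal population and lacunae, installs them
#' in the spec and renders.
#'
#' @inheritParams generate_canal_population
#' @param n_canals,n_lacunae population sizes.
#' @param ... passed to [generate_canal_population()].
#' @return A `bone_phantom` (see [render_phantom()]).
#' @export
build_phantom <- function(n_canals, mixture = c(0.25, 0.25, 0.25, 0.25),
                          n_lacunae = 0, spec = phantom_spec(), seed = 1L,
                          ...) {
  canals <- generate_canal_population(n_canals, mixture, spec, seed = seed,
                                      ...)
  lacunae <- generate_lacunae(n_lacunae, spec, canals, seed = seed + 1L)
  spec$canals <- canals
  spec$lacunae <- lacunae
  spec$seed <- as.integer(seed)
  render_phantom(spec)
}

#' Length-weighted ground-truth orientation indices of a canal table
#'
#' @param canals a canal table from [generate_canal_population()].
#' @return An `orientation_indices` object (see [orientation_indices()]).
#' @export
ground_truth_indices <- function(canals) {
  if (is.null(canals) || nrow(canals) == 0)
    stop("orientation indices are undefined for an empty canal set")
  indices_from_lengths(canals$category, canals$length_um)
}

#' Write a rendered phantom to disk
#'
#' Writes the grayscale stack and ground-truth masks as multi-page TIFF, the
#' canal/lacuna ground-truth tables as CSV, and the manifest (spec + seed) as
#' JSON.
#'
#' @param phantom a `bone_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume_tiff(phantom$grayscale, file.path(dir, "grayscale.tif"))
  write_mask_tiff(phantom$canal_mask, file.path(dir, "canal_mask.tif"))
  write_mask_tiff(phantom$lacuna_mask, file.path(dir, "lacuna_mask.tif"))
  write_mask_tiff(phantom$bone_mask, file.path(dir, "bone_mask.tif"))
  if (!is.null(phantom$canals) && nrow(phantom$canals) > 0) {
    tab <- phantom$canals
    tab$centerline <- NULL
    write.csv(tab, file.path(dir, "canals.csv"), row.names = FALSE)
  }
  if (!is.null(phantom$lacunae) && nrow(phantom$lacunae) > 0)
    write.csv(phantom$lacunae, file.path(dir, "lacunae.csv"),
              row.names = FALSE)
  jsonlite::write_json(phantom$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
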