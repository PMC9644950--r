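#' Bone coordinate frame
#'
#' The orientation analysis needs two geometric references: the bone's long
#' axis, which is the stack (z) axis by convention, and the position of the
#' bone's central axis in the transverse plane. For quadrant crops the
#' centre typically lies outside the imaged volume; it can be estimated from
#' the periosteal boundary with [estimate_center()] or supplied directly.
#'
#' @param center numeric `(x, y)` of the bone axis in world um.
#' @return An object of class `bone_frame`.
#' @export
bone_frame <- function(center) {
  if (length(center) != 2 || any(!is.finite(center)))
    stop("center must be a finite (x, y) pair in micrometres")
  structure(list(center = as.numeric(center), long_axis = c(0, 0, 1)),
            class = "bone_frame")
}

#' @export
print.bone_frame <- function(x, ...) {
  cat(sprintf("<bone_frame> centre (%.1f, %.1f) um, long axis = z\n",
              x$center[1], x$center[2]))
  invisible(x)
}

#' Estimate the bone centre by a circle fit to the periosteal boundary
#'
#' Fits a circle to the periosteal (outer) boundary pixels of the mid-slice
#' of the solid cortex mask, returning the centre even when it lies outside
#' the imaged volume (quadrant crops). The fit is a deterministic
#' three-point consensus search (circumcircles of well-separated boundary
#' triples, scored by inlier count) refined by a least-squares (Kasa) fit on
#' the inliers, which makes it robust to the straight cut faces of sector
#' crops.
#'
#' @param solid_cortex [binary_volume()] of the cortex.
#' @return A [bone_frame()] with the fitted periosteal radius (um) in
#'   `attr(, "radius_um")`.
#' @export
estimate_center <- function(solid_cortex) {
  m <- as_volume_array(solid_cortex)
  if (!any(m)) stop("degenerate input: empty cortex mask")
  vox <- solid_cortex$voxel_size
  dims <- dim(m)
  sl <- m[, , max(1L, ceiling(dims[3] / 2)), drop = FALSE]
  sl2 <- sl[, , 1]

  # background connected to the slice border = outside; pixels of the mask
  # 4-adjacent to it form the periosteal boundary
  lab <- array(cpp_label3d(array(!sl2, dim = c(dims[1], dims[2], 1L)),
                           c(dims[1], dims[2], 1L), 26L),
               dim = c(dims[1], dims[2]))
  border_labs <- unique(c(lab[1, ], lab[dims[1], ], lab[, 1], lab[, dims[2]]))
  border_labs <- border_labs[border_labs > 0]
  outside <- array(lab %in% border_labs, dim = dim(lab)) & !sl2
  shift <- function(a, dx, dy) {
    out <- array(FALSE, dim = dim(a))
    nx <- dim(a)[1]; ny <- dim(a)[2]
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    out[xs, ys] <- a[xs - dx, ys - dy]
    out
  }
  near_out <- shift(outside, 1, 0) | shift(outside, -1, 0) |
    shift(outside, 0, 1) | shift(outside, 0, -1)
  bnd <- which(sl2 & near_out, arr.ind = TRUE)
  if (nrow(bnd) < 3) stop("fit failure: too few boundary points")
  pts <- (bnd - 0.5) * vox  # world um

  # degenerate (collinear) boundary
  pc <- prcomp(pts)
  if (pc$sdev[2]^2 / pc$sdev[1]^2 < 1e-4)
    stop("fit failure: degenerate boundary (collinear points)")

  kasa <- function(p) {
    A <- cbind(2 * p[, 1], 2 * p[, 2], 1)
    b <- p[, 1]^2 + p[, 2]^2
    sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    ctr <- sol[1:2]
    r <- sqrt(max(0, sol[3] + sum(ctr^2)))
    list(center = as.numeric(ctr), radius = r)
  }

  m_pts <- nrow(pts)
  n_tri <- min(200L, m_pts)
  starts <- unique(round(seq(1, m_pts, length.out = n_tri)))
  best <- NULL
  best_inl <- -1L
  tol <- 2 * vox
  for (s in starts) {
    tri <- unique(((s - 1) + round(c(0, m_pts / 3, 2 * m_pts / 3))) %% m_pts + 1)
    if (length(tri) < 3) next
    fit <- kasa(pts[tri, , drop = FALSE])
    if (is.null(fit) || !is.finite(fit$radius)) next
    resid <- abs(sqrt((pts[, 1] - fit$center[1])^2 +
                        (pts[, 2] - fit$center[2])^2) - fit$radius)
    ninl <- sum(resid <= tol)
    if (ninl > best_inl) {
      best_inl <- ninl
      best <- fit
    }
  }
  if (is.null(best) || best_inl < max(10, 0.2 * m_pts))
    stop("fit failure: no consistent circular boundary found")
  for (it in 1:3) {
    resid <- abs(sqrt((pts[, 1] - best$center[1])^2 +
                        (pts[, 2] - best$center[2])^2) - best$radius)
    inl <- resid <= tol
    fit <- kasa(pts[inl, , drop = FALSE])
    if (is.null(fit)) break
    best <- fit
  }
  # a straight boundary segment is consistent with an arbitrarily large
  # tangent circle; reject the fit when its inliers are explained by a
  # straight line as well as by the circle (no usable curvature)
  resid <- abs(sqrt((pts[, 1] - best$center[1])^2 +
                      (pts[, 2] - best$center[2])^2) - best$radius)
  inl <- pts[resid <= tol, , drop = FALSE]
  if (!is.finite(best$radius) || nrow(inl) < max(3, 0.35 * m_pts))
    stop("fit failure: degenerate boundary (no circular arc)")
  pci <- prcomp(inl)
  rms_line <- pci$sdev[2]
  rms_circle <- sqrt(mean(resid[resid <= tol]^2))
  if (rms_line <= max(2 * vox, 3 * rms_circle))
    stop("fit failure: degenerate boundary (collinear points)")
  frame <- bone_frame(best$center)
  attr(frame, "radius_um") <- best$radius
  frame
}

#' Skeletonise a canal network
#'
#' Thins the canal mask to single-voxel-wide centrelines with a
#' topology-preserving sequential thinning: border voxels are removed in
#' order of increasing distance to the background whenever removal preserves
#' both foreground 26-connectivity and background 6-connectivity
#' (simple-point test), and curve endpoints are preserved. Because thinning
#' retreats tube ends by roughly one tube radius, endpoints are then
#' re-extended along their local tangent inside the original mask, restoring
#' full centreline length. The skeleton is a subset of the input mask plus
#' these in-mask extensions.
#'
#' @param canals non-empty [binary_volume()] of the canal network.
#' @return A [binary_volume()] labelled `"skeleton"`.
#' @export
skeletonize <- function(canals) {
  m <- as_volume_array(canals)
  if (!any(m)) stop("degenerate input: empty canal mask")
  dims <- dim(m)
  prio <- cpp_edt_sq(!m, dims)
  # one immortal anchor per connected component (its distance maximum), so
  # thinning can never erase a component entirely
  lab <- cpp_label3d(m, dims, 26L)
  idx_fg <- which(m)
  o <- order(lab[idx_fg], -prio[idx_fg])
  anchors <- idx_fg[o][!duplicated(lab[idx_fg][o])] - 1L
  sk <- cpp_thin3d(m, dims, prio, as.integer(anchors))
  sk <- cpp_extend_endpoints(sk, m, dims, 5L, 200L)
  binary_volume(array(sk, dim = dims), canals$voxel_size, "skeleton")
}

# 26-neighbourhood edge list of a voxel set given as linear indices
skeleton_graph <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  coord <- cbind((idx - 1) %% nx + 1,
                 ((idx - 1) %/% nx) %% ny + 1,
                 (idx - 1) %/% (nx * ny) + 1)
  key <- match(idx, idx)  # identity; vertex ids are positions in idx
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  # keep only "positive" half to avoid duplicate edges
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 |
               (offs$dy == 0 & offs$dx > 0))), ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    cc <- cbind(coord[, 1] + offs$dx[r], coord[, 2] + offs$dy[r],
                coord[, 3] + offs$dz[r])
    ok <- cc[, 1] >= 1 & cc[, 1] <= nx & cc[, 2] >= 1 & cc[, 2] <= ny &
      cc[, 3] >= 1 & cc[, 3] <= nz
    lin <- (cc[, 3] - 1) * nx * ny + (cc[, 2] - 1) * nx + cc[, 1]
    hit <- match(lin, idx)
    sel <- ok & !is.na(hit)
    if (any(sel))
      edges <- rbind(edges, cbind(which(sel), hit[sel]))
  }
  list(coord = coord, edges = edges)
}

#' Decompose a skeleton into straight canal segments
#'
#' The branch and end points of the skeleton define individual canals: the
#' skeleton graph (26-adjacency) is cut at its junction voxels (clusters of
#' voxels with three or more neighbours, collapsed to their centroid), and
#' each branch is reduced to the straight chord between its two terminal
#' points. Chord length is the Euclidean end-to-end distance in um (the path
#' length along the skeleton is also recorded); branches whose chord is
#' shorter than `min_length` are discarded, which removes single-voxel spurs
#' created by thinning. Cycles are split at their two most distant voxels
#' into two chords. Directions are sign-free (`v` and `-v` are equivalent).
#'
#' @param skeleton [binary_volume()] from [skeletonize()].
#' @param frame a [bone_frame()] giving the bone axis position.
#' @param min_length minimum chord length in um; default 3 voxels.
#' @return A data.frame with one row per segment: endpoints (`x1..z2`, um),
#'   `mid_x/y/z`, `dir_x/y/z`, `chord_length_um`, `path_length_um`,
#'   `theta_long_deg`, `theta_rad_deg`, `category`. Empty skeleton gives an
#'   empty data.frame.
#' @export
extract_segments <- function(skeleton, frame, min_length = NULL) {
  stopifnot(inherits(frame, "bone_frame"))
  m <- as_volume_array(skeleton)
  vox <- skeleton$voxel_size
  if (is.null(min_length)) min_length <- 3 * vox
  dims <- dim(m)
  idx <- which(m)
  empty <- data.frame(segment_id = integer(), x1 = numeric(), y1 = numeric(),
                      z1 = numeric(), x2 = numeric(), y2 = numeric(),
                      z2 = numeric(), mid_x = numeric(), mid_y = numeric(),
                      mid_z = numeric(), dir_x = numeric(), dir_y = numeric(),
                      dir_z = numeric(), chord_length_um = numeric(),
                      path_length_um = numeric(), theta_long_deg = numeric(),
                      theta_rad_deg = numeric(), category = character(),
                      stringsAsFactors = FALSE)
  if (length(idx) == 0) return(empty)

  sg <- skeleton_graph(idx, dims)
  world <- (sg$coord - 0.5) * vox
  nV <- length(idx)
  g <- igraph::make_empty_graph(n = nV, directed = FALSE)
  if (!is.null(sg$edges))
    g <- igraph::add_edges(g, t(sg$edges))
  deg <- igraph::degree(g)
  junctions <- which(deg >= 3)

  # collapse junction clusters to centroids
  jc_id <- rep(NA_integer_, nV)
  jc_centroid <- NULL
  if (length(junctions) > 0) {
    gj <- igraph::induced_subgraph(g, junctions)
    comp <- igraph::components(gj)$membership
    jc_id[junctions] <- comp
    jc_centroid <- do.call(rbind, lapply(seq_len(max(comp)), function(k) {
      colMeans(world[junctions[comp == k], , drop = FALSE])
    }))
  }

  gb <- igraph::delete_vertices(g, junctions)
  keep <- setdiff(seq_len(nV), junctions)
  if (length(keep) == 0) return(empty)
  comps <- igraph::components(gb)
  segs <- list()
  edge_len <- function(vids) {  # path length over component edges
    if (length(vids) < 2) return(0)
    sub <- igraph::induced_subgraph(g, vids)
    el <- igraph::as_edgelist(sub, names = FALSE)
    if (nrow(el) == 0) return(0)
    w <- world[vids, , drop = FALSE]
    sum(sqrt(rowSums((w[el[, 1], , drop = FALSE] -
                        w[el[, 2], , drop = FALSE])^2)))
  }

  for (ci in seq_len(comps$no)) {
    vids_local <- which(comps$membership == ci)
    vids <- keep[vids_local]
    sub_deg <- igraph::degree(igraph::induced_subgraph(g, vids))
    terminals <- vids[sub_deg <= 1]
    plen <- edge_len(vids)

    if (length(terminals) == 0) {
      # pure cycle: split at the two most distant voxels
      w <- world[vids, , drop = FALSE]
      if (nrow(w) > 1500) w <- w[round(seq(1, nrow(w), length.out = 1500)), ]
      dd <- as.matrix(dist(w))
      far <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      p1 <- w[far[1], ]; p2 <- w[far[2], ]
      segs[[length(segs) + 1]] <- list(p1 = p1, p2 = p2, plen = plen / 2)
      segs[[length(segs) + 1]] <- list(p1 = p1, p2 = p2, plen = plen / 2)
      next
    }

    # terminal -> attachment point (junction centroid if attached)
    attach_point <- function(v) {
      nb <- igraph::neighbors(g, v)
      jn <- nb[!is.na(jc_id[as.integer(nb)])]
      if (length(jn) > 0) {
        cl <- jc_id[as.integer(jn[1])]
        list(p = jc_centroid[cl, ], cluster = cl,
             extra = sqrt(sum((jc_centroid[cl, ] - world[v, ])^2)))
      } else list(p = world[v, ], cluster = NA_integer_, extra = 0)
    }
    if (length(terminals) == 1) {
      a1 <- attach_point(terminals[1])
      # single voxel / tiny branch hanging off junction(s)
      nb <- igraph::neighbors(g, terminals[1])
      jn <- nb[!is.na(jc_id[as.integer(nb)])]
      if (length(jn) >= 2) {
        cls <- unique(jc_id[as.integer(jn)])
        if (length(cls) >= 2) {
          p1 <- jc_centroid[cls[1], ]; p2 <- jc_centroid[cls[2], ]
          segs[[length(segs) + 1]] <- list(p1 = p1, p2 = p2,
                                           plen = plen + sqrt(sum((p1 - p2)^2)))
          next
        }
      }
      segs[[length(segs) + 1]] <- list(p1 = a1$p, p2 = world[terminals[1], ],
                                       plen = plen + a1$extra)
      next
    }
    a1 <- attach_point(terminals[1])
    a2 <- attach_point(terminals[2])
    if (!is.na(a1$cluster) && !is.na(a2$cluster) &&
        a1$cluster == a2$cluster) {
      # loop anchored at one junction: split at the farthest voxel
      w <- world[vids, , drop = FALSE]
      dd <- sqrt(rowSums(sweep(w, 2, a1$p)^2))
      far <- which.max(dd)
      segs[[length(segs) + 1]] <- list(p1 = a1$p, p2 = w[far, ],
                                       plen = plen / 2)
      segs[[length(segs) + 1]] <- list(p1 = a1$p, p2 = w[far, ],
                                       plen = plen / 2)
      next
    }
    segs[[length(segs) + 1]] <- list(p1 = a1$p, p2 = a2$p,
                                     plen = plen + a1$extra + a2$extra)
  }

  if (length(segs) == 0) return(empty)
  out <- do.call(rbind, lapply(segs, function(s) {
    data.frame(x1 = s$p1[1], y1 = s$p1[2], z1 = s$p1[3],
               x2 = s$p2[1], y2 = s$p2[2], z2 = s$p2[3],
               path_length_um = s$plen)
  }))
  d <- cbind(out$x2 - out$x1, out$y2 - out$y1, out$z2 - out$z1)
  out$chord_length_um <- sqrt(rowSums(d^2))
  ok <- out$chord_length_um >= min_length & out$chord_length_um > 0
  out <- out[ok, , drop = FALSE]
  d <- d[ok, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  dn <- d / out$chord_length_um
  # sign-free canonical direction: first non-zero component positive
  flip <- dn[, 1] < 0 | (dn[, 1] == 0 & (dn[, 2] < 0 |
           (dn[, 2] == 0 & dn[, 3] < 0)))
  dn[flip, ] <- -dn[flip, , drop = FALSE]
  out$mid_x <- (out$x1 + out$x2) / 2
  out$mid_y <- (out$y1 + out$y2) / 2
  out$mid_z <- (out$z1 + out$z2) / 2
  out$dir_x <- dn[, 1]; out$dir_y <- dn[, 2]; out$dir_z <- dn[, 3]

  on_axis <- sqrt((out$mid_x - frame$center[1])^2 +
                    (out$mid_y - frame$center[2])^2) < 1e-9
  if (any(on_axis)) {
    warning(sprintf("%d segment(s) with midpoint on the bone axis dropped",
                    sum(on_axis)))
    out <- out[!on_axis, , drop = FALSE]
    dn <- dn[!on_axis, , drop = FALSE]
  }
  if (nrow(out) == 0) return(empty)
  out$theta_long_deg <- longitudinal_angle(dn)
  out$theta_rad_deg <- vapply(seq_len(nrow(out)), function(i) {
    radial_angle(c(out$mid_x[i], out$mid_y[i], out$mid_z[i]), dn[i, ], frame)
  }, numeric(1))
  out$category <- classify_segment(out$theta_long_deg, out$theta_rad_deg)
  out <- cbind(segment_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out[, names(empty)]
}

#' Longitudinal angle of a canal direction
#'
#' Angle of the canal relative to the bone's long axis (z), measured so that
#' a canal parallel to the long axis has a longitudinal angle of 90 degrees:
#' `theta_L = asin(|v_z|)`, in `[0, 90]`. Directions are sign-free.
#'
#' @param direction unit 3-vector, or a matrix with one direction per row.
#' @return angle(s) in degrees.
#' @examples
#' longitudinal_angle(c(0, 0, 1))  # 90
#' longitudinal_angle(c(1, 0, 0))  # 0
#' @export
longitudinal_angle <- function(direction) {
  v <- if (is.matrix(direction)) direction else matrix(direction, nrow = 1)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("invalid argument: zero direction vector")
  rad2deg(asin(pmin(1, abs(v[, 3]) / nrm)))
}

#' Radial angle of a canal at its midpoint
#'
#' Angle by which the canal deviates from the nearest tangent plane of the
#' bone surface, approximated by the tangent plane of the circular cylinder
#' around the bone axis through the canal midpoint: with `rhat` the unit
#' vector from the bone axis to the midpoint in the transverse plane,
#' `theta_R = asin(|v . rhat|)`. 0 means the canal lies in the tangent plane
#' (circumferential or axial); 90 means purely radial.
#'
#' @param midpoint 3D point in world um; must be off the bone axis.
#' @param direction unit 3-vector (sign-free).
#' @param frame a [bone_frame()].
#' @return angle in degrees in `[0, 90]`.
#' @export
radial_angle <- function(midpoint, direction, frame) {
  stopifnot(inherits(frame, "bone_frame"))
  v <- direction / sqrt(sum(direction^2))
  if (!all(is.finite(v))) stop("invalid argument: zero direction vector")
  rxy <- c(midpoint[1] - frame$center[1], midpoint[2] - frame$center[2])
  nr <- sqrt(sum(rxy^2))
  if (nr < 1e-9)
    stop("undefined geometry: midpoint lies on the bone axis")
  rhat <- c(rxy / nr, 0)
  rad2deg(asin(min(1, abs(sum(v * rhat)))))
}

#' Classify a canal segment from its two angles
#'
#' Orientation categories on the (longitudinal, radial) angle plane:
#' longitudinal for `theta_L` in `[67.5, 90]` (any radial angle), else
#' radial for `theta_R` in `[67.5, 90]`, else laminar for `theta_R` in
#' `[0, 22.5]`; everything else is oblique. Bounds are inclusive;
#' longitudinal is tested first, so `theta_L = 67.5` is longitudinal and
#' (`theta_L < 67.5`, `theta_R = 67.5`) is radial.
#'
#' @param theta_long,theta_rad angles in degrees within `[0, 90]`
#'   (vectorised).
#' @return character vector of `"laminar"`, `"longitudinal"`, `"radial"`,
#'   `"oblique"`.
#' @examples
#' classify_segment(70, 50)  # longitudinal
#' classify_segment(30, 80)  # radial
#' classify_segment(30, 10)  # laminar
#' classify_segment(30, 45)  # oblique
#' @export
classify_segment <- function(theta_long, theta_rad) {
  if (length(theta_long) != length(theta_rad))
    stop("angle vectors must have equal length")
  if (any(!is.finite(theta_long)) || any(!is.finite(theta_rad)) ||
      any(theta_long < 0 | theta_long > 90) ||
      any(theta_rad < 0 | theta_rad > 90))
    stop("invalid argument: angles must lie in [0, 90] degrees")
  out <- rep("oblique", length(theta_long))
  out[theta_rad <= 22.5] <- "laminar"
  out[theta_rad >= 67.5] <- "radial"
  out[theta_long >= 67.5] <- "longitudinal"
  out
}

# shared by pipeline and ground truth
indices_from_lengths <- function(category, length_um) {
  tot <- sum(length_um)
  idx <- vapply(canal_categories, function(k)
    sum(length_um[category == k]) / tot, numeric(1))
  structure(list(laminar_index = idx[["laminar"]],
                 longitudinal_index = idx[["longitudinal"]],
                 radial_index = idx[["radial"]],
                 oblique_index = idx[["oblique"]],
                 total_weighted_length = tot,
                 n_segments = length(length_um)),
            class = "orientation_indices")
}

#' Length-weighted canal orientation indices
#'
#' The laminar, longitudinal, radial and oblique indices are the proportions
#' of the canal network in each orientation category, weighted by canal
#' (chord) length to reduce the undue influence of short canal segments:
#' `index_c = sum(length | category c) / sum(length)`. They sum to 1.
#'
#' @param segments segment table from [extract_segments()]; must contain at
#'   least one segment.
#' @return An object of class `orientation_indices`: the four indices,
#'   `total_weighted_length` (um) and `n_segments`.
#' @export
orientation_indices <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0)
    stop("degenerate input: orientation indices are undefined for an empty segment set")
  indices_from_lengths(segments$category, segments$chord_length_um)
}

#' @export
print.orientation_indices <- function(x, ...) {
  cat("<orientation_indices> (length-weighted)\n")
  cat(sprintf("  laminar %.3f  longitudinal %.3f  radial %.3f  oblique %.3f\n",
              x$laminar_index, x$longitudinal_index, x$radial_index,
              x$oblique_index))
  cat(sprintf("  %d segments, total weighted length %.0f um\n",
              x$n_segments, x$total_weighted_length))
  invisible(x)
}

#' @export
as.data.frame.orientation_indices <- function(x, ...) {
  data.frame(laminar_index = x$laminar_index,
             longitudinal_index = x$longitudinal_index,
             radial_index = x$radial_index,
             oblique_index = x$oblique_index,
             total_weighted_length_um = x$total_weighted_length,
             n_segments = x$n_segments)
}
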