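# Independent brute-force oracles. These recompute expected values straight
# from the definitions, by routes separate from the package implementation.

# exhaustive minimum-cross-entropy threshold from raw values: evaluates the
# Li & Lee objective for every candidate split of a 256-bin histogram by
# direct summation
li_oracle <- function(values, nbins = 256) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  w <- (hi - lo) / nbins
  bins <- pmin(nbins, floor((v - lo) / w) + 1L)
  g <- (bins - 0.5) * w + w  # positive surrogate grey value per voxel
  best <- Inf; best_t <- NA
  for (t in seq_len(nbins - 1)) {
    left <- g[bins <= t]; right <- g[bins > t]
    if (!length(left) || !length(right)) next
    eta <- -sum(left) * log(mean(left)) - sum(right) * log(mean(right))
    if (eta < best) { best <- eta; best_t <- t }
  }
  lo + best_t * w
}

# morphological closing by shift-based Minkowski operations (out-of-volume
# is background for dilation and foreground for erosion, matching the
# documented boundary convention)
ball_offsets <- function(r) {
  o <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r),
                   dz = -ceiling(r):ceiling(r))
  o[o$dx^2 + o$dy^2 + o$dz^2 <= r^2 + 1e-7, ]
}

shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
  out
}

dilate_oracle <- function(a, r) {
  offs <- ball_offsets(r)
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(offs)))
    out <- out | shift3d(a, offs$dx[i], offs$dy[i], offs$dz[i])
  out
}

closing_oracle <- function(a, r) {
  !dilate_oracle(!dilate_oracle(a, r), r)
}

# brute-force model-independent thickness: largest inscribed sphere that
# contains each voxel, spheres measured on the voxel-centre lattice with the
# half-voxel surface correction on the reported diameter
thickness_oracle <- function(mask, voxel_size) {
  arr <- if (inherits(mask, "binary_volume")) mask$data else mask
  fg <- which(arr, arr.ind = TRUE)
  bg <- which(!arr, arr.ind = TRUE)
  n <- nrow(fg)
  tf <- t(fg); tb <- t(bg)
  edt <- vapply(seq_len(n), function(i)
    sqrt(min(colSums((tb - fg[i, ])^2))), numeric(1))
  th <- numeric(n)
  for (i in seq_len(n)) {
    cov <- colSums((tf - fg[i, ])^2) <= edt[i]^2 + 1e-9
    val <- 2 * (edt[i] - 0.5)
    th[cov] <- pmax(th[cov], val)
  }
  out <- array(0, dim(arr))
  out[arr] <- th * voxel_size
  out
}

# orientation truth table evaluated by box membership (Table-style bounds,
# longitudinal first, oblique as the complement)
classify_oracle <- function(theta_long, theta_rad) {
  in_box <- function(tl, tr, tl_lo, tl_hi, tr_lo, tr_hi)
    tl >= tl_lo & tl <= tl_hi & tr >= tr_lo & tr <= tr_hi
  out <- rep(NA_character_, length(theta_long))
  long <- in_box(theta_long, theta_rad, 67.5, 90, 0, 90)
  radl <- !long & in_box(theta_long, theta_rad, 0, 67.5, 67.5, 90)
  lam <- !long & !radl & in_box(theta_long, theta_rad, 0, 67.5, 0, 22.5)
  out[long] <- "longitudinal"
  out[radl] <- "radial"
  out[lam] <- "laminar"
  out[is.na(out)] <- "oblique"
  out
}

# profile-likelihood grid search for the intercept-only beta regression
beta_intercept_oracle <- function(y, mu_grid = seq(0.02, 0.98, by = 5e-4)) {
  prof <- vapply(mu_grid, function(mu) {
    f <- function(lphi) {
      phi <- exp(lphi)
      -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
             (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
    }
    optimize(f, c(-2, 12))$objective
  }, numeric(1))
  mu_grid[which.min(prof)]
}
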