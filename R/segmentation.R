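#' Minimum cross-entropy (Li) threshold
#'
#' Computes the grey-value threshold that minimises the Li & Lee minimum
#' cross-entropy objective over a 256-bin histogram of the volume, and
#' returns the mask of voxels strictly above it (the mineralised tissue for
#' a bone scan). The objective for a split into background/foreground
#' classes with first moments m0, m1 and means mu0, mu1 is
#' `-m0 log(mu0) - m1 log(mu1)`; grey values are shifted to be strictly
#' positive before taking logarithms.
#'
#' @param volume a [grayscale_volume()] with at least two distinct values.
#' @return A [binary_volume()] labelled `"mineralised"`, with the chosen
#'   threshold in `attr(, "threshold")`.
#' @seealso [li_threshold()] for the scalar threshold.
#' @export
threshold_min_cross_entropy <- function(volume) {
  arr <- as_volume_array(volume)
  thr <- li_threshold(arr)
  mask <- binary_volume(arr > thr, volume$voxel_size, "mineralised")
  attr(mask, "threshold") <- thr
  mask
}

#' @rdname threshold_min_cross_entropy
#' @param values numeric vector or array of grey values.
#' @param nbins number of histogram bins.
#' @export
li_threshold <- function(values, nbins = 256) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate input: image is constant, no threshold exists")
  width <- (hi - lo) / nbins
  idx <- pmin(nbins, floor((v - lo) / width) + 1L)
  h <- tabulate(idx, nbins)
  centers <- lo + (seq_len(nbins) - 0.5) * width
  g <- centers - lo + width  # strictly positive surrogate values

  cum_h <- cumsum(h)
  cum_m <- cumsum(h * g)
  tot_h <- cum_h[nbins]
  tot_m <- cum_m[nbins]
  cand <- which(cum_h > 0 & cum_h < tot_h)  # both classes non-empty
  if (length(cand) == 0)
    stop("degenerate input: image is constant, no threshold exists")
  m0 <- cum_m[cand]
  m1 <- tot_m - m0
  mu0 <- m0 / cum_h[cand]
  mu1 <- m1 / (tot_h - cum_h[cand])
  eta <- -m0 * log(mu0) - m1 * log(mu1)
  best <- cand[which.min(eta)]
  lo + best * width  # upper edge of the winning bin; foreground = value > thr
}

#' Close the cortex into a solid mask
#'
#' Morphological closing (dilation then erosion with the same Euclidean ball
#' structuring element) of the mineralised mask, so intracortical canals are
#' bridged; any interior cavity fully enclosed after closing is additionally
#' filled, yielding a solid cortex mask. The outer (periosteal/endosteal)
#' boundary is preserved up to closing-radius smoothing. Voxels outside the
#' volume are treated as background for dilation and as foreground for
#' erosion, so structures touching the border are not eaten away.
#'
#' @param mineralised a [binary_volume()] of mineralised tissue.
#' @param closing_radius radius of the ball structuring element in voxels;
#'   should be at least the largest expected canal radius.
#' @return A [binary_volume()] labelled `"solid_cortex"`.
#' @export
close_cortex <- function(mineralised, closing_radius = 8) {
  if (closing_radius <= 0) stop("closing_radius must be positive")
  m <- as_volume_array(mineralised)
  dims <- dim(m)
  r2 <- closing_radius^2 + 1e-7

  dil <- array(cpp_edt_sq(m, dims) <= r2, dim = dims)
  closed <- array(cpp_edt_sq(!dil, dims) > r2, dim = dims)

  # fill cavities: background components not connected to the volume border
  bg <- !closed
  lab <- cpp_label3d(bg, dims, 26L)
  lab <- array(lab, dim = dims)
  border_labels <- unique(c(lab[1, , ], lab[dims[1], , ],
                            lab[, 1, ], lab[, dims[2], ],
                            lab[, , 1], lab[, , dims[3]]))
  border_labels <- border_labels[border_labels > 0]
  hole <- bg & !(lab %in% border_labels)
  closed[hole] <- TRUE
  binary_volume(closed, mineralised$voxel_size, "solid_cortex")
}

#' Extract the intracortical pore network
#'
#' Pores are the voxels of the solid cortex that are not mineralised and not
#' excluded (`pores = solid_cortex & !mineralised & !exclusion`); the
#' exclusion mask implements manual removal of medullary bone. Components
#' are labelled with 26-connectivity and measured in um^3
#' (`voxel_count * voxel_size^3`, no partial-volume correction). Components
#' touching the volume border are retained.
#'
#' @param solid_cortex,mineralised [binary_volume()]s of identical shape.
#' @param exclusion optional [binary_volume()] of voxels to drop.
#' @return A list of class `pore_extraction`: `labels` (integer array, 0 =
#'   background), `components` (data.frame `id`, `voxel_count`,
#'   `volume_um3`), `pores` ([binary_volume()]), `voxel_size`.
#' @export
extract_pores <- function(solid_cortex, mineralised, exclusion = NULL) {
  check_same_shape(solid_cortex, mineralised)
  sc <- as_volume_array(solid_cortex)
  mi <- as_volume_array(mineralised)
  pores <- sc & !mi
  if (!is.null(exclusion)) {
    check_same_shape(solid_cortex, exclusion)
    pores <- pores & !as_volume_array(exclusion)
  }
  dims <- dim(pores)
  lab <- cpp_label3d(pores, dims, 26L)
  nlab <- max(lab, 0L)
  counts <- if (nlab > 0) cpp_label_counts(lab, nlab) else numeric(0)
  vox <- solid_cortex$voxel_size
  comp <- data.frame(id = seq_len(nlab), voxel_count = counts,
                     volume_um3 = counts * vox^3)
  structure(list(labels = array(lab, dim = dims), components = comp,
                 pores = binary_volume(pores, vox, "pores"),
                 voxel_size = vox),
            class = "pore_extraction")
}

#' Partition pores into vascular canals and osteocyte lacunae
#'
#' Pore components with volume strictly greater than `lacuna_threshold`
#' (default 1000 um^3, the boundary below which pores are taken to be
#' osteocyte lacunae) become canals; all others become lacunae. The two
#' masks partition the pore set.
#'
#' @param pores a `pore_extraction` from [extract_pores()].
#' @param lacuna_threshold volume boundary in um^3; must be non-negative.
#' @return A list: `canals` and `lacunae` ([binary_volume()]s), and
#'   `components` with a `class` column (`"canal"` / `"lacuna"`).
#' @export
partition_pores <- function(pores, lacuna_threshold = 1000) {
  stopifnot(inherits(pores, "pore_extraction"))
  if (lacuna_threshold < 0) stop("lacuna_threshold must be non-negative")
  comp <- pores$components
  comp$class <- ifelse(comp$volume_um3 > lacuna_threshold, "canal", "lacuna")
  canal_ids <- comp$id[comp$class == "canal"]
  lab <- pores$labels
  canal <- array(lab %in% canal_ids & lab > 0, dim = dim(lab))
  lacuna <- pores$pores$data & !canal
  list(canals = binary_volume(canal, pores$voxel_size, "canals"),
       lacunae = binary_volume(lacuna, pores$voxel_size, "lacunae"),
       components = comp)
}

#' Segment a cortex volume end to end
#'
#' Convenience wrapper running [threshold_min_cross_entropy()],
#' [close_cortex()], [extract_pores()] and [partition_pores()] in order.
#'
#' @param volume a [grayscale_volume()].
#' @param closing_radius ball radius in voxels for [close_cortex()].
#' @param lacuna_threshold canal/lacuna volume boundary, um^3.
#' @param exclusion optional exclusion [binary_volume()] (e.g. medullary
#'   bone).
#' @return A list of class `cortex_segmentation` with `mineralised`,
#'   `solid_cortex`, `canals`, `lacunae`, `components`, `threshold`, and the
#'   parameters used.
#' @export
segment_cortex <- function(volume, closing_radius = 8,
                           lacuna_threshold = 1000, exclusion = NULL) {
  mineral <- threshold_min_cross_entropy(volume)
  solid <- close_cortex(mineral, closing_radius)
  pores <- extract_pores(solid, mineral, exclusion)
  part <- partition_pores(pores, lacuna_threshold)
  structure(list(mineralised = mineral, solid_cortex = solid,
                 canals = part$canals, lacunae = part$lacunae,
                 components = part$components,
                 threshold = attr(mineral, "threshold"),
                 closing_radius = closing_radius,
                 lacuna_threshold = lacuna_threshold),
            class = "cortex_segmentation")
}

#' @export
print.cortex_segmentation <- function(x, ...) {
  cat(sprintf("<cortex_segmentation> threshold %.3f, closing radius %g vox\n",
              x$threshold, x$closing_radius))
  n_can <- sum(x$components$class == "canal")
  n_lac <- sum(x$components$class == "lacuna")
  cat(sprintf("  %d canal component(s), %d lacuna component(s) (boundary %g um^3)\n",
              n_can, n_lac, x$lacuna_threshold))
  invisible(x)
}
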