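#' Grayscale and binary voxel volumes
#'
#' Light containers for 3D voxel grids with isotropic voxel size. The third
#' array axis is the stack axis and is taken to coincide with the bone's long
#' axis (z). World coordinates are in micrometres with the origin at the
#' volume corner; voxel `(i, j, k)` (1-based) has its centre at
#' `(i - 0.5, j - 0.5, k - 0.5) * voxel_size`.
#'
#' @param data 3D array; numeric grey values for [grayscale_volume()],
#'   logical for [binary_volume()].
#' @param voxel_size isotropic voxel edge length in micrometres.
#' @param label role tag for binary volumes, e.g. `"mineralised"`,
#'   `"solid_cortex"`, `"pores"`, `"canals"`, `"lacunae"`, `"exclusion"`.
#' @return An object of class `grayscale_volume` or `binary_volume`: a list
#'   with elements `data`, `voxel_size` and (binary only) `label`.
#' @examples
#' v <- grayscale_volume(array(runif(8 * 8 * 4), c(8, 8, 4)), voxel_size = 2)
#' dim(v$data)
#' @export
grayscale_volume <- function(data, voxel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a single positive number (micrometres)")
  structure(list(data = data, voxel_size = voxel_size),
            class = "grayscale_volume")
}

#' @rdname grayscale_volume
#' @export
binary_volume <- function(data, voxel_size, label = "mask") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.logical(data)) {
    storage.mode(data) <- "logical"
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a single positive number (micrometres)")
  structure(list(data = data, voxel_size = voxel_size, label = label),
            class = "binary_volume")
}

#' @export
print.grayscale_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<grayscale_volume> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  grey range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_volume:%s> %d x %d x %d voxels @ %g um, %d foreground\n",
              x$label, d[1], d[2], d[3], x$voxel_size, sum(x$data)))
  invisible(x)
}

as_volume_array <- function(x) {
  if (inherits(x, c("grayscale_volume", "binary_volume"))) x$data else x
}

check_same_shape <- function(a, b) {
  if (!identical(dim(as_volume_array(a)), dim(as_volume_array(b))))
    stop("volumes must have identical dimensions")
  invisible(TRUE)
}

#' Read and write volumes as multi-page TIFF
#'
#' Grayscale stacks are stored page-per-slice. Grey values are mapped to the
#' unit interval on write (`max_grey`, default 255 for 8-bit and 65535 for
#' 16-bit) and mapped back on read. Binary masks are written as 8-bit 0/255.
#'
#' @param path file path of the multi-page TIFF.
#' @param voxel_size isotropic voxel size in micrometres (TIFF files carry no
#'   reliable 3D calibration, so it must be supplied).
#' @param max_grey full-scale grey value used for normalisation.
#' @return [read_volume_tiff()] returns a [grayscale_volume()];
#'   [read_mask_tiff()] a [binary_volume()]. The writers return `path`
#'   invisibly.
#' @export
read_volume_tiff <- function(path, voxel_size, max_grey = 255) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  grayscale_volume(arr * max_grey, voxel_size)
}

#' @rdname read_volume_tiff
#' @param volume a [grayscale_volume()].
#' @param bits_per_sample 8 or 16.
#' @export
write_volume_tiff <- function(volume, path, max_grey = 255,
                              bits_per_sample = 8) {
  arr <- pmin(pmax(as_volume_array(volume) / max_grey, 0), 1)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' @rdname read_volume_tiff
#' @param label role tag attached to the mask on read.
#' @export
read_mask_tiff <- function(path, voxel_size, label = "mask") {
  v <- read_volume_tiff(path, voxel_size, max_grey = 255)
  binary_volume(v$data > 127, voxel_size, label = label)
}

#' @rdname read_volume_tiff
#' @param mask a [binary_volume()].
#' @export
write_mask_tiff <- function(mask, path) {
  arr <- as_volume_array(mask)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) (arr[, , k]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

# internal: squared EDT to the nearest TRUE voxel, in voxel units
edt_sq_to <- function(sites) {
  d <- dim(sites)
  cpp_edt_sq(as.logical(sites), as.integer(d))
}
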