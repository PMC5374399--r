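#' 3D image stack of one time point
#'
#' Container for a single- or multi-channel 3D fluorescence stack with
#' anisotropic voxel sizes, the native unit of the segmentation stage.
#' Arrays are indexed `[x, y, z]`; the physical position of voxel
#' `(ix, iy, iz)` is `((ix - 0.5) sx, (iy - 0.5) sy, (iz - 0.5) sz)` microns.
#'
#' @param data a 3D numeric array, or a list of equally sized 3D arrays
#'   (one per channel).
#' @param voxel_size `c(sx, sy, sz)` in microns, e.g. `c(0.1, 0.1, 0.44)`.
#' @param frame_index integer time point.
#' @return an object of class `image_stack` with fields `channels`,
#'   `voxel_size`, `frame_index`, `dim`.
#' @export
image_stack <- function(data, voxel_size, frame_index = 1L) {
  if (!is.list(data)) data <- list(data)
  stopifnot(length(data) >= 1L)
  d <- dim(data[[1L]])
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("each channel must be a 3D array with all dimensions >= 1")
  for (a in data) if (!identical(dim(a), d)) stop("channel dimensions differ")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(channels = data, voxel_size = as.numeric(voxel_size),
                 frame_index = as.integer(frame_index), dim = d),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> frame %d: %d x %d x %d voxels, %d channel(s), voxel %.3g x %.3g x %.3g um\n",
              x$frame_index, x$dim[1], x$dim[2], x$dim[3],
              length(x$channels), x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  invisible(x)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum over the z axis, the 2D view on which silhouette
#' contours and centroids are overlaid for visual track validation.
#'
#' @param stack an [image_stack].
#' @param channel channel index.
#' @return numeric matrix `[x, y]`.
#' @export
mip <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[channel]]
  do.call(pmax, lapply(seq_len(dim(a)[3L]), function(k) a[, , k]))
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages are taken as z-planes (z-major order). Voxel sizes are not stored
#' in plain TIFF and must be supplied.
#'
#' @param path TIFF file.
#' @param voxel_size `c(sx, sy, sz)` in microns.
#' @param frame_index integer time point to record.
#' @return an [image_stack].
#' @export
read_stack_tiff <- function(path, voxel_size, frame_index = 1L) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  # readTIFF returns row-major matrices [row = y, col = x]; transpose to [x, y]
  a <- array(0, c(ncol(pages[[1L]]), nrow(pages[[1L]]), nz))
  for (k in seq_len(nz)) a[, , k] <- t(pages[[k]])
  image_stack(a, voxel_size, frame_index)
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are linearly rescaled to `[0, 1]` over the whole stack
#' (constant stacks map to 0), the representation the `tiff` writer expects.
#'
#' @param stack an [image_stack].
#' @param path output file.
#' @param channel channel index.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, channel = 1L) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  a <- stack$channels[[channel]]
  rng <- range(a)
  a <- if (diff(rng) > 0) (a - rng[1L]) / diff(rng) else a * 0
  pages <- lapply(seq_len(dim(a)[3L]), function(k) t(a[, , k]))
  tiff::writeTIFF(pages, path)
  invisible(path)
}
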