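#' Threshold segmentation of a 3D stack
#'
#' Plumbing segmenter used to exercise the pipeline on synthetic stacks:
#' supra-threshold voxels are grouped into 26-connected 3D components, the
#' per-plane boundary contours of each component are extracted, and
#' components smaller than the minimum object volume are discarded (the
#' standard 5 um^3 filter against non-nuclear debris). ROIs keep the applied
#' threshold as their `optimal_threshold` feature.
#'
#' A merged pair of touching nuclei is one 26-connected component and is
#' returned as one ROI, carrying more than one contour on planes where its
#' lobes are disjoint; the shape-split post-processing stage is the tool
#' that separates such objects. Interior holes of a region are not
#' represented.
#'
#' @param stack an [image_stack].
#' @param threshold intensity threshold; voxels strictly above it are
#'   foreground.
#' @param min_object_volume minimum object volume in um^3.
#' @param channel channel to segment.
#' @return list of [roi3d] (empty for a blank stack), with per-frame ids
#'   `1..n` in raster order and intensity features from all channels.
#' @export
threshold_segment <- function(stack, threshold, min_object_volume = 5,
                              channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[channel]]
  d <- dim(a)
  fg <- a > threshold
  lin <- which(fg)
  if (!length(lin)) return(list())
  w <- arrayInd(lin, d)
  rank <- integer(prod(d))
  rank[lin] <- seq_along(lin)
  nbr_pairs <- function(dx, dy, dz) {
    x2 <- w[, 1L] + dx; y2 <- w[, 2L] + dy; z2 <- w[, 3L] + dz
    ok <- x2 >= 1L & x2 <= d[1L] & y2 >= 1L & y2 <= d[2L] &
          z2 >= 1L & z2 <= d[3L]
    n2 <- rank[(x2[ok] - 1L) + (y2[ok] - 1L) * d[1L] +
               (z2[ok] - 1L) * d[1L] * d[2L] + 1L]
    cbind(which(ok)[n2 > 0L], n2[n2 > 0L])
  }
  # 26-connected components in one graph (13 half-neighbourhood offsets)
  offs <- rbind(
    matrix(c(1, 0, 0,  0, 1, 0,  1, 1, 0,  1, -1, 0),          # in-plane
           ncol = 3, byrow = TRUE),
    unname(as.matrix(expand.grid(-1:1, -1:1, 1L))))            # next plane
  e_all <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
    nbr_pairs(offs[k, 1L], offs[k, 2L], offs[k, 3L])))
  g <- igraph::make_graph(t(e_all), n = length(lin), directed = FALSE)
  comp <- igraph::components(g)$membership
  # assemble ROIs: per component, per plane, one polygon per boundary loop
  vox_vol <- prod(stack$voxel_size)
  rois <- list()
  for (cc in unique(comp)) {
    vox <- w[comp == cc, , drop = FALSE]
    if (nrow(vox) * vox_vol < min_object_volume) next
    planes <- list()
    for (z in sort(unique(vox[, 3L]))) {
      loops <- trace_mask_outline(vox[vox[, 3L] == z, 1:2, drop = FALSE])
      for (l in loops) if (l$area > 0)
        planes[[length(planes) + 1L]] <-
          polygon2d(l$x, l$y, z_index = z, validate = FALSE)
    }
    rois[[length(rois) + 1L]] <-
      roi3d(planes, stack$voxel_size, roi_id = length(rois) + 1L,
            frame = stack$frame_index, stack = stack,
            optimal_threshold = threshold, provenance = "threshold")
  }
  # deterministic per-frame ids in raster order of the top plane
  ord <- order(vapply(rois, function(r) r$planes[[1L]]$z_index, 1L),
               vapply(rois, function(r) r$centroid[2L], 1),
               vapply(rois, function(r) r$centroid[1L], 1))
  rois <- rois[ord]
  for (i in seq_along(rois)) rois[[i]]$roi_id <- i
  rois
}

# union-find over per-plane regions; a union is skipped when the merged
# component would hold two regions on the same z-plane
.join_regions <- function(n, reg_z, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  zsets <- lapply(seq_len(n), function(i) reg_z[i])
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$a[k]); rb <- find(edges$b[k])
    if (ra == rb) next
    if (length(intersect(zsets[[ra]], zsets[[rb]]))) next
    parent[rb] <- ra
    zsets[[ra]] <- c(zsets[[ra]], zsets[[rb]])
  }
  vapply(seq_len(n), find, 1L)
}
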