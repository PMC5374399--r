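#' Planar contour of a nucleus on one focal plane
#'
#' Constructs a simple polygon given in pixel coordinates, attached to a
#' z-plane index. Vertex order is normalised to counter-clockwise. Polygons
#' are the atomic shape primitive of the pipeline: 3D nuclei are stacks of
#' one polygon per focal plane.
#'
#' @param x,y numeric vertex coordinates in pixel units (at least 3 vertices).
#' @param z_index integer focal-plane index (1-based).
#' @param validate check simplicity (no self-intersection). Validation is
#'   quadratic in the number of vertices; internal callers that construct
#'   polygons known to be simple (e.g. traced mask outlines) skip it.
#' @return an object of class `polygon2d` with fields `x`, `y`, `z_index`.
#' @export
polygon2d <- function(x, y, z_index = 1L, validate = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("invalid geometry: polygon needs >= 3 vertices")
  a <- .shoelace(x, y)
  if (abs(a) < .Machine$double.eps * 100)
    stop("invalid geometry: polygon has zero area")
  if (a < 0) { x <- rev(x); y <- rev(y) }   # normalise CCW
  if (validate && !.is_simple(x, y))
    stop("invalid geometry: polygon is self-intersecting")
  structure(list(x = x, y = y, z_index = as.integer(z_index)),
            class = "polygon2d")
}

#' @export
print.polygon2d <- function(x, ...) {
  cat(sprintf("<polygon2d> %d vertices, z = %d, area = %.2f px^2\n",
              length(x$x), x$z_index, .shoelace(x$x, x$y)))
  invisible(x)
}

# signed area, positive for counter-clockwise vertex order
.shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

.perimeter <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# simplicity check: no two non-adjacent edges touch
.is_simple <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    if (i == 1L) ks <- ks[ks != n]   # skip wrap-adjacent edge
    if (!length(ks)) next
    if (any(.segs_touch(x[i], y[i], x[j[i]], y[j[i]],
                        x[ks], y[ks], x[j[ks]], y[j[ks]])))
      return(FALSE)
  }
  TRUE
}

# vectorised: does segment (ax,ay)-(bx,by) touch any of the segments
# (px,py)-(qx,qy)?  Any contact, including collinear overlap or an endpoint
# on the other segment, counts as touching.
.segs_touch <- function(ax, ay, bx, by, px, py, qx, qy) {
  o1 <- .orient(ax, ay, bx, by, px, py)
  o2 <- .orient(ax, ay, bx, by, qx, qy)
  o3 <- .orient(px, py, qx, qy, ax, ay)
  o4 <- .orient(px, py, qx, qy, bx, by)
  proper <- (o1 * o2 < 0) & (o3 * o4 < 0)
  touch <- proper
  touch <- touch | (o1 == 0 & .on_seg(ax, ay, bx, by, px, py))
  touch <- touch | (o2 == 0 & .on_seg(ax, ay, bx, by, qx, qy))
  touch <- touch | (o3 == 0 & .on_seg(px, py, qx, qy, ax, ay))
  touch <- touch | (o4 == 0 & .on_seg(px, py, qx, qy, bx, by))
  touch
}

.orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  # snap tiny cross products to zero so collinear grid points are exact
  v[abs(v) < 1e-9] <- 0
  sign(v)
}

.on_seg <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) - 1e-9 & px <= pmax(ax, bx) + 1e-9 &
  py >= pmin(ay, by) - 1e-9 & py <= pmax(ay, by) + 1e-9
}

#' Polygon area in pixel and physical units
#'
#' Shoelace area of a planar contour. Physical area uses the in-plane voxel
#' sizes so that 1 px^2 corresponds to `sx * sy` square microns.
#'
#' @param p a [polygon2d].
#' @param pixel_size in-plane voxel size, either a scalar or `c(sx, sy)` in
#'   microns per pixel.
#' @return list with elements `px2` and `um2`.
#' @examples
#' polygon_area(polygon2d(c(0, 4, 0), c(0, 0, 3)))$px2   # 6
#' @export
polygon_area <- function(p, pixel_size = c(1, 1)) {
  stopifnot(inherits(p, "polygon2d"))
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  a <- abs(.shoelace(p$x, p$y))
  if (a == 0) stop("invalid geometry: degenerate polygon")
  list(px2 = a, um2 = a * pixel_size[1L] * pixel_size[2L])
}

#' Pixel rasterization of a polygon
#'
#' Returns the 1-based indices `(ix, iy)` of all pixels whose centres
#' `(ix - 0.5, iy - 0.5)` lie inside the polygon (even-odd rule,
#' boundary-touching centres count as inside). This single rasterization rule
#' is shared by all volume, overlap and intensity computations in the package.
#'
#' @param p a [polygon2d].
#' @return two-column integer matrix of pixel indices (possibly 0 rows).
#' @export
rasterize_polygon <- function(p) {
  ix <- seq.int(ceiling(min(p$x) + 0.5), floor(max(p$x) + 0.5))
  iy <- seq.int(ceiling(min(p$y) + 0.5), floor(max(p$y) + 0.5))
  if (!length(ix) || !length(iy))
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("ix", "iy"))))
  g <- expand.grid(ix = ix, iy = iy)
  inside <- pracma::inpolygon(g$ix - 0.5, g$iy - 0.5, p$x, p$y,
                              boundary = TRUE)
  m <- as.matrix(g[inside, , drop = FALSE])
  dimnames(m) <- list(NULL, c("ix", "iy"))
  m
}

#' 3D nucleus region of interest
#'
#' Builds a 3D ROI from a stack of per-plane contours on consecutive focal
#' planes and computes its derived features: voxel-counting volume, physical
#' centroid, projected silhouette and (optionally) per-channel intensity
#' statistics from an image stack.
#'
#' @param planes list of [polygon2d], one per plane, consecutive `z_index`.
#' @param voxel_size `c(sx, sy, sz)` in microns.
#' @param roi_id,frame integer identifiers (`roi_id` is scoped per frame).
#' @param stack optional [image_stack] used for intensity features.
#' @param optimal_threshold intensity threshold recorded by the segmenter.
#' @param provenance tag naming the originating segmentation layer.
#' @return an object of class `roi3d`.
#' @export
roi3d <- function(planes, voxel_size, roi_id = 1L, frame = 1L,
                  stack = NULL, optimal_threshold = NA_real_,
                  provenance = "primary") {
  if (!length(planes)) stop("empty roi: no planes")
  stopifnot(all(vapply(planes, inherits, TRUE, "polygon2d")))
  zs <- vapply(planes, function(p) p$z_index, 1L)
  planes <- planes[order(zs)]
  zs <- sort(zs)
  # an under-segmented (merged) object may carry more than one contour on a
  # plane, but the occupied z-range must be contiguous
  uz <- unique(zs)
  if (length(uz) > 1L && any(diff(uz) != 1L))
    stop("roi planes must lie on consecutive z-planes")
  geom <- roi_geometry(planes, voxel_size)
  r <- structure(list(
    roi_id = as.integer(roi_id), frame = as.integer(frame),
    planes = planes, voxel_size = voxel_size,
    volume = geom$volume, centroid = geom$centroid,
    silhouette = silhouette(planes),
    n_voxels = geom$n_voxels,
    optimal_threshold = optimal_threshold,
    provenance = provenance, intensity = list()
  ), class = "roi3d")
  if (!is.null(stack)) {
    for (ch in seq_along(stack$channels))
      r$intensity[[ch]] <- intensity_features(r, stack, channel = ch)
  }
  r
}

#' @export
print.roi3d <- function(x, ...) {
  cat(sprintf(
    "<roi3d> id %d frame %d: %d planes (z %d..%d), volume %.2f um^3, centroid (%.2f, %.2f, %.2f) um\n",
    x$roi_id, x$frame, length(x$planes), x$planes[[1]]$z_index,
    x$planes[[length(x$planes)]]$z_index, x$volume,
    x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Voxel-counting volume and centroid of a contour stack
#'
#' Volume is the number of voxel centres enclosed by any plane polygon
#' (even-odd rule) times the voxel volume; the centroid is the mean physical
#' coordinate of those voxel centres, with the physical position of voxel
#' `(ix, iy, iz)` taken as `((ix - 0.5) sx, (iy - 0.5) sy, (iz - 0.5) sz)`.
#'
#' @param planes a [roi3d] or a list of [polygon2d].
#' @param voxel_size `c(sx, sy, sz)` in microns.
#' @return list with `volume` (um^3), `centroid` (xyz, um), `n_voxels`.
#' @export
roi_geometry <- function(planes, voxel_size) {
  if (inherits(planes, "roi3d")) planes <- planes$planes
  if (!length(planes)) stop("empty roi: no planes")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  n <- 0L; sx <- 0; sy <- 0; sz <- 0
  for (p in planes) {
    px <- rasterize_polygon(p)
    if (!nrow(px)) next
    n <- n + nrow(px)
    sx <- sx + sum(px[, 1L] - 0.5)
    sy <- sy + sum(px[, 2L] - 0.5)
    sz <- sz + nrow(px) * (p$z_index - 0.5)
  }
  if (n == 0L) stop("empty roi: no voxel centres enclosed")
  vol <- n * prod(voxel_size)
  centroid <- c(sx / n * voxel_size[1L], sy / n * voxel_size[2L],
                sz / n * voxel_size[3L])
  names(centroid) <- c("x", "y", "z")
  list(volume = vol, centroid = centroid, n_voxels = n)
}

#' Silhouette contour of a 3D object
#'
#' Outer boundary of the union of all plane polygons projected onto the x-y
#' plane, computed on the shared pixel raster. If the projected union is
#' disconnected the largest component is returned and the number of
#' components is recorded in attribute `"multiplicity"`.
#'
#' @param planes a [roi3d] or list of [polygon2d].
#' @return a [polygon2d] (z-free, `z_index = 0`).
#' @export
silhouette <- function(planes) {
  if (inherits(planes, "roi3d")) planes <- planes$planes
  if (!length(planes)) stop("empty roi: no planes")
  px <- unique(do.call(rbind, lapply(planes, rasterize_polygon)))
  if (!nrow(px)) stop("empty roi: no voxel centres enclosed")
  loops <- trace_mask_outline(px)
  outer <- loops[vapply(loops, function(l) l$area > 0, TRUE)]
  outer <- outer[order(-vapply(outer, function(l) l$area, 1))]
  poly <- polygon2d(outer[[1L]]$x, outer[[1L]]$y, z_index = 0L,
                    validate = FALSE)
  attr(poly, "multiplicity") <- length(outer)
  poly
}

#' Intensity statistics of a ROI in an image stack
#'
#' Sum, mean and population standard deviation (divisor n) of the image
#' values at all voxel centres enclosed by the ROI's plane polygons.
#'
#' @param roi a [roi3d].
#' @param stack an [image_stack] of the same frame.
#' @param channel channel index.
#' @return named numeric vector `c(sum, mean, sd)`.
#' @export
intensity_features <- function(roi, stack, channel = 1L) {
  stopifnot(inherits(roi, "roi3d"), inherits(stack, "image_stack"))
  if (channel < 1L || channel > length(stack$channels))
    stop("channel out of range")
  a <- stack$channels[[channel]]
  d <- dim(a)
  vals <- numeric(0)
  for (p in roi$planes) {
    if (p$z_index < 1L || p$z_index > d[3L]) next
    px <- rasterize_polygon(p)
    keep <- px[, 1L] >= 1L & px[, 1L] <= d[1L] &
            px[, 2L] >= 1L & px[, 2L] <= d[2L]
    px <- px[keep, , drop = FALSE]
    if (!nrow(px)) next
    vals <- c(vals, a[cbind(px[, 1L], px[, 2L], p$z_index)])
  }
  if (!length(vals)) stop("empty roi: no voxels inside the stack")
  m <- mean(vals)
  c(sum = sum(vals), mean = m, sd = sqrt(mean((vals - m)^2)))
}

#' Trace the rectilinear outline of a pixel set
#'
#' Interprets each pixel `(ix, iy)` as the unit cell
#' `[ix-1, ix] x [iy-1, iy]` in pixel coordinates and returns the boundary
#' loops of the union of cells. Outer boundaries come out counter-clockwise
#' (positive area), hole boundaries clockwise. Collinear vertices are
#' removed. Rasterizing a returned outer loop recovers exactly the input
#' pixel set (pixel centres lie strictly inside their own cells).
#'
#' @param pixels two-column matrix of 1-based pixel indices.
#' @return list of loops, each a list with `x`, `y`, `area`.
#' @keywords internal
#' @export
trace_mask_outline <- function(pixels) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2L, nrow(pixels) >= 1L)
  ix <- as.integer(pixels[, 1L]); iy <- as.integer(pixels[, 2L])
  x0 <- min(ix) - 1L; y0 <- min(iy) - 1L
  nx <- max(ix) - x0 + 2L; ny <- max(iy) - y0 + 2L
  m <- matrix(FALSE, nx, ny)
  m[cbind(ix - x0, iy - y0)] <- TRUE
  has <- function(i, j) {
    ok <- i >= 1L & i <= nx & j >= 1L & j <= ny
    out <- logical(length(i)); out[ok] <- m[cbind(i[ok], j[ok])]
    out
  }
  w <- which(m, arr.ind = TRUE)
  ci <- w[, 1L]; cj <- w[, 2L]
  # directed boundary edges with cell interior on the left
  e <- list()
  b <- !has(ci, cj - 1L)  # bottom
  e[[1]] <- cbind(ci[b] - 1L, cj[b] - 1L, ci[b], cj[b] - 1L)
  b <- !has(ci + 1L, cj)  # right
  e[[2]] <- cbind(ci[b], cj[b] - 1L, ci[b], cj[b])
  b <- !has(ci, cj + 1L)  # top
  e[[3]] <- cbind(ci[b], cj[b], ci[b] - 1L, cj[b])
  b <- !has(ci - 1L, cj)  # left
  e[[4]] <- cbind(ci[b] - 1L, cj[b], ci[b] - 1L, cj[b] - 1L)
  ed <- do.call(rbind, e)
  nE <- nrow(ed)
  keyf <- function(i, j) i * (ny + 2L) + j
  starts <- keyf(ed[, 1L], ed[, 2L])
  ord <- order(starts)
  ed <- ed[ord, , drop = FALSE]
  starts <- starts[ord]
  first <- match(unique(starts), starts)
  idx_of <- new.env(hash = TRUE)
  us <- unique(starts)
  cnt <- c(diff(first), nE - first[length(first)] + 1L)
  for (k in seq_along(us))
    assign(as.character(us[k]), seq.int(first[k], length.out = cnt[k]),
           envir = idx_of)
  used <- logical(nE)
  loops <- list()
  for (s in seq_len(nE)) {
    if (used[s]) next
    cur <- s
    lx <- integer(0); ly <- integer(0)
    repeat {
      used[cur] <- TRUE
      lx <- c(lx, ed[cur, 1L]); ly <- c(ly, ed[cur, 2L])
      nxt_key <- as.character(keyf(ed[cur, 3L], ed[cur, 4L]))
      cand <- get0(nxt_key, envir = idx_of, ifnotfound = integer(0))
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # pinch vertex: prefer the sharpest left turn to keep loops closed
        din <- c(ed[cur, 3L] - ed[cur, 1L], ed[cur, 4L] - ed[cur, 2L])
        cross <- din[1L] * (ed[cand, 4L] - ed[cand, 2L]) -
                 din[2L] * (ed[cand, 3L] - ed[cand, 1L])
        cand <- cand[order(-cross)]
      }
      cur <- cand[1L]
    }
    # drop collinear vertices
    n <- length(lx)
    if (n >= 3L) {
      jp <- c(n, seq_len(n - 1L)); jn <- c(2:n, 1L)
      keep <- (lx[jn] - lx[jp]) * (ly - ly[jp]) !=
              (ly[jn] - ly[jp]) * (lx - lx[jp])
      lx <- lx[keep]; ly <- ly[keep]
    }
    if (length(lx) >= 3L)
      loops[[length(loops) + 1L]] <-
        list(x = lx + x0, y = ly + y0, area = .shoelace(lx, ly))
  }
  loops
}
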