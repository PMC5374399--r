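#' Constraints of the shape-split operation
#'
#' The shape-split algorithm separates touching nuclei by cutting a polygon
#' along the shortest chord between two contour vertices that satisfies
#' three constraints: the input polygon is large enough to be a merged
#' object, the smaller output piece is large enough to be a nucleus
#' cross-section, and the cut is short relative to the smaller piece (cuts
#' happen at waists, not across round bodies).
#'
#' @param min_input_area minimum input polygon area (px^2; 700 px = 7 um^2
#'   at 0.1 um pixels).
#' @param min_output_perimeter minimum perimeter of the smaller output
#'   polygon (px; the chord counts towards the perimeter).
#' @param max_cut_ratio maximum ratio of cut length to the smaller output
#'   polygon's perimeter.
#' @param volume_range volumes (um^3) of 3D objects eligible for splitting.
#' @param overlap_fraction minimum overlap (relative to the smaller polygon)
#'   joining polygons of consecutive planes during 3D reconstruction.
#' @return an object of class `split_constraints`.
#' @export
split_constraints <- function(min_input_area = 700,
                              min_output_perimeter = 70,
                              max_cut_ratio = 0.3,
                              volume_range = c(10, 1000),
                              overlap_fraction = 0.5) {
  stopifnot(min_input_area > 0, min_output_perimeter > 0,
            max_cut_ratio > 0, max_cut_ratio < 1,
            length(volume_range) == 2L, volume_range[1L] < volume_range[2L],
            all(volume_range > 0), overlap_fraction >= 0)
  structure(list(min_input_area = min_input_area,
                 min_output_perimeter = min_output_perimeter,
                 max_cut_ratio = max_cut_ratio,
                 volume_range = volume_range,
                 overlap_fraction = overlap_fraction),
            class = "split_constraints")
}

#' Split a polygon along the shortest admissible chord
#'
#' Recursively cuts a simple polygon along the shortest chord between two
#' non-adjacent vertices that lies strictly inside the polygon and satisfies
#' the [split_constraints]; splitting repeats on both pieces until no piece
#' admits a cut. Polygons below the minimum input area are returned
#' unchanged. Equal-length chords are broken by the lexicographically
#' smallest vertex-index pair. The chord has zero area, so the piece areas
#' always sum to the input area.
#'
#' @param p a [polygon2d] (simple).
#' @param constraints a [split_constraints].
#' @param validate check input simplicity.
#' @return list of [polygon2d] (length 1 when no admissible cut exists).
#' @export
shape_split_polygon <- function(p, constraints = split_constraints(),
                                validate = TRUE) {
  stopifnot(inherits(p, "polygon2d"))
  if (validate && !.is_simple(p$x, p$y))
    stop("invalid geometry: polygon is self-intersecting")
  .split_rec(p, constraints, depth = 0L)
}

.split_rec <- function(p, cons, depth) {
  if (depth > 64L) return(list(p))
  if (abs(.shoelace(p$x, p$y)) < cons$min_input_area) return(list(p))
  cut <- .best_chord(p$x, p$y, cons)
  if (is.null(cut)) return(list(p))
  i <- cut[1L]; j <- cut[2L]
  p1 <- polygon2d(p$x[i:j], p$y[i:j], p$z_index, validate = FALSE)
  idx2 <- c(j:length(p$x), 1:i)
  p2 <- polygon2d(p$x[idx2], p$y[idx2], p$z_index, validate = FALSE)
  c(.split_rec(p1, cons, depth + 1L), .split_rec(p2, cons, depth + 1L))
}

# shortest admissible chord between two non-adjacent vertices, or NULL.
# cheap perimeter/ratio prechecks are vectorised over all vertex pairs;
# the strict-interiority test runs only on surviving candidates in order
# of increasing length (ties: smallest index pair).
.best_chord <- function(x, y, cons) {
  n <- length(x)
  if (n < 4L) return(NULL)
  ii <- rep(seq_len(n - 2L), times = (n - 2L):1L)
  jj <- sequence((n - 2L):1L) + ii + 1L
  wrap <- ii == 1L & jj == n
  ii <- ii[!wrap]; jj <- jj[!wrap]
  if (!length(ii)) return(NULL)
  len <- sqrt((x[jj] - x[ii])^2 + (y[jj] - y[ii])^2)
  # piece areas and perimeters from cumulative sums
  nx2 <- c(x[-1L], x[1L]); ny2 <- c(y[-1L], y[1L])
  cr <- cumsum(x * ny2 - y * nx2)           # cross(v_k, v_{k+1})
  el <- cumsum(sqrt((nx2 - x)^2 + (ny2 - y)^2))
  tot_a <- cr[n] / 2
  tot_p <- el[n]
  cr0 <- c(0, cr); el0 <- c(0, el)   # cr0[k] = sum over edges 1..k-1
  seg_cr <- cr0[jj] - cr0[ii]
  a1 <- abs((seg_cr + x[jj] * y[ii] - y[jj] * x[ii]) / 2)
  a2 <- abs(tot_a) - a1
  per1 <- (el0[jj] - el0[ii]) + len
  per2 <- tot_p - (per1 - len) + len
  per_small <- ifelse(a1 <= a2, per1, per2)
  ok <- len > 0 & a1 > 0 & a2 > 0 &
        per_small >= cons$min_output_perimeter &
        len / per_small <= cons$max_cut_ratio
  if (!any(ok)) return(NULL)
  ord <- order(len, ii, jj)
  ord <- ord[ok[ord]]
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  for (k in ord) {
    i <- ii[k]; j <- jj[k]
    # edges not incident to either chord endpoint
    excl <- c(i, prv[i], j, prv[j])
    es <- setdiff(seq_len(n), excl)
    if (length(es) &&
        any(.segs_touch(x[i], y[i], x[j], y[j],
                        x[es], y[es], x[nxt[es]], y[nxt[es]])))
      next
    mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
    if (!pracma::inpolygon(mx, my, x, y, boundary = FALSE)) next
    return(c(i, j))
  }
  NULL
}

#' Reconstruct 3D objects from per-plane polygons
#'
#' Polygons on consecutive focal planes are joined when their rasterized
#' overlap, relative to the smaller polygon, reaches `overlap_fraction`
#' (default 50%); connected components of the join graph become 3D ROIs.
#' With `overlap_fraction = 0` any positive overlap joins; with a fraction
#' above 1 nothing joins. Joins are applied in decreasing order of overlap
#' fraction, and a join that would give an ROI two polygons on one plane is
#' skipped.
#'
#' @param polys list of [polygon2d] with their `z_index` set.
#' @param overlap_fraction minimum overlap fraction.
#' @param voxel_size `c(sx, sy, sz)` microns, for ROI features.
#' @param frame frame index for the resulting ROIs.
#' @param stack optional [image_stack] for intensity features.
#' @return list of [roi3d].
#' @export
reconstruct_3d <- function(polys, overlap_fraction = 0.5,
                           voxel_size = c(1, 1, 1), frame = 1L,
                           stack = NULL) {
  stopifnot(all(vapply(polys, inherits, TRUE, "polygon2d")))
  np <- length(polys)
  if (!np) return(list())
  zs <- vapply(polys, function(p) p$z_index, 1L)
  keysets <- lapply(polys, function(p) {
    px <- rasterize_polygon(p)
    px[, 1L] + px[, 2L] * 2^20
  })
  sizes <- lengths(keysets)
  edges <- NULL
  for (z in sort(unique(zs))) {
    a_idx <- which(zs == z); b_idx <- which(zs == z + 1L)
    if (!length(a_idx) || !length(b_idx)) next
    for (a in a_idx) for (b in b_idx) {
      ovl <- length(intersect(keysets[[a]], keysets[[b]]))
      if (ovl == 0L) next
      frac <- ovl / min(sizes[a], sizes[b])
      if (frac >= overlap_fraction)
        edges <- rbind(edges, data.frame(a = a, b = b, n = frac))
    }
  }
  memb <- seq_len(np)
  if (!is.null(edges) && nrow(edges)) {
    edges <- edges[order(-edges$n, edges$a, edges$b), ]
    memb <- .join_regions(np, zs, edges)
  }
  comps <- split(seq_len(np), memb[seq_len(np)])
  rois <- lapply(comps, function(idx)
    roi3d(polys[idx], voxel_size, frame = frame, stack = stack,
          provenance = "reconstructed"))
  ord <- order(vapply(rois, function(r) r$planes[[1L]]$z_index, 1L),
               vapply(rois, function(r) r$centroid[2L], 1),
               vapply(rois, function(r) r$centroid[1L], 1))
  rois <- rois[ord]
  names(rois) <- NULL
  for (i in seq_along(rois)) rois[[i]]$roi_id <- i
  rois
}

#' Shape-split all eligible ROIs of a segmentation layer
#'
#' Applies [shape_split_polygon()] to every plane polygon of each ROI whose
#' volume lies inside `constraints$volume_range`, then rebuilds 3D objects
#' with [reconstruct_3d()] and recomputes their features. ROIs outside the
#' volume range pass through untouched. The operation is idempotent: pieces
#' that admit no further cut are returned unchanged by a second pass.
#'
#' @param rois list of [roi3d] (one segmentation layer of one frame).
#' @param constraints a [split_constraints].
#' @param stack optional [image_stack] for recomputing intensity features.
#' @return list of [roi3d]: the new layer, ids renumbered per frame.
#' @export
split_layer <- function(rois, constraints = split_constraints(),
                        stack = NULL) {
  if (!length(rois)) return(list())
  vols <- vapply(rois, function(r) r$volume, 1)
  eligible <- vols >= constraints$volume_range[1L] &
              vols <= constraints$volume_range[2L]
  out <- rois[!eligible]
  todo <- rois[eligible]
  if (length(todo)) {
    vs <- todo[[1L]]$voxel_size
    frame <- todo[[1L]]$frame
    pieces <- list()
    for (r in todo) for (p in r$planes)
      pieces <- c(pieces, shape_split_polygon(p, constraints,
                                              validate = FALSE))
    out <- c(out, reconstruct_3d(pieces, constraints$overlap_fraction,
                                 voxel_size = vs, frame = frame,
                                 stack = stack))
  }
  for (i in seq_along(out)) out[[i]]$roi_id <- i
  out
}

#' Segmentation layers and the composite layer of one frame
#'
#' A frame can carry ROI sets from several segmentation methods (layers);
#' the composite layer is the curated combination actually used downstream.
#' The composite is initialised from one layer and then edited by removing
#' wrong objects and substituting objects from other layers. No two
#' composite ROIs may share more than half of their silhouette (relative to
#' the smaller silhouette).
#'
#' @param layers named list of ROI lists (each a list of [roi3d]).
#' @param composite_from name of the layer that seeds the composite.
#' @return an object of class `layer_set` with fields `layers`, `composite`.
#' @export
layer_set <- function(layers, composite_from = names(layers)[1L]) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            !is.null(names(layers)), composite_from %in% names(layers))
  comp <- layers[[composite_from]]
  for (i in seq_along(comp)) comp[[i]]$provenance <- composite_from
  structure(list(layers = layers, composite = comp), class = "layer_set")
}

#' @export
print.layer_set <- function(x, ...) {
  cat(sprintf("<layer_set> %d layer(s): %s; composite: %d ROI(s)\n",
              length(x$layers),
              paste(sprintf("%s (%d)", names(x$layers), lengths(x$layers)),
                    collapse = ", "),
              length(x$composite)))
  invisible(x)
}

# silhouette overlap fraction relative to the smaller silhouette
.sil_overlap <- function(a, b) {
  ka <- rasterize_polygon(a$silhouette)
  kb <- rasterize_polygon(b$silhouette)
  ka <- ka[, 1L] + ka[, 2L] * 2^20
  kb <- kb[, 1L] + kb[, 2L] * 2^20
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Edit the composite segmentation of a frame
#'
#' Removes ROIs from the composite and substitutes ROIs taken from named
#' layers, recording their provenance. An addition that would overlap an
#' existing composite ROI by more than 50% of the smaller silhouette is
#' rejected with a conflict report.
#'
#' @param ls a [layer_set].
#' @param remove_ids ROI ids to drop from the composite.
#' @param add_refs data frame with columns `layer` and `id` naming ROIs to
#'   pull into the composite.
#' @return the updated [layer_set].
#' @export
substitute_roi <- function(ls, remove_ids = integer(0), add_refs = NULL) {
  stopifnot(inherits(ls, "layer_set"))
  comp_ids <- vapply(ls$composite, function(r) r$roi_id, 1L)
  if (!all(remove_ids %in% comp_ids))
    stop("remove_ids not present in composite: ",
         paste(setdiff(remove_ids, comp_ids), collapse = ", "))
  comp <- ls$composite[!comp_ids %in% remove_ids]
  if (!is.null(add_refs)) {
    stopifnot(all(c("layer", "id") %in% names(add_refs)))
    for (k in seq_len(nrow(add_refs))) {
      lay <- as.character(add_refs$layer[k])
      if (!lay %in% names(ls$layers)) stop("unknown layer: ", lay)
      src <- ls$layers[[lay]]
      ids <- vapply(src, function(r) r$roi_id, 1L)
      pos <- match(add_refs$id[k], ids)
      if (is.na(pos))
        stop("ROI ", add_refs$id[k], " not found in layer ", lay)
      cand <- src[[pos]]
      ovl <- vapply(comp, .sil_overlap, 1, b = cand)
      if (any(ovl > 0.5))
        stop(sprintf(
          "conflict: ROI %d from layer '%s' overlaps composite ROI(s) %s by > 50%%",
          cand$roi_id, lay,
          paste(vapply(comp[ovl > 0.5], function(r) r$roi_id, 1L),
                collapse = ", ")))
      cand$provenance <- lay
      comp[[length(comp) + 1L]] <- cand
    }
  }
  ls$composite <- comp
  ls
}
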