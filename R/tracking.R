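## Frame-to-frame assignment and lineage construction.

# accept either a list of roi3d or a data frame with id/x/y/z columns
.centroid_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "x", "y", "z") %in% names(x)))
    df <- x[, c("id", "x", "y", "z")]
  } else {
    df <- data.frame(
      id = vapply(x, function(r) r$roi_id, 1L),
      x = vapply(x, function(r) r$centroid[1L], 1),
      y = vapply(x, function(r) r$centroid[2L], 1),
      z = vapply(x, function(r) r$centroid[3L], 1))
  }
  df[order(df$id), , drop = FALSE]
}

#' Bilateral nearest-neighbour assignment between two frames
#'
#' Pairs ROI centroids of adjacent frames: a pair `(a, b)` is kept iff `b`
#' is `a`'s nearest centroid in the next frame, `a` is `b`'s nearest in the
#' previous frame, and their 3D Euclidean distance does not exceed
#' `max_distance`. Unmatched ROIs are left unassigned. Nearest-neighbour
#' ties are broken towards the lower ROI id.
#'
#' @param prev,next_ ROIs of the earlier / later frame: lists of [roi3d] or
#'   data frames with columns id, x, y, z (um).
#' @param max_distance assignment gate in microns (default unbounded, the
#'   behaviour of the interactive tracker).
#' @param frame frame index recorded with the assignment.
#' @return an object of class `assignment`: data frame with columns `frame`,
#'   `from`, `to`, `dist`.
#' @export
bilateral_nn <- function(prev, next_, max_distance = Inf, frame = 1L) {
  a <- .centroid_table(prev)
  b <- .centroid_table(next_)
  out <- data.frame(frame = integer(0), from = integer(0), to = integer(0),
                    dist = numeric(0))
  if (nrow(a) && nrow(b)) {
    d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
          outer(a$z, b$z, "-")^2
    fwd <- max.col(-d2, ties.method = "first")        # a's nearest b
    bwd <- max.col(-t(d2), ties.method = "first")     # b's nearest a
    mutual <- bwd[fwd] == seq_len(nrow(a))
    dist <- sqrt(d2[cbind(seq_len(nrow(a)), fwd)])
    keep <- mutual & dist <= max_distance
    out <- data.frame(frame = rep(as.integer(frame), sum(keep)),
                      from = a$id[keep], to = b$id[fwd[keep]],
                      dist = dist[keep])
  }
  rownames(out) <- NULL
  class(out) <- c("assignment", "data.frame")
  out
}

#' Track a whole series of frames
#'
#' Runs [bilateral_nn()] over every adjacent frame pair.
#'
#' @param frames list of per-frame ROI sets (lists of [roi3d] or centroid
#'   data frames), in temporal order.
#' @param max_distance assignment gate in microns.
#' @return data frame of links (columns frame, from, to, dist) across all
#'   frame pairs.
#' @export
track_series <- function(frames, max_distance = Inf) {
  links <- lapply(seq_len(length(frames) - 1L), function(t)
    bilateral_nn(frames[[t]], frames[[t + 1L]], max_distance, frame = t))
  out <- do.call(rbind, links)
  rownames(out) <- NULL
  out
}

#' Lineage graph of tracked nuclei
#'
#' Builds the directed frame-ordered graph from automatic assignments plus
#' manual edits. Nodes are `(frame, id)` pairs, every edge spans exactly one
#' frame step. In-degree is capped at 2 (a collision of two nuclei),
#' out-degree at 2 (a division); an edit that would exceed a cap is
#' rejected. The edit log is retained in order.
#'
#' @param assignments data frame of links (frame, from, to), e.g. from
#'   [track_series()] or a scene's ground-truth links.
#' @param edits optional data frame with columns `action` ("add" or
#'   "remove"), `frame`, `from`, `to`, applied in row order.
#' @param nodes optional data frame (frame, id) declaring all nodes,
#'   including unlinked ones; defaults to the nodes named by the edges.
#' @return an object of class `lineage_graph` with fields `nodes`, `edges`,
#'   `edits`.
#' @export
build_lineage <- function(assignments, edits = NULL, nodes = NULL) {
  ed <- unique(data.frame(frame = as.integer(assignments$frame),
                          from = as.integer(assignments$from),
                          to = as.integer(assignments$to)))
  log <- list()
  if (!is.null(edits) && nrow(edits)) {
    stopifnot(all(c("action", "frame", "from", "to") %in% names(edits)))
    for (k in seq_len(nrow(edits))) {
      e <- edits[k, ]
      hit <- ed$frame == e$frame & ed$from == e$from & ed$to == e$to
      if (e$action == "remove") {
        ed <- ed[!hit, , drop = FALSE]
      } else if (e$action == "add") {
        if (!any(hit)) {
          outd <- sum(ed$frame == e$frame & ed$from == e$from)
          ind <- sum(ed$frame == e$frame & ed$to == e$to)
          if (outd >= 2L)
            stop("edit rejected: out-degree cap at frame ", e$frame,
                 " id ", e$from)
          if (ind >= 2L)
            stop("edit rejected: in-degree cap at frame ", e$frame + 1L,
                 " id ", e$to)
          ed <- rbind(ed, data.frame(frame = e$frame, from = e$from,
                                     to = e$to))
        }
      } else stop("unknown edit action: ", e$action)
      log[[length(log) + 1L]] <- e
    }
  }
  if (is.null(nodes)) {
    nodes <- unique(rbind(data.frame(frame = ed$frame, id = ed$from),
                          data.frame(frame = ed$frame + 1L, id = ed$to)))
  }
  nodes <- nodes[order(nodes$frame, nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(ed) <- NULL
  structure(list(nodes = nodes, edges = ed,
                 edits = if (length(log)) do.call(rbind, log) else NULL),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("<lineage_graph> %d nodes, %d edges over frames %d..%d, %d edit(s)\n",
              nrow(x$nodes), nrow(x$edges),
              min(x$nodes$frame), max(x$nodes$frame),
              if (is.null(x$edits)) 0L else nrow(x$edits)))
  invisible(x)
}

#' Infer collision links from unmatched predecessors
#'
#' Auto-merge rule used when two mitotic figures fuse and the segmenter sees
#' one object: an unmatched ROI of the earlier frame whose x-y centroid
#' falls inside the silhouette of a successor ROI is linked to it, provided
#' the successor's in-degree stays at most 2.
#'
#' @param prev,next_ lists of [roi3d] of the two frames.
#' @param assignment an [bilateral_nn()] assignment between them.
#' @return data frame of extra links (frame, from, to) to append.
#' @export
infer_merge_links <- function(prev, next_, assignment) {
  prev_ids <- vapply(prev, function(r) r$roi_id, 1L)
  unmatched <- prev[!prev_ids %in% assignment$from]
  extra <- NULL
  indeg <- table(assignment$to)
  for (r in unmatched) {
    for (s in next_) {
      vs <- s$voxel_size
      cx <- r$centroid[1L] / vs[1L]   # centroid in pixel coordinates
      cy <- r$centroid[2L] / vs[2L]
      if (pracma::inpolygon(cx, cy, s$silhouette$x, s$silhouette$y,
                            boundary = TRUE)) {
        deg <- sum(assignment$to == s$roi_id) +
               sum(extra$to == s$roi_id)
        if (deg < 2L)
          extra <- rbind(extra, data.frame(frame = assignment$frame[1L],
                                           from = r$roi_id,
                                           to = s$roi_id))
        break
      }
    }
  }
  if (is.null(extra))
    extra <- data.frame(frame = integer(0), from = integer(0),
                        to = integer(0))
  extra
}

#' Detect divisions and chromosome collisions in a lineage
#'
#' Divisions are nodes with out-degree 2. Candidate collisions are nodes
#' with in-degree 2; they are accepted as chromosome collisions when the
#' child volume is consistent with the sum of the parent volumes
#' (`|V_child - (V_p1 + V_p2)| / (V_p1 + V_p2) <= volume_tol`), otherwise
#' they are flagged as suspect segmentation merges. Each collision is
#' annotated with its mitotic phase (metaphase when the fused node itself is
#' in metaphase, anaphase when its parents were in anaphase) and with the
#' nuclear cycle of its parents.
#'
#' The per-cycle collision fraction counts two involved nuclei per event
#' among the nuclei belonging to that cycle (collision products themselves
#' are not double-counted as cycle members).
#'
#' @param g a [lineage_graph].
#' @param features data frame with columns frame, id, volume (e.g.
#'   [objects_table()] output or a scene's `nuclei` table).
#' @param annotation data frame with columns frame, id, phase, cycle (e.g. a
#'   scene's `nuclei` table).
#' @param volume_tol relative tolerance of the collision volume check.
#' @return list with `divisions`, `collisions`, `suspects` (data frames),
#'   `per_cycle` (cycle, n, involved, fraction), `phase_tally` and
#'   `anaphase_share`.
#' @export
detect_events <- function(g, features, annotation, volume_tol = 0.35) {
  stopifnot(inherits(g, "lineage_graph"))
  ed <- g$edges
  fkey <- paste(features$frame, features$id)
  akey <- paste(annotation$frame, annotation$id)
  vol_of <- function(frame, id) features$volume[match(paste(frame, id), fkey)]
  phase_of <- function(frame, id)
    annotation$phase[match(paste(frame, id), akey)]
  cycle_of <- function(frame, id)
    annotation$cycle[match(paste(frame, id), akey)]

  # divisions: out-degree-2 nodes (rows sorted so pair members are adjacent)
  o <- order(ed$frame, ed$from, ed$to)
  es <- ed[o, ]
  outk <- paste(es$frame, es$from)
  second <- which(duplicated(outk))
  first <- second - 1L
  divisions <- if (length(second)) data.frame(
    frame = es$frame[first], id = es$from[first],
    child1 = es$to[first], child2 = es$to[second],
    cycle = cycle_of(es$frame[first], es$from[first])) else NULL

  # collisions: in-degree 2 plus the volume consistency check
  o <- order(ed$frame, ed$to, ed$from)
  es <- ed[o, ]
  ink <- paste(es$frame, es$to)
  second <- which(duplicated(ink))
  first <- second - 1L
  collisions <- NULL; suspects <- NULL
  if (length(second)) {
    f <- es$frame[first]; child <- es$to[first]
    p1 <- es$from[first]; p2 <- es$from[second]
    vsum <- vol_of(f, p1) + vol_of(f, p2)
    vchild <- vol_of(f + 1L, child)
    chp <- phase_of(f + 1L, child)
    pap <- phase_of(f, p1)
    phase <- ifelse(!is.na(chp) & chp == "metaphase", "metaphase",
             ifelse(!is.na(pap) & pap == "anaphase", "anaphase",
                    ifelse(!is.na(chp), chp, pap)))
    rec <- data.frame(
      frame = f + 1L, id = child, parent1 = p1, parent2 = p2,
      v_child = vchild, v_parents = vsum,
      v_error = abs(vchild - vsum) / vsum,
      phase = phase, cycle = cycle_of(f, p1))
    okv <- !is.na(rec$v_error) & rec$v_error <= volume_tol
    collisions <- if (any(okv)) rec[okv, , drop = FALSE] else NULL
    suspects <- if (any(!okv)) rec[!okv, , drop = FALSE] else NULL
  }

  # per-cycle involvement: 2 nuclei per event / nuclei entering that cycle.
  # A metaphase-fused figure appears mid-cycle as a stand-in for its two
  # parents, so it is not an entrant of the cycle; an anaphase-fused nucleus
  # is born at the next cycle's start and does count there.
  per_cycle <- NULL
  if (!is.null(annotation$cycle)) {
    first_seen <- annotation[!duplicated(annotation$id), ]
    met <- function(df) if (is.null(df)) integer(0) else
      df$id[df$phase == "metaphase"]
    merge_children <- c(met(collisions), met(suspects))
    members <- first_seen[!first_seen$id %in% merge_children, ]
    n_by_cycle <- table(members$cycle)
    ev_by_cycle <- if (is.null(collisions)) integer(0) else
      table(collisions$cycle)
    cycles <- sort(unique(members$cycle))
    per_cycle <- data.frame(
      cycle = cycles,
      n = as.integer(n_by_cycle[as.character(cycles)]),
      involved = vapply(cycles, function(cc) {
        v <- ev_by_cycle[as.character(cc)]
        2L * (if (is.na(v) || !length(v)) 0L else as.integer(v))
      }, 1L))
    per_cycle$fraction <- per_cycle$involved / per_cycle$n
  }
  tally <- if (is.null(collisions)) table(character(0)) else
    table(collisions$phase)
  list(
    divisions = divisions, collisions = collisions, suspects = suspects,
    per_cycle = per_cycle, phase_tally = tally,
    anaphase_share = if (sum(tally) > 0)
      as.numeric(tally["anaphase"]) / sum(tally) else NA_real_)
}

#' Compare predicted links with ground truth
#'
#' True positives are links present in both sets, false negatives are
#' truth-only, false positives are prediction-only; recall and precision
#' follow. Every parent-daughter link of a division counts separately.
#'
#' @param pred,truth data frames of links with columns frame, from, to.
#' @return an object of class `tracking_metrics`: list with `tp`, `fn`,
#'   `fp`, `recall`, `precision` and displacement statistics of the
#'   predicted links when a `dist` column is present.
#' @export
evaluate_tracking <- function(pred, truth) {
  pk <- paste(pred$frame, pred$from, pred$to)
  tk <- paste(truth$frame, truth$from, truth$to)
  tp <- sum(pk %in% tk)
  fn <- length(tk) - tp
  fp <- length(pk) - tp
  if (!length(tk)) {
    warning("empty ground truth: recall undefined")
    recall <- NaN
  } else recall <- tp / (tp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  disp <- if (!is.null(pred$dist))
    c(mean = mean(pred$dist), sd = stats::sd(pred$dist),
      median = stats::median(pred$dist)) else NULL
  structure(list(tp = tp, fn = fn, fp = fp, recall = recall,
                 precision = precision, displacement = disp),
            class = "tracking_metrics")
}

#' @export
print.tracking_metrics <- function(x, ...) {
  cat(sprintf("<tracking_metrics> TP %d, FN %d, FP %d | recall %.1f%%, precision %.1f%%\n",
              x$tp, x$fn, x$fp, 100 * x$recall, 100 * x$precision))
  if (!is.null(x$displacement))
    cat(sprintf("  displacement: mean %.2f um, sd %.2f, median %.2f\n",
                x$displacement["mean"], x$displacement["sd"],
                x$displacement["median"]))
  invisible(x)
}
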