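## Population- and track-level quantification.

# accept roi3d lists or data frames with x/y/z/volume columns
.feature_table <- function(rois) {
  if (is.data.frame(rois)) {
    stopifnot(all(c("x", "y", "z", "volume") %in% names(rois)))
    rois
  } else {
    data.frame(
      id = vapply(rois, function(r) r$roi_id, 1L),
      x = vapply(rois, function(r) r$centroid[1L], 1),
      y = vapply(rois, function(r) r$centroid[2L], 1),
      z = vapply(rois, function(r) r$centroid[3L], 1),
      volume = vapply(rois, function(r) r$volume, 1))
  }
}

#' Convex-hull area of a point set
#'
#' @param x,y coordinates in microns.
#' @return list with `area` (um^2) and `hull` (indices of hull vertices in
#'   counter-clockwise order).
#' @export
hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) stop("degenerate hull: fewer than 3 extreme points")
  a <- .shoelace(x[h], y[h])
  if (a < 0) h <- rev(h)
  list(area = abs(a), hull = h)
}

#' Nuclear density and volume-to-hull ratio of one frame
#'
#' Eligible nuclei (volume and centroid depth inside the given ranges) are
#' enclosed by the convex hull of their x-y centroids. Nuclear density (ND)
#' is the eligible count per 1000 um^2 of hull area; the volume-to-hull
#' ratio (VHR) is the summed eligible nuclear volume divided by the hull
#' area, a tracking-free proxy for the nuclear-to-cytoplasmic ratio.
#'
#' @param rois list of [roi3d] or data frame with x, y, z, volume (um).
#' @param volume_range eligibility gate on volume (um^3).
#' @param depth_range eligibility gate on centroid depth below the first
#'   imaged plane (um).
#' @param frame frame index carried into the record.
#' @param t_min minutes since the last synchronized anaphase, if known.
#' @return one-row data frame (class `density_record`): frame, n, hull_area,
#'   nd, vhr, t_min.
#' @export
nuclear_density <- function(rois, volume_range = c(10, 1000),
                            depth_range = c(0, 25), frame = NA_integer_,
                            t_min = NA_real_) {
  d <- .feature_table(rois)
  keep <- d$volume >= volume_range[1L] & d$volume <= volume_range[2L] &
          d$z >= depth_range[1L] & d$z <= depth_range[2L]
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("degenerate hull: fewer than 3 eligible nuclei")
  h <- hull_area(d$x, d$y)
  out <- data.frame(frame = frame, n = nrow(d), hull_area = h$area,
                    nd = nrow(d) / h$area * 1000,
                    vhr = sum(d$volume) / h$area, t_min = t_min)
  class(out) <- c("density_record", "data.frame")
  out
}

#' Volume-to-hull ratio
#'
#' @param volumes eligible nuclear volumes (um^3).
#' @param hull_area enclosing hull area (um^2).
#' @return VHR in um^3 per um^2.
#' @export
vhr <- function(volumes, hull_area) {
  stopifnot(hull_area > 0)
  if (!length(volumes)) stop("zero eligible nuclei")
  sum(volumes) / hull_area
}

#' Frame of the last synchronized mitosis
#'
#' The last frame whose division events (within a two-frame window) affect
#' at least the given fraction of the nuclei present, used to align time
#' series between embryos ("minutes since last synchronized anaphase").
#'
#' @param events event log with columns frame, type (from a scene or
#'   [detect_events()] divisions).
#' @param nuclei per-frame nucleus table with columns frame, id.
#' @param min_fraction fraction of nuclei that must divide.
#' @return anaphase frame index, or `NA` if no synchronized mitosis exists.
#' @export
find_last_sync_mitosis <- function(events, nuclei, min_fraction = 0.8) {
  div <- events[events$type == "division", , drop = FALSE]
  if (!nrow(div)) return(NA_integer_)
  frames <- sort(unique(div$frame), decreasing = TRUE)
  for (f in frames) {
    n_div <- sum(div$frame >= f - 2L & div$frame <= f + 2L)
    n_all <- sum(nuclei$frame == f)
    if (n_all > 0 && n_div / n_all >= min_fraction) return(f)
  }
  NA_integer_
}

#' Density time series of a scene or tracked dataset
#'
#' Applies [nuclear_density()] to every frame and aligns time to the last
#' synchronized anaphase.
#'
#' @param nuclei per-frame table with columns frame, x, y, z, volume.
#' @param events event log (frame, type) used for alignment; optional.
#' @param frame_interval_s seconds per frame.
#' @param volume_range,depth_range eligibility gates, see
#'   [nuclear_density()].
#' @return data frame of density records, one row per frame with >= 3
#'   eligible nuclei.
#' @export
density_series <- function(nuclei, events = NULL, frame_interval_s = 55,
                           volume_range = c(10, 1000),
                           depth_range = c(0, 25)) {
  anchor <- if (!is.null(events))
    find_last_sync_mitosis(events, nuclei) else NA_integer_
  rows <- lapply(sort(unique(nuclei$frame)), function(f) {
    d <- nuclei[nuclei$frame == f, , drop = FALSE]
    rec <- tryCatch(
      nuclear_density(d, volume_range, depth_range, frame = f,
                      t_min = if (is.na(anchor)) NA_real_ else
                        (f - anchor) * frame_interval_s / 60),
      error = function(e) NULL)
    rec
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Two-phase nuclear growth regression
#'
#' Ordinary least-squares regression of volume on time in two consecutive
#' windows after anaphase: a rapid early window (default 10 frames, 9.1 min
#' at 55 s) and a slow late window (default the subsequent 30 frames).
#' Slopes are reported in um^3/min together with per-window R^2 and the
#' deceleration ratio g1/g2.
#'
#' @param volumes nuclear volume time series (um^3), indexed by frame.
#' @param anaphase_index frame index of anaphase; the first fitted frame is
#'   `anaphase_index + 1`.
#' @param frame_interval_s seconds between frames.
#' @param w1,w2 window sizes in frames.
#' @param track_id identifier carried into the result.
#' @return an object of class `growth_fit`.
#' @export
growth_fit <- function(volumes, anaphase_index, frame_interval_s = 55,
                       w1 = 10L, w2 = 30L, track_id = NA) {
  stopifnot(anaphase_index >= 0L, w1 >= 2L, w2 >= 2L)
  need <- anaphase_index + w1 + w2
  if (length(volumes) < need)
    stop(sprintf("window too short for track %s: need %d frames, have %d",
                 track_id, need, length(volumes)))
  dtm <- frame_interval_s / 60
  i1 <- anaphase_index + seq_len(w1)
  i2 <- anaphase_index + w1 + seq_len(w2)
  t1 <- (i1 - i1[1L]) * dtm
  t2 <- (i2 - i1[1L]) * dtm
  f1 <- stats::lm(v ~ t, data = data.frame(v = volumes[i1], t = t1))
  f2 <- stats::lm(v ~ t, data = data.frame(v = volumes[i2], t = t2))
  r2 <- function(f) {
    ss <- sum(stats::residuals(f)^2)
    tt <- sum((f$model$v - mean(f$model$v))^2)
    if (tt == 0) 1 else 1 - ss / tt
  }
  g1 <- unname(stats::coef(f1)[2L]); g2 <- unname(stats::coef(f2)[2L])
  structure(list(track_id = track_id, anaphase_index = anaphase_index,
                 w1 = w1, w2 = w2,
                 g1 = g1, g2 = g2,
                 intercept1 = unname(stats::coef(f1)[1L]),
                 intercept2 = unname(stats::coef(f2)[1L]),
                 r2_1 = r2(f1), r2_2 = r2(f2),
                 deceleration = g1 / g2),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> track %s: g1 %.2f um^3/min (R^2 %.3f), g2 %.2f um^3/min (R^2 %.3f), deceleration %.1f\n",
    x$track_id, x$g1, x$r2_1, x$g2, x$r2_2, x$deceleration))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(g1 = object$g1, g2 = object$g2,
    intercept1 = object$intercept1, intercept2 = object$intercept2)
}

#' Classify ploidy from mitotic chromosome volume
#'
#' Mitotic figure volume is proportional to DNA content, so ploidy is the
#' rounded ratio of volume to a haploid reference volume. Ratios whose
#' fractional part falls in (0.35, 0.65) are flagged low-confidence.
#'
#' @param volume mitotic volume(s), um^3.
#' @param haploid_reference haploid mitotic volume, um^3.
#' @return data frame with columns `ploidy` (integer, >= 1) and `confident`.
#' @export
ploidy_classify <- function(volume, haploid_reference) {
  stopifnot(haploid_reference > 0)
  if (any(volume <= 0)) stop("non-positive volume")
  ratio <- volume / haploid_reference
  frac <- ratio - floor(ratio)
  data.frame(ploidy = pmax(1L, as.integer(round(ratio))),
             confident = !(frac > 0.35 & frac < 0.65))
}

#' Haploid reference volume from a mitotic volume distribution
#'
#' The mode of the metaphase volume distribution (kernel density peak),
#' robust against the minority of higher-ploidy figures in a mixture.
#'
#' @param volumes metaphase volumes, um^3.
#' @return reference volume, um^3.
#' @export
haploid_reference <- function(volumes) {
  stopifnot(length(volumes) >= 3L)
  d <- stats::density(volumes)
  d$x[which.max(d$y)]
}

#' Per-cycle change of reporter intensity and volume
#'
#' Means of a track's intensity and volume over a fixed phase-aligned window
#' (default frames 3 to 8 after each anaphase) are compared between
#' consecutive nuclear cycles; the percent change per cycle quantifies
#' reporter accumulation and the volume measurement's robustness to it.
#'
#' @param intensity per-frame mean-intensity series of one track.
#' @param anaphase_indices frame indices of the track's anaphases (at least
#'   two complete cycles).
#' @param volume optional per-frame volume series treated identically.
#' @param window frames after anaphase over which to average.
#' @return data frame: one row per consecutive cycle pair with
#'   `intensity_pct` (and `volume_pct`) change.
#' @export
cycle_intensity_change <- function(intensity, anaphase_indices,
                                   volume = NULL, window = 3:8) {
  if (length(anaphase_indices) < 2L)
    stop("at least two complete cycles are required")
  win_mean <- function(series, a) {
    idx <- a + window
    idx <- idx[idx <= length(series)]
    if (!length(idx)) return(NA_real_)
    mean(series[idx])
  }
  mi <- vapply(anaphase_indices, win_mean, 1, series = intensity)
  out <- data.frame(
    cycle_pair = paste(seq_len(length(mi) - 1L), 2:length(mi), sep = "->"),
    intensity_pct = 100 * (mi[-1L] / mi[-length(mi)] - 1))
  if (!is.null(volume)) {
    mv <- vapply(anaphase_indices, win_mean, 1, series = volume)
    out$volume_pct <- 100 * (mv[-1L] / mv[-length(mv)] - 1)
  }
  out
}
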