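# Deterministic writers: fixed 6-decimal formatting and "\n" line endings so
# identical inputs always produce byte-identical files.

.fmt_num <- function(x) {
  out <- character(length(x))
  isna <- is.na(x)
  num <- !isna & vapply(x, is.numeric, TRUE)
  out[isna] <- "NA"
  if (is.numeric(x)) {
    ints <- !isna & x == round(x) & abs(x) < 1e15
    out[ints] <- sprintf("%d", as.integer(x[ints]))
    out[!isna & !ints] <- sprintf("%.6f", x[!isna & !ints])
  } else out[!isna] <- as.character(x[!isna])
  out
}

.write_csv_fixed <- function(df, path) {
  cols <- lapply(df, function(col)
    if (is.numeric(col)) .fmt_num(col) else {
      v <- as.character(col); v[is.na(v)] <- "NA"; v
    })
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Split a time series into processing chunks
#'
#' Large 3D time-lapse recordings are fragmented into consecutive portions
#' (default 10 time points) for batch processing. Chunks preserve order and
#' cover every frame exactly once.
#'
#' @param frames a vector or list of frames (paths, indices, stacks...).
#' @param chunk maximum chunk size (>= 1).
#' @return list of chunks, each a subset of `frames`.
#' @examples
#' lengths(fragment_series(1:35, 10))   # 10 10 10 5
#' @export
fragment_series <- function(frames, chunk = 10L) {
  stopifnot(chunk >= 1L)
  n <- if (is.list(frames)) length(frames) else length(frames)
  if (n == 0L) stop("empty series: nothing to fragment")
  grp <- ceiling(seq_len(n) / chunk)
  lapply(split(seq_len(n), grp), function(i)
    if (is.list(frames)) frames[i] else frames[i])
}

#' Write ROIs as a plain-text contour file
#'
#' Line-oriented dialect: header `CONTOURS v1`; per ROI a line
#' `ROI <id> <frame> <nplanes>`; per plane `Z <z> <n>` followed by `n`
#' `x y` vertex lines with 6 decimals.
#'
#' @param rois list of [roi3d].
#' @param path output file.
#' @param what `"planes"` writes the 3D surface contours, `"silhouette"` the
#'   projected silhouette contour (one plane, z 0) per ROI.
#' @return `path`, invisibly.
#' @export
write_contours <- function(rois, path, what = c("planes", "silhouette")) {
  what <- match.arg(what)
  lines <- "CONTOURS v1"
  for (r in rois) {
    stopifnot(inherits(r, "roi3d"))
    planes <- if (what == "planes") r$planes else list(r$silhouette)
    lines <- c(lines,
               sprintf("ROI %d %d %d", r$roi_id, r$frame, length(planes)))
    for (p in planes) {
      lines <- c(lines, sprintf("Z %d %d", p$z_index, length(p$x)),
                 sprintf("%.6f %.6f", p$x, p$y))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a plain-text contour file
#'
#' @param path a file written by [write_contours()].
#' @param voxel_size `c(sx, sy, sz)` in microns, used to recompute volumes
#'   and centroids.
#' @param stack optional [image_stack] for intensity features.
#' @return list of [roi3d].
#' @export
read_contours <- function(path, voxel_size = c(1, 1, 1), stack = NULL) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "CONTOURS v1")
    stop("version error: expected 'CONTOURS v1' header in ", path)
  rois <- list()
  i <- 2L
  while (i <= length(lines)) {
    h <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    if (h[1L] != "ROI") stop("malformed contour file at line ", i)
    id <- as.integer(h[2L]); frame <- as.integer(h[3L])
    np <- as.integer(h[4L]); i <- i + 1L
    planes <- vector("list", np)
    for (k in seq_len(np)) {
      zh <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
      if (zh[1L] != "Z") stop("malformed contour file at line ", i)
      z <- as.integer(zh[2L]); nv <- as.integer(zh[3L]); i <- i + 1L
      xy <- do.call(rbind, strsplit(lines[i:(i + nv - 1L)], " ", fixed = TRUE))
      planes[[k]] <- polygon2d(as.numeric(xy[, 1L]), as.numeric(xy[, 2L]),
                               z_index = z, validate = FALSE)
      i <- i + nv
    }
    rois[[length(rois) + 1L]] <-
      roi3d(planes, voxel_size, roi_id = id, frame = frame, stack = stack)
  }
  rois
}

# fixed column order of the segmented-objects table
.objects_cols <- function(n_channels) {
  c("frame", "id", "x", "y", "z", "volume", "threshold",
    if (n_channels > 0)
      as.vector(t(outer(paste0("ch", seq_len(n_channels)),
                        c("sum", "mean", "sd"), paste, sep = "_"))))
}

#' Feature table of segmented 3D objects
#'
#' One row per ROI: frame, per-frame id, centroid (um), volume (um^3), the
#' segmentation threshold and per-channel intensity sum/mean/sd.
#'
#' @param rois list of [roi3d].
#' @return data frame with fixed column order.
#' @export
objects_table <- function(rois) {
  nch <- if (length(rois)) length(rois[[1L]]$intensity) else 0L
  rows <- lapply(rois, function(r) {
    row <- data.frame(frame = r$frame, id = r$roi_id,
                      x = r$centroid[1L], y = r$centroid[2L],
                      z = r$centroid[3L], volume = r$volume,
                      threshold = r$optimal_threshold)
    for (ch in seq_len(nch)) {
      f <- r$intensity[[ch]]
      row[[paste0("ch", ch, "_sum")]] <- f[["sum"]]
      row[[paste0("ch", ch, "_mean")]] <- f[["mean"]]
      row[[paste0("ch", ch, "_sd")]] <- f[["sd"]]
    }
    row
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(numeric(0), 0, 7)),
                    .objects_cols(0L))
  rownames(out) <- NULL
  out
}

#' Write / read the segmented-objects CSV
#'
#' @param rois list of [roi3d] (or a data frame from [objects_table()]).
#' @param path file path.
#' @return `write_objects_csv`: `path` invisibly; `read_objects_csv`: the
#'   feature data frame.
#' @export
write_objects_csv <- function(rois, path) {
  df <- if (is.data.frame(rois)) rois else objects_table(rois)
  .write_csv_fixed(df, path)
}

#' @rdname write_objects_csv
#' @export
read_objects_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Tracking project: the manifest of a time-series analysis
#'
#' A tracking project lists, per frame, one maximum-intensity-projection
#' image and one or more ROI files (so segmentations from different methods
#' can be combined into a composite). The plain-text header carries the file
#' type string, frame count, image dimensions and feature declarations.
#'
#' @param mip_paths character vector, one MIP image path per frame.
#' @param roi_paths list (one element per frame) of character vectors of ROI
#'   file paths.
#' @param dimensions `c(nx, ny, nz)` voxel dimensions of the source stacks.
#' @param features named character vector mapping feature names to types
#'   (`"integer"`, `"double"`, `"text"`).
#' @return an object of class `tracking_project`.
#' @export
tracking_project <- function(mip_paths, roi_paths, dimensions,
                             features = c(volume = "double")) {
  stopifnot(length(mip_paths) == length(roi_paths),
            length(dimensions) == 3L,
            all(lengths(roi_paths) >= 1L))
  structure(list(file_type = "Tracking-Project 2",
                 n_frames = length(mip_paths),
                 dimensions = as.integer(dimensions),
                 features = features,
                 mip_paths = as.character(mip_paths),
                 roi_paths = lapply(roi_paths, as.character)),
            class = "tracking_project")
}

#' @export
print.tracking_project <- function(x, ...) {
  cat(sprintf("<tracking_project> %d frames, %d x %d x %d, %d feature(s)\n",
              x$n_frames, x$dimensions[1], x$dimensions[2], x$dimensions[3],
              length(x$features)))
  invisible(x)
}

#' Save / load a tracking project file
#'
#' Text format: first line `Tracking-Project 2`, then `frames <n>`,
#' `dimensions <nx> <ny> <nz>`, `features <k>` with `k` name/type lines, a
#' `MIP` section (one path per frame) and a `ROIS` section (one line of
#' comma-separated ROI file paths per frame). Paths are stored relative to
#' the project file; `load_project` verifies every referenced file exists.
#'
#' @param project a [tracking_project].
#' @param path project file path (conventionally `.trpj`).
#' @return `save_project`: `path` invisibly; `load_project`: the project.
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "tracking_project"))
  p <- project
  lines <- c(p$file_type,
             sprintf("frames %d", p$n_frames),
             sprintf("dimensions %d %d %d", p$dimensions[1L],
                     p$dimensions[2L], p$dimensions[3L]),
             sprintf("features %d", length(p$features)),
             sprintf("%s %s", names(p$features), unname(p$features)),
             "MIP", p$mip_paths, "ROIS",
             vapply(p$roi_paths, paste, "", collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname save_project
#' @param check_files verify that referenced MIP and ROI files resolve.
#' @export
load_project <- function(path, check_files = TRUE) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "Tracking-Project 2")
    stop("version error: unknown file type string in ", path)
  nf <- as.integer(sub("^frames ", "", lines[2L]))
  dims <- as.integer(strsplit(sub("^dimensions ", "", lines[3L]), " ")[[1L]])
  k <- as.integer(sub("^features ", "", lines[4L]))
  feats <- character(0)
  if (k > 0) {
    fl <- strsplit(lines[4L + seq_len(k)], " ", fixed = TRUE)
    feats <- stats::setNames(vapply(fl, `[`, "", 2L),
                             vapply(fl, `[`, "", 1L))
  }
  i <- 5L + k
  if (lines[i] != "MIP") stop("malformed project: expected MIP section")
  mips <- lines[i + seq_len(nf)]
  i <- i + nf + 1L
  if (lines[i] != "ROIS") stop("malformed project: expected ROIS section")
  rois <- strsplit(lines[i + seq_len(nf)], ",", fixed = TRUE)
  if (check_files) {
    base <- dirname(path)
    for (f in c(mips, unlist(rois))) {
      fp <- if (startsWith(f, "/")) f else file.path(base, f)
      if (!file.exists(fp)) stop("missing referenced file: ", f)
    }
  }
  tracking_project(mips, rois, dims, feats)
}

#' Export tracks as a comma-separated table
#'
#' One row per (frame, ROI) with its track assignment: columns frame,
#' roi_id, track_id, parent_tracks (';'-separated), x, y, z, volume and any
#' further feature columns present.
#'
#' @param tracks data frame with at least frame, roi_id, track_id columns.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  need <- c("frame", "roi_id", "track_id")
  stopifnot(all(need %in% names(tracks)))
  .write_csv_fixed(tracks, path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
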