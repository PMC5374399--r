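# Independent oracles used by the property tests. These are deliberately
# written from first principles (crossing-number point tests, explicit
# loops, exhaustive searches) and share no geometry code with the package.

# crossing-number point-in-polygon; boundary points count as inside
oracle_point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    # on-edge check
    dx <- vx[i] - vx[j]; dy <- vy[i] - vy[j]
    t <- if (abs(dx) >= abs(dy) && dx != 0) (px - vx[j]) / dx
         else if (dy != 0) (py - vy[j]) / dy else NA
    if (!is.na(t) && t >= 0 && t <= 1 &&
        abs(vx[j] + t * dx - px) < 1e-9 && abs(vy[j] + t * dy - py) < 1e-9)
      return(TRUE)
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[j] + (py - vy[j]) * (vx[i] - vx[j]) / (vy[i] - vy[j])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# pixel-count rasterization: pixels whose centre (i-0.5, j-0.5) is inside
oracle_raster_count <- function(vx, vy) {
  cnt <- 0L
  for (i in seq.int(ceiling(min(vx) + 0.5), floor(max(vx) + 0.5)))
    for (j in seq.int(ceiling(min(vy) + 0.5), floor(max(vy) + 0.5)))
      if (oracle_point_in_poly(i - 0.5, j - 0.5, vx, vy)) cnt <- cnt + 1L
  cnt
}

# brute-force convex hull area: an edge (i, j) lies on the hull iff every
# other point is on one side; the hull polygon is assembled from hull edges
oracle_hull_area <- function(x, y) {
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sign((x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i]))
    s <- s[-c(i, j)]
    if (all(s >= 0) || all(s <= 0)) on_hull[c(i, j)] <- TRUE
  }
  hx <- x[on_hull]; hy <- y[on_hull]
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[o]; hy <- hy[o]
  abs(sum(hx * c(hy[-1], hy[1]) - hy * c(hx[-1], hx[1])) / 2)
}

# all-pairs mutual-minimum nearest-neighbour assignment
oracle_mutual_nn <- function(a, b, max_distance = Inf) {
  pairs <- NULL
  for (i in seq_len(nrow(a))) {
    di <- sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2 + (b$z - a$z[i])^2)
    j <- order(di, b$id)[1L]
    dj <- sqrt((a$x - b$x[j])^2 + (a$y - b$y[j])^2 + (a$z - b$z[j])^2)
    i2 <- order(dj, a$id)[1L]
    if (i2 == i && di[j] <= max_distance)
      pairs <- rbind(pairs, data.frame(from = a$id[i], to = b$id[j]))
  }
  pairs
}

# closed-form simple linear regression
oracle_ols <- function(t, v) {
  tm <- mean(t); vm <- mean(v)
  slope <- sum((t - tm) * (v - vm)) / sum((t - tm)^2)
  intercept <- vm - slope * tm
  fitted <- intercept + slope * t
  r2 <- 1 - sum((v - fitted)^2) / sum((v - vm)^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# do two segments touch anywhere (own orientation code)?
.oseg <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) {
    v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
    if (abs(v) < 1e-9) 0 else sign(v)
  }
  on <- function(px, py, qx, qy, rx, ry)
    rx >= min(px, qx) - 1e-9 && rx <= max(px, qx) + 1e-9 &&
    ry >= min(py, qy) - 1e-9 && ry <= max(py, qy) + 1e-9
  o1 <- o(ax, ay, bx, by, cx, cy); o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay); o4 <- o(cx, cy, dx, dy, bx, by)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on(ax, ay, bx, by, cx, cy)) ||
  (o2 == 0 && on(ax, ay, bx, by, dx, dy)) ||
  (o3 == 0 && on(cx, cy, dx, dy, ax, ay)) ||
  (o4 == 0 && on(cx, cy, dx, dy, bx, by))
}

# exhaustive shape-split oracle: shortest admissible chord over all vertex
# pairs, lexicographic tie-break, recursion on both pieces
oracle_shape_split <- function(vx, vy, min_area, min_perim, max_ratio) {
  n <- length(vx)
  area <- abs(sum(vx * c(vy[-1], vy[1]) - vy * c(vx[-1], vx[1])) / 2)
  if (area < min_area) return(list(cbind(vx, vy)))
  perim <- function(px, py)
    sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
  best <- NULL; best_len <- Inf
  for (i in seq_len(n - 2L)) for (j in (i + 2L):n) {
    if (i == 1L && j == n) next
    len <- sqrt((vx[j] - vx[i])^2 + (vy[j] - vy[i])^2)
    if (len <= 0 || len >= best_len) next
    # strict interiority: no touch with non-incident edges, midpoint inside
    ok <- TRUE
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      if (k %in% c(i, j) || k2 %in% c(i, j)) next
      if (.oseg(vx[i], vy[i], vx[j], vy[j],
                vx[k], vy[k], vx[k2], vy[k2])) { ok <- FALSE; break }
    }
    if (!ok) next
    if (!oracle_point_in_poly((vx[i] + vx[j]) / 2, (vy[i] + vy[j]) / 2,
                              vx, vy)) next
    a1x <- vx[i:j]; a1y <- vy[i:j]
    a2x <- vx[c(j:n, 1:i)]; a2y <- vy[c(j:n, 1:i)]
    ar1 <- abs(sum(a1x * c(a1y[-1], a1y[1]) - a1y * c(a1x[-1], a1x[1])) / 2)
    ar2 <- area - ar1
    if (ar1 <= 0 || ar2 <= 0) next
    p_small <- if (ar1 <= ar2) perim(a1x, a1y) else perim(a2x, a2y)
    if (p_small < min_perim) next
    if (len / p_small > max_ratio) next
    best <- c(i, j); best_len <- len
  }
  if (is.null(best)) return(list(cbind(vx, vy)))
  i <- best[1L]; j <- best[2L]
  c(oracle_shape_split(vx[i:j], vy[i:j], min_area, min_perim, max_ratio),
    oracle_shape_split(vx[c(j:n, 1:i)], vy[c(j:n, 1:i)],
                       min_area, min_perim, max_ratio))
}

# random star-shaped (hence simple) polygon; angles keep a minimum gap so
# no two edges are numerically degenerate
random_star_polygon <- function(n_vertices, r_min = 10, r_max = 40,
                                centre = c(50, 50), z = 1L) {
  th <- (seq_len(n_vertices) - 1 + runif(n_vertices, 0.05, 0.85)) *
    (2 * pi / n_vertices)
  r <- runif(n_vertices, r_min, r_max)
  polygon2d(centre[1] + r * cos(th), centre[2] + r * sin(th), z_index = z)
}

# minimal hand-built scene for the renderer (positions/volumes chosen freely)
forge_scene <- function(nuclei, params) {
  structure(list(nuclei = nuclei, links = NULL, events = NULL,
                 n_frames = max(nuclei$frame, 1L), anaphase_frames = integer(0),
                 mbt_start = 1L, params = params),
            class = "sim_scene")
}
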