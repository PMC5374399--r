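.pts <- function(id, x, y, z = 0) data.frame(id = id, x = x, y = y, z = z)

test_that("bilateral NN matches identities, gates and the swap failure mode", {
  a <- .pts(1:3, c(0, 10, 20), c(0, 0, 0))
  m <- bilateral_nn(a, a)
  expect_equal(m$from, m$to)
  expect_true(all(m$dist == 0))
  # two nuclei swapping positions: each is matched to the other (a known
  # nearest-neighbour failure mode)
  b <- .pts(1:2, c(0, 5), c(0, 0))
  bswap <- .pts(1:2, c(5, 0), c(0, 0))
  m2 <- bilateral_nn(b, bswap)
  expect_equal(m2$to[m2$from == 1], 2)
  expect_equal(m2$to[m2$from == 2], 1)
  # a far-away newcomer stays unassigned
  m3 <- bilateral_nn(.pts(1, 0, 0), .pts(c(1, 9), c(0.4, 90), c(0, 0)))
  expect_equal(nrow(m3), 1)
  expect_false(9 %in% m3$to)
  # distance gate
  m4 <- bilateral_nn(.pts(1, 0, 0), .pts(1, 8, 0), max_distance = 5)
  expect_equal(nrow(m4), 0)
  # empty frames
  expect_equal(nrow(bilateral_nn(a[0, ], a)), 0)
})

test_that("bilateral NN is symmetric and equals the brute-force oracle", {
  set.seed(29)
  for (n in c(20, 200)) {
    a <- .pts(seq_len(n), runif(n, 0, 100), runif(n, 0, 100), runif(n, 0, 5))
    b <- .pts(seq_len(n), a$x + rnorm(n, 0, 2), a$y + rnorm(n, 0, 2), a$z)
    m <- bilateral_nn(a, b)
    want <- oracle_mutual_nn(a, b)
    expect_equal(m[order(m$from), c("from", "to")],
                 want[order(want$from), ], ignore_attr = TRUE)
    # symmetry: swapping the frames reverses the pair set
    rev <- bilateral_nn(b, a)
    expect_setequal(paste(m$from, m$to), paste(rev$to, rev$from))
  }
})

test_that("lineage construction applies edits and enforces degree caps", {
  links <- data.frame(frame = 1:4, from = c(1, 1, 1, 1), to = c(1, 1, 1, 1))
  g <- build_lineage(links)
  expect_equal(nrow(g$nodes), 5)
  expect_equal(nrow(g$edges), 4)
  # remove then re-add: identical graph, log of length 2
  ed <- data.frame(action = c("remove", "add"), frame = 2, from = 1, to = 1)
  g2 <- build_lineage(links, edits = ed)
  expect_equal(g2$edges[order(g2$edges$frame), ],
               g$edges[order(g$edges$frame), ], ignore_attr = TRUE)
  expect_equal(nrow(g2$edits), 2)
  # a second outgoing edge makes a division node; a third is rejected
  ed2 <- data.frame(action = "add", frame = 2, from = 1, to = 7)
  g3 <- build_lineage(links, edits = ed2)
  expect_equal(sum(g3$edges$frame == 2 & g3$edges$from == 1), 2)
  ed3 <- rbind(ed2, data.frame(action = "add", frame = 2, from = 1, to = 8))
  expect_error(build_lineage(links, edits = ed3), "out-degree cap")
  # in-degree cap
  ed4 <- data.frame(action = "add", frame = 1,
                    from = c(5, 6), to = c(1, 1))
  expect_error(build_lineage(links, edits = ed4), "in-degree cap")
})

test_that("lineage nodes cover all ROIs and edges span one frame step", {
  s <- simulate_scene(sim_params(seed = 3, n_initial = 16, n_cycles = 1,
                                 frames_per_cycle = 8, mbt_frames = 6,
                                 field_um = c(60, 60),
                                 elimination_prob = 0))
  g <- build_lineage(s$links,
                     nodes = data.frame(frame = s$nuclei$frame,
                                        id = s$nuclei$id))
  expect_equal(nrow(g$nodes), nrow(s$nuclei))
  # every edge connects consecutive frames by construction of the links
  key <- paste(s$nuclei$frame, s$nuclei$id)
  expect_true(all(paste(g$edges$frame, g$edges$from) %in% key))
  expect_true(all(paste(g$edges$frame + 1L, g$edges$to) %in% key))
})

test_that("event detection finds divisions, collisions and suspects", {
  # hand-built: nuclei 1,2 at frame 1; 2-parent node 3 at frame 2
  links <- data.frame(frame = c(1, 1), from = c(1, 2), to = c(3, 3))
  feats <- data.frame(frame = c(1, 1, 2), id = c(1, 2, 3),
                      volume = c(20, 20, 41))
  ann <- data.frame(frame = c(1, 1, 2), id = c(1, 2, 3),
                    phase = c("anaphase", "anaphase", "telophase"),
                    cycle = c(1, 1, 2))
  ev <- detect_events(build_lineage(links), feats, ann)
  expect_equal(nrow(ev$collisions), 1)
  expect_equal(ev$collisions$phase, "anaphase")
  expect_null(ev$suspects)
  # a volume-inconsistent merge is a suspect, not a collision
  feats2 <- feats; feats2$volume[3] <- 90
  ev2 <- detect_events(build_lineage(links), feats2, ann)
  expect_null(ev2$collisions)
  expect_equal(nrow(ev2$suspects), 1)
  # a scene without collisions yields none
  s0 <- simulate_scene(sim_params(seed = 2, n_initial = 16, n_cycles = 1,
                                  frames_per_cycle = 8, mbt_frames = 4,
                                  field_um = c(60, 60), collision_prob = 0))
  ev0 <- detect_events(build_lineage(s0$links), s0$nuclei, s0$nuclei)
  expect_null(ev0$collisions)
  expect_equal(nrow(ev0$divisions), 16)
})

test_that("the detected per-cycle collision fraction matches the event log", {
  s <- simulate_scene(sim_params(seed = 19, n_initial = 100, n_cycles = 2,
                                 mbt_frames = 5, collision_prob = 0.12,
                                 elimination_prob = 0))
  ev <- detect_events(build_lineage(s$links), s$nuclei, s$nuclei)
  log_n <- nrow(s$events[s$events$type == "collision", ])
  expect_equal(nrow(ev$collisions), log_n)
  expect_setequal(ev$collisions$id,
                  s$events$id[s$events$type == "collision"])
  expect_true(all(ev$per_cycle$fraction >= 0 & ev$per_cycle$fraction <= 1))
})

test_that("unmatched predecessors inside a successor silhouette are merged", {
  vs <- c(1, 1, 1)
  sq <- function(x0, w, id) roi3d(list(polygon2d(c(x0, x0 + w, x0 + w, x0),
                                                 c(0, 0, 8, 8), 1)),
                                  vs, roi_id = id)
  prev <- list(sq(0, 8, 1), sq(12, 8, 2))
  nxt <- list(sq(0, 20, 1))        # one object covering both predecessors
  asg <- bilateral_nn(prev, nxt, frame = 3L)
  expect_equal(nrow(asg), 1)
  extra <- infer_merge_links(prev, nxt, asg)
  expect_equal(nrow(extra), 1)
  expect_equal(extra$to, 1L)
  expect_setequal(c(asg$from, extra$from), c(1L, 2L))
  # in-degree cap: a third predecessor is not linked
  prev3 <- list(sq(0, 8, 1), sq(12, 8, 2), sq(6, 8, 3))
  extra3 <- infer_merge_links(prev3, nxt, bilateral_nn(prev3, nxt, frame = 3L))
  expect_equal(nrow(extra3), 1)
})

test_that("collisions are recovered through the full imaging pipeline", {
  # render tiny scenes around forced collisions, re-segment every frame,
  # track automatically, correct the collision links (the interactive
  # editing step) and detect events from the *segmented* volumes; nuclei
  # clipped by the field of view are excluded from the assertion
  for (seed in c(1L, 3L)) {
    p <- sim_params(seed = seed, field_um = c(60, 60), n_initial = 12,
                    n_cycles = 1, frames_per_cycle = 6, mbt_frames = 4,
                    noise_sd = 0, voxel_um = c(0.25, 0.25, 0.5),
                    elimination_prob = 0, collision_prob = 0.95)
    s <- simulate_scene(p)
    te <- s$events[s$events$type == "collision", ]
    interior <- vapply(seq_len(nrow(te)), function(k) {
      ch <- s$nuclei[s$nuclei$id == te$id[k] &
                     s$nuclei$frame == te$frame[k], ]
      pa <- s$nuclei[s$nuclei$id %in% c(te$parent1[k], te$parent2[k]) &
                     s$nuclei$frame == te$frame[k] - 1L, ]
      all(c(ch$x, pa$x, ch$y, pa$y) > 9) && all(c(ch$x, pa$x, ch$y, pa$y) < 51)
    }, TRUE)
    te <- te[interior, , drop = FALSE]
    expect_gte(nrow(te), 1)
    frames <- lapply(seq_len(s$n_frames), function(f)
      threshold_segment(render_stack(s, f), threshold = p$background + 5))
    seg_id_of <- function(f, truth_id) {
      tr <- scene_frame(s, f)
      tr <- tr[tr$id == truth_id, ]
      cent <- t(vapply(frames[[f]], function(r) r$centroid, numeric(3)))
      frames[[f]][[which.min((cent[, 1] - tr$x)^2 +
                             (cent[, 2] - tr$y)^2)]]$roi_id
    }
    links <- NULL
    for (t in seq_len(s$n_frames - 1L)) {
      asg <- bilateral_nn(frames[[t]], frames[[t + 1L]], frame = t)
      links <- rbind(links, asg[, c("frame", "from", "to")])
    }
    # interactive correction: ensure both parent links of each collision
    edits <- NULL
    for (k in seq_len(nrow(te))) {
      f <- te$frame[k]
      child <- seg_id_of(f, te$id[k])
      for (par in c(te$parent1[k], te$parent2[k])) {
        pid <- seg_id_of(f - 1L, par)
        hit <- links$frame == f - 1L & links$from == pid & links$to == child
        if (!any(hit))
          edits <- rbind(edits, data.frame(action = "add", frame = f - 1L,
                                           from = pid, to = child))
      }
    }
    feats <- do.call(rbind, lapply(seq_along(frames), function(f) {
      tab <- objects_table(frames[[f]])
      tab$frame <- f
      tab
    }))
    ann <- do.call(rbind, lapply(seq_along(frames), function(f) {
      tr <- scene_frame(s, f)
      cent <- t(vapply(frames[[f]], function(r) r$centroid, numeric(3)))
      data.frame(frame = f,
                 id = vapply(frames[[f]], function(r) r$roi_id, 1L),
                 phase = tr$phase[apply(cent, 1, function(cc)
                   which.min((tr$x - cc[1])^2 + (tr$y - cc[2])^2))],
                 cycle = 1L)
    }))
    ev <- detect_events(build_lineage(links, edits = edits), feats, ann)
    got <- paste(ev$collisions$frame, ev$collisions$phase)
    for (k in seq_len(nrow(te)))
      expect_true(paste(te$frame[k], te$phase[k]) %in% got)
  }
})

test_that("tracking evaluation computes recall and precision", {
  truth <- data.frame(frame = c(1, 1, 2, 2), from = c(1, 2, 1, 2),
                      to = c(1, 2, 1, 2))
  m <- evaluate_tracking(truth, truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  half <- truth[c(1, 3), ]
  m2 <- evaluate_tracking(half, truth)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$precision, 1)
  expect_warning(m3 <- evaluate_tracking(half, truth[0, ]), "empty")
  expect_true(is.nan(m3$recall))
})
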