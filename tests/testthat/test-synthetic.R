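test_that("scenes are bit-reproducible under a fixed seed", {
  p <- sim_params(seed = 17, n_initial = 16, n_cycles = 1,
                  frames_per_cycle = 8, mbt_frames = 8, field_um = c(60, 60))
  s1 <- simulate_scene(p)
  s2 <- simulate_scene(p)
  expect_identical(s1$nuclei, s2$nuclei)
  expect_identical(s1$links, s2$links)
  expect_identical(s1$events, s2$events)
})

test_that("lossless synchronous cycles double the nucleus count", {
  p <- sim_params(seed = 1, n_initial = 4, n_cycles = 3, collision_prob = 0,
                  elimination_prob = 0, mbt_frames = 5, field_um = c(60, 60))
  s <- simulate_scene(p)
  expect_equal(sum(s$nuclei$frame == s$n_frames), 4 * 2^3)
  expect_true(all(s$nuclei$ploidy == 1L))
  counts <- table(s$nuclei$frame)
  expect_true(all(counts %in% c(4, 8, 16, 32)))
})

test_that("interphase displacements match the configured mean", {
  s <- simulate_scene(sim_params(seed = 23))
  d <- scene_displacements(s)
  expect_equal(mean(d$interphase), 1.41, tolerance = 0.05)
  expect_lte(max(d$mitotic), 15 + 1e-9)
})

test_that("collision events are exactly the two-parent nodes of the lineage", {
  p <- sim_params(seed = 9, n_initial = 100, n_cycles = 2, mbt_frames = 5,
                  collision_prob = 0.15, elimination_prob = 0)
  s <- simulate_scene(p)
  col <- s$events[s$events$type == "collision", ]
  expect_gt(nrow(col), 0)
  ink <- paste(s$links$frame, s$links$to)
  two_parent <- unique(s$links$to[ink %in% ink[duplicated(ink)]])
  expect_setequal(col$id, two_parent)
  # phases only metaphase/anaphase, partners never identical
  expect_true(all(col$phase %in% c("metaphase", "anaphase")))
  expect_true(all(col$parent1 != col$parent2))
  # fused ploidy is the sum of the parents' ploidies
  nuc <- s$nuclei
  first <- nuc[!duplicated(nuc$id), ]
  for (k in seq_len(nrow(col))) {
    pl <- first$ploidy[match(c(col$id[k], col$parent1[k], col$parent2[k]),
                             first$id)]
    expect_equal(pl[1], pl[2] + pl[3])
  }
})

test_that("anaphase collisions never fuse siblings", {
  p <- sim_params(seed = 31, n_initial = 100, n_cycles = 2, mbt_frames = 5,
                  collision_prob = 0.2, elimination_prob = 0)
  s <- simulate_scene(p)
  col <- s$events[s$events$type == "collision", ]
  div <- s$events[s$events$type == "division", ]
  # parents of a collision are two different mothers, so the merged nucleus
  # never descends twice from the same mitosis
  expect_true(all(col$parent1 != col$parent2))
  # and no interphase fusions exist at all
  expect_false(any(col$phase == "interphase"))
})

test_that("the growth model is continuous, ploidy-scaled and decelerating", {
  p <- sim_params(seed = 1)
  expect_equal(interphase_growth_model(0, ploidy = 1, params = p),
               p$v_haploid_um3)
  expect_equal(interphase_growth_model(0, ploidy = 3, params = p),
               3 * p$v_haploid_um3)
  t1 <- p$growth_breakpoint_min
  lhs <- interphase_growth_model(t1 - 1e-9, params = p)
  rhs <- interphase_growth_model(t1 + 1e-9, params = p)
  expect_equal(lhs, rhs, tolerance = 1e-6)
  v <- interphase_growth_model(seq(0, 45, by = 55 / 60), params = p)
  gf <- growth_fit(v, anaphase_index = 0)
  expect_gte(gf$deceleration, 2.9)
  expect_lte(gf$deceleration, 9.6)
})

test_that("total nuclear volume never exceeds the NAF pool ceiling", {
  s <- simulate_scene(sim_params(seed = 13))
  for (f in seq(s$mbt_start + 2L, s$n_frames, by = 8L)) {
    d <- scene_frame(s, f)
    h <- hull_area(d$x, d$y)
    expect_lte(vhr(d$volume, h$area), s$params$vhr_ceiling * 1.05)
  }
})

test_that("rendered stacks have the configured background and noise", {
  p <- sim_params(seed = 2, field_um = c(20, 20), n_initial = 1, n_cycles = 0,
                  frames_per_cycle = 5, mbt_frames = 3, noise_sd = 1.5,
                  voxel_um = c(0.5, 0.5, 0.5))
  empty <- forge_scene(data.frame(frame = integer(0), id = integer(0),
                                  x = numeric(0), y = numeric(0),
                                  z = numeric(0), ploidy = integer(0),
                                  phase = character(0), cycle = integer(0),
                                  volume = numeric(0),
                                  mean_intensity = numeric(0)), p)
  st <- render_stack(empty, 1)
  expect_equal(mean(st$channels[[1]]), p$background, tolerance = 0.05)
  expect_equal(sd(st$channels[[1]]), 1.5, tolerance = 0.05)
})

test_that("segmentation of a zero-noise render recovers the true volume", {
  p <- sim_params(seed = 3, field_um = c(40, 40), n_initial = 9, n_cycles = 0,
                  frames_per_cycle = 5, mbt_frames = 12, noise_sd = 0,
                  voxel_um = c(0.25, 0.25, 0.5), elimination_prob = 0)
  s <- simulate_scene(p)
  st <- render_stack(s, s$n_frames)
  rois <- threshold_segment(st, threshold = p$background + 5)
  truth <- scene_frame(s, s$n_frames)
  expect_equal(length(rois), nrow(truth))
  cent <- t(vapply(rois, function(r) r$centroid, numeric(3)))
  interior <- truth$x > 5 & truth$x < 35 & truth$y > 5 & truth$y < 35
  for (i in which(interior)) {
    j <- which.min((cent[, 1] - truth$x[i])^2 + (cent[, 2] - truth$y[i])^2)
    expect_lt(abs(rois[[j]]$volume / truth$volume[i] - 1), 0.1)
  }
})

test_that("segmented intensity sums scale with ploidy", {
  p <- sim_params(seed = 8, field_um = c(60, 60), n_initial = 10, n_cycles = 1,
                  frames_per_cycle = 8, mbt_frames = 10, noise_sd = 0,
                  voxel_um = c(0.25, 0.25, 0.5), elimination_prob = 0,
                  collision_prob = 0.9)
  s <- simulate_scene(p)
  truth <- scene_frame(s, s$n_frames)
  expect_setequal(unique(truth$ploidy), c(1L, 2L))
  st <- render_stack(s, s$n_frames)
  rois <- threshold_segment(st, threshold = p$background + 5)
  cent <- t(vapply(rois, function(r) r$centroid, numeric(3)))
  sums <- vapply(rois, function(r) r$intensity[[1]][["sum"]], 1)
  interior <- truth$x > 6 & truth$x < 54 & truth$y > 6 & truth$y < 54
  by_ploidy <- vapply(c(1, 2), function(pl) {
    ids <- which(interior & truth$ploidy == pl)
    mean(vapply(ids, function(i)
      sums[which.min((cent[, 1] - truth$x[i])^2 +
                     (cent[, 2] - truth$y[i])^2)], 1))
  }, 1)
  expect_equal(by_ploidy[2] / by_ploidy[1], 2, tolerance = 0.1)
})

test_that("overcrowded configurations are rejected", {
  expect_error(sim_params(seed = 1, field_um = c(20, 20), n_initial = 64,
                          n_cycles = 3), "overcrowding")
})
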