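test_that("nuclear density applies gates and matches the worked example", {
  d <- data.frame(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100),
                  z = 5, volume = 200)
  rec <- nuclear_density(d)
  expect_equal(rec$hull_area, 10000)
  expect_equal(rec$nd, 0.4)
  # a nucleus 30 um deep is excluded
  d2 <- rbind(d, data.frame(x = 50, y = 50, z = 30, volume = 200))
  expect_equal(nuclear_density(d2)$n, 4)
  # volume gates
  d3 <- rbind(d, data.frame(x = 50, y = 50, z = 5, volume = 2000))
  expect_equal(nuclear_density(d3)$n, 4)
  expect_error(nuclear_density(d[1:2, ]), "degenerate hull")
})

test_that("hull area equals the brute-force all-pairs oracle", {
  set.seed(59)
  x <- runif(100, 0, 80); y <- runif(100, 0, 60)
  expect_equal(hull_area(x, y)$area, oracle_hull_area(x, y),
               tolerance = 1e-9)
  # ND is invariant under rigid rotation and translation
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 15
  yr <- sin(th) * x + cos(th) * y - 40
  d <- data.frame(x = x, y = y, z = 5, volume = 100)
  dr <- data.frame(x = xr, y = yr, z = 5, volume = 100)
  expect_equal(nuclear_density(dr)$nd, nuclear_density(d)$nd,
               tolerance = 1e-9)
})

test_that("vhr is the volume sum over the hull area and is linear", {
  expect_equal(vhr(rep(250, 4), 10000), 0.1)
  v <- c(120, 180, 300)
  expect_equal(vhr(2 * v, 5000), 2 * vhr(v, 5000))
  expect_error(vhr(numeric(0), 100), "zero eligible")
})

test_that("growth regression is exact on bilinear input and matches OLS", {
  dtm <- 55 / 60
  tt <- (0:39) * dtm
  v <- ifelse(tt <= 10 * dtm * 0.999, 50 + 10 * tt,
              50 + 10 * (9 * dtm) + 2 * (tt - 9 * dtm))
  # exact bilinear series built per window so both fits are perfect
  v1 <- 50 + 10 * (0:9) * dtm
  v2 <- v1[10] + 2 * (1:30) * dtm
  gf <- growth_fit(c(v1, v2), anaphase_index = 0)
  expect_equal(gf$g1, 10, tolerance = 1e-9)
  expect_equal(gf$g2, 2, tolerance = 1e-9)
  expect_equal(gf$r2_1, 1)
  expect_equal(gf$r2_2, 1)
  expect_equal(gf$deceleration, 5, tolerance = 1e-9)
  # equality with the closed-form OLS oracle on noisy windows
  set.seed(83)
  vn <- c(v1, v2) * (1 + rnorm(40, 0, 0.03))
  gfn <- growth_fit(vn, anaphase_index = 0)
  o1 <- oracle_ols((0:9) * dtm, vn[1:10])
  o2 <- oracle_ols((10:39) * dtm, vn[11:40])
  expect_equal(gfn$g1, o1$slope, tolerance = 1e-12)
  expect_equal(gfn$g2, o2$slope, tolerance = 1e-12)
  expect_equal(gfn$r2_1, o1$r2, tolerance = 1e-12)
  expect_equal(gfn$r2_2, o2$r2, tolerance = 1e-12)
  # window-too-short error names the track
  expect_error(growth_fit(vn[1:39], 0, track_id = "t7"), "t7")
})

test_that("noisy slope recovery is unbiased within 5%", {
  set.seed(11)
  dtm <- 55 / 60
  v1 <- 80 + 12 * (0:9) * dtm
  v2 <- v1[10] + 3 * (1:30) * dtm
  base <- c(v1, v2)
  g1s <- g2s <- numeric(100)
  for (i in 1:100) {
    gf <- growth_fit(base * (1 + rnorm(40, 0, 0.03)), 0)
    g1s[i] <- gf$g1; g2s[i] <- gf$g2
  }
  expect_lt(abs(mean(g1s) / 12 - 1), 0.05)
  expect_lt(abs(mean(g2s) / 3 - 1), 0.05)
})

test_that("ploidy classification rounds volume ratios with confidence", {
  expect_equal(ploidy_classify(200, 100)$ploidy, 2L)
  expect_true(ploidy_classify(200, 100)$confident)
  expect_equal(ploidy_classify(100, 100)$ploidy, 1L)
  expect_false(ploidy_classify(155, 100)$confident)
  expect_error(ploidy_classify(-5, 100), "non-positive")
  # simulated mitotic volumes, 10% CV, ploidies 1-4 at the frequencies seen
  # in haploid-derived embryos (mostly 1n, some 2n, rare 3n/4n)
  set.seed(37)
  pl <- sample(1:4, 400, replace = TRUE, prob = c(0.72, 0.22, 0.04, 0.02))
  vols <- rnorm(400, mean = 20 * pl, sd = 0.1 * 20 * pl)
  got <- ploidy_classify(vols, 20)$ploidy
  expect_gte(mean(got == pl), 0.95)
  # haploid reference from a mixture: mode near the haploid peak
  mix <- c(rnorm(300, 20, 2), rnorm(60, 40, 4))
  expect_equal(haploid_reference(mix), 20, tolerance = 0.1)
})

test_that("per-cycle intensity change recovers the reporter factor", {
  # 3 cycles of 14 frames, intensity multiplied by 1.295 per cycle
  intensity <- rep(100 * 1.295^(0:2), each = 14)
  volume <- rep(c(100, 101, 100), each = 14)
  ana <- c(0, 14, 28)
  ch <- cycle_intensity_change(intensity, ana, volume = volume)
  expect_equal(ch$intensity_pct, c(29.5, 29.5), tolerance = 1e-9)
  expect_lt(max(abs(ch$volume_pct)), 1.5)
  ch0 <- cycle_intensity_change(rep(5, 30), c(0, 12))
  expect_equal(ch0$intensity_pct, 0)
  expect_error(cycle_intensity_change(intensity, 0), "two complete cycles")
})

test_that("scene reporter intensities rise 29.5% per cycle", {
  s <- simulate_scene(sim_params(seed = 21, n_initial = 16, n_cycles = 2,
                                 frames_per_cycle = 12, mbt_frames = 14,
                                 field_um = c(60, 60), collision_prob = 0,
                                 elimination_prob = 0))
  # follow one lineage branch across the two divisions
  nuc <- s$nuclei
  track_int <- sapply(sort(unique(nuc$frame)), function(f) {
    d <- nuc[nuc$frame == f & nuc$phase %in% c("interphase", "telophase"), ]
    if (!nrow(d)) NA else mean(d$mean_intensity)
  })
  ana <- c(0, s$anaphase_frames)
  ch <- cycle_intensity_change(track_int, ana)
  expect_equal(ch$intensity_pct, c(29.5, 29.5), tolerance = 1e-6)
})

test_that("summary statistics reproduce printed proportions and cover", {
  ss <- summary_stats(c(1, 2, 3))
  expect_equal(ss$mean, 2)
  expect_equal(ss$sd, 1)
  # the rescue scoring worked example: 22 of 26 embryos diploid
  pr <- summary_stats(k = 22, n = 26)
  expect_equal(round(pr$percent, 1), 84.6)
  expect_true(pr$ci[1] < pr$percent && pr$percent < pr$ci[2])
  # t-test against a null
  set.seed(2)
  tt <- summary_stats(rnorm(30, 1, 1), null_mean = 0)
  expect_lt(tt$p, 0.01)
  expect_warning(summary_stats(c(2, 2, 2), null_mean = 0), "degenerate")
  # 95% CI long-run coverage
  set.seed(101)
  hits <- replicate(300, {
    ci <- summary_stats(rnorm(15, 10, 2))$ci
    ci[1] <= 10 && 10 <= ci[2]
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.05)
})

test_that("the last synchronized mitosis anchors density time series", {
  s <- simulate_scene(sim_params(seed = 4, n_initial = 25, n_cycles = 2,
                                 frames_per_cycle = 10, mbt_frames = 10,
                                 field_um = c(70, 70), collision_prob = 0,
                                 elimination_prob = 0))
  f <- find_last_sync_mitosis(s$events, s$nuclei)
  expect_equal(f, s$anaphase_frames[2])
  ds <- density_series(s$nuclei, s$events)
  expect_true(all(diff(ds$t_min) > 0))
  expect_equal(ds$t_min[ds$frame == f], 0)
  # ND doubles across the division (volume gate keeps mitotic figures in)
  before <- ds$nd[ds$frame == f - 1]
  after <- ds$nd[ds$frame == f + 6]
  expect_equal(after / before, 2, tolerance = 0.05)
})
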