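#' Parameters of the synthetic syncytial-embryo generator
#'
#' Bundles and validates all knobs of the ground-truth simulator. The
#' defaults emulate the cortical nuclei of a syncytial fly embryo imaged at
#' 55 s intervals: synchronous division cycles, anchored interphase jitter
#' with mean frame-to-frame displacement 1.41 um, anaphase jumps of up to
#' 15 um, rare mitotic collisions (4.5% of nuclei per cycle, 75% of them in
#' anaphase), occasional elimination of cortical nuclei after the last
#' synchronized division, mitotic-figure volume proportional to ploidy,
#' two-phase interphase growth limited by a shared nuclear-assembly-factor
#' pool (volume-to-hull ceiling 5.3 um^3/um^2), and a 29.5% per-cycle
#' increase of reporter intensity.
#'
#' @param seed integer seed; the simulator uses one global random stream and
#'   is bit-reproducible given the seed.
#' @param field_um imaged cortical field `c(Lx, Ly)` in microns. Nuclei are
#'   confined to the field (the cortical layer fills the recorded view).
#' @param n_initial nuclei at the first frame (a jittered grid that includes
#'   the field corners).
#' @param n_cycles number of synchronous division cycles before the
#'   mid-blastula transition (MBT).
#' @param frames_per_cycle frames per cycle (>= 5); the last three frames of
#'   a cycle are prophase, metaphase and anaphase.
#' @param mbt_frames interphase frames recorded after the final division.
#' @param frame_interval_s seconds between frames.
#' @param displacement_mean_um mean frame-to-frame interphase displacement in
#'   x-y. Nuclei jitter about fixed anchors with per-axis sd
#'   `displacement_mean_um / sqrt(pi)`, which makes the displacement (a
#'   difference of two Gaussians) Rayleigh with this mean.
#' @param anaphase_cap_um maximum displacement of a daughter nucleus from its
#'   mother at division.
#' @param collision_prob probability per nucleus per cycle of being involved
#'   in a mitotic chromosome collision.
#' @param collision_anaphase_prob probability that a collision happens in
#'   anaphase rather than metaphase.
#' @param elimination_prob per-frame probability of a nucleus being
#'   eliminated from the cortex after MBT.
#' @param v_haploid_um3 haploid nuclear volume at telophase (growth start).
#' @param v_mitotic_um3 haploid mitotic-figure volume; mitotic volumes are
#'   this value times ploidy.
#' @param growth_rate_um3_min early-interphase (phase 1) growth rate per
#'   ploidy unit.
#' @param growth_breakpoint_min minutes after telophase at which rapid
#'   phase-1 growth ends.
#' @param pool_rate_per_min rate constant of phase-2 growth: total uptake per
#'   minute is this fraction of the unexhausted NAF pool
#'   (`vhr_ceiling * hull area - total nuclear volume`), shared among nuclei
#'   in proportion to ploidy and never exceeding the phase-1 rate.
#' @param vhr_ceiling volume-to-hull ceiling (um^3 per um^2) set by the
#'   finite maternal NAF pool.
#' @param intensity_base mean reporter intensity of a first-cycle nucleus.
#' @param intensity_cycle_factor multiplicative increase of reporter
#'   intensity per nuclear cycle.
#' @param mitotic_brightness intensity boost of condensed mitotic figures.
#' @param background,noise_sd rendering background level and additive
#'   Gaussian noise sd.
#' @param voxel_um rendering voxel size `c(sx, sy, sz)` in microns.
#' @param depth_um mean depth of the cortical nuclear layer below the first
#'   imaged plane.
#' @param stack_depth_um axial extent of rendered stacks.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(seed,
                       field_um = c(100, 100),
                       n_initial = 64,
                       n_cycles = 2,
                       frames_per_cycle = 15,
                       mbt_frames = 44,
                       frame_interval_s = 55,
                       displacement_mean_um = 1.41,
                       anaphase_cap_um = 15,
                       collision_prob = 0.045,
                       collision_anaphase_prob = 0.75,
                       elimination_prob = 0.003,
                       v_haploid_um3 = 25,
                       v_mitotic_um3 = 20,
                       growth_rate_um3_min = 12,
                       growth_breakpoint_min = 9,
                       pool_rate_per_min = 0.075,
                       vhr_ceiling = 5.3,
                       intensity_base = 50,
                       intensity_cycle_factor = 1.295,
                       mitotic_brightness = 2,
                       background = 10,
                       noise_sd = 2,
                       voxel_um = c(0.1, 0.1, 0.44),
                       depth_um = 4,
                       stack_depth_um = 12) {
  if (missing(seed)) stop("a seed is mandatory for reproducible scenes")
  p <- as.list(environment())
  stopifnot(
    length(p$field_um) == 2L, all(p$field_um > 0),
    p$n_initial >= 1, p$n_cycles >= 0, p$frames_per_cycle >= 5,
    p$mbt_frames >= 1, p$frame_interval_s > 0,
    p$displacement_mean_um >= 0, p$anaphase_cap_um > 0,
    p$collision_prob >= 0, p$collision_prob <= 1,
    p$collision_anaphase_prob >= 0, p$collision_anaphase_prob <= 1,
    p$elimination_prob >= 0, p$elimination_prob <= 1,
    p$v_haploid_um3 > 0, p$v_mitotic_um3 > 0,
    p$growth_rate_um3_min > 0, p$growth_breakpoint_min > 0,
    p$pool_rate_per_min > 0, p$vhr_ceiling > 0,
    length(p$voxel_um) == 3L, all(p$voxel_um > 0)
  )
  # overcrowding guard: final nucleus count must fit the field at a spacing
  # that still allows distinct rendered nuclei
  n_final <- p$n_initial * 2^p$n_cycles
  if (n_final / prod(p$field_um) > 0.09)
    stop("overcrowding: field too small for the requested number of nuclei")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> seed %d: %g x %g um field, %d nuclei, %d cycle(s) of %d frames + %d MBT frames\n",
    x$seed, x$field_um[1], x$field_um[2], x$n_initial, x$n_cycles,
    x$frames_per_cycle, x$mbt_frames))
  invisible(x)
}

#' Simulate ground-truth nuclear dynamics of a syncytial embryo
#'
#' Generates per-frame nuclei (position, ploidy, phase, volume, reporter
#' intensity), the true frame-to-frame lineage links (including 1 to 2
#' division links and 2 to 1 collision links), and an event log of
#' divisions, collisions and eliminations. Deterministic given
#' `params$seed`.
#'
#' @param params a [sim_params] object.
#' @return an object of class `sim_scene`: list with `nuclei` (data frame:
#'   frame, id, x, y, z, ploidy, phase, cycle, volume, mean_intensity,
#'   parent1, parent2), `links` (frame, from, to), `events` (frame, type,
#'   id, parent1, parent2, phase, cycle), `n_frames`, `anaphase_frames`,
#'   `mbt_start`, `params`.
#' @export
simulate_scene <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  dt <- p$frame_interval_s / 60
  sig <- p$displacement_mean_um / sqrt(pi)
  F <- p$frames_per_cycle
  n_frames <- p$n_cycles * F + p$mbt_frames

  # frame schedule: phase, cycle index and time-within-block of every frame
  phase <- character(n_frames); cyc <- integer(n_frames)
  tblk <- integer(n_frames)  # frames since block start (0-based)
  anaphase_frames <- integer(0)
  f <- 1L
  if (p$n_cycles > 0) for (c in seq_len(p$n_cycles)) {
    ph <- c(if (c == 1L) "interphase" else "telophase",
            rep("interphase", F - 4L), "prophase", "metaphase", "anaphase")
    phase[f:(f + F - 1L)] <- ph
    cyc[f:(f + F - 1L)] <- c
    tblk[f:(f + F - 1L)] <- 0:(F - 1L)
    anaphase_frames <- c(anaphase_frames, f + F - 1L)
    f <- f + F
  }
  mbt_start <- f
  phase[f:n_frames] <- c(if (p$n_cycles > 0) "telophase" else "interphase",
                         rep("interphase", n_frames - f))
  cyc[f:n_frames] <- p$n_cycles + 1L
  tblk[f:n_frames] <- 0:(n_frames - f)

  # initial placement: jittered grid spanning the field, corners included
  k <- ceiling(sqrt(p$n_initial))
  slots <- expand.grid(x = seq(0, p$field_um[1], length.out = k),
                       y = seq(0, p$field_um[2], length.out = k))
  corners <- which(slots$x %in% range(slots$x) & slots$y %in% range(slots$y))
  extra <- setdiff(seq_len(nrow(slots)), corners)
  take <- c(corners, sample(extra))[seq_len(min(p$n_initial, nrow(slots)))]
  st <- data.frame(
    id = seq_along(take),
    ax = slots$x[take] + rnorm(length(take), 0, 0.5),
    ay = slots$y[take] + rnorm(length(take), 0, 0.5),
    az = p$depth_um + rnorm(length(take), 0, 0.3),
    ploidy = 1L, cycle = 1L, vol = p$v_haploid_um3,
    parent1 = NA_integer_, parent2 = NA_integer_
  )
  st$ax <- pmin(pmax(st$ax, 0), p$field_um[1])
  st$ay <- pmin(pmax(st$ay, 0), p$field_um[2])
  next_id <- nrow(st) + 1L

  rows <- vector("list", n_frames)
  links <- vector("list", n_frames)
  events <- list()
  plan <- NULL  # collision plan for the running mitosis

  jitter_xy <- function(st) {
    x <- pmin(pmax(st$ax + rnorm(nrow(st), 0, sig), 0), p$field_um[1])
    y <- pmin(pmax(st$ay + rnorm(nrow(st), 0, sig), 0), p$field_um[2])
    z <- pmax(st$az + rnorm(nrow(st), 0, 0.2), 0.2)
    cbind(x = x, y = y, z = z)
  }

  relax <- function(st, rounds = NULL) {
    # cortical nuclei repel each other (astral microtubules) and settle
    # into a near-regular array; short deterministic relaxation of the
    # anchors after each synchronous division emulates this
    n <- nrow(st)
    if (n < 2L) return(st)
    if (is.null(rounds)) rounds <- if (n > 500L) 12L else 30L
    r0 <- 0.95 * sqrt(prod(p$field_um) / n)
    ax <- st$ax; ay <- st$ay
    for (it in seq_len(rounds)) {
      dx <- outer(ax, ax, "-"); dy <- outer(ay, ay, "-")
      d <- sqrt(dx * dx + dy * dy)
      d[d < 1e-6] <- 1e-6
      w <- r0 / d - 1          # (r0 - d) / d, zero beyond the rest length
      w[w < 0] <- 0
      diag(w) <- 0
      if (!any(w > 0)) break
      ax <- pmin(pmax(ax + 0.3 * rowSums(w * dx), 0), p$field_um[1])
      ay <- pmin(pmax(ay + 0.3 * rowSums(w * dy), 0), p$field_um[2])
    }
    st$ax <- ax; st$ay <- ay
    st
  }

  grow <- function(st, t_min) {
    # shared-pool growth engine: phase 1 is chromatin-driven (rate g1 per
    # ploidy unit), phase 2 draws on the remaining NAF pool in proportion
    # to ploidy and never faster than phase 1
    n <- nrow(st)
    if (n == 0L) return(st)
    vmax <- Inf
    if (n >= 3L) {
      h <- grDevices::chull(st$ax, st$ay)
      if (length(h) >= 3L)
        vmax <- p$vhr_ceiling * abs(.shoelace(st$ax[h], st$ay[h]))
    }
    vtot <- sum(st$vol)
    g1 <- p$growth_rate_um3_min * st$ploidy * dt
    if (t_min < p$growth_breakpoint_min) {
      dv <- g1
    } else {
      budget <- max(0, p$pool_rate_per_min * (vmax - vtot) * dt)
      dv <- pmin(g1, budget * st$ploidy / sum(st$ploidy))
    }
    room <- max(0, vmax - vtot)
    if (sum(dv) > room && sum(dv) > 0) dv <- dv * room / sum(dv)
    st$vol <- st$vol + dv
    st
  }

  for (t in seq_len(n_frames)) {
    ph <- phase[t]
    mitotic <- ph %in% c("prophase", "metaphase", "anaphase")
    if (!mitotic && tblk[t] > 0L) st <- grow(st, (tblk[t] - 1L) * dt)
    pos <- jitter_xy(st)
    shown_vol <- if (mitotic) p$v_mitotic_um3 * st$ploidy else st$vol
    rows[[t]] <- data.frame(
      frame = t, id = st$id, x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
      ploidy = st$ploidy, phase = ph, cycle = st$cycle, volume = shown_vol,
      mean_intensity = p$intensity_base *
        p$intensity_cycle_factor^(st$cycle - 1L) *
        ifelse(mitotic, p$mitotic_brightness, 1),
      parent1 = st$parent1, parent2 = st$parent2
    )
    if (t == n_frames) break

    if (ph == "prophase") {
      # plan this mitosis' collisions: mark ~collision_prob of nuclei as
      # participants (even count, unbiased), pair nearest participants
      n <- nrow(st)
      kk <- rbinom(1L, n, p$collision_prob)
      if (kk %% 2L == 1L) kk <- kk + sample(c(-1L, 1L), 1L)
      kk <- max(0L, min(kk, n - n %% 2L))
      pairs <- NULL
      if (kk >= 2L) {
        # kk/2 seed nuclei each collide with their nearest free neighbour
        seeds <- sample(st$id, kk %/% 2L)
        pairs <- list()
        taken <- seeds
        for (a in seeds) {
          ia <- match(a, st$id)
          free <- which(!st$id %in% taken)
          if (!length(free)) break
          d2 <- (st$ax[free] - st$ax[ia])^2 + (st$ay[free] - st$ay[ia])^2
          b <- st$id[free[which.min(d2)]]
          taken <- c(taken, b)
          pairs[[length(pairs) + 1L]] <- c(a, b)
        }
      }
      plan <- list(pairs = pairs,
                   anaphase = if (length(pairs))
                     runif(length(pairs)) < p$collision_anaphase_prob
                   else logical(0))
      links[[t]] <- data.frame(frame = t, from = st$id, to = st$id)
    } else if (ph == "metaphase" && t > 1L && phase[t - 1L] == "prophase") {
      links[[t]] <- data.frame(frame = t, from = st$id, to = st$id)
    } else if (ph == "anaphase") {
      # divide: each nucleus is replaced by two daughters displaced along a
      # random axis, up to anaphase_cap_um from the mother
      n <- nrow(st)
      theta <- runif(n, 0, 2 * pi)
      d1 <- runif(n, 0.15, 0.5) * p$anaphase_cap_um
      d2 <- runif(n, 0.15, 0.5) * p$anaphase_cap_um
      mk <- function(sgn, d, ids) data.frame(
        id = ids,
        ax = pmin(pmax(st$ax + sgn * d * cos(theta), 0), p$field_um[1]),
        ay = pmin(pmax(st$ay + sgn * d * sin(theta), 0), p$field_um[2]),
        az = st$az, ploidy = st$ploidy, cycle = st$cycle + 1L,
        vol = p$v_haploid_um3 * st$ploidy,
        parent1 = st$id, parent2 = NA_integer_)
      da <- mk(1, d1, next_id - 1L + seq_len(n))
      db <- mk(-1, d2, next_id - 1L + n + seq_len(n))
      next_id <- next_id + 2L * n
      lk <- data.frame(frame = t, from = c(st$id, st$id),
                       to = c(da$id, db$id))
      for (i in seq_len(n))
        events[[length(events) + 1L]] <- data.frame(
          frame = t, type = "division", id = st$id[i],
          parent1 = da$id[i], parent2 = db$id[i],
          phase = "anaphase", cycle = st$cycle[i])
      new <- rbind(da, db)
      # anaphase collisions: one daughter of each planned mother pair merges
      # with the nearest daughter of its partner (never a sibling)
      if (!is.null(plan) && length(plan$pairs)) {
        ana <- plan$pairs[plan$anaphase]
        for (pr in ana) {
          ia <- which(new$parent1 == pr[1L])
          ib <- which(new$parent1 == pr[2L])
          if (length(ia) < 2L || length(ib) < 2L) next
          a2 <- ia[2L]
          d2b <- (new$ax[ib] - new$ax[a2])^2 + (new$ay[ib] - new$ay[a2])^2
          b2 <- ib[which.min(d2b)]
          w <- new$ploidy[c(a2, b2)]
          merged <- data.frame(
            id = next_id,
            ax = sum(new$ax[c(a2, b2)] * w) / sum(w),
            ay = sum(new$ay[c(a2, b2)] * w) / sum(w),
            az = mean(new$az[c(a2, b2)]),
            ploidy = sum(w), cycle = new$cycle[a2],
            vol = p$v_haploid_um3 * sum(w),
            parent1 = pr[1L], parent2 = pr[2L])
          next_id <- next_id + 1L
          events[[length(events) + 1L]] <- data.frame(
            frame = t + 1L, type = "collision", id = merged$id,
            parent1 = pr[1L], parent2 = pr[2L],
            phase = "anaphase", cycle = st$cycle[match(pr[1L], st$id)])
          drop_ids <- new$id[c(a2, b2)]
          lk$to[lk$to %in% drop_ids] <- merged$id
          new <- rbind(new[-c(a2, b2), ], merged)
        }
      }
      st <- relax(new)
      plan <- NULL
      links[[t]] <- lk
    } else {
      # plain interphase transition; post-MBT nuclei may be eliminated
      keep <- rep(TRUE, nrow(st))
      if (t >= mbt_start && p$elimination_prob > 0) {
        gone <- runif(nrow(st)) < p$elimination_prob
        for (i in which(gone))
          events[[length(events) + 1L]] <- data.frame(
            frame = t + 1L, type = "elimination", id = st$id[i],
            parent1 = NA_integer_, parent2 = NA_integer_,
            phase = "interphase", cycle = st$cycle[i])
        keep <- !gone
      }
      links[[t]] <- data.frame(frame = t, from = st$id[keep],
                               to = st$id[keep])
      st <- st[keep, , drop = FALSE]
    }

    # metaphase collision: partners merge into a single mitotic figure
    if (phase[t + 1L] == "metaphase" && !is.null(plan) &&
        length(plan$pairs) && any(!plan$anaphase)) {
      met <- plan$pairs[!plan$anaphase]
      lk <- links[[t]]
      for (pr in met) {
        ia <- match(pr[1L], st$id); ib <- match(pr[2L], st$id)
        if (is.na(ia) || is.na(ib)) next
        w <- st$ploidy[c(ia, ib)]
        merged <- data.frame(
          id = next_id,
          ax = sum(st$ax[c(ia, ib)] * w) / sum(w),
          ay = sum(st$ay[c(ia, ib)] * w) / sum(w),
          az = mean(st$az[c(ia, ib)]),
          ploidy = sum(w), cycle = st$cycle[ia],
          vol = sum(st$vol[c(ia, ib)]),
          parent1 = pr[1L], parent2 = pr[2L])
        next_id <- next_id + 1L
        events[[length(events) + 1L]] <- data.frame(
          frame = t + 1L, type = "collision", id = merged$id,
          parent1 = pr[1L], parent2 = pr[2L],
          phase = "metaphase", cycle = st$cycle[ia])
        lk$to[lk$from %in% pr] <- merged$id
        st <- rbind(st[-c(ia, ib), ], merged)
      }
      links[[t]] <- lk
      plan$pairs <- plan$pairs[plan$anaphase]
      plan$anaphase <- plan$anaphase[plan$anaphase]
    }
  }

  scene <- structure(list(
    nuclei = do.call(rbind, rows),
    links = do.call(rbind, links[!vapply(links, is.null, TRUE)]),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(frame = integer(0), type = character(0), id = integer(0),
                 parent1 = integer(0), parent2 = integer(0),
                 phase = character(0), cycle = integer(0)),
    n_frames = n_frames, anaphase_frames = anaphase_frames,
    mbt_start = mbt_start, params = p
  ), class = "sim_scene")
  rownames(scene$nuclei) <- NULL
  rownames(scene$links) <- NULL
  rownames(scene$events) <- NULL
  scene
}

#' @export
print.sim_scene <- function(x, ...) {
  nv <- table(x$events$type)
  cat(sprintf(
    "<sim_scene> %d frames, %d nucleus-frames, %d nuclei at last frame\n",
    x$n_frames, nrow(x$nuclei), sum(x$nuclei$frame == x$n_frames)))
  if (length(nv)) cat("  events:",
    paste(sprintf("%s %d", names(nv), as.integer(nv)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sim_scene <- function(object, ...) {
  d <- object$nuclei
  disp <- scene_displacements(object)
  out <- list(
    n_frames = object$n_frames,
    nuclei_final = sum(d$frame == object$n_frames),
    ploidy_table = table(d$ploidy[d$frame == object$n_frames]),
    mean_displacement_um = mean(disp$interphase),
    median_displacement_um = stats::median(disp$interphase),
    events = table(object$events$type)
  )
  class(out) <- "summary.sim_scene"
  out
}

#' @export
print.summary.sim_scene <- function(x, ...) {
  cat(sprintf("frames: %d, final nuclei: %d\n", x$n_frames, x$nuclei_final))
  cat(sprintf("interphase displacement: mean %.2f um, median %.2f um\n",
              x$mean_displacement_um, x$median_displacement_um))
  cat("final ploidies:\n"); print(x$ploidy_table)
  if (length(x$events)) { cat("events:\n"); print(x$events) }
  invisible(x)
}

#' Ground-truth nuclei of one frame
#'
#' @param scene a [sim_scene].
#' @param frame frame index.
#' @return data frame with one row per nucleus alive at `frame`.
#' @export
scene_frame <- function(scene, frame) {
  stopifnot(inherits(scene, "sim_scene"))
  scene$nuclei[scene$nuclei$frame == frame, , drop = FALSE]
}

#' True frame-to-frame displacements of a scene
#'
#' Euclidean x-y-z displacement of every one-to-one ground-truth link,
#' split into interphase moves and division/collision transitions.
#'
#' @param scene a [sim_scene].
#' @return list with numeric vectors `interphase` and `mitotic` (um).
#' @export
scene_displacements <- function(scene) {
  d <- scene$nuclei
  key <- paste(d$frame, d$id)
  lk <- scene$links
  i <- match(paste(lk$frame, lk$from), key)
  j <- match(paste(lk$frame + 1L, lk$to), key)
  ok <- !is.na(i) & !is.na(j)
  i <- i[ok]; j <- j[ok]
  dist <- sqrt((d$x[j] - d$x[i])^2 + (d$y[j] - d$y[i])^2 +
               (d$z[j] - d$z[i])^2)
  moving <- lk$from[ok] == lk$to[ok] &
    d$phase[i] %in% c("interphase", "telophase")
  list(interphase = dist[moving], mitotic = dist[!moving])
}

#' Piecewise interphase nuclear growth model
#'
#' Closed-form volume of a nucleus `t` minutes after telophase: rapid linear
#' phase-1 growth proportional to ploidy, followed by phase-2 growth that
#' draws on the remaining share of a finite nuclear-assembly-factor pool
#' (exponential approach to the pool share, never faster than phase 1).
#' The curve is continuous at the breakpoint. The per-nucleus pool share is
#' `1000 * vhr_ceiling / nd * ploidy / mean_ploidy`.
#'
#' @param t_min minutes since telophase (vectorised).
#' @param ploidy ploidy of the nucleus.
#' @param nd nuclear density of the scene (#nuclei / 1000 um^2).
#' @param params a [sim_params].
#' @param mean_ploidy mean ploidy of the surrounding nuclei (1 in a
#'   haploid-dominated embryo).
#' @return nuclear volume(s) in um^3.
#' @export
interphase_growth_model <- function(t_min, ploidy = 1, nd = 26,
                                    params = sim_params(seed = 1),
                                    mean_ploidy = 1) {
  stopifnot(all(t_min >= 0), nd > 0, ploidy >= 1)
  p <- params
  s <- 1000 * p$vhr_ceiling / nd * ploidy / mean_ploidy
  g <- p$growth_rate_um3_min * ploidy
  t1 <- p$growth_breakpoint_min
  k <- p$pool_rate_per_min
  v0 <- p$v_haploid_um3 * ploidy
  v_t1 <- min(v0 + g * t1, s)
  v <- numeric(length(t_min))
  early <- t_min <= t1
  v[early] <- pmin(v0 + g * t_min[early], s)
  if (any(!early)) {
    tt <- t_min[!early] - t1
    if (k * (s - v_t1) <= g) {
      v[!early] <- s - (s - v_t1) * exp(-k * tt)
    } else {
      # pool share still abundant: grow at the phase-1 cap until the gap
      # shrinks to g / k, then approach the share exponentially
      tc <- ((s - v_t1) - g / k) / g
      lin <- tt <= tc
      vv <- numeric(length(tt))
      vv[lin] <- v_t1 + g * tt[lin]
      vv[!lin] <- s - (g / k) * exp(-k * (tt[!lin] - tc))
      v[!early] <- vv
    }
  }
  v
}

#' Render one frame of a scene as a noisy image stack
#'
#' Each nucleus becomes a slightly oblate ellipsoid whose rasterized volume
#' matches the ground truth; mitotic figures are condensed (smaller and
#' brighter). Voxel intensity is the nucleus' mean reporter intensity
#' (proportional to ploidy times the per-cycle reporter factor at mitosis),
#' over a constant background with additive Gaussian noise.
#'
#' @param scene a [sim_scene].
#' @param frame frame index (an empty frame yields a background-only stack).
#' @param params rendering parameters; defaults to the scene's.
#' @param voxel_um voxel size override for coarser test renders.
#' @return an [image_stack].
#' @export
render_stack <- function(scene, frame, params = scene$params,
                         voxel_um = params$voxel_um) {
  stopifnot(inherits(scene, "sim_scene"))
  p <- params
  nx <- ceiling(p$field_um[1] / voxel_um[1])
  ny <- ceiling(p$field_um[2] / voxel_um[2])
  nz <- ceiling(p$stack_depth_um / voxel_um[3])
  a <- array(0, c(nx, ny, nz))
  nuc <- scene_frame(scene, frame)
  if (nrow(nuc)) {
    cx <- (seq_len(nx) - 0.5) * voxel_um[1]
    cy <- (seq_len(ny) - 0.5) * voxel_um[2]
    cz <- (seq_len(nz) - 0.5) * voxel_um[3]
    for (i in seq_len(nrow(nuc))) {
      r <- (3 * nuc$volume[i] / (4 * pi))^(1 / 3)
      rz <- min(0.8 * r, p$stack_depth_um / 2 - voxel_um[3])
      rxy <- sqrt(r^3 / rz)
      xi <- which(abs(cx - nuc$x[i]) <= rxy)
      yi <- which(abs(cy - nuc$y[i]) <= rxy)
      zi <- which(abs(cz - nuc$z[i]) <= rz)
      if (!length(xi) || !length(yi) || !length(zi)) next
      ex <- ((cx[xi] - nuc$x[i]) / rxy)^2
      ey <- ((cy[yi] - nuc$y[i]) / rxy)^2
      ez <- ((cz[zi] - nuc$z[i]) / rz)^2
      msk <- outer(outer(ex, ey, "+"), ez, "+") <= 1
      sub <- a[xi, yi, zi, drop = FALSE]
      sub[msk] <- pmax(sub[msk], nuc$mean_intensity[i])
      a[xi, yi, zi] <- sub
    }
  }
  a <- a + p$background
  if (p$noise_sd > 0) a <- a + rnorm(length(a), 0, p$noise_sd)
  image_stack(a, voxel_um, frame_index = frame)
}

#' Write a scene's ground-truth tables to a directory
#'
#' Writes `nuclei.csv`, `links.csv` and `events.csv` with fixed column order
#' and 6-decimal fixed-point numbers, so identical scenes produce
#' byte-identical files.
#'
#' @param scene a [sim_scene].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "sim_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv_fixed(scene$nuclei, file.path(dir, "nuclei.csv"))
  .write_csv_fixed(scene$links, file.path(dir, "links.csv"))
  .write_csv_fixed(scene$events, file.path(dir, "events.csv"))
  invisible(dir)
}
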