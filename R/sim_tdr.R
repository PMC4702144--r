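#' Build one planted dive as a per-sample depth segment
#'
#' Dives are piecewise-linear profiles with knots on the sampling grid:
#' transit and search dives are V-shapes (search descends faster, so its
#' near-maximum band spans fewer than 5 s and carries no foraging signature);
#' forage dives get a flat bottom phase at the maximum depth, triangle-wave
#' wiggles of fixed excursion inside the bottom phase, and an optional flat
#' shelf (plateau) at half the maximum depth during ascent.
#'
#' @return List: `depth` (vector at the sampling interval, surface-to-surface),
#'   `planted` (intended class and signature counts).
#' @noRd
build_dive_segment <- function(class, D, duration, flags, n_wiggles, cfg) {
  dv <- cfg$dive
  dt <- cfg$sample_interval
  if (class == "transit") {
    t1 <- max(1, round(D / dv$transit_speed))
    # enforce the minimum-duration detector bound
    t1 <- max(t1, ceiling(cfg$thresholds$min_duration / 2))
    knots_t <- c(0, t1, 2 * t1)
    knots_d <- c(0, D, 0)
    planted <- list(class = "transit", n_wiggles = 0L, n_plateaus = 0L,
                    has_bottom = FALSE)
  } else if (class == "search") {
    t1 <- max(1, round(D / dv$search_speed))
    t1 <- max(t1, ceiling(cfg$thresholds$min_duration / 2))
    knots_t <- c(0, t1, 2 * t1)
    knots_d <- c(0, D, 0)
    planted <- list(class = "search", n_wiggles = 0L, n_plateaus = 0L,
                    has_bottom = FALSE)
  } else {
    pl <- isTRUE(flags[["plateau"]])
    wg <- isTRUE(flags[["wiggle"]])
    bt <- isTRUE(flags[["bottom"]])
    # bottom-less forage dives travel steeply so the near-maximum band
    # stays under the bottom-time threshold
    v <- if (bt) dv$descent_speed else (dv$steep_speed %||% 4)
    d_desc <- max(1, round(D / v))
    a1 <- max(1, round(D * (1 - dv$plateau_rel_depth) / v))
    a2 <- max(1, round(D * dv$plateau_rel_depth / v))
    nw <- if (wg) max(1L, n_wiggles) else 0L
    w_dur <- 4L                    # seconds per planted wiggle oscillation
    pl_dur <- if (pl) dv$plateau_duration else 0L
    fixed <- d_desc + a1 + a2 + pl_dur + nw * w_dur
    if (bt) {
      B <- max(round(duration) - fixed, 6)
    } else {
      # no planted bottom time: the spare duration goes into the plateau
      # shelf (if any) instead of a flat segment at maximum depth
      B <- 0
      if (pl) pl_dur <- pl_dur + max(round(duration) - fixed, 0)
    }
    B1 <- ceiling(B / 2); B2 <- B - B1
    kt <- c(0, d_desc)
    kd <- c(0, D)
    if (B1 > 0) { kt <- c(kt, kt[length(kt)] + B1); kd <- c(kd, D) }
    if (nw > 0) {
      for (w in seq_len(nw)) {
        t0 <- kt[length(kt)]
        kt <- c(kt, t0 + 2, t0 + 4)
        kd <- c(kd, D - dv$wiggle_excursion, D)
      }
    }
    if (B2 > 0) { kt <- c(kt, kt[length(kt)] + B2); kd <- c(kd, D) }
    t0 <- kt[length(kt)]
    kt <- c(kt, t0 + a1)
    kd <- c(kd, D * dv$plateau_rel_depth)
    if (pl) {
      kt <- c(kt, kt[length(kt)] + pl_dur)
      kd <- c(kd, D * dv$plateau_rel_depth)
    }
    kt <- c(kt, kt[length(kt)] + a2)
    kd <- c(kd, 0)
    knots_t <- kt; knots_d <- kd
    planted <- list(class = "forage", n_wiggles = nw,
                    n_plateaus = as.integer(pl),
                    has_bottom = bt || (B1 + B2 + nw * w_dur) >= cfg$thresholds$bottom_min_time)
  }
  times <- seq(0, knots_t[length(knots_t)], by = dt)
  depth <- approx(knots_t, knots_d, xout = times, rule = 2)$y
  list(depth = depth, planted = planted)
}

#' Generate time-depth-recorder traces with planted dives and ground truth
#'
#' One continuous at-sea trace per individual per day. Dives are planted with
#' known class and signature counts; gentoo forage dives performed inside the
#' overlap zone receive the configured additive depth shift. A slow linear
#' depth-sensor drift (bounded by the configured maximum) and Gaussian sensor
#' noise are added to the measured depths; both are recorded in the truth.
#'
#' Truth shape metrics (bottom time, wiggles, plateaus, behaviour class) are
#' computed on the noise-free planted profile with the same signature
#' definitions the dive classifier uses, so noise-free recovery is exact.
#'
#' @param cfg A [sim_config()].
#' @param truth_regions Optional polygon zone for the overlap region; defaults
#'   to the configuration's overlap zone rectangle.
#' @return List with `tdr` (data frame: id, species, sex, day, date, tide,
#'   time, depth), `dives` truth table (one row per planted dive) and
#'   `traces` truth table (per-trace drift).
#' @export
generate_tdr <- function(cfg, truth_regions = NULL) {
  validate_sim_config(cfg)
  if (cfg$sample_interval <= 0) stop("configuration error: sampling interval must be > 0")
  inds <- plan_individuals(cfg)
  zone <- cfg$track$overlap_zone
  th <- cfg$thresholds
  dt <- cfg$sample_interval

  trace_rows <- list(); dive_rows <- list(); drift_rows <- list()
  for (i in seq_len(nrow(inds))) {
    ind <- inds[i, ]
    dp <- cfg$dive[[ind$species]]
    n_samp <- floor(cfg$trip_hours * 3600 / dt) + 1L
    for (d in seq_len(cfg$days)) {
      path <- build_day_path(cfg, ind, d)
      ph <- path$ph
      set.seed(derive_seed(cfg$seed, sprintf("tdr_%s_%03d", ind$id, d)))
      depth <- numeric(n_samp)
      t_cursor <- 30  # initial surface interval, s
      # per-dive truth accumulators (vectors; one data frame per day)
      acc <- list(start = numeric(0), dur = numeric(0), maxd = numeric(0),
                  bt = numeric(0), nw = integer(0), np = integer(0),
                  pw = integer(0), pp = integer(0), beh = character(0),
                  pcl = character(0), x = numeric(0), y = numeric(0),
                  ov = logical(0))
      while (TRUE) {
        in_forage_phase <- t_cursor >= ph$forage_start && t_cursor < ph$forage_end
        probs <- if (in_forage_phase) cfg$dive$class_prob_forage_phase else
          cfg$dive$class_prob_transit_phase
        cls <- sample(names(probs), 1L, prob = probs)
        pos <- c(approx(path$t, path$x, xout = t_cursor, rule = 2)$y,
                 approx(path$t, path$y, xout = t_cursor, rule = 2)$y)
        in_ov <- in_rect_zone(pos[1], pos[2], zone)
        if (cls == "transit") {
          D <- runif(1, cfg$dive$transit_depth[1], cfg$dive$transit_depth[2])
          seg <- build_dive_segment("transit", D, NA, NULL, 0L, cfg)
        } else if (cls == "search") {
          D <- runif(1, cfg$dive$search_depth[1], cfg$dive$search_depth[2])
          seg <- build_dive_segment("search", D, NA, NULL, 0L, cfg)
        } else {
          D <- rnorm_trunc(1, dp$depth_mean + ind$depth_offset, dp$depth_sd,
                           dp$depth_min, dp$depth_max)
          if (ind$species == "gentoo" && in_ov) D <- D + cfg$overlap_effect
          flags <- c(bottom = runif(1) < dp$p_bottom,
                     wiggle = runif(1) < dp$p_wiggle,
                     plateau = runif(1) < dp$p_plateau)
          if (!any(flags)) flags["bottom"] <- TRUE
          nw <- if (flags[["wiggle"]]) 1L + rpois(1, 1.2) else 0L
          dur <- rnorm_trunc(1, dp$duration_mean + ind$duration_offset,
                             dp$duration_sd, lower = 3 * dt)
          seg <- build_dive_segment("forage", D, dur, flags, nw, cfg)
        }
        n_seg <- length(seg$depth)
        i0 <- floor(t_cursor / dt) + 1L
        if (i0 + n_seg - 1L > n_samp - 10L) break
        depth[i0:(i0 + n_seg - 1L)] <- seg$depth
        # truth metrics from the clean profile via the shared definitions
        sm <- dive_shape_metrics(seg$depth, dt, th)
        true_class <- classify_dive_label(
          max_depth = max(seg$depth), bottom_time = sm$bottom_time,
          n_wiggles = sm$n_wiggles, n_plateaus = sm$n_plateaus, thresholds = th)
        acc$start <- c(acc$start, (d - 1L) * 86400 + (i0 - 1L) * dt)
        acc$dur <- c(acc$dur, (n_seg - 1L) * dt)
        acc$maxd <- c(acc$maxd, max(seg$depth))
        acc$bt <- c(acc$bt, sm$bottom_time)
        acc$nw <- c(acc$nw, sm$n_wiggles)
        acc$np <- c(acc$np, sm$n_plateaus)
        acc$pw <- c(acc$pw, seg$planted$n_wiggles)
        acc$pp <- c(acc$pp, seg$planted$n_plateaus)
        acc$beh <- c(acc$beh, true_class)
        acc$pcl <- c(acc$pcl, seg$planted$class)
        acc$x <- c(acc$x, pos[1]); acc$y <- c(acc$y, pos[2])
        acc$ov <- c(acc$ov, in_ov)
        t_cursor <- (i0 - 1L + n_seg - 1L) * dt +
          runif(1, cfg$dive$surface_interval[1], cfg$dive$surface_interval[2])
      }
      drift_end <- if (cfg$drift_max > 0) runif(1, -cfg$drift_max, cfg$drift_max) else 0
      drift <- seq(0, drift_end, length.out = n_samp)
      noise <- if (cfg$depth_noise_sd > 0) rnorm(n_samp, 0, cfg$depth_noise_sd) else 0
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        id = ind$id, species = ind$species, sex = ind$sex,
        day = d, date = cfg$start_date + d - 1L, tide = cfg$tide_labels[d],
        time = (d - 1L) * 86400 + (seq_len(n_samp) - 1L) * dt,
        depth = depth + drift + noise,
        stringsAsFactors = FALSE
      )
      drift_rows[[length(drift_rows) + 1L]] <- data.frame(
        id = ind$id, day = d, drift_end = drift_end,
        at_sea_hours = ph$trip_sec / 3600, stringsAsFactors = FALSE)
      if (length(acc$start) > 0) {
        dive_rows[[length(dive_rows) + 1L]] <- data.frame(
          id = ind$id, species = ind$species, sex = ind$sex,
          day = d, date = cfg$start_date + d - 1L, tide = cfg$tide_labels[d],
          start_time = acc$start, duration = acc$dur, max_depth = acc$maxd,
          bottom_time = acc$bt, n_wiggles = acc$nw, n_plateaus = acc$np,
          planted_wiggles = acc$pw, planted_plateaus = acc$pp,
          behavior = acc$beh, planted_class = acc$pcl,
          x = acc$x, y = acc$y, in_overlap = acc$ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(tdr = do.call(rbind, trace_rows),
       dives = do.call(rbind, dive_rows),
       traces = do.call(rbind, drift_rows))
}
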