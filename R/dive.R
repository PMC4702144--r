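#' Default dive-signature thresholds
#'
#' Bottom phase at >= 80% of maximum depth (a bottom-time signature needs
#' >= 5 s of it), wiggles are complete oscillations of >= 2 m excursion inside
#' the bottom phase, plateaus are >= 5 s runs outside the bottom phase deeper
#' than 3 m with vertical speed <= 0.25 m/s, dives must reach 3 m and last
#' 10 s, transit dives stay above 10 m. These follow common biologging
#' practice and are configuration keys, not constants.
#'
#' @return Named list of thresholds.
#' @export
dive_thresholds <- function() {
  list(dive_threshold = 1, min_depth = 3, min_duration = 10,
       bottom_frac = 0.8, bottom_min_time = 5,
       wiggle_min_excursion = 2,
       plateau_min_duration = 5, plateau_max_speed = 0.25,
       plateau_min_depth = 3, transit_max_depth = 10)
}

#' Correct depth-sensor drift in a TDR trace
#'
#' Estimates the zero offset as the modal near-surface depth within sliding
#' windows (default 30 min), interpolates the offsets across the trace and
#' subtracts them. Residual depths between -1 m and 0 are set to 0.
#'
#' @param depth Numeric depth vector (m, positive down), uniform sampling.
#' @param interval Sampling interval (s).
#' @param window Window length (s). If longer than the trace a single global
#'   offset is used, with a warning.
#' @return List: `depth` (corrected), `offset` (estimated offset per sample).
#' @export
correct_drift <- function(depth, interval = 1, window = 1800) {
  n <- length(depth)
  if (n == 0L) stop("input error: empty trace", call. = FALSE)
  wlen <- max(3L, round(window / interval))
  surface_mode <- function(d) {
    cand <- d[d <= min(d) + 2.5]
    if (length(cand) < 5L) return(stats::median(cand))
    dens <- stats::density(cand, bw = 0.1)
    dens$x[which.max(dens$y)]
  }
  if (wlen >= n) {
    warning("drift window longer than trace; using a single global offset")
    off <- rep(surface_mode(depth), n)
  } else {
    starts <- seq(1L, n - wlen + 1L, by = max(1L, wlen %/% 2L))
    centers <- starts + (wlen - 1L) / 2
    est <- vapply(starts, function(s) surface_mode(depth[s:(s + wlen - 1L)]),
                  numeric(1))
    off <- stats::approx(centers, est, xout = seq_len(n), rule = 2)$y
  }
  corrected <- depth - off
  if (any(corrected < -1)) {
    warning(sprintf("%d corrected depths below -1 m set to 0",
                    sum(corrected < -1)))
  }
  corrected[corrected < 0] <- 0
  list(depth = corrected, offset = off)
}

#' Detect dives in a drift-corrected depth trace
#'
#' A dive is a maximal interval with depth above the dive threshold
#' (default 1 m) whose maximum reaches `min_depth` and whose duration reaches
#' `min_duration`; intervals failing either bound are discarded. Dives are
#' non-overlapping and time-ordered.
#'
#' @param depth Drift-corrected depth vector (uniform sampling).
#' @param time Sample times (s), strictly increasing, fixed interval.
#' @param min_depth Minimum maximum-depth of a dive (m).
#' @param min_duration Minimum dive duration (s).
#' @param dive_threshold Surface threshold (m) defining submersion.
#' @return Data frame with one row per dive: start/end sample index,
#'   start/end time, duration, max_depth.
#' @export
detect_dives <- function(depth, time, min_depth = 3, min_duration = 10,
                         dive_threshold = 1) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("input error: time must be strictly increasing", call. = FALSE)
  }
  wet <- depth > dive_threshold
  if (!any(wet)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_time = numeric(), end_time = numeric(),
                      duration = numeric(), max_depth = numeric()))
  }
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s <- starts[keep]; e <- ends[keep]
  # include the bracketing surface samples so the full excursion is covered
  s <- pmax(1L, s - 1L); e <- pmin(length(depth), e + 1L)
  dur <- time[e] - time[s]
  mx <- vapply(seq_along(s), function(i) max(depth[s[i]:e[i]]), numeric(1))
  ok <- mx >= min_depth & dur >= min_duration
  data.frame(start_idx = s[ok], end_idx = e[ok],
             start_time = time[s][ok], end_time = time[e][ok],
             duration = dur[ok], max_depth = mx[ok])
}

#' Shape metrics of a single dive segment
#'
#' Bottom phase: first to last sample with depth >= `bottom_frac` of the
#' maximum; its length is the bottom time. Wiggle: a complete oscillation
#' (descent-ascent-descent sign-reversal sequence) inside the bottom phase
#' with vertical excursion >= the threshold. Plateau: a maximal run outside
#' the bottom phase, deeper than the plateau depth floor, of at least the
#' minimum duration with absolute vertical speed below the ceiling.
#'
#' @param depth Depth samples of one dive (surface to surface).
#' @param interval Sampling interval (s).
#' @param thresholds Threshold list, see [dive_thresholds()].
#' @return List: max_depth, bottom_time (s), n_wiggles, n_plateaus.
#' @export
dive_shape_metrics <- function(depth, interval = 1,
                               thresholds = dive_thresholds()) {
  if (length(depth) < 3L) {
    stop("degenerate-dive error: segment shorter than 3 samples", call. = FALSE)
  }
  th <- thresholds
  mx <- max(depth)
  band <- mx * th$bottom_frac
  in_band <- which(depth >= band)
  first_b <- in_band[1L]; last_b <- in_band[length(in_band)]
  bottom_time <- (last_b - first_b) * interval

  # wiggles: alternate-extrema scan within the bottom phase
  n_wiggles <- 0L
  if (last_b - first_b >= 2L) {
    seg <- depth[first_b:last_b]
    d <- diff(seg)
    d <- d[d != 0]
    if (length(d) >= 2L) {
      # positions of sign changes in the de-duplicated series
      seg2 <- seg[c(TRUE, diff(seg) != 0)]
      n2 <- length(seg2)
      if (n2 >= 3L) {
        dd <- diff(seg2)
        turns <- which(dd[-1] * dd[-length(dd)] < 0) + 1L
        ext_idx <- c(1L, turns, n2)
        ext <- seg2[ext_idx]
        # local minima of depth = tops of upward excursions
        for (j in seq_along(ext_idx)) {
          if (j > 1L && j < length(ext_idx) &&
              ext[j] < ext[j - 1L] && ext[j] < ext[j + 1L]) {
            rise <- ext[j - 1L] - ext[j]
            fall <- ext[j + 1L] - ext[j]
            if (min(rise, fall) >= th$wiggle_min_excursion) {
              n_wiggles <- n_wiggles + 1L
            }
          }
        }
      }
    }
  }

  # plateaus: slow-speed runs outside the bottom phase
  n_plateaus <- 0L
  speed <- abs(diff(depth)) / interval
  outside <- rep(TRUE, length(depth))
  outside[first_b:last_b] <- FALSE
  deep <- depth > th$plateau_min_depth
  step_ok <- speed <= th$plateau_max_speed &
    outside[-length(depth)] & outside[-1] & deep[-length(depth)] & deep[-1]
  if (any(step_ok)) {
    r <- rle(step_ok)
    run_secs <- r$lengths[r$values] * interval
    n_plateaus <- sum(run_secs >= th$plateau_min_duration)
  }
  list(max_depth = mx, bottom_time = bottom_time,
       n_wiggles = n_wiggles, n_plateaus = as.integer(n_plateaus))
}

#' Behaviour label of a dive from its shape metrics
#'
#' Forage if any foraging signature is present (bottom time of at least the
#' configured minimum, a wiggle, or a plateau); otherwise transit for shallow
#' dives and search for deeper ones.
#'
#' @param max_depth Maximum dive depth (m).
#' @param bottom_time Bottom time (s).
#' @param n_wiggles,n_plateaus Signature counts.
#' @param thresholds Threshold list.
#' @return One of `"forage"`, `"transit"`, `"search"`.
#' @export
classify_dive_label <- function(max_depth, bottom_time, n_wiggles, n_plateaus,
                                thresholds = dive_thresholds()) {
  has_sig <- bottom_time >= thresholds$bottom_min_time ||
    n_wiggles > 0 || n_plateaus > 0
  if (has_sig) "forage"
  else if (max_depth < thresholds$transit_max_depth) "transit"
  else "search"
}

#' Full dive analysis of a TDR table
#'
#' Groups the table by individual and day, corrects sensor drift, detects
#' dives, extracts shape metrics and classifies each dive.
#'
#' @param tdr Data frame with columns id, species, sex, day, date, tide, time,
#'   depth (uniform sampling within each id-day group).
#' @param thresholds Threshold list, see [dive_thresholds()].
#' @param drift_window Drift-correction window (s); `NULL` skips correction.
#' @return Data frame of dives: identifiers, timing, max_depth, duration,
#'   bottom_time, n_wiggles, n_plateaus, signature flags and behaviour label.
#' @export
analyze_dives <- function(tdr, thresholds = dive_thresholds(),
                          drift_window = 1800) {
  assert_cols(tdr, c("id", "species", "sex", "day", "date", "tide",
                     "time", "depth"), "tdr")
  groups <- split(tdr, list(tdr$id, tdr$day), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$time), ]
    interval <- stats::median(diff(g$time))
    depth <- g$depth
    if (!is.null(drift_window)) {
      depth <- correct_drift(depth, interval, drift_window)$depth
    }
    dv <- detect_dives(depth, g$time,
                       min_depth = thresholds$min_depth,
                       min_duration = thresholds$min_duration,
                       dive_threshold = thresholds$dive_threshold)
    if (nrow(dv) == 0L) return(NULL)
    shp <- lapply(seq_len(nrow(dv)), function(i) {
      dive_shape_metrics(depth[dv$start_idx[i]:dv$end_idx[i]], interval,
                         thresholds)
    })
    dv$max_depth <- vapply(shp, `[[`, numeric(1), "max_depth")
    dv$bottom_time <- vapply(shp, `[[`, numeric(1), "bottom_time")
    dv$n_wiggles <- vapply(shp, `[[`, integer(1), "n_wiggles")
    dv$n_plateaus <- vapply(shp, `[[`, integer(1), "n_plateaus")
    dv$has_bottom <- dv$bottom_time >= thresholds$bottom_min_time
    dv$has_wiggle <- dv$n_wiggles > 0L
    dv$has_plateau <- dv$n_plateaus > 0L
    dv$behavior <- mapply(classify_dive_label, dv$max_depth, dv$bottom_time,
                          dv$n_wiggles, dv$n_plateaus,
                          MoreArgs = list(thresholds = thresholds))
    dv$id <- g$id[1]; dv$species <- g$species[1]; dv$sex <- g$sex[1]
    dv$day <- g$day[1]; dv$date <- g$date[1]; dv$tide <- g$tide[1]
    dv
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Most frequent foraging depth via a 1D kernel density estimate
#'
#' Gaussian kernel with the normal-reference bandwidth, evaluated on a 0.5 m
#' grid; ties on a flat density plateau break to the shallowest depth.
#'
#' @param depths Maximum depths of forage dives (m).
#' @param grid_step Evaluation grid step (m).
#' @return The depth (m) at which the density is maximal.
#' @export
foraging_depth_mode <- function(depths, grid_step = 0.5) {
  if (length(depths) < 1L) {
    stop("undefined result: no forage dives", call. = FALSE)
  }
  if (stats::sd(depths) == 0 || length(depths) == 1L) return(depths[1])
  bw <- stats::bw.nrd(depths)
  grid <- seq(min(depths) - 3 * bw, max(depths) + 3 * bw, by = grid_step)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, depths, bw)),
                 numeric(1))
  grid[which.max(dens)]  # which.max returns the first (shallowest) maximum
}

#' Per-individual and per-species behaviour summary
#'
#' Proportions of forage dives with bottom time, wiggles and plateaus are
#' computed per individual over its forage dives, then averaged per species
#' (mean and SD). Dive frequency is forage dives per at-sea hour. Individuals
#' with no forage dives are excluded from proportion averaging (with a
#' message).
#'
#' @param dives Dive table from [analyze_dives()].
#' @param at_sea Data frame with columns id, at_sea_hours (total per
#'   individual across the study).
#' @return List: `individuals` (per-individual table) and `species`
#'   (mean/SD per species).
#' @export
summarize_behavior <- function(dives, at_sea) {
  assert_cols(dives, c("id", "species", "behavior", "has_bottom",
                       "has_wiggle", "has_plateau", "max_depth", "duration"),
              "dives")
  assert_cols(at_sea, c("id", "at_sea_hours"), "at_sea")
  ids <- unique(dives$id)
  rows <- lapply(ids, function(one) {
    dd <- dives[dives$id == one, ]
    ff <- dd[dd$behavior == "forage", ]
    hours <- sum(at_sea$at_sea_hours[at_sea$id == one])
    if (nrow(ff) == 0L) {
      message(sprintf("individual %s has no forage dives; excluded from proportions", one))
      return(data.frame(id = one, species = dd$species[1], n_forage = 0L,
                        p_bottom = NA_real_, p_wiggle = NA_real_,
                        p_plateau = NA_real_, depth_mode = NA_real_,
                        dive_freq = 0, mean_duration = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      id = one, species = dd$species[1], n_forage = nrow(ff),
      p_bottom = mean(ff$has_bottom), p_wiggle = mean(ff$has_wiggle),
      p_plateau = mean(ff$has_plateau),
      depth_mode = foraging_depth_mode(ff$max_depth),
      dive_freq = nrow(ff) / hours,
      mean_duration = mean(ff$duration),
      stringsAsFactors = FALSE
    )
  })
  ind <- do.call(rbind, rows)
  agg <- lapply(split(ind[ind$n_forage > 0L, ], ind$species[ind$n_forage > 0L]),
                function(s) {
    data.frame(
      species = s$species[1], n_individuals = nrow(s),
      p_bottom_mean = mean(s$p_bottom), p_bottom_sd = stats::sd(s$p_bottom),
      p_wiggle_mean = mean(s$p_wiggle), p_wiggle_sd = stats::sd(s$p_wiggle),
      p_plateau_mean = mean(s$p_plateau), p_plateau_sd = stats::sd(s$p_plateau),
      depth_mode_mean = mean(s$depth_mode),
      dive_freq_mean = mean(s$dive_freq), dive_freq_sd = stats::sd(s$dive_freq),
      duration_mean = mean(s$mean_duration), duration_sd = stats::sd(s$mean_duration),
      stringsAsFactors = FALSE
    )
  })
  species <- do.call(rbind, agg)
  rownames(species) <- NULL
  list(individuals = ind, species = species)
}
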