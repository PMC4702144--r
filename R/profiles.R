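#' Split a vehicle depth series into monotone legs
#'
#' Breaks at local extrema of the depth series; legs spanning less than
#' `min_span` metres vertically are merged into their neighbours. This is the
#' shared definition used both by the mission generator (for truth) and by
#' [segment_profiles()].
#'
#' @param vdepth Vehicle depth samples along track.
#' @param min_span Minimum vertical span (m) of a retained leg.
#' @return Data frame with `start`/`end` sample indices, one row per leg.
#' @export
profile_breaks <- function(vdepth, min_span = 10) {
  n <- length(vdepth)
  if (n < 2L) return(data.frame(start = 1L, end = n))
  d <- diff(vdepth)
  s <- sign(d)
  # carry the previous direction through flat steps
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1L) s[i - 1L] else 1
  turns <- which(diff(s) != 0) + 1L
  bounds <- c(1L, turns, n)
  legs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  if (nrow(legs) == 1L) {
    warning("non-undulating mission: single profile")
    return(legs)
  }
  span <- function(l) abs(vdepth[l$end] - vdepth[l$start])
  repeat {
    spans <- vapply(seq_len(nrow(legs)),
                    function(i) span(legs[i, ]), numeric(1))
    small <- which(spans < min_span)
    if (length(small) == 0L || nrow(legs) == 1L) break
    i <- small[1L]
    if (i == 1L) {
      legs$start[2L] <- legs$start[1L]
      legs <- legs[-1L, , drop = FALSE]
    } else {
      legs$end[i - 1L] <- legs$end[i]
      legs <- legs[-i, , drop = FALSE]
    }
    rownames(legs) <- NULL
  }
  legs
}

#' Segment an AUV mission into vertical profiles
#'
#' Each monotone descent or ascent leg of the see-saw is one vertical
#' profile. Every sample belongs to exactly one profile (leg boundaries are
#' assigned to the leg they start).
#'
#' @param sensor Mission sensor table (columns along_track, vehicle_depth,
#'   temperature, density, chl, par).
#' @param day Mission day used in profile ids.
#' @param min_span Minimum vertical leg span (m), see [profile_breaks()].
#' @return Data frame of profiles: profile_id, start/end sample indices,
#'   along-track span, vertical span.
#' @export
segment_profiles <- function(sensor, day = 1L, min_span = 10) {
  assert_cols(sensor, c("along_track", "vehicle_depth"), "sensor")
  brk <- profile_breaks(sensor$vehicle_depth, min_span)
  data.frame(
    profile_id = sprintf("d%02d_p%03d", day, seq_len(nrow(brk))),
    day = day,
    start_idx = brk$start, end_idx = brk$end,
    span_min = sensor$along_track[brk$start],
    span_max = sensor$along_track[brk$end],
    depth_min = pmin(sensor$vehicle_depth[brk$start],
                     sensor$vehicle_depth[brk$end]),
    depth_max = pmax(sensor$vehicle_depth[brk$start],
                     sensor$vehicle_depth[brk$end]),
    stringsAsFactors = FALSE
  )
}

#' Water-column features of one vertical profile
#'
#' Samples are binned to 1 m of depth. Features: the chlorophyll maximum and
#' its depth; chlorophyll integrated by trapezoid over 0-50 m (flagged
#' missing when vertical coverage there is under 40 m); the mixed layer
#' depth as the depth of maximum absolute density gradient (centred
#' differences on the binned profile) and the density there; surface PAR as
#' the mean over the upper 2 m; the 1 W/m2 isolume as the shallowest
#' crossing, interpolated linearly in log-PAR; the thermocline as the depth
#' of maximum absolute temperature gradient; and mean temperature above and
#' below the thermocline. Uncomputable features are returned as NA.
#'
#' @param sensor Mission sensor table.
#' @param start_idx,end_idx Sample range of the profile.
#' @param isolume_level Irradiance defining the isolume (W/m2).
#' @return One-row data frame of features.
#' @export
extract_profile_features <- function(sensor, start_idx, end_idx,
                                     isolume_level = 1) {
  s <- sensor[start_idx:end_idx, ]
  bin <- floor(s$vehicle_depth) + 0.5
  agg <- function(v) tapply(v, bin, mean)
  z <- sort(unique(bin))
  temp <- as.numeric(agg(s$temperature)[as.character(z)])
  dens <- as.numeric(agg(s$density)[as.character(z)])
  chl <- as.numeric(agg(s$chl)[as.character(z)])
  par <- as.numeric(agg(s$par)[as.character(z)])
  if (length(z) < 5L || diff(range(z)) < 20) {
    stop("degenerate profile: needs >= 5 bins spanning >= 20 m", call. = FALSE)
  }

  chl_max <- max(chl)
  depth_chl_max <- z[which.max(chl)]

  in50 <- z <= 50
  integrated_chl <- if (sum(in50) >= 2L &&
                        diff(range(z[in50])) >= 40) {
    zz <- z[in50]; cc <- chl[in50]
    sum(diff(zz) * (cc[-1] + cc[-length(cc)]) / 2)
  } else NA_real_

  grad <- function(v) {
    n <- length(v)
    g <- rep(NA_real_, n)
    g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (z[3:n] - z[1:(n - 2)])
    g
  }
  gd <- grad(dens)
  mld <- density_at_mld <- NA_real_
  if (stats::sd(dens) > 1e-9 && any(is.finite(gd))) {
    i <- which.max(abs(gd))
    mld <- z[i]; density_at_mld <- dens[i]
  }

  surface_par <- if (any(z <= 2)) mean(par[z <= 2]) else NA_real_

  isolume <- NA_real_
  lp <- log(par) - log(isolume_level)
  cross <- which(lp[-length(lp)] >= 0 & lp[-1] < 0)
  if (length(cross) > 0L) {
    i <- cross[1L]
    isolume <- z[i] + (z[i + 1L] - z[i]) * lp[i] / (lp[i] - lp[i + 1L])
  }

  gt <- grad(temp)
  thermocline <- mean_temp_above <- mean_temp_below <- NA_real_
  if (stats::sd(temp) > 1e-9 && any(is.finite(gt))) {
    i <- which.max(abs(gt))
    thermocline <- z[i]
    mean_temp_above <- mean(temp[z < thermocline])
    mean_temp_below <- mean(temp[z > thermocline])
  }

  data.frame(chl_max = chl_max, depth_chl_max = depth_chl_max,
             integrated_chl_0_50 = integrated_chl,
             mld = mld, density_at_mld = density_at_mld,
             surface_par = surface_par, isolume_1wm2 = isolume,
             thermocline_depth = thermocline,
             mean_temp_above = mean_temp_above,
             mean_temp_below = mean_temp_below)
}

#' Feature table for all profiles of a mission
#'
#' @param sensor Mission sensor table.
#' @param profiles Profile table from [segment_profiles()].
#' @return Profile table with feature columns appended.
#' @export
profile_features <- function(sensor, profiles) {
  feats <- lapply(seq_len(nrow(profiles)), function(i) {
    tryCatch(extract_profile_features(sensor, profiles$start_idx[i],
                                      profiles$end_idx[i]),
             error = function(e) {
               warning(sprintf("profile %s skipped: %s",
                               profiles$profile_id[i], conditionMessage(e)))
               NULL
             })
  })
  keep <- !vapply(feats, is.null, logical(1))
  cbind(profiles[keep, , drop = FALSE], do.call(rbind, feats[keep]))
}

#' Background Sv profiles with aggregations removed
#'
#' Masks all aggregation member cells, restricts to cells within a vertical
#' range of the vehicle, and averages the remaining Sv in 1 m depth bins per
#' profile. Averaging is linear-domain (dB to linear, mean, back to dB).
#' Depth bins with every cell masked are flagged missing.
#'
#' @param echogram An `echogram_grid`.
#' @param agg_mask Logical matrix of aggregation member cells (same shape as
#'   the Sv matrix); `NULL` for no aggregations.
#' @param sensor Mission sensor table (for the vehicle path).
#' @param profiles Profile table from [segment_profiles()].
#' @param range_m Vertical range around the vehicle (m).
#' @return Long data frame: profile_id, depth_bin, sv_db, n_cells.
#' @export
background_sv <- function(echogram, agg_mask, sensor, profiles, range_m = 3) {
  sv <- echogram$sv
  if (is.null(agg_mask)) agg_mask <- matrix(FALSE, nrow(sv), ncol(sv))
  near <- abs(outer(sensor$vehicle_depth, echogram$depth, `-`)) <= range_m
  usable <- near & !agg_mask
  bins <- floor(echogram$depth)  # 1 m bins keyed by lower edge
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    idx <- profiles$start_idx[i]:profiles$end_idx[i]
    for (bb in unique(bins)) {
      jj <- which(bins == bb)
      cells <- sv[idx, jj, drop = FALSE]
      ok <- usable[idx, jj, drop = FALSE]
      n <- sum(ok)
      out[[length(out) + 1L]] <- data.frame(
        profile_id = profiles$profile_id[i], depth_bin = bb + 0.5,
        sv_db = if (n > 0L) mean_sv_db(cells[ok]) else NA_real_,
        n_cells = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
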