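#' Analytic water-column fields for one mission day
#' @noRd
ocean_day <- function(cfg, day) {
  oc <- cfg$ocean
  list(
    mld = oc$mld + rnorm(1, 0, oc$mld_day_sd),
    thermocline = oc$thermocline + rnorm(1, 0, oc$thermocline_day_sd),
    chl_max_depth = oc$chl_max_depth + rnorm(1, 0, oc$chl_max_depth_day_sd),
    surface_par = oc$surface_par * rlnorm(1, 0, oc$surface_par_day_sdlog),
    attenuation = oc$attenuation * rlnorm(1, 0, oc$attenuation_day_sdlog)
  )
}

#' Evaluate the synthetic water column at depth
#'
#' Two-layer density and temperature with tanh transitions centred at the
#' mixed layer depth and thermocline, a Gaussian chlorophyll bump at the
#' chlorophyll-maximum depth, and exponentially decaying PAR.
#' @noRd
water_column_at <- function(z, oc_cfg, day_pars) {
  oc <- oc_cfg
  dp <- day_pars
  sig <- oc$sigma_surface + (oc$sigma_deep - oc$sigma_surface) *
    (1 + tanh((z - dp$mld) / oc$dens_trans_width)) / 2
  tmp <- oc$temp_surface + (oc$temp_deep - oc$temp_surface) *
    (1 + tanh((z - dp$thermocline) / oc$temp_trans_width)) / 2
  chl <- oc$chl_base + oc$chl_max * exp(-(z - dp$chl_max_depth)^2 /
                                          (2 * oc$chl_peak_sd^2))
  par <- dp$surface_par * exp(-dp$attenuation * z)
  list(density = sig, temperature = tmp, chl = chl, par = par)
}

#' Generate one AUV see-saw mission with ground truth
#'
#' The vehicle follows a triangular see-saw between near-surface and
#' near-bottom depths along a straight transect through one of the study
#' regions. Temperature and density follow a two-layer profile, chlorophyll
#' is a Gaussian bump, PAR decays exponentially (so the true 1 W/m2 isolume
#' is `log(P0)/k`), and the Sv field is Gaussian background noise plus
#' planted elliptical aggregations. Per-aggregation mean Sv values are drawn
#' from the dense or diffuse mode and the truth label is assigned by the
#' operational dense threshold, after which heights and length-to-height
#' ratios are drawn from the labelled type's distribution.
#'
#' @param cfg A [sim_config()].
#' @param day Study day (selects tide label, region and the day seed).
#' @return List: `echogram` (`echogram_grid`: distance/depth cell centres, Sv
#'   matrix), `sensor` (along-track sensor table), `truth` (aggregations,
#'   profile boundaries and presence flags, mission-level ocean features).
#' @export
generate_auv_mission <- function(cfg, day = 1L) {
  validate_sim_config(cfg)
  ms <- cfg$mission; ag <- cfg$aggregation; oc <- cfg$ocean
  set.seed(derive_seed(cfg$seed, paste0("auv", day)))

  region <- ms$region_cycle[(day - 1L) %% length(ms$region_cycle) + 1L]
  center <- switch(region,
    adelie = cfg$track$colony_centers$adelie + cfg$track$foraging_center_offset$adelie,
    gentoo = cfg$track$colony_centers$gentoo + cfg$track$foraging_center_offset$gentoo,
    overlap = c(mean(cfg$track$overlap_zone[c("xmin", "xmax")]),
                mean(cfg$track$overlap_zone[c("ymin", "ymax")])))
  origin <- c(center[1] - ms$length_m / 2, center[2])

  day_pars <- ocean_day(cfg, day)
  dist <- seq(ms$cell_dx / 2, ms$length_m - ms$cell_dx / 2, by = ms$cell_dx)
  depth <- seq(ms$cell_dz / 2, ms$max_depth - ms$cell_dz / 2, by = ms$cell_dz)

  # smooth along-track variability of the water column (internal-wave scale)
  wave_phase <- runif(1, 0, 2 * pi)
  u <- if (oc$horiz_amp > 0) sin(2 * pi * dist / oc$horiz_wavelength + wave_phase)
       else rep(0, length(dist))
  local_pars <- list(
    mld = day_pars$mld + oc$horiz_amp * u,
    thermocline = day_pars$thermocline + oc$horiz_amp * u,
    chl_max_depth = day_pars$chl_max_depth + oc$horiz_amp * u,
    surface_par = rep(day_pars$surface_par, length(dist)),
    attenuation = day_pars$attenuation * (1 - oc$horiz_atten_amp * u)
  )
  isolume_local <- log(local_pars$surface_par) / local_pars$attenuation

  # triangular see-saw vehicle path
  leg_len <- ms$length_m / (2 * ms$n_undulations)
  phase <- (dist %% (2 * leg_len)) / leg_len
  tri <- ifelse(phase <= 1, phase, 2 - phase)
  vdepth <- ms$profile_top + tri * (ms$profile_bottom - ms$profile_top)

  wc <- water_column_at(vdepth, oc, local_pars)
  sensor <- data.frame(
    along_track = dist,
    time = dist / 1.5,
    vehicle_depth = vdepth,
    temperature = wc$temperature + rnorm(length(dist), 0, oc$temp_noise_sd),
    density = wc$density + rnorm(length(dist), 0, oc$dens_noise_sd),
    chl = pmax(0, wc$chl + rnorm(length(dist), 0, oc$chl_noise_sd)),
    par = wc$par * rlnorm(length(dist), 0, oc$par_noise_sdlog)
  )

  sv <- matrix(rnorm(length(dist) * length(depth), ag$background_sv_mean,
                     ag$background_sv_sd),
               nrow = length(dist))

  # planted aggregations; abundance responds to the day's isolume depth
  isolume_true <- log(day_pars$surface_par) / day_pars$attenuation
  mult <- exp(ag$abundance_isolume_beta * (isolume_true - 40))
  n_int <- c(dense = if (ag$n_dense > 0) rpois(1, ag$n_dense * mult) else 0L,
             diffuse = if (ag$n_diffuse > 0) rpois(1, ag$n_diffuse * mult) else 0L)
  truth_rows <- list()
  placed <- matrix(numeric(0), ncol = 4)  # xmin, xmax, zmin, zmax
  aid <- 0L
  for (intended in c("dense", "diffuse")) {
    for (k in seq_len(n_int[[intended]])) {
      sv_mean <- rnorm(1, ag$sv_mean[[intended]], ag$sv_sd[[intended]])
      type <- if (sv_mean >= ag$dense_threshold_db) "dense" else "diffuse"
      H <- rlnorm_trunc(1, log(ag$height_median[[type]]),
                        ag$height_sdlog[[type]],
                        ag$height_range[1], ag$height_range[2])
      R <- rlnorm_trunc(1, log(ag$ratio_median[[type]]),
                        ag$ratio_sdlog[[type]],
                        ag$ratio_range[1], ag$ratio_range[2])
      L <- min(R * H, ag$length_max)
      b <- H / 2; a <- L / 2
      if (2 * b >= ms$max_depth - 4) b <- (ms$max_depth - 4) / 2
      lo <- max(ag$depth_range[1], b + 1)
      hi <- min(ag$depth_range[2], ms$max_depth - b - 1)
      if (lo >= hi) hi <- lo + 1
      # placement favours shallower local isolume (more aggregations where
      # light penetrates less deeply), matching the day-level abundance rule;
      # redrawn while the ellipse would overlap an already-planted one, so
      # each truth record describes its own patch of the field
      w <- exp(ag$abundance_isolume_beta * (isolume_local - isolume_true))
      for (try in 1:30) {
        cz <- rnorm_trunc(1, ag$depth_mean, ag$depth_sd, lo, hi)
        cx <- sample(dist, 1L, prob = w)
        cx <- min(max(cx, min(a, ms$length_m / 2)),
                  ms$length_m - min(a, ms$length_m / 2))
        box <- c(cx - a - ms$cell_dx, cx + a + ms$cell_dx,
                 cz - b - ms$cell_dz, cz + b + ms$cell_dz)
        clear <- nrow(placed) == 0L ||
          all(box[1] > placed[, 2] | box[2] < placed[, 1] |
                box[3] > placed[, 4] | box[4] < placed[, 3])
        if (clear) break
      }
      placed <- rbind(placed, box)
      inside <- outer((dist - cx) / a, rep(1, length(depth)))^2 +
        outer(rep(1, length(dist)), (depth - cz) / b)^2 <= 1
      n_cells <- sum(inside)
      if (n_cells > 0L) {
        sv[inside] <- sv_mean + rnorm(n_cells, 0, ag$sv_cell_sd)
      }
      aid <- aid + 1L
      cols <- which(apply(inside, 1, any))
      truth_rows[[aid]] <- data.frame(
        agg_id = sprintf("d%02d_a%03d", day, aid), day = day, region = region,
        type = type, intended_type = intended,
        center_along = cx, center_depth = cz,
        height = 2 * b, length = 2 * a, area = pi * a * b,
        mean_sv = sv_mean, n_cells = n_cells,
        span_min = if (length(cols)) dist[min(cols)] - ms$cell_dx / 2 else NA_real_,
        span_max = if (length(cols)) dist[max(cols)] + ms$cell_dx / 2 else NA_real_,
        truncated = length(cols) > 0 &&
          (min(cols) == 1L || max(cols) == length(dist)),
        x = origin[1] + cx, y = origin[2],
        stringsAsFactors = FALSE
      )
    }
  }
  agg_truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(agg_id = character(), day = integer(), region = character(),
               type = character(), intended_type = character(),
               center_along = numeric(), center_depth = numeric(),
               height = numeric(), length = numeric(), area = numeric(),
               mean_sv = numeric(), n_cells = integer(),
               span_min = numeric(), span_max = numeric(),
               truncated = logical(), x = numeric(), y = numeric(),
               stringsAsFactors = FALSE)

  # truth profile boundaries via the shared break-finding definition
  brk <- profile_breaks(vdepth)
  mid <- floor((brk$start + brk$end) / 2)
  prof_truth <- data.frame(
    profile_id = sprintf("d%02d_p%03d", day, seq_len(nrow(brk))),
    day = day, region = region,
    start_idx = brk$start, end_idx = brk$end,
    span_min = dist[brk$start], span_max = dist[brk$end],
    mld_true = local_pars$mld[mid],
    thermocline_true = local_pars$thermocline[mid],
    chl_max_depth_true = local_pars$chl_max_depth[mid],
    isolume_true = isolume_local[mid],
    stringsAsFactors = FALSE
  )
  prof_truth$dense_present <- vapply(seq_len(nrow(prof_truth)), function(i) {
    any(agg_truth$type == "dense" & !is.na(agg_truth$span_min) &
          agg_truth$span_min <= prof_truth$span_max[i] &
          agg_truth$span_max >= prof_truth$span_min[i])
  }, logical(1))
  prof_truth$diffuse_present <- vapply(seq_len(nrow(prof_truth)), function(i) {
    any(agg_truth$type == "diffuse" & !is.na(agg_truth$span_min) &
          agg_truth$span_min <= prof_truth$span_max[i] &
          agg_truth$span_max >= prof_truth$span_min[i])
  }, logical(1))

  echogram <- structure(
    list(distance = dist, depth = depth, sv = sv,
         cell_dx = ms$cell_dx, cell_dz = ms$cell_dz,
         day = day, date = cfg$start_date + day - 1L,
         tide = cfg$tide_labels[day], region = region, origin = origin),
    class = "echogram_grid")

  list(echogram = echogram, sensor = sensor,
       truth = list(
         aggregations = agg_truth,
         profiles = prof_truth,
         ocean = data.frame(
           day = day, mld = day_pars$mld,
           thermocline = day_pars$thermocline,
           chl_max_depth = day_pars$chl_max_depth,
           surface_par = day_pars$surface_par,
           attenuation = day_pars$attenuation,
           isolume = isolume_true)))
}

#' @export
print.echogram_grid <- function(x, ...) {
  cat(sprintf("<echogram_grid> day %d (%s, %s): %d x %d cells (%g m x %g m), Sv %.1f..%.1f dB\n",
              x$day, x$tide, x$region, length(x$distance), length(x$depth),
              x$cell_dx, x$cell_dz, min(x$sv), max(x$sv)))
  invisible(x)
}
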