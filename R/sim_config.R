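#' Simulation configuration for the synthetic foraging system
#'
#' Builds the configuration object that drives all three synthetic-data
#' generators ([generate_tracks()], [generate_tdr()], [generate_auv_mission()]).
#' Defaults emulate the study system: two penguin colonies ~20 km apart in a
#' local planar frame, an 11-day campaign (7 diurnal then 4 semidiurnal tidal
#' days), central-place foraging trips, species-specific dive shapes (gentoo
#' dives deeper and longer than Adelie), a stratified two-layer water column
#' with a chlorophyll maximum near 20 m and a 1 W/m2 isolume near 40 m, and
#' dense/diffuse prey aggregations whose morphometric and Sv distributions are
#' calibrated to the observed rank separations between the two types.
#'
#' All spatial quantities are metres in a planar (x, y) frame centred between
#' the colonies; depths are metres, positive down; Sv is dB.
#'
#' @param seed Integer root seed. Fixed seed implies byte-identical outputs.
#' @param n_individuals_per_species Individuals instrumented per species.
#' @param days Number of study days (one foraging trip and one AUV mission per
#'   day).
#' @param tide_labels Character vector, one of `"diurnal"`/`"semidiurnal"` per
#'   day. Default: a diurnal block followed by a semidiurnal block in a 7:4
#'   ratio.
#' @param trip_hours At-sea duration of each foraging trip (h).
#' @param overlap_frac Named fraction (per species) of individuals whose true
#'   foraging centre lies inside the designated overlap zone.
#' @param overlap_effect Additive depth shift (m) applied to gentoo forage
#'   dives performed inside the overlap zone.
#' @param depth_noise_sd TDR sensor noise SD (m).
#' @param drift_max Maximum absolute linear depth-sensor drift over a trace (m).
#' @param sample_interval TDR sampling interval (s).
#' @param ... Overrides for any element of the built list (e.g. `ocean`,
#'   `aggregation`, `dive`, `track` sub-lists are replaced wholesale).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_individuals_per_species = 8L,
                       days = 11L,
                       tide_labels = NULL,
                       trip_hours = 6,
                       overlap_frac = c(adelie = 0.25, gentoo = 0.5),
                       overlap_effect = 30,
                       depth_noise_sd = 0.1,
                       drift_max = 2,
                       sample_interval = 1,
                       ...) {
  if (is.null(tide_labels)) {
    n_di <- max(1L, round(days * 7 / 11))
    tide_labels <- c(rep("diurnal", n_di), rep("semidiurnal", days - n_di))
  }

  cfg <- list(
    seed = as.integer(seed),
    n_individuals_per_species = as.integer(n_individuals_per_species),
    days = as.integer(days),
    tide_labels = tide_labels,
    trip_hours = trip_hours,
    start_date = as.Date("2011-01-12"),
    overlap_frac = overlap_frac,
    overlap_effect = overlap_effect,
    depth_noise_sd = depth_noise_sd,
    drift_max = drift_max,
    sample_interval = sample_interval,

    # planar frame: colonies on the x axis, foraging grounds to the north
    track = list(
      colony_centers = list(adelie = c(-10000, 0), gentoo = c(10000, 0)),
      foraging_center_offset = list(adelie = c(3000, 6000),
                                    gentoo = c(-3000, 6000)),
      # overlap zone: rectangle between the two foraging grounds
      overlap_zone = c(xmin = -2000, xmax = 2000, ymin = 4000, ymax = 8000),
      center_scatter_sd = 1500,   # between-individual scatter of true centres
      forage_scatter_sd = 800,    # within-trip scatter of foraging positions
      position_noise_sd = 100,    # location (telemetry) noise
      fix_interval = 600,         # s between fixes
      travel_speed = 2            # m/s horizontal swimming speed
    ),

    # per-species dive shape parameters (means/SDs); depths m, durations s
    dive = list(
      adelie = list(depth_mean = 40, depth_sd = 12, depth_min = 15,
                    depth_max = 120, duration_mean = 75, duration_sd = 10,
                    p_bottom = 0.84, p_wiggle = 0.17, p_plateau = 0.16),
      gentoo = list(depth_mean = 54, depth_sd = 15, depth_min = 18,
                    depth_max = 150, duration_mean = 114, duration_sd = 15,
                    p_bottom = 0.74, p_wiggle = 0.28, p_plateau = 0.17),
      # between-individual heterogeneity (the random intercepts the mixed
      # models account for)
      individual_depth_sd = 5, individual_duration_sd = 8,
      # phase-dependent behaviour mix (transit legs vs foraging ground)
      class_prob_transit_phase = c(transit = 0.6, search = 0.4, forage = 0),
      class_prob_forage_phase = c(transit = 0.1, search = 0.2, forage = 0.7),
      surface_interval = c(20, 90),     # s, uniform
      descent_speed = 1.5,              # m/s for forage dives with bottom time
      steep_speed = 4,                  # m/s travel for bottom-less forage dives
      search_speed = 2,                 # m/s for search V-dives
      transit_speed = 1,                # m/s for transit V-dives
      transit_depth = c(5.5, 8),        # m, uniform
      search_depth = c(12, 26),         # m, uniform
      wiggle_excursion = 3,             # m planted excursion per wiggle
      plateau_duration = 8,             # s planted ascent shelf
      plateau_rel_depth = 0.5           # shelf depth as fraction of max depth
    ),

    # detector thresholds shared by the planter and the dive classifier
    thresholds = list(
      dive_threshold = 1, min_depth = 3, min_duration = 10,
      bottom_frac = 0.8, bottom_min_time = 5,
      wiggle_min_excursion = 2,
      plateau_min_duration = 5, plateau_max_speed = 0.25,
      plateau_min_depth = 3, transit_max_depth = 10
    ),

    ocean = list(
      mld = 20, mld_day_sd = 3,
      thermocline = 25, thermocline_day_sd = 3,
      chl_max_depth = 20, chl_max_depth_day_sd = 3,
      chl_max = 5, chl_peak_sd = 6, chl_base = 0.2,
      surface_par = 100, surface_par_day_sdlog = 0.3,
      attenuation = 0.115, attenuation_day_sdlog = 0.1,
      temp_surface = 2.0, temp_deep = 0.5, temp_trans_width = 4,
      sigma_surface = 26.8, sigma_deep = 27.4, dens_trans_width = 3,
      temp_noise_sd = 0.02, dens_noise_sd = 0.005,
      chl_noise_sd = 0.05, par_noise_sdlog = 0.02,
      # smooth along-track variability (internal-wave scale)
      horiz_amp = 3, horiz_wavelength = 1500, horiz_atten_amp = 0.15
    ),

    mission = list(
      length_m = 4000, cell_dx = 2, cell_dz = 1, max_depth = 90,
      profile_top = 1, profile_bottom = 88, n_undulations = 10,
      # missions cycle through the three study regions day by day
      region_cycle = c("adelie", "gentoo", "overlap")
    ),

    # dense/diffuse aggregation plant; per-aggregation mean Sv draws are
    # relabelled by the operational dense threshold before morphometrics
    aggregation = list(
      n_dense = 13, n_diffuse = 21,       # expected counts per mission
      abundance_isolume_beta = -0.06,     # log-rate slope on (isolume - 40) m
      depth_mean = 30.6, depth_sd = 16.5, depth_range = c(8, 60),
      sv_mean = c(dense = -61.9, diffuse = -66),
      sv_sd = c(dense = 2.8, diffuse = 1.9),
      sv_cell_sd = 1,
      height_median = c(dense = 3.2, diffuse = 2.29),
      height_sdlog = c(dense = 0.965, diffuse = 0.79),
      height_range = c(0.8, 40),
      ratio_median = c(dense = 5.5, diffuse = 6.67),
      ratio_sdlog = c(dense = 0.9, diffuse = 0.9),
      ratio_range = c(1.5, 80),
      length_max = 600,
      background_sv_mean = -75, background_sv_sd = 2,
      dense_threshold_db = -64
    )
  )

  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object.
#' @return The validated configuration, invisibly usable downstream.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_individuals_per_species <= 0L || cfg$days <= 0L) {
    stop("configuration error: counts must be positive", call. = FALSE)
  }
  if (length(cfg$tide_labels) != cfg$days ||
      !all(cfg$tide_labels %in% c("diurnal", "semidiurnal"))) {
    stop("configuration error: tide_labels must give diurnal|semidiurnal per day",
         call. = FALSE)
  }
  if (cfg$sample_interval <= 0) {
    stop("configuration error: sample_interval must be > 0", call. = FALSE)
  }
  sds <- c(cfg$depth_noise_sd, cfg$track$position_noise_sd,
           cfg$track$center_scatter_sd, cfg$track$forage_scatter_sd,
           cfg$aggregation$sv_cell_sd, cfg$aggregation$background_sv_sd)
  if (any(sds < 0)) stop("configuration error: all SDs must be >= 0", call. = FALSE)
  if (cfg$aggregation$sv_mean[["dense"]] <= cfg$aggregation$sv_mean[["diffuse"]]) {
    stop("configuration error: dense internal Sv mean must exceed diffuse",
         call. = FALSE)
  }
  for (sp in c("adelie", "gentoo")) {
    dp <- cfg$dive[[sp]]
    if (3 * cfg$sample_interval > dp$duration_mean - 3 * dp$duration_sd) {
      # dives must span at least 3 samples
      if (dp$duration_mean < 3 * cfg$sample_interval) {
        stop("configuration error: dive duration shorter than 3 samples",
             call. = FALSE)
      }
    }
  }
  if (cfg$mission$max_depth <= cfg$aggregation$depth_range[2]) {
    stop("configuration error: mission max depth shallower than deepest planted aggregation",
         call. = FALSE)
  }
  if (any(cfg$mission[c("cell_dx", "cell_dz")] <= 0)) {
    stop("configuration error: grid resolutions must be > 0", call. = FALSE)
  }
  cfg
}

#' Rectangular overlap zone of a configuration as a polygon
#'
#' @param cfg A `sim_config`.
#' @return A two-column matrix of polygon vertices (closed implicitly).
#' @export
overlap_zone_polygon <- function(cfg) {
  z <- cfg$track$overlap_zone
  cbind(x = c(z[["xmin"]], z[["xmax"]], z[["xmax"]], z[["xmin"]]),
        y = c(z[["ymin"]], z[["ymin"]], z[["ymax"]], z[["ymax"]]))
}

#' Test points against an axis-aligned rectangular zone
#' @noRd
in_rect_zone <- function(x, y, zone) {
  x >= zone[["xmin"]] & x <= zone[["xmax"]] &
    y >= zone[["ymin"]] & y <= zone[["ymax"]]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d individuals/species | %d days (%d diurnal)\n",
              x$seed, x$n_individuals_per_species, x$days,
              sum(x$tide_labels == "diurnal")))
  cat(sprintf("  trip %.1f h | overlap effect %.0f m | TDR %.0f s, noise %.2f m\n",
              x$trip_hours, x$overlap_effect, x$sample_interval,
              x$depth_noise_sd))
  invisible(x)
}
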