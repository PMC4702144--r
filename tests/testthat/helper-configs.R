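# Shared fixtures: configurations are built in code, never stored.

# Scaled-down spatial domain for fast end-to-end runs: colonies 10 km apart,
# foraging grounds 4-5 km from the colonies, a 3 km x 3 km overlap zone.
small_track_geometry <- function() {
  list(
    colony_centers = list(adelie = c(-5000, 0), gentoo = c(5000, 0)),
    foraging_center_offset = list(adelie = c(2000, 4000),
                                  gentoo = c(-2000, 4000)),
    overlap_zone = c(xmin = -1500, xmax = 1500, ymin = 2500, ymax = 5500),
    center_scatter_sd = 800, forage_scatter_sd = 800,
    position_noise_sd = 100, fix_interval = 600, travel_speed = 2
  )
}

small_cfg <- function(seed = 1, n = 4, days = 2, trip_hours = 2.5, ...) {
  sim_config(seed = seed, n_individuals_per_species = n, days = days,
             trip_hours = trip_hours, track = small_track_geometry(), ...)
}

# Noise-free variant: no sensor noise, no drift, clean acoustics
noise_free_cfg <- function(seed = 1, n = 2, days = 1, ...) {
  agg <- sim_config()$aggregation
  agg$n_dense <- 3; agg$n_diffuse <- 3
  agg$sv_mean <- c(dense = -60, diffuse = -66.5)
  agg$sv_sd <- c(dense = 0.4, diffuse = 0.4)
  agg$sv_cell_sd <- 0
  agg$background_sv_sd <- 0
  # plant only grid-resolvable patches (>= 2 rows x 3 columns of cells)
  agg$height_range <- c(2.5, 25)
  agg$ratio_range <- c(3, 30)
  ocean <- sim_config()$ocean
  ocean$temp_noise_sd <- 0; ocean$dens_noise_sd <- 0
  ocean$chl_noise_sd <- 0; ocean$par_noise_sdlog <- 0
  ocean$horiz_amp <- 0; ocean$horiz_atten_amp <- 0
  small_cfg(seed = seed, n = n, days = days,
            depth_noise_sd = 0, drift_max = 0,
            aggregation = agg, ocean = ocean, ...)
}

# Align detected dives with truth records by order within individual-day
# (start times may differ by one sample for slow entries/exits).
align_dives <- function(detected, truth) {
  key <- function(d) paste(d$id, d$day)
  stopifnot(setequal(unique(key(detected)), unique(key(truth))))
  detected <- detected[order(detected$id, detected$day, detected$start_time), ]
  truth <- truth[order(truth$id, truth$day, truth$start_time), ]
  stopifnot(nrow(detected) == nrow(truth),
            all(key(detected) == key(truth)))
  list(detected = detected, truth = truth)
}

# Independent brute-force oracles -------------------------------------------

# K-S statistic by direct double loop over pooled evaluation points
oracle_ks_D <- function(x, y, alternative = "two_sided") {
  pts <- c(x, y)
  best <- -Inf
  for (t in pts) {
    fx <- sum(x <= t) / length(x)
    fy <- sum(y <= t) / length(y)
    d <- switch(alternative,
                two_sided = abs(fx - fy),
                greater = fx - fy,
                less = fy - fx)
    if (d > best) best <- d
  }
  max(best, 0)
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments,
# computed from pairwise comparisons (not ranks) for independence.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  mu <- n * (N - n) / 2
  sets <- utils::combn(N, n)
  hits <- 0L
  for (j in seq_len(ncol(sets))) {
    xs <- pooled[sets[, j]]
    ys <- pooled[-sets[, j]]
    if (abs(u_of(xs, ys) - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / ncol(sets)
}
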