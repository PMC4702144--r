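#' Plan the instrumented individuals and their foraging centres
#'
#' Deterministic given the configuration seed; shared by the track and TDR
#' generators so both describe the same animals.
#'
#' @param cfg A [sim_config()].
#' @return Data frame: id, species, sex, centre coordinates, in_overlap flag.
#' @keywords internal
plan_individuals <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "individuals"))
  zone <- cfg$track$overlap_zone
  out <- list()
  for (sp in c("adelie", "gentoo")) {
    n <- cfg$n_individuals_per_species
    frac <- cfg$overlap_frac[[sp]] %||% 0
    k <- round(frac * n)
    in_overlap <- rep(FALSE, n)
    if (k > 0) in_overlap[sample.int(n, k)] <- TRUE
    base <- cfg$track$colony_centers[[sp]] + cfg$track$foraging_center_offset[[sp]]
    cx <- cy <- numeric(n)
    zone_margin <- min(1000, (zone[["xmax"]] - zone[["xmin"]]) / 3,
                       (zone[["ymax"]] - zone[["ymin"]]) / 3)
    hx <- hy <- numeric(n)
    for (i in seq_len(n)) {
      # home-ground centre (outside the overlap zone) for every individual
      repeat {
        hx[i] <- rnorm(1, base[1], cfg$track$center_scatter_sd)
        hy[i] <- rnorm(1, base[2], cfg$track$center_scatter_sd)
        if (!in_rect_zone(hx[i], hy[i], zone)) break
      }
      if (in_overlap[i]) {
        cx[i] <- runif(1, zone[["xmin"]] + zone_margin, zone[["xmax"]] - zone_margin)
        cy[i] <- runif(1, zone[["ymin"]] + zone_margin, zone[["ymax"]] - zone_margin)
      } else {
        cx[i] <- hx[i]; cy[i] <- hy[i]
      }
    }
    out[[sp]] <- data.frame(
      id = sprintf("%s%02d", substr(sp, 1, 2), seq_len(n)),
      species = sp,
      sex = rep_len(c("F", "M"), n),
      center_x = cx, center_y = cy,
      home_x = hx, home_y = hy,
      in_overlap = in_overlap,
      depth_offset = rnorm(n, 0, cfg$dive$individual_depth_sd %||% 0),
      duration_offset = rnorm(n, 0, cfg$dive$individual_duration_sd %||% 0),
      stringsAsFactors = FALSE
    )
  }
  rbind(out$adelie, out$gentoo)
}

#' Trip timing for one individual-day
#'
#' Commutes run at the configured swim speed; the trip must be long enough
#' to reach the foraging centre and spend time there.
#' @noRd
trip_phases <- function(cfg, ind) {
  colony <- cfg$track$colony_centers[[ind$species]]
  dist <- sqrt((ind$center_x - colony[1])^2 + (ind$center_y - colony[2])^2)
  trip_sec <- cfg$trip_hours * 3600
  travel <- dist / cfg$track$travel_speed
  if (2 * travel + 600 > trip_sec) {
    stop(sprintf(paste0("configuration error: trip of %.1f h too short to ",
                        "commute %.1f km at %.1f m/s"),
                 cfg$trip_hours, dist / 1000, cfg$track$travel_speed),
         call. = FALSE)
  }
  list(colony = colony, dist = dist, trip_sec = trip_sec,
       travel = travel, forage_start = travel,
       forage_end = trip_sec - travel)
}

#' Deterministic commute position of an individual at trip time t
#' @noRd
trip_position <- function(ph, ind, t) {
  cx <- c(ind$center_x, ind$center_y)
  frac <- ifelse(t < ph$travel, t / ph$travel,
          ifelse(t <= ph$forage_end, 1,
                 pmax(0, (ph$trip_sec - t) / ph$travel)))
  cbind(x = ph$colony[1] + frac * (cx[1] - ph$colony[1]),
        y = ph$colony[2] + frac * (cx[2] - ph$colony[2]))
}

#' The movement path of one individual-day
#'
#' One path per animal-day is shared by the track generator (which samples
#' it at fix times, plus telemetry noise) and the TDR generator (which
#' places dives on it), so locations are mutually consistent. The foraging
#' phase moves as an AR(1) walk about the individual's centre with
#' stationary SD equal to the configured foraging scatter. Seeded
#' independently of the callers.
#'
#' Individuals whose range enters the overlap zone split their trips between
#' the overlap ground and their home ground (per-day target, 60% overlap),
#' as overlapping animals do not abandon their own ground.
#'
#' @param cfg A [sim_config()].
#' @param ind One row of [plan_individuals()].
#' @param day Study day.
#' @return List: `t` (s within trip), `x`, `y`, and the trip phase object.
#' @keywords internal
build_day_path <- function(cfg, ind, day) {
  set.seed(derive_seed(cfg$seed, sprintf("path_%s_%03d", ind$id, day)))
  if (isTRUE(ind$in_overlap) && runif(1) > 0.6) {
    ind$center_x <- ind$home_x
    ind$center_y <- ind$home_y
  }
  ph <- trip_phases(cfg, ind)
  tt <- seq(0, ph$trip_sec, by = cfg$track$fix_interval)
  pos <- trip_position(ph, ind, tt)
  foraging <- tt >= ph$forage_start & tt <= ph$forage_end
  nf <- sum(foraging)
  if (nf > 0 && cfg$track$forage_scatter_sd > 0) {
    rho <- 0.8
    s <- cfg$track$forage_scatter_sd
    for (ax in 1:2) {
      w <- numeric(nf)
      w[1] <- rnorm(1, 0, s)
      if (nf > 1) for (j in 2:nf) {
        w[j] <- rho * w[j - 1] + rnorm(1, 0, s * sqrt(1 - rho^2))
      }
      pos[foraging, ax] <- pos[foraging, ax] + w
    }
  }
  list(t = tt, x = pos[, 1], y = pos[, 2], ph = ph)
}

#' Generate central-place foraging tracks with ground truth
#'
#' Each individual performs one trip per day from its colony to its true
#' foraging centre (species-specific grounds; a configurable fraction of
#' centres fall inside the overlap zone), moving about the centre during the
#' foraging phase; every fix carries additive telemetry noise and a location
#' quality class.
#'
#' @param cfg A [sim_config()].
#' @return List with `tracks` (data frame: id, species, sex, day, date, tide,
#'   time, x, y, quality) and `truth` (list: `individuals` table and the
#'   overlap-zone polygon).
#' @export
generate_tracks <- function(cfg) {
  validate_sim_config(cfg)
  inds <- plan_individuals(cfg)
  qual_levels <- c("3", "2", "1", "0", "A", "B")
  rows <- vector("list", nrow(inds) * cfg$days)
  k <- 0L
  for (i in seq_len(nrow(inds))) {
    ind <- inds[i, ]
    for (d in seq_len(cfg$days)) {
      path <- build_day_path(cfg, ind, d)
      set.seed(derive_seed(cfg$seed, sprintf("fix_%s_%03d", ind$id, d)))
      n <- length(path$t)
      noise <- if (cfg$track$position_noise_sd > 0) {
        matrix(rnorm(2 * n, 0, cfg$track$position_noise_sd), ncol = 2)
      } else matrix(0, n, 2)
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = ind$id, species = ind$species, sex = ind$sex,
        day = d, date = cfg$start_date + d - 1L,
        tide = cfg$tide_labels[d],
        time = (d - 1L) * 86400 + path$t,
        x = path$x + noise[, 1],
        y = path$y + noise[, 2],
        quality = sample(qual_levels, n, replace = TRUE,
                         prob = c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)),
        stringsAsFactors = FALSE
      )
    }
  }
  tracks <- do.call(rbind, rows)
  list(tracks = tracks,
       truth = list(individuals = inds,
                    overlap_polygon = overlap_zone_polygon(cfg)))
}
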