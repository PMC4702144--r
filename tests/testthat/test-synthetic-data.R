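test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 42, n = 2, days = 1)
  expect_identical(generate_tracks(cfg), generate_tracks(cfg))
  expect_identical(generate_tdr(cfg), generate_tdr(cfg))
  expect_identical(generate_auv_mission(cfg, 1), generate_auv_mission(cfg, 1))
})

test_that("every generated entity has exactly one truth record", {
  cfg <- noise_free_cfg(seed = 3)
  td <- generate_tdr(cfg)
  dv <- analyze_dives(td$tdr, drift_window = NULL)
  expect_equal(nrow(dv), nrow(td$dives))
  m <- generate_auv_mission(cfg, 1)
  expect_equal(nrow(m$truth$profiles),
               nrow(segment_profiles(m$sensor, day = 1)))
})

test_that("overlap fraction zero puts no foraging centre in the zone", {
  cfg <- small_cfg(seed = 5, overlap_frac = c(adelie = 0, gentoo = 0))
  tr <- generate_tracks(cfg)
  ind <- tr$truth$individuals
  zone <- cfg$track$overlap_zone
  expect_false(any(ind$center_x >= zone[["xmin"]] & ind$center_x <= zone[["xmax"]] &
                   ind$center_y >= zone[["ymin"]] & ind$center_y <= zone[["ymax"]]))
})

test_that("zero scatter and zero noise pin foraging fixes to the true centre", {
  geom <- small_track_geometry()
  geom$forage_scatter_sd <- 0
  geom$position_noise_sd <- 0
  cfg <- sim_config(seed = 2, n_individuals_per_species = 2, days = 1,
                    trip_hours = 2.5, track = geom)
  tr <- generate_tracks(cfg)
  ind <- tr$truth$individuals[1, ]
  g <- tr$tracks[tr$tracks$id == ind$id, ]
  ph_travel <- sqrt((ind$center_x - geom$colony_centers$adelie[1])^2 +
                    (ind$center_y - geom$colony_centers$adelie[2])^2) / 2
  mid <- g[g$time > ph_travel + 600 & g$time < max(g$time) - ph_travel - 600, ]
  expect_true(all(abs(mid$x - ind$center_x) < 1e-9))
  expect_true(all(abs(mid$y - ind$center_y) < 1e-9))
})

test_that("the planted overlap effect shifts in-zone gentoo dives by its value", {
  cfg <- small_cfg(seed = 8, n = 6, days = 3, overlap_effect = 30)
  td <- generate_tdr(cfg)
  g <- td$dives[td$dives$species == "gentoo" & td$dives$behavior == "forage", ]
  expect_gt(sum(g$in_overlap), 30)
  diff_obs <- mean(g$max_depth[g$in_overlap]) - mean(g$max_depth[!g$in_overlap])
  se <- sqrt(var(g$max_depth[g$in_overlap]) / sum(g$in_overlap) +
             var(g$max_depth[!g$in_overlap]) / sum(!g$in_overlap))
  expect_lt(abs(diff_obs - 30), 4 * se)
})

test_that("PAR decay gives the closed-form isolume and planted ellipse geometry is exact", {
  cfg <- noise_free_cfg(seed = 4)
  cfg$ocean$surface_par_day_sdlog <- 0
  cfg$ocean$attenuation_day_sdlog <- 0
  m <- generate_auv_mission(cfg, 1)
  expect_equal(m$truth$ocean$isolume,
               log(cfg$ocean$surface_par) / cfg$ocean$attenuation,
               tolerance = 1e-8)
  a <- m$truth$aggregations
  expect_true(all(abs(a$length / a$height - a$length / a$height) < 1e-12))
  expect_equal(a$area, pi * (a$length / 2) * (a$height / 2), tolerance = 1e-9)
})

test_that("zero planted aggregations leave a pure background field", {
  agg <- sim_config()$aggregation
  agg$n_dense <- 0; agg$n_diffuse <- 0
  cfg <- small_cfg(seed = 6, aggregation = agg)
  m <- generate_auv_mission(cfg, 1)
  expect_equal(nrow(m$truth$aggregations), 0L)
  expect_lt(abs(mean(m$echogram$sv) - agg$background_sv_mean), 0.1)
  expect_lt(abs(sd(as.vector(m$echogram$sv)) - agg$background_sv_sd), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(small_cfg(n = 0), "counts")
  expect_error(small_cfg(days = 3, tide_labels = c("diurnal", "neap", "x")),
               "tide_labels")
  expect_error(small_cfg(sample_interval = 0), "sample_interval")
  agg <- sim_config()$aggregation
  agg$depth_range <- c(8, 95)
  expect_error(small_cfg(aggregation = agg), "mission max depth")
  agg2 <- sim_config()$aggregation
  agg2$sv_mean <- c(dense = -70, diffuse = -66)
  expect_error(small_cfg(aggregation = agg2), "dense internal Sv")
})

test_that("dense plants are taller and stronger scatterers than diffuse on average", {
  cfg <- small_cfg(seed = 9)
  tr <- do.call(rbind, lapply(1:4, function(d) {
    generate_auv_mission(cfg, d)$truth$aggregations
  }))
  d <- tr[tr$type == "dense", ]; f <- tr[tr$type == "diffuse", ]
  expect_gt(mean(d$height), mean(f$height))
  expect_gt(mean(d$mean_sv), mean(f$mean_sv))
})
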