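# analytic sensor table: triangular see-saw over a known water column
make_sensor <- function(n_und = 20, length_m = 4000, top = 1, bottom = 80,
                        P0 = 100, k = 0.1, mld = 20, tc = 25) {
  x <- seq(1, length_m - 1, by = 2)
  leg <- length_m / (2 * n_und)
  ph <- (x %% (2 * leg)) / leg
  tri <- ifelse(ph <= 1, ph, 2 - ph)
  z <- top + tri * (bottom - top)
  data.frame(
    along_track = x, time = x / 1.5, vehicle_depth = z,
    temperature = 2 - 1.5 * (1 + tanh((z - tc) / 2)) / 2,
    density = 26.8 + 0.6 * (1 + tanh((z - mld) / 2)) / 2,
    chl = 0.2 + 5 * exp(-(z - 20)^2 / (2 * 36)),
    par = P0 * exp(-k * z)
  )
}

test_that("see-saw missions split into two profiles per undulation", {
  s <- make_sensor(n_und = 20)
  pr <- segment_profiles(s)
  expect_equal(nrow(pr), 40L)
  # every sample belongs to exactly one profile (boundaries start the next leg)
  covered <- unlist(mapply(seq, pr$start_idx, pr$end_idx))
  expect_equal(sort(unique(covered)), seq_len(nrow(s)))
  counts <- table(unlist(mapply(seq, pr$start_idx + 1, pr$end_idx)))
  expect_true(all(counts == 1))
})

test_that("monotone descents give a single profile with a warning", {
  s <- make_sensor(n_und = 20)[1:50, ]
  s$vehicle_depth <- seq(2, 80, length.out = 50)
  expect_warning(pr <- segment_profiles(s), "non-undulating")
  expect_equal(nrow(pr), 1L)
})

test_that("planted leg boundaries are recovered within one sample", {
  cfg <- noise_free_cfg(seed = 13)
  m <- generate_auv_mission(cfg, 1)
  pr <- segment_profiles(m$sensor, day = 1)
  expect_equal(nrow(pr), nrow(m$truth$profiles))
  expect_true(all(abs(pr$start_idx - m$truth$profiles$start_idx) <= 1))
  expect_true(all(abs(pr$end_idx - m$truth$profiles$end_idx) <= 1))
})

test_that("profile features match their closed forms", {
  # few undulations so each leg samples every 1 m depth bin
  s <- make_sensor(n_und = 4, P0 = 100, k = 0.1, mld = 20, tc = 25)
  pr <- segment_profiles(s)
  f <- extract_profile_features(s, pr$start_idx[1], pr$end_idx[1])
  expect_lt(abs(f$isolume_1wm2 - log(100) / 0.1), 0.5)
  expect_lt(abs(f$mld - 20), 1)
  expect_lt(abs(f$thermocline_depth - 25), 1)
  expect_lt(abs(f$depth_chl_max - 20), 1)
  expect_lt(abs(f$chl_max - 5.2), 0.1)
  # layer means are pulled slightly toward the transition by the tanh tails
  expect_equal(f$mean_temp_above, 2, tolerance = 0.03)
  expect_equal(f$mean_temp_below, 0.5, tolerance = 0.05)
  expect_lt(abs(f$surface_par - 100 * exp(-0.1 * 1.5)), 5)
  # trapezoid integral of CHL over 0-50 m
  zz <- 2:50
  expected <- sum(diff(zz) * (head(0.2 + 5 * exp(-(zz - 20)^2 / 72), -1) +
                              tail(0.2 + 5 * exp(-(zz - 20)^2 / 72), -1)) / 2)
  expect_lt(abs(f$integrated_chl_0_50 - expected) / expected, 0.05)
})

test_that("features flag missing when uncomputable", {
  s <- make_sensor(P0 = 100, k = 0.01)  # PAR never drops below 1 W/m2
  pr <- segment_profiles(s)
  f <- extract_profile_features(s, pr$start_idx[1], pr$end_idx[1])
  expect_true(is.na(f$isolume_1wm2))

  s2 <- make_sensor()
  s2$density <- 26.8  # constant density: MLD undefined
  pr2 <- segment_profiles(s2)
  f2 <- extract_profile_features(s2, pr2$start_idx[1], pr2$end_idx[1])
  expect_true(is.na(f2$mld))

  expect_error(extract_profile_features(s, 1, 3), "degenerate profile")
})

test_that("background Sv averages in the linear domain near the vehicle", {
  cfg <- noise_free_cfg(seed = 14)
  agg0 <- cfg$aggregation
  agg0$n_dense <- 0; agg0$n_diffuse <- 0
  cfg$aggregation <- agg0
  m <- generate_auv_mission(cfg, 1)
  pr <- segment_profiles(m$sensor, day = 1)
  bg <- background_sv(m$echogram, NULL, m$sensor, pr[1:4, ])
  got <- bg$sv_db[!is.na(bg$sv_db)]
  expect_true(all(abs(got - agg0$background_sv_mean) < 0.1))
  # never exceeds the maximum input Sv
  expect_true(all(got <= max(m$echogram$sv) + 1e-9))
})

test_that("masked aggregation cells do not contaminate background Sv", {
  cfg <- noise_free_cfg(seed = 15)
  m <- generate_auv_mission(cfg, 1)
  det <- detect_aggregations(m$echogram)
  pr <- segment_profiles(m$sensor, day = 1)
  bg <- background_sv(m$echogram, attr(det, "mask"), m$sensor, pr)
  got <- bg$sv_db[!is.na(bg$sv_db)]
  # aggregation interiors are >= -61 dB; clean background is -75
  expect_true(all(got < -70))
})

test_that("background Sv recovers a planted vertical gradient", {
  cfg <- noise_free_cfg(seed = 16)
  agg0 <- cfg$aggregation
  agg0$n_dense <- 0; agg0$n_diffuse <- 0
  agg0$background_sv_sd <- 1
  cfg$aggregation <- agg0
  m <- generate_auv_mission(cfg, 1)
  # impose a linear depth gradient on the background
  m$echogram$sv <- m$echogram$sv +
    matrix(0.1 * m$echogram$depth, nrow = length(m$echogram$distance),
           ncol = length(m$echogram$depth), byrow = TRUE)
  pr <- segment_profiles(m$sensor, day = 1)
  bg <- background_sv(m$echogram, NULL, m$sensor, pr)
  ok <- !is.na(bg$sv_db)
  expected <- -75 + 0.1 * bg$depth_bin[ok]
  se <- 1 / sqrt(pmax(bg$n_cells[ok], 1))
  expect_true(mean(abs(bg$sv_db[ok] - expected) <= 4 * se + 0.1) > 0.95)
})
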