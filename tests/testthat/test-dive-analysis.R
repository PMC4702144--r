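# a V-dive to depth D at `v` m/s on a 1 s grid, bracketed by surface samples
v_dive <- function(D, v = 2, pad = 30) {
  t1 <- round(D / v)
  c(rep(0, pad), approx(c(0, t1, 2 * t1), c(0, D, 0),
                        xout = 0:(2 * t1))$y, rep(0, pad))
}

test_that("correct_drift removes constant offsets and recovers linear drift", {
  depth <- v_dive(40) + 1.5
  cd <- correct_drift(depth, window = 30)
  surf <- cd$depth[c(1:20, (length(depth) - 19):length(depth))]
  expect_true(all(abs(surf) < 0.05))

  # drift-free trace is (nearly) unchanged
  depth0 <- rep(v_dive(30, pad = 200), 10)
  cd0 <- correct_drift(depth0, window = 300)
  expect_lt(max(abs(cd0$depth - depth0)), 0.05)

  # synthetic linear drift 0 -> 2 m over 6 h, recovered within 0.2 m
  n <- 6 * 3600
  base <- rep_len(v_dive(30, pad = 100), n)
  drift <- seq(0, 2, length.out = n)
  cd2 <- correct_drift(base + drift, window = 1800)
  expect_lt(max(abs(cd2$offset - drift)), 0.2)
})

test_that("correct_drift warns when the window exceeds the trace", {
  expect_warning(correct_drift(v_dive(20), window = 1e6), "global offset")
})

test_that("detect_dives applies the depth and duration bounds", {
  expect_equal(nrow(detect_dives(rep(0, 100), 0:99)), 0L)

  tr <- v_dive(40, v = 1.35)  # ~60 s planted dive
  d <- detect_dives(tr, seq_along(tr) - 1)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$duration - 60), 3)
  expect_equal(d$max_depth, 40)

  # two dives separated by 5 s of surface are not merged
  one <- approx(c(0, 10, 20), c(0, 20, 0), xout = 0:20)$y
  tr2 <- c(rep(0, 10), one, rep(0, 5), one, rep(0, 10))
  expect_equal(nrow(detect_dives(tr2, seq_along(tr2) - 1)), 2L)

  # shallow and short intervals are discarded
  expect_equal(nrow(detect_dives(v_dive(2.5), seq_along(v_dive(2.5)) - 1)), 0L)
  expect_error(detect_dives(tr, rev(seq_along(tr))), "input error")
})

test_that("shape metrics recover planted signatures exactly", {
  # pure V-dive: single-sample bottom, no wiggles, no plateaus
  sm <- dive_shape_metrics(v_dive(40, v = 4, pad = 2))
  expect_lt(sm$bottom_time, 5)
  expect_equal(sm$n_wiggles, 0L)
  expect_equal(sm$n_plateaus, 0L)

  # 3 planted wiggles of 4 m amplitude within the bottom phase
  D <- 40
  kt <- c(0, 20, 24)
  kd <- c(0, D, D)
  for (w in 1:3) { kt <- c(kt, max(kt) + 2, max(kt) + 4); kd <- c(kd, D - 4, D) }
  kt <- c(kt, max(kt) + 4, max(kt) + 24)
  kd <- c(kd, D, 0)
  seg <- approx(kt, kd, xout = 0:max(kt))$y
  sm2 <- dive_shape_metrics(seg)
  expect_equal(sm2$n_wiggles, 3L)
  expect_true(sm2$bottom_time >= 5)

  # 10 s ascent shelf at 50% of max depth
  kt3 <- c(0, 20, 30, 36, 46, 56)
  kd3 <- c(0, D, D, D / 2, D / 2, 0)
  seg3 <- approx(kt3, kd3, xout = 0:56)$y
  sm3 <- dive_shape_metrics(seg3)
  expect_equal(sm3$n_plateaus, 1L)

  expect_error(dive_shape_metrics(c(0, 5)), "degenerate")
})

test_that("behaviour labels follow the signature/depth rules", {
  expect_equal(classify_dive_label(40, 20, 0, 0), "forage")
  expect_equal(classify_dive_label(5, 0, 0, 0), "transit")
  expect_equal(classify_dive_label(30, 0, 0, 0), "search")
  expect_equal(classify_dive_label(30, 0, 1, 0), "forage")
  expect_equal(classify_dive_label(30, 0, 0, 1), "forage")
  expect_equal(classify_dive_label(9.9, 4, 0, 0), "transit")
})

test_that("foraging depth mode matches direct density evaluation", {
  expect_equal(foraging_depth_mode(rep(50, 20)), 50)

  set.seed(11)
  d <- rnorm(500, 50, 5)
  expect_true(foraging_depth_mode(d) >= 47 && foraging_depth_mode(d) <= 53)

  set.seed(12)
  bi <- c(rnorm(100, 20, 2), rnorm(200, 80, 2))
  mode_bi <- foraging_depth_mode(bi)
  # brute-force density check at the returned mode vs the minor mode
  bw <- bw.nrd(bi)
  dens <- function(g) mean(dnorm(g, bi, bw))
  expect_gt(dens(mode_bi), dens(20))
  expect_lt(abs(mode_bi - 80), 3)

  expect_error(foraging_depth_mode(numeric(0)), "undefined")
})

test_that("behaviour summaries follow the individual-then-species convention", {
  dives <- data.frame(
    id = c(rep("a", 4), rep("b", 5)),
    species = "adelie", behavior = "forage",
    has_bottom = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    has_wiggle = FALSE, has_plateau = FALSE,
    max_depth = 40, duration = 80,
    stringsAsFactors = FALSE)
  at_sea <- data.frame(id = c("a", "b"), at_sea_hours = c(2, 2))
  s <- summarize_behavior(dives, at_sea)
  expect_equal(s$individuals$p_bottom[s$individuals$id == "a"], 0.75)
  # species mean of proportions 0.75 and 1.0
  expect_equal(s$species$p_bottom_mean, mean(c(0.75, 1)))
  expect_equal(s$species$p_bottom_sd, sd(c(0.75, 1)))
  # 36 forage dives in 2 h -> 18 dives/hr
  dives36 <- data.frame(id = "c", species = "gentoo", behavior = "forage",
                        has_bottom = TRUE, has_wiggle = FALSE,
                        has_plateau = FALSE, max_depth = 50, duration = 100,
                        stringsAsFactors = FALSE)[rep(1, 36), ]
  s2 <- summarize_behavior(dives36, data.frame(id = "c", at_sea_hours = 2))
  expect_equal(s2$individuals$dive_freq, 18)
})

test_that("species means match the two-individual arithmetic example", {
  vals <- c(0.6, 1.0)
  expect_equal(mean(vals), 0.8)
  expect_equal(sd(vals), 0.2828427, tolerance = 1e-6)
})

test_that("behaviour labels are invariant to constant sensor offsets after correction", {
  cfg <- noise_free_cfg(seed = 21)
  td <- generate_tdr(cfg)
  one <- td$tdr[td$tdr$id == td$tdr$id[1], ]
  base <- analyze_dives(one, drift_window = 1800)
  for (off in c(-2, 0.7, 2)) {
    shifted <- one
    shifted$depth <- shifted$depth + off
    got <- analyze_dives(shifted, drift_window = 1800)
    expect_equal(got$behavior, base$behavior)
  }
})
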