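blank_echogram <- function(nx = 200, nz = 60, sv = -75, dx = 2, dz = 1) {
  structure(list(
    distance = seq(dx / 2, nx * dx - dx / 2, by = dx),
    depth = seq(dz / 2, nz * dz - dz / 2, by = dz),
    sv = matrix(sv, nx, nz), cell_dx = dx, cell_dz = dz,
    day = 1L, date = as.Date("2011-01-12"), tide = "diurnal",
    region = "adelie", origin = c(0, 0)), class = "echogram_grid")
}

test_that("component labelling respects 8-connectivity and matrix edges", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # diagonal: one component
  m[5, 5] <- TRUE                    # far corner: separate
  lab <- label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1] && lab[5, 5] > 0)
  # wrap check: last row and first row of next column must not connect
  m2 <- matrix(FALSE, 4, 3)
  m2[4, 1] <- TRUE; m2[1, 2] <- TRUE
  lab2 <- label_components(m2)
  expect_true(lab2[4, 1] != lab2[1, 2])
})

test_that("pure background yields no aggregations", {
  eg <- blank_echogram()
  set.seed(41)
  eg$sv <- eg$sv + rnorm(length(eg$sv), 0, 2)
  expect_equal(nrow(detect_aggregations(eg)), 0L)
})

test_that("separated planted blocks give separate aggregations", {
  eg <- blank_echogram()
  eg$sv[20:25, 10:13] <- -60
  eg$sv[60:70, 30:33] <- -67
  det <- detect_aggregations(eg)
  expect_equal(nrow(det), 2L)
  expect_setequal(det$type, c("dense", "diffuse"))
})

test_that("morphometrics follow the cell-edge arithmetic", {
  eg <- blank_echogram(dx = 2, dz = 1)
  eg$sv[11:15, 21:23] <- -60  # 5 columns x 3 rows of 2 m x 1 m cells
  det <- detect_aggregations(eg)
  expect_equal(nrow(det), 1L)
  expect_equal(det$height, 3)
  expect_equal(det$length, 10)
  expect_equal(det$area, 30)
  expect_equal(det$lh_ratio, 10 / 3, tolerance = 1e-9)
  expect_equal(det$mean_sv, -60)  # all cells equal: linear mean is exact
  expect_equal(det$mean_depth, mean(eg$depth[21:23]))
})

test_that("single-row and single-column clusters keep one-cell extents", {
  eg <- blank_echogram()
  eg$sv[30:37, 15] <- -60
  det <- detect_aggregations(eg)
  expect_equal(det$height, eg$cell_dz)
  expect_equal(det$length, 8 * eg$cell_dx)
})

test_that("type classification applies the dense threshold to the linear mean", {
  expect_equal(classify_aggregation_type(rep(-60, 10)), "dense")
  expect_equal(classify_aggregation_type(rep(-68, 10)), "diffuse")
  expect_error(classify_aggregation_type(numeric(0)), "empty")
})

test_that("raising the detection threshold never adds detected cells", {
  cfg <- small_cfg(seed = 43)
  eg <- generate_auv_mission(cfg, 1)$echogram
  cells <- vapply(c(3, 6, 9, 12), function(th) {
    sum(attr(detect_aggregations(eg, detect_threshold_db = th), "mask"))
  }, numeric(1))
  expect_true(all(diff(cells) <= 0))
})

test_that("edge-touching components are kept and flagged truncated", {
  eg <- blank_echogram()
  eg$sv[1:5, 10:12] <- -60
  det <- detect_aggregations(eg)
  expect_equal(nrow(det), 1L)
  expect_true(det$truncated)
})

test_that("presence flags follow span intersection", {
  profiles <- data.frame(profile_id = c("p1", "p2"),
                         span_min = c(0, 200), span_max = c(200, 400))
  aggs <- data.frame(type = c("dense", "diffuse"),
                     span_min = c(50, 500), span_max = c(80, 550))
  out <- attach_presence(profiles, aggs)
  expect_equal(out$dense_present, c(TRUE, FALSE))
  expect_equal(out$diffuse_present, c(FALSE, FALSE))
  none <- attach_presence(profiles, aggs[0, ])
  expect_false(any(none$dense_present, none$diffuse_present))
})

test_that("detected dense aggregations are taller, larger and stronger than diffuse, at equal depths", {
  cfg <- small_cfg(seed = 44)
  det <- do.call(rbind, lapply(1:6, function(d) {
    detect_aggregations(generate_auv_mission(cfg, d)$echogram)
  }))
  d <- det[det$type == "dense", ]; f <- det[det$type == "diffuse", ]
  expect_gt(nrow(d), 20); expect_gt(nrow(f), 20)
  expect_gt(mean(d$height), mean(f$height))
  expect_gt(mean(d$area), mean(f$area))
  expect_gt(mean(d$mean_sv), mean(f$mean_sv))
  expect_gt(mann_whitney(d$mean_depth, f$mean_depth)$p_value, 0.05)
})

test_that("type assignment against planted labels is at least 90% accurate", {
  cfg <- small_cfg(seed = 45)
  acc <- numeric(0)
  for (d in 1:4) {
    m <- generate_auv_mission(cfg, d)
    det <- detect_aggregations(m$echogram)
    mt <- match_aggregations(det, m$truth$aggregations, m$echogram)
    if (nrow(mt$pairs) > 0) {
      acc <- c(acc, det$type[mt$pairs[, 1]] ==
                 m$truth$aggregations$type[mt$pairs[, 2]])
    }
  }
  expect_gte(mean(acc), 0.9)
})
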