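test_that("speed filter keeps clean tracks and removes teleporting points", {
  tr <- data.frame(time = seq(0, 6000, by = 600),
                   x = seq(0, 6000, by = 600), y = 0)
  expect_equal(nrow(speed_filter(tr)), nrow(tr))  # speeds 1 m/s

  tr2 <- tr
  tr2$x[5] <- tr2$x[5] + 3e4  # implied ~50 m/s
  out <- speed_filter(tr2)
  expect_equal(attr(out, "removed"), 1L)
  expect_false((3e4 + tr$x[5]) %in% out$x)

  expect_equal(nrow(speed_filter(tr[1, ])), 1L)
})

test_that("speed filter removes planted outliers but spares good fixes", {
  set.seed(31)
  n <- 400
  tr <- data.frame(time = seq(0, by = 300, length.out = n),
                   x = cumsum(rnorm(n, 0, 80)),
                   y = cumsum(rnorm(n, 0, 80)))
  bad <- sort(sample(2:(n - 1), 20))
  tr$x[bad] <- tr$x[bad] + sample(c(-1, 1), 20, TRUE) * runif(20, 2e4, 4e4)
  out <- speed_filter(tr, v_max = 3)
  kept_times <- out$time
  n_bad_removed <- sum(!(tr$time[bad] %in% kept_times))
  n_good_removed <- (nrow(tr) - nrow(out)) - n_bad_removed
  expect_gte(n_bad_removed / 20, 0.9)
  expect_lte(n_good_removed / (n - 20), 0.01)
})

test_that("kde surfaces integrate to unit mass with the maximum at the centroid", {
  set.seed(32)
  x <- rnorm(500); y <- rnorm(500)
  s <- kde_surface(x, y, cell = 0.1)
  expect_lt(abs(sum(s$z) * prod(s$cell) - 1), 1e-6)
  peak <- which(s$z == max(s$z), arr.ind = TRUE)
  expect_lt(abs(s$x[peak[1]] - mean(x)), 3 * 0.1 + 0.2)
  expect_lt(abs(s$y[peak[2]] - mean(y)), 3 * 0.1 + 0.2)
  expect_error(kde_surface(1:5, 1:5), "10 points")
})

test_that("KDE mass inside the true 50% ellipse is 0.50 for a known normal", {
  set.seed(33)
  n <- 10000
  x <- rnorm(n, 0, 2); y <- rnorm(n, 0, 1)
  s <- kde_surface(x, y, cell = 0.1)
  gx <- matrix(s$x, nrow = length(s$x), ncol = length(s$y))
  gy <- matrix(s$y, nrow = length(s$x), ncol = length(s$y), byrow = TRUE)
  inside <- (gx / 2)^2 + gy^2 <= qchisq(0.5, 2)
  mass <- sum(s$z[inside]) * prod(s$cell)
  expect_lt(abs(mass - 0.50), 0.02)
})

test_that("HDR contours hit the Gaussian closed form and nest", {
  gx <- seq(-4.5, 4.5, by = 0.05)
  z <- outer(dnorm(gx), dnorm(gx))
  surf <- structure(list(x = gx, y = gx, z = z / (sum(z) * 0.05^2),
                         cell = c(0.05, 0.05)), class = "range_estimate")
  h50 <- hdr_contour(surf, 0.5)
  expect_lt(abs(h50$area_km2 * 1e6 - pi * qchisq(0.5, 2)) /
              (pi * qchisq(0.5, 2)), 0.05)
  h95 <- hdr_contour(surf, 0.95)
  expect_lt(h50$area_km2, h95$area_km2)
  expect_true(all(h95$mask[h50$mask]))  # 50% region nested in 95%

  h_all <- hdr_contour(surf, 1 - 1e-9)
  outside_mass <- sum(surf$z[!h_all$mask]) * prod(surf$cell)
  expect_lt(outside_mass, 2e-9)
  expect_error(hdr_contour(surf, 1.2), "input error")
})

test_that("range overlap is symmetric, identity-consistent and zero when disjoint", {
  set.seed(34)
  a <- kde_surface(rnorm(200, 0, 300), rnorm(200, 0, 300), cell = 100,
                   lims = c(-60000, 62000, -2000, 2000))
  b <- kde_surface(rnorm(200, 60000, 300), rnorm(200, 0, 300), cell = 100,
                   lims = c(-60000, 62000, -2000, 2000))
  same <- range_overlap(a, a)
  expect_lt(abs(same$area_km2 - hdr_contour(a, 0.95)$area_km2) /
              same$area_km2, 0.01)
  far <- range_overlap(a, b)
  expect_equal(far$area_km2, 0)
  expect_equal(range_overlap(a, b)$area_km2, range_overlap(b, a)$area_km2)
})

test_that("direct polygon overlap handles the offset unit squares", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sq2 <- sq; sq2[, 1] <- sq2[, 1] + 0.5
  expect_lt(abs(polygon_overlap_area(sq, sq2, cell = 0.004) - 0.5), 0.01)
  expect_equal(polygon_overlap_area(sq, sq2 + 100, cell = 0.25), 0)
})

test_that("region labels partition points against the two contours", {
  set.seed(35)
  lims <- c(-3000, 9000, -3000, 3000)
  a <- kde_surface(rnorm(300, 0, 800), rnorm(300, 0, 800), cell = 100,
                   lims = lims)
  b <- kde_surface(rnorm(300, 3000, 800), rnorm(300, 0, 800), cell = 100,
                   lims = lims)
  ov <- range_overlap(a, b)
  px <- c(0, 3000, 1500, 50000, NA)
  py <- c(0, 0, 0, 0, 0)
  lab <- assign_region(px, py, ov, a)
  expect_equal(lab[1], "A_only")
  expect_equal(lab[2], "B_only")
  expect_equal(lab[3], "overlap")
  expect_equal(lab[4], "outside")
  expect_equal(lab[5], "outside")
  expect_true(all(lab %in% c("A_only", "B_only", "overlap", "outside")))
})

test_that("dive positions link to the nearest fix within tolerance", {
  dives <- data.frame(id = "a", start_time = c(100, 5000, 99999))
  tracks <- data.frame(id = "a", time = c(0, 600, 4800),
                       x = c(1, 2, 3), y = c(10, 20, 30))
  expect_warning(out <- link_dive_positions(dives, tracks), "tolerance")
  expect_equal(out$x, c(1, 3, NA))
})

test_that("GeoJSON export writes valid polygon features", {
  gx <- seq(-3, 3, by = 0.1)
  z <- outer(dnorm(gx), dnorm(gx))
  surf <- structure(list(x = gx, y = gx, z = z / (sum(z) * 0.01),
                         cell = c(0.1, 0.1)), class = "range_estimate")
  h <- hdr_contour(surf, 0.5)
  path <- tempfile(fileext = ".geojson")
  write_range_geojson(h$polygons, path, properties = list(species = "test"))
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 0)
  expect_equal(gj$features[[1]]$geometry$type, "Polygon")
})
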