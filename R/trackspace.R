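#' Iterative speed filter for location tracks
#'
#' Removes, one at a time, the point responsible for the largest implied
#' travel speed above `v_max` until no speed exceeds the limit. The first and
#' last points of a track are never removed. Tracks with fewer than two
#' points are returned unchanged.
#'
#' @param track Data frame for a single individual with columns time, x, y
#'   (time sorted).
#' @param v_max Maximum plausible speed (m/s).
#' @return The filtered track (same columns), plus a `removed` attribute with
#'   the number of dropped rows.
#' @export
speed_filter <- function(track, v_max = 3) {
  if (nrow(track) < 2L) {
    attr(track, "removed") <- 0L
    return(track)
  }
  if (is.unsorted(track$time)) {
    stop("input error: track must be time-sorted", call. = FALSE)
  }
  keep <- seq_len(nrow(track))
  seg_speed <- function(i, j) {
    dt <- track$time[j] - track$time[i]
    if (dt <= 0) return(Inf)
    sqrt((track$x[j] - track$x[i])^2 + (track$y[j] - track$y[i])^2) / dt
  }
  repeat {
    v <- vapply(seq_len(length(keep) - 1L),
                function(k) seg_speed(keep[k], keep[k + 1L]), numeric(1))
    worst <- which.max(v)
    if (v[worst] <= v_max) break
    a <- worst; b <- worst + 1L  # positions in `keep` bracketing the segment
    removable <- c(a, b)
    removable <- removable[removable != 1L & removable != length(keep)]
    if (length(removable) == 0L) break
    # drop whichever endpoint leaves the lower bridged speed
    score <- vapply(removable, function(p) {
      lo <- keep[p - 1L]; hi <- keep[p + 1L]
      seg_speed(lo, hi)
    }, numeric(1))
    keep <- keep[-removable[which.min(score)]]
    if (length(keep) < 2L) break
  }
  out <- track[keep, , drop = FALSE]
  attr(out, "removed") <- nrow(track) - length(keep)
  out
}

#' Bivariate kernel density surface of foraging locations
#'
#' Product (axis-aligned) Gaussian kernel with per-axis normal-reference
#' bandwidths, normalized to unit mass over the grid. A degenerate
#' (zero-variance) axis gets its bandwidth floored at one grid cell, with a
#' warning.
#'
#' @param x,y Point coordinates (m, local planar frame); at least 10 points.
#' @param cell Grid cell size (m).
#' @param lims Optional `c(xmin, xmax, ymin, ymax)`; defaults to the data
#'   bounding box padded by three bandwidths. Pass a shared `lims` to compare
#'   surfaces across groups.
#' @return A `range_estimate`: list with grid vectors `x`, `y`, density
#'   matrix `z` (rows follow `x`), `cell`, bandwidths `h`.
#' @export
kde_surface <- function(x, y, cell = 250, lims = NULL) {
  if (length(x) < 10L) stop("input error: need >= 10 points", call. = FALSE)
  bw1 <- function(v) {
    h <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
    if (!is.finite(h) || h <= 0) {
      warning("degenerate axis: bandwidth floored at one grid cell")
      h <- 4 * cell  # kde2d divides h by 4 to get the kernel SD
    }
    h
  }
  h <- c(bw1(x), bw1(y))
  if (is.null(lims)) {
    pad <- 3 * h / 4
    lims <- c(min(x) - pad[1], max(x) + pad[1],
              min(y) - pad[2], max(y) + pad[2])
  }
  n <- c(max(16L, ceiling((lims[2] - lims[1]) / cell)) + 1L,
         max(16L, ceiling((lims[4] - lims[3]) / cell)) + 1L)
  k <- MASS::kde2d(x, y, h = h, n = n, lims = lims)
  cellx <- diff(k$x[1:2]); celly <- diff(k$y[1:2])
  mass <- sum(k$z) * cellx * celly
  k$z <- k$z / mass
  structure(list(x = k$x, y = k$y, z = k$z,
                 cell = c(cellx, celly), h = h, n_points = length(x)),
            class = "range_estimate")
}

#' Highest-density-region contour of a density surface
#'
#' Finds the density level above which the accumulated grid-cell mass equals
#' the target fraction (descending sort), and returns the region mask, its
#' area and the iso-level contour polygons.
#'
#' @param surface A `range_estimate` from [kde_surface()] (unit mass).
#' @param mass Target probability mass, in (0, 1).
#' @return List: `level`, `mask` (logical matrix), `area_km2`, `polygons`
#'   (from [grDevices::contourLines()]).
#' @export
hdr_contour <- function(surface, mass = 0.5) {
  if (!is.numeric(mass) || mass <= 0 || mass >= 1) {
    stop("input error: mass fraction must be in (0, 1)", call. = FALSE)
  }
  cell_area <- prod(surface$cell)
  dens <- sort(as.vector(surface$z), decreasing = TRUE)
  cum <- cumsum(dens) * cell_area
  idx <- which(cum >= mass)[1]
  level <- if (is.na(idx)) min(dens[dens > 0]) else dens[idx]
  mask <- surface$z >= level
  polys <- grDevices::contourLines(surface$x, surface$y, surface$z,
                                   levels = level)
  list(level = level, mask = mask,
       area_km2 = sum(mask) * cell_area / 1e6,
       polygons = polys, mass = mass)
}

#' Overlap between two foraging ranges
#'
#' Intersects the highest-density regions of two density surfaces computed on
#' the same grid (the overall foraging range is taken at 95% mass by
#' default) and reports the overlap area.
#'
#' @param range_a,range_b `range_estimate` objects on an identical grid.
#' @param mass Contour mass defining the overall range.
#' @return List: `area_km2`, `mask`, `polygons` (outline of the overlap
#'   region), plus each range's own HDR.
#' @export
range_overlap <- function(range_a, range_b, mass = 0.95) {
  if (!isTRUE(all.equal(range_a$x, range_b$x)) ||
      !isTRUE(all.equal(range_a$y, range_b$y))) {
    stop("input error: ranges must share a common grid", call. = FALSE)
  }
  ha <- hdr_contour(range_a, mass)
  hb <- hdr_contour(range_b, mass)
  mask <- ha$mask & hb$mask
  cell_area <- prod(range_a$cell)
  ind <- matrix(as.numeric(mask), nrow = nrow(mask))
  polys <- if (any(mask)) {
    grDevices::contourLines(range_a$x, range_a$y, ind, levels = 0.5)
  } else list()
  list(area_km2 = sum(mask) * cell_area / 1e6, mask = mask,
       polygons = polys, hdr_a = ha, hdr_b = hb, mass = mass)
}

#' Ray-casting point-in-polygon test
#'
#' @param px,py Point coordinates.
#' @param poly Two-column matrix of polygon vertices (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Intersection area of two polygons by rasterisation
#'
#' Used when regions are supplied directly as polygons rather than as density
#' surfaces; the polygons are rasterised over their joint bounding box.
#'
#' @param poly_a,poly_b Two-column vertex matrices.
#' @param cell Raster cell size, in the polygons' units.
#' @return Intersection area (same squared units).
#' @export
polygon_overlap_area <- function(poly_a, poly_b, cell = NULL) {
  xs <- range(c(poly_a[, 1], poly_b[, 1]))
  ys <- range(c(poly_a[, 2], poly_b[, 2]))
  if (is.null(cell)) cell <- max(diff(xs), diff(ys)) / 400
  gx <- seq(xs[1] + cell / 2, xs[2], by = cell)
  gy <- seq(ys[1] + cell / 2, ys[2], by = cell)
  pts <- expand.grid(x = gx, y = gy)
  ina <- point_in_polygon(pts$x, pts$y, poly_a)
  inb <- point_in_polygon(pts$x, pts$y, poly_b)
  sum(ina & inb) * cell^2
}

#' Link dive times to track positions
#'
#' Nearest-in-time fix per individual, within a tolerance (default 1 h);
#' dives with no fix inside the tolerance get NA coordinates (and are later
#' labelled outside, with a warning).
#'
#' @param dives Dive table with columns id, start_time.
#' @param tracks Track table with columns id, time, x, y.
#' @param max_gap Tolerance (s).
#' @return The dive table with x, y columns added.
#' @export
link_dive_positions <- function(dives, tracks, max_gap = 3600) {
  dives$x <- NA_real_; dives$y <- NA_real_
  for (one in unique(dives$id)) {
    tr <- tracks[tracks$id == one, ]
    di <- which(dives$id == one)
    if (nrow(tr) == 0L) next
    for (k in di) {
      gap <- abs(tr$time - dives$start_time[k])
      j <- which.min(gap)
      if (gap[j] <= max_gap) {
        dives$x[k] <- tr$x[j]; dives$y[k] <- tr$y[j]
      }
    }
  }
  if (anyNA(dives$x)) {
    warning(sprintf("%d dives had no track fix within tolerance; labelled outside",
                    sum(is.na(dives$x))))
  }
  dives
}

#' Region label for points against two range HDR masks
#'
#' Point-in-region lookup on the shared density grid: `overlap` when inside
#' both ranges' contours, `A_only`/`B_only` when inside one, else `outside`.
#'
#' @param x,y Point coordinates (NA gives `outside`).
#' @param overlap A [range_overlap()] result (carries both HDR masks and the
#'   grid via its masks' parent surfaces).
#' @param surface Any of the two `range_estimate`s (for the grid axes).
#' @return Character vector of labels.
#' @export
assign_region <- function(x, y, overlap, surface) {
  gx <- surface$x; gy <- surface$y
  half <- surface$cell / 2
  ix <- findInterval(x, c(gx - half[1], gx[length(gx)] + half[1]))
  iy <- findInterval(y, c(gy - half[2], gy[length(gy)] + half[2]))
  ok <- !is.na(x) & !is.na(y) &
    ix >= 1L & ix <= length(gx) & iy >= 1L & iy <= length(gy)
  lab <- rep("outside", length(x))
  ina <- inb <- rep(FALSE, length(x))
  ina[ok] <- overlap$hdr_a$mask[cbind(ix[ok], iy[ok])]
  inb[ok] <- overlap$hdr_b$mask[cbind(ix[ok], iy[ok])]
  lab[ina & !inb] <- "A_only"
  lab[!ina & inb] <- "B_only"
  lab[ina & inb] <- "overlap"
  lab
}

#' Write range contours as GeoJSON
#'
#' Coordinates are planar metres in the local study frame (documented in the
#' feature properties; no geodetic CRS applies).
#'
#' @param contours `polygons` element from [hdr_contour()] or
#'   [range_overlap()].
#' @param path Output file.
#' @param properties Named list attached to every feature.
#' @return The path, invisibly.
#' @export
write_range_geojson <- function(contours, path, properties = list()) {
  feats <- lapply(contours, function(p) {
    ring <- cbind(p$x, p$y)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = c(list(crs = "local planar metres", level = p$level),
                        properties),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
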