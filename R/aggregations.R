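#' 8-connected component labelling of a logical matrix
#'
#' Breadth-first search over flagged cells; written for sparse echogram
#' exceedance masks.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  flagged <- which(mask)
  if (length(flagged) == 0L) return(lab)
  comp <- 0L
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (start in flagged) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      nb <- cur + offs
      # drop neighbours that wrap across matrix columns
      keep <- nb >= 1L & nb <= nr * nc
      nbr <- ((nb - 1L) %% nr) + 1L
      keep <- keep & abs(nbr - r) <= 1L
      nb <- nb[keep]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb) > 0L) {
        lab[nb] <- comp
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Detect prey aggregations in an Sv echogram
#'
#' Cells exceeding the background estimate by the detection threshold are
#' flagged; 8-connected components with at least `min_cells` cells become
#' aggregations. Components touching the along-track grid edge are kept and
#' flagged truncated. Each aggregation is classified dense or diffuse by its
#' linear-domain mean Sv against the dense threshold, and Table-style
#' morphometrics are computed from cell edges.
#'
#' @param echogram An `echogram_grid`.
#' @param detect_threshold_db Detection threshold above background (dB).
#' @param dense_threshold_db Mean-Sv threshold separating dense from diffuse
#'   (dB).
#' @param min_cells Minimum component size (cells).
#' @param background Background Sv estimate (dB); defaults to the grid
#'   median (a robust global percentile).
#' @return Data frame, one row per aggregation: agg_id, day, date, tide,
#'   region, type, mean_depth, height, length, area, lh_ratio, mean_sv,
#'   n_cells, along-track span, truncated flag, planar x/y. The cell index
#'   sets are attached as the `clusters` attribute and the exceedance mask as
#'   `mask`.
#' @export
detect_aggregations <- function(echogram, detect_threshold_db = 6,
                                dense_threshold_db = -64, min_cells = 4,
                                background = NULL) {
  sv <- echogram$sv
  if (length(sv) == 0L) {
    return(empty_aggregation_table())
  }
  if (is.null(background)) background <- stats::median(sv)
  mask <- sv > background + detect_threshold_db
  lab <- label_components(mask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sizes <- tabulate(lab[lab > 0L])
  ids <- ids[sizes[ids] >= min_cells]
  if (length(ids) == 0L) {
    out <- empty_aggregation_table()
    attr(out, "mask") <- mask
    attr(out, "clusters") <- list()
    return(out)
  }
  clusters <- lapply(ids, function(k) which(lab == k, arr.ind = TRUE))
  rows <- lapply(seq_along(ids), function(k) {
    m <- cluster_morphometrics(clusters[[k]], echogram)
    m$agg_id <- sprintf("d%02d_det%03d", echogram$day, k)
    m
  })
  out <- do.call(rbind, rows)
  out$type <- ifelse(out$mean_sv >= dense_threshold_db, "dense", "diffuse")
  out$day <- echogram$day
  out$date <- echogram$date
  out$tide <- echogram$tide
  out$region <- echogram$region
  out$x <- echogram$origin[1] + out$center_along
  out$y <- echogram$origin[2]
  out <- out[, c("agg_id", "day", "date", "tide", "region", "type",
                 "center_along", "mean_depth", "height", "length", "area",
                 "lh_ratio", "mean_sv", "n_cells", "span_min", "span_max",
                 "truncated", "x", "y")]
  attr(out, "clusters") <- clusters
  attr(out, "mask") <- mask
  attr(out, "background") <- background
  out
}

empty_aggregation_table <- function() {
  data.frame(agg_id = character(), day = integer(), date = as.Date(character()),
             tide = character(), region = character(), type = character(),
             center_along = numeric(), mean_depth = numeric(),
             height = numeric(), length = numeric(), area = numeric(),
             lh_ratio = numeric(), mean_sv = numeric(), n_cells = integer(),
             span_min = numeric(), span_max = numeric(),
             truncated = logical(), x = numeric(), y = numeric(),
             stringsAsFactors = FALSE)
}

#' Morphometrics of one detected cell cluster
#'
#' Height is the distance between the deepest and shallowest cell edge,
#' length between the first and last along-track cell edge (so single-row or
#' single-column clusters get one cell extent, never zero); area is cell
#' count times cell area; mean Sv is the linear-domain mean.
#'
#' @param cells Two-column index matrix (row = along-track, col = depth).
#' @param echogram The parent `echogram_grid`.
#' @return One-row data frame.
#' @export
cluster_morphometrics <- function(cells, echogram) {
  dx <- echogram$cell_dx; dz <- echogram$cell_dz
  di <- cells[, 1]; zi <- cells[, 2]
  sv <- echogram$sv[cells]
  height <- (max(zi) - min(zi) + 1L) * dz
  length_m <- (max(di) - min(di) + 1L) * dx
  data.frame(
    center_along = mean(range(echogram$distance[di])),
    mean_depth = mean(echogram$depth[zi]),
    height = height, length = length_m,
    area = nrow(cells) * dx * dz,
    lh_ratio = length_m / height,
    mean_sv = mean_sv_db(sv),
    n_cells = nrow(cells),
    span_min = echogram$distance[min(di)] - dx / 2,
    span_max = echogram$distance[max(di)] + dx / 2,
    truncated = min(di) == 1L | max(di) == length(echogram$distance),
    stringsAsFactors = FALSE
  )
}

#' Classify an aggregation dense or diffuse by mean Sv
#'
#' @param sv_cells Member-cell Sv values (dB).
#' @param dense_threshold_db Dense threshold (dB).
#' @return `"dense"` or `"diffuse"`.
#' @export
classify_aggregation_type <- function(sv_cells, dense_threshold_db = -64) {
  if (length(sv_cells) == 0L) stop("input error: empty cluster", call. = FALSE)
  if (mean_sv_db(sv_cells) >= dense_threshold_db) "dense" else "diffuse"
}

#' Attach aggregation presence flags to vertical profiles
#'
#' A profile is flagged present for a type when at least one aggregation of
#' that type has an along-track span intersecting the profile's span
#' (optionally widened by a window).
#'
#' @param profiles Profile table with span_min/span_max.
#' @param aggregations Aggregation table with type and span columns.
#' @param window Horizontal widening of the profile span (m).
#' @return Profiles with `dense_present`/`diffuse_present` logical columns.
#' @export
attach_presence <- function(profiles, aggregations, window = 0) {
  hit <- function(type, i) {
    a <- aggregations[aggregations$type == type, , drop = FALSE]
    if (nrow(a) == 0L) return(FALSE)
    any(a$span_min <= profiles$span_max[i] + window &
          a$span_max >= profiles$span_min[i] - window)
  }
  profiles$dense_present <- vapply(seq_len(nrow(profiles)), function(i)
    hit("dense", i), logical(1))
  profiles$diffuse_present <- vapply(seq_len(nrow(profiles)), function(i)
    hit("diffuse", i), logical(1))
  profiles
}

#' Match detected aggregations to planted truth
#'
#' Greedy one-to-one matching: a detected aggregation matches a truth record
#' when its centre lies within the truth ellipse inflated by one grid cell,
#' nearest centre first. Used to score detection recall and precision.
#'
#' @param detected Aggregation table from [detect_aggregations()].
#' @param truth Truth aggregation table from [generate_auv_mission()].
#' @param echogram The `echogram_grid` (for cell sizes).
#' @return List: `pairs` (detected index, truth index), `recall`,
#'   `precision` (relative to truth records resolvable on the grid, i.e.
#'   with at least the detector's minimum cell count).
#' @export
match_aggregations <- function(detected, truth, echogram, min_cells = 4) {
  resolvable <- which(truth$n_cells >= min_cells)
  if (nrow(detected) == 0L) {
    return(list(pairs = cbind(integer(), integer()),
                recall = if (length(resolvable)) 0 else NA_real_,
                precision = NA_real_))
  }
  dx <- echogram$cell_dx; dz <- echogram$cell_dz
  used_t <- logical(nrow(truth))
  used_d <- logical(nrow(detected))
  cand <- list()
  for (d in seq_len(nrow(detected))) {
    for (t in seq_len(nrow(truth))) {
      ea <- truth$length[t] / 2 + dx
      eb <- truth$height[t] / 2 + dz
      u <- (detected$center_along[d] - truth$center_along[t]) / ea
      v <- (detected$mean_depth[d] - truth$center_depth[t]) / eb
      if (u^2 + v^2 <= 1) {
        cand[[length(cand) + 1L]] <- c(d, t, u^2 + v^2)
      }
    }
  }
  pairs <- matrix(integer(), 0, 2)
  if (length(cand) > 0L) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, 3]), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      d <- cand[i, 1]; t <- cand[i, 2]
      if (!used_d[d] && !used_t[t]) {
        used_d[d] <- TRUE; used_t[t] <- TRUE
        pairs <- rbind(pairs, c(d, t))
      }
    }
  }
  recall <- if (length(resolvable)) mean(used_t[resolvable]) else NA_real_
  precision <- mean(used_d)
  list(pairs = pairs, recall = recall, precision = precision)
}
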