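#' Default candidate presence/absence model formulas
#'
#' Hypothesis-driven combinations of water-column predictors with a random
#' intercept for sampling day; `presence` is replaced by the response being
#' modelled.
#'
#' @return Character vector of formulas.
#' @export
default_presence_candidates <- function() {
  c("presence ~ isolume_1wm2 + (1|day)",
    "presence ~ depth_chl_max + integrated_chl_0_50 + (1|day)",
    "presence ~ isolume_1wm2 + depth_chl_max + integrated_chl_0_50 + (1|day)",
    "presence ~ mld + density_at_mld + thermocline_depth + (1|day)",
    "presence ~ surface_par + isolume_1wm2 + (1|day)",
    "presence ~ 1 + (1|day)")
}

#' Run the full foraging-competition analysis on synthetic or supplied data
#'
#' Stages, in dependency order: simulate (or ingest) tracks, TDR traces and
#' AUV missions; speed-filter tracks; drift-correct, detect and classify
#' dives; estimate species-by-tide foraging ranges (bivariate KDE, HDR
#' contours) and their overlap; label every dive with its region; segment
#' AUV profiles, extract water-column features, detect and classify
#' aggregations, attach presence flags; run the statistical battery
#' (Table-style dense/diffuse comparison, gated depth-distribution
#' comparisons, behaviour GLMMs, depth LMMs, presence/absence model sets
#' with cross-validation).
#'
#' @param cfg A [sim_config()] (the run configuration: seed, study design
#'   and all module thresholds).
#' @param include_auv Run the acoustic stages (skipped with a notice when
#'   `FALSE`, emulating a run without AUV input).
#' @param contour_mass HDR mass defining the overall foraging range.
#' @param candidate_models Candidate presence-model formulas (see
#'   [default_presence_candidates()]).
#' @param run_cv Run repeated cross-validation of the best presence models.
#' @param cv_folds,cv_repeats Cross-validation design.
#' @param v_max Speed-filter limit (m/s).
#' @param grid_cell KDE grid cell size (m).
#' @param data Optional list of pre-built inputs (elements `tracks`, `tdr`,
#'   `missions`) to ingest instead of simulating; simulated ground truth is
#'   then unavailable.
#' @return A `pipeline_bundle` list: inputs, per-stage tables, fitted model
#'   objects, a `summary` of headline numbers and a `log` of record counts.
#' @export
run_pipeline <- function(cfg, include_auv = TRUE, contour_mass = 0.95,
                         candidate_models = default_presence_candidates(),
                         run_cv = TRUE, cv_folds = 10, cv_repeats = 10,
                         v_max = 3, grid_cell = 250, data = NULL) {
  validate_sim_config(cfg)
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out)
  }

  ## ---- stage 1: inputs -------------------------------------------------
  if (is.null(data)) {
    tr <- generate_tracks(cfg)
    td <- generate_tdr(cfg)
    missions <- if (include_auv) {
      lapply(seq_len(cfg$days), function(d) generate_auv_mission(cfg, d))
    } else NULL
    truth <- list(tracks = tr$truth, dives = td$dives, traces = td$traces,
                  missions = if (include_auv) lapply(missions, `[[`, "truth"))
    tracks <- tr$tracks; tdr <- td$tdr
  } else {
    assert_cols(data$tracks, c("id", "species", "time", "x", "y"), "tracks")
    assert_cols(data$tdr, c("id", "species", "sex", "day", "date", "tide",
                            "time", "depth"), "tdr")
    tracks <- data$tracks; tdr <- data$tdr
    missions <- if (include_auv) data$missions else NULL
    truth <- NULL
  }

  ## ---- stage 2: track filtering ---------------------------------------
  n_in <- nrow(tracks)
  tracks <- do.call(rbind, lapply(split(tracks, tracks$id),
                                  function(tr) speed_filter(tr, v_max = v_max)))
  rownames(tracks) <- NULL
  note("speed_filter", n_in, nrow(tracks))

  ## ---- stage 3: dive analysis ------------------------------------------
  dives <- analyze_dives(tdr, thresholds = cfg$thresholds)
  note("analyze_dives", nrow(tdr), nrow(dives))
  # at-sea time = sum of per-day trace spans (traces cover trips only)
  per_day <- stats::aggregate(time ~ id + day, data = tdr,
                              FUN = function(t) diff(range(t)) / 3600)
  at_sea <- stats::aggregate(time ~ id, data = per_day, FUN = sum)
  names(at_sea)[2] <- "at_sea_hours"
  behavior <- summarize_behavior(dives, at_sea)

  ## ---- stage 4: foraging ranges and overlap ----------------------------
  dives <- link_dive_positions(dives, tracks)
  forage <- dives[dives$behavior == "forage" & !is.na(dives$x), ]
  ranges <- list(); overlaps <- list()
  pad <- 3000
  lims <- c(min(forage$x) - pad, max(forage$x) + pad,
            min(forage$y) - pad, max(forage$y) + pad)
  dives$region <- "outside"
  for (tide in unique(dives$tide)) {
    fa <- forage[forage$tide == tide & forage$species == "adelie", ]
    fg <- forage[forage$tide == tide & forage$species == "gentoo", ]
    if (nrow(fa) < 10L || nrow(fg) < 10L) {
      message(sprintf("tide %s: too few forage positions for range estimation",
                      tide))
      next
    }
    ra <- kde_surface(fa$x, fa$y, cell = grid_cell, lims = lims)
    rg <- kde_surface(fg$x, fg$y, cell = grid_cell, lims = lims)
    ov <- range_overlap(ra, rg, mass = contour_mass)
    ranges[[tide]] <- list(adelie = ra, gentoo = rg)
    overlaps[[tide]] <- ov
    sel <- which(dives$tide == tide)
    lab <- assign_region(dives$x[sel], dives$y[sel], ov, ra)
    dives$region[sel] <- c(A_only = "adelie", B_only = "gentoo",
                           overlap = "overlap", outside = "outside")[lab]
  }

  ## ---- stage 5: acoustics ----------------------------------------------
  profiles <- aggregations <- background <- NULL
  if (include_auv && !is.null(missions)) {
    prof_list <- agg_list <- bg_list <- list()
    for (m in missions) {
      eg <- m$echogram
      aggs <- detect_aggregations(
        eg, min_cells = 4,
        dense_threshold_db = cfg$aggregation$dense_threshold_db)
      pr <- segment_profiles(m$sensor, day = eg$day)
      pr <- profile_features(m$sensor, pr)
      pr$tide <- eg$tide; pr$region <- eg$region; pr$date <- eg$date
      pr <- attach_presence(pr, aggs)
      bg <- background_sv(eg, attr(aggs, "mask"), m$sensor, pr)
      bg$day <- eg$day
      prof_list[[length(prof_list) + 1L]] <- pr
      agg_list[[length(agg_list) + 1L]] <- aggs
      bg_list[[length(bg_list) + 1L]] <- bg
    }
    profiles <- do.call(rbind, prof_list)
    aggregations <- do.call(rbind, agg_list)
    background <- do.call(rbind, bg_list)
    note("detect_aggregations", NA, nrow(aggregations))
    note("profiles", NA, nrow(profiles))
  } else if (!include_auv) {
    message("no AUV input: acoustic stages skipped")
  }

  ## ---- stage 6: statistics ---------------------------------------------
  stats_out <- list()

  forage_lab <- dives[dives$behavior == "forage", ]
  # drop fixed terms that are constant in this run (e.g. a single tide)
  varying <- function(data, terms) {
    terms[vapply(terms, function(tm) {
      length(unique(data[[tm]])) > 1L
    }, logical(1))]
  }
  build_formula <- function(resp, terms, random) {
    paste(resp, "~", paste(c(terms, random), collapse = " + "))
  }

  # species depth contrast (sqrt response for normality, as for field data)
  if (length(unique(forage_lab$species)) == 2L) {
    stats_out$species_depth_lmm <- fit_mixed(
      build_formula("max_depth", varying(forage_lab, c("species", "tide")),
                    "(1|id)"),
      forage_lab, family = "gaussian", response_transform = "sqrt")
    mg <- mean(forage_lab$max_depth[forage_lab$species == "gentoo"])
    ma <- mean(forage_lab$max_depth[forage_lab$species == "adelie"])
    stats_out$gentoo_depth_excess_pct <- 100 * (mg - ma) / ma
  }

  # gentoo overlap-vs-non-overlap contrast
  gg <- forage_lab[forage_lab$species == "gentoo" &
                     forage_lab$region != "outside", ]
  gg$in_overlap <- as.integer(gg$region == "overlap")
  if (nrow(gg) > 10L && length(unique(gg$in_overlap)) == 2L &&
      length(unique(gg$id)) >= 2L) {
    stats_out$overlap_contrast_lmm <- fit_mixed(
      build_formula("max_depth", c("in_overlap", varying(gg, "tide")),
                    "(1|id)"),
      gg, family = "gaussian")
  }

  # gated depth-distribution comparisons by tide within the overlap region
  comp_rows <- list()
  for (tide in unique(forage_lab$tide)) {
    ov <- forage_lab[forage_lab$tide == tide & forage_lab$region == "overlap", ]
    if (length(unique(ov$species)) == 2L &&
        min(table(ov$species)) >= 3L) {
      g <- gated_comparison(ov$max_depth, ov$species, ov$id)
      stat <- if (g$method == "ks") g$result$statistic else
        g$result$coefficients$stat[2]
      p <- if (g$method == "ks") g$result$p_value else
        g$result$coefficients$p[2]
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        comparison = "adelie_vs_gentoo_depth_in_overlap", tide = tide,
        n_adelie = sum(ov$species == "adelie"),
        n_gentoo = sum(ov$species == "gentoo"),
        icc = g$icc, method = g$method, statistic = stat, p = p,
        stringsAsFactors = FALSE)
    }
  }
  stats_out$depth_comparisons <- if (length(comp_rows)) {
    do.call(rbind, comp_rows)
  } else {
    data.frame(comparison = character(), tide = character(),
               n_adelie = integer(), n_gentoo = integer(), icc = numeric(),
               method = character(), statistic = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
  }

  # behaviour presence GLMMs
  stats_out$behavior_glmms <- list()
  if (length(unique(forage_lab$species)) == 2L) {
    for (sig in c("has_bottom", "has_wiggle", "has_plateau")) {
      dat <- forage_lab
      dat$y <- as.integer(dat[[sig]])
      fm <- build_formula(
        "y", c("max_depth", varying(dat, c("species", "tide", "sex"))),
        "(1|id)")
      fitb <- tryCatch(
        fit_mixed(fm, dat, family = "binomial", standardize = TRUE),
        error = function(e) NULL)
      stats_out$behavior_glmms[[sig]] <- fitb
    }
  }

  # Table-style dense/diffuse aggregation comparison
  if (!is.null(aggregations)) {
    stats_out$aggregation_table <- aggregation_comparison_table(aggregations)
  }

  # presence/absence model sets + cross-validation
  if (!is.null(profiles)) {
    stats_out$presence <- list()
    pred_cols <- c("isolume_1wm2", "depth_chl_max", "integrated_chl_0_50",
                   "mld", "density_at_mld", "thermocline_depth",
                   "surface_par")
    for (type in c("dense", "diffuse")) {
      dat <- profiles[stats::complete.cases(profiles[pred_cols]), ]
      dat$presence <- as.integer(dat[[paste0(type, "_present")]])
      dat$day <- factor(dat$day)
      std <- standardize_predictors(dat, pred_cols)
      dat <- std$data
      res <- list(
        vif = tryCatch(vif(dat[pred_cols]), error = function(e) NULL),
        model_set = tryCatch(model_set(candidate_models, dat,
                                       family = "binomial"),
                             error = function(e) NULL))
      if (run_cv && !is.null(res$model_set) &&
          sum(dat$presence == 1) >= cv_folds &&
          sum(dat$presence == 0) >= cv_folds) {
        best <- res$model_set$table$formula[1]
        res$cv <- tryCatch(
          cross_validate(best, dat, folds = cv_folds, repeats = cv_repeats,
                         seed = derive_seed(cfg$seed, paste0("cv_", type))),
          error = function(e) NULL)
      }
      stats_out$presence[[type]] <- res
    }
  }

  ## ---- summary ----------------------------------------------------------
  summary <- list(
    n_dives = nrow(dives),
    n_forage_dives = sum(dives$behavior == "forage"),
    overlap_area_km2 = vapply(overlaps, `[[`, numeric(1), "area_km2"),
    gentoo_depth_excess_pct = stats_out$gentoo_depth_excess_pct %||% NA_real_,
    overlap_contrast = if (!is.null(stats_out$overlap_contrast_lmm)) {
      co <- stats_out$overlap_contrast_lmm$coefficients
      row <- co[co$term == "in_overlap", ]
      list(estimate = row$estimate, t = row$stat, p = row$p)
    },
    n_aggregations = if (!is.null(aggregations)) {
      as.list(table(aggregations$type))
    }
  )

  structure(list(config = cfg, tracks = tracks, dives = dives,
                 behavior = behavior, ranges = ranges, overlaps = overlaps,
                 profiles = profiles, aggregations = aggregations,
                 background = background, stats = stats_out,
                 truth = truth, summary = summary,
                 log = do.call(rbind, log)),
            class = "pipeline_bundle")
}

#' Dense vs diffuse morphometric comparison table
#'
#' One row per morphometric (depth, height, length, area, length:height
#' ratio, mean Sv): per-type n, mean and SD plus the Mann-Whitney Z and
#' p-value. Rows are emitted with `n = 0` when a type is absent.
#'
#' @param aggregations Aggregation table from [detect_aggregations()].
#' @return Data frame.
#' @export
aggregation_comparison_table <- function(aggregations) {
  metrics <- c(depth = "mean_depth", height = "height", length = "length",
               area = "area", lh_ratio = "lh_ratio", sv = "mean_sv")
  rows <- lapply(names(metrics), function(mname) {
    col <- metrics[[mname]]
    xd <- aggregations[[col]][aggregations$type == "dense"]
    xf <- aggregations[[col]][aggregations$type == "diffuse"]
    mw <- if (length(xd) >= 3L && length(xf) >= 3L) {
      mann_whitney(xd, xf)
    } else NULL
    data.frame(
      metric = mname,
      n_dense = length(xd), n_diffuse = length(xf),
      dense_mean = if (length(xd)) mean(xd) else NA_real_,
      dense_sd = if (length(xd) > 1) stats::sd(xd) else NA_real_,
      diffuse_mean = if (length(xf)) mean(xf) else NA_real_,
      diffuse_sd = if (length(xf) > 1) stats::sd(xf) else NA_real_,
      mw_z = if (!is.null(mw)) mw$z else NA_real_,
      mw_p = if (!is.null(mw)) mw$p_value else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Result tables of a pipeline run
#'
#' @param bundle A `pipeline_bundle`.
#' @return List of data frames: `aggregation_table` (dense vs diffuse with
#'   Mann-Whitney columns), `depth_comparisons` (region-by-tide gated
#'   K-S/LMM comparisons), `behavior_models` (signature GLMM coefficients),
#'   `presence_models` (per-type AIC table with CV metrics).
#' @export
report_tables <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  beh <- lapply(names(bundle$stats$behavior_glmms %||% list()), function(sig) {
    f <- bundle$stats$behavior_glmms[[sig]]
    if (is.null(f)) return(NULL)
    cbind(signature = sig, f$coefficients)
  })
  beh <- if (length(beh)) do.call(rbind, beh) else
    data.frame(signature = character(), term = character(),
               estimate = numeric(), se = numeric(), stat = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  pres <- lapply(names(bundle$stats$presence %||% list()), function(type) {
    ms <- bundle$stats$presence[[type]]$model_set
    if (is.null(ms)) return(NULL)
    tab <- cbind(type = type, ms$table)
    cvr <- bundle$stats$presence[[type]]$cv
    if (!is.null(cvr)) {
      for (i in seq_len(nrow(cvr$summary))) {
        tab[[paste0("cv_", cvr$summary$metric[i])]] <-
          c(cvr$summary$mean[i], rep(NA_real_, nrow(tab) - 1L))
      }
    }
    tab
  })
  pres <- if (length(pres)) do.call(rbind, pres) else NULL
  list(
    aggregation_table = bundle$stats$aggregation_table %||%
      aggregation_comparison_table(empty_aggregation_table()),
    depth_comparisons = bundle$stats$depth_comparisons,
    behavior_models = beh,
    presence_models = pres
  )
}

#' Write a pipeline run to disk
#'
#' One directory per run: stage tables as TSV, contours as GeoJSON, the
#' headline summary and the configuration snapshot as JSON, plus the filter
#' log.
#'
#' @param bundle A `pipeline_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  wt(bundle$tracks, "tracks")
  wt(bundle$dives, "dives")
  wt(bundle$behavior$individuals, "behavior_individuals")
  wt(bundle$behavior$species, "behavior_species")
  wt(bundle$profiles, "profiles")
  wt(bundle$aggregations, "aggregations")
  wt(bundle$background, "background_sv")
  wt(bundle$log, "filter_log")
  tabs <- report_tables(bundle)
  for (nm in names(tabs)) wt(tabs[[nm]], paste0("report_", nm))
  for (tide in names(bundle$overlaps)) {
    ov <- bundle$overlaps[[tide]]
    if (length(ov$polygons)) {
      write_range_geojson(ov$polygons,
                          file.path(dir, sprintf("overlap_%s.geojson", tide)),
                          properties = list(tide = tide))
    }
  }
  cfg <- bundle$config
  cfg$start_date <- as.character(cfg$start_date)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle>\n")
  cat(sprintf("  %d dives (%d forage), %d track fixes\n",
              nrow(x$dives), sum(x$dives$behavior == "forage"),
              nrow(x$tracks)))
  if (!is.null(x$aggregations)) {
    cat(sprintf("  %d aggregations (%d dense), %d profiles\n",
                nrow(x$aggregations),
                sum(x$aggregations$type == "dense"),
                nrow(x$profiles)))
  }
  if (length(x$overlaps)) {
    cat(sprintf("  overlap area: %s\n",
                paste(sprintf("%s %.2f km2", names(x$overlaps),
                              vapply(x$overlaps, `[[`, numeric(1), "area_km2")),
                      collapse = ", ")))
  }
  invisible(x)
}
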