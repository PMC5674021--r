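# End-to-end pipeline: landscapes -> vital rates -> occupancy curves ->
# Beverton-Holt shape -> trends -> buffer test -> two-season diagnosis.

#' Pipeline configuration
#'
#' Bundles every input and switch the full analysis needs. Landscapes come
#' either from a patch table on disk (`patch_table`) or from the synthetic
#' gradient generator (`gen_config`). Vital-rate curves are either the
#' default field-estimated parameter sets or re-fitted from observations
#' (`vital_obs_path`). Breeding densities are either derived from supplied
#' population sizes (`populations`: data frame `landscape_id`,
#' `population_size`), given directly (`densities`: `landscape_id`,
#' `density_hat`), or -- the synthetic default -- set to a fixed fraction
#' of each landscape's fitted K (`density_fraction_of_K`), emulating
#' populations sitting on the shallow part of their curves. Trends come
#' from an index-series file (`index_series_path`) or are generated under
#' the two-season `scenario`.
#'
#' @param patch_table optional path to a county-level patch table
#' @param gen_config [landscape_gen_config()] used when `patch_table` is
#'   `NULL`
#' @param survival a [survival_curve()]
#' @param sat_density a [density_curve()]
#' @param vital_obs_path optional observations file; when set, both curves
#'   are re-fitted from it (the density curve under `orientation`)
#' @param orientation sigmoid orientation for a re-fitted density curve
#' @param density_fraction_of_K fraction of K used when no densities or
#'   populations are supplied (default 0.25)
#' @param populations,densities optional data frames, see above
#' @param index_series_path optional path to index series
#' @param scenario [trend_scenario_config()] used when no index series
#' @param trend_window length-2 vector of window years
#' @param d_prime `NULL` to estimate the non-breeding strength jointly, or
#'   a fixed positive value
#' @param interpolate fractional-occupancy points per class for
#'   [occupancy_curve()]
#' @param seed master seed; all stage seeds derive from it
#' @param out_dir optional directory for delimited-text outputs
#' @param verbose print stage progress
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(patch_table = NULL,
                            gen_config = landscape_gen_config(seed = seed),
                            survival = survival_curve(),
                            sat_density = density_curve(),
                            vital_obs_path = NULL,
                            orientation = c("decreasing", "literal"),
                            density_fraction_of_K = 0.25,
                            populations = NULL,
                            densities = NULL,
                            index_series_path = NULL,
                            scenario = trend_scenario_config(seed = seed),
                            trend_window = c(1987, 1997),
                            d_prime = NULL,
                            interpolate = 0L,
                            seed = 1L,
                            out_dir = NULL,
                            verbose = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(length(trend_window) == 2L, trend_window[1] < trend_window[2])
  if (!is.null(patch_table) && !file.exists(patch_table)) {
    stop("pipeline_config(): patch table not found: ", patch_table)
  }
  if (!is.null(index_series_path) && !file.exists(index_series_path)) {
    stop("pipeline_config(): index series file not found: ", index_series_path)
  }
  structure(list(patch_table = patch_table, gen_config = gen_config,
                 survival = survival, sat_density = sat_density,
                 vital_obs_path = vital_obs_path, orientation = orientation,
                 density_fraction_of_K = density_fraction_of_K,
                 populations = populations, densities = densities,
                 index_series_path = index_series_path, scenario = scenario,
                 trend_window = trend_window, d_prime = d_prime,
                 interpolate = as.integer(interpolate),
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Demo configuration: synthetic gradient, non-breeding scenario
#'
#' Eleven synthetic landscapes along the default fragmentation gradient,
#' default vital-rate curves, densities at a quarter of each K, and trends
#' generated under the non-breeding-limited scenario.
#'
#' @param seed master seed
#' @param out_dir optional output directory
#' @return a [pipeline_config()]
#' @export
demo_config <- function(seed = 1L, out_dir = NULL) {
  pipeline_config(seed = seed, out_dir = out_dir)
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message("[fragdd] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis
#'
#' Executes every stage on the configured inputs and returns an analysis
#' report; with `out_dir` set, also writes each intermediate table as
#' comma-separated text. Fully deterministic under the config seed.
#'
#' @param config a [pipeline_config()]
#' @return list of class `analysis_report`: `landscapes` (summary table),
#'   `curves` (the vital-rate curves used), `fd_points` (all
#'   fecundity-density points), `summaries` (per-landscape
#'   density-dependence rows), `trends`, `buffer` ([buffer_effect_test()]
#'   result or `NULL`), `limitation` ([diagnose_limitation()] result or
#'   `NULL`), `warnings` (character vector)
#' @export
run_full_analysis <- function(config = demo_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$verbose
  warnings <- character(0)

  landscapes <- run_stage("landscape", v, {
    if (!is.null(config$patch_table)) {
      recs <- load_patch_table(config$patch_table)
      ids <- unique(recs$landscape_id)
      lapply(ids, function(id) {
        forest <- aggregate_counties(recs, id, "total")
        has_core <- any(recs$landscape_id == id & recs$forest_type == "core")
        core <- if (has_core) aggregate_counties(recs, id, "core") else NULL
        if (is.null(core)) stop("no core records for landscape ", id)
        landscape(id, forest, core)
      })
    } else {
      generate_fragmentation_gradient(config$gen_config)
    }
  })

  curves <- run_stage("vital_rates", v, {
    if (!is.null(config$vital_obs_path)) {
      obs <- load_vital_obs(config$vital_obs_path)
      list(survival = fit_survival_curve(obs[obs$kind == "survival", ],
                                         seed = config$seed),
           sat_density = fit_density_curve(obs[obs$kind == "density", ],
                                           orientation = config$orientation,
                                           seed = config$seed))
    } else {
      list(survival = config$survival, sat_density = config$sat_density)
    }
  })

  fd_points <- run_stage("site_dependence", v, {
    do.call(rbind, lapply(landscapes, function(l) {
      occupancy_curve(l$forest, curves$survival, curves$sat_density,
                      landscape_id = l$id, interpolate = config$interpolate)
    }))
  })

  summaries <- run_stage("density_dependence", v, {
    rows <- lapply(landscapes, function(l) {
      pts <- fd_points[fd_points$landscape_id == l$id, ]
      fit <- tryCatch(fit_bh(pts, seed = config$seed),
                      error = function(e) {
                        stop("landscape ", l$id, ": ", conditionMessage(e))
                      })
      dhat <- density_for(l, fit, config)
      dd_summary(l, fit, dhat)
    })
    out <- do.call(rbind, rows)
    if (any(out$poor_fit)) {
      warnings <- c(warnings, paste0("poor Beverton-Holt fit flagged for: ",
                                      paste(out$landscape_id[out$poor_fit],
                                            collapse = ", ")))
    }
    out
  })

  trends <- run_stage("trend_stats", v, {
    series <- if (!is.null(config$index_series_path)) {
      load_index_series(config$index_series_path)
    } else {
      generate_trend_scenario(summaries, config$scenario,
                              y0 = config$trend_window[1],
                              y1 = config$trend_window[2])
    }
    do.call(rbind, lapply(split(series, series$landscape_id), function(s) {
      annual_trend(s, y0 = config$trend_window[1], y1 = config$trend_window[2])
    }))
  })

  n <- nrow(summaries)
  buffer <- NULL
  limitation <- NULL
  if (n >= 4L) {
    buffer <- run_stage("buffer_test", v, {
      buffer_effect_test(trends, summaries[, c("landscape_id", "Q")])
    })
    limitation <- run_stage("two_season", v, {
      pairs <- merge(summaries[, c("landscape_id", "b_prime")],
                     trends[, c("landscape_id", "magnitude")],
                     by = "landscape_id")
      names(pairs)[names(pairs) == "magnitude"] <- "delta_n"
      diag <- diagnose_limitation(pairs, d_prime = config$d_prime,
                                  seed = config$seed)
      if (diag$fit_nonbreeding$weakly_identified ||
          diag$fit_breeding$weakly_identified) {
        warnings <- c(warnings,
                       "weakly identified d' (b' span small relative to d')")
      }
      diag
    })
  } else {
    warnings <- c(warnings,
                  "fewer than 4 landscapes: correlation stages skipped")
    warning("run_full_analysis(): fewer than 4 landscapes; ",
            "buffer and limitation stages skipped")
  }

  report <- structure(list(
    landscapes = landscape_summary(landscapes),
    curves = curves,
    fd_points = fd_points,
    summaries = summaries,
    trends = trends,
    buffer = buffer,
    limitation = limitation,
    warnings = warnings,
    seed = config$seed), class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Per-landscape breeding density under the configured mode.
density_for <- function(l, fit, config) {
  if (!is.null(config$densities)) {
    d <- config$densities$density_hat[config$densities$landscape_id == l$id]
    if (length(d) != 1L) stop("no supplied density for landscape ", l$id)
    return(d)
  }
  if (!is.null(config$populations)) {
    p <- config$populations$population_size[
      config$populations$landscape_id == l$id]
    if (length(p) != 1L) stop("no population size for landscape ", l$id)
    return(breeding_density(p, total_area(l$forest)))
  }
  config$density_fraction_of_K * fit$K
}

#' Write an analysis report to delimited text
#'
#' @param report an `analysis_report`
#' @param out_dir directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wr(report$landscapes, "landscape_summary.csv")
  wr(report$fd_points, "fecundity_density_points.csv")
  wr(report$summaries, "density_dependence_summary.csv")
  wr(report$trends, "trends.csv")
  if (!is.null(report$buffer)) {
    cors <- rbind(cbind(comparison = "trend_vs_Q", report$buffer$cor_trend_q),
                  cbind(comparison = "magnitude_vs_Q",
                        report$buffer$cor_magnitude_q))
    wr(cors, "correlations.csv")
  }
  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  sink(con)
  print(report)
  sink()
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Density-dependence shape analysis report\n")
  cat("========================================\n\n")
  cat(sprintf("Landscapes: %d (seed %d)\n\n", nrow(x$landscapes), x$seed))
  print(x$landscapes)
  cat("\nVital-rate curves:\n")
  print(x$curves$survival)
  print(x$curves$sat_density)
  cat("\nPer-landscape density dependence:\n")
  print(x$summaries[, c("landscape_id", "Q", "quality_class", "density_hat",
                        "realized_survival", "b_prime", "gamma",
                        "tipping_density")])
  cat("\nTrends (annual proportional change):\n")
  print(x$trends)
  if (!is.null(x$buffer)) {
    cat("\n")
    print(x$buffer)
  }
  if (!is.null(x$limitation)) {
    cat("\n")
    print(x$limitation)
  }
  if (length(x$warnings) > 0) {
    cat("\nWarnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}
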