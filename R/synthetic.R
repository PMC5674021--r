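# Synthetic inputs.
#
# The generators produce the three input classes the pipeline consumes:
# patch-size mosaics along a fragmentation gradient (with core areas from
# an explicit patch geometry), noisy vital-rate observations around the
# closed-form curves, and abundance-index series built from the two-season
# shift model. Every generator is deterministic under its seed.

#' Configuration for the landscape generator
#'
#' Patch areas are log-normal: `log(A) ~ N(mu, sigma^2)` with `mu` in
#' log-hectares; the fragmentation gradient shifts only `mu` (smaller mu =
#' smaller patches = more fragmented). Per-class patch counts are rescaled
#' so every landscape has the same total forest area, so fragmentation and
#' landscape extent are not confounded. Core area uses a square-patch
#' geometry: a patch of A ha has side `L = 100 * sqrt(A)` m and core
#' `max(0, L - 2 * edge_depth_m)^2 / 1e4` ha.
#'
#' @param n_landscapes number of landscapes on the gradient
#' @param n_patches patches drawn per landscape
#' @param sigma log-scale sd of patch areas
#' @param mu_gradient vector of `mu` values (log-ha), one per landscape;
#'   default spans heavily fragmented (mean patch ~2 ha) to intact
#'   (~80 ha) mosaics
#' @param edge_depth_m depth of the edge buffer defining core forest
#'   (default 30 m)
#' @param total_area_ha common total forest area per landscape
#' @param class_edges interior size-class boundaries (ha); classes are
#'   `(0, e1], (e1, e2], ..., (ek, Inf)`
#' @param seed integer seed
#' @return list of class `landscape_gen_config`
#' @export
landscape_gen_config <- function(n_landscapes = 11L,
                                 n_patches = 3000L,
                                 sigma = 1.0,
                                 mu_gradient = seq(log(2), log(80),
                                                   length.out = n_landscapes),
                                 edge_depth_m = 30,
                                 total_area_ha = 1e5,
                                 class_edges = c(1, 5, 10, 25, 50, 100, 250, 500),
                                 seed = 1L) {
  stopifnot(n_patches > 0, edge_depth_m > 0, sigma > 0, total_area_ha > 0,
            length(mu_gradient) == n_landscapes, all(diff(class_edges) > 0))
  structure(list(n_landscapes = as.integer(n_landscapes),
                 n_patches = as.integer(n_patches), sigma = sigma,
                 mu_gradient = mu_gradient, edge_depth_m = edge_depth_m,
                 total_area_ha = total_area_ha, class_edges = class_edges,
                 seed = as.integer(seed)),
            class = "landscape_gen_config")
}

# Core area of a square patch of `area_ha` with an edge buffer (ha).
square_core_area <- function(area_ha, edge_depth_m = 30) {
  side <- 100 * sqrt(area_ha)
  pmax(0, side - 2 * edge_depth_m)^2 / 1e4
}

# Bin patch areas into the class ladder; returns a class table with
# midpoint nominal sizes for empty classes.
bin_patches <- function(areas, class_edges, scale = 1) {
  edges <- c(0, class_edges, Inf)
  n_cl <- length(edges) - 1L
  idx <- findInterval(areas, edges, left.open = TRUE, rightmost.closed = FALSE)
  labs <- sprintf("C%d", seq_len(n_cl))
  cnt <- tabulate(idx, nbins = n_cl)
  tot <- vapply(seq_len(n_cl), function(i) sum(areas[idx == i]), numeric(1))
  mid <- ifelse(cnt > 0, tot / cnt, NA_real_)
  # nominal size for empty classes: geometric midpoint of the bin
  for (i in which(cnt == 0)) {
    lo <- max(edges[i], .Machine$double.eps)
    hi <- edges[i + 1L]
    mid[i] <- if (is.finite(hi)) sqrt(lo * hi) else 2 * lo
  }
  data.frame(class_label = labs, mean_size_ha = mid,
             n_patches = cnt * scale, total_area_ha = tot * scale,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic landscape
#'
#' Draws `n_patches` log-normal patch areas at location `mu`, computes each
#' patch's core area under the square geometry, bins forest and core
#' patches into the class ladder, and rescales class counts/areas to the
#' configured common total forest area. `Q` follows as core over total
#' area.
#'
#' @param config a [landscape_gen_config()]
#' @param mu log-ha location for this landscape (defaults to the first
#'   gradient entry)
#' @param id landscape identifier
#' @param seed seed (defaults to the config seed)
#' @return a [landscape()] object
#' @export
generate_landscape <- function(config = landscape_gen_config(),
                               mu = config$mu_gradient[1L],
                               id = "SYN", seed = config$seed) {
  stopifnot(inherits(config, "landscape_gen_config"))
  set.seed(seed)
  areas <- rlnorm(config$n_patches, meanlog = mu, sdlog = config$sigma)
  k <- config$total_area_ha / sum(areas)
  cores <- square_core_area(areas, config$edge_depth_m)
  forest <- patch_dist(bin_patches(areas, config$class_edges, scale = k))
  core_areas <- cores[cores > 0]
  core <- if (length(core_areas) > 0L) {
    patch_dist(bin_patches(core_areas, config$class_edges, scale = k))
  } else NULL
  landscape(id = id, forest = forest, core = core,
            core_total_ha = k * sum(cores))
}

#' Generate a fragmentation gradient of landscapes
#'
#' One landscape per `mu` in the configured gradient, each from an
#' independent seed derived from the config seed. Landscape quality is
#' increasing in `mu` in expectation.
#'
#' @param config a [landscape_gen_config()]
#' @return list of [landscape()] objects, ids `"L01"`, `"L02"`, ...
#' @export
generate_fragmentation_gradient <- function(config = landscape_gen_config()) {
  stopifnot(inherits(config, "landscape_gen_config"))
  lapply(seq_along(config$mu_gradient), function(i) {
    generate_landscape(config, mu = config$mu_gradient[i],
                       id = sprintf("L%02d", i),
                       seed = config$seed + 1000L * i)
  })
}

#' Generate noisy vital-rate observations around the curves
#'
#' Survival values are `f(s)` plus Gaussian noise clipped to \[0, 1\];
#' density values are `d(s)` plus Gaussian noise clipped to be >= 0.
#'
#' @param survival a [survival_curve()]
#' @param sat_density a [density_curve()]
#' @param sizes patch sizes at which to observe (ha)
#' @param noise_sd named vector or list with elements `survival` and
#'   `density` (standard deviations; 0 gives exact curve values)
#' @param seed integer seed
#' @return a [vital_obs()] data frame stacking both kinds
#' @export
generate_vital_observations <- function(survival = survival_curve(),
                                        sat_density = density_curve(),
                                        sizes = exp(seq(log(1), log(500),
                                                        length.out = 40)),
                                        noise_sd = c(survival = 0.05,
                                                     density = 0.05),
                                        seed = 1L) {
  set.seed(seed)
  sv <- nest_survival(sizes, survival) +
    rnorm(length(sizes), 0, noise_sd[["survival"]])
  dv <- saturation_density(sizes, sat_density) +
    rnorm(length(sizes), 0, noise_sd[["density"]])
  rbind(vital_obs(sizes, pmin(pmax(sv, 0), 1), "survival"),
        vital_obs(sizes, pmax(dv, 0), "density"))
}

#' Configuration for a two-season trend scenario
#'
#' @param scenario `"nonbreeding"` (|dF| = 0), `"breeding"` (|dM| = 0) or
#'   `"mixed"`
#' @param delta_F,delta_M,d_prime shift magnitudes and non-breeding
#'   strength passed to [season_scenario()]; the scenario zeroes the
#'   irrelevant shift
#' @param noise_sd Gaussian sd added to the annual change magnitude
#' @param seed integer seed
#' @return list of class `trend_scenario_config`
#' @export
trend_scenario_config <- function(scenario = c("nonbreeding", "breeding", "mixed"),
                                  delta_F = 0.1, delta_M = 0.1, d_prime = 1,
                                  noise_sd = 0.005, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "nonbreeding") delta_F <- 0
  if (scenario == "breeding") delta_M <- 0
  stopifnot(noise_sd >= 0)
  structure(list(scenario = scenario,
                 season = season_scenario(delta_F, delta_M, d_prime),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trend_scenario_config")
}

#' Generate abundance-index series under a two-season scenario
#'
#' For each landscape the expected annual change magnitude comes from
#' [predicted_change()] applied to its b'; Gaussian noise is added and the
#' result truncated at 0. Both scenario shifts are declines by convention,
#' so the annual trend is `-|dn|`. The index compounds from 100 in `y0`
#' through `y1`.
#'
#' @param summaries data frame carrying `landscape_id` and `b_prime` (e.g.
#'   stacked [dd_summary()] rows)
#' @param config a [trend_scenario_config()]
#' @param y0,y1 series window (default 1987-1997)
#' @return data frame with `landscape_id`, `year`, `index`
#' @export
generate_trend_scenario <- function(summaries,
                                    config = trend_scenario_config(),
                                    y0 = 1987, y1 = 1997) {
  stopifnot(inherits(config, "trend_scenario_config"),
            all(c("landscape_id", "b_prime") %in% names(summaries)))
  set.seed(config$seed)
  years <- y0:y1
  out <- lapply(seq_len(nrow(summaries)), function(i) {
    dn <- predicted_change(summaries$b_prime[i], config$season)
    dn <- max(0, dn + rnorm(1L, 0, config$noise_sd))
    index_series(summaries$landscape_id[i], years,
                 100 * (1 - dn)^(years - y0))
  })
  do.call(rbind, out)
}

#' Write landscapes as a county-level patch table
#'
#' Serializes a list of landscapes to the delimited-text patch-table format
#' [load_patch_table()] reads (one synthetic "county" per landscape, both
#' forest types), so synthetic runs exercise the same I/O path as real
#' inventory tables.
#'
#' @param landscapes list of [landscape()] objects
#' @param path output file path
#' @return the path, invisibly
#' @export
write_patch_table <- function(landscapes, path) {
  rows <- lapply(landscapes, function(l) {
    mk <- function(dist, type) {
      if (is.null(dist)) return(NULL)
      data.frame(landscape_id = l$id, county = paste0(l$id, "-county"),
                 class_label = dist$classes$class_label,
                 mean_size_ha = dist$classes$mean_size_ha,
                 n_patches = dist$classes$n_patches,
                 total_area_ha = dist$classes$total_area_ha,
                 forest_type = type, stringsAsFactors = FALSE)
    }
    rbind(mk(l$forest, "total"), mk(l$core, "core"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
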