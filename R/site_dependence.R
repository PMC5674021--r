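# Site-dependent habitat selection.
#
# Territorial breeders are assumed to fill forest patches in order of
# decreasing size, each patch up to its saturation density d(s). When every
# class of mean size a and larger is saturated, the population-mean nest
# survival and the landscape-scale density are
#
#   F(a) = sum_{s >= a} f(s) d(s) A(s) / sum_{s >= a} d(s) A(s)
#   D(a) = sum_{s >= a} d(s) A(s) / sum_{all s} A(s)
#
# with A(s) the total area in class s. Sweeping the threshold a down from
# the largest to the smallest class traces out the fecundity-density curve.

#' One point on a landscape's fecundity-density curve
#'
#' Evaluates mean nest survival `F(a)` and landscape density `D(a)` when all
#' classes of mean size `a` and larger are saturated. Classes with zero area
#' contribute nothing.
#'
#' @param dist a [patch_dist()]
#' @param survival a [survival_curve()]
#' @param sat_density a [density_curve()]
#' @param a threshold: the mean size of one class in `dist` (ha)
#' @return one-row data frame: `threshold_class_size`, `density`,
#'   `fecundity`
#' @export
occupancy_point <- function(dist, survival = survival_curve(),
                            sat_density = density_curve(), a) {
  stopifnot(inherits(dist, "patch_dist"))
  cl <- dist$classes
  hit <- which(abs(cl$mean_size_ha - a) <= 1e-9 * pmax(a, 1))
  if (length(hit) != 1L) {
    stop("occupancy_point(): threshold a = ", a,
         " is not the mean size of a class in the distribution")
  }
  occ <- cl$mean_size_ha >= cl$mean_size_ha[hit] - 1e-12 & cl$total_area_ha > 0
  if (!any(occ)) {
    stop("occupancy_point(): all occupied classes have zero area")
  }
  s <- cl$mean_size_ha[occ]
  A <- cl$total_area_ha[occ]
  dA <- saturation_density(s, sat_density) * A
  fec <- sum(nest_survival(s, survival) * dA) / sum(dA)
  dens <- sum(dA) / sum(cl$total_area_ha)
  data.frame(threshold_class_size = a, density = dens, fecundity = fec)
}

#' Generate a landscape's fecundity-density series
#'
#' Sweeps the occupancy threshold down through the non-empty size classes,
#' largest first, producing one `(D(a), F(a))` point per class. Densities
#' increase strictly along the series and, because small patches carry the
#' lowest nest survival, fecundity is non-increasing.
#'
#' Optionally the marginal (threshold) class can be filled fractionally:
#' with `interpolate = m`, each step adds `m` intermediate points at
#' occupied fractions `1/(m+1), ..., m/(m+1)` of the marginal class, linear
#' in both weighted sums. This densifies the curve for fitting without
#' changing the class-threshold points.
#'
#' @inheritParams occupancy_point
#' @param landscape_id identifier attached to the series
#' @param interpolate number of fractional-occupancy points inserted per
#'   class (0 = class thresholds only, the default)
#' @return data frame of class `fd_series` with columns `landscape_id`,
#'   `threshold_class_size`, `density`, `fecundity`, ordered by ascending
#'   density
#' @export
occupancy_curve <- function(dist, survival = survival_curve(),
                            sat_density = density_curve(),
                            landscape_id = "landscape", interpolate = 0L) {
  stopifnot(inherits(dist, "patch_dist"))
  cl <- dist$classes[dist$classes$total_area_ha > 0, , drop = FALSE]
  if (nrow(cl) == 0L) stop("occupancy_curve(): empty distribution")
  if (nrow(cl) == 1L) {
    warning("occupancy_curve(): single non-empty class; one-point series")
  }
  cl <- cl[order(-cl$mean_size_ha), ]
  s <- cl$mean_size_ha
  A <- cl$total_area_ha
  f <- nest_survival(s, survival)
  d <- saturation_density(s, sat_density)
  Atot <- total_area(dist)
  rows <- vector("list", nrow(cl))
  cum_fdA <- 0
  cum_dA <- 0
  for (i in seq_along(s)) {
    fracs <- if (interpolate > 0L) seq_len(interpolate + 1L) / (interpolate + 1L) else 1
    pts <- lapply(fracs, function(phi) {
      num <- cum_fdA + phi * f[i] * d[i] * A[i]
      den <- cum_dA + phi * d[i] * A[i]
      data.frame(landscape_id = landscape_id,
                 threshold_class_size = s[i],
                 occupied_fraction = phi,
                 density = den / Atot,
                 fecundity = num / den)
    })
    rows[[i]] <- do.call(rbind, pts)
    cum_fdA <- cum_fdA + f[i] * d[i] * A[i]
    cum_dA <- cum_dA + d[i] * A[i]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("fd_series", "data.frame"))
}
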