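# Generalized Beverton-Holt shape analysis.
#
# F(D) = F_max / (1 + (D/K)^gamma). K is the density at which F is half of
# F_max and gamma is the abruptness: gamma <= 1 gives a concave decline,
# gamma > 1 a reverse-sigmoid, shallow at low density and dropping steeply
# past the inflection. Derivatives are closed-form; with x = D/K and
# u = x^gamma:
#
#   F'(D)  = -F_max * gamma * x^(gamma-1) / (K * (1 + u)^2)
#   F''(D) = -F_max * gamma * x^(gamma-2) * ((gamma-1) - (gamma+1) u)
#            / (K^2 * (1 + u)^3)
#
# so the inflection sits at u = (gamma-1)/(gamma+1), i.e.
# D_infl = K * ((gamma-1)/(gamma+1))^(1/gamma), only for gamma > 1.

#' Construct a generalized Beverton-Holt fit object
#'
#' @param F_max maximum nest survival (> 0)
#' @param K half-survival density (pairs/ha, > 0)
#' @param gamma abruptness (> 0)
#' @param residual_ss residual sum of squares of the generating fit
#' @return object of class `bh_fit`
#' @export
bh_fit_params <- function(F_max, K, gamma, residual_ss = NA_real_) {
  stopifnot(is.finite(F_max), F_max > 0, is.finite(K), K > 0,
            is.finite(gamma), gamma > 0)
  structure(list(F_max = F_max, K = K, gamma = gamma,
                 residual_ss = residual_ss, poor_fit = FALSE),
            class = "bh_fit")
}

#' @export
print.bh_fit <- function(x, ...) {
  cat(sprintf("Generalized Beverton-Holt: F_max = %.4g, K = %.4g, gamma = %.4g",
              x$F_max, x$K, x$gamma))
  if (is.finite(x$residual_ss)) cat(sprintf(" (RSS = %.3g)", x$residual_ss))
  if (isTRUE(x$poor_fit)) cat("  [flagged: poor fit]")
  cat("\n")
  invisible(x)
}

#' Fit the generalized Beverton-Holt to a fecundity-density series
#'
#' Nonlinear least squares over positive `(F_max, K, gamma)`. Starting
#' values: `F_max` from the largest fecundity, `K` from the density of the
#' point nearest half of it, `gamma = 1`; bounded seeded restarts. The fit
#' is flagged poor when `residual_ss / var(F) > 0.05`.
#'
#' @param series an [occupancy_curve()] result, or any data frame with
#'   `density` and `fecundity` columns; at least 3 distinct densities
#' @param seed seed for restart jitter
#' @return a `bh_fit` object
#' @export
fit_bh <- function(series, seed = 1L) {
  if (nrow(series) < 3L || length(unique(series$density)) < 3L) {
    stop("fit_bh(): need >= 3 points with distinct densities")
  }
  d <- data.frame(D = series$density, F = series$fecundity)
  fmax0 <- max(d$F)
  k0 <- d$D[which.min(abs(d$F - fmax0 / 2))]
  if (k0 <= 0) k0 <- median(d$D[d$D > 0])
  fit <- fit_with_restarts(
    F ~ F_max / (1 + (D / K)^gamma),
    data = d,
    start = list(F_max = fmax0, K = k0, gamma = 1),
    lower = list(F_max = 1e-8, K = 1e-8, gamma = 1e-8),
    seed = seed)
  p <- coef(fit)
  out <- bh_fit_params(unname(p["F_max"]), unname(p["K"]), unname(p["gamma"]),
                       residual_ss = sum(resid(fit)^2))
  vf <- var(d$F)
  out$poor_fit <- is.finite(vf) && vf > 0 && out$residual_ss / vf > 0.05
  out
}

#' Beverton-Holt fecundity at density D
#' @param D density (pairs/ha), >= 0
#' @param fit a `bh_fit`
#' @return `F_max / (1 + (D/K)^gamma)`
#' @export
bh_value <- function(D, fit) {
  stopifnot(inherits(fit, "bh_fit"))
  if (any(!is.finite(D)) || any(D < 0)) stop("bh_value(): D must be >= 0")
  fit$F_max / (1 + (D / fit$K)^fit$gamma)
}

#' First derivative dF/dD of the Beverton-Holt curve (signed)
#'
#' Closed form; at `D = 0` the limit is 0 for `gamma > 1`,
#' `-F_max / K` for `gamma = 1`, and `-Inf` for `gamma < 1`.
#'
#' @inheritParams bh_value
#' @return slope (survival per pairs/ha), <= 0
#' @export
bh_slope <- function(D, fit) {
  stopifnot(inherits(fit, "bh_fit"))
  if (any(!is.finite(D)) || any(D < 0)) stop("bh_slope(): D must be >= 0")
  x <- D / fit$K
  g <- fit$gamma
  out <- -fit$F_max * g * x^(g - 1) / (fit$K * (1 + x^g)^2)
  # x^(g-1) at x = 0: 0 for g > 1, 1 for g = 1, Inf for g < 1
  if (any(D == 0)) {
    out[D == 0] <- if (g > 1) 0 else if (g == 1) -fit$F_max / fit$K else -Inf
  }
  out
}

#' Second derivative of the Beverton-Holt curve
#' @inheritParams bh_value
#' @return d2F/dD2 (closed form)
#' @export
bh_curvature <- function(D, fit) {
  stopifnot(inherits(fit, "bh_fit"))
  if (any(!is.finite(D)) || any(D < 0)) stop("bh_curvature(): D must be >= 0")
  x <- D / fit$K
  g <- fit$gamma
  u <- x^g
  -fit$F_max * g * x^(g - 2) * ((g - 1) - (g + 1) * u) / (fit$K^2 * (1 + u)^3)
}

#' Strength of density dependence b'
#'
#' The magnitude of the fecundity-density slope at density `D`; the realized
#' strength of breeding-season regulation.
#'
#' @inheritParams bh_value
#' @return `|dF/dD|` at D
#' @export
strength_b <- function(D, fit) abs(bh_slope(D, fit))

#' Inflection density of the Beverton-Holt curve
#'
#' For `gamma > 1` the curve switches from its shallow-then-steepening
#' low-density regime to the concave high-density decline at
#' `D_infl = K * ((gamma-1)/(gamma+1))^(1/gamma)`, the root of the second
#' derivative. For `gamma <= 1` there is no inflection.
#'
#' @param fit a `bh_fit`
#' @return inflection density, or `NA` when `gamma <= 1`
#' @export
inflection_density <- function(fit) {
  stopifnot(inherits(fit, "bh_fit"))
  g <- fit$gamma
  if (g <= 1) return(NA_real_)
  fit$K * ((g - 1) / (g + 1))^(1 / g)
}

#' Tipping point: onset of strong density dependence
#'
#' The density in the convex (below-inflection) region where the strength
#' of density dependence changes most rapidly, i.e. where `|F''(D)|` is
#' maximized on `(0, D_infl)`. Found by scanning a 10^4-point grid and
#' refining with bounded scalar optimization around the grid argmax. Exists
#' only for `gamma > 1`; for `1 < gamma < 2` the curvature magnitude grows
#' without bound towards zero density and the tipping point collapses to
#' the origin.
#'
#' @param fit a `bh_fit`
#' @param grid_n number of grid points for the initial scan
#' @return tipping density, or `NA` when `gamma <= 1`
#' @export
tipping_point <- function(fit, grid_n = 1e4) {
  stopifnot(inherits(fit, "bh_fit"))
  d_infl <- inflection_density(fit)
  if (is.na(d_infl)) return(NA_real_)
  grid <- d_infl * seq_len(grid_n) / (grid_n + 1)
  obj <- function(D) abs(bh_curvature(D, fit))
  i <- which.max(obj(grid))
  lo <- if (i == 1L) d_infl * 1e-9 else grid[i - 1L]
  hi <- if (i == grid_n) d_infl else grid[i + 1L]
  opt <- tryCatch(
    optimize(obj, lower = lo, upper = hi, maximum = TRUE,
             tol = d_infl * 1e-10),
    error = function(e) NULL)
  if (is.null(opt)) return(grid[i])
  if (obj(opt$maximum) >= obj(grid[i])) opt$maximum else grid[i]
}

#' Per-landscape density-dependence summary
#'
#' Combines a landscape, its Beverton-Holt fit and an estimated breeding
#' density into the quantities the cross-landscape analysis uses: realized
#' nest survival at the density, strength of density dependence b', the
#' tipping and inflection densities, abruptness and landscape quality.
#'
#' @param landscape a [landscape()] object
#' @param fit a `bh_fit`
#' @param density_hat estimated breeding density (pairs/ha), >= 0
#' @return one-row data frame of class `dd_summary`
#' @export
dd_summary <- function(landscape, fit, density_hat) {
  stopifnot(inherits(landscape, "landscape"), inherits(fit, "bh_fit"),
            is.finite(density_hat), density_hat >= 0)
  structure(data.frame(
    landscape_id = landscape$id,
    Q = landscape$quality,
    quality_class = classify_quality(landscape$quality),
    density_hat = density_hat,
    realized_survival = bh_value(density_hat, fit),
    b_prime = strength_b(density_hat, fit),
    gamma = fit$gamma,
    F_max = fit$F_max,
    K = fit$K,
    tipping_density = tipping_point(fit),
    inflection_density = inflection_density(fit),
    residual_ss = fit$residual_ss,
    poor_fit = isTRUE(fit$poor_fit),
    stringsAsFactors = FALSE), class = c("dd_summary", "data.frame"))
}
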