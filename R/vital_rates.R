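# Patch-size-dependent vital rates.
#
# Two closed-form curves drive the occupancy model: a saturating
# (Michaelis-Menten) nest-survival curve f(s) = f_max * s / (s_half + s)
# and a sigmoid saturation-density curve. Field estimates for wood thrush
# give f_max = 0.85, s_half = 42 ha, and (l, alpha, t) = (0.13, 0.18, 13.4)
# for density. Both curves can also be re-fitted to patch-size/value
# observations by nonlinear least squares.

#' Saturating nest-survival curve
#'
#' @param f_max asymptotic nest survival probability, in (0, 1]
#' @param s_half half-saturation patch size (ha): the size at which survival
#'   is `f_max / 2`
#' @return object of class `survival_curve`
#' @export
survival_curve <- function(f_max = 0.85, s_half = 42) {
  stopifnot(is.finite(f_max), f_max > 0, f_max <= 1,
            is.finite(s_half), s_half > 0)
  structure(list(f_max = f_max, s_half = s_half), class = "survival_curve")
}

#' Sigmoid saturation-density curve
#'
#' Maximum breeding density a patch of size `s` supports. Under the default
#' `"decreasing"` orientation,
#' `d(s) = l + (1 - l) / (1 + exp(alpha * (s - t)))`,
#' which falls from about 1 pair/ha in the smallest patches to the
#' large-patch asymptote `l` -- the orientation consistent with the field
#' observation that wood thrush density is higher in small patches. The
#' `"literal"` orientation, `d(s) = 1 + (l - 1) / (1 + exp(alpha * (s - t)))`,
#' is the mirror-image (increasing) form; with the same parameter values the
#' two agree only at the midpoint `s = t`. See the package vignette for why
#' both are exposed.
#'
#' @param l large-patch asymptote density (pairs/ha), in (0, 1)
#' @param alpha steepness (1/ha)
#' @param t midpoint patch size (ha)
#' @param orientation `"decreasing"` (default) or `"literal"`
#' @return object of class `density_curve`
#' @export
density_curve <- function(l = 0.13, alpha = 0.18, t = 13.4,
                          orientation = c("decreasing", "literal")) {
  orientation <- match.arg(orientation)
  stopifnot(is.finite(l), l > 0, l < 1,
            is.finite(alpha), alpha > 0, is.finite(t), t > 0)
  structure(list(l = l, alpha = alpha, t = t, orientation = orientation),
            class = "density_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Nest survival f(s) = %.4g * s / (%.4g + s)\n", x$f_max, x$s_half))
  invisible(x)
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("Saturation density (%s): l = %.4g, alpha = %.4g, t = %.4g\n",
              x$orientation, x$l, x$alpha, x$t))
  invisible(x)
}

#' Nest survival at patch size s
#'
#' @param s patch size(s), ha, >= 0
#' @param curve a [survival_curve()]
#' @return survival probability `f_max * s / (s_half + s)`
#' @examples
#' nest_survival(42, survival_curve()) # f_max / 2 = 0.425
#' @export
nest_survival <- function(s, curve = survival_curve()) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("nest_survival(): patch size must be finite and >= 0")
  }
  curve$f_max * s / (curve$s_half + s)
}

#' Saturation density at patch size s
#'
#' @param s patch size(s), ha, >= 0
#' @param curve a [density_curve()]
#' @return density (pairs/ha) under the curve's orientation
#' @examples
#' saturation_density(13.4, density_curve()) # midpoint: (1 + 0.13)/2
#' @export
saturation_density <- function(s, curve = density_curve()) {
  stopifnot(inherits(curve, "density_curve"))
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("saturation_density(): patch size must be finite and >= 0")
  }
  logistic_tail <- 1 / (1 + exp(curve$alpha * (s - curve$t)))
  if (curve$orientation == "decreasing") {
    curve$l + (1 - curve$l) * logistic_tail
  } else {
    1 + (curve$l - 1) * logistic_tail
  }
}

#' Construct vital-rate observations
#'
#' @param patch_size_ha patch sizes (ha), > 0
#' @param value observed survival probabilities (in \[0, 1\]) or densities
#'   (>= 0, pairs/ha)
#' @param kind `"survival"` or `"density"`
#' @return data frame of class `vital_obs`
#' @export
vital_obs <- function(patch_size_ha, value, kind = c("survival", "density")) {
  kind <- match.arg(kind)
  stopifnot(length(patch_size_ha) == length(value))
  if (any(patch_size_ha <= 0)) stop("vital_obs(): patch sizes must be > 0")
  if (kind == "survival" && (any(value < 0) || any(value > 1))) {
    stop("vital_obs(): survival values must lie in [0, 1]")
  }
  if (kind == "density" && any(value < 0)) {
    stop("vital_obs(): density values must be >= 0")
  }
  structure(data.frame(patch_size_ha = patch_size_ha, value = value,
                       kind = kind, stringsAsFactors = FALSE),
            class = c("vital_obs", "data.frame"))
}

#' Read vital-rate observations from delimited text
#'
#' Expects columns `patch_size_ha`, `value`, `kind`.
#' @param path file path
#' @return a [vital_obs()] data frame (single kind per call not required;
#'   use `subset` on `kind` before fitting)
#' @export
load_vital_obs <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("patch_size_ha", "value", "kind")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0L) {
    stop("load_vital_obs(): missing column(s): ", paste(miss, collapse = ", "))
  }
  structure(d[, req], class = c("vital_obs", "data.frame"))
}

# Shared nls wrapper: nlsLM with bounded, seeded, jittered restarts.
# start/lower/upper are named lists; jitter multiplies starts by exp(N(0, 0.3)).
fit_with_restarts <- function(formula, data, start, lower,
                              upper = NULL, restarts = 10L, seed = 1L) {
  lo <- unlist(lower)
  hi <- if (is.null(upper)) rep(Inf, length(lo)) else unlist(upper)
  starts <- start
  for (i in seq_len(restarts + 1L)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = starts,
                        lower = lo, upper = hi,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
    jit <- withr_seed_jitter(unlist(start), seed + i)
    starts <- as.list(pmin(pmax(jit, lo * 1.0001 + 1e-12), hi))
  }
  stop("nonlinear fit failed to converge after ", restarts, " restarts")
}

withr_seed_jitter <- function(x, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x * exp(rnorm(length(x), 0, 0.3))
}

#' Fit a saturating nest-survival curve to observations
#'
#' Least-squares estimates of `(f_max, s_half)` for
#' `f(s) = f_max * s / (s_half + s)`. Starting values: `f_max` from the
#' largest observed survival, `s_half` from the smallest size whose
#' observation exceeds half of it; up to 10 jittered restarts.
#'
#' @param obs [vital_obs()] of kind `"survival"`, at least 3 observations at
#'   2 or more distinct patch sizes
#' @param seed seed for restart jitter (deterministic fits)
#' @return a [survival_curve()] with attribute `residual_ss`
#' @export
fit_survival_curve <- function(obs, seed = 1L) {
  obs <- obs[obs$kind == "survival", , drop = FALSE]
  if (nrow(obs) < 3L) stop("fit_survival_curve(): need >= 3 survival observations")
  if (length(unique(obs$patch_size_ha)) < 2L) {
    stop("fit_survival_curve(): observations at a single patch size are unidentifiable")
  }
  fmax0 <- max(obs$value)
  if (fmax0 <= 0) stop("fit_survival_curve(): all observations are zero")
  above <- obs$patch_size_ha[obs$value > fmax0 / 2]
  shalf0 <- if (length(above) > 0L) max(min(above), 1e-3) else median(obs$patch_size_ha)
  fit <- fit_with_restarts(
    value ~ f_max * patch_size_ha / (s_half + patch_size_ha),
    data = obs,
    start = list(f_max = min(fmax0, 1), s_half = shalf0),
    lower = list(f_max = 1e-8, s_half = 1e-8),
    upper = list(f_max = 1, s_half = Inf),
    seed = seed)
  p <- coef(fit)
  out <- survival_curve(f_max = unname(p["f_max"]), s_half = unname(p["s_half"]))
  attr(out, "residual_ss") <- sum(resid(fit)^2)
  out
}

#' Fit a sigmoid saturation-density curve to observations
#'
#' Least-squares estimates of `(l, alpha, t)` under the requested
#' orientation. Starting values: `l` from the smallest observed density,
#' `t` from the midpoint of the steepest observed change, `alpha` from the
#' logistic max-slope identity `alpha = 4 * max|slope| / (1 - l)`; up to 10
#' jittered restarts.
#'
#' @param obs [vital_obs()] of kind `"density"`, at least 4 observations
#'   spanning sizes on both sides of the apparent midpoint
#' @param orientation `"decreasing"` (default) or `"literal"`
#' @param seed seed for restart jitter
#' @return a [density_curve()] with attribute `residual_ss`
#' @export
fit_density_curve <- function(obs, orientation = c("decreasing", "literal"),
                              seed = 1L) {
  orientation <- match.arg(orientation)
  obs <- obs[obs$kind == "density", , drop = FALSE]
  if (nrow(obs) < 4L) stop("fit_density_curve(): need >= 4 density observations")
  if (length(unique(obs$patch_size_ha)) < 3L) {
    stop("fit_density_curve(): too few distinct patch sizes")
  }
  o <- obs[order(obs$patch_size_ha), ]
  l0 <- max(min(o$value), 1e-3)
  slopes <- diff(o$value) / diff(o$patch_size_ha)
  k <- which.max(abs(slopes))
  t0 <- (o$patch_size_ha[k] + o$patch_size_ha[k + 1L]) / 2
  # a logistic of amplitude (1 - l) has max |slope| = alpha * (1 - l) / 4
  a0 <- 4 * abs(slopes[k]) / max(1 - l0, 0.1)
  if (!is.finite(a0) || a0 <= 0) a0 <- 4 / diff(range(o$patch_size_ha))
  form <- if (orientation == "decreasing") {
    value ~ l + (1 - l) / (1 + exp(alpha * (patch_size_ha - t)))
  } else {
    value ~ 1 + (l - 1) / (1 + exp(alpha * (patch_size_ha - t)))
  }
  fit <- fit_with_restarts(
    form, data = o,
    start = list(l = min(l0, 0.99), alpha = a0, t = t0),
    lower = list(l = 1e-8, alpha = 1e-8, t = 1e-8),
    upper = list(l = 1 - 1e-8, alpha = Inf, t = Inf),
    seed = seed)
  p <- coef(fit)
  out <- density_curve(l = unname(p["l"]), alpha = unname(p["alpha"]),
                       t = unname(p["t"]), orientation = orientation)
  attr(out, "residual_ss") <- sum(resid(fit)^2)
  out
}
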