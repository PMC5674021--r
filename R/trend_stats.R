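# Trends, densities and the buffer-effect test.

#' Construct an abundance-index series
#'
#' @param landscape_id identifier
#' @param years strictly increasing integer years
#' @param index positive abundance index per year
#' @return data frame of class `index_series`
#' @export
index_series <- function(landscape_id, years, index) {
  stopifnot(length(years) == length(index))
  if (any(diff(years) <= 0)) stop("index_series(): years must be strictly increasing")
  if (any(index <= 0)) stop("index_series(): index values must be > 0")
  structure(data.frame(landscape_id = landscape_id, year = years,
                       index = index, stringsAsFactors = FALSE),
            class = c("index_series", "data.frame"))
}

#' Read abundance-index series from delimited text
#'
#' Expects columns `landscape_id`, `year`, `index`.
#' @param path file path
#' @return data frame with one row per landscape-year
#' @export
load_index_series <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("landscape_id", "year", "index")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0L) {
    stop("load_index_series(): missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(d$index <= 0)) stop("load_index_series(): index values must be > 0")
  d[order(d$landscape_id, d$year), req]
}

#' Average annual proportional change of an abundance index
#'
#' The default (`method = "geometric"`) is the compounding-consistent
#' endpoint change: `trend = (index(y1)/index(y0))^(1/(y1-y0)) - 1`, so a
#' trend of -0.02 means a 2 percent decline per year. The alternative
#' `"arithmetic"` method averages the year-on-year proportional changes
#' over the window.
#'
#' @param series data frame with `year` and `index` for one landscape
#' @param y0,y1 window endpoints (default 1987 and 1997, the decade around
#'   a 1992 snapshot)
#' @param method `"geometric"` (default) or `"arithmetic"`
#' @return one-row data frame: `landscape_id` (if present), `trend`,
#'   `magnitude`
#' @export
annual_trend <- function(series, y0 = 1987, y1 = 1997,
                         method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  stopifnot(y0 < y1)
  if (method == "geometric") {
    i0 <- series$index[series$year == y0]
    i1 <- series$index[series$year == y1]
    if (length(i0) != 1L || length(i1) != 1L) {
      stop("annual_trend(): window endpoint year missing from series")
    }
    tr <- (i1 / i0)^(1 / (y1 - y0)) - 1
  } else {
    w <- series[series$year >= y0 & series$year <= y1, ]
    w <- w[order(w$year), ]
    if (nrow(w) < 2L) stop("annual_trend(): need >= 2 years inside the window")
    steps <- diff(w$index) / w$index[-nrow(w)] / diff(w$year)
    tr <- mean(steps)
  }
  data.frame(
    landscape_id = if ("landscape_id" %in% names(series)) series$landscape_id[1L] else NA_character_,
    trend = tr, magnitude = abs(tr), stringsAsFactors = FALSE)
}

#' Breeding density from population size and forest area
#'
#' `density = population_size / 2 / forest_area_ha`: individuals are
#' converted to pairs and spread over the landscape's total forest.
#'
#' @param population_size number of individuals, >= 0
#' @param forest_area_ha total forest area (ha), > 0
#' @return breeding pairs per ha
#' @export
breeding_density <- function(population_size, forest_area_ha) {
  if (any(forest_area_ha <= 0)) stop("breeding_density(): forest area must be > 0")
  if (any(population_size < 0)) stop("breeding_density(): population size must be >= 0")
  population_size / 2 / forest_area_ha
}

#' Pearson correlation test
#'
#' Standard Pearson r with the two-sided t test on n - 2 degrees of
#' freedom, via [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length n >= 3 with non-zero variance
#' @return one-row data frame: `r`, `df`, `p`, `n`
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_test(): lengths differ")
  if (length(x) < 3L) stop("pearson_test(): need n >= 3")
  if (var(x) == 0 || var(y) == 0) {
    stop("pearson_test(): constant input; correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), df = unname(ct$parameter),
             p = ct$p.value, n = length(x))
}

#' Buffer / inverse buffer effect test
#'
#' Correlates trend magnitudes with landscape quality across landscapes. A
#' significant negative correlation of |trend| with Q (larger changes in
#' poorer landscapes) is the classic buffer effect; a significant positive
#' correlation (larger changes in better landscapes) is an inverse buffer
#' effect; a non-significant correlation is classified `"none"`.
#'
#' @param trends data frame with `landscape_id`, `trend`, `magnitude` (as
#'   from [annual_trend()])
#' @param qualities data frame with `landscape_id`, `Q`
#' @param alpha two-sided significance level (default 0.05)
#' @return list of class `buffer_test`: `classification` in
#'   `{"buffer", "inverse_buffer", "none"}`, `cor_trend_q` and
#'   `cor_magnitude_q` (both [pearson_test()] rows)
#' @export
buffer_effect_test <- function(trends, qualities, alpha = 0.05) {
  m <- merge(trends, qualities, by = "landscape_id")
  if (nrow(m) < 4L) stop("buffer_effect_test(): need >= 4 matched landscapes")
  ct_trend <- pearson_test(m$trend, m$Q)
  ct_mag <- pearson_test(m$magnitude, m$Q)
  classification <- if (ct_mag$p < alpha) {
    if (ct_mag$r > 0) "inverse_buffer" else "buffer"
  } else {
    "none"
  }
  structure(list(classification = classification,
                 cor_trend_q = ct_trend, cor_magnitude_q = ct_mag,
                 n = nrow(m)),
            class = "buffer_test")
}

#' @export
print.buffer_test <- function(x, ...) {
  cat(sprintf("Buffer-effect test (n = %d): %s\n", x$n, x$classification))
  cat(sprintf("  trend  vs Q: r = %+.3f (df = %d, p = %.3g)\n",
              x$cor_trend_q$r, x$cor_trend_q$df, x$cor_trend_q$p))
  cat(sprintf("  |trend| vs Q: r = %+.3f (df = %d, p = %.3g)\n",
              x$cor_magnitude_q$r, x$cor_magnitude_q$df, x$cor_magnitude_q$p))
  invisible(x)
}
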