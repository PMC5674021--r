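# Landscapes as binned patch-size distributions.
#
# Inventory-style inputs give, per county and size class, the number of
# forest patches and their summed area, both for all forest and for core
# forest (forest further than the edge-depth from any edge). All downstream
# computation needs only the per-class representative size s and total area
# A(s), so the landscape container stores exactly that.

#' Construct a patch-size distribution
#'
#' A patch-size distribution is the binned description of a landscape's
#' forest mosaic: one row per size class with a representative (mean) patch
#' size, a patch count and the total area in the class. Classes must be
#' strictly ordered by mean size. Classes with zero patches are retained --
#' they carry zero weight in every downstream sum but keep class bookkeeping
#' stable across landscapes.
#'
#' @param classes data frame with columns `class_label`, `mean_size_ha`,
#'   `n_patches`, `total_area_ha`. Counts may be non-integer when class
#'   counts have been rescaled to normalize total landscape area.
#' @return An object of class `patch_dist`: the class table plus the
#'   smallest (`sL`) and largest (`sU`) class mean sizes.
#' @examples
#' patch_dist(data.frame(
#'   class_label = c("C1", "C2"), mean_size_ha = c(10, 100),
#'   n_patches = c(5, 2), total_area_ha = c(50, 200)))
#' @export
patch_dist <- function(classes) {
  req <- c("class_label", "mean_size_ha", "n_patches", "total_area_ha")
  miss <- setdiff(req, names(classes))
  if (length(miss) > 0L) {
    stop("patch_dist(): missing column(s): ", paste(miss, collapse = ", "))
  }
  classes <- classes[order(classes$mean_size_ha), req, drop = FALSE]
  rownames(classes) <- NULL
  if (any(!is.finite(classes$mean_size_ha)) || any(classes$mean_size_ha <= 0)) {
    stop("patch_dist(): mean_size_ha must be finite and > 0")
  }
  if (any(diff(classes$mean_size_ha) <= 0)) {
    stop("patch_dist(): class mean sizes must be strictly increasing")
  }
  if (any(classes$n_patches < 0) || any(classes$total_area_ha < 0)) {
    stop("patch_dist(): counts and areas must be non-negative")
  }
  if (!any(classes$total_area_ha > 0)) {
    stop("patch_dist(): at least one class must have positive area")
  }
  structure(
    list(classes = classes,
         sL = classes$mean_size_ha[1L],
         sU = classes$mean_size_ha[nrow(classes)]),
    class = "patch_dist")
}

#' @export
print.patch_dist <- function(x, ...) {
  cat(sprintf("Patch-size distribution: %d classes, s in [%.3g, %.3g] ha, total %.4g ha\n",
              nrow(x$classes), x$sL, x$sU, sum(x$classes$total_area_ha)))
  print(x$classes)
  invisible(x)
}

#' Total forest area of a patch-size distribution
#' @param dist a [patch_dist()] object
#' @return total area (ha) summed over classes
#' @export
total_area <- function(dist) {
  stopifnot(inherits(dist, "patch_dist"))
  sum(dist$classes$total_area_ha)
}

#' Construct a landscape
#'
#' A landscape couples the all-forest and core-forest patch-size
#' distributions and carries the derived landscape quality
#' `Q = core area / total forest area`.
#'
#' @param id landscape identifier (e.g. a state code)
#' @param forest [patch_dist()] for all forest
#' @param core [patch_dist()] for core forest (forest beyond the edge-depth
#'   buffer), or `NULL` when only the core total area is known
#' @param core_total_ha core forest area; defaults to `total_area(core)`
#' @return An object of class `landscape` with fields `id`, `forest`,
#'   `core`, `quality`.
#' @export
landscape <- function(id, forest, core = NULL,
                      core_total_ha = if (!is.null(core)) total_area(core) else NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, inherits(forest, "patch_dist"))
  if (!is.null(core)) stopifnot(inherits(core, "patch_dist"))
  q <- landscape_quality(core_total_ha, total_area(forest))
  structure(list(id = id, forest = forest, core = core, quality = q),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Landscape %s: %.4g ha forest in %d classes, Q = %.3f (%s)\n",
              x$id, total_area(x$forest), nrow(x$forest$classes),
              x$quality, classify_quality(x$quality)))
  invisible(x)
}

#' Read a county-level patch-class table
#'
#' Reads delimited text (comma-separated, header row) holding per-county,
#' per-size-class patch counts and areas for one or more landscapes, in the
#' layout of forest-inventory landscape studies. Required columns:
#' `landscape_id`, `county`, `class_label`, `n_patches`, `total_area_ha`,
#' `forest_type` (`"total"` or `"core"`). `mean_size_ha` is optional and is
#' used as the nominal class size for classes that are empty everywhere.
#'
#' @param path path to the file
#' @return data frame of records, one per input row, with a logical `empty`
#'   column flagging rows with zero patches and zero area
#' @examples
#' f <- system.file("extdata", "patch_table_example.csv", package = "fragdd")
#' recs <- load_patch_table(f)
#' north <- landscape("NORTH",
#'                    aggregate_counties(recs, "NORTH", "total"),
#'                    aggregate_counties(recs, "NORTH", "core"))
#' north
#' @export
load_patch_table <- function(path) {
  if (!file.exists(path)) stop("load_patch_table(): file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("landscape_id", "county", "class_label", "n_patches",
           "total_area_ha", "forest_type")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0L) {
    stop("load_patch_table(): missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"mean_size_ha" %in% names(d)) d$mean_size_ha <- NA_real_
  bad <- which(d$n_patches < 0 | d$total_area_ha < 0)
  if (length(bad) > 0L) {
    stop("load_patch_table(): negative count or area at row(s) ",
         paste(bad, collapse = ", "))
  }
  if (!all(d$forest_type %in% c("total", "core"))) {
    stop("load_patch_table(): forest_type must be 'total' or 'core'")
  }
  d$empty <- d$n_patches == 0 & d$total_area_ha == 0
  d
}

#' Aggregate county records into a landscape-level distribution
#'
#' Pools county rows of one landscape and forest type into a single
#' patch-size distribution. Within each class, counts and areas are summed
#' and the landscape-level class mean is `sum(area) / sum(count)` -- the
#' patch-count-weighted mean implied by assuming equal patch areas within a
#' county/class cell. Classes empty in every county keep zero weight and
#' take their nominal size from `midpoints` (or the `mean_size_ha` column).
#'
#' @param records data frame as returned by [load_patch_table()]
#' @param landscape_id landscape to aggregate
#' @param forest_type `"total"` or `"core"`
#' @param midpoints optional named numeric vector of nominal class sizes,
#'   names matching `class_label`, used for all-empty classes
#' @return a [patch_dist()] object
#' @export
aggregate_counties <- function(records, landscape_id, forest_type = "total",
                               midpoints = NULL) {
  r <- records[records$landscape_id == landscape_id &
                 records$forest_type == forest_type, , drop = FALSE]
  if (nrow(r) == 0L) {
    stop("aggregate_counties(): no records for landscape ", landscape_id,
         " (", forest_type, ")")
  }
  schemes <- tapply(r$class_label, r$county,
                    function(x) paste(sort(unique(x)), collapse = "|"))
  if (length(unique(schemes)) > 1L) {
    stop("aggregate_counties(): counties use conflicting class-label schemes")
  }
  agg_n <- tapply(r$n_patches, r$class_label, sum)
  agg_a <- tapply(r$total_area_ha, r$class_label, sum)
  labs <- names(agg_n)
  mean_sz <- ifelse(agg_n > 0, agg_a / agg_n, NA_real_)
  for (i in which(is.na(mean_sz))) {
    lab <- labs[i]
    if (!is.null(midpoints) && lab %in% names(midpoints)) {
      mean_sz[i] <- midpoints[[lab]]
    } else {
      m <- r$mean_size_ha[r$class_label == lab]
      m <- m[!is.na(m)]
      if (length(m) > 0L) mean_sz[i] <- mean(m)
    }
  }
  keep <- !is.na(mean_sz)
  if (any(!keep)) {
    warning("aggregate_counties(): dropping empty class(es) with no nominal size: ",
            paste(labs[!keep], collapse = ", "))
  }
  patch_dist(data.frame(
    class_label = labs[keep],
    mean_size_ha = as.numeric(mean_sz[keep]),
    n_patches = as.numeric(agg_n[keep]),
    total_area_ha = as.numeric(agg_a[keep]),
    stringsAsFactors = FALSE))
}

#' Landscape quality
#'
#' Quality is the ratio of core forest area to total forest area,
#' `Q = core / total`, a dimensionless measure of (un)fragmentation:
#' heavily fragmented landscapes have little interior forest and low Q.
#'
#' @param core_total_ha core forest area (ha)
#' @param forest_total_ha total forest area (ha), must be > 0
#' @return Q in \[0, 1\]
#' @examples
#' landscape_quality(70, 100) # 0.7
#' @export
landscape_quality <- function(core_total_ha, forest_total_ha) {
  if (any(!is.finite(forest_total_ha)) || any(forest_total_ha <= 0)) {
    stop("landscape_quality(): total forest area must be > 0")
  }
  if (any(is.na(core_total_ha)) || any(core_total_ha < 0)) {
    stop("landscape_quality(): core area must be >= 0")
  }
  if (any(core_total_ha > forest_total_ha)) {
    stop("landscape_quality(): core area exceeds total forest area")
  }
  core_total_ha / forest_total_ha
}

#' Classify landscape quality
#'
#' Three-way partition of Q: good for `Q > 0.7`, moderate for
#' `0.6 <= Q <= 0.7`, poor for `Q < 0.6`.
#'
#' @param Q quality ratio(s) in \[0, 1\]
#' @return character vector in `{"good", "moderate", "poor"}`
#' @export
classify_quality <- function(Q) {
  if (any(!is.finite(Q)) || any(Q < 0) || any(Q > 1)) {
    stop("classify_quality(): Q must lie in [0, 1]")
  }
  ifelse(Q > 0.7, "good", ifelse(Q >= 0.6, "moderate", "poor"))
}

#' Summarize a set of landscapes
#'
#' @param landscapes list of [landscape()] objects
#' @return data frame with one row per landscape: id, number of classes,
#'   total and core forest area, Q and quality class
#' @export
landscape_summary <- function(landscapes) {
  do.call(rbind, lapply(landscapes, function(l) {
    ft <- total_area(l$forest)
    data.frame(
      landscape_id = l$id,
      n_classes = nrow(l$forest$classes),
      forest_total_ha = ft,
      core_total_ha = l$quality * ft,
      Q = l$quality,
      quality_class = classify_quality(l$quality),
      stringsAsFactors = FALSE)
  }))
}
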