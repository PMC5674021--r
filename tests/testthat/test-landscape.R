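test_that("patch tables are read and validated", {
  d <- data.frame(
    landscape_id = "A", county = c("c1", "c1", "c1"),
    class_label = c("C1", "C2", "C3"), mean_size_ha = c(3, 7.5, 50),
    n_patches = c(10, 4, 0), total_area_ha = c(30, 30, 0),
    forest_type = "total")
  f <- write_tmp_csv(d)
  recs <- load_patch_table(f)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$empty, c(FALSE, FALSE, TRUE))

  bad <- d
  bad$n_patches[2] <- -1
  expect_error(load_patch_table(write_tmp_csv(bad)), "row")

  expect_error(load_patch_table(write_tmp_csv(d[, -7])), "forest_type")
  expect_error(load_patch_table(write_tmp_csv(d[, setdiff(names(d), "total_area_ha")])),
               "total_area_ha")
})

test_that("county aggregation pools counts and areas and conserves totals", {
  recs <- data.frame(
    landscape_id = "A",
    county = c("c1", "c2", "c1", "c2"),
    class_label = c("C1", "C1", "C2", "C2"),
    mean_size_ha = NA_real_,
    n_patches = c(10, 30, 2, 1),
    total_area_ha = c(50, 250, 300, 180),
    forest_type = "total", empty = FALSE)
  dist <- aggregate_counties(recs, "A")
  c1 <- dist$classes[dist$classes$class_label == "C1", ]
  expect_equal(c1$n_patches, 40)
  expect_equal(c1$total_area_ha, 300)
  expect_equal(c1$mean_size_ha, 7.5) # Sum(area)/Sum(count) across counties
  expect_equal(sum(dist$classes$total_area_ha), sum(recs$total_area_ha))
  expect_equal(sum(dist$classes$n_patches), sum(recs$n_patches))
})

test_that("all-empty classes keep zero weight and a nominal midpoint size", {
  recs <- data.frame(
    landscape_id = "A", county = "c1",
    class_label = c("C1", "C8"), mean_size_ha = c(NA, 750),
    n_patches = c(10, 0), total_area_ha = c(50, 0),
    forest_type = "total", empty = c(FALSE, TRUE))
  dist <- aggregate_counties(recs, "A")
  c8 <- dist$classes[dist$classes$class_label == "C8", ]
  expect_equal(c8$total_area_ha, 0)
  expect_equal(c8$mean_size_ha, 750)
  # and the empty class contributes no point to the occupancy series
  # (leaving a single class, which the curve flags)
  expect_warning(series <- occupancy_curve(dist, landscape_id = "A"),
                 "one-point")
  expect_equal(nrow(series), 1L)

  mid <- aggregate_counties(recs[1, ], "A", midpoints = c(C1 = 3))
  expect_equal(mid$classes$mean_size_ha, 5) # observed mean wins when n > 0
  expect_error(
    aggregate_counties(
      rbind(recs,
            transform(recs[1, ], county = "c2", class_label = "X1")), "A"),
    "class-label schemes")
})

test_that("landscape quality is the core-to-total ratio with hard bounds", {
  expect_equal(landscape_quality(70, 100), 0.7)
  expect_equal(landscape_quality(0, 100), 0)
  expect_equal(landscape_quality(100, 100), 1)
  # scale invariance
  q <- runif(20, 0, 1)
  tot <- runif(20, 10, 1e4)
  expect_equal(landscape_quality(q * tot, tot),
               landscape_quality(q * tot * 7.3, tot * 7.3))
  expect_error(landscape_quality(10, 0), "> 0")
  expect_error(landscape_quality(101, 100), "exceeds")
})

test_that("quality classification partitions [0,1] with 0.7 in moderate", {
  expect_equal(classify_quality(0.75), "good")
  expect_equal(classify_quality(0.7), "moderate")
  expect_equal(classify_quality(0.6), "moderate")
  expect_equal(classify_quality(0.59), "poor")
  # total order-preserving partition
  qs <- seq(0, 1, by = 0.01)
  cls <- classify_quality(qs)
  expect_true(all(cls %in% c("poor", "moderate", "good")))
  rank <- c(poor = 1, moderate = 2, good = 3)[cls]
  expect_true(all(diff(rank) >= 0))
  expect_error(classify_quality(1.2), "0, 1")
})

test_that("the shipped example table aggregates into two landscapes", {
  f <- system.file("extdata", "patch_table_example.csv", package = "fragdd")
  recs <- load_patch_table(f)
  north <- landscape("NORTH", aggregate_counties(recs, "NORTH", "total"),
                     aggregate_counties(recs, "NORTH", "core"))
  south <- landscape("SOUTH", aggregate_counties(recs, "SOUTH", "total"),
                     aggregate_counties(recs, "SOUTH", "core"))
  # county pooling: C1 mean = (360 + 200) / (120 + 80)
  c1 <- north$forest$classes[north$forest$classes$class_label == "C1", ]
  expect_equal(c1$mean_size_ha, 560 / 200)
  expect_equal(north$quality, sum(recs$total_area_ha[
    recs$landscape_id == "NORTH" & recs$forest_type == "core"]) / 4710)
  # the big-patch landscape is less fragmented
  expect_gt(north$quality, south$quality)
  # empty C4 class in the south keeps zero weight
  s4 <- south$forest$classes[south$forest$classes$class_label == "C4", ]
  expect_equal(s4$total_area_ha, 0)
  expect_equal(s4$mean_size_ha, 300)
})

test_that("landscape objects and summaries carry Q consistently", {
  l <- landscape("A", toy_dist(), core_total_ha = 175)
  expect_equal(l$quality, 0.7)
  s <- landscape_summary(list(l))
  expect_equal(s$forest_total_ha, 250)
  expect_equal(s$core_total_ha, 175)
  expect_equal(s$quality_class, "moderate")
})
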