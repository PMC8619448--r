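# Crown boxes, canopy counting, and the three-class size rules.

make_img <- function(nr, nc, res = 0.5)
  parcel_image(array(0.5, dim = c(nr, nc, 4L)), resolution = res)

make_grid <- function(centers) {
  pos <- data.frame(tree_id = seq_len(nrow(centers)),
                    row_index = 0L, tree_index = seq_len(nrow(centers)) - 1L,
                    px_row = centers[, 1L], px_col = centers[, 2L])
  structure(list(positions = pos, n_rows = 1L,
                 trees_per_row = c(`0` = nrow(centers))),
            class = "tree_grid")
}

test_that("3 m boxes at 2 m spacing overlap by 2 pixels (1 m)", {
  img <- make_img(30, 30)
  grid <- make_grid(rbind(c(15, 10), c(15, 14)))  # in-row neighbors, 4 px
  boxes <- build_boxes(grid, 3, img)
  expect_identical(attr(boxes, "box_side"), 6L)
  expect_true(all(boxes$r1 - boxes$r0 == 6L & boxes$c1 - boxes$c0 == 6L))
  overlap_cols <- boxes$c1[1] - boxes$c0[2]
  expect_identical(overlap_cols, 2L)            # = 1 m at 0.5 m GSD
  expect_equal(overlap_cols * img$resolution, 1.0)
})

test_that("boxes clip at edges and survive degenerate rasters", {
  img <- make_img(20, 20)
  corner <- build_boxes(make_grid(rbind(c(0, 0))), 3, img)
  expect_identical(c(corner$r0, corner$r1, corner$c0, corner$c1),
                   c(0L, 3L, 0L, 3L))
  expect_lt((corner$r1 - corner$r0) * (corner$c1 - corner$c0), 36)
  one <- build_boxes(make_grid(rbind(c(0, 0))), 3, make_img(1, 1))
  expect_identical(c(one$r1 - one$r0, one$c1 - one$c0), c(1L, 1L))
  expect_error(build_boxes(make_grid(rbind(c(0, 0))), -1, img), "> 0")
})

test_that("canopy counts match a brute-force recount", {
  img <- make_img(25, 25)
  grid <- make_grid(rbind(c(12, 6), c(12, 10), c(12, 14)))
  boxes <- build_boxes(grid, 3, img)
  ones <- canopy_mask(matrix(1L, 25, 25))
  expect_true(all(count_canopy(ones, boxes)$canopy_pixels == 36L))
  zeros <- canopy_mask(matrix(0L, 25, 25))
  expect_true(all(count_canopy(zeros, boxes)$canopy_pixels == 0L))
  # random scenes vs the double-loop oracle
  for (s in 1:5) {
    truth <- generate_orchard(tiny_scenario(seed = s))
    counted <- count_canopy(truth$canopy_truth, truth$boxes[
      , setdiff(names(truth$boxes), c("canopy_pixels", "canopy_m2"))])
    oracle <- vapply(seq_len(nrow(counted)), function(b)
      recount_box(truth$canopy_truth$mask, counted$r0[b], counted$r1[b],
                  counted$c0[b], counted$c1[b]), integer(1L))
    expect_identical(counted$canopy_pixels, oracle)
  }
})

test_that("threshold formulas follow min + avg/5 and max - avg/5", {
  th <- compute_thresholds(c(0, 20, 36, 24))
  expect_equal(th$min_value, 0)
  expect_equal(th$avg_value, 20)
  expect_equal(th$max_value, 36)
  b <- threshold_bounds(th)
  expect_equal(unname(b["t1"]), 4)
  expect_equal(unname(b["t2"]), 32)
  expect_warning(single <- compute_thresholds(15), "degenerate")
  expect_true(single$min_value == 15 && single$avg_value == 15 &&
              single$max_value == 15)
  expect_error(compute_thresholds(numeric(0)), "empty")
})

test_that("equal counts give the degenerate t1 > t2 case, resolved by order", {
  expect_warning(th <- compute_thresholds(c(10, 10, 10)), "degenerate")
  b <- threshold_bounds(th)
  expect_gt(b["t1"], 10)
  expect_lt(b["t2"], 10)
  expect_identical(as.integer(classify_tree(10, th)), 1L)
})

test_that("classes follow the half-open interval rules", {
  th <- compute_thresholds(c(0, 20, 36, 24))
  expect_identical(as.integer(classify_tree(0, th)), 1L)
  expect_identical(as.integer(classify_tree(24, th)), 2L)
  expect_identical(as.integer(classify_tree(36, th)), 3L)
  expect_identical(as.integer(classify_tree(4, th)), 2L)   # count == t1
  expect_identical(as.integer(classify_tree(32, th)), 3L)  # count == t2
  expect_error(classify_tree(37, th), "outside")
  expect_error(classify_tree(-1, th), "outside")
})

test_that("classes partition the count range and are monotone", {
  set.seed(31)
  for (rep in 1:20) {
    counts <- sample(0:200, 30, replace = TRUE)
    th <- suppressWarnings(compute_thresholds(counts))
    cls <- suppressWarnings(as.integer(classify_tree(counts, th)))
    expect_true(all(cls %in% 1:3))
    expect_identical(length(cls), length(counts))
    # monotone in count
    o <- order(counts)
    expect_true(all(diff(cls[o]) >= 0L))
    # every integer count in [min, max] gets exactly one class
    rng <- seq(min(counts), max(counts))
    all_cls <- suppressWarnings(as.integer(classify_tree(rng, th)))
    expect_identical(sum(table(all_cls)), length(rng))
  }
})

test_that("class assignments are invariant to count rescaling", {
  counts <- c(3, 18, 44, 80, 101)
  th <- compute_thresholds(counts)
  cls <- classify_tree(counts, th)
  for (alpha in c(0.5, 2, 13.7)) {
    th2 <- compute_thresholds(counts * alpha)
    expect_equal(th2$min_value, th$min_value * alpha)
    expect_equal(th2$avg_value, th$avg_value * alpha)
    expect_equal(th2$max_value, th$max_value * alpha)
    expect_equal(threshold_bounds(th2), threshold_bounds(th) * alpha)
    expect_identical(classify_tree(counts * alpha, th2), cls)
  }
})

test_that("planted size strata separated beyond avg/5 are recovered exactly", {
  sc <- tiny_scenario(seed = 6, n_rows = 4L, trees_per_row = 8L,
                      noise_sd = 0, p_missing = 0,
                      crown_law = list(type = "strata",
                                       diameters = c(1.0, 2.2, 3.0)))
  truth <- generate_orchard(sc)
  expect_identical(length(unique(truth$true_classes)), 3L)
  # segmentation-based counts reproduce the truth classes exactly
  labels <- segment_kmeans(truth$image, k = 2)
  veg <- identify_vegetation_cluster(labels, truth$image)
  mask <- to_canopy_mask(labels, veg)
  res <- classify_trees(truth$grid, build_boxes(truth$grid, 3, truth$image),
                        mask, truth$image)
  expect_identical(res$table$class, truth$true_classes)
  expect_equal(res$table$canopy_m2,
               res$table$canopy_pixels * truth$image$resolution^2)
})
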