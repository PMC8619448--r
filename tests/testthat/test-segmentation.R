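# k-means canopy masking and the Otsu thresholding baseline.

test_that("k-means separates two well-separated interleaved populations", {
  tp <- two_population_image()
  labels <- segment_kmeans(tp$img, k = 2)
  # labels must match the generating population exactly (up to label swap)
  agree <- mean((labels$labels == 1L) == (tp$pop == 0L))
  expect_true(agree == 1 || agree == 0)
})

test_that("degenerate cluster counts behave as specified", {
  const <- parcel_image(array(0.3, dim = c(4, 4, 3)), resolution = 1)
  lab <- segment_kmeans(const, k = 1)
  expect_true(all(lab$labels == 1L))
  expect_error(segment_kmeans(const, k = 2), "distinct")
  empty <- parcel_image(array(0.3, dim = c(4, 4, 3)), resolution = 1,
                        nodata_mask = matrix(TRUE, 4, 4))
  expect_error(segment_kmeans(empty, k = 1), "empty parcel")
})

test_that("k = 3 on a noise-free scene recovers the three strata", {
  truth <- generate_orchard(tiny_scenario(seed = 2, noise_sd = 0))
  # untagged load: clipped background stays a pixel population, as when the
  # parcel raster carries black outside-parcel pixels instead of a mask
  img <- truth$image
  img$nodata_mask <- matrix(FALSE, nrow(img$nodata_mask),
                            ncol(img$nodata_mask))
  labels <- segment_kmeans(img, k = 3)
  # each stratum (0 bg, 1 soil, 2 veg) maps to exactly one cluster
  tab <- table(truth$strata, labels$labels)
  expect_true(all(rowSums(tab > 0) == 1L))
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.99)
  veg <- identify_vegetation_cluster(labels, img)
  bg <- infer_background_cluster(labels, img)
  expect_identical(sort(unique(labels$labels[truth$strata == 2L])), veg)
  expect_identical(sort(unique(labels$labels[truth$strata == 0L])), bg)
  # canopy mask equals the generator's crown raster
  mask <- to_canopy_mask(labels, veg,
                         !is.na(labels$labels) & labels$labels == bg)
  expect_identical(mask$mask, truth$canopy_truth$mask)
})

test_that("same seed gives bit-identical labels and a fixed point", {
  truth <- generate_orchard(tiny_scenario(seed = 3, noise_sd = 0.03))
  l1 <- segment_kmeans(truth$image, k = 2, seed = 99)
  l2 <- segment_kmeans(truth$image, k = 2, seed = 99)
  expect_identical(l1$labels, l2$labels)
  # final assignment is a fixed point: nearest-center reassignment is a no-op
  x <- orchardcrowns:::pixel_matrix(truth$image)
  d <- vapply(seq_len(l1$k), function(j)
    rowSums(sweep(x, 2L, l1$centers[j, ])^2), numeric(nrow(x)))
  expect_identical(max.col(-d, ties.method = "first"),
                   as.integer(l1$labels[!truth$image$nodata_mask]))
})

test_that("high spectral separation yields near-perfect masks", {
  # minimum per-band vegetation/soil contrast is 0.12; 5 noise SDs -> 0.024
  for (s in 1:3) {
    truth <- generate_orchard(tiny_scenario(seed = s, noise_sd = 0.024))
    labels <- segment_kmeans(truth$image, k = 2, seed = s)
    veg <- identify_vegetation_cluster(labels, truth$image)
    sc <- score_segmentation(to_canopy_mask(labels, veg), truth$canopy_truth)
    expect_gte(sc$precision, 0.99)
    expect_gte(sc$recall, 0.99)
  }
})

test_that("vegetation cluster choice uses NDVI, greenness, and id ties", {
  # NIR >> red marks vegetation regardless of brightness
  truth <- generate_orchard(tiny_scenario(seed = 4, noise_sd = 0))
  labels <- segment_kmeans(truth$image, k = 2)
  veg <- identify_vegetation_cluster(labels, truth$image)
  expect_identical(unique(labels$labels[truth$strata == 2L]), veg)
  # RGB-only scene: greenest cluster wins
  bm <- rbind(vegetation = c(blue = 0.08, green = 0.35, red = 0.10),
              soil = c(blue = 0.25, green = 0.22, red = 0.28))
  truth3 <- generate_orchard(tiny_scenario(seed = 4, noise_sd = 0,
                                           band_means = bm))
  lab3 <- segment_kmeans(truth3$image, k = 2)
  veg3 <- identify_vegetation_cluster(lab3, truth3$image)
  expect_identical(unique(lab3$labels[truth3$strata == 2L]), veg3)
  # identical mean NDVI in both clusters -> lower cluster id
  bands <- array(0.2, dim = c(4, 4, 4))
  bands[, , 4] <- 0.4      # uniform NDVI everywhere
  bands[, 1:2, 1] <- 0.35  # two spectral groups distinguished by blue only
  img <- parcel_image(bands, resolution = 1)
  lab <- segment_kmeans(img, k = 2)
  expect_identical(identify_vegetation_cluster(lab, img), 1L)
})

test_that("to_canopy_mask applies the vegetation-cluster and nodata rules", {
  labels <- structure(list(labels = matrix(c(1L, 1L, 2L, 2L), 2, 2), k = 2L,
                           centers = matrix(0.5, 2, 4)),
                      class = "cluster_labels")
  all1 <- to_canopy_mask(labels, 1L, matrix(FALSE, 2, 2))
  expect_identical(all1$mask, matrix(c(1L, 1L, 0L, 0L), 2, 2))
  none <- to_canopy_mask(labels, 2L, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_identical(sum(none$mask), 0L)
  expect_error(to_canopy_mask(labels, 3L), "1..k")
})

test_that("Otsu threshold separates a two-value histogram exactly", {
  v <- c(rep(0.2, 40), rep(0.7, 25))
  th <- orchardcrowns:::otsu_threshold(v)
  expect_true(th > 0.2 && th < 0.7)
  # any cut between the modes is exact; the midpoint is the documented choice
  expect_equal(th, 0.45)
  const <- parcel_image(array(0.4, dim = c(4, 4, 3)), resolution = 1)
  expect_warning(m <- segment_threshold(const), "constant")
  expect_identical(sum(m$mask), 0L)
})

test_that("Otsu agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(8)
  v <- c(rnorm(400, 0.3, 0.05), rnorm(200, 0.7, 0.05))
  v <- pmin(pmax(v, 0), 1)
  ours <- orchardcrowns:::otsu_threshold(v)
  ref <- EBImage::otsu(EBImage::Image(matrix(v, 30, 20)), range = c(0, 1),
                       levels = 256L)
  expect_equal(ours, ref, tolerance = 2 / 256)
})

test_that("thresholding underperforms k-means at high soil variance", {
  f1k <- f1t <- numeric(0)
  for (s in 1:3) {
    truth <- generate_orchard(
      tiny_scenario(seed = s, n_rows = 6L, trees_per_row = 10L,
                    noise_sd = c(vegetation = 0.02, soil = 0.1)))
    labels <- segment_kmeans(truth$image, k = 2, seed = s)
    veg <- identify_vegetation_cluster(labels, truth$image)
    f1k <- c(f1k, score_segmentation(to_canopy_mask(labels, veg),
                                     truth$canopy_truth)$f1)
    f1t <- c(f1t, score_segmentation(segment_threshold(truth$image),
                                     truth$canopy_truth)$f1)
  }
  expect_true(mean(f1t) < mean(f1k))
})
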