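# Canopy masking: k-means clustering of pixel spectra, with an Otsu
# thresholding baseline.

#' Binary canopy mask
#'
#' @param mask integer matrix in {0, 1}: 1 = tree canopy, 0 = soil.
#' @param nodata_mask logical matrix flagging outside-parcel pixels; the mask
#'   is forced to 0 there.
#' @return an object of class `canopy_mask`.
#' @export
canopy_mask <- function(mask, nodata_mask = NULL) {
  stopifnot(is.matrix(mask))
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!all(mask %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nrow(mask), ncol(mask))
  stopifnot(identical(dim(mask), dim(nodata_mask)), is.logical(nodata_mask))
  mask[nodata_mask] <- 0L
  structure(list(mask = mask, nodata_mask = nodata_mask),
            class = "canopy_mask")
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat("canopy_mask: ", nrow(x$mask), " x ", ncol(x$mask), " pixels; canopy ",
      sum(x$mask), ", nodata ", sum(x$nodata_mask), "\n", sep = "")
  invisible(x)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pixel spectra of non-nodata pixels as an n x bands matrix
pixel_matrix <- function(img) {
  keep <- !img$nodata_mask
  nb <- dim(img$bands)[3L]
  x <- matrix(NA_real_, sum(keep), nb)
  for (b in seq_len(nb)) x[, b] <- img$bands[, , b][keep]
  colnames(x) <- img$band_names
  x
}

# k-means++ seeding (squared-distance-proportional sampling)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[j + 1L, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j + 1L, ])^2))
  }
  centers
}

#' Cluster pixel spectra with k-means
#'
#' Partitions all non-nodata pixels into `k` spectral clusters by k-means
#' over the band vectors (Euclidean distance, Lloyd iterations, k-means++
#' seeding). With `k = 3` on imagery whose outside-parcel background is
#' clipped to a constant value, the three clusters recover trees, soil, and
#' background; when the background is carried as a nodata mask instead, it is
#' excluded from clustering entirely.
#'
#' @param img a [parcel_image()].
#' @param k number of clusters (default 3).
#' @param seed RNG seed for the k-means++ initialization; fixed default so
#'   repeated runs are identical.
#' @param standardize z-score each band before clustering (default `FALSE`:
#'   bands share one radiometric scale).
#' @param iter_max maximum Lloyd iterations.
#' @param nstart number of k-means++ restarts; the solution with the lowest
#'   within-cluster sum of squares is kept. Restarts guard against the local
#'   optimum where two tight strata share a cluster while a diffuse stratum
#'   is split.
#' @return an object of class `cluster_labels`: `labels` integer matrix with
#'   cluster ids 1..k (`NA` at nodata), `k`, `centers` (k x bands matrix, on
#'   the original band scale), `tot_withinss`.
#' @export
segment_kmeans <- function(img, k = 3L, seed = 20210241L,
                           standardize = FALSE, iter_max = 300L,
                           nstart = 10L) {
  stopifnot(inherits(img, "parcel_image"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  keep <- !img$nodata_mask
  if (!any(keep)) stop("empty parcel: all pixels are nodata")
  x <- pixel_matrix(img)
  n_distinct <- nrow(unique(x))
  if (n_distinct < k)
    stop("only ", n_distinct, " distinct spectral vector(s) for k = ", k,
         " clusters")
  xs <- x
  if (standardize) {
    mu <- colMeans(xs); sd <- apply(xs, 2L, stats::sd)
    sd[sd == 0] <- 1
    xs <- sweep(sweep(xs, 2L, mu), 2L, sd, "/")
  }
  fit <- with_seed(seed, {
    if (k == 1L) {
      list(cluster = rep(1L, nrow(xs)), centers = matrix(colMeans(xs), 1L),
           tot.withinss = sum(sweep(xs, 2L, colMeans(xs))^2))
    } else {
      best <- NULL
      for (r in seq_len(max(1L, nstart))) {
        centers0 <- kmeanspp_centers(xs, k)
        f <- suppressWarnings(
          stats::kmeans(xs, centers = centers0, iter.max = iter_max,
                        algorithm = "Lloyd"))
        if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
      }
      best
    }
  })
  labels <- matrix(NA_integer_, nrow(img$nodata_mask), ncol(img$nodata_mask))
  labels[keep] <- fit$cluster
  centers <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, colnames(x)))
  for (j in seq_len(k)) centers[j, ] <- colMeans(x[fit$cluster == j, , drop = FALSE])
  structure(list(labels = labels, k = k, centers = centers,
                 tot_withinss = fit$tot.withinss),
            class = "cluster_labels")
}

# mean vegetation score per cluster: NDVI when a NIR band exists, otherwise
# the green-band mean
cluster_veg_scores <- function(labels, img, eps = 1e-9) {
  nb <- img$band_names
  score_raster <- if (img$has_nir && "red" %in% nb) {
    nir <- img$bands[, , match("nir", nb)]
    red <- img$bands[, , match("red", nb)]
    (nir - red) / (nir + red + eps)
  } else if ("green" %in% nb) {
    img$bands[, , match("green", nb)]
  } else {
    img$bands[, , min(2L, length(nb))]
  }
  vapply(seq_len(labels$k), function(j) {
    v <- score_raster[!is.na(labels$labels) & labels$labels == j]
    if (length(v) == 0L) -Inf else mean(v)
  }, numeric(1L))
}

#' Identify the vegetation (tree) cluster
#'
#' Ranks clusters by mean NDVI = (NIR - red) / (NIR + red + eps) when a NIR
#' band is present, otherwise by mean green-band value, and returns the
#' highest-scoring cluster. Ties break to the lower cluster id.
#'
#' @param labels a `cluster_labels` from [segment_kmeans()].
#' @param img the [parcel_image()] that was clustered.
#' @return integer cluster id in 1..k.
#' @export
identify_vegetation_cluster <- function(labels, img) {
  stopifnot(inherits(labels, "cluster_labels"), inherits(img, "parcel_image"))
  scores <- cluster_veg_scores(labels, img)
  if (all(!is.finite(scores))) stop("all clusters are empty")
  which.max(scores)  # which.max takes the first (lowest id) on ties
}

#' Identify the background cluster of an unmasked raster
#'
#' For rasters where the outside-parcel area is clipped to a constant (no
#' nodata tag), the background is the cluster with lowest overall brightness
#' (mean over bands) among those touching the raster border.
#'
#' @param labels a `cluster_labels` from [segment_kmeans()].
#' @param img the clustered [parcel_image()].
#' @return integer cluster id, or `NA` if no cluster touches the border.
#' @export
infer_background_cluster <- function(labels, img) {
  stopifnot(inherits(labels, "cluster_labels"))
  lab <- labels$labels
  border <- unique(stats::na.omit(c(lab[1L, ], lab[nrow(lab), ],
                                    lab[, 1L], lab[, ncol(lab)])))
  if (length(border) == 0L) return(NA_integer_)
  brightness <- rowMeans(labels$centers)
  border[which.min(brightness[border])]
}

#' Binary canopy mask from cluster labels
#'
#' @param labels a `cluster_labels` from [segment_kmeans()].
#' @param veg_cluster cluster id to treat as canopy (from
#'   [identify_vegetation_cluster()]).
#' @param nodata_mask logical matrix of outside-parcel pixels; defaults to
#'   the unlabeled (NA) pixels.
#' @return a [canopy_mask()]: 1 where the label equals `veg_cluster` and the
#'   pixel is inside the parcel, 0 elsewhere.
#' @export
to_canopy_mask <- function(labels, veg_cluster, nodata_mask = NULL) {
  stopifnot(inherits(labels, "cluster_labels"))
  if (!(veg_cluster %in% seq_len(labels$k)))
    stop("veg_cluster must be in 1..k")
  if (is.null(nodata_mask)) nodata_mask <- is.na(labels$labels)
  m <- !is.na(labels$labels) & labels$labels == veg_cluster & !nodata_mask
  canopy_mask(matrix(as.integer(m), nrow(m), ncol(m)), nodata_mask)
}

# Otsu threshold: maximize between-class variance. Candidates are midpoints
# between consecutive sorted unique values (exact for few-valued histograms);
# above `max_exact` unique values a 256-bin histogram is used.
otsu_threshold <- function(v, max_exact = 2048L) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(NA_real_)
  cand <- if (length(u) <= max_exact) (u[-1L] + u[-length(u)]) / 2
          else {
            br <- seq(min(v), max(v), length.out = 257L)
            (br[-1L] + br[-257L]) / 2
          }
  n <- length(v)
  best_t <- NA_real_; best_var <- -Inf
  # cumulative formulation over sorted values
  sv <- sort(v)
  cs <- cumsum(sv); tot <- cs[n]
  for (t in cand) {
    n1 <- findInterval(t, sv)
    if (n1 == 0L || n1 == n) next
    m1 <- cs[n1] / n1
    m2 <- (tot - cs[n1]) / (n - n1)
    bv <- (n1 / n) * ((n - n1) / n) * (m1 - m2)^2
    if (bv > best_var + 1e-15) { best_var <- bv; best_t <- t }
  }
  best_t
}

#' Canopy mask by global thresholding (baseline)
#'
#' Collapses the image to a single grayscale — NDVI when a NIR band is
#' present, otherwise the per-pixel mean over bands — and splits it at the
#' Otsu threshold (maximum between-class variance). The side of the threshold
#' with the higher vegetation score becomes canopy. This is the classical
#' single-channel baseline that the k-means segmentation is compared against;
#' it ignores most of the spectral information.
#'
#' @param img a [parcel_image()].
#' @param eps NDVI zero-division guard.
#' @return a [canopy_mask()]; a constant image yields an all-zero mask with a
#'   warning (no threshold exists).
#' @export
segment_threshold <- function(img, eps = 1e-9) {
  stopifnot(inherits(img, "parcel_image"))
  nb <- img$band_names
  gray <- if (img$has_nir && "red" %in% nb) {
    nir <- img$bands[, , match("nir", nb)]
    red <- img$bands[, , match("red", nb)]
    (nir - red) / (nir + red + eps)
  } else {
    apply(img$bands, c(1L, 2L), mean)
  }
  keep <- !img$nodata_mask
  v <- gray[keep]
  th <- otsu_threshold(v)
  if (is.na(th)) {
    warning("constant image: no threshold exists; returning all-zero mask")
    return(canopy_mask(matrix(0L, nrow(gray), ncol(gray)), img$nodata_mask))
  }
  hi <- gray >= th & keep
  lo <- gray < th & keep
  # higher vegetation score side becomes canopy (same score as cluster rule)
  veg_raster <- if (img$has_nir && "red" %in% nb) gray else {
    if ("green" %in% nb) img$bands[, , match("green", nb)] else gray
  }
  hi_score <- if (any(hi)) mean(veg_raster[hi]) else -Inf
  lo_score <- if (any(lo)) mean(veg_raster[lo]) else -Inf
  m <- if (hi_score >= lo_score) hi else lo
  canopy_mask(matrix(as.integer(m), nrow(m), ncol(m)), img$nodata_mask)
}
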