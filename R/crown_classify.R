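# Crown-sampling boxes, per-tree canopy pixel counts, and three-class size
# classification.
#
# In a semi-overlapping orchard individual crowns cannot be delineated, so
# each tree's canopy is sampled through a square box of side equal to the
# maximum crown diameter centered on its planted position. With 3 m boxes and
# 2 m in-row spacing the boxes of neighboring trees share a 1 m overlap, and
# pixels in the shared strip count toward both trees.

#' Build the crown-sampling box of every tree
#'
#' Box side `s = meters_to_pixels(max_crown_diameter, res)`. For a center
#' `(r, c)` the window is the half-open rectangle
#' `[r - floor(s/2), r - floor(s/2) + s) x [c - floor(s/2), c - floor(s/2) + s)`,
#' clipped to the raster. An even side cannot center exactly on one pixel;
#' anchoring at `center - floor(s/2)` biases the window by at most half a
#' pixel.
#'
#' @param grid a `tree_grid` from [localize_trees()].
#' @param max_crown_diameter box side in meters (default 3, the study
#'   orchard's maximum crown diameter).
#' @param img a [parcel_image()] providing resolution and bounds.
#' @return data frame of class `crown_boxes`: `tree_id`, `row_index`,
#'   `tree_index`, `px_row`, `px_col`, and the half-open 0-based window
#'   `r0, r1, c0, c1`.
#' @export
build_boxes <- function(grid, max_crown_diameter = 3, img) {
  stopifnot(inherits(grid, "tree_grid"), inherits(img, "parcel_image"))
  if (max_crown_diameter <= 0) stop("max_crown_diameter must be > 0")
  if (nrow(grid$positions) == 0L) stop("empty tree grid")
  s <- meters_to_pixels(max_crown_diameter, img$resolution)
  if (s < 1L) stop("max_crown_diameter is below one pixel at this resolution")
  nr <- dim(img$bands)[1L]; nc <- dim(img$bands)[2L]
  p <- grid$positions
  r0 <- pmax(p$px_row - s %/% 2L, 0L)
  c0 <- pmax(p$px_col - s %/% 2L, 0L)
  r1 <- pmin(p$px_row - s %/% 2L + s, nr)
  c1 <- pmin(p$px_col - s %/% 2L + s, nc)
  out <- data.frame(tree_id = p$tree_id, row_index = p$row_index,
                    tree_index = p$tree_index,
                    px_row = p$px_row, px_col = p$px_col,
                    r0 = as.integer(r0), r1 = as.integer(r1),
                    c0 = as.integer(c0), c1 = as.integer(c1))
  attr(out, "box_side") <- s
  class(out) <- c("crown_boxes", "data.frame")
  out
}

#' Count canopy pixels inside each crown box
#'
#' Pixels in the overlap strip of neighboring boxes contribute to every box
#' containing them.
#'
#' @param mask a [canopy_mask()] on the same raster grid as the boxes.
#' @param boxes a `crown_boxes` data frame from [build_boxes()].
#' @return `boxes` with columns `canopy_pixels` and (given `resolution`)
#'   `canopy_m2` appended.
#' @param resolution optional meters/pixel to add a `canopy_m2` column
#'   (`canopy_pixels * resolution^2`).
#' @export
count_canopy <- function(mask, boxes, resolution = NULL) {
  stopifnot(inherits(mask, "canopy_mask"), inherits(boxes, "crown_boxes"))
  m <- mask$mask
  if (any(boxes$r1 > nrow(m)) || any(boxes$c1 > ncol(m)) ||
      any(boxes$r0 < 0L) || any(boxes$c0 < 0L))
    stop("box windows exceed the mask raster shape")
  boxes$canopy_pixels <- vapply(seq_len(nrow(boxes)), function(b) {
    sum(m[(boxes$r0[b] + 1L):boxes$r1[b], (boxes$c0[b] + 1L):boxes$c1[b]])
  }, integer(1L))
  if (!is.null(resolution))
    boxes$canopy_m2 <- boxes$canopy_pixels * resolution^2
  boxes
}

#' Per-parcel canopy size statistics and class boundaries
#'
#' The three size classes are bounded by `t1 = min + avg/5` and
#' `t2 = max - avg/5`, where min/avg/max are the minimum, arithmetic mean and
#' maximum canopy pixel count over all crown boxes of the parcel. The two
#' boundaries are always derived from the three statistics, never stored.
#'
#' @param counts integer vector of per-box canopy pixel counts (>= 1 box).
#' @return object of class `class_thresholds` with fields `min_value`,
#'   `avg_value`, `max_value`; `t1` and `t2` are available via
#'   [threshold_bounds()].
#' @export
compute_thresholds <- function(counts) {
  if (length(counts) == 0L) stop("no canopy counts: empty parcel")
  if (any(counts < 0)) stop("canopy counts must be >= 0")
  th <- structure(list(min_value = min(counts),
                       avg_value = mean(counts),
                       max_value = max(counts)),
                  class = "class_thresholds")
  b <- threshold_bounds(th)
  if (b["t1"] > b["t2"])
    warning("degenerate thresholds: t1 = ", format(b["t1"]), " > t2 = ",
            format(b["t2"]),
            " (max - min < 2*avg/5); classes assigned by rule order")
  th
}

#' Class boundaries derived from the parcel statistics
#'
#' @param th a `class_thresholds`.
#' @return named numeric `c(t1, t2)` with `t1 = min + avg/5`,
#'   `t2 = max - avg/5`.
#' @export
threshold_bounds <- function(th) {
  stopifnot(inherits(th, "class_thresholds"))
  c(t1 = th$min_value + th$avg_value / 5,
    t2 = th$max_value - th$avg_value / 5)
}

#' @export
print.class_thresholds <- function(x, ...) {
  b <- threshold_bounds(x)
  cat("class_thresholds: min ", x$min_value, ", avg ", format(x$avg_value),
      ", max ", x$max_value, "; t1 = ", format(b["t1"]), ", t2 = ",
      format(b["t2"]), "\n", sep = "")
  invisible(x)
}

#' Assign the three canopy size classes
#'
#' Class 1 (missing/weak): `min <= count < t1`; class 2 (normal):
#' `t1 <= count < t2`; class 3 (big): `t2 <= count <= max`. Rules are
#' evaluated in order 1, 2, 3 and the first match wins, which resolves the
#' overlap arising in the degenerate case `t1 > t2` and makes the assignment
#' non-decreasing in the count.
#'
#' @param count canopy pixel count(s); must lie within `[min, max]` of the
#'   parcel the thresholds were computed on.
#' @param th a `class_thresholds` from [compute_thresholds()].
#' @return integer class(es) in {1, 2, 3}.
#' @export
classify_tree <- function(count, th) {
  stopifnot(inherits(th, "class_thresholds"))
  if (any(count < th$min_value | count > th$max_value))
    stop("count outside [min_value, max_value] of the parcel")
  b <- threshold_bounds(th)
  ifelse(count < b["t1"], 1L, ifelse(count < b["t2"], 2L, 3L))
}

#' Build the per-tree table: positions, canopy sizes, classes
#'
#' Runs [count_canopy()], [compute_thresholds()] and [classify_tree()] and
#' assembles the parcel's tree table.
#'
#' @param grid a `tree_grid`.
#' @param boxes a `crown_boxes` (counted or not).
#' @param mask a [canopy_mask()] (used if `boxes` lacks counts).
#' @param img the [parcel_image()] (resolution and geotransform for the
#'   `canopy_m2`, `x`, `y` columns).
#' @return list with `table` (data frame: `tree_id`, `row_index`,
#'   `tree_index`, `px_row`, `px_col`, `x`, `y`, `canopy_pixels`,
#'   `canopy_m2`, `class`) and `thresholds`.
#' @export
classify_trees <- function(grid, boxes, mask = NULL, img) {
  stopifnot(inherits(boxes, "crown_boxes"), inherits(img, "parcel_image"))
  if (is.null(boxes$canopy_pixels)) {
    if (is.null(mask)) stop("boxes have no counts and no mask was given")
    boxes <- count_canopy(mask, boxes, resolution = img$resolution)
  }
  if (is.null(boxes$canopy_m2))
    boxes$canopy_m2 <- boxes$canopy_pixels * img$resolution^2
  th <- compute_thresholds(boxes$canopy_pixels)
  cls <- classify_tree(boxes$canopy_pixels, th)
  xy <- pixel_to_geo(as.matrix(boxes[, c("px_row", "px_col")]),
                     img$geotransform)
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  tab <- data.frame(tree_id = boxes$tree_id, row_index = boxes$row_index,
                    tree_index = boxes$tree_index,
                    px_row = boxes$px_row, px_col = boxes$px_col,
                    x = xy[, 1L], y = xy[, 2L],
                    canopy_pixels = boxes$canopy_pixels,
                    canopy_m2 = boxes$canopy_m2,
                    class = as.integer(cls))
  list(table = tab, thresholds = th)
}
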