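# Planting-grid tree localization: extend three anchor trunk positions and
# the surveyed planting distances into the full lattice of tree centers.

#' Planting pattern of a uniformly planted parcel
#'
#' @param anchor_r1t1,anchor_r1t2 pixel positions `c(row, col)` (0-based) of
#'   the first two trunks of the first row.
#' @param anchor_r2t1 pixel position of the first trunk of the second row.
#' @param d_intra distance in meters between trunks within a row (study
#'   orchard: 2 m).
#' @param d_inter distance in meters between rows (study orchard: 6 m).
#' @param max_crown_diameter maximum crown diameter in meters (study orchard:
#'   3 m); this is also the crown-sampling box side.
#' @return an object of class `planting_pattern`.
#' @export
planting_pattern <- function(anchor_r1t1, anchor_r1t2, anchor_r2t1,
                             d_intra = 2, d_inter = 6,
                             max_crown_diameter = 3) {
  anchors <- rbind(r1t1 = as.numeric(anchor_r1t1),
                   r1t2 = as.numeric(anchor_r1t2),
                   r2t1 = as.numeric(anchor_r2t1))
  if (ncol(anchors) != 2L) stop("anchors must be c(row, col) pairs")
  if (any(duplicated(anchors))) stop("anchor positions must be distinct")
  if (d_intra <= 0 || d_inter <= 0) stop("planting distances must be > 0")
  if (max_crown_diameter <= 0) stop("max_crown_diameter must be > 0")
  structure(list(anchors = anchors, d_intra = d_intra, d_inter = d_inter,
                 max_crown_diameter = max_crown_diameter),
            class = "planting_pattern")
}

# round half up, per axis
round_half_up <- function(x) floor(x + 0.5)

#' Locate every tree center from the planting pattern
#'
#' The in-row step is the unit vector from the first to the second anchor of
#' row 1, scaled to `meters_to_pixels(d_intra, res)` pixels; the row step is
#' the unit vector from the row-1 anchor to the row-2 anchor scaled to
#' `meters_to_pixels(d_inter, res)`. Directions come from the (hand-clicked)
#' anchors but magnitudes from the surveyed distances. Candidate centers
#' `anchor + i*u + j*v` are generated for integer `(i, j)` extended in both
#' directions until they leave the raster, rounded half-up per axis, and kept
#' when they land on an in-bounds non-nodata pixel. Indices are renumbered so
#' the minimal kept lattice coordinates become row 0 / tree 0.
#'
#' @param pattern a [planting_pattern()].
#' @param img a [parcel_image()] providing bounds, resolution and the nodata
#'   mask.
#' @return an object of class `tree_grid`: `positions` data frame with
#'   columns `tree_id`, `row_index`, `tree_index`, `px_row`, `px_col`;
#'   `n_rows`; `trees_per_row` (named integer vector).
#' @export
localize_trees <- function(pattern, img) {
  stopifnot(inherits(pattern, "planting_pattern"),
            inherits(img, "parcel_image"))
  res <- img$resolution
  nr <- dim(img$bands)[1L]; nc <- dim(img$bands)[2L]
  a1 <- pattern$anchors["r1t1", ]
  du <- pattern$anchors["r1t2", ] - a1
  dv <- pattern$anchors["r2t1", ] - a1
  nu <- sqrt(sum(du^2)); nv <- sqrt(sum(dv^2))
  if (nu == 0 || nv == 0) stop("coincident anchors: step vector has length 0")
  u <- du / nu * meters_to_pixels(pattern$d_intra, res)
  v <- dv / nv * meters_to_pixels(pattern$d_inter, res)
  if (abs(u[1L] * v[2L] - u[2L] * v[1L]) < 1e-9)
    stop("collinear anchors: in-row and row step vectors are parallel")
  for (a in rownames(pattern$anchors)) {
    p <- round_half_up(pattern$anchors[a, ])
    if (p[1L] < 0 || p[1L] >= nr || p[2L] < 0 || p[2L] >= nc)
      stop("anchor ", a, " outside the raster")
    if (img$nodata_mask[p[1L] + 1L, p[2L] + 1L])
      stop("anchor ", a, " lies on a nodata pixel")
  }
  # lattice index ranges: project the raster corners (with margin) onto (u, v)
  corners <- rbind(c(-1, -1), c(-1, nc), c(nr, -1), c(nr, nc))
  M <- cbind(u, v)
  ij <- t(solve(M, t(sweep(corners, 2L, a1))))
  i_range <- floor(min(ij[, 1L]) - 1):ceiling(max(ij[, 1L]) + 1)
  j_range <- floor(min(ij[, 2L]) - 1):ceiling(max(ij[, 2L]) + 1)
  cand <- expand.grid(i = i_range, j = j_range)
  pr <- a1[1L] + cand$i * u[1L] + cand$j * v[1L]
  pc <- a1[2L] + cand$i * u[2L] + cand$j * v[2L]
  r <- round_half_up(pr); c <- round_half_up(pc)
  inb <- r >= 0 & r < nr & c >= 0 & c < nc
  keep <- inb
  keep[inb] <- !img$nodata_mask[cbind(r[inb] + 1L, c[inb] + 1L)]
  if (!any(keep)) stop("no tree candidate falls inside the parcel")
  i <- cand$i[keep]; j <- cand$j[keep]; r <- r[keep]; c <- c[keep]
  row_index <- j - min(j)
  tree_index <- i - min(i)
  o <- order(row_index, tree_index)
  pos <- data.frame(tree_id = seq_along(o),
                    row_index = row_index[o], tree_index = tree_index[o],
                    px_row = as.integer(r[o]), px_col = as.integer(c[o]))
  tpr <- table(factor(pos$row_index, levels = sort(unique(pos$row_index))))
  structure(list(positions = pos,
                 n_rows = length(unique(pos$row_index)),
                 trees_per_row = stats::setNames(as.integer(tpr), names(tpr)),
                 u = u, v = v),
            class = "tree_grid")
}

#' @export
print.tree_grid <- function(x, ...) {
  cat("tree_grid: ", nrow(x$positions), " trees in ", x$n_rows, " rows\n",
      sep = "")
  invisible(x)
}

#' Check a localized grid against the known tree count
#'
#' Mirrors the field check of comparing the number of localized positions
#' with the number of trees actually planted in the orchard.
#'
#' @param grid a `tree_grid` from [localize_trees()].
#' @param expected_count optional known number of trees in the parcel.
#' @return a list with `n_rows`, `trees_per_row`, `total`, and (when
#'   `expected_count` is given) `expected` and `match`.
#' @export
validate_grid <- function(grid, expected_count = NULL) {
  stopifnot(inherits(grid, "tree_grid"))
  rep <- list(n_rows = grid$n_rows,
              trees_per_row = grid$trees_per_row,
              total = nrow(grid$positions))
  if (!is.null(expected_count)) {
    rep$expected <- as.integer(expected_count)
    rep$match <- rep$total == rep$expected
    if (!rep$match)
      message("tree count mismatch: localized ", rep$total,
              ", expected ", rep$expected)
  }
  rep
}

#' Export a tree grid as a table with projected coordinates
#'
#' @param grid a `tree_grid`.
#' @param geotransform length-6 affine used to add projected `x`, `y`.
#' @return data frame `tree_id, row_index, tree_index, px_row, px_col, x, y`.
#' @export
grid_to_table <- function(grid, geotransform) {
  stopifnot(inherits(grid, "tree_grid"))
  xy <- pixel_to_geo(as.matrix(grid$positions[, c("px_row", "px_col")]),
                     geotransform)
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  cbind(grid$positions, x = xy[, 1L], y = xy[, 2L])
}
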