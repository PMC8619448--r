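# Classified-tree map rendering and tabular summaries.

#' Class color table
#'
#' Map legend: red = missing/weak (class 1), blue = normal (class 2),
#' yellow = big (class 3); background is black. RGB values are documented
#' constants.
#'
#' @return 4 x 3 integer matrix (rows: background, class 1..3; columns
#'   R, G, B in 0..255).
#' @export
class_color_table <- function() {
  m <- rbind(background = c(0L, 0L, 0L),
             missing_weak = c(220L, 20L, 20L),
             normal = c(30L, 60L, 220L),
             big = c(240L, 200L, 0L))
  colnames(m) <- c("r", "g", "b")
  m
}

#' Render the classified-tree map
#'
#' Paints every crown box with its class value (1/2/3) over a zero
#' background. A pixel covered by several overlapping boxes takes the class
#' of the box whose center is nearest (squared pixel distance); ties break to
#' the lower `tree_id`. The result is therefore independent of box order.
#'
#' @param boxes a `crown_boxes` data frame.
#' @param classes integer vector of classes (1/2/3), one per box; taken from
#'   `boxes$class` if present and `classes` is `NULL`.
#' @param shape raster shape `c(rows, cols)`.
#' @return object of class `classified_map`: `values` integer matrix in
#'   {0, 1, 2, 3}; `color_table` as in [class_color_table()].
#' @export
render_class_map <- function(boxes, classes = NULL, shape) {
  stopifnot(inherits(boxes, "data.frame"))
  if (is.null(classes)) classes <- boxes$class
  if (length(classes) != nrow(boxes))
    stop("one class per box required")
  nr <- shape[1L]; nc <- shape[2L]
  if (nrow(boxes) > 0L &&
      (any(boxes$r0 < 0L) || any(boxes$c0 < 0L) ||
       any(boxes$r1 > nr) || any(boxes$c1 > nc)))
    stop("box outside raster")
  values <- matrix(0L, nr, nc)
  best_d2 <- matrix(Inf, nr, nc)
  best_id <- matrix(.Machine$integer.max, nr, nc)
  for (b in seq_len(nrow(boxes))) {
    rs <- (boxes$r0[b] + 1L):boxes$r1[b]
    cs <- (boxes$c0[b] + 1L):boxes$c1[b]
    d2 <- outer((rs - 1L - boxes$px_row[b])^2,
                (cs - 1L - boxes$px_col[b])^2, "+")
    id <- boxes$tree_id[b]
    win_d2 <- best_d2[rs, cs, drop = FALSE]
    win_id <- best_id[rs, cs, drop = FALSE]
    upd <- d2 < win_d2 | (d2 == win_d2 & id < win_id)
    if (any(upd)) {
      win_v <- values[rs, cs, drop = FALSE]
      win_v[upd] <- as.integer(classes[b])
      win_d2[upd] <- d2[upd]
      win_id[upd] <- id
      values[rs, cs] <- win_v
      best_d2[rs, cs] <- win_d2
      best_id[rs, cs] <- win_id
    }
  }
  structure(list(values = values, color_table = class_color_table()),
            class = "classified_map")
}

#' Write a classified map as an 8-bit raster plus optional PNG quicklook
#'
#' @param cmap a `classified_map`.
#' @param path output TIFF path (values 0..3; sidecar records the color
#'   table).
#' @param resolution,geotransform georeferencing for the sidecar.
#' @param png_path optional path for an RGB PNG quicklook using the class
#'   color table.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(cmap, path, resolution, geotransform = NULL,
                            png_path = NULL) {
  stopifnot(inherits(cmap, "classified_map"))
  v <- cmap$values
  tiff::writeTIFF(v / 255, path, bits.per.sample = 8L)
  write_sidecar(path, resolution,
                if (is.null(geotransform))
                  c(0, resolution, 0, nrow(v) * resolution, 0, -resolution)
                else geotransform,
                "class", nodata = 0)
  if (!is.null(png_path)) {
    ct <- cmap$color_table / 255
    rgb <- array(0, dim = c(nrow(v), ncol(v), 3L))
    for (ch in 1:3) rgb[, , ch] <- matrix(ct[v + 1L, ch], nrow(v), ncol(v))
    png::writePNG(rgb, png_path)
  }
  invisible(path)
}

#' Read a classified map written by [write_class_map()]
#'
#' @param path TIFF file path.
#' @return a `classified_map`.
#' @export
load_class_map <- function(path) {
  v <- round(suppressWarnings(tiff::readTIFF(path)) * 255)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  structure(list(values = matrix(as.integer(v), nrow(v), ncol(v)),
                 color_table = class_color_table()),
            class = "classified_map")
}

#' Per-row and per-parcel class summary
#'
#' @param tree_table per-tree table from [classify_trees()].
#' @return list with `per_row` (data frame: `row_index`, `n_missing_weak`,
#'   `n_normal`, `n_big`, `n_trees`, `canopy_pixels`) and `parcel` (one-row
#'   data frame with the same totals).
#' @export
summarize_trees <- function(tree_table) {
  if (is.null(tree_table) || nrow(tree_table) == 0L)
    stop("empty tree table")
  rows <- sort(unique(tree_table$row_index))
  per_row <- do.call(rbind, lapply(rows, function(ri) {
    tt <- tree_table[tree_table$row_index == ri, ]
    data.frame(row_index = ri,
               n_missing_weak = sum(tt$class == 1L),
               n_normal = sum(tt$class == 2L),
               n_big = sum(tt$class == 3L),
               n_trees = nrow(tt),
               canopy_pixels = sum(tt$canopy_pixels))
  }))
  parcel <- data.frame(n_missing_weak = sum(per_row$n_missing_weak),
                       n_normal = sum(per_row$n_normal),
                       n_big = sum(per_row$n_big),
                       n_trees = sum(per_row$n_trees),
                       canopy_pixels = sum(per_row$canopy_pixels))
  list(per_row = per_row, parcel = parcel)
}
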