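# Synthetic orchard scenes with full ground truth.
#
# The generator emulates the study orchard's geometry: rows 6 m apart,
# trunks 2 m apart within rows, crown disks up to 3 m diameter (so
# neighboring crowns overlap by up to 1 m and merge into row-shaped canopy),
# occasional missing/weak trees, vegetation vs. soil spectral contrast at
# 0.5 m/pixel, and a nodata frame outside the parcel.

#' Scenario describing a synthetic orchard scene
#'
#' Defaults are the study orchard's conditions: 2 m intra-row and 6 m
#' inter-row spacing, 3 m maximum crown diameter, 0.5 m/pixel, 10 rows of 25
#' trees with a 10% missing/weak rate.
#'
#' @param n_rows,trees_per_row grid dimensions.
#' @param d_intra,d_inter planting distances in meters.
#' @param resolution ground sampling distance in meters/pixel.
#' @param row_angle in-row direction in degrees (0 = rows run along image
#'   columns).
#' @param max_crown_diameter meters; also the crown-box side downstream.
#' @param p_missing probability that a tree is missing/weak (crown diameter
#'   0).
#' @param crown_law diameter distribution for present trees, one of
#'   `list(type = "uniform", min, max)`, `list(type = "fixed", value)`, or
#'   `list(type = "strata", diameters, probs)` (three well-separated strata
#'   give scenes whose size classes are recoverable exactly).
#' @param band_means per-stratum band intensity means: matrix with rows
#'   `vegetation`, `soil` and one column per band. The default 4-band values
#'   give NDVI about 0.76 over vegetation and 0.09 over soil, the typical
#'   citrus-canopy vs. bare-soil contrast.
#' @param noise_sd additive Gaussian noise SD; a scalar, or a named vector
#'   `c(vegetation = , soil = )` for stratum-specific noise.
#' @param soil_margin meters of bare soil between the outermost crowns and
#'   the parcel edge. The default 0 mirrors imagery clipped by a parcel
#'   polygon drawn tight around the planted rows; a margin of a full planting
#'   step or more leaves room for unplanted lattice positions inside the
#'   parcel, which the localizer will (correctly) report as extra
#'   near-zero-canopy trees.
#' @param nodata_border meters of outside-parcel (nodata) frame around the
#'   parcel.
#' @param seed RNG seed; the whole scene is deterministic given the seed.
#' @return an object of class `orchard_scenario`.
#' @export
orchard_scenario <- function(n_rows = 10L, trees_per_row = 25L,
                             d_intra = 2, d_inter = 6, resolution = 0.5,
                             row_angle = 0,
                             max_crown_diameter = 3, p_missing = 0.1,
                             crown_law = list(type = "uniform",
                                              min = 1.8, max = 3.0),
                             band_means = NULL,
                             noise_sd = 0.01,
                             soil_margin = 0, nodata_border = 2,
                             seed = 1L) {
  if (is.null(band_means))
    band_means <- rbind(
      vegetation = c(blue = 0.05, green = 0.10, red = 0.06, nir = 0.45),
      soil = c(blue = 0.18, green = 0.22, red = 0.25, nir = 0.30))
  stopifnot(n_rows >= 1L, trees_per_row >= 1L,
            d_intra > 0, d_inter > 0, resolution > 0,
            max_crown_diameter > 0, p_missing >= 0, p_missing <= 1,
            is.matrix(band_means), all(band_means >= 0),
            all(c("vegetation", "soil") %in% rownames(band_means)),
            all(noise_sd >= 0))
  structure(list(n_rows = as.integer(n_rows),
                 trees_per_row = as.integer(trees_per_row),
                 d_intra = d_intra, d_inter = d_inter,
                 resolution = resolution, row_angle = row_angle,
                 max_crown_diameter = max_crown_diameter,
                 p_missing = p_missing, crown_law = crown_law,
                 band_means = band_means, noise_sd = noise_sd,
                 soil_margin = soil_margin, nodata_border = nodata_border,
                 seed = as.integer(seed)),
            class = "orchard_scenario")
}

draw_crown_diameters <- function(law, n, max_diameter) {
  d <- switch(law$type,
    uniform = stats::runif(n, law$min, law$max),
    fixed = rep(law$value, n),
    strata = sample(law$diameters, n, replace = TRUE,
                    prob = if (is.null(law$probs)) NULL else law$probs),
    stop("unknown crown_law type: ", law$type))
  if (any(d < 0 | d > max_diameter))
    stop("crown_law draws diameters outside [0, max_crown_diameter]")
  d
}

# stratum noise sd lookup
stratum_sd <- function(noise_sd, stratum) {
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) return(noise_sd)
  if (stratum %in% names(noise_sd)) return(noise_sd[[stratum]])
  stop("noise_sd must be a scalar or named for stratum '", stratum, "'")
}

#' Generate a synthetic orchard scene with ground truth
#'
#' Plants the tree lattice at the scenario's spacings (rotated by
#' `row_angle`), draws each crown as a filled disk of its sampled diameter
#' (neighboring disks merge when the diameter exceeds the intra-row
#' spacing), fills vegetation/soil/background strata with their band means
#' plus Gaussian noise, and computes the per-tree truth: planted centers,
#' crown diameters, per-box canopy counts and size classes (the latter by
#' running the package's own threshold formulas on the true counts).
#'
#' @param sc an [orchard_scenario()].
#' @return object of class `orchard_truth` with fields `image`
#'   ([parcel_image()]), `canopy_truth` ([canopy_mask()]), `grid`
#'   (`tree_grid` of planted centers), `crown_diameters`, `true_counts`,
#'   `true_classes`, `boxes` (`crown_boxes` with truth counts), `strata`
#'   (integer matrix: 0 background, 1 soil, 2 vegetation), and `scenario`.
#' @export
generate_orchard <- function(sc) {
  stopifnot(inherits(sc, "orchard_scenario"))
  res <- sc$resolution
  step_i <- meters_to_pixels(sc$d_intra, res)
  step_j <- meters_to_pixels(sc$d_inter, res)
  if (step_i < 1L || step_j < 1L)
    stop("scene too small: planting distances are below one pixel")
  th <- sc$row_angle * pi / 180
  u <- c(sin(th), cos(th)) * step_i   # in-row step (row, col)
  v <- c(cos(th), -sin(th)) * step_j  # across-row step
  ij <- expand.grid(i = 0:(sc$trees_per_row - 1L), j = 0:(sc$n_rows - 1L))
  ctr <- cbind(row = ij$i * u[1L] + ij$j * v[1L],
               col = ij$i * u[2L] + ij$j * v[2L])
  rad_max_px <- ceiling(sc$max_crown_diameter / 2 / res)
  margin_px <- meters_to_pixels(sc$soil_margin, res)
  border_px <- meters_to_pixels(sc$nodata_border, res)
  pad <- rad_max_px + margin_px + border_px
  offset <- pad - c(min(ctr[, 1L]), min(ctr[, 2L]))
  ctr <- sweep(ctr, 2L, offset, "+")
  ctr_px <- round_half_up(ctr)
  nr <- max(ctr_px[, 1L]) + pad + 1L
  nc <- max(ctr_px[, 2L]) + pad + 1L
  n <- nrow(ctr_px)

  # nodata frame around the parcel
  nodata <- matrix(FALSE, nr, nc)
  if (border_px > 0L) {
    nodata[c(seq_len(border_px), nr - seq_len(border_px) + 1L), ] <- TRUE
    nodata[, c(seq_len(border_px), nc - seq_len(border_px) + 1L)] <- TRUE
  }

  truth <- with_seed(sc$seed, {
    missing <- stats::runif(n) < sc$p_missing
    diam <- draw_crown_diameters(sc$crown_law, n, sc$max_crown_diameter)
    diam[missing] <- 0
    canopy <- matrix(FALSE, nr, nc)
    for (t in seq_len(n)) {
      if (diam[t] <= 0) next
      rpx <- diam[t] / 2 / res
      cr <- ctr_px[t, 1L]; cc <- ctr_px[t, 2L]
      rr <- max(0L, cr - ceiling(rpx)):min(nr - 1L, cr + ceiling(rpx))
      cs <- max(0L, cc - ceiling(rpx)):min(nc - 1L, cc + ceiling(rpx))
      d2 <- outer((rr - cr)^2, (cs - cc)^2, "+")
      canopy[rr + 1L, cs + 1L] <- canopy[rr + 1L, cs + 1L] | (d2 <= rpx^2)
    }
    canopy[nodata] <- FALSE
    strata <- matrix(1L, nr, nc)  # soil
    strata[canopy] <- 2L          # vegetation
    strata[nodata] <- 0L          # background
    band_names <- colnames(sc$band_means)
    nb <- ncol(sc$band_means)
    bands <- array(0, dim = c(nr, nc, nb))
    for (b in seq_len(nb)) {
      pl <- matrix(0, nr, nc)
      for (stratum in c("soil", "vegetation")) {
        sel <- strata == if (stratum == "soil") 1L else 2L
        sd_s <- stratum_sd(sc$noise_sd, stratum)
        vals <- sc$band_means[stratum, b]
        if (sd_s > 0) vals <- vals + stats::rnorm(sum(sel), 0, sd_s)
        pl[sel] <- pmin(pmax(vals, 0.001), 1)
      }
      bands[, , b] <- quantize16(pl)
    }
    list(missing = missing, diam = diam, canopy = canopy, strata = strata,
         bands = bands, band_names = band_names)
  })

  img <- parcel_image(truth$bands, band_names = truth$band_names,
                      resolution = res, nodata_mask = nodata)
  mask <- canopy_mask(matrix(as.integer(truth$canopy), nr, nc), nodata)
  o <- order(ij$j, ij$i)
  pos <- data.frame(tree_id = seq_len(n),
                    row_index = ij$j[o], tree_index = ij$i[o],
                    px_row = as.integer(ctr_px[o, 1L]),
                    px_col = as.integer(ctr_px[o, 2L]),
                    # planted centers before pixel rounding: anchors taken
                    # from these are exact, anchors from px_row/px_col mimic
                    # hand-clicked trunks with up to half-pixel error
                    px_row_exact = ctr[o, 1L],
                    px_col_exact = ctr[o, 2L])
  tpr <- table(factor(pos$row_index, levels = 0:(sc$n_rows - 1L)))
  grid <- structure(list(positions = pos, n_rows = sc$n_rows,
                         trees_per_row = stats::setNames(as.integer(tpr),
                                                         names(tpr)),
                         u = u, v = v),
                    class = "tree_grid")
  boxes <- build_boxes(grid, sc$max_crown_diameter, img)
  boxes <- count_canopy(mask, boxes, resolution = res)
  th_counts <- suppressWarnings(compute_thresholds(boxes$canopy_pixels))
  classes <- as.integer(classify_tree(boxes$canopy_pixels, th_counts))
  structure(list(image = img, canopy_truth = mask, grid = grid,
                 crown_diameters = truth$diam[o][order(pos$tree_id)],
                 true_counts = boxes$canopy_pixels,
                 true_classes = classes,
                 boxes = boxes, thresholds = th_counts,
                 strata = truth$strata, scenario = sc),
            class = "orchard_truth")
}

#' @export
print.orchard_truth <- function(x, ...) {
  d <- dim(x$image$bands)
  cat("orchard_truth: ", nrow(x$grid$positions), " trees (",
      x$scenario$n_rows, " x ", x$scenario$trees_per_row, "), scene ",
      d[1L], " x ", d[2L], " px, canopy ", sum(x$canopy_truth$mask),
      " px\n", sep = "")
  invisible(x)
}

#' Write an orchard scene and its truth to a fixture directory
#'
#' Files: `image.tif` (+ sidecar), `truth_mask.tif` (+ sidecar),
#' `centers.geojson`, `trees.csv` (center, diameter, true count/class per
#' tree), `scenario.yaml`. The same scenario and seed always produce
#' byte-identical files.
#'
#' @param truth an `orchard_truth`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(truth, dir) {
  stopifnot(inherits(truth, "orchard_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- truth$image
  write_parcel(img, file.path(dir, "image.tif"))
  write_mask(truth$canopy_truth, file.path(dir, "truth_mask.tif"),
             img$resolution, img$geotransform)
  tab <- grid_to_table(truth$grid, img$geotransform)
  tab$crown_diameter_m <- truth$crown_diameters
  tab$canopy_pixels <- truth$true_counts
  tab$class <- truth$true_classes
  utils::write.csv(tab, file.path(dir, "trees.csv"), row.names = FALSE)
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(tab$x[i], tab$y[i])),
         properties = list(tree_id = tab$tree_id[i],
                           row_index = tab$row_index[i],
                           tree_index = tab$tree_index[i],
                           px_row = tab$px_row[i], px_col = tab$px_col[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "centers.geojson"),
                       auto_unbox = TRUE, digits = NA)
  sc <- truth$scenario
  sc_list <- unclass(sc)
  sc_list$band_means <- list(rownames = rownames(sc$band_means),
                             colnames = colnames(sc$band_means),
                             values = as.vector(t(sc$band_means)))
  yaml::write_yaml(sc_list, file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Reload a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @param nodata passed to [load_parcel()] for the image (use `NA` to keep
#'   the clipped background as an ordinary pixel population).
#' @return list with `image`, `canopy_truth`, `trees` (data frame), and
#'   `scenario`.
#' @export
load_fixture <- function(dir, nodata = NULL) {
  sc_list <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  bm <- matrix(sc_list$band_means$values,
               nrow = length(sc_list$band_means$rownames), byrow = TRUE,
               dimnames = list(sc_list$band_means$rownames,
                               sc_list$band_means$colnames))
  sc <- orchard_scenario(
    n_rows = sc_list$n_rows, trees_per_row = sc_list$trees_per_row,
    d_intra = sc_list$d_intra, d_inter = sc_list$d_inter,
    resolution = sc_list$resolution, row_angle = sc_list$row_angle,
    max_crown_diameter = sc_list$max_crown_diameter,
    p_missing = sc_list$p_missing,
    crown_law = sc_list$crown_law, band_means = bm,
    noise_sd = unlist(sc_list$noise_sd),
    soil_margin = sc_list$soil_margin,
    nodata_border = sc_list$nodata_border, seed = sc_list$seed)
  list(image = load_parcel(file.path(dir, "image.tif"), nodata = nodata),
       canopy_truth = load_mask(file.path(dir, "truth_mask.tif")),
       trees = utils::read.csv(file.path(dir, "trees.csv")),
       scenario = sc)
}
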