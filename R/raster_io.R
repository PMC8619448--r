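# Raster I/O and coordinate conventions.
#
# Conventions used throughout the package:
#   * pixel coordinates are (row, col), 0-based;
#   * band arrays are indexed [row, col, band];
#   * geographic lookups use the pixel-center convention;
#   * the geotransform is the 6-vector (x0, a, b, y0, d, e) mapping a
#     fractional pixel (row, col) to projected coordinates via
#       x = x0 + (col + 0.5) * a + (row + 0.5) * b
#       y = y0 + (col + 0.5) * d + (row + 0.5) * e
#     so that integer pixel (row, col) maps to the center of its cell.
#
# Rasters are stored on disk as multiband 16-bit TIFF (intensities in [0, 1],
# quantized to k/65535) with a JSON sidecar `<file>.json` holding the
# geotransform, resolution, band names, nodata value and CRS string.

#' Multispectral parcel raster
#'
#' Container for an already-clipped orchard parcel: a stack of spectral bands
#' plus the georeferencing needed to convert between pixels and projected
#' coordinates, and a nodata mask flagging pixels outside the parcel.
#'
#' @param bands numeric array indexed `[row, col, band]` (a matrix is accepted
#'   for a single band and promoted). Values are unitless intensities in
#'   `[0, 1]`.
#' @param band_names character vector naming each band; the defaults follow
#'   the blue/green/red/near-infrared layout of 4-band pushbroom imagery.
#' @param resolution ground sampling distance in meters/pixel (> 0).
#' @param geotransform numeric length-6 affine `(x0, a, b, y0, d, e)`; see
#'   Details. Defaults to a north-up transform with origin at the top-left
#'   corner and pixel size `resolution`.
#' @param nodata_mask logical matrix, `TRUE` where the pixel lies outside the
#'   parcel. Defaults to all-`FALSE`.
#'
#' @details
#' The geotransform maps fractional pixel `(row, col)` to projected `(x, y)`
#' at pixel centers: `x = x0 + (col + 0.5) a + (row + 0.5) b`,
#' `y = y0 + (col + 0.5) d + (row + 0.5) e`.
#'
#' @return an object of class `parcel_image` with fields `bands`,
#'   `band_names`, `resolution`, `geotransform`, `nodata_mask`, and `has_nir`
#'   (flag: a band named `"nir"` is present).
#' @export
parcel_image <- function(bands, band_names = NULL, resolution,
                         geotransform = NULL, nodata_mask = NULL) {
  if (is.matrix(bands)) bands <- array(bands, dim = c(dim(bands), 1L))
  stopifnot(is.array(bands), length(dim(bands)) == 3L)
  nr <- dim(bands)[1L]; nc <- dim(bands)[2L]; nb <- dim(bands)[3L]
  if (is.null(band_names)) {
    band_names <- if (nb == 4L) c("blue", "green", "red", "nir")
                  else paste0("band", seq_len(nb))
  }
  if (length(band_names) != nb)
    stop("band_names length (", length(band_names),
         ") does not match band count (", nb, ")")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number (meters/pixel)")
  if (is.null(geotransform))
    geotransform <- c(0, resolution, 0, nr * resolution, 0, -resolution)
  stopifnot(is.numeric(geotransform), length(geotransform) == 6L)
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nr, nc)
  if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), c(nr, nc)))
    stop("nodata_mask must be a logical matrix matching the band shape")
  structure(
    list(bands = bands, band_names = as.character(band_names),
         resolution = resolution, geotransform = as.numeric(geotransform),
         nodata_mask = nodata_mask,
         has_nir = "nir" %in% band_names),
    class = "parcel_image")
}

#' @export
print.parcel_image <- function(x, ...) {
  d <- dim(x$bands)
  cat("parcel_image: ", d[1L], " x ", d[2L], " pixels, ", d[3L], " band(s) [",
      paste(x$band_names, collapse = ", "), "]\n", sep = "")
  cat("  resolution: ", x$resolution, " m/pixel; nodata pixels: ",
      sum(x$nodata_mask), "/", d[1L] * d[2L], "\n", sep = "")
  invisible(x)
}

#' @export
dim.parcel_image <- function(x) dim(x$bands)

# intensities representable exactly in 16-bit TIFF storage
quantize16 <- function(x) round(x * 65535) / 65535

#' Convert a metric length to a pixel count
#'
#' Rounds `length_m / resolution` to the nearest integer, ties rounding half
#' up. At the 0.5 m ground sampling distance of the study imagery, the 2 m
#' intra-row spacing maps to 4 pixels and the 6 m inter-row spacing to 12.
#'
#' @param length_m length in meters (>= 0); vectorized.
#' @param resolution ground sampling distance in meters/pixel (> 0).
#' @return integer pixel count(s).
#' @export
meters_to_pixels <- function(length_m, resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number")
  if (any(length_m < 0)) stop("length_m must be >= 0")
  as.integer(floor(length_m / resolution + 0.5))
}

#' Pixel to projected coordinates (pixel-center convention)
#'
#' @param p numeric vector `c(row, col)` (0-based) or a 2-column matrix of
#'   such pixels, one per row.
#' @param geotransform length-6 affine as in [parcel_image()].
#' @return numeric `c(x, y)` or a 2-column matrix `(x, y)`.
#' @export
pixel_to_geo <- function(p, geotransform) {
  gt <- as.numeric(geotransform)
  stopifnot(length(gt) == 6L)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  row <- p[, 1L] + 0.5; col <- p[, 2L] + 0.5
  out <- cbind(x = gt[1L] + col * gt[2L] + row * gt[3L],
               y = gt[4L] + col * gt[5L] + row * gt[6L])
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Projected coordinates to pixel (inverse of [pixel_to_geo()])
#'
#' @param xy numeric `c(x, y)` or a 2-column matrix.
#' @param geotransform length-6 affine as in [parcel_image()].
#' @return fractional pixel `c(row, col)` (or matrix); exact integers are
#'   recovered exactly for pixel-center inputs. Errors on a singular
#'   transform.
#' @export
geo_to_pixel <- function(xy, geotransform) {
  gt <- as.numeric(geotransform)
  stopifnot(length(gt) == 6L)
  det <- gt[2L] * gt[6L] - gt[3L] * gt[5L]
  if (abs(det) < .Machine$double.eps * max(abs(gt[c(2L, 3L, 5L, 6L)]), 1))
    stop("singular geotransform: pixel axes are collinear")
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  dx <- xy[, 1L] - gt[1L]; dy <- xy[, 2L] - gt[4L]
  col <- ( gt[6L] * dx - gt[3L] * dy) / det - 0.5
  row <- (-gt[5L] * dx + gt[2L] * dy) / det - 0.5
  out <- cbind(row = row, col = col)
  if (nrow(out) == 1L) out[1L, ] else out
}

# sidecar path for a raster file
sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, resolution, geotransform, band_names,
                          nodata = NULL, crs = NA_character_) {
  meta <- list(resolution = resolution,
               geotransform = as.numeric(geotransform),
               band_names = as.list(band_names),
               nodata = if (is.null(nodata)) NULL else nodata,
               crs = crs)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read a parcel raster
#'
#' Reads a single- or multi-band TIFF together with its JSON sidecar
#' (georeferencing and nodata metadata). A pixel is flagged nodata when all
#' its bands equal the nodata value.
#'
#' @param path TIFF file path.
#' @param band_names optional band names overriding the sidecar/default order
#'   (default blue, green, red, nir for 4-band files).
#' @param nodata optional nodata value overriding the sidecar; `NULL` together
#'   with a sidecar lacking a nodata entry yields an all-`FALSE` mask. Use
#'   `nodata = NA` to force-ignore the sidecar's nodata tag (background pixels
#'   then stay in the image as an ordinary population, as in imagery where the
#'   outside-parcel area is clipped to black rather than masked).
#' @param resolution optional meters/pixel, required if no sidecar is present.
#' @param min_bands minimum acceptable band count (default 3: the pipeline
#'   needs at least blue/green/red).
#' @return a [parcel_image()].
#' @export
load_parcel <- function(path, band_names = NULL, nodata = NULL,
                        resolution = NULL, min_bands = 3L) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  arr <- suppressWarnings(tiff::readTIFF(path))
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  meta <- read_sidecar(path)
  if (is.null(resolution)) resolution <- meta$resolution
  if (is.null(resolution))
    stop("no resolvable resolution: none in sidecar and none supplied")
  gt <- if (!is.null(meta$geotransform)) meta$geotransform else NULL
  if (is.null(band_names) && !is.null(meta$band_names))
    band_names <- unlist(meta$band_names)
  nb <- dim(arr)[3L]
  if (nb < min_bands)
    stop("raster has ", nb, " band(s); at least ", min_bands, " required")
  nd <- if (is.null(nodata)) meta$nodata else nodata
  mask <- if (is.null(nd) || (length(nd) == 1L && is.na(nd))) NULL else {
    m <- arr[, , 1L] == nd
    if (nb > 1L) for (b in 2:nb) m <- m & (arr[, , b] == nd)
    m
  }
  parcel_image(arr, band_names = band_names, resolution = resolution,
               geotransform = gt, nodata_mask = mask)
}

#' Write a parcel raster
#'
#' Writes the band stack as a 16-bit multiband TIFF (intensities quantized to
#' `k/65535`; at most 4 bands, the codec's channel limit) plus the JSON
#' sidecar. Nodata pixels are written as the nodata value in every band.
#'
#' @param img a [parcel_image()].
#' @param path output TIFF path.
#' @param nodata value written into masked pixels and recorded in the sidecar
#'   (default 0).
#' @param crs free-text CRS description for the sidecar.
#' @return `path`, invisibly.
#' @export
write_parcel <- function(img, path, nodata = 0, crs = NA_character_) {
  stopifnot(inherits(img, "parcel_image"))
  arr <- quantize16(img$bands)
  if (any(img$nodata_mask)) {
    for (b in seq_len(dim(arr)[3L])) {
      pl <- arr[, , b]; pl[img$nodata_mask] <- nodata; arr[, , b] <- pl
    }
  }
  if (dim(arr)[3L] == 1L) arr <- arr[, , 1L]
  tiff::writeTIFF(arr, path, bits.per.sample = 16L)
  write_sidecar(path, img$resolution, img$geotransform, img$band_names,
                nodata = nodata, crs = crs)
  invisible(path)
}

#' Write a canopy mask as an 8-bit raster
#'
#' Canopy pixels are stored as 1, soil as 0, nodata as 255, with the
#' georeferencing sidecar alongside.
#'
#' @param mask a [canopy_mask()].
#' @param path output TIFF path.
#' @param resolution,geotransform georeferencing for the sidecar.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, resolution, geotransform = NULL) {
  stopifnot(inherits(mask, "canopy_mask"))
  v <- mask$mask
  v[mask$nodata_mask] <- 255L
  tiff::writeTIFF(v / 255, path, bits.per.sample = 8L)
  write_sidecar(path, resolution,
                if (is.null(geotransform))
                  c(0, resolution, 0, nrow(v) * resolution, 0, -resolution)
                else geotransform,
                "mask", nodata = 255)
  invisible(path)
}

#' Read a canopy mask written by [write_mask()]
#'
#' @param path TIFF file path.
#' @return a [canopy_mask()].
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  v <- round(suppressWarnings(tiff::readTIFF(path)) * 255)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  canopy_mask(ifelse(v == 255, 0L, as.integer(v)), nodata_mask = v == 255)
}
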