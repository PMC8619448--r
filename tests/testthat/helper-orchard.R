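# Shared fixtures and independent oracles.

# small, fast scene with the study geometry (2 m / 6 m / 3 m at 0.5 m GSD)
tiny_scenario <- function(seed = 1L, n_rows = 4L, trees_per_row = 6L, ...) {
  orchard_scenario(n_rows = n_rows, trees_per_row = trees_per_row,
                   seed = seed, ...)
}

# anchors for localization, read from a generated grid's truth
truth_anchors <- function(grid, exact = FALSE) {
  g <- grid$positions
  cols <- if (exact) c("px_row_exact", "px_col_exact")
          else c("px_row", "px_col")
  pick <- function(ri, ti)
    as.numeric(g[g$row_index == ri & g$tree_index == ti, cols])
  list(r1t1 = pick(0, 0), r1t2 = pick(0, 1), r2t1 = pick(1, 0))
}

truth_pattern <- function(grid, exact = FALSE, ...) {
  a <- truth_anchors(grid, exact = exact)
  planting_pattern(a$r1t1, a$r1t2, a$r2t1, ...)
}

# brute-force canopy recount: explicit double loop over every pixel of the
# half-open window [r0, r1) x [c0, c1), independent of count_canopy()
recount_box <- function(mask_matrix, r0, r1, c0, c1) {
  n <- 0L
  for (r in seq.int(r0, r1 - 1L)) {
    for (c in seq.int(c0, c1 - 1L)) {
      if (mask_matrix[r + 1L, c + 1L] == 1L) n <- n + 1L
    }
  }
  n
}

# brute-force disk-union rasterization: for every pixel test membership in
# every crown disk (centers/radii in pixels, pixel-center distance)
rasterize_disks <- function(nr, nc, centers, radii_px) {
  out <- matrix(FALSE, nr, nc)
  for (r in 0:(nr - 1L)) {
    for (c in 0:(nc - 1L)) {
      for (t in seq_len(nrow(centers))) {
        if (radii_px[t] > 0 &&
            (r - centers[t, 1L])^2 + (c - centers[t, 2L])^2 <=
            radii_px[t]^2) {
          out[r + 1L, c + 1L] <- TRUE
          break
        }
      }
    }
  }
  out
}

# brute-force nearest-center painting for the classified map
paint_nearest <- function(boxes, classes, nr, nc) {
  vals <- matrix(0L, nr, nc)
  for (r in 0:(nr - 1L)) {
    for (c in 0:(nc - 1L)) {
      best_d2 <- Inf; best_id <- Inf; best_cl <- 0L
      for (b in seq_len(nrow(boxes))) {
        if (r >= boxes$r0[b] && r < boxes$r1[b] &&
            c >= boxes$c0[b] && c < boxes$c1[b]) {
          d2 <- (r - boxes$px_row[b])^2 + (c - boxes$px_col[b])^2
          if (d2 < best_d2 || (d2 == best_d2 && boxes$tree_id[b] < best_id)) {
            best_d2 <- d2; best_id <- boxes$tree_id[b]
            best_cl <- as.integer(classes[b])
          }
        }
      }
      vals[r + 1L, c + 1L] <- best_cl
    }
  }
  vals
}

# 4-band image with two spectral populations on a checkerboard
two_population_image <- function(nr = 12L, nc = 12L,
                                 mu1 = c(0.1, 0.1, 0.1, 0.1),
                                 mu2 = c(0.6, 0.6, 0.6, 0.6)) {
  pop <- outer(0:(nr - 1L), 0:(nc - 1L), function(r, c) (r + c) %% 2L)
  bands <- array(0, dim = c(nr, nc, 4L))
  for (b in 1:4) bands[, , b] <- ifelse(pop == 0L, mu1[b], mu2[b])
  list(img = parcel_image(bands, resolution = 0.5), pop = pop)
}
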