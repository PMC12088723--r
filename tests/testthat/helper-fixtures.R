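# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures are stored.

# regular n-gon approximating a circle, in pixel coordinates
circle_contour <- function(r_px, n = 360L, pixel_size_mm = 1, center = c(0, 0),
                           start_angle = 0) {
  th <- start_angle + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour(cbind(center[1L] + r_px * cos(th), center[2L] + r_px * sin(th)),
          pixel_size_mm)
}

# even-odd point-in-polygon in plain R: the independent oracle for the
# rasterization property tests
in_poly_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- (yi > py) != (yj > py)
    xin <- px < (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & xin)
    j <- i
  }
  inside
}

# an annulus frame: circular lumen of radius r_lumen_mm, FT wall out to
# r_lumen + wall_mm, and an optional Ca ring in the outward depth band
# [band[1], band[2]] mm. Returns list(geometry, mask).
annulus_frame <- function(r_lumen_mm, wall_mm, px_mm, band = NULL,
                          band_class = "ca", margin_mm = 0.3, frame_id = "A") {
  r_out <- r_lumen_mm + wall_mm
  half <- r_out + margin_mm
  n <- 2L * as.integer(ceiling(half / px_mm))
  ctr <- (n - 1) / 2
  xs <- (seq_len(n) - 1 - ctr) * px_mm
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  rr <- sqrt(X^2 + Y^2)
  grid <- matrix(tissue_labels[["background"]], n, n)
  grid[rr < r_lumen_mm] <- tissue_labels[["lumen"]]
  wall <- rr >= r_lumen_mm & rr <= r_out
  grid[wall] <- tissue_labels[["ft"]]
  if (!is.null(band)) {
    ring <- rr >= r_lumen_mm + band[1L] & rr <= r_lumen_mm + band[2L] & wall
    grid[ring] <- tissue_labels[[band_class]]
  }
  lumen <- circle_contour(r_lumen_mm / px_mm, 360L, px_mm, center = c(ctr, ctr))
  eem <- circle_contour(r_out / px_mm, 360L, px_mm, center = c(ctr, ctr))
  list(geometry = frame_geometry(lumen, eem, frame_id = frame_id),
       mask = tissue_label_mask(grid, px_mm))
}

identity_landmarks <- function(k = 4L) {
  s <- (seq_len(k) - 1) / k
  landmark_correspondence(s_hist = s, s_img = s)
}

# matched pair of two annulus frames sharing identity landmarks
annulus_pair <- function(hist, img, modality = "nirs_ivus", k = 4L) {
  matched_pair(histology = list(geometry = hist$geometry, mask = hist$mask),
               imaging = list(geometry = img$geometry, mask = img$mask,
                              modality = modality),
               landmarks = identity_landmarks(k))
}

# generator configuration used by small end-to-end tests: identity
# degradation and identity classifier
identity_config <- function(...) {
  synthetic_config(shrink = 1, distortion_amp = 0, rotate = FALSE,
                   hist_pixel_mm = 0.015, img_pixel_mm = 0.015, ...)
}

# class areas (mm^2) of a label mask
mask_class_areas <- function(mask) {
  px2 <- mask$pixel_size_mm^2
  c(ft = sum(mask$grid == tissue_labels[["ft"]]) * px2,
    ca = sum(mask$grid == tissue_labels[["ca"]]) * px2,
    nc = sum(mask$grid == tissue_labels[["nc"]]) * px2)
}
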