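#' Matched histology / intravascular imaging frame pair
#'
#' @param histology list with `geometry` ([frame_geometry()]), `mask`
#'   ([tissue_label_mask()]) and optionally `cd68` (logical matrix aligned to
#'   the histology grid).
#' @param imaging list with `geometry`, `mask` and `modality`
#'   (`"nirs_ivus"` or `"oct"`).
#' @param landmarks a [landmark_correspondence()].
#' @param truth optional ground-truth record attached by the synthetic
#'   generator.
#' @return object of class `matched_pair`.
#' @export
matched_pair <- function(histology, imaging, landmarks, truth = NULL) {
  stopifnot(inherits(histology$geometry, "frame_geometry"),
            inherits(histology$mask, "tissue_label_mask"),
            inherits(imaging$geometry, "frame_geometry"),
            inherits(imaging$mask, "tissue_label_mask"),
            inherits(landmarks, "landmark_correspondence"))
  imaging$modality <- match.arg(imaging$modality, c("nirs_ivus", "oct"))
  if (histology$mask$pixel_size_mm <= 0 || imaging$mask$pixel_size_mm <= 0)
    stop("pixel sizes must be positive")
  structure(list(histology = histology, imaging = imaging,
                 landmarks = landmarks, truth = truth),
            class = "matched_pair")
}

#' @export
print.matched_pair <- function(x, ...) {
  cat(sprintf("<matched_pair> %s (%s): histology %dx%d @ %.4g mm, imaging %dx%d @ %.4g mm, %d landmarks\n",
              x$imaging$geometry$frame_id, x$imaging$modality,
              nrow(x$histology$mask$grid), ncol(x$histology$mask$grid),
              x$histology$mask$pixel_size_mm,
              nrow(x$imaging$mask$grid), ncol(x$imaging$mask$grid),
              x$imaging$mask$pixel_size_mm, nrow(x$landmarks$pairs)))
  invisible(x)
}

# default strip depth: deepest outward EEM point of the imaging frame plus a
# 0.5 mm margin, so the whole plaque band is covered
default_strip_depth <- function(geometry) {
  rc <- radial_coordinates(geometry$eem$points, geometry$lumen)
  max(rc$d_mm) + 0.5
}

#' Warp a histology label mask onto the imaging frame geometry
#'
#' Reshapes the annotated histology section to fit the pressurized lumen
#' geometry of the matched imaging frame. For every imaging pixel at radial
#' coordinates `(s_img, d_mm)` within the strip (outward depth not exceeding
#' `strip_depth_mm`), the source sample lies on the histology frame at arc
#' length `map(s_img)` — the landmark-driven circumferential scaling — and at
#' the same physical outward depth `d_mm` along the local outward normal of
#' the histology lumen. Radial transfer therefore preserves physical depth
#' (the two pixel sizes provide the scaling), which embodies the working
#' assumption that plaque is neither compressed nor elongated. Labels are
#' transferred by nearest neighbour; interpolation would invent classes.
#'
#' The mapping is evaluated inversely (target pixels pull source labels), so
#' the warped mask has no gaps or overlaps. Samples that fall outside the
#' histology image, or that fold back inside the histology lumen where
#' normals cross on a concave border, are marked invalid.
#'
#' @param pair a [matched_pair()].
#' @param strip_depth_mm strip thickness in mm; default covers the imaging
#'   frame's deepest EEM point plus 0.5 mm.
#' @param angular_samples circumferential resolution of the lumen polylines
#'   used for radial coordinates (default 720, i.e. 0.5 degrees).
#' @return object of class `warped_histology`: `mask` (a
#'   [tissue_label_mask()] on the imaging grid), `valid_region` (logical
#'   matrix), `strip_depth_mm`, and `frame_id`.
#' @export
warp_histology <- function(pair, strip_depth_mm = NULL, angular_samples = 720L) {
  stopifnot(inherits(pair, "matched_pair"))
  if (is.null(strip_depth_mm))
    strip_depth_mm <- default_strip_depth(pair$imaging$geometry)
  if (!is.numeric(strip_depth_mm) || strip_depth_mm <= 0)
    stop("strip_depth_mm must be positive")

  img_geom <- pair$imaging$geometry
  hist_geom <- pair$histology$geometry
  img_px <- pair$imaging$mask$pixel_size_mm
  hist_px <- pair$histology$mask$pixel_size_mm
  dims <- dim(pair$imaging$mask$grid)
  amap <- build_arclength_map(pair$landmarks)

  lum_img <- arc_length_parameterize(img_geom$lumen, angular_samples)
  lum_hist <- arc_length_parameterize(hist_geom$lumen, angular_samples)

  # candidate pixels: bounding box of the lumen dilated by the strip depth
  pad <- strip_depth_mm / img_px + 1
  xr <- range(lum_img$points[, 1L]); yr <- range(lum_img$points[, 2L])
  cols <- max(1L, floor(xr[1L] - pad) + 1L):min(dims[2L], ceiling(xr[2L] + pad) + 1L)
  rows <- max(1L, floor(yr[1L] - pad) + 1L):min(dims[1L], ceiling(yr[2L] + pad) + 1L)
  idx <- as.vector(outer(rows, (cols - 1L) * dims[1L], `+`))
  ctr <- pixel_centers(dims, idx)

  sd <- nearest_on_contour_cpp(ctr, lum_img$points)
  inside_lumen <- sd[, 3L] < 0
  d_mm <- sd[, 2L] * img_px
  keep <- !inside_lumen & d_mm <= strip_depth_mm
  idx <- idx[keep]

  grid <- matrix(tissue_labels[["background"]], dims[1L], dims[2L])
  valid <- matrix(FALSE, dims[1L], dims[2L])

  if (length(idx)) {
    s_hist <- amap(sd[keep, 1L])
    src <- contour_point_at(lum_hist, s_hist)
    src_pts <- src$points + src$normals * (d_mm[keep] / hist_px)
    hdims <- dim(pair$histology$mask$grid)
    src_col <- as.integer(round(src_pts[, 1L])) + 1L
    src_row <- as.integer(round(src_pts[, 2L])) + 1L
    ok <- src_col >= 1L & src_col <= hdims[2L] & src_row >= 1L & src_row <= hdims[1L]
    # folded samples: the normal offset landed back inside the histology lumen
    if (any(ok)) {
      folded <- logical(length(ok))
      folded[ok] <- nearest_on_contour_cpp(src_pts[ok, , drop = FALSE],
                                           lum_hist$points)[, 3L] < 0
      ok <- ok & !folded
    }
    lab <- pair$histology$mask$grid[cbind(src_row[ok], src_col[ok])]
    lab[lab == tissue_labels[["lumen"]]] <- tissue_labels[["background"]]
    grid[idx[ok]] <- lab
    valid[idx[ok]] <- TRUE
  }

  structure(list(
    mask = tissue_label_mask(grid, img_px),
    valid_region = valid,
    strip_depth_mm = strip_depth_mm,
    frame_id = img_geom$frame_id
  ), class = "warped_histology")
}

#' @export
print.warped_histology <- function(x, ...) {
  px2 <- x$mask$pixel_size_mm^2
  cat(sprintf("<warped_histology> %s: %d valid px, strip %.2f mm; FT %.2f / Ca %.2f / NC %.2f mm^2\n",
              x$frame_id, sum(x$valid_region), x$strip_depth_mm,
              sum(x$mask$grid == tissue_labels[["ft"]]) * px2,
              sum(x$mask$grid == tissue_labels[["ca"]]) * px2,
              sum(x$mask$grid == tissue_labels[["nc"]]) * px2))
  invisible(x)
}

# fixed class palette for overlays (background, lumen, FT, Ca, NC, macrophage)
label_palette <- function() {
  c(background = "#000000", lumen = "#303030", ft = "#2e7d32",
    ca = "#f5f5f5", nc = "#c62828", mac = "#f9a825")
}

#' Hybrid overlay of imaging labels and warped histology labels
#'
#' Deterministic colour composite for visual inspection of a co-registration;
#' no analysis depends on it. Imaging-frame labels and warped histology
#' labels are blended 50/50 where both are present.
#'
#' @param pair the [matched_pair()] the warp was produced from.
#' @param warped the corresponding [warp_histology()] output.
#' @return object of class `hybrid_overlay`: an H x W x 3 RGB array in
#'   `[0, 1]` with the palette attached as attribute `legend`.
#' @export
render_hybrid <- function(pair, warped) {
  stopifnot(inherits(pair, "matched_pair"), inherits(warped, "warped_histology"))
  if (!identical(dim(pair$imaging$mask$grid), dim(warped$mask$grid)))
    stop("grid size mismatch between imaging frame and warped histology")
  pal <- label_palette()
  col2rgb01 <- function(cols) t(grDevices::col2rgb(cols)) / 255
  rgb_tab <- col2rgb01(pal)
  base <- rgb_tab[match(as.vector(pair$imaging$mask$grid), tissue_labels), ,
                  drop = FALSE]
  over <- rgb_tab[match(as.vector(warped$mask$grid), tissue_labels), ,
                  drop = FALSE]
  blend <- ifelse(as.vector(warped$valid_region), 0.5, 0)
  out <- base * (1 - blend) + over * blend
  dims <- dim(pair$imaging$mask$grid)
  arr <- array(out, c(dims[1L], dims[2L], 3L))
  structure(arr, legend = pal, class = "hybrid_overlay")
}

#' @export
plot.hybrid_overlay <- function(x, main = "hybrid overlay", ...) {
  op <- par(mar = c(1, 1, 2, 1)); on.exit(par(op))
  plot.new()
  plot.window(c(0, 1), c(0, 1), asp = dim(x)[1L] / dim(x)[2L])
  rasterImage(unclass(x), 0, 0, 1, 1, interpolate = FALSE)
  title(main)
  invisible(x)
}

#' @export
plot.warped_histology <- function(x, ...) {
  pal <- label_palette()
  img <- matrix(pal[match(as.vector(x$mask$grid), tissue_labels)],
                nrow(x$mask$grid))
  op <- par(mar = c(1, 1, 2, 1)); on.exit(par(op))
  plot.new()
  plot.window(c(0, 1), c(0, 1), asp = nrow(img) / ncol(img))
  rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  title(sprintf("warped histology %s", x$frame_id))
  invisible(x)
}
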