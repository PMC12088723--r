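#' CD68-positive pixel mask
#'
#' Immunohistochemistry-derived macrophage evidence: a boolean grid of
#' CD68-positive pixels restricted to the plaque region of a histology frame.
#'
#' @param positive logical matrix of CD68-positive pixels.
#' @param plaque_region logical matrix of the same dimensions restricting the
#'   analysis to the plaque.
#' @param pixel_size_mm pixel size in mm.
#' @return object of class `cd68_mask`.
#' @export
cd68_mask <- function(positive, plaque_region, pixel_size_mm) {
  positive <- positive & TRUE; plaque_region <- plaque_region & TRUE
  if (!identical(dim(positive), dim(plaque_region)))
    stop("positive and plaque_region must share dimensions")
  if (any(positive & !plaque_region))
    stop("CD68-positive pixels must lie within the plaque region")
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  structure(list(positive = positive, plaque_region = plaque_region,
                 pixel_size_mm = pixel_size_mm),
            class = "cd68_mask")
}

# local sums over a circular window via shifted accumulation; the window is
# clipped at the grid edge by construction
disc_local_sum <- function(mat, radius_px) {
  r <- max(0L, as.integer(floor(radius_px)))
  nr <- nrow(mat); nc <- ncol(mat)
  acc <- matrix(0, nr, nc)
  for (di in -r:r) for (dj in -r:r) {
    if (di * di + dj * dj > radius_px^2) next
    src_r <- max(1L, 1L - di):min(nr, nr - di)
    src_c <- max(1L, 1L - dj):min(nc, nc - dj)
    acc[src_r, src_c] <- acc[src_r, src_c] +
      mat[src_r + di, src_c + dj]
  }
  acc
}

#' Detect macrophage-rich regions from a CD68 mask
#'
#' A plaque pixel is macrophage-rich when the CD68-positive fraction within a
#' circular window around it — clipped to the plaque region — reaches the
#' concentration threshold (40% by default). The neighbourhood definition is
#' this package's choice: a sliding circular window of configurable radius.
#'
#' @param cd68 a [cd68_mask()].
#' @param window_radius_mm window radius in mm (default 0.1).
#' @param threshold CD68 concentration threshold in `(0, 1]` (default 0.40).
#' @return list with `rich` (logical matrix) and `area_mm2`.
#' @export
detect_macrophage_rich <- function(cd68, window_radius_mm = 0.1,
                                   threshold = 0.40) {
  stopifnot(inherits(cd68, "cd68_mask"))
  if (window_radius_mm <= 0) stop("window_radius_mm must be positive")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (!any(cd68$plaque_region)) stop("empty plaque region")
  r_px <- window_radius_mm / cd68$pixel_size_mm
  pos <- disc_local_sum(cd68$positive * 1, r_px)
  den <- disc_local_sum(cd68$plaque_region * 1, r_px)
  frac <- ifelse(den > 0, pos / den, 0)
  rich <- cd68$plaque_region & frac >= threshold
  list(rich = rich, area_mm2 = sum(rich) * cd68$pixel_size_mm^2)
}

#' Compare histology and ML macrophage-rich areas across frames
#'
#' @param hist_areas,ml_areas per-frame macrophage-rich areas in mm^2, paired
#'   by position.
#' @return list with `n`, `total_hist_mm2`, `total_ml_mm2`, `ccc` (with CI,
#'   as [concordance_correlation()]), and `n_ml_zero_hist_positive` — frames
#'   where histology found macrophage-rich tissue but the classifier found
#'   none.
#' @export
compare_macrophage <- function(hist_areas, ml_areas) {
  if (length(hist_areas) != length(ml_areas)) stop("unpaired frames")
  cc <- concordance_correlation(hist_areas, ml_areas)
  list(n = length(hist_areas),
       total_hist_mm2 = sum(hist_areas),
       total_ml_mm2 = sum(ml_areas),
       ccc = cc,
       n_ml_zero_hist_positive = sum(ml_areas == 0 & hist_areas > 0))
}
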