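#' Tissue label codes
#'
#' Canonical integer codes for the per-pixel tissue classes. `lipid` is the
#' raw output class of the NIRS-IVUS and OCT classifiers; it is remapped to
#' `nc` (necrotic core) when a mask is loaded, reflecting the working
#' assumption that classifier-detected lipid corresponds to histological NC.
#' `mac` marks macrophage-rich pixels in OCT-style outputs.
#'
#' @format named integer vector.
#' @export
tissue_labels <- c(background = 0L, lumen = 1L, ft = 2L, ca = 3L, nc = 4L,
                   mac = 5L)

# the three plaque tissue classes, in the fixed FT, Ca, NC order used by all
# confusion matrices
plaque_classes <- c("ft", "ca", "nc")

#' Per-pixel tissue label mask
#'
#' @param grid integer matrix of label codes (row = image row, y; column = x).
#' @param pixel_size_mm physical pixel size in mm.
#' @param labels named integer vector of registered codes; defaults to
#'   [tissue_labels].
#' @return object of class `tissue_label_mask`.
#' @export
tissue_label_mask <- function(grid, pixel_size_mm, labels = tissue_labels) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0)
    stop("pixel_size_mm must be positive")
  bad <- setdiff(unique(as.vector(grid)), unname(labels))
  if (length(bad))
    stop(sprintf("unregistered label code(s) in mask: %s",
                 paste(bad, collapse = ", ")))
  structure(list(grid = grid, pixel_size_mm = pixel_size_mm, labels = labels),
            class = "tissue_label_mask")
}

#' @export
print.tissue_label_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x$grid), levels = unname(x$labels),
                      labels = names(x$labels)))
  cat(sprintf("<tissue_label_mask> %d x %d px @ %.4g mm\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size_mm))
  print(tab)
  invisible(x)
}

# logical matrix of pixels carrying any of the three plaque tissue classes
plaque_pixels <- function(mask) {
  mask$grid == tissue_labels[["ft"]] |
  mask$grid == tissue_labels[["ca"]] |
  mask$grid == tissue_labels[["nc"]]
}

# pixel-center coordinates (0-based, x = col - 1, y = row - 1) of a grid,
# as an n x 2 matrix in row-major pixel order for a subset of linear indices
pixel_centers <- function(dim_grid, idx) {
  cbind(((idx - 1L) %/% dim_grid[1L]),        # x = column - 1
        ((idx - 1L) %% dim_grid[1L]))         # y = row - 1
}

#' Per-frame quantitative record from a mask and its geometry
#'
#' Computes the Table-1-style quantities for one frame: EEM, lumen and plaque
#' areas and plaque burden from the contours, and FT/Ca/NC areas from pixel
#' counts times squared pixel size.
#'
#' @param mask a [tissue_label_mask()].
#' @param geometry a [frame_geometry()] sharing the mask's pixel size.
#' @param source `"histology"` or `"ml"`.
#' @return one-row `data.frame` with columns `frame_id`, `source`,
#'   `eem_area`, `lumen_area`, `plaque_area`, `plaque_burden`, `ft_area`,
#'   `ca_area`, `nc_area` (areas in mm^2, burden in percent).
#' @export
areas_from_mask <- function(mask, geometry, source = c("histology", "ml")) {
  stopifnot(inherits(mask, "tissue_label_mask"), inherits(geometry, "frame_geometry"))
  source <- match.arg(source)
  if (!isTRUE(all.equal(mask$pixel_size_mm, geometry$lumen$pixel_size_mm)))
    stop("mask and geometry pixel sizes differ")
  px2 <- mask$pixel_size_mm^2
  eem <- polygon_area(geometry$eem)
  lum <- polygon_area(geometry$lumen)
  pa <- plaque_area(eem, lum)
  data.frame(
    frame_id = geometry$frame_id,
    source = source,
    eem_area = eem,
    lumen_area = lum,
    plaque_area = pa,
    plaque_burden = plaque_burden(pa, eem),
    ft_area = sum(mask$grid == tissue_labels[["ft"]]) * px2,
    ca_area = sum(mask$grid == tissue_labels[["ca"]]) * px2,
    nc_area = sum(mask$grid == tissue_labels[["nc"]]) * px2,
    stringsAsFactors = FALSE
  )
}
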