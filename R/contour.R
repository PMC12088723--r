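#' Closed contour in pixel coordinates
#'
#' A contour stores the ordered vertices of a simple closed polygon in 0-based
#' pixel coordinates together with the physical size of one pixel. Lumen and
#' external elastic membrane (EEM) borders are represented this way.
#' Orientation is normalized to counter-clockwise (positive shoelace sum) at
#' construction; the start vertex is preserved because landmark arc lengths
#' are measured from it.
#'
#' @param points numeric matrix with two columns (x, y) of at least 3 vertices;
#'   the polygon is implicitly closed (do not repeat the first vertex).
#' @param pixel_size_mm physical edge length of one pixel in millimetres.
#' @param check_simple if `TRUE` (default) verify that the polygon does not
#'   self-intersect. Generated star-shaped contours may skip the quadratic
#'   check.
#' @return an object of class `contour`.
#' @export
contour <- function(points, pixel_size_mm, check_simple = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    stop("contour points must be an n x 2 matrix")
  if (anyNA(points) || any(!is.finite(points)))
    stop("contour points must be finite")
  # drop an explicitly repeated closing vertex
  n <- nrow(points)
  if (n > 1L && all(points[1L, ] == points[n, ]))
    points <- points[-n, , drop = FALSE]
  if (nrow(points) < 3L)
    stop("contour needs at least 3 distinct vertices")
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0)
    stop("pixel_size_mm must be a single positive number")

  a2 <- shoelace2(points)
  if (abs(a2) < .Machine$double.eps * 100)
    stop("degenerate polygon: zero area (collinear or repeated vertices)")
  if (a2 < 0) { # reverse to counter-clockwise, keeping the start vertex
    n <- nrow(points)
    points <- points[c(1L, n:2L), , drop = FALSE]
  }
  if (check_simple && !is_simple_polygon(points))
    stop("contour is self-intersecting; annotation is invalid")

  structure(list(points = points, pixel_size_mm = pixel_size_mm),
            class = "contour")
}

# twice the signed shoelace area, pixel units
shoelace2 <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y)
}

# quadratic segment-pair intersection test with bounding-box prefilter;
# adjacent segments (sharing a vertex) are exempt
is_simple_polygon <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    sep <- (j - i) %% n
    sep > 1L & sep < n - 1L & i < j
  }), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  # bounding boxes
  keep <- pmin(a[i, 1L], b[i, 1L]) <= pmax(a[j, 1L], b[j, 1L]) &
          pmax(a[i, 1L], b[i, 1L]) >= pmin(a[j, 1L], b[j, 1L]) &
          pmin(a[i, 2L], b[i, 2L]) <= pmax(a[j, 2L], b[j, 2L]) &
          pmax(a[i, 2L], b[i, 2L]) >= pmin(a[j, 2L], b[j, 2L])
  if (!any(keep)) return(TRUE)
  i <- i[keep]; j <- j[keep]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], a[j, 1L], a[j, 2L])
  d2 <- cross(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], b[j, 1L], b[j, 2L])
  d3 <- cross(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], a[i, 1L], a[i, 2L])
  d4 <- cross(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], b[i, 1L], b[i, 2L])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d vertices, pixel %.4g mm, area %.3f mm^2\n",
              nrow(x$points), x$pixel_size_mm, polygon_area(x)))
  invisible(x)
}

#' Polygon area of a contour
#'
#' Shoelace area of the closed polygon, scaled to square millimetres by the
#' contour's pixel size.
#'
#' @param x a [contour()].
#' @return area in mm^2 (non-negative).
#' @export
polygon_area <- function(x) {
  stopifnot(inherits(x, "contour"))
  abs(shoelace2(x$points)) / 2 * x$pixel_size_mm^2
}

# perimeter bookkeeping: edge lengths and cumulative arc length (pixel units)
contour_cumlen <- function(x) {
  p <- x$points
  n <- nrow(p)
  e <- p[c(2:n, 1L), , drop = FALSE] - p
  len <- sqrt(rowSums(e^2))
  list(edge = e, len = len, cum = c(0, cumsum(len)), total = sum(len))
}

#' Resample a contour uniformly in arc length
#'
#' Produces `n_samples` points equally spaced along the polygon boundary,
#' starting at the stored start vertex. Used as the common parameterization
#' for landmark mapping and warping.
#'
#' @param x a [contour()].
#' @param n_samples number of samples (>= 8).
#' @return a `contour` whose points are the resampled positions, carrying a
#'   field `s` with the normalized arc length of each sample in `[0, 1)`.
#' @export
arc_length_parameterize <- function(x, n_samples) {
  stopifnot(inherits(x, "contour"))
  if (n_samples < 8) stop("n_samples must be >= 8")
  s <- seq(0, 1, length.out = n_samples + 1L)[-(n_samples + 1L)]
  pts <- contour_point_at(x, s)$points
  out <- contour(pts, x$pixel_size_mm, check_simple = FALSE)
  out$s <- s
  out
}

#' Evaluate boundary points and outward normals at arc-length positions
#'
#' @param x a [contour()] (counter-clockwise).
#' @param s normalized arc lengths in `[0, 1)` (values are wrapped).
#' @return list with `points` (n x 2, pixel coordinates) and `normals`
#'   (n x 2 unit outward normals).
#' @export
contour_point_at <- function(x, s) {
  stopifnot(inherits(x, "contour"))
  cl <- contour_cumlen(x)
  s <- s %% 1
  pos <- s * cl$total
  n <- nrow(x$points)
  j <- findInterval(pos, cl$cum, rightmost.closed = TRUE)
  j[j > n] <- n
  t <- (pos - cl$cum[j]) / pmax(cl$len[j], .Machine$double.eps)
  pts <- x$points[j, , drop = FALSE] + cl$edge[j, , drop = FALSE] * t
  tan <- cl$edge[j, , drop = FALSE] / pmax(cl$len[j], .Machine$double.eps)
  # interior lies to the left of a CCW traversal, so outward is to the right
  normals <- cbind(tan[, 2L], -tan[, 1L])
  list(points = pts, normals = normals)
}

#' Radial (arc length, depth) coordinates of points relative to a lumen contour
#'
#' For each query point outside or on the lumen border, returns the normalized
#' arc-length position `s` of the nearest boundary point and the outward depth
#' `d` in millimetres. Equidistant ties resolve toward the smaller arc length.
#'
#' @param points numeric vector of length 2 or an n x 2 matrix of pixel
#'   coordinates.
#' @param lumen a [contour()].
#' @return list with numeric vectors `s` (in `[0,1)`) and `d_mm` (>= 0).
#' @export
radial_coordinates <- function(points, lumen) {
  stopifnot(inherits(lumen, "contour"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  sd <- nearest_on_contour_cpp(points, lumen$points)
  inside <- point_in_polygon_cpp(points, lumen$points)
  bad <- inside & sd[, 2L] > 1e-6
  if (any(bad))
    stop(sprintf("%d point(s) lie strictly inside the lumen; radial depth is undefined there", sum(bad)))
  list(s = sd[, 1L], d_mm = sd[, 2L] * lumen$pixel_size_mm)
}

#' Frame geometry: lumen and EEM contours of one cross-section
#'
#' @param lumen,eem [contour()] objects sharing the same pixel size; the lumen
#'   must lie strictly inside the EEM.
#' @param frame_id identifier.
#' @param longitudinal_position_mm pullback position in mm (optional).
#' @return object of class `frame_geometry`.
#' @export
frame_geometry <- function(lumen, eem, frame_id = NA_character_,
                           longitudinal_position_mm = NA_real_) {
  stopifnot(inherits(lumen, "contour"), inherits(eem, "contour"))
  if (!isTRUE(all.equal(lumen$pixel_size_mm, eem$pixel_size_mm)))
    stop("lumen and EEM must share pixel_size_mm")
  if (!all(point_in_polygon_cpp(lumen$points, eem$points)))
    stop("lumen contour is not strictly inside the EEM contour")
  structure(list(lumen = lumen, eem = eem,
                 frame_id = as.character(frame_id),
                 longitudinal_position_mm = longitudinal_position_mm),
            class = "frame_geometry")
}

#' @export
print.frame_geometry <- function(x, ...) {
  cat(sprintf("<frame_geometry> %s: lumen %.2f mm^2, EEM %.2f mm^2, plaque %.2f mm^2\n",
              x$frame_id, polygon_area(x$lumen), polygon_area(x$eem),
              plaque_area(polygon_area(x$eem), polygon_area(x$lumen))))
  invisible(x)
}

#' Plaque area from EEM and lumen areas
#'
#' Plaque area is defined as EEM area minus lumen area.
#'
#' @param eem_area,lumen_area areas in mm^2, `eem_area >= lumen_area >= 0`.
#' @return plaque area in mm^2.
#' @export
plaque_area <- function(eem_area, lumen_area) {
  if (any(lumen_area < 0) || any(eem_area < 0))
    stop("areas must be non-negative")
  if (any(lumen_area > eem_area + 1e-9))
    stop("lumen area exceeds EEM area: inconsistent annotation")
  pmax(eem_area - lumen_area, 0)
}

#' Plaque burden
#'
#' Plaque burden is plaque area as a percentage of EEM area
#' (plaque area / EEM area x 100).
#'
#' @param plaque_area,eem_area areas in mm^2; `eem_area > 0`.
#' @return percentage in `[0, 100]`.
#' @export
plaque_burden <- function(plaque_area, eem_area) {
  if (any(eem_area <= 0)) stop("EEM area must be positive")
  if (any(plaque_area < 0) || any(plaque_area > eem_area + 1e-9))
    stop("plaque area must lie in [0, EEM area]")
  pmin(pmax(plaque_area / eem_area * 100, 0), 100)
}
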