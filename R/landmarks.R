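#' Landmark correspondences between two lumen contours
#'
#' Ordered pairs of normalized arc-length positions identifying the same
#' anatomical point (e.g. a side-branch ostium) on the histology and imaging
#' lumen borders. The correspondence must be circularly monotone: after
#' rotation alignment both sequences are strictly increasing, i.e. landmark
#' pairs do not cross.
#'
#' @param s_hist,s_img numeric vectors of equal length (>= 2) with values in
#'   `[0, 1)`.
#' @return object of class `landmark_correspondence`.
#' @export
landmark_correspondence <- function(s_hist, s_img) {
  if (length(s_hist) != length(s_img))
    stop("s_hist and s_img must have equal length")
  if (length(s_img) < 2L)
    stop("at least 2 landmark pairs are required")
  if (any(s_hist < 0 | s_hist >= 1) || any(s_img < 0 | s_img >= 1))
    stop("landmark arc lengths must lie in [0, 1)")
  if (anyDuplicated(s_img) || anyDuplicated(s_hist))
    stop("duplicated landmark arc lengths")
  ord <- order(s_img)
  h <- s_hist[ord]
  # circular monotonicity of h: strictly increasing once rotated to its minimum
  k <- which.min(h)
  hr <- if (k == 1L) h else c(h[k:length(h)], h[1:(k - 1L)])
  if (any(diff(hr) <= 0)) {
    j <- which(diff(hr) <= 0)[1L]
    orig <- ord[((k - 1L + j) %% length(h)) + 1L]
    stop(sprintf("landmark pairs cross: pair %d (s_hist = %.4f, s_img = %.4f) breaks circular monotonicity",
                 orig, s_hist[orig], s_img[orig]))
  }
  structure(list(pairs = cbind(s_hist = h, s_img = s_img[ord])),
            class = "landmark_correspondence")
}

#' Piecewise-linear circular arc-length map from landmarks
#'
#' Builds the circumferential scaling map of the co-registration: a strictly
#' monotone, circularly continuous, piecewise-linear interpolation that sends
#' each imaging-frame arc length to the corresponding histology arc length,
#' mapping each landmark exactly and wrapping across the 1 -> 0 seam.
#'
#' @param landmarks a [landmark_correspondence()].
#' @return a vectorized function `s_img -> s_hist` on `[0, 1)`.
#' @export
build_arclength_map <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_correspondence"))
  p <- landmarks$pairs
  n <- nrow(p)
  h <- p[, "s_hist"]; g <- p[, "s_img"]
  gap_img <- (c(g[-1L], g[1L] + 1) - g)          # > 0, sums to 1
  gap_hist <- (c(h[-1L], h[1L]) - h) %% 1
  gap_hist[gap_hist == 0] <- 1                   # n == 1 cannot happen (n >= 2)
  function(s) {
    s <- s %% 1
    j <- findInterval(s, g)
    j[j == 0L] <- n                              # before first landmark: wrap
    frac <- ((s - g[j]) %% 1) / gap_img[j]
    (h[j] + frac * gap_hist[j]) %% 1
  }
}
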