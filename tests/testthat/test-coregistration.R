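test_that("landmark correspondences validate circular monotonicity", {
  expect_s3_class(landmark_correspondence(c(0, 0.5), c(0, 0.5)),
                  "landmark_correspondence")
  expect_error(landmark_correspondence(c(0), c(0)), "at least 2")
  expect_error(landmark_correspondence(c(0, 1.2), c(0, 0.5)), "\\[0, 1\\)")
  # crossing pairs are reported with the offending pair
  expect_error(landmark_correspondence(c(0, 0.5, 0.25), c(0, 0.25, 0.5)),
               "cross")
})

test_that("build_arclength_map interpolates piecewise-linearly with wrap", {
  ident <- build_arclength_map(landmark_correspondence(c(0, 0.5), c(0, 0.5)))
  s <- seq(0, 0.999, by = 0.0625)
  expect_equal(ident(s), s, tolerance = 1e-12)

  m <- build_arclength_map(landmark_correspondence(s_hist = c(0, 0.25),
                                                   s_img = c(0, 0.5)))
  expect_equal(m(0.25), 0.125)
  expect_equal(m(0.5), 0.25)
  expect_equal(m(0.75), 0.625)  # second half maps [0.5,1) -> [0.25,1)

  w <- build_arclength_map(landmark_correspondence(s_hist = c(0.9, 0.4),
                                                   s_img = c(0, 0.5)))
  expect_equal(w(0), 0.9)
  expect_equal(w(0.25), 0.15)
  expect_equal(w(0.5), 0.4)
  # landmarks map exactly, everywhere strictly monotone (circular)
  g <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(w(g)) %% 1 < 0.5))
})

test_that("warping a frame onto itself is the identity on the plaque band", {
  f <- annulus_frame(1.0, 0.6, 0.008, band = c(0.2, 0.4))
  pair <- annulus_pair(f, f)
  w <- warp_histology(pair, strip_depth_mm = 0.8)
  tissue <- f$mask$grid %in% tissue_labels[c("ft", "ca", "nc")]
  agree <- w$mask$grid[tissue & w$valid_region] ==
    f$mask$grid[tissue & w$valid_region]
  expect_gt(mean(agree), 0.99)
  expect_gt(sum(tissue & w$valid_region) / sum(tissue), 0.98)
})

test_that("warped band lands at the source depths with the analytic annulus area", {
  # histology: lumen r = 1 mm, Ca ring at outward depths 0.2-0.5 mm;
  # imaging: lumen twice as large, half the pixel size. The warp preserves
  # physical depth, so the ring must occupy depths 0.2-0.5 mm around the
  # imaging lumen, whose analytic area is pi*((R+0.5)^2 - (R+0.2)^2).
  hist <- annulus_frame(1.0, 0.7, 0.01, band = c(0.2, 0.5))
  img <- annulus_frame(2.0, 0.7, 0.005)
  pair <- annulus_pair(hist, img)
  w <- warp_histology(pair, strip_depth_mm = 0.7)
  ca_mm2 <- sum(w$mask$grid == tissue_labels[["ca"]]) * 0.005^2
  analytic <- pi * ((2 + 0.5)^2 - (2 + 0.2)^2)
  expect_lt(abs(ca_mm2 - analytic) / analytic, 0.05)

  # depth placement: every warped Ca pixel sits in the 0.2-0.5 band
  idx <- which(w$mask$grid == tissue_labels[["ca"]])
  yx <- cbind((idx - 1) %/% nrow(w$mask$grid), (idx - 1) %% nrow(w$mask$grid))
  d <- radial_coordinates(yx, img$geometry$lumen)$d_mm
  expect_gt(mean(d >= 0.19 & d <= 0.51), 0.99)
})

test_that("warp output is invariant to the histology start vertex", {
  hist <- annulus_frame(1.0, 0.6, 0.01, band = c(0.15, 0.35))
  img <- annulus_frame(1.3, 0.6, 0.01)
  pair <- annulus_pair(hist, img)
  w1 <- warp_histology(pair, strip_depth_mm = 0.6)

  # rotate the histology lumen start by 90 vertices (= arc length 0.25) and
  # shift the landmark arc lengths accordingly
  rot <- function(ct, k) contour(ct$points[c((k + 1):nrow(ct$points), 1:k), ],
                                 ct$pixel_size_mm, check_simple = FALSE)
  lum2 <- rot(hist$geometry$lumen, 90L)
  geom2 <- frame_geometry(lum2, hist$geometry$eem, "A")
  s <- (0:3) / 4
  lm2 <- landmark_correspondence(s_hist = (s - 0.25) %% 1, s_img = s)
  pair2 <- matched_pair(list(geometry = geom2, mask = hist$mask),
                        list(geometry = img$geometry, mask = img$mask,
                             modality = "nirs_ivus"), lm2)
  w2 <- warp_histology(pair2, strip_depth_mm = 0.6)
  expect_gt(mean(w1$mask$grid == w2$mask$grid), 0.999)
})

test_that("inverse warps compose: H -> I -> H recovers the band labels", {
  hist <- annulus_frame(1.0, 0.6, 0.01, band = c(0.15, 0.4))
  img <- annulus_frame(1.5, 0.6, 0.008)
  pair <- annulus_pair(hist, img)
  w <- warp_histology(pair, strip_depth_mm = 0.6)
  back_pair <- matched_pair(
    histology = list(geometry = img$geometry, mask = w$mask),
    imaging = list(geometry = hist$geometry, mask = hist$mask,
                   modality = "nirs_ivus"),
    landmarks = identity_landmarks(4L))
  wb <- warp_histology(back_pair, strip_depth_mm = 0.6)
  band <- hist$mask$grid %in% tissue_labels[c("ft", "ca", "nc")] &
    wb$valid_region & wb$mask$grid != tissue_labels[["background"]]
  expect_gt(mean(wb$mask$grid[band] == hist$mask$grid[band]), 0.95)
})

test_that("warping an empty histology yields an empty mask but a valid region", {
  hist <- annulus_frame(1.0, 0.5, 0.01)
  hist$mask$grid[hist$mask$grid == tissue_labels[["ft"]]] <-
    tissue_labels[["background"]]
  img <- annulus_frame(1.2, 0.5, 0.01)
  pair <- annulus_pair(hist, img)
  w <- warp_histology(pair, strip_depth_mm = 0.5)
  expect_false(any(w$mask$grid %in% tissue_labels[c("ft", "ca", "nc")]))
  expect_gt(sum(w$valid_region), 0)
  expect_error(warp_histology(pair, strip_depth_mm = -1), "positive")
})

test_that("render_hybrid composes deterministically on the imaging grid", {
  f <- annulus_frame(0.8, 0.4, 0.02, band = c(0.1, 0.3))
  pair <- annulus_pair(f, f)
  w <- warp_histology(pair, strip_depth_mm = 0.5)
  ov <- render_hybrid(pair, w)
  expect_equal(dim(ov)[1:2], dim(f$mask$grid))
  expect_true(all(ov >= 0 & ov <= 1))

  # empty warped mask: overlay equals the imaging-only rendering
  w0 <- w
  w0$mask$grid[] <- tissue_labels[["background"]]
  w0$valid_region[] <- FALSE
  ov0 <- render_hybrid(pair, w0)
  pal <- attr(ov0, "legend")
  base_r <- t(grDevices::col2rgb(pal))[, 1] / 255
  expect_equal(as.vector(ov0[, , 1]),
               unname(base_r[match(as.vector(f$mask$grid), tissue_labels)]))

  # grid mismatch errors
  f2 <- annulus_frame(0.8, 0.4, 0.025)
  pair2 <- annulus_pair(f2, f2)
  expect_error(render_hybrid(pair2, w), "mismatch")
})
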