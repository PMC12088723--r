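make_mask <- function(grid, px = 0.1) tissue_label_mask(grid, px)

test_that("overlap_analysis reports both directions of disagreement", {
  a <- matrix(FALSE, 20, 20); a[5:15, 5:15] <- TRUE
  expect_equal(overlap_analysis(a, a, 0.1)$overlap_pct, 100)
  expect_equal(overlap_analysis(a, a, 0.1)$hist_only_pct, 0)

  b <- matrix(FALSE, 20, 20); b[1:3, 1:3] <- TRUE
  ov <- overlap_analysis(a, b, 0.1)
  expect_equal(ov$overlap_pct, 0)
  expect_equal(ov$hist_only_pct, 100)
  expect_equal(ov$ml_only_pct, 100)

  half <- a; half[, 11:15] <- FALSE   # ml = left part of hist
  ovh <- overlap_analysis(a, half, 0.1)
  expect_equal(ovh$overlap_pct, 100 * sum(half) / sum(a))
  expect_equal(ovh$ml_only_pct, 0)

  expect_error(overlap_analysis(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2), 0.1),
               "empty histology")
})

test_that("extract_rois separates components by connectivity and filters area", {
  g <- matrix(tissue_labels[["background"]], 20, 20)
  g[3:6, 3:6] <- tissue_labels[["ca"]]
  rois <- extract_rois(make_mask(g), min_area_mm2 = 0.01)
  expect_length(rois, 1L)
  expect_equal(rois[[1L]]$tissue_class, "ca")
  expect_equal(rois[[1L]]$area_mm2, 16 * 0.01)

  # two blobs touching only diagonally
  g2 <- matrix(tissue_labels[["background"]], 20, 20)
  g2[3:5, 3:5] <- tissue_labels[["ca"]]
  g2[6:8, 6:8] <- tissue_labels[["ca"]]
  expect_length(extract_rois(make_mask(g2), connectivity = 8L,
                             min_area_mm2 = 0.01), 1L)
  expect_length(extract_rois(make_mask(g2), connectivity = 4L,
                             min_area_mm2 = 0.01), 2L)

  # sub-threshold blob dropped
  g3 <- g
  g3[15, 15] <- tissue_labels[["nc"]]          # 0.01 mm^2 exactly: kept
  g3[18, 18] <- tissue_labels[["ft"]]
  rois3 <- extract_rois(make_mask(g3), min_area_mm2 = 0.02)
  expect_equal(vapply(rois3, `[[`, "", "tissue_class"), "ca")

  # deterministic ordering: FT before Ca before NC
  g4 <- matrix(tissue_labels[["background"]], 20, 20)
  g4[10:12, 10:12] <- tissue_labels[["nc"]]
  g4[2:4, 2:4] <- tissue_labels[["ca"]]
  g4[15:17, 15:17] <- tissue_labels[["ft"]]
  expect_equal(vapply(extract_rois(make_mask(g4), min_area_mm2 = 0.01),
                      `[[`, "", "tissue_class"), c("ft", "ca", "nc"))
})

test_that("region_level_confusion tallies predominant classes, ties and misses", {
  px <- 0.1
  eem <- circle_contour(9, 90L, px, center = c(9.5, 9.5))
  ml_g <- matrix(tissue_labels[["background"]], 20, 20)
  ml_g[4:9, 4:9] <- tissue_labels[["ca"]]
  ml <- make_mask(ml_g)

  roi <- function(cls, idx) structure(list(tissue_class = cls, pixels = idx,
                                           area_mm2 = length(idx) * px^2,
                                           frame_id = "t"), class = "roi")
  # fully covered Ca ROI
  ca_idx <- which(ml_g == tissue_labels[["ca"]])
  cm <- region_level_confusion(list(roi("ca", ca_idx)), ml, eem)
  expect_equal(cm$mat["ca", "ca"], 1)

  # NC ROI with 60% FT / 40% NC coverage -> predominant FT
  g2 <- matrix(tissue_labels[["background"]], 20, 20)
  g2[1:10, 1] <- c(rep(tissue_labels[["ft"]], 6), rep(tissue_labels[["nc"]], 4))
  cm2 <- region_level_confusion(list(roi("nc", 1:10)), make_mask(g2), eem)
  expect_equal(cm2$mat["nc", "ft"], 1)
  expect_equal(sum(cm2$mat), 1)

  # 50/50 tie between Ca and FT -> Ca by fixed priority
  g3 <- matrix(tissue_labels[["background"]], 20, 20)
  g3[1:10, 1] <- c(rep(tissue_labels[["ft"]], 5), rep(tissue_labels[["ca"]], 5))
  cm3 <- region_level_confusion(list(roi("nc", 1:10)), make_mask(g3), eem)
  expect_equal(cm3$mat["nc", "ca"], 1)

  # ROI wholly outside the ML EEM with no ML tissue -> missed, no 3x3 cell
  far_idx <- which(row(ml_g) >= 19 & col(ml_g) >= 19)
  cm4 <- region_level_confusion(list(roi("ca", far_idx)), ml, eem)
  expect_equal(sum(cm4$mat), 0)
  expect_equal(unname(cm4$missed["ca"]), 1)

  # ROI inside the EEM left unlabeled by ML -> unclassified, surfaced apart
  in_idx <- which(row(ml_g) %in% 12:13 & col(ml_g) %in% 12:13)
  cm5 <- region_level_confusion(list(roi("nc", in_idx)), ml, eem)
  expect_equal(sum(cm5$mat), 0)
  expect_equal(unname(cm5$unclassified["nc"]), 1)
})

test_that("area_level_confusion distributes mass and conserves it", {
  f <- annulus_frame(0.8, 0.5, 0.01, band = c(0.1, 0.3), band_class = "nc")
  ml_same <- f$mask
  cm <- area_level_confusion(f$mask, ml_same, f$geometry$eem)
  expect_equal(cm$mat["ft", "ca"], 0)
  expect_equal(cm$mat["nc", "ft"], 0)
  expect_gt(cm$mat["nc", "nc"], 0)

  # relabel all ML NC as FT: the NC row mass moves to (nc, ft)
  ml2 <- f$mask
  ml2$grid[ml2$grid == tissue_labels[["nc"]]] <- tissue_labels[["ft"]]
  cm2 <- area_level_confusion(f$mask, ml2, f$geometry$eem)
  expect_equal(cm2$mat["nc", "ft"], cm$mat["nc", "nc"])
  expect_equal(cm2$mat["nc", "nc"], 0)

  # conservation: matrix + unclassified + missed = warped plaque area
  px2 <- f$mask$pixel_size_mm^2
  plaque <- sum(f$mask$grid %in% tissue_labels[c("ft", "ca", "nc")]) * px2
  total <- sum(cm2$mat) + sum(cm2$unclassified) + sum(cm2$missed)
  expect_equal(total, plaque, tolerance = 1e-9)
})

test_that("metrics_from_confusion reproduces the hand formulas", {
  cm <- confusion_matrix(diag(c(5, 5, 5)), "region")
  m <- metrics_from_confusion(cm)
  expect_equal(m$per_class$sensitivity, rep(1, 3))
  expect_equal(m$per_class$precision, rep(1, 3))
  expect_equal(m$accuracy, 100)

  # brute-force per-class TP/FP/FN oracle on random matrices
  set.seed(99)
  for (i in 1:200) {
    M <- matrix(rpois(9, 20), 3, 3)
    if (any(rowSums(M) == 0) || any(colSums(M) == 0)) next
    m <- metrics_from_confusion(confusion_matrix(M, "region"))
    for (k in 1:3) {
      tp <- M[k, k]; fn <- sum(M[k, -k]); fp <- sum(M[-k, k])
      expect_equal(m$per_class$sensitivity[k], tp / (tp + fn))
      expect_equal(m$per_class$precision[k], tp / (tp + fp))
      expect_equal(m$per_class$f_score[k],
                   2 * (tp / (tp + fp)) * (tp / (tp + fn)) /
                     (tp / (tp + fp) + tp / (tp + fn)))
    }
    expect_equal(m$accuracy, 100 * sum(diag(M)) / sum(M))
    # row-sum weighting makes weighted sensitivity identical to accuracy
    expect_equal(m$weighted_sensitivity, m$accuracy / 100)
  }
  expect_error(metrics_from_confusion(confusion_matrix(matrix(0, 3, 3), "region")),
               "empty")
})

test_that("class permutations permute the metrics consistently", {
  set.seed(41)
  M <- matrix(rpois(9, 15) + 1, 3, 3)
  base <- metrics_from_confusion(confusion_matrix(M, "region"))
  p <- c(3, 1, 2)
  perm <- metrics_from_confusion(confusion_matrix(M[p, p], "region"))
  expect_equal(perm$per_class$sensitivity, base$per_class$sensitivity[p])
  expect_equal(perm$per_class$precision, base$per_class$precision[p])
  expect_equal(perm$accuracy, base$accuracy)
  expect_equal(perm$weighted_f_score, base$weighted_f_score)
})

test_that("missed_tissue_report converts missed mass to percentages", {
  base <- matrix(0, 3, 3); base[3, 3] <- 17.9
  cm <- confusion_matrix(base, "area", missed = c(0, 0, 3.68))
  rep <- missed_tissue_report(cm)
  expect_equal(rep$missed_pct[rep$class == "nc"], 100 * 3.68 / 21.58,
               tolerance = 1e-9)
  expect_equal(rep$missed_pct[rep$class == "ft"], 0)

  cm0 <- confusion_matrix(diag(3), "area")
  expect_equal(missed_tissue_report(cm0)$missed_pct, rep(0, 3))

  cm_all <- confusion_matrix(matrix(0, 3, 3), "area", missed = c(0, 5, 0))
  expect_equal(missed_tissue_report(cm_all)$missed_pct[2], 100)
})

test_that("error_vs_burden delegates to the Pearson correlation", {
  burden <- seq(30, 80, length.out = 20)
  expect_equal(error_vs_burden(0.1 * burden, burden)$r, 1)
  set.seed(4)
  e <- rnorm(1000); b <- runif(1000, 30, 80)
  expect_lt(abs(error_vs_burden(e, b)$r), 0.1)
  expect_error(error_vs_burden(rep(1, 20), burden), "variance")
})
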