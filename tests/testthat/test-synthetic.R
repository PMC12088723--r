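test_that("generation is deterministic per seed and validates its config", {
  cfg <- synthetic_config(ca_count_range = c(1L, 2L), nc_count_range = c(1L, 2L))
  v1 <- generate_vessel(cfg, seed = 20)
  v2 <- generate_vessel(cfg, seed = 20)
  expect_identical(v1$mask$grid, v2$mask$grid)
  expect_identical(v1$truth, v2$truth)
  v3 <- generate_vessel(cfg, seed = 21)
  expect_false(identical(v1$mask$grid, v3$mask$grid))

  expect_error(synthetic_config(misclass = matrix(1, 3, 3)), "row-stochastic")
  expect_error(synthetic_config(shrink = 0), "shrink")
  expect_error(synthetic_config(nonsense = 1), "unknown config")
})

test_that("zero inclusions give a pure FT plaque matching the analytic areas", {
  cfg <- synthetic_config(ca_count_range = c(0L, 0L), nc_count_range = c(0L, 0L))
  v <- generate_vessel(cfg, seed = 3)
  areas <- mask_class_areas(v$mask)
  expect_equal(unname(areas["ca"] + areas["nc"]), 0)
  expect_equal(unname(areas["ft"]), v$truth$plaque_area, tolerance = 0.02)
  expect_equal(v$truth$ft_area, v$truth$plaque_area)
})

test_that("histology degradation scales the lumen by the squared shrink factor", {
  cfg <- synthetic_config(shrink = 0.7, ca_count_range = c(0L, 1L),
                          nc_count_range = c(0L, 1L))
  v <- generate_vessel(cfg, seed = 9)
  h1 <- degrade_to_histology(v, seed = 4)
  ratio <- polygon_area(h1$geometry$lumen) / polygon_area(v$geometry$lumen)
  expect_equal(ratio, 0.49, tolerance = 0.02)

  h2 <- degrade_to_histology(v, seed = 4)
  expect_identical(h1$mask$grid, h2$mask$grid)

  # shrink 1 with equal pixel sizes reproduces the truth frame
  cfg_id <- identity_config()
  vi <- generate_vessel(cfg_id, seed = 9)
  hi <- degrade_to_histology(vi, seed = 4)
  expect_gt(mean(hi$mask$grid == vi$mask$grid), 0.995)
  expect_equal(hi$landmarks$pairs[, "s_hist"], hi$landmarks$pairs[, "s_img"])
})

test_that("the landmark correspondence encodes the applied distortion", {
  cfg <- synthetic_config(distortion_amp = 0.05, rotate = TRUE,
                          landmark_count = 12L)
  v <- generate_vessel(cfg, seed = 15)
  h <- degrade_to_histology(v, seed = 5)
  s <- h$landmarks$pairs[, "s_img"]
  expect_equal(h$landmarks$pairs[, "s_hist"], h$distortion$g(s),
               tolerance = 1e-12)
  # the piecewise-linear landmark map approximates the smooth truth map
  amap <- build_arclength_map(h$landmarks)
  sg <- seq(0, 0.99, by = 0.01)
  err <- abs(amap(sg) - h$distortion$g(sg))
  expect_lt(max(pmin(err, 1 - err)), 0.01)
})

test_that("identity classification reproduces the truth mask exactly", {
  cfg <- synthetic_config(ca_count_range = c(1L, 2L), nc_count_range = c(1L, 2L))
  v <- generate_vessel(cfg, seed = 31)
  ml <- simulate_ml_estimation(v, seed = 6)
  expect_identical(ml$mask$grid, v$mask$grid)
  expect_equal(polygon_area(ml$geometry$eem), v$truth$eem_area)
})

test_that("an injected EEM bias shifts the ML EEM area exactly", {
  cfg <- synthetic_config(ml_eem_bias_mm2 = 1.5)
  v <- generate_vessel(cfg, seed = 32)
  ml <- simulate_ml_estimation(v, seed = 7)
  expect_equal(polygon_area(ml$geometry$eem), v$truth$eem_area + 1.5,
               tolerance = 1e-4)
})

test_that("OCT truncation hides deep tissue outside the ML EEM", {
  cfg <- synthetic_config(modality = "oct", oct_truncation_mm = 0.5,
                          wall_thickness_range = c(1.2, 1.4),
                          ca_count_range = c(0L, 0L), nc_count_range = c(0L, 0L))
  v <- generate_vessel(cfg, seed = 33)
  ml <- simulate_ml_estimation(v, seed = 8)
  expect_lt(polygon_area(ml$geometry$eem), v$truth$eem_area)
  # histology tissue (truth mask) beyond the truncated EEM is tallied missed
  cm <- area_level_confusion(v$mask, ml$mask, ml$geometry$eem)
  expect_gt(sum(cm$missed), 0)
  # deep tissue within the truncated band reads as NC
  expect_gt(sum(ml$mask$grid == tissue_labels[["nc"]]), 0)
})

test_that("cohorts are reproducible, spaced, and carry truth records", {
  cfg <- identity_config(ca_count_range = c(0L, 1L), nc_count_range = c(0L, 1L))
  co1 <- generate_cohort(cfg, n_frames = 2, seed = 77)
  co2 <- generate_cohort(cfg, n_frames = 2, seed = 77)
  expect_identical(co1[[1]]$histology$mask$grid, co2[[1]]$histology$mask$grid)
  expect_identical(co1[[2]]$imaging$mask$grid, co2[[2]]$imaging$mask$grid)
  pos <- vapply(co1, function(p) p$imaging$geometry$longitudinal_position_mm,
                numeric(1))
  expect_true(all(diff(pos) >= 0.4))
  expect_s3_class(co1[[1]], "matched_pair")
  expect_true(is.list(co1[[1]]$truth$record))
  expect_equal(co1[[1]]$imaging$geometry$frame_id, "F001")
})
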