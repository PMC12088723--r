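test_that("bland_altman computes bias, SD and limits of agreement", {
  a <- c(1, 2, 3)
  expect_equal(bland_altman(a, a)[c("bias", "sd")], list(bias = 0, sd = 0))
  ba <- bland_altman(c(1, 2, 3), c(2, 3, 5))
  expect_equal(ba$bias, -4 / 3)
  expect_equal(ba$sd, sd(c(-1, -1, -2)))
  expect_equal(ba$sd, 0.5774, tolerance = 1e-4)
  expect_equal(ba$loa_low, ba$bias - 1.96 * ba$sd)
  b2 <- bland_altman(a + 2, a)
  expect_equal(b2[c("bias", "sd")], list(bias = 2, sd = 0))
  # antisymmetry: swapping arguments flips the bias, SD unchanged
  ba2 <- bland_altman(c(2, 3, 5), c(1, 2, 3))
  expect_equal(ba2$bias, -ba$bias)
  expect_equal(ba2$sd, ba$sd)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("Lin's CCC matches the moment formula and its properties", {
  expect_equal(concordance_correlation(c(1, 2, 3), c(1, 2, 3))$ccc, 1)
  cc <- concordance_correlation(c(1, 2, 3), c(2, 4, 6))
  expect_equal(cc$ccc, 8 / 22)  # cov 4/3, vars 2/3 and 8/3, mean gap^2 = 4
  expect_lt(concordance_correlation(c(1, 2, 3), c(3, 2, 1) + 1)$ccc, 0)
  expect_error(concordance_correlation(c(1, 1, 1), c(2, 2, 2)), "constant")

  set.seed(5)
  for (i in 1:100) {
    x <- rnorm(10); y <- rnorm(10, mean = runif(1, -2, 2))
    cc <- concordance_correlation(x, y)
    expect_lte(abs(cc$ccc), abs(cor(x, y)) + 1e-12)       # Lin's inequality
    expect_true(cc$ci_low <= cc$ccc && cc$ccc <= cc$ci_high)
    expect_equal(concordance_correlation(x, x)$ccc, 1)
  }
})

test_that("rank_sum_test counts exceedance pairs and enumerates exactly", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$U, 0)
  expect_equal(rank_sum_test(c(1, 3), c(2, 4))$U, 1)
  x <- c(1, 2, 2, 5)
  expect_equal(rank_sum_test(x, x)$U, length(x)^2 / 2)

  # U + U' = n_a * n_b, and U equals the brute-force pair count
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:6, 5, replace = TRUE)
    b <- sample(1:6, 4, replace = TRUE)
    r <- rank_sum_test(a, b)
    brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(r$U, brute)
    expect_equal(r$U + rank_sum_test(b, a)$U, length(a) * length(b))
  }

  # exact p agrees with wilcox.test's exact distribution when there are no ties
  a <- c(1.1, 3.4, 0.2, 5.5)
  b <- c(2.2, 4.1, 6.3)
  expect_equal(rank_sum_test(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(rank_sum_test(a, b)$method, "exact")

  # large samples use the tie-corrected normal approximation
  set.seed(8)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  expect_equal(rank_sum_test(a, b)$p,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("normality gate selects the t or rank branch", {
  set.seed(21)
  a <- rnorm(100); b <- rnorm(100, 0.1)
  r <- normality_and_t(a, b)
  expect_equal(r$branch, "t")
  expect_gt(r$ks_p_a, 0.05)

  h <- rcauchy(100)
  r2 <- normality_and_t(h, rnorm(100))
  expect_equal(r2$branch, "rank")

  same <- normality_and_t(a, a)
  expect_gt(same$p, 0.99)
  expect_error(normality_and_t(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("pearson_correlation matches cor.test and its bounds", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x)$r, 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  set.seed(31)
  xx <- rnorm(1000); yy <- rnorm(1000)
  expect_lt(abs(pearson_correlation(xx, yy)$r), 0.1)
  expect_error(pearson_correlation(x, rep(1, 4)), "variance")
})

test_that("areas_from_mask measures classes and geometry consistently", {
  f <- annulus_frame(1.0, 0.5, 0.01)
  f$mask$grid[f$mask$grid == tissue_labels[["ft"]]] <- tissue_labels[["background"]]
  rec <- areas_from_mask(f$mask, f$geometry, "histology")
  expect_equal(rec$ft_area + rec$ca_area + rec$nc_area, 0)
  expect_equal(rec$plaque_area, rec$eem_area - rec$lumen_area)

  g <- matrix(tissue_labels[["background"]], 64, 64)
  g[1:10, 1:10] <- tissue_labels[["ft"]]
  m <- tissue_label_mask(g, 0.1)
  lum <- circle_contour(8, 90L, 0.1, center = c(40, 40))
  eem <- circle_contour(20, 90L, 0.1, center = c(40, 40))
  rec2 <- areas_from_mask(m, frame_geometry(lum, eem, "x"), "ml")
  expect_equal(rec2$ft_area, 1.0)

  # generator truth as oracle: realized areas within 2%
  v <- generate_vessel(synthetic_config(ca_count_range = c(1L, 1L),
                                        nc_count_range = c(1L, 1L)), seed = 5)
  rec3 <- areas_from_mask(v$mask, v$geometry, "histology")
  expect_equal(rec3$eem_area, v$truth$eem_area, tolerance = 0.02)
  expect_equal(rec3$ft_area, v$truth$ft_area, tolerance = 0.02)
  expect_equal(rec3$ca_area, v$truth$ca_area, tolerance = 0.02)
  expect_equal(rec3$nc_area, v$truth$nc_area, tolerance = 0.02)
})

test_that("cohort_quant_table mirrors the per-quantity statistics", {
  set.seed(13)
  n <- 12
  hist <- data.frame(frame_id = sprintf("F%02d", 1:n), source = "histology",
                     eem_area = runif(n, 10, 16), lumen_area = runif(n, 4, 6))
  hist$plaque_area <- hist$eem_area - hist$lumen_area
  hist$plaque_burden <- 100 * hist$plaque_area / hist$eem_area
  hist$ft_area <- hist$plaque_area * 0.8
  hist$ca_area <- hist$plaque_area * 0.15
  hist$nc_area <- hist$plaque_area * 0.05

  ml <- hist; ml$source <- "ml"
  tab <- cohort_quant_table(hist, ml)
  expect_equal(tab$mean_difference, rep(0, 6))
  expect_equal(tab$ccc, rep(1, 6))

  ml2 <- ml
  ml2$eem_area <- ml2$eem_area + 1
  tab2 <- cohort_quant_table(hist, ml2)
  expect_equal(tab2$mean_difference[tab2$quantity == "EEM area"], -1)
  expect_lt(tab2$ccc[tab2$quantity == "EEM area"], 1)
  # lumen is never a compared quantity
  expect_false(any(grepl("umen", tab2$quantity)))

  ml3 <- ml[sample(n), ]
  ml3$frame_id[1] <- "F99"
  expect_error(cohort_quant_table(hist, ml3), "unpaired.*F99|F99")
})
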