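#' Bland-Altman agreement of paired measurements
#'
#' @param a,b numeric vectors of equal length n >= 2. Differences are taken
#'   as `a - b`.
#' @return list with `bias` (mean difference), `sd` (sample SD of the
#'   differences), `loa_low`, `loa_high` (bias -/+ 1.96 sd) and `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("Bland-Altman needs n >= 2")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements, penalizing both location/scale
#' shift and scatter: `ccc = 2 cov(a,b) / (var(a) + var(b) + (mean(a) -
#' mean(b))^2)` with population (1/n) moments. The 95% confidence interval
#' uses the Fisher z-transform with Lin's asymptotic standard error.
#'
#' @param a,b numeric vectors, n >= 3, with non-zero variance in at least one.
#' @param conf_level confidence level (default 0.95).
#' @return list with `ccc`, `ci_low`, `ci_high`, `pearson_r` and `n`.
#' @export
concordance_correlation <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 3L) stop("CCC needs n >= 3")
  va <- mean((a - mean(a))^2)
  vb <- mean((b - mean(b))^2)
  if (va == 0 && vb == 0)
    stop("both vectors are constant; CCC is undefined")
  cab <- mean((a - mean(a)) * (b - mean(b)))
  ccc <- 2 * cab / (va + vb + (mean(a) - mean(b))^2)

  if (va == 0 || vb == 0) {
    # degenerate: one constant vector; concordance is 0 and the CI collapses
    return(list(ccc = ccc, ci_low = ccc, ci_high = ccc,
                pearson_r = NA_real_, n = n))
  }
  r <- cab / sqrt(va * vb)
  if (abs(ccc) >= 1 - 1e-12 || abs(r) < 1e-12) {
    return(list(ccc = ccc, ci_low = ccc, ci_high = ccc, pearson_r = r, n = n))
  }
  u <- (mean(a) - mean(b)) / sqrt(sqrt(va) * sqrt(vb))
  z <- atanh(ccc)
  se_z <- sqrt(((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(ccc = ccc, ci_low = tanh(z - q * se_z), ci_high = tanh(z + q * se_z),
       pearson_r = r, n = n)
}

#' Mann-Whitney U rank-sum test
#'
#' `U` counts the pairs `(a_i, b_j)` with `a_i > b_j`, plus half of the tied
#' pairs. The two-sided p-value uses the tie-corrected normal approximation
#' (with continuity correction) when both samples exceed 8 observations, and
#' exact permutation enumeration of the group assignment otherwise, so ties
#' are handled exactly in small samples.
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list with `U`, `p`, `n_a`, `n_b` and `method`.
#' @export
rank_sum_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (min(na, nb) > 8L) {
    nn <- na + nb
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, n_a = na, n_b = nb,
                                 method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  } else {
    comb <- utils::combn(na + nb, na)
    stat <- apply(comb, 2L, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    p <- mean(abs(stat - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  }
  list(U = U, p = min(p, 1), n_a = na, n_b = nb, method = method)
}

#' Normality-gated two-group comparison
#'
#' Tests each group against a fitted normal distribution with the
#' Kolmogorov-Smirnov test; if both groups pass at `alpha`, the groups are
#' compared with Student's t-test, otherwise with the Mann-Whitney U test.
#'
#' @param a,b numeric vectors, n >= 3 each.
#' @param alpha significance level of the normality gate (default 0.05).
#' @return list with `ks_p_a`, `ks_p_b`, `branch` (`"t"` or `"rank"`) and `p`.
#' @export
normality_and_t <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
  ksp <- function(x) {
    if (stats::sd(x) == 0) return(0)  # constant data: certainly not normal
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  pa <- ksp(a); pb <- ksp(b)
  if (pa > alpha && pb > alpha) {
    list(ks_p_a = pa, ks_p_b = pb, branch = "t",
         p = stats::t.test(a, b, var.equal = TRUE)$p.value)
  } else {
    list(ks_p_a = pa, ks_p_b = pb, branch = "rank",
         p = rank_sum_test(a, b)$p)
  }
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, n >= 3, both with non-zero variance.
#' @return list with `r`, `p` (t-distribution) and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohort-level quantitative agreement table
#'
#' The machine twin of a Table-1-style summary: for each of EEM area, plaque
#' area, plaque burden and FT/Ca/NC areas, group means and SDs, the mean
#' paired difference (histology minus ML, so negative values mean the
#' classifier overestimates), its SD and 95% limits of agreement, the
#' Mann-Whitney p-value between the two sets of estimations, and Lin's CCC
#' with its 95% CI. Lumen areas are computed per frame but deliberately not
#' compared: decompressed histological sections shrink, so their lumen cannot
#' be validly compared with pressurized in vivo imaging.
#'
#' @param hist_records,ml_records data frames as returned by
#'   [areas_from_mask()], paired by `frame_id`.
#' @return data.frame of class `cohort_quant_table`, one row per quantity with
#'   columns `quantity`, `n`, `mean_hist`, `sd_hist`, `mean_ml`, `sd_ml`,
#'   `mean_difference`, `sd_difference`, `loa_low`, `loa_high`, `ci_diff_low`,
#'   `ci_diff_high`, `p_rank_test`, `ccc`, `ccc_ci_low`, `ccc_ci_high`.
#' @export
cohort_quant_table <- function(hist_records, ml_records) {
  unpaired <- c(setdiff(hist_records$frame_id, ml_records$frame_id),
                setdiff(ml_records$frame_id, hist_records$frame_id))
  if (length(unpaired))
    stop(sprintf("unpaired frame id(s): %s", paste(unique(unpaired), collapse = ", ")))
  ml <- ml_records[match(hist_records$frame_id, ml_records$frame_id), ]
  quantities <- c(eem_area = "EEM area", plaque_area = "Plaque area",
                  plaque_burden = "Plaque burden", ft_area = "FT area",
                  ca_area = "Ca area", nc_area = "NC area")
  rows <- lapply(names(quantities), function(q) {
    h <- hist_records[[q]]; m <- ml[[q]]
    ba <- bland_altman(h, m)
    cc <- tryCatch(concordance_correlation(h, m),
                   error = function(e) list(ccc = NA_real_, ci_low = NA_real_,
                                            ci_high = NA_real_))
    se <- ba$sd / sqrt(ba$n)
    data.frame(
      quantity = quantities[[q]], n = ba$n,
      mean_hist = mean(h), sd_hist = stats::sd(h),
      mean_ml = mean(m), sd_ml = stats::sd(m),
      mean_difference = ba$bias, sd_difference = ba$sd,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      ci_diff_low = ba$bias - 1.96 * se, ci_diff_high = ba$bias + 1.96 * se,
      p_rank_test = rank_sum_test(h, m)$p,
      ccc = cc$ccc, ccc_ci_low = cc$ci_low, ccc_ci_high = cc$ci_high,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_quant_table", "data.frame")
  out
}

#' @export
print.cohort_quant_table <- function(x, digits = 3, ...) {
  cat("Quantitative agreement (histology - ML)\n")
  df <- data.frame(
    quantity = x$quantity,
    histology = sprintf("%.2f ± %.2f", x$mean_hist, x$sd_hist),
    ml = sprintf("%.2f ± %.2f", x$mean_ml, x$sd_ml),
    `mean diff` = sprintf("%.2f ± %.2f", x$mean_difference, x$sd_difference),
    p = format.pval(x$p_rank_test, digits = 2),
    ccc = sprintf("%.2f (%.2f-%.2f)", x$ccc, x$ccc_ci_low, x$ccc_ci_high),
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}
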