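#' Run the full histology-vs-imaging agreement analysis
#'
#' Orchestrates the validation end to end over a cohort of matched pairs:
#' applies the frame-spacing filter, warps each histology frame onto its
#' imaging geometry, builds the quantitative agreement table (EEM, plaque
#' area, plaque burden, FT/Ca/NC areas), the overlapping/non-overlapping
#' plaque-area analysis, region- and area-level confusion matrices with their
#' classification metrics, the missed-tissue accounting, the plaque-area
#' error vs burden correlation, and — when CD68 masks are present — the
#' macrophage-rich area comparison. Per-frame failures are recorded and
#' skipped.
#'
#' @param cohort list of [matched_pair()] objects, or a manifest from
#'   [read_manifest()] whose pairs are loaded on demand.
#' @param strip_depth_mm strip thickness passed to [warp_histology()];
#'   default derives it per frame from the imaging EEM.
#' @param angular_samples circumferential warp resolution (default 720).
#' @param min_spacing_mm frame-spacing filter threshold in mm (default 0.4).
#' @param connectivity,min_roi_area_mm2 ROI extraction parameters.
#' @param keep_warped if `TRUE`, retain per-frame warped masks in the result
#'   (memory-heavy; default `FALSE`).
#' @param verbose log per-frame progress (default `FALSE`).
#' @return object of class `plaque_agreement` with components `quant`
#'   (a [cohort_quant_table()]), `overlap` (per-frame data.frame and pooled
#'   means), `confusion_region`, `confusion_area`, `metrics_region`,
#'   `metrics_area`, `missed`, `error_vs_burden`, `macrophage` (or NULL),
#'   `per_frame`, `excluded`, and `failures`.
#' @export
run_pipeline <- function(cohort, strip_depth_mm = NULL, angular_samples = 720L,
                         min_spacing_mm = 0.4, connectivity = 8L,
                         min_roi_area_mm2 = 0.01, keep_warped = FALSE,
                         verbose = FALSE) {
  from_manifest <- is.list(cohort) && !is.null(cohort$pairs) &&
    !inherits(cohort, "matched_pair")
  if (from_manifest) {
    manifest <- filter_matched_frames(cohort, min_spacing_mm)
    excluded <- manifest$excluded$frame_id
    loader <- function(i) load_matched_pair(
      file.path(manifest$dir, manifest$pairs$path[i]))
    n <- nrow(manifest$pairs)
    ids <- manifest$pairs$frame_id
  } else {
    if (!length(cohort)) stop("empty cohort")
    pos <- vapply(cohort, function(p) p$imaging$geometry$longitudinal_position_mm,
                  numeric(1))
    keep <- if (all(is.na(pos))) rep(TRUE, length(cohort))
            else filter_matched_frames(pos, min_spacing_mm)
    excluded <- vapply(cohort[!keep], function(p) p$imaging$geometry$frame_id, "")
    cohort <- cohort[keep]
    loader <- function(i) cohort[[i]]
    n <- length(cohort)
    ids <- vapply(cohort, function(p) p$imaging$geometry$frame_id, "")
  }
  if (n == 0L) stop("no frames left after the spacing filter")

  hist_records <- list(); ml_records <- list()
  overlap_rows <- list(); failures <- list(); warped_list <- list()
  cm_region <- cm_area <- NULL
  mac_hist <- mac_ml <- numeric(0)

  for (i in seq_len(n)) {
    fid <- ids[i]
    res <- tryCatch({
      pair <- loader(i)
      warped <- warp_histology(pair, strip_depth_mm, angular_samples)
      hrec <- areas_from_mask(pair$histology$mask, pair$histology$geometry,
                              "histology")
      mrec <- areas_from_mask(pair$imaging$mask, pair$imaging$geometry, "ml")
      wp <- plaque_pixels(warped$mask)
      mp <- plaque_pixels(pair$imaging$mask)
      ov <- overlap_analysis(wp, mp, warped$mask$pixel_size_mm)
      rois <- extract_rois(warped, connectivity, min_roi_area_mm2)
      cr <- region_level_confusion(rois, pair$imaging$mask,
                                   pair$imaging$geometry$eem)
      ca <- area_level_confusion(warped, pair$imaging$mask,
                                 pair$imaging$geometry$eem)
      mac <- NULL
      if (!is.null(pair$histology$cd68)) {
        rich <- detect_macrophage_rich(pair$histology$cd68)
        ml_area <- if (!is.null(pair$imaging$mac_region))
          sum(pair$imaging$mac_region) * pair$imaging$mask$pixel_size_mm^2
        else sum(pair$imaging$mask$grid == tissue_labels[["mac"]]) *
          pair$imaging$mask$pixel_size_mm^2
        mac <- c(hist = rich$area_mm2, ml = ml_area)
      }
      list(hrec = hrec, mrec = mrec, ov = ov, cr = cr, ca = ca, mac = mac,
           warped = if (keep_warped) warped else NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[fid]] <- conditionMessage(res)
      if (verbose) message(sprintf("frame %s FAILED: %s", fid, failures[[fid]]))
      next
    }
    hist_records[[fid]] <- res$hrec
    ml_records[[fid]] <- res$mrec
    overlap_rows[[fid]] <- data.frame(frame_id = fid,
                                      overlap_pct = res$ov$overlap_pct,
                                      hist_only_pct = res$ov$hist_only_pct,
                                      ml_only_pct = res$ov$ml_only_pct)
    cm_region <- if (is.null(cm_region)) res$cr else add_confusion(cm_region, res$cr)
    cm_area <- if (is.null(cm_area)) res$ca else add_confusion(cm_area, res$ca)
    if (!is.null(res$mac)) {
      mac_hist <- c(mac_hist, res$mac[["hist"]])
      mac_ml <- c(mac_ml, res$mac[["ml"]])
    }
    if (keep_warped) warped_list[[fid]] <- res$warped
    if (verbose) message(sprintf("frame %s ok (overlap %.1f%%)", fid,
                                 res$ov$overlap_pct))
  }
  if (!length(hist_records)) stop("all frames failed")

  hist_df <- do.call(rbind, hist_records)
  ml_df <- do.call(rbind, ml_records)
  quant <- cohort_quant_table(hist_df, ml_df)
  overlap_df <- do.call(rbind, overlap_rows)
  rownames(overlap_df) <- NULL

  errs <- hist_df$plaque_area - ml_df$plaque_area
  evb <- tryCatch(error_vs_burden(errs, hist_df$plaque_burden),
                  error = function(e) NULL)

  macro <- if (length(mac_hist) >= 3) compare_macrophage(mac_hist, mac_ml) else NULL

  structure(list(
    quant = quant,
    overlap = list(per_frame = overlap_df,
                   mean_overlap_pct = mean(overlap_df$overlap_pct),
                   mean_hist_only_pct = mean(overlap_df$hist_only_pct),
                   mean_ml_only_pct = mean(overlap_df$ml_only_pct)),
    confusion_region = cm_region,
    confusion_area = cm_area,
    metrics_region = metrics_from_confusion(cm_region),
    metrics_area = metrics_from_confusion(cm_area),
    missed = missed_tissue_report(cm_area),
    error_vs_burden = evb,
    macrophage = macro,
    per_frame = list(histology = hist_df, ml = ml_df),
    excluded = excluded,
    failures = failures,
    warped = if (keep_warped) warped_list else NULL,
    n_frames = nrow(overlap_df)
  ), class = "plaque_agreement")
}

#' @export
print.plaque_agreement <- function(x, ...) {
  cat(sprintf("<plaque_agreement> %d frames analysed (%d excluded by spacing, %d failed)\n",
              x$n_frames, length(x$excluded), length(x$failures)))
  cat(sprintf("plaque overlap: %.1f%% (hist-only %.1f%%, ML-only %.1f%%)\n",
              x$overlap$mean_overlap_pct, x$overlap$mean_hist_only_pct,
              x$overlap$mean_ml_only_pct))
  cat(sprintf("accuracy: region %.2f%%, area %.2f%%\n",
              x$metrics_region$accuracy, x$metrics_area$accuracy))
  invisible(x)
}

#' @export
summary.plaque_agreement <- function(object, ...) {
  cat("=== Quantitative agreement ===\n")
  print(object$quant)
  cat("\n=== Region-level confusion ===\n")
  print(object$confusion_region)
  print(object$metrics_region)
  cat("\n=== Area-level confusion (mm^2) ===\n")
  print(object$confusion_area)
  print(object$metrics_area)
  cat("\n=== Missed tissue (outside ML EEM) ===\n")
  print(object$missed, row.names = FALSE)
  if (!is.null(object$error_vs_burden))
    cat(sprintf("\nplaque-area error vs burden: r = %.2f, p = %.3g\n",
                object$error_vs_burden$r, object$error_vs_burden$p))
  if (!is.null(object$macrophage))
    cat(sprintf("macrophage-rich area: histology %.2f mm^2, ML %.2f mm^2, CCC %.2f\n",
                object$macrophage$total_hist_mm2, object$macrophage$total_ml_mm2,
                object$macrophage$ccc$ccc))
  invisible(object)
}

#' @export
plot.plaque_agreement <- function(x, which = c("bland_altman", "overlap"), ...) {
  which <- match.arg(which)
  h <- x$per_frame$histology; m <- x$per_frame$ml
  if (which == "bland_altman") {
    d <- h$plaque_area - m$plaque_area
    avg <- (h$plaque_area + m$plaque_area) / 2
    ba <- bland_altman(h$plaque_area, m$plaque_area)
    plot(avg, d, xlab = "mean plaque area (mm^2)",
         ylab = "histology - ML (mm^2)", main = "Bland-Altman: plaque area",
         pch = 19)
    abline(h = ba$bias, lty = 1)
    abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  } else {
    o <- x$overlap$per_frame$overlap_pct
    plot(seq_along(o), o, type = "h", lwd = 3, ylim = c(0, 100),
         xlab = "frame", ylab = "plaque overlap (%)",
         main = "Overlapping plaque area per frame")
    abline(h = x$overlap$mean_overlap_pct, lty = 2)
  }
  invisible(x)
}

#' Write a report bundle of CSV tables from an agreement analysis
#'
#' Writes `quant.csv` (one row per quantity mirroring the quantitative table
#' column order), `confusion_region.csv`, `confusion_area.csv`,
#' `metrics.csv`, `overlap.csv` and `missed.csv`.
#'
#' @param x a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "plaque_agreement"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(x$quant), file.path(dir, "quant.csv"),
                   row.names = FALSE)
  cm_df <- function(cm) {
    df <- as.data.frame(cm$mat)
    df <- cbind(histology = rownames(cm$mat), df,
                missed = cm$missed, unclassified = cm$unclassified)
    rownames(df) <- NULL
    df
  }
  utils::write.csv(cm_df(x$confusion_region),
                   file.path(dir, "confusion_region.csv"), row.names = FALSE)
  utils::write.csv(cm_df(x$confusion_area),
                   file.path(dir, "confusion_area.csv"), row.names = FALSE)
  met_df <- function(m, level) {
    df <- m$per_class
    df$level <- level
    rbind(df,
          data.frame(class = "overall", sensitivity = m$weighted_sensitivity,
                     precision = m$weighted_precision, f_score = m$weighted_f_score,
                     weight = 1, level = level))
  }
  utils::write.csv(rbind(met_df(x$metrics_region, "region"),
                         met_df(x$metrics_area, "area")),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(x$overlap$per_frame, file.path(dir, "overlap.csv"),
                   row.names = FALSE)
  utils::write.csv(x$missed, file.path(dir, "missed.csv"), row.names = FALSE)
  invisible(dir)
}
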