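#' Tissue confusion matrix
#'
#' A 3 x 3 tally with rows = histology class and columns = ML class, in the
#' fixed order FT, Ca, NC, plus two side accounts per histology class:
#' `missed` (tissue lying outside the ML-estimated EEM border, and therefore
#' invisible to the classifier) and `unclassified` (tissue inside the ML EEM
#' that the classifier left unlabeled). The side accounts are excluded from
#' the 3 x 3 metrics and reported separately.
#'
#' @param mat 3 x 3 numeric matrix (counts for `mode = "region"`, mm^2 for
#'   `mode = "area"`), rows histology, columns ML.
#' @param mode `"region"` or `"area"`.
#' @param missed,unclassified numeric length-3 vectors (FT, Ca, NC).
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(mat, mode = c("region", "area"),
                             missed = c(0, 0, 0), unclassified = c(0, 0, 0)) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(3L, 3L))) stop("confusion matrix must be 3 x 3")
  if (any(mat < 0) || any(missed < 0) || any(unclassified < 0))
    stop("confusion entries must be non-negative")
  if (mode == "region" && any(abs(mat - round(mat)) > 1e-9))
    stop("region-mode entries must be integer counts")
  dimnames(mat) <- list(histology = plaque_classes, ml = plaque_classes)
  structure(list(mat = mat, mode = mode,
                 missed = stats::setNames(as.numeric(missed), plaque_classes),
                 unclassified = stats::setNames(as.numeric(unclassified),
                                                plaque_classes)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %s mode%s\n", x$mode,
              if (x$mode == "area") " (mm^2)" else " (counts)"))
  print(round(x$mat, 2))
  if (any(x$missed > 0))
    cat("missed outside ML EEM:", paste(sprintf("%s %.2f", plaque_classes, x$missed),
                                        collapse = ", "), "\n")
  if (any(x$unclassified > 0))
    cat("ML-unclassified:", paste(sprintf("%s %.2f", plaque_classes, x$unclassified),
                                  collapse = ", "), "\n")
  invisible(x)
}

# pool two confusion matrices of the same mode
add_confusion <- function(a, b) {
  stopifnot(a$mode == b$mode)
  confusion_matrix(a$mat + b$mat, a$mode,
                   missed = a$missed + b$missed,
                   unclassified = a$unclassified + b$unclassified)
}

#' Classification metrics from a confusion matrix
#'
#' Per class: sensitivity = TP / (TP + FN) (diagonal over row sum), precision
#' = TP / (TP + FP) (diagonal over column sum), F-score = 2 x (precision x
#' sensitivity) / (precision + sensitivity). Overall accuracy = 100 x trace /
#' total. Overall sensitivity, precision and F-score are weighted averages of
#' the per-class values, weighted by the relative proportion of each class's
#' row (its region count or tissue area). Classes absent from the reference
#' (zero row) are excluded from the weighting. The `missed`/`unclassified`
#' side accounts of the matrix do not enter any metric.
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `classification_metrics`: a list with `per_class`
#'   (data.frame with sensitivity, precision, f_score per class),
#'   `weighted_sensitivity`, `weighted_precision`, `weighted_f_score`, and
#'   `accuracy` (percent).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$mat
  total <- sum(m)
  if (total <= 0) stop("empty confusion matrix")
  rs <- rowSums(m); cs <- colSums(m)
  sens <- ifelse(rs > 0, diag(m) / rs, NA_real_)
  prec <- ifelse(cs > 0, diag(m) / cs, NA_real_)
  f <- ifelse(!is.na(sens) & !is.na(prec) & (sens + prec) > 0,
              2 * prec * sens / (prec + sens), NA_real_)
  w <- rs / sum(rs)
  wmean <- function(v) {
    ok <- !is.na(v) & rs > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * rs[ok]) / sum(rs[ok])
  }
  structure(list(
    per_class = data.frame(class = plaque_classes, sensitivity = sens,
                           precision = prec, f_score = f, weight = w,
                           row.names = NULL, stringsAsFactors = FALSE),
    weighted_sensitivity = wmean(sens),
    weighted_precision = wmean(prec),
    weighted_f_score = wmean(f),
    accuracy = 100 * sum(diag(m)) / total,
    mode = cm$mode
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("Classification metrics (%s level)\n", x$mode))
  df <- x$per_class
  df$sensitivity <- sprintf("%.2f", df$sensitivity)
  df$precision <- sprintf("%.2f", df$precision)
  df$f_score <- sprintf("%.2f", df$f_score)
  df$weight <- NULL
  print(df, row.names = FALSE)
  cat(sprintf("overall: sensitivity %.2f, precision %.2f, F %.2f, accuracy %.2f%%\n",
              x$weighted_sensitivity, x$weighted_precision,
              x$weighted_f_score, x$accuracy))
  invisible(x)
}

#' Overlapping / non-overlapping plaque area analysis
#'
#' Proportion of the histology-defined plaque area that the ML estimation
#' also labels as plaque, plus the non-overlapping remainders in each
#' direction (as a percentage of the respective total).
#'
#' @param warped_plaque,ml_plaque logical matrices on the same grid marking
#'   plaque pixels (any of FT/Ca/NC).
#' @param pixel_size_mm pixel size in mm.
#' @return list with `overlap_pct`, `hist_only_pct`, `ml_only_pct`,
#'   `hist_area_mm2`, `ml_area_mm2`, `overlap_area_mm2`.
#' @export
overlap_analysis <- function(warped_plaque, ml_plaque, pixel_size_mm) {
  if (!identical(dim(warped_plaque), dim(ml_plaque)))
    stop("masks must share the same grid")
  nh <- sum(warped_plaque)
  nm <- sum(ml_plaque)
  if (nh == 0) stop("empty histology plaque: overlap proportion undefined")
  ov <- sum(warped_plaque & ml_plaque)
  px2 <- pixel_size_mm^2
  list(overlap_pct = 100 * ov / nh,
       hist_only_pct = 100 * (nh - ov) / nh,
       ml_only_pct = if (nm > 0) 100 * (nm - ov) / nm else 0,
       hist_area_mm2 = nh * px2, ml_area_mm2 = nm * px2,
       overlap_area_mm2 = ov * px2)
}

# connected-component labelling of a logical matrix via the pixel adjacency
# graph; returns an integer vector of component ids over which(mat)
label_components <- function(mat, connectivity = 8L) {
  idx <- which(mat)
  if (!length(idx)) return(list(idx = integer(0), comp = integer(0)))
  nr <- nrow(mat)
  id <- integer(length(mat)); id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cgrid <- ((idx - 1L) %/% nr) + 1L
  nc <- ncol(mat)
  edge_to <- function(di, dj) {
    nbr_r <- r + di; nbr_c <- cgrid + dj
    ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
    nbr <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
    keep <- id[nbr] > 0L
    cbind(id[idx[ok][keep]], id[nbr[keep]])
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  else if (connectivity != 4L) stop("connectivity must be 4 or 8")
  edges <- do.call(rbind, lapply(offs, function(o) edge_to(o[1L], o[2L])))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  list(idx = idx, comp = igraph::components(g)$membership)
}

#' Extract histology-defined tissue regions of interest
#'
#' One ROI per connected component per plaque class in the warped histology
#' mask, filtered by a minimum area that suppresses warp speckle. Ordering is
#' deterministic: class (FT, Ca, NC), then reading-order position of the
#' top-left pixel.
#'
#' @param warped a [warp_histology()] result (or any [tissue_label_mask()]).
#' @param connectivity 4 or 8 (default 8).
#' @param min_area_mm2 minimum ROI area in mm^2 (default 0.01).
#' @return list of `roi` objects: `tissue_class`, `pixels` (linear indices
#'   into the grid), `area_mm2`, `frame_id`.
#' @export
extract_rois <- function(warped, connectivity = 8L, min_area_mm2 = 0.01) {
  mask <- if (inherits(warped, "warped_histology")) warped$mask else warped
  stopifnot(inherits(mask, "tissue_label_mask"))
  frame_id <- if (inherits(warped, "warped_histology")) warped$frame_id else NA_character_
  px2 <- mask$pixel_size_mm^2
  nr <- nrow(mask$grid)
  out <- list()
  for (cls in plaque_classes) {
    lc <- label_components(mask$grid == tissue_labels[[cls]], connectivity)
    if (!length(lc$idx)) next
    for (k in sort(unique(lc$comp))) {
      pix <- lc$idx[lc$comp == k]
      area <- length(pix) * px2
      if (area < min_area_mm2) next
      out[[length(out) + 1L]] <- structure(
        list(tissue_class = cls, pixels = pix, area_mm2 = area,
             frame_id = frame_id),
        class = "roi")
    }
  }
  # deterministic order: class, then reading order (row, then column) of the
  # top-left pixel
  if (length(out)) {
    key <- vapply(out, function(r) {
      rr <- ((r$pixels - 1L) %% nr) + 1L
      cc <- ((r$pixels - 1L) %/% nr) + 1L
      min((rr - 1) * ncol(mask$grid) + cc)
    }, numeric(1))
    cls_rank <- match(vapply(out, `[[`, "", "tissue_class"), plaque_classes)
    out <- out[order(cls_rank, key)]
  }
  out
}

#' Region-level confusion matrix (predominant tissue per ROI)
#'
#' Each histology ROI contributes one count to the cell (histology class,
#' predominant ML class), where the predominant class is the plaque component
#' occupying the largest share of the ROI among ML-labeled pixels. Ties break
#' by the fixed priority Ca > NC > FT, mirroring the histological precedence
#' of Ca over NC. An ROI with no ML tissue pixels is tallied as `missed` when
#' the majority of its pixels lie outside the ML-estimated EEM border, and as
#' `unclassified` otherwise.
#'
#' @param rois list of ROIs from [extract_rois()].
#' @param ml_mask ML-estimation [tissue_label_mask()] on the same grid.
#' @param ml_eem ML EEM [contour()].
#' @return a [confusion_matrix()] in region mode.
#' @export
region_level_confusion <- function(rois, ml_mask, ml_eem) {
  stopifnot(inherits(ml_mask, "tissue_label_mask"), inherits(ml_eem, "contour"))
  mat <- matrix(0, 3, 3)
  missed <- unclassified <- c(ft = 0, ca = 0, nc = 0)
  priority <- c(ft = 3L, ca = 1L, nc = 2L)  # smaller wins ties: Ca > NC > FT
  dims <- dim(ml_mask$grid)
  for (roi in rois) {
    h <- match(roi$tissue_class, plaque_classes)
    lab <- ml_mask$grid[roi$pixels]
    counts <- vapply(plaque_classes, function(cl) sum(lab == tissue_labels[[cl]]),
                     numeric(1))
    if (sum(counts) == 0) {
      ctr <- pixel_centers(dims, roi$pixels)
      outside <- !point_in_polygon_cpp(ctr, ml_eem$points)
      if (mean(outside) > 0.5) missed[[h]] <- missed[[h]] + 1
      else unclassified[[h]] <- unclassified[[h]] + 1
    } else {
      best <- which(counts == max(counts))
      m <- best[which.min(priority[best])]
      mat[h, m] <- mat[h, m] + 1
    }
  }
  confusion_matrix(mat, "region", missed = missed, unclassified = unclassified)
}

#' Area-level confusion matrix (overlap areas in mm^2)
#'
#' Cell (h, m) accumulates the area of pixels labeled `h` in the warped
#' histology and `m` by the ML classifier. Histology tissue pixels outside
#' the ML-estimated EEM border accumulate in the `missed` account; tissue
#' pixels inside the EEM that the ML left unlabeled accumulate in
#' `unclassified`.
#'
#' @param warped_mask warped histology [tissue_label_mask()] (or a
#'   [warp_histology()] result).
#' @param ml_mask ML [tissue_label_mask()] on the same grid.
#' @param ml_eem ML EEM [contour()].
#' @return a [confusion_matrix()] in area mode.
#' @export
area_level_confusion <- function(warped_mask, ml_mask, ml_eem) {
  if (inherits(warped_mask, "warped_histology")) warped_mask <- warped_mask$mask
  stopifnot(inherits(warped_mask, "tissue_label_mask"),
            inherits(ml_mask, "tissue_label_mask"),
            inherits(ml_eem, "contour"))
  if (!identical(dim(warped_mask$grid), dim(ml_mask$grid)))
    stop("masks must share the same grid")
  px2 <- warped_mask$pixel_size_mm^2
  dims <- dim(warped_mask$grid)
  mat <- matrix(0, 3, 3)
  missed <- unclassified <- c(ft = 0, ca = 0, nc = 0)
  hcodes <- tissue_labels[plaque_classes]
  hist_idx <- which(warped_mask$grid %in% hcodes)
  if (length(hist_idx)) {
    ctr <- pixel_centers(dims, hist_idx)
    inside <- nearest_on_contour_cpp(ctr, ml_eem$points)[, 3L] < 0
    h <- match(warped_mask$grid[hist_idx], hcodes)
    m <- match(ml_mask$grid[hist_idx], hcodes)  # NA for non-tissue ML labels
    out_h <- h[!inside]
    for (k in 1:3) missed[[k]] <- sum(out_h == k) * px2
    hin <- h[inside]; min_ <- m[inside]
    unl <- is.na(min_)
    for (k in 1:3) unclassified[[k]] <- sum(hin[unl] == k) * px2
    for (i in 1:3) for (j in 1:3)
      mat[i, j] <- sum(hin == i & min_ == j, na.rm = TRUE) * px2
  }
  confusion_matrix(mat, "area", missed = missed, unclassified = unclassified)
}

#' Missed-tissue report: histology tissue outside the ML-estimated EEM
#'
#' Per histology class, the absolute area missed because it lies beyond the
#' ML EEM border, and the percentage of that class's total histology-detected
#' area (inside + missed).
#'
#' @param area_cm an area-mode [confusion_matrix()].
#' @return data.frame with columns `class`, `missed_mm2`, `missed_pct`.
#' @export
missed_tissue_report <- function(area_cm) {
  stopifnot(inherits(area_cm, "confusion_matrix"))
  if (area_cm$mode != "area") stop("missed-tissue report needs an area-mode matrix")
  inside <- rowSums(area_cm$mat) + area_cm$unclassified
  total <- inside + area_cm$missed
  pct <- ifelse(total > 0, 100 * area_cm$missed / total, 0)
  data.frame(class = plaque_classes, missed_mm2 = unname(area_cm$missed),
             missed_pct = unname(pct), stringsAsFactors = FALSE)
}

#' Correlation of plaque-area error with plaque burden
#'
#' Pearson correlation of the per-frame plaque-area error (histology minus
#' ML) with the histological plaque burden; a positive r means the
#' underestimation error grows with burden.
#'
#' @param errors per-frame plaque-area errors (histology - ML), mm^2.
#' @param burdens per-frame histology plaque burden, percent.
#' @return as [pearson_correlation()].
#' @export
error_vs_burden <- function(errors, burdens) {
  if (length(errors) != length(burdens)) stop("unpaired per-frame values")
  pearson_correlation(burdens, errors)
}
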