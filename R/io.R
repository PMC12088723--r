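#' @name plaquematch-io
#' @title Readers and writers for masks, contours, landmarks and manifests
#' @description
#' All artifacts are plain, lossless formats: label masks as single-channel
#' PNG (grayscale values are the label codes) with a JSON sidecar mapping
#' codes to class names, contours and landmarks as JSON, cohort manifests as
#' JSON, configurations as YAML. Coordinates are 0-based pixel indices,
#' row-major, y down. A classifier class named `lipid` in a sidecar is
#' remapped to `nc` on load.
NULL

#' Write a tissue label mask as indexed PNG plus JSON sidecar
#'
#' @param mask a [tissue_label_mask()].
#' @param path output PNG path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_label_mask"))
  png::writePNG(mask$grid / 255, path)
  side <- list(pixel_size_mm = mask$pixel_size_mm,
               labels = as.list(stats::setNames(names(mask$labels),
                                                as.character(mask$labels))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a tissue label mask written by [write_mask()]
#'
#' Unknown class names in the sidecar raise an error naming the code and
#' file; the `lipid` class is remapped to `nc`.
#'
#' @param path PNG path with a `<path>.json` sidecar.
#' @return a [tissue_label_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop(sprintf("missing sidecar: %s", side_path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  grid <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  side <- jsonlite::read_json(side_path)
  codes <- as.integer(names(side$labels))
  nms <- vapply(side$labels, as.character, "")
  nms[nms == "lipid"] <- "nc"
  unknown <- setdiff(nms, names(tissue_labels))
  if (length(unknown))
    stop(sprintf("unknown label class '%s' (code %s) in %s",
                 unknown[1L], codes[match(unknown[1L], nms)], path))
  # remap file codes to canonical codes
  remap <- stats::setNames(tissue_labels[nms], codes)
  present <- unique(as.vector(grid))
  bad <- setdiff(present, codes)
  if (length(bad))
    stop(sprintf("unknown label code %s in %s", paste(bad, collapse = ","), path))
  grid[] <- remap[as.character(grid)]
  tissue_label_mask(grid, side$pixel_size_mm)
}

#' Write / read a contour as JSON
#'
#' @param x a [contour()].
#' @param path JSON path.
#' @export
write_contour <- function(x, path) {
  stopifnot(inherits(x, "contour"))
  jsonlite::write_json(list(points = x$points, pixel_size_mm = x$pixel_size_mm),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop(sprintf("contour file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  contour(j$points, j$pixel_size_mm[[1L]])
}

#' Write / read landmark correspondences as JSON
#'
#' @param x a [landmark_correspondence()].
#' @param path JSON path.
#' @export
write_landmarks <- function(x, path) {
  stopifnot(inherits(x, "landmark_correspondence"))
  jsonlite::write_json(list(s_hist = x$pairs[, "s_hist"],
                            s_img = x$pairs[, "s_img"]),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_correspondence(j$s_hist, j$s_img)
}

#' Write a matched pair to a directory
#'
#' Writes the mask/contour/landmark files and a `pair.json` referencing them.
#'
#' @param pair a [matched_pair()].
#' @param dir output directory (created if needed).
#' @return path of the written `pair.json`.
#' @export
write_matched_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "matched_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(fun, obj, name) { fun(obj, file.path(dir, name)); name }
  entry <- list(
    frame_id = pair$imaging$geometry$frame_id,
    position_mm = pair$imaging$geometry$longitudinal_position_mm,
    modality = pair$imaging$modality,
    histology = list(
      mask = w(write_mask, pair$histology$mask, "hist_mask.png"),
      lumen = w(write_contour, pair$histology$geometry$lumen, "hist_lumen.json"),
      eem = w(write_contour, pair$histology$geometry$eem, "hist_eem.json")
    ),
    imaging = list(
      mask = w(write_mask, pair$imaging$mask, "img_mask.png"),
      lumen = w(write_contour, pair$imaging$geometry$lumen, "img_lumen.json"),
      eem = w(write_contour, pair$imaging$geometry$eem, "img_eem.json")
    ),
    landmarks = w(write_landmarks, pair$landmarks, "landmarks.json")
  )
  if (!is.null(pair$histology$cd68)) {
    png::writePNG(pair$histology$cd68$positive * 1, file.path(dir, "cd68.png"))
    png::writePNG(pair$histology$cd68$plaque_region * 1,
                  file.path(dir, "cd68_region.png"))
    entry$histology$cd68 <- "cd68.png"
    entry$histology$cd68_region <- "cd68_region.png"
  }
  path <- file.path(dir, "pair.json")
  jsonlite::write_json(entry, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Load a matched pair from a `pair.json` manifest entry
#'
#' Reads the referenced files, validates all invariants (registered labels,
#' lumen inside EEM, monotone landmarks) and reports violations with the
#' frame id.
#'
#' @param path path to a `pair.json` written by [write_matched_pair()].
#' @return a [matched_pair()].
#' @export
load_matched_pair <- function(path) {
  if (!file.exists(path)) stop(sprintf("pair file not found: %s", path))
  dir <- dirname(path)
  j <- jsonlite::read_json(path)
  fid <- j$frame_id
  tryCatch({
    hist_mask <- read_mask(file.path(dir, j$histology$mask))
    hist_geom <- frame_geometry(read_contour(file.path(dir, j$histology$lumen)),
                                read_contour(file.path(dir, j$histology$eem)),
                                frame_id = fid,
                                longitudinal_position_mm = j$position_mm)
    img_mask <- read_mask(file.path(dir, j$imaging$mask))
    img_geom <- frame_geometry(read_contour(file.path(dir, j$imaging$lumen)),
                               read_contour(file.path(dir, j$imaging$eem)),
                               frame_id = fid,
                               longitudinal_position_mm = j$position_mm)
    lm <- read_landmarks(file.path(dir, j$landmarks))
    cd68 <- NULL
    if (!is.null(j$histology$cd68)) {
      pos <- png::readPNG(file.path(dir, j$histology$cd68)) > 0.5
      reg <- png::readPNG(file.path(dir, j$histology$cd68_region)) > 0.5
      cd68 <- cd68_mask(pos, reg, hist_mask$pixel_size_mm)
    }
    matched_pair(histology = list(geometry = hist_geom, mask = hist_mask,
                                  cd68 = cd68),
                 imaging = list(geometry = img_geom, mask = img_mask,
                                modality = j$modality),
                 landmarks = lm)
  }, error = function(e)
    stop(sprintf("frame %s: %s", fid, conditionMessage(e)), call. = FALSE))
}

#' Write a cohort and its manifest
#'
#' @param cohort list of [matched_pair()] objects.
#' @param dir output directory.
#' @param dataset dataset label stored in the manifest.
#' @return path of `manifest.json`.
#' @export
write_cohort <- function(cohort, dir, dataset = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(pair) {
    fid <- pair$imaging$geometry$frame_id
    write_matched_pair(pair, file.path(dir, fid))
    list(frame_id = fid,
         position_mm = pair$imaging$geometry$longitudinal_position_mm,
         modality = pair$imaging$modality,
         path = file.path(fid, "pair.json"))
  })
  ids <- vapply(entries, `[[`, "", "frame_id")
  if (anyDuplicated(ids)) stop("duplicate frame ids in cohort")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(dataset = dataset, pairs = entries), path,
                       auto_unbox = TRUE, digits = NA)
  path
}

#' Read a cohort manifest
#'
#' @param path path to `manifest.json`.
#' @return list with `dataset` and a data.frame `pairs` (frame_id,
#'   position_mm, modality, path).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- as.data.frame(j$pairs, stringsAsFactors = FALSE)
  if (anyDuplicated(pairs$frame_id)) stop("duplicate frame ids in manifest")
  missing <- !file.exists(file.path(dirname(path), pairs$path))
  if (any(missing))
    stop(sprintf("missing pair file(s): %s",
                 paste(pairs$path[missing], collapse = ", ")))
  list(dataset = j$dataset, pairs = pairs, dir = dirname(path))
}

#' Frame-spacing filter
#'
#' Frames used for validation must be sufficiently far apart along the
#' pullback to count as independent sections. Greedy scan from the most
#' proximal frame: a frame is kept iff its longitudinal position is at least
#' `min_spacing_mm` from the last kept frame.
#'
#' @param positions_mm numeric vector of longitudinal positions, or a
#'   manifest from [read_manifest()].
#' @param min_spacing_mm minimum spacing in mm (default 0.4).
#' @return for a numeric input, a logical keep vector (in input order); for a
#'   manifest, the manifest with only kept pairs and the exclusions recorded
#'   in attribute `excluded`.
#' @export
filter_matched_frames <- function(positions_mm, min_spacing_mm = 0.4) {
  manifest <- NULL
  if (is.list(positions_mm) && !is.null(positions_mm$pairs)) {
    manifest <- positions_mm
    positions_mm <- manifest$pairs$position_mm
  }
  ord <- order(positions_mm)
  keep <- logical(length(positions_mm))
  last <- -Inf
  for (i in ord) {
    if (positions_mm[i] - last >= min_spacing_mm || !is.finite(last)) {
      keep[i] <- TRUE
      last <- positions_mm[i]
    }
  }
  if (is.null(manifest)) return(keep)
  manifest$excluded <- manifest$pairs[!keep, , drop = FALSE]
  manifest$pairs <- manifest$pairs[keep, , drop = FALSE]
  attr(manifest, "excluded") <- manifest$excluded
  manifest
}

#' Read / write a generator or pipeline configuration as YAML
#'
#' @param path YAML path.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$misclass)) y$misclass <- matrix(unlist(y$misclass), 3L, 3L,
                                                 byrow = TRUE)
  do.call(synthetic_config, y)
}

#' @rdname read_config
#' @param config a [synthetic_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  y <- unclass(config)
  y$misclass <- lapply(seq_len(3L), function(i) as.numeric(y$misclass[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}
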