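#' Configuration for the synthetic matched-pair generator
#'
#' Defines the study conditions the generator emulates: a pressurized vessel
#' cross-section with a fibrotic plaque carrying calcific and necrotic-core
#' inclusions; a depressurized, shrunken histology counterpart at a different
#' pixel resolution with known landmark correspondences; and a simulated
#' classifier output with controlled per-region misclassification, boundary
#' noise, EEM area bias, and optional OCT-style EEM truncation with deep-
#' tissue attenuation relabelling.
#'
#' Defaults describe a mid-sized diseased coronary segment: lumen radius
#' 1.0-1.5 mm, wall (plaque) thickness 0.6-1.2 mm (EEM areas around
#' 10-17 mm^2, plaque burden near 60%), up to two calcific and two
#' necrotic-core inclusions per section, 15% histological lumen collapse, a
#' mild smooth circumferential distortion, imaging pixels of 15 um and
#' histology pixels of 7.5 um.
#'
#' @param ... named overrides of any default listed below.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    img_pixel_mm = 0.015, hist_pixel_mm = 0.0075,
    lumen_radius_range = c(1.0, 1.5),
    harmonic_orders = 2:3, harmonic_amp_max = 0.06,
    wall_thickness_range = c(0.6, 1.2), wall_variation = 0.25,
    ca_count_range = c(0L, 2L), nc_count_range = c(0L, 2L),
    ca_arc_range = c(0.2, 0.5), ca_depth_range = c(0.1, 0.25),
    nc_arc_range = c(0.2, 0.4), nc_depth_range = c(0.08, 0.2),
    shrink = 0.85, global_scale = 1.0,
    distortion_amp = 0.02, rotate = TRUE,
    misclass = diag(3), boundary_sigma_mm = 0,
    oct_truncation_mm = NULL, oct_attenuation_mm = NULL,
    ml_eem_bias_mm2 = 0, ml_eem_noise_mm2 = 0,
    n_sectors = 16L, landmark_count = 8L,
    frame_spacing_mm = 0.5, margin_mm = 0.3,
    n_theta = 720L, modality = "nirs_ivus",
    cd68 = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  cfg$misclass <- as.matrix(cfg$misclass)
  if (!all(dim(cfg$misclass) == c(3L, 3L)) ||
      any(cfg$misclass < 0) || any(abs(rowSums(cfg$misclass) - 1) > 1e-9))
    stop("misclass must be a 3 x 3 row-stochastic matrix")
  if (cfg$shrink <= 0 || cfg$shrink > 1) stop("shrink must lie in (0, 1]")
  if (cfg$global_scale <= 0) stop("global_scale must be positive")
  if (cfg$img_pixel_mm <= 0 || cfg$hist_pixel_mm <= 0)
    stop("pixel sizes must be positive")
  structure(cfg, class = "synthetic_config")
}

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-frame seed derivation from a master seed: one global stream per seed,
# split per frame by counter, independent of generation order
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 1e6 * 8191 + as.numeric(counter) * 127 + 1) %%
               2147483647)
}

runif1 <- function(range) stats::runif(1, range[1L], range[2L])

# physical ellipse membership: points n x 2, ellipse (cx, cy, a, b, ang)
in_ellipse <- function(pts, e, scale = 1) {
  dx <- pts[, 1L] - e$cx; dy <- pts[, 2L] - e$cy
  u <- (dx * cos(e$ang) + dy * sin(e$ang)) / (e$a * scale)
  v <- (-dx * sin(e$ang) + dy * cos(e$ang)) / (e$b * scale)
  u * u + v * v <= 1
}

ellipse_boundary <- function(e, n = 16L, scale = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- e$a * scale * cos(th); v <- e$b * scale * sin(th)
  cbind(e$cx + u * cos(e$ang) - v * sin(e$ang),
        e$cy + u * sin(e$ang) + v * cos(e$ang))
}

# circular linear interpolation s -> value over vertex samples
circular_fun <- function(s_vertex, values) {
  s3 <- c(s_vertex - 1, s_vertex, s_vertex + 1)
  v3 <- rep(values, 3L)
  stats::approxfun(s3, v3, rule = 2)
}

#' Generate a ground-truth pressurized vessel cross-section
#'
#' Builds a star-shaped lumen (base radius plus low-order harmonics), an EEM
#' as a normal offset of the lumen by a smoothly varying wall thickness, an
#' FT-filled plaque band, and non-overlapping elliptical Ca and NC inclusions
#' anchored at (arc length, depth) band positions but drawn in physical
#' coordinates so their areas are analytically pi*a*b. Where a sampled Ca and
#' NC position would collide the calcific tissue takes precedence (the
#' histological convention); collisions are avoided by rejection sampling and
#' the generator errors if an inclusion cannot be placed after bounded
#' retries. Deterministic for a given seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return object of class `synthetic_vessel` containing the truth mask and
#'   geometry (imaging grid), the analytic `truth` record, and cached
#'   band coordinates reused by the ML simulator.
#' @export
generate_vessel <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    n_th <- config$n_theta
    theta <- seq(0, 2 * pi, length.out = n_th + 1L)[-(n_th + 1L)]
    r0 <- runif1(config$lumen_radius_range)
    amps <- stats::runif(length(config$harmonic_orders), 0, config$harmonic_amp_max)
    phis <- stats::runif(length(config$harmonic_orders), 0, 2 * pi)
    r_fun <- function(th) {
      r <- rep(r0, length(th))
      for (k in seq_along(config$harmonic_orders))
        r <- r + r0 * amps[k] * cos(config$harmonic_orders[k] * th + phis[k])
      r
    }
    dr_fun <- function(th) {
      dr <- numeric(length(th))
      for (k in seq_along(config$harmonic_orders))
        dr <- dr - r0 * amps[k] * config$harmonic_orders[k] *
          sin(config$harmonic_orders[k] * th + phis[k])
      dr
    }
    r <- r_fun(theta)
    lumen_phys <- cbind(r * cos(theta), r * sin(theta))
    # analytic outward normal of the polar curve
    dr <- dr_fun(theta)
    tx <- dr * cos(theta) - r * sin(theta)
    ty <- dr * sin(theta) + r * cos(theta)
    tl <- sqrt(tx^2 + ty^2)
    normals <- cbind(ty / tl, -tx / tl)

    t0 <- runif1(config$wall_thickness_range)
    phit <- stats::runif(1, 0, 2 * pi)
    t_vertex <- t0 * (1 + config$wall_variation * cos(theta + phit))
    t_vertex <- pmax(t_vertex, 0.15)
    eem_phys <- lumen_phys + normals * t_vertex

    seglen <- sqrt(rowSums((lumen_phys[c(2:n_th, 1L), ] - lumen_phys)^2))
    s_vertex <- c(0, cumsum(seglen))[1:n_th] / sum(seglen)
    t_fun <- circular_fun(s_vertex, t_vertex)

    # place inclusions
    place <- function(n, arc_range, depth_range, cls, existing) {
      placed <- list()
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in 1:80) {
          j <- sample.int(n_th, 1L)
          a <- runif1(arc_range); b <- runif1(depth_range)
          tj <- t_vertex[j]
          if (tj < 2 * b + 0.1) next
          d0 <- stats::runif(1, b + 0.04, tj - b - 0.04)
          e <- list(cx = lumen_phys[j, 1L] + d0 * normals[j, 1L],
                    cy = lumen_phys[j, 2L] + d0 * normals[j, 2L],
                    a = a, b = b,
                    ang = atan2(ty[j], tx[j]), class = cls,
                    s0 = s_vertex[j], d0 = d0)
          bd <- ellipse_boundary(e, 16L)
          sd <- nearest_on_contour_cpp(bd, lumen_phys)
          inl <- point_in_polygon_cpp(bd, lumen_phys)
          if (any(inl) || any(sd[, 2L] < 0.03) ||
              any(sd[, 2L] > t_fun(sd[, 1L]) - 0.03)) next
          clash <- FALSE
          for (o in c(existing, placed)) {
            if (any(in_ellipse(bd, o, scale = 1.15)) ||
                any(in_ellipse(ellipse_boundary(o, 16L), e, scale = 1.15)) ||
                in_ellipse(matrix(c(o$cx, o$cy), 1), e)[1L] ||
                in_ellipse(matrix(c(e$cx, e$cy), 1), o)[1L]) { clash <- TRUE; break }
          }
          if (clash) next
          placed[[length(placed) + 1L]] <- e
          ok <- TRUE
          break
        }
        if (!ok) stop(sprintf("could not place %s inclusion %d after bounded retries", cls, i))
      }
      placed
    }
    n_ca <- sample(config$ca_count_range[1L]:config$ca_count_range[2L], 1L)
    n_nc <- sample(config$nc_count_range[1L]:config$nc_count_range[2L], 1L)
    ca <- place(n_ca, config$ca_arc_range, config$ca_depth_range, "ca", list())
    nc <- place(n_nc, config$nc_arc_range, config$nc_depth_range, "nc", ca)
    inclusions <- c(ca, nc)

    # imaging grid
    px <- config$img_pixel_mm
    maxr <- max(sqrt(rowSums(eem_phys^2)))
    half <- maxr + config$margin_mm
    n_px <- 2L * as.integer(ceiling(half / px))
    ctr_px <- (n_px - 1) / 2

    # band coordinates for every pixel plausibly in or near the wall
    xs <- (seq_len(n_px) - 1 - ctr_px) * px
    X <- matrix(xs, n_px, n_px, byrow = TRUE)   # x varies along columns
    Y <- matrix(xs, n_px, n_px)                  # y varies along rows
    rr <- sqrt(X^2 + Y^2)
    rmin <- min(r) * 0.95
    cand <- which(rr >= rmin & rr <= maxr + 2 * px)
    pts <- cbind(X[cand], Y[cand])
    sdm <- nearest_on_contour_cpp(pts, lumen_phys)
    in_lum <- sdm[, 3L] < 0

    grid <- matrix(tissue_labels[["background"]], n_px, n_px)
    grid[rr < rmin] <- tissue_labels[["lumen"]]
    grid[cand[in_lum]] <- tissue_labels[["lumen"]]
    band <- !in_lum & sdm[, 2L] <= t_fun(sdm[, 1L])
    bidx <- cand[band]
    lab <- rep(tissue_labels[["ft"]], length(bidx))
    bpts <- pts[band, , drop = FALSE]
    for (e in inclusions[vapply(inclusions, `[[`, "", "class") == "nc"])
      lab[in_ellipse(bpts, e)] <- tissue_labels[["nc"]]
    for (e in inclusions[vapply(inclusions, `[[`, "", "class") == "ca"])
      lab[in_ellipse(bpts, e)] <- tissue_labels[["ca"]]
    grid[bidx] <- lab

    to_px <- function(p) p / px + ctr_px
    lumen_ct <- contour(to_px(lumen_phys), px, check_simple = FALSE)
    eem_ct <- contour(to_px(eem_phys), px, check_simple = FALSE)
    geometry <- frame_geometry(lumen_ct, eem_ct, frame_id = sprintf("S%07d", seed))

    eem_area <- polygon_area(eem_ct)
    lumen_area <- polygon_area(lumen_ct)
    ca_area <- sum(vapply(ca, function(e) pi * e$a * e$b, numeric(1)))
    nc_area <- sum(vapply(nc, function(e) pi * e$a * e$b, numeric(1)))
    pa <- plaque_area(eem_area, lumen_area)

    structure(list(
      config = config, seed = seed,
      theta = theta, lumen_phys = lumen_phys, eem_phys = eem_phys,
      normals = normals, s_vertex = s_vertex, t_vertex = t_vertex,
      t_fun = t_fun, inclusions = inclusions,
      n_px = n_px, px = px, ctr_px = ctr_px,
      mask = tissue_label_mask(grid, px),
      geometry = geometry,
      pix = list(cand = cand, s = sdm[, 1L], d = sdm[, 2L],
                 in_lumen = in_lum, rr_lt_rmin = which(rr < rmin)),
      truth = list(eem_area = eem_area, lumen_area = lumen_area,
                   plaque_area = pa,
                   plaque_burden = plaque_burden(pa, eem_area),
                   ft_area = pa - ca_area - nc_area,
                   ca_area = ca_area, nc_area = nc_area)
    ), class = "synthetic_vessel")
  })
}

# smooth circular monotone distortion map s_img -> s_hist and its inverse
make_distortion <- function(amp, rotate) {
  rot <- if (rotate) stats::runif(1) else 0
  if (amp > 0) {
    b <- stats::runif(2L, 0.5, 1) * amp
    ph <- stats::runif(2L, 0, 2 * pi)
  } else { b <- c(0, 0); ph <- c(0, 0) }
  g_unwrapped <- function(s)
    s + rot + b[1L] / (2 * pi) * (sin(2 * pi * s + ph[1L]) - sin(ph[1L])) +
      b[2L] / (4 * pi) * (sin(4 * pi * s + ph[2L]) - sin(ph[2L]))
  sgrid <- seq(0, 1, length.out = 4097L)
  gu <- g_unwrapped(sgrid)
  g <- function(s) g_unwrapped(s %% 1) %% 1
  g_inv <- function(y) {
    y <- y %% 1
    m <- ceiling(gu[1L] - y)
    stats::approx(gu, sgrid, xout = y + m, rule = 2)$y
  }
  list(g = g, g_inv = g_inv, rot = rot)
}

#' Degrade a ground-truth vessel into its histology counterpart
#'
#' Emulates what sectioning does to the pressurized cross-section: the lumen
#' collapses radially by the shrink factor, an optional global scale shrinks
#' the whole section, a smooth monotone circumferential distortion
#' re-parameterizes the border (emulating non-uniform deformation), and the
#' section is resampled at the histology pixel size. Tissue is carried along
#' the known inverse map — the same physical-depth band transport the warp
#' inverts — so the warp's ideal output is known exactly. Landmark pairs at
#' true correspondences are emitted.
#'
#' @param vessel a [generate_vessel()] result.
#' @param seed integer seed (controls distortion and CD68 sampling).
#' @return list with `geometry`, `mask`, `landmarks`, `cd68` (or NULL), and
#'   `distortion` (the true map, for diagnostics).
#' @export
degrade_to_histology <- function(vessel, seed = 1L) {
  stopifnot(inherits(vessel, "synthetic_vessel"))
  config <- vessel$config
  with_seed(seed, {
    scale <- config$global_scale
    dist <- make_distortion(config$distortion_amp, config$rotate)
    lum_h_phys <- vessel$lumen_phys * config$shrink * scale
    # thickness (scaled) at each histology lumen vertex, looked up at the
    # material position on the truth frame
    t_h_vertex <- scale * vessel$t_fun(dist$g_inv(vessel$s_vertex))
    eem_h_phys <- lum_h_phys + vessel$normals * t_h_vertex
    t_h_fun <- circular_fun(vessel$s_vertex, t_h_vertex)

    if (min(t_h_vertex) <= 0 || !is_simple_polygon(eem_h_phys))
      stop("shrinkage produced a self-intersecting histology EEM")

    px <- config$hist_pixel_mm
    maxr <- max(sqrt(rowSums(eem_h_phys^2)))
    half <- maxr + config$margin_mm * scale
    n_px <- 2L * as.integer(ceiling(half / px))
    ctr_px <- (n_px - 1) / 2

    xs <- (seq_len(n_px) - 1 - ctr_px) * px
    X <- matrix(xs, n_px, n_px, byrow = TRUE)
    Y <- matrix(xs, n_px, n_px)
    rr <- sqrt(X^2 + Y^2)
    r_h <- sqrt(rowSums(lum_h_phys^2))
    rmin <- min(r_h) * 0.95
    cand <- which(rr >= rmin & rr <= maxr + 2 * px)
    pts <- cbind(X[cand], Y[cand])
    sdm <- nearest_on_contour_cpp(pts, lum_h_phys)
    in_lum <- sdm[, 3L] < 0

    grid <- matrix(tissue_labels[["background"]], n_px, n_px)
    grid[rr < rmin] <- tissue_labels[["lumen"]]
    grid[cand[in_lum]] <- tissue_labels[["lumen"]]
    band <- !in_lum & sdm[, 2L] <= t_h_fun(sdm[, 1L])
    bidx <- cand[band]

    # transport band pixels to the truth frame and classify there
    s_img <- dist$g_inv(sdm[band, 1L])
    d_img <- (sdm[band, 2L]) / scale
    lum_img_ct <- contour(vessel$lumen_phys, 1, check_simple = FALSE)
    src <- contour_point_at(lum_img_ct, s_img)
    Q <- src$points + src$normals * d_img
    lab <- rep(tissue_labels[["ft"]], length(bidx))
    cls <- vapply(vessel$inclusions, `[[`, "", "class")
    for (e in vessel$inclusions[cls == "nc"])
      lab[in_ellipse(Q, e)] <- tissue_labels[["nc"]]
    for (e in vessel$inclusions[cls == "ca"])
      lab[in_ellipse(Q, e)] <- tissue_labels[["ca"]]
    grid[bidx] <- lab

    to_px <- function(p) p / px + ctr_px
    lumen_ct <- contour(to_px(lum_h_phys), px, check_simple = FALSE)
    eem_ct <- contour(to_px(eem_h_phys), px, check_simple = FALSE)
    geometry <- frame_geometry(lumen_ct, eem_ct,
                               frame_id = vessel$geometry$frame_id)

    k <- config$landmark_count
    s_img_lm <- (seq_len(k) - 1) / k
    landmarks <- landmark_correspondence(s_hist = dist$g(s_img_lm),
                                         s_img = s_img_lm)

    cd68 <- NULL
    if (isTRUE(config$cd68)) {
      tissue <- matrix(FALSE, n_px, n_px)
      tissue[bidx] <- TRUE
      positive <- matrix(FALSE, n_px, n_px)
      nblob <- sample(1:3, 1L)
      for (bi in seq_len(nblob)) {
        j <- sample(length(bidx), 1L)
        cx <- X[bidx[j]]; cy <- Y[bidx[j]]
        rad <- stats::runif(1, 0.08, 0.2)
        inblob <- (X[bidx] - cx)^2 + (Y[bidx] - cy)^2 <= rad^2
        hit <- bidx[inblob][stats::runif(sum(inblob)) < 0.8]
        positive[hit] <- TRUE
      }
      spark <- bidx[stats::runif(length(bidx)) < 0.02]
      positive[spark] <- TRUE
      cd68 <- cd68_mask(positive, tissue, px)
    }

    list(geometry = geometry,
         mask = tissue_label_mask(grid, px),
         landmarks = landmarks, cd68 = cd68, distortion = dist)
  })
}

#' Simulate a machine-learning tissue classification of the truth frame
#'
#' Emulates the error modes of the intravascular classifiers: each tissue
#' region (every Ca/NC inclusion, and each angular sector of the contiguous
#' FT background) is relabelled according to the configured row-stochastic
#' misclassification matrix; inclusion boundaries are jittered with Gaussian
#' displacement; the ML EEM border is offset to inject a configured area bias
#' plus noise; and in OCT mode the EEM is truncated at a configured depth
#' with tissue beyond the attenuation depth relabelled NC (emulating signal
#' loss that makes deep tissue read as necrotic core). Deterministic per seed.
#'
#' @param vessel a [generate_vessel()] result.
#' @param seed integer seed.
#' @return list with `geometry` (ML lumen/EEM), `mask` (ML
#'   [tissue_label_mask()] on the imaging grid), `modality`, `mac_region`
#'   (logical matrix or NULL) and `draws` (realized region relabelling).
#' @export
simulate_ml_estimation <- function(vessel, seed = 1L) {
  stopifnot(inherits(vessel, "synthetic_vessel"))
  config <- vessel$config
  with_seed(seed, {
    M <- config$misclass
    classes <- plaque_classes
    draw <- function(row) sample(3L, 1L, prob = M[row, ])

    # ML EEM: thickness offset solving the injected area bias exactly
    t_ml_vertex <- vessel$t_vertex
    bias <- config$ml_eem_bias_mm2 +
      if (config$ml_eem_noise_mm2 > 0) stats::rnorm(1, 0, config$ml_eem_noise_mm2) else 0
    if (abs(bias) > 1e-12) {
      target <- vessel$truth$eem_area + bias
      area_of <- function(delta) {
        p <- vessel$lumen_phys + vessel$normals * pmax(t_ml_vertex + delta, 0.02)
        abs(shoelace2(p)) / 2
      }
      delta <- stats::uniroot(function(d) area_of(d) - target,
                              lower = -min(t_ml_vertex) + 0.03, upper = 1.5,
                              tol = 1e-7)$root
      t_ml_vertex <- pmax(t_ml_vertex + delta, 0.02)
    }
    oct <- identical(config$modality, "oct")
    trunc_mm <- config$oct_truncation_mm
    if (oct && !is.null(trunc_mm)) t_ml_vertex <- pmin(t_ml_vertex, trunc_mm)
    t_ml_fun <- circular_fun(vessel$s_vertex, t_ml_vertex)
    eem_ml_phys <- vessel$lumen_phys + vessel$normals * t_ml_vertex

    # region relabelling draws
    sector_draw <- vapply(seq_len(config$n_sectors), function(i) draw(1L), integer(1))
    cls <- vapply(vessel$inclusions, `[[`, "", "class")
    incl_draw <- vapply(cls, function(cl) draw(match(cl, classes)), integer(1))

    # jittered inclusion geometry
    sig <- config$boundary_sigma_mm
    incl_ml <- lapply(vessel$inclusions, function(e) {
      if (sig > 0) {
        e$cx <- e$cx + stats::rnorm(1, 0, sig)
        e$cy <- e$cy + stats::rnorm(1, 0, sig)
        e$a <- max(e$a + stats::rnorm(1, 0, sig / 2), 0.03)
        e$b <- max(e$b + stats::rnorm(1, 0, sig / 2), 0.02)
      }
      e
    })

    # rasterize using the cached band coordinates
    n_px <- vessel$n_px
    grid <- matrix(tissue_labels[["background"]], n_px, n_px)
    grid[vessel$pix$rr_lt_rmin] <- tissue_labels[["lumen"]]
    grid[vessel$pix$cand[vessel$pix$in_lumen]] <- tissue_labels[["lumen"]]
    band <- !vessel$pix$in_lumen & vessel$pix$d <= t_ml_fun(vessel$pix$s)
    bidx <- vessel$pix$cand[band]
    s_b <- vessel$pix$s[band]; d_b <- vessel$pix$d[band]
    sector <- pmin(floor(s_b * config$n_sectors) + 1L, config$n_sectors)
    lab <- tissue_labels[classes[sector_draw[sector]]]

    xs <- (seq_len(n_px) - 1 - vessel$ctr_px) * vessel$px
    X <- matrix(xs, n_px, n_px, byrow = TRUE); Y <- matrix(xs, n_px, n_px)
    bpts <- cbind(X[bidx], Y[bidx])
    ord <- c(which(cls == "nc"), which(cls == "ca"))  # Ca painted last
    for (i in ord)
      lab[in_ellipse(bpts, incl_ml[[i]])] <- tissue_labels[classes[incl_draw[i]]]

    att <- config$oct_attenuation_mm
    if (oct && !is.null(trunc_mm)) {
      if (is.null(att)) att <- max(trunc_mm - 0.2, 0.6 * trunc_mm)
      deep <- d_b > att
      lab[deep] <- tissue_labels[["nc"]]
    }
    grid[bidx] <- lab

    mac <- NULL
    if (isTRUE(config$cd68) && oct) {
      mac <- matrix(FALSE, n_px, n_px)
      for (bi in seq_len(sample(0:2, 1L))) {
        j <- sample(length(bidx), 1L)
        rad <- stats::runif(1, 0.05, 0.15)
        mac[bidx[(bpts[, 1L] - bpts[j, 1L])^2 + (bpts[, 2L] - bpts[j, 2L])^2 <= rad^2]] <- TRUE
      }
    }

    to_px <- function(p) p / vessel$px + vessel$ctr_px
    geometry <- frame_geometry(
      contour(to_px(vessel$lumen_phys), vessel$px, check_simple = FALSE),
      contour(to_px(eem_ml_phys), vessel$px, check_simple = FALSE),
      frame_id = vessel$geometry$frame_id)

    list(geometry = geometry,
         mask = tissue_label_mask(grid, vessel$px),
         modality = config$modality,
         mac_region = mac,
         draws = list(sector = sector_draw, inclusion = incl_draw,
                      eem_bias_realized = bias))
  })
}

#' Generate a cohort of matched synthetic frame pairs
#'
#' Independent seeded pairs (per-frame seeds derived from the master seed by
#' counter) with longitudinal positions spaced by the configured frame
#' spacing, so the frame-spacing filter passes by construction.
#'
#' @param config a [synthetic_config()].
#' @param n_frames number of pairs (>= 1).
#' @param seed master seed.
#' @return list of [matched_pair()] objects; each carries its `truth` record
#'   (analytic areas, applied misclassification draws, distortion).
#' @export
generate_cohort <- function(config = synthetic_config(), n_frames = 10L, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"), n_frames >= 1L)
  lapply(seq_len(n_frames), function(i) {
    si <- derive_seed(seed, i)
    vessel <- generate_vessel(config, si)
    vessel$geometry$frame_id <- sprintf("F%03d", i)
    hist <- degrade_to_histology(vessel, derive_seed(si, 1L))
    ml <- simulate_ml_estimation(vessel, derive_seed(si, 2L))
    hist$geometry$frame_id <- ml$geometry$frame_id <- vessel$geometry$frame_id
    pos <- (i - 1) * config$frame_spacing_mm
    hist$geometry$longitudinal_position_mm <- pos
    ml$geometry$longitudinal_position_mm <- pos
    matched_pair(
      histology = list(geometry = hist$geometry, mask = hist$mask,
                       cd68 = hist$cd68),
      imaging = list(geometry = ml$geometry, mask = ml$mask,
                     modality = config$modality, mac_region = ml$mac_region),
      landmarks = hist$landmarks,
      truth = list(record = vessel$truth, draws = ml$draws,
                   distortion = hist$distortion, seed = si,
                   truth_mask = vessel$mask, truth_geometry = vessel$geometry)
    )
  })
}
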