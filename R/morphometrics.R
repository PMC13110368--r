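#' 2D shape descriptors of a binary mask
#'
#' The four classic particle-analysis descriptors, computed from the moment
#' ellipse and region geometry: aspect ratio = major/minor axis of the moment
#' ellipse; circularity = `4*pi*area / perimeter^2` with the perimeter taken
#' from the sub-pixel boundary contour; roundness = `4*area / (pi*major^2)`;
#' solidity = area / convex hull area (hull of foreground pixel centres).
#'
#' @param mask a [mask2d()].
#' @return A one-row tibble: `aspect_ratio`, `circularity`, `roundness`,
#'   `solidity`, plus `area_um2` and `perimeter_um`.
#' @export
shape_descriptors <- function(mask) {
  stopifnot(inherits(mask, "mask2d"))
  if (sum(mask$mask) < 3) stop("degenerate mask", call. = FALSE)
  fit <- fit_ellipse(mask)
  sp <- mask$spacing_um
  area <- sum(mask$mask) * prod(sp)
  per <- mask_perimeter_um(mask)
  xy <- mask_coords_um(mask)
  hull <- grDevices::chull(xy[, 2], xy[, 1])
  hx <- xy[hull, 2]
  hy <- xy[hull, 1]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  tibble::tibble(
    aspect_ratio = fit$major_axis_um / fit$minor_axis_um,
    circularity = 4 * pi * area / per^2,
    roundness = 4 * area / (pi * fit$major_axis_um^2),
    solidity = if (hull_area > 0) area / hull_area else NA_real_,
    area_um2 = area,
    perimeter_um = per
  )
}

# sub-pixel boundary length from marching-squares contours at level 0.5,
# in micrometres (sums over all contour rings)
mask_perimeter_um <- function(mask) {
  m <- mask$mask * 1
  sp <- mask$spacing_um
  # pad so boundary touching the image edge still produces a closed contour
  mp <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  mp[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  cl <- grDevices::contourLines(
    x = seq_len(nrow(mp)) * sp[1], y = seq_len(ncol(mp)) * sp[2],
    z = mp, levels = 0.5)
  if (length(cl) == 0) stop("degenerate mask: no boundary", call. = FALSE)
  # smooth the closed polygon vertices (window 5) before measuring: the raw
  # marching-squares contour staircases along oblique edges and overestimates
  # smooth boundaries by ~6%
  smooth_closed <- function(v, w = 5) {
    n <- length(v)
    if (n < w) return(v)
    k <- (w - 1) / 2
    vv <- c(v[(n - k + 1):n], v, v[1:k])
    stats::filter(vv, rep(1 / w, w))[(k + 1):(k + n)]
  }
  sum(vapply(cl, function(cc) {
    x <- smooth_closed(cc$x)
    y <- smooth_closed(cc$y)
    dx <- diff(c(x, x[1]))
    dy <- diff(c(y, y[1]))
    sum(sqrt(dx^2 + dy^2))
  }, 0))
}

#' Build a radial-spoke rosette template
#'
#' Radial spokes converging on a bright centre, mimicking the membrane
#' signature of an epithelial rosette (cell walls meeting at the apical
#' constriction) on a maximum projection.
#'
#' @param radius_px rosette radius in pixels.
#' @param n_spokes number of radial spokes.
#' @return numeric matrix (square, side `2*radius_px + 1`).
#' @export
rosette_template <- function(radius_px, n_spokes = 8) {
  r <- max(3L, round(radius_px))
  n <- 2L * r + 1L
  yy <- matrix(seq_len(n) - r - 1, n, n)
  xx <- t(yy)
  rad <- sqrt(yy^2 + xx^2)
  ang <- atan2(yy, xx)
  # radial membrane walls converging on the constriction centre; wall
  # cross-section ~1.25 px sigma, matching a blurred membrane in projection
  spokes <- matrix(0, n, n)
  w <- 1.25
  for (k in seq_len(n_spokes)) {
    a <- -pi + (k - 1) * 2 * pi / n_spokes
    d <- abs(atan2(sin(ang - a), cos(ang - a)))
    spokes <- pmax(spokes, exp(-(d * pmax(rad, 1))^2 / (2 * w^2)) * (rad <= r))
  }
  centre <- exp(-rad^2 / (2 * (0.15 * r)^2))   # walls pile up at the centre
  pmin(spokes + centre, 1)
}

#' Detect rosettes on a membrane projection by template correlation
#'
#' A maximum-intensity projection of the central tissue depth (where apical
#' constrictions sit) is correlated (normalized cross-correlation on a disk
#' support) with radial-spoke templates at the expected radius, maximizing
#' over template rotations; local maxima above a score floor, separated by
#' non-maximum suppression at 1.5 x radius, become detections. Scores are
#' clipped to `[0, 1]`. External score lists (e.g. from a learned detector)
#' can be fed straight to [rosettiness()] instead.
#'
#' @param x a [voxel_stack()] (its `channel` is projected over the central
#'   30-70% of slices) or a 2D matrix already in projection form.
#' @param mask optional [mask2d()]; detections outside it are discarded.
#' @param expected_radius_um rosette radius to search for, micrometres.
#' @param channel channel to project when `x` is a stack.
#' @param floor minimum template-correlation score for a detection.
#' @param n_spokes spokes in the template (the expected wall count).
#' @param n_rotations template rotations searched within one spoke period.
#' @param spacing_um pixel spacing `(dy, dx)` when `x` is a plain matrix.
#' @return A tibble of detections: `y_um`, `x_um`, `radius_um`, `score`.
#' @export
detect_rosettes <- function(x, mask = NULL, expected_radius_um = 10,
                            channel = "membrane", floor = 0.4, n_spokes = 12,
                            n_rotations = 6, spacing_um = c(1, 1)) {
  stopifnot(expected_radius_um > 0)
  if (inherits(x, "voxel_stack")) {
    vol <- x$channels[[channel]]
    nz <- dim(vol)[1]
    z1 <- max(1L, round(0.35 * nz))
    z2 <- max(z1, round(0.65 * nz))
    img <- apply(vol[z1:z2, , , drop = FALSE], c(2, 3), max)
    sp <- x$spacing_um[2:3]
  } else {
    img <- x
    sp <- spacing_um
  }
  if (abs(sp[1] - sp[2]) > 1e-9) {
    stop("rosette detection requires square pixels in-plane", call. = FALSE)
  }
  r_px <- expected_radius_um / sp[1]
  tm <- rosette_template(r_px, n_spokes)
  empty <- tibble::tibble(y_um = numeric(0), x_um = numeric(0),
                          radius_um = numeric(0), score = numeric(0))
  if (nrow(tm) > nrow(img) || ncol(tm) > ncol(img)) {
    return(empty)
  }
  n <- nrow(tm)
  ctr <- c(n / 2, n / 2)
  rad <- sqrt((matrix(seq_len(n), n, n) - ctr[1])^2 +
                (t(matrix(seq_len(n), n, n)) - ctr[2])^2)
  support <- matrix(as.integer(rad <= (n - 1) / 2), n, n)
  angles <- seq(0, 360 / n_spokes, length.out = n_rotations + 1)[
    seq_len(n_rotations)]
  ncc <- Reduce(pmax, lapply(angles, function(a) {
    cpp_ncc2d(img, rotate_slice(tm, a, ctr), support)
  }))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mask2d"))
    ncc[!mask$mask] <- 0
  }
  # candidate local maxima above the floor, greedy non-maximum suppression
  cand <- which(ncc > floor, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  sc <- ncc[cand]
  ord <- order(sc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  min_d <- 1.5 * r_px
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) {
      keep[1] <- TRUE
      next
    }
    prev <- cand[keep, , drop = FALSE]
    dd <- sqrt((prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2)
    keep[i] <- all(dd >= min_d)
  }
  det <- cand[keep, , drop = FALSE]
  tibble::tibble(
    y_um = (det[, 1] - 0.5) * sp[1],
    x_um = (det[, 2] - 0.5) * sp[2],
    radius_um = expected_radius_um,
    score = pmin(pmax(sc[keep], 0), 1)
  )
}

#' Rosettiness: mean detection score
#'
#' The ratio of weighted detections (sum of detection scores) over the number
#' of detections. Undefined (NA with a warning) when there are no detections
#' - deliberately distinct from a score of zero.
#'
#' @param detections a [detect_rosettes()] tibble, or a numeric vector of
#'   scores.
#' @return scalar score, or `NA` when undefined.
#' @export
rosettiness <- function(detections) {
  scores <- if (is.data.frame(detections)) detections$score else detections
  if (length(scores) == 0) {
    warning("rosettiness undefined: no detections", call. = FALSE)
    return(NA_real_)
  }
  sum(scores) / length(scores)
}

#' Summarize one primordium: count, volume, shape, rosettes
#'
#' Cell count and total volume are taken over kept cells only; shape
#' descriptors come from the 2D footprint mask; rosette metrics from the
#' detection list.
#'
#' @param cells a [measure_cells()] tibble carrying `flag`.
#' @param mask optional [mask2d()] footprint for shape descriptors.
#' @param detections optional [detect_rosettes()] tibble.
#' @param diving optional logical phenotype annotation.
#' @return A one-row tibble: `cell_count`, `total_volume_um3`, shape columns
#'   (NA without a mask), `n_rosette_detections`, `rosettiness`, `diving`.
#' @export
summarize_primordium <- function(cells, mask = NULL, detections = NULL,
                                 diving = NA) {
  kept <- cells[cells$flag == "kept", , drop = FALSE]
  shp <- if (!is.null(mask) && nrow(kept) > 0) {
    shape_descriptors(mask)
  } else {
    tibble::tibble(aspect_ratio = NA_real_, circularity = NA_real_,
                   roundness = NA_real_, solidity = NA_real_,
                   area_um2 = NA_real_, perimeter_um = NA_real_)
  }
  n_det <- if (is.null(detections)) 0L else nrow(detections)
  ros <- if (is.null(detections) || n_det == 0) {
    NA_real_
  } else {
    rosettiness(detections)
  }
  tibble::tibble(
    cell_count = nrow(kept),
    total_volume_um3 = sum(kept$volume_um3),
    aspect_ratio = shp$aspect_ratio,
    circularity = shp$circularity,
    roundness = shp$roundness,
    solidity = shp$solidity,
    n_rosette_detections = n_det,
    rosettiness = ros,
    diving = diving
  )
}

#' Neuromast deposition pattern from a trunk overview image
#'
#' Threshold (bimodal minimum), connected components, size floor, centroid
#' extraction, ordering along the anteroposterior (x) axis, and normalization
#' of positions to the first cluster (the ganglion). The neuromast count
#' excludes the ganglion and, when `drop_terminal` is set, the trailing
#' primordium cluster.
#'
#' @param image 2D matrix (overview) or the result of [simulate_overview()].
#' @param spacing_um pixel spacing `(dy, dx)` um.
#' @param min_px minimum cluster size in pixels.
#' @param drop_terminal drop the most posterior cluster (migrating
#'   primordium) from the neuromast count.
#' @return A list of class `deposition_pattern`: `positions_um` (normalized,
#'   first = 0, non-decreasing), `raw_positions_um` (y, x), `n_neuromasts`.
#' @export
deposition_pattern <- function(image, spacing_um = c(1, 1), min_px = 20,
                               drop_terminal = FALSE) {
  if (is.list(image) && !is.null(image$image)) {
    spacing_um <- image$spacing_um
    image <- image$image
  }
  stopifnot(is.matrix(image))
  thr <- minimum_threshold(as.vector(image))
  bin <- image > thr
  if (!any(bin)) stop("no clusters detected", call. = FALSE)
  d <- dim(bin)
  lab <- cpp_label3d(array(as.integer(bin), c(1L, d)), c(1L, d), 26L)[1, , ]
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  if (length(keep) == 0) stop("no clusters above the size floor", call. = FALSE)
  cent <- t(vapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(mean(idx[, 1] - 0.5) * spacing_um[1], mean(idx[, 2] - 0.5) * spacing_um[2])
  }, c(0, 0)))
  ord <- order(cent[, 2])
  cent <- cent[ord, , drop = FALSE]
  pos <- cent[, 2] - cent[1, 2]
  n_nm <- nrow(cent) - 1L - if (drop_terminal && nrow(cent) > 1) 1L else 0L
  structure(
    list(positions_um = pos,
         raw_positions_um = cent,
         n_neuromasts = max(n_nm, 0L)),
    class = "deposition_pattern"
  )
}

#' @export
print.deposition_pattern <- function(x, ...) {
  cat(sprintf("<deposition_pattern> %d neuromasts; positions (um): %s\n",
              x$n_neuromasts, paste(round(x$positions_um, 1), collapse = ", ")))
  invisible(x)
}

#' Stained area of a 2D chromogenic in-situ image
#'
#' Dark stain on a light background: the image is auto-thresholded with the
#' bimodal-minimum algorithm (inverted polarity), the largest dark component
#' retained, and its area reported in physical units.
#'
#' @param image 2D matrix, single channel.
#' @param calibration_um_per_px pixel side length, micrometres.
#' @return area in square micrometres (0 with a warning when no stain is
#'   found).
#' @export
stained_area <- function(image, calibration_um_per_px = 1) {
  stopifnot(is.matrix(image), calibration_um_per_px > 0)
  thr <- tryCatch(minimum_threshold(as.vector(image)),
                  error = function(e) NA_real_)
  if (is.na(thr)) {
    warning("no stain detected", call. = FALSE)
    return(0)
  }
  bin <- image < thr                    # stain is dark
  if (!any(bin)) {
    warning("no stain detected", call. = FALSE)
    return(0)
  }
  comp <- largest_component_2d(bin)
  sum(comp) * calibration_um_per_px^2
}
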