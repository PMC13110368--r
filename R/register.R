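#' Bimodal-minimum automatic threshold
#'
#' The classic bimodal-histogram threshold: a 256-bin histogram is smoothed
#' with a 3-bin running mean until exactly two local maxima remain; the
#' threshold is the minimum between them, mapped back to the intensity scale.
#'
#' @param x numeric values (any range; binned over their own range).
#' @param max_iter smoothing-iteration bound before giving up.
#' @return threshold value on the scale of `x`.
#' @export
minimum_threshold <- function(x, max_iter = 10000L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) {
    stop("no bimodal separation: constant image", call. = FALSE)
  }
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * 256) + 1L, 1L), 256L),
                nbins = 256L)
  h <- as.numeric(h)
  local_maxima <- function(h) {
    n <- length(h)
    hp <- c(-Inf, h[1:(n - 1)])          # edge bins may be maxima
    hn <- c(h[2:n], -Inf)
    which(h > hp & h >= hn & h > 0)
  }
  it <- 0L
  while (length(local_maxima(h)) > 2) {
    h <- (c(h[1], h[-length(h)]) + h + c(h[-1], h[length(h)])) / 3
    it <- it + 1L
    if (it >= max_iter) break
  }
  peaks <- local_maxima(h)
  if (length(peaks) != 2) {
    stop("no bimodal separation", call. = FALSE)
  }
  valley <- peaks[1] + which.min(h[peaks[1]:peaks[2]]) - 1L
  rng[1] + (valley - 0.5) / 256 * diff(rng)
}

largest_component_2d <- function(mask) {
  d <- dim(mask)
  m3 <- array(as.integer(mask), dim = c(1L, d))
  lab <- cpp_label3d(m3, c(1L, d), 26L)
  lab <- lab[1, , ]
  if (all(lab == 0L)) stop("empty mask", call. = FALSE)
  counts <- tabulate(lab[lab > 0L])
  matrix(lab == which.max(counts), d[1], d[2])
}

blur2d <- function(img, sigma_px) {
  d <- dim(img)
  a <- cpp_blur3d(array(img, c(1L, d)), c(1L, d), c(0, sigma_px))
  matrix(a, d[1], d[2])
}

#' Project a stack and segment the primordium footprint in 2D
#'
#' Maximum-intensity Z projection, Gaussian blur, bimodal-minimum automatic
#' threshold, then retention of the largest connected foreground component.
#'
#' @param stack a [voxel_stack()].
#' @param channel channel name to project (default `"membrane"`).
#' @param blur_sigma_um Gaussian blur sigma in micrometres (applied in-plane).
#' @return A [mask2d()] of the primordium footprint.
#' @export
project_and_mask <- function(stack, channel = "membrane", blur_sigma_um = 2) {
  stopifnot(inherits(stack, "voxel_stack"), blur_sigma_um >= 0)
  if (!channel %in% names(stack$channels)) {
    stop("channel not found: ", channel, call. = FALSE)
  }
  proj <- apply(stack$channels[[channel]], c(2, 3), max)
  sp <- stack$spacing_um[2:3]
  if (blur_sigma_um > 0) proj <- blur2d(proj, blur_sigma_um / sp)
  thr <- minimum_threshold(as.vector(proj))
  mask <- proj > thr
  if (!any(mask)) stop("empty mask after thresholding", call. = FALSE)
  mask2d(largest_component_2d(mask), sp)
}

#' Fit the second-central-moment ellipse of a binary mask
#'
#' Axis lengths follow the standard moment-ellipse convention (axis length =
#' 4 x sqrt(eigenvalue) of the coordinate covariance); the angle is the
#' orientation of the principal eigenvector relative to the horizontal axis,
#' in degrees within (-90, 90].
#'
#' @param mask a [mask2d()].
#' @return An `ellipse_fit` list: `centroid_um` (y, x), `major_axis_um`,
#'   `minor_axis_um`, `angle_deg`, and the input `mask`.
#' @export
fit_ellipse <- function(mask) {
  stopifnot(inherits(mask, "mask2d"))
  xy <- mask_coords_um(mask)
  if (nrow(xy) < 3) stop("degenerate mask: fewer than 3 pixels", call. = FALSE)
  ctr <- colMeans(xy)
  cc <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
  if (any(!is.finite(cc)) || all(cc == 0)) {
    stop("degenerate mask: zero spatial variance", call. = FALSE)
  }
  e <- eigen(cc, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[2] <= 0) {
    stop("degenerate mask: collinear pixels", call. = FALSE)
  }
  v <- e$vectors[, 1]                    # (y, x) principal direction
  ang <- atan2(v[1], v[2]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  structure(
    list(centroid_um = ctr, major_axis_um = 4 * sqrt(lam[1]),
         minor_axis_um = 4 * sqrt(lam[2]), angle_deg = ang, mask = mask),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> centroid (%.1f, %.1f) um, axes %.1f x %.1f um, angle %.1f deg\n",
    x$centroid_um[1], x$centroid_um[2], x$major_axis_um, x$minor_axis_um,
    x$angle_deg))
  invisible(x)
}

# rotate 2D image content by angle_deg (a feature at direction phi moves to
# phi + angle) about center_px (y, x, in pixel units, 0.5-offset convention);
# interp "linear" or "nearest"; outside-image samples become `fill`
rotate_slice <- function(img, angle_deg, center_px, interp = "linear",
                         fill = 0) {
  d <- dim(img)
  th <- -angle_deg * pi / 180            # inverse map: sample source frame
  yt <- matrix(seq_len(d[1]) - 0.5, d[1], d[2]) - center_px[1]
  xt <- matrix(rep(seq_len(d[2]) - 0.5, each = d[1]), d[1], d[2]) - center_px[2]
  ys <- xt * sin(th) + yt * cos(th) + center_px[1]
  xs <- xt * cos(th) - yt * sin(th) + center_px[2]
  if (interp == "nearest") {
    iy <- round(ys + 0.5)
    ix <- round(xs + 0.5)
    ok <- iy >= 1 & iy <= d[1] & ix >= 1 & ix <= d[2]
    out <- matrix(fill, d[1], d[2])
    out[ok] <- img[cbind(iy[ok], ix[ok])]
    return(out)
  }
  fy <- ys - 0.5
  fx <- xs - 0.5
  y0 <- floor(fy)
  x0 <- floor(fx)
  wy <- fy - y0
  wx <- fx - x0
  gv <- function(iy, ix) {
    ok <- iy >= 0 & iy <= d[1] - 1 & ix >= 0 & ix <= d[2] - 1
    v <- matrix(fill, d[1], d[2])
    v[ok] <- img[cbind(iy[ok] + 1L, ix[ok] + 1L)]
    v
  }
  gv(y0, x0) * (1 - wy) * (1 - wx) + gv(y0 + 1, x0) * wy * (1 - wx) +
    gv(y0, x0 + 1) * (1 - wy) * wx + gv(y0 + 1, x0 + 1) * wy * wx
}

#' Register a stack: rotate the primordium horizontal, crop in X, Y and Z
#'
#' Every channel is rotated in-plane by the negated fitted angle about the
#' mask centroid (linear interpolation), cropped in Y/X to the rotated mask
#' bounding box plus a margin, and cropped in Z to the contiguous slice range
#' whose in-mask upper-decile intensity exceeds the out-of-mask background
#' mean by two background SDs. Optional extra volumes (e.g. ground-truth
#' labels) undergo the identical transform with nearest-neighbour
#' interpolation.
#'
#' @param stack a [voxel_stack()].
#' @param fit an [fit_ellipse()] result obtained from this stack's mask.
#' @param margin_um crop margin around the mask bounding box, um.
#' @param channel channel used for the Z-crop intensity rule.
#' @param extras named list of 3D integer arrays (same shape as the stack) to
#'   transform with nearest-neighbour interpolation.
#' @return A list: `stack` (registered [voxel_stack()]), `mask` (the
#'   footprint mask carried through the same rotation and crop), `extras`
#'   (transformed copies), `params` (angle, centroid, crop windows).
#' @export
register_stack <- function(stack, fit, margin_um = 5, channel = "membrane",
                           extras = NULL) {
  stopifnot(inherits(stack, "voxel_stack"), inherits(fit, "ellipse_fit"))
  d <- dim(stack)
  sp <- stack$spacing_um
  ctr_px <- fit$centroid_um / sp[2:3]

  rot_stack <- function(vol, interp) {
    out <- array(if (interp == "linear") 0 else 0L, dim = d)
    for (z in seq_len(d[1])) {
      out[z, , ] <- rotate_slice(vol[z, , ], -fit$angle_deg, ctr_px,
                                 interp = interp)
    }
    out
  }
  channels <- lapply(stack$channels, rot_stack, interp = "linear")
  extras_r <- lapply(extras, rot_stack, interp = "nearest")

  rmask <- rotate_slice(fit$mask$mask * 1, -fit$angle_deg, ctr_px,
                        interp = "nearest") > 0
  if (!any(rmask)) stop("empty mask after rotation", call. = FALSE)
  idx <- which(rmask, arr.ind = TRUE)
  my <- margin_um / sp[2]
  mx <- margin_um / sp[3]
  y_rng <- c(max(1L, floor(min(idx[, 1]) - my)),
             min(d[2], ceiling(max(idx[, 1]) + my)))
  x_rng <- c(max(1L, floor(min(idx[, 2]) - mx)),
             min(d[3], ceiling(max(idx[, 2]) + mx)))
  if (y_rng[1] > y_rng[2] || x_rng[1] > x_rng[2]) {
    stop("empty crop window", call. = FALSE)
  }

  ref <- matrix(channels[[channel]], nrow = d[1])   # z by (y,x)
  bg_vals <- as.vector(ref[, !as.vector(rmask), drop = FALSE])
  bg_vals <- bg_vals[bg_vals > 0]        # rotation fill must not bias the floor
  mu_bg <- if (length(bg_vals)) mean(bg_vals) else 0
  sd_bg <- if (length(bg_vals) > 1) sd(bg_vals) else 0
  # a slice is informative when its brightest in-mask decile clears the
  # background floor; a mean-based rule would shave slices where the tissue
  # covers only part of the footprint
  in_q90 <- apply(ref[, as.vector(rmask), drop = FALSE], 1, quantile,
                  probs = 0.9, names = FALSE)
  keep_z <- which(in_q90 > mu_bg + 2 * sd_bg)
  if (length(keep_z) == 0) stop("no informative Z slices", call. = FALSE)
  # pad one slice on each side: boundary slices are blur-attenuated and
  # shaving them truncates the apical/basal caps of the outer cell layer
  z_rng <- c(max(1L, min(keep_z) - 1L), min(d[1], max(keep_z) + 1L))

  crop <- function(vol) {
    vol[z_rng[1]:z_rng[2], y_rng[1]:y_rng[2], x_rng[1]:x_rng[2], drop = FALSE]
  }
  out <- voxel_stack(lapply(channels, crop), sp, origin_um = stack$origin_um +
                       (c(z_rng[1], y_rng[1], x_rng[1]) - 1) * sp)
  mask_out <- mask2d(rmask[y_rng[1]:y_rng[2], x_rng[1]:x_rng[2], drop = FALSE],
                     sp[2:3])
  list(stack = out,
       mask = mask_out,
       extras = lapply(extras_r, crop),
       params = list(angle_deg = fit$angle_deg, centroid_um = fit$centroid_um,
                     z_range = z_rng, y_range = y_rng, x_range = x_rng))
}
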