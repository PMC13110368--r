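#' Mean gray value of a channel
#'
#' Two measurement modes used for reporter quantification:
#' `whole_image_avg_projection` averages the average-intensity Z projection
#' over all pixels (identical to the full-stack mean), and
#' `single_plane_roi` averages over ROI pixels on one stated plane.
#'
#' @param stack a [voxel_stack()].
#' @param channel channel name.
#' @param roi optional [mask2d()] (required for `single_plane_roi`).
#' @param mode `"whole_image_avg_projection"` or `"single_plane_roi"`.
#' @param plane z index for `single_plane_roi` (default 1).
#' @return scalar mean gray value.
#' @export
mean_gray <- function(stack, channel = "reporter", roi = NULL,
                      mode = c("whole_image_avg_projection",
                               "single_plane_roi"),
                      plane = 1L) {
  mode <- match.arg(mode)
  vol <- stack$channels[[channel]]
  if (is.null(vol)) stop("channel not found: ", channel, call. = FALSE)
  if (mode == "whole_image_avg_projection") {
    proj <- apply(vol, c(2, 3), mean)
    return(mean(proj))
  }
  stopifnot(inherits(roi, "mask2d"))
  if (!any(roi$mask)) stop("empty ROI", call. = FALSE)
  sl <- vol[plane, , ]
  mean(sl[roi$mask])
}

#' Count reporter-positive cells
#'
#' A cell is positive when its mean reporter intensity exceeds the
#' background mean by `k` background standard deviations - the operational
#' reading of "significantly higher fluorescence than the surrounding
#' non-expressing tissue".
#'
#' @param cell_means numeric vector of per-cell mean intensities (e.g. the
#'   `mean_<channel>` column of [measure_cells()]).
#' @param background numeric vector of background intensities (pixels of a
#'   background ROI), or a list `list(mean =, sd =)`.
#' @param k threshold multiplier (default 2).
#' @return integer count of positive cells.
#' @export
count_positive_cells <- function(cell_means, background, k = 2) {
  stopifnot(k >= 0)
  if (is.list(background)) {
    mu <- background$mean
    s <- background$sd
  } else {
    mu <- mean(background)
    s <- sd(background)
    if (length(background) < 2) s <- 0
  }
  if (is.na(s)) s <- 0
  sum(cell_means > mu + k * s)
}

#' Intensity profile along a line segment
#'
#' Samples the mean gray value in a band of `width_px` pixels perpendicular
#' to the segment at `n_stations` evenly spaced stations. Station positions
#' are expressed as relative distance in `[0, 1]`; each channel is
#' normalized to its own maximum along the profile.
#'
#' @param stack a [voxel_stack()]; sampling is on a single plane.
#' @param from,to segment endpoints, `(y, x)` pixel coordinates.
#' @param channels channel names to sample.
#' @param width_px band width perpendicular to the segment, pixels.
#' @param n_stations number of stations.
#' @param plane z index to sample.
#' @return A `profile_curve` tibble: `relative_distance` plus one normalized
#'   column per channel; raw means are in the `"raw"` attribute.
#' @export
line_profile <- function(stack, from, to, channels = names(stack$channels),
                         width_px = 3, n_stations = 100, plane = 1L) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack)
  if (all(from == to)) stop("zero-length segment", call. = FALSE)
  vdir <- c(to[1] - from[1], to[2] - from[2])
  len <- sqrt(sum(vdir^2))
  u <- vdir / len
  perp <- c(-u[2], u[1])
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  tt <- seq(0, 1, length.out = n_stations)

  bilinear <- function(img, y, x) {
    # y, x are 1-based pixel indices; pixel i sits at coordinate i
    fy <- pmin(pmax(y - 1, 0), nrow(img) - 1)
    fx <- pmin(pmax(x - 1, 0), ncol(img) - 1)
    y0 <- pmin(floor(fy), nrow(img) - 2)
    x0 <- pmin(floor(fx), ncol(img) - 2)
    wy <- fy - y0
    wx <- fx - x0
    img[cbind(y0 + 1, x0 + 1)] * (1 - wy) * (1 - wx) +
      img[cbind(y0 + 2, x0 + 1)] * wy * (1 - wx) +
      img[cbind(y0 + 1, x0 + 2)] * (1 - wy) * wx +
      img[cbind(y0 + 2, x0 + 2)] * wy * wx
  }

  out <- tibble::tibble(relative_distance = tt)
  raw <- list()
  for (ch in channels) {
    img <- stack$channels[[ch]][plane, , ]
    vals <- vapply(tt, function(t1) {
      py <- from[1] + t1 * vdir[1] + offs * perp[1]
      px <- from[2] + t1 * vdir[2] + offs * perp[2]
      mean(bilinear(img, py, px))
    }, 0)
    raw[[ch]] <- vals
    mx <- max(vals)
    out[[ch]] <- if (mx > 0) vals / mx else vals
  }
  attr(out, "raw") <- raw
  class(out) <- c("profile_curve", class(out))
  out
}

#' Normalized channel ratio at the profile midpoint
#'
#' Linear interpolation of each max-normalized channel at relative distance
#' 0.5; returns the target/reference ratio. This is the nuclear-enrichment
#' readout: a nuclear-localized target scores high against a nuclear
#' reference, a cytoplasm-shifted one scores low.
#'
#' @param profile a [line_profile()] result.
#' @param target_channel,ref_channel channel names on the profile.
#' @return scalar ratio.
#' @export
midpoint_normalized_intensity <- function(profile, target_channel,
                                          ref_channel) {
  stopifnot(all(c(target_channel, ref_channel) %in% names(profile)))
  rd <- profile$relative_distance
  if (min(rd) > 0.5 || max(rd) < 0.5) {
    stop("profile does not cover relative distance 0.5", call. = FALSE)
  }
  at <- function(ch) stats::approx(rd, profile[[ch]], xout = 0.5)$y
  ref <- at(ref_channel)
  if (!is.finite(ref) || ref == 0) {
    stop("reference channel is zero at the midpoint: ratio undefined",
         call. = FALSE)
  }
  at(target_channel) / ref
}

#' EdU-positive cell counts and proliferation ratio
#'
#' Positivity by the same background + k*SD rule as
#' [count_positive_cells()]; the ratio is positives over total cells.
#'
#' @param cell_means per-cell mean EdU intensities.
#' @param background background intensities or `list(mean =, sd =)`.
#' @param k threshold multiplier.
#' @return A one-row tibble: `n_positive`, `n_total`, `ratio` (`NA` when
#'   there are no cells).
#' @export
edu_counts <- function(cell_means, background, k = 2) {
  n_total <- length(cell_means)
  if (n_total == 0) {
    warning("no cells: EdU ratio undefined", call. = FALSE)
    return(tibble::tibble(n_positive = 0L, n_total = 0L, ratio = NA_real_))
  }
  n_pos <- count_positive_cells(cell_means, background, k)
  tibble::tibble(n_positive = n_pos, n_total = n_total,
                 ratio = n_pos / n_total)
}
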