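#' Suppress shallow minima of a 3D relief (h-minima transform)
#'
#' Implemented as grayscale reconstruction by erosion of `relief + h` over
#' `relief`; regional minima shallower than `h` disappear.
#'
#' @param relief 3D numeric array.
#' @param h minimum depth to survive (> 0).
#' @return transformed array, same shape.
#' @export
hminima <- function(relief, h) {
  stopifnot(h > 0, length(dim(relief)) == 3)
  d <- dim(relief)
  -cpp_reconstruct_dilate(-(relief + h), -relief, d)
}

#' Single-cell 3D segmentation by marker-controlled watershed
#'
#' The membrane channel is treated as a topographic relief: after an
#' anisotropy-corrected 3D Gaussian blur, shallow minima are suppressed with
#' the h-minima transform, the surviving regional minima become markers, and
#' the relief is flooded by a priority queue (Meyer watershed, 6-connected,
#' no zero-width boundary voxels). Minima connected to the stack border
#' through low-intensity space seed the background.
#'
#' @param stack a [voxel_stack()].
#' @param channel membrane-style channel (bright boundaries).
#' @param sigma_um 3D Gaussian blur sigma, micrometres.
#' @param h_depth minimum-depth tolerance on the `[0, 1]` intensity scale.
#' @return A [label_volume()] with contiguous labels `1..K`; the attribute
#'   `"failed"` is `TRUE` when no cell marker survives.
#' @export
segment_cells <- function(stack, channel = "membrane", sigma_um = 0.5,
                          h_depth = 0.03) {
  stopifnot(inherits(stack, "voxel_stack"), sigma_um >= 0, h_depth > 0)
  vol <- stack$channels[[channel]]
  if (is.null(vol)) stop("channel not found: ", channel, call. = FALSE)
  d <- dim(vol)
  sp <- stack$spacing_um
  blurred <- if (sigma_um > 0) cpp_blur3d(vol, d, sigma_um / sp) else vol
  hm <- hminima(blurred, h_depth)
  markers <- cpp_regional_minima(hm, d, 26L)

  # minima components touching the stack border seed the background
  border_labels <- unique(c(markers[c(1, d[1]), , ], markers[, c(1, d[2]), ],
                            markers[, , c(1, d[3])]))
  border_labels <- setdiff(border_labels, 0L)
  n_marks <- max(markers)
  if (n_marks == 0L || n_marks == length(border_labels)) {
    out <- label_volume(array(0L, d), sp)
    attr(out, "failed") <- TRUE
    warning("segmentation failed: no cell markers survived", call. = FALSE)
    return(out)
  }
  bg_label <- n_marks + 1L
  if (length(border_labels) > 0) {
    markers[markers %in% border_labels] <- bg_label
  }
  ws <- cpp_watershed(blurred, markers, d, penalty_label = bg_label)
  ws[ws == bg_label] <- 0L
  # contiguous relabel preserving id order
  ids <- sort(setdiff(unique(as.vector(ws)), 0L))
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  ws[ws > 0L] <- remap[ws[ws > 0L]]
  label_volume(ws, sp)
}

#' Remove segments outside a physical volume range and trim blank Z slices
#'
#' Labels whose physical volume falls outside `[v_min_um3, v_max_um3]` are
#' set to background; Z slices without any remaining foreground are trimmed
#' from both stack ends; surviving labels are re-indexed contiguously.
#' Removals are recorded in the `"removed"` attribute.
#'
#' @param labels a [label_volume()].
#' @param v_min_um3,v_max_um3 inclusive volume gates, cubic micrometres.
#' @return Filtered [label_volume()] with attribute `removed` (tibble of
#'   label, volume, reason).
#' @export
filter_segments <- function(labels, v_min_um3 = 30, v_max_um3 = 3000) {
  stopifnot(inherits(labels, "label_volume"), v_min_um3 < v_max_um3)
  lab <- labels$labels
  voxel_vol <- prod(labels$spacing_um)
  n <- max(lab, 0L)
  if (n == 0L) stop("empty segmentation: no labels to filter", call. = FALSE)
  vols <- tabulate(lab[lab > 0L], nbins = n) * voxel_vol
  present <- which(vols > 0)
  bad <- present[vols[present] < v_min_um3 | vols[present] > v_max_um3]
  removed <- tibble::tibble(
    label = bad, volume_um3 = vols[bad],
    reason = ifelse(vols[bad] < v_min_um3, "below_v_min", "above_v_max"))
  if (length(bad) > 0) lab[lab %in% bad] <- 0L
  keep <- setdiff(present, bad)
  if (length(keep) == 0) {
    stop("all segments removed by the volume filter", call. = FALSE)
  }
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]

  # trim blank Z slices at either stack end
  has_fg <- apply(lab > 0L, 1, any)
  z_rng <- range(which(has_fg))
  lab <- lab[z_rng[1]:z_rng[2], , , drop = FALSE]

  out <- label_volume(lab, labels$spacing_um)
  attr(out, "removed") <- removed
  attr(out, "z_trim") <- z_rng
  out
}

#' Measure per-cell 3D geometry and channel intensities
#'
#' Volume is voxel count times the voxel volume; surface area is the sum of
#' exposed voxel faces weighted by their physical areas (`dy*dx`, `dz*dx`,
#' `dz*dy`), counting faces against other labels, background and the stack
#' boundary; centroids are physical voxel-centre means. Per-channel mean
#' intensities are computed for every channel of `stack`.
#'
#' @param labels a [label_volume()].
#' @param stack optional [voxel_stack()] with the same shape and spacing.
#' @return A tibble (one row per cell): `label`, `volume_um3`, `surface_um2`,
#'   `sv_ratio_per_um`, `centroid_z_um`, `centroid_y_um`, `centroid_x_um`,
#'   `mean_<channel>` columns, and `flag` (`"kept"`).
#' @export
measure_cells <- function(labels, stack = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  sp <- labels$spacing_um
  n <- max(lab, 0L)
  if (n == 0L) stop("no labels to measure", call. = FALSE)
  counts <- tabulate(lab[lab > 0L], nbins = n)

  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2]) # z-, y-, x-faces
  surf <- numeric(n)
  for (axis in 1:3) {
    m <- length(dim(lab))
    stopifnot(m == 3)
    nn <- d[axis]
    idx1 <- slice.index(lab, axis) <= nn - 1
    a1 <- lab[idx1]
    a2 <- lab[slice.index(lab, axis) >= 2]
    diff <- a1 != a2
    t1 <- a1[diff & a1 > 0L]
    t2 <- a2[diff & a2 > 0L]
    if (length(t1)) surf <- surf + tabulate(t1, nbins = n) * face_area[axis]
    if (length(t2)) surf <- surf + tabulate(t2, nbins = n) * face_area[axis]
    # faces against the array boundary
    first <- switch(axis, lab[1, , ], lab[, 1, ], lab[, , 1])
    last <- switch(axis, lab[nn, , ], lab[, nn, ], lab[, , nn])
    bnd <- c(first[first > 0L], last[last > 0L])
    if (length(bnd)) surf <- surf + tabulate(bnd, nbins = n) * face_area[axis]
  }

  present <- which(counts > 0L)
  if (length(present) < n) {
    warning("some label ids are absent from the volume and were excluded",
            call. = FALSE)
  }
  idx <- which(lab > 0L)
  lv <- lab[idx]
  i0 <- idx - 1L
  zi <- i0 %% d[1]
  yi <- (i0 %/% d[1]) %% d[2]
  xi <- i0 %/% (d[1] * d[2])
  np <- counts[present]
  cz <- unname(rowsum((zi + 0.5) * sp[1], lv)[, 1]) / np
  cy <- unname(rowsum((yi + 0.5) * sp[2], lv)[, 1]) / np
  cx <- unname(rowsum((xi + 0.5) * sp[3], lv)[, 1]) / np

  out <- tibble::tibble(
    label = present,
    volume_um3 = np * prod(sp),
    surface_um2 = surf[present],
    sv_ratio_per_um = surf[present] / (np * prod(sp)),
    centroid_z_um = cz, centroid_y_um = cy, centroid_x_um = cx
  )
  if (!is.null(stack)) {
    stopifnot(all(dim(stack) == d))
    for (ch in names(stack$channels)) {
      v <- stack$channels[[ch]][idx]
      out[[paste0("mean_", ch)]] <- unname(rowsum(v, lv)[, 1]) / np
    }
  }
  out$flag <- "kept"
  out
}

#' Flag outlier cells by robust fences on volume and surface/volume ratio
#'
#' Cells whose volume or surface-to-volume ratio falls outside
#' `median +/- fence_k * MAD` (scaled MAD) are flagged `outlier_volume` /
#' `outlier_sv` and excluded from counts; all records are retained with their
#' flags. Both features are positive ratio-scale quantities with
#' right-skewed distributions, so the fences are applied on the log scale by
#' default; a zero MAD falls back to IQR-based fences (`IQR / 1.349` as the
#' robust SD). Fewer than four kept cells is a no-op with a warning.
#'
#' @param cells a [measure_cells()] tibble.
#' @param fence_k fence multiplier (default 3.5).
#' @param log_scale apply the fences to log-transformed features (default
#'   `TRUE`).
#' @return The tibble with updated `flag` column.
#' @export
remove_outlier_cells <- function(cells, fence_k = 3.5, log_scale = TRUE) {
  stopifnot(is.data.frame(cells), fence_k > 0)
  kept <- cells$flag == "kept"
  if (sum(kept) < 4) {
    warning("fewer than 4 kept cells: outlier removal skipped", call. = FALSE)
    return(cells)
  }
  tf <- if (log_scale) log else identity
  fences <- function(x) {
    med <- median(x)
    s <- mad(x)                      # scaled MAD (x 1.4826)
    if (s == 0) s <- stats::IQR(x) / 1.349
    if (s == 0) return(c(-Inf, Inf))
    c(med - fence_k * s, med + fence_k * s)
  }
  v <- tf(cells$volume_um3)
  s <- tf(cells$sv_ratio_per_um)
  fv <- fences(v[kept])
  fs <- fences(s[kept])
  out_v <- kept & (v < fv[1] | v > fv[2])
  out_s <- kept & (s < fs[1] | s > fs[2])
  cells$flag[out_s] <- "outlier_sv"
  cells$flag[out_v] <- "outlier_volume"   # volume flag wins when both trip
  cells
}
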