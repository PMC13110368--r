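#' Multi-channel 3D voxel stack
#'
#' The raw unit every imaging operation consumes: a named list of 3D intensity
#' grids sharing one shape, together with the physical voxel spacing. Arrays
#' are indexed `[z, y, x]` (0-based voxel `i` spans physical interval
#' `[i, i+1) * spacing`, its centre at `(i + 0.5) * spacing` micrometres);
#' intensities live on a `[0, 1]` scale.
#'
#' @param channels named list of 3D numeric arrays with identical `dim`
#'   (`c(nz, ny, nx)`).
#' @param spacing_um numeric length-3, physical voxel size `(dz, dy, dx)` in
#'   micrometres; all components must be positive.
#' @param origin_um numeric length-3 offset of the stack origin in micrometres.
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(channels, spacing_um, origin_um = c(0, 0, 0)) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("all channels must be 3D arrays", call. = FALSE)
  }
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == d1), TRUE))) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3 || any(!is.finite(spacing_um)) || any(spacing_um <= 0)) {
    stop("spacing_um must be three positive finite values (dz, dy, dx)",
         call. = FALSE)
  }
  structure(
    list(channels = channels, spacing_um = spacing_um,
         origin_um = as.numeric(origin_um)),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<voxel_stack> %d x %d x %d voxels (z,y,x), spacing (%g, %g, %g) um\n",
    d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$channels[[1]])

#' Integer-labeled 3D segmentation
#'
#' Non-negative integer grid where 0 is background and labels `1..K` are
#' single-cell segments; same axis and spacing conventions as
#' [voxel_stack()].
#'
#' @param labels 3D integer array.
#' @param spacing_um voxel spacing `(dz, dy, dx)` in micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_um) {
  stopifnot(length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) {
    stop("labels must be non-negative", call. = FALSE)
  }
  structure(list(labels = labels, spacing_um = as.numeric(spacing_um)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d labels\n",
              d[1], d[2], d[3], n_labels(x)))
  invisible(x)
}

#' Number of distinct nonzero labels in a label volume
#' @param x a `label_volume`.
#' @return integer count of distinct labels.
#' @export
n_labels <- function(x) {
  stopifnot(inherits(x, "label_volume"))
  length(setdiff(unique(as.vector(x$labels)), 0L))
}

#' Binary 2D mask with physical pixel spacing
#'
#' @param mask logical matrix indexed `[y, x]`.
#' @param spacing_um pixel spacing `(dy, dx)` in micrometres.
#' @return An object of class `mask2d`.
#' @export
mask2d <- function(mask, spacing_um = c(1, 1)) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  structure(list(mask = mask, spacing_um = as.numeric(spacing_um)),
            class = "mask2d")
}

#' @export
print.mask2d <- function(x, ...) {
  cat(sprintf("<mask2d> %d x %d px (y,x), %d foreground px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# physical centre coordinates of foreground pixels, micrometres, cols (y, x)
mask_coords_um <- function(m) {
  idx <- which(m$mask, arr.ind = TRUE)
  cbind(y = (idx[, 1] - 0.5) * m$spacing_um[1],
        x = (idx[, 2] - 0.5) * m$spacing_um[2])
}

#' Write a voxel stack as a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are ordered channel-within-slice (for slice z: one page per channel).
#' Voxel spacing, channel names and shape are stored in a JSON sidecar at
#' `<path>.json`.
#'
#' @param stack a [voxel_stack()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack)
  meta <- list(spacing_um = stack$spacing_um, origin_um = stack$origin_um,
               channels = names(stack$channels), nz = d[1], ny = d[2], nx = d[3])
  desc <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  pages <- vector("list", d[1] * length(stack$channels))
  i <- 0L
  for (z in seq_len(d[1])) {
    for (ch in names(stack$channels)) {
      i <- i + 1L
      pages[[i]] <- pmin(pmax(stack$channels[[ch]][z, , ], 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  writeLines(as.character(desc), paste0(path, ".json"))
  invisible(path)
}

#' Read a voxel stack written by [write_stack()]
#'
#' @param path TIFF file path; metadata come from the `<path>.json` sidecar.
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("metadata sidecar not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  stopifnot(length(pages) == meta$nz * nch)
  channels <- lapply(seq_len(nch), function(ci) {
    a <- array(0, dim = c(meta$nz, meta$ny, meta$nx))
    for (z in seq_len(meta$nz)) {
      a[z, , ] <- pages[[(z - 1) * nch + ci]]
    }
    a
  })
  names(channels) <- meta$channels
  voxel_stack(channels, meta$spacing_um, meta$origin_um)
}
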