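# Small, fast parameter sets and hand-built stacks used across test files.

# a desk-sized primordium (~30 cells) for unit tests
tiny_params <- function(n_cells = 30L, ...) {
  primordium_params(n_cells = n_cells, n_rosettes = 0L, ...)
}

# a box stack with a bright outer shell and one bright mid-plane membrane,
# splitting the interior into two known compartments
two_cell_stack <- function(nz = 10L, ny = 14L, nx = 24L,
                           spacing = c(1, 1, 1)) {
  mem <- array(0, c(nz, ny, nx))
  mem[c(2, nz - 1), 2:(ny - 1), 2:(nx - 1)] <- 1
  mem[2:(nz - 1), c(2, ny - 1), 2:(nx - 1)] <- 1
  mem[2:(nz - 1), 2:(ny - 1), c(2, nx - 1)] <- 1
  mid <- nx %/% 2
  mem[2:(nz - 1), 2:(ny - 1), mid] <- 1
  truth <- array(0L, c(nz, ny, nx))
  truth[3:(nz - 2), 3:(ny - 2), 3:(mid - 1)] <- 1L
  truth[3:(nz - 2), 3:(ny - 2), (mid + 1):(nx - 2)] <- 2L
  list(stack = voxel_stack(list(membrane = mem), spacing), truth = truth)
}

# rasterize an ellipse mask (half-axes in px, rotation in degrees)
raster_ellipse <- function(a_px, b_px, angle_deg = 0, pad = 8,
                           spacing = c(1, 1)) {
  n <- 2 * ceiling(max(a_px, b_px)) + 2 * pad + 1
  ctr <- (n + 1) / 2
  yy <- matrix(seq_len(n) - ctr, n, n)
  xx <- t(yy)
  th <- angle_deg * pi / 180
  xr <- xx * cos(th) + yy * sin(th)
  yr <- -xx * sin(th) + yy * cos(th)
  mask2d((xr / a_px)^2 + (yr / b_px)^2 <= 1, spacing)
}

# per-cell Jaccard overlap of a segmentation against ground-truth labels,
# matching each truth cell to its best-overlapping segment
mean_cell_jaccard <- function(seg, truth) {
  s <- as.vector(seg)
  t <- as.vector(truth)
  both <- s > 0 & t > 0
  tab <- table(truth = t[both], seg = s[both])
  vapply(rownames(tab), function(tc) {
    sc <- colnames(tab)[which.max(tab[tc, ])]
    inter <- tab[tc, sc]
    union <- sum(t == as.integer(tc)) + sum(s == as.integer(sc)) - inter
    inter / union
  }, 0) |> mean()
}
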