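#' Parameters of a synthetic primordium
#'
#' Geometry and imaging parameters for [simulate_primordium()]. The defaults
#' emulate a migrating-stage primordium: ~120 epithelial cells packed in an
#' elongated ellipsoid, membrane-labeled, imaged with anisotropic confocal
#' voxels.
#'
#' @param n_cells positive integer, number of cells.
#' @param elongation target major/minor axis ratio (>= 1) of the cell-center
#'   ellipsoid.
#' @param n_rosettes non-negative integer, number of radial cell rosettes.
#' @param rosette_radius_um ring radius of rosette member centers, um.
#' @param cell_diameter_um nominal cell diameter, um; centers are sampled with
#'   minimum spacing `0.85 * cell_diameter_um`.
#' @param membrane_width_um full width of the rendered membrane signal, um;
#'   must be smaller than `cell_diameter_um`.
#' @param voxel_spacing_um `(dz, dy, dx)` in um.
#' @param noise_sd additive Gaussian noise SD on the `[0, 1]` intensity scale.
#' @param photon_scale Poisson photon budget per unit intensity (shot noise);
#'   larger is cleaner.
#' @param orientation_deg in-plane angle of the long axis, degrees.
#' @return A `primordium_params` list.
#' @export
primordium_params <- function(n_cells = 120L,
                              elongation = 2.5,
                              n_rosettes = 3L,
                              rosette_radius_um = 8,
                              cell_diameter_um = 5.5,
                              membrane_width_um = 1.0,
                              voxel_spacing_um = c(1, 0.4, 0.4),
                              noise_sd = 0.03,
                              photon_scale = 120,
                              orientation_deg = 0) {
  p <- list(n_cells = as.integer(n_cells), elongation = elongation,
            n_rosettes = as.integer(n_rosettes),
            rosette_radius_um = rosette_radius_um,
            cell_diameter_um = cell_diameter_um,
            membrane_width_um = membrane_width_um,
            voxel_spacing_um = as.numeric(voxel_spacing_um),
            noise_sd = noise_sd, photon_scale = photon_scale,
            orientation_deg = orientation_deg)
  validate_primordium_params(p)
  structure(p, class = "primordium_params")
}

validate_primordium_params <- function(p) {
  if (p$n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  if (p$elongation < 1) stop("elongation must be >= 1", call. = FALSE)
  if (p$n_rosettes < 0L) stop("n_rosettes must be >= 0", call. = FALSE)
  if (p$rosette_radius_um <= 0) stop("rosette_radius_um must be > 0", call. = FALSE)
  if (p$cell_diameter_um <= 0) stop("cell_diameter_um must be > 0", call. = FALSE)
  if (p$membrane_width_um >= p$cell_diameter_um) {
    stop("membrane_width_um must be smaller than cell_diameter_um", call. = FALSE)
  }
  if (length(p$voxel_spacing_um) != 3 || any(p$voxel_spacing_um <= 0)) {
    stop("voxel_spacing_um must have three positive components", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$photon_scale <= 0) stop("photon_scale must be > 0", call. = FALSE)
  invisible(p)
}

# ellipsoid semi-axes (a along x, b along y, c along z), um. The tissue volume
# is sized so cells tile at roughly 3x their nominal sphere volume, giving the
# center sampler comfortable headroom over its 0.8-diameter minimum spacing.
primordium_semiaxes <- function(p) {
  v_cell <- 4 / 3 * pi * (p$cell_diameter_um / 2)^3
  v_total <- 3.0 * p$n_cells * v_cell
  b <- (v_total / (4 / 3 * pi * p$elongation * 0.8))^(1 / 3)
  c(a = p$elongation * b, b = b, c = 0.8 * b)
}

# rotate (y, x) points by angle_deg (counter-clockwise about origin in the
# mathematical x-y sense, with y the row axis)
rot_yx <- function(y, x, angle_deg) {
  th <- angle_deg * pi / 180
  list(y = x * sin(th) + y * cos(th),
       x = x * cos(th) - y * sin(th))
}

# sample cell centers (um, local frame centred on the ellipsoid, long axis
# along x). Rosette members are placed on rings first, fillers by rejection.
sample_centers <- function(p, ax) {
  d_min <- 0.85 * p$cell_diameter_um
  centers <- matrix(numeric(0), ncol = 3)  # (z, y, x)
  rosette_centers <- matrix(numeric(0), ncol = 2)  # (y, x)
  n_ros_members <- 0L

  if (p$n_rosettes > 0) {
    members_per <- max(5L, round(2 * pi * p$rosette_radius_um / (0.9 * d_min)))
    # place rosette centers by rejection, restarting the whole set when a
    # partial placement paints itself into a corner
    placed <- NULL
    for (restart in 1:200) {
      placed <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(p$n_rosettes)) {
        done <- FALSE
        for (try in 1:100) {
          cx <- runif(1, -0.75 * ax["a"] + p$rosette_radius_um,
                      0.75 * ax["a"] - p$rosette_radius_um)
          cy <- runif(1, -0.3 * ax["b"], 0.3 * ax["b"])
          ok <- nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >
                  2.2 * p$rosette_radius_um)
          if (ok) {
            placed <- rbind(placed, c(cy, cx))
            done <- TRUE
            break
          }
        }
        if (!done) break
      }
      if (nrow(placed) == p$n_rosettes) break
      placed <- NULL
    }
    if (is.null(placed)) {
      stop("infeasible geometry: cannot place rosettes", call. = FALSE)
    }
    rosette_centers <- placed
    for (i in seq_len(p$n_rosettes)) {
      ang <- seq(0, 2 * pi, length.out = members_per + 1)[-(members_per + 1)]
      ang <- ang + runif(1, 0, 2 * pi / members_per)
      ring <- cbind(z = runif(members_per, -0.5, 0.5),
                    y = placed[i, 1] + p$rosette_radius_um * sin(ang),
                    x = placed[i, 2] + p$rosette_radius_um * cos(ang))
      centers <- rbind(centers, ring)
    }
    n_ros_members <- nrow(centers)
    if (n_ros_members > p$n_cells) {
      stop("infeasible geometry: rosette members exceed n_cells", call. = FALSE)
    }
  }

  n_free <- p$n_cells - nrow(centers)
  max_attempts <- 2000 * max(1L, n_free)
  attempts <- 0
  while (n_free > 0) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("infeasible geometry: center packing failed (n_cells too large for ",
           "cell_diameter_um)", call. = FALSE)
    }
    u <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    if (sum(u^2) > 1) next
    cand <- c(z = 0.92 * u[1] * ax["c"], y = 0.92 * u[2] * ax["b"],
              x = 0.92 * u[3] * ax["a"])
    # rosette cells are constricted wedges spanning the central depth of the
    # tissue: keep filler cells out of that part of the rosette cylinders so
    # the radial walls stay coherent without inflating member volumes
    if (nrow(rosette_centers) > 0 && abs(cand[1]) < 0.55 * ax["c"]) {
      dcyl <- sqrt((rosette_centers[, 1] - cand[2])^2 +
                     (rosette_centers[, 2] - cand[3])^2)
      if (any(dcyl < 1.3 * p$rosette_radius_um)) next
    }
    if (nrow(centers) > 0) {
      dd2 <- (centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 +
        (centers[, 3] - cand[3])^2
      if (any(dd2 < d_min^2)) next
    }
    centers <- rbind(centers, cand)
    n_free <- n_free - 1
  }
  rownames(centers) <- NULL
  list(centers = centers, rosette_centers = rosette_centers,
       n_rosette_members = n_ros_members)
}

# membrane signal density: every boundary face (between two cells, or a cell
# and background) deposits its physical face area into the foreground voxels
# on both sides, so lateral walls (large dz faces) are brighter than apical
# caps at anisotropic spacing - matching how a thin fluorescent surface
# integrates into voxels
label_boundary_density <- function(lab, sp, outer_only = FALSE) {
  d <- dim(lab)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  b <- array(0, d)
  fg <- lab != 0L
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2) next
    i1 <- slice.index(lab, axis) <= n - 1
    i2 <- slice.index(lab, axis) >= 2
    l1 <- lab[i1]
    l2 <- lab[i2]
    dd <- if (outer_only) (l1 != l2) & (l1 == 0L | l2 == 0L) else l1 != l2
    add <- array(0, d)
    add[i1] <- dd * face_area[axis]
    add[i2] <- add[i2] + dd * face_area[axis]
    b <- b + add * fg
  }
  b / max(face_area)
}

apply_imaging_noise <- function(img, noise_sd, photon_scale) {
  v <- as.vector(img)
  if (!is.null(photon_scale) && photon_scale > 0 && is.finite(photon_scale)) {
    v <- rpois(length(v), pmax(v, 0) * photon_scale) / photon_scale
  }
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  array(pmin(pmax(v, 0), 1), dim = dim(img))
}

#' Simulate a membrane-labeled 3D primordium with exact ground truth
#'
#' Samples `n_cells` cell centers inside an elongated ellipsoid (rosette
#' members on rings around rosette centers), partitions the ellipsoid interior
#' by anisotropy-aware nearest-center assignment, and renders a membrane
#' channel as the smoothed indicator of inter-cell and outer boundaries plus a
#' nuclear channel of Gaussian blobs at the centers. Poisson then Gaussian
#' noise is applied. The returned ground truth is exact in label space.
#'
#' @param params a [primordium_params()] object.
#' @param seed integer seed; identical `(params, seed)` give identical output.
#' @param edu_fraction fraction of cells rendered EdU-positive in an `edu`
#'   channel (0 disables the channel).
#' @return A list with elements `stack` (a [voxel_stack()] with channels
#'   `membrane`, `nuclei` and optionally `edu`) and `truth` (a list:
#'   `label_volume`, `cell_centers_um`, `per_cell_volume_um3`,
#'   `rosette_centers_um`, `true_count`, `edu_positive`).
#' @export
simulate_primordium <- function(params = primordium_params(), seed = 1L,
                                edu_fraction = 0) {
  validate_primordium_params(params)
  with_local_seed(seed, {
    ax <- primordium_semiaxes(params)
    sp <- params$voxel_spacing_um
    smp <- sample_centers(params, ax)

    th <- params$orientation_deg
    half_x <- sqrt((ax["a"] * cos(th * pi / 180))^2 +
                   (ax["b"] * sin(th * pi / 180))^2)
    half_y <- sqrt((ax["a"] * sin(th * pi / 180))^2 +
                   (ax["b"] * cos(th * pi / 180))^2)
    margin <- pmax(2 * sp, 2)   # >= 2 voxels and >= 2 um on each side
    ext <- c(z = 2 * ax["c"] + 2 * margin[1],
             y = 2 * half_y + 2 * margin[2],
             x = 2 * half_x + 2 * margin[3])
    dim3 <- as.integer(ceiling(ext / sp))
    ctr <- dim3 * sp / 2   # stack centre, um

    # centers into stack frame (rotate in-plane, then translate)
    r <- rot_yx(smp$centers[, 2], smp$centers[, 3], th)
    centers_um <- cbind(z = smp$centers[, 1] + ctr[1],
                        y = r$y + ctr[2], x = r$x + ctr[3])
    rosette_um <- if (nrow(smp$rosette_centers) > 0) {
      rr <- rot_yx(smp$rosette_centers[, 1], smp$rosette_centers[, 2], th)
      cbind(y = rr$y + ctr[2], x = rr$x + ctr[3])
    } else {
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("y", "x")))
    }

    # ellipsoid interior mask on the voxel grid (rotated frame)
    zc <- (seq_len(dim3[1]) - 0.5) * sp[1] - ctr[1]
    yc <- (seq_len(dim3[2]) - 0.5) * sp[2] - ctr[2]
    xc <- (seq_len(dim3[3]) - 0.5) * sp[3] - ctr[3]
    Z <- array(zc, dim3)
    Y <- array(rep(yc, each = dim3[1]), dim3)
    X <- array(rep(xc, each = dim3[1] * dim3[2]), dim3)
    un <- rot_yx(Y, X, -th)
    inside <- (un$x / ax["a"])^2 + (un$y / ax["b"])^2 + (Z / ax["c"])^2 <= 1
    storage.mode(inside) <- "integer"

    part <- cpp_partition_cells(dim3, sp, centers_um, inside,
                                params$membrane_width_um / 2.355)
    lab <- part$labels

    # drop centers that captured no voxels, relabel contiguously
    counts <- tabulate(lab[lab > 0L], nbins = nrow(centers_um))
    keep <- which(counts > 0L)
    remap <- integer(nrow(centers_um))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    centers_um <- centers_um[keep, , drop = FALSE]
    counts <- counts[keep]

    voxel_vol <- prod(sp)
    # inter-cell walls: analytic Gaussian profile centred on each bisector,
    # orientation-weighted; outer surface: boundary-face density, blurred
    sig_vox <- (params$membrane_width_um / 2.355) / sp
    outer <- label_boundary_density(lab, sp, outer_only = TRUE)
    outer <- cpp_blur3d(outer, dim3, sig_vox)
    membrane <- part$wall + outer
    # normalize to [0, 1] against the 99.5th percentile of the signal
    # (detector-saturation style), so typical lateral walls sit near 1
    # rather than being compressed by rare junction pile-ups
    pos <- membrane[membrane > 1e-9]
    if (length(pos) > 0) {
      membrane <- pmin(membrane / stats::quantile(pos, 0.995), 1)
    }

    nuc_delta <- array(0, dim3)
    vz <- pmin(pmax(ceiling(centers_um[, 1] / sp[1]), 1L), dim3[1])
    vy <- pmin(pmax(ceiling(centers_um[, 2] / sp[2]), 1L), dim3[2])
    vx <- pmin(pmax(ceiling(centers_um[, 3] / sp[3]), 1L), dim3[3])
    nuc_delta[cbind(vz, vy, vx)] <- 1
    nuc_sig <- (params$cell_diameter_um / 5) / sp
    nuclei <- cpp_blur3d(nuc_delta, dim3, nuc_sig)
    mx <- max(nuclei)
    if (mx > 0) nuclei <- nuclei / mx

    edu_positive <- integer(0)
    channels <- list(membrane = membrane, nuclei = nuclei)
    if (edu_fraction > 0) {
      n_pos <- round(edu_fraction * nrow(centers_um))
      edu_positive <- sort(sample.int(nrow(centers_um), n_pos))
      edu_delta <- array(0, dim3)
      if (n_pos > 0) {
        edu_delta[cbind(vz[edu_positive], vy[edu_positive], vx[edu_positive])] <- 1
      }
      edu <- cpp_blur3d(edu_delta, dim3, nuc_sig)
      mx <- max(edu)
      if (mx > 0) edu <- edu / mx
      channels$edu <- edu
    }

    # noise_sd == 0 is the fully noise-free (deterministic-intensity) case
    noisy <- if (params$noise_sd == 0) {
      channels
    } else {
      lapply(channels, apply_imaging_noise, noise_sd = params$noise_sd,
             photon_scale = params$photon_scale)
    }

    truth <- list(
      label_volume = label_volume(lab, sp),
      cell_centers_um = centers_um,
      per_cell_volume_um3 = counts * voxel_vol,
      rosette_centers_um = rosette_um,
      true_count = length(counts),
      edu_positive = edu_positive
    )
    list(stack = voxel_stack(noisy, sp), truth = truth)
  })
}

#' The study's genotype and treatment presets
#'
#' Effect sizes per condition, anchored to the reported phenotypes: the
#' wild-type primordium averages 120 cells, loss of yap1 reduces the count by
#' 20%, loss of vgll4b raises it by 35%, the vgll4b;vgll4l double by 50%,
#' vgll4b overexpression lowers it by 20%, yap1 overexpression in the double
#' mutant adds a further 25%, and the triple mutant sits 10% below wild type.
#' Reporter multipliers encode the Tead-reporter changes (+70% yap1-OE, -12%
#' yap1 knockdown, +27% vgll4b knockdown) and diving probabilities the
#' mispositioned-migration penetrance (1.29% WT, 16% yap1, 68% / 25% with
#' vgll4b / vgll4l overexpression in yap1 mutants).
#'
#' @return A tibble with one row per preset: `name`, `count_multiplier`,
#'   `count_cv`, `reporter_multiplier`, `diving_probability`, `edu_fraction`.
#' @export
genotype_presets <- function() {
  tibble::tribble(
    ~name,                ~count_multiplier, ~reporter_multiplier, ~diving_probability,
    "wt",                 1.00,              1.00,                 0.0129,
    "yap1",               0.80,              1.00,                 0.16,
    "vgll4b",             1.35,              1.00,                 0.0129,
    "vgll4l",             1.00,              1.00,                 0.0129,
    "vgll4b_vgll4l",      1.50,              1.00,                 0.0129,
    "vgll4b_oe",          0.80,              1.00,                 0.0129,
    "yap1_oe_in_double",  1.875,             1.00,                 0.0129,
    "triple",             0.90,              1.00,                 0.0129,
    "double_19hpf",       1.14,              1.00,                 0.0129,
    "yap1_oe",            1.00,              1.70,                 0.0129,
    "yap1_mo",            1.00,              0.88,                 0.0129,
    "vgll4b_kd",          1.00,              1.27,                 0.0129,
    "yap1_vgll4b_oe",     0.80,              1.00,                 0.68,
    "yap1_vgll4l_oe",     0.80,              1.00,                 0.25
  ) |>
    dplyr::mutate(count_cv = 0.08, edu_fraction = 0.25) |>
    dplyr::select("name", "count_multiplier", "count_cv",
                  "reporter_multiplier", "diving_probability", "edu_fraction")
}

#' Construct or look up a genotype preset
#'
#' @param name preset name; either one of [genotype_presets()] or a new name
#'   when the multipliers are supplied explicitly.
#' @param count_multiplier,count_cv,reporter_multiplier,diving_probability,edu_fraction
#'   override individual fields.
#' @return A one-row tibble.
#' @export
genotype_preset <- function(name, count_multiplier = NULL, count_cv = NULL,
                            reporter_multiplier = NULL,
                            diving_probability = NULL, edu_fraction = NULL) {
  tab <- genotype_presets()
  if (name %in% tab$name) {
    p <- tab[tab$name == name, ]
  } else {
    p <- tibble::tibble(name = name, count_multiplier = 1, count_cv = 0.08,
                        reporter_multiplier = 1, diving_probability = 0,
                        edu_fraction = 0.25)
  }
  if (!is.null(count_multiplier)) p$count_multiplier <- count_multiplier
  if (!is.null(count_cv)) p$count_cv <- count_cv
  if (!is.null(reporter_multiplier)) p$reporter_multiplier <- reporter_multiplier
  if (!is.null(diving_probability)) p$diving_probability <- diving_probability
  if (!is.null(edu_fraction)) p$edu_fraction <- edu_fraction
  stopifnot(p$count_multiplier > 0, p$count_cv >= 0,
            p$reporter_multiplier > 0,
            p$diving_probability >= 0, p$diving_probability <= 1,
            p$edu_fraction >= 0, p$edu_fraction <= 1)
  p
}

#' Draw per-embryo cohort ground truth from genotype presets
#'
#' For each embryo the cell count is a rounded normal with mean
#' `mean_count * count_multiplier` and coefficient of variation `count_cv`
#' (negative draws are resampled, bounded retries), and the diving phenotype a
#' Bernoulli draw at the preset probability.
#'
#' @param presets tibble of presets (rows of [genotype_presets()]), or a
#'   character vector of preset names.
#' @param n_embryos embryos per preset (scalar or per-preset vector).
#' @param seed integer seed.
#' @param mean_count wild-type mean cell count (default 120).
#' @return A tibble: `embryo`, `genotype`, `n_cells`, `diving`,
#'   `orientation_deg` (uniform mounting tilt within +/-15 degrees), and
#'   `embryo_seed`.
#' @export
draw_cohort_truth <- function(presets, n_embryos, seed = 1L, mean_count = 120) {
  if (is.character(presets)) {
    presets <- dplyr::bind_rows(lapply(presets, genotype_preset))
  }
  stopifnot(all(n_embryos >= 1))
  n_embryos <- rep_len(as.integer(n_embryos), nrow(presets))
  with_local_seed(seed, {
    rows <- purrr::pmap(
      list(seq_len(nrow(presets)), n_embryos),
      function(i, n) {
        p <- presets[i, ]
        mu <- mean_count * p$count_multiplier
        sdv <- p$count_cv * mu
        draws <- integer(n)
        for (j in seq_len(n)) {
          for (try in 1:100) {
            d <- round(rnorm(1, mu, sdv))
            if (d >= 1) break
            d <- NA_integer_
          }
          if (is.na(d)) stop("count draw failed: preset mean too close to zero",
                             call. = FALSE)
          draws[j] <- d
        }
        tibble::tibble(
          embryo = sprintf("%s_%02d", p$name, seq_len(n)),
          genotype = p$name,
          n_cells = draws,
          diving = rbinom(n, 1, p$diving_probability) == 1,
          orientation_deg = runif(n, -15, 15),   # mounting tilt of the embryo
          embryo_seed = sample.int(.Machine$integer.max - 1L, n)
        )
      })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a full cohort of primordium stacks
#'
#' Draws per-embryo truth with [draw_cohort_truth()], then renders each embryo
#' with [simulate_primordium()] using the drawn cell count and per-embryo seed.
#'
#' @inheritParams draw_cohort_truth
#' @param base a [primordium_params()] object supplying all non-count
#'   parameters.
#' @return A list: `embryos` (list of `simulate_primordium()` results, each
#'   with `$name`), `truth` (the cohort tibble).
#' @export
simulate_cohort <- function(presets, n_embryos, base = primordium_params(),
                            seed = 1L, mean_count = 120) {
  truth <- draw_cohort_truth(presets, n_embryos, seed = seed,
                             mean_count = mean_count)
  pl <- if (is.character(presets)) {
    dplyr::bind_rows(lapply(presets, genotype_preset))
  } else {
    presets
  }
  edu_by_geno <- stats::setNames(pl$edu_fraction, pl$name)
  embryos <- purrr::pmap(
    list(truth$embryo, truth$genotype, truth$n_cells, truth$orientation_deg,
         truth$embryo_seed),
    function(nm, geno, n, o, s) {
      pp <- base
      pp$n_cells <- as.integer(n)
      pp$orientation_deg <- o
      out <- simulate_primordium(pp, seed = s,
                                 edu_fraction = unname(edu_by_geno[[geno]]))
      out$name <- nm
      out
    })
  list(embryos = embryos, truth = truth)
}

#' Simulate a Tead-reporter image pair of channels
#'
#' Renders a mosaic reporter expression pattern: weak diffuse tissue signal
#' plus a primordium (elliptical mask) in which a random subset of cell-sized
#' sites expresses the reporter above the surrounding tissue. The pattern is
#' normalized so the in-mask mean of the noise-free reporter channel equals
#' `base_intensity * reporter_multiplier` exactly; the whole-image mean scales
#' by the same multiplier.
#'
#' @param preset a one-row preset tibble ([genotype_preset()]) supplying
#'   `reporter_multiplier`.
#' @param base_intensity mean in-mask reporter intensity of the baseline
#'   condition (on `[0, 1]`).
#' @param seed integer seed.
#' @param size_px image size `(ny, nx)`.
#' @param spacing_um pixel spacing `(dy, dx)`, um.
#' @param noise_sd additive Gaussian noise SD.
#' @param positive_fraction fraction of in-mask cell sites expressing the
#'   reporter (mosaic expression).
#' @return A list: `stack` (a one-slice [voxel_stack()] with `reporter` and
#'   `marker` channels) and `truth` (mask, positive site count, exact
#'   noise-free in-mask mean).
#' @export
simulate_reporter_image <- function(preset, base_intensity = 0.2, seed = 1L,
                                    size_px = c(96, 192),
                                    spacing_um = c(0.4, 0.4),
                                    noise_sd = 0.01,
                                    positive_fraction = 0.3) {
  stopifnot(base_intensity > 0)
  mult <- preset$reporter_multiplier
  with_local_seed(seed, {
    ny <- size_px[1]; nx <- size_px[2]
    yy <- matrix(seq_len(ny) - ny / 2, ny, nx)
    xx <- matrix(rep(seq_len(nx) - nx / 2, each = ny), ny, nx)
    a <- 0.38 * nx; b <- 0.32 * ny
    mask <- (xx / a)^2 + (yy / b)^2 <= 1

    # cell-sized expression sites on a jittered grid inside the mask
    pitch <- 14
    gy <- seq(pitch / 2, ny, by = pitch)
    gx <- seq(pitch / 2, nx, by = pitch)
    sites <- expand.grid(y = gy, x = gx)
    sites$y <- sites$y + runif(nrow(sites), -3, 3)
    sites$x <- sites$x + runif(nrow(sites), -3, 3)
    iy <- pmin(pmax(round(sites$y), 1), ny)
    ix <- pmin(pmax(round(sites$x), 1), nx)
    in_mask <- mask[cbind(iy, ix)]
    sites <- sites[in_mask, , drop = FALSE]
    n_pos <- max(1L, round(positive_fraction * nrow(sites)))
    pos <- sites[sample.int(nrow(sites), n_pos), , drop = FALSE]

    pat <- matrix(0.15, ny, nx)          # diffuse tissue signal
    sig <- 4
    for (i in seq_len(nrow(pos))) {
      pat <- pat + exp(-((yy - (pos$y[i] - ny / 2))^2 +
                         (xx - (pos$x[i] - nx / 2))^2) / (2 * sig^2))
    }
    pat <- pat / mean(pat[mask])          # in-mask mean of pattern == 1
    reporter0 <- base_intensity * mult * pat
    reporter <- reporter0
    if (noise_sd > 0) reporter <- reporter + rnorm(length(reporter), 0, noise_sd)

    marker <- matrix(0, ny, nx)
    marker[mask] <- 1

    to3d <- function(m) array(m, dim = c(1, ny, nx))
    stack <- voxel_stack(list(reporter = to3d(reporter), marker = to3d(marker)),
                         spacing_um = c(1, spacing_um))
    truth <- list(mask = mask2d(mask, spacing_um),
                  n_positive_sites = n_pos,
                  mean_in_mask = base_intensity * mult)
    list(stack = stack, truth = truth)
  })
}

#' Simulate a qPCR plate with a known fold change
#'
#' Two groups (`control`, `mutant`), one target and one reference gene. The
#' mutant target Ct is shifted by `-log2(true_fold)` cycles relative to the
#' control baseline; the reference gene is group-independent. Biological
#' replicates receive Gaussian Ct noise of SD `ct_noise_sd` per (gene,
#' sample); technical replicates add well noise at half that SD.
#'
#' @param true_fold true expression fold change of the mutant group (> 0).
#' @param ct_noise_sd biological Ct noise SD, cycles.
#' @param n_biological biological replicates per group.
#' @param n_technical technical replicates per (gene, sample).
#' @param seed integer seed.
#' @param target_gene,ref_gene gene names.
#' @param baseline_ct,ref_ct control-group target and reference Ct baselines.
#' @return A tibble: `gene`, `sample`, `group`, `replicate`, `ct`.
#' @export
simulate_qpcr_plate <- function(true_fold, ct_noise_sd = 0.15,
                                n_biological = 6L, n_technical = 3L,
                                seed = 1L, target_gene = "target",
                                ref_gene = "rpl13",
                                baseline_ct = 24, ref_ct = 18) {
  stopifnot(true_fold > 0, n_biological >= 1, n_technical >= 1,
            ct_noise_sd >= 0)
  with_local_seed(seed, {
    grid <- tidyr::expand_grid(
      group = c("control", "mutant"),
      bio = seq_len(n_biological),
      gene = c(target_gene, ref_gene)
    )
    grid$sample <- sprintf("%s_%d", grid$group, grid$bio)
    grid$mu <- ifelse(grid$gene == ref_gene, ref_ct,
                      baseline_ct - log2(true_fold) * (grid$group == "mutant"))
    grid$bio_noise <- rnorm(nrow(grid), 0, ct_noise_sd)
    out <- tidyr::expand_grid(grid, replicate = seq_len(n_technical))
    out$ct <- out$mu + out$bio_noise +
      rnorm(nrow(out), 0, ct_noise_sd / 2)
    dplyr::select(out, "gene", "sample", "group", "replicate", "ct")
  })
}

#' Simulate a 2D trunk overview with ganglion and deposited neuromasts
#'
#' The first cluster is the ganglion; each cluster is rendered as a group of
#' small nuclear blobs around its centre. Overlapping clusters are rejected.
#'
#' @param cluster_positions_um matrix of cluster centres, columns `(y, x)` um;
#'   the first row is the ganglion.
#' @param cluster_n_cells integer vector of cells per cluster.
#' @param image_size_px image size `(ny, nx)`.
#' @param spacing_um pixel spacing `(dy, dx)` um.
#' @param seed integer seed.
#' @param cluster_radius_um radius within which a cluster's cells scatter.
#' @return A list: `image` (matrix), `spacing_um`, `truth` (positions, counts).
#' @export
simulate_overview <- function(cluster_positions_um, cluster_n_cells,
                              image_size_px = c(64, 256),
                              spacing_um = c(1, 1), seed = 1L,
                              cluster_radius_um = 6) {
  pos <- as.matrix(cluster_positions_um)
  stopifnot(ncol(pos) == 2, nrow(pos) == length(cluster_n_cells),
            nrow(pos) >= 1)
  ext <- image_size_px * spacing_um
  if (any(pos[, 1] < 0 | pos[, 1] > ext[1] | pos[, 2] < 0 | pos[, 2] > ext[2])) {
    stop("cluster positions must lie inside the image", call. = FALSE)
  }
  if (nrow(pos) > 1) {
    dd <- as.matrix(stats::dist(pos))
    diag(dd) <- Inf
    if (any(dd < 2.5 * cluster_radius_um)) {
      stop("overlapping clusters rejected", call. = FALSE)
    }
  }
  with_local_seed(seed, {
    ny <- image_size_px[1]; nx <- image_size_px[2]
    yy <- matrix((seq_len(ny) - 0.5) * spacing_um[1], ny, nx)
    xx <- matrix(rep((seq_len(nx) - 0.5) * spacing_um[2], each = ny), ny, nx)
    img <- matrix(0.02, ny, nx)
    sig <- 1.6
    for (i in seq_len(nrow(pos))) {
      n <- cluster_n_cells[i]
      ang <- runif(n, 0, 2 * pi)
      rad <- cluster_radius_um * sqrt(runif(n))
      cy <- pos[i, 1] + rad * sin(ang)
      cx <- pos[i, 2] + rad * cos(ang)
      for (j in seq_len(n)) {
        img <- img + 0.6 * exp(-((yy - cy[j])^2 + (xx - cx[j])^2) / (2 * sig^2))
      }
    }
    img <- pmin(img, 1)
    truth <- list(positions_um = pos, n_cells = cluster_n_cells)
    list(image = img, spacing_um = spacing_um, truth = truth)
  })
}
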