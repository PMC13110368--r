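test_that("shape descriptors match closed forms for disc and ellipse", {
  disc <- shape_descriptors(raster_ellipse(30, 30))
  expect_equal(disc$aspect_ratio, 1, tolerance = 0.02)
  expect_gte(disc$circularity, 0.95)
  expect_gte(disc$solidity, 0.98)

  ell <- shape_descriptors(raster_ellipse(40, 20))
  expect_equal(ell$aspect_ratio, 2, tolerance = 0.025)
  expect_equal(ell$roundness, 0.5, tolerance = 0.06)
})

test_that("shape descriptors are rotation-invariant within 3%", {
  a <- shape_descriptors(raster_ellipse(35, 18, angle_deg = 0))
  b <- shape_descriptors(raster_ellipse(35, 18, angle_deg = 37))
  for (f in c("aspect_ratio", "circularity", "roundness", "solidity")) {
    expect_lt(abs(b[[f]] - a[[f]]) / a[[f]], 0.03)
  }
})

test_that("generator rosettes are detected at their true positions", {
  pp <- primordium_params(n_cells = 160, n_rosettes = 5, rosette_radius_um = 6,
                          noise_sd = 0)
  sim <- simulate_primordium(pp, seed = 11)
  # a 6-um ring packs 9 member cells, hence 9 radial walls
  det <- detect_rosettes(sim$stack, expected_radius_um = 6, n_spokes = 9)
  expect_equal(nrow(det), 5L)
  tr <- sim$truth$rosette_centers_um
  dists <- vapply(seq_len(nrow(tr)), function(i) {
    min(sqrt((det$y_um - tr[i, 1])^2 + (det$x_um - tr[i, 2])^2))
  }, 0)
  expect_true(all(dists < 3))            # within radius / 2
  expect_true(all(det$score >= 0 & det$score <= 1))
})

test_that("a rosette-free primordium yields zero detections", {
  sim <- simulate_primordium(tiny_params(n_cells = 60, noise_sd = 0), seed = 12)
  det <- detect_rosettes(sim$stack, expected_radius_um = 8)
  expect_equal(nrow(det), 0L)
})

test_that("imaging noise does not inflate matched rosette scores", {
  clean <- simulate_primordium(primordium_params(n_rosettes = 3, noise_sd = 0),
                               seed = 13)
  noisy <- simulate_primordium(primordium_params(n_rosettes = 3,
                                                 noise_sd = 0.05,
                                                 photon_scale = 60), seed = 13)
  dc <- detect_rosettes(clean$stack, expected_radius_um = 8)
  dn <- detect_rosettes(noisy$stack, expected_radius_um = 8, floor = 0.2)
  expect_gt(nrow(dc), 0)
  expect_gt(nrow(dn), 0)
  expect_lte(mean(dn$score), mean(dc$score) + 0.01)
})

test_that("a mask smaller than the template yields an empty detection list", {
  img <- matrix(0.5, 11, 11)
  det <- detect_rosettes(img, expected_radius_um = 30, spacing_um = c(1, 1))
  expect_equal(nrow(det), 0L)
})

test_that("rosettiness is the mean detection score, undefined when empty", {
  expect_equal(rosettiness(c(1, 1, 1)), 1)
  expect_equal(rosettiness(c(0.8, 0.6)), 0.7)
  expect_warning(r <- rosettiness(numeric(0)), "undefined")
  expect_true(is.na(r))
  # bounded by the score extrema whenever defined
  set.seed(14)
  for (i in 1:20) {
    sc <- runif(sample(1:8, 1))
    r <- rosettiness(sc)
    expect_gte(r, min(sc))
    expect_lte(r, max(sc))
  }
})

test_that("primordium summaries aggregate kept cells only", {
  cells <- tibble::tibble(
    label = 1:122,
    volume_um3 = c(rep(350, 120), 40, 900),
    surface_um2 = 300, sv_ratio_per_um = 1,
    flag = c(rep("kept", 120), "outlier_volume", "outlier_sv"))
  s <- summarize_primordium(cells)
  expect_equal(s$cell_count, 120L)
  expect_equal(s$total_volume_um3, 42000)
  # removing one outlier flag changes the count by exactly one
  cells$flag[121] <- "kept"
  expect_equal(summarize_primordium(cells)$cell_count, 121L)
})

test_that("cell counts are invariant under label permutation", {
  sim <- simulate_primordium(tiny_params(noise_sd = 0), seed = 15)
  lab <- sim$truth$label_volume$labels
  n <- max(lab)
  perm <- sample(n)
  lab2 <- lab
  lab2[lab > 0] <- perm[lab[lab > 0]]
  c1 <- summarize_primordium(measure_cells(label_volume(lab, c(1, 0.4, 0.4))))
  c2 <- summarize_primordium(measure_cells(label_volume(lab2, c(1, 0.4, 0.4))))
  expect_equal(c1$cell_count, c2$cell_count)
  expect_equal(c1$total_volume_um3, c2$total_volume_um3)
})

test_that("deposition pattern normalizes positions to the ganglion", {
  pos <- cbind(y = c(30, 30, 30), x = c(10, 60, 110))
  ov <- simulate_overview(pos, c(40, 15, 15), image_size_px = c(64, 160),
                          seed = 3)
  dp <- deposition_pattern(ov)
  expect_equal(length(dp$positions_um), 3L)
  expect_equal(dp$positions_um[1], 0)
  expect_equal(dp$n_neuromasts, 2L)
  expect_equal(dp$positions_um, c(0, 50, 100), tolerance = 0.04)
  expect_true(all(diff(dp$positions_um) >= 0))
})

test_that("a ganglion-only overview has zero neuromasts", {
  ov <- simulate_overview(cbind(30, 40), 40, image_size_px = c(64, 120),
                          seed = 4)
  dp <- deposition_pattern(ov)
  expect_equal(dp$n_neuromasts, 0L)
})

test_that("deposition handles six clusters and is translation-invariant", {
  pos <- cbind(y = rep(32, 6), x = seq(15, 240, length.out = 6))
  ov <- simulate_overview(pos, rep(18, 6), image_size_px = c(64, 256), seed = 5)
  dp <- deposition_pattern(ov)
  expect_equal(dp$n_neuromasts, 5L)
  expect_equal(dp$positions_um, pos[, 2] - pos[1, 2], tolerance = 2)

  pos2 <- pos
  pos2[, 2] <- pos2[, 2] + 10           # image-wide shift
  ov2 <- simulate_overview(pos2, rep(18, 6), image_size_px = c(64, 256),
                           seed = 5)
  dp2 <- deposition_pattern(ov2)
  expect_equal(dp2$positions_um, dp$positions_um, tolerance = 2)
})

test_that("stained area recovers a rendered dark disc", {
  img <- matrix(0.85, 120, 120)
  ctr <- 60
  yy <- matrix(seq_len(120) - ctr, 120, 120)
  disc <- yy^2 + t(yy)^2 <= 25^2
  img[disc] <- 0.15
  a <- stained_area(img, calibration_um_per_px = 1)
  expect_equal(a, pi * 625, tolerance = 0.05)
  # doubling the calibration quadruples the area
  expect_equal(stained_area(img, 2), 4 * a)
  expect_warning(a0 <- stained_area(matrix(0.5, 50, 50)), "no stain")
  expect_equal(a0, 0)
})
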