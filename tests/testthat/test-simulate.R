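test_that("single-cell primordium has one label and membrane only at the shell", {
  sim <- simulate_primordium(primordium_params(n_cells = 1, n_rosettes = 0,
                                               noise_sd = 0), seed = 1)
  expect_equal(sim$truth$true_count, 1L)
  expect_equal(n_labels(sim$truth$label_volume), 1L)
  # deep interior of the single cell carries no membrane signal
  lab <- sim$truth$label_volume$labels
  mem <- sim$stack$channels$membrane
  ctr <- round(dim(lab) / 2)
  expect_lt(mem[ctr[1], ctr[2], ctr[3]], 0.05)
  expect_gt(max(mem), 0.9)
})

test_that("the default primordium carries 120 cells with exact label truth", {
  sim <- simulate_primordium(primordium_params(elongation = 2.5), seed = 7)
  expect_equal(sim$truth$true_count, 120L)
  expect_equal(n_labels(sim$truth$label_volume), 120L)
})

test_that("generation is deterministic given (params, seed)", {
  p <- tiny_params()
  a <- simulate_primordium(p, seed = 42)
  b <- simulate_primordium(p, seed = 42)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$label_volume$labels, b$truth$label_volume$labels)
  c <- simulate_primordium(p, seed = 43)
  expect_false(identical(a$stack, c$stack))
})

test_that("per-cell volumes conserve the labeled volume exactly", {
  sim <- simulate_primordium(tiny_params(), seed = 3)
  lab <- sim$truth$label_volume
  expect_equal(sum(sim$truth$per_cell_volume_um3),
               sum(lab$labels > 0) * prod(lab$spacing_um))
})

test_that("rescaling voxel spacing preserves physical volumes within 2%", {
  p1 <- tiny_params(voxel_spacing_um = c(1, 0.4, 0.4))
  p2 <- tiny_params(voxel_spacing_um = c(0.5, 0.2, 0.2))
  s1 <- simulate_primordium(p1, seed = 9)
  s2 <- simulate_primordium(p2, seed = 9)
  v1 <- sum(s1$truth$per_cell_volume_um3)
  v2 <- sum(s2$truth$per_cell_volume_um3)
  expect_lt(abs(v2 - v1) / v1, 0.02)
  # voxel counts differ by ~8x while physical volume holds
  expect_gt(sum(s2$truth$label_volume$labels > 0) /
              sum(s1$truth$label_volume$labels > 0), 6)
})

test_that("invalid parameters are rejected", {
  expect_error(primordium_params(voxel_spacing_um = c(1, 0, 0.4)), "positive")
  expect_error(primordium_params(membrane_width_um = 6, cell_diameter_um = 5),
               "smaller")
  # rosette rings demand more cells than requested
  expect_error(
    simulate_primordium(primordium_params(n_cells = 10, n_rosettes = 2),
                        seed = 1),
    "infeasible")
})

test_that("cohort draws honour the genotype presets exactly at zero CV", {
  wt <- genotype_preset("wt", count_cv = 0)
  tr <- draw_cohort_truth(wt, 6, seed = 1)
  expect_true(all(tr$n_cells == 120))
  yap <- genotype_preset("yap1", count_cv = 0)
  tr2 <- draw_cohort_truth(yap, 6, seed = 1)
  expect_true(all(tr2$n_cells == 96))   # 120 x 0.80
})

test_that("the diving phenotype frequency matches its Bernoulli rate", {
  tr <- draw_cohort_truth(genotype_preset("wt"), 200, seed = 2)
  k <- sum(tr$diving)
  ci <- qbinom(c(0.005, 0.995), 200, 0.0129)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("wild-type preset is the neutral reference", {
  p <- genotype_presets()
  wt <- p[p$name == "wt", ]
  expect_equal(wt$count_multiplier, 1)
  expect_equal(wt$reporter_multiplier, 1)
  expect_equal(wt$diving_probability, 0.0129)
})

test_that("reporter images scale exactly with the preset multiplier", {
  base <- simulate_reporter_image(genotype_preset("wt"), base_intensity = 0.2,
                                  seed = 5, noise_sd = 0)
  expect_equal(mean_gray(base$stack, roi = base$truth$mask,
                         mode = "single_plane_roi"), 0.2, tolerance = 1e-12)
  oe <- simulate_reporter_image(genotype_preset("yap1_oe"), base_intensity = 0.2,
                                seed = 5, noise_sd = 0)
  r <- mean_gray(oe$stack) / mean_gray(base$stack)
  expect_equal(r, 1.70, tolerance = 1e-10)
  kd <- simulate_reporter_image(genotype_preset("yap1_mo"), base_intensity = 0.2,
                                seed = 5, noise_sd = 0.01)
  r2 <- mean_gray(kd$stack) / mean_gray(base$stack)
  expect_equal(r2, 0.88, tolerance = 0.03)
})

test_that("qPCR plates encode the fold change in target Ct shifts", {
  pl <- simulate_qpcr_plate(true_fold = 0.35, ct_noise_sd = 0, seed = 1)
  tgt <- dplyr::summarise(dplyr::filter(pl, gene == "target"),
                          ct = mean(ct), .by = group)
  shift <- tgt$ct[tgt$group == "mutant"] - tgt$ct[tgt$group == "control"]
  expect_equal(shift, log2(1 / 0.35), tolerance = 1e-10)   # ~1.515 cycles
  pl2 <- simulate_qpcr_plate(true_fold = 2, ct_noise_sd = 0, seed = 1)
  tgt2 <- dplyr::summarise(dplyr::filter(pl2, gene == "target"),
                           ct = mean(ct), .by = group)
  expect_equal(tgt2$ct[tgt2$group == "mutant"] -
                 tgt2$ct[tgt2$group == "control"], -1)
  # reference gene is group-independent at zero noise
  ref <- dplyr::filter(pl, gene == "rpl13")
  expect_equal(sd(ref$ct), 0)
})

test_that("overview truth matches the requested cluster layout", {
  pos <- cbind(y = c(30, 30, 30), x = c(20, 110, 200))
  ov <- simulate_overview(pos, c(40, 15, 15), seed = 1)
  expect_equal(ov$truth$positions_um, pos)
  expect_error(
    simulate_overview(cbind(c(30, 31), c(20, 24)), c(10, 10), seed = 1),
    "overlapping")
  expect_error(
    simulate_overview(cbind(30, 500), 10, image_size_px = c(64, 256), seed = 1),
    "inside")
})

test_that("simulate_cohort renders one stack per drawn embryo", {
  base <- tiny_params()
  co <- simulate_cohort(genotype_preset("wt", count_cv = 0), 2, base = base,
                        seed = 8, mean_count = 30)
  expect_length(co$embryos, 2L)
  expect_equal(nrow(co$truth), 2L)
  for (i in 1:2) {
    e <- co$embryos[[i]]
    expect_s3_class(e$stack, "voxel_stack")
    expect_equal(e$truth$true_count, co$truth$n_cells[i])
    expect_equal(e$name, co$truth$embryo[i])
  }
})
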