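test_that("two compartments split by a bright plane segment exactly", {
  tc <- two_cell_stack()
  seg <- segment_cells(tc$stack, sigma_um = 0.5, h_depth = 0.05)
  expect_equal(n_labels(seg), 2L)
  # every interior voxel of each compartment carries one consistent label
  l1 <- seg$labels[tc$truth == 1L]
  l2 <- seg$labels[tc$truth == 2L]
  expect_gte(mean(l1 == as.integer(names(which.max(table(l1))))), 0.99)
  expect_gte(mean(l2 == as.integer(names(which.max(table(l2))))), 0.99)
  expect_false(names(which.max(table(l1))) == names(which.max(table(l2))))
})

test_that("an all-flat relief fails loudly with zero labels", {
  st <- voxel_stack(list(membrane = array(0.5, c(6, 8, 8))), c(1, 1, 1))
  expect_warning(seg <- segment_cells(st), "failed")
  expect_equal(n_labels(seg), 0L)
  expect_true(attr(seg, "failed"))
})

test_that("shrinking h never decreases the label count (monotonicity)", {
  sim <- simulate_primordium(tiny_params(noise_sd = 0.05), seed = 6)
  n_lo <- n_labels(segment_cells(sim$stack, h_depth = 0.005))
  n_mid <- n_labels(segment_cells(sim$stack, h_depth = 0.03))
  n_hi <- n_labels(segment_cells(sim$stack, h_depth = 0.15))
  expect_gte(n_lo, n_mid)
  expect_gte(n_mid, n_hi)
})

test_that("watershed labels match ground truth on clean synthetics", {
  # noise-free input needs no pre-blur; near-isotropic sampling keeps the
  # voxel-quantization share of the boundary error small
  sim <- simulate_primordium(
    tiny_params(n_cells = 25, voxel_spacing_um = c(0.5, 0.3, 0.3),
                noise_sd = 0), seed = 7)
  seg <- segment_cells(sim$stack, sigma_um = 0)
  expect_equal(n_labels(seg), sim$truth$true_count)
  expect_gte(mean_cell_jaccard(seg$labels, sim$truth$label_volume$labels),
             0.95)
})

test_that("volume filtering removes exactly the out-of-range segments", {
  sim <- simulate_primordium(tiny_params(noise_sd = 0), seed = 8)
  seg <- segment_cells(sim$stack)
  n0 <- n_labels(seg)
  # identity when everything is in range
  same <- filter_segments(seg, v_min_um3 = 1, v_max_um3 = 1e6)
  expect_equal(n_labels(same), n0)
  expect_equal(nrow(attr(same, "removed")), 0L)

  # inject 5 sub-threshold speckles into background corners
  lab <- seg$labels
  d <- dim(lab)
  spots <- cbind(z = c(1, 1, d[1], d[1], 1),
                 y = c(1, d[2], 1, d[2], 3),
                 x = c(1, d[3], d[3], 1, d[3]))
  for (i in 1:5) {
    lab[spots[i, 1], spots[i, 2], spots[i, 3]] <- n0 + i
  }
  spiked <- label_volume(lab, seg$spacing_um)
  fl <- filter_segments(spiked, v_min_um3 = 30, v_max_um3 = 3000)
  expect_equal(nrow(attr(fl, "removed")), 5L)
  expect_true(all(attr(fl, "removed")$reason == "below_v_min"))
  expect_equal(n_labels(fl), n0)
})

test_that("voxels are conserved through filtering", {
  sim <- simulate_primordium(tiny_params(), seed = 9)
  seg <- segment_cells(sim$stack)
  fl <- filter_segments(seg)
  lab <- fl$labels
  expect_equal(sum(lab == 0) + sum(lab > 0), length(lab))
  # foreground never grows, removed voxels go to background
  expect_lte(sum(lab > 0), sum(seg$labels > 0))
})

test_that("all labels removed raises an explicit empty-result error", {
  sim <- simulate_primordium(tiny_params(noise_sd = 0), seed = 10)
  seg <- segment_cells(sim$stack)
  expect_error(filter_segments(seg, v_min_um3 = 1e5, v_max_um3 = 1e6),
               "all segments removed")
})

test_that("cuboid measurements match closed forms", {
  lab <- array(0L, c(12, 12, 12))
  lab[2:11, 2:11, 2:11] <- 1L
  cells <- measure_cells(label_volume(lab, c(1, 1, 1)))
  expect_equal(cells$volume_um3, 1000)
  expect_equal(cells$surface_um2, 600)

  cells2 <- measure_cells(label_volume(lab, c(2, 1, 1)))
  expect_equal(cells2$volume_um3, 2000)
  # two 10x10 z-faces at 1x1 um2 + four side faces of 10x10 voxels at 2x1 um2
  expect_equal(cells2$surface_um2, 2 * 100 + 4 * 200)

  single <- array(0L, c(3, 3, 3))
  single[2, 2, 2] <- 1L
  c3 <- measure_cells(label_volume(single, c(1, 1, 1)))
  expect_equal(c3$volume_um3, 1)
  expect_equal(c3$surface_um2, 6)
  expect_equal(c3$sv_ratio_per_um, 6)
})

test_that("surface counts faces against the stack boundary", {
  lab <- array(1L, c(2, 2, 2))          # cube filling the whole stack
  cells <- measure_cells(label_volume(lab, c(1, 1, 1)))
  expect_equal(cells$volume_um3, 8)
  expect_equal(cells$surface_um2, 24)
})

test_that("per-channel means are averaged over each label", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, , ] <- 1L
  lab[3:4, , ] <- 2L
  ch <- array(0, c(4, 4, 4))
  ch[1:2, , ] <- 0.25
  ch[3:4, , ] <- 0.75
  st <- voxel_stack(list(sig = ch), c(1, 1, 1))
  cells <- measure_cells(label_volume(lab, c(1, 1, 1)), st)
  expect_equal(cells$mean_sig, c(0.25, 0.75))
})

test_that("homogeneous cells produce zero outlier removals", {
  cells <- tibble::tibble(
    label = 1:20, volume_um3 = 300, surface_um2 = 250,
    sv_ratio_per_um = 250 / 300, flag = "kept")
  out <- remove_outlier_cells(cells)
  expect_true(all(out$flag == "kept"))
})

test_that("flat skin-cell segments are flagged by the S/V fence", {
  set.seed(11)
  n <- 120
  vol <- rnorm(n, 300, 25)
  sv <- rnorm(n, 1.3, 0.08)
  cells <- tibble::tibble(
    label = seq_len(n + 3),
    volume_um3 = c(vol, 280, 310, 295),
    sv_ratio_per_um = c(sv, 5.2, 5.4, 5.0),   # ~4x the median S/V
    surface_um2 = volume_um3 * sv_ratio_per_um,
    flag = "kept")
  out <- remove_outlier_cells(cells)
  expect_equal(which(out$flag == "outlier_sv"), n + 1:3)
  expect_equal(sum(out$flag != "kept"), 3L)
})

test_that("outlier flagging is invariant to row order", {
  set.seed(12)
  cells <- tibble::tibble(
    label = 1:50,
    volume_um3 = c(rnorm(48, 300, 30), 1500, 30),
    sv_ratio_per_um = rnorm(50, 1.3, 0.1),
    surface_um2 = volume_um3 * sv_ratio_per_um,
    flag = "kept")
  out1 <- remove_outlier_cells(cells)
  perm <- sample(50)
  out2 <- remove_outlier_cells(cells[perm, ])
  expect_equal(out2$flag[order(out2$label)], out1$flag[order(out1$label)])
})

test_that("fewer than four cells skips outlier removal with a warning", {
  cells <- tibble::tibble(label = 1:3, volume_um3 = c(10, 20, 3000),
                          surface_um2 = 1, sv_ratio_per_um = 1, flag = "kept")
  expect_warning(out <- remove_outlier_cells(cells), "skipped")
  expect_true(all(out$flag == "kept"))
})
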