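#' Percent change of mean recovered cell counts between two cohort arms
#'
#' Convenience wrapper used by recovery studies: runs both arms through the
#' full imaging pipeline ([run_cohort()]) and returns the percent change of
#' the mean kept-cell count of `test_preset` relative to `ref_preset`.
#'
#' @param ref_preset,test_preset preset names (see [genotype_presets()]).
#' @param n_embryos embryos per arm.
#' @param seed integer seed (each arm derives its own stream from it).
#' @param config a [pipeline_config()].
#' @return A list: `percent_change`, `ref_mean`, `test_mean`, `cohort` (the
#'   combined per-embryo tibble).
#' @export
recover_count_effect <- function(ref_preset, test_preset, n_embryos = 20,
                                 seed = 1L, config = pipeline_config()) {
  co <- run_cohort(c(ref_preset, test_preset), n_embryos, seed = seed,
                   config = config)
  ok <- co[co$status == "ok", , drop = FALSE]
  m <- tapply(ok$cell_count, ok$genotype, mean)
  list(percent_change = percent_change(m[[ref_preset]], m[[test_preset]]),
       ref_mean = m[[ref_preset]], test_mean = m[[test_preset]],
       cohort = co)
}

#' Percent change of reporter mean gray value between two presets
#'
#' Simulates paired reporter images (shared per-pair seeds) for a baseline
#' and a test preset and measures the percent change of group-mean gray
#' values with [mean_gray()].
#'
#' @param ref_preset,test_preset preset names.
#' @param n_pairs image pairs.
#' @param seed integer seed.
#' @param mode measurement mode passed to [mean_gray()].
#' @return A list: `percent_change`, `ref_mean`, `test_mean`.
#' @export
recover_reporter_effect <- function(ref_preset, test_preset, n_pairs = 10,
                                    seed = 1L,
                                    mode = "whole_image_avg_projection") {
  pr <- genotype_preset(ref_preset)
  pt <- genotype_preset(test_preset)
  vals <- vapply(seq_len(n_pairs), function(i) {
    s <- seed + 7919L * i
    a <- simulate_reporter_image(pr, seed = s)
    b <- simulate_reporter_image(pt, seed = s)
    ma <- if (mode == "single_plane_roi") {
      mean_gray(a$stack, roi = a$truth$mask, mode = mode)
    } else {
      mean_gray(a$stack, mode = mode)
    }
    mb <- if (mode == "single_plane_roi") {
      mean_gray(b$stack, roi = b$truth$mask, mode = mode)
    } else {
      mean_gray(b$stack, mode = mode)
    }
    c(ma, mb)
  }, c(0, 0))
  list(percent_change = percent_change(mean(vals[1, ]), mean(vals[2, ])),
       ref_mean = mean(vals[1, ]), test_mean = mean(vals[2, ]))
}

#' Mean delta-delta-Ct fold change recovered over simulated plates
#'
#' @param true_fold fold change injected by the generator.
#' @param n_seeds number of independent plates.
#' @param seed base seed.
#' @param ct_noise_sd,n_biological plate parameters.
#' @return mean recovered fold change.
#' @export
recover_qpcr_fold <- function(true_fold, n_seeds = 50, seed = 1L,
                              ct_noise_sd = 0.15, n_biological = 6L) {
  mean(vapply(seq_len(n_seeds), function(i) {
    pl <- simulate_qpcr_plate(true_fold, ct_noise_sd = ct_noise_sd,
                              n_biological = n_biological,
                              seed = seed + 104729L * i)
    delta_delta_ct(pl)$fold_change
  }, 0))
}
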