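#' Default pipeline configuration
#'
#' All tunable parameters of the simulate -> register -> segment -> quantify
#' -> stats pipeline in one nested list, YAML-serializable and round-trip
#' stable.
#'
#' @param ... named overrides for any top-level section (partial lists are
#'   merged over the defaults).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = list(preset = "wt", n_embryos = 5L, seed = 1L,
                    mean_count = 120,
                    base = list(elongation = 2.5, n_rosettes = 3L,
                                rosette_radius_um = 8, cell_diameter_um = 5.5,
                                membrane_width_um = 1.0,
                                voxel_spacing_um = c(1, 0.4, 0.4),
                                noise_sd = 0.03, photon_scale = 120)),
    register = list(channel = "membrane", blur_sigma_um = 2, margin_um = 5),
    segment = list(channel = "membrane", sigma_um = 0.5, h_depth = 0.03,
                   v_min_um3 = 30, v_max_um3 = 3000, fence_k = 3.5),
    rosettes = list(radius_um = 8, floor = 0.4, n_spokes = 12),
    quantify = list(k = 2),
    stats = list(ref_group = "wt", dispersion = "SD"),
    io = list(out_dir = NULL, input_dir = NULL, manifest = NULL,
              write_stacks = FALSE)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm, call. = FALSE)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]], keep.null = TRUE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_base_params <- function(config, n_cells = 120L, orientation_deg = 0) {
  b <- config$simulate$base
  primordium_params(
    n_cells = n_cells, elongation = b$elongation,
    n_rosettes = b$n_rosettes, rosette_radius_um = b$rosette_radius_um,
    cell_diameter_um = b$cell_diameter_um,
    membrane_width_um = b$membrane_width_um,
    voxel_spacing_um = b$voxel_spacing_um, noise_sd = b$noise_sd,
    photon_scale = b$photon_scale, orientation_deg = orientation_deg
  )
}

#' Process a single stack through registration, segmentation and summary
#'
#' The measurement cascade applied to one embryo: footprint mask and moment
#' ellipse, in-plane registration with X/Y/Z crop, 3D watershed
#' segmentation, volume filtering, per-cell measurement, robust outlier
#' removal, shape descriptors and rosette detection, collapsed into one
#' summary row.
#'
#' @param stack a [voxel_stack()].
#' @param config a [pipeline_config()].
#' @param diving optional phenotype annotation carried into the summary.
#' @return A list: `summary` (one-row tibble), `cells`, `mask`, `fit`,
#'   `labels`, `registered`.
#' @export
process_stack <- function(stack, config = pipeline_config(), diving = NA) {
  rg <- config$register
  sg <- config$segment
  mask <- project_and_mask(stack, channel = rg$channel,
                           blur_sigma_um = rg$blur_sigma_um)
  fit <- fit_ellipse(mask)
  reg <- register_stack(stack, fit, margin_um = rg$margin_um,
                        channel = rg$channel)
  labs <- segment_cells(reg$stack, channel = sg$channel,
                        sigma_um = sg$sigma_um, h_depth = sg$h_depth)
  labs <- filter_segments(labs, v_min_um3 = sg$v_min_um3,
                          v_max_um3 = sg$v_max_um3)
  # measure on the z-trimmed registered stack so shapes match
  zt <- attr(labs, "z_trim")
  trimmed <- voxel_stack(
    lapply(reg$stack$channels, function(a) {
      a[zt[1]:zt[2], , , drop = FALSE]
    }),
    reg$stack$spacing_um)
  cells <- measure_cells(labs, trimmed)
  cells <- remove_outlier_cells(cells, fence_k = sg$fence_k)
  rmask <- reg$mask          # the footprint mask carried through registration
  det <- detect_rosettes(reg$stack, mask = rmask,
                         expected_radius_um = config$rosettes$radius_um,
                         channel = rg$channel,
                         floor = config$rosettes$floor,
                         n_spokes = config$rosettes$n_spokes)
  summary <- summarize_primordium(cells, mask = rmask, detections = det,
                                  diving = diving)
  list(summary = summary, cells = cells, mask = rmask, fit = fit,
       labels = labs, registered = reg$stack)
}

#' Run a simulated cohort through the full measurement pipeline
#'
#' Streams embryo by embryo (stacks are generated, measured and discarded)
#' so arbitrarily large cohorts fit in memory. Per-embryo failures are
#' recorded and skipped.
#'
#' @param presets preset tibble or character vector of preset names.
#' @param n_embryos embryos per preset.
#' @param seed cohort seed.
#' @param config a [pipeline_config()].
#' @return A tibble: one row per embryo with the ground-truth draw
#'   (`true_n_cells`, `diving`), the measured summary columns, and `status`
#'   (`"ok"` or the error message).
#' @export
run_cohort <- function(presets, n_embryos, seed = 1L,
                       config = pipeline_config()) {
  truth <- draw_cohort_truth(presets, n_embryos, seed = seed,
                             mean_count = config$simulate$mean_count)
  pl <- if (is.character(presets)) {
    dplyr::bind_rows(lapply(presets, genotype_preset))
  } else {
    presets
  }
  edu_by_geno <- stats::setNames(pl$edu_fraction, pl$name)
  rows <- purrr::pmap(
    list(truth$embryo, truth$genotype, truth$n_cells, truth$diving,
         truth$orientation_deg, truth$embryo_seed),
    function(nm, geno, n, div, o, s) {
      res <- tryCatch({
        pp <- config_base_params(config, n_cells = n, orientation_deg = o)
        sim <- simulate_primordium(pp, seed = s,
                                   edu_fraction = unname(edu_by_geno[[geno]]))
        pr <- process_stack(sim$stack, config, diving = div)
        dplyr::bind_cols(
          tibble::tibble(embryo = nm, genotype = geno, true_n_cells = n,
                         status = "ok"),
          pr$summary)
      }, error = function(e) {
        tibble::tibble(embryo = nm, genotype = geno, true_n_cells = n,
                       status = conditionMessage(e))
      })
      res
    })
  dplyr::bind_rows(rows)
}

#' Run the configured end-to-end pipeline
#'
#' Simulation mode (no `io$input_dir`): simulates the configured cohort and
#' measures it. File mode: reads every stack listed in the manifest CSV
#' (`file`, `embryo`, `genotype` columns) from `io$input_dir`. Outputs - a
#' cohort CSV, a group-comparison stats CSV, the effective YAML config and a
#' JSON run log - are written to `io$out_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @return A list: `cohort` (per-embryo tibble), `stats` (pairwise
#'   comparisons vs the reference group, when >= 2 groups), `summary`
#'   (group summaries), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  if (is.null(config$io$input_dir)) {
    presets <- config$simulate$preset
    cohort <- run_cohort(presets, config$simulate$n_embryos,
                         seed = config$simulate$seed, config = config)
  } else {
    manifest <- utils::read.csv(config$io$manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("file", "embryo", "genotype") %in% names(manifest)))
    rows <- purrr::pmap(manifest[c("file", "embryo", "genotype")],
                        function(file, embryo, genotype) {
      tryCatch({
        st <- read_stack(file.path(config$io$input_dir, file))
        pr <- process_stack(st, config)
        dplyr::bind_cols(
          tibble::tibble(embryo = embryo, genotype = genotype,
                         true_n_cells = NA_integer_, status = "ok"),
          pr$summary)
      }, error = function(e) {
        tibble::tibble(embryo = embryo, genotype = genotype,
                       true_n_cells = NA_integer_,
                       status = conditionMessage(e))
      })
    })
    cohort <- dplyr::bind_rows(rows)
  }
  ok <- cohort[cohort$status == "ok", , drop = FALSE]
  groups <- unique(ok$genotype)
  stats_tab <- NULL
  summ <- NULL
  if (nrow(ok) > 0) {
    summ <- summarize_groups(ok, cell_count, genotype,
                             dispersion_mode = config$stats$dispersion)
    ref <- config$stats$ref_group
    if (length(groups) >= 2 && ref %in% groups) {
      stats_tab <- cohort_tests(ok, cell_count, genotype, ref_group = ref)
    }
  }
  out <- list(cohort = cohort, stats = stats_tab, summary = summ,
              config = config)
  od <- config$io$out_dir
  if (!is.null(od)) {
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(od, "cohort.csv"), row.names = FALSE)
    if (!is.null(stats_tab)) {
      utils::write.csv(stats_tab, file.path(od, "stats.csv"),
                       row.names = FALSE)
    }
    write_config(config, file.path(od, "config.yaml"))
    log <- list(
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      n_embryos = nrow(cohort), n_failed = sum(cohort$status != "ok"),
      r_version = R.version.string,
      config_hash = rlang::hash(unclass(config))
    )
    jsonlite::write_json(log, file.path(od, "run_log.json"),
                         auto_unbox = TRUE)
  }
  if (any(cohort$status != "ok")) {
    warning(sum(cohort$status != "ok"), " embryo(s) failed; see $cohort$status",
            call. = FALSE)
  }
  out
}
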