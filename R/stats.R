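#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged per (gene, sample) first; then
#' `dCt = Ct_target - Ct_ref` per sample, `ddCt = mean dCt(group) -
#' mean dCt(control)`, and the fold change is `2^(-ddCt)`.
#'
#' @param plate tibble with columns `gene`, `sample`, `group`, `replicate`,
#'   `ct` (a [simulate_qpcr_plate()] output or equivalent).
#' @param target_gene,ref_gene gene names; every sample must carry both.
#' @param control_group name of the reference group.
#' @return A tibble with one row per non-control group: `group`, `n_samples`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
delta_delta_ct <- function(plate, target_gene = "target", ref_gene = "rpl13",
                           control_group = "control") {
  stopifnot(all(c("gene", "sample", "group", "ct") %in% names(plate)))
  if (!control_group %in% plate$group) {
    stop("control group not present: ", control_group, call. = FALSE)
  }
  wide <- plate |>
    dplyr::filter(.data$gene %in% c(target_gene, ref_gene)) |>
    dplyr::summarise(ct = mean(.data$ct),
                     .by = c("gene", "sample", "group")) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  if (!ref_gene %in% names(wide) || anyNA(wide[[ref_gene]])) {
    missing <- if (ref_gene %in% names(wide)) {
      wide$sample[is.na(wide[[ref_gene]])]
    } else {
      wide$sample
    }
    stop("reference gene missing for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!target_gene %in% names(wide) || anyNA(wide[[target_gene]])) {
    stop("target gene missing for some samples", call. = FALSE)
  }
  wide$dct <- wide[[target_gene]] - wide[[ref_gene]]
  ctrl_mean <- mean(wide$dct[wide$group == control_group])
  wide |>
    dplyr::filter(.data$group != control_group) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     delta_delta_ct = mean(.data$dct) - ctrl_mean,
                     .by = "group") |>
    dplyr::mutate(fold_change = 2^(-.data$delta_delta_ct))
}

# exact frequency table of the Mann-Whitney U distribution for sample sizes
# (m, n): f[u + 1] = number of labelings with statistic u, u in 0..m*n.
# Classic two-sample recurrence f_{m,n}(u) = f_{m-1,n}(u - n) + f_{m,n-1}(u).
mw_exact_freq <- function(m, n) {
  f <- matrix(list(), m + 1, n + 1)
  for (i in 0:m) {
    for (j in 0:n) {
      if (i == 0 || j == 0) {
        f[[i + 1, j + 1]] <- 1   # single labeling, U = 0
        next
      }
      a <- c(rep(0, j), f[[i, j + 1]])          # add x beating all j ys? see below
      b <- f[[i + 1, j]]
      la <- max(length(a), length(b), i * j + 1)
      a <- c(a, rep(0, la - length(a)))
      b <- c(b, rep(0, la - length(b)))
      f[[i + 1, j + 1]] <- a + b
    }
  }
  f[[m + 1, n + 1]]
}

#' Two-tailed Mann-Whitney U test
#'
#' U from rank sums with midranks for ties. For small untied samples
#' (permutation table of at most one million labelings) the p value is exact
#' from the full U distribution; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. The two-tailed
#' p is `min(1, 2 * one-tailed)`.
#'
#' @param x,y numeric samples.
#' @return An object of class `mw_test`: `statistic_U`, `p_two_tailed`,
#'   `n_x`, `n_y`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (all(c(x, y) == c(x, y)[1])) {
    res <- list(statistic_U = u, p_two_tailed = 1, n_x = nx, n_y = ny,
                method = "degenerate")
    return(structure(res, class = "mw_test"))
  }
  exact_ok <- !ties && choose(nx + ny, nx) <= 1e6
  if (exact_ok) {
    freq <- mw_exact_freq(nx, ny)
    tot <- sum(freq)
    lower <- sum(freq[seq_len(u + 1)]) / tot          # P(U <= u)
    upper <- sum(freq[(u + 1):length(freq)]) / tot    # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    nn <- nx + ny
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    v <- nx * ny / 12 * ((nn + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      mu <- nx * ny / 2
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)    # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx_tie_corrected"
  }
  structure(list(statistic_U = u, p_two_tailed = p, n_x = nx, n_y = ny,
                 method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-tailed p = %.4g [%s] %s\n",
              x$statistic_U, x$n_x, x$n_y, x$p_two_tailed, x$method,
              significance_label(x$p_two_tailed)))
  invisible(x)
}

#' Tidy a Mann-Whitney test result
#'
#' @param x an `mw_test` object.
#' @param ... unused.
#' @return A one-row tibble: `statistic`, `p.value`, `n_x`, `n_y`, `method`,
#'   `label`.
#' @export
tidy.mw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic_U, p.value = x$p_two_tailed,
                 n_x = x$n_x, n_y = x$n_y, method = x$method,
                 label = significance_label(x$p_two_tailed))
}

#' @rdname tidy.mw_test
#' @export
glance.mw_test <- function(x, ...) tidy.mw_test(x, ...)

#' Star annotation for a p value
#'
#' `ns` above 0.05; `*`, `**`, `***`, `****` at the inclusive 0.05, 0.01,
#' 0.001 and 0.0001 brackets (most extreme bracket wins).
#'
#' @param p p value(s) in `[0, 1]`.
#' @return character vector of labels.
#' @export
significance_label <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    .default = "ns"
  )
}

#' Signed percent change of a test mean relative to a reference mean
#'
#' @param reference_mean,test_mean group means; the reference must be
#'   nonzero.
#' @return `100 * (test - reference) / reference`.
#' @export
percent_change <- function(reference_mean, test_mean) {
  if (any(reference_mean == 0)) {
    stop("reference mean is zero: percent change undefined", call. = FALSE)
  }
  100 * (test_mean - reference_mean) / reference_mean
}

#' Per-group mean, SD and SEM
#'
#' SD uses the n-1 denominator; SEM = SD / sqrt(n). Groups of size one get
#' `NA` dispersion and a warning.
#'
#' @param data a data frame.
#' @param value bare column name of the measured value.
#' @param group bare column name of the grouping variable.
#' @param dispersion_mode `"SD"` or `"SEM"` - which dispersion the `shown`
#'   column reports.
#' @return A tibble: `group`, `n`, `mean`, `sd`, `sem`, `dispersion_mode`,
#'   `shown`.
#' @export
summarize_groups <- function(data, value, group,
                             dispersion_mode = c("SD", "SEM")) {
  dispersion_mode <- match.arg(dispersion_mode)
  dm <- dispersion_mode
  out <- data |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sd = sd({{ value }}),
      .by = {{ group }}
    ) |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n),
                  dispersion_mode = dm,
                  shown = if (dm == "SD") .data$sd else .data$sem)
  if (any(out$n == 1)) {
    warning("group(s) of size 1: dispersion undefined", call. = FALSE)
  }
  out
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level.
#' @return A one-row tibble: `estimate`, `lower`, `upper`, `k`, `n`, `level`.
#' @export
proportion_with_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  p <- k / n
  z <- qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  tibble::tibble(estimate = p, lower = max(0, ctr - hw),
                 upper = min(1, ctr + hw), k = k, n = n, level = level)
}

#' Pairwise group comparisons for a cohort table
#'
#' For each non-reference group: percent change of the group mean relative
#' to the reference group, the two-tailed Mann-Whitney p (or Welch t behind
#' the `method` flag), and the star label.
#'
#' @param data cohort tibble.
#' @param value bare column of the measurement (e.g. `cell_count`).
#' @param group bare column of the genotype/condition.
#' @param ref_group reference level.
#' @param method `"mann_whitney"` (default) or `"welch"` for a sensitivity
#'   check.
#' @return A tibble: `group`, `n`, `ref_n`, `mean`, `ref_mean`,
#'   `percent_change`, `statistic`, `p.value`, `label`, `method`.
#' @export
cohort_tests <- function(data, value, group, ref_group,
                         method = c("mann_whitney", "welch")) {
  method <- match.arg(method)
  vals <- dplyr::pull(data, {{ value }})
  grps <- dplyr::pull(data, {{ group }})
  stopifnot(ref_group %in% grps)
  ref <- vals[grps == ref_group]
  purrr::map_dfr(setdiff(unique(grps), ref_group), function(g) {
    gv <- vals[grps == g]
    if (method == "mann_whitney") {
      tst <- mann_whitney_u(gv, ref)
      stat <- tst$statistic_U
      p <- tst$p_two_tailed
    } else {
      tst <- stats::t.test(gv, ref)
      stat <- unname(tst$statistic)
      p <- tst$p.value
    }
    tibble::tibble(
      group = g, n = length(gv), ref_n = length(ref),
      mean = mean(gv), ref_mean = mean(ref),
      percent_change = percent_change(mean(ref), mean(gv)),
      statistic = stat, p.value = p,
      label = significance_label(p), method = method
    )
  })
}
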