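#' Variance-percentile filter
#'
#' Flags cells whose replicate sample variance strictly exceeds the
#' nearest-rank percentile of the observed variance distribution (the value
#' at index `ceiling(percentile/100 * n)` of the ascending-sorted variances).
#' Ties at the threshold are retained. With fewer than 20 defined variances
#' the percentile is not meaningful: nothing is filtered and a
#' `fflscreen_filter_skip_warning` is raised.
#'
#' @param variances Numeric vector of per-cell replicate variances; `NA`
#'   entries (cells without replication) are never filtered.
#' @param percentile Percentile in (0, 100); default 95.
#' @return A list with `filtered` (logical, same length), `threshold`,
#'   and `skipped`.
#' @export
variance_filter <- function(variances, percentile = 95) {
  if (percentile <= 0 || percentile >= 100) {
    abort_ffl("`percentile` must be strictly between 0 and 100.", "argument")
  }
  defined <- variances[!is.na(variances)]
  n <- length(defined)
  if (n < 20) {
    warn_ffl(
      sprintf("Only %d defined variances (< 20); variance filter skipped.", n),
      "filter_skip"
    )
    return(list(
      filtered = rep(FALSE, length(variances)),
      threshold = NA_real_, skipped = TRUE
    ))
  }
  threshold <- sort(defined)[ceiling(percentile / 100 * n)]
  list(
    filtered = !is.na(variances) & variances > threshold,
    threshold = threshold, skipped = FALSE
  )
}

#' Model-based z-test of H0: ddCT = 0
#'
#' The averaged ddCT over K biological replicates is, under the null of no
#' modulation, assumed N(0, sigma^2 / K) with sigma^2 the biological
#' variance predicted by the fitted error model at the observed ddCT (never
#' the per-cell sample variance). Returns the z statistic and the two-sided
#' normal p-value.
#'
#' @param mean_ddct Numeric vector of replicate-averaged ddCT values.
#' @param model A converged `ddct_error_model`.
#' @param K Replicate counts (scalar or vector).
#' @return A tibble with columns `z` and `p`.
#' @export
test_modulation <- function(mean_ddct, model, K) {
  if (any(K < 1)) abort_ffl("K must be >= 1 for testing.", "argument")
  sigma2 <- predict_variance(model, mean_ddct)
  if (any(sigma2 <= 0)) {
    abort_ffl("Predicted variance must be positive for testing.", "model")
  }
  z <- mean_ddct / sqrt(sigma2 / K)
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Bonferroni adjustment
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param m Number of tests performed.
#' @return `pmin(1, m * pvals)`.
#' @export
bonferroni_adjust <- function(pvals, m) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort_ffl("p-values must lie in [0, 1].", "argument")
  }
  if (m < 1) abort_ffl("`m` must be at least 1.", "argument")
  pmin(1, m * pvals)
}

#' Run the two-stage significance-selection procedure
#'
#' Per silencing experiment: (1) cells whose replicate variance exceeds the
#' `percentile`-th nearest-rank percentile of that experiment's variance
#' distribution are filtered out; (2) every remaining (gene, time point)
#' cell is tested with the model-based z-test; (3) p-values are
#' Bonferroni-adjusted with m = number of tests performed in that experiment
#' (set `m_policy = "pre_filter"` to count filtered cells too); calls with
#' adjusted p at most `alpha` are significant. The perturbed gene's own
#' cells are excluded from target calls and reported separately as a
#' knockdown-efficiency check. Direction is `"down"` (gene down-regulated by
#' the silencing, mean ddCT > 0) or `"up"` for significant calls, `"none"`
#' otherwise.
#'
#' @param ddct A `ddct_table` from [compute_ddct()].
#' @param model A converged `ddct_error_model`.
#' @param alpha Significance cutoff on Bonferroni-adjusted p-values.
#' @param percentile Variance-filter percentile.
#' @param test_times Time points (hours) to test; defaults to every time
#'   point except 0 h (the pre-stimulation baseline).
#' @param m_policy `"post_filter"` (default; m = tests actually performed)
#'   or `"pre_filter"` (m includes filtered cells).
#' @return A tibble of class `significance_calls`, one row per tested cell,
#'   with columns `perturbation`, `gene`, `time_h`, `phase`, `mean_ddct`,
#'   `var_ddct`, `K`, `fold_change`, `filtered`, `z`, `p`, `p_adj`,
#'   `significant`, `direction`. Per-experiment m, filter thresholds and
#'   knockdown-efficiency diagnostics are stored in attributes
#'   `experiments` and `knockdown_check`.
#' @export
run_selection <- function(ddct, model, alpha = 0.05, percentile = 95,
                          test_times = NULL,
                          m_policy = c("post_filter", "pre_filter")) {
  stopifnot(inherits(ddct, "ddct_table"))
  m_policy <- match.arg(m_policy)
  x <- as_tibble(ddct)
  test_times <- test_times %||% setdiff(sort(unique(x$time_h)), 0)
  x <- x |> filter(.data$time_h %in% test_times)

  self <- x |> filter(.data$gene == .data$perturbation)
  x <- x |> filter(.data$gene != .data$perturbation)
  if (nrow(x) == 0) abort_ffl("No testable cells after exclusions.", "argument")

  one_experiment <- function(cells) {
    flt <- variance_filter(cells$var_ddct, percentile = percentile)
    cells$filtered <- flt$filtered
    m <- if (m_policy == "post_filter") sum(!cells$filtered) else nrow(cells)
    tested <- !cells$filtered
    cells$z <- NA_real_
    cells$p <- NA_real_
    if (any(tested)) {
      zp <- test_modulation(cells$mean_ddct[tested], model, cells$K[tested])
      cells$z[tested] <- zp$z
      cells$p[tested] <- zp$p
    }
    cells$p_adj <- bonferroni_adjust(cells$p, m) # NA stays NA for filtered cells
    cells$significant <- !is.na(cells$p_adj) & cells$p_adj <= alpha
    cells$direction <- ifelse(
      cells$significant,
      ifelse(cells$mean_ddct > 0, "down", "up"),
      "none"
    )
    attr(cells, "experiment_info") <- tibble(
      perturbation = cells$perturbation[1],
      m = m,
      n_cells = nrow(cells),
      n_filtered = sum(cells$filtered),
      filter_threshold = flt$threshold,
      filter_skipped = flt$skipped
    )
    cells
  }

  parts <- x |>
    group_by(.data$perturbation) |>
    group_split() |>
    purrr::map(one_experiment)
  calls <- bind_rows(parts)
  experiments <- purrr::map(parts, ~ attr(.x, "experiment_info")) |> bind_rows()

  kd_check <- NULL
  if (nrow(self) > 0) {
    zp <- test_modulation(self$mean_ddct, model, self$K)
    kd_check <- self |>
      mutate(z = zp$z, p = zp$p) |>
      select(
        "perturbation", "gene", "time_h", "phase",
        "mean_ddct", "K", "fold_change", "z", "p"
      )
  }

  genes <- attr(ddct, "genes")
  calls <- calls |>
    arrange(
      match(.data$perturbation, unique(x$perturbation)),
      match(.data$gene, genes), .data$time_h
    ) |>
    select(
      "perturbation", "gene", "time_h", "phase", "mean_ddct", "var_ddct",
      "K", "fold_change", "filtered", "z", "p", "p_adj", "significant",
      "direction"
    )
  set_ffl_attrs(
    calls,
    list(
      experiments = experiments,
      knockdown_check = kd_check,
      alpha = alpha,
      percentile = percentile,
      m_policy = m_policy,
      test_times = test_times,
      genes = genes
    ),
    class = "significance_calls"
  )
}

#' Validate an externally produced calls table
#'
#' The module-inference stage only needs a table of significance calls, so
#' results of any selection strategy (e.g. from microarray data) can be fed
#' in. Required columns: `perturbation`, `gene`, `time_h`, `significant`,
#' `direction`; `phase` is derived from `time_h` if absent; the remaining
#' `significance_calls` columns are filled with `NA` if absent.
#'
#' @param data A data frame of calls.
#' @param genes Gene-panel order for deterministic output ordering; defaults
#'   to order of appearance.
#' @param washout_after Stimulus-removal time for phase derivation.
#' @return A `significance_calls` tibble.
#' @export
as_significance_calls <- function(data, genes = NULL, washout_after = 8) {
  required <- c("perturbation", "gene", "time_h", "significant", "direction")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_ffl(
      paste0("Missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  x <- as_tibble(data)
  if (!"phase" %in% names(x)) x$phase <- phase_of_time(x$time_h, washout_after)
  for (col in c("mean_ddct", "var_ddct", "fold_change", "z", "p", "p_adj")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  if (!"K" %in% names(x)) x$K <- NA_integer_
  if (!"filtered" %in% names(x)) x$filtered <- FALSE
  bad_dir <- setdiff(unique(x$direction), c("down", "up", "none"))
  if (length(bad_dir) > 0) {
    abort_ffl(paste0("Unknown direction value(s): ", paste(bad_dir, collapse = ", ")), "schema")
  }
  genes <- genes %||% unique(c(x$gene, x$perturbation))
  x <- x |>
    select(
      "perturbation", "gene", "time_h", "phase", "mean_ddct", "var_ddct",
      "K", "fold_change", "filtered", "z", "p", "p_adj", "significant",
      "direction"
    )
  set_ffl_attrs(x, list(genes = genes), class = "significance_calls")
}

# Gene-level direction: the call that would annotate an edge for this
# (perturbation, gene) - earliest significant stimulation call, else earliest
# significant wash-out call.
gene_level_direction <- function(calls_one_gene) {
  sig <- calls_one_gene[calls_one_gene$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(NA_character_)
  }
  stim <- sig[sig$phase == "stimulation", , drop = FALSE]
  pick <- if (nrow(stim) > 0) stim else sig
  pick$direction[which.min(pick$time_h)]
}

#' Summarize a modulator's strength, sign and timing
#'
#' For each silencing experiment: *strength* is the number of distinct genes
#' with at least one significant call; *sign* is `"positive"` when more than
#' half of those genes are down-regulated by the silencing (gene-level
#' direction taken from the earliest significant stimulation-phase call),
#' `"negative"` when fewer than half, `"mixed"` at exactly half; *timing*
#' is the count of significant calls per time point and phase (a list
#' column).
#'
#' @param calls A `significance_calls` table.
#' @param perturbations Experiments to summarize; defaults to all present.
#' @return A tibble with one row per perturbation: `perturbation`,
#'   `strength`, `n_down`, `n_up`, `frac_down`, `sign`, `timing`.
#' @export
summarize_modulator <- function(calls, perturbations = NULL) {
  stopifnot(inherits(calls, "significance_calls"))
  perturbations <- perturbations %||% unique(calls$perturbation)
  purrr::map(perturbations, function(p) {
    sub <- calls |> filter(.data$perturbation == .env$p)
    sig <- sub |> filter(.data$significant)
    if (nrow(sig) == 0) {
      return(tibble(
        perturbation = p, strength = 0L, n_down = 0L, n_up = 0L,
        frac_down = NA_real_, sign = "mixed",
        timing = list(tibble(
          time_h = numeric(), phase = character(), n_significant = integer()
        ))
      ))
    }
    gene_dirs <- sig |>
      group_by(.data$gene) |>
      group_map(~ gene_level_direction(.x)) |>
      unlist()
    n_down <- sum(gene_dirs == "down")
    n_up <- sum(gene_dirs == "up")
    frac_down <- n_down / length(gene_dirs)
    timing <- as_tibble(as.data.frame(sig)) |>
      count(.data$time_h, .data$phase, name = "n_significant") |>
      arrange(.data$time_h)
    tibble(
      perturbation = p,
      strength = length(unique(sig$gene)),
      n_down = n_down, n_up = n_up, frac_down = frac_down,
      sign = if (frac_down > 0.5) "positive" else if (frac_down < 0.5) "negative" else "mixed",
      timing = list(timing)
    )
  }) |>
    bind_rows()
}

#' Write the calls table and the per-experiment summary
#'
#' @param calls A `significance_calls` table.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_selection_report <- function(calls, dir) {
  stopifnot(inherits(calls, "significance_calls"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  calls_path <- file.path(dir, "calls.csv")
  readr::write_csv(as_tibble(calls), calls_path, progress = FALSE)
  kd <- attr(calls, "knockdown_check")
  payload <- list(
    alpha = attr(calls, "alpha"),
    percentile = attr(calls, "percentile"),
    m_policy = attr(calls, "m_policy"),
    test_times = attr(calls, "test_times"),
    experiments = attr(calls, "experiments"),
    knockdown_check = kd
  )
  json_path <- file.path(dir, "selection.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(c(calls_path, json_path))
}
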