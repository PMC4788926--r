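#' Compute comparative-CT (ddCT) values against the calibrator condition
#'
#' Implements the comparative cycle-threshold method: per sample,
#' `dCT = CT_gene - CT_reference`; per perturbed condition,
#' `ddCT = dCT(knockdown) - dCT(control)`, matched within the same time
#' point. Positive ddCT means lower expression under the perturbation, and
#' relative expression is `fold_change = 2^(-mean ddCT)`.
#'
#' Two replicate-matching policies are available. `"replicate"` (default)
#' pairs knockdown replicate *i* with control replicate *i* at the same time
#' point, preserving K independent ddCT values per cell for downstream
#' variance estimation. `"mean_control"` subtracts the control-stratum mean
#' dCT instead.
#'
#' Any missing CT in a required term makes that replicate's ddCT missing and
#' reduces K; no imputation is performed. Cells ending with K = 0 are dropped
#' from the summary and counted in the `dropped` attribute.
#'
#' @param ct A [ct_table()].
#' @param reference Reference (housekeeping) gene used for normalization.
#' @param control_label Perturbation label of calibrator-siRNA samples.
#' @param pairing Replicate-matching policy, `"replicate"` or `"mean_control"`.
#' @return A tibble of class `ddct_table` with one row per
#'   (perturbation, gene, time_h): `mean_ddct`, `var_ddct` (sample variance,
#'   K-1 denominator, `NA` unless K >= 2), `K`, `fold_change`, `phase`.
#'   Per-replicate ddCT values are kept in attribute `replicates`.
#' @export
compute_ddct <- function(ct, reference, control_label = NULL,
                         pairing = c("replicate", "mean_control")) {
  stopifnot(inherits(ct, "ct_table"))
  pairing <- match.arg(pairing)
  control_label <- control_label %||% attr(ct, "control_label")
  genes <- attr(ct, "genes")
  if (!reference %in% genes) {
    abort_ffl(paste0("Reference gene '", reference, "' is not in the panel."), "argument")
  }

  x <- as_tibble(ct)
  ref <- x |>
    filter(.data$gene == reference) |>
    select("sample_id", ref_ct = "ct")

  # A sample with measurable genes but no reference CT cannot be normalized.
  bad_ref <- x |>
    left_join(ref, by = "sample_id") |>
    group_by(.data$sample_id) |>
    summarise(
      has_data = any(!is.na(.data$ct) & .data$gene != reference),
      ref_ok = any(!is.na(.data$ref_ct)),
      .groups = "drop"
    ) |>
    filter(.data$has_data, !.data$ref_ok)
  if (nrow(bad_ref) > 0) {
    abort_ffl(
      paste0(
        "Reference gene '", reference, "' is missing in sample(s) with data: ",
        paste(bad_ref$sample_id, collapse = ", ")
      ),
      "normalization"
    )
  }

  dct <- x |>
    left_join(ref, by = "sample_id") |>
    mutate(dct = .data$ct - .data$ref_ct) |>
    select("perturbation", "time_h", "phase", "replicate", "gene", "dct")

  kd <- dct |> filter(.data$perturbation != control_label)
  ctrl <- dct |> filter(.data$perturbation == control_label)
  if (nrow(kd) == 0) {
    abort_ffl("No perturbed (non-control) samples present.", "argument")
  }
  missing_strata <- setdiff(unique(kd$time_h), unique(ctrl$time_h))
  if (length(missing_strata) > 0) {
    abort_ffl(
      paste0(
        "No control samples at time point(s): ",
        paste(missing_strata, collapse = ", "), " h."
      ),
      "pairing"
    )
  }

  if (pairing == "replicate") {
    reps <- kd |>
      left_join(
        ctrl |> select("time_h", "replicate", "gene", ctrl_dct = "dct"),
        by = c("time_h", "replicate", "gene")
      ) |>
      mutate(ddct = .data$dct - .data$ctrl_dct)
  } else {
    reps <- kd |>
      left_join(
        ctrl |>
          group_by(.data$time_h, .data$gene) |>
          summarise(ctrl_dct = mean(.data$dct, na.rm = TRUE), .groups = "drop"),
        by = c("time_h", "gene")
      ) |>
      mutate(ddct = .data$dct - ifelse(is.nan(.data$ctrl_dct), NA_real_, .data$ctrl_dct))
  }

  reps <- reps |>
    select("perturbation", "gene", "time_h", "phase", "replicate", "ddct") |>
    arrange(
      match(.data$perturbation, unique(.data$perturbation)),
      match(.data$gene, genes), .data$time_h, .data$replicate
    )

  summary <- reps |>
    group_by(.data$perturbation, .data$gene, .data$time_h, .data$phase) |>
    summarise(
      K = sum(!is.na(.data$ddct)),
      mean_ddct = if (K >= 1) mean(.data$ddct, na.rm = TRUE) else NA_real_,
      var_ddct = if (K >= 2) var(.data$ddct, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(fold_change = 2^(-.data$mean_ddct)) |>
    select(
      "perturbation", "gene", "time_h", "phase",
      "mean_ddct", "var_ddct", "K", "fold_change"
    ) |>
    arrange(
      match(.data$perturbation, unique(.data$perturbation)),
      match(.data$gene, genes), .data$time_h
    )

  dropped <- summary |> filter(.data$K == 0)
  summary <- summary |> filter(.data$K >= 1)

  set_ffl_attrs(
    summary,
    list(
      replicates = reps,
      reference = reference,
      control_label = control_label,
      pairing = pairing,
      genes = genes,
      washout_after = attr(ct, "washout_after"),
      perturbations = unique(summary$perturbation),
      dropped = dropped
    ),
    class = "ddct_table"
  )
}

#' Build a ddCT table from per-replicate ddCT values
#'
#' The downstream stages (variance modelling, selection, inference) only
#' need replicate-level ddCT values, so data quantified outside this package
#' (or simulated directly on the ddCT scale) can enter the pipeline here.
#'
#' @param replicates A data frame with columns `perturbation`, `gene`,
#'   `time_h`, `replicate`, `ddct` (`NA` for missing replicates).
#' @param genes Gene-panel order; defaults to order of appearance.
#' @param washout_after Stimulus-removal time for phase derivation.
#' @return A `ddct_table` (see [compute_ddct()]).
#' @export
as_ddct_table <- function(replicates, genes = NULL, washout_after = 8) {
  required <- c("perturbation", "gene", "time_h", "replicate", "ddct")
  missing_cols <- setdiff(required, names(replicates))
  if (length(missing_cols) > 0) {
    abort_ffl(
      paste0("Missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  reps <- as_tibble(replicates)
  reps$phase <- phase_of_time(reps$time_h, washout_after)
  genes <- genes %||% unique(reps$gene)

  summary <- reps |>
    group_by(.data$perturbation, .data$gene, .data$time_h, .data$phase) |>
    summarise(
      K = sum(!is.na(.data$ddct)),
      mean_ddct = if (K >= 1) mean(.data$ddct, na.rm = TRUE) else NA_real_,
      var_ddct = if (K >= 2) var(.data$ddct, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(fold_change = 2^(-.data$mean_ddct)) |>
    select(
      "perturbation", "gene", "time_h", "phase",
      "mean_ddct", "var_ddct", "K", "fold_change"
    ) |>
    arrange(
      match(.data$perturbation, unique(.data$perturbation)),
      match(.data$gene, genes), .data$time_h
    )
  dropped <- summary |> filter(.data$K == 0)
  summary <- summary |> filter(.data$K >= 1)

  set_ffl_attrs(
    summary,
    list(
      replicates = reps,
      reference = NA_character_,
      control_label = NA_character_,
      pairing = "external",
      genes = genes,
      washout_after = washout_after,
      perturbations = unique(summary$perturbation),
      dropped = dropped
    ),
    class = "ddct_table"
  )
}

#' Write the canonical long-format ddCT summary table
#'
#' @param x A `ddct_table` from [compute_ddct()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ddct_table <- function(x, path) {
  stopifnot(inherits(x, "ddct_table"))
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @export
print.ddct_table <- function(x, ...) {
  cat(sprintf(
    "<ddct_table> %d cells, %d perturbation(s), reference = %s, pairing = %s\n",
    nrow(x), length(attr(x, "perturbations")),
    attr(x, "reference"), attr(x, "pairing")
  ))
  NextMethod()
}
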