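#' Construct a validated CT table
#'
#' A CT table holds one cycle-threshold (CT) measurement per (gene, sample)
#' from a qRT-PCR array card, in long format, together with the sample
#' metadata needed downstream: which gene was perturbed (or the calibrator
#' control), the sampling time, the experimental phase and the biological
#' replicate index. Missing amplifications ("Undetermined" wells) are stored
#' as `NA`.
#'
#' @param data A data frame with columns `sample_id`, `perturbation`,
#'   `time_h`, `replicate`, `gene`, `ct` and optionally `phase`. If `phase`
#'   is present it must agree with the schedule implied by `washout_after`;
#'   if absent it is derived.
#' @param genes Ordered character vector fixing the gene-panel order used for
#'   deterministic downstream ordering. Defaults to order of appearance.
#' @param housekeeping Character vector of candidate housekeeping genes
#'   (must be a subset of the panel).
#' @param ct_max Maximum admissible CT in cycles (instrument ceiling);
#'   values outside `[0, ct_max]` are rejected.
#' @param washout_after Stimulus-removal time passed to [phase_of_time()].
#' @param control_label Label identifying calibrator-siRNA samples in the
#'   `perturbation` column.
#' @return A tibble of class `ct_table` with attributes `genes`,
#'   `housekeeping`, `ct_max`, `washout_after`, `control_label`.
#' @seealso [read_ct_table()], [compute_ddct()], [select_reference_gene()]
#' @export
ct_table <- function(data, genes = NULL, housekeeping = character(),
                     ct_max = 40, washout_after = 8,
                     control_label = "CONTROL") {
  required <- c("sample_id", "perturbation", "time_h", "replicate", "gene", "ct")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_ffl(
      paste0("Missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  x <- as_tibble(data)
  x$ct <- suppressWarnings(as.numeric(x$ct))
  x$time_h <- as.numeric(x$time_h)
  x$replicate <- as.integer(x$replicate)
  x$sample_id <- as.character(x$sample_id)
  x$perturbation <- as.character(x$perturbation)
  x$gene <- as.character(x$gene)

  dup <- x |>
    count(.data$gene, .data$sample_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_ffl(
      paste0(
        "Duplicate (gene, sample) record(s), e.g. gene ", dup$gene[1],
        " in sample ", dup$sample_id[1], "."
      ),
      "duplicate"
    )
  }

  bad <- which(!is.na(x$ct) & (x$ct < 0 | x$ct > ct_max | !is.finite(x$ct)))
  if (length(bad) > 0) {
    abort_ffl(
      sprintf(
        "CT value %.3f outside [0, %g] for gene %s, sample %s.",
        x$ct[bad[1]], ct_max, x$gene[bad[1]], x$sample_id[bad[1]]
      ),
      "range"
    )
  }

  expected_phase <- phase_of_time(x$time_h, washout_after)
  if ("phase" %in% names(x)) {
    mismatch <- which(as.character(x$phase) != expected_phase)
    if (length(mismatch) > 0) {
      abort_ffl(
        sprintf(
          "Declared phase '%s' at %g h conflicts with the schedule (expected '%s').",
          x$phase[mismatch[1]], x$time_h[mismatch[1]], expected_phase[mismatch[1]]
        ),
        "schema"
      )
    }
  }
  x$phase <- expected_phase

  # A replicate index must identify a single sample within its stratum.
  amb <- x |>
    distinct(.data$sample_id, .data$perturbation, .data$time_h, .data$replicate) |>
    count(.data$perturbation, .data$time_h, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(amb) > 0) {
    abort_ffl(
      sprintf(
        "Replicate index %d is used by %d different samples in stratum (%s, %g h).",
        amb$replicate[1], amb$n[1], amb$perturbation[1], amb$time_h[1]
      ),
      "duplicate"
    )
  }

  genes <- genes %||% unique(x$gene)
  if (!all(x$gene %in% genes)) {
    abort_ffl("`genes` must cover every gene present in the data.", "argument")
  }
  if (!all(housekeeping %in% genes)) {
    abort_ffl("`housekeeping` genes must be part of the gene panel.", "argument")
  }

  x <- x |>
    select("sample_id", "perturbation", "time_h", "phase", "replicate", "gene", "ct") |>
    arrange(
      match(.data$perturbation, unique(.data$perturbation)),
      .data$time_h, .data$replicate, match(.data$gene, genes)
    )
  set_ffl_attrs(
    x,
    list(
      genes = genes, housekeeping = housekeeping, ct_max = ct_max,
      washout_after = washout_after, control_label = control_label
    ),
    class = "ct_table"
  )
}

#' Read a CT plate table from disk
#'
#' Reads a CSV/TSV export of cycle-threshold values in either the long
#' dialect (one row per (gene, sample) with metadata columns) or the wide
#' dialect (genes x samples matrix plus a separate metadata sheet).
#' Non-numeric CT entries such as `"Undetermined"` become `NA`.
#'
#' @param path Path to the CT file.
#' @param format `"long"` (default) or `"wide"`.
#' @param metadata For `format = "wide"`, path to the sample-metadata table
#'   with columns `sample_id`, `perturbation`, `time_h`, `replicate`
#'   (and optionally `phase`).
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @inheritParams ct_table
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, format = c("long", "wide"), metadata = NULL,
                          delim = NULL, genes = NULL, housekeeping = character(),
                          ct_max = 40, washout_after = 8,
                          control_label = "CONTROL") {
  format <- match.arg(format)
  if (!file.exists(path)) abort_ffl(paste0("File not found: ", path), "argument")
  delim <- delim %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)

  if (format == "long") {
    long <- raw
  } else {
    if (is.null(metadata)) {
      abort_ffl("Wide format requires a `metadata` table of samples.", "schema")
    }
    if (!"gene" %in% names(raw)) {
      abort_ffl("Missing mandatory column(s): gene", "schema")
    }
    meta_delim <- if (grepl("\\.(tsv|txt)$", metadata, ignore.case = TRUE)) "\t" else ","
    meta <- readr::read_delim(metadata, delim = meta_delim,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE, show_col_types = FALSE)
    meta_required <- c("sample_id", "perturbation", "time_h", "replicate")
    missing_meta <- setdiff(meta_required, names(meta))
    if (length(missing_meta) > 0) {
      abort_ffl(
        paste0("Missing mandatory column(s): ", paste(missing_meta, collapse = ", ")),
        "schema"
      )
    }
    long <- raw |>
      pivot_longer(-"gene", names_to = "sample_id", values_to = "ct") |>
      inner_join(meta, by = "sample_id")
    if (nrow(long) == 0) {
      abort_ffl("No sample columns of the wide table match the metadata.", "schema")
    }
  }

  ct_table(long,
    genes = genes, housekeeping = housekeeping, ct_max = ct_max,
    washout_after = washout_after, control_label = control_label
  )
}

#' Write a CT table in the canonical long dialect
#'
#' @param x A [ct_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Select the reference (housekeeping) gene
#'
#' Scores each candidate housekeeping gene by the pooled standard deviation
#' of its raw CT across all samples and conditions; the most stable gene
#' (smallest SD) is selected, with ties broken by candidate order.
#'
#' @param ct A [ct_table()].
#' @param candidates Character vector of candidate genes; defaults to the
#'   table's housekeeping set.
#' @return A tibble with one row per candidate: `gene`, `sd_ct`, `n_obs`,
#'   `selected`, in candidate order, with the chosen gene in attribute
#'   `reference`.
#' @export
select_reference_gene <- function(ct, candidates = NULL) {
  stopifnot(inherits(ct, "ct_table"))
  candidates <- candidates %||% attr(ct, "housekeeping")
  if (length(candidates) == 0) {
    abort_ffl("No reference-gene candidates supplied.", "argument")
  }
  if (!all(candidates %in% attr(ct, "genes"))) {
    abort_ffl("All candidates must be in the gene panel.", "argument")
  }
  scores <- tibble(gene = candidates) |>
    left_join(
      as_tibble(ct) |>
        filter(.data$gene %in% candidates) |>
        group_by(.data$gene) |>
        summarise(
          sd_ct = sd(.data$ct, na.rm = TRUE),
          n_obs = sum(!is.na(.data$ct)),
          .groups = "drop"
        ),
      by = "gene"
    ) |>
    mutate(n_obs = replace_na(.data$n_obs, 0L))
  low <- scores |> filter(.data$n_obs < 2)
  if (nrow(low) > 0) {
    abort_ffl(
      paste0(
        "Candidate(s) with fewer than 2 CT observations: ",
        paste(low$gene, collapse = ", ")
      ),
      "insufficient_data"
    )
  }
  best <- which.min(scores$sd_ct) # first minimum = candidate-order tie-break
  scores$selected <- seq_len(nrow(scores)) == best
  attr(scores, "reference") <- scores$gene[best]
  scores
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf(
    "<ct_table> %d genes x %d samples (%d housekeeping candidates, ct_max = %g)\n",
    length(attr(x, "genes")), length(unique(x$sample_id)),
    length(attr(x, "housekeeping")), attr(x, "ct_max")
  ))
  NextMethod()
}
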