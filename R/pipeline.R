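#' Assemble and validate a pipeline configuration
#'
#' Collects every setting of the end-to-end analysis: input location and
#' dialect, reference-gene candidates, control label, error-model settings,
#' selection settings, inference settings and output directory. Either an
#' `input` CT table (with optional `metadata` for the wide dialect) or a
#' `simulate` [screen_config()] must be given.
#'
#' @param input Path to a CT table (CSV/TSV), or `NULL` to simulate.
#' @param format Input dialect, `"long"` or `"wide"`.
#' @param metadata Metadata path for the wide dialect.
#' @param simulate A [screen_config()] to generate the input instead.
#' @param outdir Output directory for all artifacts.
#' @param reference Reference gene; when `NULL` it is selected from
#'   `candidates` by [select_reference_gene()].
#' @param candidates Reference-gene candidates (defaults to the input's
#'   housekeeping set).
#' @param housekeeping Housekeeping genes of a file-based input.
#' @param control_label Calibrator condition label.
#' @param pairing Replicate-matching policy for [compute_ddct()].
#' @param variants Error-model variants to compare.
#' @param n_bins,min_bin_size Binning settings for the variance fit.
#' @param cv_max Precision screen for model selection.
#' @param alpha Significance cutoff on adjusted p-values.
#' @param percentile Variance-filter percentile.
#' @param test_times Time points to test (`NULL` = all but 0 h).
#' @param m_policy Bonferroni m policy.
#' @param seed Seed used when simulating.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, format = "long", metadata = NULL,
                            simulate = NULL, outdir = tempfile("fflscreen_run_"),
                            reference = NULL, candidates = NULL,
                            housekeeping = character(),
                            control_label = "CONTROL",
                            pairing = "replicate",
                            variants = c("constant", "linear", "power"),
                            n_bins = 10, min_bin_size = 3, cv_max = 0.5,
                            alpha = 0.05, percentile = 95,
                            test_times = NULL, m_policy = "post_filter",
                            seed = 1L) {
  if (is.null(input) && is.null(simulate)) {
    abort_ffl("Either `input` or `simulate` must be provided.", "validation")
  }
  if (!is.null(input) && !file.exists(input)) {
    abort_ffl(paste0("Input file not found: ", input), "validation")
  }
  if (!is.null(metadata) && !file.exists(metadata)) {
    abort_ffl(paste0("Metadata file not found: ", metadata), "validation")
  }
  if (!is.null(simulate) && !inherits(simulate, "screen_config")) {
    abort_ffl("`simulate` must be a screen_config object.", "validation")
  }
  if (alpha <= 0 || alpha >= 1) abort_ffl("`alpha` must be in (0, 1).", "validation")
  if (percentile <= 0 || percentile >= 100) {
    abort_ffl("`percentile` must be in (0, 100).", "validation")
  }
  structure(
    list(
      input = input, format = format, metadata = metadata, simulate = simulate,
      outdir = outdir, reference = reference, candidates = candidates,
      housekeeping = housekeeping, control_label = control_label,
      pairing = pairing, variants = variants, n_bins = n_bins,
      min_bin_size = min_bin_size, cv_max = cv_max, alpha = alpha,
      percentile = percentile, test_times = test_times, m_policy = m_policy,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; a `simulate` block is passed to [screen_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_ffl(paste0("Config not found: ", path), "validation")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    effects <- sim$effects
    sim$effects <- NULL
    cfg <- do.call(screen_config, sim)
    for (e in effects %||% list()) {
      cfg <- add_effect(cfg, e$source, e$target, e$shift,
                        times = unlist(e$times %||% c(2, 8)))
    }
    raw$simulate <- cfg
  }
  do.call(pipeline_config, raw)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_ffl(
      paste0("Stage '", stage, "' failed: ", conditionMessage(e)),
      "stage", stage = stage, parent = e
    )
  })
}

#' Run the full analysis pipeline
#'
#' Executes read (or simulate) -> reference-gene selection -> ddCT ->
#' variance-model fit -> significance selection -> module inference, and
#' writes all artifacts to `config$outdir`: the canonical CT and ddCT
#' tables, the error-model report and bin table, the calls table and
#' selection summary, the module report and SIF/GraphML/DOT exports, the
#' heatmap matrix, and a run manifest with settings and md5 content hashes
#' (so identical inputs reproduce identical hashes).
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Invisibly, a list of class `ffl_pipeline` with elements `ct`,
#'   `reference`, `ddct`, `model`, `calls`, `modules`, `summary`,
#'   `manifest`, `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(outdir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  result <- tryCatch(
    {
      ct <- run_stage("input", {
        if (!is.null(config$input)) {
          read_ct_table(
            config$input,
            format = config$format, metadata = config$metadata,
            housekeeping = config$housekeeping,
            control_label = config$control_label
          )
        } else {
          screen <- generate_screen(config$simulate, seed = config$seed)
          write_module_report(
            screen$truth$modules, file.path(outdir, "truth_modules.json")
          )
          readr::write_csv(screen$truth$effects,
                           file.path(outdir, "truth_effects.csv"), progress = FALSE)
          screen$ct
        }
      })
      write_ct_table(ct, file.path(outdir, "ct_table.csv"))

      ref_scores <- NULL
      reference <- config$reference
      if (is.null(reference)) {
        ref_scores <- run_stage(
          "reference",
          select_reference_gene(ct, config$candidates)
        )
        reference <- attr(ref_scores, "reference")
        readr::write_csv(ref_scores, file.path(outdir, "reference_scores.csv"),
                         progress = FALSE)
      }

      ddct <- run_stage("ddct", compute_ddct(
        ct, reference,
        control_label = config$control_label, pairing = config$pairing
      ))
      write_ddct_table(ddct, file.path(outdir, "ddct_table.csv"))

      model <- run_stage("error_model", fit_ddct_error_model(
        ddct,
        variants = config$variants, n_bins = config$n_bins,
        min_bin_size = config$min_bin_size, cv_max = config$cv_max
      ))
      write_error_model_report(model, outdir)

      calls <- run_stage("selection", run_selection(
        ddct, model,
        alpha = config$alpha, percentile = config$percentile,
        test_times = config$test_times, m_policy = config$m_policy
      ))
      write_selection_report(calls, outdir)
      readr::write_csv(make_heatmap_table(calls),
                       file.path(outdir, "heatmap.csv"), progress = FALSE)

      modules <- run_stage("inference", infer_modules(calls))
      write_module_report(modules, file.path(outdir, "modules.json"))
      write_sif(modules, file.path(outdir, "modules.sif"))
      write_graphml(modules, file.path(outdir, "modules.graphml"))
      write_dot(modules, file.path(outdir, "modules.dot"))

      summary <- summarize_modulator(calls)

      manifest <- build_manifest(outdir, config, reference, modules)
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)

      structure(
        list(
          ct = ct, reference = reference, reference_scores = ref_scores,
          ddct = ddct, model = model, calls = calls, modules = modules,
          summary = summary, manifest = manifest, outdir = outdir
        ),
        class = "ffl_pipeline"
      )
    },
    error = function(e) {
      # Retain partial artifacts alongside an explicit failure marker.
      writeLines(conditionMessage(e), fail_marker)
      rlang::cnd_signal(e)
    }
  )
  invisible(result)
}

build_manifest <- function(outdir, config, reference, modules) {
  files <- sort(setdiff(list.files(outdir), c("manifest.json", "FAILED")))
  hashes <- as.vector(tools::md5sum(file.path(outdir, files)))
  list(
    package = "fflscreen",
    version = as.character(utils::packageVersion("fflscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    settings = list(
      input = config$input %||% "simulated",
      reference = reference,
      control_label = config$control_label,
      pairing = config$pairing,
      variants = config$variants,
      n_bins = config$n_bins,
      alpha = config$alpha,
      percentile = config$percentile,
      m_policy = config$m_policy
    ),
    n_modules = length(modules),
    artifacts = purrr::map2(files, hashes, ~ list(file = .x, md5 = .y))
  )
}

#' @export
print.ffl_pipeline <- function(x, ...) {
  cat("<ffl_pipeline>\n")
  cat(sprintf("  reference gene: %s\n", x$reference))
  cat(sprintf("  error model:    %s (WRSS %.4g)\n", x$model$variant, x$model$wrss))
  cat(sprintf(
    "  significant:    %d call(s) across %d experiment(s)\n",
    sum(x$calls$significant), nrow(attr(x$calls, "experiments"))
  ))
  cat(sprintf("  modules:        %d\n", length(x$modules)))
  cat(sprintf("  artifacts in:   %s\n", x$outdir))
  invisible(x)
}
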