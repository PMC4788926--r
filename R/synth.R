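#' Configure a synthetic perturbation screen
#'
#' Describes a qRT-PCR knockdown screen to simulate: a 96-gene array card
#' (including candidate housekeeping genes), short time series spanning
#' stimulation and wash-out phases, K biological replicates, calibrator
#' (control) plus knockdown conditions, and replicate noise drawn from the
#' variance family `sigma^2 = alpha + beta * |ddCT|^gamma`. Regulations are
#' planted as ddCT shifts via [add_effect()] or [plant_ffl()].
#'
#' @param n_genes Total panel size, housekeeping genes included.
#' @param n_housekeeping Number of candidate housekeeping genes.
#' @param perturbed Perturbed (silenced) genes; defaults to the first two
#'   panel genes. Must not be housekeeping genes.
#' @param time_points_h Sampling times in hours.
#' @param washout_after Stimulus-removal time; later samples are wash-out.
#' @param K Biological replicates per condition.
#' @param noise List with `alpha`, `beta`, `gamma` of the ddCT variance
#'   model; the default is constant variance 0.3975 cycles^2.
#' @param baseline_ct Range of per-gene mean CT (cycles).
#' @param hk_noise_sd Raw-CT noise SD of housekeeping genes (0 keeps the
#'   reference free of noise so the planted ddCT variance is exact).
#' @param gene_names Optional explicit panel names (non-housekeeping).
#' @param control_label Calibrator condition label.
#' @param seed Default seed used by [generate_screen()].
#' @return A `screen_config` object.
#' @export
screen_config <- function(n_genes = 96, n_housekeeping = 3, perturbed = NULL,
                          time_points_h = c(0, 2, 8, 12), washout_after = 8,
                          K = 2,
                          noise = list(alpha = 0.3975, beta = 0, gamma = 1),
                          baseline_ct = c(22, 30), hk_noise_sd = 0,
                          gene_names = NULL, control_label = "CONTROL",
                          seed = 1L) {
  if (n_genes < 2 || n_housekeeping < 1 || n_genes <= n_housekeeping) {
    abort_ffl("Need at least one housekeeping and one target gene.", "argument")
  }
  if (K < 1) abort_ffl("K must be a positive replicate count.", "argument")
  n_targets <- n_genes - n_housekeeping
  targets <- gene_names %||% sprintf("G%03d", seq_len(n_targets))
  if (length(targets) != n_targets) {
    abort_ffl("`gene_names` must name every non-housekeeping gene.", "argument")
  }
  hk <- sprintf("HK%d", seq_len(n_housekeeping))
  genes <- c(targets, hk)
  perturbed <- perturbed %||% targets[seq_len(min(2, n_targets))]
  if (!all(perturbed %in% targets)) {
    abort_ffl("Perturbed genes must be non-housekeeping panel genes.", "argument")
  }
  noise <- utils::modifyList(list(alpha = 0.3975, beta = 0, gamma = 1), noise)
  if (noise$alpha < 0 || noise$beta < 0 || noise$gamma < 0) {
    abort_ffl("Noise parameters must be non-negative.", "argument")
  }
  structure(
    list(
      genes = genes, housekeeping = hk, perturbed = perturbed,
      time_points_h = sort(unique(time_points_h)),
      washout_after = washout_after, K = as.integer(K),
      noise = noise, baseline_ct = baseline_ct, hk_noise_sd = hk_noise_sd,
      control_label = control_label, seed = seed,
      effects = tibble(
        source = character(), target = character(),
        shift = numeric(), time_h = numeric()
      )
    ),
    class = "screen_config"
  )
}

#' Plant a regulation effect
#'
#' Adds a ddCT shift for `target` in the silencing experiment of `source` at
#' the given time points. A positive shift raises CT under knockdown, i.e.
#' the target is down-regulated when the source is silenced (the source
#' activates the target); a negative shift encodes repression.
#'
#' @param config A `screen_config`.
#' @param source Perturbed gene whose silencing causes the effect.
#' @param target Affected gene (may equal `source` to emulate the knockdown
#'   of the silenced gene itself).
#' @param shift ddCT shift in cycles.
#' @param times Active time points (hours).
#' @return The updated `screen_config`.
#' @export
add_effect <- function(config, source, target, shift, times = c(2, 8)) {
  stopifnot(inherits(config, "screen_config"))
  if (!source %in% config$perturbed) {
    abort_ffl(paste0("`source` ('", source, "') must be a perturbed gene."), "argument")
  }
  if (!target %in% config$genes) {
    abort_ffl(paste0("`target` ('", target, "') is not in the panel."), "argument")
  }
  if (target %in% config$housekeeping) {
    abort_ffl("Housekeeping genes cannot receive planted effects.", "argument")
  }
  if (!all(times %in% config$time_points_h)) {
    abort_ffl("Effect times must be sampling time points.", "argument")
  }
  config$effects <- bind_rows(
    config$effects,
    tibble(source = source, target = target, shift = shift, time_h = times)
  ) |>
    distinct(.data$source, .data$target, .data$time_h, .keep_all = TRUE)
  config
}

#' Plant a multi-output feed-forward loop
#'
#' Adds effects so that the noiseless pipeline recovers exactly the
#' specified module: `x` regulates `y`, and both regulate every target with
#' the given signs. Activation is encoded as a positive ddCT shift
#' (silencing the regulator lowers the target's expression).
#'
#' @param config A `screen_config`.
#' @param x,y Upstream and downstream perturbed regulators.
#' @param targets Common target genes (must not be perturbed genes).
#' @param sign_xy Sign of the x -> y edge, `"activation"` or `"repression"`.
#' @param signs_x,signs_y Signs of x -> target and y -> target edges;
#'   recycled, default all activation.
#' @param shift Absolute ddCT shift in cycles for every planted edge.
#' @param times Active (stimulation) time points.
#' @return The updated `screen_config`.
#' @export
plant_ffl <- function(config, x, y, targets = character(),
                      sign_xy = "activation",
                      signs_x = "activation", signs_y = "activation",
                      shift = 3, times = c(2, 8)) {
  stopifnot(inherits(config, "screen_config"))
  if (!all(c(x, y) %in% config$perturbed)) {
    abort_ffl("Both regulators must be perturbed genes.", "argument")
  }
  if (any(targets %in% config$perturbed)) {
    abort_ffl("FFL targets must not overlap the perturbed set.", "argument")
  }
  signed <- function(sign) ifelse(sign == "repression", -shift, shift)
  signs_x <- rep(signs_x, length.out = length(targets))
  signs_y <- rep(signs_y, length.out = length(targets))
  config <- add_effect(config, x, y, signed(sign_xy), times)
  for (i in seq_along(targets)) {
    config <- add_effect(config, x, targets[i], signed(signs_x[i]), times)
    config <- add_effect(config, y, targets[i], signed(signs_y[i]), times)
  }
  config
}

#' Generate a synthetic screen with known ground truth
#'
#' Builds raw CT values so that, after comparative-CT processing against the
#' first housekeeping gene, the true mean ddCT of every cell equals its
#' planted shift (0 where unplanted) and the replicate ddCT noise has
#' variance `alpha + beta * |shift|^gamma`. The per-cell ddCT variance is
#' realized on the two target-gene CT terms: the control CT carries noise
#' variance `v0 / 2` (`v0` = model variance at shift 0) and the knockdown CT
#' carries `v(shift) - v0 / 2`; housekeeping CT noise is a separate knob
#' (default 0). Control and knockdown samples are emitted for every time
#' point and replicate, and output is byte-identical for identical
#' (config, seed).
#'
#' @param config A `screen_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `synthetic_screen`: `ct` (a [ct_table()]),
#'   `truth` (planted `effects`, the noiseless `calls` table at post-baseline
#'   time points, and the implied `modules`), and `config`.
#' @export
generate_screen <- function(config, seed = NULL) {
  stopifnot(inherits(config, "screen_config"))
  seed <- seed %||% config$seed
  set.seed(seed)

  genes <- config$genes
  hk <- config$housekeeping
  conditions <- c(config$control_label, config$perturbed)
  noise <- config$noise
  v0 <- noise$alpha # beta * 0^gamma = 0 for gamma > 0
  if (noise$gamma == 0) v0 <- noise$alpha + noise$beta

  baseline <- tibble(
    gene = genes,
    baseline_ct = runif(length(genes), config$baseline_ct[1], config$baseline_ct[2])
  )

  grid <- expand_grid(
    perturbation = conditions,
    time_h = config$time_points_h,
    replicate = seq_len(config$K),
    gene = genes
  ) |>
    left_join(baseline, by = "gene") |>
    left_join(
      config$effects |> rename(perturbation = "source", gene = "target"),
      by = c("perturbation", "gene", "time_h")
    ) |>
    mutate(shift = replace_na(.data$shift, 0))

  is_control <- grid$perturbation == config$control_label
  is_hk <- grid$gene %in% hk
  v_cell <- noise$alpha + noise$beta * abs(grid$shift)^noise$gamma
  sd_ct <- ifelse(
    is_hk, config$hk_noise_sd,
    ifelse(is_control, sqrt(v0 / 2), sqrt(pmax(v_cell - v0 / 2, 0)))
  )
  grid$ct <- grid$baseline_ct +
    ifelse(is_control, 0, grid$shift) +
    rnorm(nrow(grid), 0, sd_ct)

  samples <- grid |>
    mutate(sample_id = sprintf(
      "%s_t%g_r%d", .data$perturbation, .data$time_h, .data$replicate
    )) |>
    select("sample_id", "perturbation", "time_h", "replicate", "gene", "ct")

  ct <- ct_table(
    samples,
    genes = genes, housekeeping = hk, ct_max = 40,
    washout_after = config$washout_after,
    control_label = config$control_label
  )

  truth_calls <- noiseless_calls(config)
  truth_modules <- infer_modules(truth_calls, config$perturbed)

  structure(
    list(
      ct = ct,
      truth = list(
        effects = config$effects,
        calls = truth_calls,
        modules = truth_modules
      ),
      config = config
    ),
    class = "synthetic_screen"
  )
}

# The call matrix an ideal noiseless analysis would produce at the tested
# (post-baseline) time points: every planted shift is significant with the
# direction implied by its sign.
noiseless_calls <- function(config) {
  tested <- setdiff(config$time_points_h, 0)
  eff <- config$effects |>
    filter(.data$time_h %in% tested, .data$source != .data$target)
  calls <- tibble(
    perturbation = eff$source,
    gene = eff$target,
    time_h = eff$time_h,
    significant = eff$shift != 0,
    direction = ifelse(eff$shift > 0, "down", ifelse(eff$shift < 0, "up", "none")),
    mean_ddct = eff$shift,
    fold_change = 2^(-eff$shift),
    p_adj = ifelse(eff$shift != 0, 0, 1)
  )
  as_significance_calls(
    calls,
    genes = config$genes, washout_after = config$washout_after
  )
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(
    "<synthetic_screen> %d genes, %d perturbation(s) + control, %d time points, K = %d\n",
    length(x$config$genes), length(x$config$perturbed),
    length(x$config$time_points_h), x$config$K
  ))
  cat(sprintf(
    "  %d planted effect cell(s), %d true module(s)\n",
    nrow(x$config$effects), length(x$truth$modules)
  ))
  invisible(x)
}
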