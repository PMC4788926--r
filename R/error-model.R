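#' Collect per-cell replicate statistics for variance modelling
#'
#' Pools the (|mean ddCT|, replicate sample variance, K) records across the
#' requested silencing experiments. Only cells with at least two replicates
#' contribute (the sample variance needs K >= 2); excluded cells are counted
#' in the `diagnostics` attribute.
#'
#' @param ddct A `ddct_table` from [compute_ddct()].
#' @param perturbations Silencing experiments to pool; defaults to all.
#' @return A tibble with columns `perturbation`, `gene`, `time_h`,
#'   `abs_mean_ddct`, `var_ddct`, `K`.
#' @export
collect_replicate_stats <- function(ddct, perturbations = NULL) {
  stopifnot(inherits(ddct, "ddct_table"))
  perturbations <- perturbations %||% attr(ddct, "perturbations")
  x <- as_tibble(ddct) |> filter(.data$perturbation %in% perturbations)
  usable <- x |> filter(.data$K >= 2, !is.na(.data$var_ddct))
  if (nrow(usable) == 0) {
    abort_ffl(
      "No cell has K >= 2 replicates; cannot estimate the ddCT variance.",
      "insufficient_replication"
    )
  }
  out <- usable |>
    transmute(
      .data$perturbation, .data$gene, .data$time_h,
      abs_mean_ddct = abs(.data$mean_ddct),
      var_ddct = .data$var_ddct, K = .data$K
    )
  attr(out, "diagnostics") <- list(
    n_used = nrow(out),
    n_excluded_low_K = nrow(x) - nrow(usable)
  )
  out
}

#' Bin replicate variances by absolute ddCT intensity
#'
#' Records are sorted by `abs_mean_ddct` and split into `n_bins` equal-count
#' bins (any remainder goes to the leftmost bins); per bin, the mean absolute
#' ddCT and the mean replicate variance are returned. These binned averages
#' are the observations to which the variance model is fitted.
#'
#' @param stats Output of [collect_replicate_stats()].
#' @param n_bins Number of bins.
#' @param min_bin_size Minimum records per bin.
#' @return A tibble of class `binned_variance` with columns `bin`,
#'   `mean_abs_ddct`, `mean_var`, `n`.
#' @export
bin_variances <- function(stats, n_bins = 10, min_bin_size = 3) {
  if (n_bins < 1 || min_bin_size < 1) {
    abort_ffl("`n_bins` and `min_bin_size` must be positive.", "argument")
  }
  n <- nrow(stats)
  if (n < n_bins * min_bin_size) {
    abort_ffl(
      sprintf(
        "Only %d records for %d bins of >= %d; reduce `n_bins`.",
        n, n_bins, min_bin_size
      ),
      "binning"
    )
  }
  ord <- stats |> arrange(.data$abs_mean_ddct)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  ord$bin <- rep(seq_len(n_bins), times = sizes)
  out <- ord |>
    group_by(.data$bin) |>
    summarise(
      mean_abs_ddct = mean(.data$abs_mean_ddct),
      mean_var = mean(.data$var_ddct),
      n = n(),
      .groups = "drop"
    )
  class(out) <- c("binned_variance", class(out))
  out
}

free_params <- function(variant) {
  switch(variant,
    constant = "alpha",
    linear = c("alpha", "beta"),
    power = c("alpha", "beta", "gamma"),
    full = c("alpha", "beta", "gamma")
  )
}

new_error_model <- function(variant, coef, se, wrss, n_points, converged,
                            degraded = FALSE, message = NULL, bins = NULL) {
  structure(
    list(
      variant = variant,
      coef = coef, se = se, wrss = wrss, n_points = n_points,
      free = free_params(variant),
      converged = converged, degraded = degraded, message = message,
      bins = bins
    ),
    class = "ddct_error_model"
  )
}

#' Fit the ddCT variance model on binned data
#'
#' Fits `sigma^2(x) = alpha + beta * |x|^gamma` to the binned (mean |ddCT|,
#' mean variance) observations by weighted least squares with weights equal
#' to the bin counts. Variants of the family: `"constant"` (beta = 0; alpha
#' is the count-weighted mean of the bin variances, in closed form),
#' `"linear"` (gamma fixed at 1), and `"power"` (gamma free in `[0, 4]`);
#' `"full"` is accepted as a synonym of `"power"` (all three parameters
#' free). Nonlinear variants use bounded Levenberg-Marquardt least squares
#' with `alpha, beta >= 0` so the predicted variance is non-negative and
#' non-decreasing in |ddCT|.
#'
#' @param binned A `binned_variance` from [bin_variances()], or any data
#'   frame with columns `mean_abs_ddct`, `mean_var`, `n`.
#' @param variant One of `"constant"`, `"linear"`, `"power"`, `"full"`.
#' @param gamma_max Upper bound for the exponent.
#' @return A `ddct_error_model` object: parameter estimates, asymptotic
#'   standard errors of the free parameters, the weighted residual sum of
#'   squares (WRSS), and convergence flags. Supports [predict_variance()],
#'   [tidy()], [glance()] and [autoplot()].
#' @export
fit_error_model <- function(binned, variant = c("constant", "linear", "power", "full"),
                            gamma_max = 4) {
  variant <- match.arg(variant)
  b <- as_tibble(binned)
  stopifnot(all(c("mean_abs_ddct", "mean_var", "n") %in% names(b)))
  if (any(b$mean_var < 0)) {
    abort_ffl("Negative bin variances are not admissible.", "data")
  }
  n_free <- length(free_params(variant))
  if (nrow(b) < n_free + 1) {
    abort_ffl(
      sprintf("Need at least %d bins to fit the %s variant.", n_free + 1, variant),
      "binning"
    )
  }
  w <- as.numeric(b$n)
  x <- b$mean_abs_ddct
  y <- b$mean_var

  if (variant == "constant") {
    alpha <- sum(w * y) / sum(w)
    wrss <- sum(w * (y - alpha)^2)
    s2 <- if (nrow(b) > 1) wrss / (nrow(b) - 1) else 0
    se <- c(alpha = sqrt(s2 / sum(w)))
    return(new_error_model(
      variant,
      coef = c(alpha = alpha, beta = 0, gamma = 0),
      se = se, wrss = wrss, n_points = nrow(b), converged = TRUE, bins = b
    ))
  }

  spread <- max(y) - min(y)
  xmax <- max(x, 1e-6)
  start <- list(
    alpha = max(min(y), 1e-4),
    beta = max(spread / xmax, 1e-4)
  )
  if (variant == "linear") {
    formula <- y ~ alpha + beta * x
    lower <- c(alpha = 0, beta = 0)
    upper <- c(alpha = Inf, beta = Inf)
  } else {
    formula <- y ~ alpha + beta * x^gamma
    start$gamma <- 1
    lower <- c(alpha = 0, beta = 0, gamma = 0)
    upper <- c(alpha = Inf, beta = Inf, gamma = gamma_max)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      formula,
      data = data.frame(x = x, y = y),
      start = start, lower = lower, upper = upper, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_error_model(
      variant,
      coef = c(alpha = NA_real_, beta = NA_real_, gamma = NA_real_),
      se = setNames(rep(NA_real_, n_free), free_params(variant)),
      wrss = NA_real_, n_points = nrow(b),
      converged = FALSE, message = conditionMessage(fit), bins = b
    ))
  }

  est <- coef(fit)
  co <- c(
    alpha = unname(est["alpha"]),
    beta = unname(est["beta"]),
    gamma = if (variant == "linear") 1 else unname(est["gamma"])
  )
  se <- tryCatch(
    summary(fit)$coefficients[, "Std. Error"],
    error = function(e) setNames(rep(NA_real_, length(est)), names(est))
  )
  wrss <- sum(w * (y - (co["alpha"] + co["beta"] * x^co["gamma"]))^2)
  new_error_model(
    variant,
    coef = co, se = se[free_params(variant)][seq_along(free_params(variant))],
    wrss = wrss, n_points = nrow(b),
    converged = isTRUE(fit$convInfo$isConv), bins = b
  )
}

#' Select the best variance-model variant
#'
#' Operationalizes "best fit in terms of WRSS and precision of the parameter
#' estimates": among converged fits whose every free parameter has a
#' coefficient of variation (`se / |estimate|`) at most `cv_max`, the fit
#' with the smallest WRSS wins; ties go to the variant with fewer free
#' parameters. If no fit passes the precision screen, the converged fit with
#' the fewest free parameters is returned with `degraded = TRUE`.
#'
#' @param fits A list of `ddct_error_model` objects.
#' @param cv_max Maximum admissible coefficient of variation per parameter.
#' @return The selected `ddct_error_model`.
#' @export
select_error_model <- function(fits, cv_max = 0.5) {
  if (inherits(fits, "ddct_error_model")) fits <- list(fits)
  if (length(fits) == 0) abort_ffl("No fits supplied.", "argument")
  conv <- purrr::keep(fits, ~ isTRUE(.x$converged))
  if (length(conv) == 0) abort_ffl("No converged fit available.", "argument")

  cv_ok <- purrr::map_lgl(conv, function(f) {
    est <- f$coef[f$free]
    se <- f$se[f$free]
    cv <- ifelse(se == 0, 0, se / abs(est)) # exact fits (se = 0) always pass
    all(is.finite(cv)) && all(cv <= cv_max)
  })
  pool <- if (any(cv_ok)) conv[cv_ok] else conv
  wrss <- purrr::map_dbl(pool, "wrss")
  nf <- purrr::map_dbl(pool, ~ length(.x$free))
  if (any(cv_ok)) {
    near <- wrss <= min(wrss) * (1 + 1e-9) + 1e-15
    idx <- which(near)[which.min(nf[near])]
    out <- pool[[idx]]
    out$degraded <- FALSE
  } else {
    idx <- which(nf == min(nf))[which.min(wrss[nf == min(nf)])]
    out <- pool[[idx]]
    out$degraded <- TRUE
  }
  out
}

#' Predict the biological variance of ddCT
#'
#' Evaluates the fitted variance surface `alpha + beta * |ddct|^gamma`.
#' For the constant variant this is `alpha` for every input.
#'
#' @param model A converged `ddct_error_model`.
#' @param ddct Numeric vector of ddCT values (sign is immaterial).
#' @return Numeric vector of predicted variances (cycles^2).
#' @export
predict_variance <- function(model, ddct) {
  stopifnot(inherits(model, "ddct_error_model"))
  if (!isTRUE(model$converged)) {
    abort_ffl("Cannot predict from a non-converged variance model.", "model")
  }
  co <- model$coef
  unname(co["alpha"] + co["beta"] * abs(ddct)^co["gamma"])
}

#' @export
predict.ddct_error_model <- function(object, newdata, ...) {
  predict_variance(object, newdata)
}

#' Fit, compare and select the ddCT variance model from a ddCT table
#'
#' Convenience wrapper chaining [collect_replicate_stats()],
#' [bin_variances()], [fit_error_model()] per variant and
#' [select_error_model()]. Set `binned = FALSE` to fit on the raw per-cell
#' variances (each record weighted 1) instead of binned means, for
#' sensitivity analysis.
#'
#' @inheritParams collect_replicate_stats
#' @inheritParams bin_variances
#' @inheritParams select_error_model
#' @param variants Variants to fit and compare.
#' @param binned Fit on binned means (default) or raw per-cell variances.
#' @return The selected `ddct_error_model`, with all candidate fits in
#'   attribute `fits` and the bin table in attribute `bins`.
#' @export
fit_ddct_error_model <- function(ddct, perturbations = NULL,
                                 variants = c("constant", "linear", "power"),
                                 n_bins = 10, min_bin_size = 3,
                                 binned = TRUE, cv_max = 0.5) {
  stats <- collect_replicate_stats(ddct, perturbations)
  obs <- if (binned) {
    bin_variances(stats, n_bins = n_bins, min_bin_size = min_bin_size)
  } else {
    tibble(
      bin = seq_len(nrow(stats)),
      mean_abs_ddct = stats$abs_mean_ddct,
      mean_var = stats$var_ddct,
      n = 1L
    )
  }
  fits <- purrr::map(variants, ~ fit_error_model(obs, variant = .x))
  names(fits) <- variants
  model <- select_error_model(fits, cv_max = cv_max)
  attr(model, "fits") <- fits
  attr(model, "bins") <- obs
  model
}

#' @export
print.ddct_error_model <- function(x, ...) {
  cat(sprintf(
    "<ddct_error_model> variant = %s%s\n",
    x$variant,
    if (!x$converged) " (NOT converged)" else if (x$degraded) " (degraded selection)" else ""
  ))
  cat("  sigma^2(ddCT) = alpha + beta * |ddCT|^gamma\n")
  est <- x$coef
  for (p in x$free) {
    cat(sprintf("  %-5s = %.6g (se %.3g)\n", p, est[[p]], x$se[[p]]))
  }
  cat(sprintf("  WRSS = %.6g on %d binned points\n", x$wrss, x$n_points))
  invisible(x)
}

#' @export
tidy.ddct_error_model <- function(x, ...) {
  tibble(
    term = x$free,
    estimate = unname(x$coef[x$free]),
    std.error = unname(x$se[x$free])
  )
}

#' @export
glance.ddct_error_model <- function(x, ...) {
  tibble(
    variant = x$variant,
    wrss = x$wrss,
    n_points = x$n_points,
    n_free = length(x$free),
    converged = x$converged,
    degraded = x$degraded
  )
}

#' Write a human- and machine-readable variance-model report
#'
#' @param model A `ddct_error_model` (ideally from [fit_ddct_error_model()],
#'   so candidate fits and bins are attached).
#' @param dir Output directory.
#' @param stem File-name stem.
#' @return Character vector of the files written, invisibly.
#' @export
write_error_model_report <- function(model, dir, stem = "error_model") {
  stopifnot(inherits(model, "ddct_error_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(stem, ".json"))
  txt_path <- file.path(dir, paste0(stem, ".txt"))
  fits <- attr(model, "fits")
  payload <- list(
    selected = list(
      variant = model$variant,
      estimates = as.list(model$coef[model$free]),
      std_errors = as.list(model$se[model$free]),
      wrss = model$wrss,
      n_points = model$n_points,
      converged = model$converged,
      degraded = model$degraded
    ),
    candidates = purrr::map(fits %||% list(), function(f) {
      list(
        variant = f$variant, wrss = f$wrss, converged = f$converged,
        estimates = as.list(f$coef[f$free]), std_errors = as.list(f$se[f$free])
      )
    })
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(model))
  writeLines(txt, txt_path)
  files <- c(json_path, txt_path)
  bins <- attr(model, "bins")
  if (!is.null(bins)) {
    bins_path <- file.path(dir, paste0(stem, "_bins.csv"))
    readr::write_csv(as_tibble(bins), bins_path, progress = FALSE)
    files <- c(files, bins_path)
  }
  invisible(files)
}
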