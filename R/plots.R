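#' Plot the fitted ddCT variance model over the binned data
#'
#' Bin-mean replicate variances against bin-mean |ddCT| (point size = bin
#' count), with the fitted variance surface overlaid.
#'
#' @param object A `ddct_error_model` with bins attached (as produced by
#'   [fit_ddct_error_model()] or [fit_error_model()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddct_error_model <- function(object, ...) {
  bins <- attr(object, "bins") %||% object$bins
  if (is.null(bins)) abort_ffl("No bin table attached to this model.", "argument")
  bins <- as_tibble(bins)
  grid <- tibble(
    x = seq(0, max(bins$mean_abs_ddct) * 1.05, length.out = 200)
  )
  grid$y <- predict_variance(object, grid$x)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_abs_ddct, y = .data$mean_var)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "mean |ddCT| per bin (cycles)",
      y = "mean replicate variance (cycles^2)",
      size = "cells / bin",
      title = sprintf(
        "ddCT variance model (%s): sigma^2 = %.4g + %.4g |x|^%.3g",
        object$variant, object$coef["alpha"], object$coef["beta"],
        object$coef["gamma"]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of significant regulations
#'
#' Genes by time-point tiles, one facet per silencing experiment. Only
#' significant cells are coloured (blue = down-regulated under silencing,
#' red = up-regulated, intensity = log2 fold change); genes are ordered by
#' increasing stimulation-phase fold change.
#'
#' @param object A `significance_calls` table.
#' @param significant_only Drop genes without any significant call.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.significance_calls <- function(object, significant_only = TRUE, ...) {
  wide <- make_heatmap_table(object, significant_only = significant_only)
  long <- wide |>
    pivot_longer(
      dplyr::starts_with("t", ignore.case = FALSE),
      names_to = "time_h", values_to = "fold_change"
    ) |>
    mutate(
      time_h = as.numeric(sub("^t", "", .data$time_h)),
      log2_fc = log2(.data$fold_change)
    ) |>
    group_by(.data$perturbation) |>
    mutate(gene = factor(.data$gene, levels = rev(unique(.data$gene)))) |>
    ungroup()
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$time_h), y = .data$gene, fill = .data$log2_fc
  )) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red",
      midpoint = 0, na.value = "grey97"
    ) +
    ggplot2::facet_wrap(~perturbation, scales = "free_y") +
    ggplot2::labs(
      x = "time (h)", y = NULL, fill = "log2 FC",
      title = "Significant regulations under silencing"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a feed-forward-loop module
#'
#' Regulators on top, common targets below; solid edges are
#' stimulation-phase regulations (activation arrows point, repressions are
#' blunt), dashed edges are wash-out regulations of unspecified sign.
#'
#' @param object An `ffl_module`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ffl_module <- function(object, ...) {
  targets <- object$common_targets
  nodes <- tibble(
    name = c(object$p1, object$p2, targets),
    x = c(
      length(targets) / 2 - 0.5, length(targets) / 2 + 0.5,
      seq_along(targets) - 1
    ),
    y = c(2, 1.4, rep(0, length(targets)))
  )
  edges <- object$edges |>
    select(-"evidence") |>
    left_join(nodes |> rename(source = "name", x0 = "x", y0 = "y"), by = "source") |>
    left_join(nodes |> rename(target = "name", x1 = "x", y1 = "y"), by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linetype = .data$phase, colour = .data$sign
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      linewidth = 0.6
    ) +
    ggplot2::geom_label(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y, label = .data$name)
    ) +
    ggplot2::scale_linetype_manual(
      values = c(stimulation = "solid", washout = "dashed")
    ) +
    ggplot2::scale_colour_manual(
      values = c(
        activation = "darkgreen", repression = "firebrick",
        unspecified = "grey40"
      )
    ) +
    ggplot2::labs(
      title = sprintf(
        "Multi-output FFL module: %s (%d targets)",
        object$orientation, length(targets)
      ),
      colour = "sign", linetype = "phase"
    ) +
    ggplot2::theme_void()
}
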