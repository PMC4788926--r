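# Network exports: SIF and DOT are line formats written directly;
# GraphML goes through igraph.

module_edge_table <- function(modules) {
  if (inherits(modules, "ffl_module")) {
    modules <- structure(list(modules), class = "ffl_module_set")
  }
  stopifnot(inherits(modules, "ffl_module_set"))
  tidy(modules)
}

sif_relation <- function(sign) {
  c(activation = "activates", repression = "represses", unspecified = "regulates")[sign]
}

#' Export modules as a SIF network
#'
#' One line per edge: `source<TAB>relation<TAB>target`, with relation
#' `activates`, `represses` or `regulates` (wash-out edges of unspecified
#' sign).
#'
#' @param modules An `ffl_module` or `ffl_module_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(modules, path) {
  edges <- module_edge_table(modules)
  lines <- sprintf("%s\t%s\t%s", edges$source, sif_relation(edges$sign), edges$target)
  writeLines(lines, path)
  invisible(path)
}

#' Convert modules to an igraph graph
#'
#' Edge attributes: `sign`, `phase`, `time_h`, `p_adj`, `fold_change`,
#' `module`.
#'
#' @param modules An `ffl_module` or `ffl_module_set`.
#' @return A directed [igraph::graph] object.
#' @export
as_igraph <- function(modules) {
  edges <- module_edge_table(modules)
  if (!"module" %in% names(edges)) edges$module <- 1L
  nodes <- unique(c(edges$source, edges$target))
  igraph::graph_from_data_frame(
    edges |>
      select(
        "source", "target", "sign", "phase", "time_h",
        "p_adj", "fold_change", "module"
      ),
    directed = TRUE,
    vertices = nodes
  )
}

#' Export modules as GraphML
#'
#' @inheritParams write_sif
#' @return `path`, invisibly.
#' @export
write_graphml <- function(modules, path) {
  g <- as_igraph(modules)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export modules as Graphviz DOT
#'
#' Solid edges are stimulation-phase regulations (arrowhead `normal` for
#' activation, `tee` for repression); dashed edges with a `dot` arrowhead
#' are wash-out regulations of unspecified sign.
#'
#' @inheritParams write_sif
#' @return `path`, invisibly.
#' @export
write_dot <- function(modules, path) {
  edges <- module_edge_table(modules)
  style <- ifelse(edges$phase == "washout", "dashed", "solid")
  head <- c(activation = "normal", repression = "tee", unspecified = "dot")[edges$sign]
  lines <- c(
    "digraph ffl_modules {",
    sprintf(
      "  \"%s\" -> \"%s\" [style=%s, arrowhead=%s];",
      edges$source, edges$target, style, head
    ),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write the module report as JSON
#'
#' Pairs, common targets and per-edge evidence (the annotating calls) for
#' every inferred module, plus cross-regulating pairs without common
#' targets.
#'
#' @param modules An `ffl_module_set`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_module_report <- function(modules, path) {
  if (inherits(modules, "ffl_module")) {
    modules <- structure(list(modules), class = "ffl_module_set")
  }
  payload <- list(
    n_modules = length(modules),
    modules = purrr::map(unclass(modules), function(m) {
      list(
        p1 = m$p1, p2 = m$p2, orientation = m$orientation,
        mutual = isTRUE(m$mutual),
        common_targets = m$common_targets,
        nodes = m$nodes,
        edges = m$edges |> select(-"evidence"),
        evidence = purrr::map(m$edges$evidence, ~ as_tibble(.x) |>
          select("perturbation", "gene", "time_h", "phase", "direction", "p_adj"))
      )
    }),
    bare_pairs = attr(modules, "bare_pairs")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Heatmap-ready matrix of significant fold changes
#'
#' Genes x time-point table with the fold change of significant calls and
#' `NA` elsewhere, one block per perturbation. Genes are ordered by
#' increasing fold change in the stimulation phase (taken from each gene's
#' annotating stimulation call); genes significant only in the wash-out
#' phase follow, ordered by their wash-out fold change, and never-significant
#' panel genes come last in panel order.
#'
#' @param calls A `significance_calls` table.
#' @param significant_only Keep only rows for genes with at least one
#'   significant call (default keeps the full panel, with blank rows).
#' @return A tibble with columns `perturbation`, `gene`, `direction` and one
#'   `t<time>` column per tested time point.
#' @export
make_heatmap_table <- function(calls, significant_only = FALSE) {
  stopifnot(inherits(calls, "significance_calls"))
  genes <- attr(calls, "genes") %||% unique(calls$gene)
  times <- sort(unique(calls$time_h))

  one_block <- function(sub) {
    p <- sub$perturbation[1]
    sig <- sub |> filter(.data$significant)
    ord <- sig |>
      group_by(.data$gene) |>
      summarise(
        stim_fc = {
          s <- pick(everything()) |> filter(.data$phase == "stimulation")
          if (nrow(s) > 0) s$fold_change[which.min(s$time_h)] else NA_real_
        },
        wash_fc = {
          s <- pick(everything()) |> filter(.data$phase == "washout")
          if (nrow(s) > 0) s$fold_change[which.min(s$time_h)] else NA_real_
        },
        direction = gene_level_direction(pick(everything())),
        .groups = "drop"
      ) |>
      arrange(
        is.na(.data$stim_fc), .data$stim_fc, .data$wash_fc,
        match(.data$gene, genes)
      )
    gene_order <- c(ord$gene, setdiff(genes, c(ord$gene, p)))
    wide <- sub |>
      mutate(value = ifelse(.data$significant, .data$fold_change, NA_real_)) |>
      select("gene", "time_h", "value") |>
      pivot_wider(
        names_from = "time_h", values_from = "value", names_prefix = "t"
      )
    out <- tibble(gene = gene_order) |>
      left_join(wide, by = "gene") |>
      left_join(ord |> select("gene", "direction"), by = "gene") |>
      mutate(perturbation = p, .before = 1)
    if (significant_only) out <- out |> filter(.data$gene %in% ord$gene)
    out
  }

  calls |>
    group_by(.data$perturbation) |>
    group_split() |>
    purrr::map(one_block) |>
    bind_rows()
}
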