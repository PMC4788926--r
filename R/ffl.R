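#' Find pairs of perturbed genes with significant cross-regulation
#'
#' Step 1 of module inference: among all pairs of perturbed genes, keep
#' those for which silencing one significantly modulates the other. The
#' regulating gene takes the upstream role (P1). When both directions are
#' significant, both orientations are emitted with `mutual = TRUE`.
#'
#' @param calls A `significance_calls` table.
#' @param perturbed Perturbed genes to consider; defaults to every
#'   perturbation present in `calls`.
#' @return A tibble with columns `p1` (upstream), `p2`, `mutual`.
#' @export
find_regulating_pairs <- function(calls, perturbed = NULL) {
  stopifnot(inherits(calls, "significance_calls"))
  perturbed <- perturbed %||% unique(calls$perturbation)
  regulates <- function(a, b) {
    any(calls$perturbation == a & calls$gene == b & calls$significant)
  }
  out <- list()
  if (length(perturbed) >= 2) {
    for (i in seq_len(length(perturbed) - 1)) {
      for (j in (i + 1):length(perturbed)) {
        a <- perturbed[i]
        b <- perturbed[j]
        ab <- regulates(a, b)
        ba <- regulates(b, a)
        if (ab) out[[length(out) + 1]] <- tibble(p1 = a, p2 = b, mutual = ab && ba)
        if (ba) out[[length(out) + 1]] <- tibble(p1 = b, p2 = a, mutual = ab && ba)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(p1 = character(), p2 = character(), mutual = logical()))
  }
  bind_rows(out)
}

#' Common targets of a pair of perturbed genes
#'
#' Step 2: the intersection of the gene lists significantly regulated by P1
#' and by P2, excluding the perturbed pair itself, in gene-panel order.
#'
#' @param calls A `significance_calls` table.
#' @param p1,p2 The perturbed pair.
#' @param genes Panel order; defaults to the calls table's `genes` attribute.
#' @return Character vector of common target genes.
#' @export
common_targets <- function(calls, p1, p2, genes = NULL) {
  stopifnot(inherits(calls, "significance_calls"))
  genes <- genes %||% attr(calls, "genes") %||% unique(calls$gene)
  sig_genes <- function(p) {
    unique(calls$gene[calls$perturbation == p & calls$significant])
  }
  common <- setdiff(intersect(sig_genes(p1), sig_genes(p2)), c(p1, p2))
  common[order(match(common, genes))]
}

#' Annotate an edge's phase and regulation sign from its evidence
#'
#' Stimulation-phase regulation takes precedence: if the regulator has any
#' significant call on the target at a stimulation time point, the edge is a
#' stimulation-phase edge and its sign follows that call's direction
#' (silencing the source lowers the target, direction `"down"`, means
#' activation; direction `"up"` means repression), with the earliest
#' significant stimulation time point winning if directions conflict (the
#' conflict is flagged). Otherwise the edge is a wash-out edge with
#' unspecified sign.
#'
#' @param evidence Rows of a `significance_calls` table for one
#'   (source, target) edge; at least one must be significant.
#' @return A one-row tibble: `phase`, `sign`, `time_h` (the annotating time
#'   point), `conflict`.
#' @export
annotate_phase <- function(evidence) {
  sig <- evidence[evidence$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    abort_ffl("Edge annotation requires at least one significant call.", "argument")
  }
  stim <- sig[sig$phase == "stimulation", , drop = FALSE]
  if (nrow(stim) > 0) {
    k <- which.min(stim$time_h)
    tibble(
      phase = "stimulation",
      sign = if (stim$direction[k] == "down") "activation" else "repression",
      time_h = stim$time_h[k],
      conflict = length(unique(stim$direction)) > 1
    )
  } else {
    k <- which.min(sig$time_h)
    tibble(
      phase = "washout",
      sign = "unspecified",
      time_h = sig$time_h[k],
      conflict = FALSE
    )
  }
}

# One signed, phase-annotated edge with the call that determined it.
make_edge <- function(calls, source, target) {
  ev <- calls |>
    filter(.data$perturbation == source, .data$gene == target, .data$significant)
  if (nrow(ev) == 0) {
    abort_ffl(
      paste0("No significant regulation of ", target, " by ", source, "."),
      "inconsistent_call"
    )
  }
  ann <- annotate_phase(ev)
  chosen <- ev |> filter(.data$time_h == ann$time_h)
  tibble(
    source = source, target = target,
    sign = ann$sign, phase = ann$phase, time_h = ann$time_h,
    conflict = ann$conflict,
    p_adj = chosen$p_adj[1], fold_change = chosen$fold_change[1],
    mean_ddct = chosen$mean_ddct[1],
    evidence = list(ev)
  )
}

#' Reconstruct one feed-forward loop
#'
#' Step 3: given upstream regulator `x`, downstream regulator `y` and a
#' common target `z`, builds the closed unidirectional loop X->Y, X->Z,
#' Y->Z with per-edge sign and phase from [annotate_phase()].
#'
#' @param calls A `significance_calls` table.
#' @param x,y,z Genes: upstream regulator, downstream regulator, target.
#' @return An object of class `ffl`: list with `x`, `y`, `z` and a
#'   three-row `edges` tibble.
#' @export
build_ffl <- function(calls, x, y, z) {
  stopifnot(inherits(calls, "significance_calls"))
  edges <- bind_rows(
    make_edge(calls, x, y),
    make_edge(calls, x, z),
    make_edge(calls, y, z)
  )
  structure(list(x = x, y = y, z = z, edges = edges), class = "ffl")
}

#' Merge FFLs sharing a regulator pair into a multi-output module
#'
#' Step 4: FFLs with the same (X, Y) pair are merged into one completely
#' connected module formed by the two regulators and their common targets;
#' the duplicated X->Y edge is kept once, so a single-orientation module has
#' `1 + 2 * n_targets` edges and `2 + n_targets` nodes.
#'
#' @param ffls A list of `ffl` objects sharing the same (x, y).
#' @return An object of class `ffl_module`: `p1`, `p2`, `orientation`,
#'   `common_targets`, `nodes`, `edges` (deduplicated tibble), `ffls`.
#' @export
merge_ffls <- function(ffls) {
  if (length(ffls) == 0) abort_ffl("Cannot merge an empty FFL list.", "argument")
  stopifnot(all(purrr::map_lgl(ffls, inherits, "ffl")))
  xs <- unique(purrr::map_chr(ffls, "x"))
  ys <- unique(purrr::map_chr(ffls, "y"))
  if (length(xs) > 1 || length(ys) > 1) {
    abort_ffl("All FFLs to merge must share the same (X, Y) pair.", "argument")
  }
  targets <- purrr::map_chr(ffls, "z")
  edges <- purrr::map(ffls, "edges") |>
    bind_rows() |>
    distinct(.data$source, .data$target, .keep_all = TRUE)
  structure(
    list(
      p1 = xs, p2 = ys,
      orientation = paste0(xs, "->", ys),
      common_targets = unique(targets),
      nodes = c(xs, ys, unique(targets)),
      edges = edges,
      ffls = ffls
    ),
    class = "ffl_module"
  )
}

#' Infer multi-output FFL regulatory modules from significance calls
#'
#' Composes the four inference steps over all qualifying pairs of perturbed
#' genes: select cross-regulating pairs, intersect their target lists, build
#' the component FFLs, and merge them into one module per oriented pair.
#' Pairs whose target lists do not intersect yield no module and are listed
#' in the `bare_pairs` attribute. Module order follows gene-panel order of
#' the pair, so identical inputs give identical output.
#'
#' @param calls A `significance_calls` table.
#' @param perturbed Perturbed genes to consider; defaults to all present.
#' @return A list of `ffl_module` objects (class `ffl_module_set`), with
#'   attribute `bare_pairs`.
#' @export
infer_modules <- function(calls, perturbed = NULL) {
  stopifnot(inherits(calls, "significance_calls"))
  perturbed <- perturbed %||% unique(calls$perturbation)
  genes <- attr(calls, "genes") %||% unique(c(calls$gene, perturbed))
  pairs <- find_regulating_pairs(calls, perturbed)
  if (nrow(pairs) > 0) {
    pairs <- pairs |> arrange(match(.data$p1, genes), match(.data$p2, genes))
  }
  modules <- list()
  bare <- pairs[0, ]
  for (i in seq_len(nrow(pairs))) {
    p1 <- pairs$p1[i]
    p2 <- pairs$p2[i]
    targets <- common_targets(calls, p1, p2, genes)
    if (length(targets) == 0) {
      bare <- bind_rows(bare, pairs[i, ])
      next
    }
    ffls <- purrr::map(targets, ~ build_ffl(calls, p1, p2, .x))
    mod <- merge_ffls(ffls)
    mod$mutual <- pairs$mutual[i]
    modules[[length(modules) + 1]] <- mod
  }
  structure(modules, class = "ffl_module_set", bare_pairs = bare)
}

#' @export
print.ffl_module <- function(x, ...) {
  cat(sprintf(
    "<ffl_module> %s with %d common target(s): %s\n",
    x$orientation, length(x$common_targets),
    paste(x$common_targets, collapse = ", ")
  ))
  cat(sprintf(
    "  %d nodes, %d edges, %d component FFLs\n",
    length(x$nodes), nrow(x$edges), length(x$ffls)
  ))
  invisible(x)
}

#' @export
print.ffl_module_set <- function(x, ...) {
  cat(sprintf("<ffl_module_set> %d module(s)\n", length(x)))
  for (m in x) print(m)
  bare <- attr(x, "bare_pairs")
  if (!is.null(bare) && nrow(bare) > 0) {
    cat(sprintf(
      "  %d cross-regulating pair(s) without common targets\n", nrow(bare)
    ))
  }
  invisible(x)
}

#' Flatten modules to an edge tibble
#'
#' @param x An `ffl_module` or `ffl_module_set`.
#' @param ... Unused.
#' @return A tibble of edges with a `module` id column.
#' @export
tidy.ffl_module_set <- function(x, ...) {
  if (length(x) == 0) {
    return(tibble(
      module = integer(), source = character(), target = character(),
      sign = character(), phase = character(), time_h = numeric(),
      conflict = logical(), p_adj = numeric(), fold_change = numeric(),
      mean_ddct = numeric()
    ))
  }
  purrr::imap(x, function(m, i) {
    m$edges |>
      select(-"evidence") |>
      mutate(module = i, .before = 1)
  }) |>
    bind_rows()
}

#' @rdname tidy.ffl_module_set
#' @export
tidy.ffl_module <- function(x, ...) {
  x$edges |> select(-"evidence")
}
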