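# Shared fixtures and independent oracles, all built in code.

# Small long-format CT table: 2 perturbations + control, 2 time points,
# 2 replicates, 4 genes (1 housekeeping).
make_ct_long <- function(ref_ct = 20, noise = 0) {
  genes <- c("A", "B", "P1", "HK")
  grid <- expand.grid(
    perturbation = c("CONTROL", "P1"),
    time_h = c(2, 12),
    replicate = 1:2,
    gene = genes,
    stringsAsFactors = FALSE
  )
  grid$sample_id <- sprintf(
    "%s_t%g_r%d", grid$perturbation, grid$time_h, grid$replicate
  )
  base <- c(A = 25, B = 27, P1 = 24, HK = ref_ct)
  grid$ct <- base[grid$gene] + noise * seq_len(nrow(grid)) / nrow(grid)
  grid
}

make_ct_fixture <- function(...) {
  ct_table(make_ct_long(...), housekeeping = "HK")
}

# Calls fixture encoding the worked example from the published screen:
# STAT1 silencing significantly regulates 21 genes (17 down at 2 h, 4 up at
# 8 h), IFIH1 silencing 12 genes; 6 genes are regulated by both, and IFIH1
# acts on SAMD9 only in the wash-out phase.
worked_example_calls <- function() {
  stat1_down_2h <- c(
    "IFIH1", "IDO1", "DDX60", "FAM46A", "CXCL10",
    "MX1", "OAS1", "IFIT1", "IFIT3", "ISG15", "IRF7",
    "RSAD2", "IFITM1", "PSMB9", "GBP1", "IRF1", "STAT2"
  )
  stat1_up_8h <- c("IFNA1", "ZC3HAV1", "SAMD9", "IFNAR1")
  ifih1_down_2h <- c("IDO1", "DDX60", "CXCL10")
  ifih1_down_8h <- c("FAM46A", "MX2", "OAS2", "IFI6", "BST2")
  ifih1_up_8h <- c("IFNAR1", "USP18", "IFI27")

  row <- function(pert, gene, time, dir) {
    data.frame(
      perturbation = pert, gene = gene, time_h = time,
      significant = TRUE, direction = dir,
      mean_ddct = if (dir == "down") 1.5 else -1.5,
      fold_change = if (dir == "down") 2^-1.5 else 2^1.5,
      p_adj = 0.001,
      stringsAsFactors = FALSE
    )
  }
  calls <- rbind(
    do.call(rbind, lapply(stat1_down_2h, row, pert = "STAT1", time = 2, dir = "down")),
    do.call(rbind, lapply(stat1_up_8h, row, pert = "STAT1", time = 8, dir = "up")),
    # FAM46A also regulated in the wash-out phase: stimulation must win.
    row("STAT1", "FAM46A", 12, "down"),
    do.call(rbind, lapply(ifih1_down_2h, row, pert = "IFIH1", time = 2, dir = "down")),
    do.call(rbind, lapply(ifih1_down_8h, row, pert = "IFIH1", time = 8, dir = "down")),
    do.call(rbind, lapply(ifih1_up_8h, row, pert = "IFIH1", time = 8, dir = "up")),
    # SAMD9 regulated by IFIH1 only during wash-out.
    row("IFIH1", "SAMD9", 12, "up")
  )
  panel <- unique(c(
    "STAT1", "IFIH1", stat1_down_2h, stat1_up_8h,
    ifih1_down_2h, ifih1_down_8h, ifih1_up_8h
  ))
  as_significance_calls(calls, genes = panel)
}

# Random significance-call matrix for property tests.
random_calls <- function(n_genes = 20, n_perturbed = 4, p_sig = 0.08,
                         times = c(2, 8, 12)) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  perturbed <- genes[seq_len(n_perturbed)]
  grid <- expand.grid(
    perturbation = perturbed, gene = genes, time_h = times,
    stringsAsFactors = FALSE
  )
  grid <- grid[grid$perturbation != grid$gene, ]
  grid$significant <- runif(nrow(grid)) < p_sig
  grid$direction <- ifelse(
    grid$significant, sample(c("down", "up"), nrow(grid), replace = TRUE), "none"
  )
  grid$mean_ddct <- ifelse(grid$direction == "down", 2, ifelse(grid$direction == "up", -2, 0))
  grid$fold_change <- 2^(-grid$mean_ddct)
  grid$p_adj <- ifelse(grid$significant, 0.01, 1)
  list(
    calls = as_significance_calls(grid, genes = genes),
    perturbed = perturbed, genes = genes
  )
}

# ---- Independent brute-force oracle for module inference -------------------
# Written against the raw call data frame with plain base R, re-deriving the
# phase/sign rules from scratch; returns a canonical character representation
# so module sets can be compared exactly.

oracle_edge <- function(df, src, tgt) {
  ev <- df[df$perturbation == src & df$gene == tgt & df$significant, ]
  stim <- ev[ev$time_h <= 8, ]
  if (nrow(stim) > 0) {
    k <- which.min(stim$time_h)
    sign <- if (stim$direction[k] == "down") "activation" else "repression"
    phase <- "stimulation"
  } else {
    sign <- "unspecified"
    phase <- "washout"
  }
  paste(src, tgt, sign, phase, sep = "|")
}

oracle_modules <- function(df, perturbed, genes) {
  sig_on <- function(a, b) any(df$perturbation == a & df$gene == b & df$significant)
  targets_of <- function(p) unique(df$gene[df$perturbation == p & df$significant])
  out <- character()
  for (a in perturbed) {
    for (b in perturbed) {
      if (a == b || !sig_on(a, b)) next
      common <- setdiff(intersect(targets_of(a), targets_of(b)), c(a, b))
      common <- common[order(match(common, genes))]
      if (length(common) == 0) next
      edges <- c(
        oracle_edge(df, a, b),
        unlist(lapply(common, function(z) c(oracle_edge(df, a, z), oracle_edge(df, b, z))))
      )
      out <- c(out, paste(
        a, b, paste(common, collapse = ","),
        paste(sort(edges), collapse = ";"),
        sep = " :: "
      ))
    }
  }
  sort(out)
}

# Canonical representation of the package's module set, for oracle comparison.
modules_signature <- function(modules) {
  sort(vapply(modules, function(m) {
    ed <- m$edges
    edges <- paste(ed$source, ed$target, ed$sign, ed$phase, sep = "|")
    paste(
      m$p1, m$p2, paste(m$common_targets, collapse = ","),
      paste(sort(edges), collapse = ";"),
      sep = " :: "
    )
  }, character(1)))
}

# Null screen simulated directly on the ddCT scale (true ddCT = 0 everywhere).
simulate_null_ddct <- function(n_genes = 96, times = c(2, 8, 12), K = 2,
                               sigma2 = 0.3975, perturbation = "KD1") {
  genes <- sprintf("G%03d", seq_len(n_genes))
  reps <- expand.grid(
    perturbation = perturbation, gene = genes, time_h = times,
    replicate = seq_len(K), stringsAsFactors = FALSE
  )
  reps$ddct <- rnorm(nrow(reps), 0, sqrt(sigma2))
  as_ddct_table(reps, genes = genes)
}

constant_model_0.3975 <- function() {
  fit_error_model(
    tibble::tibble(mean_abs_ddct = c(0, 1), mean_var = c(0.3975, 0.3975), n = c(5, 5)),
    "constant"
  )
}
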