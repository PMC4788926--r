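test_that("variance filter uses the nearest-rank percentile, strict exceedance", {
  # brute-force oracle: 20 variances 1..20, 95th percentile = 19th sorted value
  flt <- variance_filter(as.numeric(1:20), percentile = 95)
  expect_equal(flt$threshold, 19)
  expect_equal(which(flt$filtered), 20L)

  # ties at the threshold are retained
  flt_eq <- variance_filter(rep(0.4, 25))
  expect_equal(sum(flt_eq$filtered), 0)

  # nearest-rank on 1000 iid values retains exactly 950
  withr::local_seed(8)
  v <- rexp(1000)
  flt_big <- variance_filter(v)
  expect_equal(sum(!flt_big$filtered), 950)

  # NA variances (unreplicated cells) are never filtered
  flt_na <- variance_filter(c(as.numeric(1:20), NA))
  expect_equal(flt_na$threshold, 19)
  expect_false(flt_na$filtered[21])

  # fewer than 20 defined variances: skip with a classed warning
  expect_warning(
    flt_few <- variance_filter(as.numeric(1:10)),
    class = "fflscreen_filter_skip_warning"
  )
  expect_true(flt_few$skipped)
  expect_equal(sum(flt_few$filtered), 0)

  expect_error(variance_filter(1:30, percentile = 0), class = "fflscreen_argument_error")
})

test_that("z-test matches a numerical-integration normal oracle", {
  model <- constant_model_0.3975()

  # null value
  z0 <- test_modulation(0, model, K = 2)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)

  # worked value: mean 1.25, sigma^2 = 0.3975, K = 2
  r <- test_modulation(1.25, model, K = 2)
  expect_equal(r$z, 1.25 / sqrt(0.3975 / 2), tolerance = 1e-12)
  expect_equal(r$z, 2.8037, tolerance = 1e-4)
  expect_equal(r$p, 0.00506, tolerance = 1e-2)

  # oracle equivalence to 1e-10 over a grid of (mean, sigma^2, K)
  norm_tail <- function(z) {
    stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
      lower = abs(z), upper = Inf,
      rel.tol = 1e-13, abs.tol = 1e-15
    )$value
  }
  grid <- expand.grid(mean = c(-2.5, -0.3, 0.7, 1.25, 4), K = c(1, 2, 5))
  for (i in seq_len(nrow(grid))) {
    got <- test_modulation(grid$mean[i], model, grid$K[i])
    expected_p <- 2 * norm_tail(grid$mean[i] / sqrt(0.3975 / grid$K[i]))
    expect_equal(got$p, expected_p, tolerance = 1e-10)
  }

  # symmetry and monotonicity in |mean|
  ms <- seq(0, 4, by = 0.25)
  p_pos <- test_modulation(ms, model, 2)$p
  p_neg <- test_modulation(-ms, model, 2)$p
  expect_equal(p_pos, p_neg)
  expect_true(all(diff(p_pos) < 0))
})

test_that("Bonferroni adjustment is min(1, m p)", {
  expect_equal(bonferroni_adjust(c(0.2, 0.8), 1), c(0.2, 0.8))
  expect_equal(bonferroni_adjust(0.01, 10), 0.1)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_error(bonferroni_adjust(1.2, 5), class = "fflscreen_argument_error")
})

test_that("selection returns no calls under the exact global null", {
  reps <- expand.grid(
    perturbation = "KD1", gene = sprintf("g%02d", 1:30),
    time_h = c(2, 8, 12), replicate = 1:2, stringsAsFactors = FALSE
  )
  reps$ddct <- 0
  reps$ddct[reps$replicate == 2] <- 1e-9 # minimal spread so variances exist
  dd <- as_ddct_table(reps)
  calls <- run_selection(dd, constant_model_0.3975())
  expect_equal(sum(calls$significant), 0)
  expect_true(all(calls$direction == "none"))
  expect_true(all(calls$p_adj[!calls$filtered] == 1))
})

test_that("a single planted effect is called with the right direction and m", {
  withr::local_seed(31)
  genes <- sprintf("g%02d", 1:40)
  reps <- expand.grid(
    perturbation = "KD1", gene = genes, time_h = c(2, 8, 12),
    replicate = 1:2, stringsAsFactors = FALSE
  )
  reps$ddct <- rnorm(nrow(reps), 0, sqrt(0.3975))
  reps$ddct[reps$gene == "g05" & reps$time_h == 2] <- c(4.0, 4.2)
  dd <- as_ddct_table(reps, genes = genes)
  calls <- run_selection(dd, constant_model_0.3975(), alpha = 0.05)
  sig <- calls[calls$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$gene, "g05")
  expect_equal(sig$time_h, 2)
  expect_equal(sig$direction, "down")

  exps <- attr(calls, "experiments")
  expect_equal(exps$m, sum(!calls$filtered)) # post-filter m
  expect_equal(exps$n_cells, 120L)
  # Bonferroni: adjusted p = min(1, m p) on every tested cell
  tested <- !calls$filtered
  expect_equal(calls$p_adj[tested], pmin(1, exps$m * calls$p[tested]))

  pre <- run_selection(dd, constant_model_0.3975(), m_policy = "pre_filter")
  expect_equal(attr(pre, "experiments")$m, 120L)
})

test_that("the perturbed gene's own cells become a knockdown-efficiency check", {
  genes <- c("KD1", sprintf("g%02d", 1:30))
  reps <- expand.grid(
    perturbation = "KD1", gene = genes, time_h = c(2, 8), replicate = 1:2,
    stringsAsFactors = FALSE
  )
  reps$ddct <- rep(c(0, 0.1), length.out = nrow(reps))
  reps$ddct[reps$gene == "KD1"] <- 3 + reps$replicate[reps$gene == "KD1"] / 10
  dd <- as_ddct_table(reps, genes = genes)
  calls <- run_selection(dd, constant_model_0.3975())
  expect_false("KD1" %in% calls$gene)
  kd <- attr(calls, "knockdown_check")
  expect_equal(unique(kd$gene), "KD1")
  expect_equal(nrow(kd), 2)
  expect_true(all(kd$z > 5)) # strong knockdown signal
})

test_that("filtering is per silencing experiment and time 0 is excluded", {
  withr::local_seed(32)
  genes <- sprintf("g%02d", 1:25)
  reps <- expand.grid(
    perturbation = c("KD1", "KD2"), gene = genes, time_h = c(0, 2, 8, 12),
    replicate = 1:2, stringsAsFactors = FALSE
  )
  reps$ddct <- rnorm(nrow(reps), 0, sqrt(0.4))
  # KD2 gets a much noisier replicate spread: its threshold must differ
  reps$ddct[reps$perturbation == "KD2"] <- reps$ddct[reps$perturbation == "KD2"] * 3
  dd <- as_ddct_table(reps, genes = genes)
  calls <- run_selection(dd, constant_model_0.3975())
  expect_false(0 %in% calls$time_h)
  exps <- attr(calls, "experiments")
  expect_equal(nrow(exps), 2)
  expect_gt(
    exps$filter_threshold[exps$perturbation == "KD2"],
    exps$filter_threshold[exps$perturbation == "KD1"]
  )
  # each experiment filters its own 5%: 75 cells -> threshold = 72nd value
  expect_equal(exps$n_filtered, c(3L, 3L))
})

test_that("power to detect a planted effect rises with effect size and K", {
  withr::local_seed(33)
  model <- constant_model_0.3975()
  detect_rate <- function(shift, K, n_rep = 60) {
    hits <- 0
    for (r in seq_len(n_rep)) {
      reps <- expand.grid(
        perturbation = "KD1", gene = sprintf("g%02d", 1:25),
        time_h = c(2, 8, 12), replicate = seq_len(K), stringsAsFactors = FALSE
      )
      reps$ddct <- rnorm(nrow(reps), 0, sqrt(0.3975))
      sel <- reps$gene == "g01" & reps$time_h == 2
      reps$ddct[sel] <- reps$ddct[sel] + shift
      calls <- run_selection(as_ddct_table(reps), model)
      hits <- hits + any(calls$significant & calls$gene == "g01" & calls$time_h == 2)
    }
    hits / n_rep
  }
  rates_by_shift <- c(detect_rate(1, 2), detect_rate(2.5, 2), detect_rate(4, 2))
  expect_true(all(diff(rates_by_shift) >= 0))
  expect_lt(rates_by_shift[1], 0.7)
  expect_gt(rates_by_shift[3], 0.9)
  expect_lte(detect_rate(2.5, 2), detect_rate(2.5, 6))
})

test_that("modulator summaries report strength, sign and timing", {
  calls <- worked_example_calls()
  s <- summarize_modulator(calls)
  stat1 <- s[s$perturbation == "STAT1", ]
  expect_equal(stat1$strength, 21L)
  expect_equal(stat1$n_down, 17L) # down-regulated in the early stimulation phase
  expect_equal(stat1$sign, "positive")
  timing <- stat1$timing[[1]]
  expect_equal(timing$n_significant[timing$time_h == 2], 17L)

  ifih1 <- s[s$perturbation == "IFIH1", ]
  expect_equal(ifih1$strength, 12L)
  expect_equal(ifih1$n_down, 8L)
  expect_equal(ifih1$sign, "positive")
  timing_i <- ifih1$timing[[1]]
  expect_equal(timing_i$n_significant[timing_i$time_h == 2], 3L)

  # empty input: strength 0, sign mixed
  none <- calls[calls$perturbation == "STAT1", ]
  none$significant <- FALSE
  none$direction <- "none"
  none <- as_significance_calls(none)
  empty <- summarize_modulator(none)
  expect_equal(empty$strength, 0L)
  expect_equal(empty$sign, "mixed")
})
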