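test_that("cross-regulating pairs are found with the regulator upstream", {
  calls <- worked_example_calls()
  pairs <- find_regulating_pairs(calls)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$p1, "STAT1") # STAT1 silencing down-regulates IFIH1
  expect_equal(pairs$p2, "IFIH1")
  expect_false(pairs$mutual)

  # no cross-regulation -> empty result
  none <- as_significance_calls(data.frame(
    perturbation = c("A", "B"), gene = c("x", "y"), time_h = 2,
    significant = TRUE, direction = "down"
  ))
  expect_equal(nrow(find_regulating_pairs(none, c("A", "B"))), 0)

  # mutual regulation -> both orientations
  mut <- as_significance_calls(data.frame(
    perturbation = c("A", "B"), gene = c("B", "A"), time_h = 2,
    significant = TRUE, direction = "down"
  ))
  p2 <- find_regulating_pairs(mut, c("A", "B"))
  expect_equal(nrow(p2), 2)
  expect_true(all(p2$mutual))
})

test_that("common targets are the intersection of the regulated lists", {
  calls <- worked_example_calls()
  expect_equal(
    common_targets(calls, "STAT1", "IFIH1"),
    c("IDO1", "DDX60", "FAM46A", "CXCL10", "SAMD9", "IFNAR1")
  )

  disj <- as_significance_calls(data.frame(
    perturbation = c("A", "A", "B"), gene = c("B", "x", "y"), time_h = 2,
    significant = TRUE, direction = "down"
  ))
  expect_equal(common_targets(disj, "A", "B"), character(0))

  single <- as_significance_calls(data.frame(
    perturbation = c("A", "A", "B"), gene = c("B", "g", "g"), time_h = 2,
    significant = TRUE, direction = "down"
  ))
  expect_equal(common_targets(single, "A", "B"), "g")
})

test_that("phase annotation gives stimulation precedence and signed edges", {
  mk_ev <- function(times, dirs, phases = NULL) {
    df <- data.frame(
      perturbation = "A", gene = "z", time_h = times,
      significant = TRUE, direction = dirs
    )
    as_significance_calls(df)
  }
  # significant at 2 h and 12 h: stimulation-phase signed edge
  ann <- annotate_phase(mk_ev(c(2, 12), c("down", "up")))
  expect_equal(ann$phase, "stimulation")
  expect_equal(ann$sign, "activation")
  expect_equal(ann$time_h, 2)
  expect_false(ann$conflict)

  # significant only at 12 h: wash-out, unspecified sign
  ann12 <- annotate_phase(mk_ev(12, "up"))
  expect_equal(ann12$phase, "washout")
  expect_equal(ann12$sign, "unspecified")

  # conflicting stimulation directions: earliest wins, conflict flagged
  ann_c <- annotate_phase(mk_ev(c(2, 8), c("down", "up")))
  expect_equal(ann_c$sign, "activation")
  expect_true(ann_c$conflict)

  expect_error(
    annotate_phase(mk_ev(2, "none")[0, ]),
    class = "fflscreen_argument_error"
  )
})

test_that("FFLs are closed signed triangles with evidence attached", {
  calls <- worked_example_calls()
  # up-regulated target: repression edges from both regulators
  ffl_ifnar1 <- build_ffl(calls, "STAT1", "IFIH1", "IFNAR1")
  e <- ffl_ifnar1$edges
  expect_equal(e$source, c("STAT1", "STAT1", "IFIH1"))
  expect_equal(e$target, c("IFIH1", "IFNAR1", "IFNAR1"))
  expect_equal(e$sign, c("activation", "repression", "repression"))
  expect_true(all(e$phase == "stimulation"))

  # all-down FFL: all activations
  ffl_ido1 <- build_ffl(calls, "STAT1", "IFIH1", "IDO1")
  expect_equal(ffl_ido1$edges$sign, rep("activation", 3))

  # target regulated only at 12 h by IFIH1: wash-out, unspecified sign
  ffl_samd9 <- build_ffl(calls, "STAT1", "IFIH1", "SAMD9")
  yz <- ffl_samd9$edges[3, ]
  expect_equal(yz$phase, "washout")
  expect_equal(yz$sign, "unspecified")
  # STAT1 regulates SAMD9 in stimulation: solid repression edge
  expect_equal(ffl_samd9$edges$sign[2], "repression")

  # FAM46A regulated in both phases: stimulation reported
  ffl_fam <- build_ffl(calls, "STAT1", "IFIH1", "FAM46A")
  expect_equal(ffl_fam$edges$phase[2], "stimulation")

  expect_error(
    build_ffl(calls, "STAT1", "IFIH1", "NOT_A_TARGET"),
    "NOT_A_TARGET", class = "fflscreen_inconsistent_call_error"
  )
})

test_that("merging FFLs yields the multi-output module invariants", {
  calls <- worked_example_calls()
  targets <- common_targets(calls, "STAT1", "IFIH1")
  ffls <- lapply(targets, function(z) build_ffl(calls, "STAT1", "IFIH1", z))
  mod <- merge_ffls(ffls)
  expect_equal(length(mod$nodes), 8) # 2 regulators + 6 targets
  expect_equal(nrow(mod$edges), 13) # 1 + 2 * 6
  expect_equal(length(mod$ffls), 6)
  expect_equal(sum(mod$edges$source == "STAT1" & mod$edges$target == "IFIH1"), 1)

  single <- merge_ffls(ffls[1])
  expect_equal(length(single$nodes), 3)
  expect_equal(nrow(single$edges), 3)

  expect_error(merge_ffls(list()), class = "fflscreen_argument_error")
  other <- build_ffl(
    as_significance_calls(data.frame(
      perturbation = c("P", "P", "Q"), gene = c("Q", "t", "t"),
      time_h = 2, significant = TRUE, direction = "down"
    )), "P", "Q", "t"
  )
  expect_error(merge_ffls(c(ffls[1], list(other))), class = "fflscreen_argument_error")
})

test_that("the worked example yields exactly the published six-output module", {
  calls <- worked_example_calls()
  mods <- infer_modules(calls)
  expect_length(mods, 1)
  m <- mods[[1]]
  expect_equal(m$p1, "STAT1")
  expect_equal(m$p2, "IFIH1")
  expect_setequal(
    m$common_targets,
    c("IDO1", "DDX60", "FAM46A", "CXCL10", "SAMD9", "IFNAR1")
  )
  expect_equal(length(m$ffls), 6)
  expect_equal(length(m$nodes), 8)
  expect_equal(nrow(m$edges), 13)
  # both regulators repress the receptor gene
  ifnar1 <- m$edges[m$edges$target == "IFNAR1", ]
  expect_equal(sort(ifnar1$source), c("IFIH1", "STAT1"))
  expect_equal(unique(ifnar1$sign), "repression")
})

test_that("pairs without common targets yield no module but are reported", {
  df <- data.frame(
    perturbation = c("A", "A", "B"), gene = c("B", "x", "y"),
    time_h = 2, significant = TRUE, direction = "down"
  )
  calls <- as_significance_calls(df)
  mods <- infer_modules(calls, c("A", "B"))
  expect_length(mods, 0)
  bare <- attr(mods, "bare_pairs")
  expect_equal(nrow(bare), 1)
  expect_equal(bare$p1, "A")
})

test_that("module inference matches the brute-force oracle on random matrices", {
  withr::local_seed(99)
  for (i in 1:120) {
    rc <- random_calls(
      n_genes = sample(6:30, 1), n_perturbed = sample(2:4, 1),
      p_sig = runif(1, 0.03, 0.25)
    )
    got <- modules_signature(infer_modules(rc$calls, rc$perturbed))
    want <- oracle_modules(as.data.frame(rc$calls), rc$perturbed, rc$genes)
    expect_identical(got, want)
  }
})

test_that("structural invariants hold on random module sets", {
  withr::local_seed(101)
  checked <- 0
  for (i in 1:40) {
    rc <- random_calls(n_genes = 15, n_perturbed = 4, p_sig = 0.2)
    mods <- infer_modules(rc$calls, rc$perturbed)
    for (m in mods) {
      checked <- checked + 1
      expect_equal(length(m$nodes), 2 + length(m$common_targets))
      expect_equal(nrow(m$edges), 1 + 2 * length(m$common_targets))
      # every component FFL is a closed unidirectional X->Y, X->Z, Y->Z loop
      for (f in m$ffls) {
        expect_equal(
          unname(as.matrix(f$edges[, c("source", "target")])),
          matrix(c(f$x, f$x, f$y, f$y, f$z, f$z), ncol = 2)
        )
      }
      # activation iff the annotating stimulation call is a down-regulation
      stim <- m$edges[m$edges$phase == "stimulation", ]
      expect_true(all(stim$sign %in% c("activation", "repression")))
      wo <- m$edges[m$edges$phase == "washout", ]
      expect_true(all(wo$sign == "unspecified"))
    }
  }
  expect_gt(checked, 10)
})

test_that("network exports are deterministic and well-formed", {
  calls <- worked_example_calls()
  mods <- infer_modules(calls)

  sif1 <- withr::local_tempfile(fileext = ".sif")
  sif2 <- withr::local_tempfile(fileext = ".sif")
  write_sif(mods, sif1)
  write_sif(mods, sif2)
  expect_identical(readLines(sif1), readLines(sif2))
  lines <- readLines(sif1)
  expect_length(lines, 13)
  expect_true("STAT1\tactivates\tIFIH1" %in% lines)
  expect_true("STAT1\trepresses\tIFNAR1" %in% lines)
  expect_true("IFIH1\tregulates\tSAMD9" %in% lines) # wash-out, unspecified

  dot <- withr::local_tempfile(fileext = ".dot")
  write_dot(mods, dot)
  dl <- readLines(dot)
  expect_true(any(grepl("style=dashed, arrowhead=dot", dl))) # wash-out styling
  expect_true(any(grepl("arrowhead=tee", dl))) # repression styling

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(mods, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 8)
  expect_equal(igraph::ecount(g), 13)
  expect_true("sign" %in% igraph::edge_attr_names(g))

  mj <- withr::local_tempfile(fileext = ".json")
  write_module_report(mods, mj)
  rep <- jsonlite::read_json(mj)
  expect_equal(rep$n_modules, 1)
  expect_length(rep$modules[[1]]$common_targets, 6)

  td <- tidy(mods)
  expect_equal(nrow(td), 13)
  expect_true(all(td$module == 1))
})
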