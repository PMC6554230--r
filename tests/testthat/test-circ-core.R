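test_that("each exclusion criterion fires with the documented reason", {
  # low score: strict > retains, equality discards
  low <- circ_filter(make_psm(score = c(25, 30, 31)), 30, "mascot")
  expect_equal(unname(low$discarded_by_reason[["low_score"]]), 2L)
  expect_equal(nrow(low$retained), 1L)

  # null or 0.0 ratio in any condition channel
  psm <- make_psm(score = 50)
  psm$ratio_116 <- 0
  expect_equal(circ_filter(psm, 30)$discarded_by_reason[["null_ratio"]], 1L)
  psm$ratio_116 <- NA_real_
  expect_equal(circ_filter(psm, 30)$discarded_by_reason[["null_ratio"]], 1L)

  # annotations
  frag <- circ_filter(make_psm(annotation = "Actin, partial (Fragment)"), 30)
  expect_equal(frag$discarded_by_reason[["fragment_annotation"]], 1L)
  rev <- circ_filter(make_psm(annotation = "REVERSED Keratin"), 30)
  expect_equal(rev$discarded_by_reason[["reversed_annotation"]], 1L)

  # shared peptides: multi-accession rows and same sequence across accessions
  sh <- make_psm(sequence = c("AAK", "AAK", "CCK"),
                 accessions = c("P1", "P2", "P3;P4"))
  out <- circ_filter(sh, 30)
  expect_equal(out$discarded_by_reason[["shared_peptide"]], 3L)
})

test_that("the first failing criterion wins, in the documented order", {
  # a decoy with a low score is counted as low_score, not reversed
  psm <- make_psm(annotation = "REVERSED Protein", score = 10)
  out <- circ_filter(psm, 30)
  expect_equal(out$discarded_by_reason[["low_score"]], 1L)
  expect_equal(out$discarded_by_reason[["reversed_annotation"]], 0L)
  # a fragment with a null ratio is counted as null_ratio
  psm <- make_psm(annotation = "X (Fragment)", score = 50)
  psm$ratio_115 <- 0
  out <- circ_filter(psm, 30)
  expect_equal(out$discarded_by_reason[["null_ratio"]], 1L)
  expect_equal(out$discarded_by_reason[["fragment_annotation"]], 0L)
})

test_that("the filter partitions its input exactly, per replicate", {
  psm <- random_psm_table(n = 80, n_replicates = 3, seed = 2)
  out <- circ_filter(psm, 30)
  expect_equal(nrow(out$retained) + sum(out$discarded_by_reason), nrow(psm))
  pr <- out$per_replicate
  expect_equal(pr$retained + pr$discarded, pr$input)
  reasons <- c("low_score", "null_ratio", "fragment_annotation",
               "reversed_annotation", "shared_peptide")
  expect_equal(rowSums(pr[, reasons]), pr$discarded, ignore_attr = TRUE)
})

test_that("the filter is idempotent and monotone in the score threshold", {
  psm <- random_psm_table(n = 100, n_replicates = 2, seed = 5)
  out <- circ_filter(psm, 30)
  again <- circ_filter(out$retained, 30)
  expect_equal(nrow(again$retained), nrow(out$retained))
  expect_equal(sum(again$discarded_by_reason), 0L)

  retained_at <- vapply(c(10, 20, 30, 40, 60), function(thr) {
    nrow(circ_filter(psm, thr)$retained)
  }, integer(1))
  expect_true(all(diff(retained_at) <= 0))
})

test_that("the catalog re-keys channels to conditions through the rotation", {
  design <- read_design(extdata("design_rotation.tsv"))
  # same channel ratio means different conditions in replicates 1 vs 2:
  # replicate 1 has CsA on 115, replicate 2 has VIVIT on 114 and CsA on 116
  p1 <- make_psm(sequence = "AAK", score = 50, replicate_id = 1,
                 ratios = c(`115` = 2.0, `116` = 1.0, `117` = 1.0),
                 ref_channel = "114")
  p2 <- make_psm(sequence = "AAK", score = 50, replicate_id = 2,
                 ratios = c(`114` = 1.0, `116` = 2.0, `117` = 1.0),
                 ref_channel = "115")
  cat12 <- build_catalog(rbind(p1, p2), design)
  e <- cat12$entries
  csa <- e[e$condition == "CsA", ]
  expect_equal(csa$ratio[csa$replicate_id == 1], 2.0)
  expect_equal(csa$ratio[csa$replicate_id == 2], 2.0)
  expect_equal(e$condition[e$replicate_id == 2 & e$ratio == 1.0],
               c("Tac", "VIVIT"))
})

test_that("frequency index counts replicates with a retained match", {
  design <- default_design(5)
  tabs <- lapply(c(1, 3), function(r) {
    ref <- design_reference(design, r)$channel
    non_ref <- setdiff(c("114", "115", "116", "117"), ref)
    make_psm(sequence = "AAK", score = 50, replicate_id = r,
             ratios = setNames(c(1.2, 0.9, 1.1), non_ref), ref_channel = ref)
  })
  cat2 <- build_catalog(do.call(rbind, tabs), design)
  expect_equal(cat2$frequency$frequency_index, 2L)
  # retained in all five replicates -> index 5
  tabs5 <- lapply(1:5, function(r) {
    ref <- design_reference(design, r)$channel
    non_ref <- setdiff(c("114", "115", "116", "117"), ref)
    make_psm(sequence = "AAK", score = 50, replicate_id = r,
             ratios = setNames(c(1.2, 0.9, 1.1), non_ref), ref_channel = ref)
  })
  cat5 <- build_catalog(do.call(rbind, tabs5), design)
  expect_equal(cat5$frequency$frequency_index, 5L)
  # replicates missing from the design are an error
  expect_error(build_catalog(make_psm(score = 50, replicate_id = 9),
                             design_table(default_design(2))),
               "missing from the design")
})

test_that("rollup medians, weighted means and SD follow the definitions", {
  design <- default_design(1, conditions = c("Ref", "A", "B", "C"))
  ratios <- c(0.8, 1.0, 1.2, 2.0)
  psm <- make_psm(sequence = sprintf("PEP%dK", 1:4), score = 50,
                  replicate_id = 1)
  for (ch in c("115", "116", "117")) psm[[paste0("ratio_", ch)]] <- ratios
  cat1 <- build_catalog(psm, design)
  out <- rollup_proteins(cat1, min_frequency = 1)
  a <- out[out$condition == "A", ]
  expect_equal(a$overall_median, 1.1)  # even count: mean of central pair
  expect_equal(a$sd, sd(ratios))
  expect_equal(a$n_peptides, 4L)

  # equal intensities -> weighted mean equals the plain mean
  expect_equal(a$weighted_mean, mean(ratios))

  # unequal weights pull the weighted mean; uniform weighting ignores them
  psm$i114 <- c(1e5, 10, 10, 10); psm$i115 <- psm$i116 <- psm$i117 <- 0
  cat2 <- build_catalog(psm, design)
  w <- rowSums(cbind(psm$i114, psm$i115, psm$i116, psm$i117))
  out2 <- rollup_proteins(cat2, min_frequency = 1)
  expect_equal(out2$weighted_mean[out2$condition == "A"],
               sum(w * ratios) / sum(w))
  out2u <- rollup_proteins(cat2, min_frequency = 1, weights = "uniform")
  expect_equal(out2u$weighted_mean[out2u$condition == "A"], mean(ratios))

  # single pooled ratio: median = weighted mean = value, sd absent
  one <- make_psm(score = 50, ratios = c(`115` = 1.3, `116` = 1.3,
                                         `117` = 1.3))
  out1 <- rollup_proteins(build_catalog(one, design), min_frequency = 1)
  expect_equal(out1$overall_median, rep(1.3, 3))
  expect_equal(out1$weighted_mean, rep(1.3, 3))
  expect_true(all(is.na(out1$sd)))
})

test_that("the frequency threshold excludes below-threshold proteins", {
  design <- default_design(5)
  tabs <- lapply(1:4, function(r) {
    ref <- design_reference(design, r)$channel
    non_ref <- setdiff(c("114", "115", "116", "117"), ref)
    make_psm(sequence = "AAK", score = 50, replicate_id = r,
             ratios = setNames(rep(1.2, 3), non_ref), ref_channel = ref)
  })
  cat4 <- build_catalog(do.call(rbind, tabs), design)
  expect_equal(nrow(rollup_proteins(cat4, min_frequency = 5)), 0L)
  expect_gt(nrow(rollup_proteins(cat4, min_frequency = 4)), 0L)
  expect_error(rollup_proteins(cat4, min_frequency = 6), "between 1 and")
})

test_that("rollup is permutation-invariant and scale-equivariant", {
  sim <- simulate_dataset(simulation_config(n_proteins = 8, seed = 13))
  psm <- do.call(rbind, sim$psm_tables)
  filt <- circ_filter(psm, 30)
  base <- rollup_proteins(build_catalog(filt, sim$design), 4)

  # permute the PSM rows: identical output (rows are ordered on the way out)
  set.seed(1)
  perm <- psm[sample(nrow(psm)), ]
  permed <- rollup_proteins(build_catalog(circ_filter(perm, 30), sim$design), 4)
  expect_equal(permed, base)

  # scale all ratios by k: medians and means scale by k
  k <- 3.7
  scaled <- psm
  for (ch in c("114", "115", "116", "117")) {
    scaled[[paste0("ratio_", ch)]] <- scaled[[paste0("ratio_", ch)]] * k
  }
  out_k <- rollup_proteins(build_catalog(circ_filter(scaled, 30), sim$design), 4)
  expect_equal(out_k$overall_median, k * base$overall_median, tolerance = 1e-12)
  expect_equal(out_k$weighted_mean, k * base$weighted_mean, tolerance = 1e-12)
})
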