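make_labels <- function(n_normal, n_tumor) {
  label_vector(c(sprintf("n%03d", seq_len(n_normal)),
                 sprintf("t%03d", seq_len(n_tumor))),
               c(rep(0, n_normal), rep(1, n_tumor)))
}

test_that("resampling plan honors the ratio design", {
  labels <- make_labels(59, 400)
  plan <- make_resampling_plan(labels, n_iterations = 10, ratio = 6, seed = 4)
  expect_length(plan$normal_ids, 59)
  expect_true(all(vapply(plan$draws, length, 1L) == 354))
  expect_true(all(vapply(plan$draws, anyDuplicated, 1L) == 0))

  # exhaustive draw: pool exactly ratio x normals -> every iteration is a
  # permutation of the full pool
  labels2 <- make_labels(5, 5)
  plan2 <- make_resampling_plan(labels2, n_iterations = 3, ratio = 1, seed = 1)
  for (d in plan2$draws) expect_setequal(d, plan2$tumor_pool_ids)

  # determinism
  expect_identical(make_resampling_plan(labels, 5, 6, seed = 99)$draws,
                   make_resampling_plan(labels, 5, 6, seed = 99)$draws)
  expect_error(make_resampling_plan(make_labels(10, 20), ratio = 6),
               "need 60")
})

test_that("exact test matches the brute-force enumeration oracle", {
  phi <- 0.2
  for (s in c(1, 5, 17, 40)) {
    for (yA in unique(c(0, floor(s / 3), floor(s / 2), s))) {
      expect_equal(
        vaemarker:::exact_nb_pvalue(yA, s - yA, 2, 2, phi),
        oracle_exact_p(yA, s - yA, 2, 2, phi),
        tolerance = 1e-8,
        label = sprintf("s=%d yA=%d", s, yA))
    }
  }
  # unbalanced group sizes too
  expect_equal(vaemarker:::exact_nb_pvalue(20, 4, 3, 1, 0.4),
               oracle_exact_p(20, 4, 3, 1, 0.4), tolerance = 1e-8)
})

test_that("exact test handles perfect nulls and empty genes", {
  m <- matrix(10, nrow = 2, ncol = 6,
              dimnames = list(c("flat", "zero"), paste0("s", 1:6)))
  m["zero", ] <- 0
  res <- nb_exact_test(count_matrix(m), paste0("s", 1:3), paste0("s", 4:6),
                       dispersion = 0.1)
  expect_equal(res$pvalue[res$gene_id == "flat"], 1, tolerance = 1e-9)
  expect_equal(res$log2fc[res$gene_id == "flat"], 0, tolerance = 1e-12)
  expect_true(res$flagged[res$gene_id == "zero"])
  expect_equal(res$pvalue[res$gene_id == "zero"], 1)
  expect_error(nb_exact_test(count_matrix(m), character(), paste0("s", 1:3)),
               "non-empty")
})

test_that("exact test agrees with edgeR's exact test in rank and scale", {
  sim <- simulate_counts(simulation_config(n_genes = 150, n_normal = 8,
                                           n_tumor = 8, n_de = 20,
                                           n_biomarkers = 20, seed = 17))
  groupA <- names(sim$labels)[sim$labels == 1]
  groupB <- names(sim$labels)[sim$labels == 0]
  mine <- nb_exact_test(sim$counts, groupA, groupB, dispersion = 0.2)

  suppressPackageStartupMessages(requireNamespace("edgeR"))
  dge <- edgeR::DGEList(counts = unclass(sim$counts),
                        group = sim$labels[colnames(sim$counts)])
  dge <- edgeR::calcNormFactors(dge, method = "none")
  et <- edgeR::exactTest(dge, pair = c("0", "1"), dispersion = 0.2)
  theirs <- et$table[mine$gene_id, ]
  # same decisions at the 0.05 / |lfc|>1 thresholds for nearly every gene,
  # and strongly correlated p-values (implementations differ in
  # normalization details, so numerical identity is not claimed)
  sig_mine <- mine$pvalue < 0.05 & abs(mine$log2fc) > 1
  sig_theirs <- theirs$PValue < 0.05 & abs(theirs$logFC) > 1
  expect_gt(mean(sig_mine == sig_theirs), 0.95)
  expect_gt(cor(log(mine$pvalue + 1e-300), log(theirs$PValue + 1e-300)),
            0.95)
})

test_that("stability counting and feature sets behave as designed", {
  sim <- simulate_counts(simulation_config(n_genes = 200, n_normal = 10,
                                           n_tumor = 60, n_de = 20,
                                           n_biomarkers = 8,
                                           de_log2fc_range = c(2, 3),
                                           seed = 23))
  plan <- make_resampling_plan(sim$labels, n_iterations = 20, ratio = 6,
                               seed = 2)
  freq <- run_stability(sim$counts, sim$labels, plan)
  bm <- sim$truth$biomarker_gene_ids

  # fully penetrant strong genes are significant in (nearly) every iteration
  expect_gte(mean(freq$frequency[bm] >= 19), 0.9)
  # null genes essentially never pass the combined |lfc| + p filter
  nulls <- setdiff(names(freq$frequency), sim$truth$de_gene_ids)
  expect_lt(mean(freq$frequency[nulls]), 0.5)

  sets <- build_feature_sets(freq, thresholds = c(19, 10))
  expect_named(sets, c("All", "Freq>=19", "Freq>=10"))
  # monotone nesting
  expect_true(all(sets[["Freq>=19"]]$gene_ids %in%
                    sets[["Freq>=10"]]$gene_ids))
  expect_true(all(sets[["Freq>=10"]]$gene_ids %in% sets[["All"]]$gene_ids))
  # threshold 0 collapses to the ever-significant set
  expect_setequal(build_feature_sets(freq, 0)[[2]]$gene_ids,
                  sets[["All"]]$gene_ids)
  # vacuous threshold warns and yields the empty set
  expect_warning(empty <- build_feature_sets(freq, 21)[[2]], "exceeds")
  expect_length(empty$gene_ids, 0)
})

test_that("frequency counting matches a hand-tallied toy run", {
  # one gene differential, tiny plan; frequency equals the number of
  # significant iterations by direct count
  sim <- simulate_counts(simulation_config(n_genes = 50, n_normal = 6,
                                           n_tumor = 24, n_de = 4,
                                           n_biomarkers = 4,
                                           de_log2fc_range = c(2.5, 3),
                                           seed = 29))
  plan <- make_resampling_plan(sim$labels, n_iterations = 4, ratio = 4,
                               seed = 3)
  freq <- run_stability(sim$counts, sim$labels, plan)
  manual <- stats::setNames(integer(nrow(sim$counts)), rownames(sim$counts))
  for (d in plan$draws) {
    res <- nb_exact_test(sim$counts, d, plan$normal_ids)
    sig <- abs(res$log2fc) > 1 & res$pvalue < 0.05
    manual[res$gene_id[sig]] <- manual[res$gene_id[sig]] + 1L
  }
  expect_identical(freq$frequency, manual)
  expect_true(all(freq$frequency <= 4))
})
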