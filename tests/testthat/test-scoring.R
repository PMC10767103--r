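# small attribution-like object for scoring tests
fake_attr <- function(values) {
  structure(list(values = values, base_value = 0,
                 explained_output = "tumor_logit",
                 settings = list(background = "b", n_steps = 1, seed = 1)),
            class = "attribution_matrix")
}

test_that("quantile cutoffs follow the linear-interpolation convention", {
  thr <- compute_thresholds(matrix(1:100, 10), 0.05, method = "quantile")
  expect_equal(thr$pos_cutoff, 95.05)
  expect_equal(thr$neg_cutoff, 5.95)

  # symmetric pooled values give symmetric cutoffs
  v <- c(-5:-1, 1:5)
  thr2 <- compute_thresholds(v, 0.1, method = "quantile")
  expect_equal(thr2$neg_cutoff, -thr2$pos_cutoff)

  # rate convention: absolute cutoffs at +/- q
  thr3 <- compute_thresholds(v, 0.05, method = "rate")
  expect_equal(thr3$pos_cutoff, 0.05)
  expect_equal(thr3$neg_cutoff, -0.05)

  expect_error(compute_thresholds(v, 0.5), "\\(0, 0.5\\)")
  expect_error(compute_thresholds(v, 0), "\\(0, 0.5\\)")
})

test_that("contribution rates are signed shares summing to one", {
  v <- matrix(c(2, -1, 1, 0.5, -0.25, 0.25), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  r <- attribution_rates(fake_attr(v))
  expect_equal(unname(rowSums(abs(r))), c(1, 1))
  expect_equal(unname(r["s1", ]), c(0.5, -0.25, 0.25))
})

test_that("the harmonic-mean score reproduces hand-counted toys", {
  # 3 tumors, 3 normals x 4 genes with hand-set cutoffs at +/-1
  v <- rbind(
    t1 = c(2,  2, 0,  2),
    t2 = c(2,  0, 0,  2),
    t3 = c(0,  0, 0,  2),
    n1 = c(-2, 0, 0, -2),
    n2 = c(0,  0, 0, -2),
    n3 = c(0,  2, 0, -2))
  colnames(v) <- c("gA", "gB", "gC", "gD")
  labels <- label_vector(rownames(v), c(1, 1, 1, 0, 0, 0))
  thr <- structure(list(q = 0.1, pos_cutoff = 1, neg_cutoff = -1,
                        method = "quantile"),
                   class = "contribution_thresholds")
  tab <- score_genes(fake_attr(v), labels, thr, only_significant = FALSE)
  tab <- tab[order(tab$gene_id), ]
  # gA: C_P = 2 of 3, C_N = 1 of 3 -> 2*(2/3)*(1/3)/(2/3+1/3) = 4/9
  expect_equal(tab$c_p, c(2L, 1L, 0L, 3L))
  expect_equal(tab$c_n, c(1L, 0L, 0L, 3L))
  expect_equal(tab$score[tab$gene_id == "gA"], 4 / 9)
  # zero annihilator: gB contributes positively in tumors only
  expect_equal(tab$score[tab$gene_id == "gB"], 0)
  # equal proportions give the proportion itself
  expect_equal(tab$score[tab$gene_id == "gD"], 1)
  # gC has no significant cells and is dropped under the default filter
  tab_sig <- score_genes(fake_attr(v), labels, thr)
  expect_false("gC" %in% tab_sig$gene_id)
  expect_true(all(c("gA", "gB", "gD") %in% tab_sig$gene_id))

  one_class <- label_vector(rownames(v), rep(1, 6))
  expect_error(score_genes(fake_attr(v), one_class, thr), "both classes")
})

test_that("score bounds, symmetry and monotonicity hold over random tables", {
  hm <- function(pt, pn) ifelse(pt + pn == 0, 0, 2 * pt * pn / (pt + pn))
  set.seed(4)
  for (i in 1:200) {
    pt <- sample(0:10, 1) / 10
    pn <- sample(0:10, 1) / 10
    s <- hm(pt, pn)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_lte(s, min(1, 2 * min(pt, pn)))
    expect_equal(s, hm(pn, pt))
    # monotone non-decreasing in each argument
    expect_gte(hm(min(pt + 0.1, 1), pn), s)
    expect_gte(hm(pt, min(pn + 0.1, 1)), s)
    if (pt == 0 || pn == 0) expect_equal(s, 0)
  }
})

test_that("raising q never decreases significant-contribution counts", {
  set.seed(8)
  v <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(sprintf("s%02d", 1:40), sprintf("g%02d", 1:30)))
  labels <- label_vector(rownames(v), rep(c(0, 1), each = 20))
  attr <- fake_attr(v)
  for (method in c("quantile", "rate")) {
    # "wider tails" = larger q under the quantile convention, but a LOWER
    # absolute cutoff means smaller q under the rate convention
    qs <- if (method == "quantile") c(0.005, 0.01, 0.05, 0.2) else
      c(0.2, 0.05, 0.01, 0.005)
    prev <- NULL
    for (q in qs) {
      tab <- score_genes(attr, labels,
                         compute_thresholds(attr, q, method),
                         only_significant = FALSE)
      tab <- tab[order(tab$gene_id), ]
      if (!is.null(prev)) {
        expect_true(all(tab$c_p >= prev$c_p), label = method)
        expect_true(all(tab$c_n >= prev$c_n), label = method)
      }
      prev <- tab
    }
  }
})

test_that("quartile filter keeps the descending top quarter with ties", {
  t8 <- data.frame(gene_id = letters[1:8], score = (1:8) / 10)
  expect_setequal(quartile_filter(t8), c("g", "h"))
  tied <- data.frame(gene_id = letters[1:5], score = rep(0.4, 5))
  expect_setequal(quartile_filter(tied), letters[1:5])
  t4 <- data.frame(gene_id = c("w", "x", "y", "z"),
                   score = c(0.9, 0.8, 0.4, 0.1))
  expect_setequal(quartile_filter(t4), "w")   # bound 0.825 by type-7 quantile
  expect_error(quartile_filter(t4[1:3, ]), "at least 4")
})

test_that("candidate intersection is a plain set intersection with provenance", {
  a <- candidate_set(c("A", "B", "C"), list(run = 1))
  b <- candidate_set(c("B", "C", "D"), list(run = 2))
  c3 <- candidate_set(c("C", "B"), list(run = 3))
  out <- intersect_candidates(list(a, b, c3))
  expect_setequal(out$gene_ids, c("B", "C"))
  expect_setequal(intersect_candidates(list(a, a))$gene_ids, a$gene_ids)
  expect_error(intersect_candidates(list()), "no candidate")
})

test_that("discovery config validation catches cross-field errors", {
  expect_error(discovery_config(q_list = c(0.05, 0.6)), "q_list")
  expect_error(discovery_config(n_iterations = 5, n_sample_sets = 6),
               "n_sample_sets")
  expect_error(discovery_config(freq_fractions = c(0.95, 1.5)),
               "freq_fractions")
  expect_error(discovery_config(quartile = 0), "quartile")
  # reference defaults validate cleanly
  cfg <- discovery_config()
  expect_length(validate_config(cfg), 0)
  expect_equal(cfg$n_iterations, 1000L)
  expect_equal(ceiling(cfg$freq_fractions * cfg$n_iterations), c(950, 750))
  expect_equal(cfg$q_list, c(0.05, 0.01, 0.005))
  expect_equal(cfg$schedule$total_epochs, 250L)
  expect_equal(cfg$schedule$lambda, 0.001)
})

test_that("a small discovery run is deterministic and degrades gracefully", {
  sim <- simulate_counts(simulation_config(n_genes = 120, n_normal = 8,
                                           n_tumor = 32, n_de = 24,
                                           n_biomarkers = 8, seed = 41))
  sched <- training_schedule(vae_epochs = 8, mlp_epochs = 8,
                             joint_epochs = 16)
  cfg <- discovery_config(n_iterations = 1, ratio = 4, n_sample_sets = 1,
                          q_list = 0.01, schedule = sched, seed = 7)
  res <- run_discovery(sim$counts, sim$labels, cfg)
  # single iteration + single threshold: one candidate set, final = that set
  expect_length(res$candidate_sets, length(res$feature_sets))
  expect_setequal(res$final_genes,
                  intersect_candidates(res$candidate_sets)$gene_ids)
  # every final gene sits in every candidate set
  for (cs in res$candidate_sets) {
    expect_true(all(res$final_genes %in% cs$gene_ids))
  }
  res2 <- run_discovery(sim$counts, sim$labels, cfg)
  expect_identical(res2$final_genes, res$final_genes)
  expect_identical(res2$metrics, res$metrics)
})
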