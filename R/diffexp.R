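#' Build a ratio-controlled resampling plan
#'
#' Stability selection draws repeated tumor subsamples while keeping every
#' normal sample in every iteration: with `n` normals and ratio `r`, each
#' iteration contains all `n` normals plus `r * n` tumors drawn without
#' replacement from the tumor pool. With 59 normals and ratio 6 each
#' iteration draws exactly 354 tumors.
#'
#' @param labels named 0/1 vector (0 = normal, 1 = tumor).
#' @param n_iterations number of resampling iterations (default 1000).
#' @param ratio tumors drawn per normal sample (default 6).
#' @param seed RNG seed.
#' @return A `resampling_plan`: list with `normal_ids`, `tumor_pool_ids`,
#'   `draws` (list of tumor-id vectors, one per iteration), `ratio`, `seed`.
#' @export
make_resampling_plan <- function(labels, n_iterations = 1000, ratio = 6,
                                 seed = 1) {
  normal_ids <- names(labels)[labels == 0L]
  pool <- names(labels)[labels == 1L]
  n_draw <- ratio * length(normal_ids)
  if (length(pool) < n_draw) {
    stop(sprintf(
      "tumor pool too small: need %d (= ratio %d x %d normals), have %d",
      n_draw, ratio, length(normal_ids), length(pool)), call. = FALSE)
  }
  if (length(normal_ids) == 0) stop("no normal samples", call. = FALSE)
  draws <- with_seed(seed, {
    lapply(seq_len(n_iterations), function(i) sample(pool, n_draw))
  })
  structure(list(normal_ids = normal_ids, tumor_pool_ids = pool,
                 draws = draws, n_iterations = as.integer(n_iterations),
                 ratio = ratio, seed = seed),
            class = "resampling_plan")
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat(sprintf(
    "resampling_plan: %d iterations, %d normals + %d drawn tumors (1:%s) from a pool of %d\n",
    x$n_iterations, length(x$normal_ids), length(x$draws[[1]]), x$ratio,
    length(x$tumor_pool_ids)))
  invisible(x)
}

# Total-count normalization to a common pseudo-library size (geometric mean
# of library sizes). Returns unrounded normalized values; the exact test
# rounds them to integer pseudo-counts.
normalize_counts <- function(m) {
  lib <- colSums(m)
  if (all(lib == 0)) stop("all library sizes are zero", call. = FALSE)
  ref <- exp(mean(log(lib[lib > 0])))
  f <- ifelse(lib > 0, ref / lib, 1)
  sweep(m, 2, f, "*")
}

# Method-of-moments common dispersion on normalized counts: per gene, a
# df-weighted within-group estimate (v - m) / m^2, summarized by the median
# over genes and floored at 1e-4.
estimate_common_dispersion <- function(norm, groups, floor = 1e-4) {
  phis <- rep(NA_real_, nrow(norm))
  num <- numeric(nrow(norm))
  den <- numeric(nrow(norm))
  for (g in unique(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    n <- ncol(sub)
    if (n < 2) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    ok <- m > 0
    contrib <- ifelse(ok, (v - m) / m^2, NA_real_)
    w <- n - 1
    num <- num + ifelse(is.na(contrib), 0, contrib * w)
    den <- den + ifelse(is.na(contrib), 0, w)
  }
  phis <- ifelse(den > 0, num / den, NA_real_)
  est <- stats::median(phis, na.rm = TRUE)
  if (!is.finite(est)) est <- floor
  max(est, floor)
}

# Conditional NB exact p-value for group totals yA, yB from nA and nB
# samples sharing dispersion phi. Under a common per-sample mean the sums
# are NB with sizes nA/phi and nB/phi and a common success probability, so
# the distribution of yA given the total s is free of the mean:
#   P(a | s) = C(a + r1 - 1, a) C(s - a + r2 - 1, s - a) / C(s + r1 + r2 - 1, s)
# Two-sided p by doubling the smaller tail (capped at 1), or by summing all
# outcomes at most as probable as the observed one (method "smallp", with an
# edgeR-style 1 + 1e-8 tie tolerance).
exact_nb_pvalue <- function(yA, yB, nA, nB, phi,
                            method = c("doubling", "smallp")) {
  method <- match.arg(method)
  s <- yA + yB
  if (s == 0) return(1)
  r1 <- nA / phi
  r2 <- nB / phi
  a <- 0:s
  logp <- lgamma(a + r1) - lgamma(a + 1) - lgamma(r1) +
    lgamma(s - a + r2) - lgamma(s - a + 1) - lgamma(r2) -
    (lgamma(s + r1 + r2) - lgamma(s + 1) - lgamma(r1 + r2))
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  if (method == "doubling") {
    pl <- sum(p[a <= yA])
    pu <- sum(p[a >= yA])
    min(1, 2 * min(pl, pu))
  } else {
    min(1, sum(p[p <= p[yA + 1] * (1 + 1e-8)]))
  }
}

#' Negative-binomial exact test between two sample groups
#'
#' Per gene, a conditional exact test on the group totals of total-count
#' normalized pseudo-counts, assuming a common NB dispersion: the two-sided
#' p-value comes from the conditional distribution of the group-A total
#' given the overall total (see the package vignette for the construction).
#' log2 fold-changes are ratios of normalized group means with a 0.5
#' pseudo-count. Genes with zero counts in both groups get `p = 1`,
#' `log2fc = 0` and are flagged.
#'
#' @param counts a [count_matrix()].
#' @param groupA,groupB disjoint character vectors of sample ids; the
#'   reported log2 fold-change is groupA over groupB (tumor over normal in
#'   the stability loop).
#' @param dispersion `"estimate"` for a method-of-moments common dispersion,
#'   or a fixed positive number.
#' @param p_method `"doubling"` (two-sided p = twice the smaller tail,
#'   capped at 1; the default) or `"smallp"` (sum of outcomes no more
#'   probable than observed).
#' @return data.frame with columns `gene_id`, `log2fc`, `pvalue`, `flagged`.
#' @export
nb_exact_test <- function(counts, groupA, groupB, dispersion = "estimate",
                          p_method = c("doubling", "smallp")) {
  p_method <- match.arg(p_method)
  m <- unclass(as.matrix(counts))
  if (length(groupA) == 0 || length(groupB) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(groupA, groupB))) {
    stop("groups overlap", call. = FALSE)
  }
  sub <- m[, c(groupA, groupB), drop = FALSE]
  norm <- normalize_counts(sub)
  groups <- rep(c("A", "B"), c(length(groupA), length(groupB)))
  phi <- if (identical(dispersion, "estimate")) {
    estimate_common_dispersion(norm, groups)
  } else {
    stopifnot(is.numeric(dispersion), dispersion > 0)
    dispersion
  }
  pseudo <- round(norm)
  nA <- length(groupA)
  nB <- length(groupB)
  yA <- rowSums(pseudo[, groups == "A", drop = FALSE])
  yB <- rowSums(pseudo[, groups == "B", drop = FALSE])
  mA <- rowMeans(norm[, groups == "A", drop = FALSE])
  mB <- rowMeans(norm[, groups == "B", drop = FALSE])
  flagged <- (yA + yB) == 0
  log2fc <- ifelse(flagged, 0, log2((mA + 0.5) / (mB + 0.5)))
  pvalue <- vapply(seq_len(nrow(m)), function(i) {
    if (flagged[i]) return(1)
    exact_nb_pvalue(yA[i], yB[i], nA, nB, phi, method = p_method)
  }, numeric(1))
  data.frame(gene_id = rownames(m), log2fc = log2fc, pvalue = pvalue,
             flagged = flagged, stringsAsFactors = FALSE, row.names = NULL)
}

#' Count per-gene differential-expression frequency over a resampling plan
#'
#' Runs the NB exact test on every iteration of the plan (all normals vs the
#' drawn tumors) and counts, per gene, the iterations in which it is
#' significant (`|log2fc| > lfc_threshold` and `p < p_threshold`, both raw -
#' no multiple-testing correction inside the loop).
#'
#' @param counts a [count_matrix()].
#' @param labels named 0/1 vector consistent with the plan.
#' @param plan a [make_resampling_plan()].
#' @param lfc_threshold absolute log2 fold-change cut (default 1).
#' @param p_threshold raw p-value cut (default 0.05).
#' @param dispersion passed to [nb_exact_test()].
#' @return A `frequency_table`: list with `frequency` (named integer vector,
#'   0..n_iterations), `n_iterations`, and `all_genes` (genes significant in
#'   at least one iteration, the "All" feature set).
#' @export
run_stability <- function(counts, labels, plan, lfc_threshold = 1,
                          p_threshold = 0.05, dispersion = "estimate") {
  stopifnot(inherits(plan, "resampling_plan"))
  if (!all(plan$normal_ids %in% names(labels)) ||
      !all(plan$tumor_pool_ids %in% names(labels))) {
    stop("plan references samples absent from labels", call. = FALSE)
  }
  genes <- rownames(counts)
  freq <- stats::setNames(integer(length(genes)), genes)
  for (i in seq_along(plan$draws)) {
    res <- nb_exact_test(counts, groupA = plan$draws[[i]],
                         groupB = plan$normal_ids, dispersion = dispersion)
    sig <- abs(res$log2fc) > lfc_threshold & res$pvalue < p_threshold
    freq[res$gene_id[sig]] <- freq[res$gene_id[sig]] + 1L
  }
  structure(list(frequency = freq,
                 n_iterations = length(plan$draws),
                 all_genes = names(freq)[freq > 0]),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf(
    "frequency_table: %d genes over %d iterations; %d ever significant\n",
    length(x$frequency), x$n_iterations, length(x$all_genes)))
  invisible(x)
}

#' Write a frequency table as a two-column TSV (gene, frequency)
#' @param freq a `frequency_table`.
#' @param path output file.
#' @export
write_frequency_table <- function(freq, path) {
  utils::write.table(
    data.frame(gene_id = names(freq$frequency),
               frequency = as.integer(freq$frequency)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Threshold a frequency table into nested feature sets
#'
#' Returns the "All" set (genes significant at least once) plus one set per
#' frequency threshold (`frequency >= threshold`); higher thresholds always
#' give subsets of lower ones.
#'
#' @param freq a `frequency_table` from [run_stability()].
#' @param thresholds integer thresholds (default `c(950, 750)` out of 1000
#'   iterations).
#' @return Named list of `feature_set` objects (`name`, `gene_ids`,
#'   `threshold`).
#' @export
build_feature_sets <- function(freq, thresholds = c(950, 750)) {
  stopifnot(inherits(freq, "frequency_table"))
  sets <- list(All = structure(
    list(name = "All", gene_ids = freq$all_genes, threshold = 1L),
    class = "feature_set"))
  for (t in thresholds) {
    nm <- paste0("Freq>=", t)
    if (t > freq$n_iterations) {
      warning(sprintf("threshold %d exceeds n_iterations (%d); set '%s' is empty",
                      t, freq$n_iterations, nm), call. = FALSE)
    }
    # Freq sets are subsets of "All" by construction, so a threshold of 0
    # coincides with the ever-significant set.
    genes <- names(freq$frequency)[freq$frequency >= max(t, 1L)]
    sets[[nm]] <- structure(
      list(name = nm, gene_ids = genes, threshold = as.integer(t)),
      class = "feature_set")
  }
  sets
}
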