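#' Per-sample contribution rates
#'
#' Converts signed attribution values into contribution *rates*: each
#' gene's share of its sample's total attribution magnitude,
#' `r_ij = f_ij / sum_j |f_ij|`, so that `sum_j |r_ij| = 1` for every
#' sample. Rates put samples with different prediction scales on a common
#' footing; a rate of 0.05 reads "this gene carries 5% of everything the
#' model used for this sample".
#'
#' @param attr an [attribute_genes()] result.
#' @return samples x genes matrix of signed rates.
#' @export
attribution_rates <- function(attr) {
  v <- if (inherits(attr, "attribution_matrix")) attr$values else attr
  v / pmax(rowSums(abs(v)), 1e-12)
}

#' Significant-contribution cutoffs
#'
#' Two conventions for turning the reference levels 5% / 1% / 0.5% into
#' cutoffs on the contribution values:
#'
#' * `"rate"` (the discovery default): absolute cutoffs `+/- q` on the
#'   per-sample contribution-rate scale (see [attribution_rates()]) - a
#'   contribution is significant when the gene accounts for more than a
#'   fraction `q` of its sample's total attribution magnitude.
#' * `"quantile"`: empirical upper/lower `q` tails of the distribution
#'   formed by all raw attribution values pooled over samples and genes
#'   (linear-interpolation quantiles, `stats::quantile` type 7).
#'
#' The rate convention adapts to how concentrated the model's evidence is
#' (a sparsely-relying model yields many significant cells, a diffuse one
#' few), whereas quantile tails mark a fixed `2q` fraction of all
#' gene-sample cells significant by construction; the vignette discusses
#' the choice.
#'
#' @param attr an [attribute_genes()] result (or a numeric matrix/vector of
#'   attribution values).
#' @param q significance level, in (0, 0.5).
#' @param method `"rate"` or `"quantile"`.
#' @return A `contribution_thresholds` list: `q`, `pos_cutoff`,
#'   `neg_cutoff`, `method` (`neg_cutoff <= pos_cutoff` always).
#' @export
compute_thresholds <- function(attr, q, method = c("rate", "quantile")) {
  method <- match.arg(method)
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 0.5) {
    stop("q must be a single value in (0, 0.5)", call. = FALSE)
  }
  if (method == "rate") {
    structure(list(q = q, pos_cutoff = q, neg_cutoff = -q, method = method),
              class = "contribution_thresholds")
  } else {
    v <- if (inherits(attr, "attribution_matrix")) attr$values else attr
    v <- as.numeric(v)
    structure(list(q = q,
                   pos_cutoff = unname(stats::quantile(v, 1 - q, type = 7)),
                   neg_cutoff = unname(stats::quantile(v, q, type = 7)),
                   method = method),
              class = "contribution_thresholds")
  }
}

#' Harmonic-mean biomarker potential score per gene
#'
#' For each gene, `C_P` counts tumor samples whose attribution exceeds the
#' positive cutoff and `C_N` counts normal samples whose attribution falls
#' below the negative cutoff (contributions are only counted in the
#' class-concordant direction). With `P_tumor = C_P / N_tumor` and
#' `P_normal = C_N / N_normal`, the score is their harmonic mean
#' `2 P_tumor P_normal / (P_tumor + P_normal)`, defined as 0 when both
#' proportions are 0. The score lies in \[0,1\], is symmetric and monotone in
#' each proportion, and is 0 whenever either proportion is 0 - so only genes
#' contributing consistently in *both* classes score highly.
#'
#' Only genes with at least one significant contribution (a cell beyond
#' either cutoff, in any sample) enter the score table - these are the
#' "significantly contributing genes" over which the downstream quartile
#' filter operates; set `only_significant = FALSE` to score every gene.
#'
#' @param attr an [attribute_genes()] result.
#' @param labels named 0/1 vector covering the attributed samples.
#' @param thr a [compute_thresholds()] result; with `method = "rate"` the
#'   counting happens on the contribution-rate scale.
#' @param only_significant restrict the table to significantly contributing
#'   genes (default TRUE).
#' @return data.frame with columns `gene_id`, `c_p`, `c_n`, `p_tumor`,
#'   `p_normal`, `score`, sorted by decreasing score.
#' @export
score_genes <- function(attr, labels, thr, only_significant = TRUE) {
  stopifnot(inherits(thr, "contribution_thresholds"))
  v <- if (identical(thr$method, "rate")) {
    attribution_rates(attr)
  } else {
    attr$values
  }
  ids <- rownames(v)
  if (!all(ids %in% names(labels))) {
    stop("labels missing for some attributed samples", call. = FALSE)
  }
  y <- labels[ids]
  n_tumor <- sum(y == 1)
  n_normal <- sum(y == 0)
  if (n_tumor == 0 || n_normal == 0) {
    stop("both classes required to score genes", call. = FALSE)
  }
  c_p <- colSums(v[y == 1, , drop = FALSE] > thr$pos_cutoff)
  c_n <- colSums(v[y == 0, , drop = FALSE] < thr$neg_cutoff)
  p_tumor <- c_p / n_tumor
  p_normal <- c_n / n_normal
  denom <- p_tumor + p_normal
  score <- ifelse(denom == 0, 0, 2 * p_tumor * p_normal / denom)
  out <- data.frame(gene_id = colnames(v), c_p = as.integer(c_p),
                    c_n = as.integer(c_n), p_tumor = p_tumor,
                    p_normal = p_normal, score = score,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (only_significant) {
    sig <- colSums(v > thr$pos_cutoff | v < thr$neg_cutoff) > 0
    out <- out[sig, , drop = FALSE]
  }
  out[order(-out$score, out$gene_id), , drop = FALSE]
}

#' Top-quartile score filter
#'
#' Retains genes whose score is at least the 25th percentile of all scores
#' in descending order - i.e. the top quartile, with the lower bound at the
#' 75th ascending percentile (linear-interpolation quantile) and boundary
#' ties included.
#'
#' @param table a [score_genes()] data.frame.
#' @param fraction fraction of top scores retained (default 0.25).
#' @return Character vector of retained gene ids.
#' @export
quartile_filter <- function(table, fraction = 0.25) {
  if (nrow(table) < 4) {
    stop("need at least 4 scored genes for a quartile cut", call. = FALSE)
  }
  bound <- stats::quantile(table$score, 1 - fraction, type = 7)
  table$gene_id[table$score >= bound]
}

#' Construct a candidate gene set with provenance
#'
#' @param gene_ids character vector.
#' @param provenance named list describing how the set was produced (sample
#'   set index, feature configuration, threshold groups intersected, ...).
#' @return A `candidate_set`.
#' @export
candidate_set <- function(gene_ids, provenance = list()) {
  structure(list(gene_ids = unique(as.character(gene_ids)),
                 provenance = provenance),
            class = "candidate_set")
}

#' Intersect candidate gene sets
#'
#' @param sets non-empty list of `candidate_set` objects (or plain character
#'   vectors).
#' @return A `candidate_set` whose genes lie in every input set and whose
#'   provenance is the list of input provenances.
#' @export
intersect_candidates <- function(sets) {
  if (length(sets) == 0) stop("no candidate sets to intersect", call. = FALSE)
  gene_lists <- lapply(sets, function(s) {
    if (inherits(s, "candidate_set")) s$gene_ids else as.character(s)
  })
  prov <- lapply(sets, function(s) {
    if (inherits(s, "candidate_set")) s$provenance else NULL
  })
  candidate_set(Reduce(intersect, gene_lists),
                provenance = list(intersected = prov))
}

# stratified train/test split by class; returns list(train_ids, test_ids)
stratified_split <- function(ids, labels, fraction, seed) {
  y <- labels[ids]
  with_seed(seed, {
    train <- unlist(lapply(split(ids, y), function(g) {
      sample(g, max(1, round(fraction * length(g))))
    }), use.names = FALSE)
    list(train_ids = sort(train), test_ids = sort(setdiff(ids, train)))
  })
}

#' Configuration for the end-to-end biomarker discovery run
#'
#' Defaults are the reference settings: 1000 resampling iterations at a 1:6
#' normal:tumor ratio, significance at |log2FC| > 1 and p < 0.05, frequency
#' cutoffs at 95% and 75% of the iteration count, contribution tails at
#' 5%/1%/0.5%, a top-quartile score cut, and the reference training
#' schedule. `n_sample_sets` limits how many resampled sets get the neural
#' stage (default: all of them).
#'
#' @param n_iterations,ratio resampling design.
#' @param lfc_threshold,p_threshold per-iteration significance cuts.
#' @param freq_fractions frequency cutoffs as fractions of `n_iterations`
#'   (thresholds are `ceiling(fraction * n_iterations)`).
#' @param n_sample_sets number of resampled sample sets carried through
#'   training/attribution/scoring (`NULL` = all iterations).
#' @param q_list contribution significance levels.
#' @param threshold_method convention for turning `q_list` into cutoffs;
#'   see [compute_thresholds()].
#' @param quartile fraction of top scores kept per threshold group.
#' @param schedule a [training_schedule()].
#' @param arch optional [vaejmlp_architecture()] override (default:
#'   auto-scaled per feature set).
#' @param dispersion dispersion setting for the exact test.
#' @param seed master seed; stage seeds are derived from it.
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(n_iterations = 1000, ratio = 6,
                             lfc_threshold = 1, p_threshold = 0.05,
                             freq_fractions = c(0.95, 0.75),
                             n_sample_sets = NULL,
                             q_list = c(0.05, 0.01, 0.005),
                             threshold_method = c("rate", "quantile"),
                             quartile = 0.25,
                             schedule = training_schedule(),
                             arch = NULL,
                             dispersion = "estimate",
                             seed = 1) {
  threshold_method <- match.arg(threshold_method)
  cfg <- structure(list(n_iterations = as.integer(n_iterations),
                        ratio = ratio, lfc_threshold = lfc_threshold,
                        p_threshold = p_threshold,
                        freq_fractions = freq_fractions,
                        n_sample_sets = n_sample_sets,
                        q_list = q_list, threshold_method = threshold_method,
                        quartile = quartile,
                        schedule = schedule, arch = arch,
                        dispersion = dispersion, seed = seed),
                   class = "discovery_config")
  errs <- validate_config(cfg)
  if (length(errs)) {
    stop("invalid discovery config: ", paste(errs, collapse = "; "),
         call. = FALSE)
  }
  cfg
}

#' Validate a discovery configuration
#'
#' @param config a [discovery_config()] (checked for cross-field
#'   consistency: tail fractions below 0.5, frequency fractions in (0,1\],
#'   sample-set count within the iteration count, positive quartile
#'   fraction).
#' @return Character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  if (config$n_iterations < 1) errs <- c(errs, "n_iterations must be >= 1")
  if (config$ratio < 1) errs <- c(errs, "ratio must be >= 1")
  if (any(config$q_list <= 0 | config$q_list >= 0.5)) {
    errs <- c(errs, "q_list entries must be in (0, 0.5)")
  }
  if (any(config$freq_fractions <= 0 | config$freq_fractions > 1)) {
    errs <- c(errs, "freq_fractions must be in (0, 1]")
  }
  if (!is.null(config$n_sample_sets) &&
      config$n_sample_sets > config$n_iterations) {
    errs <- c(errs, "n_sample_sets exceeds n_iterations")
  }
  if (config$quartile <= 0 || config$quartile >= 1) {
    errs <- c(errs, "quartile must be in (0, 1)")
  }
  if (!inherits(config$schedule, "training_schedule")) {
    errs <- c(errs, "schedule must be a training_schedule")
  }
  errs
}

#' Run the full biomarker discovery pipeline
#'
#' Orchestrates: stability resampling and frequency-thresholded feature sets
#' -> per sample set and per feature configuration, a jointly trained VAE +
#' MLP classifier -> expected-gradients attribution -> per tail fraction,
#' significance thresholds, harmonic-mean scores and a top-quartile cut ->
#' intersection of the tail-fraction groups into one candidate set per
#' (sample set, feature configuration) -> global intersection of all
#' candidate sets into the final gene list. Deterministic under the config
#' seed.
#'
#' @param counts a [count_matrix()].
#' @param labels named 0/1 vector (0 = normal, 1 = tumor).
#' @param config a [discovery_config()].
#' @return A `biomarker_result`: list with `final_genes`, `candidate_sets`,
#'   `feature_sets`, `frequency` (the frequency table), `metrics` (one row
#'   per trained model), and `config`.
#' @export
run_discovery <- function(counts, labels, config = discovery_config()) {
  stopifnot(inherits(config, "discovery_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("discovery failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  plan <- stage("resampling_plan",
                make_resampling_plan(labels, config$n_iterations,
                                     config$ratio,
                                     seed = derive_seed(config$seed, "plan")))
  freq <- stage("stability",
                run_stability(counts, labels, plan,
                              lfc_threshold = config$lfc_threshold,
                              p_threshold = config$p_threshold,
                              dispersion = config$dispersion))
  thresholds <- ceiling(config$freq_fractions * config$n_iterations)
  fsets <- stage("feature_sets", build_feature_sets(freq, thresholds))
  fsets <- Filter(function(s) length(s$gene_ids) >= 2, fsets)
  if (length(fsets) == 0) {
    stop("discovery failed at stage 'feature_sets': no non-trivial feature set",
         call. = FALSE)
  }

  n_sets <- config$n_sample_sets %||% config$n_iterations
  candidates <- list()
  metrics <- list()
  for (s in seq_len(n_sets)) {
    set_ids <- c(plan$normal_ids, plan$draws[[s]])
    for (fs in fsets) {
      run_tag <- sprintf("set%d/%s", s, fs$name)
      sub <- counts[fs$gene_ids, set_ids, drop = FALSE]
      split <- stratified_split(set_ids, labels,
                                config$schedule$split_fraction,
                                seed = derive_seed(config$seed, run_tag,
                                                   "split"))
      scaled <- stage(paste0("scale/", run_tag),
                      minmax_scale(count_matrix(sub), split$train_ids))
      sched <- config$schedule
      sched$seed <- derive_seed(config$seed, run_tag, "train")
      arch <- config$arch %||% vaejmlp_architecture(length(fs$gene_ids))
      model <- stage(paste0("train/", run_tag),
                     vaejmlp_train(scaled, labels, arch, sched,
                                   split = split))
      attr <- stage(paste0("attribute/", run_tag),
                    attribute_genes(model, scaled,
                                    background = split$train_ids,
                                    seed = derive_seed(config$seed, run_tag,
                                                       "attr")))
      groups <- lapply(config$q_list, function(q) {
        thr <- compute_thresholds(attr, q, method = config$threshold_method)
        tab <- score_genes(attr, labels, thr)
        keep <- if (nrow(tab) >= 4) {
          quartile_filter(tab, config$quartile)
        } else {
          tab$gene_id    # too few significant genes for a quartile cut
        }
        candidate_set(keep, provenance = list(sample_set = s,
                                              feature_set = fs$name, q = q))
      })
      cand <- intersect_candidates(groups)
      cand$provenance <- list(sample_set = s, feature_set = fs$name,
                              q_intersected = config$q_list)
      candidates[[run_tag]] <- cand
      metrics[[run_tag]] <- data.frame(
        sample_set = s, feature_set = fs$name,
        n_features = length(fs$gene_ids),
        auc = model$metrics$auc, accuracy = model$metrics$accuracy,
        precision = model$metrics$precision, recall = model$metrics$recall,
        n_candidates = length(cand$gene_ids))
    }
  }
  final <- intersect_candidates(candidates)
  structure(list(final_genes = final$gene_ids,
                 candidate_sets = candidates,
                 feature_sets = fsets,
                 frequency = freq,
                 metrics = do.call(rbind, c(metrics,
                                            list(make.row.names = FALSE))),
                 config = config),
            class = "biomarker_result")
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat(sprintf(
    "biomarker_result: %d final genes from %d candidate sets (%d feature sets x %d sample sets)\n",
    length(x$final_genes), length(x$candidate_sets), length(x$feature_sets),
    length(unique(x$metrics$sample_set))))
  cat("  final genes:", paste(x$final_genes, collapse = ", "), "\n")
  invisible(x)
}
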