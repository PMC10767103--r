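#' Configuration for the negative-binomial count simulator
#'
#' The simulator emulates a two-class (normal vs tumor) bulk RNA-seq cohort:
#' per-gene baseline means drawn from a log-normal, negative-binomial
#' sampling noise with variance `mu + phi * mu^2`, multiplicative log-normal
#' library-size factors, a planted set of differential genes with
#' |log2 fold-change| in a stated range, and - central to the scoring stage -
#' a gradient of *consistency*: a subset of the differential genes
#' ("biomarkers") carries its fold-change in every tumor sample
#' (penetrance 1), while the remaining differential genes are heterogeneous,
#' shifted only in a `heterogeneous_penetrance` fraction of tumors. Ground
#' truth is recorded so recovery can be verified downstream.
#'
#' Defaults describe a small discovery cohort: 2000 genes, 10 normal and 60
#' tumor samples, 200 differential genes of which 20 are fully penetrant
#' biomarkers, |log2FC| in \[1.5, 3\], common dispersion 0.2 and 30%
#' library-size coefficient of variation.
#'
#' @param n_genes,n_normal,n_tumor cohort dimensions.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param baseline_logmean_dist `c(meanlog, sdlog)` of the log-normal from
#'   which per-gene baseline means are drawn.
#' @param dispersion common NB dispersion phi (`var = mu + phi mu^2`); may be
#'   a vector of length `n_genes` for gene-wise overrides.
#' @param n_de number of differential genes.
#' @param de_log2fc_range range of the |log2 fold-change| applied in carrier
#'   tumor samples. Biomarkers (penetrance 1) carry either sign;
#'   heterogeneous genes are up-shifted only, because a carrier fraction `p`
#'   caps any cohort-level down effect at `1/(1-p)` (a gene silenced in 30%
#'   of tumors changes the class mean less than 1.5-fold), so planted
#'   down-shifts at partial penetrance would not be differential at the
#'   class level. The recorded truth carries both the carrier-level and the
#'   implied cohort-level effect.
#' @param n_biomarkers number of differential genes planted with penetrance
#'   1 (the "consistent" biomarkers); must not exceed `n_de`.
#' @param heterogeneous_penetrance fraction of tumor samples carrying the
#'   shift for non-biomarker differential genes.
#' @param libsize_cv coefficient of variation of the multiplicative
#'   library-size factors.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_normal = 10, n_tumor = 60,
                              seed = 1,
                              baseline_logmean_dist = c(meanlog = 4, sdlog = 1),
                              dispersion = 0.2,
                              n_de = 200,
                              de_log2fc_range = c(1.5, 3),
                              n_biomarkers = 20,
                              heterogeneous_penetrance = 0.3,
                              libsize_cv = 0.3) {
  cfg <- list(n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
              n_tumor = as.integer(n_tumor), seed = seed,
              baseline_logmean_dist = baseline_logmean_dist,
              dispersion = dispersion, n_de = as.integer(n_de),
              de_log2fc_range = as.numeric(de_log2fc_range),
              n_biomarkers = as.integer(n_biomarkers),
              heterogeneous_penetrance = heterogeneous_penetrance,
              libsize_cv = libsize_cv)
  if (cfg$n_de > cfg$n_genes) {
    stop("n_de exceeds n_genes", call. = FALSE)
  }
  if (cfg$n_biomarkers > cfg$n_de) {
    stop("n_biomarkers exceeds n_de", call. = FALSE)
  }
  if (any(cfg$dispersion <= 0)) stop("dispersion must be > 0", call. = FALSE)
  if (cfg$heterogeneous_penetrance <= 0 || cfg$heterogeneous_penetrance > 1) {
    stop("heterogeneous_penetrance must be in (0, 1]", call. = FALSE)
  }
  if (cfg$libsize_cv < 0) stop("libsize_cv must be >= 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Simulate a two-class NB count matrix with planted biomarkers
#'
#' Counts for gene g, sample j are drawn NB with mean `s_j * mu_gj` and
#' dispersion phi, where `mu_gj = mu_g * 2^(lfc_g)` for tumor samples that
#' carry the planted shift and `mu_g` otherwise. Deterministic under the
#' configured seed.
#'
#' @param config a [simulation_config()].
#' @return List with `counts` (a [count_matrix()]), `labels` (named 0/1
#'   vector), and `truth`: a list with `de_gene_ids`, `biomarker_gene_ids`,
#'   per-gene cohort-level `log2fc` and carrier-level `carrier_log2fc`, the
#'   tumor `carriers` indicator matrix (DE genes x tumor samples) and
#'   per-sample library-size `factors`.
#' @export
simulate_counts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    nn <- config$n_normal
    nt <- config$n_tumor
    gene_ids <- sprintf("gene%04d", seq_len(ng))
    sample_ids <- c(sprintf("normal%03d", seq_len(nn)),
                    sprintf("tumor%03d", seq_len(nt)))
    labels <- label_vector(sample_ids, c(rep(0L, nn), rep(1L, nt)))

    mu <- stats::rlnorm(ng, meanlog = config$baseline_logmean_dist[[1]],
                        sdlog = config$baseline_logmean_dist[[2]])
    phi <- rep_len(config$dispersion, ng)

    de_idx <- sort(sample.int(ng, config$n_de))
    bm_idx <- sort(sample(de_idx, config$n_biomarkers))
    log2fc <- numeric(ng)        # cohort-level effect, tumor over normal
    carrier_lfc <- numeric(ng)   # shift applied in carrier tumor samples
    if (config$n_de > 0) {
      mag <- stats::runif(config$n_de, config$de_log2fc_range[1],
                          config$de_log2fc_range[2])
      # Heterogeneous genes are up-shifted only (see de_log2fc_range docs);
      # fully penetrant biomarkers carry either sign.
      pen <- ifelse(de_idx %in% bm_idx, 1, config$heterogeneous_penetrance)
      sgn <- ifelse(pen < 1, 1, sample(c(-1, 1), config$n_de, replace = TRUE))
      carrier_lfc[de_idx] <- mag * sgn
      # implied cohort-level (class-mean) effect: 2^L = 1 + pen*(2^delta - 1)
      log2fc[de_idx] <- ifelse(
        carrier_lfc[de_idx] > 0,
        log2(1 + pen * (2^(carrier_lfc[de_idx]) - 1)),
        carrier_lfc[de_idx])
    }

    # carrier indicators: biomarkers shift every tumor sample, heterogeneous
    # DE genes only a penetrance fraction
    carriers <- matrix(0L, nrow = config$n_de, ncol = nt,
                       dimnames = list(gene_ids[de_idx],
                                       sample_ids[labels == 1L]))
    if (config$n_de > 0) {
      pen <- ifelse(de_idx %in% bm_idx, 1, config$heterogeneous_penetrance)
      carriers[] <- stats::rbinom(config$n_de * nt, 1L,
                                  rep(pen, times = nt))
    }

    if (config$libsize_cv > 0) {
      sdlog <- sqrt(log(1 + config$libsize_cv^2))
      sf <- stats::rlnorm(nn + nt, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      sf <- rep(1, nn + nt)
    }
    names(sf) <- sample_ids

    mu_mat <- matrix(mu, nrow = ng, ncol = nn + nt)
    if (config$n_de > 0) {
      fc <- 2^(carrier_lfc[de_idx])
      tum_cols <- which(labels == 1L) # appended after normals
      mu_mat[de_idx, tum_cols] <- mu_mat[de_idx, tum_cols] *
        ifelse(carriers == 1L, fc, 1)
    }
    mu_mat <- sweep(mu_mat, 2, sf, "*")
    counts <- matrix(stats::rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                                    size = rep(1 / phi, nn + nt)),
                     nrow = ng, dimnames = list(gene_ids, sample_ids))
    truth <- list(de_gene_ids = gene_ids[de_idx],
                  biomarker_gene_ids = gene_ids[bm_idx],
                  log2fc = stats::setNames(log2fc, gene_ids),
                  carrier_log2fc = stats::setNames(carrier_lfc, gene_ids),
                  carriers = carriers,
                  factors = sf,
                  baseline_mu = stats::setNames(mu, gene_ids),
                  dispersion = stats::setNames(phi, gene_ids))
    list(counts = count_matrix(counts), labels = labels, truth = truth)
  })
}

#' Simulate survival outcomes driven by a risk score
#'
#' Event times are exponential with hazard proportional to
#' `exp(effect * z)` where `z` is the standardized risk score; a
#' `censor_rate` fraction of samples (in expectation) is censored at an
#' independent uniform time before the event.
#'
#' @param risk_scores named numeric vector, one score per sample.
#' @param baseline_hazard events per day at the average score.
#' @param effect log-hazard increase per standard deviation of score.
#' @param censor_rate expected fraction of censored samples in \[0, 1\].
#' @param seed RNG seed.
#' @return A [survival_table()].
#' @export
simulate_survival <- function(risk_scores, baseline_hazard = 1 / 1000,
                              effect = 1, censor_rate = 0.3, seed = 1) {
  if (any(!is.finite(risk_scores))) {
    stop("risk scores must be finite", call. = FALSE)
  }
  if (is.null(names(risk_scores))) {
    names(risk_scores) <- sprintf("sample%03d", seq_along(risk_scores))
  }
  if (censor_rate < 0 || censor_rate > 1) {
    stop("censor_rate must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    z <- if (stats::sd(risk_scores) > 0) {
      (risk_scores - mean(risk_scores)) / stats::sd(risk_scores)
    } else {
      rep(0, length(risk_scores))
    }
    haz <- baseline_hazard * exp(effect * z)
    t_event <- stats::rexp(length(z), rate = haz)
    censored <- stats::runif(length(z)) < censor_rate
    time <- ifelse(censored, stats::runif(length(z), 0, t_event), t_event)
    survival_table(names(risk_scores), time, as.integer(!censored))
  })
}
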