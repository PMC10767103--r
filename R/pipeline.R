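#' Assemble a full pipeline configuration
#'
#' Binds input paths, the discovery configuration and the optional
#' prognostic step into one serializable object. All randomness downstream
#' is derived from `discovery$seed`, so a config fully determines a run.
#'
#' @param counts path to a count matrix (TSV/CSV/MTX) or a [count_matrix()].
#' @param labels path to a labels TSV or a named 0/1 vector.
#' @param outdir output directory (created if needed).
#' @param survival optional path to a survival TSV or a [survival_table()];
#'   enables the risk-model step on the discovered genes.
#' @param discovery a [discovery_config()].
#' @param cox_p univariate Cox p-value cut for genes entering the
#'   multivariate risk model.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(counts, labels, outdir, survival = NULL,
                            discovery = discovery_config(), cox_p = 0.05) {
  stopifnot(inherits(discovery, "discovery_config"))
  structure(list(counts = counts, labels = labels, survival = survival,
                 outdir = outdir, discovery = discovery, cox_p = cox_p),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `counts`, `labels`, `survival`, `outdir`, `cox_p` plus a
#' `discovery` block whose keys are [discovery_config()] arguments and a
#' nested `schedule` block with [training_schedule()] arguments. Unknown
#' keys are rejected by name.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("counts", "labels", "survival", "outdir", "cox_p",
                 "discovery")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  disc_args <- raw$discovery %||% list()
  sched_args <- disc_args$schedule %||% list()
  disc_args$schedule <- NULL
  bad <- setdiff(names(disc_args), names(formals(discovery_config)))
  if (length(bad)) {
    stop("unknown discovery config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(names(sched_args), names(formals(training_schedule)))
  if (length(bad)) {
    stop("unknown schedule config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  disc_args$schedule <- do.call(training_schedule, sched_args)
  pipeline_config(counts = raw$counts, labels = raw$labels,
                  outdir = raw$outdir %||% ".",
                  survival = raw$survival,
                  discovery = do.call(discovery_config, disc_args),
                  cox_p = raw$cox_p %||% 0.05)
}

#' Run the complete pipeline and persist all artifacts
#'
#' Executes discovery (stability DE, model training, attribution, scoring,
#' intersection) and, when survival data are supplied, the prognostic step:
#' univariate Cox screening of the final genes, a multivariate Cox risk
#' model, median-split risk groups and a log-rank comparison. All tabular
#' outputs are TSV, gene lists are one id per line, and a JSON manifest
#' records the config, seeds, package version and per-stage wall-clock so a
#' run can be reproduced exactly.
#'
#' @param config a [pipeline_config()].
#' @return The `biomarker_result`, invisibly, with a `risk` element when the
#'   prognostic step ran.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name, t_start) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t_start, 3)
  }

  counts <- if (is.character(config$counts)) {
    read_count_matrix(config$counts)
  } else {
    validate_count_matrix(config$counts)
  }
  labels <- if (is.character(config$labels)) {
    read_labels(config$labels)
  } else {
    config$labels
  }
  surv <- if (is.character(config$survival)) {
    read_survival(config$survival)
  } else {
    config$survival
  }
  tick("load", t0)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t1 <- proc.time()[["elapsed"]]
  result <- run_discovery(counts, labels, config$discovery)
  tick("discovery", t1)

  out <- function(...) file.path(config$outdir, ...)
  write_frequency_table(result$frequency, out("frequency.tsv"))
  for (fs in result$feature_sets) {
    writeLines(fs$gene_ids,
               out(sprintf("features_%s.txt", gsub("[^A-Za-z0-9]+", "_",
                                                   fs$name))))
  }
  utils::write.table(result$metrics, out("metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(result$final_genes, out("final_genes.txt"))

  risk_out <- NULL
  if (!is.null(surv) && length(result$final_genes) > 0) {
    t2 <- proc.time()[["elapsed"]]
    norm <- normalize_counts(unclass(as.matrix(counts)))
    uni <- fit_cox(norm, surv, genes = result$final_genes,
                   mode = "univariate")
    sig <- uni$gene_id[!is.na(uni$p_value) & uni$p_value < config$cox_p]
    risk_out <- list(univariate = uni, significant = sig)
    if (length(sig) >= 1) {
      multi <- fit_cox(norm, surv, genes = sig, mode = "multivariate")
      rm_model <- risk_model(multi$gene_id, multi$coef,
                             expression_source = "total-count normalized")
      ids <- intersect(colnames(norm), surv$sample_id)
      scores <- risk_score(rm_model, norm[, ids, drop = FALSE])
      groups <- median_split(scores)
      lr <- logrank_test(groups, surv)
      risk_out$multivariate <- multi
      risk_out$model <- rm_model
      risk_out$groups <- groups
      risk_out$logrank <- lr
      utils::write.table(
        data.frame(gene_id = rm_model$gene_ids,
                   coefficient = unname(rm_model$coefficients)),
        out("risk_model.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = names(scores), risk_score = unname(scores),
                   group = as.character(groups$group[names(scores)])),
        out("risk_groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(uni, out("cox_univariate.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tick("prognostic", t2)
  }

  manifest <- list(
    package = "vaemarker",
    version = as.character(utils::packageVersion("vaemarker")),
    r_version = R.version.string,
    seed = config$discovery$seed,
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_final_genes = length(result$final_genes),
    final_genes = result$final_genes,
    logrank_p = if (!is.null(risk_out$logrank)) risk_out$logrank$p_value,
    config = serialize_config(config),
    timings_sec = timings)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  result$risk <- risk_out
  invisible(result)
}

# plain-list view of a pipeline config for the manifest
serialize_config <- function(config) {
  disc <- unclass(config$discovery)
  disc$schedule <- unclass(disc$schedule)
  disc$arch <- if (!is.null(disc$arch)) unclass(disc$arch)
  list(counts = if (is.character(config$counts)) config$counts else "<in-memory>",
       labels = if (is.character(config$labels)) config$labels else "<in-memory>",
       survival = if (is.character(config$survival)) config$survival
                  else if (!is.null(config$survival)) "<in-memory>",
       outdir = config$outdir, cox_p = config$cox_p, discovery = disc)
}
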