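#' Construct a linear risk model from signature genes and coefficients
#'
#' @param gene_ids signature gene identifiers.
#' @param coefficients finite regression coefficients, one per gene
#'   (typically from a multivariate Cox fit, see [fit_cox()]).
#' @param expression_source free-text note on the expression scale the
#'   coefficients were fitted on.
#' @return A `risk_model`.
#' @export
risk_model <- function(gene_ids, coefficients,
                       expression_source = "normalized counts") {
  gene_ids <- as.character(gene_ids)
  coefficients <- as.numeric(coefficients)
  if (length(gene_ids) != length(coefficients)) {
    stop("one coefficient per gene required", call. = FALSE)
  }
  if (any(!is.finite(coefficients))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  structure(list(gene_ids = gene_ids,
                 coefficients = stats::setNames(coefficients, gene_ids),
                 expression_source = expression_source),
            class = "risk_model")
}

#' Per-sample linear risk score
#'
#' `RiskScore_j = sum_i coef_i * expr_ij` over the signature genes - a
#' weighted sum of expression, linear and invariant to gene order.
#'
#' @param model a [risk_model()].
#' @param expr genes x samples numeric matrix containing all signature genes
#'   (same expression scale the coefficients were estimated on).
#' @return Named numeric vector of risk scores.
#' @export
risk_score <- function(model, expr) {
  stopifnot(inherits(model, "risk_model"))
  missing <- setdiff(model$gene_ids, rownames(expr))
  if (length(missing)) {
    stop("signature genes absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  drop(model$coefficients %*% expr[model$gene_ids, , drop = FALSE])
}

#' Median split into high- and low-risk groups
#'
#' Samples with score strictly above the median go to `High`; scores at or
#' below the median go to `Low` (deterministic tie rule). With distinct
#' scores the group sizes differ by at most one.
#'
#' @param scores named numeric vector of per-sample risk scores.
#' @return A `risk_groups` list: `scores`, `median`, `group` (named factor
#'   with levels `Low`, `High`).
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(names(scores))) {
    names(scores) <- sprintf("sample%03d", seq_along(scores))
  }
  med <- stats::median(scores)
  grp <- factor(ifelse(scores > med, "High", "Low"),
                levels = c("Low", "High"))
  if (all(grp == "Low")) {
    warning("all scores at or below the median; High group is empty",
            call. = FALSE)
  }
  structure(list(scores = scores, median = med,
                 group = stats::setNames(grp, names(scores))),
            class = "risk_groups")
}

#' Two-group log-rank test between risk groups
#'
#' Standard log-rank chi-square (1 df) comparing survival of the high- and
#' low-risk groups, computed with [survival::survdiff()].
#'
#' @param groups a [median_split()] result.
#' @param surv a [survival_table()] covering the grouped samples.
#' @return list with `statistic` (chi-square), `p_value`, and the per-group
#'   observed/expected event table.
#' @export
logrank_test <- function(groups, surv) {
  stopifnot(inherits(groups, "risk_groups"))
  ids <- names(groups$group)
  rownames(surv) <- surv$sample_id
  if (!all(ids %in% surv$sample_id)) {
    stop("survival data missing for some samples", call. = FALSE)
  }
  surv <- surv[ids, ]
  if (sum(surv$event) == 0) stop("no events observed", call. = FALSE)
  grp <- groups$group
  if (length(unique(grp)) < 2) {
    stop("both risk groups must be non-empty", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  stat <- sd$chisq
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = data.frame(group = sub("^grp=", "", names(sd$n)),
                          n = as.vector(sd$n),
                          observed = sd$obs, expected = sd$exp))
}

#' Cox proportional-hazards coefficients for candidate genes
#'
#' Delegates to [survival::coxph()]: in `"univariate"` mode each gene is fit
#' separately (the screening step for survival-associated biomarkers); in
#' `"multivariate"` mode all genes enter one model, whose coefficients feed
#' [risk_model()].
#'
#' @param expr genes x samples numeric matrix.
#' @param surv a [survival_table()].
#' @param genes genes to fit (default: all rows of `expr`).
#' @param mode `"univariate"` or `"multivariate"`.
#' @return data.frame with `gene_id`, `coef`, `hr` (hazard ratio), `p_value`
#'   and `converged`; non-converging fits are flagged rather than fatal.
#' @export
fit_cox <- function(expr, surv, genes = rownames(expr),
                    mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  rownames(surv) <- surv$sample_id
  ids <- intersect(colnames(expr), surv$sample_id)
  if (length(ids) < 2) stop("too few samples with survival data",
                            call. = FALSE)
  surv <- surv[ids, ]
  y <- survival::Surv(surv$time, surv$event)
  if (mode == "univariate") {
    rows <- lapply(genes, function(g) {
      x <- expr[g, ids]
      fit <- tryCatch(survival::coxph(y ~ x), error = function(e) NULL,
                      warning = function(w) {
                        suppressWarnings(survival::coxph(y ~ x))
                      })
      if (is.null(fit) || !is.finite(stats::coef(fit)[1])) {
        return(data.frame(gene_id = g, coef = NA_real_, hr = NA_real_,
                          p_value = NA_real_, converged = FALSE))
      }
      s <- summary(fit)
      data.frame(gene_id = g, coef = unname(stats::coef(fit)[1]),
                 hr = unname(s$conf.int[1, 1]),
                 p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
                 converged = TRUE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    X <- t(expr[genes, ids, drop = FALSE])
    colnames(X) <- make.names(genes)
    df <- data.frame(X, check.names = FALSE)
    fit <- survival::coxph(y ~ ., data = df)
    s <- summary(fit)
    data.frame(gene_id = genes, coef = unname(stats::coef(fit)),
               hr = unname(s$conf.int[, 1]),
               p_value = unname(s$coefficients[, "Pr(>|z|)"]),
               converged = is.finite(stats::coef(fit)),
               row.names = NULL)
  }
}
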