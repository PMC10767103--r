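# Gradient of the tumor-class logit with respect to the input features,
# through the deterministic encoder mean (no sampling at explanation time).
# X: samples x features. Returns a matrix of the same shape.
input_gradient <- function(model, X) {
  slope <- model$arch$activation_slope
  ec <- encode_params(model$params, X, slope)
  mlp_cache <- stack_forward(model$params$mlp, ec$mu$out, slope,
                             final_preact = TRUE)
  dL <- matrix(0, nrow(X), model$arch$n_classes)
  dL[, 2] <- 1   # tumor-class logit
  dz <- stack_backward(model$params$mlp, mlp_cache, dL, slope,
                       final_preact = TRUE)$dX
  dH <- stack_backward(model$params$mu, ec$mu, dz, slope,
                       final_preact = TRUE)$dX
  dX <- stack_backward(model$params$enc, ec$enc, dH, slope)$dX
  if (any(!is.finite(dX))) {
    bad <- which(rowSums(!is.finite(dX)) > 0)[1]
    stop("non-finite input gradient for sample index ", bad, call. = FALSE)
  }
  dX
}

#' Per-sample, per-gene contributions to the tumor-class output
#'
#' Expected-gradients estimate of SHAP-style additive attributions for the
#' composite map input -> encoder mean -> classifier -> tumor-class logit:
#' for each explained sample, input gradients are averaged along straight
#' paths from background references (drawn from the training split) to the
#' sample, with a stratified midpoint grid over the path position, and
#' multiplied by (sample - reference). The attributions decompose each
#' prediction as `y_i = y_base + sum_j f(x_ij)` where `y_base` is the mean
#' tumor logit over the drawn background; a positive value pushes the sample
#' toward the tumor class. Deterministic under `seed`.
#'
#' @param model a trained [vaejmlp_train()] model.
#' @param scaled a `scaled_matrix` over the model's features.
#' @param samples sample ids to explain (default: all columns of `scaled`).
#' @param background sample ids for the reference distribution (default: the
#'   model's training split).
#' @param n_background maximum number of background references; by default
#'   the whole background set is used (the base value is defined as the mean
#'   prediction over the training samples), and a subsample is only drawn
#'   when the background exceeds `n_background`.
#' @param n_steps path-integration points per reference (midpoint rule).
#' @param seed RNG seed for the background draw (only consumed when the
#'   background is subsampled).
#' @return An `attribution_matrix`: list with `values` (samples x genes),
#'   `base_value` (mean background tumor logit), `explained_output`
#'   (`"tumor_logit"`) and the estimator `settings`.
#' @export
attribute_genes <- function(model, scaled, samples = colnames(scaled$values),
                            background = model$split$train_ids,
                            n_background = 64, n_steps = 32, seed = 1) {
  if (length(background) == 0) stop("background is empty", call. = FALSE)
  X_all <- t(scaled$values)
  missing <- setdiff(c(samples, background), rownames(X_all))
  if (length(missing)) {
    stop("samples absent from scaled matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bg_ids <- with_seed(seed, {
    if (length(background) <= n_background) background
    else sample(background, n_background)
  })
  B <- X_all[bg_ids, , drop = FALSE]
  nb <- nrow(B)
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  base_value <- mean(vaejmlp_logits(model, B)[, 2])

  d <- ncol(X_all)
  vals <- matrix(0, length(samples), d,
                 dimnames = list(samples, colnames(X_all)))
  # one batched gradient evaluation per explained sample: all references x
  # all path positions stacked into a single forward/backward pass
  Brep <- B[rep(seq_len(nb), each = n_steps), , drop = FALSE]
  arep <- rep(alphas, times = nb)
  for (i in seq_along(samples)) {
    x <- X_all[samples[i], ]
    diffs <- matrix(x, nb * n_steps, d, byrow = TRUE) - Brep
    pts <- Brep + arep * diffs
    g <- input_gradient(model, pts)
    vals[i, ] <- colMeans(g * diffs)
  }
  structure(list(values = vals, base_value = base_value,
                 explained_output = "tumor_logit",
                 settings = list(background = bg_ids, n_steps = n_steps,
                                 seed = seed)),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf(
    "attribution_matrix: %d samples x %d genes (base value %.4f, output %s)\n",
    nrow(x$values), ncol(x$values), x$base_value, x$explained_output))
  invisible(x)
}

#' Check the additive decomposition of the attributions
#'
#' Reports, per explained sample, the residual
#' `r_i = y_i - y_base - sum_j f(x_ij)` between the model prediction and the
#' attribution sum, together with a per-sample tolerance
#' `0.05 * |y_i - y_base| + 1e-3` and the fraction of samples within it.
#'
#' @param attr an [attribute_genes()] result.
#' @param model,scaled the model and scaled matrix used for attribution.
#' @param rel_tol,abs_tol tolerance parameters.
#' @return list with `residuals` (data.frame: sample_id, prediction,
#'   residual, tol, within) and `fraction_within`.
#' @export
check_additivity <- function(attr, model, scaled, rel_tol = 0.05,
                             abs_tol = 1e-3) {
  ids <- rownames(attr$values)
  X <- t(scaled$values)[ids, , drop = FALSE]
  pred <- vaejmlp_logits(model, X)[, 2]
  res <- pred - attr$base_value - rowSums(attr$values)
  tol <- rel_tol * abs(pred - attr$base_value) + abs_tol
  df <- data.frame(sample_id = ids, prediction = pred, residual = res,
                   tol = tol, within = abs(res) <= tol,
                   stringsAsFactors = FALSE, row.names = NULL)
  list(residuals = df, fraction_within = mean(df$within))
}

#' Write an attribution matrix as TSV
#'
#' Samples as rows, genes as columns; a `#`-prefixed header line records the
#' base value and estimator settings.
#'
#' @param attr an `attribution_matrix`.
#' @param path output file.
#' @export
write_attribution <- function(attr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# base_value=%.10g explained_output=%s n_background=%d n_steps=%d seed=%s",
    attr$base_value, attr$explained_output,
    length(attr$settings$background), attr$settings$n_steps,
    format(attr$settings$seed)), con)
  df <- data.frame(sample_id = rownames(attr$values), attr$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
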