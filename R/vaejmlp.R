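#' Architecture of the joint VAE + MLP classifier
#'
#' The encoder is a stack of LeakyReLU dense layers (reference widths 1024,
#' 1024, 512, 128) feeding two linear heads that output the latent mean and
#' log-variance of a 128-dimensional Gaussian posterior; the decoder mirrors
#' the encoder and ends in a sigmoid so reconstructions live in \[0,1\]; the
#' classifier head is an MLP (reference hidden widths 128, 64) on the latent
#' vector with a two-logit softmax output.
#'
#' For inputs much narrower than the reference 1024-wide first layer the
#' widths are scaled proportionally (keeping the 8:8:4:1 encoder ratio) with
#' a floor of 8 units, so small feature sets get a commensurately small
#' network rather than a fixed 1024-wide one.
#'
#' @param input_dim number of input features (feature-set size).
#' @param encoder_widths hidden widths of the encoder (decoder mirrors them).
#' @param latent_dim dimension of the latent representation.
#' @param mlp_widths hidden widths of the classifier head.
#' @param activation_slope negative slope of the LeakyReLU.
#' @param auto_scale scale widths down proportionally when
#'   `input_dim < encoder_widths[1]`.
#' @return An `architecture_spec` list.
#' @export
vaejmlp_architecture <- function(input_dim,
                                 encoder_widths = c(1024, 1024, 512, 128),
                                 latent_dim = 128,
                                 mlp_widths = c(128, 64),
                                 activation_slope = 0.01,
                                 auto_scale = TRUE) {
  input_dim <- as.integer(input_dim)
  if (auto_scale && length(encoder_widths) &&
      input_dim < encoder_widths[1]) {
    f <- input_dim / encoder_widths[1]
    encoder_widths <- pmax(8L, as.integer(round(encoder_widths * f)))
    latent_dim <- max(8L, as.integer(round(latent_dim * f)))
    mlp_widths <- pmax(8L, as.integer(round(mlp_widths * f)))
  }
  structure(list(input_dim = input_dim,
                 encoder_widths = as.integer(encoder_widths),
                 latent_dim = as.integer(latent_dim),
                 decoder_widths = rev(as.integer(encoder_widths)),
                 mlp_widths = as.integer(mlp_widths),
                 n_classes = 2L,
                 activation_slope = activation_slope),
            class = "architecture_spec")
}

#' Three-phase training schedule for the joint model
#'
#' Training runs in three consecutive phases: unsupervised VAE-only epochs
#' (reconstruction + KL loss), classifier-only epochs with the encoder and
#' decoder frozen, and joint epochs minimizing `lambda * L_VAE + L_MLP`.
#' The reference schedule is 250 epochs split 50 / 50 / 150 with
#' `lambda = 0.001` and a stratified 80/20 train/test split.
#'
#' @param vae_epochs,mlp_epochs,joint_epochs epochs per phase.
#' @param lambda weight of the VAE loss in the joint phase.
#' @param lr Adam learning rate.
#' @param weight_decay decoupled L2 weight decay on weight matrices; spreads
#'   credit evenly across correlated informative genes, stabilizing
#'   attribution across retrainings.
#' @param batch_size minibatch size.
#' @param split_fraction fraction of samples in the training split
#'   (stratified by class).
#' @param seed RNG seed governing the split, weight init, minibatch order
#'   and reparameterization noise.
#' @return A `training_schedule` list.
#' @export
training_schedule <- function(vae_epochs = 50, mlp_epochs = 50,
                              joint_epochs = 150, lambda = 0.001,
                              lr = 1e-3, weight_decay = 1e-3,
                              batch_size = 32,
                              split_fraction = 0.8, seed = 1) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(vae_epochs = as.integer(vae_epochs),
                 mlp_epochs = as.integer(mlp_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 total_epochs = as.integer(vae_epochs + mlp_epochs +
                                             joint_epochs),
                 lambda = lambda, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction, seed = seed),
            class = "training_schedule")
}

#' Reparameterized sampling of the latent variable
#'
#' `z = mu + sigma * epsilon` with `epsilon ~ N(0, 1)`: moving the sampling
#' noise outside the network makes the draw differentiable in `mu` and
#' `sigma`.
#'
#' @param mu latent mean vector (or matrix, samples as rows).
#' @param sigma latent standard deviation, elementwise positive (the model
#'   produces it as `exp(0.5 * logvar)`).
#' @param epsilon standard-normal noise of the same shape.
#' @return `mu + sigma * epsilon`, exactly.
#' @export
reparameterize <- function(mu, sigma, epsilon) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  mu + sigma * epsilon
}

#' VAE loss: binary cross-entropy plus closed-form KL divergence
#'
#' `total = BCE(x, x_recon) + KL(N(mu, sigma) || N(0, 1))` where BCE is
#' summed over features and averaged over samples, and the KL term has the
#' diagonal-Gaussian closed form `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)`
#' (averaged over samples), which is non-negative and zero exactly at
#' `mu = 0, sigma = 1`.
#'
#' @param x original input in \[0,1\] (vector or samples x features matrix).
#' @param x_recon reconstruction in \[0,1\] (the decoder ends in a sigmoid).
#' @param mu,sigma latent posterior parameters (sigma > 0).
#' @return list with `total`, `bce`, `kl`.
#' @export
vae_loss <- function(x, x_recon, mu, sigma) {
  x <- rbind(x)
  x_recon <- rbind(x_recon)
  mu <- rbind(mu)
  sigma <- rbind(sigma)
  if (any(x < 0 | x > 1)) stop("x must lie in [0,1]", call. = FALSE)
  if (any(x_recon < 0 | x_recon > 1)) {
    stop("x_recon must lie in [0,1] (decoder must end in a sigmoid)",
         call. = FALSE)
  }
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  eps <- 1e-12
  xr <- pmin(pmax(x_recon, eps), 1 - eps)
  bce <- mean(rowSums(-(x * log(xr) + (1 - x) * log(1 - xr))))
  kl <- mean(rowSums(0.5 * (mu^2 + sigma^2 - log(sigma^2) - 1)))
  list(total = bce + kl, bce = bce, kl = kl)
}

#' Joint loss of the VAE + MLP model
#'
#' `lambda * l_vae + l_mlp`; `lambda` (default 0.001 in the reference
#' schedule) balances representation learning against classification.
#'
#' @param l_vae,l_mlp component losses.
#' @param lambda balance hyperparameter.
#' @return The weighted sum.
#' @export
joint_loss <- function(l_vae, l_mlp, lambda) {
  stopifnot(is.finite(l_vae), is.finite(l_mlp), is.finite(lambda))
  lambda * l_vae + l_mlp
}

init_logvar_bias <- function(stack, bias) {
  stack[[length(stack)]]$b <- rep(bias, length(stack[[length(stack)]]$b))
  stack
}

# Initialize all parameter stacks of the joint model. Caller owns the RNG.
vaejmlp_init <- function(arch) {
  enc_dims <- c(arch$input_dim, arch$encoder_widths)
  trunk_out <- if (length(arch$encoder_widths)) {
    utils::tail(arch$encoder_widths, 1)
  } else {
    arch$input_dim
  }
  dec_dims <- c(arch$latent_dim, arch$decoder_widths, arch$input_dim)
  mlp_dims <- c(arch$latent_dim, arch$mlp_widths, arch$n_classes)
  list(
    enc = make_stack(enc_dims, rep("leaky_relu", length(arch$encoder_widths))),
    mu = make_stack(c(trunk_out, arch$latent_dim), "linear"),
    # log-variance head starts near sigma ~ 0.22 so the latent code is
    # informative from the first epochs; the KL term then regularizes it
    # upward (guards against posterior collapse at small input widths)
    lv = init_logvar_bias(make_stack(c(trunk_out, arch$latent_dim), "linear",
                                     init_scale = 0.01), -3),
    dec = make_stack(dec_dims, c(rep("leaky_relu", length(arch$decoder_widths)),
                                 "sigmoid")),
    mlp = make_stack(mlp_dims, c(rep("leaky_relu", length(arch$mlp_widths)),
                                 "linear"))
  )
}

# Deterministic encoder pass: latent mean and log-variance for X (samples x
# features).
encode_params <- function(params, X, slope) {
  enc_cache <- stack_forward(params$enc, X, slope)
  mu_cache <- stack_forward(params$mu, enc_cache$out, slope,
                            final_preact = TRUE)
  lv_cache <- stack_forward(params$lv, enc_cache$out, slope,
                            final_preact = TRUE)
  list(enc = enc_cache, mu = mu_cache, lv = lv_cache)
}

# One minibatch update. phase in c("vae", "mlp", "joint"). kl_weight ramps
# 0 -> 1 across the VAE-only phase (standard KL warm-up; the optimized loss
# equals the stated objective once the ramp completes). Returns updated
# params/opt plus the batch loss components (KL reported unweighted).
vaejmlp_batch <- function(params, opt, X, Y, phase, lambda, lr, t, slope,
                          kl_weight = 1, weight_decay = 0) {
  n <- nrow(X)
  ec <- encode_params(params, X, slope)
  mu <- ec$mu$out
  lv <- ec$lv$out
  sigma <- exp(0.5 * lv)
  epsn <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  z <- mu + sigma * epsn

  # decoder (from logits for numerical stability)
  dec_cache <- stack_forward(params$dec, z, slope, final_preact = TRUE)
  u <- dec_cache$out
  xr <- 1 / (1 + exp(-u))
  bce <- sum(bce_from_logits(u, X)) / n
  kl <- sum(0.5 * (mu^2 + exp(lv) - lv - 1)) / n

  # classifier head
  mlp_cache <- stack_forward(params$mlp, z, slope, final_preact = TRUE)
  p <- softmax_rows(mlp_cache$out)
  Yoh <- cbind(1 - Y, Y)
  ce <- -sum(Yoh * log(pmax(p, 1e-12))) / n

  w_vae <- switch(phase, vae = 1, mlp = 0, joint = lambda)
  w_mlp <- switch(phase, vae = 0, mlp = 1, joint = 1)
  loss <- w_vae * (bce + kl_weight * kl) + w_mlp * ce
  if (!is.finite(loss)) {
    stop("non-finite loss in phase '", phase, "'", call. = FALSE)
  }

  dz <- matrix(0, nrow(z), ncol(z))
  dec_bw <- NULL
  if (w_vae > 0) {
    dU <- w_vae * (xr - X) / n
    dec_bw <- stack_backward(params$dec, dec_cache, dU, slope,
                             final_preact = TRUE)
    dz <- dz + dec_bw$dX
  }
  mlp_bw <- NULL
  if (w_mlp > 0) {
    dL <- w_mlp * (p - Yoh) / n
    mlp_bw <- stack_backward(params$mlp, mlp_cache, dL, slope,
                             final_preact = TRUE)
    if (phase != "mlp") dz <- dz + mlp_bw$dX
  }

  if (phase != "mlp") {
    dmu <- dz + kl_weight * w_vae * mu / n
    dlv <- dz * (0.5 * sigma * epsn) +
      kl_weight * w_vae * 0.5 * (exp(lv) - 1) / n
    mu_bw <- stack_backward(params$mu, ec$mu, dmu, slope, final_preact = TRUE)
    lv_bw <- stack_backward(params$lv, ec$lv, dlv, slope, final_preact = TRUE)
    denc <- mu_bw$dX + lv_bw$dX
    enc_bw <- stack_backward(params$enc, ec$enc, denc, slope)

    up <- adam_step(params$enc, enc_bw$grads, opt$enc, lr, t,
                    weight_decay = weight_decay)
    params$enc <- up$stack; opt$enc <- up$state
    up <- adam_step(params$mu, mu_bw$grads, opt$mu, lr, t,
                    weight_decay = weight_decay)
    params$mu <- up$stack; opt$mu <- up$state
    up <- adam_step(params$lv, lv_bw$grads, opt$lv, lr, t,
                    weight_decay = weight_decay)
    params$lv <- up$stack; opt$lv <- up$state
    if (!is.null(dec_bw)) {
      up <- adam_step(params$dec, dec_bw$grads, opt$dec, lr, t,
                      weight_decay = weight_decay)
      params$dec <- up$stack; opt$dec <- up$state
    }
  }
  if (!is.null(mlp_bw)) {
    up <- adam_step(params$mlp, mlp_bw$grads, opt$mlp, lr, t,
                    weight_decay = weight_decay)
    params$mlp <- up$stack; opt$mlp <- up$state
  }
  list(params = params, opt = opt, bce = bce, kl = kl, ce = ce, loss = loss)
}

#' Train the joint VAE + MLP classifier
#'
#' Runs the three-phase schedule (VAE-only, classifier-only with frozen
#' encoder/decoder, joint) on a \[0,1\]-scaled expression matrix with binary
#' labels, recording per-epoch loss components tagged by phase, and computes
#' held-out classification metrics. Fully deterministic under the schedule
#' seed.
#'
#' @param scaled a `scaled_matrix` from [minmax_scale()] (genes x samples).
#' @param labels named 0/1 vector covering the scaled samples.
#' @param arch an [vaejmlp_architecture()]; default: auto-scaled reference
#'   architecture for the input dimension.
#' @param schedule a [training_schedule()].
#' @param model optional pre-initialized/trained `vaejmlp` to continue
#'   training (its architecture and split are reused).
#' @param split optional pre-computed split, a list with `train_ids` and
#'   `test_ids` (used by the discovery driver so that min-max scaling
#'   parameters and the training split agree); default: stratified split
#'   drawn under the schedule seed.
#' @return A `vaejmlp` object: architecture, schedule, parameter stacks,
#'   per-epoch `losses` (epoch, phase, bce, kl, ce, total), held-out
#'   `metrics` (auc, accuracy, precision, recall) and `split` membership.
#' @export
vaejmlp_train <- function(scaled, labels, arch = NULL,
                          schedule = training_schedule(), model = NULL,
                          split = NULL) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  X_all <- t(scaled$values)
  if (!all(rownames(X_all) %in% names(labels))) {
    stop("labels missing for some samples", call. = FALSE)
  }
  y_all <- labels[rownames(X_all)]
  if (length(unique(y_all)) < 2) {
    stop("both classes must be present for training", call. = FALSE)
  }
  if (is.null(arch)) arch <- vaejmlp_architecture(ncol(X_all))
  if (arch$input_dim != ncol(X_all)) {
    stop("architecture input_dim does not match feature-set size",
         call. = FALSE)
  }
  slope <- arch$activation_slope

  with_seed(schedule$seed, {
    if (is.null(model)) {
      if (!is.null(split)) {
        stopifnot(all(c(split$train_ids, split$test_ids) %in%
                        rownames(X_all)))
        split_info <- split
      } else {
        # stratified split
        idx_by_class <- base::split(seq_along(y_all), y_all)
        train_idx <- sort(unlist(lapply(idx_by_class, function(ix) {
          sample(ix, max(1, round(schedule$split_fraction * length(ix))))
        }), use.names = FALSE))
        split_info <- list(train_ids = rownames(X_all)[train_idx],
                           test_ids = rownames(X_all)[-train_idx])
      }
      params <- vaejmlp_init(arch)
    } else {
      split_info <- model$split
      params <- model$params
    }
    opt <- list(enc = adam_init(params$enc), mu = adam_init(params$mu),
                lv = adam_init(params$lv), dec = adam_init(params$dec),
                mlp = adam_init(params$mlp))

    Xtr <- X_all[split_info$train_ids, , drop = FALSE]
    ytr <- y_all[split_info$train_ids]
    phases <- rep(c("vae", "mlp", "joint"),
                  c(schedule$vae_epochs, schedule$mlp_epochs,
                    schedule$joint_epochs))
    losses <- vector("list", length(phases))
    t_adam <- 0
    for (e in seq_along(phases)) {
      ph <- phases[e]
      ord <- sample(nrow(Xtr))
      starts <- seq(1, nrow(Xtr), by = schedule$batch_size)
      acc <- c(bce = 0, kl = 0, ce = 0, loss = 0)
      for (s in starts) {
        bi <- ord[s:min(s + schedule$batch_size - 1, nrow(Xtr))]
        t_adam <- t_adam + 1
        kl_w <- if (ph == "vae" && schedule$vae_epochs > 0) {
          min(1, e / schedule$vae_epochs)
        } else 1
        step <- tryCatch(
          vaejmlp_batch(params, opt, Xtr[bi, , drop = FALSE], ytr[bi],
                        ph, schedule$lambda, schedule$lr, t_adam, slope,
                        kl_weight = kl_w,
                        weight_decay = schedule$weight_decay %||% 0),
          error = function(err) {
            stop("training diverged at epoch ", e, ": ",
                 conditionMessage(err), call. = FALSE)
          })
        params <- step$params
        opt <- step$opt
        w <- length(bi) / nrow(Xtr)
        acc <- acc + w * c(step$bce, step$kl, step$ce, step$loss)
      }
      losses[[e]] <- data.frame(epoch = e, phase = ph, bce = acc[["bce"]],
                                kl = acc[["kl"]], ce = acc[["ce"]],
                                total = acc[["loss"]])
    }
    model_out <- structure(
      list(arch = arch, schedule = schedule, params = params,
           losses = do.call(rbind, losses), split = split_info),
      class = "vaejmlp")
    model_out$metrics <- if (length(split_info$test_ids) > 0) {
      vaejmlp_evaluate(model_out, scaled, labels, split = "test")
    } else {
      NULL
    }
    model_out
  })
}

#' @export
print.vaejmlp <- function(x, ...) {
  cat(sprintf(
    "vaejmlp: %d features -> encoder [%s] -> latent %d -> mlp [%s] -> 2 classes\n",
    x$arch$input_dim, paste(x$arch$encoder_widths, collapse = ", "),
    x$arch$latent_dim, paste(x$arch$mlp_widths, collapse = ", ")))
  cat(sprintf("  trained %d epochs (%d vae / %d mlp / %d joint), lambda = %g\n",
              x$schedule$total_epochs, x$schedule$vae_epochs,
              x$schedule$mlp_epochs, x$schedule$joint_epochs,
              x$schedule$lambda))
  if (!is.null(x$metrics)) {
    cat(sprintf("  held-out AUC %.3f, accuracy %.3f\n",
                x$metrics$auc, x$metrics$accuracy))
  }
  invisible(x)
}

#' Deterministic latent representation (encoder mean)
#'
#' @param model a trained [vaejmlp_train()] model.
#' @param scaled a `scaled_matrix` with the model's input features.
#' @return samples x latent_dim matrix of posterior means (no sampling).
#' @export
vaejmlp_encode <- function(model, scaled) {
  X <- t(scaled$values)
  ec <- encode_params(model$params, X, model$arch$activation_slope)
  mu <- ec$mu$out
  rownames(mu) <- rownames(X)
  mu
}

# class logits through the deterministic encoder mean; samples x 2
vaejmlp_logits <- function(model, X) {
  slope <- model$arch$activation_slope
  ec <- encode_params(model$params, X, slope)
  stack_forward(model$params$mlp, ec$mu$out, slope, final_preact = TRUE)$out
}

#' Tumor-class probabilities for each sample
#'
#' @inheritParams vaejmlp_encode
#' @return Named vector of softmax probabilities of the tumor class,
#'   computed through the deterministic encoder mean.
#' @export
vaejmlp_predict <- function(model, scaled) {
  X <- t(scaled$values)
  p <- softmax_rows(vaejmlp_logits(model, X))[, 2]
  stats::setNames(p, rownames(X))
}

# Mann-Whitney AUC with midrank tie handling; positive class = 1.
compute_auc <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics on a data split
#'
#' Standard definitions with tumor as the positive class; probabilities come
#' from the final softmax through the deterministic encoder mean, and the
#' class decision threshold is 0.5.
#'
#' @inheritParams vaejmlp_encode
#' @param labels named 0/1 vector.
#' @param split `"test"`, `"train"` or `"all"` (membership recorded at
#'   training time).
#' @return list with `auc`, `accuracy`, `precision`, `recall`, `n`.
#' @export
vaejmlp_evaluate <- function(model, scaled, labels,
                             split = c("test", "train", "all")) {
  split <- match.arg(split)
  ids <- switch(split,
                test = model$split$test_ids,
                train = model$split$train_ids,
                all = colnames(scaled$values))
  if (length(ids) == 0) stop("empty split: ", split, call. = FALSE)
  X <- t(scaled$values[, ids, drop = FALSE])
  y <- labels[ids]
  p <- softmax_rows(vaejmlp_logits(model, X))[, 2]
  pred <- as.integer(p > 0.5)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  list(auc = compute_auc(p, y),
       accuracy = mean(pred == y),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       n = length(y))
}
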