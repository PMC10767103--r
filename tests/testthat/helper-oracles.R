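# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check: the conditional NB
# pmf is built by brute-force convolution of per-sample pmfs, Shapley values
# by exhaustive coalition enumeration, and the log-rank statistic from a
# hand-style risk-set table.

# --- conditional NB exact test oracle ---------------------------------------

# pmf of the sum of n iid NB(size = r, prob = p) variables on 0..smax by
# repeated convolution (no closed form used)
convolve_nb_sum <- function(n, r, p, smax) {
  single <- stats::dnbinom(0:smax, size = r, prob = p)
  out <- single
  if (n > 1) {
    for (i in 2:n) {
      new <- numeric(smax + 1)
      for (s in 0:smax) {
        new[s + 1] <- sum(out[1:(s + 1)] * single[(s + 1):1])
      }
      out <- new
    }
  }
  out
}

# two-sided conditional exact p-value by enumeration; mirrors the doubling
# tail rule but computes the conditional distribution by convolution
oracle_exact_p <- function(yA, yB, nA, nB, phi, prob = 0.4) {
  s <- yA + yB
  if (s == 0) return(1)
  pA <- convolve_nb_sum(nA, 1 / phi, prob, s)
  pB <- convolve_nb_sum(nB, 1 / phi, prob, s)
  joint <- pA[1:(s + 1)] * pB[(s + 1):1]
  cond <- joint / sum(joint)
  a <- 0:s
  min(1, 2 * min(sum(cond[a <= yA]), sum(cond[a >= yA])))
}

# --- exhaustive Shapley oracle ----------------------------------------------

# exact Shapley values for explained function f at point x against a set of
# background rows B: value of coalition S is the mean of f over backgrounds
# with coordinates in S replaced by x
oracle_shapley <- function(f, x, B) {
  d <- length(x)
  phi <- numeric(d)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  vals <- apply(subsets, 1, function(S) {
    Xs <- B
    Xs[, S] <- matrix(x[S], nrow(B), sum(S), byrow = TRUE)
    mean(f(Xs))
  })
  key <- apply(subsets, 1, function(S) paste(as.integer(S), collapse = ""))
  v <- stats::setNames(vals, key)
  for (j in seq_len(d)) {
    contrib <- 0
    for (i in seq_len(nrow(subsets))) {
      S <- as.logical(subsets[i, ])
      if (S[j]) next
      k <- sum(S)
      Sj <- S
      Sj[j] <- TRUE
      w <- factorial(k) * factorial(d - k - 1) / factorial(d)
      contrib <- contrib +
        w * (v[paste(as.integer(Sj), collapse = "")] -
               v[paste(as.integer(S), collapse = "")])
    }
    phi[j] <- contrib
  }
  phi
}

# --- hand log-rank oracle ----------------------------------------------------

# log-rank chi-square from first principles: at each distinct event time,
# observed vs expected events in group 1 under the hypergeometric risk-set
# model
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- (O - E)^2 / V
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# --- fixtures ----------------------------------------------------------------

toy_counts <- function(n_genes = 4, n_samples = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = 30), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  count_matrix(m)
}

# small separable cohort + trained model, shared by the attribution and
# evaluation tests (built once per test file via the lazy cache below)
train_toy_model <- function(seed = 7, n_genes = 60, n_normal = 12,
                            n_tumor = 36, epochs = c(15, 15, 40)) {
  sim <- simulate_counts(simulation_config(
    n_genes = n_genes, n_normal = n_normal, n_tumor = n_tumor,
    n_de = 12, n_biomarkers = 6, seed = seed))
  split <- vaemarker:::stratified_split(names(sim$labels), sim$labels,
                                        0.8, seed + 1)
  scaled <- minmax_scale(sim$counts, split$train_ids)
  sched <- training_schedule(vae_epochs = epochs[1], mlp_epochs = epochs[2],
                             joint_epochs = epochs[3], seed = seed + 2)
  model <- vaejmlp_train(scaled, sim$labels, schedule = sched, split = split)
  list(sim = sim, scaled = scaled, model = model, split = split)
}

toy_cache <- local({
  env <- new.env()
  function(key, builder) {
    if (is.null(env[[key]])) env[[key]] <- builder()
    env[[key]]
  }
})

# hand-buildable model: explicit weights through the same forward machinery
# (used for the linear closed form and the hand forward-pass checks)
model_from_weights <- function(enc = list(), mu, lv = NULL, dec = list(),
                               mlp, input_dim, latent_dim) {
  if (is.null(lv)) {
    lv <- list(list(W = matrix(0, nrow(mu[[1]]$W), ncol(mu[[1]]$W)),
                    b = rep(0, ncol(mu[[1]]$W)), act = "linear"))
  }
  arch <- list(input_dim = input_dim,
               encoder_widths = if (length(enc)) {
                 vapply(enc, function(l) ncol(l$W), 1L)
               } else integer(0),
               latent_dim = latent_dim,
               decoder_widths = integer(0),
               mlp_widths = if (length(mlp) > 1) {
                 vapply(mlp[-length(mlp)], function(l) ncol(l$W), 1L)
               } else integer(0),
               n_classes = 2L, activation_slope = 0.01)
  structure(list(arch = arch,
                 params = list(enc = enc, mu = mu, lv = lv, dec = dec,
                               mlp = mlp),
                 split = list(train_ids = character(), test_ids = character()),
                 schedule = NULL, losses = NULL, metrics = NULL),
            class = "vaejmlp")
}

# a purely linear explained map f(x) = w . x + c wrapped as a model:
# identity-free encoder (empty trunk), linear mu head = identity, and a
# linear "MLP" whose tumor logit is w . z + c
linear_model <- function(w, c = 0) {
  d <- length(w)
  mu <- list(list(W = diag(d), b = rep(0, d), act = "linear"))
  mlp <- list(list(W = cbind(-w, w), b = c(0, c), act = "linear"))
  model_from_weights(mu = mu, mlp = mlp, input_dim = d, latent_dim = d)
}

scaled_from_matrix <- function(X) {
  # wrap an already-[0,1] samples x features matrix as a scaled_matrix
  structure(list(values = t(X), min = rep(0, ncol(X)), max = rep(1, ncol(X)),
                 train_samples = rownames(X)),
            class = "scaled_matrix")
}
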