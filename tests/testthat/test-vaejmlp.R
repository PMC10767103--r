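test_that("reparameterization is the exact affine identity", {
  expect_equal(reparameterize(0.5, 0.1, 0), 0.5)
  e <- c(-1.3, 0.2, 2.1)
  expect_equal(reparameterize(rep(0, 3), rep(1, 3), e), e)
  expect_equal(reparameterize(1.0, 2.0, -0.5), 0.0)
  expect_error(reparameterize(0, 0, 1), "positive")
})

test_that("VAE loss has the closed-form KL with its equality case", {
  # exact reconstruction at the prior: KL = 0, total = BCE = entropy of x
  x <- c(0.2, 0.7, 0.5)
  l <- vae_loss(x, x, mu = rep(0, 2), sigma = rep(1, 2))
  expect_equal(l$kl, 0)
  entropy <- -sum(x * log(x) + (1 - x) * log(1 - x))
  expect_equal(l$bce, entropy)
  expect_equal(l$total, l$bce)

  # hand value: single unit, mu = 1, sigma = 1 -> KL = 1/2
  expect_equal(vae_loss(0.5, 0.5, mu = 1, sigma = 1)$kl, 0.5)

  # KL >= 0 everywhere, = 0 only at (0, 1)
  set.seed(1)
  for (i in 1:50) {
    mu <- rnorm(4)
    sigma <- exp(rnorm(4) / 2)
    kl <- vae_loss(0.5, 0.5, mu, sigma)$kl
    expect_gte(kl, 0)
    if (max(abs(mu)) > 0.1 || max(abs(sigma - 1)) > 0.1) expect_gt(kl, 1e-4)
  }
  expect_error(vae_loss(0.5, 1.2, 0, 1), "\\[0,1\\]")
})

test_that("joint loss is the stated lambda-weighted sum and is bilinear", {
  expect_equal(joint_loss(10, 0.7, 0.001), 0.71)
  expect_equal(joint_loss(5, 0.7, 0), 0.7)
  expect_equal(joint_loss(0, 0.7, 0.001), 0.7)
  # linearity in each argument
  expect_equal(joint_loss(2 + 3, 0, 0.5), joint_loss(2, 0, 0.5) +
                 joint_loss(3, 0, 0.5))
  expect_equal(joint_loss(0, 2 + 3, 0.5), joint_loss(0, 2, 0.5) +
                 joint_loss(0, 3, 0.5))
})

test_that("architecture auto-scales widths with the stated ratio and floor", {
  a <- vaejmlp_architecture(1024)
  expect_equal(a$encoder_widths, c(1024, 1024, 512, 128))
  expect_equal(a$latent_dim, 128)
  expect_equal(a$decoder_widths, rev(a$encoder_widths))

  b <- vaejmlp_architecture(256)
  expect_equal(b$encoder_widths, c(256, 256, 128, 32))
  expect_equal(b$latent_dim, 32)
  expect_equal(b$mlp_widths, c(32, 16))

  tiny <- vaejmlp_architecture(10)
  expect_true(all(c(tiny$encoder_widths, tiny$latent_dim,
                    tiny$mlp_widths) >= 8))
})

test_that("encoder matches a hand-computed forward pass", {
  # 2 features -> 2 hidden (leaky relu) -> 1 latent, hand-set weights
  enc <- list(list(W = matrix(c(1, 0, -1, 1), 2, 2), b = c(0.5, -0.5),
                   act = "leaky_relu"))
  mu <- list(list(W = matrix(c(2, -1), 2, 1), b = 0.25, act = "linear"))
  mlp <- list(list(W = matrix(0, 1, 2), b = c(0, 0), act = "linear"))
  m <- model_from_weights(enc = enc, mu = mu, mlp = mlp,
                          input_dim = 2, latent_dim = 1)
  X <- matrix(c(1, 0.5), 1, 2, dimnames = list("s1", c("f1", "f2")))
  # hidden pre-act: (1*1 + 0.5*0 + 0.5, 1*(-1) + 0.5*1 - 0.5) = (1.5, -1)
  # leaky relu(0.01): (1.5, -0.01); mu = 2*1.5 - 1*(-0.01) + 0.25 = 3.26
  z <- vaejmlp_encode(m, scaled_from_matrix(X))
  expect_equal(unname(z[1, 1]), 3.26)

  # duplicate samples map to identical rows; all-zero input stays finite
  X2 <- rbind(s1 = c(0.3, 0.9), s2 = c(0.3, 0.9), s3 = c(0, 0))
  colnames(X2) <- c("f1", "f2")
  z2 <- vaejmlp_encode(m, scaled_from_matrix(X2))
  expect_equal(unname(z2["s1", ]), unname(z2["s2", ]))
  expect_true(all(is.finite(z2)))
})

test_that("training separates planted classes and phases stay isolated", {
  fx <- toy_cache("sep", function() {
    train_toy_model(seed = 7, n_genes = 80, n_normal = 15, n_tumor = 45,
                    epochs = c(12, 12, 30))
  })
  m <- fx$model
  expect_gte(m$metrics$auc, 0.95)

  # VAE-only phase: reconstruction error trends down (the total carries the
  # KL warm-up ramp, so BCE is the stable sanity signal)
  vae_bce <- m$losses$bce[m$losses$phase == "vae"]
  expect_lt(vae_bce[length(vae_bce)], vae_bce[1])
  # KL component non-negative at every epoch, all losses finite
  expect_true(all(m$losses$kl >= 0))
  expect_true(all(is.finite(m$losses$total)))

  # determinism: identical schedule seed -> identical loss trace
  m2 <- vaejmlp_train(fx$scaled, fx$sim$labels, m$arch, m$schedule,
                      split = fx$split)
  expect_identical(m2$losses$total, m$losses$total)

  # phase isolation, bit-level: train a fresh tiny model one phase at a time
  sched0 <- training_schedule(vae_epochs = 0, mlp_epochs = 3,
                              joint_epochs = 0, seed = 11)
  base <- vaejmlp_train(fx$scaled, fx$sim$labels, m$arch,
                        training_schedule(vae_epochs = 1, mlp_epochs = 0,
                                          joint_epochs = 0, seed = 11),
                        split = fx$split)
  after_mlp <- vaejmlp_train(fx$scaled, fx$sim$labels, m$arch, sched0,
                             model = base)
  expect_identical(after_mlp$params$enc, base$params$enc)
  expect_identical(after_mlp$params$dec, base$params$dec)
  expect_identical(after_mlp$params$mu, base$params$mu)
  expect_false(identical(after_mlp$params$mlp, base$params$mlp))

  sched1 <- training_schedule(vae_epochs = 3, mlp_epochs = 0,
                              joint_epochs = 0, seed = 12)
  after_vae <- vaejmlp_train(fx$scaled, fx$sim$labels, m$arch, sched1,
                             model = base)
  expect_identical(after_vae$params$mlp, base$params$mlp)
  expect_false(identical(after_vae$params$enc, base$params$enc))
})

test_that("classification metrics follow their standard definitions", {
  # rank-enumeration AUC
  expect_equal(vaemarker:::compute_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)),
               1.0)
  expect_equal(vaemarker:::compute_auc(c(0.1, 0.9), c(1, 0)), 0)
  expect_equal(vaemarker:::compute_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)),
               0.5)

  # degenerate all-positive classifier on a balanced set: recall 1, accuracy .5
  w <- rep(0, 3)
  m <- linear_model(w, c = 5)   # tumor logit always 5 -> always predicts tumor
  X <- matrix(runif(12), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  m$split$test_ids <- rownames(X)
  labs <- label_vector(rownames(X), c(1, 1, 0, 0))
  met <- vaejmlp_evaluate(m, scaled_from_matrix(X), labs, split = "test")
  expect_equal(met$recall, 1)
  expect_equal(met$accuracy, 0.5)
  expect_equal(met$precision, 0.5)
})

test_that("schedule and training preconditions are enforced", {
  expect_error(training_schedule(lambda = 0), "lambda")
  expect_error(training_schedule(split_fraction = 1), "split_fraction")
  fx <- toy_cache("sep", function() train_toy_model())
  one_class <- fx$sim$labels
  one_class[] <- 1L
  expect_error(vaejmlp_train(fx$scaled, one_class), "both classes")
})
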