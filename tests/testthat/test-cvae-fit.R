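test_that("layer shapes follow the mirrored architecture", {
  lab <- condition_labels(rep(paste0("s", 1:5), 4), rep(paste0("t", 1:4), 5))
  hyper <- cvae_hyperparameters(hidden_dims = c(1024L, 512L), latent_dim = 8L)
  m <- build_cvae(hyper, 100L, lab, seed = 1L)
  # encoder 109 -> 1024 -> 512 -> (8, 8)
  expect_equal(dim(m$params$enc_W1), c(109L, 1024L))
  expect_equal(dim(m$params$enc_W2), c(1024L, 512L))
  expect_equal(dim(m$params$mu_W), c(512L, 8L))
  expect_equal(dim(m$params$lv_W), c(512L, 8L))
  # decoder 17 -> 512 -> 1024 -> 100
  expect_equal(dim(m$params$dec_W1), c(17L, 512L))
  expect_equal(dim(m$params$dec_W2), c(512L, 1024L))
  expect_equal(dim(m$params$out_W), c(1024L, 100L))
})

test_that("weight initialization and training are seed-reproducible", {
  m1 <- tiny_model(seed = 5L)
  m2 <- tiny_model(seed = 5L)
  m3 <- tiny_model(seed = 6L)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))

  comp <- generate_compendium(S = 4L, T_ = 3L, M = 20L, seed = 51L)
  hy <- cvae_hyperparameters(hidden_dims = 8L, latent_dim = 2L,
                             epochs = 10L, batch_size = 16L)
  f1 <- cvae(comp$values, comp$labels, hy, seed = 52L)
  f2 <- cvae(comp$values, comp$labels, hy, seed = 52L)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$trace, f2$trace)
})

test_that("training reduces the loss on a small synthetic compendium", {
  comp <- generate_compendium(S = 5L, T_ = 4L, M = 50L,
                              mean_samples_per_combo = 3, seed = 61L)
  hy <- cvae_hyperparameters(hidden_dims = c(32L, 16L), latent_dim = 4L,
                             epochs = 40L, batch_size = 32L)
  fit <- cvae(comp$values, comp$labels, hy, seed = 62L)
  expect_lt(fit$trace$total[nrow(fit$trace)], fit$trace$total[1])
  expect_true(all(is.finite(fit$trace$total)))
})

test_that("mc_samples > 1 and a one-dimensional latent space both train", {
  comp <- generate_compendium(S = 3L, T_ = 3L, M = 12L, seed = 63L)
  hyL <- cvae_hyperparameters(hidden_dims = 8L, latent_dim = 2L,
                              epochs = 5L, batch_size = 16L, mc_samples = 2L)
  fitL <- cvae(comp$values, comp$labels, hyL, seed = 64L)
  expect_true(fitL$trained)
  hy1 <- cvae_hyperparameters(hidden_dims = 8L, latent_dim = 1L,
                              epochs = 5L, batch_size = 16L)
  fit1 <- cvae(comp$values, comp$labels, hy1, seed = 64L)
  expect_true(fit1$trained)
  imp <- impute_combination_mean(fit1, comp$labels$species[1],
                                 comp$labels$tissue[1], seed = 9L)
  expect_true(all(imp$values > 0 & imp$values < 1))
})

test_that("averaging the reconstruction term over draws matches mc_samples", {
  m <- tiny_model(M = 4L, seed = 7L)
  lab <- condition_labels(c("sp1", "sp2"), c("ti1", "ti2"),
                          species_vocab = m$species_vocab,
                          tissue_vocab = m$tissue_vocab)
  set.seed(8)
  X <- matrix(runif(8), 2, 4)
  Y <- encode_condition_labels(lab)
  e1 <- matrix(rnorm(4), 2, 2); e2 <- matrix(rnorm(4), 2, 2)
  l1 <- cmimpute:::cvae_loss_only(m, X, Y, list(e1))
  l2 <- cmimpute:::cvae_loss_only(m, X, Y, list(e2))
  l12 <- cmimpute:::cvae_loss_only(m, X, Y, list(e1, e2))
  kl <- kl_divergence_term(cmimpute:::encoder_forward(m, cbind(X, Y))$mu,
                           cmimpute:::encoder_forward(m, cbind(X, Y))$lv)
  expect_equal(l12 - kl, ((l1 - kl) + (l2 - kl)) / 2, tolerance = 1e-12)
})

test_that("model serialization round-trips and guards the probe count", {
  fx <- trained_fixture()
  p <- withr::local_tempfile(fileext = ".rds")
  save_cvae(fx$fit, p)
  m <- load_cvae(p)
  expect_identical(m$params, fx$fit$params)
  wrong <- tiny_matrix(3L, 5L)
  lab <- condition_labels(rep(fx$comp$labels$species[1], 3),
                          rep(fx$comp$labels$tissue[1], 3),
                          species_vocab = m$species_vocab,
                          tissue_vocab = m$tissue_vocab)
  expect_error(residuals(m, wrong, lab), "expects")
})

test_that("grid search scores validation imputation and picks the best point", {
  comp <- generate_compendium(S = 6L, T_ = 4L, M = 30L,
                              observed_fraction = 1, seed = 81L)
  cm <- compute_combination_means(comp$values, comp$labels)
  val_idx <- c(1L, 5L, 9L)
  val_cm <- combination_means(cm$species[val_idx], cm$tissue[val_idx],
                              cm$values[val_idx, , drop = FALSE])
  train_rows <- !(paste(comp$labels$species, comp$labels$tissue) %in%
                    paste(cm$species[val_idx], cm$tissue[val_idx]))
  x_tr <- comp$values[train_rows, ]
  lab_tr <- condition_labels(comp$labels$species[train_rows],
                             comp$labels$tissue[train_rows],
                             species_vocab = comp$labels$species_vocab,
                             tissue_vocab = comp$labels$tissue_vocab)
  single <- list(cvae_hyperparameters(hidden_dims = 16L, latent_dim = 4L,
                                      epochs = 15L, batch_size = 32L))
  gs1 <- grid_search_hyperparameters(single, x_tr, lab_tr, val_cm, seed = 82L)
  expect_identical(gs1$best, single[[1L]])
  expect_equal(gs1$best_index, 1L)

  grid2 <- c(single,
             list(cvae_hyperparameters(hidden_dims = 16L, latent_dim = 1L,
                                       epochs = 2L, batch_size = 32L)))
  gs2 <- grid_search_hyperparameters(grid2, x_tr, lab_tr, val_cm, seed = 82L)
  expect_equal(gs2$best_index, which.max(gs2$scores))
  expect_error(grid_search_hyperparameters(list(), x_tr, lab_tr, val_cm),
               "empty")
})

test_that("an undefined validation score is never selected", {
  # constant validation targets make every correlation undefined -> error;
  # a finite-scoring point must win whenever one exists
  comp <- generate_compendium(S = 3L, T_ = 3L, M = 10L,
                              observed_fraction = 1, seed = 83L)
  cm <- compute_combination_means(comp$values, comp$labels)
  flat <- combination_means(cm$species[1], cm$tissue[1],
                            matrix(0.5, 1L, ncol(cm$values),
                                   dimnames = list(NULL, colnames(cm$values))))
  grid <- list(cvae_hyperparameters(hidden_dims = 8L, latent_dim = 2L,
                                    epochs = 2L, batch_size = 16L))
  expect_error(grid_search_hyperparameters(grid, comp$values, comp$labels,
                                           flat, seed = 84L),
               "undefined")
})
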