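#' Hyperparameters for the conditional VAE
#'
#' Defaults are the winning configuration of the reference grid search on
#' the full mammalian compendium: two hidden layers of 1024 and 512 units,
#' tanh activation, an 8-dimensional latent space, Adam with learning rate
#' 1e-3 and epsilon 1e-4.  Training length and batch size are configurable
#' (no early stopping); `mc_samples` is the number of Monte-Carlo latent
#' draws per sample per step (L, default 1).
#'
#' @param hidden_dims integer vector of encoder hidden layer widths; the
#'   decoder mirrors them in reverse.
#' @param activation one of "tanh", "relu", "sigmoid", "elu".
#' @param latent_dim latent space dimension Z (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param optimizer_epsilon Adam epsilon.
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param mc_samples Monte-Carlo draws L per sample per step (>= 1).
#' @return object of class `cvae_hyperparameters`.
#' @export
cvae_hyperparameters <- function(hidden_dims = c(1024L, 512L),
                                 activation = c("tanh", "relu", "sigmoid", "elu"),
                                 latent_dim = 8L,
                                 learning_rate = 1e-3,
                                 optimizer_epsilon = 1e-4,
                                 epochs = 200L,
                                 batch_size = 64L,
                                 mc_samples = 1L) {
  activation <- match.arg(activation)
  hidden_dims <- as.integer(hidden_dims)
  if (length(hidden_dims) < 1L || any(hidden_dims < 1L))
    stopf("hidden_dims must be positive integers")
  if (latent_dim < 1L) stopf("latent_dim must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (mc_samples < 1L) stopf("mc_samples must be >= 1")
  if (epochs < 1L || batch_size < 1L) stopf("epochs and batch_size must be >= 1")
  structure(list(n_hidden_layers = length(hidden_dims),
                 hidden_dims = hidden_dims,
                 activation = activation,
                 latent_dim = as.integer(latent_dim),
                 learning_rate = learning_rate,
                 optimizer_epsilon = optimizer_epsilon,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 mc_samples = as.integer(mc_samples)),
            class = "cvae_hyperparameters")
}

#' Default hyperparameter grid
#'
#' Ships the reference winning point first plus a few neighbouring
#' configurations; fully replaceable by the user (any list of
#' [cvae_hyperparameters()] is a valid grid).
#'
#' @param ... arguments forwarded to every grid point (e.g. `epochs`).
#' @export
default_hyperparameter_grid <- function(...) {
  list(cvae_hyperparameters(hidden_dims = c(1024L, 512L), activation = "tanh",
                            latent_dim = 8L, ...),
       cvae_hyperparameters(hidden_dims = c(1024L, 512L), activation = "relu",
                            latent_dim = 8L, ...),
       cvae_hyperparameters(hidden_dims = c(512L, 256L), activation = "tanh",
                            latent_dim = 8L, ...),
       cvae_hyperparameters(hidden_dims = c(1024L, 512L), activation = "tanh",
                            latent_dim = 16L, ...))
}

activation_fun <- function(name) {
  switch(name,
         tanh = tanh,
         relu = function(x) pmax(x, 0),
         sigmoid = sigmoid,
         elu = function(x) ifelse(x > 0, x, expm1(x)),
         stopf("unknown activation '%s'", name))
}

# derivative as a function of the pre-activation a
activation_grad <- function(name) {
  switch(name,
         tanh = function(a) 1 - tanh(a)^2,
         relu = function(a) (a > 0) + 0,
         sigmoid = function(a) { s <- sigmoid(a); s * (1 - s) },
         elu = function(a) ifelse(a > 0, 1, exp(a)),
         stopf("unknown activation '%s'", name))
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Build an untrained conditional VAE
#'
#' The encoder is a fully connected stack from the concatenated
#' (methylation, one-hot label) input of width M + S + T through
#' `hidden_dims` to two separate linear heads of width Z: the posterior
#' mean mu and the log-variance sigma (= log of the diagonal covariance).
#' The decoder mirrors the stack: input (z, label) of width Z + S + T
#' through `rev(hidden_dims)` to an M-wide linear logit head; methylation
#' values are obtained by applying the logistic sigmoid to those logits.
#' Weight initialization is a seeded fan-based uniform (Glorot) scheme.
#'
#' @param hyper a [cvae_hyperparameters()].
#' @param M number of probes.
#' @param vocab a [condition_labels()] (only its vocabularies are kept).
#' @param seed integer seed for weight initialization.
#' @return object of class `cvae` (untrained).
#' @export
build_cvae <- function(hyper, M, vocab, seed = 1L) {
  stopifnot(inherits(hyper, "cvae_hyperparameters"))
  if (M < 1L) stopf("M must be >= 1")
  S <- length(vocab$species_vocab); T_ <- length(vocab$tissue_vocab)
  L <- S + T_
  Z <- hyper$latent_dim
  enc_dims <- c(M + L, hyper$hidden_dims)
  dec_dims <- c(Z + L, rev(hyper$hidden_dims))
  params <- list()
  with_seed(seed, {
    for (i in seq_len(hyper$n_hidden_layers)) {
      params[[paste0("enc_W", i)]] <- glorot(enc_dims[i], enc_dims[i + 1L])
      params[[paste0("enc_b", i)]] <- numeric(enc_dims[i + 1L])
    }
    hlast <- enc_dims[length(enc_dims)]
    params$mu_W <- glorot(hlast, Z); params$mu_b <- numeric(Z)
    params$lv_W <- glorot(hlast, Z); params$lv_b <- numeric(Z)
    for (i in seq_len(hyper$n_hidden_layers)) {
      params[[paste0("dec_W", i)]] <- glorot(dec_dims[i], dec_dims[i + 1L])
      params[[paste0("dec_b", i)]] <- numeric(dec_dims[i + 1L])
    }
    dlast <- dec_dims[length(dec_dims)]
    params$out_W <- glorot(dlast, M); params$out_b <- numeric(M)
  })
  structure(list(hyper = hyper, M = as.integer(M),
                 species_vocab = vocab$species_vocab,
                 tissue_vocab = vocab$tissue_vocab,
                 probe_ids = NULL,
                 params = params, trained = FALSE, trace = NULL,
                 init_seed = as.integer(seed)),
            class = "cvae")
}

dense <- function(X, W, b) X %*% W + rep(b, each = nrow(X))

encoder_forward <- function(model, XY) {
  p <- model$params; H <- model$hyper$n_hidden_layers
  act <- activation_fun(model$hyper$activation)
  hs <- vector("list", H + 1L); as_ <- vector("list", H)
  hs[[1L]] <- XY
  for (i in seq_len(H)) {
    as_[[i]] <- dense(hs[[i]], p[[paste0("enc_W", i)]], p[[paste0("enc_b", i)]])
    hs[[i + 1L]] <- act(as_[[i]])
  }
  list(mu = dense(hs[[H + 1L]], p$mu_W, p$mu_b),
       lv = dense(hs[[H + 1L]], p$lv_W, p$lv_b),
       hs = hs, as = as_)
}

decoder_forward <- function(model, ZY) {
  p <- model$params; H <- model$hyper$n_hidden_layers
  act <- activation_fun(model$hyper$activation)
  hs <- vector("list", H + 1L); as_ <- vector("list", H)
  hs[[1L]] <- ZY
  for (i in seq_len(H)) {
    as_[[i]] <- dense(hs[[i]], p[[paste0("dec_W", i)]], p[[paste0("dec_b", i)]])
    hs[[i + 1L]] <- act(as_[[i]])
  }
  list(logits = dense(hs[[H + 1L]], p$out_W, p$out_b), hs = hs, as = as_)
}

#' Reparameterization of the latent draw
#'
#' `z = mu + exp(sigma / 2) * eps`, where `sigma` holds log-variances and
#' `eps` is standard-normal noise; expressing the draw this way keeps the
#' sampling step differentiable.
#'
#' @param mu,sigma,eps numeric vectors (or conformable matrices) of equal
#'   shape; `sigma` is the log of the diagonal posterior covariance.
#' @return z of the same shape.
#' @export
reparameterize <- function(mu, sigma, eps) {
  if (length(mu) != length(sigma) || length(mu) != length(eps))
    stopf("mu, sigma and eps must have the same shape")
  mu + exp(sigma / 2) * eps
}

#' KL regularization term
#'
#' KL divergence between the diagonal-Gaussian posterior N(mu, exp(sigma))
#' and the standard-normal prior, summed over the latent dimensions:
#' `0.5 * sum(exp(sigma) + mu^2 - 1 - sigma)`.  For a matrix input (rows =
#' batch) the per-row KL is averaged over the batch.
#'
#' @param mu,sigma numeric vectors, or matrices with one row per sample.
#' @return scalar KL term in nats (always >= 0).
#' @export
kl_divergence_term <- function(mu, sigma) {
  if (is.matrix(mu)) {
    per_row <- 0.5 * rowSums(exp(sigma) + mu^2 - 1 - sigma)
    mean(per_row)
  } else {
    0.5 * sum(exp(sigma) + mu^2 - 1 - sigma)
  }
}

# numerically stable elementwise BCE of target x against sigmoid(logit)
bce_elements <- function(x, logits) {
  pmax(logits, 0) - logits * x + log1p(exp(-abs(logits)))
}

#' Reconstruction term (binary cross-entropy with continuous targets)
#'
#' The negated Bernoulli log-likelihood of beta-value targets under
#' sigmoid-transformed decoder logits, summed over probes and averaged
#' over the batch.  Evaluated in logit form, so large-magnitude logits do
#' not overflow.
#'
#' @param X_batch targets in [0,1]; vector or batch x M matrix.
#' @param logits decoder logits of the same shape.
#' @return scalar loss in nats (>= 0).
#' @export
reconstruction_term <- function(X_batch, logits) {
  if (length(X_batch) != length(logits)) stopf("shape mismatch")
  b <- bce_elements(X_batch, logits)
  if (is.matrix(X_batch)) mean(rowSums(b)) else sum(b)
}

#' Training loss decomposition
#'
#' Total minimized objective = reconstruction term + KL term (the negated
#' empirical lower bound up to the constant Bernoulli base measure).
#'
#' @inheritParams reconstruction_term
#' @inheritParams kl_divergence_term
#' @return object of class `cvae_loss` with fields `recon`, `kl`, `total`.
#' @export
training_loss <- function(X_batch, logits, mu, sigma) {
  recon <- reconstruction_term(X_batch, logits)
  kl <- kl_divergence_term(mu, sigma)
  structure(list(recon = recon, kl = kl, total = recon + kl),
            class = "cvae_loss")
}

#' @export
print.cvae_loss <- function(x, ...) {
  cat(sprintf("cvae loss: total %.4f = recon %.4f + kl %.4f\n",
              x$total, x$recon, x$kl))
  invisible(x)
}

# Loss and analytic gradients for one minibatch.
# X: B x M targets; Y: B x (S+T) labels; eps_list: list of B x Z draws.
cvae_loss_grads <- function(model, X, Y, eps_list) {
  p <- model$params; H <- model$hyper$n_hidden_layers
  B <- nrow(X); L <- length(eps_list)
  dact <- activation_grad(model$hyper$activation)
  Z <- model$hyper$latent_dim

  grads <- lapply(p, function(w) array(0, dim = dim(w) %||% length(w)))
  names(grads) <- names(p)
  enc <- encoder_forward(model, cbind(X, Y))
  mu <- enc$mu; lv <- enc$lv

  dmu <- matrix(0, B, Z); dlv <- matrix(0, B, Z)
  recon <- 0
  for (l in seq_len(L)) {
    eps <- eps_list[[l]]
    z <- mu + exp(lv / 2) * eps
    dec <- decoder_forward(model, cbind(z, Y))
    recon <- recon + mean(rowSums(bce_elements(X, dec$logits))) / L
    delta <- (sigmoid(dec$logits) - X) / (B * L)
    grads$out_W <- grads$out_W + crossprod(dec$hs[[H + 1L]], delta)
    grads$out_b <- grads$out_b + colSums(delta)
    dh <- delta %*% t(p$out_W)
    for (i in rev(seq_len(H))) {
      dpre <- dh * dact(dec$as[[i]])
      grads[[paste0("dec_W", i)]] <- grads[[paste0("dec_W", i)]] +
        crossprod(dec$hs[[i]], dpre)
      grads[[paste0("dec_b", i)]] <- grads[[paste0("dec_b", i)]] + colSums(dpre)
      dh <- dpre %*% t(p[[paste0("dec_W", i)]])
    }
    dz <- dh[, seq_len(Z), drop = FALSE]
    dmu <- dmu + dz
    dlv <- dlv + dz * eps * exp(lv / 2) * 0.5
  }
  kl <- mean(0.5 * rowSums(exp(lv) + mu^2 - 1 - lv))
  dmu <- dmu + mu / B
  dlv <- dlv + (exp(lv) - 1) / (2 * B)

  grads$mu_W <- grads$mu_W + crossprod(enc$hs[[H + 1L]], dmu)
  grads$mu_b <- grads$mu_b + colSums(dmu)
  grads$lv_W <- grads$lv_W + crossprod(enc$hs[[H + 1L]], dlv)
  grads$lv_b <- grads$lv_b + colSums(dlv)
  dh <- dmu %*% t(p$mu_W) + dlv %*% t(p$lv_W)
  for (i in rev(seq_len(H))) {
    dpre <- dh * dact(enc$as[[i]])
    grads[[paste0("enc_W", i)]] <- grads[[paste0("enc_W", i)]] +
      crossprod(enc$hs[[i]], dpre)
    grads[[paste0("enc_b", i)]] <- grads[[paste0("enc_b", i)]] + colSums(dpre)
    dh <- dpre %*% t(p[[paste0("enc_W", i)]])
  }
  list(loss = list(recon = recon, kl = kl, total = recon + kl), grads = grads)
}

# loss only (same path, no gradients) — used by the finite-difference check
cvae_loss_only <- function(model, X, Y, eps_list) {
  enc <- encoder_forward(model, cbind(X, Y))
  recon <- 0
  for (eps in eps_list) {
    z <- enc$mu + exp(enc$lv / 2) * eps
    dec <- decoder_forward(model, cbind(z, Y))
    recon <- recon + mean(rowSums(bce_elements(X, dec$logits))) / length(eps_list)
  }
  kl <- mean(0.5 * rowSums(exp(enc$lv) + enc$mu^2 - 1 - enc$lv))
  recon + kl
}

#' Train a conditional VAE on a labelled methylation compendium
#'
#' Minimizes the reconstruction + KL objective with the Adam optimizer at
#' the configured learning rate and epsilon, drawing `mc_samples` (default
#' one) Monte-Carlo latent samples per training sample per step.  All
#' randomness (weight initialization, minibatch shuffling, latent noise)
#' derives from `seed`, so identical seeds reproduce identical weights and
#' loss traces.
#'
#' @param x sample matrix of beta values (samples x probes, named dims).
#' @param labels a [condition_labels()] aligned with `x`.
#' @param hyper a [cvae_hyperparameters()].
#' @param seed integer seed.
#' @param model optional pre-built [build_cvae()] model to train (its
#'   vocabularies must match `labels`); default builds one from `hyper`.
#' @param verbose print per-epoch losses.
#' @return a trained object of class `cvae` carrying the per-epoch loss
#'   trace (`$trace`: data.frame epoch/recon/kl/total).
#' @seealso [predict.cvae()], [impute_combination_mean()], [build_cvae()]
#' @export
cvae <- function(x, labels, hyper = cvae_hyperparameters(), seed = 1L,
                 model = NULL, verbose = FALSE) {
  validate_sample_matrix(x)
  if (nrow(x) != length(labels$species))
    stopf("matrix rows (%d) and labels (%d) must align", nrow(x),
          length(labels$species))
  if (is.null(model)) {
    model <- build_cvae(hyper, ncol(x), labels, seed = seed)
  } else {
    stopifnot(inherits(model, "cvae"))
    hyper <- model$hyper
    if (model$M != ncol(x))
      stopf("model expects %d probes, matrix has %d", model$M, ncol(x))
    if (!identical(model$species_vocab, labels$species_vocab) ||
        !identical(model$tissue_vocab, labels$tissue_vocab))
      stopf("model and labels vocabularies differ")
  }
  Y <- encode_condition_labels(labels)
  N <- nrow(x); B <- min(hyper$batch_size, N); Z <- hyper$latent_dim

  p <- model$params
  mstate <- lapply(p, function(w) w * 0)
  vstate <- lapply(p, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; t_ <- 0L
  trace <- matrix(NA_real_, hyper$epochs, 3L,
                  dimnames = list(NULL, c("recon", "kl", "total")))

  with_seed(derive_seed(seed, "cvae-fit"), {
    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample.int(N)
      starts <- seq(1L, N, by = B)
      ep <- c(recon = 0, kl = 0, total = 0); nb <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + B - 1L, N)]
        Xb <- x[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        eps_list <- lapply(seq_len(hyper$mc_samples), function(l)
          matrix(stats::rnorm(length(idx) * Z), length(idx), Z))
        lg <- cvae_loss_grads(model, Xb, Yb, eps_list)
        if (!is.finite(lg$loss$total))
          stopf("non-finite training loss at epoch %d (recon %g, kl %g); try a lower learning rate",
                epoch, lg$loss$recon, lg$loss$kl)
        t_ <- t_ + 1L
        corr <- sqrt(1 - beta2^t_) / (1 - beta1^t_)
        for (nm in names(p)) {
          g <- lg$grads[[nm]]
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
          p[[nm]] <- p[[nm]] - hyper$learning_rate * corr * mstate[[nm]] /
            (sqrt(vstate[[nm]]) + hyper$optimizer_epsilon)
        }
        model$params <- p
        ep <- ep + c(lg$loss$recon, lg$loss$kl, lg$loss$total); nb <- nb + 1L
      }
      trace[epoch, ] <- ep / nb
      if (verbose)
        message(sprintf("epoch %3d  total %.4f  recon %.4f  kl %.4f",
                        epoch, trace[epoch, "total"], trace[epoch, "recon"],
                        trace[epoch, "kl"]))
    }
  })
  model$params <- p
  model$trained <- TRUE
  model$trace <- data.frame(epoch = seq_len(hyper$epochs), trace)
  model$probe_ids <- colnames(x)
  model$fit_seed <- as.integer(seed)
  model
}

#' @export
print.cvae <- function(x, ...) {
  cat(sprintf("conditional VAE: %d probes, %d species + %d tissues, Z=%d\n",
              x$M, length(x$species_vocab), length(x$tissue_vocab),
              x$hyper$latent_dim))
  cat(sprintf("  encoder %s -> (%d,%d); decoder mirrors; activation %s\n",
              paste(c(x$M + length(x$species_vocab) + length(x$tissue_vocab),
                      x$hyper$hidden_dims), collapse = " -> "),
              x$hyper$latent_dim, x$hyper$latent_dim, x$hyper$activation))
  if (x$trained)
    cat(sprintf("  trained %d epochs; final loss %.4f (recon %.4f, kl %.4f)\n",
                nrow(x$trace), x$trace$total[nrow(x$trace)],
                x$trace$recon[nrow(x$trace)], x$trace$kl[nrow(x$trace)]))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.cvae <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, integer(1)))
  out <- list(hyper = object$hyper, n_parameters = n_par,
              trained = object$trained,
              final_loss = if (object$trained)
                object$trace[nrow(object$trace), ] else NULL)
  class(out) <- "summary.cvae"
  out
}

#' @export
print.summary.cvae <- function(x, ...) {
  cat(sprintf("conditional VAE with %d parameters (%s)\n", x$n_parameters,
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  hidden %s, activation %s, Z=%d, lr=%g, eps=%g\n",
              paste(x$hyper$hidden_dims, collapse = "/"),
              x$hyper$activation, x$hyper$latent_dim,
              x$hyper$learning_rate, x$hyper$optimizer_epsilon))
  if (!is.null(x$final_loss))
    cat(sprintf("  final epoch loss %.4f (recon %.4f, kl %.4f)\n",
                x$final_loss$total, x$final_loss$recon, x$final_loss$kl))
  invisible(x)
}

#' @export
coef.cvae <- function(object, ...) object$params

#' Loss-trace plot for a trained CVAE
#' @param x a trained `cvae`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cvae <- function(x, ...) {
  if (!x$trained) stopf("model is untrained")
  graphics::matplot(x$trace$epoch,
                    cbind(x$trace$total, x$trace$recon, x$trace$kl),
                    type = "l", lty = 1, xlab = "epoch", ylab = "loss (nats)",
                    ...)
  graphics::legend("topright", c("total", "recon", "kl"), lty = 1, col = 1:3)
  invisible(x)
}

#' Reconstruction residuals on training-scale data
#'
#' Deterministic reconstruction (latent noise set to zero, i.e. z = mu)
#' of each sample through encoder and decoder; residuals are observed
#' minus reconstructed beta values.
#'
#' @param object a trained `cvae`.
#' @param x sample matrix; `newdata` alias for modelling-idiom callers.
#' @param labels matching [condition_labels()].
#' @param ... unused.
#' @export
residuals.cvae <- function(object, x, labels, ...) {
  validate_sample_matrix(x)
  if (ncol(x) != object$M)
    stopf("model expects %d probes, matrix has %d", object$M, ncol(x))
  Y <- encode_condition_labels(object, species = labels$species,
                               tissue = labels$tissue)
  enc <- encoder_forward(object, cbind(x, Y))
  dec <- decoder_forward(object, cbind(enc$mu, Y))
  x - sigmoid(dec$logits)
}

#' Hyperparameter grid search by validation imputation
#'
#' Fits a model per grid point on the training data, imputes every
#' validation combination, and scores the mean sample-wise Pearson
#' correlation between imputed and observed validation combination means.
#' Returns the first grid point attaining the maximum score (NaN scores —
#' e.g. constant imputations — are never selected over a finite score).
#'
#' @param grid list of [cvae_hyperparameters()].
#' @param x,labels training sample matrix and labels.
#' @param val_means a [combination_means()] of validation targets; every
#'   validation key must have same-species and same-tissue training data.
#' @param seed integer seed (per-point fitting seeds are derived from it).
#' @param verbose print per-point scores.
#' @return list with `best` (hyperparameters), `best_index`, `scores`
#'   (numeric, NA where undefined), `models` not retained.
#' @export
grid_search_hyperparameters <- function(grid, x, labels, val_means,
                                        seed = 1L, verbose = FALSE) {
  if (length(grid) == 0L) stopf("hyperparameter grid is empty")
  scores <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    fit <- cvae(x, labels, grid[[i]], seed = derive_seed(seed, paste0("grid", i)))
    imp <- impute_keys(fit, val_means$species, val_means$tissue,
                       seed = derive_seed(seed, "grid-val"))
    r <- vapply(seq_len(nrow(imp$values)), function(j)
      safe_cor(imp$values[j, ], val_means$values[j, ]), numeric(1))
    scores[i] <- mean(r)   # NA-poisoned if any validation row is undefined
    if (verbose) message(sprintf("grid point %d: mean val r = %.4f",
                                 i, scores[i]))
  }
  if (all(is.na(scores)))
    stopf("every grid point produced an undefined validation score")
  best <- which.max(scores)   # first max wins; NA never beats finite
  list(best = grid[[best]], best_index = best, scores = scores)
}

#' Save / load a trained CVAE
#'
#' Single-file archive holding weights, hyperparameters and both label
#' vocabularies.  `load_cvae` restores the object; downstream calls refuse
#' matrices whose probe count differs from the model's M.
#'
#' @param model a `cvae`.
#' @param path file path.
#' @export
save_cvae <- function(model, path) {
  stopifnot(inherits(model, "cvae"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_cvae
#' @export
load_cvae <- function(path) {
  obj <- readRDS(path)
  need <- c("hyper", "M", "species_vocab", "tissue_vocab", "params")
  if (!all(need %in% names(obj))) stopf("not a saved cvae archive: %s", path)
  class(obj$hyper) <- "cvae_hyperparameters"
  structure(obj, class = "cvae")
}
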