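# Shared fixture builders; everything is generated in code at test time.

tiny_matrix <- function(n = 4L, m = 3L, seed = 1L, values = NULL) {
  x <- if (is.null(values)) {
    set.seed(seed)
    matrix(runif(n * m), n, m)
  } else matrix(values, n, m)
  dimnames(x) <- list(paste0("s", seq_len(nrow(x))),
                      paste0("p", seq_len(ncol(x))))
  x
}

tiny_model <- function(M = 5L, S = 2L, T_ = 2L, Z = 2L, hidden = 4L,
                       seed = 1L) {
  lab <- condition_labels(rep(paste0("sp", seq_len(S)), each = T_),
                          rep(paste0("ti", seq_len(T_)), times = S))
  hyper <- cvae_hyperparameters(hidden_dims = hidden, latent_dim = Z,
                                epochs = 2L, batch_size = 4L)
  build_cvae(hyper, M, lab, seed = seed)
}

# small trained model + its compendium, cached across tests in one run
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      comp <- generate_compendium(S = 6L, T_ = 4L, M = 40L,
                                  observed_fraction = 0.9, seed = 71L)
      hy <- cvae_hyperparameters(hidden_dims = c(24L, 12L), latent_dim = 4L,
                                 epochs = 80L, batch_size = 32L)
      fit <- cvae(comp$values, comp$labels, hy, seed = 72L)
      cache <<- list(comp = comp, fit = fit)
    }
    cache
  }
})

expect_combination_means <- function(x) {
  expect_s3_class(x, "combination_means")
  expect_true(all(x$values >= 0 & x$values <= 1))
  expect_equal(length(x$species), nrow(x$values))
}
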