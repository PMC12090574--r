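#' Impute one species-tissue combination mean sample
#'
#' Draws z ~ N(0, I_Z) with the given seed, concatenates it with the
#' two-hot (species, tissue) label, and decodes; the sigmoid of the
#' decoder logits is the imputed combination mean profile.  The encoder is
#' never involved: imputation is individual-agnostic by construction.
#'
#' @param model a trained [cvae()].
#' @param species,tissue target combination; must be in the model's
#'   vocabularies.
#' @param seed integer seed for the latent draw.
#' @return list with `species`, `tissue`, `values` (named numeric vector
#'   in (0,1)), `latent_seed`.
#' @export
impute_combination_mean <- function(model, species, tissue, seed = 1L) {
  stopifnot(inherits(model, "cvae"))
  if (!(species %in% model$species_vocab))
    stopf("species '%s' is not in the model vocabulary", species)
  if (!(tissue %in% model$tissue_vocab))
    stopf("tissue '%s' is not in the model vocabulary", tissue)
  Z <- model$hyper$latent_dim
  z <- with_seed(seed, matrix(stats::rnorm(Z), 1L, Z))
  y <- encode_condition_labels(model, species = species, tissue = tissue)
  dec <- decoder_forward(model, cbind(z, y))
  vals <- as.vector(sigmoid(dec$logits))
  names(vals) <- model$probe_ids %||% paste0("p", seq_along(vals))
  list(species = species, tissue = tissue, values = vals,
       latent_seed = as.integer(seed))
}

# Vectorized imputation of many keys; per-key seeds derived by stable
# hashing so the result is independent of key order.
impute_keys <- function(model, species, tissue, seed = 1L) {
  stopifnot(inherits(model, "cvae"))
  n <- length(species)
  Z <- model$hyper$latent_dim
  zs <- matrix(NA_real_, n, Z)
  for (i in seq_len(n)) {
    ks <- derive_seed(seed, combo_id(species[i], tissue[i]))
    zs[i, ] <- with_seed(ks, stats::rnorm(Z))
  }
  y <- encode_condition_labels(model, species = species, tissue = tissue)
  dec <- decoder_forward(model, cbind(zs, y))
  vals <- sigmoid(dec$logits)
  colnames(vals) <- model$probe_ids %||% paste0("p", seq_len(ncol(vals)))
  combination_means(species, tissue, vals,
                    counts = rep(0L, n), method = "cmimpute",
                    metadata = list(base_seed = seed))
}

#' Impute every missing combination of the species-tissue grid
#'
#' Enumerates the full S x T grid against the observed labels and decodes
#' one combination mean sample per missing cell.  Per-key latent seeds are
#' derived from `seed` by stable hashing of the key, so the output does
#' not depend on enumeration order.
#'
#' @param model a trained [cvae()].
#' @param labels the [condition_labels()] describing observed coverage.
#' @param seed base integer seed.
#' @return a [combination_means()] with method `"cmimpute"` and counts 0;
#'   empty (0 rows) if the grid is fully observed.
#' @export
impute_missing_grid <- function(model, labels, seed = 1L) {
  combos <- enumerate_combinations(labels)
  miss <- combos$missing
  if (nrow(miss) == 0L)
    return(combination_means(character(0), character(0),
                             matrix(numeric(0), 0L, model$M,
                                    dimnames = list(NULL, model$probe_ids)),
                             integer(0), method = "cmimpute",
                             metadata = list(base_seed = seed)))
  impute_keys(model, miss$species, miss$tissue, seed = seed)
}

#' Latent-draw stability of imputed combination means
#'
#' For each key, imputes `n_draws` replicate combination mean samples with
#' different latent draws and records the per-probe variance across the
#' replicates (within-key); the per-probe variance across the per-key mean
#' profiles of different keys (between-key) quantifies the genuine
#' species/tissue signal.  A well-behaved model shows within-key variance
#' orders of magnitude below between-key variance.
#'
#' @param model a trained [cvae()].
#' @param species,tissue key vectors (>= 2 keys for the between-key part).
#' @param n_draws replicate latent draws per key (>= 2).
#' @param seed base seed.
#' @return list with `median_within` (median over probes and keys of the
#'   within-key replicate variance), `median_between` (median over probes
#'   of the across-key variance), plus the underlying matrices.
#' @export
latent_stability_report <- function(model, species, tissue, n_draws = 20L,
                                    seed = 1L) {
  if (n_draws < 2L) stopf("n_draws must be >= 2")
  n <- length(species)
  within <- matrix(NA_real_, n, model$M)
  key_means <- matrix(NA_real_, n, model$M)
  for (i in seq_len(n)) {
    draws <- vapply(seq_len(n_draws), function(d)
      impute_combination_mean(model, species[i], tissue[i],
                              seed = derive_seed(seed,
                                paste0(combo_id(species[i], tissue[i]), "#", d))
                              )$values,
      numeric(model$M))
    draws <- t(draws)                      # n_draws x M
    within[i, ] <- apply(draws, 2L, pop_var)
    key_means[i, ] <- colMeans(draws)
  }
  between <- if (n >= 2L) apply(key_means, 2L, pop_var) else rep(NA_real_, model$M)
  list(median_within = stats::median(within),
       median_between = stats::median(between),
       within = within, between = between,
       n_draws = as.integer(n_draws))
}

#' Predict method: impute combination mean samples
#'
#' @param object a trained [cvae()].
#' @param newdata data.frame with columns `species` and `tissue`; default
#'   imputes every missing combination implied by the model vocabularies
#'   is not possible without label coverage, so `newdata` is required.
#' @param seed base seed for the latent draws.
#' @param ... unused.
#' @return a [combination_means()] with method `"cmimpute"`.
#' @export
predict.cvae <- function(object, newdata, seed = 1L, ...) {
  if (missing(newdata) || !all(c("species", "tissue") %in% names(newdata)))
    stopf("newdata must be a data.frame with columns species and tissue")
  impute_keys(object, as.character(newdata$species),
              as.character(newdata$tissue), seed = seed)
}

#' Simulate replicate imputations for one combination
#'
#' @param object a trained [cvae()].
#' @param nsim number of replicate latent draws.
#' @param seed base seed.
#' @param species,tissue the target combination.
#' @param ... unused.
#' @return nsim x M matrix of imputed profiles.
#' @export
simulate.cvae <- function(object, nsim = 1L, seed = 1L, species, tissue, ...) {
  out <- vapply(seq_len(nsim), function(d)
    impute_combination_mean(object, species, tissue,
                            seed = derive_seed(seed, paste0("sim#", d)))$values,
    numeric(object$M))
  t(out)
}
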