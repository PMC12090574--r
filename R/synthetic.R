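#' Generate a synthetic methylation compendium
#'
#' Seeded generator of individual beta-value samples with known species
#' and tissue structure, emulating a cross-species methylation-array
#' compendium: on the logit scale every probe p has a baseline b_p and
#' additive species (u_sp), tissue (v_tp) and interaction (w_stp)
#' effects, all drawn from centred normals with the given sds; individual
#' samples add normal noise and map through the logistic sigmoid into
#' (0, 1).  The observed mask keeps every species in at least one tissue
#' and every tissue in at least one species, and per-combination sample
#' counts follow a geometric-like distribution to mimic the strong
#' coverage imbalance of real compendia.
#'
#' Defaults mirror the structure reported for real data (species signal
#' dominating tissue signal, which dominates the interaction) at a size
#' that exercises every downstream module quickly.
#'
#' @param S,T_,M numbers of species, tissues, probes (>= 2 each).
#' @param mean_samples_per_combo expected individuals per observed
#'   combination (geometric imbalance around this mean).
#' @param observed_fraction fraction of the S x T grid that is observed.
#' @param effect_sds named numeric vector with entries `baseline`,
#'   `species`, `tissue`, `interaction`, `noise` (logit-scale sds).
#' @param seed integer seed; identical seeds give identical compendia.
#' @return list with `values` (sample matrix), `labels`
#'   ([condition_labels()]), and `truth` (class `synthetic_truth`:
#'   full-grid true combination means, the effect vectors, the observed
#'   mask, counts and the seed).
#' @export
generate_compendium <- function(S = 20L, T_ = 6L, M = 300L,
                                mean_samples_per_combo = 3,
                                observed_fraction = 0.8,
                                effect_sds = c(baseline = 1.5, species = 1,
                                               tissue = 0.5,
                                               interaction = 0.1,
                                               noise = 0.1),
                                seed = 1L) {
  if (S < 2L || T_ < 2L || M < 2L) stopf("S, T_ and M must all be >= 2")
  if (!(observed_fraction > 0 && observed_fraction <= 1))
    stopf("observed_fraction must be in (0, 1]")
  need <- c("baseline", "species", "tissue", "interaction", "noise")
  if (!all(need %in% names(effect_sds)))
    stopf("effect_sds needs entries: %s", paste(need, collapse = ", "))
  n_target <- round(observed_fraction * S * T_)
  if (n_target < max(S, T_))
    stopf("observed fraction %.2f cannot cover all %d species and %d tissues",
          observed_fraction, S, T_)
  species_ids <- sprintf("species%02d", seq_len(S))
  tissue_ids <- sprintf("tissue%02d", seq_len(T_))
  probe_ids <- sprintf("cg%05d", seq_len(M))

  with_seed(seed, {
    b <- stats::rnorm(M, 0, effect_sds["baseline"])
    u <- matrix(stats::rnorm(S * M, 0, effect_sds["species"]), S, M,
                dimnames = list(species_ids, probe_ids))
    v <- matrix(stats::rnorm(T_ * M, 0, effect_sds["tissue"]), T_, M,
                dimnames = list(tissue_ids, probe_ids))
    w <- array(stats::rnorm(S * T_ * M, 0, effect_sds["interaction"]),
               c(S, T_, M))

    mask <- matrix(stats::runif(S * T_) <= observed_fraction, S, T_,
                   dimnames = list(species_ids, tissue_ids))
    for (s in which(rowSums(mask) == 0L))
      mask[s, sample.int(T_, 1L)] <- TRUE
    for (t in which(colSums(mask) == 0L))
      mask[sample.int(S, 1L), t] <- TRUE

    true_means <- matrix(NA_real_, S * T_, M)
    keys <- expand.grid(si = seq_len(S), ti = seq_len(T_),
                        KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(keys))) {
      si <- keys$si[i]; ti <- keys$ti[i]
      true_means[i, ] <- sigmoid(b + u[si, ] + v[ti, ] + w[si, ti, ])
    }
    colnames(true_means) <- probe_ids

    obs_idx <- which(mask[cbind(keys$si, keys$ti)])
    counts <- 1L + stats::rgeom(length(obs_idx),
                                prob = 1 / max(1, mean_samples_per_combo))
    rows <- sum(counts)
    values <- matrix(NA_real_, rows, M,
                     dimnames = list(sprintf("sample%04d", seq_len(rows)),
                                     probe_ids))
    sp_lab <- ti_lab <- character(rows)
    r <- 0L
    for (j in seq_along(obs_idx)) {
      i <- obs_idx[j]; si <- keys$si[i]; ti <- keys$ti[i]
      logit_mean <- b + u[si, ] + v[ti, ] + w[si, ti, ]
      for (rep_ in seq_len(counts[j])) {
        r <- r + 1L
        noise <- if (effect_sds["noise"] > 0)
          stats::rnorm(M, 0, effect_sds["noise"]) else 0
        values[r, ] <- sigmoid(logit_mean + noise)
        sp_lab[r] <- species_ids[si]; ti_lab[r] <- tissue_ids[ti]
      }
    }
    labels <- condition_labels(sp_lab, ti_lab,
                               species_vocab = species_ids,
                               tissue_vocab = tissue_ids)
    truth <- structure(list(species_ids = species_ids,
                            tissue_ids = tissue_ids,
                            probe_ids = probe_ids,
                            grid = data.frame(species = species_ids[keys$si],
                                              tissue = tissue_ids[keys$ti]),
                            true_means = true_means,
                            baseline = b, species_effects = u,
                            tissue_effects = v, interaction_effects = w,
                            effect_sds = effect_sds,
                            observed_mask = mask,
                            counts = stats::setNames(counts,
                              combo_id(species_ids[keys$si[obs_idx]],
                                       tissue_ids[keys$ti[obs_idx]])),
                            seed = as.integer(seed)),
                       class = "synthetic_truth")
    list(values = values, labels = labels, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic truth: %d species x %d tissues x %d probes, %d observed combinations\n",
              length(x$species_ids), length(x$tissue_ids),
              length(x$probe_ids), sum(x$observed_mask)))
  invisible(x)
}

#' True combination means for a set of keys
#'
#' @param truth a `synthetic_truth`.
#' @param keys data.frame with columns `species`, `tissue`; default the
#'   full grid.
#' @return a [combination_means()] with method `"truth"`.
#' @export
true_combination_means <- function(truth, keys = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  keys <- keys %||% truth$grid
  idx <- match(combo_id(keys$species, keys$tissue),
               combo_id(truth$grid$species, truth$grid$tissue))
  if (anyNA(idx)) stopf("unknown combination key(s)")
  combination_means(keys$species, keys$tissue,
                    truth$true_means[idx, , drop = FALSE],
                    method = "truth")
}

#' Generate species lifespans linearly tied to methylation
#'
#' Log maximum lifespan is an affine function of the species-level mean
#' (over all tissues of the true grid) of `signal_probes` randomly chosen
#' probes, plus normal noise; lifespans are the exponential, hence always
#' positive.  With `signal_probes = 0` the lifespans carry no methylation
#' signal at all.
#'
#' @param truth a `synthetic_truth`.
#' @param signal_probes number of probes carrying signal (<= M).
#' @param noise_sd sd of the additive log-scale noise.
#' @param intercept,effect_sd location of log-lifespans and sd of the
#'   per-probe regression weights.
#' @param seed integer seed.
#' @return data.frame with columns `species`, `max_lifespan` plus an
#'   attribute `signal_probes` naming the probes used.
#' @export
generate_lifespans <- function(truth, signal_probes = 10L, noise_sd = 0,
                               intercept = 3, effect_sd = 2, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  M <- length(truth$probe_ids)
  if (signal_probes > M) stopf("signal_probes must be <= %d", M)
  S <- length(truth$species_ids)
  sp_mean <- t(vapply(truth$species_ids, function(s)
    colMeans(truth$true_means[truth$grid$species == s, , drop = FALSE]),
    numeric(M)))
  with_seed(seed, {
    probes <- if (signal_probes > 0L) sample(truth$probe_ids, signal_probes)
      else character(0)
    loglife <- rep(intercept, S)
    if (signal_probes > 0L) {
      wts <- stats::rnorm(signal_probes, 0, effect_sd)
      loglife <- loglife + as.vector(sp_mean[, probes, drop = FALSE] %*% wts)
    }
    if (noise_sd > 0) loglife <- loglife + stats::rnorm(S, 0, noise_sd)
    out <- data.frame(species = truth$species_ids,
                      max_lifespan = exp(loglife))
    attr(out, "signal_probes") <- probes
    out
  })
}

#' Random probe-by-species mappability mask
#'
#' Interface-testing helper only: mappability is drawn independently per
#' (probe, species) cell and carries no sequence biology.
#'
#' @param probe_ids,species_ids identifiers.
#' @param prob per-cell mappable probability.
#' @param seed integer seed.
#' @return a [mappability_table()].
#' @export
generate_mappability <- function(probe_ids, species_ids, prob = 0.95,
                                 seed = 1L) {
  m <- with_seed(seed,
                 matrix(stats::rbinom(length(probe_ids) * length(species_ids),
                                      1L, prob),
                        length(probe_ids), length(species_ids),
                        dimnames = list(probe_ids, species_ids)))
  mappability_table(m)
}
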