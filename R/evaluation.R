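#' Sample-wise agreement between imputed and observed combination means
#'
#' For every shared (species, tissue) key, computes the Pearson
#' correlation and mean squared error between the imputed and observed
#' profiles across the selected probes.  Keys where either profile is
#' constant have an undefined correlation: they are flagged and excluded
#' from the correlation summaries (their MSE is still computed).
#'
#' @param imputed,observed [combination_means()] with matching keys.
#' @param probes optional probe-id subset (e.g. the highest-coverage set).
#' @return list of class `agreement_report` with `per_sample` data.frame
#'   (species, tissue, r, mse, r_defined) and `summary` (means/medians and
#'   the undefined count).
#' @export
sample_wise_agreement <- function(imputed, observed, probes = NULL) {
  al <- align_combination_means(imputed, observed, probes)
  if (ncol(al$a) < 2L) stopf("at least 2 probes are required")
  n <- nrow(al$a)
  r <- mse <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- safe_cor(al$a[i, ], al$b[i, ])
    mse[i] <- mean((al$a[i, ] - al$b[i, ])^2)
  }
  per <- data.frame(species = al$species, tissue = al$tissue,
                    r = r, mse = mse, r_defined = !is.na(r))
  structure(list(per_sample = per,
                 summary = agreement_summary(per)),
            class = "agreement_report")
}

#' Probe-wise agreement between imputed and observed combination means
#'
#' For every probe, computes Pearson correlation and MSE between the
#' imputed and observed values across the shared combinations.  Probes
#' with zero variance in either vector are flagged undefined for r.
#'
#' @inheritParams sample_wise_agreement
#' @return list of class `agreement_report` with `per_probe` data.frame
#'   (probe, r, mse, r_defined) and `summary`.
#' @export
probe_wise_agreement <- function(imputed, observed, probes = NULL) {
  al <- align_combination_means(imputed, observed, probes)
  if (nrow(al$a) < 2L) stopf("at least 2 shared combinations are required")
  m <- ncol(al$a)
  r <- mse <- numeric(m)
  for (j in seq_len(m)) {
    r[j] <- safe_cor(al$a[, j], al$b[, j])
    mse[j] <- mean((al$a[, j] - al$b[, j])^2)
  }
  per <- data.frame(probe = colnames(al$a), r = r, mse = mse,
                    r_defined = !is.na(r))
  names(per)[1] <- "probe"
  structure(list(per_probe = per, summary = agreement_summary(per)),
            class = "agreement_report")
}

agreement_summary <- function(per) {
  r <- per$r[per$r_defined]
  list(mean_r = if (length(r)) mean(r) else NA_real_,
       median_r = if (length(r)) stats::median(r) else NA_real_,
       mean_mse = mean(per$mse), median_mse = stats::median(per$mse),
       n = nrow(per), n_undefined_r = sum(!per$r_defined),
       variance_convention = "population")
}

#' @export
print.agreement_report <- function(x, ...) {
  s <- x$summary
  what <- if (!is.null(x$per_sample)) "sample-wise" else "probe-wise"
  cat(sprintf("%s agreement over %d units: mean r %.4f (median %.4f), mean MSE %.3e; %d undefined r\n",
              what, s$n, s$mean_r, s$median_r, s$mean_mse, s$n_undefined_r))
  invisible(x)
}

align_combination_means <- function(imputed, observed, probes = NULL) {
  stopifnot(inherits(imputed, "combination_means"),
            inherits(observed, "combination_means"))
  ka <- combo_id(imputed$species, imputed$tissue)
  kb <- combo_id(observed$species, observed$tissue)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stopf("no shared (species, tissue) keys")
  ia <- match(shared, ka); ib <- match(shared, kb)
  pa <- colnames(imputed$values); pb <- colnames(observed$values)
  probes <- probes %||% intersect(pa, pb)
  if (!all(probes %in% pa) || !all(probes %in% pb))
    stopf("probe subset contains ids absent from one of the inputs")
  parts <- do.call(rbind, strsplit(shared, "\t", fixed = TRUE))
  list(a = imputed$values[ia, probes, drop = FALSE],
       b = observed$values[ib, probes, drop = FALSE],
       species = parts[, 1L], tissue = parts[, 2L])
}

#' Per-probe variance profile of a labelled compendium
#'
#' Computes, per probe, the three staged variance measures over
#' combination means: (1) inter-combination variance — variance across all
#' observed species-tissue combination means; (2) mean inter-tissue
#' variance — variance across tissue means within a species, averaged
#' over species with more than one tissue; (3) mean inter-species
#' variance — variance across species means within a tissue, averaged
#' over tissues with more than one species.  Population variance
#' (divide by n) throughout, recorded in the result.
#'
#' @param x sample matrix of individual samples.
#' @param labels matching [condition_labels()].
#' @return list of class `variance_profile` with numeric vectors
#'   `inter_combination`, `mean_inter_tissue`, `mean_inter_species`
#'   (named by probe; absent with a warning if no qualifying species or
#'   tissue exists) and `variance_convention`.
#' @export
probe_variance_profile <- function(x, labels) {
  cm <- compute_combination_means(x, labels)
  vals <- cm$values
  inter_comb <- if (nrow(vals) >= 2L) apply(vals, 2L, pop_var) else {
    warning("fewer than 2 combinations; inter-combination variance unavailable")
    NULL
  }
  group_var <- function(groups) {
    per <- vapply(groups, function(rows)
      apply(vals[rows, , drop = FALSE], 2L, pop_var), numeric(ncol(vals)))
    stats::setNames(rowMeans(matrix(per, nrow = ncol(vals))), colnames(vals))
  }
  sp_tab <- split(seq_len(nrow(vals)), cm$species)
  multi_t <- sp_tab[vapply(sp_tab, length, integer(1)) > 1L]
  mean_it <- if (length(multi_t)) {
    group_var(multi_t)
  } else {
    warning("no species with more than one tissue; mean inter-tissue variance unavailable")
    NULL
  }
  ti_tab <- split(seq_len(nrow(vals)), cm$tissue)
  multi_s <- ti_tab[vapply(ti_tab, length, integer(1)) > 1L]
  mean_is <- if (length(multi_s)) {
    group_var(multi_s)
  } else {
    warning("no tissue with more than one species; mean inter-species variance unavailable")
    NULL
  }
  structure(list(inter_combination = inter_comb,
                 mean_inter_tissue = mean_it,
                 mean_inter_species = mean_is,
                 probe_ids = colnames(vals),
                 variance_convention = "population"),
            class = "variance_profile")
}

#' Rank-based variance quartiles
#'
#' Assigns each probe of the selected subset to a variance quartile
#' (Q1 = lowest) such that group sizes differ by at most one, with extra
#' probes going to the lower quartiles; ties are broken by stable probe
#' order.
#'
#' @param profile a [probe_variance_profile()].
#' @param metric which variance: `"inter_combination"`,
#'   `"mean_inter_tissue"`, or `"mean_inter_species"`.
#' @param probes optional probe-id subset.
#' @return factor of quartile labels Q1..Q4 named by probe.
#' @export
assign_variance_quartiles <- function(profile,
                                      metric = c("inter_combination",
                                                 "mean_inter_tissue",
                                                 "mean_inter_species"),
                                      probes = NULL) {
  metric <- match.arg(metric)
  v <- profile[[metric]]
  if (is.null(v)) stopf("metric '%s' is unavailable in this profile", metric)
  names(v) <- profile$probe_ids
  if (!is.null(probes)) v <- v[probes]
  n <- length(v)
  if (n < 4L) stopf("at least 4 probes are required for quartiles")
  ord <- order(v)                       # stable: ties keep probe order
  sizes <- rep(n %/% 4L, 4L) + c(rep(1L, n %% 4L), rep(0L, 4L - n %% 4L))
  lab <- rep(paste0("Q", 1:4), times = sizes)
  out <- factor(character(n), levels = paste0("Q", 1:4))
  out[ord] <- lab
  names(out) <- names(v)
  out
}

#' Subtract same-species training means from combination mean samples
#'
#' Removes the dominant species signal by subtracting, from each sample,
#' the mean of all same-species training individuals, exposing the
#' tissue-specific methylation differences.
#'
#' @param samples a [combination_means()].
#' @param x,labels the training individuals and their labels.
#' @return matrix of deltas in [-1, 1], rows aligned with `samples`.
#' @export
remove_species_signal <- function(samples, x, labels) {
  stopifnot(inherits(samples, "combination_means"))
  out <- samples$values
  for (i in seq_len(nrow(out))) {
    rows <- which(labels$species == samples$species[i])
    if (length(rows) == 0L)
      stopf("species '%s' has no training samples", samples$species[i])
    mu <- if (length(rows) == 1L) x[rows, ] else colMeans(x[rows, , drop = FALSE])
    out[i, ] <- out[i, ] - mu
  }
  out
}

# Mann-Whitney AUC with ties counted 1/2.
rank_auc <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stopf("need at least one positive and one negative pair")
  r <- rank(scores)                      # average ranks handle ties as 1/2
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Species/tissue signal AUC of combination mean samples
#'
#' Scores every unordered pair of samples by the Pearson correlation of
#' their profiles and asks how well that score separates same-species
#' (or same-tissue) pairs from the rest, as an area under the ROC curve
#' (ties counted one half).
#'
#' @param samples a [combination_means()].
#' @param mode `"species"` or `"tissue"`.
#' @param probes optional probe-id subset.
#' @return scalar AUC in [0, 1].
#' @export
label_signal_auc <- function(samples, mode = c("species", "tissue"),
                             probes = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(samples, "combination_means"))
  samples <- subset_probes(samples, probes)
  n <- nrow(samples$values)
  if (n < 2L) stopf("at least 2 samples are required")
  lab <- if (mode == "species") samples$species else samples$tissue
  cors <- suppressWarnings(stats::cor(t(samples$values)))
  iu <- which(upper.tri(cors), arr.ind = TRUE)
  scores <- cors[iu]
  if (anyNA(scores))
    stopf("constant sample profile makes pair correlations undefined")
  positive <- lab[iu[, 1L]] == lab[iu[, 2L]]
  rank_auc(scores, positive)
}

#' Paired comparison of two methods' per-key scores
#'
#' Reports the fraction of keys where method a strictly beats method b
#' and the two-sided Wilcoxon signed-rank p-value on the paired
#' differences (zero differences dropped, as in the standard paired
#' test).  When every difference is zero the test is flagged undefined.
#'
#' @param scores_a,scores_b aligned numeric vectors of per-key scores.
#' @return list with `fraction_a_better`, `p_value` (NA if undefined),
#'   `n`, `n_zero_diff`, `test`.
#' @export
paired_method_comparison <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stopf("scores must be aligned")
  d <- scores_a - scores_b
  frac <- mean(d > 0)
  nz <- sum(d == 0)
  p <- if (all(d == 0)) NA_real_ else {
    if (length(d) - nz < 5L)
      warning("fewer than 5 nonzero differences; signed-rank p-value unstable")
    suppressWarnings(stats::wilcox.test(scores_a, scores_b, paired = TRUE,
                                        alternative = "two.sided")$p.value)
  }
  list(fraction_a_better = frac, p_value = p, n = length(d),
       n_zero_diff = nz, test = "wilcoxon signed-rank, two-sided")
}

#' Individual-to-individual variability within combinations
#'
#' For each combination with at least two individual samples, the mean
#' Pearson correlation over all unordered pairs of individuals — an upper
#' reference for what any imputation method can reproduce.
#'
#' @param x sample matrix of individuals.
#' @param labels matching [condition_labels()].
#' @param probes optional probe subset.
#' @return data.frame (species, tissue, n_individuals, mean_pairwise_r);
#'   singleton combinations are omitted.
#' @export
individual_to_individual_variability <- function(x, labels, probes = NULL) {
  if (!is.null(probes)) x <- x[, probes, drop = FALSE]
  key <- combo_id(labels$species, labels$tissue)
  out <- list()
  for (k in sort_c(key)) {
    rows <- which(key == k)
    if (length(rows) < 2L) next
    cors <- stats::cor(t(x[rows, , drop = FALSE]))
    parts <- strsplit(k, "\t", fixed = TRUE)[[1L]]
    out[[k]] <- data.frame(species = parts[1L], tissue = parts[2L],
                           n_individuals = length(rows),
                           mean_pairwise_r = mean(cors[upper.tri(cors)]))
  }
  if (length(out) == 0L)
    return(data.frame(species = character(0), tissue = character(0),
                      n_individuals = integer(0),
                      mean_pairwise_r = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
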