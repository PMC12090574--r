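#' Random outer folds over eligible combinations
#'
#' Seeded uniform partition of the eligible (species, tissue) combinations
#' into k near-equal test sets (sizes differ by at most one, larger sets
#' first).
#'
#' @param eligible data.frame with columns `species`, `tissue`.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of k data.frames.
#' @export
make_outer_folds <- function(eligible, k = 5L, seed = 1L) {
  n <- nrow(eligible)
  if (k < 2L) stopf("k must be >= 2")
  if (n < k) stopf("need at least k=%d eligible combinations, have %d", k, n)
  ord <- with_seed(derive_seed(seed, "outer-folds"), sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split_idx <- split(ord, rep(seq_len(k), times = sizes))
  lapply(split_idx, function(i) {
    d <- eligible[sort(i), , drop = FALSE]; rownames(d) <- NULL; d
  })
}

#' Split non-test combinations into training and validation sets
#'
#' Draws a seeded `val_frac` (default 20%) candidate validation set of
#' combinations; any validation combination lacking at least one
#' same-species combination and at least one same-tissue combination in
#' the candidate training set is moved to training.  If the surviving
#' validation set holds less than `min_frac` (default 10%) of the
#' non-test combinations, the split is redrawn with the next derived
#' seed, up to `max_retries` times.
#'
#' @param non_test data.frame of combinations with columns `species`,
#'   `tissue`.
#' @param seed integer base seed.
#' @param val_frac candidate validation fraction.
#' @param min_frac minimum acceptable validation fraction.
#' @param max_retries redraw budget.
#' @return list with `train`, `val` (data.frames) and `attempts`.
#' @export
split_train_validation <- function(non_test, seed = 1L, val_frac = 0.2,
                                   min_frac = 0.1, max_retries = 20L) {
  n <- nrow(non_test)
  if (n == 0L) stopf("non_test set is empty")
  best <- NULL
  for (attempt in seq_len(max_retries)) {
    n_val <- max(1L, round(val_frac * n))
    val_idx <- with_seed(derive_seed(seed + attempt - 1L, "train-val"),
                         sample.int(n, n_val))
    val <- sort(val_idx); train <- setdiff(seq_len(n), val)
    # single pass in stable order; training only grows, so earlier moves
    # can only help later combinations
    for (i in val) {
      same_sp <- any(non_test$species[train] == non_test$species[i])
      same_ti <- any(non_test$tissue[train] == non_test$tissue[i])
      if (!(same_sp && same_ti)) {
        train <- sort(c(train, i))
        val <- setdiff(val, i)
      }
    }
    if (is.null(best) || length(val) > nrow(best$val))
      best <- list(train = non_test[train, , drop = FALSE],
                   val = non_test[val, , drop = FALSE],
                   attempts = attempt)
    if (length(val) >= min_frac * n) {
      out <- list(train = non_test[train, , drop = FALSE],
                  val = non_test[val, , drop = FALSE],
                  attempts = attempt)
      rownames(out$train) <- rownames(out$val) <- NULL
      return(out)
    }
  }
  stopf("no train/validation split reached %.0f%% validation in %d attempts (best: %d of %d combinations)",
        100 * min_frac, max_retries, nrow(best$val), n)
}

combo_in <- function(species, tissue, keys) {
  combo_id(species, tissue) %in% combo_id(keys$species, keys$tissue)
}

# test keys retained for evaluation: same-species different-tissue AND
# same-tissue different-species data present in the final training set
evaluable_keys <- function(test, train) {
  keep <- vapply(seq_len(nrow(test)), function(i) {
    any(train$species == test$species[i] & train$tissue != test$tissue[i]) &&
      any(train$tissue == test$tissue[i] & train$species != test$species[i])
  }, logical(1))
  test[keep, , drop = FALSE]
}

#' Grouped cross-validation of imputation methods
#'
#' Runs the full protocol: eligible combinations are partitioned into k
#' outer test folds; within each fold the remaining observed combinations
#' are split into training and validation combination sets; the CVAE
#' hyperparameters are selected by grid search on validation imputation;
#' the fold's final model is fit on the training combinations (optionally
#' training + validation); and every requested method imputes the fold's
#' evaluable test keys from identical training data.  All individual
#' samples of a test combination are excluded from training.
#'
#' @param x sample matrix of individuals.
#' @param labels matching [condition_labels()].
#' @param grid list of [cvae_hyperparameters()] for the grid search.
#' @param methods subset of c("cmimpute", "species", "tissue", "global",
#'   "logistic").
#' @param k number of outer folds.
#' @param seed integer base seed.
#' @param include_val_in_final if TRUE the fold's final model (and the
#'   baselines) also train on validation-combination individuals.
#' @param logistic_lambda ridge penalty for the logistic baseline; a
#'   vector is swept and the value with the best validation mean r wins.
#' @param verbose print progress.
#' @return list of class `cv_result`: `imputed` (named list of
#'   [combination_means()], keys concatenated across folds), `observed`
#'   (matching observed combination means), `fold_plan`, `chosen`
#'   (per-fold hyperparameter index and lambda).
#' @export
run_cross_validation <- function(x, labels, grid = default_hyperparameter_grid(),
                                 methods = c("cmimpute", "species", "tissue",
                                             "global", "logistic"),
                                 k = 5L, seed = 1L,
                                 include_val_in_final = FALSE,
                                 logistic_lambda = 2,
                                 verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  combos <- enumerate_combinations(labels)
  if (nrow(combos$eligible) == 0L) stopf("no eligible combinations")
  folds <- make_outer_folds(combos$eligible, k = k, seed = seed)
  obs_cm <- compute_combination_means(x, labels)
  obs_key <- combo_id(obs_cm$species, obs_cm$tissue)
  sample_key <- combo_id(labels$species, labels$tissue)

  res_keys <- list(); res_vals <- lapply(methods, function(m) list())
  names(res_vals) <- methods
  chosen <- list(); plan <- list()

  for (f in seq_along(folds)) {
    test <- folds[[f]]
    non_test <- combos$observed[!combo_in(combos$observed$species,
                                          combos$observed$tissue, test), ,
                                drop = FALSE]
    tv <- split_train_validation(non_test, seed = derive_seed(seed,
                                                              paste0("fold", f)))
    train_keys <- tv$train; val_keys <- tv$val
    train_rows <- which(combo_in(labels$species, labels$tissue, train_keys))
    sub_labels <- condition_labels(labels$species[train_rows],
                                   labels$tissue[train_rows],
                                   species_vocab = labels$species_vocab,
                                   tissue_vocab = labels$tissue_vocab)
    val_cm <- obs_cm
    vi <- match(combo_id(val_keys$species, val_keys$tissue), obs_key)
    val_cm <- combination_means(obs_cm$species[vi], obs_cm$tissue[vi],
                                obs_cm$values[vi, , drop = FALSE],
                                obs_cm$counts[vi], method = "observed")
    gs <- if (length(grid) > 1L) {
      grid_search_hyperparameters(grid, x[train_rows, , drop = FALSE],
                                  sub_labels, val_cm,
                                  seed = derive_seed(seed, paste0("gs", f)),
                                  verbose = verbose)
    } else list(best = grid[[1L]], best_index = 1L, scores = NA_real_)

    final_rows <- train_rows
    final_keys <- train_keys
    if (include_val_in_final) {
      final_keys <- rbind(train_keys, val_keys)
      final_rows <- which(combo_in(labels$species, labels$tissue, final_keys))
    }
    final_labels <- condition_labels(labels$species[final_rows],
                                     labels$tissue[final_rows],
                                     species_vocab = labels$species_vocab,
                                     tissue_vocab = labels$tissue_vocab)
    ev <- evaluable_keys(test, final_keys)
    plan[[f]] <- list(test = test, train = train_keys, val = val_keys,
                      evaluable = ev, attempts = tv$attempts)
    lam_used <- logistic_lambda[1L]
    if (nrow(ev) == 0L) { chosen[[f]] <- list(hyper_index = gs$best_index,
                                              lambda = lam_used); next }

    if ("cmimpute" %in% methods) {
      fit <- cvae(x[final_rows, , drop = FALSE], final_labels, gs$best,
                  seed = derive_seed(seed, paste0("final", f)))
      res_vals$cmimpute[[f]] <- impute_keys(fit, ev$species, ev$tissue,
                                            seed = derive_seed(seed,
                                              paste0("imp", f)))
    }
    for (b in intersect(methods, c("species", "tissue", "global"))) {
      res_vals[[b]][[f]] <- mean_baseline_grid(x[final_rows, , drop = FALSE],
                                               final_labels, ev, kind = b)
    }
    if ("logistic" %in% methods) {
      if (length(logistic_lambda) > 1L) {
        val_scores <- vapply(logistic_lambda, function(lam) {
          mods <- fit_logistic_baseline(x[train_rows, , drop = FALSE],
                                        sub_labels, lambda = lam)
          imp <- logistic_impute(mods, labels, val_cm)
          mean(vapply(seq_len(nrow(imp$values)), function(j)
            safe_cor(imp$values[j, ], val_cm$values[j, ]), numeric(1)))
        }, numeric(1))
        lam_used <- logistic_lambda[which.max(val_scores)]
      }
      mods <- fit_logistic_baseline(x[final_rows, , drop = FALSE],
                                    final_labels, lambda = lam_used)
      res_vals$logistic[[f]] <- logistic_impute(mods, labels, ev)
    }
    chosen[[f]] <- list(hyper_index = gs$best_index, lambda = lam_used)
    if (verbose) message(sprintf("fold %d: %d evaluable keys", f, nrow(ev)))
  }

  bind_cm <- function(lst, method) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    combination_means(unlist(lapply(lst, `[[`, "species")),
                      unlist(lapply(lst, `[[`, "tissue")),
                      do.call(rbind, lapply(lst, `[[`, "values")),
                      method = method, metadata = list(seed = seed, k = k))
  }
  imputed <- lapply(methods, function(m) bind_cm(res_vals[[m]], m))
  names(imputed) <- methods
  all_keys <- combo_id(imputed[[1L]]$species, imputed[[1L]]$tissue)
  oi <- match(all_keys, obs_key)
  observed <- combination_means(obs_cm$species[oi], obs_cm$tissue[oi],
                                obs_cm$values[oi, , drop = FALSE],
                                obs_cm$counts[oi], method = "observed")
  structure(list(imputed = imputed, observed = observed,
                 fold_plan = list(k = k, seed = seed, folds = plan),
                 chosen = chosen),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation over %d folds, %d evaluable keys, methods: %s\n",
              x$fold_plan$k, nrow(x$imputed[[1L]]$values),
              paste(names(x$imputed), collapse = ", ")))
  invisible(x)
}

#' Serialize a fold plan to JSON for exact rerun
#'
#' @param cv a `cv_result` (or its `fold_plan`).
#' @param path output path.
#' @export
write_fold_plan <- function(cv, path) {
  plan <- if (inherits(cv, "cv_result")) cv$fold_plan else cv
  jsonlite::write_json(plan, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Select final-model hyperparameters on random splits
#'
#' The protocol for the production model trained on all data: draw
#' `n_splits` random 80-20 train-test splits of the eligible
#' combinations, grid search each split, and for each split-best
#' hyperparameter combination average its sample-wise validation
#' correlation across all splits; the highest average wins.
#'
#' @inheritParams run_cross_validation
#' @param n_splits number of random splits (default 4).
#' @param train_frac training fraction per split.
#' @return list with `best` ([cvae_hyperparameters()]), `best_index`,
#'   `mean_scores` (per grid point, NA where never evaluated) and the
#'   per-split score matrix.
#' @export
select_final_hyperparameters <- function(x, labels, grid, n_splits = 4L,
                                         train_frac = 0.8, seed = 1L,
                                         verbose = FALSE) {
  combos <- enumerate_combinations(labels)
  elig <- combos$eligible
  if (nrow(elig) < 2L) stopf("need at least 2 eligible combinations")
  obs_cm <- compute_combination_means(x, labels)
  obs_key <- combo_id(obs_cm$species, obs_cm$tissue)
  score_mat <- matrix(NA_real_, n_splits, length(grid))
  for (s in seq_len(n_splits)) {
    n <- nrow(elig)
    tr_idx <- with_seed(derive_seed(seed, paste0("split", s)),
                        sample.int(n, round(train_frac * n)))
    test_keys <- elig[-tr_idx, , drop = FALSE]
    train_keys <- combos$observed[!combo_in(combos$observed$species,
                                            combos$observed$tissue,
                                            test_keys), , drop = FALSE]
    rows <- which(combo_in(labels$species, labels$tissue, train_keys))
    sub_labels <- condition_labels(labels$species[rows], labels$tissue[rows],
                                   species_vocab = labels$species_vocab,
                                   tissue_vocab = labels$tissue_vocab)
    ti <- match(combo_id(test_keys$species, test_keys$tissue), obs_key)
    test_cm <- combination_means(obs_cm$species[ti], obs_cm$tissue[ti],
                                 obs_cm$values[ti, , drop = FALSE],
                                 obs_cm$counts[ti], method = "observed")
    gs <- grid_search_hyperparameters(grid, x[rows, , drop = FALSE],
                                      sub_labels, test_cm,
                                      seed = derive_seed(seed, paste0("fgs", s)),
                                      verbose = verbose)
    score_mat[s, ] <- gs$scores
  }
  split_best <- apply(score_mat, 1L, which.max)
  cand <- unique(split_best)
  mean_scores <- rep(NA_real_, length(grid))
  mean_scores[cand] <- colMeans(score_mat[, cand, drop = FALSE])
  best <- cand[which.max(mean_scores[cand])]
  list(best = grid[[best]], best_index = best, mean_scores = mean_scores,
       score_matrix = score_mat)
}
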