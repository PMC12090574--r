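#' Mean imputation baselines
#'
#' Imputes a combination mean sample as the average of all training
#' samples of the target species (`kind = "species"`), of the target
#' tissue (`"tissue"`), or of the whole training set (`"global"`).  The
#' species baseline is by construction identical for every tissue within
#' a species, and vice versa.
#'
#' @param x training sample matrix.
#' @param labels matching [condition_labels()].
#' @param species,tissue the target combination.
#' @param kind which baseline.
#' @return named numeric vector of length M.
#' @export
mean_baseline_impute <- function(x, labels, species, tissue,
                                 kind = c("species", "tissue", "global")) {
  kind <- match.arg(kind)
  rows <- switch(kind,
                 species = which(labels$species == species),
                 tissue = which(labels$tissue == tissue),
                 global = seq_len(nrow(x)))
  if (length(rows) == 0L)
    stopf("no training samples for %s '%s'", kind,
          if (kind == "tissue") tissue else species)
  if (length(rows) == 1L) x[rows, ] else colMeans(x[rows, , drop = FALSE])
}

#' Impute a set of keys with a mean baseline
#'
#' @inheritParams mean_baseline_impute
#' @param keys data.frame with columns `species`, `tissue`.
#' @return a [combination_means()] with `method = kind`.
#' @export
mean_baseline_grid <- function(x, labels, keys,
                               kind = c("species", "tissue", "global")) {
  kind <- match.arg(kind)
  vals <- t(vapply(seq_len(nrow(keys)), function(i)
    mean_baseline_impute(x, labels, keys$species[i], keys$tissue[i], kind),
    numeric(ncol(x))))
  colnames(vals) <- colnames(x)
  combination_means(keys$species, keys$tissue, vals,
                    counts = rep(0L, nrow(keys)), method = kind)
}

#' Per-probe weighted logistic regression
#'
#' Fits one logistic model of a probe's beta value on the two-hot
#' (species, tissue) design.  Each training sample contributes a positive
#' instance weighted by its beta value and a negative instance weighted by
#' one minus the beta value, so the fitted success probability is the
#' predicted methylation value.  The objective is the summed weighted log
#' loss plus `lambda * ||W||^2` on the feature weights (intercept
#' unpenalized), minimized with BFGS using the analytic gradient.
#'
#' @param x training sample matrix.
#' @param labels matching [condition_labels()].
#' @param probe probe id (column of `x`).
#' @param lambda ridge penalty (>= 0).
#' @param maxit,reltol optimizer controls, recorded in the result.
#' @return object of class `probe_logistic` with fields `weights`,
#'   `intercept`, `lambda`, `probe`, `converged`, `solver`.
#' @export
fit_probe_logistic <- function(x, labels, probe, lambda = 2,
                               maxit = 500L, reltol = 1e-12) {
  if (lambda < 0) stopf("lambda must be >= 0")
  j <- match(probe, colnames(x))
  if (is.na(j)) stopf("unknown probe '%s'", probe)
  beta <- x[, j]
  if (length(beta) == 0L)
    stopf("degenerate input: no training samples (all instance weights zero)")
  D <- encode_condition_labels(labels)
  k <- ncol(D)
  # objective over duplicated rows: sum_i beta_i*(-log p_i) + (1-beta_i)*(-log(1-p_i))
  obj <- function(par) {
    w <- par[seq_len(k)]; c0 <- par[k + 1L]
    eta <- as.vector(D %*% w) + c0
    # -log p = softplus(-eta); -log(1-p) = softplus(eta)
    sum(beta * (pmax(-eta, 0) + log1p(exp(-abs(eta)))) +
          (1 - beta) * (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
      lambda * sum(w^2)
  }
  grad <- function(par) {
    w <- par[seq_len(k)]; c0 <- par[k + 1L]
    p <- sigmoid(as.vector(D %*% w) + c0)
    r <- p - beta
    c(as.vector(crossprod(D, r)) + 2 * lambda * w, sum(r))
  }
  fit <- stats::optim(numeric(k + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  structure(list(weights = stats::setNames(fit$par[seq_len(k)], colnames(D)),
                 intercept = fit$par[k + 1L], lambda = lambda,
                 probe = probe, converged = fit$convergence == 0L,
                 solver = list(method = "BFGS", maxit = maxit,
                               reltol = reltol)),
            class = "probe_logistic")
}

#' Fit the logistic baseline for every probe
#'
#' @inheritParams fit_probe_logistic
#' @return list of [fit_probe_logistic()] models, one per probe, in probe
#'   order.
#' @export
fit_logistic_baseline <- function(x, labels, lambda = 2, ...) {
  models <- lapply(colnames(x), function(p)
    fit_probe_logistic(x, labels, p, lambda = lambda, ...))
  names(models) <- colnames(x)
  models
}

#' Predict combination mean samples from per-probe logistic models
#'
#' Evaluates each probe model's sigmoid prediction on the target key's
#' two-hot feature vector and concatenates across probes.
#'
#' @param models list of `probe_logistic` models (one per probe).
#' @param labels a [condition_labels()] supplying the vocabularies.
#' @param keys data.frame with columns `species`, `tissue`.
#' @return a [combination_means()] with method `"logistic"`.
#' @export
logistic_impute <- function(models, labels, keys) {
  if (any(!vapply(models, inherits, logical(1), "probe_logistic")))
    stopf("models must be a list of probe_logistic fits")
  D <- encode_condition_labels(labels, species = as.character(keys$species),
                               tissue = as.character(keys$tissue))
  vals <- vapply(models, function(m)
    sigmoid(as.vector(D %*% m$weights) + m$intercept),
    numeric(nrow(keys)))
  if (nrow(keys) == 1L) vals <- matrix(vals, 1L,
                                       dimnames = list(NULL, names(models)))
  colnames(vals) <- names(models)
  combination_means(keys$species, keys$tissue, vals,
                    counts = rep(0L, nrow(keys)), method = "logistic",
                    metadata = list(lambda = models[[1L]]$lambda))
}
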