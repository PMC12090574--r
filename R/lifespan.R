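#' Read a species maximum-lifespan table
#'
#' TSV with header `species  max_lifespan_years`.
#'
#' @param path file path.
#' @return data.frame with columns `species`, `max_lifespan`.
#' @export
read_lifespan_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#")
  names(tab)[names(tab) == "max_lifespan_years"] <- "max_lifespan"
  if (!all(c("species", "max_lifespan") %in% names(tab)))
    stopf("lifespan table needs columns species and max_lifespan_years")
  validate_lifespan_table(tab)
}

validate_lifespan_table <- function(tab) {
  if (anyDuplicated(tab$species)) stopf("duplicate species in lifespan table")
  if (any(!is.finite(tab$max_lifespan)) || any(tab$max_lifespan <= 0))
    stopf("maximum lifespans must be positive")
  tab[, c("species", "max_lifespan")]
}

# minimum-norm least squares with intercept column; for full-rank
# overdetermined designs this is ordinary least squares
minnorm_lm <- function(X, y) {
  A <- cbind(1, X)
  as.vector(MASS::ginv(A) %*% y)
}

minnorm_predict <- function(coefs, X) {
  as.vector(cbind(1, X) %*% coefs)
}

#' Leave-one-species-out regression of log maximum lifespan
#'
#' Regresses the natural logarithm of species maximum lifespan on
#' combination mean methylation.  In `tissue_agnostic` mode the rows of
#' each species are first averaged into a single species profile and each
#' LOSO iteration holds out one species; in `tissue_specific` mode the
#' rows stay intact, every row of a species shares the species' lifespan,
#' and each iteration holds out all rows of one species, predicting each
#' held-out row.  Fits are minimum-norm least squares (ordinary least
#' squares when the design is full-rank overdetermined), so the
#' conventional behaviour with many more probes than species is
#' well-defined.
#'
#' @param samples a [combination_means()].
#' @param lifespans data.frame with columns `species`, `max_lifespan`
#'   (years, > 0).
#' @param mode `"tissue_agnostic"` or `"tissue_specific"`.
#' @return object of class `lifespan_report`: `per_unit` data.frame
#'   (species, tissue in tissue_specific mode, predicted, reported — both
#'   natural-log lifespans), `r` (NA and flagged if undefined), `mse`,
#'   `mode`, `log_base = "natural"`.
#' @export
loso_lifespan_regression <- function(samples, lifespans,
                                     mode = c("tissue_agnostic",
                                              "tissue_specific")) {
  mode <- match.arg(mode)
  stopifnot(inherits(samples, "combination_means"))
  lifespans <- validate_lifespan_table(lifespans)
  have <- samples$species %in% lifespans$species
  if (!all(have)) {
    warning(sprintf("excluding %d sample(s) of species without lifespan: %s",
                    sum(!have),
                    paste(unique(samples$species[!have]), collapse = ", ")))
  }
  vals <- samples$values[have, , drop = FALSE]
  sp <- samples$species[have]; ti <- samples$tissue[have]
  uniq_sp <- sort_c(sp)
  if (length(uniq_sp) < 3L) stopf("need at least 3 species with lifespans")
  y_sp <- log(lifespans$max_lifespan[match(uniq_sp, lifespans$species)])
  names(y_sp) <- uniq_sp

  if (mode == "tissue_agnostic") {
    X <- t(vapply(uniq_sp, function(s)
      colMeans(vals[sp == s, , drop = FALSE]), numeric(ncol(vals))))
    pred <- numeric(length(uniq_sp))
    for (i in seq_along(uniq_sp)) {
      coefs <- minnorm_lm(X[-i, , drop = FALSE], y_sp[-i])
      pred[i] <- minnorm_predict(coefs, X[i, , drop = FALSE])
    }
    per <- data.frame(species = uniq_sp, predicted = pred,
                      reported = unname(y_sp))
  } else {
    pred <- rep(NA_real_, nrow(vals))
    y_row <- y_sp[sp]
    for (s in uniq_sp) {
      hold <- which(sp == s)
      coefs <- minnorm_lm(vals[-hold, , drop = FALSE], y_row[-hold])
      pred[hold] <- minnorm_predict(coefs, vals[hold, , drop = FALSE])
    }
    per <- data.frame(species = sp, tissue = ti, predicted = pred,
                      reported = unname(y_row))
  }
  r <- safe_cor(per$predicted, per$reported)
  structure(list(per_unit = per, r = r,
                 r_defined = !is.na(r),
                 mse = mean((per$predicted - per$reported)^2),
                 mode = mode, log_base = "natural"),
            class = "lifespan_report")
}

#' @export
print.lifespan_report <- function(x, ...) {
  cat(sprintf("LOSO lifespan regression (%s, natural log): r = %s, MSE = %.4f over %d units\n",
              x$mode, if (x$r_defined) sprintf("%.4f", x$r) else "undefined",
              x$mse, nrow(x$per_unit)))
  invisible(x)
}

#' Per-tissue evaluation of tissue-specific lifespan predictions
#'
#' Restricts to tissues observed in at least `min_species` species and
#' reports each tissue's Pearson correlation and MSE between predicted
#' and reported log-lifespans, plus the average of the per-tissue
#' correlations and the median of the per-tissue MSEs.
#'
#' @param report a tissue-specific [loso_lifespan_regression()] result.
#' @param min_species minimum species per tissue (default 3).
#' @return list with `per_tissue` data.frame (tissue, n_species, r, mse),
#'   `mean_r`, `median_mse`.
#' @export
tissue_specific_lifespan_eval <- function(report, min_species = 3L) {
  stopifnot(inherits(report, "lifespan_report"))
  if (report$mode != "tissue_specific")
    stopf("report must come from tissue_specific mode")
  per <- report$per_unit
  out <- list()
  for (t in sort_c(per$tissue)) {
    rows <- per[per$tissue == t, ]
    ns <- length(unique(rows$species))
    if (ns < min_species) next
    out[[t]] <- data.frame(tissue = t, n_species = ns,
                           r = safe_cor(rows$predicted, rows$reported),
                           mse = mean((rows$predicted - rows$reported)^2))
  }
  if (length(out) == 0L)
    stopf("no tissue is observed in %d or more species", min_species)
  per_tissue <- do.call(rbind, out)
  rownames(per_tissue) <- NULL
  list(per_tissue = per_tissue,
       mean_r = mean(per_tissue$r, na.rm = TRUE),
       median_mse = stats::median(per_tissue$mse))
}

#' Correlation between two sets of lifespan predictions
#'
#' Mirrors the observed-vs-imputed comparison: correlates the predicted
#' log-lifespans of two reports across their shared species (averaging
#' within species for tissue-specific reports).
#'
#' @param report_a,report_b [loso_lifespan_regression()] results.
#' @return scalar Pearson correlation.
#' @export
compare_lifespan_predictions <- function(report_a, report_b) {
  by_species <- function(rep) {
    p <- tapply(rep$per_unit$predicted, rep$per_unit$species, mean)
    p[sort_c(names(p))]
  }
  a <- by_species(report_a); b <- by_species(report_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) stopf("need at least 3 shared species")
  safe_cor(a[shared], b[shared])
}
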