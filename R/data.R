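#' Condition labels for a methylation compendium
#'
#' Bundles the per-sample species and tissue assignments with deterministic
#' (lexicographically sorted) vocabularies.  The one-hot label matrix used
#' by the conditional VAE and by the logistic baseline is the column-wise
#' concatenation of an N x S species block and an N x T tissue block, both
#' in vocabulary order.
#'
#' @param species character vector, one species per sample.
#' @param tissue character vector, one tissue per sample (same length).
#' @param species_vocab,tissue_vocab optional explicit vocabularies; must
#'   contain every label that occurs.  Defaults to the sorted unique labels.
#' @return An object of class `condition_labels` with fields `species`,
#'   `tissue`, `species_vocab`, `tissue_vocab`.
#' @export
condition_labels <- function(species, tissue,
                             species_vocab = NULL, tissue_vocab = NULL) {
  species <- as.character(species)
  tissue <- as.character(tissue)
  if (length(species) != length(tissue))
    stopf("species (%d) and tissue (%d) differ in length",
          length(species), length(tissue))
  if (length(species) < 1L) stopf("at least one sample is required")
  if (anyNA(species) || anyNA(tissue) || any(!nzchar(species)) ||
      any(!nzchar(tissue)))
    stopf("species and tissue labels must be non-empty strings")
  species_vocab <- species_vocab %||% sort_c(species)
  tissue_vocab <- tissue_vocab %||% sort_c(tissue)
  bad_s <- setdiff(species, species_vocab)
  if (length(bad_s)) stopf("species not in vocabulary: %s",
                           paste(bad_s, collapse = ", "))
  bad_t <- setdiff(tissue, tissue_vocab)
  if (length(bad_t)) stopf("tissue not in vocabulary: %s",
                           paste(bad_t, collapse = ", "))
  if (anyDuplicated(species_vocab) || anyDuplicated(tissue_vocab))
    stopf("vocabularies must not contain duplicates")
  structure(list(species = species, tissue = tissue,
                 species_vocab = species_vocab, tissue_vocab = tissue_vocab),
            class = "condition_labels")
}

#' @export
print.condition_labels <- function(x, ...) {
  cat(sprintf("condition_labels: %d samples, %d species, %d tissues\n",
              length(x$species), length(x$species_vocab),
              length(x$tissue_vocab)))
  invisible(x)
}

#' Validate a beta-value sample matrix
#'
#' A sample matrix is a plain numeric matrix of beta values in [0,1] with
#' unique sample ids as rownames and unique probe ids as colnames.  Any
#' non-finite or out-of-range value is an error naming the offending sample
#' and probe; missing values are rejected rather than silently imputed.
#'
#' @param values numeric matrix.
#' @return The validated matrix, invisibly usable as-is.
#' @export
validate_sample_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("sample matrix must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stopf("sample matrix must have at least one row and column")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("sample matrix needs sample ids as rownames and probe ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate probe ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  bad <- !is.finite(values) | values < 0 | values > 1
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("value %s at sample '%s', probe '%s' is not a beta value in [0,1]",
          format(values[idx[1L], idx[2L]]),
          rownames(values)[idx[1L]], colnames(values)[idx[2L]])
  }
  values
}

#' Read a sample matrix and its label table
#'
#' The matrix file is TSV with a header row of probe ids and sample ids in
#' the first column; the labels file is TSV with columns `sample_id`,
#' `species`, `tissue`.  Label rows are reordered to the matrix sample
#' order and vocabularies are built lexicographically.
#'
#' @param path path to the matrix TSV.
#' @param labels_path path to the labels TSV.
#' @return list with elements `values` (validated matrix) and `labels`
#'   (a [condition_labels()]).
#' @export
read_sample_matrix <- function(path, labels_path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  if (!file.exists(labels_path)) stopf("labels file not found: %s", labels_path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  values <- as.matrix(tab)
  suppressWarnings(storage.mode(values) <- "double")
  nonnum <- which(is.na(values) & tab != "NA", arr.ind = TRUE)
  if (nrow(nonnum)) {
    stopf("non-numeric value '%s' at sample '%s', probe '%s'",
          tab[nonnum[1L, 1L], nonnum[1L, 2L]],
          rownames(values)[nonnum[1L, 1L]], colnames(values)[nonnum[1L, 2L]])
  }
  validate_sample_matrix(values)
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#")
  need <- c("sample_id", "species", "tissue")
  if (!all(need %in% names(lab)))
    stopf("labels file must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(lab$sample_id))
    stopf("duplicate sample ids in labels file: %s",
          paste(unique(lab$sample_id[duplicated(lab$sample_id)]),
                collapse = ", "))
  missing <- setdiff(rownames(values), lab$sample_id)
  if (length(missing))
    stopf("labels file is missing sample(s): %s",
          paste(missing, collapse = ", "))
  lab <- lab[match(rownames(values), lab$sample_id), ]
  list(values = values,
       labels = condition_labels(lab$species, lab$tissue))
}

#' Write a sample matrix and label table as TSV
#'
#' @param values sample matrix (see [validate_sample_matrix()]).
#' @param labels a [condition_labels()].
#' @param path,labels_path output paths.
#' @export
write_sample_matrix <- function(values, labels, path, labels_path) {
  validate_sample_matrix(values)
  df <- data.frame(sample_id = rownames(values), values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = rownames(values),
                    species = labels$species, tissue = labels$tissue)
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Binary single-file container for large matrices
#'
#' RDS-based container holding `values`, `sample_ids`, `probe_ids` (and the
#' labels, if given); round-trips ids bit-exactly and values losslessly.
#'
#' @param values sample matrix.
#' @param labels optional [condition_labels()].
#' @param path output path.
#' @export
write_sample_matrix_binary <- function(values, path, labels = NULL) {
  validate_sample_matrix(values)
  saveRDS(list(values = unname(values), sample_ids = rownames(values),
               probe_ids = colnames(values), labels = labels),
          path)
  invisible(path)
}

#' @rdname write_sample_matrix_binary
#' @export
read_sample_matrix_binary <- function(path) {
  obj <- readRDS(path)
  values <- obj$values
  rownames(values) <- obj$sample_ids
  colnames(values) <- obj$probe_ids
  validate_sample_matrix(values)
  list(values = values, labels = obj$labels)
}

#' Two-hot encode species and tissue labels
#'
#' Produces the N x (S+T) binary design used by the CVAE and the logistic
#' baseline: each row has exactly one 1 in the species block (first S
#' columns, vocabulary order) and one in the tissue block.
#'
#' @param labels a [condition_labels()], or any object with
#'   `species`/`tissue`/vocab fields.
#' @param species,tissue optional explicit label vectors to encode against
#'   `labels`' vocabularies (defaults to the labels' own samples).
#' @return binary matrix with named columns `species:<s>` and `tissue:<t>`.
#' @export
encode_condition_labels <- function(labels, species = NULL, tissue = NULL) {
  species <- species %||% labels$species
  tissue <- tissue %||% labels$tissue
  si <- match(species, labels$species_vocab)
  if (anyNA(si)) stopf("species not in vocabulary: %s",
                       paste(unique(species[is.na(si)]), collapse = ", "))
  ti <- match(tissue, labels$tissue_vocab)
  if (anyNA(ti)) stopf("tissue not in vocabulary: %s",
                       paste(unique(tissue[is.na(ti)]), collapse = ", "))
  n <- length(species)
  S <- length(labels$species_vocab)
  T_ <- length(labels$tissue_vocab)
  out <- matrix(0, n, S + T_,
                dimnames = list(NULL, c(paste0("species:", labels$species_vocab),
                                        paste0("tissue:", labels$tissue_vocab))))
  out[cbind(seq_len(n), si)] <- 1
  out[cbind(seq_len(n), S + ti)] <- 1
  out
}

#' Combination mean container
#'
#' One row per (species, tissue) pair holding the mean methylation profile
#' of that combination; `counts` records how many individual samples
#' contributed (0 for imputed rows).
#'
#' @param species,tissue character vectors naming the combinations.
#' @param values numeric |C| x M matrix, rows aligned with the keys.
#' @param counts integer vector of contributing sample counts.
#' @param method provenance tag, e.g. "observed", "cmimpute", "species".
#' @param metadata optional named list stored with the object.
#' @export
combination_means <- function(species, tissue, values, counts = NULL,
                              method = "observed", metadata = list()) {
  species <- as.character(species); tissue <- as.character(tissue)
  if (!is.matrix(values)) values <- matrix(values, nrow = length(species))
  if (length(species) != nrow(values) || length(tissue) != nrow(values))
    stopf("keys (%d) and value rows (%d) must align",
          length(species), nrow(values))
  if (anyDuplicated(combo_id(species, tissue)))
    stopf("duplicate (species, tissue) keys")
  counts <- counts %||% rep(0L, length(species))
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stopf("combination mean values must lie in [0,1]")
  structure(list(species = species, tissue = tissue,
                 values = values, counts = as.integer(counts),
                 method = method, metadata = metadata),
            class = "combination_means")
}

#' @export
print.combination_means <- function(x, ...) {
  cat(sprintf("combination_means [%s]: %d combinations x %d probes\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Mean methylation of every observed species-tissue combination
#'
#' Collapses individual samples to one arithmetic-mean row per observed
#' (species, tissue) pair.  This is the first step of the probe variance
#' calculations and produces the observed targets that imputed combination
#' mean samples are compared with.
#'
#' @param values sample matrix.
#' @param labels a [condition_labels()].
#' @return a [combination_means()] with method `"observed"`; rows are
#'   ordered by species then tissue (C locale).
#' @export
compute_combination_means <- function(values, labels) {
  validate_sample_matrix(values)
  if (nrow(values) != length(labels$species))
    stopf("matrix rows (%d) and labels (%d) must align",
          nrow(values), length(labels$species))
  key <- combo_id(labels$species, labels$tissue)
  ord <- sort_c(key)
  m <- matrix(NA_real_, length(ord), ncol(values),
              dimnames = list(NULL, colnames(values)))
  counts <- integer(length(ord))
  for (i in seq_along(ord)) {
    rows <- which(key == ord[i])
    counts[i] <- length(rows)
    m[i, ] <- if (length(rows) == 1L) values[rows, ] else colMeans(values[rows, , drop = FALSE])
  }
  parts <- do.call(rbind, strsplit(ord, "\t", fixed = TRUE))
  combination_means(parts[, 1L], parts[, 2L], m, counts, method = "observed")
}

#' Enumerate observed, missing and imputation-eligible combinations
#'
#' `observed` are the distinct (species, tissue) pairs present in the
#' labels; `missing` is the complement within the full S x T grid; and
#' `eligible` are the observed pairs whose species occurs with more than
#' one distinct tissue AND whose tissue occurs with more than one distinct
#' species — the pairs that can be held out while leaving same-species and
#' same-tissue information in training.
#'
#' @param labels a [condition_labels()].
#' @return list of three data.frames (`observed`, `missing`, `eligible`)
#'   with columns `species`, `tissue`.
#' @export
enumerate_combinations <- function(labels) {
  obs_key <- sort_c(combo_id(labels$species, labels$tissue))
  parts <- do.call(rbind, strsplit(obs_key, "\t", fixed = TRUE))
  observed <- data.frame(species = parts[, 1L], tissue = parts[, 2L],
                         stringsAsFactors = FALSE)
  grid <- expand.grid(species = labels$species_vocab,
                      tissue = labels$tissue_vocab,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid_key <- combo_id(grid$species, grid$tissue)
  missing <- grid[!(grid_key %in% obs_key), , drop = FALSE]
  rownames(missing) <- NULL
  tissues_per_species <- tapply(observed$tissue, observed$species,
                                function(x) length(unique(x)))
  species_per_tissue <- tapply(observed$species, observed$tissue,
                               function(x) length(unique(x)))
  keep <- tissues_per_species[observed$species] > 1L &
    species_per_tissue[observed$tissue] > 1L
  eligible <- observed[keep, , drop = FALSE]
  rownames(eligible) <- NULL
  list(observed = observed, missing = missing, eligible = eligible)
}

#' Probe-by-species mappability table
#'
#' @param mappable logical/0-1 matrix, rows = probes, columns = species.
#' @export
mappability_table <- function(mappable) {
  if (!is.matrix(mappable)) stopf("mappability must be a matrix")
  if (is.null(rownames(mappable)) ||
      (ncol(mappable) > 0L && is.null(colnames(mappable))))
    stopf("mappability matrix needs probe rownames and species colnames")
  if (is.null(colnames(mappable))) colnames(mappable) <- character(0)
  vals <- as.vector(mappable)
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stopf("mappability values must be 0/1")
  storage.mode(mappable) <- "integer"
  structure(list(probe_ids = rownames(mappable),
                 species_ids = colnames(mappable),
                 mappable = mappable),
            class = "mappability_table")
}

#' @rdname mappability_table
#' @param path TSV path (rows = probes, columns = species, cells 0/1).
#' @export
read_mappability <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  mappability_table(as.matrix(tab))
}

#' Select probes mappable in at least a fraction of species
#'
#' The "highest-coverage" probe subset: probes that map to a unique genomic
#' location in at least `fraction` (default 90%, inclusive) of the species
#' with mappability annotation.
#'
#' @param map a [mappability_table()].
#' @param fraction inclusive mappable-fraction threshold in (0, 1].
#' @return character vector of probe ids.
#' @export
select_highest_coverage_probes <- function(map, fraction = 0.9) {
  if (!inherits(map, "mappability_table")) stopf("map must be a mappability_table")
  if (length(map$species_ids) == 0L) stopf("mappability table has no species")
  if (!(fraction > 0 && fraction <= 1)) stopf("fraction must be in (0, 1]")
  frac <- rowMeans(map$mappable)
  map$probe_ids[frac >= fraction]
}

#' Write / read combination mean tables
#'
#' TSV with metadata comment lines (`#key value`), then columns `species`,
#' `tissue`, `count`, followed by one column per probe.
#'
#' @param x a [combination_means()].
#' @param path file path.
#' @export
write_combination_means <- function(x, path) {
  stopifnot(inherits(x, "combination_means"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(method = x$method), x$metadata)
  for (k in names(meta))
    writeLines(sprintf("#%s\t%s", k, format(meta[[k]], digits = 17)), con)
  df <- data.frame(species = x$species, tissue = x$tissue, count = x$counts,
                   x$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_combination_means
#' @export
read_combination_means <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    kv <- strsplit(sub("^#", "", l), "\t")[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  tab <- utils::read.table(text = lines[setdiff(seq_along(lines), meta_lines)],
                           header = TRUE, sep = "\t", check.names = FALSE)
  probes <- setdiff(names(tab), c("species", "tissue", "count"))
  vals <- as.matrix(tab[, probes, drop = FALSE])
  combination_means(tab$species, tab$tissue, vals, tab$count,
                    method = meta$method %||% "unknown",
                    metadata = meta[setdiff(names(meta), "method")])
}

# Subset a combination_means to given probe ids (internal convenience).
subset_probes <- function(x, probes) {
  if (is.null(probes)) return(x)
  idx <- match(probes, colnames(x$values))
  if (anyNA(idx)) stopf("unknown probe id(s): %s",
                        paste(probes[is.na(idx)], collapse = ", "))
  x$values <- x$values[, idx, drop = FALSE]
  x
}
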