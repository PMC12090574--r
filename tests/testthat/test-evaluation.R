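make_cm <- function(values, species = NULL, tissue = NULL) {
  n <- nrow(values)
  species <- species %||% paste0("sp", seq_len(n))
  tissue <- tissue %||% rep("t1", n)
  colnames(values) <- colnames(values) %||% paste0("p", seq_len(ncol(values)))
  combination_means(species, tissue, values)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sample-wise agreement handles identity, reversal and constants", {
  obs <- make_cm(tiny_matrix(3L, 5L, seed = 2L))
  same <- obs; same$method <- "cmimpute"
  rep1 <- sample_wise_agreement(same, obs)
  expect_true(all(rep1$per_sample$r == 1))
  expect_true(all(rep1$per_sample$mse == 0))

  anti <- obs; anti$values <- 1 - obs$values
  rep2 <- sample_wise_agreement(anti, obs)
  expect_true(all(abs(rep2$per_sample$r + 1) < 1e-12))

  ex <- make_cm(matrix(c(0.2, 0.4), 1, 2))
  ey <- make_cm(matrix(c(0.3, 0.5), 1, 2))
  expect_equal(sample_wise_agreement(ex, ey)$per_sample$mse, 0.01)

  # a constant imputed row is flagged and excluded from r summaries only
  con <- obs; con$values[1, ] <- 0.5
  rep3 <- sample_wise_agreement(con, obs)
  expect_false(rep3$per_sample$r_defined[1])
  expect_equal(rep3$summary$n_undefined_r, 1L)
  expect_true(is.finite(rep3$per_sample$mse[1]))
  expect_equal(rep3$summary$mean_r, mean(rep3$per_sample$r[-1]))

  expect_error(sample_wise_agreement(make_cm(matrix(0.1, 1, 1)),
                                     make_cm(matrix(0.2, 1, 1))),
               "2 probes")
})

test_that("probe-wise agreement works across combinations and flags zero variance", {
  obs <- make_cm(matrix(c(0.1, 0.9, 0.3, 0.3), 2, 2))
  imp <- make_cm(matrix(c(0.2, 0.8, 0.6, 0.6), 2, 2))
  rep <- probe_wise_agreement(imp, obs)
  expect_equal(rep$per_probe$r[1], 1)          # two points, positive slope
  expect_false(rep$per_probe$r_defined[2])     # constant in both
  expect_error(probe_wise_agreement(make_cm(matrix(0.5, 1, 3)),
                                    make_cm(matrix(0.5, 1, 3))),
               "2 shared combinations")
})

test_that("mean probe-wise MSE equals mean sample-wise MSE on complete grids", {
  set.seed(33)
  for (rep_ in 1:3) {
    obs <- make_cm(tiny_matrix(6L, 9L, seed = 40L + rep_))
    imp <- make_cm(pmin(pmax(obs$values +
                               matrix(rnorm(54, 0, 0.05), 6, 9), 0), 1))
    sw <- sample_wise_agreement(imp, obs)
    pw <- probe_wise_agreement(imp, obs)
    expect_equal(sw$summary$mean_mse, pw$summary$mean_mse, tolerance = 1e-12)
  }
})

test_that("staged variance formulas match direct evaluation and a naive oracle", {
  # two combination means 0.2 and 0.4 -> population variance 0.01
  x <- tiny_matrix(2L, 1L, values = c(0.2, 0.4))
  lab <- condition_labels(c("a", "b"), c("t", "t"))
  pr <- suppressWarnings(probe_variance_profile(x, lab))
  expect_equal(unname(pr$inter_combination), 0.01)
  expect_equal(unname(pr$mean_inter_species), 0.01)

  # one species, tissue means 0 and 1 -> mean inter-tissue variance 0.25
  x2 <- tiny_matrix(2L, 1L, values = c(0, 1))
  lab2 <- condition_labels(c("a", "a"), c("t1", "t2"))
  pr2 <- suppressWarnings(probe_variance_profile(x2, lab2))
  expect_equal(unname(pr2$mean_inter_tissue), 0.25)

  # constant probe -> all variances zero
  x3 <- tiny_matrix(4L, 1L, values = rep(0.3, 4))
  lab3 <- condition_labels(c("a", "a", "b", "b"), c("t1", "t2", "t1", "t2"))
  pr3 <- probe_variance_profile(x3, lab3)
  expect_equal(max(pr3$inter_combination, pr3$mean_inter_tissue,
                   pr3$mean_inter_species), 0)

  # naive nested-loop oracle on a random 30-sample fixture
  set.seed(44)
  x4 <- tiny_matrix(30L, 6L, seed = 44L)
  sp <- sample(c("a", "b", "c", "d"), 30, replace = TRUE)
  ti <- sample(c("t1", "t2", "t3"), 30, replace = TRUE)
  lab4 <- condition_labels(sp, ti)
  pr4 <- probe_variance_profile(x4, lab4)
  popv <- function(v) sum((v - mean(v))^2) / length(v)
  combo <- paste(sp, ti)
  cm <- sapply(sort(unique(combo)), function(k)
    colMeans(x4[combo == k, , drop = FALSE]))      # M x |C|
  expect_equal(unname(pr4$inter_combination),
               unname(apply(cm, 1, popv)), tolerance = 1e-12)
  csp <- sub(" .*", "", colnames(cm))
  cti <- sub(".* ", "", colnames(cm))
  sp_multi <- names(which(tapply(cti, csp, length) > 1))
  oracle_it <- rowMeans(sapply(sp_multi, function(s)
    apply(cm[, csp == s, drop = FALSE], 1, popv)))
  expect_equal(unname(pr4$mean_inter_tissue), unname(oracle_it),
               tolerance = 1e-12)
  ti_multi <- names(which(tapply(csp, cti, length) > 1))
  oracle_is <- rowMeans(sapply(ti_multi, function(t)
    apply(cm[, cti == t, drop = FALSE], 1, popv)))
  expect_equal(unname(pr4$mean_inter_species), unname(oracle_is),
               tolerance = 1e-12)
})

test_that("variance quartiles are rank-based with near-equal group sizes", {
  prof <- structure(list(inter_combination = c(8:1) / 100,
                         probe_ids = paste0("p", 1:8)),
                    class = "variance_profile")
  q <- assign_variance_quartiles(prof, "inter_combination")
  expect_equal(as.integer(table(q)), rep(2L, 4))
  expect_equal(as.character(q[["p8"]]), "Q1")   # smallest variance
  expect_equal(as.character(q[["p1"]]), "Q4")

  prof5 <- structure(list(inter_combination = c(5, 4, 3, 2, 1) / 10,
                          probe_ids = paste0("p", 1:5)),
                     class = "variance_profile")
  q5 <- assign_variance_quartiles(prof5, "inter_combination")
  expect_equal(as.integer(table(q5)), c(2L, 1L, 1L, 1L))

  proft <- structure(list(inter_combination = rep(0.2, 9),
                          probe_ids = paste0("p", 1:9)),
                     class = "variance_profile")
  qt <- assign_variance_quartiles(proft, "inter_combination")
  expect_lte(diff(range(table(qt))), 1L)
  # stable tie-break: identical call, identical labels
  expect_identical(qt, assign_variance_quartiles(proft, "inter_combination"))
})

test_that("species-signal removal subtracts same-species training means", {
  x <- tiny_matrix(2L, 1L, values = c(0.4, 0.6))   # species mean 0.5
  lab <- condition_labels(c("a", "a"), c("t1", "t2"))
  cm <- make_cm(matrix(0.7, 1, 1), species = "a", tissue = "t3")
  d <- remove_species_signal(cm, x, lab)
  expect_equal(unname(d[1, 1]), 0.2)

  cm0 <- make_cm(matrix(0.5, 1, 1), species = "a", tissue = "t3")
  expect_equal(unname(remove_species_signal(cm0, x, lab)[1, 1]), 0)
  expect_true(all(d >= -1 & d <= 1))
  cmz <- make_cm(matrix(0.5, 1, 1), species = "zz", tissue = "t3")
  expect_error(remove_species_signal(cmz, x, lab), "zz")
})

test_that("label-signal AUC matches brute-force pair enumeration", {
  # perfectly separated: same-species pairs correlate higher
  set.seed(55)
  base <- runif(10)
  v <- rbind(base + rnorm(10, 0, 0.001), base + rnorm(10, 0, 0.001),
             rev(base) + rnorm(10, 0, 0.001), rev(base) + rnorm(10, 0, 0.001))
  v <- pmin(pmax(v, 0), 1)
  cm <- make_cm(v, species = c("a", "a", "b", "b"),
                tissue = c("t1", "t2", "t1", "t2"))
  expect_equal(label_signal_auc(cm, "species"), 1)

  # brute-force Mann-Whitney oracle on 4 samples
  set.seed(56)
  v4 <- tiny_matrix(4L, 6L, seed = 56L)
  cm4 <- make_cm(v4, species = c("a", "a", "b", "c"),
                 tissue = c("t1", "t2", "t1", "t2"))
  cors <- cor(t(v4))
  pairs <- t(combn(4, 2))
  scores <- cors[pairs]
  pos <- c("a", "a", "b", "c")[pairs[, 1]] == c("a", "a", "b", "c")[pairs[, 2]]
  oracle <- 0
  for (i in which(pos)) for (j in which(!pos))
    oracle <- oracle + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  oracle <- oracle / (sum(pos) * sum(!pos))
  expect_equal(label_signal_auc(cm4, "species"), oracle, tolerance = 1e-10)

  expect_error(label_signal_auc(make_cm(tiny_matrix(2L, 4L),
                                        species = c("a", "b")), "species"),
               "positive")
})

test_that("AUC is invariant under monotone transforms and handles ties", {
  set.seed(57)
  scores <- rnorm(20)
  pos <- rep(c(TRUE, FALSE), 10)
  a1 <- cmimpute:::rank_auc(scores, pos)
  expect_equal(cmimpute:::rank_auc(tanh(scores), pos), a1)
  expect_equal(cmimpute:::rank_auc(exp(scores), pos), a1)
  expect_equal(cmimpute:::rank_auc(rep(1, 20), pos), 0.5)
})

test_that("paired comparison reports the win fraction and signed-rank p", {
  b <- seq(0.1, 0.8, length.out = 8)
  out <- paired_method_comparison(b + 0.1, b)
  expect_equal(out$fraction_a_better, 1)
  expect_lt(out$p_value, 0.05)

  tie <- paired_method_comparison(b, b)
  expect_equal(tie$fraction_a_better, 0)
  expect_true(is.na(tie$p_value))

  # exhaustive signed-rank null on 8 handmade pairs (no ties)
  set.seed(58)
  d <- c(0.11, -0.23, 0.31, 0.07, -0.41, 0.19, 0.27, -0.03)
  a <- b + d
  out8 <- paired_method_comparison(a, b)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  null_W <- as.matrix(signs) %*% r
  p_oracle <- mean(null_W >= max(W, sum(r) - W)) +
    mean(null_W <= min(W, sum(r) - W))
  expect_equal(out8$p_value, p_oracle, tolerance = 1e-10)
})

test_that("individual-to-individual variability averages pairwise correlations", {
  set.seed(59)
  x <- rbind(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9),
             c(0.2, 0.5, 0.8), c(0.9, 0.4, 0.1), c(0.3, 0.3, 0.5))
  dimnames(x) <- list(paste0("s", 1:5), paste0("p", 1:3))
  lab <- condition_labels(c("a", "a", "a", "b", "c"),
                          c("t", "t", "t", "t", "t"))
  out <- individual_to_individual_variability(x, lab)
  expect_equal(nrow(out), 1L)     # singletons b and c omitted
  cors <- cor(t(x[1:3, ]))
  expect_equal(out$mean_pairwise_r, mean(cors[upper.tri(cors)]))

  x2 <- x[1:2, ]
  lab2 <- condition_labels(c("a", "a"), c("t", "t"))
  expect_equal(individual_to_individual_variability(x2, lab2)$mean_pairwise_r,
               1)
})
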