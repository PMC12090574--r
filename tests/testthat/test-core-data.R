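test_that("matrix + labels TSV round-trip preserves values, ids and order", {
  x <- tiny_matrix(2L, 3L, values = c(0, 1, 0.5, 0, 1, 0.5))
  lab <- condition_labels(c("horse", "human"), c("liver", "blood"))
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_sample_matrix(x, lab, mp, lp)
  rt <- read_sample_matrix(mp, lp)
  expect_identical(dim(rt$values), c(2L, 3L))
  expect_equal(rt$values, x)
  expect_identical(rt$labels$species, lab$species)
  expect_identical(rt$labels$species_vocab, c("horse", "human"))
})

test_that("binary container round-trips ids bit-exactly and values losslessly", {
  x <- tiny_matrix(5L, 7L, seed = 3L)
  lab <- condition_labels(rep(c("a", "b"), c(2, 3)), rep("t", 5))
  p <- withr::local_tempfile(fileext = ".rds")
  write_sample_matrix_binary(x, p, labels = lab)
  rt <- read_sample_matrix_binary(p)
  expect_identical(rownames(rt$values), rownames(x))
  expect_identical(rt$values, x)
  expect_identical(rt$labels$tissue_vocab, "t")
})

test_that("loader errors name the offending sample, probe or missing id", {
  x <- tiny_matrix(2L, 3L, values = c(0, 1, 0.5, 0, 1, 0.5))
  lab <- condition_labels(c("horse", "human"), c("liver", "blood"))
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_sample_matrix(x, lab, mp, lp)

  # out-of-range value cites its sample and probe
  bad <- x; bad["s1", "p2"] <- 1.2
  df <- data.frame(sample_id = rownames(bad), bad, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_matrix(mp, lp), "s1.*p2")

  # non-numeric cell is reported, not silently coerced
  df[1, 2] <- "abc"
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_matrix(mp, lp), "abc")

  # labels file missing a sample names it
  write_sample_matrix(x, lab, mp, lp)
  ltab <- read.table(lp, header = TRUE, sep = "\t")
  write.table(ltab[-1, ], lp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_matrix(mp, lp), "s1")
})

test_that("duplicate ids are rejected", {
  x <- tiny_matrix(2L, 2L)
  rownames(x) <- c("s1", "s1")
  expect_error(validate_sample_matrix(x), "duplicate sample ids")
  x <- tiny_matrix(2L, 2L)
  colnames(x) <- c("p", "p")
  expect_error(validate_sample_matrix(x), "duplicate probe ids")
})

test_that("two-hot encoding places species then tissue blocks in vocab order", {
  lab <- condition_labels(c("b", "a"), c("x", "y"))
  enc <- encode_condition_labels(lab)
  # sample 1 is (b, x): species block is (a, b) so [0,1], tissue block [1,0]
  expect_equal(unname(enc[1, ]), c(0, 1, 1, 0))
  expect_equal(unname(enc[2, ]), c(1, 0, 0, 1))

  lab1 <- condition_labels(rep("only", 3), rep("t", 3))
  expect_true(all(encode_condition_labels(lab1) == 1))

  expect_error(encode_condition_labels(lab, species = "zz", tissue = "x"),
               "zz")
})

test_that("two-hot rows always sum to 2 and block sums count the labels", {
  set.seed(42)
  for (rep_ in 1:5) {
    sp <- sample(letters[1:4], 30, replace = TRUE)
    ti <- sample(c("t1", "t2", "t3"), 30, replace = TRUE)
    lab <- condition_labels(sp, ti)
    enc <- encode_condition_labels(lab)
    expect_true(all(rowSums(enc) == 2))
    expect_equal(unname(colSums(enc)),
                 unname(c(table(factor(sp, lab$species_vocab)),
                          table(factor(ti, lab$tissue_vocab)))))
  }
})

test_that("combination means equal brute-force group-by means", {
  x <- tiny_matrix(2L, 2L, values = c(0.2, 0.6, 0.4, 0.8))
  lab <- condition_labels(c("horse", "horse"), c("liver", "liver"))
  cm <- compute_combination_means(x, lab)
  expect_equal(unname(cm$values[1, ]), c(0.4, 0.6))
  expect_equal(cm$counts, 2L)

  # single-sample combination returns the sample itself
  lab2 <- condition_labels(c("horse", "cow"), c("liver", "liver"))
  cm2 <- compute_combination_means(x, lab2)
  expect_equal(nrow(cm2$values), 2L)
  i <- which(cm2$species == "cow")
  expect_equal(unname(cm2$values[i, ]), unname(x[2, ]))

  # random fixture vs naive double loop
  set.seed(7)
  x3 <- tiny_matrix(20L, 10L, seed = 8L)
  sp <- sample(c("a", "b", "c"), 20, replace = TRUE)
  ti <- sample(c("x", "y"), 20, replace = TRUE)
  lab3 <- condition_labels(sp, ti)
  cm3 <- compute_combination_means(x3, lab3)
  for (i in seq_along(cm3$species)) {
    rows <- which(sp == cm3$species[i] & ti == cm3$tissue[i])
    oracle <- colMeans(x3[rows, , drop = FALSE])
    expect_equal(unname(cm3$values[i, ]), unname(oracle), tolerance = 1e-12)
    expect_equal(cm3$counts[i], length(rows))
  }
})

test_that("observed + missing tile the full grid and eligibility needs both directions", {
  # the real compendium's geometry: 348 species x 59 tissues, 746 observed
  set.seed(11)
  sp_ids <- sprintf("sp%03d", 1:348)
  ti_ids <- sprintf("ti%02d", 1:59)
  base <- data.frame(species = sp_ids, tissue = ti_ids[(0:347 %% 59) + 1])
  all_cells <- expand.grid(species = sp_ids, tissue = ti_ids,
                           stringsAsFactors = FALSE)
  key <- paste(all_cells$species, all_cells$tissue)
  extra_pool <- all_cells[!(key %in% paste(base$species, base$tissue)), ]
  extra <- extra_pool[sample(nrow(extra_pool), 746 - 348), ]
  obs <- rbind(base, extra)
  lab <- condition_labels(obs$species, obs$tissue)
  combos <- enumerate_combinations(lab)
  expect_equal(nrow(combos$observed), 746L)
  expect_equal(nrow(combos$missing), 19786L)
  expect_equal(nrow(combos$observed) + nrow(combos$missing), 348L * 59L)

  # fully observed grid has no missing cells
  full <- condition_labels(rep(c("a", "b"), each = 2), rep(c("x", "y"), 2))
  expect_equal(nrow(enumerate_combinations(full)$missing), 0L)

  # eligibility needs >1 tissue for the species AND >1 species for the tissue
  lab3 <- condition_labels(c("a", "a", "b"), c("x", "y", "x"))
  el <- enumerate_combinations(lab3)$eligible
  expect_equal(nrow(el), 1L)
  expect_equal(el$species, "a")
  expect_equal(el$tissue, "x")
})

test_that("highest-coverage probe selection uses an inclusive threshold", {
  n_sp <- 57L
  m <- matrix(0L, 3, n_sp,
              dimnames = list(c("pIn", "pOut", "pAll"),
                              paste0("sp", seq_len(n_sp))))
  m["pIn", 1:52] <- 1L    # 52/57 = 0.912 >= 0.9
  m["pOut", 1:51] <- 1L   # 51/57 = 0.895 <  0.9
  m["pAll", ] <- 1L
  map <- mappability_table(m)
  sel <- select_highest_coverage_probes(map, 0.9)
  expect_true("pIn" %in% sel)
  expect_false("pOut" %in% sel)
  expect_identical(select_highest_coverage_probes(map, 1.0), "pAll")
  empty <- mappability_table(matrix(integer(0), 3, 0,
                                    dimnames = list(rownames(m),
                                                    character(0))))
  expect_error(select_highest_coverage_probes(empty), "no species")
})

test_that("combination mean tables round-trip through TSV with metadata", {
  cm <- combination_means(c("a", "b"), c("x", "x"),
                          tiny_matrix(2L, 3L, seed = 5L),
                          counts = c(2L, 0L), method = "species",
                          metadata = list(seed = 7))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_combination_means(cm, p)
  rt <- read_combination_means(p)
  expect_equal(rt$method, "species")
  expect_equal(rt$species, cm$species)
  expect_equal(unname(rt$values), unname(cm$values), tolerance = 1e-12)
  expect_equal(rt$counts, cm$counts)
})
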