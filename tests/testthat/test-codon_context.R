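test_that("pair_counts walks in-frame pairs inside gene boundaries", {
  g <- list(coding_sequence("a", "ATGAAAGAATAA"))
  m <- pair_counts(g)
  expect_identical(m$total_pairs, 2L)
  expect_identical(m$observed["ATG", "AAA"], 2L - 1L)
  expect_identical(m$observed["AAA", "GAA"], 1L)
  expect_identical(sum(m$observed), 2L)
  # L sense codons -> L - 1 pairs; doubling the set doubles counts
  set.seed(2)
  genes <- generate_mutation_regime(
    regime_spec(4, length_range = c(50L, 90L), regime = "mutation_only",
                seed = 2))
  m1 <- pair_counts(genes)
  lens <- vapply(genes, function(g) length(cubkit:::split_codons(
    g$sequence)) - 1L, integer(1))   # sense codons (stop dropped)
  expect_identical(m1$total_pairs, sum(lens - 1L))
  m2 <- pair_counts(c(genes, genes))
  expect_identical(m2$observed, m1$observed * 2L)
  # gene order never matters
  m3 <- pair_counts(rev(genes))
  expect_identical(m3$observed, m1$observed)
  expect_error(pair_counts(list()), "empty")
})

test_that("expected counts and adjusted residuals match the oracle", {
  set.seed(12)
  for (i in 1:20) {
    genes <- generate_mutation_regime(
      regime_spec(2, length_range = c(40L, 120L),
                  regime = "mutation_only", seed = 1000 + i))
    m <- expected_and_residuals(pair_counts(genes))
    ora <- oracle_pair_stats(m$observed)
    expect_equal(m$expected, ora$expected, tolerance = 1e-8)
    expect_equal(m$residual, ora$residual, tolerance = 1e-8)
    expect_equal(sum(m$expected), sum(m$observed), tolerance = 1e-6)
  }
})

test_that("degenerate single-pair matrix yields undefined residuals", {
  g <- list(coding_sequence("a", "ATGATGATGTAA"))  # only (ATG,ATG) pairs
  m <- expected_and_residuals(pair_counts(g))
  expect_equal(m$expected["ATG", "ATG"], m$observed["ATG", "ATG"])
  expect_true(is.na(m$residual["ATG", "ATG"]))
})

test_that("classification definitions: absent, thresholds, summaries", {
  obs <- matrix(0L, 61, 61, dimnames = list(CODE$sense_codons,
                                            CODE$sense_codons))
  obs["AAA", "AAA"] <- 50L; obs["AAA", "GGG"] <- 50L
  obs["GGG", "AAA"] <- 50L; obs["GGG", "GGG"] <- 5L
  m <- structure(list(observed = obs, expected = NULL, residual = NULL,
                      class = NULL, total_pairs = sum(obs)),
                 class = "codon_pair_matrix")
  m <- suppressWarnings(classify_pairs(m))
  expect_identical(m$class["CCC", "CCC"], "absent")
  expect_identical(m$class["GGG", "GGG"], "under")
  expect_equal(sum(m$summary), 1)
  expect_equal(unname(m$summary["absent"]), (61 * 61 - 4) / 3721)
})

test_that("an engineered x5-enriched pair is classified over", {
  spec <- regime_spec(60, length_range = c(300L, 500L),
                      regime = "mutation_only",
                      pair_bias = c("GAG-GAG" = 5), seed = 77)
  genes <- generate_pair_biased(spec)
  m <- suppressWarnings(classify_pairs(
    expected_and_residuals(pair_counts(genes))))
  expect_identical(m$class["GAG", "GAG"], "over")
  expect_gt(m$residual["GAG", "GAG"], 3)
})

test_that("null simulation keeps false over/under calls rare", {
  for (seed in 1:3) {
    genes <- generate_mutation_regime(
      regime_spec(40, length_range = c(300L, 500L),
                  regime = "mutation_only", gc_range = c(0.45, 0.55),
                  seed = 500 + seed))
    m <- suppressWarnings(classify_pairs(
      expected_and_residuals(pair_counts(genes))))
    informative <- m$expected >= 5
    flagged <- m$class %in% c("over", "under") & informative
    expect_lt(mean(flagged[informative]), 0.015)
  }
})

test_that("heatmap export codes and round-trips", {
  g <- list(coding_sequence("a", "ATGAAAGAAGAAGAATAA"))
  m <- suppressWarnings(classify_pairs(
    expected_and_residuals(pair_counts(g))))
  grid <- context_heatmap_matrix(m)
  expect_identical(dim(grid), c(61L, 61L))
  expect_setequal(unique(as.vector(grid)), c(0L, -2L))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(grid, tmp, sep = "\t", quote = FALSE)
  back <- as.matrix(utils::read.table(tmp, header = TRUE, sep = "\t",
                                      row.names = 1, check.names = FALSE))
  storage.mode(back) <- "integer"
  expect_identical(back, grid)
  expect_error(context_heatmap_matrix(pair_counts(g)), "not classified")
})

test_that("pair table writer emits RNA spelling on request", {
  g <- list(coding_sequence("a", "ATGGAACTGTAA"))
  m <- suppressWarnings(classify_pairs(
    expected_and_residuals(pair_counts(g))))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(m, tmp, rna_style = TRUE)
  tab <- utils::read.table(tmp, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expect_true(any(grepl("U", tab$codon1)))
  expect_identical(nrow(tab), 61L * 61L)
})
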