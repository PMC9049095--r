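test_that("ENc hits its analytic limits", {
  one <- codon_counts(one_codon_per_aa_cds())
  expect_equal(enc(one)$enc, 20)
  expect_equal(enc(one, estimator = "plugin")$enc, 20)
  uniform <- make_counts(stats::setNames(rep(12L, 61), CODE$sense_codons))
  expect_equal(enc(uniform)$enc, 61)
  expect_equal(enc(uniform, estimator = "plugin")$enc, 61)
})

test_that("ENc matches the brute-force family-homozygosity oracle", {
  set.seed(42)
  for (i in 1:25) {
    cc <- random_counts()
    for (est in c("corrected", "plugin"))
      expect_equal(enc(cc, estimator = est)$enc, oracle_enc(cc, est),
                   tolerance = 1e-10)
  }
})

test_that("plugin ENc is scale invariant; corrected converges to it", {
  set.seed(9)
  cc <- random_counts()
  cc100 <- make_counts(cc$counts[CODE$sense_codons] * 100L)
  expect_equal(enc(cc, estimator = "plugin")$enc,
               enc(cc100, estimator = "plugin")$enc, tolerance = 1e-12)
  gap1 <- abs(enc(cc)$enc - enc(cc, estimator = "plugin")$enc)
  gap100 <- abs(enc(cc100)$enc - enc(cc100, estimator = "plugin")$enc)
  expect_lt(gap100, gap1)
})

test_that("ENc handles missing classes and degenerate input", {
  # only a 2-fold family used: other classes imputed, value in range
  cc <- make_counts(c(AAA = 10L, AAG = 5L))
  v <- enc(cc)
  expect_identical(v$n_missing_classes, 3L)
  expect_true(v$enc >= 20 && v$enc <= 61)
  expect_equal(enc(cc, missing_class = "uniform")$family_homozygosity[["F4"]],
               0.25)
  expect_error(enc(make_counts(c(ATG = 5L))), "too short")
})

test_that("RSCU definition, family sums and classification thresholds", {
  uniform <- make_counts(stats::setNames(rep(3L, 61), CODE$sense_codons))
  tab <- rscu(uniform)
  expect_equal(tab$rscu, rep(1, 61))
  two <- rscu(make_counts(c(AAA = 4L)))
  expect_equal(two$rscu[two$codon %in% c("AAA", "AAG")], c(2, 0))
  four <- rscu(make_counts(c(GGA = 2L, GGC = 1L, GGG = 1L)))
  expect_equal(four$rscu[four$codon %in% c("GGA", "GGC", "GGG", "GGT")],
               c(2, 1, 1, 0))
  expect_identical(four$class[four$codon == "GGA"], "over")
  expect_identical(four$class[four$codon == "GGT"], "under")
  expect_true(is.na(tab$class[tab$codon == "ATG"]))
  # family sums equal family size on random genes
  set.seed(13)
  for (i in 1:10) {
    t2 <- rscu(random_counts())
    for (aa in names(CODE$families)) {
      fam <- CODE$families[[aa]]
      if (length(fam) == 1 || sum(t2$count[t2$codon %in% fam]) == 0) next
      expect_equal(sum(t2$rscu[t2$codon %in% fam]), length(fam),
                   tolerance = 1e-9)
    }
  }
})

test_that("RSCU matches the oracle and pooled RSCU is scale invariant", {
  set.seed(17)
  for (i in 1:20) {
    cc <- random_counts()
    expect_equal(rscu(cc)$rscu, unname(oracle_rscu(cc)),
                 tolerance = 1e-10)
  }
  cc <- random_counts()
  single <- pooled_rscu(list(cc))
  expect_equal(single$table$rscu, rscu(cc)$rscu)
  doubled <- pooled_rscu(list(cc, cc))
  expect_equal(doubled$table$rscu, single$table$rscu)
})

test_that("CAI weights and geometric mean behave per definition", {
  uniform <- make_counts(stats::setNames(rep(4L, 61), CODE$sense_codons))
  w <- derive_weights(uniform)
  expect_equal(unname(w[CODE$sense_codons]), rep(1, 61))
  expect_equal(cai(uniform, w), 1)
  w2 <- derive_weights(make_counts(stats::setNames(
    c(10L, 5L, rep(2L, 59)), c("AAA", "AAG", setdiff(CODE$sense_codons,
                                                     c("AAA", "AAG"))))))
  expect_equal(unname(w2[c("AAA", "AAG")]), c(1, 0.5))
  # two codons, weights 1 and 0.25, equal counts -> sqrt(0.25)
  wmix <- w
  wmix["AAG"] <- 0.25
  expect_equal(cai(make_counts(c(AAA = 7L, AAG = 7L)), wmix), 0.5)
  expect_warning(wf <- derive_weights(make_counts(
    stats::setNames(c(3L, 0L, rep(1L, 59)),
                    c("AAA", "AAG", setdiff(CODE$sense_codons,
                                            c("AAA", "AAG")))))),
    "floored")
  expect_equal(unname(wf[["AAG"]]), 0.01)
  expect_error(cai(uniform, replace(w, "GGA", -1)), "invalid")
})

test_that("CAI matches the log-domain oracle and stays in [min w, 1]", {
  set.seed(23)
  for (i in 1:20) {
    cc <- random_counts()
    w <- stats::setNames(stats::runif(61, 0.05, 1), CODE$sense_codons)
    for (a in names(CODE$families))
      w[CODE$families[[a]][1]] <- 1   # every family has a w = 1 codon
    v <- cai(cc, w)
    expect_equal(v, oracle_cai(cc, w), tolerance = 1e-10)
    expect_true(v >= min(w) - 1e-12 && v <= 1 + 1e-12)
  }
})

test_that("GRAVY and aromaticity follow their residue tables", {
  expect_equal(gravy("III"), 4.5)
  expect_equal(gravy("RRR"), -4.5)
  expect_equal(gravy("MKWIV"), mean(c(1.9, -3.9, -0.9, 4.5, 4.2)))
  p <- "MKLVWFYA"
  perm <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(gravy(perm), gravy(p))
  expect_equal(aromaticity("FYWA"), 0.75)
  expect_equal(aromaticity("AAAA"), 0)
  expect_equal(aromaticity("W"), 1)
  expect_error(gravy(""), "empty")
  expect_error(gravy("XZ"), "unknown")
})

test_that("amino_acid_usage pools counts and closes to 1", {
  u <- amino_acid_usage(list(codon_counts("ATGAAATAA")))
  expect_equal(u$frequency[u$amino_acid %in% c("M", "K")], c(0.5, 0.5))
  leu <- amino_acid_usage(list(codon_counts("CTGCTACTT")))
  expect_equal(leu$frequency[leu$amino_acid == "L"], 1)
  set.seed(3)
  pool <- lapply(1:5, function(i) random_counts())
  u2 <- amino_acid_usage(pool)
  expect_equal(sum(u2$frequency), 1)
  tot <- Reduce(`+`, lapply(pool, `[[`, "counts"))
  expect_equal(u2$count[u2$amino_acid == "L"],
               sum(tot[CODE$families$L]))
})

test_that("gene_metrics assembles the per-gene table", {
  set.seed(19)
  genes <- generate_mixed_regime(
    regime_spec(10, length_range = c(100L, 200L), regime = "mixed",
                seed = 19))
  met <- gene_metrics(genes)
  expect_identical(nrow(met$table), 10L)
  expect_true(all(met$table$cai > 0 & met$table$cai <= 1))
  expect_true(all(met$table$enc >= 20 & met$table$enc <= 61))
  expect_identical(met$table$hydropathy_class,
                   ifelse(met$table$gravy > 0, "hydrophobic",
                          "hydrophilic"))
})
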