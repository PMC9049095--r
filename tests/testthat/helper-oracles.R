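# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition with a different code path than the
# package (explicit loops, eigen instead of svd, log-domain products) so
# that agreement is evidence, not tautology.

CODE <- standard_genetic_code()

# build a codon_counts object directly from a named count vector
make_counts <- function(x, id = "t") {
  counts <- stats::setNames(integer(64), names(CODE$codon_table))
  counts[names(x)] <- as.integer(x)
  structure(list(id = id, counts = counts, stop = integer(0),
                 n_sense = sum(counts[CODE$sense_codons]),
                 n_ambiguous = 0L),
            class = "codon_counts")
}

# random codon count vector over the sense codons
random_counts <- function(n_codons = 300, lambda = 5) {
  x <- stats::rpois(61, lambda)
  names(x) <- CODE$sense_codons
  make_counts(x[x > 0])
}

# a CDS string using one fixed codon per amino acid, reps copies each
one_codon_per_aa_cds <- function(reps = 15) {
  picks <- vapply(CODE$families, `[[`, character(1), 1L)
  body <- paste(rep(picks[picks != "ATG"], reps), collapse = "")
  paste0("ATG", body, "TAA")
}

oracle_enc <- function(cc, estimator = "corrected") {
  cs <- cc$counts
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(CODE$families)) {
    fam <- CODE$families[[aa]]
    k <- length(fam)
    if (k == 1) next
    n <- sum(cs[fam])
    p2 <- sum((cs[fam] / n)^2)
    if (estimator == "corrected") {
      if (n < 2) next
      f <- (n * p2 - 1) / (n - 1)
      if (f <= 0) next
    } else {
      if (n < 1) next
      f <- p2
    }
    f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], f)
  }
  weights <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  ks <- c(2, 3, 4, 6)
  fbar <- sapply(f_by_class, function(v) if (length(v)) mean(v) else NA)
  if (any(is.na(fbar))) {
    shift <- mean(fbar[!is.na(fbar)] - 1 / ks[!is.na(fbar)])
    fbar[is.na(fbar)] <- pmin(1, pmax(1e-6, 1 / ks[is.na(fbar)] + shift))
  }
  min(61, max(20, 2 + sum(weights / fbar)))
}

oracle_rscu <- function(cc) {
  out <- stats::setNames(rep(NA_real_, 61), CODE$sense_codons)
  for (codon in CODE$sense_codons) {
    aa <- CODE$codon_table[[codon]]
    fam <- CODE$families[[aa]]
    if (length(fam) == 1) { out[codon] <- 1; next }
    tot <- sum(cc$counts[fam])
    if (tot > 0) out[codon] <- length(fam) * cc$counts[codon] / tot
  }
  out
}

oracle_cai <- function(cc, w) {
  logs <- 0; n <- 0
  for (codon in CODE$degenerate_codons) {
    k <- cc$counts[[codon]]
    if (k > 0) { logs <- logs + k * log(w[[codon]]); n <- n + k }
  }
  exp(logs / n)
}

# correspondence analysis through an eigen decomposition of S'S
oracle_coa <- function(x) {
  P <- x / sum(x)
  r <- rowSums(P); cm <- colSums(P)
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  E <- eigen(crossprod(S), symmetric = TRUE)
  sv <- sqrt(pmax(E$values, 0))
  keep <- which(sv > 1e-10)
  V <- E$vectors[, keep, drop = FALSE]
  sv <- sv[keep]
  G <- sweep(V %*% diag(sv, length(sv)), 1, sqrt(cm), "/")
  Fc <- sweep((S %*% V), 1, sqrt(r), "/")
  list(row = Fc, col = G, sv = sv,
       inertia = sv^2 / sum(eigen(crossprod(S),
                                  only.values = TRUE)$values))
}

oracle_pair_stats <- function(obs) {
  n <- sum(obs)
  rs <- rowSums(obs); cs <- colSums(obs)
  expd <- obs * 0; resid <- obs * NA_real_
  for (i in seq_len(nrow(obs))) for (j in seq_len(ncol(obs))) {
    e <- rs[i] * cs[j] / n
    expd[i, j] <- e
    d <- sqrt(e * (1 - rs[i] / n) * (1 - cs[j] / n))
    resid[i, j] <- if (e > 0 && d > 0) (obs[i, j] - e) / d else NA_real_
  }
  list(expected = expd, residual = resid)
}

# compare two coordinate matrices axis-by-axis up to sign
expect_coords_equal <- function(a, b, tol = 1e-8) {
  expect_equal(dim(a), dim(b))
  for (j in seq_len(ncol(a))) {
    d1 <- max(abs(a[, j] - b[, j]))
    d2 <- max(abs(a[, j] + b[, j]))
    expect_lt(min(d1, d2), tol)
  }
}

tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
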