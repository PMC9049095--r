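#' Effective number of codons (ENc)
#'
#' Wright's summary statistic of codon usage bias. For every synonymous
#' family the homozygosity F — the probability that two codons of that
#' amino acid drawn at random are identical — is estimated from the codon
#' fractions \eqn{p_i}: the bias-corrected form
#' \eqn{F = (n \sum p_i^2 - 1)/(n - 1)} (default) or the plugin form
#' \eqn{F = \sum p_i^2}. Class means \eqn{\bar F_k} over the 2-, 3-, 4-
#' and 6-fold families then give
#' \deqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6,}
#' capped into \[20, 61\]: 20 is extreme bias (one codon per amino acid),
#' 61 is uniform usage. Families with fewer than 2 counts (corrected) or
#' no counts (plugin), and families whose corrected F estimate is not
#' positive, are skipped; a degeneracy class with no usable family has its
#' mean imputed (see `missing_class`).
#'
#' @param counts A `codon_counts` object.
#' @param code A `genetic_code`.
#' @param estimator `"corrected"` (Wright's finite-sample form, default)
#'   or `"plugin"`.
#' @param missing_class How to impute the mean F of an entirely missing
#'   degeneracy class: `"deviation"` (default) uses `1/k` shifted by the
#'   average deviation of the observed class means from their own `1/k`;
#'   `"uniform"` uses `1/k` as-is.
#' @return An `enc_value`: list with `enc`, `family_homozygosity` (named
#'   vector `F2`, `F3`, `F4`, `F6`), `n_missing_classes`, `estimator`.
#' @examples
#' g <- coding_sequence("x", paste0("ATG", strrep("AAA", 40), "TAA"))
#' enc(codon_counts(g))$enc
#' @export
enc <- function(counts, code = standard_genetic_code(),
                estimator = c("corrected", "plugin"),
                missing_class = c("deviation", "uniform")) {
  estimator <- match.arg(estimator)
  missing_class <- match.arg(missing_class)
  stopifnot(inherits(counts, "codon_counts"))
  cs <- counts$counts
  classes <- c(2L, 3L, 4L, 6L)
  n_fam <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  fbar <- stats::setNames(rep(NA_real_, 4L), classes)
  for (k in classes) {
    fs <- c()
    for (aa in families_of_class(code, k)) {
      ni <- cs[code$families[[aa]]]
      n <- sum(ni)
      if (estimator == "corrected") {
        if (n < 2L) next
        f <- (n * sum((ni / n)^2) - 1) / (n - 1)
        if (f <= 0) next   # uninformative finite-sample estimate
      } else {
        if (n < 1L) next
        f <- sum((ni / n)^2)
      }
      fs <- c(fs, f)
    }
    if (length(fs)) fbar[[as.character(k)]] <- mean(fs)
  }
  n_missing <- sum(is.na(fbar))
  if (n_missing == 4L) stop("sequence too short for ENc: no usable family")
  if (n_missing > 0L) {
    obs <- !is.na(fbar)
    shift <- if (missing_class == "deviation")
      mean(fbar[obs] - 1 / classes[obs]) else 0
    imp <- pmin(1, pmax(1e-6, 1 / classes[!obs] + shift))
    fbar[!obs] <- imp
  }
  nc <- 2 + sum(n_fam / fbar)
  structure(list(enc = min(61, max(20, nc)),
                 family_homozygosity = stats::setNames(fbar,
                   paste0("F", classes)),
                 n_missing_classes = n_missing,
                 estimator = estimator),
            class = "enc_value")
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon i in a family of size k with counts \eqn{n_i} is
#' \eqn{k \, n_i / \sum n}: the observed count divided by the equal-usage
#' expectation. Values within a family sum to k. Codons with RSCU > 1.6
#' are classed over-represented, RSCU < 0.6 under-represented, otherwise
#' typical; Met and Trp are carried with RSCU fixed at 1 but never
#' classified, and families with zero total yield `NA` (unclassified).
#'
#' @param counts A `codon_counts` object.
#' @param code A `genetic_code`.
#' @param over,under Classification thresholds (defaults 1.6 and 0.6).
#' @return Data frame with one row per sense codon: `codon`, `amino_acid`,
#'   `family_size`, `count`, `rscu`, `class` (`over`/`under`/`typical`,
#'   `NA` for Met/Trp and empty families).
#' @export
rscu <- function(counts, code = standard_genetic_code(),
                 over = 1.6, under = 0.6) {
  stopifnot(inherits(counts, "codon_counts"))
  cs <- counts$counts
  if (sum(cs[code$sense_codons]) == 0L) stop("no sense codons counted")
  codons <- code$sense_codons
  aa <- code$codon_aa[codons]
  k <- code$degeneracy[aa]
  val <- rep(NA_real_, length(codons))
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    idx <- match(fam, codons)
    if (length(fam) == 1L) { val[idx] <- 1; next }
    tot <- sum(cs[fam])
    if (tot > 0L) val[idx] <- length(fam) * cs[fam] / tot
  }
  cls <- ifelse(k == 1L | is.na(val), NA_character_,
                ifelse(val > over, "over",
                       ifelse(val < under, "under", "typical")))
  data.frame(codon = codons, amino_acid = unname(aa),
             family_size = unname(k), count = unname(cs[codons]),
             rscu = val, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pooled RSCU over a gene set
#'
#' Codon counts are summed across genes before computing RSCU, so the
#' result is scale invariant (duplicating every gene changes nothing).
#'
#' @param count_list List of `codon_counts` (one per gene).
#' @param code A `genetic_code`.
#' @param over,under Thresholds passed to [rscu()].
#' @return List with `table` (the [rscu()] data frame of the pooled
#'   counts) and `summary`: counts of degenerate codons with RSCU > 1,
#'   over- and under-represented.
#' @export
pooled_rscu <- function(count_list, code = standard_genetic_code(),
                        over = 1.6, under = 0.6) {
  stopifnot(length(count_list) >= 1L)
  tab <- rscu(pool_codon_counts(count_list, code), code,
              over = over, under = under)
  deg <- tab$family_size > 1L & !is.na(tab$rscu)
  list(table = tab,
       summary = c(n_gt1 = sum(tab$rscu[deg] > 1),
                   n_over = sum(tab$class[deg] == "over"),
                   n_under = sum(tab$class[deg] == "under")))
}

#' Gene-by-codon RSCU matrix
#'
#' Rows are genes, columns the 59 degenerate sense codons (alphabetical).
#' `NA` values from empty families are set to 0 so the matrix is a valid
#' non-negative input for [coa()] and [rscu_distance_matrix()].
#'
#' @param count_list Named list of `codon_counts`.
#' @param code A `genetic_code`.
#' @return Numeric matrix, genes x 59 codons.
#' @export
rscu_matrix <- function(count_list, code = standard_genetic_code()) {
  stopifnot(length(count_list) >= 1L)
  rows <- lapply(count_list, function(cc) {
    tab <- rscu(cc, code)
    v <- stats::setNames(tab$rscu, tab$codon)[code$degenerate_codons]
    v[is.na(v)] <- 0
    v
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(count_list, `[[`, character(1), "id")
  m
}

#' Relative adaptiveness weights for CAI
#'
#' From a reference codon-usage table, each codon's weight is its count
#' divided by the maximum count within its synonymous family, so every
#' family has at least one codon of weight 1. Codons unused in the
#' reference receive a small floor (default 0.01) with a warning, the
#' conventional guard against log(0) in the CAI geometric mean.
#'
#' @param reference A `codon_counts` object (typically pooled over a
#'   high-expression reference gene set).
#' @param code A `genetic_code`.
#' @param floor Weight assigned to zero-count codons.
#' @return A `cai_weights`: named numeric vector over the sense codons
#'   (Met/Trp weight 1).
#' @export
derive_weights <- function(reference, code = standard_genetic_code(),
                           floor = 0.01) {
  stopifnot(inherits(reference, "codon_counts"))
  cs <- reference$counts
  w <- stats::setNames(rep(NA_real_, length(code$sense_codons)),
                       code$sense_codons)
  floored <- character(0)
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    if (length(fam) == 1L) { w[fam] <- 1; next }
    tot <- sum(cs[fam])
    if (tot == 0L) stop("reference has zero counts for family ", a)
    wi <- cs[fam] / max(cs[fam])
    zero <- wi == 0
    if (any(zero)) { wi[zero] <- floor; floored <- c(floored, fam[zero]) }
    w[fam] <- wi
  }
  if (length(floored))
    warning("zero-count reference codon(s) floored to ", floor, ": ",
            paste(floored, collapse = ", "))
  structure(w, class = "cai_weights")
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness weights over all counted
#' codons of the degenerate families (Met, Trp and stops excluded):
#' \eqn{CAI = \exp(\sum n_i \log w_i / \sum n_i)}.
#'
#' @param counts A `codon_counts` object.
#' @param weights A `cai_weights` vector from [derive_weights()] (or any
#'   named vector over the sense codons with values in (0, 1\]).
#' @param code A `genetic_code`.
#' @return CAI in \[0, 1\].
#' @export
cai <- function(counts, weights, code = standard_genetic_code()) {
  stopifnot(inherits(counts, "codon_counts"))
  deg <- code$degenerate_codons
  w <- weights[deg]
  if (anyNA(w) || any(w <= 0))
    stop("invalid CAI weights: every degenerate codon needs w in (0, 1]")
  n <- counts$counts[deg]
  if (sum(n) == 0L) stop("no degenerate-family codons counted")
  exp(sum(n * log(w)) / sum(n))
}

#' Read or write a CAI weight table
#'
#' TSV with columns `codon`, `w`.
#'
#' @param weights A `cai_weights` vector.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   `cai_weights` vector.
#' @export
write_cai_weights <- function(weights, path) {
  utils::write.table(
    data.frame(codon = names(weights), w = as.numeric(weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cai_weights
#' @export
read_cai_weights <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  structure(stats::setNames(tab$w, tab$codon), class = "cai_weights")
}

# Kyte-Doolittle hydropathy values
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over the residues
#' of a protein. Positive GRAVY marks a hydrophobic protein.
#'
#' @param protein One-letter amino-acid string.
#' @return Mean hydropathy.
#' @examples
#' gravy("III")  # 4.5
#' @export
gravy <- function(protein) {
  if (!nzchar(protein)) stop("empty protein")
  aa <- strsplit(protein, "")[[1]]
  h <- KD_HYDROPATHY[aa]
  if (anyNA(h))
    stop("unknown residue(s): ",
         paste(unique(aa[is.na(h)]), collapse = ", "))
  mean(h)
}

#' Aromaticity of a protein
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp).
#'
#' @param protein One-letter amino-acid string.
#' @return Fraction in \[0, 1\].
#' @export
aromaticity <- function(protein) {
  if (!nzchar(protein)) stop("empty protein")
  aa <- strsplit(protein, "")[[1]]
  if (any(!aa %in% names(KD_HYDROPATHY)))
    stop("unknown residue(s): ",
         paste(unique(aa[!aa %in% names(KD_HYDROPATHY)]), collapse = ", "))
  mean(aa %in% c("F", "Y", "W"))
}

#' Amino-acid usage across a gene set
#'
#' Pooled relative frequency of each of the 20 amino acids (stops
#' excluded), ranked from most to least used.
#'
#' @param count_list List of `codon_counts`.
#' @param code A `genetic_code`.
#' @return Data frame `amino_acid`, `count`, `frequency`, sorted by
#'   decreasing frequency; frequencies sum to 1.
#' @export
amino_acid_usage <- function(count_list, code = standard_genetic_code()) {
  stopifnot(length(count_list) >= 1L)
  pooled <- pool_codon_counts(count_list, code)
  by_aa <- vapply(code$families, function(fam)
    sum(pooled$counts[fam]), numeric(1))
  tot <- sum(by_aa)
  if (tot == 0) stop("no sense codons in gene set")
  out <- data.frame(amino_acid = names(by_aa), count = unname(by_aa),
                    frequency = unname(by_aa) / tot,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$frequency, out$amino_acid), , drop = FALSE]
}

#' Per-gene expression-related metrics
#'
#' ENc, CAI, GRAVY, aromaticity and the hydropathy class (hydrophobic if
#' GRAVY > 0) for every gene in a set.
#'
#' @param genes A `cds_set` of valid coding sequences.
#' @param weights `cai_weights`; if `NULL` (default) weights are derived
#'   from the pooled counts of the 10% of genes with the lowest ENc, the
#'   self-contained stand-in for an external high-expression reference.
#' @param code A `genetic_code`.
#' @param estimator ENc estimator, see [enc()].
#' @return List with `table` (data frame `gene_id`, `enc`, `cai`, `gravy`,
#'   `aromaticity`, `hydropathy_class`) and `weights` (the `cai_weights`
#'   used).
#' @export
gene_metrics <- function(genes, weights = NULL,
                         code = standard_genetic_code(),
                         estimator = c("corrected", "plugin")) {
  estimator <- match.arg(estimator)
  stopifnot(length(genes) >= 1L)
  counts <- lapply(genes, codon_counts, code = code)
  encs <- vapply(counts, function(cc)
    enc(cc, code, estimator = estimator)$enc, numeric(1))
  if (is.null(weights)) {
    n_ref <- max(1L, ceiling(0.1 * length(genes)))
    ref <- counts[order(encs)[seq_len(n_ref)]]
    weights <- suppressWarnings(
      derive_weights(pool_codon_counts(ref, code), code))
  }
  cais <- vapply(counts, cai, numeric(1), weights = weights, code = code)
  prots <- vapply(genes, translate_cds, character(1), code = code)
  gr <- vapply(prots, gravy, numeric(1))
  data.frame(
    gene_id = vapply(genes, `[[`, character(1), "id"),
    enc = unname(encs), cai = unname(cais), gravy = unname(gr),
    aromaticity = unname(vapply(prots, aromaticity, numeric(1))),
    hydropathy_class = ifelse(gr > 0, "hydrophobic", "hydrophilic"),
    stringsAsFactors = FALSE, row.names = NULL
  ) -> tab
  list(table = tab, weights = weights)
}
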