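#' Count codons in a coding sequence
#'
#' Tallies the in-frame codons of a CDS over the 64-codon alphabet. The
#' terminal stop is recorded in a separate `stop` field and excluded from
#' sense totals. Codons containing an ambiguous base (`N`) are skipped and
#' counted in `n_ambiguous` (permissive policy); under the default strict
#' QC they never reach this point.
#'
#' @param seq A `coding_sequence` or nucleotide string.
#' @param code A `genetic_code`.
#' @return A `codon_counts` object: list with `counts` (named integer
#'   vector over all 64 codons), `stop` (named count of the terminal stop,
#'   if any), `n_sense`, `n_ambiguous`, `id`.
#' @examples
#' cc <- codon_counts("ATGAAATAA")
#' cc$counts[c("ATG", "AAA")]
#' @export
codon_counts <- function(seq, code = standard_genetic_code()) {
  id <- if (inherits(seq, "coding_sequence")) seq$id else NA_character_
  s <- if (inherits(seq, "coding_sequence")) seq$sequence else
    chartr("U", "T", toupper(seq))
  codons <- split_codons(s)
  n <- length(codons)
  if (n == 0L) stop("sequence shorter than one codon")
  stop_field <- integer(0)
  if (codons[[n]] %in% code$stop_codons) {
    stop_field <- stats::setNames(1L, codons[[n]])
    codons <- codons[-n]
  }
  ambiguous <- grepl("N", codons, fixed = TRUE)
  kept <- codons[!ambiguous]
  counts <- stats::setNames(integer(64L), names(code$codon_table))
  tab <- table(factor(kept, levels = names(counts)))
  counts[] <- as.integer(tab)
  structure(list(id = id, counts = counts, stop = stop_field,
                 n_sense = sum(counts[code$sense_codons]),
                 n_ambiguous = sum(ambiguous)),
            class = "codon_counts")
}

#' Sum codon count tables across genes
#'
#' @param count_list List of `codon_counts`.
#' @param code A `genetic_code`.
#' @return A pooled `codon_counts` (stop field dropped).
#' @export
pool_codon_counts <- function(count_list, code = standard_genetic_code()) {
  stopifnot(length(count_list) >= 1L)
  counts <- Reduce(`+`, lapply(count_list, `[[`, "counts"))
  structure(list(id = "pooled", counts = counts, stop = integer(0),
                 n_sense = sum(counts[code$sense_codons]),
                 n_ambiguous = sum(vapply(count_list, `[[`, integer(1),
                                          "n_ambiguous"))),
            class = "codon_counts")
}

# base composition of a set of codons weighted by counts, by position
positional_base_counts <- function(counts, codons) {
  pos <- lapply(1:3, function(p) {
    b <- substr(codons, p, p)
    vapply(c("A", "C", "G", "T"),
           function(x) sum(counts[codons[b == x]]), numeric(1))
  })
  names(pos) <- c("p1", "p2", "p3")
  pos
}

#' Per-gene nucleotide composition profile
#'
#' Computes overall base fractions, positional GC content, synonymous
#' third-position base counts and compositional skews from a codon count
#' table. `GC1` and `GC2` are taken over all sense codons; `GC3` (reported
#' as the synonymous-position measure `GC3s`), `A3/T3/G3/C3`, `AT3` and
#' `GC3s` are taken over synonymous codons only — the 59 degenerate sense
#' codons, excluding Met, Trp and stops, matching the convention of the
#' correspondence-analysis codon universe. Skews are computed over the
#' coding strand excluding the terminal stop:
#' `at_skew = (A - T)/(A + T)`, `gc_skew = (G - C)/(G + C)`.
#'
#' @param counts A `codon_counts` object.
#' @param code A `genetic_code`.
#' @return A `composition_profile`: one-row data frame with columns
#'   `gene_id`, `len_codons`, `A`, `C`, `G`, `T`, `GC`, `GC1`, `GC2`,
#'   `GC3`, `GC12`, `A3`, `T3`, `G3`, `C3`, `AT3`, `GC3s`, `at_skew`,
#'   `gc_skew`.
#' @export
composition_profile <- function(counts, code = standard_genetic_code()) {
  stopifnot(inherits(counts, "codon_counts"))
  cs <- counts$counts[code$sense_codons]
  n_sense <- sum(cs)
  if (n_sense == 0L) stop("zero sense codons: cannot profile composition")
  pos <- positional_base_counts(counts$counts, code$sense_codons)
  base_tot <- pos$p1 + pos$p2 + pos$p3
  tot <- sum(base_tot)
  gc1 <- (pos$p1[["G"]] + pos$p1[["C"]]) / sum(pos$p1)
  gc2 <- (pos$p2[["G"]] + pos$p2[["C"]]) / sum(pos$p2)
  syn <- positional_base_counts(counts$counts, code$degenerate_codons)
  n3 <- sum(syn$p3)
  a3 <- syn$p3[["A"]]; t3 <- syn$p3[["T"]]
  g3 <- syn$p3[["G"]]; c3 <- syn$p3[["C"]]
  gc3s <- if (n3 > 0) (g3 + c3) / n3 else NA_real_
  at <- base_tot[["A"]] + base_tot[["T"]]
  gcb <- base_tot[["G"]] + base_tot[["C"]]
  data.frame(
    gene_id = counts$id,
    len_codons = n_sense,
    A = base_tot[["A"]] / tot, C = base_tot[["C"]] / tot,
    G = base_tot[["G"]] / tot, T = base_tot[["T"]] / tot,
    GC = gcb / tot,
    GC1 = gc1, GC2 = gc2, GC3 = gc3s, GC12 = (gc1 + gc2) / 2,
    A3 = a3, T3 = t3, G3 = g3, C3 = c3,
    AT3 = if (n3 > 0) (a3 + t3) / n3 else NA_real_,
    GC3s = gc3s,
    at_skew = if (at > 0) (base_tot[["A"]] - base_tot[["T"]]) / at
              else NA_real_,
    gc_skew = if (gcb > 0) (base_tot[["G"]] - base_tot[["C"]]) / gcb
              else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Composition profiles for a set of genes
#'
#' @param genes A `cds_set`.
#' @param code A `genetic_code`.
#' @return Data frame with one [composition_profile()] row per gene.
#' @export
composition_table <- function(genes, code = standard_genetic_code()) {
  stopifnot(length(genes) >= 1L)
  do.call(rbind, lapply(genes, function(g)
    composition_profile(codon_counts(g, code), code)))
}

#' Three-way positional comparisons across genes
#'
#' Fractions of genes with `G3 > A3`, `G3 = A3`, `A3 > G3`, and with
#' `GC3s > AT3`, `GC3s = AT3`, `AT3 > GC3s`; each triple sums to 1.
#'
#' @param profiles Data frame of composition profiles.
#' @return List with numeric triples `g3_vs_a3` and `gc3s_vs_at3`
#'   (components `gt`, `eq`, `lt`) and `n`.
#' @export
positional_comparisons <- function(profiles) {
  if (NROW(profiles) == 0L) stop("empty profile collection")
  three_way <- function(x, y) {
    c(gt = mean(x > y), eq = mean(x == y), lt = mean(x < y))
  }
  list(g3_vs_a3 = three_way(profiles$G3, profiles$A3),
       gc3s_vs_at3 = three_way(profiles$GC3s, profiles$AT3),
       n = NROW(profiles))
}

#' Pairwise correlation matrix over gene-level metrics
#'
#' Correlation coefficients and two-sided p-values for every pair of
#' selected numeric columns. A constant column yields `NA` entries with a
#' warning rather than an error.
#'
#' @param metrics Data frame with one row per gene.
#' @param columns Character vector of column names (default: all numeric
#'   columns except `len_codons`-style identifiers).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with matrices `r` and `p` (symmetric, unit/zero diagonal),
#'   `n`, and `method`.
#' @export
correlation_matrix <- function(metrics, columns = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(columns)) {
    columns <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(columns, names(metrics))
  if (length(missing_cols))
    stop("unknown columns: ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(metrics[columns])
  if (nrow(x) < 3L) stop("need at least 3 genes for correlations")
  constant <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE)) == 0 |
    is.na(apply(x, 2, function(v) stats::sd(v, na.rm = TRUE)))
  if (any(constant))
    warning("constant column(s), correlations undefined: ",
            paste(columns[constant], collapse = ", "))
  k <- length(columns)
  r <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  p <- r
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    if (constant[i] || constant[j]) next
    ct <- suppressWarnings(
      stats::cor.test(x[, i], x[, j], method = method, exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(x), method = method)
}

#' Write a composition table to TSV
#'
#' Columns: `gene_id, len_codons, A, C, G, T, GC, GC1, GC2, GC3, GC12,
#' A3, T3, G3, C3, AT3, GC3s, at_skew, gc_skew`.
#'
#' @param profiles Data frame from [composition_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(profiles, path) {
  cols <- c("gene_id", "len_codons", "A", "C", "G", "T", "GC", "GC1",
            "GC2", "GC3", "GC12", "A3", "T3", "G3", "C3", "AT3", "GC3s",
            "at_skew", "gc_skew")
  utils::write.table(profiles[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
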