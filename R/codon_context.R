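#' Count adjacent in-frame codon pairs across a gene set
#'
#' For every gene, each pair of consecutive in-frame sense codons
#' (positions i, i+1) is counted into a pooled 61 x 61 matrix (first codon
#' of the pair x second). Pairs involving the terminal stop are excluded
#' and pairs never cross gene boundaries; a gene of L sense codons
#' contributes exactly L - 1 pairs. Codons containing `N` break the chain:
#' neither the pair ending at nor starting from them is counted.
#'
#' @param genes A `cds_set` of valid coding sequences.
#' @param code A `genetic_code`.
#' @return A `codon_pair_matrix`: list with `observed` (61 x 61 integer
#'   matrix, codons in alphabetical order), `total_pairs`, and `NULL`
#'   placeholders for `expected`, `residual`, `class`.
#' @export
pair_counts <- function(genes, code = standard_genetic_code()) {
  if (length(genes) == 0L) stop("empty gene set")
  sense <- code$sense_codons
  obs <- matrix(0L, 61L, 61L, dimnames = list(sense, sense))
  total <- 0L
  for (g in genes) {
    s <- if (inherits(g, "coding_sequence")) g$sequence else g
    codons <- split_codons(s)
    n <- length(codons)
    if (n > 0L && codons[[n]] %in% code$stop_codons)
      codons <- codons[-n]
    if (length(codons) < 2L) next
    first <- codons[-length(codons)]
    second <- codons[-1L]
    ok <- first %in% sense & second %in% sense
    if (!any(ok)) next
    tab <- table(factor(first[ok], levels = sense),
                 factor(second[ok], levels = sense))
    obs <- obs + matrix(as.integer(tab), 61L, 61L)
    total <- total + sum(ok)
  }
  structure(list(observed = obs, expected = NULL, residual = NULL,
                 class = NULL, total_pairs = total),
            class = "codon_pair_matrix")
}

#' Independence expectations and adjusted residuals for codon pairs
#'
#' Under the chi-square test of independence the expected count of pair
#' (i, j) is `rowsum_i * colsum_j / total`, and the adjusted standardized
#' residual is
#' `(obs - exp) / sqrt(exp * (1 - rowsum_i/total) * (1 - colsum_j/total))`,
#' which is approximately standard normal cell-wise under independence.
#' Cells with a zero expectation (empty margin) carry `NA` residuals.
#'
#' @param m A `codon_pair_matrix` with observed counts.
#' @return The matrix with `expected` and `residual` filled.
#' @export
expected_and_residuals <- function(m) {
  stopifnot(inherits(m, "codon_pair_matrix"))
  if (m$total_pairs == 0L) stop("no codon pairs counted")
  obs <- m$observed
  n <- m$total_pairs
  rs <- rowSums(obs)
  cs <- colSums(obs)
  expd <- outer(rs, cs) / n
  denom <- sqrt(expd * outer(1 - rs / n, 1 - cs / n))
  resid <- (obs - expd) / denom
  resid[expd == 0 | denom == 0] <- NA_real_
  m$expected <- expd
  m$residual <- resid
  m
}

#' Classify codon pairs as over-, under-represented, absent or typical
#'
#' A pair is `absent` iff it is never observed; `over` (`under`) requires
#' a defined adjusted residual at least `threshold` above (below) zero,
#' a positive observed count, and an expectation of at least `min_expected`
#' — below that the normal approximation to the residual is unreliable,
#' so such cells stay `typical` (or `absent`).
#'
#' @param m A `codon_pair_matrix` with residuals (see
#'   [expected_and_residuals()]; computed on the fly if missing).
#' @param threshold Residual magnitude for over/under calls (default 3).
#' @param min_expected Minimum expectation for an over/under call
#'   (default 1); excluded cells are tallied in a warning.
#' @return The matrix with `class` filled (61 x 61 character) plus a
#'   `summary` element: named fractions `over`, `under`, `absent`,
#'   `typical` over the 3721 sense pairs.
#' @export
classify_pairs <- function(m, threshold = 3, min_expected = 1) {
  stopifnot(inherits(m, "codon_pair_matrix"))
  if (is.null(m$residual)) m <- expected_and_residuals(m)
  obs <- m$observed
  cls <- matrix("typical", nrow(obs), ncol(obs), dimnames = dimnames(obs))
  eligible <- !is.na(m$residual) & m$expected >= min_expected & obs > 0
  cls[eligible & m$residual >= threshold] <- "over"
  cls[eligible & m$residual <= -threshold] <- "under"
  cls[obs == 0L] <- "absent"
  n_small <- sum(m$expected < min_expected & obs > 0, na.rm = TRUE)
  if (n_small > 0L)
    warning(n_small, " observed pair(s) with expected < ", min_expected,
            " excluded from over/under classification")
  m$class <- cls
  m$summary <- c(over = mean(cls == "over"),
                 under = mean(cls == "under"),
                 absent = mean(cls == "absent"),
                 typical = mean(cls == "typical"))
  m
}

#' Dense class-code grid for heat-map plotting
#'
#' Integer codes over the alphabetically ordered 61 x 61 codon grid:
#' over = +1, typical = 0, under = -1, absent = -2.
#'
#' @param m A classified `codon_pair_matrix`.
#' @return 61 x 61 integer matrix.
#' @export
context_heatmap_matrix <- function(m) {
  stopifnot(inherits(m, "codon_pair_matrix"))
  if (is.null(m$class)) stop("matrix not classified; run classify_pairs()")
  codes <- c(over = 1L, typical = 0L, under = -1L, absent = -2L)
  grid <- matrix(codes[m$class], nrow(m$class), ncol(m$class),
                 dimnames = dimnames(m$class))
  storage.mode(grid) <- "integer"
  grid
}

#' Write the codon-pair table to TSV
#'
#' One row per sense-codon pair: `codon1`, `codon2`, `observed`,
#' `expected`, `residual`, `class`. With `rna_style = TRUE` codons are
#' spelled with `U` for display.
#'
#' @param m A classified `codon_pair_matrix`.
#' @param path Output path.
#' @param rna_style Spell codons with U (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(m, path, rna_style = FALSE) {
  stopifnot(inherits(m, "codon_pair_matrix"), !is.null(m$class))
  sense <- rownames(m$observed)
  disp <- if (rna_style) chartr("T", "U", sense) else sense
  tab <- data.frame(
    codon1 = rep(disp, times = length(sense)),
    codon2 = rep(disp, each = length(sense)),
    observed = as.vector(m$observed),
    expected = as.vector(m$expected),
    residual = as.vector(m$residual),
    class = as.vector(m$class),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
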