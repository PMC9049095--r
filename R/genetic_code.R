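#' Genetic-code tables for codon usage analysis
#'
#' A `genetic_code` object bundles everything the codon usage statistics
#' need: the codon-to-amino-acid map, the stop-codon set, the synonymous
#' families and their degeneracy classes (2-, 3-, 4- and 6-fold), and the
#' 59-codon "degenerate" universe used for RSCU, GC3s and correspondence
#' analysis (sense codons excluding the single-codon families Met and Trp).
#'
#' @param id Genetic code identifier passed to
#'   [Biostrings::getGeneticCode()]; `"1"` (default) is the standard code.
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_table` (named character vector, 64 codons to one-letter amino
#'   acids, `"*"` for stop), `stop_codons`, `sense_codons` (61, sorted),
#'   `degenerate_codons` (59, sorted), `families` (list of codon vectors
#'   keyed by amino acid), `degeneracy` (named integer vector per amino
#'   acid), and `codon_aa` (amino acid per sense codon).
#' @examples
#' gc <- standard_genetic_code()
#' length(gc$sense_codons)      # 61
#' gc$degeneracy[["L"]]         # 6
#' @export
standard_genetic_code <- function(id = "1") {
  tab <- Biostrings::getGeneticCode(id)
  codons <- sort(names(tab))
  tab <- tab[codons]
  stops <- codons[tab == "*"]
  sense <- codons[tab != "*"]
  fams <- split(sense, tab[sense])
  deg <- vapply(fams, length, integer(1))
  structure(list(
    id = id,
    codon_table = tab,
    stop_codons = stops,
    sense_codons = sense,
    degenerate_codons = sense[deg[tab[sense]] > 1L],
    families = fams,
    degeneracy = deg,
    codon_aa = tab[sense]
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cls <- table(x$degeneracy[x$degeneracy > 1L])
  cat(sprintf(
    "<genetic_code %s>: %d sense codons, %d stops; degeneracy classes: %s\n",
    x$id, length(x$sense_codons), length(x$stop_codons),
    paste(sprintf("%s-fold x%d", names(cls), as.integer(cls)), collapse = ", ")
  ))
  invisible(x)
}

# Amino acids of the degenerate families in a given degeneracy class.
families_of_class <- function(code, k) {
  names(code$degeneracy)[code$degeneracy == k]
}
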