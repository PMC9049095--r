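#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped), uppercases each
#' sequence and maps RNA-style `U` to `T`. Any residual character outside
#' `{A,C,G,T}` is normalised to `N` so downstream quality control can flag
#' it as an ambiguous base. Record identifiers are the first
#' whitespace-delimited token of each header; input order is preserved.
#' No validity checks are applied here — see [validate_cds()].
#'
#' @param path Path to a FASTA file.
#' @return A `cds_set`: a named list of `coding_sequence` objects, each a
#'   list with `id`, `sequence` and (initially `NULL`) `qc`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(raw) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids)))
    stop("malformed header at record index ",
         paste(which(!nzchar(ids)), collapse = ", "))
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_dup")
  seqs <- chartr("U", "T", toupper(as.character(raw)))
  seqs <- gsub("[^ACGT]", "N", seqs)
  out <- lapply(seq_along(ids), function(i) {
    structure(list(id = ids[[i]], sequence = unname(seqs[[i]]), qc = NULL),
              class = "coding_sequence")
  })
  names(out) <- ids
  structure(out, class = c("cds_set", "list"))
}

#' Construct a coding sequence in code
#'
#' Convenience constructor used by the synthetic generator and in tests.
#'
#' @param id Identifier string.
#' @param sequence Nucleotide string; uppercased, `U` mapped to `T`.
#' @return A `coding_sequence`.
#' @export
coding_sequence <- function(id, sequence) {
  sequence <- chartr("U", "T", toupper(sequence))
  structure(list(id = id, sequence = sequence, qc = NULL),
            class = "coding_sequence")
}

split_codons <- function(sequence) {
  n <- nchar(sequence) %/% 3L
  if (n == 0L) return(character(0))
  substring(sequence, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Validate a coding sequence
#'
#' Applies the standard CDS gate: the sequence must be a perfect multiple
#' of 3 bases, begin with an initiation codon, end with a termination
#' codon, contain no internal stop and no ambiguous base, and carry at
#' least `min_codons` sense codons. All applicable failure codes are
#' reported, not just the first.
#'
#' @param seq A `coding_sequence` (or plain nucleotide string).
#' @param code A `genetic_code`, default the standard code.
#' @param min_codons Minimum sense-codon count (default 30).
#' @param start_codons Admissible initiation codons; `"ATG"` only by
#'   default, extend to e.g. `c("ATG","CTG","GTG")` for alternative starts.
#' @return A `qc_report`: list with `valid` (logical) and `failures`
#'   (character vector drawn from `NOT_MULTIPLE_OF_3`, `NO_START`,
#'   `NO_STOP`, `INTERNAL_STOP`, `AMBIGUOUS_BASE`, `TOO_SHORT`).
#' @examples
#' validate_cds("ATGAAATAA", min_codons = 1)$valid   # TRUE
#' validate_cds("ATGAATA")$failures
#' @export
validate_cds <- function(seq, code = standard_genetic_code(),
                         min_codons = 30L, start_codons = "ATG") {
  s <- if (inherits(seq, "coding_sequence")) seq$sequence else
    chartr("U", "T", toupper(seq))
  if (!nzchar(s)) stop("empty sequence")
  failures <- character(0)
  if (nchar(s) %% 3L != 0L) failures <- c(failures, "NOT_MULTIPLE_OF_3")
  codons <- split_codons(s)
  n <- length(codons)
  if (n == 0L || !(codons[[1L]] %in% start_codons))
    failures <- c(failures, "NO_START")
  has_stop <- n > 0L && codons[[n]] %in% code$stop_codons &&
    nchar(s) %% 3L == 0L
  if (!has_stop) failures <- c(failures, "NO_STOP")
  internal <- if (n > 1L) codons[seq_len(n - 1L)] else character(0)
  if (any(internal %in% code$stop_codons))
    failures <- c(failures, "INTERNAL_STOP")
  if (grepl("[^ACGT]", s)) failures <- c(failures, "AMBIGUOUS_BASE")
  n_sense <- n - as.integer(has_stop)
  if (n_sense < min_codons) failures <- c(failures, "TOO_SHORT")
  structure(list(valid = length(failures) == 0L, failures = failures),
            class = "qc_report")
}

#' Quality-control a set of coding sequences
#'
#' Runs [validate_cds()] on every record and attaches the report. Under
#' the default strict policy, failing records are excluded from the
#' returned set (they remain in the QC table); with `keep_invalid = TRUE`
#' they are kept, with a warning.
#'
#' @param genes A `cds_set` from [read_fasta()], or list of
#'   `coding_sequence`.
#' @param code A `genetic_code`.
#' @param min_codons,start_codons Passed to [validate_cds()].
#' @param keep_invalid Keep records that fail QC (default `FALSE`).
#' @return A list with `genes` (the retained `cds_set`, QC attached) and
#'   `qc_table` (data.frame: `gene_id`, `valid`, `failures`
#'   semicolon-joined).
#' @export
qc_cds_set <- function(genes, code = standard_genetic_code(),
                       min_codons = 30L, start_codons = "ATG",
                       keep_invalid = FALSE) {
  reports <- lapply(genes, validate_cds, code = code,
                    min_codons = min_codons, start_codons = start_codons)
  for (i in seq_along(genes)) genes[[i]]$qc <- reports[[i]]
  ok <- vapply(reports, `[[`, logical(1), "valid")
  qc_table <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "id"),
    valid = ok,
    failures = vapply(reports, function(r)
      paste(r$failures, collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  kept <- genes
  if (!keep_invalid) {
    kept <- genes[ok]
  } else if (any(!ok)) {
    warning(sum(!ok), " sequence(s) failed QC but were kept (override)")
  }
  list(genes = structure(kept, class = c("cds_set", "list")),
       qc_table = qc_table)
}

#' Translate a coding sequence
#'
#' Translates a valid CDS to its one-letter amino-acid string, dropping
#' the terminal stop. An internal stop is an error naming the codon index.
#'
#' @param seq A `coding_sequence` or nucleotide string.
#' @param code A `genetic_code`.
#' @return Amino-acid string of length equal to the sense-codon count.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(seq, code = standard_genetic_code()) {
  s <- if (inherits(seq, "coding_sequence")) seq$sequence else
    chartr("U", "T", toupper(seq))
  codons <- split_codons(s)
  n <- length(codons)
  if (n == 0L) stop("sequence shorter than one codon")
  if (codons[[n]] %in% code$stop_codons) codons <- codons[-n]
  aa <- unname(code$codon_table[codons])
  if (anyNA(aa))
    stop("untranslatable codon at position ", which(is.na(aa))[1L])
  if (any(aa == "*"))
    stop("internal stop codon at codon index ", which(aa == "*")[1L])
  paste(aa, collapse = "")
}

#' Write a QC table to TSV
#'
#' @param qc_table Data frame from [qc_cds_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_table <- function(qc_table, path) {
  utils::write.table(qc_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
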