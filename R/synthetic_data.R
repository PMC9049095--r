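# Approximate vertebrate protein amino-acid composition, used as the
# fixed target of the selection regime (positions 1+2 then barely move).
AA_FREQS_DEFAULT <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, Q = 0.047,
  E = 0.071, G = 0.066, H = 0.026, I = 0.043, L = 0.099, K = 0.057,
  M = 0.022, F = 0.037, P = 0.063, S = 0.083, T = 0.053, W = 0.012,
  Y = 0.027, V = 0.060)

#' Specify a synthetic coding-sequence regime
#'
#' Describes a set of genes to simulate. Three regimes are available:
#' `mutation_only` draws every codon position of a gene from one shared
#' GC-parameterised nucleotide pool, so GC12 and GC3 share a single driver
#' (the neutrality-plot null of pure directional mutation pressure);
#' `selection` fixes the amino-acid composition (so GC12 is nearly
#' constant) while the synonymous third-position GC of each gene is drawn
#' from `gc3_range` (GC12 decoupled from GC3); `mixed` draws GC3 per gene
#' and couples positions 1+2 to it only partially, emulating real gene
#' sets where both forces act.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_range Sense-codon length range, inclusive (default
#'   300-3000).
#' @param regime `"mutation_only"`, `"selection"` or `"mixed"`.
#' @param gc_range GC range for the mutation regime (default 0.3-0.7).
#' @param gc3_range Third-position GC range for the selection and mixed
#'   regimes (default 0.3-0.9).
#' @param gc12_center Mean GC at positions 1+2 in the mixed regime
#'   (default 0.48, which together with the default `gc3_range` gives an
#'   overall GC near 0.52).
#' @param coupling Mixed-regime slope of GC12 on GC3 (default 0.4).
#' @param bias_concentration Dirichlet concentration of per-gene,
#'   per-family codon-weight noise; lower means more within-family skew,
#'   `Inf` (default) disables the noise.
#' @param pair_bias Optional named numeric vector of codon-pair enrichment
#'   multipliers, names like `"GAG-GAG"`, for [generate_pair_biased()].
#' @param aa_freqs Amino-acid frequencies for the selection regime.
#' @param seed Integer seed; all draws are deterministic functions of
#'   `(seed, gene index)`.
#' @return A `regime_spec` list.
#' @export
regime_spec <- function(n_genes, length_range = c(300L, 3000L),
                        regime = c("mutation_only", "selection", "mixed"),
                        gc_range = c(0.3, 0.7), gc3_range = c(0.3, 0.9),
                        gc12_center = 0.48, coupling = 0.4,
                        bias_concentration = Inf, pair_bias = NULL,
                        aa_freqs = AA_FREQS_DEFAULT, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_genes >= 1L, length_range[1] >= 2L,
            all(gc_range > 0 & gc_range < 1),
            all(gc3_range > 0 & gc3_range < 1),
            bias_concentration > 0,
            is.null(pair_bias) || all(pair_bias > 0))
  structure(list(n_genes = as.integer(n_genes),
                 length_range = as.integer(length_range), regime = regime,
                 gc_range = gc_range, gc3_range = gc3_range,
                 gc12_center = gc12_center, coupling = coupling,
                 bias_concentration = bias_concentration,
                 pair_bias = pair_bias,
                 aa_freqs = aa_freqs / sum(aa_freqs),
                 seed = as.integer(seed)),
            class = "regime_spec")
}

#' The default emulation preset
#'
#' 82 GC-rich genes (overall GC near 0.52), sense-codon lengths 300-3000,
#' mixed mutation/selection regime with per-gene GC3 spanning 0.3-0.9.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 82).
#' @return A `regime_spec`.
#' @export
ec_like_spec <- function(seed = 1L, n_genes = 82L) {
  regime_spec(n_genes = n_genes, length_range = c(300L, 3000L),
              regime = "mixed", gc3_range = c(0.3, 0.9), seed = seed)
}

gene_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% 2147483629)
}

sample_len <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

# Stop-codon rejection conditions the positional model on "not a stop";
# these closed forms give the composition the generator actually targets,
# recorded as ground truth so recovery checks compare like with like.
p_stop_pool <- function(p1, p2, p3) {
  p1[["T"]] * (p2[["A"]] * (p3[["A"]] + p3[["G"]]) + p2[["G"]] * p3[["A"]])
}

conditional_gc <- function(p1, p2, p3) {
  gc_unc <- (p1[["G"]] + p1[["C"]] + p2[["G"]] + p2[["C"]] +
               p3[["G"]] + p3[["C"]]) / 3
  gc_stop <- p1[["T"]] * (p2[["A"]] * p3[["G"]] + p2[["G"]] * p3[["A"]]) / 3
  (gc_unc - gc_stop) / (1 - p_stop_pool(p1, p2, p3))
}

conditional_gc3 <- function(p1, p2, p3) {
  (p3[["G"]] + p3[["C"]] - p1[["T"]] * p2[["A"]] * p3[["G"]]) /
    (1 - p_stop_pool(p1, p2, p3))
}

base_pool <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                            G = gc / 2, T = (1 - gc) / 2)

# sample n codons with per-position base probabilities, rejecting stops
sample_codons <- function(n, p1, p2, p3, stops) {
  draw <- function(m) paste0(
    sample(names(p1), m, replace = TRUE, prob = p1),
    sample(names(p2), m, replace = TRUE, prob = p2),
    sample(names(p3), m, replace = TRUE, prob = p3))
  codons <- draw(n)
  bad <- which(codons %in% stops)
  while (length(bad)) {
    codons[bad] <- draw(length(bad))
    bad <- bad[codons[bad] %in% stops]
  }
  codons
}

finish_gene <- function(id, codons, stops) {
  stop_codon <- sample(stops, 1L)
  coding_sequence(id, paste0("ATG", paste(codons, collapse = ""),
                             stop_codon))
}

# per-gene, per-family Dirichlet weight noise (identity when alpha = Inf)
family_weights <- function(u, alpha) {
  if (!is.finite(alpha)) return(u)
  g <- stats::rgamma(length(u), shape = alpha * u * length(u))
  if (sum(g) == 0) return(u)
  g / sum(g)
}

#' Generate genes under the mutation-only regime
#'
#' Every codon position of a gene is drawn i.i.d. from one nucleotide pool
#' whose GC level is drawn per gene from `gc_range`; codons that would be
#' stops are rejected and redrawn, then the ATG start and a stop codon are
#' attached. Because all three positions share one driver, regressing GC12
#' on GC3 across such genes recovers a slope near 1.
#'
#' @param spec A `regime_spec` with `regime = "mutation_only"`.
#' @param code A `genetic_code`.
#' @return A `cds_set` with a `truth` attribute: data frame `gene_id`,
#'   `regime`, `gc_target`, `gc3_target`, `length_codons`.
#' @export
generate_mutation_regime <- function(spec, code = standard_genetic_code()) {
  stopifnot(inherits(spec, "regime_spec"), spec$regime == "mutation_only")
  genes <- vector("list", spec$n_genes)
  truth <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    set.seed(gene_seed(spec$seed, i))
    gc <- stats::runif(1, spec$gc_range[1], spec$gc_range[2])
    len <- sample_len(spec$length_range)
    p <- base_pool(gc)
    codons <- sample_codons(len - 1L, p, p, p, code$stop_codons)
    id <- sprintf("mut_%03d", i)
    genes[[i]] <- finish_gene(id, codons, code$stop_codons)
    truth[[i]] <- data.frame(gene_id = id, regime = "mutation_only",
                             gc_drawn = gc,
                             gc_target = conditional_gc(p, p, p),
                             gc3_target = conditional_gc3(p, p, p),
                             length_codons = len,
                             stringsAsFactors = FALSE)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "id")
  structure(genes, class = c("cds_set", "list"),
            truth = do.call(rbind, truth))
}

#' Generate genes under the selection regime
#'
#' The amino-acid sequence is drawn from a fixed composition, pinning GC12
#' to a narrow band, while each gene's synonymous third-position GC target
#' is drawn from `gc3_range` and synonymous codons are chosen with
#' third-base probabilities tilted to that target (plus optional Dirichlet
#' within-family noise controlled by `bias_concentration`). GC3 thus
#' varies freely while GC12 barely moves: the neutrality slope is near 0.
#'
#' @inheritParams generate_mutation_regime
#' @export
generate_selection_regime <- function(spec,
                                      code = standard_genetic_code()) {
  stopifnot(inherits(spec, "regime_spec"), spec$regime == "selection")
  fams <- code$families
  third <- lapply(fams, function(f) substr(f, 3, 3))
  genes <- vector("list", spec$n_genes)
  truth <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    set.seed(gene_seed(spec$seed, i))
    gc3 <- stats::runif(1, spec$gc3_range[1], spec$gc3_range[2])
    len <- sample_len(spec$length_range)
    p3 <- base_pool(gc3)
    probs <- lapply(names(fams), function(a) {
      u <- p3[third[[a]]]
      u <- u / sum(u)
      family_weights(u, spec$bias_concentration)
    })
    names(probs) <- names(fams)
    aa <- sample(names(spec$aa_freqs), len - 1L, replace = TRUE,
                 prob = spec$aa_freqs)
    codons <- character(len - 1L)
    for (a in unique(aa)) {
      at <- aa == a
      f <- fams[[a]]
      codons[at] <- if (length(f) == 1L) f else
        sample(f, sum(at), replace = TRUE, prob = probs[[a]])
    }
    id <- sprintf("sel_%03d", i)
    genes[[i]] <- finish_gene(id, codons, code$stop_codons)
    truth[[i]] <- data.frame(gene_id = id, regime = "selection",
                             gc_drawn = NA_real_, gc_target = NA_real_,
                             gc3_target = gc3, length_codons = len,
                             stringsAsFactors = FALSE)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "id")
  structure(genes, class = c("cds_set", "list"),
            truth = do.call(rbind, truth))
}

#' Generate genes under the mixed regime
#'
#' Per gene, GC3 is drawn from `gc3_range` and the GC of positions 1+2 is
#' coupled to it only partially:
#' `gc12 = gc12_center + coupling * (gc3 - mean(gc3_range))`. Codons are
#' then drawn positionally as in the mutation regime but with distinct
#' pools for positions 1+2 and position 3.
#'
#' @inheritParams generate_mutation_regime
#' @export
generate_mixed_regime <- function(spec, code = standard_genetic_code()) {
  stopifnot(inherits(spec, "regime_spec"), spec$regime == "mixed")
  gc3_center <- mean(spec$gc3_range)
  genes <- vector("list", spec$n_genes)
  truth <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    set.seed(gene_seed(spec$seed, i))
    gc3 <- stats::runif(1, spec$gc3_range[1], spec$gc3_range[2])
    gc12 <- min(0.95, max(0.05,
      spec$gc12_center + spec$coupling * (gc3 - gc3_center)))
    len <- sample_len(spec$length_range)
    p12 <- base_pool(gc12)
    p3 <- base_pool(gc3)
    codons <- sample_codons(len - 1L, p12, p12, p3, code$stop_codons)
    id <- sprintf("mix_%03d", i)
    genes[[i]] <- finish_gene(id, codons, code$stop_codons)
    truth[[i]] <- data.frame(gene_id = id, regime = "mixed",
                             gc_drawn = (2 * gc12 + gc3) / 3,
                             gc_target = conditional_gc(p12, p12, p3),
                             gc3_target = conditional_gc3(p12, p12, p3),
                             length_codons = len,
                             stringsAsFactors = FALSE)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "id")
  structure(genes, class = c("cds_set", "list"),
            truth = do.call(rbind, truth))
}

#' Generate genes with engineered codon-pair context bias
#'
#' Sequences follow a first-order codon chain: the stationary codon
#' distribution comes from a GC-0.5 positional pool over the 61 sense
#' codons, and the transition weight from codon i to codon j multiplies
#' that base distribution by the configured enrichment for listed pairs.
#' Ground-truth enriched pairs are recorded so classification power can be
#' checked against construction.
#'
#' @param spec A `regime_spec` with non-empty `pair_bias` (named numeric
#'   vector, names `"XXX-YYY"` over sense codons, values > 0).
#' @param code A `genetic_code`.
#' @return A `cds_set` with `truth` and `pair_bias` attributes.
#' @export
generate_pair_biased <- function(spec, code = standard_genetic_code()) {
  stopifnot(inherits(spec, "regime_spec"), length(spec$pair_bias) >= 1L)
  sense <- code$sense_codons
  p <- base_pool(0.5)
  q <- vapply(sense, function(cd)
    p[substr(cd, 1, 1)] * p[substr(cd, 2, 2)] * p[substr(cd, 3, 3)],
    numeric(1))
  q <- q / sum(q)
  trans <- matrix(q, length(sense), length(sense), byrow = TRUE,
                  dimnames = list(sense, sense))   # trans[i, j] = q[j]
  for (nm in names(spec$pair_bias)) {
    ij <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(ij) != 2L || !all(ij %in% sense))
      stop("pair_bias name not a sense-codon pair: ", nm)
    trans[ij[1], ij[2]] <- trans[ij[1], ij[2]] * spec$pair_bias[[nm]]
  }
  trans <- trans / rowSums(trans)
  cum <- t(apply(trans, 1, cumsum))
  start_idx <- match("ATG", sense)
  genes <- vector("list", spec$n_genes)
  truth <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    set.seed(gene_seed(spec$seed, i))
    len <- sample_len(spec$length_range)
    idx <- integer(len)
    idx[1L] <- start_idx
    u <- stats::runif(len - 1L)
    for (t in 2:len)
      idx[t] <- findInterval(u[t - 1L], cum[idx[t - 1L], ]) + 1L
    id <- sprintf("pair_%03d", i)
    genes[[i]] <- coding_sequence(id, paste0(
      paste(sense[idx], collapse = ""), sample(code$stop_codons, 1L)))
    truth[[i]] <- data.frame(gene_id = id, regime = "pair_biased",
                             gc_drawn = NA_real_, gc_target = NA_real_,
                             gc3_target = NA_real_, length_codons = len,
                             stringsAsFactors = FALSE)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "id")
  structure(genes, class = c("cds_set", "list"),
            truth = do.call(rbind, truth), pair_bias = spec$pair_bias)
}

#' Generate a synthetic gene set for any regime
#'
#' Dispatches on `spec$regime` (or to [generate_pair_biased()] when
#' `pair_bias` is set).
#'
#' @inheritParams generate_mutation_regime
#' @export
generate_cds_set <- function(spec, code = standard_genetic_code()) {
  stopifnot(inherits(spec, "regime_spec"))
  if (!is.null(spec$pair_bias)) return(generate_pair_biased(spec, code))
  switch(spec$regime,
         mutation_only = generate_mutation_regime(spec, code),
         selection = generate_selection_regime(spec, code),
         mixed = generate_mixed_regime(spec, code))
}

#' Write a gene set as multi-FASTA (plus optional ground-truth TSV)
#'
#' @param genes A `cds_set`.
#' @param path Output FASTA path.
#' @param truth_path Optional path for the generator's ground-truth table.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genes, path, truth_path = NULL, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genes) {
    writeLines(paste0(">", g$id), con)
    s <- g$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  truth <- attr(genes, "truth")
  if (!is.null(truth_path) && !is.null(truth))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
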