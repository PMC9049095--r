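#' Configure a full analysis run
#'
#' @param input Path(s) to input FASTA file(s).
#' @param outdir Output directory (created if absent).
#' @param qc_policy `"strict"` (default; genes failing QC are excluded) or
#'   `"permissive"` (kept with a warning).
#' @param min_codons,start_codons QC parameters, see [validate_cds()].
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param enc_estimator `"corrected"` or `"plugin"`.
#' @param cai_weights Optional path to a CAI weight TSV; `NULL` derives
#'   weights from the input's lowest-ENc decile.
#' @param pr2_convention Third-position universe for the PR2 plot,
#'   `"synonymous"` (default) or `"fourfold"`; see
#'   [third_position_counts()].
#' @param coa_axes Number of ordination axes to write (default 4).
#' @param pair_threshold Residual threshold for pair classification.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed governs any upstream simulation).
#' @return A `run_config` list.
#' @export
run_config <- function(input, outdir,
                       qc_policy = c("strict", "permissive"),
                       min_codons = 30L, start_codons = "ATG",
                       correlation_method = c("pearson", "spearman"),
                       enc_estimator = c("corrected", "plugin"),
                       cai_weights = NULL,
                       pr2_convention = c("synonymous", "fourfold"),
                       coa_axes = 4L, pair_threshold = 3, seed = 1L) {
  structure(list(input = input, outdir = outdir,
                 qc_policy = match.arg(qc_policy),
                 min_codons = as.integer(min_codons),
                 start_codons = start_codons,
                 correlation_method = match.arg(correlation_method),
                 enc_estimator = match.arg(enc_estimator),
                 cai_weights = cai_weights,
                 pr2_convention = match.arg(pr2_convention),
                 coa_axes = as.integer(coa_axes),
                 pair_threshold = pair_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the complete codon usage bias analysis
#'
#' Executes every stage in order — QC, composition, per-gene metrics,
#' pooled RSCU, correlation matrix, neutrality fit, PR2, correspondence
#' analysis, neighbor-joining tree, codon-pair context — writing one TSV
#' (or newick) per stage into `config$outdir` plus a JSON run manifest
#' with input digests and per-stage row counts. Raw correlation p-values
#' are reported alongside Benjamini-Hochberg adjusted ones.
#'
#' @param config A `run_config`.
#' @param code A `genetic_code`.
#' @return Invisibly, a list with the in-memory stage results and
#'   `outdir`.
#' @export
run_all <- function(config, code = standard_genetic_code()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  stage <- "read"
  res <- tryCatch({
    genes <- do.call(c, lapply(config$input, read_fasta))
    genes <- structure(genes, class = c("cds_set", "list"))

    stage <- "qc"
    qcres <- qc_cds_set(genes, code, min_codons = config$min_codons,
                        start_codons = config$start_codons,
                        keep_invalid = config$qc_policy == "permissive")
    write_qc_table(qcres$qc_table, out("qc.tsv"))
    genes <- qcres$genes
    if (length(genes) == 0L) stop("no gene passed QC")

    stage <- "composition"
    comp <- composition_table(genes, code)
    write_composition_table(comp, out("composition.tsv"))

    stage <- "metrics"
    counts <- lapply(genes, codon_counts, code = code)
    weights <- if (!is.null(config$cai_weights))
      read_cai_weights(config$cai_weights) else NULL
    met <- gene_metrics(genes, weights = weights, code = code,
                        estimator = config$enc_estimator)
    write_tsv(met$table, out("gene_metrics.tsv"))
    write_cai_weights(met$weights, out("cai_weights.tsv"))

    stage <- "rscu"
    pr <- pooled_rscu(counts, code)
    write_tsv(pr$table, out("rscu_pooled.tsv"))
    write_tsv(amino_acid_usage(counts, code), out("amino_acid_usage.tsv"))

    stage <- "correlation"
    merged <- merge(comp, met$table, by = "gene_id", sort = FALSE)
    cols <- c("GC", "GC1", "GC2", "GC3", "GC12", "AT3", "GC3s",
              "at_skew", "gc_skew", "enc", "cai", "gravy", "aromaticity")
    cm <- tryCatch(
      correlation_matrix(merged, cols, method = config$correlation_method),
      error = function(e) NULL)
    if (!is.null(cm)) {
      lt <- which(lower.tri(cm$r), arr.ind = TRUE)
      corr_tab <- data.frame(
        var1 = rownames(cm$r)[lt[, 1]], var2 = colnames(cm$r)[lt[, 2]],
        r = cm$r[lt], p = cm$p[lt],
        p_adj = stats::p.adjust(cm$p[lt], "BH"),
        stringsAsFactors = FALSE)
      write_tsv(corr_tab, out("correlation.tsv"))
    }

    stage <- "neutrality"
    nf <- tryCatch(neutrality_fit(comp), error = function(e) NULL)
    if (!is.null(nf))
      write_tsv(data.frame(slope = nf$slope, intercept = nf$intercept,
                           r = nf$r, p = nf$p, n = nf$n),
                out("neutrality.tsv"))

    stage <- "pr2"
    pr2 <- pr2_table(comp, counts = counts,
                     convention = config$pr2_convention, code = code)
    ps <- pr2_summary(pr2)
    write_tsv(pr2, out("pr2.tsv"))
    write_tsv(data.frame(mean_x = ps$mean_x, mean_y = ps$mean_y,
                         n_defined_x = ps$n_defined_x,
                         n_defined_y = ps$n_defined_y,
                         t(ps$quadrants)),
              out("pr2_summary.tsv"))

    stage <- "coa"
    rm <- rscu_matrix(counts, code)
    ca <- suppressWarnings(coa(rm, k = config$coa_axes))
    write_tsv(data.frame(gene_id = rownames(ca$row_coords),
                         ca$row_coords), out("coa_genes.tsv"))
    write_tsv(data.frame(codon = rownames(ca$col_coords),
                         ca$col_coords), out("coa_codons.tsv"))
    write_tsv(data.frame(axis = seq_along(ca$inertia_fraction),
                         inertia_fraction = ca$inertia_fraction),
              out("coa_inertia.tsv"))

    stage <- "cluster"
    ct <- nj_tree(rscu_distance_matrix(rm))
    write_cluster_tree(ct, out("tree.nwk"))

    stage <- "context"
    pm <- suppressWarnings(classify_pairs(
      expected_and_residuals(pair_counts(genes, code)),
      threshold = config$pair_threshold))
    write_pair_table(pm, out("codon_pairs.tsv"))
    write_tsv(data.frame(t(pm$summary)), out("pair_summary.tsv"))
    write_tsv(data.frame(codon = rownames(pm$observed),
                         context_heatmap_matrix(pm)),
              out("pair_heatmap.tsv"))

    list(genes = genes, qc = qcres$qc_table, composition = comp,
         metrics = met$table, rscu = pr, correlation = cm,
         neutrality = nf, pr2 = pr2, pr2_summary = ps, coa = ca,
         tree = ct, pairs = pm)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    tool = "cubkit",
    version = as.character(utils::packageVersion("cubkit")),
    config = unclass(config),
    inputs = lapply(config$input, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = list(qc = nrow(res$qc), composition = nrow(res$composition),
                  metrics = nrow(res$metrics),
                  rscu = nrow(res$rscu$table),
                  pr2 = nrow(res$pr2),
                  coa_axes = length(res$coa$inertia_fraction),
                  tree_tips = length(res$tree$tree$tip.label),
                  pairs = res$pairs$total_pairs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$outdir <- config$outdir
  invisible(res)
}

#' One-page text summary of a completed run
#'
#' Recomputes nothing: every number is read back from the bundle's tables,
#' mirroring the reporting style of codon usage surveys (gene count, mean
#' +/- sd and range of ENc, overall GC, extreme RSCU codons, neutrality
#' slope, PR2 means, leading ordination inertias, pair-class percentages).
#'
#' @param outdir Directory produced by [run_all()].
#' @return Character vector of report lines (also printed).
#' @export
summarize_run <- function(outdir) {
  need <- function(f) {
    p <- file.path(outdir, f)
    if (!file.exists(p)) stop("incomplete bundle: missing stage file ", f)
    utils::read.table(p, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  met <- need("gene_metrics.tsv")
  comp <- need("composition.tsv")
  rscu_tab <- need("rscu_pooled.tsv")
  pr2s <- need("pr2_summary.tsv")
  inertia <- need("coa_inertia.tsv")
  pairs <- need("pair_summary.tsv")
  n <- nrow(met)
  sd_txt <- if (n > 1L) sprintf("%.2f", stats::sd(met$enc)) else "NA"
  deg <- rscu_tab[rscu_tab$family_size > 1 & !is.na(rscu_tab$rscu), ]
  deg <- deg[order(-deg$rscu), ]
  slope_txt <- if (file.exists(file.path(outdir, "neutrality.tsv"))) {
    nf <- need("neutrality.tsv")
    sprintf("neutrality slope %.4f (r = %.3f, p = %.3g, n = %d)",
            nf$slope, nf$r, nf$p, nf$n)
  } else "neutrality fit: not available"
  lines <- c(
    sprintf("genes analysed: %d", n),
    sprintf("ENc: mean %.2f +/- %s, range %.2f-%.2f", mean(met$enc),
            sd_txt, min(met$enc), max(met$enc)),
    sprintf("overall GC: %.2f%%", 100 * mean(comp$GC)),
    sprintf("CAI: range %.3f-%.3f", min(met$cai), max(met$cai)),
    sprintf("top RSCU codons: %s",
            paste(sprintf("%s (%.2f)", utils::head(deg$codon, 3),
                          utils::head(deg$rscu, 3)), collapse = ", ")),
    sprintf("bottom RSCU codons: %s",
            paste(sprintf("%s (%.2f)", utils::tail(deg$codon, 3),
                          utils::tail(deg$rscu, 3)), collapse = ", ")),
    slope_txt,
    sprintf("PR2 means: A3/(A3+T3) = %.4f, G3/(G3+C3) = %.4f",
            pr2s$mean_x, pr2s$mean_y),
    sprintf("COA inertia: axis 1 %.1f%%, axis 2 %s",
            100 * inertia$inertia_fraction[1],
            if (nrow(inertia) > 1)
              sprintf("%.1f%%", 100 * inertia$inertia_fraction[2])
            else "NA"),
    sprintf("codon pairs: %.2f%% over, %.2f%% under, %.2f%% absent",
            100 * pairs$over, 100 * pairs$under, 100 * pairs$absent))
  cat(lines, sep = "\n")
  invisible(lines)
}
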