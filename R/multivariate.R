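#' Correspondence analysis of a gene-by-codon RSCU matrix
#'
#' Classic chi-square-metric correspondence analysis, the ordination used
#' throughout the codon usage literature. The matrix is treated as a
#' contingency-style table: with grand-total-normalised matrix P, row
#' masses r and column masses c, the standardised residual matrix
#' \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}} is decomposed by SVD, and
#' row (gene) and column (codon) coordinates are returned in principal
#' scaling, so axis variances equal the per-axis inertias. Axis signs are
#' canonicalised (the largest-magnitude codon loading on each axis is made
#' positive) for reproducible output. All-zero rows or columns are dropped
#' with a warning.
#'
#' @param x Non-negative numeric matrix, genes x codons (e.g. from
#'   [rscu_matrix()]).
#' @param k Number of axes to retain; default the full rank.
#' @return A `coa_result`: list with `row_coords` (genes x k),
#'   `col_coords` (codons x k), `inertia_fraction`, `total_inertia`,
#'   `singular_values`.
#' @export
coa <- function(x, k = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("matrix must be non-negative")
  zr <- rowSums(x) == 0
  zc <- colSums(x) == 0
  if (any(zr)) warning("dropping all-zero row(s): ",
                       paste(rownames(x)[zr], collapse = ", "))
  if (any(zc)) warning("dropping all-zero column(s): ",
                       paste(colnames(x)[zc], collapse = ", "))
  x <- x[!zr, !zc, drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 genes for correspondence analysis")
  P <- x / sum(x)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  dec <- svd(S)
  rank <- min(nrow(x), ncol(x)) - 1L
  sv <- dec$d[seq_len(rank)]
  keep <- if (is.null(k)) rank else min(k, rank)
  idx <- seq_len(keep)
  # principal coordinates
  F <- sweep(dec$u[, idx, drop = FALSE] %*% diag(sv[idx], keep), 1,
             sqrt(r), "/")
  G <- sweep(dec$v[, idx, drop = FALSE] %*% diag(sv[idx], keep), 1,
             sqrt(cm), "/")
  for (j in idx) {                      # canonical axis orientation
    s <- sign(G[which.max(abs(G[, j])), j])
    if (!is.na(s) && s < 0) { G[, j] <- -G[, j]; F[, j] <- -F[, j] }
  }
  dimnames(F) <- list(rownames(x), paste0("axis", idx))
  dimnames(G) <- list(colnames(x), paste0("axis", idx))
  total <- sum(dec$d^2)
  if (total < .Machine$double.eps^0.5) {
    frac <- rep(0, keep)
  } else {
    frac <- sv[idx]^2 / total
  }
  structure(list(row_coords = F, col_coords = G,
                 inertia_fraction = frac, total_inertia = total,
                 singular_values = sv),
            class = "coa_result")
}

#' Euclidean distance matrix between gene RSCU profiles
#'
#' @param x Genes x codons RSCU matrix.
#' @return Symmetric `dist`-convertible matrix with zero diagonal.
#' @export
rscu_distance_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 genes")
  as.matrix(stats::dist(x, method = "euclidean"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou & Nei's agglomeration, implemented with deterministic
#' tie-breaking (among equally minimal Q values the lexicographically
#' first label pair is joined) and the usual non-negativity adjustment: a
#' negative branch length is clamped to 0 and the deficit moved to its
#' sibling branch so path lengths through the join are preserved.
#'
#' @param d Symmetric numeric matrix with zero diagonal and labels (e.g.
#'   from [rscu_distance_matrix()]).
#' @return A `cluster_tree`: list with `tree` (an [ape] `phylo`, unrooted
#'   with a basal trichotomy) and `newick` (the serialized string).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  labels <- rownames(d)
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]
  sub <- labels                     # newick fragment per active node
  fmt <- function(x) formatC(max(0, x), digits = 15, format = "g")
  pair_branches <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(li, lj)
  }
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    b <- pair_branches(li, lj)
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(b[1]),
                       sub[j], fmt(b[2]))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], "internal")
    d <- d2
  }
  # final 3-star: l_i = (d_ij + d_ik - d_jk) / 2
  l <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
         (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
         (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  neg <- l < 0
  if (any(neg)) { l[!neg] <- l[!neg] + sum(l[neg]) / sum(!neg); l[neg] <- 0 }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    sub[1], fmt(l[1]), sub[2], fmt(l[2]), sub[3], fmt(l[3]))
  tree <- ape::read.tree(text = newick)
  structure(list(tree = tree, newick = ape::write.tree(tree)),
            class = "cluster_tree")
}

#' Write a cluster tree as newick
#'
#' @param ct A `cluster_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tree <- function(ct, path) {
  ape::write.tree(ct$tree, file = path)
  invisible(path)
}
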