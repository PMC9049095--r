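#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of the mean GC content at codon positions 1 and
#' 2 (GC12) on the synonymous third-position GC content (GC3). A slope
#' near 1 indicates that all three positions respond to the same
#' directional mutation pressure; a slope near 0 indicates that selection
#' holds positions 1+2 while position 3 drifts.
#'
#' @param profiles Data frame of composition profiles (needs `GC12`,
#'   `GC3`).
#' @return A `neutrality_fit`: list with `slope`, `intercept`, `r`
#'   (Pearson), `p` (two-sided), `n`.
#' @export
neutrality_fit <- function(profiles) {
  ok <- stats::complete.cases(profiles[c("GC12", "GC3")])
  d <- profiles[ok, ]
  if (nrow(d) < 3L) stop("need at least 3 genes with defined GC12 and GC3")
  if (stats::sd(d$GC3) == 0) stop("degenerate regressor: GC3 is constant")
  fit <- stats::lm(GC12 ~ GC3, data = d)
  if (stats::sd(d$GC12) == 0) {
    r <- 0; p <- 1          # constant response: no association, by convention
  } else {
    ct <- suppressWarnings(stats::cor.test(d$GC3, d$GC12))
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, p = p, n = nrow(d)),
            class = "neutrality_fit")
}

#' Parity rule 2 coordinates of a gene
#'
#' The PR2 plot places each gene at `x = A3/(A3+T3)`, `y = G3/(G3+C3)`,
#' computed over synonymous third positions. Under strict parity (A = T
#' and G = C at silent sites) a gene sits at the center (0.5, 0.5). A zero
#' denominator leaves the coordinate undefined (`NA`) rather than 0.
#'
#' @param profile One composition profile row (needs `A3`, `T3`, `G3`,
#'   `C3`).
#' @return A `pr2_point`: list with `x`, `y`, `x_defined`, `y_defined`.
#' @export
pr2_point <- function(profile) {
  at <- profile$A3 + profile$T3
  gc <- profile$G3 + profile$C3
  structure(list(
    x = if (at > 0) profile$A3 / at else NA_real_,
    y = if (gc > 0) profile$G3 / gc else NA_real_,
    x_defined = at > 0, y_defined = gc > 0),
    class = "pr2_point")
}

#' Third-position base counts under a PR2 convention
#'
#' `"synonymous"` counts third positions over all 59 degenerate sense
#' codons (the package-wide default); `"fourfold"` restricts to the five
#' 4-fold degenerate families (Ala, Gly, Pro, Thr, Val), the convention of
#' the original parity-rule literature. Only the fourfold universe is
#' symmetric under complementation of the third base — in the synonymous
#' universe the stop codons remove the A/G partners of the Tyr and Cys
#' third positions, so even a strand-symmetric mutation process sits
#' slightly off the (0.5, 0.5) center.
#'
#' @param counts A `codon_counts` object.
#' @param code A `genetic_code`.
#' @param convention `"synonymous"` or `"fourfold"`.
#' @return Named numeric vector `A3`, `T3`, `G3`, `C3`.
#' @export
third_position_counts <- function(counts, code = standard_genetic_code(),
                                  convention = c("synonymous",
                                                 "fourfold")) {
  convention <- match.arg(convention)
  stopifnot(inherits(counts, "codon_counts"))
  universe <- if (convention == "synonymous") code$degenerate_codons
  else unlist(code$families[code$degeneracy == 4L], use.names = FALSE)
  p3 <- positional_base_counts(counts$counts, universe)$p3
  stats::setNames(p3[c("A", "T", "G", "C")], c("A3", "T3", "G3", "C3"))
}

#' PR2 coordinates for a gene set
#'
#' @param profiles Data frame of composition profiles (used directly under
#'   the `"synonymous"` convention).
#' @param counts Optional named list of `codon_counts`, required for the
#'   `"fourfold"` convention.
#' @param convention See [third_position_counts()].
#' @param code A `genetic_code`.
#' @return Data frame: `gene_id`, `x`, `y`, `x_defined`, `y_defined`.
#' @export
pr2_table <- function(profiles, counts = NULL,
                      convention = c("synonymous", "fourfold"),
                      code = standard_genetic_code()) {
  convention <- match.arg(convention)
  if (convention == "fourfold") {
    if (is.null(counts))
      stop("fourfold convention needs the per-gene codon counts")
    rows <- lapply(counts, function(cc)
      as.data.frame(as.list(third_position_counts(cc, code, "fourfold"))))
    profiles <- cbind(gene_id = vapply(counts, `[[`, character(1), "id"),
                      do.call(rbind, rows))
    rownames(profiles) <- NULL
  }
  pts <- lapply(seq_len(nrow(profiles)), function(i)
    pr2_point(profiles[i, ]))
  data.frame(
    gene_id = profiles$gene_id,
    x = vapply(pts, `[[`, numeric(1), "x"),
    y = vapply(pts, `[[`, numeric(1), "y"),
    x_defined = vapply(pts, `[[`, logical(1), "x_defined"),
    y_defined = vapply(pts, `[[`, logical(1), "y_defined"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Summary of a PR2 point cloud
#'
#' Mean coordinates over defined points plus counts per quadrant relative
#' to the (0.5, 0.5) center; fully defined points lying exactly on a
#' center line are excluded from the quadrant counts.
#'
#' @param points Data frame from [pr2_table()].
#' @return List with `mean_x`, `mean_y`, `n_defined_x`, `n_defined_y`, and
#'   `quadrants` (named counts `q1`..`q4`, counter-clockwise from
#'   top-right).
#' @export
pr2_summary <- function(points) {
  if (!any(points$x_defined) && !any(points$y_defined))
    stop("all PR2 points undefined")
  mean_x <- mean(points$x[points$x_defined])
  mean_y <- mean(points$y[points$y_defined])
  full <- points$x_defined & points$y_defined &
    points$x != 0.5 & points$y != 0.5
  q <- c(q1 = sum(full & points$x > 0.5 & points$y > 0.5),
         q2 = sum(full & points$x < 0.5 & points$y > 0.5),
         q3 = sum(full & points$x < 0.5 & points$y < 0.5),
         q4 = sum(full & points$x > 0.5 & points$y < 0.5))
  list(mean_x = mean_x, mean_y = mean_y,
       n_defined_x = sum(points$x_defined),
       n_defined_y = sum(points$y_defined),
       quadrants = q)
}
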