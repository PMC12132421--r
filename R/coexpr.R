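#' Binarise a cell-by-gene count matrix
#'
#' A cell expresses a gene when its raw count is greater than zero.
#'
#' @param counts Matrix (dense or \code{Matrix} sparse), cells in rows,
#'   genes in columns, with dimnames.
#' @return Logical matrix of the same shape.
#' @export
detect_expression <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  out <- as.matrix(counts > 0)
  dimnames(out) <- dimnames(counts)
  out
}

.gene_detected <- function(detected, gene) {
  if (!gene %in% colnames(detected)) stop("gene not found: ", gene)
  detected[, gene]
}

#' Percent co-expression
#'
#' Percentage of gene1-expressing cells that also express gene2:
#' 100 * (cells expressing both) / (cells expressing gene1).  Note the
#' asymmetry: swapping the genes changes the denominator.
#'
#' @param detected Logical cell-by-gene matrix
#'   (\code{\link{detect_expression}}).
#' @param gene1,gene2 Gene identifiers (columns of \code{detected}).
#' @return Percentage in [0, 100].
#' @export
percent_coexpression <- function(detected, gene1, gene2) {
  g1 <- .gene_detected(detected, gene1)
  g2 <- .gene_detected(detected, gene2)
  n1 <- sum(g1)
  if (n1 == 0) stop("no cells express ", gene1,
                    "; percent co-expression undefined")
  100 * sum(g1 & g2) / n1
}

#' 2x2 co-detection contingency table
#'
#' Partitions cells by detection of two genes: \code{a} = both,
#' \code{b} = gene1 only, \code{c} = gene2 only, \code{d} = neither.
#'
#' @inheritParams percent_coexpression
#' @return Named integer vector \code{c(a, b, c, d)}, summing to the
#'   cell count.
#' @export
contingency <- function(detected, gene1, gene2) {
  g1 <- .gene_detected(detected, gene1)
  g2 <- .gene_detected(detected, gene2)
  c(a = sum(g1 & g2), b = sum(g1 & !g2),
    c = sum(!g1 & g2), d = sum(!g1 & !g2))
}

#' Two-sided Fisher's exact test p-value
#'
#' Conditional on the table margins, sums the hypergeometric
#' probabilities of all tables at least as extreme as the observed one
#' (probability-mass ordering, the conventional two-sided definition).
#'
#' @param table Numeric vector \code{c(a, b, c, d)} or 2x2 matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- if (is.matrix(table)) table else matrix(as.numeric(table), 2L, 2L,
                                               byrow = TRUE)
  fisher.test(m)$p.value
}

#' Odds ratio with Haldane-Anscombe zero correction
#'
#' (a*d)/(b*c); when any cell is zero, \code{zero_correction} (default
#' 0.5) is added to every cell first so the ratio stays finite.
#'
#' @param table Numeric vector \code{c(a, b, c, d)}.
#' @param zero_correction Continuity constant applied only when a cell
#'   is zero (default 0.5).
#' @return Odds ratio (>= 0).
#' @export
odds_ratio <- function(table, zero_correction = 0.5) {
  stopifnot(zero_correction >= 0)
  t <- as.numeric(table)
  if (any(t == 0)) t <- t + zero_correction
  (t[1] * t[4]) / (t[2] * t[3])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: p * m / rank followed by a cumulative
#' minimum from the largest p down, capped at 1.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Co-expression enrichment screen against an anchor gene
#'
#' For each target gene, builds the 2x2 table against the anchor gene,
#' applies Fisher's exact test and the Haldane-Anscombe-corrected odds
#' ratio, and BH-adjusts the p-values across the screen.  An odds
#' ratio above 1 indicates enrichment of the target in anchor-positive
#' cells; below 1, depletion.
#'
#' @param counts Cell-by-gene count matrix with dimnames.
#' @param anchor_gene The anchor gene (e.g. a lineage marker).
#' @param genes Target genes (default: all other columns).
#' @return Data frame: \code{gene}, \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{percent_coexpression}, \code{odds_ratio},
#'   \code{p_value}, \code{q_value}.
#' @export
coexpression_enrichment <- function(counts, anchor_gene, genes = NULL) {
  det <- detect_expression(counts)
  if (is.null(genes)) genes <- setdiff(colnames(det), anchor_gene)
  rows <- lapply(genes, function(g) {
    tb <- contingency(det, anchor_gene, g)
    data.frame(gene = g, a = tb["a"], b = tb["b"], c = tb["c"],
               d = tb["d"],
               percent_coexpression =
                 if (sum(tb[c("a", "b")]) > 0)
                   100 * tb[["a"]] / sum(tb[c("a", "b")]) else NA_real_,
               odds_ratio = odds_ratio(tb),
               p_value = fisher_exact(tb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- bh_fdr(out$p_value)
  out
}

#' Information content and bit heights of a position frequency matrix
#'
#' Adds a pseudocount, renormalises each position, computes the Shannon
#' entropy H = -sum(p log2 p) and the information content IC = 2 - H
#' (bits), and scales frequencies by IC to give the letter heights of a
#' sequence logo.  Bit heights at each position sum exactly to the IC.
#'
#' @param pfm Numeric matrix, positions in rows, 4 base columns
#'   (A, C, G, T), nonnegative (counts or frequencies).
#' @param pseudocount Added to every entry before normalisation
#'   (default 1e-6).
#' @return List with \code{frequencies} (renormalised), \code{ic}
#'   (bits per position, in [0, 2]) and \code{bit_heights}.
#' @export
pfm_information <- function(pfm, pseudocount = 1e-6) {
  pfm <- as.matrix(pfm)
  if (ncol(pfm) != 4L) stop("PFM must have 4 base columns")
  if (any(pfm < 0)) stop("PFM entries must be nonnegative")
  rs <- rowSums(pfm)
  if (any(rs == 0) && pseudocount == 0)
    stop("all-zero PFM row with zero pseudocount")
  p <- pfm + pseudocount
  p <- p / rowSums(p)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  ic <- 2 - h
  list(frequencies = p, ic = ic, bit_heights = p * ic)
}
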