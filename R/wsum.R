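#' Relative expression weights of a miRNA set
#'
#' Normalizes abundance levels to weights summing to 1 over the supplied
#' miRNA set. Weights are computed within the analyzed set, not the whole
#' miRNome, so rescaling all levels by a common factor leaves them
#' unchanged. Levels of exactly 0 are tolerated here (weight 0), although
#' [mirna_expression()] itself requires positive levels.
#'
#' @param expr a [mirna_expression()] table or named non-negative numeric
#'   vector of levels.
#' @return named numeric weights in \[0, 1\] summing to 1.
#' @examples
#' relative_weights(mirna_expression(c("a", "b"), c(1, 3)))  # 0.25, 0.75
#' @export
relative_weights <- function(expr) {
  lev <- expr_levels(expr)
  if (any(!is.finite(lev) | lev < 0))
    stop("expression levels must be finite and >= 0")
  tot <- sum(lev)
  if (tot <= 0) stop("all expression levels are 0; weights undefined")
  lev / tot
}

#' Expression-weighted sum gene score
#'
#' Combination rule for predictors whose site scores are not energies
#' (e.g. n-mer match counts or regression scores): for each miRNA, its site
#' scores on the gene are summed and the sum is weighted by the miRNA's
#' relative expression. A binary predictor (every site scored 1) therefore
#' contributes expression-weighted site counts.
#'
#' Sites of miRNAs absent from the weight vector are dropped with a
#' warning, matching the occupancy combiner's treatment of unexpressed
#' miRNAs.
#'
#' @param sites a [site_table()] with scores oriented larger = stronger,
#'   usually all rows of one gene.
#' @param weights a [relative_weights()] vector (or an expression table,
#'   which is converted).
#' @return a single numeric score; 0 for a gene with no sites.
#' @examples
#' s <- site_table(gene_id = "g", mirna_id = c("a", "a"), start = c(0, 20),
#'                 end = c(7, 27), tool = "scoreC", score = c(2, 4))
#' wsum_gene_score(s, c(a = 1))  # 6
#' @export
wsum_gene_score <- function(sites, weights) {
  validate_site_table(sites)
  if (is.data.frame(weights)) weights <- relative_weights(weights)
  if (nrow(sites) == 0) return(0)
  keep <- sites$mirna_id %in% names(weights)
  if (any(!keep))
    warning(sum(!keep), " site(s) dropped: miRNA not in weight vector (",
            paste(unique(sites$mirna_id[!keep]), collapse = ", "), ")")
  s <- sites[keep, , drop = FALSE]
  if (nrow(s) == 0) return(0)
  sum(unname(weights[s$mirna_id]) * s$score)
}
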