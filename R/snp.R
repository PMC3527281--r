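#' A single-nucleotide variant within a 3'UTR
#'
#' @param snp_id variant identifier.
#' @param gene_id gene whose 3'UTR carries the variant.
#' @param pos 0-based offset within the 3'UTR.
#' @param ref,alt single nucleotides (DNA or RNA; `T` mapped to `U`);
#'   `ref != alt`.
#' @param maf optional minor allele frequency, carried as metadata.
#' @return a list of class `snp_record`.
#' @export
snp_record <- function(snp_id, gene_id, pos, ref, alt, maf = NA_real_) {
  ref <- chartr("tT", "uU", toupper(ref))
  alt <- chartr("tT", "uU", toupper(alt))
  if (nchar(ref) != 1 || nchar(alt) != 1 ||
      !ref %in% c("A", "C", "G", "U") || !alt %in% c("A", "C", "G", "U"))
    stop("ref and alt must be single A/C/G/U(/T) nucleotides")
  if (ref == alt) stop("ref and alt must differ for ", snp_id)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 0) stop("pos must be a non-negative 0-based offset")
  structure(list(snp_id = as.character(snp_id),
                 gene_id = as.character(gene_id),
                 pos = pos, ref = ref, alt = alt, maf = as.numeric(maf)),
            class = "snp_record")
}

#' Substitute a SNP into a 3'UTR
#'
#' Returns a copy of the UTR with the alternate allele substituted at the
#' variant position. The observed reference base is checked against the
#' record's `ref`; a mismatch raises an error reporting the observed base,
#' which guards against coordinate-convention mistakes.
#'
#' @param utr a [utr_sequence()].
#' @param snp a [snp_record()] for the same gene.
#' @return a [utr_sequence()] of identical length.
#' @export
apply_snp <- function(utr, snp) {
  stopifnot(inherits(utr, "utr_sequence"), inherits(snp, "snp_record"))
  if (!identical(utr$gene_id, snp$gene_id))
    stop("SNP ", snp$snp_id, " annotates gene ", snp$gene_id,
         " but the UTR is for ", utr$gene_id)
  if (snp$pos >= utr$length)
    stop("SNP position ", snp$pos, " outside UTR of length ", utr$length,
         " (0-based)")
  observed <- substr(utr$seq, snp$pos + 1, snp$pos + 1)
  if (observed != snp$ref)
    stop("reference mismatch for ", snp$snp_id, " at 0-based position ",
         snp$pos, ": expected ", snp$ref, ", observed ", observed)
  s <- utr$seq
  substr(s, snp$pos + 1, snp$pos + 1) <- snp$alt
  utr_sequence(utr$gene_id, s)
}

# targeting probability of one gene for ONE miRNA from its scanned sites.
# Without an ensemble model this is the probability that at least one site
# is occupied (independent sites): 1 - prod(1 - p_j).
single_mirna_probability <- function(sites, level, config) {
  if (nrow(sites) == 0) return(0)
  mu <- chemical_potential(config$expression_scale * level, RT = config$RT)
  p <- fd_site_probability(sites$score, mu, RT = config$RT)
  1 - prod(1 - p)
}

# targeting probability through a fitted ensemble: the scanned site table
# stands in for every tool; each tool's feature is computed with the
# combination method recorded in the model ("fd" unless stated otherwise).
ensemble_probability <- function(model, sites, mirna_id, level, config) {
  expr1 <- mirna_expression(mirna_id, level)
  methods <- model$methods
  if (is.null(methods))
    methods <- stats::setNames(rep("fd", length(model$tools)), model$tools)
  feats <- vapply(model$tools, function(tl) {
    switch(methods[[tl]],
      fd = fd_gene_score(sites, expr1, config),
      wsum = {
        s2 <- sites; s2$score <- -s2$score   # orient larger = stronger
        wsum_gene_score(s2, relative_weights(expr1))
      },
      naive = naive_gene_score(sites))
  }, numeric(1))
  x <- matrix(feats, nrow = 1, dimnames = list(sites$gene_id[1], model$tools))
  # a single gene cannot be rank-normalized against itself meaningfully;
  # score on the training scale directly
  unname(predict(model, x, type = "prob", renormalize = FALSE))
}

#' Score the targeting change induced by a SNP
#'
#' Re-runs the site-discovery and scoring pipeline on the reference and the
#' SNP-bearing 3'UTR and reports, per miRNA, the targeting probabilities
#' `P_ref` and `P_alt` and a ranking score `delta`:
#'
#' * `mode = "weighted"` (default): `delta = P_ref * (P_ref - P_alt)`,
#'   which up-weights variants that disrupt high-confidence reference
#'   targets;
#' * `mode = "plain"`: `delta = P_ref - P_alt`.
#'
#' With no ensemble model, `P` is the probability that at least one scanned
#' site of the miRNA is occupied, using the surrogate energies of `spec`
#' and the miRNA's expression-derived chemical potential. With a fitted
#' [fit_ensemble()] model, the scanned sites are combined into per-tool
#' features with the methods recorded in the model and the calibrated
#' ensemble probability is used.
#'
#' When no expression table is supplied, uniform levels of 1 are assumed
#' for every miRNA and a warning is emitted (rankings then reflect site
#' strength only).
#'
#' @param utr the reference [utr_sequence()].
#' @param snp a [snp_record()] on the same gene.
#' @param mirna_seqs named character vector of mature miRNA sequences.
#' @param expr optional [mirna_expression()] covering the miRNA set.
#' @param spec a [seed_match_spec()].
#' @param config a [thermo_config()].
#' @param model optional `mir_ensemble`.
#' @param mode ranking mode, see above.
#' @return a `data.frame` with one row per miRNA: `snp_id`, `mirna_id`,
#'   `P_ref`, `P_alt`, `delta`, `mode`.
#' @export
snp_delta_score <- function(utr, snp, mirna_seqs, expr = NULL,
                            spec = seed_match_spec(),
                            config = thermo_config(), model = NULL,
                            mode = c("weighted", "plain")) {
  mode <- match.arg(mode)
  if (is.null(names(mirna_seqs))) stop("mirna_seqs must be named")
  if (is.null(expr)) {
    warning("no miRNA expression supplied; assuming uniform levels")
    expr <- mirna_expression(names(mirna_seqs), rep(1, length(mirna_seqs)))
  }
  lev <- expr_levels(expr)
  missing_e <- setdiff(names(mirna_seqs), names(lev))
  if (length(missing_e))
    stop("no expression level for miRNA(s): ",
         paste(missing_e, collapse = ", "))
  alt_utr <- apply_snp(utr, snp)
  rows <- lapply(names(mirna_seqs), function(mi) {
    s_ref <- find_seed_sites(utr, mirna_seqs[[mi]], mirna_id = mi, spec = spec)
    s_alt <- find_seed_sites(alt_utr, mirna_seqs[[mi]], mirna_id = mi, spec = spec)
    if (is.null(model)) {
      p_ref <- single_mirna_probability(s_ref, lev[[mi]], config)
      p_alt <- single_mirna_probability(s_alt, lev[[mi]], config)
    } else {
      p_ref <- ensemble_probability(model, s_ref, mi, lev[[mi]], config)
      p_alt <- ensemble_probability(model, s_alt, mi, lev[[mi]], config)
      if (nrow(s_ref) == 0 && nrow(s_alt) == 0) p_alt <- p_ref  # no sites at all
    }
    delta <- if (mode == "weighted") p_ref * (p_ref - p_alt) else p_ref - p_alt
    data.frame(snp_id = snp$snp_id, mirna_id = mi,
               P_ref = p_ref, P_alt = p_alt, delta = delta, mode = mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank SNP:miRNA pairs by targeting disruption
#'
#' Orders scored records by decreasing `delta` (ties broken
#' lexicographically by `snp_id`, then `mirna_id`) and drops records with
#' `delta <= threshold`. All records must have been scored in the same
#' mode.
#'
#' @param records a `data.frame` of [snp_delta_score()] rows (possibly
#'   rbind-ed over SNPs).
#' @param threshold minimum `delta` retained (exclusive); default 0.01.
#' @return the filtered, ranked `data.frame` with an added `rank` column.
#' @export
rank_snp_mirna_pairs <- function(records, threshold = 0.01) {
  req <- c("snp_id", "mirna_id", "P_ref", "P_alt", "delta", "mode")
  if (!all(req %in% names(records)))
    stop("records must contain columns: ", paste(req, collapse = ", "))
  if (nrow(records) && length(unique(records$mode)) > 1)
    stop("records scored in mixed modes: ",
         paste(unique(records$mode), collapse = ", "))
  keep <- records[records$delta > threshold, , drop = FALSE]
  ord <- order(-keep$delta, keep$snp_id, keep$mirna_id)
  out <- keep[ord, , drop = FALSE]
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  else out$rank <- integer(0)
  rownames(out) <- NULL
  out
}
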