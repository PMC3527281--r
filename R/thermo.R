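#' Chemical potential of a miRNA
#'
#' The chemical potential mu = RT * ln(level) of a miRNA at abundance
#' `level`. In the occupancy model a binding site is appreciably occupied
#' only when its free energy of binding falls below mu, so more abundant
#' miRNAs fill weaker sites.
#'
#' @param level strictly positive abundance (vectorized).
#' @param RT thermal energy in kcal/mol.
#' @param mirna_id optional identifier(s) used in error messages.
#' @return mu in kcal/mol, same length as `level`; strictly increasing in
#'   `level`.
#' @examples
#' chemical_potential(1, RT = 0.6163)        # 0
#' chemical_potential(exp(2), RT = 0.5)      # 1
#' @export
chemical_potential <- function(level, RT = 0.6163, mirna_id = NULL) {
  if (!is.numeric(RT) || length(RT) != 1 || !is.finite(RT) || RT <= 0)
    stop("RT must be a single finite value > 0")
  bad <- !is.finite(level) | level <= 0
  if (any(bad)) {
    who <- if (!is.null(mirna_id)) paste(mirna_id[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("abundance must be > 0 to define a chemical potential; ",
         "offending miRNA(s): ", who)
  }
  RT * log(level)
}

#' Fermi-Dirac occupancy probability of a binding site
#'
#' Probability that a site of binding free energy `E` is occupied at
#' chemical potential `mu`: `p = 1 / (1 + exp((E - mu) / RT))`. The site is
#' treated as a two-state system; `p = 1/2` exactly at `E = mu`, approaches
#' 1 for strong sites (`E << mu`) and 0 for weak ones (`E >> mu`).
#'
#' Evaluated through [stats::plogis()], so it is numerically stable for
#' arbitrarily large `|E - mu| / RT`. `E = +Inf`/`-Inf` are accepted as
#' limits and give 0/1.
#'
#' @param E site free energy of binding, kcal/mol (vectorized).
#' @param mu chemical potential, kcal/mol (vectorized).
#' @param RT thermal energy in kcal/mol, > 0.
#' @return occupancy probabilities in \[0, 1\]; strictly decreasing in `E`,
#'   strictly increasing in `mu`.
#' @examples
#' fd_site_probability(-8, -8)                      # 0.5
#' fd_site_probability(-8 - 0.6163 * log(3), -8)    # 0.75
#' @export
fd_site_probability <- function(E, mu, RT = 0.6163) {
  if (!is.numeric(RT) || length(RT) != 1 || !is.finite(RT) || RT <= 0)
    stop("RT must be a single finite value > 0")
  if (any(is.na(E)) || any(is.na(mu)))
    stop("E and mu must not contain NA")
  if (any(!is.finite(mu)))
    stop("mu must be finite")
  stats::plogis((mu - E) / RT)
}

# per-site occupancy for a site table: drops sites of miRNAs absent from
# the expression table (with one warning), returns numeric p per kept row
# together with the kept row index.
site_occupancies <- function(sites, expr, config = thermo_config()) {
  lev <- expr_levels(expr)
  keep <- sites$mirna_id %in% names(lev)
  if (any(!keep))
    warning(sum(!keep), " site(s) dropped: miRNA not in expression table (",
            paste(unique(sites$mirna_id[!keep]), collapse = ", "), ")")
  s <- sites[keep, , drop = FALSE]
  mu <- chemical_potential(config$expression_scale * lev[s$mirna_id],
                           RT = config$RT, mirna_id = s$mirna_id)
  list(p = fd_site_probability(s$score, mu, RT = config$RT), keep = keep)
}

#' Fermi-Dirac gene score
#'
#' Combined occupancy score of one gene: the sum of Fermi-Dirac occupancy
#' probabilities over all of its binding sites for all considered miRNAs.
#' Sites with very negative energies and highly expressed miRNAs dominate
#' the sum. The score lies between 0 and the number of sites.
#'
#' Sites whose miRNA is absent from the expression table are dropped with a
#' warning (only expressed miRNAs are considered).
#'
#' @param sites a [site_table()] with energy scores (kcal/mol), usually all
#'   rows of one gene.
#' @param expr a [mirna_expression()] table.
#' @param config a [thermo_config()].
#' @return a single numeric score.
#' @examples
#' s <- site_table(gene_id = "g", mirna_id = c("a", "b"), start = c(0, 20),
#'                 end = c(7, 27), tool = "energyA", score = c(-9, -4))
#' fd_gene_score(s, mirna_expression(c("a", "b"), c(200, 5000)),
#'               thermo_config(expression_scale = 1e-3))
#' @export
fd_gene_score <- function(sites, expr, config = thermo_config()) {
  validate_site_table(sites)
  if (nrow(sites) == 0) return(0)
  sum(site_occupancies(sites, expr, config)$p)
}

#' Naive combined gene score
#'
#' Expression-blind baseline: the unweighted sum of site scores, oriented so
#' that larger means a stronger target (energies are negated). A gene is
#' scored as a target of a miRNA set if it is a target of at least one
#' member; the score simply accumulates all predicted sites.
#'
#' @param sites a [site_table()], usually all rows of one gene.
#' @param energy `TRUE` if `score` holds binding energies (negated before
#'   summation); `FALSE` if already oriented larger = stronger. Default
#'   `NULL` infers energies when any score is negative.
#' @return a single numeric score.
#' @examples
#' s <- site_table(gene_id = "g", mirna_id = c("a", "b"), start = c(0, 20),
#'                 end = c(7, 27), tool = "energyA", score = c(-5, -3))
#' naive_gene_score(s)   # 8
#' @export
naive_gene_score <- function(sites, energy = NULL) {
  validate_site_table(sites)
  if (nrow(sites) == 0) return(0)
  if (is.null(energy)) energy <- any(sites$score < 0)
  sum(if (energy) -sites$score else sites$score)
}

#' Combined gene scores for a whole site table
#'
#' Vectorized front end to the three per-gene combiners: Fermi-Dirac
#' occupancy (`"fd"`, energy scores), expression-weighted sum (`"wsum"`,
#' positive scores), or the expression-blind naive sum (`"naive"`).
#' Genes listed in `genes` but absent from `sites` score 0 (no detected
#' sites).
#'
#' @param sites a [site_table()]; should contain a single predictor
#'   (`tool`) so that scores are on one scale.
#' @param expr a [mirna_expression()] table; required for `"fd"` and
#'   `"wsum"`, ignored by `"naive"`.
#' @param method combination method.
#' @param config a [thermo_config()] (used by `"fd"`).
#' @param genes optional character vector fixing the output gene universe.
#' @param energy see [naive_gene_score()] (used by `"naive"`).
#' @return a `data.frame` with columns `gene_id` and `score`, sorted by
#'   `gene_id`, with attributes `method` and `tool`.
#' @export
gene_scores <- function(sites, expr = NULL,
                        method = c("fd", "wsum", "naive"),
                        config = thermo_config(), genes = NULL,
                        energy = NULL) {
  method <- match.arg(method)
  validate_site_table(sites)
  if (is.null(genes)) genes <- unique(sites$gene_id)
  genes <- sort(genes)
  if (method %in% c("fd", "wsum") && is.null(expr))
    stop("method '", method, "' requires an expression table")
  per_site <- switch(method,
    fd = {
      occ <- site_occupancies(sites, expr, config)
      sites <- sites[occ$keep, , drop = FALSE]
      occ$p
    },
    wsum = {
      w <- relative_weights(expr)
      keep <- sites$mirna_id %in% names(w)
      if (any(!keep))
        warning(sum(!keep), " site(s) dropped: miRNA not in weight vector (",
                paste(unique(sites$mirna_id[!keep]), collapse = ", "), ")")
      sites <- sites[keep, , drop = FALSE]
      unname(w[sites$mirna_id]) * sites$score
    },
    naive = {
      if (is.null(energy)) energy <- any(sites$score < 0)
      if (energy) -sites$score else sites$score
    })
  score <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(sites)) {
    agg <- rowsum(per_site, group = sites$gene_id)
    hit <- intersect(rownames(agg), genes)
    score[hit] <- agg[hit, 1]
  }
  out <- data.frame(gene_id = genes, score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "tool") <- if (nrow(sites)) unique(sites$tool) else character()
  out
}

#' Call targets from the top fraction of scores
#'
#' Returns the genes whose combined score is at least the `(1 - q)` empirical
#' quantile (linear interpolation) of the score distribution. Boundary ties
#' are all included, so slightly more than `q * n` genes may be returned.
#'
#' @param scores a `data.frame` with `gene_id` and `score` columns (as from
#'   [gene_scores()]) or a named numeric vector.
#' @param q fraction of top scores to call, in (0, 1\].
#' @return character vector of gene ids, sorted.
#' @examples
#' top_fraction_targets(c(a = 1, b = 2, c = 2, d = 3), q = 0.5)
#' @export
top_fraction_targets <- function(scores, q = 0.1) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$gene_id)
  if (length(scores) == 0) stop("empty score table")
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1)
    stop("q must be a single fraction in (0, 1]")
  thr <- stats::quantile(scores, probs = 1 - q, names = FALSE, type = 7)
  sort(names(scores)[scores >= thr])
}
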