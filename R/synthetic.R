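#' Configuration of the synthetic benchmark generator
#'
#' Defines the statistical structure of a simulated dataset: a population
#' of genes carrying miRNA binding sites with negative free energies,
#' read-count-like miRNA abundances spanning several orders of magnitude,
#' ground-truth occupancy computed with the Fermi-Dirac model, balanced
#' positive/negative labels derived from the occupancy quantiles, and four
#' noisy "tools" observing the sites (two reporting energies, two reporting
#' positive scores). Each tool additionally reports tool-specific spurious
#' weak sites, emulating the low inter-predictor agreement of real target
#' finders.
#'
#' Defaults (documented in the methods vignette): 2000 genes, 25 expressed
#' miRNAs; Poisson(6) true sites per gene assigned uniformly to miRNAs;
#' energies N(-8, 3) truncated at 0 kcal/mol; abundances log-normal
#' (meanlog log(500), sdlog 2) floored at 50 reads; expression scale 1e-10
#' so that the chemical potentials span the middle of the energy
#' distribution; labels: positives are the top occupancy quantile (0.25),
#' negatives sampled from the bottom quantile; per-tool energy noise sd 1.5,
#' site dropout 0.2, and Poisson(6) spurious sites per gene with energies
#' N(-4, 2) truncated at 0.
#'
#' @param n_genes,n_mirnas population sizes.
#' @param sites_per_gene Poisson mean of true sites per gene.
#' @param energy_mean,energy_sd site free-energy distribution (kcal/mol,
#'   truncated at 0).
#' @param expr_meanlog,expr_sdlog,expr_floor log-normal abundance
#'   parameters and the minimum retained level (reads).
#' @param expression_scale,RT thermodynamic configuration used for the
#'   ground-truth occupancy (see [thermo_config()]).
#' @param label_quantile fraction of genes per class; positives come from
#'   the top occupancy quantile, negatives from the bottom.
#' @param noise_sd per-tool energy/score noise sd.
#' @param dropout per-tool probability of missing a true site.
#' @param spurious_rate Poisson mean of tool-specific spurious sites per
#'   gene.
#' @param spurious_mean,spurious_sd spurious-site energy distribution.
#' @param seed mandatory integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_mirnas = 25, sites_per_gene = 6,
                       energy_mean = -8, energy_sd = 3,
                       expr_meanlog = log(500), expr_sdlog = 2,
                       expr_floor = 50,
                       expression_scale = 1e-10, RT = 0.6163,
                       label_quantile = 0.25,
                       noise_sd = 1.5, dropout = 0.2,
                       spurious_rate = 6, spurious_mean = -4,
                       spurious_sd = 2, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_genes >= 10, n_mirnas >= 1, sites_per_gene >= 0,
            energy_sd >= 0, expr_sdlog >= 0, expr_floor > 0,
            label_quantile > 0, label_quantile <= 0.5,
            noise_sd >= 0, dropout >= 0, dropout < 1,
            spurious_rate >= 0, spurious_sd >= 0)
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              sites_per_gene = sites_per_gene,
              energy_mean = energy_mean, energy_sd = energy_sd,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              expr_floor = expr_floor,
              thermo = thermo_config(RT = RT,
                                     expression_scale = expression_scale),
              label_quantile = label_quantile,
              noise_sd = noise_sd, dropout = dropout,
              spurious_rate = spurious_rate, spurious_mean = spurious_mean,
              spurious_sd = spurious_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))
mirna_ids <- function(n) sprintf("mir-%03d", seq_len(n))

#' Simulate a benchmark dataset with planted occupancy ground truth
#'
#' Draws the gene/site/expression population described by [sim_config()],
#' computes each gene's true Fermi-Dirac occupancy (the sum of site
#' occupancy probabilities under the configured thermodynamics), and
#' derives balanced labels: positives are the `n_genes * label_quantile`
#' genes with the highest occupancy; an equal number of negatives is
#' sampled from the genes at or below the `label_quantile` occupancy
#' quantile. Everything is reproducible from the seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `sites` (true [site_table()], tool `"truth"`, energy
#'   scores), `expression` ([mirna_expression()]), `labels` (`data.frame`
#'   of `gene_id`, `label`), `occupancy` (`data.frame` of `gene_id`,
#'   `occupancy` for every gene), `genes`, and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- gene_ids(cfg$n_genes)
  mirnas <- mirna_ids(cfg$n_mirnas)
  lev <- pmax(cfg$expr_floor,
              stats::rlnorm(cfg$n_mirnas, cfg$expr_meanlog, cfg$expr_sdlog))
  expr <- mirna_expression(mirnas, lev)

  tot <- stats::rpois(cfg$n_genes, cfg$sites_per_gene)
  g <- rep(genes, tot)
  m <- sample(mirnas, length(g), replace = TRUE)
  E <- pmin(0, stats::rnorm(length(g), cfg$energy_mean, cfg$energy_sd))
  start <- unlist(lapply(tot, function(k) if (k) 40L * seq_len(k) else integer()))
  sites <- site_table(gene_id = g, mirna_id = m, start = start,
                      end = start + 7L, tool = "truth", score = E)

  occ_tab <- gene_scores(sites, expr, method = "fd", config = cfg$thermo,
                         genes = genes)
  occ <- stats::setNames(occ_tab$score, occ_tab$gene_id)

  n_per_class <- floor(cfg$n_genes * cfg$label_quantile)
  if (n_per_class < 1) stop("label_quantile too small for n_genes")
  ord <- order(-occ, names(occ))
  pos <- names(occ)[ord[seq_len(n_per_class)]]
  bottom <- names(occ)[occ <= stats::quantile(occ, cfg$label_quantile,
                                              names = FALSE)]
  bottom <- setdiff(bottom, pos)
  if (length(bottom) < n_per_class)
    stop("infeasible class balance: only ", length(bottom),
         " bottom-quantile genes for ", n_per_class, " negatives")
  neg <- sort(sample(bottom, n_per_class))
  labels <- data.frame(gene_id = c(pos, neg),
                       label = rep(c(1L, 0L), each = n_per_class),
                       stringsAsFactors = FALSE)
  list(sites = sites, expression = expr, labels = labels,
       occupancy = data.frame(gene_id = genes, occupancy = unname(occ[genes]),
                              stringsAsFactors = FALSE),
       genes = genes, config = cfg)
}

#' Simulate four noisy per-tool site tables from a planted truth
#'
#' Each simulated tool observes the true sites with independent dropout
#' and score noise and adds its own spurious weak sites, so that tools
#' agree on the strong shared signal but disagree on the rest:
#'
#' * `energy_a`, `energy_b`: energies (kcal/mol; Fermi-Dirac path);
#' * `score_c`: binary detector, every reported site scored 1
#'   (weighted-sum path);
#' * `score_d`: positive continuous scores increasing with site strength
#'   (weighted-sum path).
#'
#' @param truth a [simulate_dataset()] result.
#' @param cfg the same [sim_config()]; the tool draw is seeded from
#'   `cfg$seed` (offset so it does not replay the population draw).
#' @return named list of four [site_table()]s, with an attribute
#'   `methods` mapping each tool to its intended combination method.
#' @export
simulate_tool_scores <- function(truth, cfg = truth$config) {
  stopifnot(inherits(cfg, "sim_config"))
  sites <- truth$sites
  genes <- truth$genes
  set.seed(cfg$seed + 1000L)
  observe_energy <- function(tool) {
    keep <- stats::runif(nrow(sites)) >= cfg$dropout
    s <- sites[keep, , drop = FALSE]
    s$score <- pmin(0, s$score + stats::rnorm(nrow(s), 0, cfg$noise_sd))
    ns <- stats::rpois(length(genes), cfg$spurious_rate)
    sg <- rep(genes, ns)
    spur <- site_table(gene_id = sg,
                       mirna_id = sample(mirna_ids(cfg$n_mirnas),
                                         length(sg), replace = TRUE),
                       start = 13L + 40L * unlist(lapply(ns, seq_len)),
                       end = 20L + 40L * unlist(lapply(ns, seq_len)),
                       tool = rep(tool, length(sg)),
                       score = pmin(0, stats::rnorm(length(sg),
                                                    cfg$spurious_mean,
                                                    cfg$spurious_sd)))
    s$tool <- tool
    out <- rbind(s, spur)
    out[order(out$gene_id, out$mirna_id, out$start), , drop = FALSE]
  }
  to_positive <- function(s, binary) {
    if (binary) s$score <- rep(1, nrow(s))
    else s$score <- pmax(0.05, -s$score / abs(cfg$energy_mean) +
                           stats::rnorm(nrow(s), 0, cfg$noise_sd /
                                          abs(cfg$energy_mean)))
    s
  }
  tools <- list(energy_a = observe_energy("energy_a"),
                energy_b = observe_energy("energy_b"),
                score_c = to_positive(observe_energy("score_c"), binary = TRUE),
                score_d = to_positive(observe_energy("score_d"), binary = FALSE))
  attr(tools, "methods") <- c(energy_a = "fd", energy_b = "fd",
                              score_c = "wsum", score_d = "wsum")
  tools
}

#' Per-tool combined gene scores for a simulated dataset
#'
#' Scores each simulated tool's site table over the full gene universe with
#' either its intended expression-aware method (FD for the energy tools,
#' weighted sum for the score tools) or the expression-blind naive sum.
#'
#' @param tool_tables a [simulate_tool_scores()] result.
#' @param truth the matching [simulate_dataset()] result.
#' @param naive use the naive combiner for every tool instead.
#' @return named list of score `data.frame`s, ready for
#'   [build_feature_matrix()].
#' @export
score_simulated_tools <- function(tool_tables, truth, naive = FALSE) {
  methods <- attr(tool_tables, "methods")
  out <- lapply(names(tool_tables), function(tl) {
    if (naive)
      gene_scores(tool_tables[[tl]], method = "naive", genes = truth$genes)
    else
      gene_scores(tool_tables[[tl]], truth$expression,
                  method = methods[[tl]], config = truth$config$thermo,
                  genes = truth$genes)
  })
  names(out) <- names(tool_tables)
  out
}

#' Simulate transfection fold changes with a planted interaction
#'
#' Generates per-gene log fold changes for two single-miRNA perturbations
#' and their co-perturbation,
#' `FC_lm = intercept + a FC_l + b FC_m + c FC_l FC_m + noise`, for testing
#' the additivity regression: with `c = 0` regulation is exactly additive.
#'
#' @param n_genes number of genes.
#' @param a,b,c planted coefficients.
#' @param noise_sd sd of the additive noise on `FC_lm`.
#' @param seed integer seed.
#' @param intercept planted intercept.
#' @return list with vectors `fc_l`, `fc_m`, `fc_lm` and the planted
#'   `coefficients`.
#' @export
simulate_transfection_fc <- function(n_genes, a, b, c, noise_sd, seed,
                                     intercept = 0) {
  set.seed(seed)
  fc_l <- stats::rnorm(n_genes, -0.3, 1)
  fc_m <- stats::rnorm(n_genes, -0.3, 1)
  fc_lm <- intercept + a * fc_l + b * fc_m + c * fc_l * fc_m +
    stats::rnorm(n_genes, 0, noise_sd)
  list(fc_l = fc_l, fc_m = fc_m, fc_lm = fc_lm,
       coefficients = c(intercept = intercept, a = a, b = b, c = c))
}
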