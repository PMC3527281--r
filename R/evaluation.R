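#' ROC curve and AUC
#'
#' Builds the ROC curve by thresholding at every distinct score and
#' computes the area under it by trapezoidal integration, which equals
#' `P(score_pos > score_neg) + 0.5 * P(tie)` over random positive/negative
#' pairs.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 (or logical) labels; both classes required.
#' @return an object of class `roc_result`: list with `points`
#'   (`data.frame` of `fpr`, `tpr`, monotone non-decreasing), `auc`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(3, 2, 1, 0.5), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties: threshold only between distinct score values
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]; fp <- cumsum(1 - y)[grp_end]
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Paired comparison of two AUCs
#'
#' Tests whether two score vectors for the same items (and the same labels)
#' differ in AUC, either with DeLong's paired test or with a paired
#' bootstrap (items resampled jointly; normal approximation on the
#' bootstrap distribution of the AUC difference).
#'
#' @param scoresA,scoresB numeric score vectors on the same items.
#' @param labels shared 0/1 labels.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples (>= 2000 recommended).
#' @param seed seed for the bootstrap resampling.
#' @return list with `auc_a`, `auc_b`, `difference`, `p_value`, `method`,
#'   and `degenerate` (`TRUE` when the variance of the difference is zero,
#'   in which case `p_value` is 1 for a zero difference and NA otherwise).
#' @export
compare_auc <- function(scoresA, scoresB, labels,
                        method = c("delong", "bootstrap"),
                        n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  if (length(scoresA) != length(labels) || length(scoresB) != length(labels))
    stop("scores and labels differ in length")
  auc_a <- roc_auc(scoresA, labels)$auc
  auc_b <- roc_auc(scoresB, labels)$auc
  d_obs <- auc_a - auc_b
  if (identical(as.numeric(scoresA), as.numeric(scoresB)))
    return(list(auc_a = auc_a, auc_b = auc_b, difference = 0, p_value = 1,
                method = method, degenerate = TRUE))
  if (method == "delong") {
    ra <- pROC::roc(labels, scoresA, quiet = TRUE, direction = "<")
    rb <- pROC::roc(labels, scoresB, quiet = TRUE, direction = "<")
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    p <- as.numeric(tst$p.value)
    degen <- !is.finite(p)
    if (degen) p <- if (abs(d_obs) < .Machine$double.eps^0.5) 1 else NA_real_
    list(auc_a = auc_a, auc_b = auc_b, difference = d_obs, p_value = p,
         method = "delong", degenerate = degen)
  } else {
    set.seed(seed)
    n <- length(labels)
    diffs <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2) return(NA_real_)
      roc_auc(scoresA[idx], labels[idx])$auc -
        roc_auc(scoresB[idx], labels[idx])$auc
    })
    diffs <- diffs[is.finite(diffs)]
    s <- stats::sd(diffs)
    if (!is.finite(s) || s == 0)
      return(list(auc_a = auc_a, auc_b = auc_b, difference = d_obs,
                  p_value = if (d_obs == 0) 1 else NA_real_,
                  method = "bootstrap", degenerate = TRUE))
    z <- d_obs / s
    list(auc_a = auc_a, auc_b = auc_b, difference = d_obs,
         p_value = 2 * stats::pnorm(-abs(z)), method = "bootstrap",
         degenerate = FALSE)
  }
}

#' Precision-recall curve
#'
#' Thresholds at every distinct score (ties grouped) and reports precision
#' and recall at each, plus the area under the curve by trapezoidal
#' integration over recall.
#'
#' @inheritParams roc_auc
#' @return list with `points` (`data.frame` of `recall`, `precision`,
#'   `threshold`) and `area`.
#' @export
precision_recall_curve <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels))
    stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  n_called <- grp_end
  points <- data.frame(recall = tp / n_pos, precision = tp / n_called,
                       threshold = s[grp_end])
  r <- points$recall; p <- points$precision
  if (length(r) == 1) area <- p[1] * r[1]
  else area <- sum(diff(c(0, r)) * (p + c(p[1], utils::head(p, -1))) / 2)
  list(points = points, area = area)
}

#' Fraction of positives called versus score threshold
#'
#' For datasets with a trusted positive set but no usable negative set:
#' at each threshold, the fraction of positive-set genes whose score is at
#' least the threshold. The summary area is computed by trapezoidal
#' integration over the (normalized) threshold grid. This is flagged as
#' not a standard ROC: without negatives it measures sensitivity only.
#'
#' @param scores_all scores of the whole gene set (named or not); used to
#'   build the default threshold grid.
#' @param scores_pos scores of the positive set (a subset of the whole
#'   set's genes).
#' @param grid optional numeric threshold grid; default: all distinct
#'   values of `scores_all`.
#' @return list with `points` (`threshold`, `fraction`), `area`, and
#'   `not_standard_roc = TRUE`.
#' @export
sensitivity_vs_threshold <- function(scores_all, scores_pos, grid = NULL) {
  if (length(scores_pos) == 0) stop("empty positive score set")
  if (is.null(grid)) grid <- sort(unique(scores_all))
  grid <- sort(grid)
  frac <- vapply(grid, function(th) mean(scores_pos >= th), numeric(1))
  span <- diff(range(grid))
  area <- if (length(grid) < 2 || span == 0) mean(frac)
          else sum(diff(grid) / span *
                   (utils::head(frac, -1) + utils::tail(frac, -1)) / 2)
  list(points = data.frame(threshold = grid, fraction = frac),
       area = area, not_standard_roc = TRUE)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability that a random draw of `n_predicted` genes from a
#' universe of `n_universe` (containing `n_set` genes of interest) overlaps
#' the set in at least `n_overlap` genes: `P(X >= n_overlap)` for
#' hypergeometric X.
#'
#' @param n_universe universe size.
#' @param n_set genes of interest in the universe.
#' @param n_predicted genes drawn (predicted targets).
#' @param n_overlap observed overlap.
#' @return p-value in (0, 1\].
#' @examples
#' enrichment_pvalue(10, 5, 5, 5)  # 1/252
#' @export
enrichment_pvalue <- function(n_universe, n_set, n_predicted, n_overlap) {
  v <- c(n_universe, n_set, n_predicted, n_overlap)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (n_set > n_universe || n_predicted > n_universe)
    stop("set and prediction sizes cannot exceed the universe")
  if (n_overlap > min(n_set, n_predicted))
    stop("overlap cannot exceed min(set, predicted)")
  stats::phyper(n_overlap - 1, n_set, n_universe - n_set, n_predicted,
                lower.tail = FALSE)
}

#' Decile-wise ECDF comparison against a reference gene set
#'
#' Scored genes are split into deciles by prediction score (decile 1 =
#' highest scores) and each decile's per-gene measure (e.g. log2 fold
#' change after miRNA perturbation) is compared with the measure of a
#' disjoint reference gene set using the two-sample Kolmogorov-Smirnov
#' distance and the two-sided Wilcoxon rank-sum test. A well-behaved
#' predictor concentrates the signal in decile 1.
#'
#' @param scores named numeric prediction scores per gene.
#' @param measure named numeric per-gene measure covering the scored and
#'   reference genes.
#' @param reference_genes character vector, disjoint from the scored genes.
#' @return a `data.frame`, one row per decile: `decile`, `n`, `mean`,
#'   `sdm` (standard error of the mean), `ks_d`, `ks_p`, `wilcox_p`,
#'   `flagged` (`TRUE` when the decile has fewer than 3 genes; tests are
#'   then skipped and reported NA).
#' @export
decile_ecdf_analysis <- function(scores, measure, reference_genes) {
  if (is.null(names(scores)) || is.null(names(measure)))
    stop("scores and measure must be named by gene")
  if (length(intersect(names(scores), reference_genes)))
    stop("reference genes must be disjoint from the scored genes")
  ref <- measure[reference_genes]
  if (any(is.na(ref))) stop("measure missing for some reference genes")
  m <- measure[names(scores)]
  if (any(is.na(m))) stop("measure missing for some scored genes")
  # decile 1 = highest scores; ties resolved by first-occurrence rank
  dec <- ceiling(rank(-scores, ties.method = "first") / (length(scores) / 10))
  dec <- pmin(dec, 10L)
  out <- lapply(1:10, function(d) {
    v <- m[dec == d]
    n <- length(v)
    flagged <- n < 3
    if (flagged) {
      data.frame(decile = d, n = n,
                 mean = if (n) mean(v) else NA_real_,
                 sdm = NA_real_, ks_d = NA_real_, ks_p = NA_real_,
                 wilcox_p = NA_real_, flagged = TRUE)
    } else {
      ks <- suppressWarnings(stats::ks.test(v, ref))
      w <- suppressWarnings(stats::wilcox.test(v, ref))
      data.frame(decile = d, n = n, mean = mean(v),
                 sdm = stats::sd(v) / sqrt(n),
                 ks_d = unname(ks$statistic), ks_p = ks$p.value,
                 wilcox_p = w$p.value, flagged = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Additivity regression with backward elimination
#'
#' Linear model of the co-perturbation fold change on the two single
#' perturbations and their interaction,
#' `FC_lm ~ intercept + a * FC_l + b * FC_m + c * FC_l * FC_m`, pruned by
#' backward elimination: while the least significant slope has p > `alpha`
#' it is removed (the interaction before its main effects). Additive
#' regulation shows up as the interaction term being eliminated with a
#' negligible drop in R-squared.
#'
#' With a numerically perfect fit (residual variance at machine precision)
#' t-statistics are meaningless; a slope is then retained only when its
#' contribution to the fitted values is above numerical noise.
#'
#' @param fc_l,fc_m,fc_lm aligned per-gene fold-change vectors (>= 10
#'   genes).
#' @param alpha significance threshold for retaining a term.
#' @return an object of class `additivity_fit`: coefficients of the final
#'   model, `r2_full`, `r2_reduced`, the elimination `trace` (term, p-value
#'   at removal, R-squared after removal), and `collinear` flag.
#' @export
additivity_regression <- function(fc_l, fc_m, fc_lm, alpha = 0.05) {
  n <- length(fc_lm)
  if (length(fc_l) != n || length(fc_m) != n)
    stop("fold-change vectors must be aligned")
  if (n < 10) stop("at least 10 genes are required")
  dat <- data.frame(fc_l = fc_l, fc_m = fc_m, fc_lm = fc_lm)
  collinear <- FALSE
  qx <- qr(cbind(1, fc_l, fc_m, fc_l * fc_m))
  if (qx$rank < 4) {
    collinear <- TRUE
    warning("collinear predictors: design matrix rank ", qx$rank, " < 4")
  }
  terms_now <- c("fc_l", "fc_m", "fc_l:fc_m")
  fit_formula <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    stats::lm(stats::as.formula(paste("fc_lm ~", rhs)), data = dat)
  }
  r2 <- function(fit) suppressWarnings(summary(fit)$r.squared)
  term_p <- function(fit, terms) {
    if (!length(terms)) return(numeric(0))
    cf <- suppressWarnings(summary(fit)$coefficients)
    # numerically perfect fit: decide by contribution, not by t-statistic
    if (r2(fit) > 1 - 1e-12) {
      contrib <- vapply(terms, function(tm) {
        xv <- if (tm == "fc_l:fc_m") dat$fc_l * dat$fc_m else dat[[tm]]
        abs(cf[tm, "Estimate"]) * stats::sd(xv)
      }, numeric(1))
      scale_y <- max(stats::sd(dat$fc_lm), .Machine$double.eps)
      return(ifelse(contrib / scale_y < 1e-8, 1, 0))
    }
    p <- rep(1, length(terms))          # aliased/dropped terms: no evidence
    names(p) <- terms
    found <- intersect(terms, rownames(cf))
    p[found] <- cf[found, "Pr(>|t|)"]
    p[is.na(p)] <- 1
    p
  }
  full <- fit_formula(terms_now)
  r2_full <- r2(full)
  fit <- full
  trace <- data.frame(term = character(), p_value = numeric(),
                      r2_after = numeric(), stringsAsFactors = FALSE)
  repeat {
    removable <- terms_now
    if ("fc_l:fc_m" %in% terms_now)           # marginality: mains stay while
      removable <- "fc_l:fc_m"                # the interaction is in
    p <- term_p(fit, removable)
    if (!length(p) || min(p) <= alpha) break
    drop_term <- removable[which.max(p)]
    terms_now <- setdiff(terms_now, drop_term)
    fit <- fit_formula(terms_now)
    trace <- rbind(trace, data.frame(term = drop_term, p_value = max(p),
                                     r2_after = r2(fit)))
  }
  structure(list(coefficients = stats::coef(fit), terms = terms_now,
                 r2_full = r2_full, r2_reduced = r2(fit), trace = trace,
                 alpha = alpha, collinear = collinear, model = fit),
            class = "additivity_fit")
}

#' @export
print.additivity_fit <- function(x, ...) {
  cat("Additivity regression (backward elimination, alpha =", x$alpha, ")\n")
  cat(sprintf("  R-squared: full = %.4f, reduced = %.4f\n",
              x$r2_full, x$r2_reduced))
  cat("  retained terms:", if (length(x$terms)) paste(x$terms, collapse = ", ")
                           else "(intercept only)", "\n")
  if (nrow(x$trace)) {
    cat("  eliminated:\n")
    print(x$trace, row.names = FALSE)
  }
  cat("  coefficients:\n")
  print(round(x$coefficients, 6))
  invisible(x)
}
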