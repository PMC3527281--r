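#' Assemble the gene-by-tool feature matrix
#'
#' Joins per-tool combined gene scores (from [gene_scores()]) into the dense
#' matrix consumed by the ensemble. Rows are the union of all gene ids,
#' columns the tool labels, both in lexicographic order. A gene absent from
#' a tool's table gets 0 in that cell ("no detected sites").
#'
#' @param tables a named list of `data.frame`s with `gene_id` and `score`
#'   columns; names are the tool labels and must be unique.
#' @return a numeric matrix with gene rownames and tool colnames.
#' @export
build_feature_matrix <- function(tables) {
  if (length(tables) == 0) stop("at least one score table is required")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("score tables must be named by tool label")
  if (anyDuplicated(names(tables)))
    stop("duplicate tool labels: ",
         paste(unique(names(tables)[duplicated(names(tables))]), collapse = ", "))
  genes <- sort(unique(unlist(lapply(tables, function(t) t$gene_id))))
  tools <- sort(names(tables))
  x <- matrix(0, nrow = length(genes), ncol = length(tools),
              dimnames = list(genes, tools))
  for (tl in tools) {
    t <- tables[[tl]]
    x[t$gene_id, tl] <- t$score
  }
  x
}

#' Fit the linear-SVM targeting ensemble
#'
#' Trains a linear support vector machine on a gene-by-tool feature matrix
#' of combined target scores against binary labels (1 = functional target),
#' and calibrates its decision values into probabilities. The fitted object
#' stores everything needed to score new datasets deterministically:
#'
#' * per-tool normalization maps fitted on the training scores (so scores
#'   computed on another dataset or species are first mapped onto the
#'   training distribution; see [fit_normalization()]);
#' * per-tool standardization (training mean/sd);
#' * the linear weights and bias of the SVM, oriented so that a larger
#'   decision value means a more likely target;
#' * a Platt-style sigmoid fitted to out-of-fold decision values, mapping
#'   decisions monotonically into \[0, 1\].
#'
#' @param x numeric feature matrix (genes x tools) with tool colnames, as
#'   from [build_feature_matrix()].
#' @param labels 0/1 vector (or logical), one per row of `x`; both classes
#'   must be present.
#' @param cost SVM regularization constant C.
#' @param seed integer seed controlling the SVM fit and the calibration
#'   folds; the fit is deterministic given the seed.
#' @param normalize normalization method recorded for prediction-time use.
#' @param calibration_folds folds of seeded cross-validation used to obtain
#'   unbiased decision values for the probability calibration.
#' @param methods optional named character vector giving, for each tool, the
#'   score-combination method that produced its column (`"fd"`, `"wsum"` or
#'   `"naive"`); stored as metadata and used by the variant-ranking
#'   pipeline.
#' @return an object of class `mir_ensemble` with `print`, `summary`,
#'   `coef` and `predict` methods.
#' @examples
#' set.seed(1)
#' x <- cbind(toolA = rnorm(60), toolB = rnorm(60))
#' rownames(x) <- sprintf("g%02d", 1:60)
#' y <- as.integer(x[, 1] + x[, 2] + rnorm(60, sd = 0.3) > 0)
#' fit <- fit_ensemble(x, y, seed = 7)
#' head(predict(fit, x))
#' @export
fit_ensemble <- function(x, labels, cost = 1, seed = 1L,
                         normalize = c("rank", "mean", "none"),
                         calibration_folds = 3L, methods = NULL) {
  normalize <- match.arg(normalize)
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature matrix must have tool colnames")
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(labels) != nrow(x)) stop("labels and feature rows differ in length")
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the training labels")
  if (!is.null(methods)) {
    if (is.null(names(methods)) || !setequal(names(methods), colnames(x)))
      stop("methods must be named by the feature-matrix tools")
    methods <- methods[colnames(x)]
  }

  norm <- lapply(colnames(x), function(tl)
    fit_normalization(x[, tl], method = normalize, tool = tl))
  names(norm) <- colnames(x)
  # training scores are their own reference: rank/none leave them unchanged,
  # mean rescales to its own mean (identity); normalize here for symmetry
  # with prediction time.
  xn <- x
  for (tl in colnames(x)) xn[, tl] <- apply_normalization(norm[[tl]], x[, tl])

  center <- colMeans(xn)
  scl <- apply(xn, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(xn, 2, center), 2, scl, "/")

  y <- factor(labels, levels = c(0, 1))
  set.seed(seed)
  svm_fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(crossprod(svm_fit$coefs, svm_fit$SV))
  names(w) <- colnames(x)
  b <- -svm_fit$rho
  d_train <- as.numeric(xs %*% w) + b
  # orient the decision axis toward class 1
  if (stats::cor(d_train, labels) < 0) {
    w <- -w; b <- -b; d_train <- -d_train
  }

  # out-of-fold decision values for Platt calibration
  k <- max(2L, min(as.integer(calibration_folds), min(table(labels))))
  set.seed(seed + 1L)
  fold <- sample(rep_len(seq_len(k), nrow(xs)))
  d_cv <- numeric(nrow(xs))
  ok <- TRUE
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2) { ok <- FALSE; break }
    m_f <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    w_f <- as.numeric(crossprod(m_f$coefs, m_f$SV))
    d_f <- as.numeric(xs[!tr, , drop = FALSE] %*% w_f) - m_f$rho
    if (stats::cor(as.numeric(xs[tr, , drop = FALSE] %*% w_f) - m_f$rho,
                   labels[tr]) < 0) d_f <- -d_f
    d_cv[!tr] <- d_f
  }
  d_cal <- if (ok) d_cv else d_train
  platt <- suppressWarnings(
    stats::glm(labels ~ d_cal, family = stats::binomial()))
  a_cal <- unname(stats::coef(platt)[2])
  b_cal <- unname(stats::coef(platt)[1])
  if (!is.finite(a_cal) || a_cal <= 0) {
    # degenerate calibration sample (e.g. constant decisions): fall back to
    # a unit-slope logistic link, which is still monotone in the decision.
    a_cal <- 1; b_cal <- 0
  }

  structure(list(tools = colnames(x), weights = w, bias = b,
                 platt = c(slope = a_cal, intercept = b_cal),
                 center = center, scale = scl, normalization = norm,
                 normalize_method = normalize, methods = methods,
                 cost = cost, seed = as.integer(seed),
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0),
                 n_sv = nrow(svm_fit$SV)),
            class = "mir_ensemble")
}

# shared feature -> decision plumbing; reconciles tool order by label
ensemble_decision <- function(object, newdata, renormalize = TRUE) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) stop("feature matrix must have tool colnames")
  missing_t <- setdiff(object$tools, colnames(x))
  extra_t <- setdiff(colnames(x), object$tools)
  if (length(missing_t) || length(extra_t))
    stop("feature tools do not match the model's tools; missing: {",
         paste(missing_t, collapse = ", "), "}, unexpected: {",
         paste(extra_t, collapse = ", "), "}")
  x <- x[, object$tools, drop = FALSE]
  if (renormalize)
    for (tl in object$tools)
      x[, tl] <- apply_normalization(object$normalization[[tl]], x[, tl])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.numeric(xs %*% object$weights) + object$bias
}

#' Predict targeting probabilities from a fitted ensemble
#'
#' Scores a gene-by-tool feature matrix with a fitted [fit_ensemble()]
#' model. Columns are matched to the model's tools by label (any order);
#' per-tool normalization and standardization stored in the model are
#' applied first. Probabilities are the calibrated class-1 probabilities,
#' in \[0, 1\] and monotone in the SVM decision value.
#'
#' @param object a `mir_ensemble`.
#' @param newdata feature matrix with tool colnames.
#' @param type `"prob"` for calibrated probabilities (default) or
#'   `"decision"` for raw decision values.
#' @param renormalize apply the stored per-tool normalization maps to
#'   `newdata` (default). Set to `FALSE` when scoring features already on
#'   the training scale.
#' @param ... unused.
#' @return named numeric vector (gene rownames preserved).
#' @export
predict.mir_ensemble <- function(object, newdata,
                                 type = c("prob", "decision"),
                                 renormalize = TRUE, ...) {
  type <- match.arg(type)
  d <- ensemble_decision(object, newdata, renormalize = renormalize)
  out <- if (type == "prob")
    stats::plogis(object$platt[["slope"]] * d + object$platt[["intercept"]])
  else d
  names(out) <- rownames(newdata)
  out
}

#' @export
coef.mir_ensemble <- function(object, ...) {
  c(object$weights, `(bias)` = object$bias)
}

#' @export
print.mir_ensemble <- function(x, ...) {
  cat("Linear-SVM targeting ensemble\n")
  cat("  tools:", paste(x$tools, collapse = ", "), "\n")
  cat(sprintf("  training: %d positives / %d negatives, C = %g, seed = %d\n",
              x$n_pos, x$n_neg, x$cost, x$seed))
  cat("  normalization:", x$normalize_method, "\n")
  cat("  weights (standardized scale):\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
summary.mir_ensemble <- function(object, ...) {
  cat("Linear-SVM targeting ensemble\n\n")
  cat(sprintf("Training set: %d positives, %d negatives (%d support vectors)\n",
              object$n_pos, object$n_neg, object$n_sv))
  cat(sprintf("Regularization C = %g; seed = %d; normalization = %s\n\n",
              object$cost, object$seed, object$normalize_method))
  tab <- data.frame(tool = object$tools,
                    weight = unname(object$weights),
                    center = unname(object$center),
                    sd = unname(object$scale))
  if (!is.null(object$methods)) tab$method <- unname(object$methods)
  print(tab, row.names = FALSE)
  cat(sprintf("\nbias = %.4f; calibration: p = plogis(%.3f * d %+.3f)\n",
              object$bias, object$platt[["slope"]], object$platt[["intercept"]]))
  invisible(object)
}

#' Serialize a fitted ensemble to JSON
#'
#' Writes every component needed to reproduce predictions (tool order,
#' weights, bias, calibration, standardization, normalization references,
#' seed) to a versioned JSON file. [read_ensemble()] restores a model whose
#' predictions are identical to the original's.
#'
#' @param model a `mir_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(model, path) {
  stopifnot(inherits(model, "mir_ensemble"))
  payload <- list(
    schema = "mir_ensemble/1",
    tools = model$tools,
    weights = as.list(model$weights),
    bias = model$bias,
    platt = as.list(model$platt),
    center = as.list(model$center),
    scale = as.list(model$scale),
    normalize_method = model$normalize_method,
    normalization = lapply(model$normalization, function(nm)
      list(method = nm$method, tool = nm$tool,
           reference = nm$reference, ref_mean = nm$ref_mean)),
    methods = if (is.null(model$methods)) NULL else as.list(model$methods),
    cost = model$cost, seed = model$seed,
    n_pos = model$n_pos, n_neg = model$n_neg, n_sv = model$n_sv)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a fitted ensemble from JSON
#'
#' @param path a file written by [write_ensemble()].
#' @return a `mir_ensemble`.
#' @export
read_ensemble <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "mir_ensemble/1"))
    stop("unrecognized model schema: ", p$schema)
  norm <- lapply(p$normalization, function(nm)
    structure(list(method = nm$method,
                   reference = if (is.null(nm$reference)) NULL else as.numeric(nm$reference),
                   ref_mean = if (is.null(nm$ref_mean)) NULL else as.numeric(nm$ref_mean),
                   tool = nm$tool), class = "score_norm"))
  structure(list(tools = p$tools,
                 weights = unlist(p$weights)[p$tools],
                 bias = p$bias,
                 platt = unlist(p$platt),
                 center = unlist(p$center)[p$tools],
                 scale = unlist(p$scale)[p$tools],
                 normalization = norm[p$tools],
                 normalize_method = p$normalize_method,
                 methods = if (is.null(p$methods)) NULL else unlist(p$methods)[p$tools],
                 cost = p$cost, seed = as.integer(p$seed),
                 n_pos = p$n_pos, n_neg = p$n_neg, n_sv = p$n_sv),
            class = "mir_ensemble")
}
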