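#' Fit a cross-dataset score normalization
#'
#' Per-tool gene scores computed on different datasets or species live on
#' different scales (different 3'UTR lengths, miRNA sets, expression units).
#' Before an ensemble trained on one dataset is applied to another, each
#' tool's scores are mapped onto the training (reference) distribution.
#'
#' Two maps are supported: `"rank"` replaces each score by the reference
#' quantile at its empirical quantile (a quantile-matching transform that
#' preserves order exactly, ties sharing their average rank), and `"mean"`
#' rescales scores so their mean equals the reference mean. `"none"` is the
#' identity.
#'
#' @param reference numeric reference scores (non-empty, finite).
#' @param method `"rank"`, `"mean"` or `"none"`.
#' @param tool optional tool label stored in the map.
#' @return an object of class `score_norm`.
#' @seealso [apply_normalization()]
#' @export
fit_normalization <- function(reference, method = c("rank", "mean", "none"),
                              tool = NA_character_) {
  method <- match.arg(method)
  if (length(reference) == 0) stop("empty reference score vector")
  if (any(!is.finite(reference))) stop("reference scores must be finite")
  structure(list(method = method,
                 reference = if (method == "rank") sort(reference) else NULL,
                 ref_mean = if (method == "mean") mean(reference) else NULL,
                 tool = tool),
            class = "score_norm")
}

#' Apply a fitted score normalization
#'
#' @param map a [fit_normalization()] object.
#' @param scores numeric scores to transform.
#' @return transformed scores, same length and order as the input. The rank
#'   map is strictly order-preserving up to ties; applied to its own
#'   reference it reproduces the reference values.
#' @examples
#' m <- fit_normalization(c(10, 20, 30), "rank")
#' apply_normalization(m, c(1, 2, 3))  # 10 20 30
#' @export
apply_normalization <- function(map, scores) {
  if (!inherits(map, "score_norm")) stop("map must be a score_norm object")
  if (length(scores) == 0) return(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  switch(map$method,
    none = scores,
    mean = {
      m <- mean(scores)
      if (m == 0) stop("mean normalization undefined: input mean is 0")
      scores * (map$ref_mean / m)
    },
    rank = {
      n <- length(scores)
      p <- if (n == 1) 0.5 else (rank(scores, ties.method = "average") - 1) / (n - 1)
      stats::quantile(map$reference, probs = p, names = FALSE, type = 7)
    })
}

#' @export
print.score_norm <- function(x, ...) {
  cat("score normalization map: method =", x$method)
  if (!is.na(x$tool)) cat(", tool =", x$tool)
  if (x$method == "rank")
    cat(sprintf(", reference n = %d [%.3g, %.3g]",
                length(x$reference), min(x$reference), max(x$reference)))
  if (x$method == "mean") cat(sprintf(", reference mean = %.4g", x$ref_mean))
  cat("\n")
  invisible(x)
}
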