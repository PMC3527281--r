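#' Construct and validate a binding-site table
#'
#' A site table is the package's exchange format for predicted miRNA binding
#' sites: one row per predicted site of one miRNA on one gene's 3'UTR, as
#' emitted by an external target predictor or by [find_seed_sites()].
#'
#' Coordinates are 0-based half-open offsets within the gene's 3'UTR
#' (`end > start >= 0`). The `score` column carries the predictor's raw
#' value: for energy-based predictors a free energy of binding in kcal/mol
#' (finite, typically negative); for score-based predictors a value oriented
#' so that larger means a stronger site.
#'
#' @param gene_id,mirna_id character identifiers.
#' @param start,end integer 0-based half-open site coordinates.
#' @param tool label of the originating predictor.
#' @param score numeric site score or energy; must be finite.
#' @param ... further columns carried along (e.g. a seed-match `class`).
#' @return A `data.frame` with (at least) columns `gene_id`, `mirna_id`,
#'   `start`, `end`, `tool`, `score`.
#' @examples
#' site_table(gene_id = "g1", mirna_id = "miR-1", start = 10L, end = 17L,
#'            tool = "energyA", score = -8.2)
#' @export
site_table <- function(gene_id = character(), mirna_id = character(),
                       start = integer(), end = integer(),
                       tool = character(), score = numeric(), ...) {
  df <- data.frame(gene_id = as.character(gene_id),
                   mirna_id = as.character(mirna_id),
                   start = as.integer(start), end = as.integer(end),
                   tool = as.character(tool), score = as.numeric(score),
                   ..., stringsAsFactors = FALSE)
  validate_site_table(df)
}

#' Validate a binding-site table
#'
#' Checks the structural invariants of a site table: required columns,
#' `end > start >= 0`, finite scores, and uniqueness of
#' `(gene_id, mirna_id, start, end, tool)`.
#'
#' @param sites a data.frame as produced by [site_table()].
#' @return `sites`, invisibly unchanged, or an error.
#' @export
validate_site_table <- function(sites) {
  req <- c("gene_id", "mirna_id", "start", "end", "tool", "score")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols))
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(sites) == 0) return(sites)
  if (any(!is.finite(sites$score)))
    stop("site table contains non-finite scores")
  if (any(sites$start < 0) || any(sites$end <= sites$start))
    stop("site coordinates must satisfy end > start >= 0 (0-based half-open)")
  key <- paste(sites$gene_id, sites$mirna_id, sites$start, sites$end,
               sites$tool, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, miRNA, start, end, tool) rows in site table")
  sites
}

#' Construct a miRNA expression table
#'
#' Abundance levels per miRNA, e.g. small-RNA read counts. Levels set the
#' chemical potential of the occupancy model and the relative weights of the
#' weighted-sum combiner, so they must be strictly positive and unique per
#' miRNA.
#'
#' @param mirna_id character miRNA identifiers (unique).
#' @param level strictly positive abundances.
#' @return A `data.frame` with columns `mirna_id` and `level`.
#' @examples
#' mirna_expression(c("miR-1", "miR-2"), c(120, 3500))
#' @export
mirna_expression <- function(mirna_id, level) {
  mirna_id <- as.character(mirna_id)
  level <- as.numeric(level)
  if (length(mirna_id) != length(level))
    stop("mirna_id and level differ in length")
  if (anyDuplicated(mirna_id))
    stop("duplicate mirna_id in expression table: ",
         paste(unique(mirna_id[duplicated(mirna_id)]), collapse = ", "))
  bad <- !is.finite(level) | level <= 0
  if (any(bad))
    stop("expression level must be finite and > 0; offending miRNA(s): ",
         paste(mirna_id[bad], collapse = ", "))
  data.frame(mirna_id = mirna_id, level = level, stringsAsFactors = FALSE)
}

# named numeric vector of levels from an expression table (or pass-through
# for an already-named vector)
expr_levels <- function(expr) {
  if (is.numeric(expr) && !is.null(names(expr))) return(expr)
  stopifnot(is.data.frame(expr), all(c("mirna_id", "level") %in% names(expr)))
  stats::setNames(expr$level, expr$mirna_id)
}

#' Thermodynamic configuration for occupancy scoring
#'
#' @param RT thermal energy in kcal/mol; the default corresponds to
#'   R = 1.987e-3 kcal/(mol K) at 310.15 K (37 C). Sets the sharpness of
#'   the occupancy transition around the chemical potential.
#' @param expression_scale global factor applied to abundance levels before
#'   taking the logarithm that defines the chemical potential. Abundances
#'   are often in arbitrary units (read counts); this factor converts them
#'   to effective activities. The chemical potential shifts additively with
#'   `RT * log(expression_scale)`.
#' @return A list of class `thermo_config`.
#' @examples
#' thermo_config()                      # physiological RT, unit scale
#' thermo_config(expression_scale = 1e-10)
#' @export
thermo_config <- function(RT = 0.6163, expression_scale = 1) {
  if (!is.numeric(RT) || length(RT) != 1 || !is.finite(RT) || RT <= 0)
    stop("RT must be a single finite value > 0 (kcal/mol)")
  if (!is.numeric(expression_scale) || length(expression_scale) != 1 ||
      !is.finite(expression_scale) || expression_scale <= 0)
    stop("expression_scale must be a single finite value > 0")
  structure(list(RT = RT, expression_scale = expression_scale),
            class = "thermo_config")
}
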