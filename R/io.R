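# ---- metadata headers ----------------------------------------------------
# Every emitted file starts with '#'-prefixed metadata lines (version,
# config hash, seed) so a run can be audited and reproduced.

# tiny rolling polynomial hash of a character vector, for config fingerprints
config_hash <- function(...) {
  x <- paste(unlist(list(...)), collapse = "|")
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

meta_lines <- function(seed = NA, extra = character()) {
  c(paste0("# mircombine ", as.character(utils::packageVersion("mircombine"))),
    paste0("# seed: ", seed),
    paste0("# config: ", config_hash(seed, extra)),
    if (length(extra)) paste0("# ", extra))
}

write_tsv_meta <- function(df, path, seed = NA, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(seed = seed, extra = extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path, colClasses = NA) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE)
}

# ---- FASTA ---------------------------------------------------------------

#' Load 3'UTR sequences from a FASTA file
#'
#' Reads a FASTA of 3'UTRs (DNA or RNA), parses the gene id from the first
#' whitespace-delimited token of each header, keeps the longest isoform per
#' gene (first by file order on an exact length tie), and drops sequences
#' shorter than `min_length`. Filter counts are reported via `message()`.
#'
#' @param path FASTA file path.
#' @param min_length minimum UTR length retained (default 50 nt).
#' @return named character vector of RNA sequences (names = gene ids).
#' @export
load_utrs <- function(path, min_length = 50) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  sq <- chartr("tT", "uU", toupper(as.character(seqs)))
  names(sq) <- ids
  n_in <- length(sq)
  # longest isoform per gene; ties: first in file order
  ord <- order(factor(ids, levels = unique(ids)), -nchar(sq))
  sq <- sq[ord]
  dup <- duplicated(names(sq))
  if (any(dup))
    message(sum(dup), " shorter/duplicate isoform(s) dropped")
  sq <- sq[!dup]
  short <- nchar(sq) < min_length
  if (any(short))
    message(sum(short), " UTR(s) shorter than ", min_length, " nt dropped")
  sq <- sq[!short]
  message(length(sq), " of ", n_in, " UTR records kept")
  for (g in names(sq)) utr_sequence(g, sq[[g]])  # alphabet validation
  sq
}

#' Write UTR sequences to FASTA
#'
#' @param utrs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_utrs <- function(utrs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(utrs)) {
    writeLines(paste0(">", g), con)
    s <- utrs[[g]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Load mature miRNA sequences from FASTA
#'
#' Like [load_utrs()] but with no length filter and no isoform collapsing;
#' duplicate ids are an error.
#'
#' @param path FASTA file path.
#' @return named character vector of RNA sequences.
#' @export
load_mirnas <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate miRNA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(chartr("tT", "uU", toupper(as.character(seqs))), ids)
}

# ---- TSV tables ----------------------------------------------------------

#' Load a miRNA expression table
#'
#' Reads a TSV with header columns `mirna_id` and `level`, drops miRNAs
#' below `min_level` (boundary inclusive: a level equal to `min_level` is
#' kept), and validates the result. Non-numeric levels are reported with
#' their line number.
#'
#' @param path TSV path ('#' metadata lines are skipped).
#' @param min_level minimum abundance retained (default 50, the usual
#'   read-count floor for calling a miRNA expressed).
#' @return a [mirna_expression()] table.
#' @export
load_expression <- function(path, min_level = 50) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("mirna_id", "level") %in% names(raw)))
    stop("expression table must have columns mirna_id and level")
  lev <- suppressWarnings(as.numeric(raw$level))
  if (any(is.na(lev))) {
    first_bad <- which(is.na(lev))[1]
    stop("non-numeric expression level '", raw$level[first_bad],
         "' at data line ", first_bad, " of ", path)
  }
  if (anyDuplicated(raw$mirna_id))
    stop("duplicate mirna_id in ", path, ": ",
         paste(unique(raw$mirna_id[duplicated(raw$mirna_id)]), collapse = ", "))
  keep <- lev >= min_level
  if (any(!keep))
    message(sum(!keep), " miRNA(s) below the expression floor of ",
            min_level, " dropped")
  message(sum(keep), " of ", length(lev), " miRNAs kept")
  mirna_expression(raw$mirna_id[keep], lev[keep])
}

#' Read a binding-site table from TSV
#'
#' @param path TSV with header columns `gene_id`, `mirna_id`, `start`,
#'   `end`, `tool`, `score` ('#' metadata lines are skipped).
#' @return a validated [site_table()].
#' @export
read_site_table <- function(path) {
  df <- read_tsv_meta(path)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$score <- as.numeric(df$score)
  validate_site_table(df)
}

#' Write a binding-site table to TSV
#'
#' @param sites a [site_table()].
#' @param path output path.
#' @param seed seed recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path, seed = NA) {
  validate_site_table(sites)
  write_tsv_meta(sites, path, seed = seed,
                 extra = paste0("tool: ", paste(unique(sites$tool),
                                                collapse = ",")))
}

#' Write a miRNA expression table to TSV
#' @param expr a [mirna_expression()] table.
#' @param path output path.
#' @param seed seed recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, seed = NA) {
  write_tsv_meta(expr, path, seed = seed)
}

#' Read a gene label table from TSV
#' @param path TSV with header columns `gene_id` and `label` (0/1).
#' @return a `data.frame`.
#' @export
read_labels <- function(path) {
  df <- read_tsv_meta(path)
  if (!all(c("gene_id", "label") %in% names(df)))
    stop("label table must have columns gene_id and label")
  df$label <- as.integer(df$label)
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0/1")
  df
}

#' Read a SNP table from TSV
#'
#' @param path TSV with header columns `snp_id`, `gene_id`, `pos` (0-based
#'   offset within the 3'UTR), `ref`, `alt`, and optionally `maf`.
#' @param min_maf optional minor-allele-frequency filter; rows with
#'   `maf <= min_maf` (or missing `maf`) are dropped when set.
#' @return list of [snp_record()]s.
#' @export
read_snp_table <- function(path, min_maf = NULL) {
  df <- read_tsv_meta(path)
  req <- c("snp_id", "gene_id", "pos", "ref", "alt")
  if (!all(req %in% names(df)))
    stop("SNP table must have columns: ", paste(req, collapse = ", "))
  if (!"maf" %in% names(df)) df$maf <- NA_real_
  if (!is.null(min_maf)) {
    keep <- !is.na(df$maf) & df$maf > min_maf
    message(sum(!keep), " SNP(s) dropped by MAF filter (> ", min_maf, ")")
    df <- df[keep, , drop = FALSE]
  }
  lapply(seq_len(nrow(df)), function(i)
    snp_record(df$snp_id[i], df$gene_id[i], df$pos[i], df$ref[i],
               df$alt[i], df$maf[i]))
}

#' Write a gene score table to TSV
#'
#' @param scores a `data.frame` from [gene_scores()].
#' @param path output path.
#' @param seed seed recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, seed = NA) {
  extra <- c(paste0("method: ", attr(scores, "method")),
             paste0("tool: ", paste(attr(scores, "tool"), collapse = ",")))
  write_tsv_meta(scores, path, seed = seed, extra = extra)
}

#' Read a gene score table written by [write_scores()]
#'
#' Restores the `method` and `tool` attributes from the metadata header.
#'
#' @param path TSV path.
#' @return a `data.frame` with `gene_id` and `score`.
#' @export
read_scores <- function(path) {
  df <- read_tsv_meta(path)
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "# ")]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NA_character_
  }
  df$score <- as.numeric(df$score)
  attr(df, "method") <- get_field("method")
  attr(df, "tool") <- get_field("tool")
  df
}
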