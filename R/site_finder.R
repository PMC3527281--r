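#' A 3'UTR sequence
#'
#' Normalizes and validates one 3'UTR: upper-cased, DNA `T` mapped to `U`,
#' alphabet restricted to A/C/G/U. Coordinates elsewhere in the package are
#' 0-based half-open offsets into this sequence.
#'
#' @param gene_id gene identifier.
#' @param seq character scalar, the 5'->3' UTR sequence (DNA or RNA).
#' @return a list of class `utr_sequence` with `gene_id`, `seq` (RNA,
#'   uppercase) and `length`.
#' @examples
#' utr_sequence("g1", "acguACGT")
#' @export
utr_sequence <- function(gene_id, seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- chartr("tT", "uU", toupper(seq))
  if (nchar(s) < 1) stop("empty UTR sequence for gene ", gene_id)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0)
    stop("invalid character '", substr(s, bad, bad), "' at 0-based offset ",
         bad - 1, " in UTR of gene ", gene_id)
  structure(list(gene_id = as.character(gene_id), seq = s,
                 length = nchar(s)),
            class = "utr_sequence")
}

#' @export
print.utr_sequence <- function(x, ...) {
  preview <- if (x$length > 40) paste0(substr(x$seq, 1, 40), "...") else x$seq
  cat(sprintf("3'UTR %s (%d nt): %s\n", x$gene_id, x$length, preview))
  invisible(x)
}

# reverse complement of an RNA string (strict Watson-Crick)
rna_revcomp <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# complement of a single RNA base
rna_comp <- function(b) chartr("ACGU", "UGCA", b)

#' Seed-match specification
#'
#' Defines which canonical seed-site classes the scanner reports and the
#' surrogate energy assigned to each. Classes follow the standard seed
#' nomenclature (miRNA positions counted 5'->3'):
#'
#' * `8mer` - Watson-Crick match to positions 2-8 plus `A` opposite
#'   position 1;
#' * `7mer-m8` - match to positions 2-8;
#' * `7mer-A1` - match to positions 2-7 plus `A` opposite position 1;
#' * `6mer` - match to positions 2-7.
#'
#' Surrogate scores are energy-oriented (more negative = stronger) so that
#' scanned sites feed directly into the occupancy combiner; users with real
#' per-site energies supply them through a site table instead.
#'
#' @param classes subset of the four class names, in any order; at least
#'   one.
#' @param scores named numeric surrogate energies per class.
#' @return a list of class `seed_match_spec`.
#' @export
seed_match_spec <- function(classes = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                            scores = c("8mer" = -1, "7mer-m8" = -0.75,
                                       "7mer-A1" = -0.75, "6mer" = -0.5)) {
  all_classes <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  classes <- match.arg(classes, all_classes, several.ok = TRUE)
  if (length(classes) == 0) stop("at least one seed class must be enabled")
  if (!all(classes %in% names(scores)))
    stop("scores must cover every enabled class")
  structure(list(classes = intersect(all_classes, classes),  # priority order
                 scores = scores),
            class = "seed_match_spec")
}

#' Scan a 3'UTR for canonical miRNA seed matches
#'
#' Reports every UTR window whose sequence is the Watson-Crick reverse
#' complement of the miRNA seed per the enabled classes (no G:U wobble;
#' sense strand only). A window qualifying for several classes is reported
#' once at the highest-priority class (8mer > 7mer-m8 > 7mer-A1 > 6mer);
#' overlapping matches at different offsets are each reported.
#'
#' Coordinates are 0-based half-open and cover the full matched window
#' (including the m8-pairing base and/or the A opposite position 1 where
#' those define the class).
#'
#' @param utr a [utr_sequence()] (or `gene_id`/`seq` pair via
#'   [utr_sequence()] coercion of a character scalar named by `gene_id`).
#' @param mirna_seq mature miRNA sequence 5'->3', length >= 8 (DNA or RNA).
#' @param mirna_id identifier recorded in the output.
#' @param spec a [seed_match_spec()].
#' @param tool tool label recorded in the output.
#' @return a [site_table()] with an extra `class` column; zero rows when no
#'   window matches.
#' @examples
#' utr <- utr_sequence("g1", paste0(strrep("C", 30), "AACAUUCCA", strrep("C", 20)))
#' find_seed_sites(utr, "ugaauguuacaugu", "miR-x")
#' @export
find_seed_sites <- function(utr, mirna_seq, mirna_id = "miRNA",
                            spec = seed_match_spec(), tool = "seedscan") {
  if (!inherits(utr, "utr_sequence"))
    stop("utr must be a utr_sequence object")
  if (!inherits(spec, "seed_match_spec"))
    stop("spec must be a seed_match_spec object")
  m <- chartr("tT", "uU", toupper(mirna_seq))
  if (nchar(m) < 8) stop("miRNA sequence must be at least 8 nt")
  if (regexpr("[^ACGU]", m) > 0) stop("invalid character in miRNA sequence")

  core <- rna_revcomp(substr(m, 2, 7))      # matches miRNA positions 2-7
  m8 <- rna_comp(substr(m, 8, 8))           # pairs miRNA position 8
  s <- utr$seq
  L <- utr$length

  starts <- integer(); ends <- integer(); classes <- character()
  hit <- gregexpr(core, s, fixed = TRUE)[[1]]
  # fixed-pattern gregexpr skips overlapping hits; rescan manually
  pos <- integer()
  if (hit[1] != -1) {
    i <- 1
    while (i <= L - 5) {
      if (substr(s, i, i + 5) == core) pos <- c(pos, i)
      i <- i + 1
    }
  }
  for (i in pos) {               # 1-based start of the 6-nt core
    s0 <- i - 1                  # 0-based
    m8_ok <- s0 >= 1 && substr(s, i - 1, i - 1) == m8
    a_ok <- s0 + 6 <= L - 1 && substr(s, i + 6, i + 6) == "A"
    qual <- c("8mer"[m8_ok && a_ok], "7mer-m8"[m8_ok], "7mer-A1"[a_ok], "6mer")
    cls <- intersect(spec$classes, qual)     # spec$classes is priority-ordered
    if (length(cls) == 0) next
    cls <- cls[1]
    win <- switch(cls,
      "8mer"    = c(s0 - 1, s0 + 7),
      "7mer-m8" = c(s0 - 1, s0 + 6),
      "7mer-A1" = c(s0, s0 + 7),
      "6mer"    = c(s0, s0 + 6))
    starts <- c(starts, win[1]); ends <- c(ends, win[2])
    classes <- c(classes, cls)
  }
  if (length(starts) == 0)
    return(site_table(class = character()))
  site_table(gene_id = utr$gene_id, mirna_id = mirna_id,
             start = starts, end = ends, tool = tool,
             score = unname(spec$scores[classes]), class = classes)
}

#' Scan a set of UTRs against a set of miRNAs
#'
#' Convenience wrapper over [find_seed_sites()] for every (UTR, miRNA)
#' pair.
#'
#' @param utrs named character vector of UTR sequences (names = gene ids),
#'   or a list of [utr_sequence()] objects.
#' @param mirna_seqs named character vector of mature miRNA sequences.
#' @param spec a [seed_match_spec()].
#' @param tool tool label recorded in the output.
#' @return a combined [site_table()].
#' @export
scan_seed_sites <- function(utrs, mirna_seqs, spec = seed_match_spec(),
                            tool = "seedscan") {
  if (is.character(utrs)) {
    if (is.null(names(utrs))) stop("utrs must be named by gene id")
    utrs <- Map(utr_sequence, names(utrs), utrs)
  }
  if (is.null(names(mirna_seqs))) stop("mirna_seqs must be named")
  out <- list()
  for (u in utrs)
    for (mi in names(mirna_seqs))
      out[[length(out) + 1L]] <- find_seed_sites(u, mirna_seqs[[mi]],
                                                 mirna_id = mi, spec = spec,
                                                 tool = tool)
  res <- do.call(rbind, out)
  if (is.null(res)) site_table(class = character()) else res
}
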