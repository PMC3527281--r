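# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain arithmetic, exhaustive enumeration,
# O(n^2) pairwise comparison, and a naive sliding-window sequence scan.

# brute-force Fermi-Dirac gene score: per-site 1/(1+exp((E-mu)/RT)) summed
# with a plain loop
oracle_fd_score <- function(E, level, RT, expression_scale = 1) {
  total <- 0
  for (j in seq_along(E)) {
    mu_j <- RT * log(expression_scale * level[j])
    total <- total + 1 / (1 + exp((E[j] - mu_j) / RT))
  }
  unname(total)
}

# exhaustive pairwise AUC: P(pos > neg) + 0.5 P(tie)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# exhaustive hypergeometric upper tail P(X >= k) via binomial coefficients
oracle_hyper_upper <- function(n_universe, n_set, n_predicted, k) {
  ks <- k:min(n_set, n_predicted)
  sum(choose(n_set, ks) * choose(n_universe - n_set, n_predicted - ks)) /
    choose(n_universe, n_predicted)
}

# naive sliding-window seed scan, independent of the package scanner.
# Returns data.frame(start, end, class) using the same class priority.
oracle_seed_scan <- function(utr_seq, mirna_seq,
                             classes = c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
  comp1 <- function(b) c(A = "U", C = "G", G = "C", U = "A")[[b]]
  rc <- function(x) paste(rev(vapply(strsplit(x, "")[[1]], comp1, "")),
                          collapse = "")
  u <- chartr("tT", "uU", toupper(utr_seq))
  m <- chartr("tT", "uU", toupper(mirna_seq))
  core <- rc(substr(m, 2, 7))
  m8 <- comp1(substr(m, 8, 8))
  L <- nchar(u)
  out <- data.frame(start = integer(), end = integer(), class = character())
  for (s0 in 0:(L - 6)) {                      # 0-based core start
    if (substr(u, s0 + 1, s0 + 6) != core) next
    m8_ok <- s0 >= 1 && substr(u, s0, s0) == m8
    a_ok <- s0 + 6 < L && substr(u, s0 + 7, s0 + 7) == "A"
    qual <- c(if (m8_ok && a_ok) "8mer", if (m8_ok) "7mer-m8",
              if (a_ok) "7mer-A1", "6mer")
    cls <- intersect(c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                     intersect(classes, qual))
    if (!length(cls)) next
    cls <- cls[1]
    win <- switch(cls,
                  "8mer" = c(s0 - 1, s0 + 7), "7mer-m8" = c(s0 - 1, s0 + 6),
                  "7mer-A1" = c(s0, s0 + 7), "6mer" = c(s0, s0 + 6))
    out <- rbind(out, data.frame(start = win[1], end = win[2], class = cls))
  }
  out
}

# random site table for one or more genes (energy-oriented scores)
random_site_table <- function(n_sites, genes = "g1",
                              mirnas = c("mir-a", "mir-b", "mir-c"),
                              tool = "energy_a") {
  site_table(gene_id = sample(genes, n_sites, replace = TRUE),
             mirna_id = sample(mirnas, n_sites, replace = TRUE),
             start = 10L * seq_len(n_sites),
             end = 10L * seq_len(n_sites) + 7L,
             tool = tool,
             score = -round(runif(n_sites, 0.5, 15), 3))
}

# random RNA string
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
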