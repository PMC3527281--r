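rc <- function(x) paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]),
                        collapse = "")

mir_hi <- "UGAGGUAGUAGGUUGUAUAGUU"
# a UTR whose only site for mir_hi is a planted 7mer-m8 at offset 30
planted_utr <- function(gene = "gX") {
  utr_sequence(gene, paste0(strrep("C", 30), rc(substr(mir_hi, 2, 8)), "G",
                            strrep("C", 15)))
}

test_that("SNP substitution validates coordinates and the reference base", {
  utr <- planted_utr()
  snp <- snp_record("rs1", "gX", 33L, utr_char <- substr(utr$seq, 34, 34),
                    if (utr_char == "C") "G" else "C")
  mut <- apply_snp(utr, snp)
  expect_equal(mut$length, utr$length)
  diffs <- which(strsplit(utr$seq, "")[[1]] != strsplit(mut$seq, "")[[1]])
  expect_equal(diffs, 34)                        # exactly one position (1-based)
  # wrong ref base reports the observed one
  bad <- snp_record("rs2", "gX", 33L, "A", "G")
  expect_error(apply_snp(utr, bad), "observed")
  expect_error(apply_snp(utr, snp_record("rs3", "gX", 1000L, "C", "G")),
               "outside")
  expect_error(apply_snp(utr, snp_record("rs4", "gOther", 3L, "C", "G")),
               "gOther")
  expect_error(snp_record("rs5", "g", 3L, "C", "C"), "differ")
})

test_that("a SNP outside every predicted site scores delta 0 exactly", {
  utr <- planted_utr()
  far <- snp_record("rs_far", "gX", 5L, "C", "A")   # in the poly-C spacer
  d <- suppressWarnings(snp_delta_score(utr, far, c(hi = mir_hi)))
  expect_identical(d$delta, 0)
  expect_identical(d$P_ref, d$P_alt)
})

test_that("disrupting a high-expression miRNA's site outranks the low-expression case", {
  utr <- planted_utr()
  # the SNP hits the planted seed match (core spans offsets 31..36)
  hit <- snp_record("rs_hit", "gX", 33L, substr(utr$seq, 34, 34), "G")
  expr_hi <- mirna_expression("hi", 100)
  expr_lo <- mirna_expression("hi", 0.05)
  d_hi <- snp_delta_score(utr, hit, c(hi = mir_hi), expr = expr_hi)
  d_lo <- snp_delta_score(utr, hit, c(hi = mir_hi), expr = expr_lo)
  expect_gt(d_hi$P_ref, d_lo$P_ref)     # occupancy rises with abundance
  expect_equal(d_hi$P_alt, 0)           # site destroyed
  expect_gt(d_hi$delta, d_lo$delta)
  # plain mode antisymmetry: swapping ref and alt negates the difference
  mut <- apply_snp(utr, hit)
  back <- snp_record("rs_back", "gX", 33L, "G", hit$ref)
  d_fwd <- snp_delta_score(utr, hit, c(hi = mir_hi), expr = expr_hi,
                           mode = "plain")
  d_rev <- snp_delta_score(mut, back, c(hi = mir_hi), expr = expr_hi,
                           mode = "plain")
  expect_equal(d_fwd$delta, -d_rev$delta)
})

test_that("weighted mode up-weights high-confidence reference targets", {
  # fixed probability drop, increasing P_ref -> increasing weighted delta
  p_ref <- seq(0.3, 0.9, by = 0.1)
  delta <- p_ref * (p_ref - (p_ref - 0.2))
  expect_true(all(diff(delta) > 0))
  # and the package's weighted score follows the same law end to end
  utr <- planted_utr()
  hit <- snp_record("rs_hit", "gX", 33L, substr(utr$seq, 34, 34), "G")
  for (lv in c(0.2, 2, 200)) {
    d <- snp_delta_score(utr, hit, c(hi = mir_hi),
                         expr = mirna_expression("hi", lv))
    expect_equal(d$delta, d$P_ref * (d$P_ref - d$P_alt))
  }
})

test_that("missing expression falls back to uniform levels with a warning", {
  utr <- planted_utr()
  hit <- snp_record("rs_hit", "gX", 33L, substr(utr$seq, 34, 34), "G")
  expect_warning(d <- snp_delta_score(utr, hit, c(hi = mir_hi)),
                 "uniform")
  expect_true(d$P_ref > 0)
})

test_that("ranking filters by threshold and breaks ties lexicographically", {
  rec <- data.frame(snp_id = c("s1", "s2", "s3", "s2", "s1"),
                    mirna_id = c("mB", "mA", "mA", "mB", "mA"),
                    P_ref = 0.9, P_alt = 0.5,
                    delta = c(0.05, 0.005, 0.02, 0.05, 0.05),
                    mode = "weighted", stringsAsFactors = FALSE)
  r <- rank_snp_mirna_pairs(rec, threshold = 0.01)
  expect_equal(nrow(r), 4)
  expect_equal(r$delta, c(0.05, 0.05, 0.05, 0.02))
  # exact ties ordered by (snp_id, mirna_id)
  expect_equal(r$snp_id[1:3], c("s1", "s1", "s2"))
  expect_equal(r$mirna_id[1:3], c("mA", "mB", "mB"))
  expect_equal(r$rank, 1:4)
  # all below threshold -> empty
  expect_equal(nrow(rank_snp_mirna_pairs(rec, threshold = 1)), 0)
  rec$mode[1] <- "plain"
  expect_error(rank_snp_mirna_pairs(rec), "mixed")
})

test_that("an ensemble model can drive the variant scoring pipeline", {
  set.seed(31)
  n <- 120
  x <- cbind(toolA = rnorm(n), toolB = rnorm(n))
  rownames(x) <- sprintf("g%03d", 1:n)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  fit <- fit_ensemble(x, y, seed = 6,
                      methods = c(toolA = "fd", toolB = "wsum"))
  utr <- planted_utr()
  hit <- snp_record("rs_hit", "gX", 33L, substr(utr$seq, 34, 34), "G")
  d <- snp_delta_score(utr, hit, c(hi = mir_hi),
                       expr = mirna_expression("hi", 100), model = fit)
  expect_true(all(c(d$P_ref, d$P_alt) >= 0 & c(d$P_ref, d$P_alt) <= 1))
  expect_gt(d$P_ref, d$P_alt)   # site destruction lowers the probability
})
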