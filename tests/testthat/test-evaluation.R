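test_that("ROC handles perfect, inverted, and tied scores", {
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 0)
  # curve points are monotone and anchored at (0,0) and (1,1)
  set.seed(10)
  r <- roc_auc(rnorm(50), rbinom(50, 1, 0.4))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the exhaustive pairwise probability", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(8:30, 1)
    scores <- round(rnorm(n), 1)            # coarse grid forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("paired AUC comparison detects real differences and not identical scores", {
  set.seed(15)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  good <- y + rnorm(n, 0, 0.2)              # near-perfect separation
  noise <- rnorm(n)
  same <- compare_auc(noise, noise, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  dl <- compare_auc(good, noise, y, method = "delong")
  expect_lt(dl$p_value, 0.01)
  expect_gt(dl$difference, 0.3)
  bs <- compare_auc(good, noise, y, method = "bootstrap", seed = 2)
  expect_lt(bs$p_value, 0.01)
  # the two tests agree to within an order of magnitude on a moderate case
  mid <- y * 0.8 + rnorm(n)
  p_d <- compare_auc(mid, noise, y, method = "delong")$p_value
  p_b <- compare_auc(mid, noise, y, method = "bootstrap", seed = 3)$p_value
  expect_lt(abs(log10(p_d) - log10(p_b)), 1)
})

test_that("precision-recall curve matches brute-force threshold enumeration", {
  # perfect classifier: precision 1 at every achieved recall below 1
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(6, 5, 4, 3, 2, 1)
  pr <- precision_recall_curve(s, y)
  expect_true(all(pr$points$precision[pr$points$recall <= 1 &
                                      pr$points$threshold >= 4] == 1))
  expect_gte(pr$area, 0.99)
  # all scores equal: a single point at precision = prevalence
  flat <- precision_recall_curve(rep(2, 10), rep(c(1, 0), 5))
  expect_equal(nrow(flat$points), 1)
  expect_equal(flat$points$precision, 0.5)
  expect_equal(flat$points$recall, 1)
  # small instance against direct enumeration over distinct thresholds
  set.seed(3)
  s2 <- round(runif(15), 1)
  y2 <- rbinom(15, 1, 0.5)
  pr2 <- precision_recall_curve(s2, y2)
  for (i in seq_len(nrow(pr2$points))) {
    th <- pr2$points$threshold[i]
    called <- s2 >= th
    expect_equal(pr2$points$precision[i], sum(y2[called]) / sum(called))
    expect_equal(pr2$points$recall[i], sum(y2[called]) / sum(y2))
  }
})

test_that("positives-only sensitivity curve is a flagged, hand-checkable summary", {
  all_s <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  pos_s <- c(8, 9, 10)
  sv <- sensitivity_vs_threshold(all_s, pos_s, grid = c(0, 8.5, 11))
  expect_identical(sv$points$fraction, c(1, 2 / 3, 0))
  expect_true(sv$not_standard_roc)
  sv2 <- sensitivity_vs_threshold(all_s, pos_s, grid = c(5, 7.5, 9.5))
  expect_identical(sv2$points$fraction, c(1, 1, 1 / 3))
  expect_error(sensitivity_vs_threshold(all_s, numeric()), "empty")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(enrichment_pvalue(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(enrichment_pvalue(10, 5, 5, 5),
               oracle_hyper_upper(10, 5, 5, 5), tolerance = 1e-12)
  expect_equal(enrichment_pvalue(1000, 10, 0, 0), 1)
  # overlap at its expectation sits in the mid-range, not significant
  p_mid <- enrichment_pvalue(60, 20, 30, 10)   # E[X] = 10
  expect_gt(p_mid, 0.05)
  expect_lt(p_mid, 0.7)
  expect_error(enrichment_pvalue(10, 5, 5, 6), "overlap")
  expect_error(enrichment_pvalue(10, 50, 5, 2), "universe")
})

test_that("decile ECDF analysis localizes a planted shift in the top decile", {
  set.seed(6)
  genes <- sprintf("g%04d", 1:500)
  ref_genes <- sprintf("r%03d", 1:150)
  scores <- setNames(rnorm(500), genes)
  measure <- setNames(rnorm(500), genes)
  top <- names(sort(scores, decreasing = TRUE))[1:50]
  measure[top] <- measure[top] - 1.5           # decile 1 strongly shifted
  measure <- c(measure, setNames(rnorm(150), ref_genes))
  out <- decile_ecdf_analysis(scores, measure, ref_genes)
  expect_equal(nrow(out), 10)
  expect_equal(out$n, rep(50, 10))
  expect_equal(which.max(out$ks_d), 1)
  expect_lt(out$ks_p[1], 1e-6)
  expect_lt(out$wilcox_p[1], 1e-6)
  # a decile drawn from the reference distribution has small D
  expect_lt(min(out$ks_d[-1]), 0.2)
  expect_error(decile_ecdf_analysis(scores, measure, genes[1]), "disjoint")
})

test_that("small deciles are flagged and their tests skipped", {
  scores <- setNames(rnorm(15), sprintf("g%02d", 1:15))
  measure <- c(scores * 0 + rnorm(15), setNames(rnorm(20), sprintf("r%02d", 1:20)))
  out <- decile_ecdf_analysis(scores, measure, sprintf("r%02d", 1:20))
  expect_true(any(out$flagged))
  expect_true(all(is.na(out$ks_p[out$flagged])))
})

test_that("noiseless additive fold changes are recovered exactly, interaction pruned", {
  sim <- simulate_transfection_fc(100, a = 0.5, b = 0.3, c = 0,
                                  noise_sd = 0, seed = 12, intercept = 0.1)
  fit <- additivity_regression(sim$fc_l, sim$fc_m, sim$fc_lm)
  expect_false("fc_l:fc_m" %in% fit$terms)
  expect_equal(unname(fit$coefficients["fc_l"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["fc_m"]), 0.3, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0.1, tolerance = 1e-8)
  expect_equal(fit$r2_reduced, 1, tolerance = 1e-10)
})

test_that("a planted interaction is retained and pure noise collapses to the intercept", {
  sim <- simulate_transfection_fc(500, a = 0.5, b = 0.3, c = 0.5,
                                  noise_sd = 0.1, seed = 4)
  fit <- additivity_regression(sim$fc_l, sim$fc_m, sim$fc_lm)
  expect_true("fc_l:fc_m" %in% fit$terms)
  expect_equal(unname(fit$coefficients["fc_l:fc_m"]), 0.5, tolerance = 0.1)
  noise <- simulate_transfection_fc(300, a = 0, b = 0, c = 0,
                                    noise_sd = 1, seed = 2)
  fit0 <- additivity_regression(noise$fc_l, noise$fc_m, noise$fc_lm)
  expect_length(fit0$terms, 0)
  expect_lte(fit0$r2_reduced, fit0$r2_full)
  # elimination trace records each removal with its p-value
  expect_equal(sort(fit0$trace$term),
               sort(c("fc_l", "fc_m", "fc_l:fc_m")))
  expect_true(all(fit0$trace$p_value > 0.05))
})

test_that("collinear inputs are reported, not silently fitted", {
  x <- rnorm(50)
  expect_warning(additivity_regression(x, 2 * x, x + rnorm(50, 0, 0.1)),
                 "collinear")
  expect_error(additivity_regression(1:5, 1:5, 1:5), "at least 10")
})
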