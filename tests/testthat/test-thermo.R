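test_that("chemical potential is RT ln(level), increasing, and guards its domain", {
  expect_equal(chemical_potential(1, RT = 0.6163), 0)
  expect_equal(chemical_potential(exp(2), RT = 0.5), 1)
  lv <- c(1, 10, 100, 1e6)
  expect_true(all(diff(chemical_potential(lv, RT = 0.6163)) > 0))
  expect_error(chemical_potential(0, mirna_id = "mir-x"), "mir-x")
  expect_error(chemical_potential(-3), "> 0")
  expect_error(chemical_potential(1, RT = 0), "RT")
})

test_that("occupancy probability obeys the Fermi-Dirac identities", {
  RT <- 0.6163
  expect_equal(fd_site_probability(-8, -8, RT), 0.5)
  expect_equal(fd_site_probability(-8 - RT * log(3), -8, RT), 0.75)
  expect_equal(fd_site_probability(Inf, 0, RT), 0)
  expect_equal(fd_site_probability(-Inf, 0, RT), 1)
  # strict monotonicity: decreasing in E, increasing in mu
  E <- seq(-20, 5, length.out = 101)
  expect_true(all(diff(fd_site_probability(E, -8, RT)) < 0))
  mus <- seq(-15, 0, length.out = 101)
  expect_true(all(diff(fd_site_probability(-8, mus, RT)) > 0))
  # bounded and stable far into both tails
  p <- fd_site_probability(c(-1e4, 1e4) * RT, 0, RT)
  expect_identical(p, c(1, 0))
  expect_true(all(fd_site_probability(rnorm(50, -8, 5), -8, RT) >= 0))
  expect_error(fd_site_probability(-8, -8, RT = -1), "RT")
})

test_that("gene occupancy score matches a brute-force per-site sum", {
  cfg <- thermo_config()
  expect_equal(fd_gene_score(site_table(), mirna_expression("a", 1), cfg), 0)
  # sites exactly at their miRNA's chemical potential contribute 1/2 each
  lev <- c(a = 20, b = 500)
  mu <- 0.6163 * log(lev)
  s <- site_table(gene_id = "g", mirna_id = c("a", "a", "b"),
                  start = c(0, 10, 20), end = c(7, 17, 27),
                  tool = "t", score = mu[c("a", "a", "b")])
  expect_equal(fd_gene_score(s, mirna_expression(names(lev), lev), cfg), 1.5)
  # random instances against the independent oracle
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    mir <- sample(c("a", "b", "c"), n, replace = TRUE)
    E <- -runif(n, 0, 15)
    lv <- c(a = runif(1, 1, 1e4), b = runif(1, 1, 1e4), c = runif(1, 1, 1e4))
    st <- site_table(gene_id = "g", mirna_id = mir, start = 10 * seq_len(n),
                     end = 10 * seq_len(n) + 7, tool = "t", score = E)
    expect_equal(fd_gene_score(st, mirna_expression(names(lv), lv),
                               thermo_config(expression_scale = 1e-3)),
                 oracle_fd_score(E, lv[mir], 0.6163, 1e-3),
                 tolerance = 1e-13)
  }
})

test_that("occupancy score is monotone in expression, energy, and additive over sites", {
  set.seed(7)
  cfg <- thermo_config(expression_scale = 1e-2)
  st <- random_site_table(10)
  lv <- c("mir-a" = 50, "mir-b" = 500, "mir-c" = 5000)
  base <- fd_gene_score(st, mirna_expression(names(lv), lv), cfg)
  # raising any one miRNA's level cannot lower the score; raising all
  # strictly increases it (finite-energy sites present)
  for (m in names(lv)) {
    lv2 <- lv; lv2[m] <- lv2[m] * 10
    expect_gte(fd_gene_score(st, mirna_expression(names(lv2), lv2), cfg), base)
  }
  expect_gt(fd_gene_score(st, mirna_expression(names(lv), lv * 5), cfg), base)
  # lowering every energy raises the score
  st2 <- st; st2$score <- st2$score - 1
  expect_gt(fd_gene_score(st2, mirna_expression(names(lv), lv), cfg), base)
  # additivity over a disjoint split
  idx <- sample(c(TRUE, FALSE), nrow(st), replace = TRUE)
  expect_equal(fd_gene_score(st[idx, ], mirna_expression(names(lv), lv), cfg) +
                 fd_gene_score(st[!idx, ], mirna_expression(names(lv), lv), cfg),
               base)
  # bounded by the site count
  expect_lte(base, nrow(st))
  expect_gte(base, 0)
})

test_that("sites of unexpressed miRNAs are dropped with a warning", {
  st <- site_table(gene_id = "g", mirna_id = c("a", "zz"), start = c(0, 10),
                   end = c(7, 17), tool = "t", score = c(-5, -20))
  expr <- mirna_expression("a", 100)
  expect_warning(s1 <- fd_gene_score(st, expr), "zz")
  expect_equal(s1, fd_gene_score(st[1, ], expr))
})

test_that("naive combined score sums oriented site scores and ignores expression", {
  expect_equal(naive_gene_score(site_table()), 0)
  st <- site_table(gene_id = "g", mirna_id = c("a", "b"), start = c(0, 10),
                   end = c(7, 17), tool = "t", score = c(-5, -3))
  expect_equal(naive_gene_score(st), 8)            # energies negated
  st$score <- c(2, 3.5)
  expect_equal(naive_gene_score(st), 5.5)          # already oriented
  set.seed(11)
  r <- random_site_table(15)
  expect_equal(naive_gene_score(r), sum(-r$score))
})

test_that("top-fraction calling uses an inclusive boundary with ties", {
  set.seed(5)
  s20 <- setNames(sample(seq(1, 40, 2)), paste0("g", 1:20))
  top <- top_fraction_targets(s20, q = 0.1)
  expect_setequal(top, names(sort(s20, decreasing = TRUE))[1:2])
  expect_setequal(top_fraction_targets(s20, q = 1), names(s20))
  tied <- c(g1 = 1, g2 = 2, g3 = 2, g4 = 3)
  expect_setequal(top_fraction_targets(tied, q = 0.25), "g4")
  expect_setequal(top_fraction_targets(tied, q = 0.5), c("g2", "g3", "g4"))
  expect_error(top_fraction_targets(numeric()), "empty")
  expect_error(top_fraction_targets(tied, q = 0), "fraction")
})

test_that("vectorized gene scoring agrees with per-gene combiners and imputes 0", {
  set.seed(13)
  st <- random_site_table(40, genes = c("g1", "g2", "g3"))
  expr <- mirna_expression(c("mir-a", "mir-b", "mir-c"), c(60, 600, 6000))
  cfg <- thermo_config(expression_scale = 1e-2)
  tab <- gene_scores(st, expr, method = "fd", config = cfg,
                     genes = c("g1", "g2", "g3", "g4"))
  expect_equal(tab$gene_id, c("g1", "g2", "g3", "g4"))
  for (g in c("g1", "g2", "g3"))
    expect_equal(tab$score[tab$gene_id == g],
                 fd_gene_score(st[st$gene_id == g, ], expr, cfg))
  expect_equal(tab$score[tab$gene_id == "g4"], 0)
  ntab <- gene_scores(st, method = "naive", genes = "g2")
  expect_equal(ntab$score, naive_gene_score(st[st$gene_id == "g2", ]))
  expect_error(gene_scores(st, method = "fd"), "expression")
})

test_that("site tables reject malformed rows", {
  expect_error(site_table(gene_id = "g", mirna_id = "a", start = 5, end = 5,
                          tool = "t", score = -1), "half-open")
  expect_error(site_table(gene_id = "g", mirna_id = "a", start = 0, end = 7,
                          tool = "t", score = NaN), "finite")
  expect_error(site_table(gene_id = c("g", "g"), mirna_id = "a",
                          start = 0, end = 7, tool = "t", score = -1),
               "duplicate")
  expect_error(mirna_expression(c("a", "a"), c(1, 2)), "duplicate")
  expect_error(mirna_expression("a", 0), "a")
})
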