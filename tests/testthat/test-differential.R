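test_that("tc_diff computes FC, exact binomial p and status calls", {
  # symmetric pair: FC = 1, maximal p, unchanged
  a <- make_tc(100, 50, min_tags = 4L)
  b <- make_tc(100, 50, min_tags = 4L)
  d <- tc_diff(a, b)
  expect_equal(d$fc, 1)
  expect_equal(d$p, 1)
  expect_equal(d$status, "unchanged")
  # one-sided clusters
  a2 <- make_tc(c(100, 500), c(100, 20), min_tags = 4L)
  b2 <- make_tc(500, 30, min_tags = 4L)
  d2 <- tc_diff(a2, b2)
  only <- d2[is.na(d2$id_b), ]
  expect_equal(only$status, "translatome_only")
  expect_true(is.na(only$fc))
  # 80 vs 20 with equal library sizes: log2 FC = 2, p = two-sided
  # binomial tail of Bin(100, 0.5) at 80
  a3 <- make_tc(100, 80, min_tags = 4L)
  b3 <- make_tc(100, 20, min_tags = 4L)
  a3$library_size <- 1e6; b3$library_size <- 1e6
  d3 <- tc_diff(a3, b3)
  expect_equal(d3$log2fc, 2)
  expect_equal(d3$p, bf_binom_two_sided(80, 100, 0.5), tolerance = 1e-12)
  expect_equal(d3$status, "enriched")
  # unequal library sizes shift the null success probability
  a4 <- make_tc(100, 30, min_tags = 4L); a4$library_size <- 2e6
  b4 <- make_tc(100, 30, min_tags = 4L); b4$library_size <- 1e6
  d4 <- tc_diff(a4, b4)
  expect_equal(d4$p, bf_binom_two_sided(30, 60, 2 / 3), tolerance = 1e-12)
  expect_equal(d4$fc, 0.5)
})

test_that("s_du matches its analytic edge cases", {
  expect_equal(s_du(c(100, 0), c(0, 50)), 1)
  expect_equal(s_du(c(50, 50), c(200, 200)), 0)
  expect_equal(s_du(c(50, 50), c(100, 0)), 0.5)
  expect_true(is.na(s_du(10, 20)))          # single promoter
  expect_true(is.na(s_du(c(0, 0), c(1, 2))))  # zero abundance on one side
  expect_error(s_du(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("s_du properties hold on random abundance vectors", {
  withr::local_seed(77)
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    p <- rgamma(n, 0.5); t <- rgamma(n, 0.5)
    v <- s_du(p, t)
    expect_gte(v, 0)
    expect_lte(v, 1)
    # equal proportions -> 0
    expect_equal(s_du(p, p * 3.7), 0, tolerance = 1e-12)
    # disjoint supports -> 1
    q <- c(p, rep(0, n)); r <- c(rep(0, n), t)
    expect_equal(s_du(q, r), 1, tolerance = 1e-12)
  }
})

test_that("gene scores aggregate promoters and test summed counts", {
  prom <- data.frame(gene = c("g1", "g1", "g2"),
                     id_a = c("a1", "a2", "a3"), id_b = c("b1", "b2", "b3"),
                     count_a = c(80, 20, 50), count_b = c(20, 30, 50),
                     rpm_a = c(80, 20, 50), rpm_b = c(20, 30, 50),
                     stringsAsFactors = FALSE)
  gs <- gene_scores(prom, c(1e6, 1e6))
  g1 <- gs[gs$gene == "g1", ]
  expect_equal(g1$E_p, 100)   # E_p is the sum of promoter RPMs
  expect_equal(g1$E_t, 50)
  expect_equal(g1$S_fc, 2)
  expect_equal(g1$p, bf_binom_two_sided(100, 150, 0.5), tolerance = 1e-12)
  expect_equal(g1$S_du, s_du(c(80, 20), c(20, 30)))
  g2 <- gs[gs$gene == "g2", ]
  expect_true(is.na(g2$S_du))  # single promoter
  expect_equal(g2$S_fc, 1)
})

test_that("matched group selection follows the three ranking rules", {
  # synthetic pool engineered so each rule selects known genes
  n <- 40
  gs <- data.frame(gene = sprintf("g%02d", 1:n),
                   E_t = seq(1000, 22, length.out = n),
                   S_fc = rep(1, n), p = rep(0.5, n),
                   significant = rep(FALSE, n), stringsAsFactors = FALSE)
  gs$S_fc[1:10] <- 3;   gs$p[1:10] <- seq(1e-10, 1e-6, length.out = 10)
  gs$significant[1:10] <- TRUE
  gs$S_fc[11:22] <- 0.3; gs$p[11:22] <- seq(1e-9, 1e-5, length.out = 12)
  gs$significant[11:22] <- TRUE
  gs$S_fc[23:40] <- 1.0  # unchanged band, ranked by E_t
  g <- select_matched_groups(gs, group_size = 5L)
  expect_equal(g$enriched, sprintf("g%02d", 1:5))
  # depleted: ranked 6th-10th by p among the S_fc < 0.5 genes
  expect_equal(g$depleted, sprintf("g%02d", 16:20))
  # unchanged: top by transcriptome abundance within the band
  expect_equal(g$unchanged, sprintf("g%02d", 23:27))
  expect_length(intersect(g$enriched, g$depleted), 0)
  expect_length(intersect(g$enriched, g$unchanged), 0)
  expect_true(all(is.finite(g$mean_rpm_t)))
  # insufficient pool -> warning and shorter group
  ws <- testthat::capture_warnings(g2 <- select_matched_groups(gs, group_size = 15L))
  expect_true(any(grepl("qualify", ws)))
  expect_lt(length(g2$enriched), 15L)
})

test_that("enrichment test matches the hypergeometric oracle", {
  fam <- data.frame(gene = c(sprintf("h%d", 1:5), sprintf("r%d", 1:10)),
                    family = c(rep("histone", 5), rep("ribosomal", 10)),
                    stringsAsFactors = FALSE)
  universe <- c(fam$gene, sprintf("x%d", 1:85))
  # query = all histones plus noise: histone family strongly enriched
  query <- c(sprintf("h%d", 1:5), "x1", "x2")
  et <- enrichment_test(query, fam, universe)
  his <- et[et$family == "histone", ]
  expect_equal(his$n_overlap, 5L)
  expect_equal(his$p, bf_fisher_p(5, 2, 0, 93), tolerance = 1e-10)
  expect_equal(his$odds_ratio, Inf)
  # disjoint query: odds ratio <= 1
  et2 <- enrichment_test(sprintf("x%d", 1:10), fam, universe)
  expect_true(all(et2$odds_ratio <= 1 | is.na(et2$odds_ratio)))
  expect_error(enrichment_test(query, fam, character(0)), "universe")
})

test_that("Fisher p-values are calibrated under label permutation", {
  withr::local_seed(202)
  fam <- data.frame(gene = sprintf("m%d", 1:20), family = "fam",
                    stringsAsFactors = FALSE)
  universe <- c(fam$gene, sprintf("x%d", 1:80))
  ps <- vapply(1:400, function(i) {
    enrichment_test(sample(universe, 15), fam, universe)$p
  }, numeric(1))
  # discrete conservative uniform: no excess of small p
  expect_lte(mean(ps < 0.05), 0.07)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("bh_adjust reproduces the step-up adjustment", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  q <- bh_adjust(p)
  expect_true(all(q >= p) && all(q <= 1) && !is.unsorted(q[order(p)]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("binomial differential p-values are calibrated under the null", {
  withr::local_seed(303)
  n_rep <- 2000
  k1 <- rpois(n_rep, 300); k2 <- rpois(n_rep, 300)
  ps <- vapply(seq_len(n_rep), function(i) {
    if (k1[i] + k2[i] == 0) return(NA_real_)
    binom.test(k1[i], k1[i] + k2[i], 0.5)$p.value
  }, numeric(1))
  rej <- mean(ps < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
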