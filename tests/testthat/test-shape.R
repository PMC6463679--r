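test_that("shape criteria are applied in order with nearest-rank percentiles", {
  # all tags at one position: percentile distance 0 -> SP
  expect_equal(classify_shape(100, 100)$class, "SP")
  # dominant peak over a 10-nt spread: fails (i), passes (ii) -> DP
  r <- classify_shape(c(100, 110, 120), c(60, 25, 15))
  expect_equal(r$class, "DP")
  expect_gte(r$q75 - r$q25, 4)
  expect_gte(r$q85 - r$q15, 6)
  # three >15% peaks exactly 5 nt apart: 5 is not > 5 -> BP
  expect_equal(classify_shape(c(100, 110, 105), c(40, 40, 20))$class, "BP")
  # two 25% peaks 8 nt apart over a broad floor -> MP
  pos <- c(100, 108, 90:99, 101:107, 109:120)
  cnt <- c(50, 50, rep(100 / 29, 29))
  expect_equal(classify_shape(pos, round(cnt * 2))$class, "MP")
  # below the tag threshold: no classification
  expect_true(is.na(classify_shape(c(100), 99)$class))
})

test_that("classification agrees with an independent literal oracle", {
  withr::local_seed(101)
  for (i in 1:300) {
    cl <- random_cluster()
    expect_equal(classify_shape(cl$pos, cl$count)$class,
                 bf_shape(cl$pos, cl$count),
                 info = paste("case", i, paste(cl$pos, cl$count, collapse = ";")))
  }
})

test_that("every classified cluster gets exactly one of the four classes", {
  withr::local_seed(7)
  classes <- vapply(1:200, function(i) {
    cl <- random_cluster(n_tags = 120)
    classify_shape(cl$pos, cl$count)$class
  }, character(1))
  expect_true(all(classes %in% c("SP", "DP", "MP", "BP")))
})

test_that("match_clusters pairs by overlap and maximal shared mass", {
  # identical spans -> one pair
  a <- make_tc(c(100, 105), c(30, 80))
  b <- make_tc(c(100, 105), c(40, 60))
  m <- match_clusters(a, b)
  expect_equal(nrow(m$pairs), 1L)
  expect_length(m$only_a, 0)
  # no overlap -> listed one-sided
  b2 <- make_tc(500, 50)
  m2 <- match_clusters(a, b2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$only_a, a$clusters$id)
  expect_equal(m2$only_b, b2$clusters$id)
  # two candidate partners: the larger shared-position mass wins
  a3 <- make_tc(c(100, 160), c(50, 5))  # two clusters (bodies disjoint)
  expect_equal(nrow(a3$clusters), 2L)
  # one b cluster spanning 100-186: shares pos 100 with a1 (mass
  # min(50,4)=4) and pos 160 with a2 (mass min(5,40)=5) -> a2 wins
  b3 <- make_tc(c(100, 126, 152, 160), c(4, 1, 1, 40))
  expect_equal(nrow(b3$clusters), 1L)
  m3 <- match_clusters(a3, b3)
  expect_equal(nrow(m3$pairs), 1L)
  expect_equal(m3$pairs$id_a, "chr1:+:160-186")
  expect_equal(m3$pairs$shared_mass, 5)
  expect_equal(m3$only_a, "chr1:+:100-126")
})

test_that("KS statistic and p-value behave at the extremes and are symmetric", {
  expect_equal(ks_stat(c(100, 105), c(50, 50), c(100, 105), c(50, 50)), 0)
  expect_equal(ks_pvalue(0, 100, 100), 1)
  expect_equal(ks_stat(100, 100, 200, 100), 1)
  expect_lt(ks_pvalue(1, 100, 100), 1e-10)
  # symmetry under argument swap
  withr::local_seed(5)
  for (i in 1:20) {
    pa <- sample(100:130, 5); ca <- sample.int(40, 5)
    pb <- sample(100:130, 5); cb <- sample.int(40, 5)
    expect_equal(ks_stat(pa, ca, pb, cb), ks_stat(pb, cb, pa, ca))
  }
})

test_that("weighted KS matches stats::ks.test on expanded multisets", {
  withr::local_seed(33)
  for (i in 1:20) {
    pa <- sort(sample(100:140, 6)); ca <- sample.int(60, 6)
    pb <- sort(sample(100:140, 6)); cb <- sample.int(60, 6)
    xa <- rep(pa, ca); xb <- rep(pb, cb)
    ref <- suppressWarnings(stats::ks.test(xa, xb, exact = FALSE))
    D <- ks_stat(pa, ca, pb, cb)
    expect_equal(D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ks_pvalue(D, sum(ca), sum(cb)), ref$p.value, tolerance = 1e-6)
  }
})

test_that("ks_disparity tests qualifying pairs and flags disparity", {
  a <- make_tc(c(100, 105, 300), c(80, 40, 150))
  b <- make_tc(c(100, 105, 312), c(75, 45, 150))
  m <- match_clusters(a, b)
  d <- ks_disparity(a, b, m$pairs, min_tags = 100)
  expect_equal(nrow(d), 2L)  # both pairs have >= 100 tags on both sides
  same <- d[d$id_a == "chr1:+:100-131", ]
  expect_lt(same$ks_D, 0.1)
  expect_false(same$changed)
  shifted <- d[d$id_a == "chr1:+:300-326", ]
  expect_equal(shifted$ks_D, 1)   # disjoint supports
  expect_true(shifted$changed)
  expect_true(all(d$q >= d$p))
  # pairs below the threshold are skipped, not errors
  small <- ks_disparity(make_tc(100, 50), make_tc(100, 50), min_tags = 100)
  expect_equal(nrow(small), 0L)
})

test_that("shape_fc_trend recovers fractions and degenerate correlations", {
  # hand-built 8-cluster table over thresholds 1, 2, 4, 8
  shape <- c("SP", "SP", "BP", "SP", "BP", "SP", "SP", "MP")
  fc <- c(1, 1.5, 2, 3, 4, 8, 9, 10)
  enr <- rep(TRUE, 8)
  tr <- shape_fc_trend(shape, fc, enr, thresholds = c(1, 2, 4, 8))
  # qualifying sets: fc>=1 {all 8, 5 SP}, fc>=2 {6, SP at 3/8/9},
  # fc>=4 {4, SP at 8/9}, fc>=8 {3, SP at 8/9}
  expect_equal(tr$table$n, c(8L, 6L, 4L, 3L))
  expect_equal(tr$table$pct_SP, 100 * c(5 / 8, 3 / 6, 2 / 4, 2 / 3))
  expect_equal(tr$table$pct_BP, 100 * c(2 / 8, 2 / 6, 1 / 4, 0))
  # all-SP input: 100% at every threshold, correlation undefined
  tr2 <- shape_fc_trend(rep("SP", 5), c(1, 2, 4, 8, 16), rep(TRUE, 5),
                        thresholds = c(1, 2, 4))
  expect_true(all(tr2$table$pct_SP == 100))
  expect_true(is.na(tr2$r_SP))
  # empty bins are excluded from the correlation
  tr3 <- shape_fc_trend(shape, fc, enr, thresholds = c(1, 2, 4, 8, 1000))
  expect_equal(tr3$table$n[5], 0L)
  expect_true(is.na(tr3$table$pct_SP[5]))
  expect_false(is.na(tr3$r_SP))
})

test_that("a planted monotone SP trend yields a positive correlation", {
  withr::local_seed(12)
  # higher fold changes drawn preferentially for SP clusters
  n <- 400
  shape <- sample(c("SP", "BP"), n, replace = TRUE)
  fc <- ifelse(shape == "SP", 2^runif(n, 1, 4), 2^runif(n, 0, 2))
  tr <- shape_fc_trend(shape, fc, rep(TRUE, n), thresholds = 2^(0:3))
  expect_gt(tr$r_SP, 0)
  expect_lt(tr$r_BP, 0)
})
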