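# Fixture: two overlapping genes on chr1.
#   gene B (+): exon 1001-2000, CDS 1201-1800 -> 5'UTR(ext) 901-1200,
#     3'UTR 1801-2000, start codon 1201
#   gene A (+): exons 500-1600 and 3001-3600 with CDS 600-1600/3001-3400
#     -> intron 1601-3000 (overlaps gene B entirely)
annotation_fixture <- function() {
  f <- tempfile(fileext = ".gtf")
  rows <- rbind(
    simple_gene_rows("exon", 1001, 2000, gene = "gB", tx = "tB"),
    simple_gene_rows("CDS", 1201, 1800, gene = "gB", tx = "tB"),
    simple_gene_rows("exon", 500, 1600, gene = "gA", tx = "tA"),
    simple_gene_rows("exon", 3001, 3600, gene = "gA", tx = "tA"),
    simple_gene_rows("CDS", 600, 1600, gene = "gA", tx = "tA"),
    simple_gene_rows("CDS", 3001, 3400, gene = "gA", tx = "tA"))
  write_gtf_text(rows, f)
  idx <- read_annotation(f)
  unlink(f)
  idx
}

test_that("representative TSS is the argmax with a 5'-most tie rule", {
  expect_equal(representative_tss(c(100, 105, 110), c(3, 9, 2), "+"), 105)
  expect_equal(representative_tss(c(100, 110), c(5, 5), "+"), 100)
  expect_equal(representative_tss(c(100, 110), c(5, 5), "-"), 110)
})

test_that("feature assignment follows the 5utr > 3utr > cds > intron priority", {
  idx <- annotation_fixture()
  # cluster at 1100: inside gene A's CDS-bearing exon region? -> 1100 is in
  # gene A's CDS (600-1600) AND gene B's 5'UTR (1001-1200): 5'UTR wins
  tc <- make_tc(1100, 10)
  ann <- annotate_clusters(tc, idx)
  expect_equal(ann$feature, "5utr")
  expect_equal(ann$gene, "gB")
  # cluster at 1900: gene A intron (1601-3000) and gene B 3'UTR -> 3utr
  ann <- annotate_clusters(make_tc(1900, 10), idx)
  expect_equal(ann$feature, "3utr")
  expect_equal(ann$gene, "gB")
  # cluster at 2500: intron of gene A only
  ann <- annotate_clusters(make_tc(2500, 10), idx)
  expect_equal(ann$feature, "intron")
  expect_equal(ann$gene, "gA")
  # 40 nt upstream of gene B's annotated 5'UTR -> still 5utr (100-nt ext)
  ann <- annotate_clusters(make_tc(961, 10), idx)
  expect_equal(ann$feature, "5utr")
  # far away -> intergenic
  ann <- annotate_clusters(make_tc(9000, 10), idx)
  expect_equal(ann$feature, "intergenic")
  expect_true(is.na(ann$gene))
})

test_that("adding a lower-priority interval never changes an assignment", {
  idx <- annotation_fixture()
  f <- tempfile(fileext = ".gtf")
  rows <- rbind(
    simple_gene_rows("exon", 1001, 2000, gene = "gB", tx = "tB"),
    simple_gene_rows("CDS", 1201, 1800, gene = "gB", tx = "tB"),
    # a new gene whose CDS covers the probe position (lower priority than 5utr)
    simple_gene_rows("exon", 900, 1600, gene = "gC", tx = "tC"),
    simple_gene_rows("CDS", 905, 1595, gene = "gC", tx = "tC"))
  write_gtf_text(rows, f)
  idx2 <- read_annotation(f)
  unlink(f)
  tc <- make_tc(1100, 10)
  expect_equal(annotate_clusters(tc, idx)$feature,
               annotate_clusters(tc, idx2)$feature)
})

test_that("5'UTR lengths and their differences are strand-aware", {
  idx <- annotation_fixture()
  # gene B: start codon 1201; rep TSS at 1171 -> length 30
  ann_p <- annotate_clusters(make_tc(1171, 10), idx)
  expect_equal(five_prime_utr_length(ann_p, idx), 30L)
  # same rep TSS in both samples -> difference 0, status "same"
  d <- utr_length_difference(30L, 30L)
  expect_equal(d$difference, 0L)
  expect_equal(d$status, "same")
  # translatome rep TSS 10 nt downstream (+ strand) -> shorter by 10
  ann_p2 <- annotate_clusters(make_tc(1181, 10), idx)
  d <- utr_length_difference(five_prime_utr_length(ann_p2, idx),
                             five_prime_utr_length(ann_p, idx))
  expect_equal(d$difference, -10L)
  expect_equal(d$status, "shorter")
  # minus-strand mirror: exon 1001-2000, CDS 1201-1800 on '-': start codon
  # 1800; rep TSS 1830 -> length 30
  f <- tempfile(fileext = ".gtf")
  write_gtf_text(rbind(simple_gene_rows("exon", 1001, 2000, strand = "-"),
                       simple_gene_rows("CDS", 1201, 1800, strand = "-")), f)
  idxm <- read_annotation(f)
  unlink(f)
  annm <- annotate_clusters(make_tc(1830, 10, strand = "-"), idxm)
  expect_equal(annm$feature, "5utr")
  expect_equal(five_prime_utr_length(annm, idxm), 30L)
  # rep TSS downstream of the start codon -> undefined
  f2 <- tempfile(fileext = ".gtf")
  write_gtf_text(rbind(simple_gene_rows("exon", 1001, 2000),
                       simple_gene_rows("CDS", 1050, 1800)), f2)
  idx2 <- read_annotation(f2)
  unlink(f2)
  ann3 <- annotate_clusters(make_tc(1100, 10), idx2)
  expect_equal(ann3$feature, "cds")
  expect_true(is.na(five_prime_utr_length(ann3, idx2)))
})

test_that("first-nucleotide frequencies are strand-aware and sum to one", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("AC", 50)), f)  # ACAC...: odd pos A, even C
  g <- read_fasta(f)
  unlink(f)
  idx <- annotation_fixture()
  tc <- make_tc(c(11, 31, 51), c(5, 6, 7))  # all odd -> A on +
  ann <- annotate_clusters(tc, idx, genome = g)
  fr <- first_nt_frequency(ann)
  expect_equal(unname(fr["A"]), 1)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # minus strand: base at odd position is A -> complement T
  tcm <- make_tc(c(31, 61), c(5, 5), strand = "-")
  annm <- annotate_clusters(tcm, idx, genome = g)
  expect_equal(unname(first_nt_frequency(annm)["T"]), 1)
})

test_that("g_correction shifts only mismatched G starts and conserves tags", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "AAGAAAAAAA"), f)  # G at position 3 only
  g <- read_fasta(f)
  unlink(f)
  ctss <- make_ctss(c(3, 5), c(4, 6))
  ctss$first_nt <- c("G", "G")
  out <- g_correction(ctss, g)
  # pos 3 sits on genomic G -> unchanged; pos 5 over A -> shifted to 6
  expect_equal(out$pos, c(3L, 6L))
  expect_equal(sum(out$count), sum(ctss$count))
  # without first_nt information the records pass through untouched
  expect_equal(g_correction(make_ctss(5, 6), g), make_ctss(5, 6))
  # minus strand shifts 3'-ward, i.e. to lower coordinates
  cm <- make_ctss(8, 2, strand = "-")
  cm$first_nt <- "G"   # genomic base at 8 on '-' is complement(A) = T
  outm <- g_correction(cm, g)
  expect_equal(outm$pos, 7L)
  # counts at the shifted position merge with existing ones
  c2 <- make_ctss(c(5, 6), c(4, 1))
  c2$first_nt <- c("G", "A")
  out2 <- g_correction(c2, g)
  expect_equal(out2$pos, 6L)
  expect_equal(out2$count, 5L)
})

test_that("expressed flags follow the transcriptome 5'UTR definition", {
  idx <- annotation_fixture()
  # transcriptome TC in gene B's extended 5'UTR -> tB and gB expressed
  ann_b <- annotate_clusters(make_tc(1100, 10), idx)
  fl <- expressed_flags(ann_b, idx)
  expect_true(fl$transcript[["tB"]])
  expect_true(fl$gene[["gB"]])
  expect_false(fl$gene[["gA"]])
  # a CDS-only TC does not make a gene expressed
  ann_cds <- annotate_clusters(make_tc(700, 10), idx)
  expect_equal(annotate_clusters(make_tc(700, 10), idx)$feature, "cds")
  fl2 <- expressed_flags(ann_cds, idx)
  expect_false(fl2$gene[["gA"]])
})

test_that("feature categories partition the clusters", {
  idx <- annotation_fixture()
  ctss <- make_ctss(c(961, 1171, 1900, 2500, 700, 9000),
                    rep(10L, 6))
  tc <- suppressWarnings(cluster_tags(ctss, cluster_params(1e7, min_tags = 4L)))
  ann <- annotate_clusters(tc, idx)
  expect_equal(sum(table(ann$feature)), nrow(tc$clusters))
  expect_true(all(ann$feature %in% c("5utr", "3utr", "cds", "intron", "intergenic")))
  # 5utr assignment implies a gene
  expect_true(all(!is.na(ann$gene[ann$feature == "5utr"])))
})
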