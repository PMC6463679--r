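# Shared fixtures and independent brute-force oracles used across the suite.
# Oracles are coded from first principles, independently of the package's
# implementation paths.

# -- fixtures -----------------------------------------------------------------

make_ctss <- function(pos, count, strand = "+", chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             count = as.integer(count), stringsAsFactors = FALSE)
}

# A tc_set holding exactly the given positions/counts as one sample.
make_tc <- function(pos, count, strand = "+", chrom = "chr1",
                    genome_length = 1e7, min_tags = 1L) {
  ctss <- make_ctss(pos, count, strand, chrom)
  suppressWarnings(cluster_tags(ctss, cluster_params(genome_length,
                                                     min_tags = min_tags)))
}

write_gtf_text <- function(rows, path) {
  # rows: data.frame seqnames,source?,type,start,end,strand,gene,tx
  lines <- sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                   rows$seqnames, rows$type, rows$start, rows$end,
                   rows$strand, rows$gene, rows$tx)
  writeLines(lines, path)
  path
}

simple_gene_rows <- function(type, start, end, strand = "+", gene = "gA",
                             tx = "tA", seqnames = "chr1") {
  data.frame(seqnames = seqnames, type = type, start = start, end = end,
             strand = strand, gene = gene, tx = tx, stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# -- oracles ------------------------------------------------------------------

# Poisson upper tail by direct summation of the density.
bf_poisson_tail <- function(n, lambda) {
  if (lambda == 0) return(if (n >= 1) 0 else 1)
  k <- n:(n + 2000)
  sum(exp(k * log(lambda) - lambda - lgamma(k + 1)))
}

# Transitive closure of pairwise tag-body overlap; returns a partition
# label per tag (small inputs only).
bf_cluster_labels <- function(ctss, tag_length = 27L) {
  n <- nrow(ctss)
  start <- ifelse(ctss$strand == "+", ctss$pos, ctss$pos - tag_length + 1L)
  end <- start + tag_length - 1L
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- ctss$chrom[i] == ctss$chrom[j] &&
      ctss$strand[i] == ctss$strand[j] &&
      start[i] <= end[j] && start[j] <= end[i]
  }
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && lab[j] != lab[i]) {
        new <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# Literal transcription of the four shape criteria, working on the
# expanded (per-tag) position vector rather than weighted counts.
bf_shape <- function(pos, count, min_tags = 100L) {
  x <- sort(rep(pos, count))
  n <- length(x)
  if (n < min_tags) return(NA_character_)
  pct <- function(q) x[ceiling(q * n)]
  if ((pct(0.75) - pct(0.25)) < 4 || (pct(0.85) - pct(0.15)) < 6) return("SP")
  tab <- table(x)
  cnt <- sort(as.integer(tab), decreasing = TRUE)
  highest <- cnt[1]
  second <- if (length(cnt) > 1) cnt[2] else 0
  if ((second == 0 || highest / second > 2) && highest > 0.2 * n) return("DP")
  peaks <- sort(as.integer(names(tab)[as.integer(tab) > 0.15 * n]))
  if (length(peaks) >= 2 && all(diff(peaks) > 5)) return("MP")
  "BP"
}

# Two-sided exact binomial p by direct summation (binom.test convention:
# sum of outcome probabilities not exceeding the observed one).
bf_binom_two_sided <- function(k, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
bf_fisher_p <- function(a, b, c_, d) {
  K <- a + c_          # family size
  n <- a + b           # query size
  N <- a + b + c_ + d
  xs <- max(0, n - (N - K)):min(K, n)
  dens <- dhyper(xs, K, N - K, n)
  obs <- dhyper(a, K, N - K, n)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Overlap-aware motif count by a position-by-position triple loop.
bf_count_motif <- function(s, motif_chars) {
  chars <- strsplit(s, "")[[1]]
  w <- length(motif_chars)
  total <- 0L
  for (i in seq_len(max(length(chars) - w + 1L, 0L))) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!chars[i + j - 1L] %in% motif_chars[[j]]) { ok <- FALSE; break }
    }
    if (ok) total <- total + 1L
  }
  total
}

# Random weighted cluster for shape property tests.
random_cluster <- function(n_tags = 150L, span = 30L) {
  k <- sample(1:8, 1)
  pos <- sort(sample.int(span, k))
  w <- rgamma(k, shape = sample(c(0.3, 1, 5), 1))
  count <- as.integer(rmultinom(1, n_tags, w / sum(w)))
  keep <- count > 0
  list(pos = pos[keep] + 100L, count = count[keep])
}
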