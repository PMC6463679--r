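# Sequence-window characterization of differentially used clusters:
# GC content, AUG counts and TATA-box enrichment in 100-nt windows around
# representative TSSs.

#' Pick enriched / depleted / control cluster groups
#'
#' Selects the top `k` translatome-enriched clusters by p-value, the top
#' `k` depleted clusters by p-value, and `k` clusters drawn uniformly at
#' random (fixed seed) from the fold-change band `fc_band` (default
#' 0.95-1.05). When the band holds fewer than `k` clusters, all of its
#' members are returned with a warning.
#'
#' @param diff a [tc_diff()] table.
#' @param k group size (default 200).
#' @param fc_band numeric length-2 fold-change band for the control group.
#' @param seed RNG seed for the control draw.
#' @return list of three data.frames (`enriched`, `depleted`, `control`)
#'   of rows from `diff`.
#' @export
pick_groups <- function(diff, k = 200L, fc_band = c(0.95, 1.05), seed = 1L) {
  top <- function(d) head(d[order(d$p), , drop = FALSE], k)
  enr <- top(diff[diff$status == "enriched", , drop = FALSE])
  dep <- top(diff[diff$status == "depleted", , drop = FALSE])
  band <- diff[!is.na(diff$fc) & diff$fc > fc_band[1] & diff$fc < fc_band[2], ,
               drop = FALSE]
  if (nrow(band) <= k) {
    if (nrow(band) < k) {
      warning(sprintf("fold-change band holds only %d clusters (requested %d)",
                      nrow(band), k), call. = FALSE)
    }
    ctrl <- band
  } else {
    ctrl <- with_local_seed(seed, band[sample.int(nrow(band), k), , drop = FALSE])
  }
  lapply(list(enriched = enr, depleted = dep, control = ctrl),
         function(d) { rownames(d) <- NULL; d })
}

#' Sequence windows around representative TSSs
#'
#' Extracts strand-aware 100-nt (by default) windows for a set of
#' clusters. The downstream window runs from the representative TSS
#' (position 1 of the window) `width` nt in transcript orientation; the
#' upstream window covers the `width` nt immediately 5' of it. Windows
#' extending past a contig edge are dropped and counted.
#'
#' @param ann an [annotate_clusters()] table (rows for the wanted
#'   clusters).
#' @param genome a [Biostrings::DNAStringSet].
#' @param side `"downstream"` or `"upstream"` of the representative TSS.
#' @param width window width in nt (default 100).
#' @return list with `seq` (character vector, one string per kept window,
#'   named by cluster id), and `n_dropped`.
#' @export
tss_windows <- function(ann, genome, side = c("downstream", "upstream"),
                        width = 100L) {
  side <- match.arg(side)
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (side == "downstream") {
    start <- ifelse(ann$strand == "+", ann$rep_tss, ann$rep_tss - width + 1L)
  } else {
    start <- ifelse(ann$strand == "+", ann$rep_tss - width, ann$rep_tss + 1L)
  }
  end <- start + width - 1L
  ok <- start >= 1L & end <= lens[ann$chrom] & ann$chrom %in% names(genome)
  seqs <- character(sum(ok))
  rows <- which(ok)
  for (j in seq_along(rows)) {
    i <- rows[j]
    seqs[j] <- fetch_seq(genome, ann$chrom[i], start[i], end[i], ann$strand[i])
  }
  list(seq = setNames(seqs, ann$id[ok]), n_dropped = sum(!ok))
}

#' GC content and per-position base frequencies of a window set
#'
#' @param seqs character vector of equal-length windows.
#' @return list with `gc` (overall G+C fraction over counted bases),
#'   `freq` (4 x width matrix of A/C/G/T frequencies per position, columns
#'   summing to 1 over counted bases) and `n_other` (non-ACGT bases,
#'   excluded from denominators).
#' @export
gc_profile <- function(seqs) {
  if (!length(seqs)) stop_validation("empty window set")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop_validation("windows must have equal length")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = w, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  freq <- vapply(seq_len(w), function(j) {
    tab <- table(factor(m[, j], levels = bases))
    tot <- sum(tab)
    if (tot == 0) rep(NA_real_, 4) else as.numeric(tab) / tot
  }, numeric(4))
  rownames(freq) <- bases
  counted <- m %in% bases
  gc <- sum(m %in% c("G", "C")) / sum(counted)
  list(gc = gc, freq = freq, n_other = sum(!counted))
}

# All (overlap-aware) match positions of a fixed-width pattern, scanned
# base by base. `pattern` is a character-class regex over single bases,
# e.g. "TATA[AT]A[AT]" -> width 7.
count_pattern <- function(seqs, pattern) {
  vapply(seqs, function(s) {
    hits <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, integer(1), USE.NAMES = FALSE)
}

#' Count AUG (start-codon) occurrences in a window set
#'
#' Counts `ATG` trinucleotides in the DNA windows, overlap-aware (a
#' sliding scan, although ATG cannot overlap itself).
#'
#' @param seqs character vector of windows.
#' @return list with `total` and `per_window` counts.
#' @export
count_aug <- function(seqs) {
  per <- if (length(seqs)) count_pattern(seqs, "ATG") else integer(0)
  list(total = sum(per), per_window = per)
}

#' Two-group proportion test on motif match counts
#'
#' Compares total match counts between two window sets, relative to the
#' number of scanned start positions in each; a convenience wrapper around
#' [stats::prop.test()] used for AUG and TATA comparisons.
#'
#' @param count_a,count_b total match counts.
#' @param n_a,n_b number of scanned positions (window length minus pattern
#'   width plus 1, summed over windows) per group.
#' @return p-value.
#' @export
window_prop_test <- function(count_a, count_b, n_a, n_b) {
  suppressWarnings(prop.test(c(count_a, count_b), c(n_a, n_b))$p.value)
}

#' TATA-box enrichment between two upstream window sets
#'
#' Counts matches of a TATA-box pattern (default consensus TATAWAW,
#' `TATA[AT]A[AT]`) in each group's upstream windows and reports the fold
#' enrichment of per-window match rates with a proportion-test p-value.
#' When group b has zero matches the fold is reported as `Inf`.
#'
#' @param seqs_a,seqs_b character vectors of upstream windows.
#' @param pattern single-base-class regex of fixed width.
#' @return list with `count_a`, `count_b`, `rate_a`, `rate_b`, `fold`, `p`.
#' @export
tata_enrichment <- function(seqs_a, seqs_b, pattern = "TATA[AT]A[AT]") {
  if (!length(seqs_a) || !length(seqs_b)) {
    stop_validation("both window sets must be nonempty")
  }
  ca <- sum(count_pattern(seqs_a, pattern))
  cb <- sum(count_pattern(seqs_b, pattern))
  ra <- ca / length(seqs_a)
  rb <- cb / length(seqs_b)
  fold <- if (cb == 0) Inf else ra / rb
  # scanned start positions per group (pattern width from its class count)
  w <- nchar(gsub("\\[[^]]*\\]", "N", pattern))
  scan_a <- sum(pmax(nchar(seqs_a) - w + 1L, 0L))
  scan_b <- sum(pmax(nchar(seqs_b) - w + 1L, 0L))
  p <- window_prop_test(ca, cb, scan_a, scan_b)
  list(count_a = ca, count_b = cb, rate_a = ra, rate_b = rb,
       fold = fold, p = p)
}

#' Write a window set as FASTA
#'
#' Export hook for external motif tools: writes the (named) window
#' sequences of a group as a plain FASTA file.
#'
#' @param seqs named character vector of windows.
#' @param path output file.
#' @export
write_window_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("window_%d", seq_along(seqs))
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

#' Full sequence-feature comparison of enriched/depleted/control groups
#'
#' Convenience wrapper: picks the three groups, extracts downstream and
#' upstream windows, and reports GC content, AUG totals and TATA
#' enrichment (enriched vs control and depleted vs control).
#'
#' @param diff a [tc_diff()] table.
#' @param ann_a translatome [annotate_clusters()] table (windows are taken
#'   around translatome representative TSSs; control/depleted clusters
#'   absent from translatome use the transcriptome side).
#' @param ann_b transcriptome annotation table.
#' @param genome a [Biostrings::DNAStringSet].
#' @param k group size (default 200).
#' @param seed control-group seed.
#' @return list with `groups`, per-group `gc`, `aug`, and `tata`
#'   comparisons.
#' @export
seqfeat_compare <- function(diff, ann_a, ann_b, genome, k = 200L, seed = 1L) {
  groups <- pick_groups(diff, k = k, seed = seed)
  ann_for <- function(d) {
    use_a <- !is.na(d$id_a)
    rbind(ann_a[match(d$id_a[use_a], ann_a$id), , drop = FALSE],
          ann_b[match(d$id_b[!use_a], ann_b$id), , drop = FALSE])
  }
  res <- lapply(groups, function(d) {
    ann <- ann_for(d)
    down <- tss_windows(ann, genome, "downstream")
    up <- tss_windows(ann, genome, "upstream")
    list(ann = ann, down = down, up = up,
         gc = gc_profile(down$seq), aug = count_aug(down$seq))
  })
  list(groups = groups,
       gc = vapply(res, function(r) r$gc$gc, numeric(1)),
       aug = vapply(res, function(r) r$aug$total, numeric(1)),
       tata_enriched_vs_control = tata_enrichment(res$enriched$up$seq,
                                                  res$control$up$seq),
       tata_depleted_vs_control = tata_enrichment(res$depleted$up$seq,
                                                  res$control$up$seq),
       detail = res)
}
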