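# Promoter annotation: representative TSSs, feature-priority assignment
# (5'UTR > 3'UTR > CDS > intron > intergenic), 5'UTR lengths, first-nucleotide
# frequencies, expressed-transcript/gene flags and the optional G-addition
# correction.

#' Representative TSS of a tag cluster
#'
#' The position with the highest 5'-end count (the most frequently used
#' TSS). Ties are broken in favour of the 5'-most position: the smallest
#' coordinate on the plus strand, the largest on the minus strand.
#'
#' @param pos integer positions.
#' @param count tag counts at each position.
#' @param strand `"+"` or `"-"`.
#' @return The representative position (integer scalar).
#' @export
representative_tss <- function(pos, count, strand = "+") {
  if (!length(pos)) stop_validation("empty cluster")
  top <- pos[count == max(count)]
  if (strand == "+") min(top) else max(top)
}

#' Annotate tag clusters
#'
#' For each cluster, computes the representative TSS, assigns the cluster
#' to the highest-priority genomic feature containing that position
#' (5'UTR including its 100-nt upstream extension > 3'UTR > CDS > intron,
#' else intergenic), resolves the gene through the containing transcript
#' (when several transcripts qualify, the one whose annotated TSS is
#' nearest the representative TSS), and — when a genome is supplied —
#' records the first nucleotide at the representative TSS in transcript
#' orientation.
#'
#' @param tc a `tc_set` from [cluster_tags()].
#' @param index a `feature_index` from [read_annotation()].
#' @param genome optional [Biostrings::DNAStringSet].
#' @return A data.frame (one row per cluster): id, chrom, strand, rep_tss,
#'   rep_count, n, rpm, feature, gene, tx, first_nt.
#' @export
annotate_clusters <- function(tc, index, genome = NULL) {
  cl <- tc$clusters
  by_cl <- split_cluster_ctss(tc)
  rep_tss <- mapply(function(d, strand) representative_tss(d$pos, d$count, strand),
                    by_cl, cl$strand)
  rep_count <- vapply(by_cl, function(d) max(d$count), numeric(1))
  ann <- data.frame(id = cl$id, chrom = cl$chrom, strand = cl$strand,
                    rep_tss = as.integer(rep_tss),
                    rep_count = as.integer(rep_count),
                    n = cl$n, rpm = cl$rpm,
                    feature = "intergenic", gene = NA_character_,
                    tx = NA_character_, first_nt = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(ann)) {
    pts <- GenomicRanges::GRanges(ann$chrom,
                                  IRanges::IRanges(ann$rep_tss, ann$rep_tss),
                                  strand = ann$strand)
    unassigned <- rep(TRUE, nrow(ann))
    for (kind in FEATURE_PRIORITY) {
      gr <- index$features[[kind]]
      if (!length(gr)) next
      hit <- GenomicRanges::findOverlaps(pts, gr)
      q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
      use <- unassigned[q]
      q <- q[use]; s <- s[use]
      if (!length(q)) next
      # nearest annotated TSS breaks ties between containing transcripts
      tssdist <- abs(index$tx_tss[gr$tx[s]] - ann$rep_tss[q])
      ord <- order(q, tssdist)
      q <- q[ord]; s <- s[ord]
      first <- !duplicated(q)
      ann$feature[q[first]] <- kind
      ann$tx[q[first]] <- gr$tx[s[first]]
      ann$gene[q[first]] <- gr$gene[s[first]]
      unassigned[q] <- FALSE
    }
    if (!is.null(genome)) {
      ann$first_nt <- mapply(function(chrom, pos, strand) {
        fetch_seq(genome, chrom, pos, pos, strand)
      }, ann$chrom, ann$rep_tss, ann$strand)
    }
  }
  rownames(ann) <- NULL
  ann
}

#' 5' UTR length implied by a representative TSS
#'
#' Strand-aware genomic distance from the representative TSS to the first
#' base of the annotated start codon of the transcript the cluster was
#' assigned to. Undefined (NA) when the cluster is not 5'UTR-assigned, the
#' transcript has no CDS, or the start codon lies upstream of the
#' representative TSS.
#'
#' @param ann one or more rows of an [annotate_clusters()] table.
#' @param index the `feature_index`.
#' @return Integer vector of lengths in nt (NA when undefined).
#' @export
five_prime_utr_length <- function(ann, index) {
  len <- rep(NA_integer_, nrow(ann))
  ok <- ann$feature == "5utr" & !is.na(ann$tx)
  sc <- index$start_codon[ann$tx[ok]]
  d <- ifelse(ann$strand[ok] == "+", sc - ann$rep_tss[ok], ann$rep_tss[ok] - sc)
  d[!is.na(d) & d < 0] <- NA_integer_
  len[ok] <- as.integer(d)
  len
}

#' 5' UTR length difference between conditions
#'
#' @param len_translatome,len_transcriptome lengths from
#'   [five_prime_utr_length()] for matched clusters.
#' @return data.frame with `difference` (translatome - transcriptome, nt)
#'   and `status` in same/shorter/longer (NA when either length is
#'   undefined).
#' @export
utr_length_difference <- function(len_translatome, len_transcriptome) {
  diff <- len_translatome - len_transcriptome
  status <- ifelse(is.na(diff), NA_character_,
                   ifelse(diff == 0, "same", ifelse(diff < 0, "shorter", "longer")))
  data.frame(difference = diff, status = status, stringsAsFactors = FALSE)
}

#' First-nucleotide frequencies at representative TSSs
#'
#' @param ann an [annotate_clusters()] table with `first_nt` filled in.
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
first_nt_frequency <- function(ann) {
  nt <- ann$first_nt[!is.na(ann$first_nt)]
  if (!length(nt)) stop_validation("no first-nucleotide calls available (genome not supplied?)")
  tab <- table(factor(nt, levels = c("A", "C", "G", "T")))
  as.vector(tab / sum(tab)) -> f
  setNames(f, c("A", "C", "G", "T"))
}

#' Single-base G-addition correction
#'
#' CAGE library preparation adds an untemplated G to many tag 5' ends. This
#' deterministic single-base rule moves the 5' end of a tag 1 nt 3'-ward
#' (downstream in transcript orientation) when the tag's observed first
#' base is G but the genomic base at its position is not G; counts at the
#' corrected positions are re-aggregated. Records without an observed first
#' base (`first_nt` missing or NA) are left unchanged.
#'
#' @param ctss CTSS data.frame, optionally with a `first_nt` column holding
#'   the sequenced first base of the tags at each position.
#' @param genome a [Biostrings::DNAStringSet].
#' @return A corrected CTSS data.frame (total count conserved).
#' @export
g_correction <- function(ctss, genome) {
  if (!nrow(ctss) || is.null(ctss$first_nt)) return(ctss)
  gbase <- mapply(function(chrom, pos, strand) fetch_seq(genome, chrom, pos, pos, strand),
                  ctss$chrom, ctss$pos, ctss$strand)
  shift <- !is.na(ctss$first_nt) & ctss$first_nt == "G" & gbase != "G"
  pos <- ctss$pos + ifelse(ctss$strand == "+", 1L, -1L) * shift
  aggregate_ctss(ctss$chrom, pos, ctss$strand, ctss$count)
}

#' Expressed transcripts and genes
#'
#' A transcript is expressed when at least one tag cluster (by its
#' representative TSS) lies within the transcript's 5' UTR or the 100 nt
#' upstream region; a gene is expressed when at least one of its annotated
#' transcripts is expressed in the transcriptome.
#'
#' @param ann_transcriptome an [annotate_clusters()] table for the
#'   transcriptome sample.
#' @param index the `feature_index`.
#' @return list with logical vectors `transcript` (named by transcript) and
#'   `gene` (named by gene).
#' @export
expressed_flags <- function(ann_transcriptome, index) {
  txs <- names(index$tx2gene)
  tx_flag <- setNames(rep(FALSE, length(txs)), txs)
  gr <- index$features[["5utr"]]
  if (length(gr) && nrow(ann_transcriptome)) {
    pts <- GenomicRanges::GRanges(ann_transcriptome$chrom,
                                  IRanges::IRanges(ann_transcriptome$rep_tss,
                                                   ann_transcriptome$rep_tss),
                                  strand = ann_transcriptome$strand)
    hit <- GenomicRanges::findOverlaps(pts, gr)
    tx_flag[unique(gr$tx[S4Vectors::subjectHits(hit)])] <- TRUE
  }
  genes <- unique(unname(index$tx2gene))
  gene_flag <- vapply(genes, function(g) any(tx_flag[names(index$tx2gene)[index$tx2gene == g]]),
                      logical(1))
  list(transcript = tx_flag, gene = setNames(gene_flag, genes))
}
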