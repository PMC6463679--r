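# Synthetic two-condition CAGE dataset generator with a truth key.
#
# The generator emulates the statistical structure the pipeline assumes:
# genes with 1-3 core promoters in their (extended) 5' UTRs, promoter
# emitters of parameterized shape (SP/DP/MP/BP), gene-level abundance
# effects between translatome and transcriptome, independent within-gene
# usage effects, a subset of promoters with shifted 5'-end distributions,
# planted sequence context (first nucleotide, TATA box, GC composition)
# and uniform genomic background noise.

GENE_SLOT <- 2500L   # nt of genome reserved per gene model
TSS_OFFSET <- 400L   # annotated TSS position within the slot
PROM_SPACING <- 70L  # nt between promoter anchors of one gene

#' Simulation configuration
#'
#' Defaults describe a full-size desk run: ~2e4 tag clusters and 1e6 tags
#' per condition on a ~25-Mb synthetic genome.
#'
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @param n_genes number of gene models.
#' @param promoter_probs probability of a gene having 1, 2 or 3 core
#'   promoters.
#' @param shape_mix probabilities over SP/DP/MP/BP emitters (must sum
#'   to 1).
#' @param library_size tags per condition.
#' @param background_rate fraction of each library emitted as uniform
#'   genomic background noise.
#' @param abundance_meanlog,abundance_sdlog log-normal baseline promoter
#'   abundance; a floor of `abundance_floor` keeps every promoter
#'   detectable in expectation.
#' @param abundance_floor additive abundance floor.
#' @param frac_fc fraction of genes with a planted gene-level abundance
#'   effect.
#' @param lfc_magnitudes planted |log2 fold change| values (sign random).
#' @param frac_usage fraction of multi-promoter genes with a planted
#'   usage effect (within-gene promoter-share redistribution in the
#'   translatome, preserving the gene total so that usage and abundance
#'   effects are independent).
#' @param usage_sdlog log-normal sd of the usage multipliers.
#' @param frac_shift fraction of promoters whose translatome 5'-end
#'   distribution is shifted downstream by `shift_offset` nt.
#' @param shift_offset shift in nt (default 6).
#' @param first_nt_probs planted base composition at promoter anchors.
#' @param tata_frac_high,tata_frac_low rate of planted upstream TATA boxes
#'   for promoters with planted log2 FC >= 1 versus all others.
#' @param gc_high,gc_mid,gc_low GC fraction of the planted downstream
#'   window composition for promoters with planted log2 FC <= -1,
#'   in (-1, 1), and >= 1 respectively (translatome-enriched promoters get
#'   the least GC, mirroring the biology the pipeline is built to detect).
#' @param chrom name of the single synthetic chromosome.
#' @param genome_length override for the genome length; must be at least
#'   the capacity the gene models require.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 10000L,
                       promoter_probs = c(0.35, 0.30, 0.35),
                       shape_mix = c(SP = 0.30, DP = 0.25, MP = 0.15, BP = 0.30),
                       library_size = 1e6,
                       background_rate = 0.02,
                       abundance_meanlog = log(20), abundance_sdlog = 1,
                       abundance_floor = 8,
                       frac_fc = 0.4, lfc_magnitudes = c(1, 2, 3),
                       frac_usage = 0.3, usage_sdlog = 1.5,
                       frac_shift = 0.3, shift_offset = 6L,
                       first_nt_probs = c(A = 0.3, C = 0.2, G = 0.4, T = 0.1),
                       tata_frac_high = 0.4, tata_frac_low = 0.02,
                       gc_high = 0.55, gc_mid = 0.45, gc_low = 0.35,
                       chrom = "chrS1",
                       genome_length = NULL) {
  if (abs(sum(shape_mix) - 1) > 1e-8) stop_validation("shape_mix must sum to 1")
  fr <- c(background_rate, frac_fc, frac_usage, frac_shift,
          tata_frac_high, tata_frac_low)
  if (any(fr < 0 | fr > 1)) stop_validation("fractions must lie in [0, 1]")
  if (abs(sum(first_nt_probs) - 1) > 1e-8) {
    stop_validation("first_nt_probs must sum to 1")
  }
  required <- n_genes * GENE_SLOT + 1000L
  if (is.null(genome_length)) {
    genome_length <- required
  } else if (genome_length < required) {
    stop_validation("genome_length %d too small for %d gene models (need >= %d)",
                    genome_length, n_genes, required)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Emitter probability mass over 5'-end offsets (transcript orientation,
# offset 0 = the promoter anchor / intended representative TSS).
emitter_pmf <- function(shape) {
  switch(shape,
    SP = data.frame(offset = -2:2, prob = c(0.015, 0.06, 0.85, 0.06, 0.015)),
    DP = {
      off <- -15:15
      p <- rep(0.7 / 30, 31)
      p[off == 0] <- 0.30
      data.frame(offset = off, prob = p)
    },
    MP = {
      off <- -12:20
      p <- rep(0.5 / 31, 33)
      p[off %in% c(0, 8)] <- 0.25
      data.frame(offset = off, prob = p)
    },
    BP = {
      off <- -16:16
      p <- stats::dnorm(off, 0, 8)
      data.frame(offset = off, prob = p / sum(p))
    },
    stop_validation("unknown shape '%s'", shape))
}

# Lay out gene models: returns list(annotation = exon/CDS data.frame,
# promoters = per-promoter table with gene/tx/strand/anchor/tss).
layout_genes <- function(cfg, n_promoters) {
  n <- cfg$n_genes
  slot0 <- (seq_len(n) - 1L) * GENE_SLOT + 500L
  strand <- rep(c("+", "-"), length.out = n)
  two_exon <- (seq_len(n) %% 2L) == 0L
  tss <- ifelse(strand == "+", slot0 + TSS_OFFSET, slot0 + TSS_OFFSET + 1200L)
  gene <- sprintf("g%05d", seq_len(n))
  tx <- sprintf("t%05d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- if (strand[i] == "+") 1L else -1L
    t0 <- tss[i]
    seg <- function(type, a, b) {
      data.frame(seqnames = cfg$chrom, start = min(a, b), end = max(a, b),
                 strand = strand[i], type = type, transcript_id = tx[i],
                 gene_id = gene[i], stringsAsFactors = FALSE)
    }
    if (two_exon[i]) {
      rows[[i]] <- rbind(
        seg("exon", t0, t0 + s * 500L),
        seg("exon", t0 + s * 701L, t0 + s * 1199L),
        seg("cds", t0 + s * 250L, t0 + s * 500L),
        seg("cds", t0 + s * 701L, t0 + s * 1049L))
    } else {
      rows[[i]] <- rbind(
        seg("exon", t0, t0 + s * 999L),
        seg("cds", t0 + s * 250L, t0 + s * 849L))
    }
  }
  prom <- data.frame(
    gene = rep(gene, n_promoters), tx = rep(tx, n_promoters),
    strand = rep(strand, n_promoters), tss = rep(tss, n_promoters),
    prom_i = sequence(n_promoters), stringsAsFactors = FALSE)
  dirn <- ifelse(prom$strand == "+", 1L, -1L)
  prom$anchor <- prom$tss + dirn * (-50L + (prom$prom_i - 1L) * PROM_SPACING)
  list(annotation = do.call(rbind, rows), promoters = prom)
}

# Random base vector with a given GC fraction.
random_bases <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

revcomp_chars <- function(x) rev(chartr("ACGT", "TGCA", x))

#' Simulate a two-condition CAGE dataset
#'
#' Draws tag counts per condition multinomially from each promoter's shape
#' emitter, scaled by its condition abundance, adds uniform Poisson
#' background, builds a synthetic genome with planted sequence context and
#' a matching gene annotation, and returns everything with a truth key.
#' With `out_dir` set, writes `genome.fa`, `annotation.gtf`,
#' `ctss_translatome.tsv`, `ctss_transcriptome.tsv` and `truth.tsv`;
#' identical seeds yield byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list of class `cage_sim` with `genome`
#'   ([Biostrings::DNAStringSet]), `annotation` (exon/CDS data.frame),
#'   `ctss_translatome`, `ctss_transcriptome` (CTSS data.frames), `truth`
#'   (per-promoter truth key: tc_id, gene, chrom, strand, anchor, shape,
#'   gene_lfc, true_log2fc, shifted, true S_du of the gene, emitted counts
#'   per condition), `config`, and `files` when written.
#' @export
simulate_cage <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    n_promoters <- sample(seq_along(cfg$promoter_probs), cfg$n_genes,
                          replace = TRUE, prob = cfg$promoter_probs)
    lay <- layout_genes(cfg, n_promoters)
    prom <- lay$promoters
    m <- nrow(prom)
    prom <- prom[order(prom$gene, prom$prom_i), , drop = FALSE]
    prom$tc_id <- sprintf("tc%05d", seq_len(m))
    prom$shape <- sample(names(cfg$shape_mix), m, replace = TRUE,
                         prob = cfg$shape_mix)
    prom$shifted <- stats::runif(m) < cfg$frac_shift
    prom$base_w <- rlnorm(m, cfg$abundance_meanlog, cfg$abundance_sdlog) +
      cfg$abundance_floor

    # gene-level abundance effect, independent within-gene usage effect
    genes <- unique(prom$gene)
    has_fc <- stats::runif(length(genes)) < cfg$frac_fc
    g_lfc <- ifelse(has_fc,
                    sample(c(-1, 1), length(genes), replace = TRUE) *
                      sample(cfg$lfc_magnitudes, length(genes), replace = TRUE),
                    0)
    names(g_lfc) <- genes
    prom$gene_lfc <- g_lfc[prom$gene]
    gsz <- table(prom$gene)[genes]
    has_usage <- stats::runif(length(genes)) < cfg$frac_usage & gsz > 1L
    names(has_usage) <- genes
    u <- rep(1, m)
    ui <- has_usage[prom$gene]
    u[ui] <- rlnorm(sum(ui), 0, cfg$usage_sdlog)
    # renormalize within gene so the gene total is set by gene_lfc alone
    bw_gene <- tapply(prom$base_w, prom$gene, sum)
    buw_gene <- tapply(prom$base_w * u, prom$gene, sum)
    prom$w_t <- prom$base_w
    prom$w_p <- prom$base_w * u *
      as.numeric(bw_gene[prom$gene] / buw_gene[prom$gene]) *
      2^prom$gene_lfc
    prom$true_log2fc <- log2((prom$w_p / sum(prom$w_p)) /
                             (prom$w_t / sum(prom$w_t)))
    sdu_gene <- vapply(split(prom[c("w_p", "w_t")], prom$gene),
                       function(d) s_du(d$w_p, d$w_t), numeric(1))
    prom$true_s_du <- unname(sdu_gene[prom$gene])

    # draw tag counts: multinomial over promoters, then over emitter offsets
    n_fg <- round(cfg$library_size * (1 - cfg$background_rate))
    pmfs <- lapply(setNames(SHAPE_CLASSES, SHAPE_CLASSES), emitter_pmf)
    draw_condition <- function(weights, use_shift) {
      n_tc <- as.vector(rmultinom(1, n_fg, weights))
      pos_l <- vector("list", m); cnt_l <- vector("list", m)
      str_l <- vector("list", m)
      for (j in seq_len(m)) {
        if (n_tc[j] == 0L) next
        pmf <- pmfs[[prom$shape[j]]]
        off <- pmf$offset
        if (use_shift && prom$shifted[j]) off <- off + cfg$shift_offset
        cnt <- as.vector(rmultinom(1, n_tc[j], pmf$prob))
        keep <- cnt > 0L
        dirn <- if (prom$strand[j] == "+") 1L else -1L
        pos_l[[j]] <- prom$anchor[j] + dirn * off[keep]
        cnt_l[[j]] <- cnt[keep]
        str_l[[j]] <- rep(prom$strand[j], sum(keep))
      }
      n_bg <- rpois(1, cfg$library_size * cfg$background_rate)
      pos <- c(unlist(pos_l), sample.int(cfg$genome_length, n_bg, replace = TRUE))
      cnt <- c(unlist(cnt_l), rep(1L, n_bg))
      strand <- c(unlist(str_l), sample(STRANDS, n_bg, replace = TRUE))
      ctss <- aggregate_ctss(rep(cfg$chrom, length(pos)), pos, strand, cnt)
      list(ctss = ctss, n_tc = n_tc)
    }
    dt <- draw_condition(prom$w_t, use_shift = FALSE)
    dp <- draw_condition(prom$w_p, use_shift = TRUE)
    prom$n_transcriptome <- dt$n_tc
    prom$n_translatome <- dp$n_tc

    # genome with planted context
    bases <- random_bases(cfg$genome_length, 0.5)
    tata_rate <- ifelse(prom$true_log2fc >= 1, cfg$tata_frac_high,
                        cfg$tata_frac_low)
    has_tata <- stats::runif(m) < tata_rate
    down_gc <- ifelse(prom$true_log2fc >= 1, cfg$gc_low,
                      ifelse(prom$true_log2fc <= -1, cfg$gc_high, cfg$gc_mid))
    tata <- c("T", "A", "T", "A", "A", "A", "A")
    for (j in seq_len(m)) {
      a <- prom$anchor[j]
      if (prom$strand[j] == "+") {
        win <- a:(a + 110L)
        bases[win] <- random_bases(length(win), down_gc[j])
        if (has_tata[j]) bases[(a - 30L):(a - 24L)] <- tata
      } else {
        win <- (a - 110L):a
        bases[win] <- random_bases(length(win), down_gc[j])
        if (has_tata[j]) bases[(a + 24L):(a + 30L)] <- revcomp_chars(tata)
      }
      first <- sample(names(cfg$first_nt_probs), 1, prob = cfg$first_nt_probs)
      bases[a] <- if (prom$strand[j] == "+") first else chartr("ACGT", "TGCA", first)
    }
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- cfg$chrom

    # truth key keeps only promoters detectable in at least one condition
    min_tags <- 4L
    detectable <- prom$n_translatome >= min_tags | prom$n_transcriptome >= min_tags
    truth <- prom[detectable,
                  c("tc_id", "gene", "tx", "strand", "anchor", "shape",
                    "gene_lfc", "true_log2fc", "shifted", "true_s_du",
                    "n_translatome", "n_transcriptome")]
    truth$chrom <- cfg$chrom
    rownames(truth) <- NULL

    out <- structure(list(genome = genome, annotation = lay$annotation,
                          ctss_translatome = dp$ctss,
                          ctss_transcriptome = dt$ctss,
                          truth = truth, config = cfg,
                          n_undetectable = sum(!detectable)),
                     class = "cage_sim")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- list(genome = file.path(out_dir, "genome.fa"),
                    annotation = file.path(out_dir, "annotation.gtf"),
                    ctss_translatome = file.path(out_dir, "ctss_translatome.tsv"),
                    ctss_transcriptome = file.path(out_dir, "ctss_transcriptome.tsv"),
                    truth = file.path(out_dir, "truth.tsv"))
      Biostrings::writeXStringSet(genome, files$genome)
      write_gtf(lay$annotation, files$annotation)
      write_ctss(dp$ctss, files$ctss_translatome)
      write_ctss(dt$ctss, files$ctss_transcriptome)
      write_tsv_provenance(truth, files$truth, params = list(seed = cfg$seed))
      out$files <- files
    }
    out
  })
}

#' @export
print.cage_sim <- function(x, ...) {
  cat(sprintf("cage_sim: %d genes, %d promoters in truth key, %s + %s tags\n",
              x$config$n_genes, nrow(x$truth),
              format(sum(x$ctss_translatome$count), big.mark = ","),
              format(sum(x$ctss_transcriptome$count), big.mark = ",")))
  invisible(x)
}

# Minimal GTF writer for the simulated annotation (exon/CDS rows).
write_gtf <- function(ann, path) {
  lines <- sprintf('%s\tpolycage\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                   ann$seqnames, ifelse(ann$type == "cds", "CDS", ann$type),
                   ann$start, ann$end, ann$strand, ann$gene_id, ann$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Compare pipeline output with the simulation truth key
#'
#' Maps each truth promoter to the discovered cluster (same strand) whose
#' span contains its anchor, then reports: a shape confusion matrix
#' (transcriptome shape calls for clusters above the classification
#' threshold), fold-change recovery (bias and RMSE of predicted versus
#' planted log2 FC on tested pairs), disparity sensitivity and empirical
#' FDR against the planted shift flags, and the mean absolute error of
#' per-gene differential-usage scores.
#'
#' @param result a `cage_compare` object from [cage_pipeline()].
#' @param truth the `truth` data.frame from [simulate_cage()].
#' @return list with `shape_confusion`, `fc_bias`, `fc_rmse`,
#'   `disparity_sensitivity`, `disparity_fdr`, `s_du_mae`, and the
#'   underlying per-promoter table `map`.
#' @export
truth_compare <- function(result, truth) {
  stopifnot(inherits(result, "cage_compare"))
  map_side <- function(tc) {
    cl <- tc$clusters
    gr <- GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$start, cl$end),
                                 strand = cl$strand)
    pts <- GenomicRanges::GRanges(truth$chrom,
                                  IRanges::IRanges(truth$anchor, truth$anchor),
                                  strand = truth$strand)
    hit <- GenomicRanges::findOverlaps(pts, gr, select = "first")
    cl$id[hit]
  }
  map <- truth
  map$id_a <- map_side(result$tc_translatome)
  map$id_b <- map_side(result$tc_transcriptome)

  shp <- result$shapes_transcriptome
  map$shape_pred <- shp$class[match(map$id_b, shp$id)]
  ok <- !is.na(map$shape_pred)
  shape_confusion <- table(truth = factor(map$shape[ok], levels = SHAPE_CLASSES),
                           predicted = factor(map$shape_pred[ok],
                                              levels = SHAPE_CLASSES))

  d <- result$tc_diff
  key <- paste(d$id_a, d$id_b)
  mk <- match(paste(map$id_a, map$id_b), key)
  map$log2fc_pred <- d$log2fc[mk]
  fc_ok <- !is.na(map$log2fc_pred)
  fc_err <- map$log2fc_pred[fc_ok] - map$true_log2fc[fc_ok]

  dis <- result$disparity
  md <- match(paste(map$id_a, map$id_b), paste(dis$id_a, dis$id_b))
  map$changed_pred <- dis$changed[md]
  tested <- !is.na(map$changed_pred)
  sens <- if (any(tested & map$shifted)) {
    mean(map$changed_pred[tested & map$shifted])
  } else NA_real_
  fdr <- if (any(tested & map$changed_pred)) {
    mean(!map$shifted[tested & map$changed_pred])
  } else NA_real_

  gs <- result$gene_scores
  tg <- unique(truth[c("gene", "true_s_du")])
  mg <- match(tg$gene, gs$gene)
  if (all(is.na(mg)) && nrow(gs)) {
    stop_validation("no truth gene ids found in the gene-score table")
  }
  both <- !is.na(mg) & !is.na(tg$true_s_du) & !is.na(gs$S_du[mg])
  s_du_mae <- if (any(both)) {
    mean(abs(gs$S_du[mg][both] - tg$true_s_du[both]))
  } else NA_real_

  list(shape_confusion = shape_confusion,
       fc_bias = mean(fc_err), fc_rmse = sqrt(mean(fc_err^2)),
       disparity_sensitivity = sens, disparity_fdr = fdr,
       s_du_mae = s_du_mae, map = map)
}
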