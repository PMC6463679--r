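# End-to-end driver: chain clustering, annotation, shape/disparity,
# differential and (optionally) sequence-feature stages over a
# translatome/transcriptome pair, and write the result tables.

#' Compare CAGE 5' ends between translatome and transcriptome
#'
#' Runs the full comparison on in-memory inputs: clusters each sample,
#' annotates clusters against the gene annotation, matches clusters across
#' samples, classifies shapes and tests 5'-end distribution disparity,
#' computes per-cluster differential abundance and per-gene selection
#' scores, and (when a genome is given) the sequence-feature comparison of
#' enriched/depleted/control groups.
#'
#' @param ctss_translatome,ctss_transcriptome CTSS data.frames
#'   (see [read_ctss()]).
#' @param index a `feature_index` from [read_annotation()].
#' @param genome optional [Biostrings::DNAStringSet].
#' @param genome_length genome length N for the Poisson background model;
#'   defaults to the summed genome width when `genome` is given, else
#'   required.
#' @param min_tags cluster threshold (default 4).
#' @param shape_min_tags shape/disparity threshold (default 100).
#' @param disparity_alpha KS significance threshold (default 0.001).
#' @param diff_alpha,diff_lfc differential thresholds (defaults 0.05, 1).
#' @param seqfeat_k sequence-feature group size (default 200).
#' @param seed seed for the seqfeat control-group draw.
#' @param library_sizes optional numeric length-2 override for the mapped
#'   totals (translatome, transcriptome); defaults to the summed counts.
#' @return object of class `cage_compare`; see the individual stage
#'   functions for the component tables.
#' @export
cage_pipeline <- function(ctss_translatome, ctss_transcriptome, index,
                          genome = NULL, genome_length = NULL,
                          min_tags = 4L, shape_min_tags = 100L,
                          disparity_alpha = 0.001,
                          diff_alpha = 0.05, diff_lfc = 1,
                          seqfeat_k = 200L, seed = 1L,
                          library_sizes = NULL) {
  if (is.null(genome_length)) {
    if (is.null(genome)) stop_validation("genome_length is required when no genome is given")
    genome_length <- sum(Biostrings::width(genome))
  }
  Ts <- if (is.null(library_sizes)) {
    c(sum(ctss_translatome$count), sum(ctss_transcriptome$count))
  } else library_sizes
  par_a <- cluster_params(genome_length, Ts[1], min_tags = min_tags)
  par_b <- cluster_params(genome_length, Ts[2], min_tags = min_tags)
  tc_a <- cluster_tags(ctss_translatome, par_a)
  tc_b <- cluster_tags(ctss_transcriptome, par_b)
  ann_a <- annotate_clusters(tc_a, index, genome)
  ann_b <- annotate_clusters(tc_b, index, genome)
  match <- match_clusters(tc_a, tc_b)
  shapes_a <- classify_shapes(tc_a, shape_min_tags)
  shapes_b <- classify_shapes(tc_b, shape_min_tags)
  disparity <- ks_disparity(tc_a, tc_b, match$pairs, min_tags = shape_min_tags,
                            alpha = disparity_alpha)
  diff <- tc_diff(tc_a, tc_b, match, alpha = diff_alpha, lfc = diff_lfc)
  # 5'UTR lengths of matched 5'UTR clusters
  la <- five_prime_utr_length(ann_a, index)
  lb <- five_prime_utr_length(ann_b, index)
  mp <- match$pairs
  utr <- data.frame(id_a = mp$id_a, id_b = mp$id_b,
                    len_translatome = la[match(mp$id_a, ann_a$id)],
                    len_transcriptome = lb[match(mp$id_b, ann_b$id)],
                    stringsAsFactors = FALSE)
  utr <- cbind(utr, utr_length_difference(utr$len_translatome,
                                          utr$len_transcriptome))
  utr <- utr[!is.na(utr$len_translatome) | !is.na(utr$len_transcriptome), ,
             drop = FALSE]
  rownames(utr) <- NULL
  promoters <- gene_promoters(ann_a, ann_b, diff)
  scores <- gene_scores(promoters, Ts, alpha = diff_alpha, lfc = diff_lfc)
  expressed <- expressed_flags(ann_b, index)
  # SP/BP share of translatome-enriched clusters versus minimal fold change
  sh_a <- setNames(shapes_a$class, shapes_a$id)
  dd <- diff[!is.na(diff$id_a), , drop = FALSE]
  shape_trend <- shape_fc_trend(unname(sh_a[dd$id_a]), dd$fc,
                                dd$status == "enriched")
  seqfeat <- NULL
  if (!is.null(genome)) {
    seqfeat <- seqfeat_compare(diff, ann_a, ann_b, genome, k = seqfeat_k,
                               seed = seed)
  }
  structure(list(tc_translatome = tc_a, tc_transcriptome = tc_b,
                 annotation_translatome = ann_a, annotation_transcriptome = ann_b,
                 match = match, shapes_translatome = shapes_a,
                 shapes_transcriptome = shapes_b, disparity = disparity,
                 utr_lengths = utr, tc_diff = diff,
                 gene_promoters = promoters, gene_scores = scores,
                 expressed = expressed, shape_trend = shape_trend,
                 seqfeat = seqfeat,
                 library_sizes = Ts,
                 params = list(genome_length = genome_length,
                               min_tags = min_tags,
                               shape_min_tags = shape_min_tags,
                               disparity_alpha = disparity_alpha,
                               diff_alpha = diff_alpha, diff_lfc = diff_lfc,
                               seqfeat_k = seqfeat_k, seed = seed)),
            class = "cage_compare")
}

#' @export
print.cage_compare <- function(x, ...) {
  cat("cage_compare\n")
  cat(sprintf("  clusters: %d translatome, %d transcriptome (min %d tags)\n",
              nrow(x$tc_translatome$clusters), nrow(x$tc_transcriptome$clusters),
              x$params$min_tags))
  cat(sprintf("  matched pairs: %d; disparity-tested (>=%d tags both): %d\n",
              nrow(x$match$pairs), x$params$shape_min_tags, nrow(x$disparity)))
  cat(sprintf("  genes scored: %d\n", nrow(x$gene_scores)))
  invisible(x)
}

#' @export
summary.cage_compare <- function(object, ...) {
  x <- object
  dis <- x$disparity
  d <- x$tc_diff
  tested <- d[d$status %in% c("enriched", "depleted", "unchanged"), , drop = FALSE]
  gs <- x$gene_scores
  out <- list(
    n_clusters = c(translatome = nrow(x$tc_translatome$clusters),
                   transcriptome = nrow(x$tc_transcriptome$clusters)),
    feature_distribution = lapply(
      list(translatome = x$annotation_translatome,
           transcriptome = x$annotation_transcriptome),
      function(a) table(factor(a$feature, levels = c(FEATURE_PRIORITY, "intergenic")))),
    n_disparity_tested = nrow(dis),
    pct_disparity_changed = if (nrow(dis)) 100 * mean(dis$changed) else NA_real_,
    pct_tc_changed = if (nrow(tested)) {
      100 * mean(tested$status %in% c("enriched", "depleted"))
    } else NA_real_,
    n_genes_significant = sum(gs$significant, na.rm = TRUE),
    n_genes_scored = nrow(gs),
    s_du_s_fc_cor = {
      ok <- !is.na(gs$S_du) & !is.na(gs$S_fc) & is.finite(gs$S_fc)
      if (sum(ok) > 2) cor(gs$S_du[ok], gs$S_fc[ok]) else NA_real_
    })
  class(out) <- "summary.cage_compare"
  out
}

#' @export
print.summary.cage_compare <- function(x, ...) {
  cat("Tag clusters:", x$n_clusters["translatome"], "translatome /",
      x$n_clusters["transcriptome"], "transcriptome\n")
  cat(sprintf("5'-end distribution disparity: %d pairs tested, %.1f%% changed\n",
              x$n_disparity_tested, x$pct_disparity_changed))
  cat(sprintf("Differential clusters: %.1f%% with significant RPM change\n",
              x$pct_tc_changed))
  cat(sprintf("Genes: %d scored, %d significantly enriched/depleted\n",
              x$n_genes_scored, x$n_genes_significant))
  cat(sprintf("cor(S_du, S_fc) = %.3f\n", x$s_du_s_fc_cor))
  invisible(x)
}

#' Read a key=value run configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments
#' allowed. Values are parsed as numbers when possible.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop_validation("malformed config line: '%s'", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  num <- suppressWarnings(as.numeric(vals))
  out <- lapply(seq_along(vals), function(i) if (is.na(num[i])) vals[i] else num[i])
  names(out) <- keys
  out
}

#' Run the full pipeline from files and write result tables
#'
#' File-level front end of [cage_pipeline()]: reads the CTSS, annotation
#' and (optional) genome files named in `config`, runs the comparison, and
#' writes five TSV tables (with `#` provenance headers) into
#' `config$out_dir`: `disparity.tsv`, `utr_lengths.tsv`, `tc_diff.tsv`,
#' `gene_scores.tsv` and `s_du.tsv`, plus `tc_translatome.tsv` /
#' `tc_transcriptome.tsv` cluster tables and, when a genome is given,
#' `seqfeat.tsv`.
#'
#' @param config named list (or path to a `key = value` file, see
#'   [read_run_config()]) with entries `ctss_translatome`,
#'   `ctss_transcriptome`, `annotation`, `out_dir`, optional `genome`,
#'   `genome_length`, and the [cage_pipeline()] thresholds `min_tags`,
#'   `shape_min_tags`, `disparity_alpha`, `diff_alpha`, `diff_lfc`,
#'   `seqfeat_k`, `seed`.
#' @return The `cage_compare` object, invisibly; tables on disk.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  required <- c("ctss_translatome", "ctss_transcriptome", "annotation", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop_validation("config is missing required field(s): %s",
                    paste(missing, collapse = ", "))
  }
  for (f in c("ctss_translatome", "ctss_transcriptome", "annotation", "genome")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop_validation("config field '%s': file not found: %s", f, config[[f]])
    }
  }
  ctss_a <- read_ctss(config$ctss_translatome)
  ctss_b <- read_ctss(config$ctss_transcriptome)
  index <- read_annotation(config$annotation)
  genome <- if (!is.null(config$genome)) read_fasta(config$genome) else NULL
  opt <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  res <- cage_pipeline(
    ctss_a, ctss_b, index, genome = genome,
    genome_length = config$genome_length,
    min_tags = opt("min_tags", 4L),
    shape_min_tags = opt("shape_min_tags", 100L),
    disparity_alpha = opt("disparity_alpha", 0.001),
    diff_alpha = opt("diff_alpha", 0.05),
    diff_lfc = opt("diff_lfc", 1),
    seqfeat_k = opt("seqfeat_k", 200L),
    seed = opt("seed", 1L))
  write_run_tables(res, config$out_dir)
  invisible(res)
}

#' Write the result tables of a comparison
#'
#' @param res a `cage_compare` object.
#' @param out_dir output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_run_tables <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- res$params
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_provenance(df, path, params = p)
    path
  }
  files <- c(
    tc_translatome = {
      path <- file.path(out_dir, "tc_translatome.tsv")
      write_tc_table(res$tc_translatome, path, params = p)
      path
    },
    tc_transcriptome = {
      path <- file.path(out_dir, "tc_transcriptome.tsv")
      write_tc_table(res$tc_transcriptome, path, params = p)
      path
    },
    disparity = w(res$disparity, "disparity.tsv"),
    utr_lengths = w(res$utr_lengths, "utr_lengths.tsv"),
    tc_diff = w(res$tc_diff, "tc_diff.tsv"),
    gene_scores = w(res$gene_scores, "gene_scores.tsv"),
    s_du = w(res$gene_scores[!is.na(res$gene_scores$S_du),
                             c("gene", "n_promoters", "S_du")], "s_du.tsv"))
  if (!is.null(res$seqfeat)) {
    sf <- res$seqfeat
    tab <- data.frame(group = names(sf$gc), gc = unname(sf$gc),
                      aug_total = unname(sf$aug),
                      tata_fold_vs_control = c(sf$tata_enriched_vs_control$fold,
                                               sf$tata_depleted_vs_control$fold, 1),
                      stringsAsFactors = FALSE)
    files <- c(files, seqfeat = w(tab, "seqfeat.tsv"))
    for (grp in names(sf$detail)) {
      fa <- file.path(out_dir, sprintf("windows_%s.fa", grp))
      write_window_fasta(sf$detail[[grp]]$down$seq, fa)
      files <- c(files, setNames(fa, paste0("fasta_", grp)))
    }
  }
  invisible(files)
}
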