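# Readers and writers for the external formats the pipeline touches.
#
# Coordinate conventions: CTSS files and all user-facing tables are 1-based
# single positions / closed intervals. Internally, interval work is done with
# IRanges (1-based, closed); conversions from GTF/GFF (also 1-based closed)
# are therefore the identity and trivially lossless.

#' Read a CTSS table
#'
#' Reads a tab-separated CAGE transcription start site (CTSS) file with
#' columns chrom, pos (1-based 5'-end position), strand and tag count.
#' Lines starting with `#` are ignored.
#'
#' @param path path to a CTSS TSV file.
#' @return A data.frame with columns `chrom`, `pos`, `strand`, `count`,
#'   sorted by (chrom, strand, pos). The (chrom, pos, strand) key is unique.
#' @export
read_ctss <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    stop_validation("malformed CTSS line %d: expected 4 tab-separated fields, got %d",
                    lineno[which(nf != 4L)[1]], nf[nf != 4L][1])
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  count <- suppressWarnings(as.integer(m[, 4]))
  bad <- is.na(pos) | is.na(count)
  if (any(bad)) {
    stop_validation("malformed CTSS line %d: non-integer pos or count",
                    lineno[which(bad)[1]])
  }
  if (any(pos < 1L)) {
    stop_validation("invalid CTSS line %d: pos must be >= 1", lineno[which(pos < 1L)[1]])
  }
  if (any(count < 0L)) {
    stop_validation("invalid CTSS line %d: negative count", lineno[which(count < 0L)[1]])
  }
  check_strand(m[, 3])
  df <- data.frame(chrom = m[, 1], pos = pos, strand = m[, 3], count = count,
                   stringsAsFactors = FALSE)
  key <- paste(df$chrom, df$pos, df$strand)
  if (anyDuplicated(key)) {
    stop_validation("duplicate CTSS key (chrom, pos, strand): %s",
                    key[duplicated(key)][1])
  }
  df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
}

#' Write a CTSS table
#'
#' Inverse of [read_ctss()]; writes chrom/pos/strand/count as plain TSV
#' (no header, no comments) so the file is readable by other CAGE tools.
#'
#' @param ctss a CTSS data.frame as returned by [read_ctss()].
#' @param path output path.
#' @export
write_ctss <- function(ctss, path) {
  write.table(ctss[, c("chrom", "pos", "strand", "count")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Sniff GTF (key "value";) vs GFF3 (key=value) attribute dialect.
sniff_annotation_format <- function(path) {
  lines <- readLines(path, n = 200L)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop_validation("annotation file %s has no feature lines", path)
  attr9 <- sub("^([^\t]*\t){8}", "", lines[1])
  if (grepl("=", attr9, fixed = TRUE) && !grepl("\"", attr9, fixed = TRUE)) "gff3" else "gtf"
}

#' Read a gene annotation into a feature index
#'
#' Imports a GTF/GFF file (exon and CDS features carrying
#' transcript_id/gene_id attributes; both the `key "value";` and `key=value`
#' attribute dialects are accepted) and derives the strand-aware interval
#' sets used to annotate tag clusters:
#' \itemize{
#'   \item `five_prime_utr_ext`: exonic sequence 5' of the first CDS base,
#'     plus the 100 nt immediately upstream of the annotated transcript start;
#'   \item `three_prime_utr`: exonic sequence 3' of the last CDS base;
#'   \item `cds`: the annotated CDS intervals;
#'   \item `intron`: gaps between consecutive exons of a transcript.
#' }
#' Transcripts without CDS contribute no UTR/CDS intervals.
#'
#' @param path path to a GTF or GFF3 file.
#' @param utr_extension nt of upstream sequence merged into the 5' UTR
#'   (default 100).
#' @return An object of class `feature_index`: a list with `features`
#'   (a named list of [GenomicRanges::GRanges] with `tx` and `gene`
#'   metadata columns), `tx2gene`, and per-transcript `tx_chrom`,
#'   `tx_strand`, `tx_tss` (annotated transcript 5' end) and `start_codon`
#'   (first CDS base in transcript orientation; NA when absent).
#' @export
read_annotation <- function(path, utr_extension = 100L) {
  fmt <- sniff_annotation_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- tolower(as.character(df$type))
  if (!all(c("transcript_id", "gene_id") %in% names(df))) {
    stop_validation("annotation lacks transcript_id/gene_id attributes")
  }
  build_feature_index(df[df$type %in% c("exon", "cds"), , drop = FALSE],
                      utr_extension = utr_extension)
}

# df: seqnames,start,end,strand,type("exon"/"cds"),transcript_id,gene_id
build_feature_index <- function(df, utr_extension = 100L) {
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  check_strand(df$strand)
  exons <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "cds", , drop = FALSE]
  no_exon <- setdiff(unique(cds$transcript_id), unique(exons$transcript_id))
  if (length(no_exon)) {
    stop_validation("transcript(s) with CDS but no exons: %s",
                    paste(head(no_exon, 3), collapse = ", "))
  }
  txs <- unique(exons$transcript_id)
  out <- list(five_prime_utr_ext = list(), three_prime_utr = list(),
              cds = list(), intron = list())
  tx_meta <- data.frame(tx = txs, gene = NA_character_, chrom = NA_character_,
                        strand = NA_character_, tss = NA_integer_,
                        start_codon = NA_integer_, stringsAsFactors = FALSE)
  exon_by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  cds_by_tx <- split(seq_len(nrow(cds)), cds$transcript_id)
  for (i in seq_along(txs)) {
    tx <- txs[i]
    ex <- exons[exon_by_tx[[tx]], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    strand <- ex$strand[1]
    chrom <- ex$seqnames[1]
    gene <- ex$gene_id[1]
    tss <- if (strand == "+") min(ex$start) else max(ex$end)
    tx_meta$gene[i] <- gene
    tx_meta$chrom[i] <- chrom
    tx_meta$strand[i] <- strand
    tx_meta$tss[i] <- tss
    add <- function(kind, start, end) {
      keep <- start <= end
      if (!any(keep)) return()
      out[[kind]][[length(out[[kind]]) + 1L]] <<- data.frame(
        chrom = chrom, start = start[keep], end = end[keep], strand = strand,
        tx = tx, gene = gene, stringsAsFactors = FALSE)
    }
    if (nrow(ex) > 1L) {
      add("intron", head(ex$end, -1L) + 1L, tail(ex$start, -1L) - 1L)
    }
    ci <- cds_by_tx[[tx]]
    if (!is.null(ci)) {
      cd <- cds[ci, , drop = FALSE]
      add("cds", cd$start, cd$end)
      if (strand == "+") {
        first_cds <- min(cd$start); last_cds <- max(cd$end)
        tx_meta$start_codon[i] <- first_cds
        # exonic sequence strictly 5' of the first CDS base
        u5s <- pmin(ex$start, first_cds); u5e <- pmin(ex$end, first_cds - 1L)
        add("five_prime_utr_ext", u5s, u5e)
        add("five_prime_utr_ext", tss - utr_extension, tss - 1L)
        u3s <- pmax(ex$start, last_cds + 1L); u3e <- pmax(ex$end, last_cds)
        add("three_prime_utr", u3s, u3e)
      } else {
        first_cds <- max(cd$end); last_cds <- min(cd$start)
        tx_meta$start_codon[i] <- first_cds
        u5s <- pmax(ex$start, first_cds + 1L); u5e <- pmax(ex$end, first_cds)
        add("five_prime_utr_ext", u5s, u5e)
        add("five_prime_utr_ext", tss + 1L, tss + utr_extension)
        u3s <- pmin(ex$start, last_cds); u3e <- pmin(ex$end, last_cds - 1L)
        add("three_prime_utr", u3s, u3e)
      }
    }
  }
  to_granges <- function(lst) {
    if (!length(lst)) {
      return(GenomicRanges::GRanges(tx = character(), gene = character()))
    }
    d <- do.call(rbind, lst)
    d <- d[d$start <= d$end, , drop = FALSE]
    GenomicRanges::GRanges(d$chrom,
                           IRanges::IRanges(pmax(d$start, 1L), d$end),
                           strand = d$strand, tx = d$tx, gene = d$gene)
  }
  idx <- list(features = lapply(out, to_granges),
              tx2gene = setNames(tx_meta$gene, tx_meta$tx),
              tx_chrom = setNames(tx_meta$chrom, tx_meta$tx),
              tx_strand = setNames(tx_meta$strand, tx_meta$tx),
              tx_tss = setNames(tx_meta$tss, tx_meta$tx),
              start_codon = setNames(tx_meta$start_codon, tx_meta$tx),
              utr_extension = as.integer(utr_extension))
  names(idx$features) <- c("5utr", "3utr", "cds", "intron")
  class(idx) <- "feature_index"
  idx
}

#' @export
print.feature_index <- function(x, ...) {
  cat("feature_index:", length(x$tx2gene), "transcripts,",
      length(unique(x$tx2gene)), "genes\n")
  for (k in names(x$features)) {
    cat(sprintf("  %-6s %d intervals\n", k, length(x$features[[k]])))
  }
  invisible(x)
}

#' Read a genome FASTA
#'
#' @param path FASTA file; sequence names are truncated at the first
#'   whitespace.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Fetch a genomic sequence window
#'
#' Returns the sequence of `chrom:start-end` (1-based, closed) on the given
#' strand; on the minus strand the reverse complement is returned, so the
#' result always reads 5' to 3' in transcript orientation.
#'
#' @param genome a [Biostrings::DNAStringSet] from [read_fasta()].
#' @param chrom,start,end,strand window coordinates.
#' @return A character scalar.
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop_validation("chromosome '%s' not present in genome", chrom)
  }
  len <- length(genome[[chrom]])
  if (start < 1 || end > len || start > end) {
    stop_validation("window %s:%d-%d out of bounds (length %d)",
                    chrom, start, end, len)
  }
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Write / read a tag-cluster table
#'
#' Serializes the cluster table of a [cluster_tags()] result as TSV (with
#' `#` provenance header lines); the per-position 5'-end counts are encoded
#' in a `ctss` column as `pos:count` pairs separated by commas. A
#' write-then-read round trip reproduces every field exactly.
#'
#' @param tc a `tc_set` object from [cluster_tags()].
#' @param path file path.
#' @param params optional named list recorded in the header.
#' @return `read_tc_table()` returns a `tc_set` object.
#' @export
write_tc_table <- function(tc, path, params = NULL) {
  stopifnot(inherits(tc, "tc_set"))
  cl <- tc$clusters
  ctss_by_cluster <- split(tc$ctss[c("pos", "count")], tc$ctss$cluster_id)
  enc <- vapply(cl$id, function(id) {
    d <- ctss_by_cluster[[id]]
    paste(sprintf("%d:%d", d$pos, d$count), collapse = ",")
  }, character(1))
  out <- cbind(cl, data.frame(ctss = enc, stringsAsFactors = FALSE))
  write_tsv_provenance(out, path,
                       params = c(list(library_size = tc$library_size), params))
  invisible(path)
}

#' @rdname write_tc_table
#' @export
read_tc_table <- function(path) {
  df <- read_tsv_provenance(path)
  ctss <- lapply(seq_len(nrow(df)), function(i) {
    pairs <- strsplit(strsplit(df$ctss[i], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    m <- matrix(as.integer(unlist(pairs)), ncol = 2L, byrow = TRUE)
    data.frame(chrom = df$chrom[i], pos = m[, 1], strand = df$strand[i],
               count = m[, 2], cluster_id = df$id[i], stringsAsFactors = FALSE)
  })
  lib <- NA_real_
  hdr <- grep("^# library_size=", readLines(path, n = 20L), value = TRUE)
  if (length(hdr)) lib <- as.numeric(sub("^# library_size=", "", hdr[1]))
  structure(list(clusters = df[setdiff(names(df), "ctss")],
                 ctss = do.call(rbind, ctss),
                 library_size = lib),
            class = "tc_set")
}
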