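# Tag clustering: merge overlapping 27-nt tag bodies into tag clusters and
# keep those with at least `min_tags` tags, the threshold justified by a
# Poisson background model of randomly scattered tags.

#' Clustering parameters
#'
#' @param genome_length total genome length N in nt (used by the Poisson
#'   background model).
#' @param library_size total number of uniquely mapped tags T; when `NULL`
#'   it defaults, at clustering time, to the summed counts of the input.
#' @param tag_length CAGE tag length in nt (default 27).
#' @param min_tags minimum tags for a tag set to become a cluster (default 4).
#' @param alpha significance bound the min_tags rule is checked against
#'   (default 0.001).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(genome_length, library_size = NULL,
                           tag_length = 27L, min_tags = 4L, alpha = 0.001) {
  if (tag_length < 1L) stop_validation("tag_length must be >= 1")
  if (min_tags < 1L) stop_validation("min_tags must be >= 1")
  if (genome_length <= 0) stop_validation("genome_length N must be positive")
  if (!is.null(library_size) && library_size <= 0) {
    stop_validation("library_size T must be positive")
  }
  structure(list(genome_length = as.numeric(genome_length),
                 library_size = library_size,
                 tag_length = as.integer(tag_length),
                 min_tags = as.integer(min_tags), alpha = alpha),
            class = "cluster_params")
}

# Genomic span of the tag body whose 5' end is at `pos`: the tag runs
# 5'->3' from the cap, so on the minus strand the body covers the
# `tag_length` nt ending at `pos`.
tag_body <- function(pos, strand, tag_length) {
  start <- ifelse(strand == "+", pos, pos - tag_length + 1L)
  data.frame(start = as.integer(start),
             end = as.integer(start + tag_length - 1L))
}

#' Group overlapping same-strand tags into tag sets
#'
#' Single-linkage merge: tag bodies (tag_length-nt spans downstream of each
#' 5' end in transcript orientation) that overlap by at least 1 nt on the
#' same strand belong to the same set; the merge is transitive.
#'
#' @param ctss a CTSS data.frame (see [read_ctss()]).
#' @param params a [cluster_params()] object.
#' @return The input with an added integer `set_id` column, plus a `sets`
#'   attribute data.frame (set_id, chrom, strand, start, end, n).
#' @export
build_tag_sets <- function(ctss, params) {
  if (!nrow(ctss)) {
    ctss$set_id <- integer()
    attr(ctss, "sets") <- data.frame(set_id = integer(), chrom = character(),
                                     strand = character(), start = integer(),
                                     end = integer(), n = integer())
    return(ctss)
  }
  body <- tag_body(ctss$pos, ctss$strand, params$tag_length)
  gr <- GenomicRanges::GRanges(ctss$chrom,
                               IRanges::IRanges(body$start, body$end),
                               strand = ctss$strand)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  set_id <- integer(nrow(ctss))
  set_id[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  ctss$set_id <- set_id
  n <- as.integer(tapply(ctss$count, ctss$set_id, sum)[as.character(seq_along(merged))])
  attr(ctss, "sets") <- data.frame(
    set_id = seq_along(merged),
    chrom = as.character(GenomicRanges::seqnames(merged)),
    strand = as.character(GenomicRanges::strand(merged)),
    start = GenomicRanges::start(merged), end = GenomicRanges::end(merged),
    n = n, stringsAsFactors = FALSE)
  ctss
}

#' Poisson background p-value for a tag set
#'
#' Under a background model of `T` tags scattered uniformly on a genome of
#' length `N`, the number of tags falling in a tag set of length
#' `(n-1) * tag_length` nt is Poisson with
#' `lambda = (n-1) * tag_length / N * T`. The returned value is the upper
#' tail `P(X >= n)`. For `n = 1` the set has zero length, `lambda = 0`, and
#' the tail is 0.
#'
#' @param n observed tag count(s); vectorized.
#' @param params a [cluster_params()] object with `genome_length` and
#'   `library_size` set.
#' @return `P(X >= n)` for each `n`.
#' @export
poisson_pvalue <- function(n, params) {
  if (any(n < 1)) stop_validation("n must be >= 1")
  T <- params$library_size
  if (is.null(T)) stop_validation("params$library_size (T) is required")
  if (T <= 0 || params$genome_length <= 0) {
    stop_validation("genome_length and library_size must be positive")
  }
  lambda <- (n - 1) * params$tag_length / params$genome_length * T
  ppois(n - 1, lambda, lower.tail = FALSE)
}

#' Identify tag clusters in one sample
#'
#' Tag sets (see [build_tag_sets()]) with at least `params$min_tags` tags
#' become tag clusters. The min-tags rule is the operative filter; the
#' Poisson background p-value of each kept cluster is computed and reported,
#' and a warning is raised if any kept cluster exceeds `params$alpha`
#' (possible when N is small relative to T, unlike a mammalian genome).
#'
#' @param ctss one sample's CTSS data.frame.
#' @param params a [cluster_params()] object.
#' @return An object of class `tc_set`: list with
#'   \describe{
#'     \item{clusters}{data.frame id, chrom, strand, start, end, n, rpm,
#'       pvalue; `id` is `"chrom:strand:start-end"`.}
#'     \item{ctss}{the clustered CTSS rows with a `cluster_id` column.}
#'     \item{library_size}{T used for RPM and the Poisson model.}
#'     \item{params}{the parameters used.}
#'   }
#' @export
cluster_tags <- function(ctss, params) {
  total_input <- sum(ctss$count)
  if (is.null(params$library_size)) params$library_size <- total_input
  tagged <- build_tag_sets(ctss, params)
  sets <- attr(tagged, "sets")
  keep <- sets[sets$n >= params$min_tags, , drop = FALSE]
  id_map <- setNames(rep(NA_character_, nrow(sets)), sets$set_id)
  cl <- data.frame(id = character(0))
  if (nrow(keep)) {
    cl <- data.frame(
      id = sprintf("%s:%s:%d-%d", keep$chrom, keep$strand, keep$start, keep$end),
      chrom = keep$chrom, strand = keep$strand,
      start = keep$start, end = keep$end, n = keep$n,
      rpm = rpm(keep$n, params$library_size),
      pvalue = poisson_pvalue(keep$n, params),
      stringsAsFactors = FALSE)
    id_map[as.character(keep$set_id)] <- cl$id
    if (any(cl$pvalue > params$alpha)) {
      warning(sprintf("%d cluster(s) exceed the Poisson background bound alpha=%g; min_tags=%d is not significant for this N/T",
                      sum(cl$pvalue > params$alpha), params$alpha, params$min_tags),
              call. = FALSE)
    }
  }
  kept_ctss <- tagged
  kept_ctss$cluster_id <- unname(id_map[as.character(tagged$set_id)])
  kept_ctss <- kept_ctss[!is.na(kept_ctss$cluster_id), , drop = FALSE]
  kept_ctss$set_id <- NULL
  attr(kept_ctss, "sets") <- NULL
  rownames(kept_ctss) <- NULL
  rownames(cl) <- NULL
  structure(list(clusters = cl, ctss = kept_ctss,
                 library_size = params$library_size, params = params),
            class = "tc_set")
}

#' @export
print.tc_set <- function(x, ...) {
  cat(sprintf("tc_set: %d clusters, %d tags clustered (library size %s)\n",
              nrow(x$clusters), sum(x$clusters$n),
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

# Per-cluster CTSS rows as a named list of data.frames (pos, count),
# in cluster-table order.
split_cluster_ctss <- function(tc) {
  out <- split(tc$ctss[c("pos", "count")],
               factor(tc$ctss$cluster_id, levels = tc$clusters$id))
  out
}

#' Reads-per-million normalization
#'
#' @param count read/tag count(s) of a cluster or position.
#' @param total_mapped total mapped reads of the library.
#' @return `count / total_mapped * 1e6`.
#' @export
rpm <- function(count, total_mapped) {
  if (is.null(total_mapped) || length(total_mapped) != 1L || total_mapped <= 0) {
    stop_validation("total_mapped must be a single positive number")
  }
  if (any(count < 0)) stop_validation("count must be non-negative")
  count / total_mapped * 1e6
}
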