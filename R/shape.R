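# Core-promoter shape classification (SP/DP/MP/BP) and 5'-end distribution
# disparity testing between conditions.

# Nearest-rank percentile on the tag-weighted position multiset: the
# smallest position whose cumulative count reaches ceiling(q * n).
weighted_percentile <- function(pos, count, q) {
  ord <- order(pos)
  pos <- pos[ord]; count <- count[ord]
  cum <- cumsum(count)
  n <- cum[length(cum)]
  vapply(q, function(p) pos[which(cum >= ceiling(p * n))[1]], numeric(1))
}

#' Classify the shape of a tag cluster
#'
#' Four-way promoter-architecture classification of the 5'-end
#' distribution, applied to clusters with at least `min_tags` tags.
#' The criteria are evaluated strictly in order; the first match wins:
#' \enumerate{
#'   \item SP (single dominant peak): the distance between the 25th and
#'     75th percentile of the tag positions is < 4 nt, or the distance
#'     between the 15th and 85th percentile is < 6 nt;
#'   \item DP (broad, one dominant peak): the ratio of the highest to
#'     second-highest single-position count is > 2 and the highest peak
#'     holds > 20% of all tags;
#'   \item MP (bi-/multi-peak): taking as peaks all positions holding
#'     > 15% of the tags, every pair of consecutive peaks (sorted by
#'     coordinate) is > 5 nt apart (at least two such peaks required);
#'   \item BP (generally broad): everything else.
#' }
#' Percentiles are nearest-rank values on the tag-weighted position
#' multiset; a "peak" is the count at a single genomic position; distances
#' are absolute coordinate differences.
#'
#' @param pos,count per-position 5'-end counts of one cluster.
#' @param min_tags minimum tag count for classification (default 100).
#' @return list with `class` (`"SP"|"DP"|"MP"|"BP"`, or NA below
#'   `min_tags`), percentile positions q15/q25/q75/q85 and the top two
#'   peak counts.
#' @export
classify_shape <- function(pos, count, min_tags = 100L) {
  n <- sum(count)
  if (n < min_tags) {
    return(list(class = NA_character_, q15 = NA, q25 = NA, q75 = NA, q85 = NA,
                peak1 = NA, peak2 = NA))
  }
  qs <- weighted_percentile(pos, count, c(0.15, 0.25, 0.75, 0.85))
  srt <- sort(count, decreasing = TRUE)
  peak1 <- srt[1]
  peak2 <- if (length(srt) > 1L) srt[2] else 0
  cls <- if ((qs[3] - qs[2]) < 4 || (qs[4] - qs[1]) < 6) {
    "SP"
  } else if (peak1 / max(peak2, .Machine$double.xmin) > 2 && peak1 / n > 0.2) {
    "DP"
  } else {
    peaks <- sort(pos[count / n > 0.15])
    if (length(peaks) >= 2L && all(diff(peaks) > 5)) "MP" else "BP"
  }
  list(class = cls, q15 = qs[1], q25 = qs[2], q75 = qs[3], q85 = qs[4],
       peak1 = peak1, peak2 = peak2)
}

#' Classify every cluster of a sample
#'
#' @param tc a `tc_set`.
#' @param min_tags classification threshold (default 100).
#' @return data.frame id, n, class, q15, q25, q75, q85, peak1, peak2
#'   (class NA below the threshold).
#' @export
classify_shapes <- function(tc, min_tags = 100L) {
  by_cl <- split_cluster_ctss(tc)
  res <- lapply(by_cl, function(d) classify_shape(d$pos, d$count, min_tags))
  data.frame(id = tc$clusters$id, n = tc$clusters$n,
             class = vapply(res, `[[`, character(1), "class"),
             q15 = vapply(res, function(r) as.numeric(r$q15), numeric(1)),
             q25 = vapply(res, function(r) as.numeric(r$q25), numeric(1)),
             q75 = vapply(res, function(r) as.numeric(r$q75), numeric(1)),
             q85 = vapply(res, function(r) as.numeric(r$q85), numeric(1)),
             peak1 = vapply(res, function(r) as.numeric(r$peak1), numeric(1)),
             peak2 = vapply(res, function(r) as.numeric(r$peak2), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Match clusters between two samples by genomic overlap
#'
#' Pairs same-strand clusters whose spans overlap by at least 1 nt.
#' Many-to-many overlaps are resolved greedily to the pairs with maximal
#' shared-position tag mass (sum over positions present in both clusters of
#' the smaller of the two counts; ties broken by overlap width, then by
#' cluster id), each cluster used at most once.
#'
#' @param tc_a,tc_b `tc_set` objects (conventionally translatome = a,
#'   transcriptome = b).
#' @return list with `pairs` (data.frame id_a, id_b, shared_mass,
#'   overlap_width), `only_a` and `only_b` (unmatched cluster ids).
#' @export
match_clusters <- function(tc_a, tc_b) {
  a <- tc_a$clusters; b <- tc_b$clusters
  empty <- data.frame(id_a = character(), id_b = character(),
                      shared_mass = numeric(), overlap_width = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) {
    return(list(pairs = empty, only_a = a$id, only_b = b$id))
  }
  gra <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end),
                                strand = a$strand)
  grb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end),
                                strand = b$strand)
  hit <- GenomicRanges::findOverlaps(gra, grb)
  qa <- S4Vectors::queryHits(hit); qb <- S4Vectors::subjectHits(hit)
  if (!length(qa)) return(list(pairs = empty, only_a = a$id, only_b = b$id))
  ca <- split_cluster_ctss(tc_a); cb <- split_cluster_ctss(tc_b)
  mass <- numeric(length(qa)); width <- integer(length(qa))
  for (i in seq_along(qa)) {
    da <- ca[[qa[i]]]; db <- cb[[qb[i]]]
    common <- intersect(da$pos, db$pos)
    mass[i] <- sum(pmin(da$count[match(common, da$pos)],
                        db$count[match(common, db$pos)]))
    width[i] <- min(a$end[qa[i]], b$end[qb[i]]) - max(a$start[qa[i]], b$start[qb[i]]) + 1L
  }
  ord <- order(-mass, -width, a$id[qa], b$id[qb])
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(length(ord))
  for (k in ord) {
    if (!used_a[qa[k]] && !used_b[qb[k]]) {
      keep[k] <- TRUE
      used_a[qa[k]] <- TRUE
      used_b[qb[k]] <- TRUE
    }
  }
  pairs <- data.frame(id_a = a$id[qa[keep]], id_b = b$id[qb[keep]],
                      shared_mass = mass[keep], overlap_width = width[keep],
                      stringsAsFactors = FALSE)
  list(pairs = pairs, only_a = a$id[!used_a], only_b = b$id[!used_b])
}

#' Two-sample Kolmogorov-Smirnov statistic on weighted position multisets
#'
#' Each tag is one sample point; `D` is the maximum absolute difference of
#' the two empirical CDFs over the union of positions.
#'
#' @param pos_a,count_a,pos_b,count_b per-position counts of the two
#'   clusters.
#' @return The statistic `D` in [0, 1].
#' @export
ks_stat <- function(pos_a, count_a, pos_b, count_b) {
  grid <- sort(unique(c(pos_a, pos_b)))
  cdf <- function(pos, count) {
    ord <- order(pos)
    pos <- pos[ord]; cum <- cumsum(count[ord]) / sum(count)
    idx <- findInterval(grid, pos)
    c(0, cum)[idx + 1L]
  }
  max(abs(cdf(pos_a, count_a) - cdf(pos_b, count_b)))
}

#' Asymptotic two-sample KS p-value
#'
#' Upper tail of the Kolmogorov distribution,
#' `Q(x) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 x^2)` at
#' `x = sqrt(n_a n_b / (n_a + n_b)) * D`.
#'
#' @param D the KS statistic.
#' @param n_a,n_b the two sample sizes (tag counts).
#' @return p-value in [0, 1].
#' @export
ks_pvalue <- function(D, n_a, n_b) {
  x <- sqrt(n_a * n_b / (n_a + n_b)) * D
  if (x < 0.05) return(1)
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

#' 5'-end distribution disparity between matched clusters
#'
#' For each matched pair where both clusters have at least `min_tags` tags,
#' performs a two-sample KS test on the tag-position multisets (each tag a
#' sample point, asymptotic p-value), adjusts p-values across all tested
#' pairs with Benjamini-Hochberg, and flags pairs as changed at
#' `p < alpha` (raw p by default; set `use_adjusted = TRUE` to threshold
#' the BH-adjusted values instead — both are always reported).
#'
#' @param tc_a,tc_b the two `tc_set` objects.
#' @param pairs the `pairs` data.frame from [match_clusters()] (computed
#'   when omitted).
#' @param min_tags minimum tags in both clusters (default 100).
#' @param alpha significance threshold (default 0.001).
#' @param use_adjusted threshold the BH q-values instead of raw p.
#' @param shape_min_tags threshold for the accompanying shape calls.
#' @return data.frame id_a, id_b, n_a, n_b, ks_D, p, q, shape_a, shape_b,
#'   changed, shape_changed — one row per tested pair.
#' @export
ks_disparity <- function(tc_a, tc_b, pairs = NULL, min_tags = 100L,
                         alpha = 0.001, use_adjusted = FALSE,
                         shape_min_tags = min_tags) {
  if (is.null(pairs)) pairs <- match_clusters(tc_a, tc_b)$pairs
  ca <- split_cluster_ctss(tc_a); cb <- split_cluster_ctss(tc_b)
  na <- setNames(tc_a$clusters$n, tc_a$clusters$id)
  nb <- setNames(tc_b$clusters$n, tc_b$clusters$id)
  tested <- pairs[na[pairs$id_a] >= min_tags & nb[pairs$id_b] >= min_tags, ,
                  drop = FALSE]
  k <- nrow(tested)
  out <- data.frame(id_a = tested$id_a, id_b = tested$id_b,
                    n_a = unname(na[tested$id_a]), n_b = unname(nb[tested$id_b]),
                    ks_D = rep(NA_real_, k), p = rep(NA_real_, k),
                    q = rep(NA_real_, k),
                    shape_a = rep(NA_character_, k),
                    shape_b = rep(NA_character_, k),
                    changed = rep(NA, k), shape_changed = rep(NA, k),
                    stringsAsFactors = FALSE)
  if (!k) return(out)
  ia <- match(out$id_a, tc_a$clusters$id)
  ib <- match(out$id_b, tc_b$clusters$id)
  for (i in seq_len(nrow(out))) {
    da <- ca[[ia[i]]]; db <- cb[[ib[i]]]
    out$ks_D[i] <- ks_stat(da$pos, da$count, db$pos, db$count)
    out$p[i] <- ks_pvalue(out$ks_D[i], out$n_a[i], out$n_b[i])
    out$shape_a[i] <- classify_shape(da$pos, da$count, shape_min_tags)$class
    out$shape_b[i] <- classify_shape(db$pos, db$count, shape_min_tags)$class
  }
  out$q <- bh_adjust(out$p)
  out$changed <- (if (use_adjusted) out$q else out$p) < alpha
  out$shape_changed <- out$shape_a != out$shape_b
  out
}

#' Shape-class share of translatome-enriched clusters versus fold change
#'
#' For each minimal fold-change cutoff, the percentage of qualifying
#' translatome-enriched clusters in the SP and BP shape classes, and the
#' Pearson correlation of each percentage against the cutoff (NA when
#' fewer than 3 non-empty bins or zero variance).
#'
#' @param shape_class shape class per cluster (`"SP"`..., NA allowed).
#' @param fc fold change per cluster (translatome / transcriptome RPM).
#' @param enriched logical, cluster significantly translatome-enriched.
#' @param thresholds fold-change cutoffs (default `2^(0:4)`).
#' @return list with `table` (threshold, n, pct_SP, pct_BP) and
#'   correlations `r_SP`, `r_BP`.
#' @export
shape_fc_trend <- function(shape_class, fc, enriched,
                           thresholds = 2^(0:4)) {
  ok <- enriched & !is.na(shape_class) & !is.na(fc)
  tab <- data.frame(threshold = thresholds, n = NA_integer_,
                    pct_SP = NA_real_, pct_BP = NA_real_)
  for (i in seq_along(thresholds)) {
    sel <- shape_class[ok & fc >= thresholds[i]]
    tab$n[i] <- length(sel)
    if (length(sel)) {
      tab$pct_SP[i] <- 100 * mean(sel == "SP")
      tab$pct_BP[i] <- 100 * mean(sel == "BP")
    }
  }
  safe_cor <- function(y) {
    d <- tab[!is.na(y), , drop = FALSE]
    yy <- y[!is.na(y)]
    if (nrow(d) < 3L || stats::sd(yy) == 0 || stats::sd(d$threshold) == 0) {
      return(NA_real_)
    }
    cor(d$threshold, yy)
  }
  list(table = tab, r_SP = safe_cor(tab$pct_SP), r_BP = safe_cor(tab$pct_BP))
}
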