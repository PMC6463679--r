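# Polysome-selection quantification: per-cluster abundance change between
# translatome and transcriptome, and per-gene abundance (E_p, E_t),
# fold-change score S_fc and differential-usage score S_du.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p p-values in [0, 1] (NA allowed, ignored and propagated).
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop_validation("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

# Exact two-library binomial test: k1 successes out of k1+k2 trials with
# success probability T1/(T1+T2) under the null of equal relative abundance.
binom_two_lib <- function(k1, k2, T1, T2) {
  if (k1 + k2 < 1) return(NA_real_)
  binom.test(k1, k1 + k2, p = T1 / (T1 + T2))$p.value
}

#' Per-cluster differential abundance between two libraries
#'
#' For each matched cluster pair (plus unmatched clusters, which enter with
#' a zero count on the absent side), computes RPM in both libraries, the
#' fold change `FC = RPM_translatome / RPM_transcriptome`, an exact
#' two-sided binomial test of the translatome count against the pair total
#' with success probability `T1/(T1+T2)`, a normal-approximation z score,
#' BH-adjusted q-values, and a status call:
#' `enriched` when `log2 FC >= lfc` and `p < alpha`, `depleted` when
#' `log2 FC <= -lfc` and `p < alpha`, `translatome_only` /
#' `transcriptome_only` when the count is zero on exactly one side
#' (FC undefined), otherwise `unchanged`.
#'
#' @param tc_a,tc_b `tc_set` objects (a = translatome, b = transcriptome).
#' @param match a [match_clusters()] result (computed when omitted).
#' @param alpha significance level (default 0.05).
#' @param lfc minimal |log2 FC| (default 1).
#' @return data.frame id_a, id_b, count_a, count_b, rpm_a, rpm_b, fc,
#'   log2fc, z, p, q, status.
#' @export
tc_diff <- function(tc_a, tc_b, match = NULL, alpha = 0.05, lfc = 1) {
  if (is.null(match)) match <- match_clusters(tc_a, tc_b)
  na <- setNames(tc_a$clusters$n, tc_a$clusters$id)
  nb <- setNames(tc_b$clusters$n, tc_b$clusters$id)
  df <- data.frame(
    id_a = c(match$pairs$id_a, match$only_a, rep(NA_character_, length(match$only_b))),
    id_b = c(match$pairs$id_b, rep(NA_character_, length(match$only_a)), match$only_b),
    stringsAsFactors = FALSE)
  df$count_a <- ifelse(is.na(df$id_a), 0L, na[df$id_a])
  df$count_b <- ifelse(is.na(df$id_b), 0L, nb[df$id_b])
  df <- df[df$count_a + df$count_b >= 1, , drop = FALSE]
  T1 <- tc_a$library_size; T2 <- tc_b$library_size
  df$rpm_a <- rpm(df$count_a, T1)
  df$rpm_b <- rpm(df$count_b, T2)
  df$fc <- ifelse(df$count_a > 0 & df$count_b > 0, df$rpm_a / df$rpm_b, NA_real_)
  df$log2fc <- log2(df$fc)
  pr <- T1 / (T1 + T2)
  tot <- df$count_a + df$count_b
  df$z <- (df$count_a - tot * pr) / sqrt(tot * pr * (1 - pr))
  df$p <- vapply(seq_len(nrow(df)),
                 function(i) binom_two_lib(df$count_a[i], df$count_b[i], T1, T2),
                 numeric(1))
  df$q <- bh_adjust(df$p)
  df$status <- ifelse(df$count_b == 0, "translatome_only",
               ifelse(df$count_a == 0, "transcriptome_only",
               ifelse(df$log2fc >= lfc & df$p < alpha, "enriched",
               ifelse(df$log2fc <= -lfc & df$p < alpha, "depleted", "unchanged"))))
  rownames(df) <- NULL
  df
}

#' Differential core-promoter usage score
#'
#' `S_du = 1/2 * sum_i | p_i/E_p - t_i/E_t |` with `E_p = sum(p)`,
#' `E_t = sum(t)`: half the L1 distance between the gene's promoter-usage
#' proportion vectors in the two samples. Defined only for genes with at
#' least two core promoters and positive abundance in both samples
#' (otherwise NA). Properties: `S_du` lies in [0, 1]; it is 0 when the
#' proportions agree (in particular for single-promoter genes, for which NA
#' is returned here because the score is not informative); it is 1 when the
#' translatome-supported and transcriptome-supported promoter sets are
#' disjoint.
#'
#' @param p,t promoter abundance vectors (same length, common unit, e.g.
#'   RPM) in translatome and transcriptome.
#' @return The score, or NA when undefined.
#' @export
s_du <- function(p, t) {
  stopifnot(length(p) == length(t))
  if (any(p < 0) || any(t < 0)) stop_validation("abundances must be non-negative")
  Ep <- sum(p); Et <- sum(t)
  if (length(p) < 2L || Ep <= 0 || Et <= 0) return(NA_real_)
  0.5 * sum(abs(p / Ep - t / Et))
}

#' Gene promoter table
#'
#' Collects, per gene, the matched cluster pairs assigned to the 5' UTR
#' (plus unmatched single-sample 5'UTR clusters, entering with zero on the
#' absent side) with raw counts and RPM in both samples. The gene of a pair
#' is taken from the transcriptome annotation when available, else from the
#' translatome annotation.
#'
#' @param ann_a,ann_b [annotate_clusters()] tables for translatome and
#'   transcriptome.
#' @param diff a [tc_diff()] table.
#' @return data.frame gene, id_a, id_b, count_a, count_b, rpm_a, rpm_b.
#' @export
gene_promoters <- function(ann_a, ann_b, diff) {
  feat_a <- setNames(ann_a$feature, ann_a$id)
  feat_b <- setNames(ann_b$feature, ann_b$id)
  gene_a <- setNames(ann_a$gene, ann_a$id)
  gene_b <- setNames(ann_b$gene, ann_b$id)
  fa <- ifelse(is.na(diff$id_a), NA, feat_a[diff$id_a])
  fb <- ifelse(is.na(diff$id_b), NA, feat_b[diff$id_b])
  is5 <- (!is.na(fa) & fa == "5utr") | (!is.na(fb) & fb == "5utr")
  d <- diff[is5, , drop = FALSE]
  gb <- ifelse(is.na(d$id_b), NA_character_, gene_b[d$id_b])
  ga <- ifelse(is.na(d$id_a), NA_character_, gene_a[d$id_a])
  d$gene <- ifelse(!is.na(gb), gb, ga)
  d <- d[!is.na(d$gene), c("gene", "id_a", "id_b", "count_a", "count_b",
                           "rpm_a", "rpm_b")]
  rownames(d) <- NULL
  d
}

#' Per-gene polysome-selection scores
#'
#' For each gene with promoter-level abundances `(p_i, t_i)` (RPM of its
#' core-promoter clusters in translatome and transcriptome), computes the
#' gene abundances `E_p = sum(p_i)` and `E_t = sum(t_i)`, the fold-change
#' score `S_fc = E_p / E_t`, its significance from an exact binomial test
#' on the summed raw counts (BH-adjusted across genes), and the
#' differential-usage score [s_du()] (genes with >= 2 promoters and
#' positive abundance in both samples).
#'
#' @param promoters a [gene_promoters()] table.
#' @param library_sizes numeric length-2: total mapped tags in translatome
#'   and transcriptome.
#' @param alpha,lfc significance level and minimal |log2 S_fc| for the
#'   `significant` flag (defaults 0.05 and 1).
#' @return data.frame gene, n_promoters, E_p, E_t, S_fc, log2_S_fc, p, q,
#'   significant, S_du.
#' @export
gene_scores <- function(promoters, library_sizes, alpha = 0.05, lfc = 1) {
  stopifnot(length(library_sizes) == 2L)
  idx <- split(seq_len(nrow(promoters)), promoters$gene)
  genes <- names(idx)
  out <- data.frame(gene = genes, n_promoters = lengths(idx),
                    E_p = NA_real_, E_t = NA_real_, S_fc = NA_real_,
                    log2_S_fc = NA_real_, p = NA_real_, q = NA_real_,
                    significant = NA, S_du = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    d <- promoters[idx[[i]], , drop = FALSE]
    out$E_p[i] <- sum(d$rpm_a)
    out$E_t[i] <- sum(d$rpm_b)
    out$S_fc[i] <- if (out$E_t[i] > 0) out$E_p[i] / out$E_t[i] else NA_real_
    out$p[i] <- binom_two_lib(sum(d$count_a), sum(d$count_b),
                              library_sizes[1], library_sizes[2])
    out$S_du[i] <- s_du(d$rpm_a, d$rpm_b)
  }
  out$log2_S_fc <- log2(out$S_fc)
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$log2_S_fc) & !is.na(out$p) &
    abs(out$log2_S_fc) >= lfc & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Three RPM-matched gene groups for downstream comparison
#'
#' Selects (1) the top `group_size` translatome-enriched genes
#' (significant, `S_fc > 2`) ranked by p-value, (2) the top `group_size`
#' unchanged genes (`0.9 < S_fc < 1.1`) ranked by transcriptome RPM, and
#' (3) the translatome-depleted genes (significant, `S_fc < 0.5`) ranked
#' `group_size+1` through `2*group_size` by p-value. A warning is issued
#' (and a shorter group returned) when too few genes qualify.
#'
#' @param scores a [gene_scores()] table.
#' @param group_size genes per group (default 100).
#' @return list with `enriched`, `unchanged`, `depleted` (character gene
#'   ids) and `mean_rpm_t` (mean transcriptome gene RPM per group).
#' @export
select_matched_groups <- function(scores, group_size = 100L) {
  take <- function(pool, ord, from = 1L) {
    pool <- pool[ord, , drop = FALSE]
    to <- from + group_size - 1L
    if (nrow(pool) < to) {
      warning(sprintf("only %d of %d requested genes qualify",
                      max(nrow(pool) - from + 1L, 0L), group_size), call. = FALSE)
      to <- nrow(pool)
    }
    if (from > to) character(0) else pool$gene[from:to]
  }
  enr <- scores[scores$significant & !is.na(scores$S_fc) & scores$S_fc > 2, , drop = FALSE]
  unc <- scores[!is.na(scores$S_fc) & scores$S_fc > 0.9 & scores$S_fc < 1.1, , drop = FALSE]
  dep <- scores[scores$significant & !is.na(scores$S_fc) & scores$S_fc < 0.5, , drop = FALSE]
  groups <- list(enriched = take(enr, order(enr$p)),
                 unchanged = take(unc, order(-unc$E_t)),
                 depleted = take(dep, order(dep$p), from = group_size + 1L))
  Et <- setNames(scores$E_t, scores$gene)
  groups$mean_rpm_t <- vapply(groups[1:3], function(g) mean(Et[g]), numeric(1))
  groups
}

#' Gene-family enrichment by Fisher's exact test
#'
#' One 2x2 Fisher test per family: membership in the query set against
#' membership in the family, within the stated gene universe; BH
#' adjustment across families. An infinite odds ratio (empty off-diagonal)
#' is reported as `Inf`.
#'
#' @param query character vector of gene ids.
#' @param family_map data.frame with columns `gene`, `family`.
#' @param universe character vector of gene ids forming the background.
#' @return data.frame family, n_family, n_overlap, odds_ratio, p, q.
#' @export
enrichment_test <- function(query, family_map, universe) {
  if (!length(universe)) stop_validation("empty gene universe")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  fams <- split(family_map$gene, family_map$family)
  out <- data.frame(family = names(fams), n_family = NA_integer_,
                    n_overlap = NA_integer_, odds_ratio = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(fams)) {
    fam <- intersect(fams[[i]], universe)
    a <- length(intersect(query, fam))
    b <- length(query) - a
    c_ <- length(fam) - a
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2))
    out$n_family[i] <- length(fam)
    out$n_overlap[i] <- a
    out$odds_ratio[i] <- if (b == 0L || c_ == 0L) {
      if (a > 0L) Inf else NA_real_
    } else {
      unname(ft$estimate)
    }
    out$p[i] <- ft$p.value
  }
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
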