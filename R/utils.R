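#' @keywords internal
"_PACKAGE"

#' @importFrom stats ppois binom.test p.adjust fisher.test cor rmultinom
#'   rlnorm rpois prop.test setNames
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

STRANDS <- c("+", "-")
FEATURE_PRIORITY <- c("5utr", "3utr", "cds", "intron")
SHAPE_CLASSES <- c("SP", "DP", "MP", "BP")

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_strand <- function(strand) {
  bad <- !strand %in% STRANDS
  if (any(bad)) {
    stop_validation("invalid strand value(s): %s",
                    paste(unique(strand[bad]), collapse = ", "))
  }
  invisible(strand)
}

#' Fraction of a genome covered by a number of single-base positions
#'
#' Utility used to put a count of unique 5'-end positions in perspective:
#' the fraction (as a percentage) of a genome of length `genome_length`
#' that `n_positions` single-nucleotide positions cover.
#'
#' @param n_positions number of distinct single-base positions.
#' @param genome_length total genome length in nucleotides.
#' @return Percentage of the genome covered, a single numeric value.
#' @examples
#' genome_fraction_pct(1e5, 3095693983)
#' @export
genome_fraction_pct <- function(n_positions, genome_length) {
  if (genome_length <= 0) stop_validation("genome_length must be positive")
  if (n_positions < 0) stop_validation("n_positions must be non-negative")
  n_positions / genome_length * 100
}

# Write a data.frame as TSV with '#'-prefixed provenance header lines.
write_tsv_provenance <- function(df, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# polycage %s", as.character(packageVersion("polycage"))),
             con)
  if (length(params)) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(x) paste(format(x), collapse = ","),
                              character(1))), con)
  }
  # full precision so that write -> read round-trips are exact
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_provenance <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# Sum counts over identical (chrom, pos, strand) keys; returns a sorted
# CTSS data.frame. Much faster than stats::aggregate for millions of rows.
aggregate_ctss <- function(chrom, pos, strand, count) {
  o <- order(chrom, strand, pos)
  chrom <- chrom[o]; pos <- pos[o]; strand <- strand[o]; count <- count[o]
  n <- length(pos)
  if (!n) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  new <- c(TRUE, chrom[-1] != chrom[-n] | strand[-1] != strand[-n] |
             pos[-1] != pos[-n])
  gid <- cumsum(new)
  data.frame(chrom = chrom[new], pos = as.integer(pos[new]),
             strand = strand[new],
             count = as.integer(rowsum(count, gid)[, 1]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Restore the caller's RNG state on exit; seed the local computation.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
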