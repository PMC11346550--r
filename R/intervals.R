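#' Genomic interval overlap length
#'
#' Length in bp of the intersection of two intervals under the 0-based
#' half-open convention used throughout the package. Strand is ignored;
#' intervals on different chromosomes overlap by 0. All arguments are
#' vectorized and recycled.
#'
#' @param start1,end1 integer start (inclusive) and end (exclusive) of the
#'   first interval(s).
#' @param start2,end2 coordinates of the second interval(s).
#' @param chrom1,chrom2 optional chromosome names; when given, pairs on
#'   different chromosomes return 0.
#' @return integer vector of overlap lengths in bp (>= 0).
#' @examples
#' interval_overlap(0, 10, 5, 8)   # 3
#' interval_overlap(0, 10, 10, 20) # 0 (half-open adjacency)
#' @export
interval_overlap <- function(start1, end1, start2, end2,
                             chrom1 = NULL, chrom2 = NULL) {
  ov <- pmax(0L, pmin(end1, end2) - pmax(start1, start2))
  if (!is.null(chrom1) && !is.null(chrom2)) {
    ov[as.character(chrom1) != as.character(chrom2)] <- 0L
  }
  as.integer(ov)
}

# internal: validate an interval data.frame (chrom/start/end, optional strand)
check_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  if (any(df$start < 0)) stop(what, ": negative start coordinate")
  if (any(df$end <= df$start)) stop(what, ": end must exceed start (half-open)")
  if (!is.null(df$strand) && !all(df$strand %in% c("+", "-"))) {
    stop(what, ": strand must be '+' or '-'")
  }
  invisible(df)
}

# internal: GRanges from a 0-based half-open data.frame; 1-based inside GRanges
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(df$strand)) "*" else df$strand
  )
}
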