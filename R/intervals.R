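#' @importFrom data.table data.table setkey setkeyv := .N .SD setorder as.data.table setnames rbindlist
#' @importFrom stats lm coef cor rnorm runif rpois rlnorm rbinom rbeta rgamma sd
#'   quantile wilcox.test fisher.test cor.test ks.test pnorm qnorm setNames
#' @importFrom utils write.table read.delim head tail
NULL

# All coordinates inside the package are 0-based half-open [start, end):
# length == end - start, BED-native. VCF input is converted on read and back
# on write. GRanges (1-based closed) is only an internal computational
# representation, never part of the API.

#' Validate a 0-based half-open interval table
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return `df` invisibly; errors describe the first offending row.
#' @export
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(as.character(df$chrom))))
    stop("interval table has empty chromosome names")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("invalid interval at row %d: [%s, %s)", bad[1],
                 format(df$start[bad[1]]), format(df$end[bad[1]])))
  invisible(df)
}

# Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
as_granges0 <- function(df, keep = character()) {
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}

# Back-convert GRanges to the package's 0-based half-open data.frame.
as_intervals0 <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = s,
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

#' Merge overlapping intervals into a sorted, disjoint union
#'
#' Overlapping or bookended intervals are collapsed, as when building a
#' consensus set of CTCF-binding regions from peaks called in several
#' tissues. Output covers exactly the union of the input base pairs.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open). Strand is ignored.
#' @return data.frame of disjoint intervals sorted by (chrom, start).
#' @examples
#' merge_intervals(data.frame(chrom = "chrS1", start = c(0, 5), end = c(10, 20)))
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  validate_intervals(intervals)
  out <- as_intervals0(GenomicRanges::reduce(as_granges0(intervals)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Promoter windows upstream of each TSS
#'
#' Promoters are defined as the `upstream_bp` window (default 2 kb) upstream
#' of the transcription start site, strand-aware and truncated at position 0.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (0-based position
#'   of the TSS base) and `strand` (`+` or `-`).
#' @param upstream_bp window size in bp upstream of the TSS.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`;
#'   on `+` the window is `[tss - upstream_bp, tss)`, on `-` it is
#'   `[tss + 1, tss + 1 + upstream_bp)`.
#' @export
promoter_regions <- function(genes, upstream_bp = 2000L) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$tss - upstream_bp), genes$tss + 1L)
  end <- ifelse(plus, genes$tss, genes$tss + 1L + upstream_bp)
  keep <- start < end  # a + strand gene with tss = 0 has no upstream window
  data.frame(gene_id = genes$gene_id[keep], chrom = genes$chrom[keep],
             start = as.integer(start[keep]), end = as.integer(end[keep]),
             strand = genes$strand[keep], stringsAsFactors = FALSE)
}

# Overlap width between one interval and a set, both 0-based half-open.
# Returns total overlapped bp of `query` rows against the union of `subject`.
overlap_bp <- function(q_start, q_end, s_start, s_end) {
  pmax(0L, pmin(q_end, s_end) - pmax(q_start, s_start))
}
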