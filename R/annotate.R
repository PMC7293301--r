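# Per-SV annotation classes and per-SV x gene dosage-model covariates from
# interval overlaps, plus sample-level CNV QC. All overlap arithmetic is
# any-bp (a single shared base pair counts), computed on the exon *union*
# across isoforms.

FUNCTIONAL_CLASSES <- c("coding", "other_transcribed", "promoter", "enhancer", "ctcf")

#' Fraction of a gene's exonic sequence overlapped by one SV
#'
#' Overlap is computed against the per-gene exon union, so the value is
#' invariant to how the union is partitioned into blocks.
#'
#' @param sv_start,sv_end SV interval, 0-based half-open.
#' @param exons data.frame of the gene's (disjoint) exon blocks with
#'   `start`, `end`.
#' @return fraction of exonic bp inside the SV, in `[0, 1]`; 0 when the
#'   gene has no exons.
#' @export
exonic_fraction <- function(sv_start, sv_end, exons) {
  total <- sum(exons$end - exons$start)
  if (total == 0) return(0)
  sum(overlap_bp(sv_start, sv_end, exons$start, exons$end)) / total
}

# Overlap join: per (sv row, feature row) overlapped bp, as a data.table
# with columns sv_idx, feat_idx, bp. Chromosome-aware via GRanges.
overlap_pairs <- function(svs, feats) {
  if (nrow(feats) == 0 || nrow(svs) == 0)
    return(data.table::data.table(sv_idx = integer(), feat_idx = integer(),
                                  bp = integer()))
  hits <- GenomicRanges::findOverlaps(as_granges0(svs), as_granges0(feats),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.table::data.table(
    sv_idx = qi, feat_idx = si,
    bp = overlap_bp(svs$start[qi], svs$end[qi], feats$start[si], feats$end[si]))
}

#' Build the SV x gene dosage feature table
#'
#' Emits one row per (SV, gene) pair whose TSS lies within `window` bp of
#' the SV interval, with the five dosage-model covariates: proportion of
#' exonic sequence overlapped (`p_exon`), proportion of the 2 kb promoter
#' overlapped (`p_prom`), summed overlapped fraction of the gene's linked
#' enhancers (`enh_sum`, can exceed 1), an indicator that one TAD contains
#' both the gene's TSS and at least 1 bp of the SV (`within_tad`), and the
#' SV length in bp. `affects_tss_end` records whether the SV touches the
#' TSS-containing (5') and/or terminal (3') exon block, for the positional
#' analysis.
#'
#' @param svs an [sv_set].
#' @param annotation a [build_annotation] object.
#' @param window max TSS distance from the SV interval in bp (default 1 Mb,
#'   the standard cis-eQTL window).
#' @return data.frame ordered by (sv_id, gene_id), one row per pair.
#' @export
build_feature_table <- function(svs, annotation, window = 1e6) {
  genes <- annotation$genes
  empty <- data.frame(sv_id = character(), gene_id = character(),
                      sv_type = character(), p_exon = numeric(),
                      p_prom = numeric(), enh_sum = numeric(),
                      within_tad = integer(), sv_length = numeric(),
                      affects_tss_end = character(), stringsAsFactors = FALSE)
  if (nrow(svs) == 0 || nrow(genes) == 0) return(empty)
  sv_df <- as.data.frame(svs[, c("sv_id", "chrom", "start", "end", "sv_type", "length")])
  tss <- data.frame(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1L)
  hits <- GenomicRanges::findOverlaps(as_granges0(sv_df), as_granges0(tss),
                                      maxgap = as.integer(window),
                                      ignore.strand = TRUE)
  pairs <- data.table::data.table(sv_idx = S4Vectors::queryHits(hits),
                                  gene_idx = S4Vectors::subjectHits(hits))
  if (nrow(pairs) == 0) return(empty)

  exons <- annotation$exons
  gidx_of_exon <- match(exons$gene_id, genes$gene_id)
  exon_total <- tapply(exons$end - exons$start, factor(gidx_of_exon, seq_len(nrow(genes))), sum)
  exon_total[is.na(exon_total)] <- 0
  eo <- overlap_pairs(sv_df, exons)
  eo[, gene_idx := gidx_of_exon[feat_idx]]
  exon_bp <- eo[, list(bp = sum(bp)), by = c("sv_idx", "gene_idx")]

  proms <- annotation$promoters
  gidx_of_prom <- match(proms$gene_id, genes$gene_id)
  po <- overlap_pairs(sv_df, proms)
  po[, gene_idx := gidx_of_prom[feat_idx]]
  po[, frac := bp / (proms$end[feat_idx] - proms$start[feat_idx])]
  prom_frac <- po[, list(p_prom = sum(frac)), by = c("sv_idx", "gene_idx")]

  enh <- annotation$enhancers
  links <- annotation$links
  if (nrow(enh) && nrow(links)) {
    eno <- overlap_pairs(sv_df, enh)
    eno[, frac := bp / (enh$end[feat_idx] - enh$start[feat_idx])]
    eno[, enhancer_id := enh$enhancer_id[feat_idx]]
    ldt <- data.table::as.data.table(links)
    ldt[, gene_idx := match(gene_id, genes$gene_id)]
    enl <- merge(eno, ldt, by = "enhancer_id", allow.cartesian = TRUE)
    enh_sum <- enl[, list(enh_sum = sum(frac)), by = c("sv_idx", "gene_idx")]
  } else {
    enh_sum <- data.table::data.table(sv_idx = integer(), gene_idx = integer(),
                                      enh_sum = numeric())
  }

  tads <- annotation$tads
  if (nrow(tads)) {
    tss_tad <- GenomicRanges::findOverlaps(as_granges0(tss), as_granges0(tads),
                                           ignore.strand = TRUE)
    tad_of_gene <- rep(NA_integer_, nrow(genes))
    tad_of_gene[S4Vectors::queryHits(tss_tad)] <- S4Vectors::subjectHits(tss_tad)
    svtad <- overlap_pairs(sv_df, tads)
    sv_in_tad <- data.table::data.table(sv_idx = svtad$sv_idx, tad = svtad$feat_idx,
                                        hit = 1L)
    data.table::setkey(sv_in_tad, sv_idx, tad)
  } else {
    tad_of_gene <- rep(NA_integer_, nrow(genes))
    sv_in_tad <- data.table::data.table(sv_idx = integer(), tad = integer(), hit = integer())
    data.table::setkey(sv_in_tad, sv_idx, tad)
  }

  # 5'/3' terminal exon blocks per gene (strand-aware)
  first_exon <- last_exon <- rep(NA_integer_, nrow(genes))
  if (nrow(exons)) {
    ed <- data.table::data.table(idx = seq_len(nrow(exons)), gene_idx = gidx_of_exon,
                                 start = exons$start)
    lo <- ed[, list(lo = idx[which.min(start)], hi = idx[which.max(start)]), by = "gene_idx"]
    minus <- genes$strand[lo$gene_idx] == "-"
    first_exon[lo$gene_idx] <- ifelse(minus, lo$hi, lo$lo)
    last_exon[lo$gene_idx] <- ifelse(minus, lo$lo, lo$hi)
  }

  out <- pairs
  out <- merge(out, exon_bp, by = c("sv_idx", "gene_idx"), all.x = TRUE)
  out <- merge(out, prom_frac, by = c("sv_idx", "gene_idx"), all.x = TRUE)
  out <- merge(out, enh_sum, by = c("sv_idx", "gene_idx"), all.x = TRUE)
  out[is.na(bp), bp := 0L]
  out[is.na(p_prom), p_prom := 0]
  out[is.na(enh_sum), enh_sum := 0]
  out[, p_exon := ifelse(exon_total[gene_idx] > 0, bp / exon_total[gene_idx], 0)]
  tad_idx <- tad_of_gene[out$gene_idx]
  lookup <- data.table::data.table(sv_idx = out$sv_idx, tad = tad_idx)
  hit_vec <- sv_in_tad[lookup, on = c("sv_idx", "tad"), hit]
  wt <- as.integer(!is.na(tad_idx) & !is.na(hit_vec))
  out[, within_tad := wt]
  five <- overlap_flag(sv_df, exons, first_exon, out)
  three <- overlap_flag(sv_df, exons, last_exon, out)
  out[, affects_tss_end := c("neither", "five_prime", "three_prime", "both")[
        1L + five + 2L * three]]
  out[, `:=`(sv_id = sv_df$sv_id[sv_idx], gene_id = genes$gene_id[gene_idx],
             sv_type = sv_df$sv_type[sv_idx], sv_length = sv_df$length[sv_idx])]
  res <- as.data.frame(out[, c("sv_id", "gene_id", "sv_type", "p_exon", "p_prom",
                               "enh_sum", "within_tad", "sv_length",
                               "affects_tss_end"), with = FALSE])
  res <- res[order(res$sv_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Does each (sv_idx, gene_idx) pair's SV overlap the given exon block of the
# gene? exon_of is a per-gene exon row index (or NA).
overlap_flag <- function(sv_df, exons, exon_of, pairs) {
  ei <- exon_of[pairs$gene_idx]
  ok <- !is.na(ei)
  res <- integer(nrow(pairs))
  res[ok] <- as.integer(overlap_bp(sv_df$start[pairs$sv_idx[ok]],
                                   sv_df$end[pairs$sv_idx[ok]],
                                   exons$start[ei[ok]], exons$end[ei[ok]]) > 0)
  res
}

#' Classify SVs by the annotation classes they touch
#'
#' Functional classes (`coding`, `other_transcribed`, `promoter`,
#' `enhancer`, `ctcf`) are assigned by any-bp overlap and are not mutually
#' exclusive. SVs touching no functional element fall back to `intronic`
#' (inside a gene body) or `intergenic` (outside every gene).
#'
#' @param svs an [sv_set].
#' @param annotation a [build_annotation] object.
#' @return data.frame with `sv_id`, `classes` (comma-separated),
#'   `unique_class` (the single functional class when exactly one applies,
#'   else `"none"`) and `n_functional_classes`.
#' @export
classify_svs <- function(svs, annotation) {
  sv_df <- as.data.frame(svs[, c("sv_id", "chrom", "start", "end")])
  n <- nrow(sv_df)
  genes <- annotation$genes
  exons <- annotation$exons
  coding_gene <- genes$gene_id[genes$is_coding]
  flag_hit <- function(feats) {
    f <- logical(n)
    f[unique(overlap_pairs(sv_df, feats)$sv_idx)] <- TRUE
    f
  }
  hit <- cbind(
    coding = flag_hit(exons[exons$gene_id %in% coding_gene, , drop = FALSE]),
    other_transcribed = flag_hit(exons[!exons$gene_id %in% coding_gene, , drop = FALSE]),
    promoter = flag_hit(annotation$promoters),
    enhancer = flag_hit(annotation$enhancers),
    ctcf = flag_hit(annotation$ctcf))
  in_gene <- flag_hit(genes)
  nf <- rowSums(hit)
  classes <- apply(hit, 1, function(r) paste(FUNCTIONAL_CLASSES[r], collapse = ","))
  classes[nf == 0 & in_gene] <- "intronic"
  classes[nf == 0 & !in_gene] <- "intergenic"
  unique_class <- ifelse(nf == 1, classes, "none")
  data.frame(sv_id = sv_df$sv_id, classes = classes, unique_class = unique_class,
             n_functional_classes = as.integer(nf), stringsAsFactors = FALSE)
}

#' Exclude samples with outlying CNV burden
#'
#' A sample is excluded when its CNV count or its total altered bp lies
#' outside `[Q1 - 3 IQR, Q3 + 3 IQR]` of the per-sample distribution
#' (quartiles over all samples in the callset, zero-burden samples
#' included).
#'
#' @param svs an [sv_set]; only DEL/DUP records contribute to the burden.
#' @return list with `kept`, `excluded` (character vectors of sample ids)
#'   and `stats` (per-sample `n_cnv`, `altered_bp`).
#' @export
qc_exclude_sample_outliers <- function(svs) {
  samples <- attr(svs, "sample_ids")
  if (length(samples) < 4) stop("need at least 4 samples to define quartile fences")
  cnv <- svs[svs$sv_type %in% CNV_TYPES, , drop = FALSE]
  carrier <- unlist(cnv$carriers)
  bp <- rep(cnv$end - cnv$start, lengths(cnv$carriers))
  n_cnv <- table(factor(carrier, levels = samples))
  altered <- tapply(bp, factor(carrier, levels = samples), sum)
  altered[is.na(altered)] <- 0
  stats <- data.frame(sample_id = samples, n_cnv = as.integer(n_cnv),
                      altered_bp = as.numeric(altered), stringsAsFactors = FALSE)
  out_of_fence <- function(x) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    x < q[1] - 3 * iqr | x > q[2] + 3 * iqr
  }
  bad <- out_of_fence(stats$n_cnv) | out_of_fence(stats$altered_bp)
  list(kept = samples[!bad], excluded = samples[bad], stats = stats)
}
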