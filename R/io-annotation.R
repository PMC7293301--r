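# Genome-annotation I/O and the `genome_annotation` container: genes with
# unioned exons, promoters (2 kb upstream of the TSS), enhancers with
# enhancer-gene links, CTCF consensus sites and TADs.

#' Read gene models from a GTF/GFF2 file
#'
#' Requires `gene` and/or `exon` features carrying a `gene_id` attribute.
#' Exons are unioned per gene across transcripts/isoforms; the TSS is
#' strand-aware (interval start on `+`, `end - 1` on `-`). Exons extending
#' outside the gene body are clipped with a warning. Genes are flagged as
#' protein-coding from the `gene_biotype`/`gene_type` attribute when
#' present (otherwise all genes are treated as coding).
#'
#' @param path path to a GTF file.
#' @return list with `genes` (gene_id, chrom, start, end, strand, tss,
#'   is_coding) and `exons` (gene_id, chrom, start, end), both 0-based
#'   half-open, exons disjoint within gene.
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_intervals0(gr)
  df$type <- as.character(df$type)
  if (!"gene_id" %in% names(df)) stop("GTF lacks gene_id attributes: ", path)
  exons <- df[df$type == "exon", c("gene_id", "chrom", "start", "end")]
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gene_rows) == 0) {
    # derive gene bodies from the exon span
    dt <- data.table::as.data.table(df[df$type == "exon", ])
    gene_rows <- as.data.frame(dt[, list(
      chrom = chrom[1], start = min(start), end = max(end),
      strand = if ("strand" %in% names(dt)) strand[1] else "+"), by = "gene_id"])
    gene_rows$type <- "gene"
    for (col in c("gene_biotype", "gene_type"))
      if (col %in% names(df)) gene_rows[[col]] <- df[[col]][match(gene_rows$gene_id, df$gene_id)]
  }
  biotype <- if ("gene_biotype" %in% names(gene_rows)) gene_rows$gene_biotype
             else if ("gene_type" %in% names(gene_rows)) gene_rows$gene_type
             else rep("protein_coding", nrow(gene_rows))
  biotype[is.na(biotype)] <- "protein_coding"
  strand <- as.character(gene_rows$strand)
  genes <- data.frame(
    gene_id = gene_rows$gene_id, chrom = gene_rows$chrom,
    start = gene_rows$start, end = gene_rows$end, strand = strand,
    tss = ifelse(strand == "-", gene_rows$end - 1L, gene_rows$start),
    is_coding = biotype == "protein_coding", stringsAsFactors = FALSE)

  # clip exons to the gene body, then union across isoforms
  m <- match(exons$gene_id, genes$gene_id)
  if (anyNA(m)) stop("exon with unknown gene_id: ", exons$gene_id[which(is.na(m))[1]])
  clip_lo <- pmax(exons$start, genes$start[m])
  clip_hi <- pmin(exons$end, genes$end[m])
  if (any(clip_lo != exons$start | clip_hi != exons$end))
    warning("some exons extend outside their gene body; clipped")
  exons$start <- clip_lo
  exons$end <- clip_hi
  exons <- exons[exons$start < exons$end, , drop = FALSE]
  exons <- union_exons(exons)
  list(genes = genes, exons = exons)
}

# Union exon intervals within each gene (isoform collapse).
union_exons <- function(exons) {
  if (nrow(exons) == 0) return(exons)
  dt <- data.table::as.data.table(exons)
  out <- dt[, {
    red <- merge_intervals(data.frame(chrom = chrom, start = start, end = end))
    list(chrom = red$chrom, start = red$start, end = red$end)
  }, by = "gene_id"]
  as.data.frame(out[order(gene_id, start)])
}

#' Write gene models to GTF
#'
#' @param genes,exons as returned by [read_gene_model].
#' @param path output path.
#' @export
write_gene_gtf <- function(genes, exons, path) {
  attr_of <- function(id, coding)
    sprintf('gene_id "%s"; gene_biotype "%s";', id,
            ifelse(coding, "protein_coding", "processed_transcript"))
  g <- paste(genes$chrom, "svdosage", "gene", genes$start + 1L, genes$end, ".",
             genes$strand, ".", attr_of(genes$gene_id, genes$is_coding), sep = "\t")
  m <- match(exons$gene_id, genes$gene_id)
  e <- paste(exons$chrom, "svdosage", "exon", exons$start + 1L, exons$end, ".",
             genes$strand[m], ".", attr_of(exons$gene_id, genes$is_coding[m]), sep = "\t")
  writeLines(c(g, e), path)
  invisible(path)
}

#' Read a BED3/BED4/BED6 file
#'
#' @param path BED file; 0-based half-open as native to BED.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as_intervals0(gr)
  df[, intersect(c("chrom", "start", "end", "name"), names(df)), drop = FALSE]
}

#' Write a BED file
#'
#' @param df data.frame with `chrom`, `start`, `end`, optional `name`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- df[, intersect(c("chrom", "start", "end", "name"), names(df)), drop = FALSE]
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Assemble a genome annotation
#'
#' Bundles gene models, regulatory elements and chromatin domains into the
#' single container consumed by the annotation and simulation stages, and
#' validates the cross-references.
#'
#' @param genes,exons as from [read_gene_model].
#' @param enhancers data.frame `enhancer_id`, `chrom`, `start`, `end`.
#' @param links data.frame `enhancer_id`, `gene_id` (enhancer-gene pairs,
#'   e.g. Hi-C predicted targets).
#' @param ctcf data.frame `chrom`, `start`, `end` of consensus CTCF sites.
#' @param tads data.frame `chrom`, `start`, `end`; must be non-overlapping
#'   within a chromosome.
#' @param upstream_bp promoter window upstream of the TSS (default 2000).
#' @return object of class `genome_annotation`: a list with elements
#'   `genes`, `exons`, `promoters`, `enhancers`, `links`, `ctcf`, `tads`.
#' @export
build_annotation <- function(genes, exons, enhancers = NULL, links = NULL,
                             ctcf = NULL, tads = NULL, upstream_bp = 2000L) {
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (is.null(enhancers))
    enhancers <- empty(enhancer_id = character(), chrom = character(),
                       start = integer(), end = integer())
  if (is.null(links))
    links <- empty(enhancer_id = character(), gene_id = character())
  if (is.null(ctcf))
    ctcf <- empty(chrom = character(), start = integer(), end = integer())
  if (is.null(tads))
    tads <- empty(chrom = character(), start = integer(), end = integer())
  stopifnot(!anyDuplicated(genes$gene_id), !anyDuplicated(enhancers$enhancer_id))
  if (nrow(links)) {
    if (!all(links$gene_id %in% genes$gene_id))
      stop("enhancer link references unknown gene_id")
    if (!all(links$enhancer_id %in% enhancers$enhancer_id))
      stop("enhancer link references unknown enhancer_id")
  }
  if (nrow(tads) > 1) {
    o <- order(tads$chrom, tads$start)
    tt <- tads[o, ]
    same <- tt$chrom[-1] == tt$chrom[-nrow(tt)]
    if (any(same & tt$start[-1] < tt$end[-nrow(tt)]))
      stop("TADs overlap within a chromosome")
    tads <- tt
  }
  ann <- list(genes = genes, exons = exons,
              promoters = promoter_regions(genes, upstream_bp),
              enhancers = enhancers, links = links, ctcf = ctcf, tads = tads)
  stopifnot(all(ann$promoters$end - ann$promoters$start <= upstream_bp))
  class(ann) <- "genome_annotation"
  ann
}

#' @exportS3Method base::print
print.genome_annotation <- function(x, ...) {
  cat(sprintf(paste0("genome_annotation: %d genes (%d coding), %d exon blocks, ",
                     "%d enhancers (%d links), %d CTCF sites, %d TADs\n"),
              nrow(x$genes), sum(x$genes$is_coding), nrow(x$exons),
              nrow(x$enhancers), nrow(x$links), nrow(x$ctcf), nrow(x$tads)))
  invisible(x)
}
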