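# SV callset I/O. The on-disk interchange format is VCF 4.x with SVTYPE and
# END INFO keys and per-sample GT; in memory an SV callset is a data.frame
# ("sv_set") with one row per variant and a list-column of carrier sample ids.

INSERTION_TYPES <- c("INS", "ALU", "LINE1", "SVA")
SV_TYPES <- c("DEL", "DUP", "INS", "INV", "ALU", "LINE1", "SVA", "CPX")
CNV_TYPES <- c("DEL", "DUP")

#' Construct an SV callset table
#'
#' @param sv_id,chrom,start,end,sv_type,length vectors of equal length;
#'   coordinates 0-based half-open. Insertion classes (INS/ALU/LINE1/SVA) are
#'   represented as 1-bp point intervals at the insertion site; their
#'   `length` carries the insert size.
#' @param carriers list of character vectors of carrier sample ids (all SVs
#'   are treated as heterozygous).
#' @param sample_ids character vector of all samples in the callset; the
#'   allele frequency is `length(carriers) / (2 * length(sample_ids))`.
#' @return data.frame of class `sv_set` with columns `sv_id`, `chrom`,
#'   `start`, `end`, `sv_type`, `length`, `carriers`, `af` and attribute
#'   `sample_ids`.
#' @export
sv_set <- function(sv_id, chrom, start, end, sv_type, length, carriers, sample_ids) {
  stopifnot(all(sv_type %in% SV_TYPES), !anyDuplicated(sv_id))
  df <- data.frame(sv_id = as.character(sv_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   sv_type = as.character(sv_type), length = as.numeric(length),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  bad <- !vapply(carriers, function(x) all(x %in% sample_ids), TRUE)
  if (any(bad)) stop("carriers of ", df$sv_id[which(bad)[1]], " not in sample_ids")
  df$carriers <- carriers
  df$af <- vapply(carriers, base::length, 1L) / (2 * base::length(sample_ids))
  attr(df, "sample_ids") <- as.character(sample_ids)
  class(df) <- c("sv_set", "data.frame")
  df
}

#' @exportS3Method base::print
print.sv_set <- function(x, ...) {
  cat(sprintf("sv_set: %d SVs across %d samples\n", nrow(x),
              length(attr(x, "sample_ids"))))
  print(table(x$sv_type))
  invisible(x)
}

n_samples <- function(svs) length(attr(svs, "sample_ids"))

#' Read a structural-variant VCF
#'
#' Parses a VCF 4.x file with `SVTYPE` and `END` INFO keys and per-sample
#' `GT` fields. 1-based VCF coordinates are converted to the package's
#' 0-based half-open convention; carriers are samples with at least one
#' alternate allele; allele frequency assumes all carriers are heterozygous.
#' Records missing `SVTYPE`, or missing `END` for a non-insertion type, are
#' dropped with a message (to stderr) naming the offending file line.
#'
#' @param path path to an (optionally bgzipped) VCF.
#' @return an [sv_set] data.frame. Insertions get point intervals at the
#'   insertion site with `length` taken from `SVLEN` when present.
#' @export
read_sv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  end <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "END")))
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "SVLEN")))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no genotype (GT) columns: ", path)
  if (any(!grepl("^\\.?[0-9.]([/|][0-9.])?$", gt[!is.na(gt)])))
    stop("malformed GT field(s) in ", path)
  sample_ids <- colnames(gt)
  pos <- as.integer(fix[, "POS"])
  header_lines <- length(vcf@meta) + 1L  # meta lines plus the #CHROM line

  is_ins <- !is.na(svtype) & svtype %in% INSERTION_TYPES
  bad <- is.na(svtype) | (!is_ins & is.na(end))
  if (any(bad)) {
    for (i in which(bad)) {
      reason <- if (is.na(svtype[i])) "missing SVTYPE" else "missing END"
      message(sprintf("read_sv_vcf: dropping record at line %d (%s:%s): %s",
                      header_lines + i, fix[i, "CHROM"], fix[i, "POS"], reason))
    }
  }
  keep <- which(!bad)
  carrier <- grepl("1", gt, fixed = TRUE)
  dim(carrier) <- dim(gt)
  carriers <- lapply(keep, function(i) sample_ids[carrier[i, ]])
  start0 <- pos[keep] - 1L
  end0 <- ifelse(is_ins[keep], pos[keep], end[keep])
  len <- ifelse(is_ins[keep],
                ifelse(is.na(svlen[keep]), 1, abs(svlen[keep])),
                end0 - start0)
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("sv_line", header_lines + keep[is.na(ids) | ids == "."])
  message(sprintf("read_sv_vcf: %d records read, %d kept (%s)", n, length(keep), path))
  sv_set(ids, fix[keep, "CHROM"], start0, end0, svtype[keep], len, carriers, sample_ids)
}

#' Write an SV callset as VCF
#'
#' Inverse of [read_sv_vcf]: internal 0-based half-open coordinates are
#' converted back to 1-based `POS`/`END`, carriers become `0/1` genotypes and
#' all other samples `0/0`.
#'
#' @param svs an [sv_set].
#' @param path output path (plain text).
#' @export
write_sv_vcf <- function(svs, path) {
  sample_ids <- attr(svs, "sample_ids")
  contigs <- sort(unique(svs$chrom))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svdosage",
    paste0("##contig=<ID=", contigs, ">"),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length (insert size for insertions)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  is_ins <- svs$sv_type %in% INSERTION_TYPES
  pos <- svs$start + 1L
  end <- ifelse(is_ins, pos, svs$end)
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", svs$sv_type, end,
                  as.integer(round(svs$length)))
  gt <- matrix("0/0", nrow = nrow(svs), ncol = length(sample_ids))
  idx <- match(unlist(svs$carriers), sample_ids)
  row_of <- rep(seq_len(nrow(svs)), lengths(svs$carriers))
  gt[cbind(row_of, idx)] <- "0/1"
  body <- paste(svs$chrom, pos, svs$sv_id, "N", paste0("<", svs$sv_type, ">"),
                ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
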