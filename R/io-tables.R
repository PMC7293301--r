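# Tabular I/O: expression matrices, intolerance tables, enhancer-gene links
# and the pipeline's schema-checked TSV tables.

#' Read an expression matrix (genes x samples TSV)
#'
#' @param path TSV with a `gene_id` first column and one column per sample.
#' @param scale `"cpm"` (non-negative counts-per-million) or `"adjusted"`
#'   (covariate-adjusted residual expression).
#' @return numeric matrix with gene rownames and sample colnames; attribute
#'   `scale` records the expression scale.
#' @export
read_expression_tsv <- function(path, scale = c("cpm", "adjusted")) {
  scale <- match.arg(scale)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("expression TSV must start with gene_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (scale == "cpm" && any(m < 0)) stop("cpm matrix has negative values")
  attr(m, "scale") <- scale
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix, genes in rows (rownames) and samples in
#'   columns (colnames).
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene intolerance table
#'
#' @param path TSV with header `gene_id`, `raw_lof`, `raw_cnv` (and
#'   optionally `weight`). `raw_lof` is a LOEUF-like loss-of-function
#'   metric where higher means more tolerant.
#' @return data.frame.
#' @export
read_intolerance_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "raw_lof", "raw_cnv")
  if (!all(need %in% names(df)))
    stop("intolerance TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read enhancer-gene links
#'
#' @param path TSV with header `enhancer_id`, `gene_id`.
#' @return data.frame.
#' @export
read_links_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("enhancer_id", "gene_id") %in% names(df)))
    stop("links TSV must have columns enhancer_id, gene_id")
  df
}

# Named schemas for the pipeline's interchange tables: column name -> type.
sv_schemas <- list(
  features = c(sv_id = "character", gene_id = "character", sv_type = "character",
               p_exon = "numeric", p_prom = "numeric", enh_sum = "numeric",
               within_tad = "integer", sv_length = "numeric",
               affects_tss_end = "character"),
  classes = c(sv_id = "character", classes = "character",
              unique_class = "character", n_functional_classes = "integer"),
  effects = c(sv_id = "character", gene_id = "character", sv_type = "character",
              relative_expression = "numeric", z_score = "numeric",
              n_carriers = "integer", outlier = "character"),
  scores = c(sv_id = "character", sv_type = "character", score = "numeric",
             n_genes_scored = "integer"),
  truth = c(sv_id = "character", gene_id = "character", cohort = "character",
            mu = "numeric"),
  intolerance = c(gene_id = "character", raw_lof = "numeric",
                  raw_cnv = "numeric", weight = "numeric"),
  curves = c(ranking = "character", sv_type = "character", rank = "integer",
             cum_pathogenic = "integer")
)

#' Write a schema-checked pipeline table
#'
#' Tab-separated, header row, deterministic column order; round-trips
#' losslessly through [read_table].
#'
#' @param rows data.frame conforming to a named schema.
#' @param path output path.
#' @param schema one of `names(sv_schemas)`: `"features"`, `"classes"`,
#'   `"effects"`, `"scores"`, `"truth"`, `"intolerance"`, `"curves"`.
#' @export
write_table <- function(rows, path, schema) {
  sch <- sv_schemas[[match.arg(schema, names(sv_schemas))]]
  missing_cols <- setdiff(names(sch), names(rows))
  if (length(missing_cols))
    stop("schema '", schema, "': missing column ", missing_cols[1])
  rows <- rows[, names(sch), drop = FALSE]
  num <- names(sch)[sch == "numeric"]
  for (col in num) rows[[col]] <- format(rows[[col]], digits = 15, trim = TRUE,
                                         scientific = FALSE)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a schema-checked pipeline table
#'
#' @param path TSV written by [write_table].
#' @param schema schema name, see [write_table].
#' @return data.frame with the schema's column types.
#' @export
read_table <- function(path, schema) {
  sch <- sv_schemas[[match.arg(schema, names(sv_schemas))]]
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = unname(sch),
                   col.names = names(sch), check.names = FALSE)
  if (nrow(df) == 0)
    df <- as.data.frame(lapply(sch, function(t) vector(t, 0)),
                        stringsAsFactors = FALSE)
  df
}
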