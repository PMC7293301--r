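# Regulatory disruption: per-SV aggregate of predicted per-gene expression
# z-scores weighted by normalized gene intolerance, pathogenic labeling by
# >= 50% overlap with known pathogenic CNVs of the same type, and
# rank-ordering prioritization curves.

#' Normalize a gene intolerance metric to [0, 1]
#'
#' Linear min-max transform of `raw_lof`, orientation-corrected so the most
#' intolerant gene (lowest raw LOEUF-like value) maps to 1 and the most
#' tolerant to 0. A rank-based alternative is available.
#'
#' @param records data.frame with `gene_id` and `raw_lof` (higher = more
#'   tolerant).
#' @param method `"minmax"` (default) or `"rank"`.
#' @return `records` with a `weight` column in `[0, 1]`.
#' @export
normalize_intolerance <- function(records, method = c("minmax", "rank")) {
  method <- match.arg(method)
  x <- records$raw_lof
  ok <- !is.na(x)
  if (length(unique(x[ok])) < 2) stop("constant intolerance metric")
  w <- rep(NA_real_, length(x))
  if (method == "minmax") {
    w[ok] <- (max(x[ok]) - x[ok]) / (max(x[ok]) - min(x[ok]))
  } else {
    r <- rank(x[ok], ties.method = "average")
    w[ok] <- (max(r) - r) / (max(r) - min(r))
  }
  records$weight <- w
  records
}

#' Per-SV regulatory disruption scores
#'
#' For each SV, the score is the sum over protein-coding genes within the
#' window, possessing both a predicted z-score and an intolerance weight,
#' of `predicted_z * weight`. Genes lacking an intolerance metric are
#' excluded; weights of zero contribute nothing.
#'
#' @param predicted data.frame with `sv_id`, `gene_id`, `sv_type`,
#'   `predicted_z` (e.g. feature rows plus [predict_z] output).
#' @param intolerance table with `gene_id` and `weight` (see
#'   [normalize_intolerance]).
#' @param annotation optional [build_annotation] object; when given, only
#'   protein-coding genes are scored.
#' @return list: `scores` data.frame (`sv_id`, `sv_type`, `score`,
#'   `n_genes_scored`) with one row per SV in `predicted`, and `breakdown`
#'   (`sv_id`, `gene_id`, `predicted_z`, `weight`, `contribution`).
#' @export
disruption_score <- function(predicted, intolerance, annotation = NULL) {
  stopifnot(all(c("sv_id", "gene_id", "sv_type", "predicted_z") %in% names(predicted)))
  w <- setNames(intolerance$weight, intolerance$gene_id)
  keep <- predicted$gene_id %in% names(w)[!is.na(w)]
  if (!is.null(annotation)) {
    coding <- annotation$genes$gene_id[annotation$genes$is_coding]
    keep <- keep & predicted$gene_id %in% coding
  }
  br <- predicted[keep, c("sv_id", "gene_id", "predicted_z"), drop = FALSE]
  br$weight <- unname(w[br$gene_id])
  br$contribution <- br$predicted_z * br$weight
  bdt <- data.table::as.data.table(br)
  agg <- bdt[, list(score = sum(contribution), n_genes_scored = .N), by = "sv_id"]
  ids <- unique(predicted[, c("sv_id", "sv_type"), drop = FALSE])
  scores <- merge(ids, as.data.frame(agg), by = "sv_id", all.x = TRUE)
  scores$score[is.na(scores$score)] <- 0
  scores$n_genes_scored[is.na(scores$n_genes_scored)] <- 0L
  scores <- scores[order(scores$sv_id), , drop = FALSE]
  rownames(scores) <- NULL
  list(scores = scores, breakdown = br)
}

#' Label SVs pathogenic by overlap with known pathogenic CNVs
#'
#' An SV is labeled pathogenic when it covers at least 50% of a known
#' pathogenic CNV of the same type; the overlap fraction denominator is the
#' known variant's length (not reciprocal overlap). `complete_overlap`
#' flags a best overlap of 100%.
#'
#' @param svs an [sv_set] (DEL/DUP rows are evaluated; other types get
#'   `best_overlap = 0`).
#' @param known data.frame with `chrom`, `start`, `end`, `sv_type` of known
#'   pathogenic CNVs.
#' @param threshold overlap fraction required (default 0.5).
#' @return data.frame `sv_id`, `pathogenic`, `best_overlap`,
#'   `complete_overlap`.
#' @export
label_pathogenic <- function(svs, known, threshold = 0.5) {
  best <- numeric(nrow(svs))
  for (ty in unique(known$sv_type)) {
    k <- known[known$sv_type == ty, , drop = FALSE]
    s_rows <- which(svs$sv_type == ty)
    if (!length(s_rows) || !nrow(k)) next
    ov <- overlap_pairs(as.data.frame(svs[s_rows, c("chrom", "start", "end")]), k)
    if (!nrow(ov)) next
    ov[, frac := bp / (k$end[feat_idx] - k$start[feat_idx])]
    mx <- ov[, list(frac = max(frac)), by = "sv_idx"]
    best[s_rows[mx$sv_idx]] <- pmax(best[s_rows[mx$sv_idx]], mx$frac)
  }
  data.frame(sv_id = svs$sv_id, pathogenic = best >= threshold,
             best_overlap = best, complete_overlap = best >= 1,
             stringsAsFactors = FALSE)
}

#' Cumulative-pathogenic prioritization curves
#'
#' Rank-orders CNVs of one type by five statistics -- regulatory disruption
#' (most negative score first for deletions, most positive first for
#' duplications), SV length (descending), number of genes with exonic
#' overlap (descending), number of intolerant genes (top 10% of weight)
#' with exonic overlap (descending), and allele frequency (ascending,
#' rarest first) -- and emits the cumulative count of pathogenic variants
#' at each rank. Ties are ordered randomly under the supplied seed.
#'
#' @param svs an [sv_set] restricted (internally) to `sv_type`.
#' @param scores the `scores` element of [disruption_score].
#' @param labels a [label_pathogenic] table.
#' @param features a [build_feature_table] output (for gene counts).
#' @param intolerance table with `gene_id`, `weight`.
#' @param sv_type `"DEL"` or `"DUP"`.
#' @param seed tie-shuffling seed.
#' @return data.frame `ranking`, `sv_type`, `rank`, `sv_id`, `pathogenic`,
#'   `cum_pathogenic`.
#' @export
prioritization_curves <- function(svs, scores, labels, features, intolerance,
                                  sv_type = c("DEL", "DUP"), seed = 1L) {
  sv_type <- match.arg(sv_type)
  sv <- as.data.frame(svs[svs$sv_type == sv_type,
                          c("sv_id", "length", "af"), drop = FALSE])
  if (nrow(sv) == 0) return(data.frame())
  s <- setNames(scores$score, scores$sv_id)[sv$sv_id]
  s[is.na(s)] <- 0
  top_genes <- intolerance$gene_id[!is.na(intolerance$weight) &
    intolerance$weight >= quantile(intolerance$weight, 0.9, na.rm = TRUE)]
  f <- features[features$sv_type == sv_type & features$p_exon > 0, , drop = FALSE]
  fdt <- data.table::as.data.table(f)
  ng <- fdt[, list(n_genes = .N,
                   n_intol = sum(gene_id %in% top_genes)), by = "sv_id"]
  n_genes <- setNames(ng$n_genes, ng$sv_id)[sv$sv_id]
  n_intol <- setNames(ng$n_intol, ng$sv_id)[sv$sv_id]
  n_genes[is.na(n_genes)] <- 0
  n_intol[is.na(n_intol)] <- 0
  path <- setNames(labels$pathogenic, labels$sv_id)[sv$sv_id]
  path[is.na(path)] <- FALSE

  keys <- list(
    disruption = if (sv_type == "DEL") s else -s,  # most extreme first
    length = -sv$length,
    n_genes = -n_genes,
    n_intolerant_genes = -n_intol,
    allele_frequency = sv$af)
  tie <- withr::with_seed(seed, runif(nrow(sv)))
  out <- lapply(names(keys), function(nm) {
    o <- order(keys[[nm]], tie)
    data.frame(ranking = nm, sv_type = sv_type, rank = seq_len(nrow(sv)),
               sv_id = sv$sv_id[o], pathogenic = path[o],
               cum_pathogenic = cumsum(path[o]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Wilcoxon comparison of disruption scores by pathogenic status
#'
#' @param scores the `scores` element of [disruption_score].
#' @param labels a [label_pathogenic] table.
#' @param sv_type restrict to one CNV type.
#' @return list `mean_pathogenic`, `mean_nonpathogenic`, `p` (two-sided
#'   Wilcoxon rank-sum).
#' @export
disruption_by_pathogenicity <- function(scores, labels, sv_type = c("DEL", "DUP")) {
  sv_type <- match.arg(sv_type)
  df <- merge(scores[scores$sv_type == sv_type, , drop = FALSE],
              labels[, c("sv_id", "pathogenic")], by = "sv_id")
  if (!any(df$pathogenic) || all(df$pathogenic))
    return(list(mean_pathogenic = NA_real_, mean_nonpathogenic = NA_real_,
                p = NA_real_))
  list(mean_pathogenic = mean(df$score[df$pathogenic]),
       mean_nonpathogenic = mean(df$score[!df$pathogenic]),
       p = suppressWarnings(wilcox.test(score ~ pathogenic, data = df)$p.value))
}
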