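# Transcriptional consequences of SVs: relative expression on the CPM
# scale, carrier z-scores on the covariate-adjusted scale (noncarrier mean
# and sd only, to avoid frequency-driven shrinkage), outlier calls at
# |z| > 2, and the outlier-enrichment contingency tests.

#' Relative expression of carriers for one gene
#'
#' @param cpm CPM-scale expression matrix (genes x samples).
#' @param gene_id gene row to use.
#' @param carriers character vector of carrier sample ids.
#' @return mean carrier CPM divided by mean noncarrier CPM; `NA` when the
#'   noncarrier mean is zero or there are no carriers / fewer than two
#'   noncarriers.
#' @export
relative_expression <- function(cpm, gene_id, carriers) {
  x <- cpm[gene_id, ]
  is_c <- colnames(cpm) %in% carriers
  if (!any(is_c) || sum(!is_c) < 2) return(NA_real_)
  denom <- mean(x[!is_c])
  if (denom == 0) return(NA_real_)
  mean(x[is_c]) / denom
}

#' Carrier z-score for one gene
#'
#' @param adjusted covariate-adjusted expression matrix (genes x samples).
#' @param gene_id gene row to use.
#' @param carriers character vector of carrier sample ids; with several
#'   carriers the mean carrier value is standardized.
#' @param min_noncarriers floor on the number of noncarriers used to
#'   estimate the mean and sd (default 20).
#' @return `(mean(carrier) - mean(noncarrier)) / sd(noncarrier)`; `NA` when
#'   too few noncarriers or zero noncarrier sd.
#' @export
carrier_zscore <- function(adjusted, gene_id, carriers, min_noncarriers = 20) {
  x <- adjusted[gene_id, ]
  is_c <- colnames(adjusted) %in% carriers
  if (!any(is_c) || sum(!is_c) < min_noncarriers) return(NA_real_)
  s <- sd(x[!is_c])
  if (s == 0) return(NA_real_)
  (mean(x[is_c]) - mean(x[!is_c])) / s
}

#' Per SV x gene expression effects
#'
#' Computes, for every row of the feature table, the relative expression
#' (CPM scale), the carrier z-score (adjusted scale) and the outlier call
#' (`positive` if z > 2, `negative` if z < -2, else `none`).
#'
#' @param svs an [sv_set] (provides carrier sets).
#' @param features a [build_feature_table] output (defines the pairs).
#' @param cpm,adjusted expression matrices (genes x samples); `samples`
#'   restricts both to a subset (e.g. one cohort).
#' @param samples optional character vector of sample ids to use.
#' @param min_noncarriers floor for the z-score denominator estimate.
#' @return data.frame `sv_id`, `gene_id`, `sv_type`, `relative_expression`,
#'   `z_score`, `n_carriers`, `outlier`, ordered as `features`.
#' @export
expression_effects <- function(svs, features, cpm, adjusted, samples = NULL,
                               min_noncarriers = 20) {
  if (is.null(samples)) samples <- colnames(adjusted)
  stopifnot(all(samples %in% colnames(adjusted)), all(samples %in% colnames(cpm)))
  cpm <- cpm[, samples, drop = FALSE]
  adjusted <- adjusted[, samples, drop = FALSE]
  nS <- length(samples)
  gene_ids <- rownames(adjusted)

  cpm_tot <- rowSums(cpm)
  adj_tot <- rowSums(adjusted)
  adj_tot2 <- rowSums(adjusted^2)

  carr <- data.table::data.table(
    sv_id = rep(svs$sv_id, lengths(svs$carriers)),
    sample_id = unlist(svs$carriers))
  carr <- carr[sample_id %in% samples]
  fdt <- data.table::data.table(row = seq_len(nrow(features)),
                                sv_id = features$sv_id,
                                gene_idx = match(features$gene_id, gene_ids))
  if (anyNA(fdt$gene_idx)) stop("feature table gene absent from expression matrix")
  pc <- merge(fdt, carr, by = "sv_id", allow.cartesian = TRUE)
  pc[, sample_idx := match(sample_id, samples)]
  agg <- pc[, list(n_c = .N,
                   cpm_c = sum(cpm[cbind(gene_idx, sample_idx)]),
                   adj_c = sum(adjusted[cbind(gene_idx, sample_idx)]),
                   adj_c2 = sum(adjusted[cbind(gene_idx, sample_idx)]^2)),
            by = "row"]

  n_c <- integer(nrow(features)); n_c[agg$row] <- agg$n_c
  cpm_c <- adj_c <- adj_c2 <- numeric(nrow(features))
  cpm_c[agg$row] <- agg$cpm_c
  adj_c[agg$row] <- agg$adj_c
  adj_c2[agg$row] <- agg$adj_c2

  gi <- fdt$gene_idx
  n_nc <- nS - n_c
  mean_nc_cpm <- (cpm_tot[gi] - cpm_c) / n_nc
  rel <- ifelse(n_c > 0 & n_nc >= 2 & mean_nc_cpm > 0,
                (cpm_c / pmax(n_c, 1)) / mean_nc_cpm, NA_real_)
  mean_nc <- (adj_tot[gi] - adj_c) / n_nc
  var_nc <- (adj_tot2[gi] - adj_c2 - n_nc * mean_nc^2) / (n_nc - 1)
  var_nc <- pmax(var_nc, 0)
  ok <- n_c > 0 & n_nc >= min_noncarriers & var_nc > 0
  z <- ifelse(ok, (adj_c / pmax(n_c, 1) - mean_nc) / sqrt(var_nc), NA_real_)
  outlier <- ifelse(is.na(z), NA_character_,
                    ifelse(z > 2, "positive", ifelse(z < -2, "negative", "none")))
  data.frame(sv_id = features$sv_id, gene_id = features$gene_id,
             sv_type = features$sv_type, relative_expression = rel,
             z_score = z, n_carriers = n_c, outlier = outlier,
             stringsAsFactors = FALSE)
}

TABLE1_CLASSES <- c("coding", "other_transcribed", "intronic", "intergenic")
TABLE1_TYPES <- c("DEL", "DUP", "INS", "INV", "ALU")
OUTLIER_DIRECTIONS <- c("z>2", "z<-2", "|z|>2")

#' Bonferroni threshold for the outlier-enrichment family
#'
#' The family is 5 SV types x 4 annotation classes x 3 outlier directions
#' = 60 tests.
#' @return the familywise per-test threshold `0.05 / 60`.
#' @export
enrichment_bonferroni <- function() 0.05 / (length(TABLE1_TYPES) *
  length(TABLE1_CLASSES) * length(OUTLIER_DIRECTIONS))

#' Outlier enrichment by SV type and annotation class
#'
#' Tests whether SV x gene pairs of a class are enriched for expression
#' outliers relative to the intergenic pairs of the same SV type (for the
#' intergenic class itself, relative to all non-intergenic pairs of the
#' type), with a one-sided Fisher's exact test per outlier direction, and
#' flags significance at the 60-test Bonferroni threshold. Class
#' assignment is at the pair level for the genic classes -- a pair is
#' `coding`/`other_transcribed` when the SV overlaps exonic sequence of
#' that (coding / other transcribed) gene -- while `intronic` and
#' `intergenic` SVs contribute every gene within their window, which is
#' what makes the nonfunctional classes a cis-window baseline.
#'
#' @param effects an [expression_effects] table.
#' @param classes a [classify_svs] table (supplies the intronic/intergenic
#'   SV-level fallbacks).
#' @param features a [build_feature_table] output (supplies per-pair exonic
#'   overlap).
#' @param annotation a [build_annotation] object (supplies the coding
#'   flag); when `NULL` every gene is treated as coding.
#' @return data.frame with one row per (sv_type, class, direction) cell
#'   having at least one pair: `n`, `n_outliers`, `proportion`, `fisher_p`,
#'   `bonferroni_significant`.
#' @export
outlier_enrichment <- function(effects, classes, features, annotation = NULL) {
  eff <- effects[!is.na(effects$z_score), , drop = FALSE]
  m <- match(paste(eff$sv_id, eff$gene_id),
             paste(features$sv_id, features$gene_id))
  if (anyNA(m)) stop("effects row missing from the feature table")
  p_exon <- features$p_exon[m]
  coding_gene <- if (is.null(annotation)) rep(TRUE, nrow(eff)) else
    eff$gene_id %in% annotation$genes$gene_id[annotation$genes$is_coding]
  cls_tokens <- strsplit(classes$classes, ",", fixed = TRUE)
  names(cls_tokens) <- classes$sv_id
  sv_cls <- vapply(cls_tokens[eff$sv_id], `[`, "", 1)
  member <- cbind(
    coding = p_exon > 0 & coding_gene,
    other_transcribed = p_exon > 0 & !coding_gene,
    intronic = sv_cls == "intronic",
    intergenic = sv_cls == "intergenic")
  out <- list()
  for (ty in intersect(TABLE1_TYPES, unique(eff$sv_type))) {
    in_ty <- eff$sv_type == ty
    z <- eff$z_score[in_ty]
    for (cl in TABLE1_CLASSES) {
      in_cl <- member[in_ty, cl]
      base <- if (cl == "intergenic") !member[in_ty, "intergenic"]
              else member[in_ty, "intergenic"]
      if (!any(in_cl) || !any(base)) next
      for (dir in OUTLIER_DIRECTIONS) {
        is_out <- switch(dir, "z>2" = z > 2, "z<-2" = z < -2, "|z|>2" = abs(z) > 2)
        tab <- matrix(c(sum(is_out & in_cl), sum(!is_out & in_cl),
                        sum(is_out & base), sum(!is_out & base)), 2, byrow = TRUE)
        p <- fisher.test(tab, alternative = "greater")$p.value
        out[[length(out) + 1]] <- data.frame(
          sv_type = ty, class = cl, direction = dir, n = sum(in_cl),
          n_outliers = sum(is_out & in_cl),
          proportion = sum(is_out & in_cl) / sum(in_cl), fisher_p = p,
          bonferroni_significant = p < enrichment_bonferroni(),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Positional (5' vs 3') effect of CNVs on expression magnitude
#'
#' Stratifies |z| of CNV pairs touching only the TSS-containing (5') or
#' only the terminal (3') exon block into matched deciles of exonic
#' proportion, reports per-decile group means and a rank-sum test of the
#' overall 5' vs 3' difference.
#'
#' @param effects an [expression_effects] table.
#' @param features the matching [build_feature_table] output.
#' @return list with `strata` (decile x end group mean |z| and n),
#'   `p_value` (two-sided Wilcoxon of |z|, 5' vs 3'), `n_five`, `n_three`.
#' @export
positional_effect <- function(effects, features) {
  key <- paste(features$sv_id, features$gene_id)
  m <- match(paste(effects$sv_id, effects$gene_id), key)
  end <- features$affects_tss_end[m]
  keep <- effects$sv_type %in% CNV_TYPES & end %in% c("five_prime", "three_prime") &
    !is.na(effects$z_score)
  df <- data.frame(end = end[keep], absz = abs(effects$z_score[keep]),
                   p_exon = features$p_exon[m][keep], stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(list(strata = data.frame(), p_value = NA_real_, n_five = 0L, n_three = 0L))
  brks <- unique(quantile(df$p_exon, seq(0, 1, 0.1), names = FALSE))
  df$decile <- if (length(brks) > 1)
    cut(df$p_exon, brks, include.lowest = TRUE, labels = FALSE) else 1L
  dt <- data.table::as.data.table(df)
  strata <- as.data.frame(dt[, list(mean_absz = mean(absz), n = .N),
                             by = c("decile", "end")][order(decile, end)])
  p <- if (length(unique(df$end)) == 2)
    wilcox.test(absz ~ end, data = df)$p.value else NA_real_
  list(strata = strata, p_value = p,
       n_five = sum(df$end == "five_prime"), n_three = sum(df$end == "three_prime"))
}
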