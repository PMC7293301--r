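# Frequency-based selection analyses: length-matched allele-frequency
# comparisons between functional and intergenic SVs, singleton proportions
# with bootstrap intervals, the annotation-count / AF trend, and the
# relationships between gene intolerance and SV placement.

#' Match functional SVs to intergenic controls by length
#'
#' Greedy nearest-length matching without replacement, processing the
#' functional SVs in seeded random order. A pair is admissible when the
#' control has the same SV type and a length within
#' `min(500, 0.10 * functional length)` bp of the functional SV's length.
#' Unmatched functional SVs are dropped (and counted).
#'
#' @param functional,controls [sv_set] tables (or data.frames with
#'   `sv_id`, `sv_type`, `length`).
#' @param seed integer seed for the processing order.
#' @param cap absolute tolerance ceiling in bp (default 500).
#' @return data.frame `functional_sv_id`, `control_sv_id`, `length_diff`;
#'   attribute `n_unmatched` counts dropped functional SVs.
#' @export
match_by_length <- function(functional, controls, seed = 1L, cap = 500) {
  if (nrow(controls) == 0) {
    warning("empty control pool; no matches")
    out <- data.frame(functional_sv_id = character(), control_sv_id = character(),
                      length_diff = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_unmatched") <- nrow(functional)
    return(out)
  }
  ord <- withr::with_seed(seed, sample.int(nrow(functional)))
  res_f <- res_c <- character(0)
  res_d <- numeric(0)
  by_type <- split(seq_len(nrow(controls)), controls$sv_type)
  avail <- lapply(by_type, function(ix) {
    o <- order(controls$length[ix])
    list(len = controls$length[ix][o], idx = ix[o], used = logical(length(ix)))
  })
  for (i in ord) {
    ty <- functional$sv_type[i]
    pool <- avail[[ty]]
    if (is.null(pool)) next
    L <- functional$length[i]
    tol <- min(cap, 0.10 * L)
    free <- which(!pool$used)
    if (!length(free)) next
    d <- abs(pool$len[free] - L)
    j <- free[which.min(d)]
    if (abs(pool$len[j] - L) <= tol) {
      pool$used[j] <- TRUE
      avail[[ty]] <- pool
      res_f <- c(res_f, functional$sv_id[i])
      res_c <- c(res_c, controls$sv_id[pool$idx[j]])
      res_d <- c(res_d, abs(pool$len[j] - L))
    }
  }
  out <- data.frame(functional_sv_id = res_f, control_sv_id = res_c,
                    length_diff = res_d, stringsAsFactors = FALSE)
  attr(out, "n_unmatched") <- nrow(functional) - nrow(out)
  out
}

#' Allele-frequency comparison on matched pairs
#'
#' One-sided two-sample Wilcoxon rank-sum test of the matched AF lists
#' (alternative: functional SVs are rarer than their length-matched
#' intergenic controls).
#'
#' @param pairs a [match_by_length] result.
#' @param svs the [sv_set] the pair ids refer to.
#' @return list `mean_af_functional`, `mean_af_control`, `wilcoxon_p`, `n`.
#' @export
af_comparison <- function(pairs, svs) {
  if (nrow(pairs) < 10) stop("need at least 10 matched pairs")
  af <- setNames(svs$af, svs$sv_id)
  af_f <- af[pairs$functional_sv_id]
  af_c <- af[pairs$control_sv_id]
  p <- if (length(unique(c(af_f, af_c))) == 1) {
    warning("all allele frequencies identical; p = 1")
    1
  } else {
    suppressWarnings(wilcox.test(af_f, af_c, alternative = "less")$p.value)
  }
  list(mean_af_functional = mean(af_f), mean_af_control = mean(af_c),
       wilcoxon_p = p, n = nrow(pairs))
}

#' Singleton proportions by annotation class with bootstrap CIs
#'
#' A singleton is an SV carried by exactly one individual. SVs are
#' stratified by each annotation class they touch (intronic/intergenic as
#' fallbacks); the CI is a percentile bootstrap over SVs within class.
#'
#' @param svs an [sv_set].
#' @param classes a [classify_svs] table.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return data.frame `class`, `proportion`, `ci_low`, `ci_high`, `n_svs`.
#' @export
singleton_proportions <- function(svs, classes, n_boot = 1000, seed = 1L) {
  singleton <- lengths(svs$carriers) == 1
  names(singleton) <- svs$sv_id
  tokens <- strsplit(classes$classes, ",", fixed = TRUE)
  long <- data.frame(class = unlist(tokens),
                     sv_id = rep(classes$sv_id, lengths(tokens)),
                     stringsAsFactors = FALSE)
  all_classes <- c(FUNCTIONAL_CLASSES, "intronic", "intergenic")
  out <- withr::with_seed(seed, {
    rows <- lapply(intersect(all_classes, unique(long$class)), function(cl) {
      s <- singleton[long$sv_id[long$class == cl]]
      n <- length(s)
      if (n == 0) return(NULL)
      boot <- vapply(seq_len(n_boot),
                     function(i) mean(s[sample.int(n, n, replace = TRUE)]), 1)
      ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
      data.frame(class = cl, proportion = mean(s), ci_low = ci[1],
                 ci_high = ci[2], n_svs = n, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  empty <- setdiff(all_classes, out$class)
  if (length(empty)) warning("classes with no SVs omitted: ",
                             paste(empty, collapse = ", "))
  out
}

#' Spearman trend between annotation-class count and allele frequency
#'
#' @param classes a [classify_svs] table.
#' @param svs the matching [sv_set].
#' @return list `rho`, `p`; both `NA` (with a message) when either input
#'   is constant.
#' @export
annotation_count_af_trend <- function(classes, svs) {
  af <- setNames(svs$af, svs$sv_id)[classes$sv_id]
  k <- classes$n_functional_classes
  if (length(unique(k)) < 2 || length(unique(af)) < 2) {
    message("annotation_count_af_trend: constant input, correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(k, af, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Gene-intolerance relationships of genic and regulatory CNVs
#'
#' Emits (a) the Spearman correlation between gene intolerance and the
#' proportion of exonic sequence affected, per CNV type and metric, (b) a
#' Wilcoxon test of the gene metric by whether the gene has any exonic
#' (genic) CNV, and (c) quintile summaries: genes are split into five
#' equal-size bins from least to most intolerant (ties broken by gene_id)
#' and observed CNV counts per bin are compared with the uniform
#' expectation, separately for genic, promoter-only and enhancer-only
#' (noncoding) CNVs.
#'
#' @param features a [build_feature_table] output.
#' @param intolerance table with `gene_id`, `raw_lof`, `raw_cnv` (higher =
#'   more tolerant).
#' @return list `spearman` (data.frame), `wilcoxon` (data.frame),
#'   `quintiles` (data.frame with `deviation = observed/expected - 1`).
#' @export
intolerance_relationships <- function(features, intolerance) {
  cnv <- features[features$sv_type %in% CNV_TYPES, , drop = FALSE]
  for (m in c("raw_lof", "raw_cnv")) {
    frac_na <- mean(is.na(intolerance[[m]]))
    if (frac_na > 0.5) stop("metric ", m, " missing for >50% of genes")
  }
  metric_of <- function(m) setNames(intolerance[[m]], intolerance$gene_id)

  sp <- do.call(rbind, lapply(CNV_TYPES, function(ty) {
    rows <- cnv$sv_type == ty & cnv$p_exon > 0
    do.call(rbind, lapply(c("raw_lof", "raw_cnv"), function(m) {
      v <- metric_of(m)[cnv$gene_id[rows]]
      ok <- !is.na(v)
      if (sum(ok) < 3 || length(unique(v[ok])) < 2 ||
          length(unique(cnv$p_exon[rows][ok])) < 2)
        return(data.frame(sv_type = ty, metric = m, rho = NA_real_, p = NA_real_))
      ct <- suppressWarnings(cor.test(v[ok], cnv$p_exon[rows][ok],
                                      method = "spearman", exact = FALSE))
      data.frame(sv_type = ty, metric = m, rho = unname(ct$estimate),
                 p = ct$p.value, stringsAsFactors = FALSE)
    }))
  }))

  genic_genes <- unique(cnv$gene_id[cnv$p_exon > 0])
  wx <- do.call(rbind, lapply(c("raw_lof", "raw_cnv"), function(m) {
    v <- metric_of(m)
    grp <- names(v) %in% genic_genes
    p <- if (length(unique(grp)) == 2)
      suppressWarnings(wilcox.test(v[grp], v[!grp])$p.value) else NA_real_
    data.frame(metric = m, p = p,
               median_genic = stats::median(v[grp], na.rm = TRUE),
               median_other = stats::median(v[!grp], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  qs <- do.call(rbind, lapply(c("raw_lof", "raw_cnv"), function(m) {
    v <- metric_of(m)
    # higher raw metric = more tolerant; quintile 5 = most intolerant
    ord <- order(-v, names(v))
    quint <- integer(length(v))
    quint[ord] <- ceiling(seq_along(ord) / (length(ord) / 5))
    names(quint) <- names(v)
    do.call(rbind, lapply(CNV_TYPES, function(ty) {
      tyrows <- cnv$sv_type == ty
      genic <- tyrows & cnv$p_exon > 0
      prom_only <- tyrows & cnv$p_exon == 0 & cnv$p_prom > 0
      enh_only <- tyrows & cnv$p_exon == 0 & cnv$p_prom == 0 & cnv$enh_sum > 0
      rows <- list(genic = genic, promoter_only = prom_only, enhancer_only = enh_only)
      do.call(rbind, lapply(names(rows), function(cat) {
        sel <- rows[[cat]]
        q_of <- quint[cnv$gene_id[sel]]
        obs <- tabulate(q_of, 5)
        expd <- sum(obs) / 5
        pe <- vapply(1:5, function(q) {
          x <- cnv$p_exon[sel][q_of == q]
          c(mean(x), sd(x))
        }, c(1, 1))
        data.frame(metric = m, sv_type = ty, category = cat, quintile = 1:5,
                   observed = obs, expected = expd,
                   deviation = if (expd > 0) obs / expd - 1 else NA_real_,
                   mean_p_exon = pe[1, ], sd_p_exon = pe[2, ],
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  list(spearman = sp, wilcoxon = wx, quintiles = qs)
}
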