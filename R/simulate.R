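# Synthetic-study generator. Emulates the statistical structure of a
# brain-tissue SV/expression study: a gene-tiled synthetic genome with
# regulatory elements, a rare heterozygous SV callset with length-dependent
# log-normal sizes and selection-shifted carrier counts for functional SVs,
# per-gene intolerance metrics, and expression on two scales -- raw CPM with
# a multiplicative heterozygous dosage factor (0.5x / 1.5x for full-gene
# deletion / duplication) and covariate-adjusted expression generated from
# the joint linear dosage model itself, so that model fitting on simulated
# data is a parameter-recovery experiment.

#' Default generative coefficients of the joint dosage model
#'
#' Per-CNV-type coefficients of the linear model of carrier expression
#' z-scores on (`p_exon`, `enh_sum`, `p_prom`, `sv_length`, `within_tad`).
#' Deletions lower expression roughly in proportion to the exonic fraction
#' removed; duplications raise it; promoter overlap acts in the same
#' direction; enhancer overlap has a small negative effect; SV length a
#' per-bp effect; TAD co-membership a small modifier.
#'
#' @return named list with numeric vectors `DEL` and `DUP`.
#' @export
default_dosage_betas <- function() {
  list(
    DEL = c(p_exon = -1.7762, enh_sum = -0.0152, p_prom = -0.1726,
            sv_length = -2.14e-07, within_tad = -0.0090),
    DUP = c(p_exon = 0.7825, enh_sum = -0.0157, p_prom = 0.3735,
            sv_length = 3.99e-07, within_tad = 0.0046)
  )
}

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: two cohorts of 300
#' samples, a 120 Mb single-chromosome genome tiled with 1200 genes, 20,000
#' rare SVs with log-normal lengths (median 280 bp), selection shift
#' `af_shift` on functional SVs, and expression generated under
#' [default_dosage_betas] with unit noise on the adjusted scale and
#' mean-one log-normal noise (sdlog 0.15) on the CPM scale.
#'
#' @param ... overrides of any default field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_samples = c(cohortA = 300L, cohortB = 300L),
    chrom = "chrS1",
    genome_length = 120e6,
    n_genes = 1200L,
    frac_coding = 0.8,
    exons_per_gene = c(1L, 20L),
    exon_len_meanlog = log(200), exon_len_sdlog = 0.6,
    intron_len_meanlog = log(1500), intron_len_sdlog = 1,
    frac_genes_enhanced = 0.3,
    enh_per_gene = c(1L, 5L),
    enh_len_range = c(200L, 2000L),
    n_ctcf = 2000L, ctcf_len_range = c(150L, 400L),
    n_tads = 60L,
    n_svs = c(DEL = 8000L, DUP = 4000L, INS = 4000L, ALU = 2500L,
              INV = 1000L, CPX = 500L),
    sv_len_meanlog = log(280), sv_len_sdlog = 2.2,
    sv_len_min = 50, sv_len_max = 5e6,
    base_extra_carriers = 0.6,
    af_shift = 0.3,
    betas = default_dosage_betas(),
    cohort_beta_sd = 0,
    noise_sd = 1,
    cpm_baseline_meanlog = log(50), cpm_baseline_sdlog = 1,
    cpm_noise_sdlog = 0.15,
    intolerance_rho = 0.7,
    placement_bias = FALSE,
    bias_strength = 0.8,
    window = 1e6,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(all(cfg$n_svs >= 0), cfg$noise_sd > 0, cfg$n_samples > 0)
  class(cfg) <- "sim_config"
  cfg
}

sample_ids_of <- function(cfg) {
  unlist(lapply(names(cfg$n_samples), function(co)
    sprintf("%s_s%04d", co, seq_len(cfg$n_samples[[co]]))), use.names = FALSE)
}

cohort_of_samples <- function(cfg) {
  ids <- sample_ids_of(cfg)
  setNames(rep(names(cfg$n_samples), cfg$n_samples), ids)
}

#' Simulate a genome annotation
#'
#' Genes (with exon/intron structure drawn per gene) tile the genome with
#' exponential intergenic gaps; a fraction of genes receive 1-5 linked
#' enhancers placed within 1 Mb of their TSS; TADs partition the
#' chromosome; CTCF sites sit at TAD boundaries and in intergenic space.
#'
#' @param cfg a [sim_config]. Randomness is drawn from the current RNG
#'   stream (seed it, or call via [simulate_study]).
#' @return a [build_annotation] object.
#' @export
simulate_annotation <- function(cfg) {
  n <- cfg$n_genes
  if (n == 0) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(), strand = character(),
                        tss = integer(), is_coding = logical(),
                        stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(), stringsAsFactors = FALSE)
    return(build_annotation(genes, exons))
  }
  n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), n, replace = TRUE)
  struct <- lapply(n_ex, function(k) {
    e <- pmax(20, round(rlnorm(k, cfg$exon_len_meanlog, cfg$exon_len_sdlog)))
    i <- if (k > 1) pmax(50, round(rlnorm(k - 1, cfg$intron_len_meanlog,
                                          cfg$intron_len_sdlog))) else numeric(0)
    list(exon = e, intron = i, len = sum(e) + sum(i))
  })
  glen <- vapply(struct, `[[`, 1, "len")
  budget <- cfg$genome_length - sum(glen)
  if (budget <= n) stop("genome too small for requested gene content")
  u <- stats::rexp(n + 1)
  gaps <- floor(budget * u / sum(u))
  starts <- cumsum(c(gaps[1], glen[-n] + gaps[2:n]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("gene%04d", seq_len(n))
  genes <- data.frame(
    gene_id = gene_id, chrom = cfg$chrom, start = as.integer(starts),
    end = as.integer(starts + glen), strand = strand,
    tss = as.integer(ifelse(strand == "-", starts + glen - 1, starts)),
    is_coding = runif(n) < cfg$frac_coding, stringsAsFactors = FALSE)
  exons <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    s <- struct[[i]]
    off <- cumsum(c(0, head(as.vector(rbind(s$exon, c(s$intron, 0))), -1)))
    es <- starts[i] + off[seq(1, length(off), by = 2)]
    data.table::data.table(gene_id = gene_id[i], chrom = cfg$chrom,
                           start = as.integer(es),
                           end = as.integer(es + s$exon))
  }))
  exons <- as.data.frame(exons)

  enhanced <- sample(gene_id, round(cfg$frac_genes_enhanced * n))
  enh_list <- lapply(enhanced, function(g) {
    k <- sample(seq(cfg$enh_per_gene[1], cfg$enh_per_gene[2]), 1)
    tss <- genes$tss[genes$gene_id == g]
    len <- round(runif(k, cfg$enh_len_range[1], cfg$enh_len_range[2]))
    pos <- round(runif(k, pmax(0, tss - 1e6), pmin(cfg$genome_length - len, tss + 1e6)))
    data.frame(gene_id = g, chrom = cfg$chrom, start = as.integer(pos),
               end = as.integer(pos + len), stringsAsFactors = FALSE)
  })
  enh <- if (length(enh_list)) do.call(rbind, enh_list) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  enhancers <- data.frame(enhancer_id = sprintf("enh%05d", seq_len(nrow(enh))),
                          chrom = enh$chrom, start = enh$start, end = enh$end,
                          stringsAsFactors = FALSE)
  links <- data.frame(enhancer_id = enhancers$enhancer_id, gene_id = enh$gene_id,
                      stringsAsFactors = FALSE)

  brk <- sort(round(runif(max(0, cfg$n_tads - 1), 1e5, cfg$genome_length - 1e5)))
  edges <- unique(c(0, brk, cfg$genome_length))
  tads <- data.frame(chrom = cfg$chrom, start = as.integer(edges[-length(edges)]),
                     end = as.integer(edges[-1]), stringsAsFactors = FALSE)

  boundary_pool <- tads$start[tads$start > 0]
  n_boundary <- if (length(boundary_pool)) min(cfg$n_ctcf %/% 2, cfg$n_ctcf) else 0L
  blen <- round(runif(cfg$n_ctcf, cfg$ctcf_len_range[1], cfg$ctcf_len_range[2]))
  at_boundary <- if (n_boundary)
    boundary_pool[sample.int(length(boundary_pool), n_boundary,
                             replace = n_boundary > length(boundary_pool))]
  else integer(0)
  free <- round(runif(cfg$n_ctcf - n_boundary, 0, cfg$genome_length - max(blen)))
  pos <- c(at_boundary, free)
  ctcf <- data.frame(chrom = cfg$chrom, start = as.integer(pos),
                     end = as.integer(pos + blen[seq_along(pos)]),
                     stringsAsFactors = FALSE)
  build_annotation(genes, exons, enhancers, links, ctcf, tads)
}

#' Simulate a rare heterozygous SV callset
#'
#' Positions are uniform, lengths log-normal; every SV is rare (carrier
#' fraction < 1%, AF < 0.5%, all heterozygous). SVs overlapping a gene
#' body, enhancer or CTCF site get their expected extra-carrier count
#' multiplied by `exp(-af_shift)`, emulating selection against functional
#' SVs. With `placement_bias`, CNVs landing on exons of the most intolerant
#' gene quintile are redrawn with probability `bias_strength`.
#'
#' @param annotation a [build_annotation] object.
#' @param cfg a [sim_config].
#' @param intolerance optional intolerance table (needed for
#'   `placement_bias`).
#' @return an [sv_set].
#' @export
simulate_svs <- function(annotation, cfg, intolerance = NULL) {
  samples <- sample_ids_of(cfg)
  N <- length(samples)
  types <- rep(names(cfg$n_svs), cfg$n_svs)
  n <- length(types)
  len <- pmin(cfg$sv_len_max,
              pmax(cfg$sv_len_min, round(rlnorm(n, cfg$sv_len_meanlog, cfg$sv_len_sdlog))))
  is_ins <- types %in% INSERTION_TYPES
  span <- ifelse(is_ins, 1, len)
  start <- floor(runif(n, 0, cfg$genome_length - span))
  end <- start + span

  if (isTRUE(cfg$placement_bias)) {
    if (is.null(intolerance)) stop("placement_bias requires an intolerance table")
    w <- normalize_intolerance(intolerance)
    top <- w$gene_id[w$weight >= quantile(w$weight, 0.8)]
    top_ex <- annotation$exons[annotation$exons$gene_id %in% top, , drop = FALSE]
    if (nrow(top_ex)) {
      for (it in 1:10) {
        df <- data.frame(chrom = cfg$chrom, start = start, end = end)
        hit <- logical(n)
        hit[unique(overlap_pairs(df, top_ex)$sv_idx)] <- TRUE
        redo <- which(hit & types %in% CNV_TYPES & runif(n) < cfg$bias_strength)
        if (!length(redo)) break
        start[redo] <- floor(runif(length(redo), 0, cfg$genome_length - span[redo]))
        end[redo] <- start[redo] + span[redo]
      }
    }
  }

  sv_df <- data.frame(chrom = cfg$chrom, start = start, end = end)
  functional <- logical(n)
  for (feats in list(annotation$genes, annotation$enhancers, annotation$ctcf))
    if (nrow(feats)) functional[unique(overlap_pairs(sv_df, feats)$sv_idx)] <- TRUE

  max_extra <- max(0L, as.integer(ceiling(0.01 * N)) - 2L)  # carrier fraction < 1%
  lambda <- cfg$base_extra_carriers * ifelse(functional, exp(-cfg$af_shift), 1)
  extra <- pmin(rpois(n, lambda), max_extra)
  carriers <- lapply(1L + extra, sample, x = samples)
  ids <- sprintf("sv%05d_%s", seq_len(n), types)
  sv_set(ids, cfg$chrom, start, end, types, len, carriers, samples)
}

#' Simulate per-gene intolerance metrics
#'
#' `raw_lof` is LOEUF-like (log-normal, higher = more tolerant); `raw_cnv`
#' is drawn with Gaussian-copula rank correlation `intolerance_rho` to
#' `raw_lof` and shares its orientation.
#'
#' @param annotation a [build_annotation] object.
#' @param cfg a [sim_config].
#' @return data.frame `gene_id`, `raw_lof`, `raw_cnv`, `weight` (min-max
#'   normalized, 1 = most intolerant).
#' @export
simulate_intolerance <- function(annotation, cfg) {
  g <- annotation$genes$gene_id
  n <- length(g)
  z1 <- rnorm(n)
  z2 <- cfg$intolerance_rho * z1 + sqrt(1 - cfg$intolerance_rho^2) * rnorm(n)
  rec <- data.frame(gene_id = g, raw_lof = exp(0.6 * z1 - 0.3),
                    raw_cnv = exp(0.6 * z2 - 0.3), stringsAsFactors = FALSE)
  normalize_intolerance(rec)
}

#' Simulate expression (CPM and adjusted scales) with SV dosage effects
#'
#' On the CPM scale each gene has a log-normal baseline; carriers of a CNV
#' covering exonic fraction p have their value multiplied by `1 - 0.5 p`
#' (deletion) or `1 + 0.5 p` (duplication), the heterozygous dosage
#' expectation, times mean-one log-normal noise (`cpm_noise_sdlog = 0`
#' disables the noise). On the adjusted scale noncarriers are standard
#' normal per gene and carriers are `N(mu, noise_sd)` with
#' `mu = X beta` from the joint dosage model evaluated on the pair's
#' covariates (cohort-specific betas when `cohort_beta_sd > 0`); `mu` is
#' recorded in the truth table for every SV x gene pair within the window
#' (zero for non-CNV types).
#'
#' @param annotation a [build_annotation] object.
#' @param svs an [sv_set] on the same genome.
#' @param cfg a [sim_config].
#' @param features optional precomputed [build_feature_table] output.
#' @return list with `cpm`, `adjusted` (matrices with `scale` attribute),
#'   `truth` (sv_id, gene_id, cohort, mu), `features`, `betas_by_cohort`.
#' @export
simulate_expression <- function(annotation, svs, cfg, features = NULL) {
  for (ty in intersect(CNV_TYPES, names(cfg$n_svs)[cfg$n_svs > 0]))
    if (is.null(cfg$betas[[ty]])) stop("no generative betas for SV type ", ty)
  if (is.null(features)) features <- build_feature_table(svs, annotation, cfg$window)
  samples <- sample_ids_of(cfg)
  cohort_of <- cohort_of_samples(cfg)
  cohorts <- names(cfg$n_samples)
  genes <- annotation$genes$gene_id
  nG <- length(genes)
  nS <- length(samples)

  betas_by_cohort <- lapply(cohorts, function(co) {
    lapply(cfg$betas, function(b) b + rnorm(length(b), 0, cfg$cohort_beta_sd))
  })
  names(betas_by_cohort) <- cohorts

  X <- as.matrix(features[, c("p_exon", "enh_sum", "p_prom", "sv_length", "within_tad")])
  mu_by_cohort <- if (nrow(features) == 0)
    matrix(numeric(0), 0, length(cohorts), dimnames = list(NULL, cohorts))
  else matrix(vapply(cohorts, function(co) {
    mu <- numeric(nrow(features))
    for (ty in CNV_TYPES) {
      rows <- features$sv_type == ty
      if (any(rows)) mu[rows] <- X[rows, , drop = FALSE] %*%
          betas_by_cohort[[co]][[ty]][c("p_exon", "enh_sum", "p_prom",
                                        "sv_length", "within_tad")]
    }
    mu
  }, numeric(nrow(features))), ncol = length(cohorts),
  dimnames = list(NULL, cohorts))
  truth <- data.table::rbindlist(lapply(cohorts, function(co)
    data.table::data.table(sv_id = features$sv_id, gene_id = features$gene_id,
                           cohort = co, mu = mu_by_cohort[, co])))
  truth <- as.data.frame(truth[order(sv_id, gene_id, cohort)])

  # expand (pair, carrier) and accumulate per (gene, sample)
  carr <- data.table::data.table(
    sv_id = rep(svs$sv_id, lengths(svs$carriers)),
    sample_id = unlist(svs$carriers))
  fdt <- data.table::as.data.table(features)
  fdt[, `:=`(row = .I, gene_idx = match(gene_id, genes))]
  pc <- merge(fdt, carr, by = "sv_id", allow.cartesian = TRUE)

  adjusted <- matrix(rnorm(nG * nS), nG, nS, dimnames = list(genes, samples))
  b <- rlnorm(nG, cfg$cpm_baseline_meanlog, cfg$cpm_baseline_sdlog)
  s <- cfg$cpm_noise_sdlog
  cpm <- matrix(b, nG, nS, dimnames = list(genes, samples))
  if (s > 0) cpm <- cpm * matrix(rlnorm(nG * nS, -s^2 / 2, s), nG, nS)

  if (nrow(pc)) {
    pc[, sample_idx := match(sample_id, samples)]
    cnv <- pc[sv_type %in% CNV_TYPES]
    if (nrow(cnv)) {
      cnv[, mu := mu_by_cohort[cbind(row, match(cohort_of[sample_id], cohorts))]]
      cnv[, logfac := log1p(ifelse(sv_type == "DEL", -0.5, 0.5) * p_exon)]
      agg <- cnv[, list(mu = sum(mu), logfac = sum(logfac)),
                 by = c("gene_idx", "sample_idx")]
      idx <- cbind(agg$gene_idx, agg$sample_idx)
      if (cfg$noise_sd != 1)
        adjusted[idx] <- adjusted[idx] * cfg$noise_sd
      adjusted[idx] <- adjusted[idx] + agg$mu
      cpm[idx] <- cpm[idx] * exp(agg$logfac)
    }
  }
  attr(cpm, "scale") <- "cpm"
  attr(adjusted, "scale") <- "adjusted"
  list(cpm = cpm, adjusted = adjusted, truth = truth, features = features,
       betas_by_cohort = betas_by_cohort)
}

#' Simulate a complete synthetic study
#'
#' Deterministic for a given config (the seed is part of the config):
#' annotation, intolerance, SV callset, expression on both scales, truth
#' table and cohort map.
#'
#' @param cfg a [sim_config].
#' @return list of class `synthetic_study` with elements `annotation`,
#'   `svs`, `cpm`, `adjusted`, `intolerance`, `cohort_of`, `truth`,
#'   `features`, `betas_by_cohort`, `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  withr::with_seed(cfg$seed, {
    annotation <- simulate_annotation(cfg)
    intolerance <- simulate_intolerance(annotation, cfg)
    svs <- simulate_svs(annotation, cfg, intolerance)
    expr <- simulate_expression(annotation, svs, cfg)
  })
  study <- list(annotation = annotation, svs = svs, cpm = expr$cpm,
                adjusted = expr$adjusted, intolerance = intolerance,
                cohort_of = cohort_of_samples(cfg), truth = expr$truth,
                features = expr$features, betas_by_cohort = expr$betas_by_cohort,
                config = cfg)
  class(study) <- "synthetic_study"
  study
}

#' @exportS3Method base::print
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes, %d SVs, %d samples (%s), %d SVxgene pairs\n",
              nrow(x$annotation$genes), nrow(x$svs), length(x$cohort_of),
              paste(names(x$config$n_samples), collapse = "+"), nrow(x$features)))
  invisible(x)
}

#' Simulate SV x gene rows directly from the joint dosage model
#'
#' Draws the five covariates from marginal distributions that mirror the
#' study's feature table -- point masses at 0 and 1 for the exonic and
#' promoter proportions (an SV typically either misses or engulfs a 2 kb
#' promoter), a zero-inflated gamma for the enhancer sum (genes carry many
#' linked enhancers, so a large SV can accumulate a sum well above 1),
#' log-normal lengths and a Bernoulli TAD indicator -- and generates
#' `z = X beta + noise`. This is the workhorse for parameter-recovery
#' experiments on the OLS fit.
#'
#' @param n number of rows.
#' @param sv_type `"DEL"` or `"DUP"`.
#' @param betas named coefficient vector (default [default_dosage_betas]).
#' @param noise_sd residual standard deviation of z.
#' @return data.frame with `sv_id`, `gene_id`, `sv_type`, the five
#'   covariates, and `z_score`.
#' @export
simulate_dosage_rows <- function(n, sv_type = c("DEL", "DUP"), betas = NULL,
                                 noise_sd = 1) {
  sv_type <- match.arg(sv_type)
  if (is.null(betas)) betas <- default_dosage_betas()[[sv_type]]
  mix01 <- function(n, p0, p1, a, b) {
    u <- runif(n)
    x <- rbeta(n, a, b)
    x[u < p0] <- 0
    x[u > 1 - p1] <- 1
    x
  }
  p_exon <- mix01(n, 0.35, 0.25, 0.7, 0.9)
  p_prom <- mix01(n, 0.45, 0.35, 1, 1)
  enh_sum <- ifelse(runif(n) < 0.45, 0, rgamma(n, shape = 0.7, scale = 5))
  sv_length <- pmin(5e6, pmax(50, round(rlnorm(n, log(280), 2.2))))
  within_tad <- rbinom(n, 1, 0.6)
  X <- cbind(p_exon = p_exon, enh_sum = enh_sum, p_prom = p_prom,
             sv_length = sv_length, within_tad = within_tad)
  z <- drop(X %*% betas[colnames(X)]) + rnorm(n, 0, noise_sd)
  data.frame(sv_id = sprintf("sim%06d", seq_len(n)),
             gene_id = sprintf("g%06d", seq_len(n)), sv_type = sv_type,
             p_exon = p_exon, p_prom = p_prom, enh_sum = enh_sum,
             within_tad = within_tad, sv_length = sv_length, z_score = z,
             stringsAsFactors = FALSE)
}

#' Write a synthetic study to a directory of standard-format files
#'
#' @param study a [simulate_study] result.
#' @param dir output directory (created if needed). Writes `svs.vcf`,
#'   `genes.gtf`, `enhancers.bed`, `links.tsv`, `ctcf.bed`, `tads.bed`,
#'   `cpm.tsv`, `adjusted.tsv`, `intolerance.tsv`, `truth.tsv`,
#'   `cohorts.tsv`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_sv_vcf(study$svs, p("svs.vcf"))
  write_gene_gtf(study$annotation$genes, study$annotation$exons, p("genes.gtf"))
  enh <- study$annotation$enhancers
  write_bed(data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                       name = enh$enhancer_id), p("enhancers.bed"))
  write.table(study$annotation$links, p("links.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bed(study$annotation$ctcf, p("ctcf.bed"))
  write_bed(study$annotation$tads, p("tads.bed"))
  write_expression_tsv(study$cpm, p("cpm.tsv"))
  write_expression_tsv(study$adjusted, p("adjusted.tsv"))
  write_table(study$intolerance, p("intolerance.tsv"), "intolerance")
  write_table(study$truth, p("truth.tsv"), "truth")
  write.table(data.frame(sample_id = names(study$cohort_of),
                         cohort = unname(study$cohort_of)),
              p("cohorts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
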