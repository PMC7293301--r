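# Properties of the synthetic-study generator: determinism, referential
# integrity, the rare-variant and dosage conventions, and calibration of
# the generative expression model.

test_that("identical config yields an identical study; annotation is coherent", {
  cfg <- small_cfg(seed = 99L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$svs$start, b$svs$start)
  expect_identical(a$adjusted, b$adjusted)
  expect_identical(a$truth, b$truth)
  ann <- a$annotation
  expect_true(all(ann$links$gene_id %in% ann$genes$gene_id))
  expect_true(all(ann$links$enhancer_id %in% ann$enhancers$enhancer_id))
  o <- order(ann$tads$start)
  expect_true(all(diff(ann$tads$start[o]) > 0))
  expect_true(all(ann$tads$start[o][-1] >= ann$tads$end[o][-nrow(ann$tads)]))
  # exons inside gene bodies
  m <- match(ann$exons$gene_id, ann$genes$gene_id)
  expect_true(all(ann$exons$start >= ann$genes$start[m]))
  expect_true(all(ann$exons$end <= ann$genes$end[m]))
})

test_that("an empty gene list still yields a valid annotation", {
  cfg <- small_cfg(n_genes = 0L)
  ann <- withr::with_seed(1, simulate_annotation(cfg))
  expect_equal(nrow(ann$genes), 0L)
  expect_s3_class(ann, "genome_annotation")
})

test_that("every simulated SV is rare, heterozygous and definitionally consistent", {
  study <- small_study()
  svs <- study$svs
  N <- length(attr(svs, "sample_ids"))
  expect_equal(svs$af, lengths(svs$carriers) / (2 * N))
  expect_true(all(lengths(svs$carriers) / N < 0.01))
  expect_true(all(svs$af < 0.005))
  expect_true(all(!vapply(svs$carriers, anyDuplicated, 1L) > 0))
  ins <- svs$sv_type %in% c("INS", "ALU", "LINE1", "SVA")
  expect_true(all(svs$end[ins] - svs$start[ins] == 1L))
  expect_true(all(svs$end[!ins] - svs$start[!ins] == svs$length[!ins]))
})

test_that("noncarrier adjusted expression is standard normal per gene", {
  study <- small_study()
  # (gene, sample) cells not touched by any CNV pair are pure noise
  ft <- study$features[study$features$sv_type %in% c("DEL", "DUP"), ]
  carr <- data.frame(sv_id = rep(study$svs$sv_id, lengths(study$svs$carriers)),
                     sample_id = unlist(study$svs$carriers))
  touched <- merge(ft[, c("sv_id", "gene_id")], carr, by = "sv_id")
  idx <- cbind(match(touched$gene_id, rownames(study$adjusted)),
               match(touched$sample_id, colnames(study$adjusted)))
  mask <- matrix(TRUE, nrow(study$adjusted), ncol(study$adjusted))
  mask[idx] <- FALSE
  sub <- study$adjusted[mask]
  n <- length(sub)
  expect_lt(abs(mean(sub)), 4 / sqrt(n))
  expect_lt(abs(sd(sub) - 1), 4 / sqrt(2 * n))
})

test_that("truth table and feature table agree on the model covariates", {
  study <- small_study()
  ft <- study$features
  X <- as.matrix(ft[, c("p_exon", "enh_sum", "p_prom", "sv_length", "within_tad")])
  betas <- study$config$betas
  mu <- numeric(nrow(ft))
  for (ty in c("DEL", "DUP")) {
    r <- ft$sv_type == ty
    mu[r] <- X[r, , drop = FALSE] %*% betas[[ty]][colnames(X)]
  }
  tr <- study$truth[study$truth$cohort == "cohortA", ]
  m <- match(paste(ft$sv_id, ft$gene_id), paste(tr$sv_id, tr$gene_id))
  expect_false(anyNA(m))
  expect_equal(tr$mu[m], mu, tolerance = 1e-9)
  expect_equal(nrow(tr), nrow(ft))  # truth covers exactly the windowed pairs
})

test_that("full-gene heterozygous deletions halve CPM exactly when noise is off", {
  cfg <- small_cfg(cpm_noise_sdlog = 0, seed = 17L,
                   sv_len_meanlog = log(3e4), sv_len_sdlog = 0.8,
                   n_samples = c(cohortA = 120L),
                   n_svs = c(DEL = 250L, DUP = 120L, INS = 0L, ALU = 0L,
                             INV = 0L, CPX = 0L))
  study <- simulate_study(cfg)
  eff <- expression_effects(study$svs, study$features, study$cpm, study$adjusted)
  ft <- study$features
  # exactness requires the gene's CPM to be touched by this CNV alone
  exonic <- ft$p_exon > 0
  sole_cnv <- ft$gene_id %in% names(which(table(ft$gene_id[exonic]) == 1))
  full_del <- exonic & sole_cnv & ft$sv_type == "DEL" & ft$p_exon == 1
  expect_gt(sum(full_del), 10)
  expect_equal(eff$relative_expression[full_del], rep(0.5, sum(full_del)),
               tolerance = 1e-9)
  full_dup <- exonic & sole_cnv & ft$sv_type == "DUP" & ft$p_exon == 1
  expect_gt(sum(full_dup), 3)
  expect_equal(eff$relative_expression[full_dup], rep(1.5, sum(full_dup)),
               tolerance = 1e-9)
})

test_that("carrier z-draws have the generative mean (CLT check)", {
  mu <- -1
  z <- withr::with_seed(12, rnorm(10000, mu, 1))
  rows <- withr::with_seed(12, simulate_dosage_rows(10000, "DEL",
    betas = c(p_exon = mu, enh_sum = 0, p_prom = 0, sv_length = 0, within_tad = 0),
    noise_sd = 1))
  # rows with p_exon == 1 have true mean mu; all draws jointly stay within 4 SE
  sel <- rows$p_exon == 1
  se <- 1 / sqrt(sum(sel))
  expect_lt(abs(mean(rows$z_score[sel]) - mu), 4 * se)
  expect_lt(abs(mean(z) - mu), 4 / sqrt(length(z)))
})

test_that("af_shift = 0 gives frequency-matched genic and intergenic SVs", {
  cfg <- small_cfg(af_shift = 0, seed = 7L)
  svs <- withr::with_seed(7, {
    ann <- simulate_annotation(cfg)
    simulate_svs(ann, cfg)
  })
  ann <- withr::with_seed(7, simulate_annotation(cfg))
  cl <- classify_svs(svs, ann)
  genic <- svs$af[cl$classes != "intergenic" & cl$classes != "intronic"]
  inter <- svs$af[cl$classes == "intergenic"]
  se <- sqrt(var(genic) / length(genic) + var(inter) / length(inter))
  expect_lt(abs(mean(genic) - mean(inter)), 3 * se)
})

test_that("af_shift > 0 depresses functional SV frequencies detectably", {
  study <- small_study()  # af_shift = 0.3 by default
  cl <- classify_svs(study$svs, study$annotation)
  func <- study$svs[cl$n_functional_classes > 0, ]
  ctrl <- study$svs[cl$classes == "intergenic", ]
  pairs <- match_by_length(func, ctrl, seed = 3L)
  cmp <- af_comparison(pairs, study$svs)
  expect_lt(cmp$mean_af_functional, cmp$mean_af_control)
  expect_lt(cmp$wilcoxon_p, 0.05)
})

test_that("intolerance weights span [0,1] with the most intolerant gene at 1", {
  study <- small_study()
  w <- study$intolerance$weight
  expect_equal(range(w), c(0, 1))
  expect_equal(study$intolerance$gene_id[which.max(w)],
               study$intolerance$gene_id[which.min(study$intolerance$raw_lof)])
})

test_that("a study round-trips through its on-disk formats", {
  cfg <- small_cfg(n_svs = c(DEL = 150L, DUP = 80L, INS = 40L, ALU = 20L,
                             INV = 10L, CPX = 5L), n_genes = 40L, seed = 23L)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  svs <- suppressMessages(read_sv_vcf(file.path(dir, "svs.vcf")))
  expect_equal(nrow(svs), nrow(study$svs))
  expect_equal(svs$start, study$svs$start)
  expect_setequal(attr(svs, "sample_ids"), attr(study$svs, "sample_ids"))
  gm <- read_gene_model(file.path(dir, "genes.gtf"))
  expect_equal(gm$genes$tss, study$annotation$genes$tss)
  expect_equal(nrow(gm$exons), nrow(study$annotation$exons))
  cpm <- read_expression_tsv(file.path(dir, "cpm.tsv"), "cpm")
  expect_equal(dim(cpm), dim(study$cpm))
  expect_equal(unname(cpm[3, 5]), unname(study$cpm[3, 5]), tolerance = 1e-6)
  ann2 <- build_annotation(gm$genes, gm$exons,
                           local({b <- read_bed(file.path(dir, "enhancers.bed"));
                                  data.frame(enhancer_id = b$name, chrom = b$chrom,
                                             start = b$start, end = b$end)}),
                           read_links_tsv(file.path(dir, "links.tsv")),
                           read_bed(file.path(dir, "ctcf.bed")),
                           read_bed(file.path(dir, "tads.bed")))
  ft2 <- build_feature_table(svs, ann2)
  expect_equal(ft2$p_exon, study$features$p_exon, tolerance = 1e-9)
  expect_equal(ft2$within_tad, study$features$within_tad)
})
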