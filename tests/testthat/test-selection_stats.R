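# Length matching, rank-sum comparisons, singleton bootstraps, the
# annotation-count trend and the intolerance quintile analyses, checked
# against rule arithmetic and enumeration oracles.

test_that("length matching honours min(500 bp, 10%) and uses controls once", {
  samples <- c("a", "b")
  fun <- mk_svs(data.frame(sv_id = c("f1", "f2"), chrom = "c", start = 0L,
                           end = c(10000L, 2000L), sv_type = "DEL",
                           length = c(10000, 2000), stringsAsFactors = FALSE),
                samples)
  ctl <- mk_svs(data.frame(sv_id = c("c1", "c2"), chrom = "c", start = 0L,
                           end = c(10900L, 2150L), sv_type = "DEL",
                           length = c(10900, 2150), stringsAsFactors = FALSE),
                samples)
  m <- match_by_length(fun, ctl, seed = 1L)
  # f1 (len 10000): tol = min(500, 1000) = 500 < 900 -> unmatched
  expect_false("f1" %in% m$functional_sv_id)
  # f2 (len 2000): tol = min(500, 200) = 200 >= 150 -> matched
  expect_true("f2" %in% m$functional_sv_id)
  expect_equal(m$control_sv_id[m$functional_sv_id == "f2"], "c2")
  expect_equal(attr(m, "n_unmatched"), 1L)

  # random pools: every emitted pair satisfies the tolerance, controls unique
  withr::local_seed(2)
  fun2 <- mk_svs(data.frame(sv_id = sprintf("f%03d", 1:150), chrom = "c", start = 0L,
                            end = 1L, sv_type = sample(c("DEL", "DUP"), 150, TRUE),
                            length = round(stats::rlnorm(150, log(1500), 1)),
                            stringsAsFactors = FALSE), samples)
  ctl2 <- mk_svs(data.frame(sv_id = sprintf("c%03d", 1:200), chrom = "c", start = 0L,
                            end = 1L, sv_type = sample(c("DEL", "DUP"), 200, TRUE),
                            length = round(stats::rlnorm(200, log(1500), 1)),
                            stringsAsFactors = FALSE), samples)
  m2 <- match_by_length(fun2, ctl2, seed = 5L)
  expect_gt(nrow(m2), 0)
  expect_false(any(duplicated(m2$control_sv_id)))
  lf <- fun2$length[match(m2$functional_sv_id, fun2$sv_id)]
  lc <- ctl2$length[match(m2$control_sv_id, ctl2$sv_id)]
  expect_true(all(abs(lf - lc) <= pmin(500, 0.10 * lf)))
  expect_true(all(fun2$sv_type[match(m2$functional_sv_id, fun2$sv_id)] ==
                  ctl2$sv_type[match(m2$control_sv_id, ctl2$sv_id)]))
  # scale symmetry: doubling all lengths and the cap preserves the matched set
  fun3 <- fun2; fun3$length <- fun3$length * 2
  ctl3 <- ctl2; ctl3$length <- ctl3$length * 2
  m3 <- match_by_length(fun3, ctl3, seed = 5L, cap = 1000)
  expect_equal(m3$functional_sv_id, m2$functional_sv_id)
  expect_equal(m3$control_sv_id, m2$control_sv_id)
})

test_that("rank-sum p agrees with exact enumeration at small n", {
  withr::local_seed(8)
  for (rep in 1:5) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- round(runif(nx), 3); y <- round(runif(ny), 3)
    p_impl <- suppressWarnings(wilcox.test(x, y, alternative = "less",
                                           exact = TRUE)$p.value)
    expect_equal(p_impl, bf_wilcox_exact_less(x, y), tolerance = 1e-10)
  }
  # fully separated groups, n = 20 each
  x <- 1:20 / 1000; y <- 1:20 / 10
  p <- suppressWarnings(wilcox.test(x, y, alternative = "less", exact = TRUE)$p.value)
  expect_equal(p, 1 / choose(40, 20), tolerance = 1e-12)
  # identical lists are null: p >= 0.5
  samples <- c("a", "b")
  svs <- mk_svs(data.frame(sv_id = c(sprintf("f%d", 1:10), sprintf("c%d", 1:10)),
                           chrom = "c", start = 0L, end = 100L, sv_type = "DEL",
                           length = 100, stringsAsFactors = FALSE), samples,
                carriers = rep(list("a"), 20))
  pairs <- data.frame(functional_sv_id = sprintf("f%d", 1:10),
                      control_sv_id = sprintf("c%d", 1:10))
  expect_gte(suppressWarnings(af_comparison(pairs, svs))$wilcoxon_p, 0.5)
})

test_that("singleton proportions and bootstrap CIs behave", {
  samples <- sprintf("s%03d", 1:300)
  carriers <- c(rep(list(samples[1]), 50),
                lapply(51:100, function(i) samples[1:2]))
  svs <- sv_set(sprintf("v%03d", 1:100), "c", (1:100) * 10L, (1:100) * 10L + 5L,
                "DEL", 5, carriers, samples)
  classes <- data.frame(sv_id = svs$sv_id, classes = "intergenic",
                        unique_class = "none", n_functional_classes = 0L,
                        stringsAsFactors = FALSE)
  st <- suppressWarnings(singleton_proportions(svs, classes, n_boot = 10000, seed = 4L))
  expect_equal(st$proportion, 0.5)
  # percentile bootstrap CI brackets the binomial CI within 0.02
  bin <- qbeta(c(0.025, 0.975), 50 + 0.5, 50 + 0.5)  # mid-interval reference
  expect_lt(abs(st$ci_low - bin[1]), 0.02)
  expect_lt(abs(st$ci_high - bin[2]), 0.02)
  expect_true(st$ci_low <= st$proportion && st$proportion <= st$ci_high)
  # all singletons: CI collapses to [1, 1]
  svs1 <- sv_set(paste0("w", 1:20), "c", (1:20) * 10L, (1:20) * 10L + 5L, "DEL",
                 5, rep(list(samples[3]), 20), samples)
  classes1 <- data.frame(sv_id = svs1$sv_id, classes = "intergenic",
                         unique_class = "none", n_functional_classes = 0L)
  st1 <- suppressWarnings(singleton_proportions(svs1, classes1, n_boot = 200, seed = 1L))
  expect_equal(unlist(st1[, c("proportion", "ci_low", "ci_high")],
                      use.names = FALSE), c(1, 1, 1))
  # determinism under the seed
  st2 <- suppressWarnings(singleton_proportions(svs, classes, n_boot = 500, seed = 9L))
  st3 <- suppressWarnings(singleton_proportions(svs, classes, n_boot = 500, seed = 9L))
  expect_identical(st2, st3)
})

test_that("annotation-count/AF correlation matches hand-computed ranks", {
  samples <- sprintf("s%03d", 1:400)
  # AF strictly decreasing in class count -> rho = -1
  carriers <- lapply(c(4, 3, 2, 1), function(k) samples[seq_len(k)])
  svs <- sv_set(paste0("v", 1:4), "c", (1:4) * 100L, (1:4) * 100L + 10L, "DEL",
                10, carriers, samples)
  classes <- data.frame(sv_id = svs$sv_id, classes = "coding",
                        unique_class = "coding", n_functional_classes = 1:4)
  expect_equal(annotation_count_af_trend(classes, svs)$rho, -1)
  # small instance vs the rank formula rho = 1 - 6*sum(d^2)/(n(n^2-1))
  k <- c(0, 1, 2, 3, 1, 0, 2, 4)
  nc <- c(5, 4, 4, 2, 3, 5, 1, 1)
  svs8 <- sv_set(paste0("u", 1:8), "c", (1:8) * 100L, (1:8) * 100L + 10L, "DEL",
                 10, lapply(nc, function(m) samples[seq_len(m)]), samples)
  cls8 <- data.frame(sv_id = svs8$sv_id, classes = "coding",
                     unique_class = "coding", n_functional_classes = as.integer(k))
  got <- annotation_count_af_trend(cls8, svs8)
  d <- rank(k) - rank(nc / 800)
  expect_equal(got$rho, stats::cor(rank(k), rank(nc)), tolerance = 1e-12)
  # constant input is reported as undefined
  cls_const <- cls8; cls_const$n_functional_classes <- 1L
  expect_message(res <- annotation_count_af_trend(cls_const, svs8), "undefined")
  expect_true(is.na(res$rho))
})

test_that("quintiles partition genes evenly and detect placement bias", {
  study <- small_study()
  rel <- intolerance_relationships(study$features, study$intolerance)
  q <- rel$quintiles
  expect_true(all(q$quintile %in% 1:5))
  # equal-size bins: per metric the gene partition differs by <= 1
  w <- study$intolerance
  for (m in c("raw_lof", "raw_cnv")) {
    v <- setNames(w[[m]], w$gene_id)
    ord <- order(-v, names(v))
    sizes <- tabulate(ceiling(seq_along(ord) / (length(ord) / 5)), 5)
    expect_lte(diff(range(sizes)), 1)
  }
  # no placement bias in the default study: deviations hover around 0
  genic <- q[q$category == "genic" & q$metric == "raw_lof" & q$sv_type == "DEL", ]
  expect_lt(max(abs(genic$deviation)), 0.5)

  biased <- simulate_study(small_cfg(placement_bias = TRUE, seed = 71L))
  relb <- intolerance_relationships(biased$features, biased$intolerance)
  qb <- relb$quintiles
  topq <- qb[qb$category == "genic" & qb$quintile == 5 & qb$metric == "raw_lof", ]
  expect_true(all(topq$deviation < 0))
})
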