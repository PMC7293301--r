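# Shared fixtures (built once per test run) and independent brute-force
# oracles used to cross-check the interval arithmetic and the statistics.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small but complete two-cohort study used across test files.
small_cfg <- function(...) {
  sim_config(
    n_genes = 120L, genome_length = 2.4e7,
    n_svs = c(DEL = 900L, DUP = 450L, INS = 300L, ALU = 200L, INV = 120L, CPX = 60L),
    n_ctcf = 250L, n_tads = 16L, seed = 42L, ...)
}

small_study <- function() fixture("small_study", function() simulate_study(small_cfg()))

# ---- brute-force oracles -------------------------------------------------

# Per-base union size of a set of 0-based half-open intervals (coordinates
# shifted to a local origin so genome-scale positions stay cheap).
bf_union_bp <- function(starts, ends) {
  if (!length(starts)) return(0L)
  off <- min(starts)
  covered <- logical(max(ends) - off)
  for (i in seq_along(starts))
    if (starts[i] < ends[i]) covered[(starts[i] - off + 1):(ends[i] - off)] <- TRUE
  sum(covered)
}

# Per-base overlap of [s1,e1) with a set of intervals (their union): only
# bases inside the query can contribute, so scan the query base by base.
bf_overlap_bp <- function(s1, e1, starts, ends) {
  if (!length(starts) || e1 <= s1) return(0L)
  cov <- logical(e1 - s1)
  for (i in seq_along(starts)) {
    lo <- max(s1, starts[i]); hi <- min(e1, ends[i])
    if (lo < hi) cov[(lo - s1 + 1):(hi - s1)] <- TRUE
  }
  sum(cov)
}

# Exact one-sided rank-sum tail P(W <= w_obs) by full enumeration (small n).
bf_wilcox_exact_less <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(ws <= w_obs)
}

# One-sided Fisher p for a 2x2 table via the hypergeometric tail.
bf_fisher_greater <- function(a, b, c, d) {
  # P(X >= a) with X ~ Hypergeom(m = a+b draws from (a+c) successes, total n)
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

# Quartile fences (Q1 - 3 IQR, Q3 + 3 IQR) recomputed from first principles.
bf_fence_outliers <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  x < q[1] - 3 * (q[2] - q[1]) | x > q[2] + 3 * (q[2] - q[1])
}

# Minimal sv_set builder for hand-constructed cases.
mk_svs <- function(df, sample_ids, carriers = NULL) {
  if (is.null(carriers)) carriers <- rep(list(sample_ids[1]), nrow(df))
  sv_set(df$sv_id, df$chrom, df$start, df$end, df$sv_type,
         if ("length" %in% names(df)) df$length else df$end - df$start,
         carriers, sample_ids)
}

# A study with longer CNVs (more exonic overlap) for enrichment analyses.
enr_study <- function() fixture("enr_study", function() simulate_study(
  small_cfg(seed = 77L, sv_len_meanlog = log(8000), sv_len_sdlog = 1.6,
            n_svs = c(DEL = 1200L, DUP = 900L, INS = 200L, ALU = 150L,
                      INV = 100L, CPX = 50L))))
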