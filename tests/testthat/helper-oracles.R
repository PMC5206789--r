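# Independent oracles and tiny fixture builders. Everything here is written
# against the definitions, not against the package's code paths.

# --- survival oracles -------------------------------------------------------

# empirical survivor function: with no censoring KM must equal 1 - ECDF
oracle_ecdf_survival <- function(times, at) {
  vapply(at, function(t) mean(times > t), 0)
}

# brute-force log-rank chi-square: direct O(n^2) summation over the distinct
# event times, no shared code with the implementation
oracle_logrank_chisq <- function(time, event, g1) {
  evt <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in evt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g1)
    O1 <- O1 + d1
    E1 <- E1 + n1 * d / n
    if (n > 1) V <- V + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  (O1 - E1)^2 / V
}

# exact permutation p-value of the chi-square statistic over all C(n, n1)
# group assignments
oracle_permutation_p <- function(time, event, g1) {
  n <- length(time)
  n1 <- sum(g1)
  obs <- oracle_logrank_chisq(time, event, g1)
  combos <- combn(n, n1)
  stats <- apply(combos, 2L, function(idx) {
    gg <- rep(FALSE, n); gg[idx] <- TRUE
    oracle_logrank_chisq(time, event, gg)
  })
  mean(stats >= obs - 1e-12)
}

# --- enrichment oracles -----------------------------------------------------

# hypergeometric upper tail P[X >= k] by exhaustive enumeration of all
# C(N, n) draws from a universe with K marked elements
oracle_hyper_tail <- function(N, K, n, k) {
  marked <- seq_len(K)
  draws <- combn(N, n)
  hits <- apply(draws, 2L, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# BH step-up closed form: p_adj[(i)] = min_{j >= i} m p_(j) / j (quadratic)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, 0)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- catalog oracle ---------------------------------------------------------

# literal transcription of the membership rules, straight-line booleans
oracle_isoform_verdict <- function(n_seg, seg_end, sp_positive, cleavage_pos,
                                   boundary = 50L) {
  if (n_seg == 0L) return("no_tm")
  if (n_seg == 1L && seg_end <= boundary) return("secreted")
  if (sp_positive && n_seg == 1L && seg_end <= cleavage_pos) return("secreted")
  "pass"
}

# --- tiny omics fixture builder ---------------------------------------------

# builds aligned expr/cna/maf layers for a handful of genes and samples from
# explicit per-cell assignments
make_omics <- function(genes, samples, expr_cells = NULL, cna_cells = NULL,
                       maf_rows = NULL) {
  expr <- matrix(0, length(genes), length(samples),
                 dimnames = list(genes, samples))
  cna <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (!is.null(expr_cells)) {
    for (i in seq_len(nrow(expr_cells))) {
      expr[expr_cells$gene[i], expr_cells$sample[i]] <- expr_cells$z[i]
    }
  }
  if (!is.null(cna_cells)) {
    for (i in seq_len(nrow(cna_cells))) {
      cna[cna_cells$gene[i], cna_cells$sample[i]] <- as.integer(cna_cells$call[i])
    }
  }
  maf <- if (is.null(maf_rows)) {
    data.frame(sample_id = character(), gene_id = character(),
               variant_class = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = maf_rows$sample, gene_id = maf_rows$gene,
               variant_class = maf_rows$class, stringsAsFactors = FALSE)
  }
  list(expr = expr, cna = cna, maf = maf)
}

# partition agreement up to relabeling (adjusted-Rand = 1 iff identical
# partitions); checked structurally
same_partition <- function(a, b) {
  ta <- as.integer(factor(a, levels = unique(a)))
  tb <- as.integer(factor(b, levels = unique(b)))
  identical(ta, tb)
}
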