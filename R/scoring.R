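# Integrative S-score: per-sample alteration evidence in {-1, 0, +1} is
# summed over the cohort and scaled to a percent-like magnitude,
#   S(g) = 100 * sum_i e(g, i) / N,
# so sign encodes the role (suppressor < 0 < oncogene) and magnitude the net
# alteration frequency. S-scores are standardized to z-scores against the
# distribution of all scored genes within one tumor type, and genes are
# called at a z threshold (|z| >= 3 by default; a relaxed strict |z| > 2 mode
# is used for survival screening).

#' Scoring configuration
#'
#' All signal definitions live here so the evidence rule can be re-weighted
#' without touching the scoring code.
#'
#' @param cna_amplified,cna_deleted GISTIC-style calls counting as
#'   oncogene-like amplification / suppressor-like deletion (high-level only
#'   by default).
#' @param expr_high,expr_low expression z-score cutoffs (strict inequalities).
#' @param deleterious_classes variant classes counting as suppressor-like.
#' @param missense_role `"neutral"` (default) or `"oncogenic"`: whether a
#'   missense mutation contributes an oncogene-like signal.
#' @return a list consumed by [evidence_matrix()] and friends.
#' @export
score_config <- function(cna_amplified = 2L, cna_deleted = -2L,
                         expr_high = 2, expr_low = -2,
                         deleterious_classes = c("nonsense", "frameshift",
                                                 "splice_site"),
                         missense_role = c("neutral", "oncogenic")) {
  list(cna_amplified = cna_amplified, cna_deleted = cna_deleted,
       expr_high = expr_high, expr_low = expr_low,
       deleterious_classes = deleterious_classes,
       missense_role = match.arg(missense_role))
}

# align one omics layer onto the (genes x samples) frame; missing rows /
# columns are filled with `fill` (no signal) and reported once
align_layer <- function(m, genes, samples, fill, what) {
  out <- matrix(fill, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (is.null(m)) {
    notify("omics layer '%s' absent: contributes no signal", what)
    return(out)
  }
  gi <- intersect(genes, rownames(m))
  si <- intersect(samples, colnames(m))
  if (length(gi) < length(genes)) {
    notify("%d gene(s) missing from %s layer: no signal", length(genes) - length(gi), what)
  }
  out[gi, si] <- m[gi, si]
  out
}

# genes x samples count matrix of mutations in the given classes
mutation_count_matrix <- function(maf, genes, samples, classes) {
  out <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (is.null(maf) || nrow(maf) == 0L) return(out)
  keep <- maf$variant_class %in% classes &
    maf$gene_id %in% genes & maf$sample_id %in% samples
  if (!any(keep)) return(out)
  tt <- table(factor(maf$gene_id[keep], levels = genes),
              factor(maf$sample_id[keep], levels = samples))
  out[] <- as.integer(tt)
  out
}

#' Per-sample alteration evidence matrix
#'
#' For each (gene, sample): oncogene-like signals are high-level
#' amplification and expression z above `expr_high` (plus missense if so
#' configured); suppressor-like signals are deep deletion, expression z below
#' `expr_low`, and at least one deleterious mutation. The evidence is the
#' sign of (#oncogene-like - #suppressor-like): conflicting evidence cancels.
#'
#' @param expr gene-by-sample expression z-score matrix (NA = missing).
#' @param cna gene-by-sample GISTIC-style call matrix.
#' @param maf mutation table from [parse_maf()].
#' @param genes,samples the frame to score; defaults to the expression
#'   matrix's dimnames.
#' @param config see [score_config()].
#' @return integer matrix in \{-1, 0, +1\}, genes x samples.
#' @export
evidence_matrix <- function(expr, cna, maf, genes = rownames(expr),
                            samples = colnames(expr),
                            config = score_config()) {
  if (is.null(genes) || is.null(samples)) abort("genes and samples must be known")
  e <- align_layer(expr, genes, samples, NA_real_, "expression")
  c2 <- align_layer(cna, genes, samples, 0L, "copy-number")
  mut_del <- mutation_count_matrix(maf, genes, samples, config$deleterious_classes)
  expr_hi <- !is.na(e) & e > config$expr_high
  expr_lo <- !is.na(e) & e < config$expr_low
  onc <- (c2 == config$cna_amplified) + expr_hi
  if (config$missense_role == "oncogenic") {
    onc <- onc + (mutation_count_matrix(maf, genes, samples, "missense") > 0L)
  }
  sup <- (c2 == config$cna_deleted) + expr_lo + (mut_del > 0L)
  out <- sign(onc - sup)
  storage.mode(out) <- "integer"
  out
}

#' Evidence for a single (gene, sample) pair
#'
#' Scalar convenience wrapper around [evidence_matrix()].
#'
#' @inheritParams evidence_matrix
#' @param gene,sample identifiers.
#' @return -1, 0 or +1.
#' @export
per_sample_evidence <- function(gene, sample, expr, cna, maf,
                                config = score_config()) {
  suppressMessages(
    evidence_matrix(expr, cna, maf, genes = gene, samples = sample,
                    config = config)[1L, 1L])
}

#' S-score from an evidence matrix
#'
#' `S = 100 * sum_i e(g, i) / N`, bounded in [-100, 100].
#'
#' @param evidence integer matrix from [evidence_matrix()] (or a single
#'   gene's evidence vector).
#' @return named numeric vector of S-scores (one per gene).
#' @export
s_score <- function(evidence) {
  if (is.matrix(evidence)) {
    if (ncol(evidence) == 0L) abort("S-score requires >= 1 sample")
    return(100 * rowMeans(evidence))
  }
  if (length(evidence) == 0L) abort("S-score requires >= 1 sample")
  100 * mean(evidence)
}

#' Standardize S-scores to z-scores within one tumor type
#'
#' `z = (S - mean(S)) / sd(S)` over all scored genes (sample standard
#' deviation, n - 1 denominator).
#'
#' @param s numeric vector of S-scores (>= 2 genes, nonzero variance).
#' @return numeric vector of z-scores (mean 0, sd 1).
#' @export
standardize_scores <- function(s) {
  if (length(s) < 2L) abort("standardization requires >= 2 genes")
  sdev <- sd(s)
  if (!is.finite(sdev) || sdev == 0) abort("zero variance: cannot standardize")
  (s - mean(s)) / sdev
}

#' Call oncogenes and suppressors from z-scores
#'
#' Oncogene iff `z >= t` (or `z > t` with `inclusive = FALSE`), suppressor
#' symmetric, otherwise none. Given a genes-by-tumor-types z matrix the
#' pan-cancer union (genes classified in >= 1 tumor type) is reported too.
#'
#' @param z numeric vector or genes x tumor-types matrix of z-scores.
#' @param threshold positive z threshold; default 3. The relaxed screen uses
#'   `threshold = 2, inclusive = FALSE`.
#' @param inclusive boundary convention; the main threshold is inclusive
#'   (`>= 3`), the relaxed one strict (`> 2`).
#' @return list with `classes` (character vector or matrix:
#'   `oncogene`/`suppressor`/`none`) and `union` (sorted genes classified in
#'   at least one column).
#' @export
classify_cancer_genes <- function(z, threshold = 3, inclusive = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0) abort("threshold must be positive")
  cls <- function(v) {
    onc <- if (inclusive) v >= threshold else v > threshold
    sup <- if (inclusive) v <= -threshold else v < -threshold
    ifelse(onc, "oncogene", ifelse(sup, "suppressor", "none"))
  }
  if (is.matrix(z)) {
    classes <- apply(z, 2L, cls)
    dimnames(classes) <- dimnames(z)
    hit <- rowSums(classes != "none") > 0L
    union <- sort(rownames(z)[hit])
  } else {
    classes <- stats::setNames(cls(z), names(z))
    union <- sort(names(classes)[classes != "none"])
  }
  list(classes = classes, union = union)
}

#' Score one tumor type end to end
#'
#' Convenience wrapper: evidence -> S -> z -> class for a single cohort.
#'
#' @inheritParams evidence_matrix
#' @inheritParams classify_cancer_genes
#' @return data.frame with columns `gene_id`, `S`, `z`, `class`.
#' @export
score_tumor <- function(expr, cna, maf, genes = rownames(expr),
                        samples = colnames(expr), config = score_config(),
                        threshold = 3, inclusive = TRUE) {
  ev <- evidence_matrix(expr, cna, maf, genes, samples, config)
  S <- s_score(ev)
  z <- standardize_scores(S)
  cl <- classify_cancer_genes(z, threshold, inclusive)$classes
  data.frame(gene_id = genes, S = unname(S), z = unname(z),
             class = unname(cl), stringsAsFactors = FALSE)
}
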