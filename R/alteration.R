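# Sample-level altered/unaltered classification for survival analysis:
# a sample is altered for a gene when the gene is differentially expressed
# (|expression z| > 2), carries a high-level copy-number event (GISTIC +/-2),
# or a deleterious mutation (nonsense / frameshift / splice-site). Shallow
# copy-number events (+/-1) never trigger alteration under the default
# configuration.

ALTERATION_REASONS <- c("expr_up", "expr_down", "amplified", "deleted",
                        "deleterious_mutation")

#' Alteration-rule configuration
#'
#' @param expr_high,expr_low expression z cutoffs (strict inequalities).
#' @param cna_amplified,cna_deleted copy-number calls counting as events;
#'   high-level only by default (cBioPortal-style "altered" convention).
#' @param deleterious_classes mutation classes counting as deleterious.
#' @return configuration list.
#' @export
alteration_config <- function(expr_high = 2, expr_low = -2,
                              cna_amplified = 2L, cna_deleted = -2L,
                              deleterious_classes = c("nonsense", "frameshift",
                                                      "splice_site")) {
  list(expr_high = expr_high, expr_low = expr_low,
       cna_amplified = cna_amplified, cna_deleted = cna_deleted,
       deleterious_classes = deleterious_classes)
}

#' Build a gene-by-sample alteration matrix
#'
#' A cell is TRUE iff at least one of the five disjuncts holds; the reason
#' codes (`expr_up`, `expr_down`, `amplified`, `deleted`,
#' `deleterious_mutation`) for every TRUE cell are kept in the `"reasons"`
#' attribute (comma-joined character matrix). A missing omics layer simply
#' contributes no events (reported via a message). Duplicate mutation rows do
#' not change the result.
#'
#' @param genes genes to classify.
#' @param expr,cna,maf omics layers as read by the parsers (each may be NULL).
#' @param samples samples to classify; defaults to the union of samples seen
#'   in the layers.
#' @param config see [alteration_config()].
#' @return logical genes x samples matrix with a `"reasons"` attribute.
#' @export
build_alteration_matrix <- function(genes, expr = NULL, cna = NULL, maf = NULL,
                                    samples = NULL,
                                    config = alteration_config()) {
  if (is.null(samples)) {
    samples <- unique(c(colnames(expr), colnames(cna), maf$sample_id))
  }
  if (length(genes) == 0L || length(samples) == 0L) {
    abort("alteration matrix requires >= 1 gene and >= 1 sample")
  }
  e <- align_layer(expr, genes, samples, NA_real_, "expression")
  c2 <- align_layer(cna, genes, samples, 0L, "copy-number")
  mut <- mutation_count_matrix(maf, genes, samples, config$deleterious_classes)
  flags <- list(
    expr_up = !is.na(e) & e > config$expr_high,
    expr_down = !is.na(e) & e < config$expr_low,
    amplified = c2 == config$cna_amplified,
    deleted = c2 == config$cna_deleted,
    deleterious_mutation = mut > 0L
  )
  altered <- Reduce(`|`, flags)
  reasons <- matrix("", length(genes), length(samples),
                    dimnames = list(genes, samples))
  for (code in names(flags)) {
    hit <- flags[[code]]
    reasons[hit] <- ifelse(reasons[hit] == "", code,
                           paste(reasons[hit], code, sep = ","))
  }
  attr(altered, "reasons") <- reasons
  altered
}

#' Alteration status of one (gene, sample) pair
#'
#' @inheritParams build_alteration_matrix
#' @param gene,sample identifiers.
#' @return list with `altered` (logical) and `reasons` (character vector of
#'   fired codes, empty when unaltered).
#' @export
is_altered <- function(gene, sample, expr = NULL, cna = NULL, maf = NULL,
                       config = alteration_config()) {
  m <- suppressMessages(
    build_alteration_matrix(gene, expr, cna, maf, samples = sample,
                            config = config))
  rs <- attr(m, "reasons")[1L, 1L]
  list(altered = m[1L, 1L],
       reasons = if (nzchar(rs)) strsplit(rs, ",", fixed = TRUE)[[1L]] else character())
}

#' Signature-level alteration (OR semantics)
#'
#' A sample carries the signature alteration when at least one gene of the
#' set is altered in it.
#'
#' @param genes character vector: the gene set.
#' @param alteration logical matrix from [build_alteration_matrix()].
#' @param sample optional single sample id; when NULL the full per-sample
#'   logical vector is returned.
#' @return logical vector (or scalar when `sample` is given).
#' @export
signature_altered <- function(genes, alteration, sample = NULL) {
  missing <- setdiff(genes, rownames(alteration))
  if (length(missing) > 0L) abort("gene '%s' absent from alteration matrix", missing[1L])
  v <- colSums(alteration[genes, , drop = FALSE]) > 0L
  if (is.null(sample)) v else unname(v[sample])
}
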