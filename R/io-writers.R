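# Writers for every table the pipeline emits or the generators produce.
# Numeric columns are written with 17 significant digits so that a write/parse
# round trip reproduces the in-memory value exactly; all outputs are plain TSV
# with fixed headers.

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a protein FASTA file
#'
#' Headers follow the `proteinID|geneID` convention read by [parse_fasta()].
#'
#' @param proteins data.frame with `protein_id`, `gene_id`, `sequence`.
#' @param path output path.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- paste0(proteins$protein_id, "|", proteins$gene_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @param segments data.frame as returned by [parse_tm_segments()].
#' @export
write_tm_segments <- function(segments, path) {
  write_tsv(segments[, c("protein_id", "start", "end")], path)
}

#' @rdname write_fasta
#' @param calls data.frame as returned by [parse_signalp()].
#' @export
write_signalp <- function(calls, path) {
  df <- data.frame(protein_id = calls$protein_id,
                   call = ifelse(calls$positive, "YES", "NO"),
                   cleavage_pos = ifelse(calls$positive,
                                         as.character(calls$cleavage_pos), "-"),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_fasta
#' @param compartments data.frame as returned by [parse_go_compartments()].
#' @export
write_go_compartments <- function(compartments, path) {
  write_tsv(compartments[, c("gene_id", "compartment")], path)
}

#' @rdname write_fasta
#' @param mutations data.frame as returned by [parse_maf()].
#' @export
write_maf <- function(mutations, path) {
  df <- data.frame(Hugo_Symbol = mutations$gene_id,
                   Tumor_Sample_Barcode = mutations$sample_id,
                   Variant_Classification = mutations$variant_class,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a gene-by-sample matrix as TSV
#'
#' First column `gene_id`, then one column per sample; readable back with
#' [parse_matrix()].
#'
#' @param m matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    vals <- if (is.double(m)) format_num(m[i, ]) else as.character(m[i, ])
    paste(c(rownames(m)[i], vals), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_fasta
#' @param clinical data.frame as returned by [parse_clinical()].
#' @export
write_clinical <- function(clinical, path) {
  write_tsv(clinical[, c("sample_id", "os_time_days", "os_event")], path)
}
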