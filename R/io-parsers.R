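# Readers for every external file the pipeline consumes. All coordinates are
# 1-based inclusive residue positions (TMHMM convention). Gene identifiers are
# HGNC-style symbol strings, case-sensitive, and are the join key everywhere.

VARIANT_CLASSES <- c("nonsense", "frameshift", "splice_site",
                     "missense", "silent", "other")

# declared mapping from MAF Variant_Classification values onto the closed
# internal vocabulary; anything else falls back to "other" with a warning
MAF_CLASS_MAP <- c(
  Nonsense_Mutation   = "nonsense",
  Frame_Shift_Del     = "frameshift",
  Frame_Shift_Ins     = "frameshift",
  Splice_Site         = "splice_site",
  Missense_Mutation   = "missense",
  Silent              = "silent"
)

#' Parse a protein FASTA file
#'
#' Headers follow the `proteinID|geneID` convention (configurable via
#' `header_regex`, whose first two capture groups must be the protein and the
#' gene identifier). Sequence length is computed from the sequence itself.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @param header_regex regular expression with two capture groups
#'   (protein id, gene id) applied to each header line.
#' @return a data.frame with columns `protein_id`, `gene_id`, `length`,
#'   `sequence`; one row per FASTA entry.
#' @export
parse_fasta <- function(path, header_regex = "^([^|]+)\\|(.+)$") {
  if (!file.exists(path)) abort("FASTA file not found: %s", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    return(data.frame(protein_id = character(), gene_id = character(),
                      length = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  headers <- names(seqs)
  m <- regexec(header_regex, headers)
  parts <- regmatches(headers, m)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0L) {
    abort("malformed FASTA header (entry %d): '%s' does not match '%s'",
          bad[1L], headers[bad[1L]], header_regex)
  }
  protein_id <- vapply(parts, `[[`, "", 2L)
  gene_id <- vapply(parts, `[[`, "", 3L)
  sequence <- as.character(seqs)
  len <- nchar(sequence)
  if (any(len == 0L)) {
    abort("empty sequence for protein '%s'", protein_id[which(len == 0L)[1L]])
  }
  dup <- protein_id[duplicated(protein_id)]
  if (length(dup) > 0L) abort("duplicate protein_id: '%s'", dup[1L])
  data.frame(protein_id = protein_id, gene_id = gene_id,
             length = as.integer(len), sequence = unname(sequence),
             stringsAsFactors = FALSE)
}

validate_segments <- function(start, end, protein_id = "?", length = NULL) {
  if (length(start) == 0L) return(invisible(TRUE))
  if (any(start > end)) {
    abort("TM segment with start > end for protein '%s'", protein_id)
  }
  if (any(start < 1L)) abort("TM segment start < 1 for protein '%s'", protein_id)
  o <- order(start)
  s <- start[o]; e <- end[o]
  if (length(s) > 1L && any(s[-1L] <= e[-length(e)])) {
    abort("overlapping TM segments for protein '%s'", protein_id)
  }
  if (!is.null(length) && any(e > length)) {
    abort("TM segment end %d exceeds protein length %d for '%s'",
          max(e), length, protein_id)
  }
  invisible(TRUE)
}

#' Parse transmembrane-helix segments
#'
#' Accepts either the simplified 3-column TSV (`protein_id`, `start`, `end`,
#' one row per helix, optional header) or TMHMM long-format output, from which
#' only `TMhelix` topology lines are used. Proteins with no lines simply have
#' zero TM domains. Segments are validated (1 <= start <= end, pairwise
#' nonoverlapping) and, when `protein_lengths` is supplied (a named integer
#' vector), checked against the protein length.
#'
#' @param path input file path.
#' @param protein_lengths optional named vector of protein lengths.
#' @return data.frame with columns `protein_id`, `start`, `end`, sorted by
#'   protein then start.
#' @export
parse_tm_segments <- function(path, protein_lengths = NULL) {
  if (!file.exists(path)) abort("TM segment file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[\t ]+")
  rows <- list()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) >= 4L) {
      # TMHMM long format: <protein> <method> <topology> <start> <end>;
      # non-helix topology lines (inside/outside) are ignored
      if (!any(tk == "TMhelix")) next
      n <- length(tk)
      rows[[length(rows) + 1L]] <- c(tk[1L], tk[n - 1L], tk[n])
    } else if (length(tk) == 3L) {
      if (i == 1L && identical(tolower(tk), c("protein_id", "start", "end"))) next
      rows[[length(rows) + 1L]] <- tk
    } else {
      abort("cannot parse TM segment line %d: '%s'", i, lines[i])
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  m <- do.call(rbind, rows)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) abort("non-numeric TM segment coordinates")
  out <- data.frame(protein_id = m[, 1L], start = start, end = end,
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  for (pid in unique(out$protein_id)) {
    sel <- out$protein_id == pid
    len <- if (!is.null(protein_lengths)) unname(protein_lengths[pid]) else NULL
    if (!is.null(len) && is.na(len)) len <- NULL
    validate_segments(out$start[sel], out$end[sel], pid, len)
  }
  out
}

#' Parse signal-peptide calls
#'
#' Portable 3-column TSV dialect: `protein_id`, `YES`/`NO`, cleavage position
#' (last residue of the signal peptide, 1-based; `-` or empty for negatives).
#' An optional header line is skipped.
#'
#' @param path input file path.
#' @return data.frame with columns `protein_id`, `positive` (logical),
#'   `cleavage_pos` (integer, `NA` for negative calls).
#' @export
parse_signalp <- function(path) {
  if (!file.exists(path)) abort("signal-peptide file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[\t ]+")
  out <- list()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (i == 1L && length(tk) >= 2L && tolower(tk[1L]) == "protein_id") next
    if (length(tk) < 2L) abort("cannot parse signal-peptide line %d", i)
    call <- toupper(tk[2L])
    if (!call %in% c("YES", "NO")) {
      abort("signal-peptide call must be YES or NO, got '%s' (line %d)", tk[2L], i)
    }
    pos_field <- if (length(tk) >= 3L) tk[3L] else ""
    has_pos <- nzchar(pos_field) && pos_field != "-" && toupper(pos_field) != "NA"
    if (call == "YES") {
      if (!has_pos) abort("positive signal-peptide call without cleavage_pos (line %d)", i)
      cp <- suppressWarnings(as.integer(pos_field))
      if (is.na(cp) || cp < 1L) abort("invalid cleavage_pos '%s' (line %d)", pos_field, i)
    } else {
      if (has_pos) abort("cleavage_pos present without positive flag (line %d)", i)
      cp <- NA_integer_
    }
    out[[length(out) + 1L]] <- data.frame(
      protein_id = tk[1L], positive = call == "YES", cleavage_pos = cp,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(), positive = logical(),
               cleavage_pos = integer(), stringsAsFactors = FALSE)
  dup <- res$protein_id[duplicated(res$protein_id)]
  if (length(dup) > 0L) abort("duplicate signal-peptide call for '%s'", dup[1L])
  res
}

#' Parse a gene -> GO cellular-compartment table
#'
#' Two-column TSV (`gene_id`, `compartment`), one row per annotation pair.
#' Labels are lower-cased on read (documented normalization); when a
#' `vocabulary` is supplied, labels outside it are rejected.
#'
#' @param path input file path.
#' @param vocabulary optional character vector of allowed labels.
#' @return data.frame with columns `gene_id`, `compartment`.
#' @export
parse_go_compartments <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) abort("GO compartment file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(), compartment = character(),
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(toks, length, 1L) != 2L)) {
    abort("GO compartment table must have exactly two tab-separated columns")
  }
  m <- do.call(rbind, toks)
  if (identical(tolower(m[1L, ]), c("gene_id", "compartment"))) {
    m <- m[-1L, , drop = FALSE]
  }
  out <- data.frame(gene_id = m[, 1L], compartment = tolower(trimws(m[, 2L])),
                    stringsAsFactors = FALSE)
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(out$compartment), vocabulary)
    if (length(bad) > 0L) {
      abort("compartment label(s) outside the declared vocabulary: %s",
            paste(bad, collapse = ", "))
    }
  }
  unique(out)
}

#' Parse a (minimal) MAF mutation table
#'
#' Requires the columns `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`. MAF classes are mapped onto the closed vocabulary
#' `nonsense`, `frameshift`, `splice_site`, `missense`, `silent`; already
#' normalized values pass through; anything unknown becomes `other` with a
#' warning.
#'
#' @param path input file path (tab-separated, with header).
#' @return data.frame with columns `sample_id`, `gene_id`, `variant_class`.
#' @export
parse_maf <- function(path) {
  if (!file.exists(path)) abort("MAF file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    abort("MAF is missing required column(s): %s", paste(miss, collapse = ", "))
  }
  raw <- tab$Variant_Classification
  vc <- unname(MAF_CLASS_MAP[raw])
  vc[is.na(vc) & raw %in% VARIANT_CLASSES] <- raw[is.na(vc) & raw %in% VARIANT_CLASSES]
  unknown <- unique(raw[is.na(vc)])
  if (length(unknown) > 0L) {
    warning(sprintf("unknown MAF variant class(es) mapped to 'other': %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    vc[is.na(vc)] <- "other"
  }
  data.frame(sample_id = tab$Tumor_Sample_Barcode, gene_id = tab$Hugo_Symbol,
             variant_class = vc, stringsAsFactors = FALSE)
}

#' Parse a gene-by-sample matrix (copy-number calls or expression z-scores)
#'
#' TSV with a header row of sample identifiers and gene identifiers in the
#' first column. `kind = "cna"` enforces GISTIC-style 5-level integer calls in
#' \{-2,...,2\}; `kind = "expr"` accepts real values (`NA` allowed, treated as
#' missing downstream).
#'
#' @param path input file path.
#' @param kind `"cna"` or `"expr"`.
#' @return numeric (or integer) matrix, genes in rows, samples in columns.
#' @export
parse_matrix <- function(path, kind = c("cna", "expr")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort("matrix file not found: %s", path)
  tab <- read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  if (!is.numeric(m)) abort("%s matrix contains non-numeric values", kind)
  if (kind == "cna") {
    vals <- m[!is.na(m)]
    if (any(vals != as.integer(vals)) || any(vals < -2) || any(vals > 2)) {
      abort("CNA matrix values must be integers in {-2,-1,0,1,2}")
    }
    if (anyNA(m)) abort("CNA matrix must not contain NA")
    storage.mode(m) <- "integer"
  } else {
    if (any(is.infinite(m))) abort("expression matrix contains non-finite values")
    if (anyNA(m)) notify("expression matrix contains %d NA cells (treated as missing)",
                         sum(is.na(m)))
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup) > 0L) abort("duplicate gene row '%s' in %s matrix", dup[1L], kind)
  m
}

#' Parse a clinical table
#'
#' TSV with header columns `sample_id`, `os_time_days` (overall-survival time,
#' days, nonnegative) and `os_event` (1 = death observed, 0 = censored).
#'
#' @param path input file path.
#' @return data.frame with the three validated columns.
#' @export
parse_clinical <- function(path) {
  if (!file.exists(path)) abort("clinical file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "os_time_days", "os_event")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    abort("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  }
  t <- as.numeric(tab$os_time_days)
  if (anyNA(t) || any(!is.finite(t))) abort("os_time_days must be finite numbers")
  if (any(t < 0)) abort("negative os_time_days")
  ev <- tab$os_event
  if (!all(ev %in% c(0L, 1L))) abort("os_event must be 0 or 1")
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup) > 0L) abort("duplicate sample_id '%s' in clinical table", dup[1L])
  data.frame(sample_id = as.character(tab$sample_id), os_time_days = t,
             os_event = as.integer(ev), stringsAsFactors = FALSE)
}

#' Reconcile sample sets across omics and clinical tables
#'
#' The pipeline operates on the intersection of samples present in every
#' provided table; dropped samples are reported via a message.
#'
#' @param ... character vectors of sample identifiers (named arguments are
#'   used in the log message).
#' @return character vector: the common samples, in the order of the first
#'   argument.
#' @export
reconcile_samples <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, TRUE)]
  if (length(sets) == 0L) abort("no sample sets supplied")
  common <- Reduce(intersect, sets)
  dropped <- length(unique(unlist(sets))) - length(common)
  if (dropped > 0L) notify("dropped %d sample(s) absent from >=1 table", dropped)
  sets[[1L]][sets[[1L]] %in% common]
}
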