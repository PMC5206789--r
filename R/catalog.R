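# Surfaceome membership rules.
#
# A protein isoform is a surface candidate when it carries at least one
# predicted TM helix that cannot be explained away as a signal peptide:
#   R1  zero TM segments                                -> no_tm
#   R2  exactly one TM segment ending within the first
#       `tm_boundary` (default 50) residues             -> secreted
#   R3  signal-peptide positive, exactly one TM segment
#       and that segment lies within the predicted
#       signal peptide (end <= cleavage_pos)            -> secreted
# A gene with >=1 candidate isoform is then excluded only when its GO
# cellular-component annotation places it EXCLUSIVELY in internal
# compartments (R4); otherwise it enters the surfaceome catalog (R5).

#' Default internal-compartment exclusion vocabulary
#'
#' Genes whose GO cellular-component annotation is nonempty and entirely
#' contained in this set are excluded from the surfaceome catalog. The default
#' list is: lysosome, endoplasmic reticulum, mitochondria, cytoskeleton,
#' endosome, liposome, nucleolus, nucleus, ribosome.
#'
#' @return character vector of lower-case compartment labels.
#' @export
default_exclusion_vocabulary <- function() {
  c("lysosome", "endoplasmic reticulum", "mitochondria", "cytoskeleton",
    "endosome", "liposome", "nucleolus", "nucleus", "ribosome")
}

#' Catalog rule configuration
#'
#' @param tm_boundary residue boundary for the single-TM signal-peptide-like
#'   exclusion (rule R2); default 50.
#' @param boundary_anchor which coordinate of the single TM segment is
#'   compared against `tm_boundary`: `"end"` (default, strictest reading that
#'   cannot misclassify a genuine TM straddling the boundary) or `"start"`.
#' @param exclusion_vocabulary compartment labels counting as internal.
#' @return a list used by the classification functions.
#' @export
catalog_config <- function(tm_boundary = 50L,
                           boundary_anchor = c("end", "start"),
                           exclusion_vocabulary = default_exclusion_vocabulary()) {
  boundary_anchor <- match.arg(boundary_anchor)
  if (!is_count(tm_boundary) || tm_boundary < 1L) abort("tm_boundary must be a positive integer")
  list(tm_boundary = as.integer(tm_boundary),
       boundary_anchor = boundary_anchor,
       exclusion_vocabulary = exclusion_vocabulary)
}

#' Classify one protein isoform
#'
#' Applies rules R1-R3 (see package docs) in fixed order and returns the
#' verdict for this isoform together with the rule that decided it.
#'
#' @param length protein length in residues.
#' @param segments data.frame (or NULL) with columns `start`, `end`: the TM
#'   helices of this isoform, 1-based inclusive.
#' @param sp_positive logical: signal-peptide call.
#' @param cleavage_pos last residue of the predicted signal peptide; must be
#'   present iff `sp_positive`.
#' @param config see [catalog_config()].
#' @return list with `verdict` (`"no_tm"`, `"secreted"` or `"pass"`), `rule`
#'   (the rule that fired, `"candidate"` for pass) and `trace` (ordered rule
#'   evaluations).
#' @export
classify_isoform <- function(length, segments, sp_positive = FALSE,
                             cleavage_pos = NA_integer_,
                             config = catalog_config()) {
  if (!is_count(length) || length < 1L) abort("protein length must be >= 1")
  if (!is.na(cleavage_pos) && !isTRUE(sp_positive)) {
    abort("cleavage_pos present without positive signal-peptide flag")
  }
  if (isTRUE(sp_positive) && is.na(cleavage_pos)) {
    abort("positive signal-peptide call requires cleavage_pos")
  }
  n_seg <- if (is.null(segments)) 0L else nrow(segments)
  if (n_seg > 0L) validate_segments(segments$start, segments$end, length = length)

  if (n_seg == 0L) {
    return(list(verdict = "no_tm", rule = "R1", trace = "R1:fired"))
  }
  trace <- "R1:no"
  anchor <- function(i) {
    if (config$boundary_anchor == "end") segments$end[i] else segments$start[i]
  }
  if (n_seg == 1L && anchor(1L) <= config$tm_boundary) {
    return(list(verdict = "secreted", rule = "R2", trace = c(trace, "R2:fired")))
  }
  trace <- c(trace, "R2:no")
  if (isTRUE(sp_positive) && n_seg == 1L && segments$end[1L] <= cleavage_pos) {
    return(list(verdict = "secreted", rule = "R3", trace = c(trace, "R3:fired")))
  }
  list(verdict = "pass", rule = "candidate", trace = c(trace, "R3:no", "candidate"))
}

#' Exclusive internal-compartment predicate
#'
#' TRUE iff the annotation set is nonempty and entirely contained in the
#' exclusion vocabulary. Unannotated genes (empty set) are never excluded:
#' exclusion requires positive evidence of exclusive internal localization.
#'
#' @param compartments character vector of compartment labels (may be empty).
#' @param vocabulary exclusion vocabulary.
#' @return logical scalar.
#' @export
exclusively_internal <- function(compartments,
                                 vocabulary = default_exclusion_vocabulary()) {
  length(compartments) > 0L && all(compartments %in% vocabulary)
}

#' Aggregate isoform verdicts into a gene-level membership decision
#'
#' A gene is a surface candidate if ANY isoform passes R1-R3 (inclusive
#' reading of sequence-level filtering reported at gene level). Candidates
#' annotated exclusively to internal compartments become
#' `internal_compartment`; all other candidates are `surfaceome`. Genes with
#' no candidate isoform take the most permissive isoform verdict
#' (secreted > no_tm).
#'
#' @param isoform_verdicts character vector of per-isoform verdicts
#'   (`"pass"`, `"secreted"`, `"no_tm"`), or a list of [classify_isoform()]
#'   results.
#' @param compartments character vector of the gene's GO compartments.
#' @param config see [catalog_config()].
#' @return list with `verdict` (one of `surfaceome`, `secreted`,
#'   `internal_compartment`, `no_tm`), `rule` and `isoform_verdicts`.
#' @export
classify_gene <- function(isoform_verdicts, compartments = character(),
                          config = catalog_config()) {
  if (is.list(isoform_verdicts)) {
    isoform_verdicts <- vapply(isoform_verdicts, `[[`, "", "verdict")
  }
  if (length(isoform_verdicts) == 0L) abort("gene with zero isoforms")
  bad <- setdiff(isoform_verdicts, c("pass", "secreted", "no_tm"))
  if (length(bad) > 0L) abort("unknown isoform verdict '%s'", bad[1L])
  if (any(isoform_verdicts == "pass")) {
    if (exclusively_internal(compartments, config$exclusion_vocabulary)) {
      verdict <- "internal_compartment"; rule <- "R4"
    } else {
      verdict <- "surfaceome"; rule <- "R5"
    }
  } else if (any(isoform_verdicts == "secreted")) {
    verdict <- "secreted"; rule <- "R2/R3"
  } else {
    verdict <- "no_tm"; rule <- "R1"
  }
  list(verdict = verdict, rule = rule, isoform_verdicts = isoform_verdicts)
}

#' Build the surfaceome catalog
#'
#' Classifies every gene in `proteins` from its isoforms' TM segments,
#' signal-peptide calls and GO compartments, and returns the catalog (the
#' surfaceome gene set) together with the full per-gene decision table.
#'
#' @param proteins data.frame from [parse_fasta()] (column `sequence`
#'   optional; `length` is required).
#' @param tm data.frame from [parse_tm_segments()].
#' @param signalp data.frame from [parse_signalp()]; proteins without a row
#'   are treated as negative calls.
#' @param go data.frame from [parse_go_compartments()]; genes without rows are
#'   unannotated.
#' @param config see [catalog_config()].
#' @param genes optional character vector of genes that MUST be present; a
#'   listed gene with zero isoforms is an error.
#' @return an object of class `surfaceome_catalog`: list with `catalog`
#'   (character vector of surfaceome genes), `decisions` (data.frame: gene_id,
#'   verdict, rule, n_isoforms, isoform_verdicts, reasons) and `counts`
#'   (named verdict counts).
#' @export
build_catalog <- function(proteins, tm, signalp = NULL, go = NULL,
                          config = catalog_config(), genes = NULL) {
  if (nrow(proteins) == 0L) {
    decisions <- data.frame(gene_id = character(), verdict = character(),
                            rule = character(), n_isoforms = integer(),
                            isoform_verdicts = character(), reasons = character(),
                            stringsAsFactors = FALSE)
    counts <- stats::setNames(integer(4L), c("surfaceome", "secreted",
                                             "internal_compartment", "no_tm"))
    return(structure(list(catalog = character(), decisions = decisions,
                          counts = counts), class = "surfaceome_catalog"))
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, proteins$gene_id)
    if (length(missing) > 0L) abort("gene with zero isoforms: '%s'", missing[1L])
  }
  seg_by_prot <- if (!is.null(tm) && nrow(tm) > 0L) {
    split(tm[, c("start", "end")], tm$protein_id)
  } else list()
  sp_pos <- sp_cp <- NULL
  if (!is.null(signalp) && nrow(signalp) > 0L) {
    sp_pos <- stats::setNames(signalp$positive, signalp$protein_id)
    sp_cp <- stats::setNames(signalp$cleavage_pos, signalp$protein_id)
  }
  comp_by_gene <- if (!is.null(go) && nrow(go) > 0L) {
    split(go$compartment, go$gene_id)
  } else list()

  gene_ids <- unique(proteins$gene_id)
  rows_by_gene <- split(seq_len(nrow(proteins)), proteins$gene_id)
  decisions <- vector("list", length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    g <- gene_ids[gi]
    idx <- rows_by_gene[[g]]
    iso <- vector("list", length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      pid <- proteins$protein_id[i]
      segs <- seg_by_prot[[pid]]
      pos <- isTRUE(unname(sp_pos[pid]))
      cp <- if (pos) unname(sp_cp[pid]) else NA_integer_
      iso[[j]] <- classify_isoform(proteins$length[i], segs, pos, cp, config)
    }
    comp <- comp_by_gene[[g]] %||% character()
    dec <- classify_gene(iso, comp, config)
    decisions[[gi]] <- data.frame(
      gene_id = g, verdict = dec$verdict, rule = dec$rule,
      n_isoforms = length(idx),
      isoform_verdicts = paste(dec$isoform_verdicts, collapse = "|"),
      reasons = paste(c(vapply(iso, `[[`, "", "rule"), dec$rule), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, decisions)
  lev <- c("surfaceome", "secreted", "internal_compartment", "no_tm")
  counts <- table(factor(decisions$verdict, levels = lev))
  structure(list(catalog = decisions$gene_id[decisions$verdict == "surfaceome"],
                 decisions = decisions,
                 counts = stats::setNames(as.integer(counts), lev)),
            class = "surfaceome_catalog")
}

#' @export
print.surfaceome_catalog <- function(x, ...) {
  cat("surfaceome catalog:", length(x$catalog), "of",
      nrow(x$decisions), "genes\n")
  for (v in names(x$counts)) cat(sprintf("  %-21s %d\n", v, x$counts[[v]]))
  invisible(x)
}

#' Family coverage of the catalog
#'
#' Fraction of a known surface-protein family (e.g. GPCR, SLC, CD) captured by
#' the catalog: `|family intersect catalog| / |family|`.
#'
#' @param catalog a `surfaceome_catalog` or character vector of genes.
#' @param family nonempty character vector of family member genes.
#' @return fraction in [0, 1].
#' @export
family_coverage <- function(catalog, family) {
  family <- unique(as.character(family))
  if (length(family) == 0L) abort("family must be nonempty")
  length(intersect(family, as_gene_set(catalog))) / length(family)
}

#' Overlap between the catalog and an external gene set
#'
#' @param catalog a `surfaceome_catalog` or character vector of genes.
#' @param external nonempty character vector (e.g. a mass-spectrometry-derived
#'   surfaceome).
#' @return list with `n_intersect`, `frac_of_external` and `frac_of_catalog`.
#' @export
set_overlap <- function(catalog, external) {
  cat_set <- unique(as_gene_set(catalog))
  external <- unique(as.character(external))
  if (length(cat_set) == 0L || length(external) == 0L) {
    abort("set_overlap requires two nonempty sets")
  }
  n <- length(intersect(cat_set, external))
  list(n_intersect = n,
       frac_of_external = n / length(external),
       frac_of_catalog = n / length(cat_set))
}
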