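# Synthetic-data generators. Every generator is deterministic given its
# config (the seed is mandatory) and returns its ground-truth labels
# alongside, so every downstream stage can be tested against construction.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# largest-remainder allocation: integer counts summing to n, proportional to
# props (deterministic; remainders broken by size then position)
alloc_counts <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, seq_along(raw), decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(props))
}

random_sequence <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# one isoform's TM geometry for a given stratum; returns list(segments,
# sp_positive, cleavage_pos, min_length)
stratum_geometry <- function(stratum) {
  switch(stratum,
    no_tm = list(segments = NULL, sp_positive = FALSE,
                 cleavage_pos = NA_integer_, tail = 0L),
    secreted_tm = {                      # single TM ending within residue 50
      s <- sample(5:28, 1L)
      e <- s + sample(16:min(22L, 50L - s), 1L)
      list(segments = data.frame(start = s, end = e), sp_positive = FALSE,
           cleavage_pos = NA_integer_, tail = e)
    },
    signal_covered = {                   # single TM inside the signal peptide
      e <- sample(51:70, 1L)
      s <- e - sample(18:24, 1L)
      list(segments = data.frame(start = s, end = e), sp_positive = TRUE,
           cleavage_pos = e + sample(1:5, 1L), tail = e)
    },
    surface = ,                          # multi-TM candidate
    internal = {
      k <- sample(2:6, 1L)
      pos <- sample(20:60, 1L)
      starts <- ends <- integer(k)
      for (i in seq_len(k)) {
        starts[i] <- pos + sample(5:15, 1L)
        ends[i] <- starts[i] + sample(18:24, 1L)
        pos <- ends[i]
      }
      list(segments = data.frame(start = starts, end = ends),
           sp_positive = FALSE, cleavage_pos = NA_integer_, tail = pos)
    },
    abort("unknown stratum '%s'", stratum))
}

#' Generate a protein-annotation bundle with known surfaceome truth
#'
#' Emits genes in five designed strata: `no_tm`, `secreted_tm` (single TM
#' ending within the first 50 residues), `signal_covered` (single TM inside a
#' predicted signal peptide), `surface` (multi-TM candidate, compartments
#' empty / plasma membrane / mixed) and `internal` (multi-TM candidate
#' annotated exclusively to internal compartments). Stratum counts are
#' deterministic largest-remainder allocations of `proportions`; a fraction
#' of genes gets a second isoform with same-stratum geometry.
#'
#' @param n_genes number of genes (default 100).
#' @param proportions named stratum proportions (default
#'   `c(no_tm = .2, secreted_tm = .2, signal_covered = .1, surface = .4,
#'   internal = .1)`).
#' @param two_isoform_frac fraction of genes with two isoforms (default 0.2).
#' @param seed mandatory RNG seed.
#' @return list with `proteins`, `tm`, `signalp`, `go` (parser-shaped
#'   data.frames) and `truth` (gene_id, stratum, verdict, rule).
#' @export
gen_annotation_bundle <- function(n_genes = 100L,
                                  proportions = c(no_tm = 0.2,
                                                  secreted_tm = 0.2,
                                                  signal_covered = 0.1,
                                                  surface = 0.4,
                                                  internal = 0.1),
                                  two_isoform_frac = 0.2, seed) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  counts <- alloc_counts(n_genes, proportions)
  strata <- rep(names(counts), counts)
  gene_ids <- sprintf("SYNG%04d", seq_len(n_genes))

  vocab <- default_exclusion_vocabulary()
  proteins <- tm <- sp <- go <- list()
  truth <- data.frame(gene_id = gene_ids, stratum = strata,
                      verdict = NA_character_, rule = NA_character_,
                      stringsAsFactors = FALSE)
  two_iso <- runif(n_genes) < two_isoform_frac
  iso_n <- 0L
  for (i in seq_len(n_genes)) {
    g <- gene_ids[i]
    st <- strata[i]
    for (iso in seq_len(1L + two_iso[i])) {
      iso_n <- iso_n + 1L
      pid <- sprintf("SYNP%05d", iso_n)
      geo <- stratum_geometry(st)
      len <- geo$tail + sample(30:120, 1L)
      proteins[[iso_n]] <- data.frame(
        protein_id = pid, gene_id = g, length = len,
        sequence = random_sequence(len), stringsAsFactors = FALSE)
      if (!is.null(geo$segments)) {
        tm[[length(tm) + 1L]] <- data.frame(
          protein_id = pid, start = geo$segments$start, end = geo$segments$end,
          stringsAsFactors = FALSE)
      }
      sp[[iso_n]] <- data.frame(protein_id = pid, positive = geo$sp_positive,
                                cleavage_pos = geo$cleavage_pos,
                                stringsAsFactors = FALSE)
    }
    comp <- switch(st,
      internal = sample(vocab, sample(1:3, 1L)),
      surface = switch(1L + (i %% 3L),
                       character(),                    # unannotated
                       "plasma membrane",
                       c("plasma membrane", sample(vocab, 1L))),  # mixed
      character())
    if (length(comp) > 0L) {
      go[[length(go) + 1L]] <- data.frame(gene_id = g, compartment = comp,
                                          stringsAsFactors = FALSE)
    }
    truth$verdict[i] <- switch(st, no_tm = "no_tm", secreted_tm = "secreted",
                               signal_covered = "secreted",
                               surface = "surfaceome",
                               internal = "internal_compartment")
    truth$rule[i] <- switch(st, no_tm = "R1", secreted_tm = "R2",
                            signal_covered = "R3", surface = "R5",
                            internal = "R4")
  }
  list(proteins = do.call(rbind, proteins),
       tm = if (length(tm)) do.call(rbind, tm) else
         data.frame(protein_id = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE),
       signalp = do.call(rbind, sp),
       go = if (length(go)) do.call(rbind, go) else
         data.frame(gene_id = character(), compartment = character(),
                    stringsAsFactors = FALSE),
       truth = truth)
}

#' Write an annotation bundle to disk
#'
#' Produces `proteins.fasta`, `tm.tsv`, `signalp.tsv`, `go.tsv` and
#' `truth.tsv` in `dir`, in exactly the formats the parsers read.
#'
#' @param bundle result of [gen_annotation_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotation_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$proteins, file.path(dir, "proteins.fasta"))
  write_tm_segments(bundle$tm, file.path(dir, "tm.tsv"))
  write_signalp(bundle$signalp, file.path(dir, "signalp.tsv"))
  write_go_compartments(bundle$go, file.path(dir, "go.tsv"))
  write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Generate a TCGA-like tumor cohort with planted cancer genes
#'
#' Null genes receive each alteration channel (amplification, deep deletion,
#' expression up, expression down, deleterious mutation) independently at the
#' background rate. Planted suppressors additionally receive suppressor-like
#' events (deletion / expression down / deleterious mutation, channel chosen
#' uniformly per event) in a `planted_freq` fraction of samples; oncogenes
#' analogously (amplification / expression up). Expression z-scores are
#' standard normal for unaltered cells and `+/-(2.5 + |N(0, 0.5)|)` for cells
#' altered through the expression channel. Passenger missense mutations are
#' added independently at `missense_rate`.
#'
#' @param n_genes,n_samples cohort dimensions (defaults 2000 x 500).
#' @param background_rate per-channel background event rate (default 0.01).
#' @param n_oncogenes,n_suppressors number of planted genes (default 10
#'   each).
#' @param planted_freq per-sample alteration frequency of planted genes
#'   (default 0.15); may be a named vector keyed by gene to plant
#'   gene-specific frequencies.
#' @param missense_rate passenger missense rate (default 0.01).
#' @param genes optional gene ids (default `SYNG0001` ...).
#' @param signature_genes optional character vector of genes (subset of the
#'   planted suppressors, created if absent) forming a survival signature;
#'   recorded in the truth table.
#' @param seed mandatory RNG seed.
#' @return list with `maf`, `cna`, `expr` (parser-shaped), `truth` (gene_id,
#'   role, freq, signature), `planted_events` (logical genes x samples matrix
#'   of explicitly planted or background channel events) and `samples`.
#' @export
gen_cohort <- function(n_genes = 2000L, n_samples = 500L,
                       background_rate = 0.01, n_oncogenes = 10L,
                       n_suppressors = 10L, planted_freq = 0.15,
                       missense_rate = 0.01, genes = NULL,
                       signature_genes = NULL, seed) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("SYNG%04d", seq_len(n_genes))
  n_genes <- length(genes)
  samples <- sprintf("TCGA-SYN-%04d", seq_len(n_samples))

  planted <- sample(genes, n_oncogenes + n_suppressors)
  onc_genes <- planted[seq_len(n_oncogenes)]
  sup_genes <- setdiff(planted, onc_genes)
  if (is.null(signature_genes)) signature_genes <- character()
  if (!all(signature_genes %in% genes)) abort("signature genes must be cohort genes")
  # signature genes act as suppressors if not already planted
  sup_genes <- union(sup_genes, setdiff(signature_genes, onc_genes))

  freq_of <- function(g) {
    if (!is.null(names(planted_freq)) && g %in% names(planted_freq)) {
      planted_freq[[g]]
    } else if (is.null(names(planted_freq))) planted_freq[1L] else planted_freq[[1L]]
  }

  dims <- list(genes, samples)
  draw <- function(rate) matrix(runif(n_genes * n_samples) < rate,
                                n_genes, n_samples, dimnames = dims)
  amp <- draw(background_rate)
  del <- draw(background_rate)
  expr_up <- draw(background_rate)
  expr_dn <- draw(background_rate)
  mut_del <- draw(background_rate)

  plant <- function(g, channels) {
    hit <- runif(n_samples) < freq_of(g)
    if (!any(hit)) return(invisible())
    ch <- sample(channels, sum(hit), replace = TRUE)
    idx <- which(hit)
    for (nm in unique(ch)) {
      cols <- idx[ch == nm]
      switch(nm,
             amp = amp[g, cols] <<- TRUE,
             del = del[g, cols] <<- TRUE,
             expr_up = expr_up[g, cols] <<- TRUE,
             expr_dn = expr_dn[g, cols] <<- TRUE,
             mut_del = mut_del[g, cols] <<- TRUE)
    }
    invisible()
  }
  for (g in sup_genes) plant(g, c("del", "expr_dn", "mut_del"))
  for (g in onc_genes) plant(g, c("amp", "expr_up"))

  # expression: N(0,1) background, pushed past the cutoff where planted
  expr <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples, dimnames = dims)
  n_up <- sum(expr_up)
  if (n_up > 0L) expr[expr_up] <- 2.5 + abs(rnorm(n_up, 0, 0.5))
  n_dn <- sum(expr_dn & !expr_up)
  if (n_dn > 0L) expr[expr_dn & !expr_up] <- -(2.5 + abs(rnorm(n_dn, 0, 0.5)))

  cna <- matrix(0L, n_genes, n_samples, dimnames = dims)
  shallow <- matrix(runif(n_genes * n_samples), n_genes, n_samples)
  cna[shallow < 0.03] <- 1L          # shallow events: never alteration-relevant
  cna[shallow > 0.97] <- -1L
  cna[amp] <- 2L
  cna[del & !amp] <- -2L

  del_idx <- which(mut_del, arr.ind = TRUE)
  maf_del <- if (nrow(del_idx) > 0L) {
    data.frame(sample_id = samples[del_idx[, 2L]],
               gene_id = genes[del_idx[, 1L]],
               variant_class = sample(c("nonsense", "frameshift", "splice_site"),
                                      nrow(del_idx), replace = TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  mis <- which(draw(missense_rate), arr.ind = TRUE)
  maf_mis <- if (nrow(mis) > 0L) {
    data.frame(sample_id = samples[mis[, 2L]], gene_id = genes[mis[, 1L]],
               variant_class = "missense", stringsAsFactors = FALSE)
  } else NULL
  maf <- rbind(maf_del, maf_mis)
  if (is.null(maf)) {
    maf <- data.frame(sample_id = character(), gene_id = character(),
                      variant_class = character(), stringsAsFactors = FALSE)
  }
  maf <- maf[order(maf$sample_id, maf$gene_id, maf$variant_class), , drop = FALSE]
  rownames(maf) <- NULL

  role <- rep("null", n_genes)
  role[genes %in% onc_genes] <- "oncogene"
  role[genes %in% sup_genes] <- "suppressor"
  freq <- ifelse(role == "null", NA_real_,
                 vapply(genes, freq_of, 0))
  truth <- data.frame(gene_id = genes, role = role, freq = freq,
                      signature = genes %in% signature_genes,
                      stringsAsFactors = FALSE)
  planted_events <- amp | del | expr_up | expr_dn | mut_del
  list(maf = maf, cna = cna, expr = expr, truth = truth,
       planted_events = planted_events, samples = samples)
}

#' Write a cohort to disk
#'
#' Produces `<prefix>maf.tsv`, `<prefix>cna.tsv`, `<prefix>expr.tsv` and
#' `<prefix>truth.tsv` in `dir`.
#'
#' @param cohort result of [gen_cohort()].
#' @param dir output directory.
#' @param prefix filename prefix, e.g. `"BRCA_"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_maf(cohort$maf, file.path(dir, paste0(prefix, "maf.tsv")))
  write_matrix_tsv(cohort$cna, file.path(dir, paste0(prefix, "cna.tsv")))
  write_matrix_tsv(cohort$expr, file.path(dir, paste0(prefix, "expr.tsv")))
  write_tsv(cohort$truth, file.path(dir, paste0(prefix, "truth.tsv")))
  invisible(dir)
}

#' Generate overall-survival times under a proportional-hazards alteration
#' effect
#'
#' Event times are exponential with rate `baseline_hazard` for unaltered
#' samples and `baseline_hazard * hazard_ratio` for signature-altered ones.
#' Censoring is independent exponential with its rate chosen (numerically) so
#' that the expected censoring fraction equals `censoring_rate`;
#' `censoring_rate = 0` disables censoring.
#'
#' @param samples character vector of sample ids.
#' @param altered logical vector: signature alteration status per sample.
#' @param hazard_ratio hazard ratio for altered samples (default 3).
#' @param baseline_hazard events per day (default 1/1000).
#' @param censoring_rate expected fraction censored (default 0.3).
#' @param seed mandatory RNG seed.
#' @return clinical data.frame (`sample_id`, `os_time_days`, `os_event`).
#' @export
gen_survival <- function(samples, altered, hazard_ratio = 3,
                         baseline_hazard = 1 / 1000, censoring_rate = 0.3,
                         seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (length(samples) != length(altered)) abort("samples/altered length mismatch")
  if (hazard_ratio <= 0 || baseline_hazard <= 0) abort("hazards must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) abort("censoring_rate must be in [0, 1)")
  set.seed(seed)
  n <- length(samples)
  rate <- baseline_hazard * ifelse(altered, hazard_ratio, 1)
  t_event <- rexp(n, rate)
  if (censoring_rate > 0) {
    # E[censored] = mean_i lc / (lc + rate_i); solve for lc
    f <- function(lc) mean(lc / (lc + rate)) - censoring_rate
    lc <- uniroot(f, lower = 1e-12, upper = 1e6 * baseline_hazard,
                  tol = 1e-12)$root
    t_cens <- rexp(n, lc)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(sample_id = samples,
             os_time_days = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Write every input of a full pipeline run
#'
#' Generates an annotation bundle, one cohort per tumor type over the
#' resulting surfaceome genes (the survival tumor type gets a planted 3-gene
#' suppressor signature with a survival effect), a clinical table, a toy
#' biological-process term map, and a flat `config.txt`; everything lands in
#' `dir` in exactly the formats [run_pipeline()] reads.
#'
#' @param dir output directory.
#' @param seed mandatory RNG seed.
#' @param n_genes annotation-bundle size (default 300).
#' @param n_samples samples per cohort (default 200).
#' @param tumor_types character vector of tumor-type codes (default
#'   `c("SYNT1", "SYNT2")`); the first is the survival tumor type.
#' @param hazard_ratio,censoring_rate survival-effect parameters.
#' @return invisibly, a list with the generated objects and `config_path`.
#' @export
simulate_pipeline_inputs <- function(dir, seed, n_genes = 300L,
                                     n_samples = 200L,
                                     tumor_types = c("SYNT1", "SYNT2"),
                                     hazard_ratio = 3, censoring_rate = 0.3) {
  if (missing(seed)) abort("seed is mandatory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- gen_annotation_bundle(n_genes = n_genes, seed = seed)
  write_annotation_bundle(bundle, dir)
  catalog <- suppressMessages(build_catalog(bundle$proteins, bundle$tm,
                                            bundle$signalp, bundle$go))
  surf <- catalog$catalog

  cohorts <- list()
  signature <- sort(sample(surf, 3L))
  for (ti in seq_along(tumor_types)) {
    tt <- tumor_types[ti]
    is_surv <- ti == 1L
    cohort <- gen_cohort(
      n_samples = n_samples, genes = surf,
      n_oncogenes = 5L, n_suppressors = if (is_surv) 5L else 8L,
      planted_freq = 0.15,
      signature_genes = if (is_surv) signature else NULL,
      seed = seed + 1000L * ti)
    write_cohort(cohort, dir, prefix = paste0(tt, "_"))
    cohorts[[tt]] <- cohort
  }
  surv_cohort <- cohorts[[tumor_types[1L]]]
  sig_status <- colSums(surv_cohort$planted_events[signature, , drop = FALSE]) > 0L
  clinical <- gen_survival(surv_cohort$samples, sig_status,
                           hazard_ratio = hazard_ratio,
                           censoring_rate = censoring_rate,
                           seed = seed + 77L)
  write_clinical(clinical, file.path(dir, "clinical.tsv"))

  # toy biological-process term map over the surfaceome genes
  set.seed(seed + 99L)
  terms <- sprintf("TERM%03d", 1:20)
  t2g <- do.call(rbind, lapply(terms, function(t) {
    data.frame(term_id = t, term_name = paste0("process ", t),
               gene_id = sample(surf, sample(8:25, 1L)),
               stringsAsFactors = FALSE)
  }))
  write_tsv(t2g, file.path(dir, "term_map.tsv"))

  config <- c(
    paste0("input_dir: ", dir),
    paste0("out_dir: ", file.path(dir, "results")),
    paste0("tumor_types: ", paste(tumor_types, collapse = ",")),
    paste0("survival_tumor: ", tumor_types[1L]),
    "z_main: 3", "z_relaxed: 2", "alpha: 0.05", "top_k: 20", "k: 3",
    "enrich_cutoff: 0.01", "n_clusters: 3",
    paste0("seed: ", seed))
  config_path <- file.path(dir, "config.txt")
  writeLines(config, config_path)
  invisible(list(bundle = bundle, catalog = catalog, cohorts = cohorts,
                 clinical = clinical, signature = signature,
                 term_map = t2g, config_path = config_path))
}
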