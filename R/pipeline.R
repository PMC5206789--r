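# End-to-end orchestration: catalog -> per-tumor scoring -> clustering and
# enrichment -> alteration model -> survival screen and exhaustive signature
# search, from one flat config, writing every intermediate table plus a
# machine-readable report. All outputs are deterministic given fixed inputs
# (no timestamps), so a rerun with the same config is byte-identical.

PIPELINE_DEFAULTS <- list(
  z_main = 3, z_relaxed = 2, alpha = 0.05, top_k = 20L, k = 3L,
  enrich_cutoff = 0.01, n_clusters = 3L, seed = NA_integer_)

#' Read a flat run configuration
#'
#' Minimal `key: value` format (a flat YAML subset): one pair per line,
#' `#` comments and blank lines ignored; `tumor_types` is a comma-separated
#' list; numeric-looking values are coerced.
#'
#' @param path config file path.
#' @return named list merged over the pipeline defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- PIPELINE_DEFAULTS
  for (ln in lines) {
    m <- regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln)[[1L]]
    if (m[1L] == -1L) abort("cannot parse config line: '%s'", ln)
    key <- substr(ln, m[2L], m[2L] + attr(m, "match.length")[2L] - 1L)
    val <- substr(ln, m[3L], m[3L] + attr(m, "match.length")[3L] - 1L)
    if (key == "tumor_types") {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    } else if (grepl("^-?[0-9.]+([eE][+-]?[0-9]+)?$", val)) {
      val <- as.numeric(val)
    }
    cfg[[key]] <- val
  }
  cfg
}

validate_run_config <- function(config) {
  need <- c("input_dir", "out_dir", "tumor_types", "survival_tumor")
  miss <- need[!vapply(need, function(k) !is.null(config[[k]]), TRUE)]
  if (length(miss) > 0L) {
    abort("config is missing required key(s): %s", paste(miss, collapse = ", "))
  }
  for (th in c("z_main", "z_relaxed", "alpha", "top_k", "k", "enrich_cutoff",
               "n_clusters")) {
    if (!is.numeric(config[[th]]) || config[[th]] <= 0) {
      abort("config threshold '%s' must be positive", th)
    }
  }
  if (!config$survival_tumor %in% config$tumor_types) {
    abort("survival_tumor '%s' is not in tumor_types", config$survival_tumor)
  }
  files <- c("proteins.fasta", "tm.tsv", "signalp.tsv", "go.tsv", "clinical.tsv",
             as.vector(outer(config$tumor_types,
                             c("_maf.tsv", "_cna.tsv", "_expr.tsv"), paste0)))
  paths <- file.path(config$input_dir, files)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) abort("missing input file(s): %s",
                                  paste(missing, collapse = ", "))
  config
}

# canonical md5 of the configuration (computed from its deparsed, sorted form)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(md5sum(tmp))
}

#' Run the full pipeline
#'
#' Stages, in order: surfaceome catalog; per-tumor S-scoring and cancer-gene
#' calls (z threshold `z_main`, inclusive); clustering of the cancer-gene
#' S-score matrix plus per-cluster term enrichment (when a `term_map.tsv`
#' exists and enough genes were called); alteration model and survival screen
#' on the `survival_tumor` cohort using the relaxed strict threshold
#' `|z| > z_relaxed`; exhaustive k-gene signature search over the screened
#' genes. Every intermediate table is written as TSV under `out_dir`; a JSON
#' `report.json` and a deterministic `run.log` summarize the run. Any stage
#' error aborts with the stage name.
#'
#' @param config path to a config file ([read_run_config()]) or an
#'   equivalent named list.
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return the run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("surfscore ", as.character(utils::packageVersion("surfscore"))),
                 R.version.string,
                 paste0("config_hash: ", config_hash(config)),
                 paste0("seed: ", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  ip <- function(f) file.path(config$input_dir, f)

  # --- stage 1: catalog -----------------------------------------------------
  catalog <- stage("catalog", {
    proteins <- parse_fasta(ip("proteins.fasta"))
    tm <- parse_tm_segments(ip("tm.tsv"),
                            stats::setNames(proteins$length, proteins$protein_id))
    sp <- parse_signalp(ip("signalp.tsv"))
    go <- parse_go_compartments(ip("go.tsv"))
    build_catalog(proteins, tm, sp, go)
  })
  write_tsv(catalog$decisions, file.path(out_dir, "catalog.tsv"))
  log_lines <- c(log_lines, paste0("catalog: ", length(catalog$catalog),
                                   " surfaceome genes"))

  # --- stage 2: per-tumor scoring ------------------------------------------
  surf <- catalog$catalog
  s_cols <- list(); cancer_per_tumor <- list(); z_cols <- list()
  for (tt in config$tumor_types) {
    tab <- stage(paste0("score:", tt), {
      maf <- parse_maf(ip(paste0(tt, "_maf.tsv")))
      cna <- parse_matrix(ip(paste0(tt, "_cna.tsv")), "cna")
      expr <- parse_matrix(ip(paste0(tt, "_expr.tsv")), "expr")
      samples <- reconcile_samples(expr = colnames(expr), cna = colnames(cna))
      score_tumor(expr, cna, maf, genes = surf, samples = samples,
                  threshold = config$z_main, inclusive = TRUE)
    })
    write_tsv(tab, file.path(out_dir, paste0("scores_", tt, ".tsv")))
    s_cols[[tt]] <- stats::setNames(tab$S, tab$gene_id)
    z_cols[[tt]] <- stats::setNames(tab$z, tab$gene_id)
    cancer_per_tumor[[tt]] <- tab$gene_id[tab$class != "none"]
  }
  s_matrix <- do.call(cbind, s_cols)
  write_matrix_tsv(s_matrix, file.path(out_dir, "s_matrix.tsv"))
  union_genes <- sort(unique(unlist(cancer_per_tumor)))
  log_lines <- c(log_lines,
                 vapply(config$tumor_types, function(tt)
                   sprintf("score %s: %d cancer genes", tt,
                           length(cancer_per_tumor[[tt]])), ""),
                 paste0("pan-cancer union: ", length(union_genes), " genes"))

  # --- stage 3: clustering + enrichment ------------------------------------
  enrichment_rows <- 0L
  term_path <- ip("term_map.tsv")
  if (length(union_genes) >= config$n_clusters) {
    clusters <- stage("cluster", {
      cluster_genes(s_matrix[union_genes, , drop = FALSE],
                    n_clusters = config$n_clusters)
    })
    write_tsv(data.frame(gene_id = names(clusters),
                         cluster = as.integer(clusters),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "clusters.tsv"))
    if (file.exists(term_path)) {
      enr <- stage("enrich", {
        t2g <- read.delim(term_path, stringsAsFactors = FALSE)
        universe <- intersect(surf, unique(t2g$gene_id))
        res <- list()
        for (cl in sort(unique(clusters))) {
          q <- intersect(names(clusters)[clusters == cl], universe)
          if (length(q) == 0L) next
          r <- enrich_terms(q, t2g, universe, cutoff = config$enrich_cutoff)
          if (nrow(r) > 0L) res[[length(res) + 1L]] <- cbind(cluster = cl, r)
        }
        if (length(res)) do.call(rbind, res) else NULL
      })
      if (!is.null(enr)) {
        write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
        enrichment_rows <- nrow(enr)
      }
    }
  } else {
    notify("skipping clustering: only %d cancer gene(s)", length(union_genes))
  }

  # --- stage 4: alteration + survival --------------------------------------
  tt <- config$survival_tumor
  surv <- stage("survival", {
    maf <- parse_maf(ip(paste0(tt, "_maf.tsv")))
    cna <- parse_matrix(ip(paste0(tt, "_cna.tsv")), "cna")
    expr <- parse_matrix(ip(paste0(tt, "_expr.tsv")), "expr")
    clinical <- parse_clinical(ip("clinical.tsv"))
    z <- z_cols[[tt]]
    relaxed <- classify_cancer_genes(z, threshold = config$z_relaxed,
                                     inclusive = FALSE)
    cand <- relaxed$union
    if (length(cand) == 0L) abort("no gene passes the relaxed z threshold")
    samples <- reconcile_samples(expr = colnames(expr),
                                 clinical = clinical$sample_id)
    alt <- build_alteration_matrix(cand, expr, cna, maf, samples = samples)
    screen <- gene_screen(alt, clinical, alpha = config$alpha,
                          top_k = config$top_k)
    combos <- NULL
    if (length(screen$screened) >= config$k) {
      combos <- combination_search(screen$screened, alt, clinical,
                                   k = config$k)
    } else {
      notify("skipping combination search: only %d screened gene(s)",
             length(screen$screened))
    }
    list(candidates = cand, alt = alt, screen = screen, combos = combos,
         clinical = clinical)
  })
  write_matrix_tsv(1L * surv$alt, file.path(out_dir, "alteration.tsv"))
  write_tsv(surv$screen$table, file.path(out_dir, "screen.tsv"))
  top_sig <- NULL
  if (!is.null(surv$combos)) {
    write_tsv(as.data.frame(surv$combos), file.path(out_dir, "combinations.tsv"))
    best <- surv$combos[1L, ]
    top_genes <- unlist(best[paste0("gene_", seq_len(config$k))], use.names = FALSE)
    top_sig <- list(genes = top_genes, p = best$p,
                    n_altered = best$n_altered)
    # KM curves of the top signature, enough to replot the survival figure
    cl <- surv$clinical[match(surv$screen$samples, surv$clinical$sample_id), ]
    g1 <- signature_altered(top_genes, surv$alt[, surv$screen$samples,
                                                drop = FALSE])
    for (grp in c("altered", "unaltered")) {
      sel <- if (grp == "altered") g1 else !g1
      curve <- km_estimate(cl$os_time_days[sel], cl$os_event[sel])
      write_tsv(as.data.frame(curve),
                file.path(out_dir, paste0("km_top_signature_", grp, ".tsv")))
    }
  }
  log_lines <- c(log_lines,
                 sprintf("survival %s: %d candidates, %d screened", tt,
                         length(surv$candidates), length(surv$screen$screened)),
                 if (!is.null(top_sig))
                   sprintf("top signature: %s (p = %s)",
                           paste(top_sig$genes, collapse = "+"),
                           format_num(top_sig$p)))

  # --- report ---------------------------------------------------------------
  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    catalog = list(n_genes = nrow(catalog$decisions),
                   n_surfaceome = length(catalog$catalog),
                   counts = as.list(catalog$counts)),
    cancer_genes = lapply(cancer_per_tumor, length),
    pan_cancer_union = length(union_genes),
    enrichment_rows = enrichment_rows,
    survival = list(tumor_type = tt,
                    n_candidates = length(surv$candidates),
                    n_screened = length(surv$screen$screened),
                    n_combinations = if (is.null(surv$combos)) 0L else
                      attr(surv$combos, "n_evaluated"),
                    top_signature = top_sig))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}
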