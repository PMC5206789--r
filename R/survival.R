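# Kaplan-Meier estimation and the two-group log-rank test, implemented from
# first principles. Tie rule: censored subjects at an event time remain at
# risk for that time (events before censoring). Log-rank:
#   O1 = observed events in group 1
#   E1 = sum_j n1j * dj / nj
#   V  = sum_j dj (n1j/nj)(n2j/nj)(nj - dj)/(nj - 1)     (nj = 1 strata skipped)
#   X2 = (O1 - E1)^2 / V, p = upper tail of chi-square with 1 df.

check_surv_input <- function(time, event) {
  if (length(time) == 0L) abort("survival input is empty")
  if (length(time) != length(event)) abort("time and event lengths differ")
  if (any(!is.finite(time)) || any(time < 0)) abort("times must be finite and >= 0")
  ev <- as.logical(event)
  if (anyNA(ev)) abort("event indicators must be 0/1 or logical")
  ev
}

#' Kaplan-Meier product-limit estimate
#'
#' Returns the survival curve evaluated at the distinct event times; before
#' the first event the estimate is 1 by construction.
#'
#' @param time follow-up times (>= 0).
#' @param event event indicators (1/TRUE = death observed, 0/FALSE = censored).
#' @return data.frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `survival` (one row per distinct event time), plus attributes
#'   `n` and `n_events`.
#' @export
km_estimate <- function(time, event) {
  event <- check_surv_input(time, event)
  evt <- sort(unique(time[event]))
  st <- sort(time)
  n_risk <- length(time) - findInterval(evt, st, left.open = TRUE)
  d <- as.integer(table(factor(time[event], levels = evt)))
  surv <- cumprod(1 - d / n_risk)
  out <- data.frame(time = evt, n_risk = as.integer(n_risk),
                    n_event = d, survival = surv)
  attr(out, "n") <- length(time)
  attr(out, "n_events") <- sum(event)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a [km_estimate()] result.
#' @param at numeric times.
#' @return survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(curve, at) {
  if (nrow(curve) == 0L) return(rep(1, length(at)))
  idx <- findInterval(at, curve$time)
  ifelse(idx == 0L, 1, curve$survival[pmax(idx, 1L)])
}

# fast core shared by the public test, the screen and the combination search;
# g1 is a logical vector marking group-1 membership
logrank_core <- function(time, event, g1) {
  evt <- sort(unique(time[event]))
  if (length(evt) == 0L) {
    return(list(chisq = 0, p = 1, O1 = 0, E1 = 0, V = 0, n_events = 0L))
  }
  st <- sort(time)
  st1 <- sort(time[g1])
  n_j <- length(time) - findInterval(evt, st, left.open = TRUE)
  n1_j <- length(st1) - findInterval(evt, st1, left.open = TRUE)
  d_j <- as.integer(table(factor(time[event], levels = evt)))
  d1_j <- as.integer(table(factor(time[event & g1], levels = evt)))
  O1 <- sum(d1_j)
  E1 <- sum(n1_j * d_j / n_j)
  ok <- n_j > 1L
  V <- sum((d_j * (n1_j / n_j) * ((n_j - n1_j) / n_j) *
              (n_j - d_j) / (n_j - 1))[ok])
  if (V <= 0) {
    chisq <- 0; p <- 1
  } else {
    chisq <- (O1 - E1)^2 / V
    p <- pchisq(chisq, df = 1L, lower.tail = FALSE)
  }
  list(chisq = chisq, p = p, O1 = O1, E1 = E1, V = V, n_events = sum(d_j))
}

#' Two-group log-rank test
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level grouping (logical, factor or character); both
#'   groups must be nonempty.
#' @return object of class `logrank_test`: list with `chisq`, `df`, `p`,
#'   `observed`, `expected`, `variance`, `n` (group sizes) and `n_events`.
#'   With zero total events the statistic is 0 and p = 1, with a warning.
#' @export
logrank_test <- function(time, event, group) {
  event <- check_surv_input(time, event)
  if (length(group) != length(time)) abort("group length differs from time")
  f <- as.factor(group)
  f <- droplevels(f)
  if (nlevels(f) != 2L) abort("log-rank test requires exactly two nonempty groups")
  g1 <- f == levels(f)[1L]
  res <- logrank_core(time, event, g1)
  if (res$n_events == 0L) {
    warning("no events observed: log-rank statistic is 0, p = 1", call. = FALSE)
  }
  total <- res$n_events
  structure(list(chisq = res$chisq, df = 1L, p = res$p,
                 observed = stats::setNames(c(res$O1, total - res$O1), levels(f)),
                 expected = stats::setNames(c(res$E1, total - res$E1), levels(f)),
                 variance = res$V,
                 n = stats::setNames(c(sum(g1), sum(!g1)), levels(f)),
                 n_events = total),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chisq = %.4g on 1 df, p = %.4g\n", x$chisq, x$p))
  cat(sprintf("  groups (n): %s\n",
              paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", ")))
  invisible(x)
}

#' Per-gene survival screen
#'
#' Tests every gene's altered-vs-unaltered split with the log-rank test,
#' collapses redundant genes and returns the screened list. Redundant =
#' identical altered-sample sets (they yield identical tests); the
#' lexicographically first symbol is kept. Genes with an empty group are
#' skipped with a recorded reason. Selection uses the raw p (`p < alpha`);
#' BH-adjusted values are reported alongside but not used for selection.
#'
#' @param alteration logical genes x samples matrix
#'   ([build_alteration_matrix()]).
#' @param clinical data.frame from [parse_clinical()]; samples are matched to
#'   the matrix columns (intersection, with a message when samples drop).
#' @param alpha raw log-rank p cutoff (default 0.05).
#' @param top_k maximum number of screened genes returned (default 20).
#' @param redundancy `"identical"` (default) or `"jaccard"`.
#' @param jaccard_threshold similarity above which two altered sets are
#'   considered redundant in `"jaccard"` mode.
#' @return object of class `gene_screen`: list with `table` (per-gene
#'   data.frame: gene_id, n_altered, n_unaltered, chisq, p, p_adj, kept,
#'   reason) and `screened` (character vector, ranked by ascending p, ties
#'   broken lexicographically).
#' @export
gene_screen <- function(alteration, clinical, alpha = 0.05, top_k = 20L,
                        redundancy = c("identical", "jaccard"),
                        jaccard_threshold = 0.95) {
  redundancy <- match.arg(redundancy)
  samples <- reconcile_samples(matrix = colnames(alteration),
                               clinical = clinical$sample_id)
  if (length(samples) == 0L) abort("no samples shared by matrix and clinical table")
  m <- alteration[, samples, drop = FALSE]
  cl <- clinical[match(samples, clinical$sample_id), ]
  event <- cl$os_event == 1L
  time <- cl$os_time_days

  genes <- rownames(m)
  n <- length(genes)
  tab <- data.frame(gene_id = genes,
                    n_altered = as.integer(rowSums(m)),
                    n_unaltered = as.integer(ncol(m) - rowSums(m)),
                    chisq = NA_real_, p = NA_real_, p_adj = NA_real_,
                    kept = FALSE, reason = "", stringsAsFactors = FALSE)
  testable <- tab$n_altered > 0L & tab$n_unaltered > 0L
  tab$reason[!testable] <- "empty group"
  for (i in which(testable)) {
    res <- logrank_core(time, event, m[i, ])
    tab$chisq[i] <- res$chisq
    tab$p[i] <- res$p
  }
  tab$p_adj[testable] <- bh_adjust(tab$p[testable])

  # collapse redundant genes (identical altered-sample sets by default)
  ord <- order(tab$gene_id)
  seen <- character()
  redundant_with <- stats::setNames(rep(NA_character_, n), genes)
  if (any(testable)) {
    keys <- vapply(genes, function(g) paste(which(m[g, ]), collapse = ","), "")
    if (redundancy == "identical") {
      first_by_key <- tapply(genes[testable], keys[testable],
                             function(v) sort(v)[1L])
      for (g in genes[testable]) {
        keeper <- first_by_key[[keys[g]]]
        if (!identical(keeper, g)) redundant_with[g] <- keeper
      }
    } else {
      kept_sets <- list()
      for (g in sort(genes[testable])) {
        dupof <- NA_character_
        for (h in names(kept_sets)) {
          a <- kept_sets[[h]]; b <- which(m[g, ])
          jac <- length(intersect(a, b)) / length(union(a, b))
          if (is.finite(jac) && jac > jaccard_threshold) { dupof <- h; break }
        }
        if (is.na(dupof)) kept_sets[[g]] <- which(m[g, ]) else redundant_with[g] <- dupof
      }
    }
  }
  dup <- !is.na(redundant_with)
  tab$reason[dup] <- paste0("redundant with ", redundant_with[dup])

  pass <- testable & !dup & !is.na(tab$p) & tab$p < alpha
  ranked <- tab$gene_id[pass][order(tab$p[pass], tab$gene_id[pass])]
  screened <- head(ranked, top_k)
  tab$kept <- tab$gene_id %in% screened
  structure(list(table = tab, screened = screened,
                 samples = samples, alpha = alpha, top_k = top_k),
            class = "gene_screen")
}

#' @export
print.gene_screen <- function(x, ...) {
  cat(sprintf("survival screen: %d/%d genes kept (alpha = %g, top %d)\n",
              length(x$screened), nrow(x$table), x$alpha, x$top_k))
  invisible(x)
}

#' Exhaustive k-gene signature search
#'
#' Evaluates the altered/unaltered split induced by every k-subset of the
#' given genes (OR over the subset's alteration rows) with the log-rank test.
#' Exactly `choose(length(genes), k)` subsets are evaluated. Subsets where
#' one group is empty get `p = NA` and rank last. Ranking is by ascending p,
#' ties broken lexicographically by the sorted gene symbols; the search is
#' fully deterministic.
#'
#' @param genes character vector of candidate genes (>= k).
#' @param alteration logical genes x samples matrix.
#' @param clinical clinical table.
#' @param k subset size (default 3).
#' @return data.frame of class `signature_search` with columns `gene_1` ..
#'   `gene_k`, `n_altered`, `n_unaltered`, `chisq`, `p`, `rank`; attribute
#'   `n_evaluated` records the exhaustive count.
#' @export
combination_search <- function(genes, alteration, clinical, k = 3L) {
  genes <- as.character(genes)
  if (length(genes) < k) abort("need >= %d genes, got %d", k, length(genes))
  missing <- setdiff(genes, rownames(alteration))
  if (length(missing) > 0L) abort("gene '%s' absent from alteration matrix", missing[1L])
  samples <- reconcile_samples(matrix = colnames(alteration),
                               clinical = clinical$sample_id)
  m <- alteration[genes, samples, drop = FALSE]
  cl <- clinical[match(samples, clinical$sample_id), ]
  event <- cl$os_event == 1L
  time <- cl$os_time_days

  combos <- combn(sort(genes), k)
  n_combo <- ncol(combos)
  n_alt <- integer(n_combo); chisq <- p <- rep(NA_real_, n_combo)
  for (j in seq_len(n_combo)) {
    g1 <- colSums(m[combos[, j], , drop = FALSE]) > 0L
    n_alt[j] <- sum(g1)
    if (n_alt[j] == 0L || n_alt[j] == length(g1)) next
    res <- logrank_core(time, event, g1)
    chisq[j] <- res$chisq
    p[j] <- res$p
  }
  key <- apply(combos, 2L, paste, collapse = "|")
  ord <- order(p, key, na.last = TRUE)
  out <- as.data.frame(t(combos), stringsAsFactors = FALSE)
  names(out) <- paste0("gene_", seq_len(k))
  out$n_altered <- n_alt
  out$n_unaltered <- length(samples) - n_alt
  out$chisq <- chisq
  out$p <- p
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(n_combo)
  attr(out, "n_evaluated") <- n_combo
  class(out) <- c("signature_search", "data.frame")
  out
}
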