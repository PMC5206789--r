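# survival_signatures: KM estimator, log-rank test, screen, combination search

test_that("km_estimate reproduces hand and ECDF-oracle values", {
  # 4 subjects, one event at t = 1, rest censored later
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_equal(km$survival, 0.75)
  expect_equal(km$n_risk, 4L)

  # no events -> survival identically 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km0), 0L)
  expect_equal(km_survival_at(km0, c(0, 10)), c(1, 1))

  # all events, no censoring: steps equal the empirical survivor function
  km1 <- km_estimate(1:4, rep(1, 4))
  expect_equal(km1$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km1$survival, oracle_ecdf_survival(1:4, km1$time))

  expect_error(km_estimate(numeric(), logical()), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("KM invariants hold on random censored instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    time <- round(rexp(n, 0.1), 2)
    event <- runif(n) < 0.7
    if (!any(event)) event[1] <- TRUE
    km <- km_estimate(time, event)
    expect_true(all(diff(km$survival) <= 1e-12))          # nonincreasing
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    expect_true(all(diff(km$n_risk) < 0))                 # strictly decreasing
    # censored-at-event-time subjects remain at risk for that time
    expect_equal(km$n_risk[1], sum(time >= km$time[1]))
  }
})

test_that("km tie rule: censoring at an event time keeps the subject at risk", {
  km <- km_estimate(c(5, 5, 8), c(1, 0, 1))
  expect_equal(km$n_risk, c(3L, 1L))
  expect_equal(km$survival, c(1 - 1 / 3, 0))
})

test_that("log-rank statistic agrees with the brute-force oracle and survival::survdiff", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(6:60, 1)
    time <- round(rexp(n, 0.05), 1)
    event <- runif(n) < 0.8
    group <- runif(n) < 0.5
    if (length(unique(group)) < 2) group[1] <- !group[1]
    if (!any(event)) event[1] <- TRUE
    res <- logrank_test(time, event, group)
    expect_equal(res$chisq, oracle_logrank_chisq(time, event, group),
                 tolerance = 1e-10)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(res$chisq, sd$chisq, tolerance = 1e-8)
    # label swap leaves the statistic unchanged
    expect_equal(logrank_test(time, event, !group)$chisq, res$chisq)
  }
})

test_that("log-rank degenerate cases follow the contract", {
  # identical groups -> chisq 0, p 1
  t <- c(1, 2, 3, 1, 2, 3)
  e <- c(1, 1, 0, 1, 1, 0)
  g <- rep(c("a", "b"), each = 3)
  res <- logrank_test(t, e, g)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
  expect_error(logrank_test(t, e, rep("a", 6)), "two nonempty groups")
  expect_warning(res0 <- logrank_test(t, rep(0, 6), g), "no events")
  expect_equal(res0$p, 1)
})

test_that("gene_screen ranks, collapses redundancy and respects alpha", {
  set.seed(33)
  n <- 120L
  samples <- sprintf("S%03d", 1:n)
  m <- matrix(FALSE, 4, n, dimnames = list(c("BAD1", "DUP1", "DUP2", "NULL1"),
                                           samples))
  risk <- sample(n, 40)
  m["BAD1", risk] <- TRUE
  m["DUP1", 1:30] <- TRUE
  m["DUP2", 1:30] <- TRUE          # identical altered set as DUP1
  m["NULL1", sample(n, 35)] <- TRUE
  time <- rexp(n, 1 / 100)
  time[risk] <- rexp(length(risk), 1 / 100 * 6)  # strong effect on BAD1 carriers
  clinical <- data.frame(sample_id = samples, os_time_days = time,
                         os_event = 1L, stringsAsFactors = FALSE)
  scr <- suppressMessages(gene_screen(m, clinical))
  expect_equal(scr$screened[1], "BAD1")
  # redundant pair: lexicographically first kept, second flagged
  expect_false("DUP2" %in% scr$screened)
  expect_match(scr$table$reason[scr$table$gene_id == "DUP2"], "redundant with DUP1")
  # alpha = 0 -> empty list (p values are never < 0)
  scr0 <- suppressMessages(gene_screen(m, clinical, alpha = 0))
  expect_length(scr0$screened, 0L)
  # genes with an empty group are skipped with a reason
  m2 <- rbind(m, ALLALT = rep(TRUE, n))
  scr2 <- suppressMessages(gene_screen(m2, clinical))
  expect_equal(scr2$table$reason[scr2$table$gene_id == "ALLALT"], "empty group")
})

test_that("combination_search is exhaustive, deterministic, reduces at k = 1", {
  set.seed(44)
  n <- 80L
  samples <- sprintf("S%03d", 1:n)
  genes <- sprintf("G%02d", 1:6)
  m <- matrix(runif(6 * n) < 0.2, 6, n, dimnames = list(genes, samples))
  clinical <- data.frame(sample_id = samples,
                         os_time_days = rexp(n, 0.01),
                         os_event = rbinom(n, 1, 0.8), stringsAsFactors = FALSE)
  res <- suppressMessages(combination_search(genes, m, clinical, k = 3))
  expect_equal(attr(res, "n_evaluated"), choose(6, 3))
  expect_equal(nrow(res), choose(6, 3))
  expect_equal(res$n_altered + res$n_unaltered, rep(n, nrow(res)))
  # deterministic: identical rerun
  res2 <- suppressMessages(combination_search(genes, m, clinical, k = 3))
  expect_identical(as.data.frame(res), as.data.frame(res2))
  # k = 1 reduces to the per-gene log-rank p-values
  res1 <- suppressMessages(combination_search(genes, m, clinical, k = 1))
  scr <- suppressMessages(gene_screen(m, clinical, alpha = 1, top_k = 100))
  per_gene <- scr$table$p[match(res1$gene_1, scr$table$gene_id)]
  expect_equal(res1$p, per_gene, tolerance = 1e-12)
  expect_error(combination_search(genes[1:2], m, clinical, k = 3), "need >= 3")
})
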