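# alteration_model: altered/unaltered classification and signature OR

test_that("is_altered matches the five-disjunct truth table at boundaries", {
  grid <- expand.grid(ez = c(-2.5, -2, 1.9, 2, 2.4),
                      cna = c(-2L, -1L, 0L, 1L, 2L),
                      class = c("none", "missense", "splice_site", "nonsense"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    omics <- make_omics("G1", "S1",
                        expr_cells = data.frame(gene = "G1", sample = "S1", z = g$ez),
                        cna_cells = data.frame(gene = "G1", sample = "S1", call = g$cna),
                        maf_rows = if (g$class != "none")
                          data.frame(gene = "G1", sample = "S1", class = g$class))
    want <- (g$ez > 2) || (g$ez < -2) || (g$cna == 2L) || (g$cna == -2L) ||
      g$class %in% c("nonsense", "frameshift", "splice_site")
    got <- is_altered("G1", "S1", omics$expr, omics$cna, omics$maf)
    expect_identical(got$altered, want,
                     info = sprintf("ez=%.1f cna=%d class=%s", g$ez, g$cna, g$class))
    expect_identical(length(got$reasons) > 0L, want)
  }
})

test_that("reason codes name the triggering channels", {
  omics <- make_omics("G1", "S1",
                      expr_cells = data.frame(gene = "G1", sample = "S1", z = 2.4))
  expect_equal(is_altered("G1", "S1", omics$expr, omics$cna, omics$maf)$reasons,
               "expr_up")
  omics <- make_omics("G1", "S1",
                      expr_cells = data.frame(gene = "G1", sample = "S1", z = -3),
                      cna_cells = data.frame(gene = "G1", sample = "S1", call = -2L),
                      maf_rows = data.frame(gene = "G1", sample = "S1",
                                            class = "splice_site"))
  expect_setequal(is_altered("G1", "S1", omics$expr, omics$cna, omics$maf)$reasons,
                  c("expr_down", "deleted", "deleterious_mutation"))
})

test_that("matrix construction is deterministic and idempotent to duplicates", {
  genes <- c("G1", "G2")
  samples <- c("S1", "S2", "S3")
  maf1 <- data.frame(sample_id = "S2", gene_id = "G1",
                     variant_class = "nonsense", stringsAsFactors = FALSE)
  maf2 <- rbind(maf1, maf1, maf1)   # duplicate rows
  m1 <- suppressMessages(build_alteration_matrix(genes, maf = maf1, samples = samples))
  m2 <- suppressMessages(build_alteration_matrix(genes, maf = maf2, samples = samples))
  expect_identical(m1, m2)
  expect_true(m1["G1", "S2"])
  expect_equal(sum(m1), 1L)

  # all-zero omics -> all-false matrix
  omics <- make_omics(genes, samples)
  m0 <- suppressMessages(build_alteration_matrix(genes, omics$expr, omics$cna,
                                                 omics$maf))
  expect_false(any(m0))

  # permutation invariance in mutation row order
  maf3 <- data.frame(sample_id = c("S1", "S3"), gene_id = c("G2", "G1"),
                     variant_class = c("frameshift", "splice_site"),
                     stringsAsFactors = FALSE)
  a <- suppressMessages(build_alteration_matrix(genes, maf = maf3, samples = samples))
  b <- suppressMessages(build_alteration_matrix(genes, maf = maf3[2:1, ],
                                                samples = samples))
  expect_identical(a, b)
})

test_that("planted alteration frequencies are recovered within binomial error", {
  co <- gen_cohort(n_genes = 100L, n_samples = 500L, n_oncogenes = 0L,
                   n_suppressors = 1L, planted_freq = 0.30,
                   background_rate = 0, missense_rate = 0, seed = 21)
  g <- co$truth$gene_id[co$truth$role == "suppressor"]
  alt <- suppressMessages(build_alteration_matrix(g, co$expr, co$cna, co$maf,
                                                  samples = co$samples))
  frac <- mean(alt)
  ci <- qbinom(c(0.005, 0.995), 500, 0.30) / 500
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("signature_altered is an OR and therefore monotone", {
  m <- matrix(FALSE, 3, 4, dimnames = list(c("A", "B", "C"),
                                           paste0("S", 1:4)))
  m["A", 2] <- TRUE
  m["B", 3] <- TRUE
  expect_false(signature_altered(c("A", "B", "C"), m, "S1"))
  expect_true(signature_altered(c("A", "B", "C"), m, "S2"))
  v1 <- signature_altered(c("A", "B"), m)
  v2 <- signature_altered(c("A", "B", "C"), m)
  expect_true(all(v2 >= v1))   # adding a gene never flips TRUE -> FALSE
  expect_error(signature_altered("Z", m), "absent")
})
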