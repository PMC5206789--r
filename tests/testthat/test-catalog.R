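# surfaceome_catalog: membership rules, aggregation, benchmark operations

seg <- function(...) {
  v <- c(...)
  if (is.null(v)) return(data.frame(start = integer(), end = integer()))
  m <- matrix(v, ncol = 2L, byrow = TRUE)
  data.frame(start = m[, 1L], end = m[, 2L])
}

test_that("isoform rules R1-R3 fire in fixed order", {
  expect_equal(classify_isoform(300L, NULL)$verdict, "no_tm")
  expect_equal(classify_isoform(300L, seg())$verdict, "no_tm")
  # single TM ending within the first 50 residues -> secreted
  r2 <- classify_isoform(300L, seg(10, 32))
  expect_equal(r2$verdict, "secreted")
  expect_equal(r2$rule, "R2")
  # two TM domains: R2/R3 out of scope -> candidate
  expect_equal(classify_isoform(300L, seg(10, 32, 60, 82))$verdict, "pass")
  # single TM beyond 50 but inside the signal peptide -> secreted via R3
  r3 <- classify_isoform(300L, seg(40, 60), sp_positive = TRUE, cleavage_pos = 65L)
  expect_equal(r3$rule, "R3")
  # TM not within the signal region -> candidate
  expect_equal(classify_isoform(300L, seg(55, 77), sp_positive = TRUE,
                                cleavage_pos = 25L)$verdict, "pass")
  expect_error(classify_isoform(300L, seg(10, 32), sp_positive = FALSE,
                                cleavage_pos = 20L),
               "cleavage_pos present without positive")
  # boundary anchor is configurable
  cfg <- catalog_config(boundary_anchor = "start")
  expect_equal(classify_isoform(300L, seg(45, 70), config = cfg)$verdict,
               "secreted")
  expect_equal(classify_isoform(300L, seg(45, 70))$verdict, "pass")
})

test_that("R1-R3 match the truth-table oracle over boundary geometries", {
  # boundary TM geometries: end = 49/50/51, cleavage_pos = end -/+ 1
  for (end in c(49L, 50L, 51L)) {
    for (n_seg in c(1L, 2L)) {
      for (sp in c(FALSE, TRUE)) {
        cps <- if (sp) c(end - 1L, end + 1L) else NA_integer_
        for (cp in cps) {
          segs <- if (n_seg == 1L) seg(end - 20L, end) else
            seg(end - 20L, end, end + 10L, end + 30L)
          got <- classify_isoform(200L, segs, sp_positive = sp,
                                  cleavage_pos = cp)$verdict
          want <- oracle_isoform_verdict(n_seg, end, sp, cp)
          expect_identical(got, want,
                           info = sprintf("end=%d n_seg=%d sp=%d cp=%s",
                                          end, n_seg, sp, as.character(cp)))
        }
      }
    }
  }
})

test_that("gene aggregation honors the exclusivity predicate", {
  cfg <- catalog_config()
  expect_equal(classify_gene("pass", c("nucleus", "ribosome"))$verdict,
               "internal_compartment")
  expect_equal(classify_gene("pass", c("nucleus", "plasma membrane"))$verdict,
               "surfaceome")
  expect_equal(classify_gene("pass", character())$verdict, "surfaceome")
  # no candidate isoform: most permissive verdict, secreted > no_tm
  expect_equal(classify_gene(c("no_tm", "secreted"))$verdict, "secreted")
  expect_equal(classify_gene(c("no_tm", "no_tm"))$verdict, "no_tm")
  # any-isoform aggregation
  expect_equal(classify_gene(c("secreted", "pass"))$verdict, "surfaceome")
  expect_error(classify_gene(character()), "zero isoforms")
})

test_that("exclusivity predicate equals brute force over all 2^10 subsets", {
  vocab <- default_exclusion_vocabulary()
  toy <- c(vocab[1:7], "plasma membrane", "cell junction", "extracellular")
  for (mask in 0:(2^10 - 1)) {
    comp <- toy[bitwAnd(mask, 2^(0:9)) > 0]
    brute <- length(comp) > 0 && all(comp %in% vocab)
    expect_identical(exclusively_internal(comp, vocab), brute)
  }
})

test_that("R2 monotonicity: adding a second TM never moves away from surface", {
  # gene rejected by R2 (single TM ending <= 50)
  one <- classify_gene(list(classify_isoform(300L, seg(10, 32))))
  expect_equal(one$verdict, "secreted")
  two <- classify_gene(list(classify_isoform(300L, seg(10, 32, 60, 82))))
  expect_equal(two$verdict, "surfaceome")
})

test_that("build_catalog partitions genes, recovers planted truth, handles edges", {
  b <- gen_annotation_bundle(n_genes = 120L, seed = 31)
  cat_obj <- suppressMessages(build_catalog(b$proteins, b$tm, b$signalp, b$go))
  # verdict partition: one verdict per gene, counts sum to gene count
  expect_equal(nrow(cat_obj$decisions), length(unique(b$proteins$gene_id)))
  expect_equal(sum(cat_obj$counts), nrow(cat_obj$decisions))
  # exact truth recovery
  got <- cat_obj$decisions$verdict[match(b$truth$gene_id,
                                         cat_obj$decisions$gene_id)]
  expect_identical(got, b$truth$verdict)

  # empty input -> empty catalog
  empty <- build_catalog(b$proteins[0, ], b$tm[0, ])
  expect_length(empty$catalog, 0L)
  expect_equal(sum(empty$counts), 0L)

  # R2 saturation: every gene a single early TM -> catalog empty, all secreted
  prot <- data.frame(protein_id = c("P1", "P2"), gene_id = c("G1", "G2"),
                     length = c(100L, 100L), sequence = NA, stringsAsFactors = FALSE)
  tm <- data.frame(protein_id = c("P1", "P2"), start = c(10L, 12L),
                   end = c(30L, 34L), stringsAsFactors = FALSE)
  sat <- build_catalog(prot, tm)
  expect_length(sat$catalog, 0L)
  expect_equal(unname(sat$counts["secreted"]), 2L)

  expect_error(build_catalog(prot, tm, genes = c("G1", "G3")), "zero isoforms")
})

test_that("family_coverage and set_overlap compute exact fractions", {
  catalog <- paste0("G", 1:100)
  expect_equal(family_coverage(catalog, paste0("G", 1:10)), 1.0)
  expect_equal(family_coverage(catalog, paste0("X", 1:10)), 0.0)
  fam <- c(paste0("G", 1:44), paste0("X", 1:6))   # 44 of 50 present
  expect_equal(family_coverage(catalog, fam), 0.88)
  expect_error(family_coverage(catalog, character()), "nonempty")

  ext <- c(paste0("G", 1:30), paste0("Y", 1:10))
  ov <- set_overlap(catalog, ext)
  expect_equal(ov$n_intersect, 30L)
  expect_equal(ov$frac_of_external, 0.75)
  expect_equal(ov$frac_of_catalog, 0.30)
  same <- set_overlap(catalog, catalog)
  expect_equal(same$frac_of_external, 1.0)
  expect_equal(same$frac_of_catalog, 1.0)
  expect_error(set_overlap(catalog, character()), "nonempty")
})
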