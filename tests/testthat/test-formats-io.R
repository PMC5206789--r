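# formats_io: parsers, validation, writers, round trips

test_that("parse_fasta reads proteinID|geneID entries and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1|G1", "MKT", ">P2|G1", "MKTAAR"), f)
  rec <- parse_fasta(f)
  expect_equal(rec$protein_id, c("P1", "P2"))
  expect_equal(rec$gene_id, c("G1", "G1"))
  expect_equal(rec$length, c(3L, 6L))
  expect_equal(nchar(rec$sequence), rec$length)

  writeLines(c(">P1|G1", "MKT", ">P1|G2", "MKTA"), f)
  expect_error(parse_fasta(f), "duplicate protein_id")
  writeLines(c(">P1-noseparator", "MKT"), f)
  expect_error(parse_fasta(f), "malformed FASTA header")
  writeLines(c(">P1|G1", "", ">P2|G2", "MK"), f)
  expect_error(parse_fasta(f), "empty sequence")
})

test_that("parse_tm_segments handles both dialects and validates geometry", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # TMHMM long format: only TMhelix topology lines count
  writeLines(c("P1\tTMHMM2.0\tinside\t1\t6",
               "P1\tTMHMM2.0\tTMhelix\t7\t29",
               "P1\tTMHMM2.0\toutside\t30\t100",
               "P1\tTMHMM2.0\tTMhelix\t101\t123"), f)
  tab <- parse_tm_segments(f)
  expect_equal(tab$start, c(7L, 101L))
  expect_equal(tab$end, c(29L, 123L))

  writeLines(c("protein_id\tstart\tend", "P1\t7\t29", "P2\t5\t30"), f)
  tab <- parse_tm_segments(f)
  expect_equal(nrow(tab), 2L)

  writeLines("P1\t5\t3", f)
  expect_error(parse_tm_segments(f), "start > end")
  writeLines(c("P1\t5\t30", "P1\t20\t44"), f)
  expect_error(parse_tm_segments(f), "overlapping")
  writeLines("P1\t5\t30", f)
  expect_error(parse_tm_segments(f, c(P1 = 20L)), "exceeds protein length")
})

test_that("parse_signalp enforces the positive/cleavage contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tYES\t23", "P2\tNO\t-"), f)
  sp <- parse_signalp(f)
  expect_equal(sp$positive, c(TRUE, FALSE))
  expect_equal(sp$cleavage_pos, c(23L, NA_integer_))

  writeLines("P1\tNO\t23", f)
  expect_error(parse_signalp(f), "cleavage_pos present without positive")
  writeLines("P1\tYES\t-", f)
  expect_error(parse_signalp(f), "without cleavage_pos")
  writeLines("P1\tMAYBE\t-", f)
  expect_error(parse_signalp(f), "YES or NO")
})

test_that("parse_maf applies the declared class mapping with 'other' fallback", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "G1\tS1\tNonsense_Mutation",
               "G1\tS2\tFrame_Shift_Del",
               "G2\tS1\tFrame_Shift_Ins",
               "G2\tS2\tSplice_Site",
               "G3\tS1\tMissense_Mutation",
               "G3\tS2\tSilent"), f)
  maf <- parse_maf(f)
  expect_equal(maf$variant_class,
               c("nonsense", "frameshift", "frameshift", "splice_site",
                 "missense", "silent"))

  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "G1\tS1\tTranslation_Start_Site"), f)
  expect_warning(maf <- parse_maf(f), "mapped to 'other'")
  expect_equal(maf$variant_class, "other")

  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode", "G1\tS1"), f)
  expect_error(parse_maf(f), "missing required column")
})

test_that("parse_matrix validates CNA levels and parse_clinical its fields", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "G1\t-2\t2", "G2\t0\t1"), f)
  m <- parse_matrix(f, "cna")
  expect_identical(m["G1", "S2"], 2L)

  writeLines(c("gene_id\tS1", "G1\t3"), f)
  expect_error(parse_matrix(f, "cna"), "\\{-2,-1,0,1,2\\}")

  writeLines(c("sample_id\tos_time_days\tos_event", "S1\t1200\t1", "S2\t300\t0"), f)
  cl <- parse_clinical(f)
  expect_equal(cl$os_event, c(1L, 0L))
  writeLines(c("sample_id\tos_time_days\tos_event", "S1\t-5\t1"), f)
  expect_error(parse_clinical(f), "negative os_time")
})

test_that("every table writer round-trips to an identical in-memory value", {
  d <- withr::local_tempdir()
  set.seed(42)
  bundle <- gen_annotation_bundle(n_genes = 30L, seed = 7)
  write_annotation_bundle(bundle, d)
  prot <- parse_fasta(file.path(d, "proteins.fasta"))
  expect_equal(prot[, c("protein_id", "gene_id", "length", "sequence")],
               bundle$proteins[, c("protein_id", "gene_id", "length", "sequence")],
               ignore_attr = TRUE)
  tm <- parse_tm_segments(file.path(d, "tm.tsv"))
  reord <- bundle$tm[order(bundle$tm$protein_id, bundle$tm$start), ]
  expect_equal(tm, reord, ignore_attr = TRUE)
  sp <- parse_signalp(file.path(d, "signalp.tsv"))
  expect_equal(sp, bundle$signalp, ignore_attr = TRUE)
  go <- parse_go_compartments(file.path(d, "go.tsv"))
  expect_equal(go, unique(bundle$go), ignore_attr = TRUE)

  cohort <- gen_cohort(n_genes = 15L, n_samples = 10L, n_oncogenes = 2L,
                       n_suppressors = 2L, seed = 8)
  write_cohort(cohort, d)
  expect_identical(parse_matrix(file.path(d, "cna.tsv"), "cna"), cohort$cna)
  # doubles written with 17 significant digits reparse exactly
  expect_identical(parse_matrix(file.path(d, "expr.tsv"), "expr"), cohort$expr)
  maf <- parse_maf(file.path(d, "maf.tsv"))
  expect_equal(maf, cohort$maf, ignore_attr = TRUE)

  clin <- gen_survival(cohort$samples, rep(c(TRUE, FALSE), 5), seed = 9)
  write_clinical(clin, file.path(d, "clinical.tsv"))
  expect_identical(parse_clinical(file.path(d, "clinical.tsv")), clin)
})

test_that("sample reconciliation intersects and reports drops", {
  expect_message(
    common <- reconcile_samples(a = c("S1", "S2", "S3"), b = c("S2", "S3", "S4")),
    "dropped 2")
  expect_equal(common, c("S2", "S3"))
})
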