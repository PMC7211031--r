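test_that("read_maf parses the TCGA dialect and round-trips via write_maf", {
  path <- write_toy_maf(toy_maf_rows)
  rec <- read_maf(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$gene, c("BRAF", "BRAF", "TP53"))
  expect_equal(rec$protein_pos, c(600L, 600L, 175L))
  expect_equal(rec$aa_change[1], "V600E")
  expect_equal(rec$consequence, rep("missense", 3))
  expect_equal(attr(rec, "load_report")$rows_skipped, 0L)

  # regex oracle over the p.<AA><pos><AA> pattern
  pc <- c("p.V600E", "p.R175H", "p.*757L", "p.M1?", "")
  expected_pos <- vapply(pc, function(x) {
    m <- regmatches(x, regexec("^p\\.[A-Z*]([0-9]+)", x))[[1L]]
    if (length(m) == 2L) as.integer(m[2L]) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  got <- read_maf(write_toy_maf(lapply(seq_along(pc), function(i)
    c("G", paste0("P", i), "T1", pc[i], "Silent", "chr1", "1", "A", "G", "X"))))
  expect_equal(got$protein_pos, expected_pos)
  expect_true(is.na(got$protein_pos[5]))  # empty protein change kept, pos NA

  # identity round-trip on canonical records
  rt <- tempfile(fileext = ".tsv")
  write_maf(rec, rt)
  rec2 <- read_maf(rt)
  attr(rec, "load_report") <- attr(rec2, "load_report") <- NULL
  expect_equal(rec2, rec)
})

test_that("read_maf errors on missing mandatory columns, skips bad rows", {
  bad <- tempfile()
  writeLines(c("Hugo_Symbol\tVariant_Classification", "BRAF\tSilent"), bad)
  expect_error(read_maf(bad), "patient_id")

  skipfile <- write_toy_maf(c(toy_maf_rows, list(
    c("EGFR", "PT9", "T9", "p.L858R", "Missense_Mutation", "chr7",
      "not_a_number", "T", "G", "LUAD"))))
  expect_warning(rec <- read_maf(skipfile), "unparseable genomic position")
  expect_equal(nrow(rec), 3L)
  expect_equal(attr(rec, "load_report")$rows_skipped, 1L)
})

test_that("filter_coding keeps exactly the positioned subset, idempotently", {
  expect_equal(nrow(filter_coding(read_maf(write_toy_maf(list())))), 0L)

  rows <- list(
    c("G1", "P1", "T", "p.A10V", "Missense_Mutation", "c", "1", "A", "G", "X"),
    c("G1", "P2", "T", "",       "Splice_Site",       "c", "2", "A", "G", "X"),
    c("G2", "P3", "T", "p.R5H",  "Missense_Mutation", "c", "3", "A", "G", "X"),
    c("G2", "P4", "T", "",       "3'UTR",             "c", "4", "A", "G", "X"),
    c("G3", "P5", "T", "p.K9N",  "Missense_Mutation", "c", "5", "A", "G", "X"))
  rec <- read_maf(write_toy_maf(rows))
  cod <- filter_coding(rec)
  expect_equal(cod$patient_id, c("P1", "P3", "P5"))       # order preserved
  expect_identical(filter_coding(cod), cod)               # idempotent
  none <- rec[is.na(rec$protein_pos), ]
  expect_equal(nrow(filter_coding(none)), 0L)
})

test_that("aggregate_positions counts distinct patients and matches a group-by oracle", {
  # same patient twice at one site -> 1
  rec <- data.frame(patient_id = c("P1", "P1"), gene = "G", transcript_id = "T",
                    protein_pos = 10L, aa_change = "A10V",
                    consequence = "missense", chrom = "c", genomic_pos = 1L,
                    ref_allele = "A", alt_allele = "G", cancer_type = "X",
                    stringsAsFactors = FALSE)
  pc <- aggregate_positions(rec)
  expect_equal(unname(pc$G$counts["10"]), 1L)
  expect_equal(unname(aggregate_positions(rec, dedup_patients = FALSE)$G$counts["10"]), 2L)

  # three patients, one position
  rec3 <- rec[c(1, 1, 1), ]; rec3$patient_id <- paste0("P", 1:3)
  expect_equal(unname(aggregate_positions(rec3)$G$counts["10"]), 3L)

  # 1000 simulated records over 2 genes vs brute-force oracle
  set.seed(101)
  big <- data.frame(
    patient_id = sample(sprintf("P%03d", 1:60), 1000, replace = TRUE),
    gene = sample(c("GA", "GB"), 1000, replace = TRUE),
    transcript_id = "T", protein_pos = sample(1:40, 1000, replace = TRUE),
    aa_change = "X", consequence = "missense", chrom = "c",
    genomic_pos = 1L, ref_allele = "A", alt_allele = "G", cancer_type = "X",
    stringsAsFactors = FALSE)
  pcs <- aggregate_positions(big)
  got <- do.call(rbind, lapply(pcs, function(p) data.frame(
    gene = p$gene, protein_pos = as.integer(names(p$counts)),
    n = unname(p$counts), stringsAsFactors = FALSE)))
  rownames(got) <- NULL
  want <- oracle_group_by(big); rownames(want) <- NULL
  expect_equal(got, want)
  # totals bounded by record count
  expect_lte(sum(got$n), nrow(big))
})

test_that("aggregate_positions picks the majority transcript and honors lengths", {
  rec <- data.frame(patient_id = paste0("P", 1:3), gene = "G",
                    transcript_id = c("T1", "T2", "T2"),
                    protein_pos = c(5L, 6L, 7L), aa_change = "X",
                    consequence = "missense", chrom = "c", genomic_pos = 1L,
                    ref_allele = "A", alt_allele = "G", cancer_type = "X",
                    stringsAsFactors = FALSE)
  expect_equal(aggregate_positions(rec)$G$transcript_id, "T2")
  expect_error(aggregate_positions(rec, protein_lengths = c(G = 6L)),
               "beyond protein length")
})

test_that("cohort_summary matches a group-by oracle", {
  expect_equal(nrow(cohort_summary(read_maf(write_toy_maf(list())))), 0L)

  rec <- data.frame(patient_id = c("P1", "P1", "P2", "P2"), gene = "G",
                    transcript_id = "T", protein_pos = 1L, aa_change = "X",
                    consequence = "missense", chrom = "c", genomic_pos = 1L,
                    ref_allele = "A", alt_allele = "G", cancer_type = "LUAD",
                    stringsAsFactors = FALSE)
  cs <- cohort_summary(rec)
  expect_equal(cs, data.frame(cancer_type = "LUAD", n_patients = 2L,
                              n_mutations = 4L, stringsAsFactors = FALSE))

  set.seed(7)
  big <- rec[sample(1:4, 300, replace = TRUE), ]
  big$cancer_type <- sample(c("A", "B", "C"), 300, replace = TRUE)
  big$patient_id <- sample(sprintf("P%02d", 1:20), 300, replace = TRUE)
  cs <- cohort_summary(big)
  for (ct in cs$cancer_type) {
    sub <- big[big$cancer_type == ct, ]
    expect_equal(cs$n_patients[cs$cancer_type == ct], length(unique(sub$patient_id)))
    expect_equal(cs$n_mutations[cs$cancer_type == ct], nrow(sub))
  }
})

test_that("classify_consequence maps the MAF dialect and excludes the rest", {
  expect_equal(classify_consequence(c("Missense_Mutation", "Silent",
                                      "Nonsense_Mutation", "Frame_Shift_Del",
                                      "3'UTR", "IGR")),
               c("missense", "silent", "nonsense", "frameshift",
                 "other", "other"))
})
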