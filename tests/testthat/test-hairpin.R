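test_that("extract_context windows, pads, and round-trips the centre base", {
  ref <- c(c1 = "ACGTACGTACGT")
  # pos 6 (1-based) window 2 -> "TACGT"? manual substring: positions 4..8
  expect_equal(extract_context(ref, "c1", 6, window = 2),
               substr("ACGTACGTACGT", 4, 8))
  expect_equal(extract_context(ref, "c1", 6, window = 2), "TACGT")
  # padding at the contig edge
  expect_warning(ctx <- extract_context(ref, "c1", 1, window = 3), "padded")
  expect_equal(ctx, "NNNACGT")
  expect_error(extract_context(ref, "c9", 1), "unknown contig")
  # centre always equals the base at pos
  set.seed(21)
  for (pos in sample(1:12, 6)) {
    ctx <- suppressWarnings(extract_context(ref, "c1", pos, window = 4))
    expect_equal(substr(ctx, 5, 5), substr(ref[["c1"]], pos, pos))
  }
})

test_that("extract_context reads FASTA files via Biostrings", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrT some description", "ACGTACGTAC"), fa)
  expect_equal(extract_context(fa, "chrT", 5, window = 2), "GTACG")
})

test_that("orient_sequence flips G/T centres and is idempotent", {
  expect_equal(orient_sequence("ACA"), list(context = "ACA",
                                            strand_flipped = FALSE))
  flipped <- orient_sequence("AGA")   # centre G -> reverse complement
  expect_equal(flipped, list(context = "TCT", strand_flipped = TRUE))
  # after flipping the centre is C or A; double orientation is identity
  again <- orient_sequence(flipped$context)
  expect_false(again$strand_flipped)
  expect_equal(again$context, flipped$context)
})

test_that("stem_strength scores contiguous pairs by 3xGC + 1xAT", {
  # context: loop AAC (centre C at loop position 3), stem G:C, G:C then mismatch
  s1 <- make_hairpin_sequence(3, 3, c("GC", "GC"), flank_len = 5)
  ctx <- s1$sequence
  # centre the context on the mutated base for the scorer
  w <- min(s1$center_index - 1, nchar(ctx) - s1$center_index)
  ctx <- substr(ctx, s1$center_index - w, s1$center_index + w)
  expect_equal(stem_strength(ctx, 3, 3), 6L)

  # (G:C, A:T, G:C) then edge -> 7
  s2 <- make_hairpin_sequence(3, 3, c("GC", "AT", "GC"), flank_len = 4)
  w <- min(s2$center_index - 1, nchar(s2$sequence) - s2$center_index)
  ctx2 <- substr(s2$sequence, s2$center_index - w, s2$center_index + w)
  expect_equal(stem_strength(ctx2, 3, 3), 7L)

  expect_error(stem_strength("ACGTACG", 11, 3), "exceeds")

  # 200 random contexts vs the independent pairing oracle
  set.seed(31)
  for (rep in 1:200) {
    ctx <- random_context(25)
    len <- sample(3:11, 1); pos <- sample(1:len, 1)
    got <- tryCatch(stem_strength(ctx, len, pos), error = function(e) NA)
    if (is.na(got)) next
    expect_equal(got, oracle_stem(ctx, len, pos))
  }
})

test_that("best_hairpin equals exhaustive enumeration and breaks ties low", {
  # designed unique 4-loop hairpin
  s <- make_hairpin_sequence(4, 3, c("GC", "GC", "AT", "GC"))
  ori <- orient_sequence(substr(s$sequence, s$center_index - 20,
                                s$center_index + 20))
  best <- best_hairpin(ori$context)
  expect_equal(best$loop_length, 4L)
  expect_equal(best$loop_position, 3L)
  expect_equal(best$stem_strength, s$expected_ss)

  # all-N flanks: every config scores 0, tie-break picks (3, 1)
  ctx <- paste0(strrep("N", 12), "C", strrep("N", 12))
  best0 <- best_hairpin(ctx)
  expect_equal(best0[c("loop_length", "loop_position", "stem_strength")],
               list(loop_length = 3L, loop_position = 1L, stem_strength = 0L))

  # agreement with brute-force enumeration on random contexts
  set.seed(41)
  for (rep in 1:300) {
    ctx <- random_context(51)
    got <- best_hairpin(ctx)
    want <- oracle_best_hairpin(ctx)
    expect_equal(got$stem_strength, want$stem_strength)
    expect_equal(got$loop_length, want$loop_length)
    expect_equal(got$loop_position, want$loop_position)
  }
})

test_that("classify_hairpin follows the nine-combination threshold table", {
  mk <- function(len, pos, ss) list(loop_length = len, loop_position = pos,
                                    stem_strength = ss)
  expect_equal(classify_hairpin(mk(3, 3, 7)), "Likely")
  expect_equal(classify_hairpin(mk(3, 3, 6)), "Unlikely")
  expect_equal(classify_hairpin(mk(3, 1, 30)), "No")
  # full table sweep: at threshold -> Likely, below -> Unlikely
  tab <- hairpin_thresholds()
  for (j in seq_len(nrow(tab))) {
    expect_equal(classify_hairpin(mk(tab$loop_length[j], tab$loop_position[j],
                                     tab$min_ss[j])), "Likely")
    expect_equal(classify_hairpin(mk(tab$loop_length[j], tab$loop_position[j],
                                     tab$min_ss[j] - 1L)), "Unlikely")
  }
  # monotonicity: increasing ss never demotes Likely
  for (ss in 0:40) {
    lab <- classify_hairpin(mk(6, 5, ss))
    expect_equal(lab, if (ss >= 14) "Likely" else "Unlikely")
  }
})

test_that("annotate_mutation composes the full chain with strand symmetry", {
  # strong designed hairpin (3:3, ss 9) placed inside a contig
  s <- make_hairpin_sequence(3, 3, c("GC", "GC", "GC"), flank_len = 30)
  ref <- c(chrH = s$sequence)
  rec <- list(chrom = "chrH", genomic_pos = s$center_index, ref_allele = "C")
  ann <- annotate_mutation(ref, rec)
  expect_equal(ann$label, "Likely")
  expect_equal(ann$best$stem_strength, 9L)
  expect_false(ann$strand_flipped)

  # no complementary flanks: ss 0 -> No or Unlikely
  ref2 <- c(chrF = strrep("A", 30))
  ann2 <- suppressWarnings(
    annotate_mutation(ref2, list(chrom = "chrF", genomic_pos = 15)))
  expect_equal(ann2$best$stem_strength, 0L)
  expect_true(ann2$label %in% c("No", "Unlikely"))

  # G-reference variant: flipped, same result as annotating the revcomp
  refG <- c(chrG = revcomp_str(s$sequence))
  posG <- nchar(s$sequence) - s$center_index + 1L
  annG <- annotate_mutation(refG, list(chrom = "chrG", genomic_pos = posG))
  expect_true(annG$strand_flipped)
  expect_equal(annG$label, ann$label)
  expect_equal(annG$best, ann$best)

  # N at the mutated base -> No with warning
  refN <- c(chrN = paste0(strrep("A", 30), "N", strrep("A", 30)))
  expect_warning(annN <- annotate_mutation(refN, list(chrom = "chrN",
                                                      genomic_pos = 31)),
                 "not possible")
  expect_equal(annN$label, "No")
})

test_that("strand symmetry holds for random contexts (property)", {
  set.seed(51)
  for (rep in 1:50) {
    ctx <- random_context(51)
    o1 <- orient_sequence(ctx)
    o2 <- orient_sequence(revcomp_str(ctx))
    b1 <- best_hairpin(o1$context)
    b2 <- best_hairpin(o2$context)
    expect_equal(b1, b2)
    expect_equal(classify_hairpin(b1), classify_hairpin(b2))
  }
})
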