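# shared fixtures and independent oracles for the test suite

# write a small TCGA-dialect MAF to a temp file, return the path
write_toy_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  header <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Transcript_ID",
              "Protein_Change", "Variant_Classification", "Chromosome",
              "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
              "Cancer_Type")
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

toy_maf_rows <- list(
  c("BRAF", "PT1", "ENST0001", "p.V600E", "Missense_Mutation",
    "chr7", "140453136", "A", "T", "SKCM"),
  c("BRAF", "PT2", "ENST0001", "p.V600E", "Missense_Mutation",
    "chr7", "140453136", "A", "T", "THCA"),
  c("TP53", "PT1", "ENST0002", "p.R175H", "Missense_Mutation",
    "chr17", "7578406", "G", "A", "SKCM")
)

# independent group-by oracle: count distinct patients per (gene, pos)
# with plain environments and loops (no tapply/split)
oracle_group_by <- function(records) {
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(records))) {
    key <- paste(records$gene[r], records$protein_pos[r], sep = "\r")
    pats <- if (is.null(seen[[key]])) character(0) else seen[[key]]
    seen[[key]] <- union(pats, records$patient_id[r])
  }
  keys <- ls(seen)
  out <- data.frame(
    gene = sub("\r.*", "", keys),
    protein_pos = as.integer(sub(".*\r", "", keys)),
    n = vapply(keys, function(k) length(seen[[k]]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$gene, out$protein_pos), , drop = FALSE]
}

# direct Beta-function-ratio pmf oracle (linear space, n <= 50)
oracle_bb_pmf <- function(i, n, a, b) {
  choose(n, i) * beta(i + a, n - i + b) / beta(a, b)
}

# independent stem-strength oracle: vectorized arm comparison + cumprod
oracle_stem <- function(context, loop_length, loop_position, max_stem = 10L) {
  b <- strsplit(context, "")[[1L]]
  centre <- (length(b) + 1L) %/% 2L
  ls <- centre - loop_position + 1L
  le <- ls + loop_length - 1L
  left <- rev(b[seq_len(ls - 1L)])
  right <- b[seq(le + 1L, length(b))]
  m <- min(length(left), length(right), max_stem)
  if (m == 0L) return(0L)
  l <- left[1:m]; r <- right[1:m]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  ok <- comp[l] == r & l %in% c("A", "C", "G", "T")
  run <- cumprod(ok) == 1
  sum(ifelse(l %in% c("G", "C"), 3L, 1L)[run])
}

# exhaustive best-hairpin oracle over all 63 configurations
oracle_best_hairpin <- function(context, max_stem = 10L) {
  best <- NULL
  for (len in 3:11) for (pos in 1:len) {
    centre <- (nchar(context) + 1L) %/% 2L
    ls <- centre - pos + 1L
    if (ls < 1L || ls + len - 1L > nchar(context)) next
    ss <- oracle_stem(context, len, pos, max_stem)
    if (is.null(best) || ss > best$stem_strength)
      best <- list(loop_length = len, loop_position = pos, stem_strength = ss)
  }
  best
}

random_context <- function(n = 51L) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# canonical spiked-cohort spec used in several tests
spiked_spec <- function(seed, n_sites = 5000L, n_spikes = 5L,
                        spike_rec = 25L) {
  genes <- data.frame(name = "G1", protein_length = n_sites,
                      a = 0.05, b = 400)
  spikes <- data.frame(gene = "G1",
                       position = seq(10L, by = 10L, length.out = n_spikes),
                       recurrence = spike_rec)
  sim_spec(500L, genes, spikes, seed = seed)
}
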