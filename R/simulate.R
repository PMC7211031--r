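#' Synthetic cohort and fixture generators
#'
#' Deterministic (seeded) generators used to test every stage of the
#' pipeline without external data: beta-binomial mutation cohorts with
#' spiked hotspots, designed hairpin sequences with known stem strength,
#' and neutral mutation sets for dN/dS calibration.
#'
#' @name synthetic
NULL

#' Specify a synthetic cohort
#'
#' @param n_patients cohort size.
#' @param genes data.frame with columns `name`, `protein_length`, `a`, `b`
#'   (per-gene beta-binomial background).
#' @param spikes optional data.frame with columns `gene`, `position`,
#'   `recurrence`: sites whose recurrence is forced to the stated value.
#' @param seed integer seed making the cohort reproducible.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_patients, genes, spikes = NULL, seed = 1L) {
  stopifnot(is.data.frame(genes),
            all(c("name", "protein_length", "a", "b") %in% names(genes)))
  if (is.null(spikes))
    spikes <- data.frame(gene = character(), position = integer(),
                         recurrence = integer(), stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "position", "recurrence") %in% names(spikes)))
  if (any(spikes$recurrence > n_patients))
    stop("spike recurrence exceeds n_patients")
  for (j in seq_len(nrow(spikes))) {
    g <- match(spikes$gene[j], genes$name)
    if (is.na(g)) stop("spike in unknown gene: ", spikes$gene[j])
    if (spikes$position[j] > genes$protein_length[g])
      stop("spike position beyond protein length in ", spikes$gene[j])
  }
  structure(list(n_patients = as.integer(n_patients), genes = genes,
                 spikes = spikes, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a mutation cohort with spiked hotspots
#'
#' Each gene's per-site patient count is drawn from
#' `BetaBin(n_patients, a, b)` (a Beta(a, b) site-level mutation
#' probability, then a binomial over patients); spiked sites are overridden
#' to their stated recurrence. Counts are then expanded into canonical
#' mutation records by sampling that many distinct patients per site.
#' Deterministic under the spec's seed.
#'
#' @param spec a [sim_spec()].
#' @return list with `records` (canonical mutation record data.frame),
#'   `truth` (the spike table), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  patients <- sprintf("P%04d", seq_len(spec$n_patients))
  rows <- list()
  offset <- 0L
  for (g in seq_len(nrow(spec$genes))) {
    gene <- spec$genes$name[g]
    L <- spec$genes$protein_length[g]
    a <- spec$genes$a[g]; b <- spec$genes$b[g]
    counts <- if (a <= 0) integer(L) else {
      p <- stats::rbeta(L, a, b)
      stats::rbinom(L, spec$n_patients, p)
    }
    sp <- spec$spikes[spec$spikes$gene == gene, , drop = FALSE]
    counts[sp$position] <- sp$recurrence
    mutated <- which(counts > 0L)
    for (pos in mutated) {
      who <- sample(patients, counts[pos])
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = who,
        gene = gene,
        transcript_id = paste0("TX_", gene),
        protein_pos = pos,
        aa_change = paste0("A", pos, "V"),
        consequence = "missense",
        chrom = "chrS",
        genomic_pos = offset + 3L * pos,
        ref_allele = "C",
        alt_allele = "T",
        cancer_type = "SIM",
        stringsAsFactors = FALSE
      )
    }
    offset <- offset + 3L * L + 100L
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      data.frame(matrix(character(), ncol = 11), stringsAsFactors = FALSE),
      .maf_canonical_cols)
  list(records = records, truth = spec$spikes, spec = spec)
}

#' Build a sequence containing a designed hairpin
#'
#' Constructs an oriented context whose best hairpin configuration is, by
#' construction, the requested one: a loop of `loop_length` filler bases
#' with a `C` (the "mutated" base) at `loop_position`, flanked by the
#' requested stem pairs, inside non-pairing homopolymer flanks that cannot
#' extend or out-compete the designed stem.
#'
#' @param loop_length loop size (3..11).
#' @param loop_position 1-based position of the mutated base in the loop.
#' @param stem_pairs character vector over `"GC"`/`"AT"`, innermost pair
#'   first; the expected stem strength is `3 * #GC + 1 * #AT`.
#' @param flank_len filler bases added on each side beyond the stem.
#' @param flank_base filler base (must not pair with itself).
#' @return list with `sequence`, `center_index` (position of the mutated
#'   base), `expected_ss`.
#' @export
make_hairpin_sequence <- function(loop_length, loop_position, stem_pairs,
                                  flank_len = 15L, flank_base = "A") {
  stopifnot(loop_length >= 3L, loop_length <= 11L,
            loop_position >= 1L, loop_position <= loop_length,
            length(stem_pairs) >= 1L, all(stem_pairs %in% c("GC", "AT")))
  left_inner_first <- ifelse(stem_pairs == "GC", "G", "A")
  right_inner_first <- ifelse(stem_pairs == "GC", "C", "T")
  # loop filler must not pair with either arm, or a shifted loop could tie
  # the designed configuration and win the smaller-loop tie-break: "A" is
  # safe against G/C arms, "G" against the A/T arms of a pure A:T stem
  loop_fill <- if (all(stem_pairs == "AT")) "G" else "A"
  loop <- rep(loop_fill, loop_length)
  loop[loop_position] <- "C"
  seqv <- c(rep(flank_base, flank_len),
            rev(left_inner_first),
            loop,
            right_inner_first,
            rep(flank_base, flank_len))
  center_index <- flank_len + length(stem_pairs) + loop_position
  list(sequence = paste(seqv, collapse = ""),
       center_index = center_index,
       expected_ss = sum(ifelse(stem_pairs == "GC", 3L, 1L)))
}

#' Simulate a neutrally evolving gene for dN/dS calibration
#'
#' Draws `n_mutations` mutation classes from the gene's opportunity
#' fractions (the neutral expectation), so every `w` has expectation 1.
#'
#' @param opp an `opportunity_counts`.
#' @param n_mutations total number of SNV mutations to draw.
#' @param seed integer seed.
#' @return named count vector over `silent`, `missense`, `nonsense`.
#' @export
simulate_neutral_gene <- function(opp, n_mutations, seed = 1L) {
  set.seed(seed)
  pr <- c(silent = opp$silent, missense = opp$missense,
          nonsense = opp$nonsense)
  draws <- sample(names(pr), n_mutations, replace = TRUE, prob = pr)
  c(silent = sum(draws == "silent"),
    missense = sum(draws == "missense"),
    nonsense = sum(draws == "nonsense"))
}

#' Generate a random coding sequence
#'
#' Random codons avoiding internal stops, with ATG start and TGA stop.
#'
#' @param n_codons total codon count including start and stop.
#' @param seed integer seed.
#' @return character CDS of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed = 1L) {
  stopifnot(n_codons >= 3L)
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         "TGA")
}
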