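#' APOBEC3A hairpin stem-strength annotation
#'
#' APOBEC3A deaminates cytosines exposed in the single-stranded loop of DNA
#' hairpins formed transiently during replication, generating recurrent
#' *passenger* mutations at positions with no selective advantage. These
#' functions score the hairpin-forming potential of a mutated site's
#' genomic context and label it Likely / Unlikely / No as an APOBEC3A
#' artifact.
#'
#' @name hairpin
NULL

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1L]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

#' Threshold table for the Likely label
#'
#' The nine loop position : loop length combinations amenable to APOBEC3A,
#' with the minimum stem strength at which a site is labelled "Likely".
#'
#' @return data.frame with columns `loop_position`, `loop_length`, `min_ss`.
#' @export
hairpin_thresholds <- function() {
  data.frame(
    loop_position = c(3L, 3L, 4L, 4L, 4L, 5L, 4L, 5L, 6L),
    loop_length   = c(3L, 4L, 4L, 5L, 6L, 6L, 7L, 7L, 8L),
    min_ss        = c(7L, 12L, 11L, 12L, 15L, 14L, 18L, 15L, 16L)
  )
}

#' Extract the sequence context around a genomic position
#'
#' Returns `2 * window + 1` uppercase bases centred on the mutated base,
#' padding with `N` where the window runs off the contig.
#'
#' @param reference a named [Biostrings::DNAStringSet], a named character
#'   vector of contig sequences, or a path to a FASTA file.
#' @param chrom contig name.
#' @param genomic_pos 1-based position of the mutated base.
#' @param window bases to keep on each side.
#' @return character scalar of length `2 * window + 1`, centre at index
#'   `window + 1`.
#' @export
extract_context <- function(reference, chrom, genomic_pos, window = 25L) {
  seqs <- .as_reference(reference)
  if (!chrom %in% names(seqs)) stop("unknown contig: ", chrom)
  s <- seqs[[chrom]]
  len <- nchar(s)
  if (genomic_pos < 1L || genomic_pos > len)
    stop("position ", genomic_pos, " outside contig ", chrom, " (length ", len, ")")
  from <- genomic_pos - window
  to <- genomic_pos + window
  left_pad <- max(0L, 1L - from)
  right_pad <- max(0L, to - len)
  core <- substr(s, max(1L, from), min(len, to))
  if (left_pad > 0L || right_pad > 0L)
    warning("context window extends past contig ", chrom, "; padded with N")
  paste0(strrep("N", left_pad), toupper(core), strrep("N", right_pad))
}

# normalize the various reference representations to a named character vector
.as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (inherits(reference, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(reference))
    reference <- stats::setNames(as.character(reference), nm)
  }
  if (!is.character(reference) || is.null(names(reference)))
    stop("'reference' must be a FASTA path, DNAStringSet, or named character vector")
  reference
}

#' Orient a context for hairpin scoring
#'
#' APOBEC3A acts on cytosine (and the scoring convention also covers A), so
#' when the mutated base on the reference strand is G or T the reverse
#' complement of the context is scored instead.
#'
#' @param context odd-length context string with the mutated base at the
#'   centre.
#' @return list with `context` (possibly reverse-complemented) and
#'   `strand_flipped`.
#' @export
orient_sequence <- function(context) {
  n <- nchar(context)
  if (n %% 2L != 1L) stop("context must have odd length")
  centre <- substr(context, (n + 1L) %/% 2L, (n + 1L) %/% 2L)
  if (centre %in% c("G", "T")) {
    list(context = .revcomp(context), strand_flipped = TRUE)
  } else {
    list(context = context, strand_flipped = FALSE)
  }
}

#' Stem strength of one loop configuration
#'
#' Places a loop of `loop_length` bases over the context so that the centre
#' (mutated) base sits at `loop_position` within the loop, then pairs the
#' flanking arms outward from the loop: the base immediately 5' of the loop
#' with the base immediately 3' of it, and so on. Contiguous Watson-Crick
#' pairs score 3 (G:C) or 1 (A:T); pairing stops at the first mismatch, at
#' an N, at a context edge, or after `max_stem` pairs. `ss = 3*GC + 1*AT`.
#'
#' @param context oriented odd-length context string.
#' @param loop_length loop size in bases (3..11 in the standard scan).
#' @param loop_position 1-based position of the mutated base in the loop.
#' @param max_stem maximum number of stem pairs scored.
#' @return integer stem strength (>= 0).
#' @export
stem_strength <- function(context, loop_length, loop_position, max_stem = 10L) {
  n <- nchar(context)
  if (n %% 2L != 1L) stop("context must have odd length")
  stopifnot(loop_position >= 1L, loop_position <= loop_length)
  centre <- (n + 1L) %/% 2L
  loop_start <- centre - loop_position + 1L
  loop_end <- loop_start + loop_length - 1L
  if (loop_start < 1L || loop_end > n)
    stop("loop (", loop_length, ",", loop_position, ") exceeds the context")
  bases <- strsplit(context, "")[[1L]]
  score <- 0L
  for (j in seq_len(max_stem)) {
    l <- loop_start - j
    r <- loop_end + j
    if (l < 1L || r > n) break
    pair <- paste0(bases[l], bases[r])
    if (pair %in% c("GC", "CG")) score <- score + 3L
    else if (pair %in% c("AT", "TA")) score <- score + 1L
    else break
  }
  score
}

#' Best hairpin configuration for an oriented context
#'
#' Scans all loop lengths 3..11 crossed with all loop positions 1..length
#' (63 configurations) and returns the maximum stem strength; ties are
#' broken by the smaller loop length, then the smaller loop position.
#'
#' @inheritParams stem_strength
#' @param loop_lengths loop sizes to scan.
#' @return a `hairpin_config`: list with `loop_length`, `loop_position`,
#'   `stem_strength`.
#' @export
best_hairpin <- function(context, loop_lengths = 3:11, max_stem = 10L) {
  best <- NULL
  for (len in loop_lengths) {
    for (pos in seq_len(len)) {
      ss <- tryCatch(stem_strength(context, len, pos, max_stem = max_stem),
                     error = function(e) NA_integer_)
      if (is.na(ss)) next
      if (is.null(best) || ss > best$stem_strength)
        best <- list(loop_length = len, loop_position = pos, stem_strength = ss)
    }
  }
  if (is.null(best)) stop("no loop configuration fits inside the context")
  structure(best, class = "hairpin_config")
}

#' Label a hairpin configuration Likely / Unlikely / No
#'
#' Pure function of (loop position, loop length, stem strength) against the
#' nine-combination threshold table; deliberately independent of the
#' surrounding sequence context. "Likely": the combination is amenable to
#' APOBEC3A and the stem strength reaches its threshold. "Unlikely": the
#' combination is amenable but the stem is too weak. "No": the combination
#' is not an APOBEC3A target geometry at all.
#'
#' @param config a `hairpin_config` (or list with the same fields).
#' @param table threshold table, by default [hairpin_thresholds()].
#' @return `"Likely"`, `"Unlikely"` or `"No"`.
#' @export
classify_hairpin <- function(config, table = hairpin_thresholds()) {
  hit <- table$loop_position == config$loop_position &
    table$loop_length == config$loop_length
  if (!any(hit)) return("No")
  if (config$stem_strength >= table$min_ss[hit][1L]) "Likely" else "Unlikely"
}

#' Annotate one mutation for APOBEC3A hairpin potential
#'
#' Composition: extract the context, orient it (reverse complement when the
#' reference base is G or T), find the best hairpin configuration, and
#' classify it. An `N` at the mutated position yields label `"No"` with a
#' warning.
#'
#' @param reference see [extract_context()].
#' @param record a canonical mutation record (one row with `chrom`,
#'   `genomic_pos`), or any list with those fields.
#' @param table threshold table.
#' @param window context half-width.
#' @param max_stem maximum stem pairs scored.
#' @return a `hairpin_annotation`: list with `best` (`hairpin_config` or
#'   `NULL`), `label`, `strand_flipped`, `context` (oriented).
#' @export
annotate_mutation <- function(reference, record, table = hairpin_thresholds(),
                              window = 25L, max_stem = 10L) {
  ctx <- extract_context(reference, record$chrom, record$genomic_pos,
                         window = window)
  centre <- substr(ctx, window + 1L, window + 1L)
  if (!centre %in% c("A", "C", "G", "T")) {
    warning("mutated base is '", centre, "': hairpin annotation not possible")
    return(structure(list(best = NULL, label = "No", strand_flipped = NA,
                          context = ctx), class = "hairpin_annotation"))
  }
  ori <- orient_sequence(ctx)
  best <- best_hairpin(ori$context, max_stem = max_stem)
  structure(list(best = best, label = classify_hairpin(best, table),
                 strand_flipped = ori$strand_flipped, context = ori$context),
            class = "hairpin_annotation")
}

#' @export
print.hairpin_annotation <- function(x, ...) {
  cat("APOBEC3A hairpin annotation:", x$label, "\n")
  if (!is.null(x$best))
    cat(sprintf("  loop length %d, loop position %d, stem strength %d%s\n",
                x$best$loop_length, x$best$loop_position,
                x$best$stem_strength,
                if (isTRUE(x$strand_flipped)) " (reverse strand)" else ""))
  invisible(x)
}
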