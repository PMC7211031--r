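#' Simplified gene-level dN/dS annotation
#'
#' A counting estimator of selection pressure: the ratio of observed
#' non-silent mutations of each class (missense, nonsense, splice, indel)
#' to the number expected under neutrality, where the neutral expectation
#' is anchored on the observed silent count and the gene's mutational
#' opportunity derived from its coding sequence. `w = 1` is neutrality,
#' `w > 1` an excess (positive selection or a mutational artifact),
#' `w < 1` depletion. This is deliberately a simplified estimator: no
#' covariate regression and a context-free substitution model by default.
#'
#' @name dnds
NULL

# unordered base-pair keys for the 6-parameter substitution model
.pair_key <- function(x, y) {
  paste0(pmin(x, y), pmax(x, y))
}

#' Mutational opportunity of a coding sequence
#'
#' Enumerates all `3 * L` possible single-nucleotide changes of the CDS,
#' classifies each against the standard genetic code, and weights it by the
#' substitution model, returning the normalized fractions of changes that
#' are silent, missense, or nonsense. Stop-gain changes are nonsense;
#' stop-loss changes count as missense (non-synonymous but not truncating);
#' the three fractions sum to 1.
#'
#' @param cds coding sequence (character or DNAString), length divisible
#'   by 3.
#' @param rates optional named vector of relative rates for the six
#'   unordered base pairs (`AC`, `AG`, `AT`, `CG`, `CT`, `GT`); default
#'   uniform.
#' @param splice_opportunity optional scalar opportunity for splice-site
#'   changes relative to the SNV opportunity space (e.g. from counting
#'   2 essential sites per intron boundary); `NA` if unknown.
#' @param indel_rate optional per-base indel opportunity rate; the indel
#'   opportunity is `indel_rate * nchar(cds)`; `NA` if unknown.
#' @return an `opportunity_counts`: list with fractions `silent`,
#'   `missense`, `nonsense`, plus `splice`, `indel` scalars (possibly
#'   `NA`) and `n_changes`.
#' @export
opportunities_from_cds <- function(cds, rates = NULL,
                                   splice_opportunity = NA_real_,
                                   indel_rate = NA_real_) {
  cds <- toupper(as.character(cds))
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (L == 0L) stop("empty CDS")
  bases <- c("A", "C", "G", "T")
  seqv <- strsplit(cds, "")[[1L]]
  if (!all(seqv %in% bases)) stop("CDS must contain only A/C/G/T")
  if (is.null(rates)) {
    rates <- stats::setNames(rep(1, 6),
                             c("AC", "AG", "AT", "CG", "CT", "GT"))
  }
  code <- Biostrings::GENETIC_CODE
  w <- c(silent = 0, missense = 0, nonsense = 0)
  n_changes <- 0L
  for (p in seq_len(L)) {
    cstart <- p - (p - 1L) %% 3L
    codon <- substr(cds, cstart, cstart + 2L)
    aa <- code[[codon]]
    off <- p - cstart + 1L
    for (alt in setdiff(bases, seqv[p])) {
      mut <- codon
      substr(mut, off, off) <- alt
      aa2 <- code[[mut]]
      cls <- if (aa2 == aa) "silent"
      else if (aa2 == "*" && aa != "*") "nonsense"
      else "missense"   # includes stop-loss
      w[cls] <- w[cls] + rates[[.pair_key(seqv[p], alt)]]
      n_changes <- n_changes + 1L
    }
  }
  fr <- w / sum(w)
  structure(list(silent = fr[["silent"]], missense = fr[["missense"]],
                 nonsense = fr[["nonsense"]],
                 splice = splice_opportunity,
                 indel = if (is.na(indel_rate)) NA_real_ else indel_rate * L,
                 n_changes = n_changes),
            class = "opportunity_counts")
}

#' Estimate gene-level dN/dS ratios
#'
#' For each non-silent class X, `wX = observed_X / expected_X` with
#' `expected_X = observed_silent * (opportunity_X / opportunity_silent)`.
#' P-values come from a one-sided Poisson test of the observed count
#' against its expectation, in the direction of the departure (upper tail
#' for an excess, lower tail for a deficit). The headline summary is
#' `w_summary = max(wmis, wnon)`.
#'
#' @param mutations either a canonical mutation record data.frame (its
#'   `consequence` column is tallied) or a named count vector with any of
#'   `silent`, `missense`, `nonsense`, `splice`, `indel` (frameshift +
#'   in-frame indels).
#' @param opp an `opportunity_counts` for the gene.
#' @param pseudocount added to a zero silent count (flagged in the result).
#' @return a `dnds_estimate`: list with `wmis`, `wnon`, `wspl`, `wind`,
#'   `p_mis`, `p_non`, `p_spl`, `p_ind`, `w_summary`, `counts`,
#'   `silent_pseudocount`.
#' @export
estimate_dnds <- function(mutations, opp, pseudocount = 0.5) {
  if (is.data.frame(mutations)) {
    cons <- mutations$consequence
    counts <- c(
      silent   = sum(cons == "silent"),
      missense = sum(cons %in% c("missense", "nonstop")),
      nonsense = sum(cons == "nonsense"),
      splice   = sum(cons == "splice"),
      indel    = sum(cons %in% c("frameshift", "inframe_indel"))
    )
  } else {
    counts <- c(silent = 0, missense = 0, nonsense = 0, splice = 0, indel = 0)
    counts[names(mutations)] <- mutations
  }
  n_sil <- counts[["silent"]]
  used_pseudo <- n_sil == 0
  if (used_pseudo) n_sil <- pseudocount

  one <- function(obs, opp_x) {
    if (is.na(opp_x) || opp_x <= 0 || opp$silent <= 0)
      return(c(w = NA_real_, p = NA_real_))
    expected <- n_sil * opp_x / opp$silent
    w <- obs / expected
    p <- if (obs >= expected) {
      stats::ppois(obs - 1, lambda = expected, lower.tail = FALSE)
    } else {
      stats::ppois(obs, lambda = expected)
    }
    c(w = w, p = p)
  }
  mis <- one(counts[["missense"]], opp$missense)
  non <- one(counts[["nonsense"]], opp$nonsense)
  spl <- one(counts[["splice"]], opp$splice)
  ind <- one(counts[["indel"]], opp$indel)
  structure(
    list(wmis = mis[["w"]], wnon = non[["w"]], wspl = spl[["w"]],
         wind = ind[["w"]], p_mis = mis[["p"]], p_non = non[["p"]],
         p_spl = spl[["p"]], p_ind = ind[["p"]],
         w_summary = max(mis[["w"]], non[["w"]], na.rm = TRUE),
         counts = counts, silent_pseudocount = used_pseudo),
    class = "dnds_estimate"
  )
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("dN/dS: wmis = %.3g  wnon = %.3g  wspl = %s  wind = %s\n",
              x$wmis, x$wnon,
              ifelse(is.na(x$wspl), "NA", sprintf("%.3g", x$wspl)),
              ifelse(is.na(x$wind), "NA", sprintf("%.3g", x$wind))))
  cat(sprintf("  summary max(wmis, wnon) = %.3g%s\n", x$w_summary,
              if (x$silent_pseudocount) "  [silent pseudocount]" else ""))
  invisible(x)
}
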