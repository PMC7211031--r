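#' Stepwise fixed-effect estimation over a recurrence histogram
#'
#' Decomposes the observed histogram as `h_i = BetaBin(a, b)_i + F_i`: a
#' beta-binomial background plus a non-negative fixed-effect vector `F`
#' absorbing the sites (hotspots) the background cannot explain.
#'
#' At each step a candidate grid is scanned: for every non-empty bin
#' `i >= 1` and every fraction `f` in `frac_grid`, `round(f * h_i)` sites
#' (at least 1) are removed from bin `i`, the background is refit on the
#' reduced histogram (warm-started from the current fit), and the fit
#' divergence is scored. The best cell — lowest divergence, ties broken by
#' smaller `i` then smaller `f` — is committed and its removed count added
#' to `F_i`. Iteration stops when the count-scaled divergence drops below
#' `kl_stop`, when no candidate improves it, or after `max_steps` steps.
#'
#' The stopping rule compares `kl_stop` against the *count-scaled*
#' divergence `n_sites * KL(normalized h || model)` (twice this quantity is
#' the likelihood-ratio G-statistic, asymptotically chi-squared), so "below
#' 1" means the histogram is statistically indistinguishable from the
#' background; on the plain normalized divergence a handful of spiked sites
#' among thousands would be invisible. See the methods vignette.
#'
#' @param hist a `position_histogram`.
#' @param frac_grid fractions of a bin to try removing at each step.
#' @param kl_stop stop once the scaled divergence is below this value.
#' @param max_steps step cap; defaults to `3 * k` histogram bins.
#' @param objective fit objective passed to [fit_betabinomial()].
#' @return list with `fit` (the [fit_betabinomial()] result on the final
#'   reduced histogram), `F` (numeric, bins `0..k`), `reduced` (the reduced
#'   histogram bin counts), `kl_path` (scaled divergence after each commit,
#'   starting with the initial fit), `n_steps`.
#' @export
stepwise_fixed_effects <- function(hist, frac_grid = seq(0.1, 1, by = 0.1),
                                   kl_stop = 1, max_steps = NULL,
                                   objective = c("kl", "ml")) {
  objective <- match.arg(objective)
  stopifnot(inherits(hist, "position_histogram"))
  h0 <- hist$h
  k <- hist$k
  n <- hist$n_patients
  if (is.null(max_steps)) max_steps <- 3L * max(k, 1L)
  FF <- numeric(k + 1L)

  if (k == 0L || sum(h0) == 0) {
    fit <- fit_betabinomial(hist, objective = objective)
    return(list(fit = fit, F = FF, reduced = h0,
                kl_path = fit$kl_scaled, n_steps = 0L))
  }

  cur <- h0
  fit <- fit_betabinomial(hist, objective = objective)
  kl_path <- fit$kl_scaled
  steps <- 0L

  while (fit$kl_scaled >= kl_stop && steps < max_steps) {
    best <- NULL
    seen <- character(0)  # memo: distinct (bin, removal) cells
    for (i in seq_len(k)) {
      hi <- cur[i + 1L]
      if (hi <= 0) next
      for (f in frac_grid) {
        r <- min(hi, max(1L, round(f * hi)))
        key <- paste0(i, ":", r)
        if (key %in% seen) next
        seen <- c(seen, key)
        cand <- cur
        cand[i + 1L] <- cand[i + 1L] - r
        cfit <- fit_betabinomial(cand, init = c(fit$a, fit$b), n = n,
                                 objective = objective)
        if (is.null(best) || cfit$kl_scaled < best$kl_scaled) {
          best <- list(i = i, r = r, kl_scaled = cfit$kl_scaled, fit = cfit)
        }
      }
    }
    if (is.null(best) || best$kl_scaled >= fit$kl_scaled) break  # no improvement
    cur[best$i + 1L] <- cur[best$i + 1L] - best$r
    FF[best$i + 1L] <- FF[best$i + 1L] + best$r
    # full multi-start refit on the committed histogram; keep the better of
    # the two so the committed divergence sequence is non-increasing
    rfit <- fit_betabinomial(cur, n = n, objective = objective)
    fit <- if (rfit$kl_scaled <= best$fit$kl_scaled) rfit else best$fit
    steps <- steps + 1L
    kl_path <- c(kl_path, fit$kl_scaled)
  }

  list(fit = fit, F = FF, reduced = cur, kl_path = kl_path, n_steps = steps)
}

#' Call per-position hotspot candidates for one gene
#'
#' Every mutated position receives an upper-tail p-value
#' `P(X >= recurrence)` under the fitted background; positions whose
#' recurrence bin carries fixed-effect mass (`F_i > 0`) are additionally
#' flagged as hotspot candidates.
#'
#' @param pc a `position_counts` object (or named recurrence vector).
#' @param fit a `betabin_fit` from the (reduced) histogram.
#' @param F fixed-effect vector over bins `0..k` from the same histogram.
#' @return data.frame: `gene`, `transcript_id`, `protein_pos`, `recurrence`,
#'   `flagged`, `p_value` (plus `q_value`, `is_warm`, `passes_filter` set to
#'   `NA` until [fdr_correct()] / [filter_hotspots()] run).
#' @export
call_hotspots <- function(pc, fit, F) {
  if (is.list(pc)) {
    counts <- pc$counts
    gene <- pc$gene
    tx <- if (is.null(pc$transcript_id)) NA_character_ else pc$transcript_id
  } else {
    counts <- pc; gene <- NA_character_; tx <- NA_character_
  }
  if (!length(counts)) {
    return(data.frame(gene = character(), transcript_id = character(),
                      protein_pos = integer(), recurrence = integer(),
                      flagged = logical(), p_value = numeric(),
                      q_value = numeric(), is_warm = logical(),
                      passes_filter = logical()))
  }
  pos <- as.integer(names(counts))
  rec <- as.integer(counts)
  k <- length(F) - 1L
  flagged <- rec <= k & F[pmin(rec, k) + 1L] > 0
  p <- betabin_sf(pmin(rec, fit$n), fit$n, fit$a, fit$b)
  out <- data.frame(
    gene = gene, transcript_id = tx, protein_pos = pos, recurrence = rec,
    flagged = flagged, p_value = p,
    q_value = NA_real_, is_warm = NA, passes_filter = NA,
    stringsAsFactors = FALSE
  )
  out[order(-out$recurrence, out$protein_pos), , drop = FALSE]
}

#' Benjamini-Hochberg correction over warm spots
#'
#' Positions with recurrence at least `warm_min` ("warm" spots) form the
#' multiple-testing family; their p-values are BH-adjusted. Colder
#' positions keep `q_value = NA`.
#'
#' @param calls data.frame from [call_hotspots()] (possibly several genes
#'   concatenated — the correction batch is whatever is passed in).
#' @param warm_min minimum recurrence for FDR eligibility.
#' @return `calls` with `q_value` and `is_warm` filled in.
#' @export
fdr_correct <- function(calls, warm_min = 4L) {
  stopifnot(is.data.frame(calls), "p_value" %in% names(calls))
  calls$is_warm <- calls$recurrence >= warm_min
  calls$q_value <- NA_real_
  if (any(calls$is_warm))
    calls$q_value[calls$is_warm] <-
      stats::p.adjust(calls$p_value[calls$is_warm], method = "BH")
  calls
}

#' Final hotspot filter
#'
#' A warm spot passes if its q-value is below `q_max` *or* it was observed
#' in at least `patients_min` patients. Non-warm positions never pass.
#'
#' @param calls data.frame after [fdr_correct()].
#' @param q_max FDR threshold.
#' @param patients_min recurrence that passes regardless of q.
#' @return `calls` with `passes_filter` filled in.
#' @export
filter_hotspots <- function(calls, q_max = 0.01, patients_min = 7L) {
  stopifnot(is.data.frame(calls), "q_value" %in% names(calls))
  q_ok <- !is.na(calls$q_value) & calls$q_value < q_max
  calls$passes_filter <- calls$is_warm &
    (q_ok | calls$recurrence >= patients_min)
  calls
}
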