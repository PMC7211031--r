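#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution, the binomial whose success
#' probability is itself Beta(a, b) distributed. It is the per-site model for
#' the number of patients mutated at one protein position, and captures the
#' over-dispersion that a plain binomial cannot.
#'
#' Computed in log space via `lchoose()` and `lbeta()`:
#' \deqn{P(X = i) = \binom{n}{i} \frac{B(i + a, n - i + b)}{B(a, b)}}
#'
#' @param i integer vector of counts, each in `0..n`.
#' @param n binomial size (number of patients in the cohort).
#' @param a,b positive beta shape parameters.
#' @param log if `TRUE` return log probabilities.
#' @return numeric vector of probabilities (or log probabilities).
#' @examples
#' betabin_pmf(0:2, 2, 1, 1)     # Beta(1,1) mixing: discrete uniform 1/3
#' betabin_pmf(0, 1, 2, 3)       # b/(a+b) = 0.6
#' @export
betabin_pmf <- function(i, n, a, b, log = FALSE) {
  stopifnot(length(n) == 1L, length(a) == 1L, length(b) == 1L)
  if (a <= 0 || b <= 0) stop("shape parameters 'a' and 'b' must be positive")
  if (n < 0 || n != round(n)) stop("'n' must be a non-negative integer")
  if (any(i < 0 | i > n)) stop("'i' must lie in 0..n")
  lp <- lchoose(n, i) + lbeta(i + a, n - i + b) - lbeta(a, b)
  if (log) lp else exp(lp)
}

#' Beta-binomial upper tail probability P(X >= i)
#'
#' Inclusive survival function used as the hotspot p-value: the probability
#' that a single site accumulates at least `i` distinct mutated patients
#' under the fitted background model.
#'
#' @inheritParams betabin_pmf
#' @return numeric vector, `P(X >= i)` for each element of `i`.
#' @export
betabin_sf <- function(i, n, a, b) {
  stopifnot(all(i >= 0), all(i <= n))
  pmf <- betabin_pmf(0:n, n, a, b)
  # reverse cumulative sum; clamp tiny negative rounding to 0
  tail <- rev(cumsum(rev(pmf)))
  p <- tail[i + 1L]
  pmin(pmax(p, 0), 1)
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `sum(p * log(p / q))` over the support of `p`, in nats. Bins where the
#' observed probability is zero contribute nothing; the model vector is
#' floored at `floor` so that a structurally impossible model bin yields a
#' large but finite penalty instead of `Inf`.
#'
#' @param observed,model probability vectors of equal length.
#' @param floor minimum model probability before taking logs.
#' @return non-negative scalar divergence (0 iff the vectors are equal).
#' @export
kl_divergence <- function(observed, model, floor = 1e-300) {
  if (length(observed) != length(model))
    stop("'observed' and 'model' must have equal length")
  keep <- observed > 0
  if (!any(keep)) return(0)
  q <- pmax(model[keep], floor)
  sum(observed[keep] * (log(observed[keep]) - log(q)))
}

#' Build the per-gene recurrence histogram
#'
#' Tallies, for a gene, how many protein positions were mutated in exactly
#' `i` distinct patients, for `i = 0..k` where `k` is the maximum observed
#' recurrence. Bin 0 counts the assayable positions that were never mutated,
#' so the total number of sites must be known: the protein length when
#' available, otherwise the maximum mutated position (logged fallback).
#'
#' @param pc a `position_counts` object (see [aggregate_positions()]), or a
#'   named integer vector mapping protein position to recurrence.
#' @param n_patients cohort size; becomes the binomial size `n` of the model.
#' @param n_sites override for the number of assayable sites.
#' @return a `position_histogram`: list with `gene`, `h` (numeric, bins
#'   `0..k`), `k`, `n_sites`, `n_patients`.
#' @export
build_histogram <- function(pc, n_patients, n_sites = NULL) {
  if (is.list(pc)) {
    counts <- pc$counts
    gene <- pc$gene
    if (is.null(n_sites)) {
      if (!is.null(pc$protein_length) && !is.na(pc$protein_length)) {
        n_sites <- pc$protein_length
      } else if (length(counts)) {
        n_sites <- max(as.integer(names(counts)))
        message("build_histogram: no protein length for ", gene,
                "; using max mutated position (", n_sites, ") as n_sites")
      } else {
        stop("empty counts and no 'n_sites': cannot size bin 0")
      }
    }
  } else {
    counts <- pc
    gene <- NA_character_
    if (is.null(n_sites)) {
      if (!length(counts)) stop("empty counts and no 'n_sites'")
      n_sites <- max(as.integer(names(counts)))
    }
  }
  counts <- as.integer(counts)
  if (length(counts) && any(counts < 1)) stop("all recurrence counts must be >= 1")
  if (n_sites < length(counts))
    stop("n_sites (", n_sites, ") smaller than the number of mutated positions (",
         length(counts), "): inconsistent protein length")
  k <- if (length(counts)) max(counts) else 0L
  if (k > n_patients)
    stop("max recurrence (", k, ") exceeds n_patients (", n_patients, ")")
  h <- numeric(k + 1L)
  if (k > 0L) {
    tab <- tabulate(counts, nbins = k)
    h[2:(k + 1L)] <- tab
  }
  h[1L] <- n_sites - length(counts)
  structure(
    list(gene = gene, h = h, k = k, n_sites = n_sites, n_patients = n_patients),
    class = "position_histogram"
  )
}

#' @export
print.position_histogram <- function(x, ...) {
  cat("Position histogram", if (!is.na(x$gene)) paste0("for ", x$gene), "\n")
  cat("  sites:", x$n_sites, " patients:", x$n_patients, " k:", x$k, "\n")
  cat("  h:", paste(x$h, collapse = " "), "\n")
  invisible(x)
}

# Normalized truncated model pmf over bins 0..k.
.bb_model_pmf <- function(k, n, a, b) {
  q <- betabin_pmf(0:k, n, a, b)
  s <- sum(q)
  if (s <= 0 || !is.finite(s)) return(rep(1 / (k + 1), k + 1))
  q / s
}

# Objective for the fit, on log-parameters. h: raw bin counts.
.bb_objective <- function(lpar, h, n, objective, floor = 1e-300) {
  a <- exp(lpar[1L]); b <- exp(lpar[2L])
  k <- length(h) - 1L
  q <- .bb_model_pmf(k, n, a, b)
  if (objective == "ml") {
    keep <- h > 0
    -sum(h[keep] * log(pmax(q[keep], floor)))
  } else {
    kl_divergence(h / sum(h), q, floor = floor)
  }
}

#' Fit a beta-binomial model to a recurrence histogram
#'
#' Finds `(a, b)` minimizing the Kullback-Leibler divergence between the
#' normalized histogram and the model pmf truncated and renormalized to bins
#' `0..k` (or, with `objective = "ml"`, maximizing the multinomial
#' likelihood). Optimization is bounded quasi-Newton (`L-BFGS-B`) on
#' `log(a), log(b)` with `a, b` constrained to `[1e-6, 1e6]`, started from a
#' deterministic 4-point grid `(a, b) in {0.01, 1} x {10, 1000}`, best final
#' objective wins. Supplying `init` replaces the grid with that single start,
#' so the result is deterministic given `init`.
#'
#' @param hist a `position_histogram`, or a bare numeric vector of bin counts
#'   (then `n` must be given).
#' @param init optional `c(a, b)` starting point.
#' @param n binomial size override (defaults to `hist$n_patients`).
#' @param objective `"kl"` (default) or `"ml"`.
#' @param bounds length-2 box constraint for both shape parameters.
#' @return a `betabin_fit`: list with `a`, `b`, `n`, `kl` (divergence of the
#'   fitted model from the normalized histogram), `kl_scaled`
#'   (`n_sites * kl`, the count-scaled divergence used by the stepwise
#'   stopping rule), `converged`, `n_steps` (optimizer iterations).
#' @export
fit_betabinomial <- function(hist, init = NULL, n = NULL,
                             objective = c("kl", "ml"),
                             bounds = c(1e-6, 1e6)) {
  objective <- match.arg(objective)
  if (inherits(hist, "position_histogram")) {
    h <- hist$h
    if (is.null(n)) n <- hist$n_patients
  } else {
    h <- as.numeric(hist)
    if (is.null(n)) stop("'n' is required when 'hist' is a bare count vector")
  }
  n_sites <- sum(h)
  if (n_sites <= 0) {
    return(structure(list(a = 1, b = 1, n = n, kl = 0, kl_scaled = 0,
                          converged = FALSE, n_steps = 0L),
                     class = "betabin_fit"))
  }
  starts <- if (is.null(init)) {
    list(c(0.01, 10), c(0.01, 1000), c(1, 10), c(1, 1000))
  } else {
    stopifnot(length(init) == 2L, all(init > 0))
    list(init)
  }
  lb <- log(bounds[1L]); ub <- log(bounds[2L])
  best <- NULL
  degenerate <- sum(h > 0) < 2L
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(log(s), lb), ub), .bb_objective,
                   h = h, n = n, objective = objective,
                   method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(a = 1, b = 1, n = n, kl = Inf, kl_scaled = Inf,
                          converged = FALSE, n_steps = 0L),
                     class = "betabin_fit"))
  }
  a <- exp(best$par[1L]); b <- exp(best$par[2L])
  kl <- kl_divergence(h / n_sites, .bb_model_pmf(length(h) - 1L, n, a, b))
  structure(
    list(a = a, b = b, n = n, kl = kl, kl_scaled = n_sites * kl,
         converged = best$convergence == 0 && !degenerate,
         n_steps = as.integer(best$counts[1L])),
    class = "betabin_fit"
  )
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat(sprintf("Beta-binomial fit: a = %.4g, b = %.4g, n = %d\n", x$a, x$b, x$n))
  cat(sprintf("  mean = %.3g  KL = %.4g (scaled %.4g)  converged: %s\n",
              x$a / (x$a + x$b), x$kl, x$kl_scaled, x$converged))
  invisible(x)
}
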