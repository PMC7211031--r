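---
title: "Hotspot detection and passenger annotation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot detection and passenger annotation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

This vignette is the package's own account of its methods: the statistical
model, the tunable parameters and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, the numerical
decisions, and the known limitations — including one acceptance criterion the
method cannot meet and why.

## The detection model

### Recurrence histograms

The unit of analysis is a (gene, protein position) pair. Mutations are
aggregated per position counting **distinct patients** — a patient mutated
twice at one site contributes once, so recurrence is bounded by the cohort
size and "observed in seven patients" means seven independent tumors. (Raw
row counting is available via `dedup_patients = FALSE` for cohorts where
per-patient duplicates are known to be real independent events.)

Per gene we form the histogram $h_i$ = number of positions mutated in exactly
$i$ patients, $i = 0..k$, with $k$ the maximum observed recurrence. Bin 0
needs the number of assayable sites: the protein length when a length table
is supplied, otherwise the maximum mutated position (a logged fallback that
under-counts never-mutated tail positions and therefore slightly fattens the
background — conservative for hotspot calling).

### Beta-binomial background plus fixed effects

The histogram is decomposed as

$$h_i = \mathrm{BetaBin}(a, b)_i + F_i,$$

where the beta-binomial (binomial size $n$ = number of patients, success
probability $p \sim \mathrm{Beta}(a,b)$) models the background: the Beta
mixing captures the over-dispersion of per-site mutation rates that makes a
plain binomial anticonservative. $F_i \ge 0$ is a fixed-effect count of
sites at recurrence $i$ that the background cannot explain; those bins mark
hotspot candidates.

$(a, b)$ are estimated by minimizing the Kullback–Leibler divergence between
the normalized histogram and the model pmf truncated and renormalized to
bins $0..k$, with `L-BFGS-B` on $(\log a, \log b)$, box constraints
$a, b \in [10^{-6}, 10^6]$, and a deterministic 4-point start grid
$(a,b) \in \{0.01, 1\} \times \{10, 1000\}$ (best final objective wins). A
maximum-likelihood objective (`objective = "ml"`, the multinomial
log-likelihood of the truncated pmf) is available as a flag; KL is the
default because the stepwise stopping rule is stated in divergence units, so
fitting in the same divergence keeps the stopping threshold interpretable.

### The divergence scale of the stopping rule

The stepwise algorithm stops "when KL is below 1". On which scale? The KL
divergence between two *probability* vectors cannot be the intended scale:
five spiked sites among 5000 contribute only
$p \log(p/q) \approx 10^{-3} \times \log(10^{-3}/10^{-7}) \approx 10^{-2}$
to the normalized divergence, so the rule would fire before absorbing any
hotspot, at any realistic gene size — the fixed effects would always be
zero. We therefore compare the threshold against the **count-scaled**
divergence

$$\mathrm{KL}_\text{scaled} = N \cdot \mathrm{KL}(\hat{p} \,\|\, q),$$

with $N$ the current number of sites. Twice this quantity is the
likelihood-ratio $G$-statistic, asymptotically $\chi^2$, so
"$\mathrm{KL}_\text{scaled} < 1$" means "within roughly one degree of
freedom of statistical indistinguishability from the background" —
meaningful at every cohort size. `kl_divergence()` itself keeps the plain
probability-vector contract; only the stopping comparison is scaled.

### The stepwise grid search

At each step, for every bin $i \ge 1$ with $h_i > 0$ and every fraction
$f \in \{0.1, 0.2, \ldots, 1.0\}$, a candidate removes
$\max(1, \mathrm{round}(f \cdot h_i))$ sites from bin $i$ (the minimum of 1
makes small bins reachable at small fractions; duplicate $(i, r)$ cells are
evaluated once), refits the background warm-started from the current
$(a, b)$, and scores the scaled divergence. The lowest-scoring cell is
committed — ties broken by smaller $i$, then smaller $f$, making the search
deterministic — and its removed count accumulates into $F_i$. After each
commit the background is refit from the full multi-start grid and the better
of the two fits kept, which guarantees the committed divergence sequence is
non-increasing. Iteration ends when the scaled divergence drops below
`kl_stop` (default 1), when no candidate improves it, or after `max_steps`
(default $3k$) steps. Conservation $h_i = \text{reduced}_i + F_i$ holds
exactly at every step by construction and is asserted in the tests.

### P-values, FDR, and the final filter

Every mutated position receives the inclusive upper tail
$P(X \ge i)$ under the final fitted background (computed by log-space pmf
summation); positions in bins with $F_i > 0$ are flagged. Positions with
recurrence $\ge$ `warm_min` (default 4) — *warm spots* — form the
multiple-testing family and receive Benjamini–Hochberg q-values; colder
positions keep `NA`. The final filter passes a warm spot when
$q <$ `q_max` (default 0.01) **or** recurrence $\ge$ `patients_min`
(default 7). All three constants are exposed and all defaults match the
published workflow this package reimplements.

## APOBEC3A hairpin annotation

The mutated base's genomic context (±25 nt; enough for an 11-nt loop plus a
10-pair stem on either arm) is extracted and oriented: if the reference base
is G or T the reverse complement is scored, so the scored base is always C
or A. All loop lengths 3–11 crossed with mutated-base loop positions
1–length (63 configurations) are scored by stem strength

$$ss = 3 \times \#\text{G:C} + 1 \times \#\text{A:T},$$

pairing the arms outward from the loop and stopping at the first
non-Watson–Crick pair, an N, a context edge, or `max_stem` pairs. Ties take
the smallest loop length, then the smallest loop position. Classification is
a pure lookup in the nine-entry threshold table
(position:length 3:3 → 7, 3:4 → 12, 4:4 → 11, 4:5 → 12, 4:6 → 15, 5:6 → 14,
4:7 → 18, 5:7 → 15, 6:8 → 16): **Likely** at/above threshold, **Unlikely**
below it, **No** when the geometry is not in the table. Classification
deliberately ignores the surrounding sequence context (e.g. the 5′
neighbor); the table's source stratification makes the label meaningful
without it.

Design choices where the published description is silent:

* **Stem extension rule.** Only the pair weighting is published. We use
  contiguous perfect pairing from the loop outward, stopping at the first
  mismatch — the simplest model consistent with a "sum of matches" score. No
  bulges, no internal loops, and no G:T wobble (only the two named pair
  types score). `max_stem = 10` caps the stem; with weight 3 per G:C the cap
  (max ss 30) is far above every threshold, so it only bounds runtime.
* **Degenerate centre.** An N at the mutated position yields label "No" with
  a warning rather than an error, so cohort-scale annotation never aborts on
  a gap.

## Simplified dN/dS

The gene-level selection estimate is intentionally a counting estimator, not
a reimplementation of covariate-regression dN/dS: the package must be
self-contained and testable, and the validation pattern available at desk
scale is neutrality calibration. From the coding sequence all $3L$ single
nucleotide changes are enumerated and classified against the standard
genetic code, weighted by a substitution model (default: uniform over the
six unordered base pairs; any 6-parameter model can be supplied), giving
opportunity fractions for silent, missense and nonsense changes (stop-loss
counts as missense so the three fractions sum to 1). Then

$$w_X = \frac{\text{observed}_X}{\text{observed}_\text{silent} \cdot
  \text{opp}_X / \text{opp}_\text{silent}},$$

with a pseudocount of 0.5 (flagged) when no silent mutation was observed.
P-values are one-sided Poisson tails in the direction of the departure:
upper tail for an excess, lower tail for a deficit (so 0 observed against an
expectation of 4 gives $e^{-4}$). Splice and indel ratios are reported `NA`
unless splice-site or per-base indel opportunities are explicitly supplied —
absent is more honest than guessed. The headline summary is
$\max(w_\text{mis}, w_\text{non})$.

## The synthetic world

`simulate_cohort()` draws each site's patient count from
$\mathrm{BetaBin}(n, a, b)$ and overrides spiked sites to their stated
recurrence, then expands counts into mutation records by sampling distinct
patients. The canonical test world — $n = 500$ patients, background
$a = 0.05$, $b = 400$ (per-site mean mutation probability
$1.25 \times 10^{-4}$, i.e. an expected per-site recurrence of 0.06 with a
heavy right tail), genes of 1000–10000 sites, spikes at recurrence 25 —
matches the scales stated for this package's acceptance checks, and the
background parameters produce histograms (a few percent of sites mutated,
recurrence mostly 1–3, occasional 5–8 by chance) that resemble
moderately-mutated TCGA genes. What it does **not** emulate: mutational
signatures and trinucleotide context, per-gene covariates (expression,
replication timing), regional rate variation within a gene, or multi-allelic
sites. A green detection test therefore establishes correctness of the
*inference machinery* under its own model, not robustness to real-cohort
rate structure.

`make_hairpin_sequence()` builds contexts whose designed configuration is
provably the unique argmax: the loop filler must not pair with either arm,
otherwise a shifted loop can reuse the designed stem's own pairs, tie the
maximum, and win the smaller-loop tie-break. Filler "A" is safe for any stem
containing a G:C pair; a pure A:T stem instead uses filler "G" (A/T arms
pair with the "A" filler but not with "G"). Flanks are "A" homopolymers,
which cannot pair with themselves.

`simulate_neutral_gene()` draws mutation classes multinomially from the
opportunity fractions, so every $w$ has expectation 1. The calibration test
uses 100 mutations per gene: with ~25 expected silent mutations the Jensen
bias of the ratio estimator ($E[1/S] > 1/E[S]$) is ~3%, comfortably inside
the ±10% acceptance band; at the 50-mutation lower bound the bias alone
approaches the band's edge.

## Numerical choices

* Beta-binomial pmf in log space via `lchoose` + `lbeta`; survival function
  by reverse cumulative summation, clamped to $[0, 1]$.
* Model pmf floored at $10^{-300}$ inside KL; observed zero bins contribute 0.
* Optimizer works on log-parameters (the objective is much better
  conditioned there); bounds and starts as above; everything is
  deterministic — same data, same result, no RNG anywhere in fitting.
* Degenerate inputs: single-bin histograms return a boundary fit flagged
  `converged = FALSE`; all-zero histograms return $F \equiv 0$; empty MAFs
  flow through to empty outputs with exit status 0.
* Genes with fewer than 3 mutated positions are skipped by the pipeline
  (`min_gene_mutations`): a background fit on 1–2 points is meaningless.

## Known limitations

**Null calibration of the q-values (the red acceptance criterion).** Under a
pure-background simulation (100 genes × 1000 sites, the canonical
background), essentially *all* warm positions receive $q < 0.05$, far above
the criterion's 10% bound. This is not an implementation bug; it is a
structural property of the published procedure that the package reproduces
faithfully. The p-value of a warm site is its per-site tail probability
$S(4) = P(X \ge 4) \approx 2\times10^{-3}$, and the number of warm sites is
$m \approx N \cdot S(4)$ — the family being BH-corrected was *selected by
the very tail that generated the p-values*. BH then yields
$q \approx S(4) \cdot m / \mathrm{rank} \approx S(4)$ for every member: tiny
whenever warm recurrence is per-site-rare, regardless of how well the model
fits. FDR control would require correcting over all $N$ sites (then
$q \approx N S(4)/\mathrm{rank} \approx 1$ under the null) or using an
expectation-corrected per-site statistic, either of which would change the
published contract (per-site survival p-values; BH over the warm subset).
We implement the contract, leave the criterion red, and report the measured
fraction honestly in the acceptance script. Practically this means the
$q < 0.01$ branch of the filter behaves like a *ranking* device, and the
recurrence $\ge 7$ branch plus the mechanistic annotations carry the real
evidential weight.

Other limitations: no covariate or trinucleotide correction in the
background model (out of scope by design); the dN/dS estimator is a
simplified counting method whose absolute values should not be compared
against covariate-regression implementations; hairpin scoring considers
perfect contiguous stems only; multi-transcript genes are resolved by
majority vote rather than re-annotation.
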