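---
title: "Dinucleotide weight matrices: model, estimation, and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dinucleotide weight matrices: model, estimation, and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwmotif)
```

## The problem and the model

A position weight matrix (PWM) models a transcription-factor binding
motif of length $L$ as $L$ independent categorical distributions
$w_i(\alpha)$ over the four bases. Independence is the PWM's defining
simplification and its defining weakness: it cannot represent a motif
in which, say, two positions read `AA` or `TT` equally often but never
`AT` or `TA` — the marginals are identical in both cases. Real binding
sites show such dinucleotide correlations, and not only between
adjacent columns: correlated pairs occur at every separation ("gap")
within a binding region.

The dinucleotide weight matrix (DWM) drops the independence assumption
without pre-selecting which pairs matter: it stores, for *every*
ordered pair $i<j$, the $4\times4$ joint probability
$D_{ij}(\alpha,\beta)$, together with the marginal PWM. The object is
quadratic in $L$; only $i<j$ tables are stored and the convention
$D_{ji}(\beta,\alpha) = D_{ij}(\alpha,\beta)$ defines the rest.

### Estimation

From $N$ aligned sites with base counts $n_i(\alpha)$ and joint counts
$m_{ij}(\alpha,\beta)$:

$$w_i(\alpha) = \frac{n_i(\alpha)+\kappa}{N+4\kappa}, \qquad
D_{ij}(\alpha,\beta) = \frac{m_{ij}(\alpha,\beta) +
16\,w_i(\alpha)w_j(\beta)}{N+16}.$$

The PWM pseudocount is a symmetric Dirichlet prior; the default
$\kappa = 1$ is the flat "know-nothing" prior, and it is a parameter
everywhere because the appropriate value is genuinely debatable (the
originating analysis is ambiguous between 1 and other small values; we
fix 1 as the uniform-prior convention and expose the knob).

The DWM prior deserves the emphasis: a flat Dirichlet over 16
dinucleotides would say "I know nothing about the joint", but we know
quite a lot — motif columns are *roughly* independent, and with $N$
sites the marginals are estimated far better than the joints. The prior
is therefore the product of the marginal PWM columns carrying total
mass 16 (one pseudocount per dinucleotide in the factorised limit), so
with little data the joint shrinks toward the PWM product, and the DWM
only departs from PWM behaviour where the data insist.

### Scoring: posterior-product likelihood

Joint tables for different pairs share variables, so no exact
factorised likelihood exists. The score used is the product over
positions of the Bayesian posterior of the observed base given all the
others, with the conditional likelihoods approximated as products of
pairwise conditionals:

$$u_i(\alpha) = w_i(\alpha)\prod_{j\neq i}
\frac{D_{ij}(\alpha, s_j)}{w_i(\alpha)}, \qquad
\log P(S\mid D) \approx \sum_i \left[\log u_i(s_i) - \log Z_i\right],
\quad Z_i = \sum_\alpha u_i(\alpha).$$

Three properties matter in practice:

* **Reduction.** If every $D_{ij}$ factorises, the ratio
  $D_{ij}(\alpha,s_j)/w_i(\alpha) = w_j(s_j)$ is independent of
  $\alpha$, and the expression collapses exactly to the PWM
  log-likelihood. `dwm_from_pwm()` embeds a PWM this way, and the test
  suite holds the two scores equal to $10^{-9}$ over randomised models
  and windows.
* **Normalisation.** Each posterior factor sums to 1 over $\alpha$
  (asserted to $10^{-9}$), but the product over a window is *not* a
  normalised distribution over sequences; it is a discrimination score,
  used only inside log-odds ratios.
* **Numerics.** With $L\approx30$ each $u_i$ multiplies ~29 likelihood
  ratios; in linear space that underflows, so everything is computed in
  natural-log space with a log-sum-exp over the four bases for $Z_i$.
  The per-window kernel is $O(L^2)$ and implemented in C++ — a pure-R
  scan was roughly two orders of magnitude too slow for the benchmark
  suite.

Log-odds subtract a mononucleotide background log-likelihood (uniform
by default; `background_from_sequences()` estimates genomic
frequencies, adding one smoothing count per base). Scans score both the
window and its reverse complement and keep the better orientation,
with ties resolved to the plus strand. Windows containing non-ACGT
characters are skipped. All coordinates are 0-based half-open; all
log-odds are natural-log.

## Correlation statistics

For each column pair and dinucleotide, the observed count $n$ is
compared with the independence expectation $E = Np$,
$p = w_i(\alpha)w_j(\beta)$, $\sigma = \sqrt{Np(1-p)}$. A record is
*significant* when $|n - E| > 2\sigma$ (strict inequality) and
*abundant* when $\max(n, E) \ge 0.3N$ (at least) — the abundance filter
removes the many trivially "significant" records whose expected counts
are near zero. Gap histograms are reported both as dinucleotide records
and as distinct column pairs (the two units used in different
summaries), normalised by availability: one motif of length $L$ offers
$\max(L-g, 0)$ pairs at gap $g$.

Two calibration facts, both established by the test suite:

* With expectations taken from the **true generating** PWM, the
  fraction of significant records under the null (independent sampling)
  matches the two-sided normal $2\sigma$ tail, about 4.6%, within
  Monte-Carlo error at $N = 500$.
* With expectations from the PWM **estimated on the same sites** — the
  pipeline's normal operating mode — the rate drops to roughly 1%:
  self-estimation absorbs part of every deviation. Flagged-pair counts
  from this procedure are therefore conservative, and the two modes
  should not be compared across studies. (A related printed claim that
  fewer than 0.05% of points should exceed $2\sigma$ is inconsistent
  with the normal tail and is not reproduced here.)

A further documented consequence of using pseudocounted expectations:
perfectly conserved column pairs can be flagged at large $N$, because
$\kappa$ biases $w$ strictly below 1.

## The two-step bootstrap

Given a prior PWM and a set of ChIP target (probe) sequences:

1. **Select** sites per probe: every window with log-odds above 3.0
   (natural log); if none, the single best window if it reaches 1.5;
   otherwise the probe is rejected. Selected sites are widened by a
   configurable flank (10 bp in the reference configuration) of real
   genomic context, orientation-normalised, and used to build *interim*
   PWM and DWM matrices. Sites whose widened window overruns the probe
   are dropped, not padded — padding would inject background
   composition into the estimates.
2. **Re-predict** on all probes with the interim matrices (same
   criteria, no further flank) and build the final posterior matrices,
   plus, for every probe, *leave-one-out* matrices omitting all of that
   probe's sites. All predictions on a probe use its leave-one-out
   matrix, so no site ever contributes to the model that scores it.
   The PWM and DWM tracks refine independently.

The procedure is deterministic given its inputs. Leave-one-out
matrices are built by count subtraction and are bit-identical to
rebuilding from the final site list with the probe's sites removed
(tested); note they are *not* identical to re-running the whole
pipeline without the probe, since that would also change the interim
matrices.

Per-probe aggregation follows the "total log-odds" convention: the sum
over *all* window positions of the best-orientation log-odds, treating
a probe with several weak sites on a par with one strong site. Whether
negative windows should be included is not decidable from the
reference description ("all possible sites"); both behaviours are
exposed (`positive_only`), with inclusion as the default reading.

## Benchmark metrics

* **Probe-level precision/sensitivity** against an annotated target
  list, sweeping the cutoff over observed best scores; a probe counts
  as predicted when its best site reaches the cutoff (targets are
  gene-level, so probe-level counting is the coherent unit). At
  cutoffs above all scores precision is 1 by convention with
  `n_predicted = 0` flagging the degeneracy.
* **Site-level hits** by two rules: midpoint-within-10bp-of-midpoint
  (for point-like annotated sites) and midpoint-within-widened-region
  (for footprints of heterogeneous size). Tolerance defaults to 10 bp.
* **Discriminative precision** $(N_{real}-N_{fake})/N_{tot}$ against
  decoys sampled from the PWM itself: negative values mean the model's
  predictions resemble its own samples more than genuine sites.
* **Correlation with binding**: per probe, the combined p-value is the
  geometric mean of the rich-medium p and up to the two smallest other
  condition p-values in which binding was reported; "reported" is
  operationalised as $p \le 0.001$ (a config knob — the reference
  procedure does not define it). The default correlates total log-odds
  with $-\log p$ so a better predictor yields a positive coefficient;
  the raw-p variant exists for exact-procedure replication. Degenerate
  inputs (zero variance) return 0 with a flag rather than NA.

## Synthetic data: what it does and does not establish

Correlated sites are generated from **mixtures of PWMs**: each site
picks a component, then samples independently within it. The induced
pair joint $\sum_c \pi_c\, w^c_i(\alpha) w^c_j(\beta)$ is available in
closed form (`mixture_pair_joint()`), giving an analytic oracle for
recovery tests — the reason mixtures were chosen over Gibbs sampling
from a pairwise field, which has no tractable joint. Benchmark
sequences concatenate random spacers (100 bp default) with embedded
units: each unit is one site plus background flanks (10 bp default),
real sites interleaved in random order with an equal number of decoys
sampled from the marginal PWM. All generators are bit-exactly
reproducible given a seed.

The directional benchmark property (leave-one-out DWM precision at 50%
sensitivity at least matching the PWM's, in at least 8 of 10 seeded
replicates at 200 training sites) is evaluated on this world with the
bootstrap's training flank set to **0**. This is deliberate: synthetic
flanks are i.i.d. background, so unlike genomic flanks they carry no
signal by construction, and including them only adds noisy pair tables
to the DWM (measured: with 5 bp training flanks the DWM advantage
nearly vanishes). A green result therefore establishes that the DWM
ranks genuinely correlated sites above marginally identical decoys —
it does *not* establish the flank effect reported for genomic data,
which this generator cannot emulate, nor any particular effect size.
Other known gaps between the generator and real data: no footprint
length heterogeneity, no chromosomal background composition structure,
and decoys drawn exactly from the marginal (real negatives are harder
and easier in ways PWM samples are not).

## Numerical and degenerate-input choices

* Strand ties break to `+`; selection uses strict `>` for the primary
  3.0 cutoff and `>=` for the 1.5 fallback, matching the reference
  wording ("above" versus "at least").
* $\sigma = 0$ cannot occur in deviation statistics with $\kappa > 0$;
  it is guarded anyway with $z = 0$.
* Sequences shorter than the model yield an empty scan with a warning;
  an all-N sequence yields an empty scan silently (the skip rule).
* Fewer than two probes contributing sites aborts the bootstrap with
  an error naming the factor.
* Matrix serialisations carry 17 significant digits and round-trip
  bit-exactly.

## Limitations

The posterior-product likelihood is an uncontrolled approximation —
useful as a discrimination score, not a probability. Estimating
$O(L^2)$ joint tables needs dozens of sites where a PWM needs a
handful, and scoring is $O(L^2)$ per window against the PWM's $O(L)$.
No p-value calibration of log-odds is provided, no multiple-testing
correction beyond the abundance filter, and no higher-order
(trinucleotide) models; ab initio motif discovery and phylogenetic
filtering are out of scope.
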