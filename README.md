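# dwmotif — dinucleotide weight matrices for binding-site prediction

Transcription factors recognise short, variable DNA motifs. The standard
model, the position weight matrix (PWM), stores one probability
`w_i(α)` per motif position `i` and base `α ∈ {A,C,G,T}` and assumes the
positions are independent. That assumption is demonstrably wrong for
many factors: dinucleotide correlations occur between motif columns at
*all* separations, not just between neighbours. `dwmotif` implements the
generalisation that drops the independence assumption wholesale: the
**dinucleotide weight matrix (DWM)**, which stores a 4×4 joint
probability table `D_ij(α,β)` for *every* pair of positions `i < j`.

## The model

**Estimation.** From `N` aligned sites, with `n_i(α)` single-base counts
and `m_ij(α,β)` joint counts:

```
w_i(α)    = (n_i(α) + κ) / (N + 4κ)                      κ = 1 by default
D_ij(α,β) = (m_ij(α,β) + 16 w_i(α) w_j(β)) / (N + 16)
```

The PWM uses a flat Dirichlet pseudocount; the DWM's prior is the
product of the marginal PWM columns normalised to total mass 16 — motif
columns are *roughly* independent, and the marginal is far better
estimated than the joint, so the joint shrinks toward the PWM product
rather than toward uniformity.

**Scoring.** Because the pair tables are not independent, the window
likelihood is approximated as the product over positions of the
Bayesian posterior of the observed base given all other bases:

```
u_i(α) = w_i(α) · Π_{j≠i} D_ij(α, s_j) / w_i(α)
P(S|D) ≈ Π_i u_i(s_i) / Z_i,     Z_i = Σ_α u_i(α)
```

computed in log space with a stable log-sum-exp (the hot loop is in
C++). When every `D_ij` factorises as `w_i(α) w_j(β)` this reduces
*exactly* to the PWM likelihood. Log-odds are taken against a
mononucleotide background, scanning both strands and keeping the better
orientation per start position.

On top of the two model types the package provides:

* **correlation statistics** — per column pair and dinucleotide, the
  observed count versus the independence expectation `E = N w_i(α)w_j(β)`,
  `σ = sqrt(Np(1−p))`, flagged at `|n−E| > 2σ` plus a 30%-of-N abundance
  filter, with gap histograms normalised by the `L−g` pairs available at
  gap `g`;
* **the two-step bootstrap** — select sites in ChIP target sequences
  with a prior PWM (all log-odds > 3.0, else the single best ≥ 1.5,
  else reject), optionally widen by 10 bp flanks, build interim
  matrices, re-predict, and build posterior PWMs/DWMs plus per-target
  leave-one-out matrices that never contain the scored target's own
  sites;
* **benchmark metrics** — probe-level precision/sensitivity curves,
  site-level precision with midpoint hit rules, discriminative
  precision against decoy sites sampled from the PWM itself, and
  Pearson correlation of per-probe total log-odds with combined ChIP
  binding p-values;
* **synthetic data** — PWM samplers, mixture-of-PWMs models with
  analytically known pair correlations, background sequence, and
  embedded-site benchmark sequences (real + decoy units separated by
  random spacers).

## Worked example

The canonical failure of the PWM: sites that read `AA` or `TT` equally
often, but never `AT`/`TA`.

```r
library(dwmotif)
aln <- site_alignment(c("AA", "TT"))
p <- build_pwm(aln)        # kappa = 1
d <- build_dwm(aln)
p
#> pwm: L = 2 bp, pseudocount = 1
#>          A     C     G     T
#> [1,] 0.333 0.167 0.167 0.333
#> [2,] 0.333 0.167 0.167 0.333
pwm_log_likelihood(p, "AA"); pwm_log_likelihood(p, "AT")
#> [1] -2.197225        # (1/3)^2 — the PWM cannot tell the two apart
#> [1] -2.197225
dwm_log_likelihood(d, "AA"); dwm_log_likelihood(d, "AT")
#> [1] -1.648351        # (25/57)^2
#> [1] -2.540925        # (16/57)^2 — the DWM penalises the unseen combo
```

The correlation module flags the same signal from counts. For 50×`AA` +
50×`TT`:

```r
devs <- pair_deviation_stats(site_alignment(rep(c("AA", "TT"), each = 50)))
devs[devs$alpha == "A" & devs$beta == "A", ]
#>  i j gap alpha beta n_obs        E    sigma        z significant abundant
#>  1 2   1     A    A    50 24.04771 4.273732 6.072513        TRUE     TRUE
```

50 observed `AA` against 24.05 expected under independence is a 6.1 σ
deviation — a correlated column pair by the 2σ + abundance rule.

## Command line

```sh
inst/cli/dwmotif build --sites sites.fa --out-pwm m.pwm --out-dwm m.dwm
inst/cli/dwmotif scan --model m.dwm --fasta promoters.fa --out hits.bed
inst/cli/dwmotif correlate --sites sites.fa --out deviations.tsv
inst/cli/dwmotif simulate --mode benchmark --sites real.fa --model m.pwm \
    --seed 1 --out bench.fa --truth truth.tsv
inst/cli/dwmotif benchmark --predictions hits.bed --truth truth.tsv --out curve.tsv
```

Coordinates are 0-based half-open throughout; log-odds are natural-log.

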