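---
title: "Predicting tissue-specific TF binding from PBM and DNase data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tissue-specific TF binding from PBM and DNase data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfpipes)
```

## The problem

Protein binding microarrays (PBMs) measure, in vitro, the fluorescence
intensity of a transcription factor (TF) bound to tens of thousands of DNA
probes, each carrying a 36bp variable region.  That assay characterises
*sequence preference*, but actual binding in a living cell also depends on
tissue-specific chromatin state: a perfect motif buried in closed chromatin
is not bound.  `tfpipes` implements a pipeline that (i) learns a k-mer level
binding model from PBM intensities, (ii) scores any sequence in sliding 36bp
windows, (iii) converts DNase I hypersensitivity tag densities into an
open-chromatin probability, (iv) combines both (optionally with sequence
conservation) into a posterior probability that a site is bound in vivo, and
(v) summarises, per TF and tissue, how strongly the TF's candidate sites are
enriched in that tissue's accessible chromatin.

## The PBM model

Probe intensity is modelled linearly in an unobserved binding propensity
$F(i)$:

$$ Y_i = a + c\,F(i) + \varepsilon_i, \qquad
   F(i) = \sum_{j} \lambda_j\, \beta_{S_i(j)} $$

where $S_i(j)$ is the k-mer starting at position $j$ of probe $i$,
$\beta_s \ge 0$ is the binding coefficient of k-mer $s$ (shared with its
reverse complement — binding is strand symmetric, so every coefficient is
keyed by the *canonical* form, the lexicographic minimum of a pattern and
its reverse complement), and $\lambda_j$ is a multiplicative position
effect.  Occurrences may overlap, k-mers of several lengths contribute
simultaneously, and patterns may contain interior `N` wildcards (gapped
k-mers).

Coefficients are estimated by **positive lasso** — L1-penalised least
squares with $\beta \ge 0$:

$$ \min_{a,\,\beta \ge 0}\; \lVert y - a - X\beta \rVert^2
   + \alpha \sum_s \beta_s . $$

Training starts from all canonical 4–6-mers (2,728 features), then
repeatedly merges the 100 top-coefficient features whose $(k-1)$-suffix
and -prefix overlap into $(k{+}1)$-mers (plus gapped joins with 1–3 `N`s),
refitting after each round, until nothing new up to length 8 appears.
Finally $\beta'_s = \beta_s / \max_s \beta_s$, so the strongest k-mer has
normalised coefficient 1.

Design choices worth knowing:

* **Penalty selection.** $\alpha$ defaults to 5-fold cross-validation on a
  logarithmic grid, taking the largest penalty within one standard error of
  the minimum (the sparser model).  Folds are a deterministic function of
  the training seed, which makes retraining byte-for-byte reproducible.
* **Debiasing.** After the support is selected, coefficients are refit by
  non-negative least squares on the active set (a relaxed lasso).  The
  soft-thresholding of the lasso shrinks every coefficient by roughly the
  same absolute amount, which distorts *ratios* between k-mers; the
  normalised coefficients are interpreted as relative binding
  probabilities, so the refit matters (a planted 2:1 pair of 5-mers is
  recovered at its true ratio with the refit, and far from it without).
* **Position effects.** $\lambda$ is uniform in the first fit and refined
  by one alternating pass: with $\beta$ fixed, the centred intensity is
  regressed (non-negatively) on the per-position aggregate coefficient
  mass, then normalised to mean 1.  One vector is kept *per k-mer length*.
  A single start-indexed vector shared across k would not be mirror
  symmetric (start $j$ maps to $L-k+2-j$, which depends on $k$), and
  training on reverse-complemented probes would give different
  coefficients; per-k vectors make the flipped problem an exact column
  permutation, so the canonical coefficient map is invariant — a property
  the test suite asserts exactly.
* **Gapped joins.** Two top features joined with 1–3 `N`s are subject to
  the same total-length-8 cap.  With the default 4–6-mer seeds the
  smallest join (4+1+4) already exceeds the cap, so gapped features only
  arise in configurations with shorter seeds; the matching machinery
  (wildcard, both strands) is exercised by the unit tests regardless.

## Scoring sequences

A 36bp *site* scores

$$ B = \min\!\left(1,\; \tfrac{1}{B_{\max}} \sum_s \beta'_s\, C_s\right), $$

with $C_s$ the occurrence count of $s$ in the site and $B_{\max}$ the
largest unscaled score among 100,000 uniform-random 36-mers (seeded, hence
reproducible).  Because $B_{\max}$ is a sampled maximum, a real site can
exceed it; $B$ is clipped at 1 and the downstream model only ever sees
values in $[0,1]$.  A longer sequence takes the maximum over all
overlapping windows (step 1 by default; a larger step is available for
genome scans).

## Chromatin accessibility

Per-site DNase tag counts (length-weighted mean density over the 36bp site,
rounded) are modelled as a two-component mixture: a low-mean *closed* and a
high-mean *open* negative-binomial component with a **shared dispersion**,
fit by EM (relabelled so the open mean is larger; log-likelihood is
non-decreasing by construction, and the dispersion update is accepted only
if it improves the expected complete-data log-likelihood).  The shared
dispersion is what makes the posterior $P(\mathrm{open}\mid\mathrm{count})$
provably monotone in the count — the downstream model implicitly relies on
that.  If every site has the same count the fit is flagged degenerate and
callers are directed to the hard density threshold (> 15) used in the
activity analysis.  Occupancy is then simply $X = B \cdot P(\mathrm{open})$.

## The integrated model

Each candidate site carries a latent indicator $Z$ of true in vivo binding
in the graphical model $X \leftarrow Z \rightarrow C \rightarrow S$:
occupancy $X \mid Z$ is Beta-distributed with a higher mean for bound
sites; $C$ is a latent conserved/unconserved indicator with
$P(C{=}1 \mid Z{=}1) > P(C{=}1 \mid Z{=}0)$; and the conservation score
$S \mid C$ is Beta.  $C$ is always marginalised — it is a nuisance
variable.  Fitting is EM over $Z$ with exact M-steps (weighted Beta
maximum likelihood via a two-parameter concave optimisation warm-started
at the previous estimate), so the log-likelihood trace never decreases;
components are relabelled after convergence to satisfy the mean orderings.
The posterior $P(Z{=}1 \mid X, S)$ is a closed-form Bayes quotient.

Two numerical choices matter:

* **Exact zeros in X.** Genome tiles in closed chromatin, or without a
  single positive-coefficient k-mer, have $X = 0$ exactly — often the
  majority.  By default such values are clamped to
  $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$.  When zeros are
  abundant the clamp lets the $Z{=}0$ Beta collapse onto the boundary atom
  (its density there is effectively unbounded), and the posterior
  degenerates into an open/closed indicator that ignores the sequence
  signal.  `fit_pipes(zero_inflated = TRUE)` instead gives each component
  an explicit point mass at zero and fits the Betas on the positive part;
  this is the recommended setting for genome-tiling applications and the
  one used in the package's own genome-scale demonstrations.
* **Initialisation.** $\pi = P(Z{=}1)$ starts at 0.05 and responsibilities
  are seeded from the ranking of $X$ (top 5% treated as likely bound), so
  the fit is deterministic for fixed inputs.

## Tissue-specific activity

For TF $f$ and tissue $T$, $R(f,T)$ is the fraction of $T$'s DNase-open
sites containing a *high-scoring* site of $f$ — one whose $B$ exceeds the
top 0.1% of the sampled score distribution.  The activity score is

$$ \mathrm{Activity}(f,T) = R(f,T) \,/\, R(f,\bar T), $$

with $\bar T$ pooling all other tissues, and equals 1 in expectation for a
TF with no tissue preference.  Sites open in more than 1/3 of tissues are
excluded first (they carry no tissue-specific information; both boundaries
— density "higher than 15" and "more than 1/3" — are strict).  Both
fractions receive Laplace pseudocounts $(x+1)/(n+2)$ so the ratio is
always finite; note the pseudocounts only cancel exactly when the two
denominators match.  Significance comes from a one-sided binomial upper
tail: $x$ of the TF's $n$ high-scoring sites fall in $T$'s open sites,
against success probability $p = R(f,\bar T)$.  With only two tissues the
strict 1/3 rule removes every open site (1 of 2 > 1/3), so the ubiquity
filter must be disabled (`max_fraction = 1`) for two-tissue comparisons.

## Evaluation harness

Bound/unbound sets follow the ChIP-seq protocol: the top 3,000 peaks by
enrichment become 600bp positives centred on the peak midpoint (or summit
when present); each positive's negative is the 600bp window 300bp further
upstream, kept only when it stays on the chromosome and overlaps no
positive.  AUC is the rank-based (Mann–Whitney) statistic with ties counted
one half, verified in the tests against exhaustive pair counting.

## What the synthetic data does and does not show

The generators plant known truth in every format the pipeline reads:
probe intensities from the linear model with Gaussian noise; genomes with
motif copies embedded at recorded, non-overlapping 36bp windows; per-tissue
tag counts from the two NB components; conservation elevated (Beta(5,2) vs
Beta(2,5)) at true sites; and peak lists at bound sites.  Every generator
is a pure function of its parameters and seed.  Default problem sizes are
chosen so the whole suite runs in a couple of minutes: 10,000 probes for
motif-recovery checks, 10,000–20,000 sites for parameter recovery, a 126kb
genome with 50 planted sites for the integration demonstration.

Passing on these fixtures establishes internal correctness — formulas,
estimators and orderings — under the model's own assumptions.  It does not
establish performance on real arrays or tissues: real PBM intensities have
probe-specific artefacts and "sticky" k-mer backgrounds the generator does
not emulate, real DNase densities are spatially autocorrelated rather than
independent per site, and real conservation tracks are block-structured.
The qualitative findings the fixtures do reproduce — DNase integration
improves the bound/unbound AUC over sequence alone, and pure-noise
conservation changes it by less than 0.01 — are properties of the method,
demonstrated under controlled conditions.

## Known limitations

* The exact distributional families for the accessibility mixture and the
  $X,S$ conditionals are this package's documented choices (negative
  binomial with shared dispersion; Beta/Bernoulli); other reasonable
  choices exist.
* Raw sequencing reads are out of scope: DNase input is a precomputed
  density track, peaks are a precomputed list.
* The activity analysis assumes one fixed site tiling (non-overlapping
  36bp windows) for count independence in the binomial test.
* No multiple-testing correction is applied across a TF-by-tissue matrix;
  p-values are raw binomial tails.
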