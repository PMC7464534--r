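---
title: "Measuring and modelling microsatellite evolution with msatphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling microsatellite evolution with msatphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatphylo)
```

msatphylo measures perfect microsatellite (simple sequence repeat) content
in genome assemblies and asks how that content evolves across a
time-calibrated phylogeny: how fast, whether the tempo differs between
chromosome types (holocentric vs monocentric centromeres), and whether
content and its rate of change track chromosome number or genome size.
This vignette explains the models, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## Repeat detection

A microsatellite here is a *perfect* tandem repeat of a 2–6 bp motif.
`scan_sequence()` reports maximal runs satisfying `s[i] == s[i + p]` for a
period `p`, subject to per-period minimum complete-copy thresholds
(defaults: 2-mers 6 copies, 3-mers 4, 4–6-mers 3 — the standard defaults
for this class of scanner). Key conventions, chosen where a scanner has
genuine freedom:

* **Maximality and partial copies.** A locus extends as far as perfectness
  allows, so it can end mid-copy; the copy threshold applies to
  *complete* copies (`floor(length/p)`). Maximality makes output unique;
  integral thresholds stay interpretable.
* **Primitive periods.** A run is classed by the smallest period of its
  motif: `ATATAT...` is a 2-mer, never a 4-mer, and mononucleotide runs
  are never reported because period 1 is outside the scanned set.
* **Overlaps.** Scanning is single-pass left-to-right: at each position
  the longest qualifying run wins (smallest period on ties) and scanning
  resumes after its end. Reported loci therefore never overlap, and
  compound repeats such as `(AC)n(AG)m` resolve deterministically into at
  most two loci.
* **Case and ambiguity.** Lowercase (soft-masked) bases are folded to
  uppercase so masked assemblies are not silently under-counted; any
  non-ACGT character terminates a run.
* **Coordinates** are 0-based half-open (BED convention) in memory and in
  TSV output.
* **Strand.** Motif labels are canonicalised by rotation only
  (`CA -> AC`); bp totals are strand-invariant regardless, and
  `fold_strands = TRUE` additionally folds reverse complements for
  motif-class reporting.

A second, deliberately naive implementation (`scan_sequence_ref()`,
per-position extension by direct character comparison, in C++) exists
purely as a cross-check; the test suite requires set-identical output from
the two on thousands of random and repeat-planted sequences.

Per-genome content is summarised (`summarize_genome()`) as bp per period
class, total bp, bp per Mbp of assembly (`content_per_mbp`), and the
proportion of the assembly that is microsatellite. The comparative
analyses below use `content_per_mbp` for rate fits and `total_bp` for tip
rates, so both columns are first-class throughout.

## Brownian rates, ancestral states, tip rates

Continuous-trait evolution is modelled as Brownian motion: over a branch
of length $t$ My, trait change is Normal$(0, \sigma^2 t)$. The rate
$\sigma^2$ has units (trait units)$^2$/My — e.g. (bp/Mbp)$^2$/My when the
trait is content per Mbp.

`fit_bm()` uses the closed-form REML estimator from phylogenetically
independent contrasts, $\hat\sigma^2 = \sum_i u_i^2/(n-1)$ over the $n-1$
standardised contrasts, with the restricted log-likelihood of the
corresponding multivariate normal; the ML variant divides by $n$ and
profiles the root analytically. There is *no numerical optimiser* in this
fit, hence no tolerance or initialisation choices to document. Tests
verify the contrast likelihood against dense restricted-MVN matrix algebra
to $10^{-8}$.

Ancestral states are joint ML (equivalently GLS) estimates computed by a
linear-time two-pass message-passing algorithm; the root estimate equals
the GLS mean $(\mathbf{1}^\top C^{-1}x)/(\mathbf{1}^\top C^{-1}\mathbf{1})$
and all node estimates are invariant to rescaling $\sigma^2$. Polytomies
are resolved internally into arbitrary bifurcations with zero-length
branches; likelihoods and estimates are invariant to the arbitrary
resolution (tested), and estimates are mapped back to the original nodes.
Zero-length *terminal* branches are rejected by `tip_rates()` with a named
error, since the statistic divides by them.

The **tip rate** of a species is
$(x_\text{tip} - \hat{a}_\text{parent}) / t_\text{terminal}$: the signed
recent rate of change, in trait units per My, since the last sampled
speciation event. By default the parent estimate is the joint estimate
over *all* data (the focal tip contributes); `include_tip = FALSE` gives a
leave-one-out variant for sensitivity analysis, verified in tests against
dense GLS with the focal row removed. Under pure Brownian motion tip
rates are centred on zero — the acceptance suite checks this at 200 tips
over 500 replicates.

`rates_by_group()` fits each group (e.g. taxonomic order) on the induced
subtree of its members only — no stem branch, keeping the estimate
within-group — and skips groups below `min_n = 10` members.

## Centromere type: Mk model and stochastic maps

Centromere type is a binary character (holocentric/monocentric) evolving
under a continuous-time Markov model with asymmetric rates
(`fit_mk_ard()`), using the closed-form two-state transition matrix and
scaled pruning. The root prior defaults to flat over the two states —
the common default when nothing is known — with stationary and fixed
options for sensitivity; missing tip states enter as partial likelihood 1
and are imputed when maps are sampled. The optimiser is Nelder–Mead on
log rates from a 3×3 grid of starts scaled to tree height (relative
tolerance $10^{-10}$); with a single observed state the ML rates sit on
the zero boundary and the fit is flagged degenerate.

`sample_stochastic_map()` draws full character histories conditional on
the tips: node states from their exact joint conditional distribution,
then each branch's internal history conditional on its endpoints by
**uniformization** — exact conditional sampling with bounded runtime even
on long branches with rare transitions, unlike rejection sampling. The
number-of-jumps series is truncated when its conditional CDF is exhausted
(cap 10⁴). Sampled maps always satisfy the structural invariants
(segment durations sum to branch lengths, adjacent segments differ,
endpoints match node states); the change-count distribution on a single
branch is tested against the closed-form conditional Poisson law. Maps
serialise to the SIMMAP annotated-Newick dialect for interchange.

## The three hypothesis tests

**Phylogenetic ANOVA** (`phylo_anova()`): the classical one-way F
statistic on tip values is compared to a null distribution of F values
from single-rate Brownian traits simulated on the tree (default 100
simulations), with the plus-one empirical p-value
$(\#\{F_\text{sim} \ge F_\text{obs}\}+1)/(n_\text{sim}+1)$. The null
simulates with the REML $\sigma^2$ of the observed trait, estimated
blind to group structure — the standard choice where the procedure is
otherwise unspecified. The classical p-value is reported alongside, as
analyses of this kind conventionally pair them. On a star tree the
simulation null converges to the classical p (tested); type-I error at
$\alpha = 0.05$ is verified to lie in [0.03, 0.07] over 1000 replicates.

**Censored two-rate test** (`censored_rate_test()`): given a stochastic
map, the single-rate Brownian model is compared to a model where each
centromere state carries its own rate on the branch segments it paints.
The two-rate restricted likelihood rescales every branch to effective
length $\sum_\text{segments}\sigma^2_\text{state}\,\text{duration}$; the
rate *ratio* is profiled numerically (golden-section on log-ratio in
[-16, 16], tolerance $10^{-8}$) while the overall scale has the usual
closed form, and the one-rate model is recomputed at ratio 1 as a
safeguard so the nesting inequality holds exactly. Likelihoods are
restricted (REML) by default, with an ML switch for cross-checks; tests
compare both rates and likelihoods to an independent restricted-likelihood
implementation. "Favours two rates" is operationalised as a
likelihood-ratio test at $\chi^2_1$, p < α, with ΔAIC also reported.
`censored_over_maps()` repeats the test across a set of maps (e.g. one
per posterior tree) and tallies outcomes, mirroring how such analyses
report "k of 100 maps favoured two rates". Calibration and power
(≥ 0.8 at a tenfold ratio, 128 tips) are part of the acceptance suite.

**Phylogenetic linear models** (`phylo_lm()`): GLS under covariance
$\sigma^2 C$ with ML residual variance; t-tests use the
$(n-k)$-denominator variance estimate, matching ordinary regression
output. Confidence intervals come from a *parametric* bootstrap —
responses re-simulated as $X\hat\beta$ + Brownian noise and refit —
because residual resampling is invalid under phylogenetic covariance
(residuals are not exchangeable). In the whitened (Cholesky) basis the
refits collapse to one matrix product, so bootstraps are cheap.
`lm_over_trees()` fits every tree of a posterior set and tallies per-tree
significance and slope signs rather than averaging statistics, which is
how multi-tree analyses of this kind are reported. On star trees the
estimates equal OLS to $10^{-8}$; slope recovery and ~0.95 bootstrap
coverage are in the acceptance suite.

Raw p-values are reported without multiple-testing correction, with
$\alpha = 0.05$ throughout, matching the analysis style this pipeline
reproduces.

## Synthetic data: what it emulates, and what it does not

`simulate_study()` generates the complete input bundle with known truth:

* an ultrametric birth–death tree (defaults: 200 taxa, birth 0.015 /
  death 0.005 per My, giving clade depths of a few hundred My — the scale
  of an order-level insect phylogeny);
* a 100-tree pseudo-posterior made by lognormal branch-length jitter
  (sd 0.1) around the true tree, re-ultrametrised by extending terminal
  branches — emulating dating uncertainty, *not* topological uncertainty;
* centromere type under a symmetric Mk process (q = 0.005/My) from a
  monocentric root;
* content per Mbp from a root of 5000 bp/Mbp with state-dependent
  Brownian rates (holocentric 10⁴, monocentric 10⁵ (bp/Mbp)²/My — a
  tenfold monocentric excess) plus a genome-size effect of +10 bp/Mbp per
  Mbp on a lognormally varying genome size (root 500 Mbp);
* chromosome numbers with *no* effect on content (a built-in negative
  control), and 10% of species given BUSCO scores below 0.90 to exercise
  the quality filter;
* optionally, per-species FASTA assemblies with planted repeats whose
  truth tables come from the reference scanner run on the *finished*
  sequence, so background repeats that arise by chance — or merge with a
  plant — are ground truth too, never spurious "false positives".

Passing tests on these data show that the estimators recover known
generating processes of the assumed form. They do not show that real
microsatellite evolution is Brownian, that real posteriors are mere
branch-length jitter, or that real assemblies contain only perfect
repeats on i.i.d. background; interrupted repeats, assembly error and
topological uncertainty are outside the generator by design.

## Pipeline, sizes, and reproducibility

`run_study()` chains the stages (optional FASTA scans → BUSCO filter at
0.90, boundary inclusive → trait/tree join with pruning → global and
per-order rates on content/Mbp → tip rates on total bp → per-tree
phylogenetic ANOVAs by centromere type for each content response → Mk
fit, stochastic maps, censored tally → regressions of content and tip
rate on chromosome number and genome size across all trees). Species
missing a field are excluded only from the analyses that need it. A
master seed spawns one named substream per stage, so reruns are
identical; each stage failure aborts with the stage name.

The test suite and `scripts/acceptance.R` run everything at reduced but
statistically meaningful sizes chosen as this package's own desk scale
(e.g. 120-species studies, 20-tree posteriors, 50 maps, 400–1000 scanner
sequences, 500–1000 Monte-Carlo replicates for calibrations); the
defaults in `study_sim_config()` and `study_config()` remain at the full
study scale (200 taxa, 100 trees/maps/simulations/bootstraps).

## Known limitations

* Only perfect repeats are detected: a single interruption splits a locus,
  so content is a lower bound relative to imperfect-repeat scanners.
* Brownian motion only — no Ornstein–Uhlenbeck, early-burst, or
  measurement-error models; rate heterogeneity is expressible only
  through the two-state censored model.
* The Mk model has two states and no hidden-rate structure.
* The censored test conditions on sampled maps; map uncertainty is
  propagated by repeating over maps, not by joint inference, and a strong
  rate signal confined to one clade can masquerade as a state effect —
  the usual caveat for discrete-state rate comparisons.
* The pseudo-posterior generator varies branch lengths only; analyses
  robust to it may still be sensitive to topological error.
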