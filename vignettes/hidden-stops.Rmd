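---
title: "Hidden stop codons in prokaryotic coding sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden stop codons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscan)
library(dplyr)
```

## The question

A coding sequence read in the wrong frame usually runs into a stop codon
quickly. These out-of-frame stop codons (OSCs, "hidden stops") terminate
translation after an accidental ribosomal frameshift, limiting the metabolic
cost of producing a useless peptide. The *ambush hypothesis* predicts that
selection should enrich coding sequences for OSCs beyond what their
composition would produce by chance. `oscan` implements the machinery needed
to ask that question genome by genome: count OSCs per frame, model the
compositional biases of the coding sequence, simulate stop-free random
genomes from those models, and test whether the observed OSC density exceeds
the simulated expectation.

Frame conventions: frame +2 starts one base into the gene (the frame reached
by a +1 frameshift), frame +3 starts two bases in (a -1 frameshift). Every
scanned OSC window straddles a junction between two in-frame codons, which
is why codon-pair (dicodon) bias is the natural alternative explanation for
any OSC excess.

## The null models

The central difficulty is that "by chance" depends on which compositional
regularities one conditions on. `oscan` fits a nested family of generative
models to a genome's own filtered CDS set, all sharing one crucial property:
they never emit an in-frame stop, because in-frame stop avoidance by itself
asymmetrically shapes trinucleotide counts in the shifted frames.

* `codon_usage` — independent draws from the genome's sense-codon
  frequencies.
* `dipeptide` — a first-order chain over amino acids, with synonymous codons
  drawn from genome-wide usage within each amino acid.
* `dicodon` — a first-order chain over codons, fitted from all adjacent
  within-gene codon pairs.
* `periodic2` / `periodic5` — second- and fifth-order three-periodic
  nucleotide Markov chains: the transition table depends on the codon phase
  of the emitted base, the standard model family of prokaryotic gene
  finders. Fitted with zero pseudocounts, so completions that would form an
  in-frame stop have exactly zero probability.

Orders above five are deliberately unsupported: prokaryotic genomes do not
contain enough coding sequence to estimate 4^7-cell tables, and no clear
biological mechanism produces such long-range oligonucleotide bias.

Sparse high-order contexts back off to the longest shorter context with data
at the same phase; the stop-codon mask is enforced at every order and again
at generation time, so back-off can never leak an in-frame stop. The initial
m-mer of each simulated gene is drawn from the empirical distribution of
gene starts, so start-codon structure emerges from the data rather than
being imposed.

Simulated genomes reproduce the exact multiset of observed gene lengths (the
strongest reading of "matching the gene-length distribution"), which makes
per-100-codon densities directly comparable across trials.

## The test, and an honest caveat about its calibration

For each genome and model, 200 Monte Carlo trials produce simulated OSC
densities per 100 sense codons. The published comparison is a one-sample
t-test treating the 200 trial densities as the sample and the observed
density as the reference constant, two-tailed, with Benjamini–Hochberg FDR
control at 5% across genomes within each (model, frame) family. The
percentage deviation `100 * (observed - mean expected) / mean expected` is
positive for overrepresentation. All of this is implemented exactly as
described.

That t statistic divides by the standard error of the *simulated mean*,
which shrinks as `1/sqrt(n_trials)`, while the observed density carries the
genome-level sampling variance of a single realisation. Under a true null
(genome actually drawn from the fitted model family) the statistic is
therefore inflated by roughly `sqrt(n_trials)`, and almost every null genome
is called significant. This is a property of the method as published, not of
this implementation — it is why reported p-values reach 10^-190 — and it
means the t-test measures "the deviation is larger than Monte Carlo noise",
not "the deviation is larger than genome-level noise". `run_expectation()`
therefore also reports `p_z`, a two-sided normal tail probability of the
observed deviation in units of the *per-trial* standard deviation. In the
package's null simulations `p_z` rejects at roughly the nominal rate (it is
mildly conservative), and we recommend reading `pct_deviation` together with
`p_z` as the effect-size-honest summary, with the t-based `q` retained for
comparability with the published analysis.

## Synthetic genomes: what they emulate and what they do not

`synth_genome()` generates stop-free CDS sets with a controllable coding
G+C content, achieved by exponentially tilting a base codon distribution by
codon G+C count and solving the tilt parameter by one-dimensional root
finding (tolerance 1e-4 on the expected G+C). Genes default to a fixed 300
codons — chosen to keep test runtimes small while staying near the
prokaryotic average gene length — with a lognormal option for more realistic
length spread. An OSC excess can be planted by reweighting every dicodon
transition whose junction spells an OSC by `1 + epsilon` and renormalising
rows; the reweighted chain's exact expected density is available in closed
form (`analytic_osc_expectation_dicodon()`), giving the pipeline a
planted-truth oracle.

Two honest notes on the planted signal. First, renormalisation means a
nominal `epsilon = 0.02` raises the chain's exact density by about 1.2%
relative to the unweighted chain (the spec of the mechanism, verified
analytically in the tests), not by 2%. Second, when the detection pipeline
refits a codon-usage model *on the planted genome itself*, the stationary
codon marginal of the reweighted chain — which is slightly enriched for
OSC-prone codons — is absorbed into the null, leaving a measurable deviation
of roughly +0.9 to +1.1% at G+C 0.5. Detection (`direction = "over"`) is
essentially certain at 10^5 codons, but the measured percentage deviation
sits near the lower edge of the nominal [1, 3] band and individual
replicates fall below 1 regularly. We report this as-is rather than
enlarging the planted effect.

What the generator does not emulate: real codon usage is shaped by
translational selection and mutation bias jointly, not by a G+C tilt alone;
real genomes have positional G+C structure (GC3 far more variable than
GC1/GC2), strand-specific skews, horizontally transferred segments, and
operon structure. Passing tests on synthetic genomes therefore validate the
*machinery* — counting, model fitting, generation, calibration of the
statistics — and deliberately not any biological claim about real genomes.
The frame-equality composition (the G+C at which frames +2 and +3 carry
equal OSC counts) illustrates this: tilted-uniform genomes cross near
G+C 40%, whereas real genomes, with their different stop-usage balance,
cross near 48%.

## Filtering and other data-handling choices

`filter_cds()` excludes annotated pseudogenes, incomplete features
(locations with `<`/`>`), plasmid-flagged records (configurable), sequences
with ambiguous bases, genes shorter than 100 codons, lengths not divisible
by three, and genes with internal in-frame stops (annotation artefacts and
recoded genes such as selenoproteins, which would poison a zero-pseudocount
stop-free model). Terminal stop codons are stripped by default so that both
real and simulated sequences consist of sense codons only; every density
uses total sense codons as its denominator. A `keep_terminal_stop` flag
restores the alternative convention.

Stop-codon sets follow the NCBI translation tables (11 for
bacteria/archaea; 4 for *Mycoplasma*-like genomes where TGA is tryptophan;
2, 3 and 13 for mitochondrial variants), so OSC counting, model fitting and
generation all respect alternate genetic codes end to end.

Genus-level trimming (`select_one_per_genus()`) draws one genome per genus
uniformly under a seed, and `build_metagenome()` pools whole genomes in
seed-determined order until a target coding size is reached — both mirror
standard precautions against phylogenetic oversampling.

## Descriptive statistics layer

OSC usage bias is the vector of relative stop-codon frequencies within each
alternate frame (two 3-simplices, normalised per frame; frames with no OSC
are flagged undefined and dropped from multivariate analyses with a logged
count). The PCA of usage is centred but not scaled, since all six variables
already share the frequency scale, with a deterministic sign convention.

Relative importance of correlated regressors uses the proportional marginal
variance decomposition (PMVD): sequential R² increments averaged over all
regressor orderings with data-dependent weights (each ordering weighted
inversely to the product of unexplained variance remaining after each
step), computed by exact enumeration — all analyses here use at most six
regressors, so enumeration is exact and cheap — with case-resampling
percentile bootstrap intervals. PMVD and the equal-weights LMG decomposition
coincide on orthogonal designs, which the tests verify to 1e-9; PMVD's
distinguishing property, a near-zero share for a regressor with no partial
effect, is also tested directly.

Stepwise model selection minimises the Gaussian AIC (2k penalty) by greedy
add/drop from the full model with deterministic tie-breaking. The
growth-temperature analysis regresses percentage deviation on optimal
growth temperature, G+C and AT skew; when only thermal categories are
available they enter as midpoints (psychrophile 10, mesophile 37,
thermophile 60, hyperthermophile 85 °C).

## Reproducibility and numerical choices

Every stochastic routine takes an integer seed; per-trial and per-genome
seeds are derived deterministically from it, so results are bit-identical
across reruns and invariant to execution order. Generation is implemented in
C++ (Rcpp) using R's RNG, so `set.seed()` governs everything. Degenerate
situations have defined behaviour: zero-variance trial densities equal to
the observed value give `t = 0, p = 1` and otherwise a degeneracy flag with
`p = 0`; a frame with no OSCs yields an undefined usage vector and an
undefined frame bias rather than an infinity.

Problem sizes in the test-suite were chosen to finish in minutes on one
core: genomes of 10^4–10^5 codons, 200 trials where the comparison is
quantitative, fewer where only determinism or plumbing is being checked;
the order-2 parameter-recovery check uses 10^6 simulated nucleotides, which
bounds every transition-probability error below 0.01.

## Known limitations

* Exact analytic OSC expectations are provided for the i.i.d. codon model
  and the dicodon chain; the periodic and dipeptide models are covered by
  Monte Carlo only.
* No within-gene positional analysis of OSCs (where in the gene the hidden
  stops sit) and no overlapping-window scanning.
* The GenBank reader is a minimal flat-file parser (CDS features,
  `complement`/`join` locations, the qualifiers the filters need); unusual
  location syntax falls back to marking the record incomplete rather than
  guessing.
* The t-test calibration caveat above applies to any use of the published
  statistic on data that were not generated by the fitted model family.
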