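---
title: "Translatome analysis of paired total and polysomal RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translatome analysis of paired total and polysomal RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(polysomics)
library(dplyr)
```

## The design

Polysome profiling separates mRNAs on a sucrose gradient by the number of
ribosomes they carry; the polysomal fraction approximates the actively
translated transcriptome. Sequencing a *total* library and a *polysomal*
library for each of two conditions (here labelled `PRE` for presenescent
and `SEN` for senescent cells) gives a 2x2 design with four libraries and —
in the budget-constrained experiments this package targets — **no
biological replicates**: one library per cell of the design.

The questions such an experiment answers are:

1. Which genes change *transcriptionally* (total fraction, SEN vs PRE)?
2. Among genes whose transcription is unchanged, which change
   *translationally* (polysomal fraction, SEN vs PRE)?
3. Are translationally suppressed transcripts enriched for 5' terminal
   oligopyrimidine (TOP) tracts, the sequence element through which mTORC1
   controls translation?
4. Do bench assays (spike-normalized RT-qPCR, growth curves, SA-beta-gal
   staining) confirm the sequencing calls?

`polysomics` implements each step as a tibble-in / tibble-out function, plus
a simulator with known ground truth so that the whole pipeline can be
exercised and calibrated end to end.

## The simulator

`sim_config()` + `simulate_polysome_experiment()` generate the four count
libraries. The expected count of gene $g$ in library $L$ is

$$\mu_{gL} \propto b_g \cdot
  \tau_g^{[\mathrm{SEN}]} \cdot
  \left(\gamma_g \, s\right)^{[\mathrm{polysomal\ and\ SEN}]}
  \cdot \ell_g,$$

scaled so each column sums to its configured depth, where $b_g$ is the
baseline abundance (log-normal across genes), $\tau_g$ the transcriptional
fold change, $\gamma_g$ the translational fold change, $s$ the **global
polysomal scalar** (a uniform suppression of the senescent polysomal
fraction, modelling a genome-wide reduction of translation) and $\ell_g$
the transcript length (longer transcripts yield more fragments). Counts are
drawn negative-binomially with $\mathrm{Var} = \mu + \phi\mu^2$; $\phi = 0$
gives Poisson draws. The dispersion default is $\phi = 0.1$, a typical
bulk-RNA-seq biological dispersion; it is a user choice because a design
with one library per group leaves dispersion unidentifiable from the data.

Two structural features matter downstream:

* **The spike transcript.** One extra row (default `spike_mScarlet`,
  1000 bp) is present only in the polysomal libraries, at an abundance that
  is identical in both conditions and deliberately *not* multiplied by the
  global scalar — it models an exogenous RNA added at a fixed concentration
  to each collected fraction.
* **Composition invariance.** Because the global scalar multiplies every
  endogenous gene equally and columns are renormalized to depth, it leaves
  the relative proportions of endogenous genes unchanged. Any
  internal-control normalization is therefore blind to global suppression;
  only the spike can reveal it. `expected_counts()` exposes the
  deterministic means so this invariance can be checked exactly.

Designed effects come from nine design classes (transcriptional x
translational: up / down / unchanged). Defaults: 70% of genes doubly
unchanged, the rest split evenly across the eight effect classes; effect
magnitudes 2.0 (up) and 0.4 (down), comfortably outside the 1.5 / 0.667
calling thresholds. Library depth defaults to 2x10^6 reads per library —
small enough to iterate quickly, deep enough that per-gene counts (mean
~1000) put the analysis in the regime where dispersion, not counting noise,
limits inference.

All randomness flows from the single `seed` in `sim_config()` with fixed
stream offsets per stage (truth +0, counts +1, UTRs +2 and +20, qPCR +3),
so stages rerun individually reproduce the end-to-end run.

What the simulator does **not** emulate: read-level artefacts (mapping
bias, duplication, GC effects), transcript-isoform ambiguity,
length-dependent biases beyond the linear length term, correlated
dispersion across libraries, or ribosome-footprint resolution. Passing
tests demonstrate that the analysis recovers what the model puts in — not
that real libraries satisfy the model.

## Normalization: TMM and FPKM

`tmm_factors()` implements trimmed-mean-of-M-values scaling. For library
$k$ against a reference $r$, over genes with nonzero counts in both,

$$M_g = \log_2 \frac{x_{gk}/N_k}{x_{gr}/N_r}, \qquad
  A_g = \tfrac12\left(\log_2 \frac{x_{gk}}{N_k} + \log_2 \frac{x_{gr}}{N_r}\right),$$

the most extreme 30% of $M$ and 5% of $A$ are dropped from each tail
(ranks `floor(n*trim)+1 … n-floor(n*trim)`, ties broken by input order),
and the factor is $2$ to the precision-weighted mean of the surviving $M$,
with delta-method weights
$1/\big(\tfrac{N_k-x_{gk}}{N_k x_{gk}} + \tfrac{N_r-x_{gr}}{N_r x_{gr}}\big)$
(an unweighted mean is available via `weighted = FALSE`). The reference is
chosen automatically as the library whose upper-quartile count proportion
is closest to the mean upper quartile. Factors are rescaled to geometric
mean 1 so effective sizes stay near raw sizes; downstream ratios depend
only on relative factors, so the convention is cosmetic but fixed.

`fpkm()` applies $\mathrm{FPKM} = 10^9 x / (\tilde N \,\ell)$ with
$\tilde N$ the TMM-effective size by default (`use_effective = FALSE`
switches to raw column sums; the choice only rescales columns and the
package defaults to the TMM-corrected version for consistency with the
factor estimation).

## Testing without replicates

With one library per condition there is no within-group variance to
estimate, so `exact_pair_test()` conditions on the per-gene total
$t = x_{\mathrm{PRE}} + x_{\mathrm{SEN}}$. Under the null and $\phi = 0$,

$$x_{\mathrm{SEN}} \mid t \sim
  \mathrm{Binomial}\!\left(t,\ \frac{\tilde N_{\mathrm{SEN}}}
  {\tilde N_{\mathrm{PRE}} + \tilde N_{\mathrm{SEN}}}\right),$$

and the two-sided p-value sums the probabilities of all outcomes no more
likely than the observed one (minimum-likelihood convention, as in exact
binomial tests; tail-doubling is available via `two_sided = "double"`).
With `dispersion` $\phi > 0$ the same conditioning is applied with outcome
weights proportional to the product of two negative-binomial masses at
fixed $\phi$. $t = 0$ returns p = 1. The test is symmetric in the two
libraries and invariant to rescaling both effective sizes.

`run_contrast()` assembles a per-fraction result: FPKM ratio with a
pseudocount ($\varepsilon = 0.1$ FPKM on both numerator and denominator, so
zero-denominator genes stay classifiable), exact-test p-values, and
Benjamini–Hochberg q-values computed *within* the fraction (the two
contrasts answer different questions, so each carries its own FDR).
The test model (`binomial` vs fixed-$\phi$ `nb`) is a pipeline-level
switch. The binomial default is exact for Poisson noise but anti-conservative
when counts are overdispersed; the `nb` mode is calibrated at its assumed
$\phi$ but, like any fixed-dispersion choice in a replicate-free design, the
value of $\phi$ is an assumption, not an estimate.

## The two-stage classifier

`classify_genes()` applies the fold-change gates: transcriptional class
`up` above 1.5, `down` below 0.667, `unchanged` otherwise — strict
inequalities, so a gene at exactly 1.5 is unchanged. Only transcriptionally
unchanged genes receive a translational trend (same thresholds on the
polysomal ratio), and a trend is *significant* when the polysomal q-value
is below 0.05. Genes with a transcriptional call get
`translational_trend = "not_applicable"`: the partition is exact by
construction, and restricting translational calls to the transcriptionally
flat stratum is what makes a polysomal change interpretable as a change in
translation rather than in transcript supply. The down threshold is 0.667
by default (0.67 is also in circulation; the value used is echoed in the
result's `"thresholds"` attribute so either convention can be reproduced).
Both a q-gated and a trend-only (no q) reading are available from the same
output, since both conventions are used for such designs.

`recovery_report()` scores the significant translational-down set against
designed truth (positives are genes designed translationally down with
unchanged transcription — the only genes the two-stage gate can call by
design).

### What recovery one can expect

A replicate-free design has an information floor: the variance of the
observed log fold change cannot drop below $2\phi$ (natural-log scale)
however deep the sequencing, because each condition contributes one
realisation of the gene's biological dispersion. At $\phi = 0.1$ that floor
is $\mathrm{sd}(\log_2 \mathrm{ratio}) \approx 0.65$, so a designed fold
change of 0.4 ($|\log_2| = 1.32$) sits only ~2 standard deviations from
the null — raw per-gene power near 0.5 at p < 0.05, far less after BH, and
the designed-down genes themselves pass the transcriptional-unchanged gate
only ~60% of the time for the same reason. The package reports what the
data admit: at these settings the significant set is nearly pure
(empirical FDR ~0) but small (sensitivity of a few percent). Treating
trend calls (no q gate) as the readout, sensitivity rises to roughly the
gate ceiling. This is a property of the design, not of the implementation;
it is why bench validation of individual candidates matters in such
studies.

## TOP and TOP-like scanning

`scan_utr()` takes a TSS-anchored 5'UTR (position 1 = +1 base) and calls:

* **TOP** — base 1 is `C` and the maximal pyrimidine run starting at
  position 1 has length >= 5 (the canonical C followed by at least 4
  pyrimidines). Runs longer than 15 still call TOP by default;
  `strict_max = TRUE` enforces the classical 14-pyrimidine cap, in which
  case longer tracts fall through to the TOP-like rule.
* **TOP-like** — not TOP, but some maximal pyrimidine run of length >= 5
  starts within the first 4 positions. The near-TSS window and the minimum
  run are parameters because the literature does not fix a single
  convention.
* Ambiguity codes (`N` etc.) terminate runs — conservative, a run is never
  called across uncertain bases. Lowercase input is uppercased.

`generate_utr_set()` constructs sequences whose designed class is forced by
the rule (and whose "none" sequences place a purine at position 5, so no
qualifying run can start inside the window), which gives the scanner an
exact round-trip test; an independent regex oracle in the test suite
provides a second route. In the pipeline, translationally-down genes
receive TOP/TOP-like designs at ~3%/2% (the approximate enrichment seen
among translationally suppressed transcripts in senescent fibroblasts) and
other genes at a 1%/1% background.

## Validation-assay arithmetic

`ddct_ratio()` implements Livak relative quantification: replicate Ct
values are averaged *before* differencing
($\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{control}$ per
condition, ratio $= 2^{-\Delta\Delta Ct}$); the error bar is the SEM of the
exponentiated per-replicate test-condition values (replicates paired by
index against the mean reference $\Delta Ct$), matching the
"mean ± SEM, n = 3" convention of bench figures rather than a delta-method
approximation on Ct. The ratio is invariant to any constant Ct offset.

`spike_double_ratio()` computes the target's spike-normalized ratio divided
by the internal control's spike-normalized ratio. Against a fixed exogenous
spike, a global suppression shows up in *both* numerator and denominator
(each ≈ the global scalar), while the quotient isolates the
target-specific change; with noiseless data it equals the plain
internal-control ddCt exactly. Spike normalization is applied per fraction
(the spike is added to each collected fraction, so each fraction carries
its own spike reference).

`growth_curve()` accumulates population doublings
($PD = \log_2(\text{collected}/\text{plated})$, summed over passages) and
`betagal_rate()` converts stain counts to percentages with a counting-depth
QC flag (>= 200 cells for presenescent, >= 100 for senescent samples, the
weaker senescent minimum reflecting how few adherent senescent cells a
field contains).

## Problem sizes and numerical choices

* Tests and the acceptance script simulate 2000 genes at 2x10^6 reads per
  library (50-gene tables for normalization oracles, 10^4 random sequences
  for the scanner), sizes chosen so the full suite exercises every code
  path in a couple of minutes on a laptop while keeping per-gene counts in
  a realistic bulk range.
* Exact-test enumeration is over the full conditional support; for
  binomial totals above 10^5 the enumeration is windowed to the central
  1 - 10^-15 of the null mass with the excluded tails added to the p-value
  (they are strictly less likely than any retained outcome), an error far
  below reporting precision.
* Probability ties in the minimum-likelihood sum use a 1 + 10^-7 relative
  slack, the standard guard against floating-point ties in exact tests.
* TMM trimming keeps rank windows, ties broken by input order, making the
  factor exactly reproducible under gene permutation (up to the documented
  tie rule) and comparable to an independently coded oracle at 10^-10.

## Limitations

* The exact conditional test treats the assumed dispersion as known;
  p-values are exact only under that assumption. No shrinkage or empirical
  Bayes is possible without replicates.
* TMM assumes most genes are not differentially expressed between the
  compared libraries; a genuinely global shift (the very thing the spike
  qPCR is designed to detect) is invisible to count-based normalization.
* The scanner requires TSS-anchored input; it does not infer TSSs from
  annotation, and alternative TSS usage will mis-anchor the window.
* Designed UTRs are rule-forced constructions, not draws from genomic
  5'UTR composition; scanner specificity on real UTRs depends on TSS
  annotation quality, which the simulation cannot capture.
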