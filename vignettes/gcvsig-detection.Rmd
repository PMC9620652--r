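---
title: "Detecting the ganciclovir mutational signature in sparse panel data"
author: "sparsesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the ganciclovir mutational signature in sparse panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsesig)
```

## The problem

Ganciclovir (GCV), an antiviral given to most solid-organ and stem-cell
transplant recipients for cytomegalovirus, is mutagenic: it leaves a highly
distinctive single-base-substitution signature (GCVsig) dominated by C>A
substitutions with a 3' adenine — CA>AA dinucleotide changes. Screening for
this signature in the large clinical sequencing cohorts where transplant
histories are hidden requires calling a 96-channel signature from *targeted
panel* data, where a typical sample carries fewer than ten somatic SNVs.
At such depths, naive signature refitting is dominated by noise: an exposure
estimate from 15 mutations can easily place 20--30% of them on any C>A-rich
signature by chance.

sparsesig implements a screening pipeline for this regime:

1. build SBS96 trinucleotide spectra from MAF-like mutation tables;
2. estimate per-sample signature exposures ("contribution scores") by
   maximum-likelihood refitting against a fixed catalog;
3. calibrate, by simulation, the GCVsig score that a *null* sample —
   one whose mutations come from SBS18 (the most GCVsig-like common
   process) plus a clock-like SBS5 background — exceeds only 1% of the
   time, as a function of mutation count;
4. compress that calibration into a regression surface so per-sample
   cutoffs are a formula evaluation, not a fresh simulation;
5. call samples, attach chi-square p-values against the cohort-average
   expectation with Benjamini--Hochberg correction, and estimate a
   cohort-level false discovery rate by permutation.

Replication-strand asymmetry summaries and driver-hotspot accessibility
scores provide orthogonal corroboration of a GCV aetiology.

## Exposure estimation

Refitting treats a sample's 96-channel count vector $x$ as multinomial with
channel probabilities $\sum_k e_k P_{ck}$, where $P$ is the fixed
column-stochastic signature catalog and $e$ the exposure vector on the
simplex. Exposures are found by a monotone EM update
($e_k \leftarrow e_k \sum_c x_c P_{ck} / m_c / n$, with $m = Pe$) from
uniform initialisation, run to a $10^{-8}$ change tolerance (cap 10,000
iterations — the fit costs microseconds at 96 channels, so the generous cap
is free). The sample's **GCVsig contribution score** is the fitted exposure
of the signature named `GCVsig`.

A Bayesian refit with a flat prior concentrates at this same maximum
likelihood point as counts grow; we use the MLE directly because the
pipeline needs *deterministic* scores — identical inputs must give bitwise
identical calls, both for reproducible cohort screens and for frozen-seed
testing. With disjoint signature supports the MLE is exactly the count
split between supports, which anchors the unit tests; on overlapping
catalogs the EM solution is verified against dense grid searches of the
likelihood.

## FDR calibration

The null model for a GCVsig-looking-but-innocent sample is a spectrum of
$n$ mutations drawn from $0.95\,\text{SBS18} + 0.05\,\text{SBS5}$ (SBS18 is
the common signature most similar to GCVsig; the small SBS5 term represents
the ubiquitous clock-like background). For each mutation count on a
log-spaced grid spanning 1--10,000, 1000 such spectra are simulated
(`rmultinom`) and refit, and the 99th-percentile GCVsig score — nearest-rank
definition, i.e. the 990th order statistic — becomes the **1% FDR cutoff**
at that count. Queries between grid counts interpolate linearly in
$\log(n)$, where the curve is nearly linear; simulating every integer count
would cost three orders of magnitude more for accuracy far below the Monte
Carlo noise of the percentile itself. An identically built SBS38 curve is
applied *in addition* to skin malignancies only, since UV-associated SBS38
is an alternative source of C>A enrichment there.

The dominant-process curve is deliberately stringent for samples whose
mutations come from several processes at once. For those, cutoffs are
simulated over a grid of null contributions 0.05--0.95 (step 0.05, the
remainder SBS5) by mutation counts 5--250 (step 5), and the surface is
summarised by ordinary least squares as

$$\text{cutoff} = \beta_0 + \beta_1 n + \beta_2 \log n + \beta_3 c +
\beta_4\, c \log n,$$

with $n$ the count and $c$ the null-signature contribution. Predictions are
clamped to $[0,1]$. On noiseless synthetic surfaces the fit recovers
generating coefficients exactly; on simulated surfaces from the packaged
synthetic catalog it attains $R^2 \approx 0.96$ (SBS18) and
$\approx 0.89$ (SBS38) — the SBS18 surface is smoother because that
signature overlaps GCVsig more uniformly across contexts.

### Per-sample decision logic

* Samples with fewer than 10 mutations are **not evaluable**: below that
  count the refit assigns diffuse low scores to everything and the cutoffs
  are unreliable.
* Samples with more than 10 CA>AA mutations take their cutoff from the
  regression surface, entering their CA>AA fraction as the estimated null
  contribution $c$ — the screen for samples with mixed mutational
  processes.
* All other samples are compared against the 0.95-mixture curve at their
  count.
* A sample is **positive** when its score exceeds the SBS18 cutoff and, for
  skin samples only, also the SBS38 cutoff.

### Statistical behaviour, honestly stated

Two properties of this design are worth knowing. First, the cutoff at each
grid count is itself an order statistic of 1000 simulations, so the
realised false-positive rate of fresh nulls against it is unbiased at
$10/1001 \approx 1\%$ but has roughly twice the variance of a binomial rate
at a *known* 1% cutoff; single-batch checks of "is the rate 1%?" should
budget for that. Second, the regression surface carries lack-of-fit
residuals of about $\pm 0.01$--$0.02$ in score units; samples whose scores
sit within a residual of their cutoff can flip either way relative to a
direct simulation of their exact (contribution, count) cell. Both effects
are inherent to the published design; the chi-square/BH stage and the
cohort permutation FDR exist precisely to keep such borderline calls
honest at cohort level.

## Cohort-level significance

For every evaluable sample the observed GCVsig frequency
$(s \cdot n,\ (1-s)\cdot n)$ is compared to the expectation under the
cohort-wide average spectrum — the mean refit score over 1000 multinomial
draws of size $n$ from the pooled cohort frequencies — with a 1-df
chi-square statistic $\sum (O-E)^2/E$ (frequencies used as-is, not
rounded). P-values are Benjamini--Hochberg adjusted across evaluable
samples. Separately, the whole calling procedure is re-run 10 times on
permuted cohorts in which every sample's spectrum is replaced by a draw of
the same size from the cohort average; the mean positive count over
permutations divided by the observed positive count estimates the cohort
FDR. Preserving each sample's count keeps the permutation null matched on
power.

## The synthetic cohort generator

Real screening cohorts (GENIE-like multi-panel registries; single-platform
FM-like cohorts) are access controlled, so the package generates cohorts
with the statistical structure the analysis assumes: per-sample counts from
a rounded lognormal with mean near 8 (GENIE-like preset truncated at
10,000; FM-like at 400, matching the printed ranges of such cohorts);
per-sample background mixtures sampled from a configurable list —
defaults: pure SBS5 (50%), half SBS18 for ROS-driven epithelial tumours
(30%), an SBS38 blend (20%) so the skin branch is exercised; and GCVsig
spike-ins at a controlled exposure in a controlled fraction of samples,
forced to at least 50 mutations so spiked samples are evaluable. Contexts
are emitted directly with each record (half on the purine strand to
exercise reverse complementing); a random reference FASTA covers the
sequence-lookup path. The generator is a pure function of its spec and
seed.

What the generator does *not* emulate: panel footprint differences,
copy-number, allele frequencies, sequencing artefacts, or the true COSMIC
signature shapes — the packaged catalog is a synthetic stand-in with the
right qualitative structure (GCVsig holds ≥ 75% of its mass on the four
CA>AA channels; SBS18 is broadly C>A-heavy; SBS38's C>A mass favours
5'/3'-T contexts; SBS5 is flat-ish). Passing tests therefore demonstrate
the statistical machinery, not performance on real panels; runs on real
data should load the real COSMIC v3 catalog plus a measured GCVsig
spectrum via `readSignatureCatalog()`.

## Numerical choices and edge cases

* Percentile: nearest rank (`ceiling(p/100 * N)`-th order statistic) —
  exact at the design point (rank 990 of 1000) and free of interpolation
  conventions.
* Age ties in patient dedup resolve to the lexicographically first sample
  id; samples without age are never preferred over dated ones, and
  patients with no dated sample keep their first-listed one (logged).
* Coordinates are 1-based inclusive on disk (MAF convention).
* Empty spectra are unfittable (error); zero-total CA>AA fractions are 0
  and flagged undefined.
* All simulation cells derive independent child seeds from one root via a
  31-bit hash of (signature, contribution, count), so any cell can be
  reproduced in isolation and the 0.95-mixture surface column equals the
  curve at the same seed.
* Replication-strand convention: a pyrimidine-strand C>A in a
  right-replicating region (fork moving toward increasing coordinates) is
  "leading"; the G>T representation flips. The annotation generator uses
  the same convention, so planted biases round-trip.
* Hotspot gene selection computes count variance over *annotated* positions
  (zero-count positions are not enumerable from census-style exports), drops
  TP53 whose hotspot volume would dominate any variance ranking, keeps the
  top 50 genes and hotspots with ≥ 100 occurrences.

## Validation scale

The shipped tests and the acceptance script run desk-scale versions of the
full design: curves at full depth (1000 reps) on reduced count grids;
regression surfaces at 150--300 reps per cell on grids of 49--475 cells;
cohorts of 120--500 samples; 1000-draw self-consistency checks at three
counts. These sizes give Monte Carlo error comfortably below the effect
sizes being asserted while keeping a complete run in minutes; production
calibrations should use `calibrateDetection()` defaults (950 cells, 1000
reps) and cache the JSON artifact.

## Known limitations

* The CA>AA fraction entered into the regression as the null contribution
  *underestimates* the true SBS18 weight of an SBS18-dominated sample
  (SBS18 spends only part of its C>A mass on CA>AA channels), so
  regression-path cutoffs are mildly anti-conservative for strongly
  SBS18-driven tumours; the BH and permutation stages are the guard rails.
* No opportunity (trinucleotide abundance) normalisation is applied by
  default: panel spectra are fit raw, matching how the cutoffs are
  calibrated. An opportunities vector can be supplied when building
  catalogs externally, but both sides of the comparison must use the same
  convention.
* No indel/doublet channels, no transcription-strand asymmetry, no de novo
  signature extraction.
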