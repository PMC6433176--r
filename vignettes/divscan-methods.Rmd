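---
title: "divscan: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{divscan: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

## What this package computes

`divscan` is a windowed population-genomic divergence toolkit for a pair of
closely related species sampled with multi-sample whole-genome resequencing
(the motivating system is a pair of northeastern-Asian columbines with 16
accessions per species plus two F1 hybrids, 7 nuclear chromosomes and a
~129 kb chloroplast).  From a filtered genotype matrix it computes, per
non-overlapping 100-kb window: nucleotide diversity (π), segregating sites
(S) and Tajima's D per population; Weir–Cockerham F~ST~, absolute divergence
D~xy~ and fixation-site counts (Fs) between the species pair.  On top of the
window table it classifies outlier windows into selection-candidate
categories, runs a SweepFinder-style composite-likelihood sweep scan, and
builds NJ/UPGMA distance trees.  A bundled coalescent simulator generates
data with the statistical structure the analysis assumes, so the whole
pipeline is testable end to end without any real data.

## Variant filtering

Raw variants are filtered with strict cutoffs: site mapping quality MQ > 20
and per-sample read depth DP > 3 (genotypes at lower depth are set to
missing, not dropped with the site).  Only biallelic SNPs feed the window
statistics; multiallelic records are removed, never decomposed, and INDELs
are parsed (they participate in the shared-variant Venn analysis via
`keep_indels = TRUE`) but excluded from all diversity statistics.  The
per-site missing-call ceiling after depth masking is a knob
(`max_missing`, default 0.2): the upstream convention it mirrors is not
fully specified, and 20% is a common working value in resequencing studies
of this size.

## Estimators

**π** is computed per window as
\(\pi = \tfrac{1}{L}\sum_s \tfrac{n_s}{n_s-1} 2p_s(1-p_s)\), the unbiased
per-site mean pairwise difference summed over SNPs and divided by the full
window length \(L\) — the `--window-pi` convention of the tool family this
package emulates, in which invariant and uncallable positions contribute
zero to the numerator but stay in the denominator.  An alternative
"callable-sites" denominator is deliberately not the default: it changes the
scale of every published comparison.

**Tajima's D** uses the 1989 constants with \(\hat k\) the absolute mean
pairwise difference count.  With missing data the per-site sample size
varies; each window uses the median called-allele count as \(n\) and
excludes sites deviating from it by more than 20%, which keeps the variance
constants coherent without discarding whole windows.  \(S = 0\) yields `NA`,
never 0 — an undefined D is not evidence of neutrality.

**F~ST~** is the Weir–Cockerham (1984) two-population estimator computed
from the per-site variance components \(a\) (between populations), \(b\)
(between individuals within populations) and \(c\) (within individuals,
from observed heterozygote frequencies).  The windowed value is the
ratio-of-sums \(\sum a / \sum(a+b+c)\) ("weighted"); the mean of per-site
ratios is reported as a secondary column, mirroring the two outputs users
know from VCFtools.  Negative estimates are reported as computed.

**D~xy~** is \(\tfrac{1}{L}\sum_s [p_{1s}(1-p_{2s}) + (1-p_{1s})p_{2s}]\),
length-normalized (the standard definition; whether the original analysis
normalized by length or SNP count is not recoverable, so the standard was
chosen and flagged).  **Fs** counts sites at which the two populations carry
disjoint allele sets; a population containing a heterozygote carries both
alleles and is never fixed.

The chloroplast is short and non-recombining, so it is analysed as a single
matrix (one "window" spanning the molecule) with haploid coding.

## Outlier-window classification

Within each species the bottom 5% of windows by π are low-nucleotide-
diversity (LND) candidates; the top 5% of interspecific F~ST~ windows are
high-genetic-divergence (HIGD) windows.  LND in exactly one species ∧ HIGD
⇒ adaptive-selection candidate for that species; LND in both ∧ HIGD ⇒
divergent-selection candidate; shared LND windows in the bottom 5% of
F~ST~ are reported separately.  Quantiles are computed genome-wide (the
single printed thresholds of the motivating study imply genome-wide tails)
over windows with defined values; ties at the threshold are inclusive, so a
tail can exceed \(q \cdot n\) — an arbitrary, seed-dependent exclusion of
tied windows would be worse.  Because a claimed count of "species-specific"
LND windows is ambiguous when most LNDs are shared, the summary always
reports shared and exclusive counts side by side.

## The composite-likelihood sweep scan

Each chromosome is divided into 2,000 near-equal bins (widths differ by at
most 1 bp) and a composite likelihood ratio is evaluated at every bin
midpoint.  The background model is the genome-wide folded site-frequency
spectrum (folded because no outgroup polarization is assumed).  The sweep
model distorts the background through an escape probability: a lineage at
distance \(d\) from the swept site escapes the sweep with probability
\(p_e = 1 - e^{-d/\alpha}\).

A note on the parameterization: α here is the *physical footprint scale of
the sweep in bp*, so α = 0 means "no footprint" and the model collapses
exactly onto the background — the CLR is then non-negative by construction
because the maximized grid contains the exact null.  (Writing the exponent
as α·d instead would invert the role of the null; the collapse-at-zero
requirement fixes the choice.)  The grid is 15 log-spaced footprints from
1/200 of the flank to twice the flank, plus exact 0.

Given pre-sweep sample frequency \(j/n\) and escape probability \(p_e\),
the post-sweep sample is modelled by drawing the escaped lineages *without
replacement* from the pre-sweep sample, with the swept block inheriting one
further draw.  The hypergeometric sampling matters: at \(p_e = 1\) the
post-sweep sample *is* the pre-sweep sample, so the model also collapses to
the background far from the test site, which keeps distant sites from
contributing spurious signal.  Probabilities are conditioned on
polymorphism, folded, and tabulated on a 101-point \(p_e\) grid for speed.
Sites not fully called in the focal population are excluded (the class
model needs a uniform \(n\)); fixed differences are excluded — only
polymorphic classes are modelled, a documented simplification relative to
SweepFinder's invariant-class option.  Bins with no site within the 200-kb
flank yield `NA`, and `CLR > 20` flags a sweep candidate.

The scan claims *calibration*, not bit-parity with SweeD: under a neutral
constant-size simulation fewer than 2% of bins exceed the threshold, and a
planted sweep's maximum-CLR bin localizes to within a few bins of truth
(both are acceptance-tested).

## Distance trees

Following the matrix-construction convention of the motivating study, sites
with any missing call are removed; the *homozygous* matrix keeps sites
homozygous in every sample and the *full* matrix keeps everything.  The hom
matrix uses the p-distance on the single allele each sample carries; the
full matrix uses the allele-sharing distance
\(d = \mathrm{mean}(|g_i - g_j|/2)\) on unphased dosages, equivalent to
comparing unordered allele pairs (how IUPAC heterozygote codes were handled
by the original GUI tool is undocumented; allele sharing is the defensible
choice).  UPGMA (average linkage, ultrametric, rooted) and NJ (Saitou–Nei,
unrooted) come from `stats::hclust` and `ape::nj`; negative NJ branches are
clamped to zero with the deficit moved to the adjacent branch.  A
site-resampling bootstrap with majority-rule support is available
(`bootstrap_tree`, default 100 replicates).  p-distances only — model
corrections (JC, K2P) are out of scope, with the distance function as the
extension hook.

## The simulator: what it emulates and what it does not

`simulate_divergence()` realizes a structured coalescent for two demes that
merge into a common ancestor at `t_split`, with per-species bottleneck
epochs inside the species branches, optional secondary-contact migration
restricted to `[0, t_contact]`, and a haploid uniparental chloroplast with
effective size N/2 and a reduced mutation rate (μ/5, giving roughly the
10-fold diversity gap seen between organellar and nuclear genomes in this
system).  Defaults mirror the motivating design: 16 + 16 diploids + 2 F1
hybrids, 7 nuclear chromosomes, ~129 kb chloroplast, μ = 10⁻⁸ per bp per
generation, 1-year generations, t_split = 2N generations with bottlenecks
to N/5 near the split and weak recent migration.  Chromosomes default to a
desk-scale 5 Mb rather than real chromosome lengths.

Three deliberate approximations, and their consequences for what a green
test establishes:

* **Independent loci.** Each 100-kb locus is an independent non-recombining
  genealogy; there is no intra-window recombination and no linkage between
  windows.  Per-window statistics have realistic means (π ≈ 4Nμ is
  acceptance-tested to 15%) but *larger* between-window variance than real
  data, and window autocorrelation is absent.  Tests of genome-wide means
  and of per-window machinery are meaningful; tests of spatial clustering
  of windows would not be.
* **Post-hoc sweeps.** A hard sweep is imposed by overwriting each lineage's
  allele with a randomly chosen beneficial haplotype's allele with
  probability \((1-p_e)\,e^{-t_{fix}/2N}\), per site independently, with the
  classic footprint \(s/(r\log 2Ns)\).  This reproduces the diversity trough
  and SFS distortion the CLR model expects (deliberately model-matched: the
  sweep-recovery acceptance test calibrates the scan's localization, not its
  power against nature), but ignores the correlation of escape events along
  a haplotype.
* **Unphased hybrid gametes.** F1 hybrids draw one gamete per parental
  species from unphased parents, so heterozygous parental sites transmit
  independently.  Fixed-difference sites are deterministic — every hybrid is
  heterozygous there, which is the contract the hybrid tests exercise.

Determinism: one seed drives everything; identical seeds give byte-identical
VCFs, and the truth record (JSON sidecar) suffices to replay a run exactly.

## Numerical and degenerate-input conventions

Undefined statistics are `NA` (written as the literal `NA` token), never 0.
Empty filter results warn and return an empty matrix.  Zero-length
chromosomes produce no windows, with a warning.  Constant statistic vectors
make every window tie at the outlier threshold, with a warning.  UPGMA and
hclust tie-breaks are deterministic in label order.  Model probabilities are
floored at 1e-300 before logging.  A diploid VCF that encodes a missing
genotype as `.` rather than `./.` is rejected as mixed ploidy (the writer
always emits `./.`).

## Known limitations

Parsing is delegated to `VariantAnnotation`, so malformed-record errors name
the file, not the offending line.  The CLR scan is O(bins × flank sites);
with very dense data reduce `n_bins` or the flank.  Window quantiles are
genome-wide only.  No LD-based statistics, no gene annotation of candidate
windows, no demographic inference — the simulator states scenarios, it does
not fit them.
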