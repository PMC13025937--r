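---
title: "BSA-seq genome scans: simulation, ED4 and G' statistics, and interval calling"
author: "bsascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BSA-seq genome scans: simulation, ED4 and G' statistics, and interval calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The problem

Bulked segregant analysis sequencing (BSA-seq) localizes loci underlying a
quantitative trait by pooling the DNA of phenotypically extreme individuals
from a segregating population and sequencing the two pools. At a marker
linked to a causal locus, the two bulks inherit different parental alleles
preferentially, so their allele frequencies — estimated from pooled read
depths — diverge; at unlinked markers they agree up to sampling noise.

`bsascan` implements this analysis for a biparental recombinant inbred
line (RIL) design, motivated by postharvest soluble-sugar degradation in
sweet corn kernels: two inbred parents with contrasting degradation rates,
an F6 RIL population of 204 lines, and extreme bulks of 30 lines per tail
sequenced at roughly 30x (parents at roughly 10x). Because the package has
no access to raw sequencing data, a first-class simulator generates
populations with the statistical structure the association analysis
assumes, and the whole pipeline is validated against that simulator's
ground truth.

## The simulator

`simulate_bsa()` draws, in order:

* **Genotypes.** An F1 is heterozygous everywhere; each of `n_selfing_generations`
  (default 5, giving an F6) selfing rounds performs two meioses per line.
  Each meiosis draws a Poisson number of crossovers per chromosome under
  the Haldane map, with physical length converted to genetic length at
  `cm_per_mb` (default 1 cM/Mb, a realistic genome-wide average for
  maize). Lines are therefore mosaics of parental blocks, and marginal
  per-locus heterozygosity decays as $(1/2)^g$ — about 3.1% at F6.
* **Phenotypes.** Soluble-sugar reduction over 0–72 h of storage (mg/g):
  `baseline + sum(effect * dosage) + N(0, noise_sd)`, dosage counting the
  origin parent's allele (0, 0.5, 1). The default three-QTL panel (effects
  +12 and +8 from the high-degradation parent, +6 from the low-degradation
  parent) with `baseline = 1` and `noise_sd = 5` gives a population mean
  near 14 mg/g, a range of roughly −10 to +35 mg/g, and bidirectional
  transgressive segregation — the qualitative features reported for this
  design. Absolute 0/8/72 h contents for the phenotype table are derived
  around a mean 0 h content of 84.47 mg/g with 60% of the reduction
  realized by 8 h.
* **Bulks.** The `n_bulk` largest and smallest phenotypes (ties broken by
  line index, so a fully tied population takes the first and last lines).
* **Read depths.** Parent depths are Poisson(10); each bulk's
  alternate-allele frequency is the mean dosage over its members, its
  depth Poisson(30) and its alternate reads Binomial(depth, frequency),
  with a per-read error of 0.001 so filters see realistic noise. Every
  locus receives a SnpEff-style impact label drawn from
  (HIGH, MODERATE, LOW, MODIFIER) = (0.002, 0.01, 0.05, 0.938), and 10%
  of loci are labelled InDels, which are excluded from scans but used for
  effective-variant bookkeeping.

Two defaults deserve explanation:

* **Genome scale.** The default genome is 10 chromosomes of 30 Mb with
  600 uniformly placed SNPs each (6000 loci, one per 50 kb), not a
  full-size maize genome. The scan-relevant geometry is preserved — a 1 Mb
  smoothing window holds about 20 markers, so the "at least 10 markers
  above threshold" interval rule is satisfiable at the 0.5–3 Mb interval
  scale the method reports. Uniform marker placement at the real density
  of a few thousand filtered SNPs over 2.1 Gb would leave ~4 markers per
  window and make that rule geometrically unsatisfiable; real marker maps
  are strongly clustered, which the simulator does not model.
* **Causal variants are effective variants.** The causal locus of each
  QTL is annotated MODERATE (`qtl_impact`). A causal coding variant is by
  definition functional, and the interval funnel requires at least one
  HIGH/MODERATE variant per retained interval; with purely random impact
  labels at the default rates a true QTL interval (~1.5 Mb, ~30 markers)
  would contain an effective variant only ~30% of the time, and the
  pipeline's own end-to-end recovery property could not hold.

What the simulator does **not** emulate: clustered marker maps, depth
heterogeneity along the genome, segregation distortion, genotyping error
beyond the per-read flip, epistasis and genotype-by-environment effects.
Passing tests therefore demonstrate the statistical machinery under the
assumed design, not performance on any particular real data set.

## Statistics

For each locus, with bulk alternate-allele frequencies $f_H$ and $f_L$:

* **ED.** The Euclidean distance between the bulks' two-allele frequency
  vectors, $ED = \sqrt{(f_H-f_L)^2 + ((1-f_H)-(1-f_L))^2} = \sqrt{2}\,|f_H-f_L|$,
  bounded by $\sqrt 2$. The fourth power $ED^4$ suppresses single-locus
  background noise before smoothing.
* **G.** The log-likelihood-ratio statistic of the 2×2 table of (ref, alt)
  × (high, low) read counts, $G = 2\sum_i n_i \ln(n_i/\hat e_i)$ with
  expected counts from the margins and $0\ln 0 = 0$. It equals the
  classical likelihood-ratio statistic for independence; the tests verify
  this against an algebraically independent entropy form and against
  expected counts from `chisq.test`.

Both statistics are invariant under swapping the bulks and (for G)
relabelling ref/alt. Loci with zero reads in either bulk are excluded
before scanning and counted.

**Smoothing.** $ED^4$ is smoothed by an unweighted mean over 1 Mb windows
anchored every 50 kb; each locus reports the value of the window whose
center is nearest (that window always contains the locus because the step
does not exceed the window). G is smoothed into G' by a tricube-weighted
average over loci within half a window on either side — the established
G' convention; an isolated locus keeps its own G. Smoothed values always
lie within the range of the contributing raw values. Window-mean
smoothing is noisier near chromosome ends, where windows hold fewer loci;
this is inherent to the estimator and left visible rather than corrected.

**Threshold.** The association threshold is the genome-wide empirical
quantile (default 99.5%) of the smoothed track, computed with R's default
linear-interpolation quantile (type 7) for reproducibility. By
construction about 0.5% of loci exceed it regardless of signal; the
interval-level filters, not the threshold alone, control false positives.
Whether a fitted-null quantile was intended instead is unknowable from
the method description; the empirical quantile is implemented and
labelled as such.

## Interval calling

Above-threshold loci on a chromosome are merged into candidate regions
while consecutive hits are within `merge_gap` (default 1 Mb, one
smoothing window); boundaries are the first and last hit positions.
Regions then pass through:

1. **Marker support:** at least 10 above-threshold loci, applied to
   ED^4 regions as described for that method; for G' regions the rule is
   available but off by default (`min_loci_gprime = 1`), mirroring the
   asymmetric description of the two methods.
2. **Effective variants:** at least one HIGH or MODERATE impact SNP or
   InDel inside the closed interval.
3. **Consensus:** the pairwise interval intersection of the two methods'
   retained regions — matching the convention that reported consensus
   coordinates equal the narrower method's interval.

Gene content is counted by any-overlap of gene and region intervals (a
1 bp edge overlap counts); coordinates are 1-based inclusive throughout.
Interval spans are reported as `(end - start)/1e6` rounded to two
decimals with standard round-half-even. Note one printed-value
discrepancy this convention exposes: an interval of 44,205,775–45,290,843
bp spans 1.0851 Mb, which rounds to 1.09, while the source report prints
1.08; the rounding here is documented rather than matched.

## Phenotype and candidate-gene metrics

Per-line metrics are plain arithmetic, reported at two decimals:
reduction $c_0 - c_{72}$ (may be negative), percent decrease
$100(c_0-c_{72})/c_0$ (defined for $c_0 > 0$), population means and
ranges, and qRT-PCR relative expression $2^{-\Delta CT}$ against a
reference gene. Group-difference testing (ANOVA and post-hoc grouping) is
deliberately out of scope; the package exposes group means only.

The candidate-gene funnel is mechanical: a case-insensitive keyword
screen over a user-supplied functional annotation (defaults target
sugar-metabolism vocabulary: sugar, sucrose, carbohydrate, kinase,
glycosyl, amylase, invertase, FGGY), a strict FPKM > 1 expression screen
over configured tissues (default seed and endosperm), and a stable
deterministic ranking by keyword flag, expression flag, then the absolute
low-vs-high-line mean $2^{-\Delta CT}$ contrast (descriptive only; no
hypothesis test). Live ontology enrichment is out of scope; the keyword
screen over a local table is the clearly labelled mechanical stand-in.
The annotation, FPKM and CT tables shipped under `inst/extdata/` are
synthetic fixtures constructed for the examples and tests.

## Numerical and degenerate-input choices

* Multiallelic VCF records are dropped (with a warning and count);
  biallelic records only are scanned.
* Parental homozygosity is called at a minor-read fraction of at most
  0.1; parents must be fixed for different alleles. Depth floors default
  to 4 (parents) and 10 (bulks). These defaults are documented as
  configuration — the exact cutoffs behind any particular reported locus
  count are not recoverable from a method description alone.
* A locus table that filters to zero rows, an empty VCF body, and an
  empty region list are all valid empty results, not errors; an empty
  phenotype table is an error.
* All randomness flows from a single integer seed; rerunning any
  simulation or pipeline with the same config is byte-identical.

## Known limitations

The hard one is localization precision. With 30 + 30 extreme lines from
204 F6 RILs, selection fixes a multi-megabase hitchhiking plateau around
a major QTL: the *true* bulk allele-frequency divergence often peaks —
sometimes at complete fixation — one to three Mb away from the causal
locus. The 99.5% empirical threshold retains only the top 0.5% of loci
(about 0.5% of the genome, ~1.5 Mb of interval), so the called interval
is the top slice of that plateau. In repeated simulations the consensus
interval covers the causal position in roughly two-thirds to four-fifths
of replicates, with median spans near the smoothing window — honest
behavior for this design, and the reason interval coverage of the exact
causal point should not be over-interpreted in studies of this size.
Raising coverage would require a more permissive threshold quantile or
larger bulks, both of which are fixed conditions of the emulated design.
There is also a structural tension between false-positive control and
recovery: the effective-variant filter is what removes most noise
intervals, and any change that lets noise intervals survive (denser
effective variants, wider intervals) weakens the null behavior.

Problem sizes used by the test suite and the acceptance script — 6000
markers, 10 replicate null seeds, 20 replicate QTL seeds — are the
package's chosen simulation scale for stable statistics at interactive
runtimes.
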