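---
title: "Methods: simulated STARR-seq enhancer evolution with starrpop"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated STARR-seq enhancer evolution with starrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`starrpop` models a comparative STARR-seq study of enhancer activity across
populations of a socially flexible bee: six populations (three social, three
solitary), each assayed in three replicate flasks, with genomic DNA input and
reporter RNA output libraries per flask. The package provides a synthetic
study generator with known ground truth and the full analysis chain: peak
calling, consensus enhancers, activity quantification, differential activity
between social classes, genomic feature assignment, conserved-element overlap
testing, allele-frequency/activity association, population-branch statistics
and motif-disruption scoring.

```{r load}
library(starrpop)
library(GenomicRanges)
```

## The synthetic study

`simConfig()` fixes every generator knob; `simulateStudy()` derives all
randomness from the single `seed` via per-stage child seeds, so any two runs
of one configuration are identical.

The default configuration is the study condition, chosen once:

* genome: 2 chromosomes of 500 kb; 80 genes, 120 enhancers;
* design: populations `soc1`–`soc3` (social) and `sol1`–`sol3` (solitary),
  3 flasks each, preparation batches crossing populations;
* activity: enhancer fold enrichments drawn from [4, 16]; a `frac_conserved`
  = 0.11 fraction active in all populations, `frac_population_specific`
  = 0.40 active in a single population, the rest in intermediate subsets;
* class bias: `frac_dae` = 0.05 of enhancers carry a `dae_effect` = 2-fold
  multiplicative shift in one class, plus convergently targeted genes whose
  enhancer clusters are active in one class only;
* counts: negative-binomial DNA and RNA fragments over 100-bp bins at
  5e5 fragments per library (dispersion 0.05, roughly 50x per bin);
* variation: 3 SNPs per enhancer, 30% causal with slope 0.1 frequency units
  per log2 activity unit; an outgroup for polarization with 5%
  misidentification; 2% of sites carry a +0.35 focal-class frequency shift
  (selection).

Replicate-to-replicate activity noise is planted at the *flask* level
(`rep_activity_sd` = 0.25 on log2 activity). Population-level jitter would be
a class-level confounder that no replicated test could remove; flask-level
variation is what replicate flasks actually measure.

```{r simulate}
study <- simulateStudy(simConfig(seed = 1))
length(study$truths)
study$counts
```

## Peaks, consensus and activity

Peaks are called per replicate by comparing binned RNA to depth-scaled DNA
with an upper-tail Poisson test (BH-corrected, minimum fold 2), merging
significant bins within 500 bp. Consensus enhancers require support from at
least 2 replicates and are capped at 10 kb. Activity is the normalized log2
RNA/DNA ratio with 0.5-count smoothing.

```{r peaks}
peaks <- callPeaksAll(study$counts)
cons <- buildConsensus(peaks)
act <- quantifyActivity(cons, study$counts)
head(activityMatrix(act)[, 1:4])
```

## Differential activity: the population is the unit

Flasks within a population share one genetic background, so they are not
independent samples of the class. `fitDifferential()` therefore averages
log2 activities within populations first and contrasts the class means with
a pooled two-sample t-test (df = 4 for the 3+3 design). This is the
fixed-data analogue of a mixed model with a population random intercept;
batch cancels under population averaging because batches cross populations.
The same aggregation is applied in `associateActivity()` before the per-SNP
regression of allele frequency on activity.

```{r differential}
diff_res <- fitDifferential(act)
table(diff_res$bias)
```

## Feature assignment and overlap

`assignGenes()` ranks candidate gene contexts with a fixed priority
(TSS flanks ±50 bp, 200-bp upstream, 5-kb promoter, first intron, other
introns, UTRs, exons, 10-kb upstream/downstream, intergenic), strand-aware
and with inclusive edge distances. `permutationOverlapTest()` randomizes
one region set across the genome and reports the representation factor
(observed/expected), an empirical +1-corrected p-value and a z-score.

## Population genetics

`hudsonFst()` implements the two-population Hudson estimator;
`branchLength()` transforms it as −ln(1 − Fst) (capped below 1, floored at
0) and `pbs()` combines three branch lengths into the population-branch
statistic. `computePbs()` polarizes by the outgroup, scans all polymorphic
sites and flags values strictly above the 95th percentile as outliers.
Variant filters (biallelic SNPs, QUAL ≥ 30, missingness ≤ 25 %, MAF ≥ 0.05
inclusive) are applied in that order by `filterVariants()`.

## Motif effects

`scanWindow()` scores 101-bp allele windows against PWMs with log-odds
scores discretized to 1e-3-bit bins and an *exact* match p-value from a
dynamic program over the discretized score distribution (it agrees with
full 4^L enumeration for short motifs). The two-allele rule calls `gain`
or `loss` when exactly one allele matches at p < 1e-4, `modulated` when
both scores are positive and their ratio exceeds 1.5.

## Coordinates and I/O

All in-memory regions are 1-based closed `GRanges`. BED files are converted
to and from the 0-based half-open convention at the I/O boundary
(`readBedRegions()`/`writeBedRegions()`); annotations round-trip through
GFF3 and variants through a minimal VCF dialect with per-replicate
frequency columns.

## The pipeline

`runPipeline(pipelineConfig(seed = ...))` chains every stage and returns a
nested report (also serializable with `writeReport()` as JSON and
Markdown), including recovery metrics against the simulation's ground
truth: consensus recall/precision, differential power/FDR, causal-SNP
power/FDR and the PBS selected-site enrichment.

## Scope and limitations

The generator is deliberately small-scale (1 Mb, hundreds of enhancers) so
the full chain runs in about a minute; problem sizes are package choices,
not biological claims. It plants independent enhancers without linkage
between SNPs, draws populations independently rather than from a
phylogeny, and models selection as a simple frequency shift. These
simplifications keep every planted effect analytically checkable, which is
what the test suite exploits.
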