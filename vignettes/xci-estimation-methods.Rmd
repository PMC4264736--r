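---
title: "Estimating X-inactivation ratios from allele-specific expression: models and design"
author: "xcisight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating X-inactivation ratios from allele-specific expression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcisight)
```

## The measurement problem

In female cells one of the two X chromosomes is epigenetically silenced
(X-chromosome inactivation, XCI). The XCI ratio — the proportion of cells
expressing the maternal versus the paternal X — ranges from 50:50 (random
inactivation) to 100:0 (complete skewing) and modulates the severity of
X-linked disease in carriers. At a heterozygous X-linked SNP, the fraction of
RNA-seq reads carrying the variant allele (the *allelic ratio*) is a direct
read-out of the relative expression of the chromosome carrying that allele.
A single locus is unreliable — local epigenetic effects, escape from
inactivation and mapping artifacts perturb it — so the estimators here pool
heterozygous SNPs chromosome-wide.

`xcisight` implements the full desk-scale workflow: a simulator of
allele-specific read and count data with known ground truth, allele counting
from mpileup text with the standard quality-filter cascade, a phased
(beta-MLE) and an unphased (semiparametric mixture) estimator of the XCI
ratio, trio phase-by-transmission with hemizygous-deletion evidence,
read-depth deletion detection, and escape-gene classification.

## Phased estimation: beta MLE

With trio phasing, every heterozygous SNP's alt allele is labeled maternal or
paternal. Within a phase group the allelic ratios are modelled as
$x_i \sim \mathrm{Beta}(\alpha, \beta)$; the two shape parameters absorb the
over-dispersion of RNA-seq counts relative to a binomial. `fit_beta()`
maximizes the likelihood numerically from a method-of-moments start (via
`MASS::fitdistr`), and the group's XCI percentage is $100\,\alpha/(\alpha+\beta)$.
The maternal and paternal percentages are reported as a pair ("82.7:20.3");
they need not sum to 100 because each is the mean of its own distribution.

**Boundary handling.** Ratios of exactly 0 or 1 (ubiquitous under complete
skewing) have zero beta density. Each observation is clamped into
$[1/(2d),\ 1 - 1/(2d)]$ at its own depth $d$ — a half-read shrinkage that
vanishes as coverage grows. Its visible consequence: at a true 100:0 ratio
the fitted maternal mean sits slightly below 100 (about 99 at the default
depth distribution), because no finite-depth experiment can distinguish 100:0
from 99.x:0.y.

**Dispersion.** The reported SD is the fitted beta SD on the percentage
scale; the empirical SD of the raw ratios is attached alongside, since the
two differ when the fit down-weights outliers.

## Unphased estimation: semiparametric stochastic EM

Without parental genotypes the pooled ratios form a two-component mixture
$\lambda f(x-\mu_1) + (1-\lambda) f(x-\mu_2)$ with unknown symmetric noise
density $f$ — no normality or modality assumption on the data. It is fitted
by a stochastic EM: each iteration draws a hard component assignment for
every point from its current posterior, updates $\mu_k$ as the component-wise
means and $\lambda$ as the assignment fraction, and re-estimates $f$ by a
kernel density (Gaussian kernel, Silverman bandwidth) on the symmetrized
centered residuals. Parameter chains are averaged after burn-in (defaults:
200 iterations, 50 burn-in, 5 starts initialized from a perturbed 2-means
split), and the start with the best pseudo-log-likelihood is kept. Components
are reported sorted descending and deliberately unlabeled — without
transmission information the method sees two expression modes, not parents.

Two numerical safeguards stabilize the fit:

* **Unimodality of $f$.** $f$ is a noise density, so the kernel estimate is
  made non-increasing in $|u|$ by decreasing rearrangement. Without this the
  model is unidentified near $\lambda = 1/2$: a bimodal $f$ can absorb the
  whole two-component structure and collapse the locations.
* **Tail regularization.** A small-weight (2%) broad Gaussian is mixed into
  $f$ so points far outside both components' support still prefer the nearer
  component instead of receiving a coin-flip posterior; tight clusters (e.g.
  a 100:0 dataset) destabilize otherwise.

**Known limitation — near-random XCI.** When the separation between
components is comparable to the noise SD (near 55:45 at typical coverage),
the pooled density is unimodal and *any* estimator of this model class is
blind: the collapsed representation $(\mu_1 = \mu_2,\ f = \text{the pooled
shape})$ fits exactly, the likelihood ridge between collapse and split is
flat, and the stochastic-EM chain drifts to the collapsed fixed point. In
package tests the SP estimate at a true 55:45 lands near 50:49, ~4 points
from the beta estimate, while from 60:40 outward the two agree within a
fraction of a point. A residual shrinkage of ~0.3 points remains detectable
at 60:40 over many replicates. Consequence for practice: the unphased
estimator reliably distinguishes *skewed* from *random* XCI and quantifies
moderate-to-complete skewing, but cannot resolve mild skewing below ~60:40 —
exactly the regime where the distinction is clinically immaterial.

## The in-silico experiment

The simulator reproduces the benchmark design at two levels.

*Read level*: SNP alt alleles are randomly binned maternal/paternal
(`assign_phase_bins()`), introduced into two copies of a transcript FASTA
(`build_haplotype_transcriptomes()`, minus-strand transcripts complemented),
and error-bearing 100 bp read pairs (outer distance 150 bp, uniform Q40,
per-base substitution rate $10^{-5}$, no indels, transcripts ≥ 500 bp) are
drawn uniformly across transcripts and mixed at the target ratio by exact
count (`mix_at_ratio()`). Reads carry their source coordinates, so
`count_from_attributed_reads()` tallies alleles without an aligner —
short-read alignment is deliberately outside this package's scope, and the
FASTQ route remains available for any external aligner.

*Count level* (`simulate_counts()`): the alt count at a maternal-phased SNP
of depth $d$ is $\mathrm{Binomial}(d, p)$ with
$p = m(1-b)/(m(1-b) + (1-m))$, where $m$ is the maternal fraction and $b$ the
reference-mapping bias (an alt-carrying read is lost with probability $b$);
paternal-phased SNPs use $1-m$. Sequencing errors then move counted reads to
a random different base, so third alleles appear in the depth denominator.

Default study conditions, chosen once to match the benchmark design: a pool
of 4996 heterozygous SNPs; per-SNP depths lognormal (meanlog $\log 8$,
sdlog 2), a heavy-tailed distribution calibrated so ~32% (≈1600) of SNPs
reach the 20X filter while retained depths span 20 to several hundred, as
deep transcriptome sequencing produces; reference bias $b = 0.02$, which
reproduces the observed sub-percent downward deviation of recovered means
(e.g. ~84.7 at a true 85). The default panel covers eleven ratios, 100:0 to
50:50 in steps of 5, with per-dataset child seeds derived deterministically
from one master seed.

What the generator does *not* emulate: expression-level variation tied to
specific genes, splice junctions, positional coverage bias, escape genes
(unless planted), or correlated mapping artifacts. Passing tests therefore
demonstrate estimator correctness under the stated sampling model, not
robustness to every artifact of real RNA-seq.

## Filters and counting conventions

The filter cascade mirrors standard practice and is applied in a fixed
order with per-stage accounting: heterozygous in the child's DNA (never
inferred from RNA), within transcripts (optional), outside PAR1/PAR2
(GRCh37 defaults X:60001–2699520 and X:154931044–155260560, overridable by
BED), recalibration status PASS, dbSNP membership, and depth ≥ 20.
Pileup bases are counted at Phred quality strictly greater than 20
(configurable); read-start/end marks and indel tokens are consumed, never
counted. The ratio denominator is the full quality-passing depth over all
four bases, so third-allele reads deflate both allele fractions slightly; a
ref+alt-only denominator is available. Overlapping mates are each counted —
the naive-pileup convention; with 150 bp outer distance and 100 bp reads,
mates overlap over half the fragment, so depths are up to 2x the fragment
count there.

## Trio phasing

On X outside the pseudo-autosomal regions a father is hemizygous, so
genotypes are first recoded to their true ploidy ("A/A" → "A"; likewise
genotypes inside a hemizygous deletion). For a heterozygous daughter the
paternal allele is then forced to the father's single allele and the
maternal allele is the other — this asymmetry is why essentially all
heterozygous X SNPs phase in a trio, unlike autosomal sites where double-het
configurations stay uninformative. A child allele neither parent could have
transmitted is a Mendelian error (a de novo point variant is
indistinguishable from a genotyping error here; both are reported, never
silently dropped, and downstream estimation excludes them). An apparently
homozygous child missing an obligate parental allele is an *out-of-phase*
genotype — evidence that the corresponding parental copy is deleted;
`phase_deletion()` aggregates such sites by majority vote.

## Deletion detection from physical coverage

Each proper mate pair is one fragment spanning its outer coordinates (the
unsequenced gap filled in). Fragments are counted into 100 bp windows tiled
from coordinate 0, per-sample counts are normalized to sum to one (half-read
pseudocount; windows empty in both samples are reported missing, not zero),
and the case-minus-control log2 difference is smoothed with a centered
25-window sliding mean. A heterozygous deletion sits near $-1$; calling uses
a margin (default threshold $-0.7$) because capture noise scatters around
that level. Runs of sub-threshold windows are merged across gaps shorter
than six smoothing spans — at realistic noise the smoothed series makes
brief excursions above threshold inside a real event, so nearer events are
below the detector's resolution.

**Breakpoint refinement.** The smoothed series alone displaces the threshold
crossing several windows into the event (the sliding mean must average ~80%
deleted windows before crossing $-0.7$), so run bounds are refined in two
stages: a fixed-level two-segment least-squares change-point fit on the raw
log2 series, then — when fragment tables are available — a Poisson
change-point fit on per-window fragment *end* counts (left edge) and *start*
counts (right edge). A deletion removes every fragment of the lost allele
overlapping it, so its edges are exact in endpoint coordinates, and endpoint
counts are independent across windows, unlike overlap counts which are
autocorrelated over the fragment length. At 100 fragments per window
(a deep exome at 250 bp inserts) this localizes breakpoints to 1–2 windows.
The mean log2 difference inside a called heterozygous deletion sits slightly
above $-1$ (≈ $-0.9$ for a 1.6 Mb event on a 12 Mb region) because removing
the event's reads shrinks the case total, lifting all normalized values — an
expected property of total-count normalization, not a miscalibration.

## Escape classification

A phased variant is an escape candidate when its ratio lies more than 2 SD
from its phase group's chromosome-wide mean *and* shows bi-allelic
expression (ratio in [0.1, 0.9]); candidates under 7 reads are downgraded to
low-confidence rather than dropped, mirroring post-hoc false-positive
labeling. Group mean and SD default to the empirical per-group summaries
(not the beta-fit SD, and not pooled across groups); both choices are
switchable. Gene-level calls take any candidate variant as gene-level
evidence.

## Skew classes

Classes are named after the panel's canonical ratios and cut at their
midpoints: ≥ 97.5 complete, [87.5, 97.5) extreme, [77.5, 87.5) moderate,
< 77.5 random. An "above 80:20" convention also circulates in the
literature; the midpoint rule is used here because the class names attach to
example ratios, not cutoffs.

## Problem sizes and determinism

All package tests and the acceptance script run the count-level simulator:
the full 11-ratio panel at the 4996-SNP scale fits in about a second, a
semiparametric fit on ~1600 ratios takes ~2 s, and the 12 Mb deletion
benchmark ~8 s. Every stochastic routine takes an explicit seed and is
reproducible bit-for-bit given (inputs, parameters, seed); panel child seeds
are derived from the master seed, and CLI runs record all parameters, input
digests and the seed in a manifest.
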