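---
title: "Designing and validating a targeted-capture SNP panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating a targeted-capture SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

## The problem

Liquid SNP chips genotype by targeted sequencing (GBTS): a set of capture
probes in solution pulls down the genomic neighbourhood of a designed locus
list, and the loci are genotyped from the resulting reads. Designing such a
panel from whole-genome resequencing of diverged breed groups involves three
candidate sources — selective-sweep regions between the groups, known
trait-tagged QTL intervals, and GWAS hits on breeding-value responses — and a
gap-filling step that pads the candidate set to a uniform genome-wide
density. Validating the built panel involves depth-based detection rates,
the capture depth profile around targets, the allele-frequency spectrum of
the captured loci, and genotype concordance against whole-genome sequencing
of the same animals.

panelforge implements this computation end to end on standard formats (VCF,
BED, TSV), together with a synthetic-data module that generates every input
with known ground truth, so each stage can be verified against the
parameters that produced its data.

## Population simulation and Fst

Populations are simulated under the Balding–Nichols model: per locus an
ancestral frequency $p$ is drawn (Uniform(0.05, 0.5) by default), each
population's frequency is drawn from
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, and
diploid genotypes are binomial. The construction gives direct analytic
control of the differentiation parameter $F$: Hudson's ratio-of-averages
estimator applied to such data converges to $F$ as loci grow, which is what
the recovery tests assert (tolerance 0.02 at 20,000 loci). We chose
Balding–Nichols over a coalescent simulator because the acceptance
properties need a *known* differentiation parameter, not realistic
haplotype structure; loci are exchangeable and unlinked.

Per-site Hudson components are

$$\mathrm{num} = (\hat p_a - \hat p_b)^2
  - \frac{\hat p_a(1-\hat p_a)}{n_a - 1}
  - \frac{\hat p_b(1-\hat p_b)}{n_b - 1},\qquad
  \mathrm{den} = \hat p_a(1-\hat p_b) + \hat p_b(1-\hat p_a),$$

with $n$ observed chromosome counts; a window's Fst is
$\sum \mathrm{num} / \sum \mathrm{den}$ (ratio of averages). Hudson's
estimator is the default because it is robust to small and unequal sample
sizes; a two-population Weir–Cockerham variant is provided as a config
switch for parity with common VCF tooling. Nucleotide diversity uses the
unbiased per-site heterozygosity $\frac{n}{n-1} 2\hat p(1-\hat p)$, which
equals the average pairwise difference among the observed chromosomes —
the property the test suite checks by exhaustive pair enumeration.

## The sweep scan

`sweep_scan()` slides fixed windows (50 kb window / 25 kb step by default,
at least 5 SNPs per scored window; all configurable, since the appropriate
scale depends on SNP density) and computes Fst, $\pi$ per population,
$\log_2(\pi_a/\pi_b)$ and an XP-CLR-style composite likelihood score with
population *a* as reference and *b* as the putatively selected (test)
population.

The composite score models the latent test-population frequency $q$ at a
site as Normal around a transform of the reference frequency, truncated to
$[0,1]$ with the clipped tails collapsed to boundary point masses:

* under drift only, the mean is the reference frequency $\hat p$ and the
  variance is $\omega\, \hat p(1-\hat p)$, with $\omega$ estimated
  genome-wide by method of moments (sampling-noise corrected);
* under selection intensity $s$, the favoured allele's frequency is pushed
  toward fixation by $p \mapsto p^{1/(1+s)}$ before the same drift
  dispersion is applied.

Observed counts enter through a binomial likelihood integrated over $q$ by
Gauss–Legendre quadrature (48 nodes over the $\pm 10\sigma$ support; the
unit tests pin the quadrature to a dense adaptive integration oracle at
relative $10^{-6}$). The window score maximises the summed log-likelihood
ratio over a grid of intensities ($s \in \{0, 0.5, 1, 2, 5, 10\}$) and over
which allele is favoured, so it is non-negative by construction and
invariant to consistent allele relabelling. Two simplifications relative to
the original cross-population CLR program are deliberate: there is no
linkage-disequilibrium down-weighting of correlated SNPs (simulated loci
are independent) and $\omega$ is estimated genome-wide rather than per
chromosome.

Candidate regions combine the three statistics. The paperless question of
*how* to combine them we resolved as a 2-of-3 vote at the 99th percentile
(high Fst, high $\log_2(\pi_a/\pi_b)$, high composite score), merging
touching windows; intersection and union are available. The vote is a
compromise: intersection is near-silent on noisy data, union fires on any
single inflated statistic.

```{r sweep-demo}
cfg <- pop_sim_config(samples_per_pop = 30, n_loci = 3000,
                      chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                      target_fst = 0.05, seed = 42)
g <- simulate_populations(cfg)
g <- simulate_sweep_region(g, list(chrom = "chr1", start = 4e6, end = 4.4e6),
                           strength = 5, seed = 43)
w <- sweep_scan(g, attr(g, "pops"), window = 4e5, step = 2e5)
select_sweep_regions(w, combine = "vote2")
```

The sweep overlay pushes the favoured-allele frequency toward fixation by
the same $p^{1/(1+s)}$ map and redraws the affected population's genotypes
in the region, so the scan's positive control and the selection model are
the same mechanism applied and detected.

## Breeding values, de-regression and the mixed-model scan

The trait simulator draws Gaussian allele-substitution effects at
`n_causal` loci, scales environmental noise so
$\mathrm{Var(TBV)}/\mathrm{Var(phenotype)} = h^2$, and emits EBVs as
BLUP-consistent shrunken predictors,
$\mathrm{EBV} = r^2\,\mathrm{TBV} + \varepsilon$ with
$\mathrm{Var}(\varepsilon) = r^2(1-r^2)\mathrm{Var(TBV)}$. This form
satisfies both calibration targets at once: the squared correlation with
TBV equals the drawn reliability $r^2$, and
$\mathrm{Cov(EBV, TBV)} = \mathrm{Var(EBV)}$ — the genetic-evaluation
property that de-regression presumes, without which a de-regressed proof
would not track true breeding values with unit slope. Animals are
simulated unrelated, so parent averages are centred at zero with a small
reliability (drawn in (0.05, 0.2), capped below half the own reliability).

`deregress_ebv()` follows the two-equation Garrick recipe: with
$\lambda = (1-h^2)/h^2$, the information contents of the parent average and
the individual are recovered from the reliabilities, the parent-average
contribution is subtracted, and the shrinkage undone; the analysis weight
is $w = (1-h^2)\,/\,[(c + (1-r^{*2})/r^{*2})h^2]$, with $c$ the fraction of
genetic variance not captured by markers. Since no value of $h^2$ or $c$
is universal, they are explicit arguments defaulting to 0.3 and 0.1 and
echoed by the CLI. The blending inverse (`blend_debv()`) reconstructs EBV
and reliability from (DEBV, weight, parent average) and the tests require
an exact round-trip at $10^{-8}$.

The association model is the standard single-marker mixed model
$y = Xm + Wa + e$ with $a \sim N(0, G\sigma_a^2)$,
$e \sim N(0, I\sigma_e^2)$, and $G$ the VanRaden method-1 realized
relationship matrix (markers centred by $2p_k$, denominator
$2\sum p_k(1-p_k)$, missing genotypes mean-imputed, ridge $10^{-6}$ on the
diagonal). Variance components are estimated once on the null model by
restricted maximum likelihood using the single-eigendecomposition trick —
rotate into the eigenbasis of $G$, profile the likelihood down to the
scalar ratio $\sigma_e^2/\sigma_a^2$, optimise on the log scale over
$[e^{-12}, e^{12}]$ — and held fixed across markers (EMMAX-style), which is
orders of magnitude faster than per-marker REML and closely matches exact
mixed-model scans at this scale. The residual scale is re-profiled per
marker, so with $G = I$ the scan collapses exactly to ordinary least
squares — the closed-form oracle the tests compare against at $10^{-8}$.
De-regression weights enter as residual precision scalings; they are
normalised to mean one, so equal weights reproduce the unweighted fit.
Genome-wide and suggestive thresholds default to $5\times10^{-8}$ and
$1\times10^{-5}$.

One caution the calibration tests make explicit: variance-component
estimates from a genomic relationship matrix of *unrelated* individuals are
weakly identified (the likelihood is nearly flat when $G \approx I$); the
recovery tests therefore use either structured populations or marker
panels smaller than the cohort, where the eigenvalue spread of $G$ carries
real information.

## Panel assembly

`assemble_panel()` deduplicates the union of candidates with source
priority `gwas > qtl > sweep > gapfill` — trait-linked content is the
scarcest and most valuable, so it survives collisions — and enforces an
exact panel size $K$:

* short of $K$: greedy gap filling per chromosome inserts, in each
  over-spaced interval, the pool locus with MAF $\ge$ 0.05 nearest to each
  ideal equally-spaced position (insertions only split gaps, so no
  chromosome's maximum adjacent gap can grow — a property the tests
  assert); any residue is topped up into the largest remaining gaps;
* over $K$: loci are dropped lowest-priority class first, and within a
  class the most densely packed first (ranked once per class by the sum of
  the two adjacent gaps; one-pass, deterministic).

Ties everywhere break by genomic order, so assembly is reproducible. The
gap-fill MAF floor is 0.05, consistent with the site filter, and
overridable. A `probe_designable()` helper flags loci whose 120 bp probe
window contains no other pool variant — a transparent proxy for commercial
probe scoring; sequence-level criteria (GC content, off-target screens)
need a reference genome and are out of scope. `density_report()` summarises
adjacent-gap distributions and the fraction of gaps within 100 kb.

## Capture simulation and QC

The capture simulator draws per-target, per-sample depths from a Gamma law
(shape 10 by default) with mean 91 reads on target, and flank depths along
a piecewise-exponential decay interpolating 91×, 60× and 26× at 0, 100 and
250 bp — three anchors typical of in-solution capture, used as simulator
defaults and recovered by `flank_profile()`'s two-segment log-linear fit
(the tests close this loop at 5%). Genotype errors are injected on the
capture side only: a target drops to no-call with probability
`dropout_prob`, and a heterozygote suffers allele drop-out with
probability `ado_prob`, emitting either homozygote with probability ½ —
the PCR mechanism in which only one of the two alleles amplifies to a
detectable level. Defaults are 1% dropout and 2% ADO, a plausibly
well-behaved assay; the QC tests inject larger values and re-estimate them
from the outputs.

Detection rates use `depth > 0` for dp0 and `depth >= t` for the higher
cuts (so dp5 means at least five reads); this makes the three labels a
coherent monotone family, and the convention is switchable. Concordance
classification is a six-way rulebook over (capture, WGS) genotype pairs:
`concordant`, `gbts_miss`, `wgs_miss`, `gbts_hom` (capture lost an
allele), `wgs_hom` (the mirror), and `opposite_hom`, which we added so the
categories partition all compared pairs; pairs missing on both platforms
are excluded from the denominator. Because the simulator injects only
capture-side errors, the capture-attributed share
(`gbts_miss + gbts_hom`) of discordances is 100% on synthetic data, and
the `gbts_hom` rate equals heterozygosity × ADO — closed-form expectations
the tests verify. Overall concordance is reported both pooled over all
pairs and as the mean of per-sample values, since either aggregation is
defensible.

```{r qc-demo}
cap <- simulate_capture_experiment(
  g, g$loci[1:500, c("chrom", "pos")],
  capture_sim_config(ado_prob = 0.05, dropout_prob = 0.01, seed = 7))
concordance_summary(cap$gbts, cap$truth)
```

## Numerical and interface choices

* Coordinates: VCF positions are 1-based; BED intervals are 0-based
  half-open; conversions are centralised, and the boundary tests pin the
  convention (a locus on a region start is inside, on the end is outside).
* Site filters: missing rate $\ge$ 0.1 removes, MAF $<$ 0.05 removes (a
  locus at exactly 0.05 survives); both statistics are recomputed from the
  call matrix, never trusted from annotations, and the missing rate is
  computed as an exact count ratio so the boundary is not blurred by
  floating point.
* Hard filters use any-rule-fires semantics with the standard seven
  annotations (QD, QUAL, SOR, MQ, FS, MQRankSum, ReadPosRankSum); a
  missing annotation passes its rule, and the common `MORankSum`
  transcription of the rank-sum key is accepted as an alias.
* Frequencies inside the composite-likelihood model are shrunk by
  $(x+\tfrac12)/(n+1)$ and clamped to $[10^{-6}, 1-10^{-6}]$ to keep the
  drift variance positive at sample fixation.
* Monomorphic markers in the scan are flagged and reported with $p = 1$
  rather than erroring, so locus bookkeeping stays aligned.
* All simulators take integer seeds and are bit-reproducible; the pipeline
  derives per-stage seeds from one master seed.

Problem sizes in the shipped tests and the acceptance script (thousands of
loci, tens to hundreds of samples, 10–100 replicate genomes) were chosen as
the smallest scales at which the stochastic properties under test are
stable; every statistic scales linearly in loci × samples and can be rerun
at cohort scale unchanged.

## Limitations

* Loci are simulated independent: no linkage disequilibrium, so
  haplotype-based sweep statistics are out of scope and the composite
  score's LD weighting is omitted.
* Animals are unrelated within populations; parent-average structure in
  the EBV tables is a stand-in, not a pedigree simulation.
* Binary responses (e.g. coat colour) are handled on the linear mixed
  model; no liability-scale transform is provided.
* The capture simulator models depth and genotype-level errors, not reads:
  no FASTQ, mapping or base-quality modelling, so mapping-rate metrics are
  accepted as precomputed inputs rather than computed.
* Multiallelic VCF records can be rejected or dropped, not split.
* Passing tests on synthetic data show the statistics recover the
  generating parameters under the stated models; they cannot certify
  performance on real cohorts with LD, pedigree structure, batch effects
  or reference bias.
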