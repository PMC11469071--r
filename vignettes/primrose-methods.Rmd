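---
title: "Methods: population-genomic inference for range expansion and mating-system transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic inference for range expansion and mating-system transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model system

`primrose` implements the population-genomic toolchain used to study a
westward range expansion with a recent transition from heterostyly
(outcrossing) to homostyly (selfing), as exemplified by *Primula vulgaris*
sampled from Turkey to England: nine populations (six dimorphic, two
trimorphic, one monomorphic for the selfing homostyle morph; 105 diploid
individuals), genotyped against the *P. veris* reference. The package starts
from a VCF: read processing, mapping and variant calling are out of scope.

The pipeline has five statistical stages, each usable on its own:

1. **Filtering and site-class annotation** (`applySiteFilters`,
   `applyGenotypeFilters`, `finalizeCallset`, `annotateDegeneracy`,
   `buildNeutralMask`),
2. **Site-frequency spectra** (`unfoldedSFS`, `makeJointSFS`, `projectSFS`),
3. **Demographic inference** (`simulateGenealogies`, `expectedJointSFS`,
   `fitModel`, `modelSelect`, `parametricBootstrapCI`,
   `fitSinglePopEpochs`),
4. **Selection** (`windowedStats`, `pinpsRatio`, `fitDFE`, `bootstrapDFE`),
5. **TE content** (`normalizeDepth`, `interactionLM`,
   `pairwiseWilcoxonBonferroni`).

A synthetic-data generator (`studyDesign`, `generateDataset`) emulates the
study's sampling structure so that every stage is testable without any data
download.

# Filtering cascade

Site-level thresholds follow standard short-read hard-filtering practice:
QD > 2, MQ > 40, FS < 60, MQRankSum > -12.5, ReadPosRankSum > -8, site depth
within [0.5, 3] times the dataset mean depth, and InbreedingCoeff >= -0.99
(sites of fixed heterozygosity are usually collapsed paralogs). Records
missing an annotation *pass* that single criterion: GATK emits rank-sum
annotations only where both alleles are observed in reads, so treating
absence as failure would silently discard most homozygous sites. All site
filters are set intersections, hence order-insensitive.

Genotype-level filters: calls with total allele depth outside [6, 60] become
missing; a site is removed outright if any heterozygous call has allelic
balance outside [0.30, 0.70] (AB = alt depth / total depth). The AB interval
is closed; values exactly at the bounds are kept. The final callset keeps
biallelic SNPs on the assembled-chromosome whitelist with per-site
missingness below 20%.

Degeneracy annotation classifies every CDS base under the standard nuclear
code as 0-fold (every substitution changes the amino acid), 4-fold (none
does), or other-coding; stop codons, ambiguity codes, phase-trimmed and
overlapping-transcript-conflicting positions are all other-coding. The
neutral accessibility mask removes genes, 2 kb flanks and repeat/centromere
intervals; all internal interval logic is delegated to
`IRanges`/`GenomicRanges`, with VCF 1-based and BED 0-based half-open
conventions converted at the format boundary.

# Coalescent machinery

The simulator is a continuous-time structured coalescent over demes with two
event types, applied backward in time: `split` (lineages of a derived deme
merge into its ancestor, optionally resetting the ancestor's size) and
`size` (instantaneous size change). Within a deme holding $k$ lineages of
diploid size $N$, coalescence occurs at rate $k(k-1)/(4N)$ per generation.
Sizes are diploid throughout and every model object carries an explicit
`neUnits` tag, because SFS tools differ on whether printed sizes count gene
copies — a documented source of factor-two confusion.

Mutations follow the infinite-sites model: Poisson($\mu L \cdot$ branch
length) per branch, each mutation a unique site carried by the subtending
leaves. Recombination is not simulated; independent loci stand in for
unlinked windows, which is consistent with the SFS methods' site-independence
assumption. For LD-specific tests, `generateBlockLD` injects
distance-decaying genotype correlation by copy-with-mutation chaining — a
fixture device, not a population-genetic model.

Diploids pair consecutive haplotypes; partial selfing is emulated by making
an individual's two haplotypes identical copies with probability $F$. This
reproduces the first-order consequences relevant here (excess homozygosity,
reduced effective sample size) without modelling the full selfing
genealogy.

The expected joint SFS is the Monte-Carlo mean of branch lengths subtending
each joint derived-count cell, normalized over polymorphic cells
(`expectedJointSFS`); with `counts = TRUE` it is scaled by $\mu L$ into
expected SNP counts. The implementation is in C++ (Rcpp) because the fitter
evaluates millions of genealogies; a 2,000-genealogy four-population
evaluation takes about 0.1 s on one core.

Correctness is pinned by analytic identities (E[TMRCA] $=2N$ for $n=2$,
total length $4N\sum 1/i$, E[$\xi_i$] $\propto 1/i$, $\theta_W = \pi =
4N\mu$ under neutrality) and by agreement with msprime's branch-mode allele
frequency spectrum on a two-deme split model (the external oracle runs only
inside the test suite, and those checks are skipped when msprime is not
available).

# Composite-likelihood demographic fitting

The observed joint SFS is treated as multinomial over polymorphic cells
(monomorphic corners excluded; the observed SNP total is conditioned on).
Cells with observed count below `minEntry` (default 10) are pooled into one
lumped cell before evaluation. An important structural fact, verified
numerically during development: this relative-SFS likelihood is exactly
invariant to a joint rescaling of all sizes and times, so absolute
parameters are identified only when something anchors the scale — fixed
template constants (as in the four-population model), or the optional
Poisson likelihood, in which expected cell counts $\mu L \cdot$ E[branch
length] carry the scale. Both modes are available on `compositeLogLik`,
`fitModel` and `parametricBootstrapCI`.

The optimizer mirrors the ECM-style protocol of SFS fitters: multiple
independent runs from random log-uniform starts within box bounds, each run
performing cyclic coordinate-wise improvement with a multiplicative step
that shrinks geometrically across cycles. Within a run, every likelihood
evaluation reuses one simulation seed (common random numbers), making the
Monte-Carlo objective a deterministic function of the parameters; without
this the coordinate search cannot distinguish signal from resimulation
noise. Consequences worth knowing:

- the final step size bounds the attainable resolution (with `stepInit =
  1.6`, `stepShrink = 0.9` and 30 cycles, about 2–4%);
- `simsPerEval` bounds the accuracy of the objective itself; the desk
  default (2,000) suits five-parameter refits of the anchored
  four-population template, while unanchored single-population fits need
  5,000–10,000;
- bootstrap refits start from the point estimate and therefore use a much
  finer step schedule (`stepInit = 1.15`), but still need enough initial
  travel to track the bootstrap perturbation.

Times are optimized as positive increments (the first split time plus
increments to the older splits), which enforces event ordering by
construction. Size changes scheduled on a deme after the proposed time of
its merge are vacuous and dropped by the template builder.

Model choice uses AIC ($2k - 2\ln\hat L$); models whose per-run likelihood
ranges overlap the best model's range are lumped into one selected tie
group. Confidence intervals are parametric-bootstrap percentiles (2.5/97.5)
over refits of SFSs simulated from the fitted model, refit from the point
estimate as initial values.

## The four-population expansion template

`vulgarisTemplates()` ships the selected expansion history (`model5`) for
TR-D, CH-D, EN1-D and EN6-M with its published values: TR/Europe split
79,000 ybp, ancestral $N_e$ 13,419, current TR $N_e$ 95,627, CH/EN split
65,500 ybp, CH contraction/recovery 64,000/62,300 ybp, EN-lineage
contraction/recovery 48,000/31,000 ybp, EN1/EN6 split 24,000 ybp, EN6
contraction 100 ybp, with $\mu = 1.23\times10^{-8}$ and a 2-year generation
time. Sizes that were not printed alongside the model are fixed template
constants calibrated once from the single-population trajectories and
per-population diversity: current CH $\approx$ 100,000 (its stable
trajectory level), current EN1 20,000 (consistent with $\pi_S \approx
4N_e\mu$ at the observed $\approx 0.0011$), EN6 8,000 before its recent
contraction and a few hundred after, bottleneck sizes 2,000–3,000. Free
parameters of the template are the three split times (as increments) plus
current TR and ancestral sizes; everything else is deliberately fixed, which
also anchors the scale of the multinomial likelihood. Two simplified
alternates (`nobottleneck`, `singlebottleneck`) share the grammar and form a
testable model family; the full six-model set of the original analysis is
not recoverable from the main text, and the alternates are labelled
stand-ins, not reconstructions.

## Identifiability of single-population histories

For a recent bottleneck observed through a one-population SFS, duration and
severity are confounded: the likelihood is flat (under one log-unit at
4×10^5 simulations per evaluation) along the constant-intensity ridge
$T/(2N_{\mathrm{bot}})$. `fitSinglePopEpochs` therefore recovers epoch
*histories* whose identifiable features are the ancestral size and the
bottleneck intensity; the recovery and confidence-interval calibration tests
are phrased in those coordinates. This is a property of the data, not of the
optimizer.

# Distribution of fitness effects

The selected-site SFS expectation uses the diffusion sojourn density of a
deleterious derived allele under genic selection with $\gamma = 4N_e s$:
$$E[\xi_i] = \frac{\theta}{2}\int_0^1
\frac{2\,(e^{\gamma(1-x)}-1)}{(e^{\gamma}-1)\,x(1-x)}
\binom{n}{i} x^i (1-x)^{n-i}\,dx,$$
which tends to $\theta/i$ as $\gamma \to 0$ and concentrates variants at low
frequency for strong selection. The integrand is polynomial (the endpoint
singularities cancel for $1 \le i \le n-1$), so fixed Gauss–Legendre
quadrature (80 nodes) is accurate to machine noise; the implementation is
validated against a Wright–Fisher transition-matrix oracle (expected sojourn
generations of a new mutation, Richardson-extrapolated across $N$ = 200 and
400).

The DFE over $N_e s$ is a gamma distribution fitted in the
distortion-factor framework: per-frequency-class factors $r_i =
\xi_i^{\mathrm{neutral}} i/\theta_{\mathrm{neutral}}$ absorb demography and
are shared with the selected class; the selected SFS is then fit by Poisson
likelihood with expectation $\theta_{\mathrm{sel}}\, r_i\, E[\xi_i \mid
\Gamma(\beta, \bar{N_e s})]$. The gamma mixture is integrated by equal-mass
quantile discretization (64 points), which is robust for shapes below 1
where Gauss–Laguerre weights would need the generalized recursion. Reported
bins over $N_e s$ — $[0,1)$, $[1,10)$, $[10,100)$, $[100,\infty)$ — use the
$\gamma/4$ convention.

Supplying `lengthRatio` (the selected/neutral mutational-target ratio) ties
$\theta_{\mathrm{sel}} = \theta_{\mathrm{neutral}} \cdot$ ratio, so the
*deficit* of selected SNPs informs the DFE mean. This is the recommended
mode: with $\theta_{\mathrm{sel}}$ profiled free, the SFS shape alone
constrains the mean only weakly once selection is strong (the fitted mean
can wander an order of magnitude at essentially constant likelihood, which
we verified numerically). Bin-mass confidence intervals come from
multinomial resampling of the selected SFS with the neutral SFS held fixed.

# Diversity, LD and the TE statistic

Windowed statistics tile each chromosome in units of 50,000 *accessible*
sites (not raw bp and not variants), which makes the missing-data correction
exact and windows comparable across populations; a bp-window mode exists for
sensitivity analysis. $\pi$ uses per-site called-haplotype counts
($2c(n_c-c)/(n_c(n_c-1))$ summed and divided by accessible length);
$\theta_W = S/(a_{n-1}L)$; Tajima's D uses the standard constants and is
reported only where $S > 0$. $\pi_N/\pi_S$ is the ratio of mean window
$\pi$ at 0-fold to 4-fold sites.

LD is genotype (composite) $r^2$ — the squared Pearson correlation of
diploid dosages — because the data are unphased. Decay curves bin all
intra-chromosomal pairs by physical distance after excluding singletons
(default `mafMin` $= 1.5/2n$, implementing the "exclude singletons" rule;
the exact per-population thresholds of the original analysis are not
printed). Pruning is the greedy left-to-right window pass (50 kb windows,
10 kb steps, $r^2 > 0.1$ removes the later site), audited against an
exhaustive-pass oracle in the tests. PCA mean-imputes, centers, optionally
scales, and reports variance fractions; the intended input is the
singleton-free, LD-pruned callset.

The TE content statistic normalizes each individual's TE superfamily depth
by its genome-wide depth, filters superfamilies by mean consensus coverage
(at least 80%; the coverage denominator is not defined in the source
analysis, and the per-superfamily mean is our documented reading), and fits
the Gaussian identity-link interaction model `depth ~ population *
superfamily` with treatment coding and a releveled intercept (TR-D for the
expansion contrasts, EN1-D for the homostyly contrasts). Pairwise
Wilcoxon rank-sum tests against the reference population are
Bonferroni-corrected over the comparisons actually performed per
superfamily.

# Synthetic data: what it emulates and what it does not

`studyDesign()` encodes a nine-deme serial-founder expansion: deme $i$ is
founded from deme $i-1$ at a declining series of split times, with a founder
bottleneck of a few hundred diploids for 200 generations, declining
present-day sizes along the axis, selfing $F$ = 0.45 in trimorphic and 0.9
in the monomorphic deme (free knobs; the original study provides no usable
selfing-rate estimates), 105 individuals with the study's per-deme sample
sizes and morph labels, and eleven chromosomes. Sizes and sequence length
are scaled down (thousands of diploids, ~1 Mb genome) so the full pipeline
runs in minutes; the mutation rate is scaled up tenfold to
$1.23\times10^{-7}$ to keep per-site diversity near the study's order of
magnitude. 0-fold sites are thinned by acceptance sampling toward the
selected-SFS shape under the design's gamma DFE; TE tables are Gaussian
around population-by-superfamily means; VCF quality annotations are drawn
from simple calibrated distributions solely to exercise the filter cascade.

What passing tests on these data do *not* show: robustness to real
read-level artifacts (mapping bias, paralog collapse, batch effects),
recombination-driven LD structure beyond the geometric fixture, ancestral
state misassignment (polarization is by construction correct in the
generator — the reference-allele polarization of real data conflates
reference with ancestral state at sites where the reference lineage carries
the derived allele), or gene conversion and linked selection.

# Numerical conventions and scaled problem sizes

All rates are per generation; conversions to years happen only at reporting
boundaries (2 years per generation). Optimization is on the log scale;
probability floors ($10^{-12}$) prevent $-\infty$ likelihoods in empty
cells; percentile CIs use type-7 quantiles. The test suite and the
acceptance script run everything at reduced scale chosen once for stability:
10,000–20,000-SNP spectra with 2,000–3,000 simulations per likelihood
evaluation for the four-population refits, 2,000 replicate genealogies for
neutrality calibration, 20 replicates for DFE recovery, and a 5-dataset ×
20-bootstrap calibration of CI coverage.

# Known limitations

- The coalescent has no recombination; within-locus LD is therefore
  complete, and LD-decay inference is exercised only through the block
  fixture.
- The selfing device (haplotype copying with probability $F$) compresses
  genealogical consequences of selfing into its first-order effect on
  homozygosity.
- The six-model family of the original demographic analysis cannot be fully
  reconstructed from the main text; only the selected model is encoded with
  published values.
- Monte-Carlo expected spectra make the likelihood itself stochastic;
  common random numbers tame this within runs, but fitted values carry
  Monte-Carlo error that shrinks only with `simsPerEval`.
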