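---
title: "Models and methods behind paleostack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleostack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleostack)
```

paleostack implements the statistical stack that ancient-DNA studies use to
reconstruct population continuity, turnover, admixture and demography from
sparse pseudohaploid genotype data. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical and design choices
made where the methods literature leaves them open. Nothing here states an
empirical result beyond what the package's own tests and acceptance script
compute on synthetic data.

## Genotype data model

The central container holds an individuals-by-SNPs matrix coded 0/1/2
(count of the alternative allele) with 9 for missing. Pseudohaploid
individuals — the norm for low-coverage ancient samples — carry a single
randomly drawn allele represented as a homozygote, so their codes are
restricted to {0, 2, 9}. Genetic positions are carried in Morgans
internally; centimorgans appear only at I/O boundaries, and the EIGENSTRAT
reader auto-detects centimorgan files (any per-chromosome span of at least
4) and converts with a warning. Physical positions follow the 1-based
EIGENSTRAT convention, and the sex code `U` is permitted and propagated.

Jackknife blocks are greedy contiguous map segments: a block starts at
every chromosome start and whenever a SNP lies at least 5 cM (the
conventional unit, configurable) past the block's first SNP. Blocks never
span chromosomes, so delete-one-block resampling respects linkage.

## Adaptive pseudohaploid calling

Sequencing ancient DNA leaves characteristic errors, above all terminal
C→T deamination. The caller estimates substitution error rates
*empirically* from reads at sites known to be monomorphic (flagged in the
SNP table), stratified by library, read-terminal versus central position
(a base more than 10 bp from either read end is central), strand, and
binary mapping- and base-quality bins. The methods that inspired this
stack do not publish their quality bin edges; both bins split at 30, the
conventional confident-quality cut, and the edges are constants at the top
of the module. Strata never observed in the training data fall back to a
configurable pseudo-rate (default 0.001) rather than 0 — an unseen stratum
must not be certified reliable by absence of evidence.

Because the two directions of an allele pair can err at very different
rates, reliability is the symmetric score S = max(E(a→b), E(b→a)). Reads
whose stratum has S at or above the threshold (default 0.02) are
discarded; the call is a single base drawn uniformly from the surviving
pileup, so the achieved error is bounded by the threshold. Randomness is
reproducible and order-independent: one global seed is expanded into a
per-site stream keyed by the SNP id, and the surviving bases are put in
canonical order before the draw, so permuting reads cannot change a call.

QC follows the published thresholds verbatim, with strict inequalities so
exact-threshold values pass: fewer than 15,000 SNPs covered; terminal
damage below 3% (UDG-treated) or 10% (untreated); a contamination lower
bound above 0.01; an mtDNA consensus match below 0.90; a sex ratio
strictly between 0.05 and 0.3; or a date-based exclusion. The sex ratio is
taken as Y/(X+Y) aligned-read counts — the definition is not stated
algebraically in the source methods, but it is the only common convention
compatible with a 0.05–0.3 indeterminate window. Every failing individual
reports *all* triggered reasons; among passers, the lower-coverage member
of each first-degree pair is dropped for grouped analyses only, with a
distinct reason code.

## f-statistics and the weighted block jackknife

f2, f3 and f4 are moments of allele-frequency differences. With sample
frequencies and haploid sample sizes, the per-SNP terms are

* f4: $(\hat a-\hat b)(\hat c-\hat d)$ — unbiased without correction;
* f3(A,B;X): $(\hat x-\hat a)(\hat x-\hat b) - h_x$;
* f2(A,B): $(\hat a-\hat b)^2 - h_a - h_b$;

where $h = \hat p(1-\hat p)/(n-1)$ is the sampling-heterozygosity
correction, skipped when $n = 1$. Two conventions exist for $n$: counting
individuals with data (the "inbred" mode that pseudohaploid data require,
the default) or counting alleles; both are implemented and selectable.
Pseudohaploid individuals contribute one haploid observation and diploids
two, so mixed panels are handled by total haploid counts. SNPs with any
required population fully missing are masked per statistic, never by a
global intersection, and monomorphic SNPs are retained (they contribute
zero and do not change estimates).

Standard errors use the weighted delete-one-block jackknife with block
weights equal to valid SNP counts; with equal weights it reduces exactly
to the textbook delete-one jackknife, which the tests assert. The
conventional significance flag for a battery of statistics is |Z| > 3.

## PCA with least-squares projection

Axes are fit on complete reference individuals after per-SNP
normalization by $\sqrt{\hat p(1-\hat p)}$; SNPs monomorphic in the
reference set are dropped because their normalization is undefined. The
eigenvector sign is fixed by making each vector's largest-magnitude entry
positive, so runs are deterministic. Ancient samples are placed by least
squares on the eigenvector rows restricted to their non-missing SNPs,
which imputes nothing and is invariant to dropping SNPs the sample lacks.
No shrinkage remapping of reference scores is applied (the transformation
used by some PCA tools for co-visualization is unpublished); reference
individuals are reported as fitted scores with that caveat documented.

## Cladality testing and admixture weights

For a left set L (first element the base) and right set R, the package
builds the matrix $X_{ij} = f_4(L_{i+1}, L_1; R_{j+1}, R_1)$ and the block
jackknife covariance of its stacked entries. Entry masks follow the
per-statistic ("allsnps") convention; the covariance uses the intersection
mask's block weights, which coincides with the per-entry masks whenever
missingness is population-balanced (always true for the synthetic
cohorts).

The rank test asks whether X is consistent with rank r: the best rank-r
approximation is found by alternating generalized least squares on the two
factors, the minimized covariance-weighted quadratic form is the
chi-square statistic, and the degrees of freedom are
$(|L|-1-r)(|R|-1-r)$. Rank 0 reduces to $x^\top \Sigma^{-1} x$ and is the
pairwise cladality test. Jackknife covariances estimated from few blocks
can be near-singular, so inversion applies a relative ridge
($\lambda = 10^{-6}\times$ mean diagonal, escalated if needed) once the
condition number passes $10^{12}$, with a warning.

Admixture weights come from the canonical construction: with the target
as the left base, the source rows satisfy
$\sum_i w_i (x_{S_i} - x_T) = 0$ exactly when the target is the
$w$-mixture, so the weights are the left null vector of the best
rank-(k−1) GLS approximation, normalized to sum to one. Standard errors
re-run the whole fit with each block deleted (covariance held fixed, the
standard simplification); the model p-value is the rank test at
r = k−1, and weights outside [0, 1] are reported but flagged infeasible.

Grouping individuals by cladality runs all pairwise rank-0 tests, links
pairs with p above the threshold (default 0.05), and reports connected
components. The multistep grouping procedure in the source literature is
only sketched; this package's concrete rendering flags as *ambiguous* any
individual whose removal leaves its neighbors in two or more disconnected
components — such bridges are left ungrouped rather than arbitrarily
assigned.

## Dating admixture from ancestry-covariance decay

In an admixed population, alleles at two loci carry correlated ancestry
that decays with genetic distance $d$ as $w(1-w)e^{-td}$, where $t$ is the
age of admixture in generations. The estimator weights each SNP by the
signed source frequency difference $a_i - b_i$, residualizes genotypes
against twice the pooled sample frequency (a population-level statistic
that needs no per-individual ancestry estimates), accumulates
weight-products of pairwise covariances into distance bins (default bin
width 0.001 Morgans up to 0.20), and fits $y(d) = A e^{-td} + c$ by
nonlinear least squares over bins in [0.005, 0.20]. Conventions differ on
the exponent; here it is exactly $t$ per Morgan with no +1 adjustment,
stated explicitly. The lower fit bound excludes the shortest bins where
background linkage disequilibrium contaminates the signal; the value
0.005 M is a configurable default chosen to sit past the background-LD
range of typical SNP panels. The affine offset $c$ absorbs the
distance-independent covariance floor that arises because individuals
vary in genome-wide ancestry fraction.

Uncertainty comes from refitting with each chromosome's pair
contributions removed, combined by the weighted jackknife with pair-count
weights. Dates convert to years through a configurable generation time
(default 28.9 years, consistent with the ratio of published
generation/year pairs for this class of study); the constant is a
parameter, never baked into results. An all-zero curve returns a flagged
"no signal" result rather than an error.

## Runs of homozygosity and effective population size

The two copies of a locus in a diploid coalesce $t$ generations back with
geometric probability $(1/2N_e)(1-1/2N_e)^{t-1}$; a coalescence at $t$
leaves homozygous tracts of approximately exponential length (rate $2t$
per Morgan) at density $4t^2 L e^{-2tl}$ over a genome of map length $L$.
The expected tract count per length bin is therefore a geometric mixture
of closed-form integrals, truncated at $t_{\max} = 3000$ generations
(the truncation error is below 0.1% for $2N_e \le 5000$, asserted by a
test against $t_{\max} = 10000$). Chromosome-edge effects on tract counts
are ignored, a documented approximation; the generator places each
simulated segment wholly within a chromosome so that realized lengths
follow the model's bin densities.

Calling uses a windowed heterozygosity scan (50-SNP windows, at most one
heterozygote per marked window, merged runs of at least 4 cM) — a
deliberate simplification standing in for haplotype-copying HMMs, which
need external reference panels; the likelihood model above is the
testable core. The window caller presumes a realistic outside-ROH
heterozygosity: ascertained SNP panels show on the order of 0.2
heterozygous calls per covered SNP, and the synthetic-data tests use that
value (at per-SNP rates far below ~0.1 the windows cannot discriminate,
whatever the marker density).

The fit maximizes a composite Poisson likelihood of per-individual bin
counts (bins 4–8, 8–12, 12–20, 20–300 cM, the conventional classes) over
a log-spaced $2N_e$ grid from 20 to 20,000 (400 points) refined by
golden-section search; the 95% interval is the likelihood profile set
within 1.92 log-units of the maximum, and the reported size is
$N_e = 2N_e/2$. Individuals with more than 50 cM total in tracts longer
than 20 cM are the signature of close-kin unions and are excluded from
the fit, as is anyone below the 300,000-SNP coverage gate. Zero observed
segments leave the upper confidence bound open, reported as such.

## Kinship from pairwise mismatch

For two pseudohaploid genotype rows, the mismatch rate over the shared
non-missing SNPs has expectation $b$ (the background rate, estimated as
the per-population *median* of within-group pairs so a few true relatives
cannot contaminate it) for unrelated pairs, $3b/4$ for first degree, and
$b/2$ for two calls of the same genome. The relatedness estimate is
$\hat r = 2(1-\text{pmr}/b)$ with class boundaries at the midpoints of
the expected values (0.75, 0.375, 0.1875, 0.0625), which symmetrizes
misclassification risk. Pairs with under 3,000 overlapping SNPs, or whose
±1.96 SE interval straddles a boundary, are reported *insufficient*
rather than guessed. Distinguishing parent–offspring from siblings is out
of scope (it needs X-chromosome or segment methods).

## Inverse-f3 trees

Outgroup-f3 values measure shared drift, so their inverses behave as
distances. Neighbor joining is implemented with the classic Q-criterion
and Saitou–Nei branch lengths; ties in Q are broken by lexicographic
order of the joined labels, making the output a deterministic function of
the matrix (an independent NJ implementation serves as the test oracle).
No scaling constant is applied to 1/f3 before joining; NJ topology is
scale-invariant, so the choice is cosmetic. The tree is rooted at the
midpoint of the outgroup's pendant edge (configurable to attach at the
tip; the source methods say only that the tree was rooted on the
outgroup). For visualization, Grafen's transform sets each node's height
to its descendant-tip count minus one, normalized so the root sits at 1
and tips at 0, then raises heights to a power (default 0.5) that expands
the scale near the tips while preserving topology exactly.

## Radiocarbon combination and calibration

Replicate measurements of the same event pool by inverse-variance
weighting; the Ward–Wilson statistic
$T=\sum_i ((x_i-\bar x)/\sigma_i)^2$ on $n-1$ degrees of freedom flags
inconsistent replicates at the 5% level. Calibration evaluates the
calendar posterior on a 1-year grid (matching the reporting precision of
published ranges) with the curve linearly interpolated between knots and
measurement and curve variances added; the report is the highest
posterior density set at 95.4%, as maximal contiguous intervals — HPD,
not central, because that is what the standard calibration software
reports. Calendar conversion uses the no-year-zero convention
(1950 cal BP is 1 BCE). No reservoir or fractionation corrections are
applied; dates are assumed already normalized. Curves are read from the
standard `.14c` comma/whitespace layout. The IntCal20 curve itself is not
bundled — it must be supplied by the user as a file.

## What the synthetic data do and do not emulate

The generators provide every input with known truth: Balding–Nichols
drift on an acyclic admixture graph (exact beta support, no truncation
artifacts of a normal approximation); pseudohaploid and diploid sampling
with independent per-cell missingness; stratified read pileups with
rule-based substitution errors and designated monomorphic training sites;
mosaic admixed chromosomes whose ancestry switches follow a Poisson
process of rate $t$ per Morgan with the state redrawn Bernoulli(w) at
each switch (giving exactly the $w(1-w)e^{-td}$ ancestry covariance the
estimator assumes); ROH placement from the geometric-coalescent model;
pedigree trios; and QC tables of known pass/fail composition. All
generators are pure functions of (parameters, seed).

Real data differ in ways the simulations deliberately omit: linkage
disequilibrium *within* source populations (background LD), ascertainment
bias of SNP panels, reference bias and contamination in reads,
non-uniform recombination maps, and overlapping generations. Passing
recovery tests therefore demonstrates correctness of the estimators under
their own model assumptions, not robustness to every artifact of
empirical data.

## Problem sizes and determinism in the test suite

The recovery studies run at sizes chosen to mirror the study designs they
emulate while remaining desk-scale: admixture-weight recovery at 200k
SNPs with 30 pseudohaploid targets and 10% missingness against 8
outgroups; dating recovery at 100k SNPs, 100 diploids, 20 chromosomes of
1 Morgan with truth 137 generations; cladality null calibration over 200
replicates of 5k SNPs; effective-size coverage over 20 replicates of 21
individuals at $2N_e = 240$ on a 35-Morgan genome; kinship classification
over 100 trio replicates at 100k SNPs. All randomness flows through
explicit integer seeds, and every simulation-backed assertion uses a
tolerance derived from the binomial or Poisson noise of its own design
(three standard deviations unless the quantity is exact).
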