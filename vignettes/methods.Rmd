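---
title: "Models and methods behind devilclones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind devilclones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`devilclones` analyses the long-term somatic evolution of transmissible
cancer clones — lineages such as the Tasmanian devil facial tumours DFT1 and
DFT2 that spread between hosts as cell allografts — from time-stamped
whole-genome variant calls. This vignette is the package's own account of
its models: what each method assumes, which knobs matter, what the synthetic
cohort generator does and does not emulate, and where the known limitations
lie.

## The synthetic cohort generator

Every analysis in the package can be exercised on cohorts from
`simulate_cohort()`, which carries a complete truth table (per-branch
counts, per-tip burdens, subclone fractions, WGD dates, LoY branches, LINE-1
source attributions). The generator's defaults are the published study
conditions: a DFT1-like clone arising in 1986 with 63 tumours sampled
2003–2018 at 163.2 substitutions and 22.2 indels per genome per year
(regression rates), and a DFT2-like clone arising in 2011 with 41 tumours
sampled 2014–2018 at 496.3 substitutions, 86.5 indels and 24.1 LINE-1
insertions per genome per year; signature mixtures default to SBS1:SBS5 of
8:92 (DFT1) or 3.4:96.6 (DFT2) and ID1:ID2 of 66:34 or 47:53; sequencing
depth defaults to 83x and purity to U(0.75, 1), matching the sequenced
cohorts.

**Transmission tree.** The topology is a random coalescent of the sampled
tumours; sampling dates are uniform draws over the sampling window (the real
sampling design is unknown, so this is configurable, not inferred); internal
node dates are drawn sequentially in preorder, uniformly between the parent
date and the earliest descendant tip. The root *is* the clone origin: the
published trees show rapid early diversification, so no unobserved trunk is
inserted by default (a trunk of clone-shared variants can still be supplied
to `origin_interval_with_ambiguity()`). This is not a literal constant-rate
birth process — conditioning a birth process jointly on the tip count and a
fixed sampling window has no convenient exact sampler — and we verified that
the obvious alternative (dates uniform over the whole constrained polytope)
concentrates deep nodes against the root and makes the origin practically
unidentifiable, so the sequential-uniform scheme was kept. An optional
`multifurcation_prob` collapses internal nodes into their parents to emulate
single donors seeding several recipients.

**Mutations.** Per branch and class, counts are Poisson(rate x duration),
with all rates expressed genome-wide: the simulated reference is
`callable_genome x genome_scale` base pairs (default 2,983,750,195 / 300,
about 10 Mb, so cohorts simulate in seconds), but burdens are drawn at the
genome-wide rate, keeping fitted slopes directly comparable to the
published per-genome rates. Substitution channels are drawn from the
configured signature mixture and placed at genomic sites whose
trinucleotide context matches the channel, without collisions (infinite
sites); indels are placed at compatible homopolymer runs. A hypermutator
specification multiplies substitution and indel rates from one branch
onward and draws the excess from the mismatch-repair signatures (SBS6,
ID7), mirroring a lineage that lost mismatch repair. WGD events scale
post-duplication substitution accrual by `kappa` (default 2: accrual
follows DNA content; `kappa = 1` is also supported and all outputs are
labelled with the value used).

**Reads.** Bulk allele counts are depth ~ Poisson(depth_mean) and alt ~
Binomial(depth, VAF) with

VAF = purity x multiplicity x cellfraction / (purity x copies + 2(1 − purity)),

germline heterozygous sites at VAF 0.5. Population germline variation uses a
pool of variants with per-variant heterozygosity and a per-host scaling
factor calibrated so per-sample heterozygosity centres on 0.132 sites/kb
with a realistic 0.08–0.15 range. Coverage bins are Gaussian around the
purity-corrected copy-number ratio, with host (contaminating) cells
contributing sex-aware copy numbers on chrX/chrY.

**What the generator does not emulate:** sequencing error and artefactual
calls (somatic specificity in tests is therefore near-perfect by
construction), alignment and calling biases, mutation-rate heterogeneity
along the genome beyond trinucleotide context, minor-allele (copy-neutral
LOH) structure, host contamination of somatic VAFs, and epidemiological
structure (R0, host death). Passing recovery tests therefore demonstrates
the correctness of the estimators under their stated models, not robustness
to real-data artefacts.

## Germline filtering and purity

A variant is germline if any panel normal shows at least `min_alt = 2`
supporting reads at depth `min_depth = 10` (the thresholds are exposed; the
published analysis does not state its own). Matched-host subtraction is
applied first where a host link exists, then the full panel; the order is
recorded per variant, and enlarging the panel can only move variants toward
germline. Variants present in every tumour of the clone and absent from all
normals are genuinely ambiguous — the founder devil is not sampled — and are
kept in the somatic partition but flagged for the clock module. Purity is
twice the median clonal VAF in diploid copy-neutral regions, capped at 1,
flagged below 50 usable variants.

## Tree building and the strict clock

Clonal presence is called at VAF >= 0.2 x purity. The greedy
perfect-phylogeny construction processes variants by decreasing sharing
count and accepts a carrier set if nested or disjoint with everything
accepted so far; under infinite sites with clonal variants the accepted
laminar family is the transmission tree, and conflicts arise only from
genotyping noise (a conflict fraction above 20% warns that the clonal
threshold is probably wrong). Parked variants are assigned afterwards to the
branch minimising the symmetric difference with their carriers.

The clock sampler (Rcpp) is Metropolis-Hastings over the rate and the
internal node dates, with likelihood `prod Poisson(count | r x duration)`,
uniform priors (rate on (0, 10 x max burden / window span); dates subject to
parent <= child), 50,000 sweeps with 10,000 burn-in by default, multiplicative
rate proposals and single-site date proposals (half-width `span/10` years).
Convergence is reported as split-half disagreement of the posterior rate
median; values above a few percent warrant longer chains. Dating uses
substitutions only; other classes are dated post hoc through the fitted
rate. The origin interval integrates over the somatic fraction
`f ~ Uniform(0, 1)` of trunk variants — a package choice, reported in the
output, since the published prior is unstated. The pretransmission interval
(lag between clone emergence and the sampled divergence) is deliberately not
modelled, matching the published analysis.

**Calibration.** With the true topology recovered and the origin fixed at
its true value, the posterior medians are unbiased at both study designs
(bias below 0.05 years), but the 95% credible intervals are mildly
anticonservative as frequentist intervals: measured coverage is about 88%
(DFT1-like design) and 80% (DFT2-like, whose 4-year sampling window carries
little root-ward information). The intervals condition on the reconstructed
tree and exact branch counts; a fixed true origin is a point the flat prior
does not favour. Users comparing a known date against the interval should
treat near-misses of a few tenths of a year accordingly.

## Subclone deconvolution

VAFs of somatic variants in copy-neutral diploid regions (variants in CNV
regions are excluded — their expected VAF is CN-dependent) are fitted with
binomial mixtures for k = 1..3 components, chosen by BIC; k = 1 has a
closed-form MLE, k >= 2 uses EM with 10 short seeded restarts and one long
refinement, and at most 5,000 variants enter the fit (a seeded subsample;
binomial error on a fraction at that size is ~0.01, far below the 5-point
reporting scale). Component VAF `p` converts to cell fraction `2p/purity`.
`k_max = 3` because ~80x bulk depth cannot resolve more; the practical
detection floor is a ~0.1 cell fraction at depth 80. Ties in assignment
go to the larger-fraction component. Pseudo-samples (clonal plus own
private variants) attach to the branch maximising path-variant presence
minus absence; attachments within one variant are reported as ambiguous.

## Spectra, signatures, rates

Substitution spectra use the standard 96 trinucleotide channels on the
pyrimidine strand. Indels use a reduced 24-channel scheme — insertion or
deletion, crossed with the repeated unit (1-bp A, 1-bp T, 1-bp C/G,
multi-base) and the reference run length at the site (1, 2–4, >= 5) — which
is sufficient to express the ID1/ID2/ID7 contrasts at desk scale without the
full 83-channel catalogue. The packaged reference profiles are deterministic
*synthetic analogues* built from the signatures' qualitative definitions
(SBS1: C>T at NpCpG; SBS5: flat; SBS6: broad C>T with CpG emphasis; ID1/ID2:
1-bp T/A insertion/deletion at long homopolymers; ID7: deletion-dominated
mismatch-repair mix); they are not the COSMIC estimates, and the simulator
draws from the same profiles, so fitting and simulation are coherent.
Exposure fitting is non-negative least squares with a 1% sparsity pass.

Rates are unweighted OLS of burden on sampling date with t-based CIs and an
F test; non-significant classes are labelled and their ratios suppressed.
No phylogenetic correction is applied — tumours sharing branches share
mutation-count deviations, so residuals are positively correlated; measured
consequences at the study designs are slope CIs that cover truth ~88–96% of
the time (nominal 95%) and an inflated naive type-I rate for the clade
rate-shift test when burdens are fully tree-generated. The rate-shift test
(burden ~ date + clade indicator per internal branch with >= 4 descendants,
BH-corrected) is therefore calibrated under independent Poisson noise and
should be read as a flagging tool, with the planted-deficit recovery test
showing its estimates are accurate when the effect is real (~1,200-mutation
deficits recovered within 20%). Ratio intervals are first-order delta
method, with a parametric bootstrap co-reported; the published error
propagation behind the printed ratio intervals is unstated and is not
reproduced by the delta method applied to the printed CIs, so the printed
interval bounds are not used as reference values. Regressions use a free
intercept (whether the published fits were constrained through the origin
is unstated). Hypermutators are flagged at 3x the leave-one-out prediction
by default (no published threshold exists); hypermutator lineages are
excluded from clone-level rate fits, as in the published rate table.

## Copy number, WGD, LoY

Segmentation is recursive least-squares binary splitting with a
`3 sigma^2 log n` penalty (sigma robustly estimated from first differences
of bin depths) and 10-bin minimum segments; integer CN inverts the
purity-corrected depth ratio. Tetraploidy requires modal CN 4 *and* a
bimodal clonal VAF distribution at the multiplicity-1 and -2 positions, each
cluster holding at least 10% of variants (the published tetraploidy
criterion is unstated; this is a documented substitute). WGD dates are
`post_count / (kappa x r)` before sampling, with exact Poisson uncertainty
on the post-duplication count propagated with the rate's CI; the simulator
and the dating operation share `kappa`, so dating inverts the simulation by
construction. LoY uses the sex-aware expected chrY/autosome ratio
`(purity x ploidy/2 + (1 − purity) x hostY) / (purity x ploidy + 2(1 − purity))`
(chromosome Y doubles with the genome at WGD), flagging below half the
expectation; a female founder has no Y baseline and the operation refuses.
Recurrence maps match CNVs across samples by direction and boundary
agreement (±1 bin) and count parsimony origins, so mitotically inherited
CNVs are represented once.

## Selection

The dN/dS module is a deliberate "dNdScv-lite": per-channel rates are fitted
to synonymous sites genome-wide (so summed expected synonymous counts equal
the observed total by construction), per-gene expectations enumerate every
CDS site x 3 alternates, and Poisson LRTs test missense, truncating and
global excess per gene with BH correction over genes carrying at least one
protein-altering mutation (testing all genes is a flag). There is no
negative-binomial covariate shrinkage, rates are pooled across the clone,
and CDS models are single-exon plus-strand — adequate for the simulator's
annotation, stated limitations for real annotation. Indel expectations are
proportional to CDS length times the cohort coding-indel rate.

## LINE-1 attribution

An insertion carrying a 3' transduction is attributed to the annotated
full-length element whose 3' end lies within 10 kb upstream of the
transduced segment on the matching strand (the published assignment window
is unstated; 10 kb is the package default, exposed); nearest wins, ties are
flagged, orphans are reported, and attributed plus orphans always equals the
transduction-bearing total. Per-branch activity uses gain-polarity
parsimony placement of each insertion's carriers.

## Numerical and testing choices

Problem sizes in the test-suite and acceptance script are chosen to keep a
full run within a few minutes on one CPU: module tests run 6–10-tumour
cohorts at 1/1000–1/2000 genome scale with read-level calls, while recovery
experiments use burden-level simulation at the full published designs (63-
and 41-tumour cohorts, 100 replicates for rate recovery, 10 seeds for origin
recovery). Degenerate inputs are handled explicitly: constant burdens give a
0/0 F statistic and are declared non-significant; all-identical sampling
dates, empty normal panels, female-founder LoY calls, zero observed
synonymous mutations, and cyclic parent pointers raise informative errors;
exhausted placement pools (a genome too small for the requested mutation
load) fail loudly with advice to widen the genome. All stochastic functions
take explicit seeds and restore the caller's RNG state.
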