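---
title: "Methods: quantitative genetics of expression in replicated F2 crosses"
author: "f2eqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative genetics of expression in replicated F2 crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(f2eqtl)
```

## The design and what the package estimates

`f2eqtl` analyses gene expression in a *replicated F2* design: one reference
inbred line is crossed as a common parent to each of several alternative
inbred lines (ten lines, nine crosses by default), a single F1 per cross is
self-fertilized, and the resulting F2 families are measured by RNA-seq
together with replicate plants of the parental lines. Within any one family
exactly two founder haplotypes segregate, so every locus is a three-state
system (RR, RA, AA); across families, up to ten functionally distinct
founder alleles can be compared at every gene. The package implements the
full chain from allele-specific read counts to:

* line-of-origin genotypes via a hidden Markov model (HMM) and a
  relatedness matrix on the 0-2 scale (twice the coancestry);
* per-gene variance partitioning into a cis component, a trans (rest of
  genome) component and residual noise, by maximum-likelihood animal models;
* an allelic series at each cis locus (how many functionally distinct
  founder alleles, and which lines share them);
* beta-binomial tests of allele-specific expression (ASE) in heterozygotes;
* genetic covariances of gene pairs via the variance-of-sums identity;
* per-family marker-regression scans, trans-eQTL clustering with hotspot
  calling, and QTL scans on principal-component scores.

A synthetic-data generator with a fully known architecture drives the test
suite and the estimator benchmark; its defaults are the study conditions the
analysis methods are meant for.

## Genotyping: putative calls, HMM, maps, relatedness

Marker genes with allele-resolved read counts give a putative call per plant
per marker: RR when the alternative-allele read fraction is at most
`tau_hom` (default 0.15), AA when at least `1 - tau_hom`, RA otherwise, and
missing below `min_total = 2` reads. These calls are noisy at low coverage,
and ASE makes heterozygotes resemble the high-expressing homozygote, so the
calls are treated as *emissions* of an HMM whose hidden states are the true
genotypes.

The chain per chromosome uses the F2 segregation (1/4, 1/2, 1/4) as the
initial distribution; the transition between adjacent markers is the
two-gamete transmission matrix parameterised by a recombination fraction
`r_k` per interval; the emission observes the true state with probability
`1 - eps_m` and each wrong state with `eps_m / 2`, with a marker-specific
error rate `eps_m` (missing calls are emitted with state-independent
probability and drop out of the likelihood). Estimation is plain EM over
forward-backward statistics summed over plants; both M-steps are closed
form: `eps_m` is the expected mismatch fraction at marker m, and `r_k`
follows from the expected number of recombinant gametes in the interval
(every genotype transition is two independent gamete transmissions, so the
RA-to-RA transition contributes `2 r^2 / ((1-r)^2 + r^2)` expected
recombinants). Convergence is declared when the log-likelihood moves by
less than `1e-4`; 200 iterations are the cap, and a non-converged fit is
flagged, not silently returned. Parameters are bounded to `eps_m <= 0.49`
and `1e-9 <= r_k <= 0.5`.

Genetic maps come from the fitted `r_k` through the inverse Haldane
function `d = -50 log(1 - 2r)` cM (Kosambi is not offered: the crossover
generator is interference-free, so Haldane is the matching map function
throughout). Genes without informative markers are interpolated: equal
decoded flanking markers pass their genotype on, disagreeing flanks (a
recombination interval) give an unknown genotype, and genes outside the
flanked range take the nearest marker. Markers whose fitted `eps_m`
exceeds 0.3 are excluded from mapping and interpolation.

Relatedness is computed from line-of-origin genotypes: at one locus the
coancestry of two plants is a quarter of the number of founder-line matches
among the four allele cross-pairs (founder lines are treated as unrelated
and fully inbred), and `R = 2 * coancestry` averaged over loci. Identical
inbred plants reach R = 2, F2s of different families centre on 0.5, plants
of different founder lines sit at 0. Because marker averaging can leave the
matrix very slightly indefinite, the smallest ridge restoring positive
semi-definiteness is added (warning if it exceeds `1e-6` of the mean
diagonal).

## Expression preparation

Genes with mean counts-per-million below 0.5 are dropped. Retained genes
are converted to CPM, offset by 0.5 (so zero counts are transformable; the
offset is configurable and recorded), Box-Cox transformed gene by gene with
the profile-likelihood lambda on a grid from -2 to 2 in steps of 0.05, and
standardized to mean zero and unit variance. Standardization uses the
population (n) denominator so the variance components of a fitted gene sum
to one exactly. Per-gene transform records are kept so any phenotype value
traces back to a raw count. Precision-weight normalisation of the
cross-specific pipeline is not reproduced; the marker-regression scan
accepts user-supplied observation weights instead.

## The animal model and the cis tests

For each gene the phenotype is modelled as `y = X b + g + e` with
`g ~ N(0, Vg K)` over the relatedness matrix `K` and `e ~ N(0, Ve I)`,
fitted by full maximum likelihood (not REML, which is available nowhere in
the sequence because the likelihood-ratio tests require ML). One
eigendecomposition of `K` serves every gene: rotating by the eigenvectors
diagonalises the covariance in the mixing proportion `s = Vg / (Vg + Ve)`,
and the profile likelihood is maximised by a one-dimensional search with
GLS fixed effects at each `s`. `Vg = 0` boundary solutions are reported as
such. Chi-square p-values are computed through the log-scale survival
function so statistics in the hundreds do not underflow.

Three nested models are fitted per gene: Model 0 (cohort fixed effects
only), Model 1 (adds one additive cis parameter per family: heterozygotes
move by `a_z`, alternative homozygotes by `2 a_z`; parental plants enter
their family block at dose 0 or 2), and Model 2 (adds one dominance
deviation per family, genotypic values 0, `a_z + d_z`, `2 a_z`). Each step
adds one parameter per segregating family, so `LRT1 = 2(LL1 - LL0)` and
`LRT2 = 2(LL2 - LL1)` are referred to chi-square with that many degrees of
freedom (nine in the full design). Under Model 1 the genetic variance is
the trans component, because the cis effect sits in the fixed effects.

Two estimators of the cis locus variance are provided: the model contrast
`Vg(r2) = Vg(Model 0) - Vg(Model 1)`, and the effect-dispersion estimator
`Vg(a) = 2 (s_a^2 - mean(se_a^2))` where `s_a^2` is the sample variance
(n-1 denominator, i.e. 8 for nine families) among the family additive
estimates and the second term removes estimation error. Both are reported
signed; clipping negative estimates to zero is a reporting choice, not an
estimation one. Haseman-Elston regression is the least-squares alternative:
by default it regresses squared pair differences on `(R_ii + R_jj, R_ij)`
jointly, so `-coef(R_ij)/2` estimates Vg and any shift common to a pair
cancels exactly; the classical cross-product form is available but leaks
the estimated mean into the products and visibly attenuates at a few
hundred plants, which is why it is not the default.

Over/underdominance is probed per family by comparing Model 2 against the
complete-dominance constraints `d_z = +a_z` and `d_z = -a_z` (each merges
the family's dose and heterozygote columns into one), a 1-df test per sign;
only beating *both* constraints argues for a heterozygote outside the
homozygote range. Multiple testing uses Benjamini-Hochberg q-values.

## Allelic series

The nine family additive estimates plus the reference anchored at zero are
ranked; cutting the ranking at any non-empty subset of the nine gaps yields
`2^9 - 1 = 511` configurations, from two to ten alleles. Each configuration
is refitted with rank-bin members sharing one additive parameter (the bin
holding the reference is fixed at zero); for each allele count the best
configuration is kept, and the count grows stepwise from two while twice
the likelihood gain exceeds 3.84 (the 5% chi-square point with 1 df). Ties
among estimates are broken by founder-line index, so the procedure is
deterministic and invariant to line relabeling. Because the paper leaves
open whether genes without cis signal report one or two alleles, the search
floors at two by default and an optional 1-vs-2 comparison with the same
rule (`allow_k1 = TRUE`) collapses no-signal genes to a single allele.
Heterozygosity summarises a series as `H = 1 - sum(q_i^2)` over the line
counts per allele class.

A property worth knowing: the per-step threshold is nominal for a *fixed*
split, but each step selects the best configuration among many, so the
realized rate of accepting a spurious extra allele exceeds 5%. The
procedure is implemented as specified; the test suite therefore asserts
recovery of a generating three-allele series as the majority outcome over
noise replicates rather than for every single draw.

## Allele-specific expression

For cis-heterozygous plants of one gene and family, the alternative-allele
read counts are modelled as beta-binomial (binomial mixed over a Beta
allele fraction), which absorbs the overdispersion that a plain binomial
misses; the comparative simulation in the test suite shows the binomial
test's size inflating several-fold on overdispersed balanced data while the
beta-binomial test stays near nominal. The null fixes `alpha = beta` (mean
fraction one half); the alternative frees the mean; both are optimised over
`(logit mu, log theta)` with `theta = alpha + beta` bounded at `1e6` (the
binomial limit) and the 1-df LRT is reported together with the ML mean
`mu` and the naive mean of per-plant fractions. Plants with zero reads are
excluded; two informative plants are the minimum. With the generator's
`ase_coupling` switched on, the alternative-read fraction of a heterozygote
is `plogis(ase_strength * a_z)`, so whichever allele raises expression is
over-represented among its transcripts, as real cis variation produces.

## Genetic covariance of gene pairs

For a pair of standardized phenotypes the null animal model is fitted to
`y1`, `y2` and the raw sum `Z = y1 + y2` (deliberately not restandardized:
the identity `Var Z = Var y1 + Var y2 + 2 Cov` needs the raw-sum variance),
giving `C_G = (VgZ - Vg1 - Vg2)/2` and likewise `C_E`. Background sets pair
each gene with `k = 10` random partners, deduplicated; contrast sets (for
example pairs sharing a trans eQTL) are compared on squared covariances
with a Welch t test.

## Scans, clustering, PCA

The cross-specific scan regresses a family's phenotype on marker dose and a
heterozygote indicator plus cohort covariates (optionally weighted),
reporting additive and dominance estimates and the model-vs-null F;
gene-specific permutation p-values come from the genomewide-maximum null
distribution over phenotype shuffles, stratified within cohort by default
to respect the design, `p = (1 + #exceedances)/(B + 1)`. Significant trans
hits are chained single-linkage within 2 cM per family and chromosome;
loci affecting at least 30 distinct genes are hotspots. PCA of the
standardized expression matrix uses the standard singular value
decomposition with the sign convention that each component's largest
loading is positive; PC scores are then scanned like any other trait with
Models 0/1/2 at every second gene position, retaining the best position per
chromosome, with `LRT_total = LRT_additive + LRT_dominance` by construction
and a pcQTL declared below `p = 1e-5`.

## The synthetic generator and the estimator benchmark

`founder_panel()` fixes the design constants (ten lines, one reference,
marker and gene positions on a shared cM map); `simulate_meiosis()` places
Poisson crossovers with no interference (Haldane; at the study-average 90
cM chromosome a diploid F2 chromosome carries ~1.8 crossovers);
`simulate_f2_family()` builds each F2 from two independent F1 gametes;
`simulate_expression()` adds cis, trans, cohort and Gaussian environmental
effects, draws totals from a negative-binomial depth model (lognormal gene
abundance around 50 reads, lognormal library-size factors, dispersion 0.05)
and splits heterozygote reads binomially. Putative-call miscalls are
injected at the call level at a configurable rate, matching the HMM's
emission abstraction. One global seed expands into counter-based substreams
per family and stage, so any subset regenerates identically.

The generator emulates the features the estimators rely on - line-of-origin
segregation, realized relatedness, cis/trans genotypic values, depth-driven
count noise, coupled ASE - and deliberately omits others: no sequence-level
reads, no read-mapping bias, no inversions or meiotic drive (observed in
real data but not modelled), no interference. Passing tests therefore
validate the estimators under the stated model, not robustness to, say,
segregation distortion.

The estimator benchmark redraws, on a fixed realized genotype matrix, iid
Normal founder-haplotype effects per replicate, so the locus's genetic
values have covariance `Va * R_locus` with `Va = 2 sigma_alpha^2`; all
three estimators (HE on the locus relatedness, Vg(r2), Vg(a)) then target
the same `Va` without bias and their mean squared errors are comparable.
The default cis scenario uses `Va ~ 0.1` against `Ve ~ 0.9`, the scale of
typical per-gene components in this kind of data; there MSE(HE) >
MSE(Vg(r2)) >= MSE(Vg(a)). Holding the effects fixed across replicates
instead makes the model-contrast estimator conditionally biased at desk
scale and is not the default frame.

## Desk-scale behaviour worth knowing

The test suite runs on compact genomes (two to ten chromosomes of 90 cM,
60-500 markers, 9 x 25-100 F2s, tens to hundreds of genes - sizes chosen so
a full run finishes in minutes on one CPU). Three finite-size effects are
documented rather than hidden:

* **Proximal contamination.** With a toy genome of few chromosomes, the cis
  dose columns explain a visible share of the realized genome-wide
  relatedness, so adding them inflates `LRT1` under a *polygenic* null.
  Null calibration is therefore checked on genes with no genetic effect
  (the natural null of an eQTL screen), where the empirical size is ~0.05;
  at a real 14-chromosome scale the artifact is small.
* **Vg(trans) absorption.** Model 1's family-dose columns absorb
  between-family genetic contrasts, so its Vg leans on within-family
  relatedness and underestimates the generating trans variance at small
  family sizes (recovering ~0.24 of a generating 0.3 at 60 F2s per family
  and ~0.26 at 100); the bias shrinks as families grow.
* **Stepwise allele-count multiplicity** (described above).

Degenerate inputs are errors, not silent results: zero library sizes,
constant phenotypes, singular designs (with the collinear columns named),
non-segregating genes (flagged untestable), empty configuration bins, and
recombination fractions at one half (map distance capped with a warning).

## Pipeline

`run_pipeline()` executes the stages in dependency order - simulate,
genotype, normalize, cis fits, allelic series, ASE, covariance, PCA/pcQTL,
sequence-variation regression - on a configuration object whose thresholds
default to the analysis constants (CPM 0.5, FDR 0.05, 2 cM window, 30-gene
hotspots, pcQTL at 1e-5) and whose scale parameters default to a demo-sized
study. Each stage writes TSV tables to the run directory, a JSON manifest
records configuration, package version and per-stage timing, and a rerun
with the same configuration reproduces every table exactly. A stage whose
prerequisite is disabled refuses to run and names the missing stage. The
sequence-variation stage consumes per-gene, per-window alignment summaries
(total, aligned and mismatching base pairs, giving nucleotide diversity
`pi = mismatch/aligned` and the indel statistic
`U = (total - aligned)/total`); on synthetic runs these summaries are
generated with variation loosely coupled to the cis architecture, and the
per-gene predictors (mean over the nine line comparisons) feed a
standardized multiple regression on cis-eQTL significance.
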