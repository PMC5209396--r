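---
title: "Methods: panel design, marker diagnostics, structure, trial analysis and dual association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel design, marker diagnostics, structure, trial analysis and dual association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`kaspanel` re-implements, as one tested chain, the computational steps
behind a KASP genotyping panel for an inbred crop diversity set: SNP
discovery from a dual-transcriptome comparison, marker diagnostics,
admixture-based population structure, REML analysis of an alpha-design
insect-count trial, and a dual (rank-sum + mixed model) marker--trait
association scan.  This vignette records the models, the tunable
parameters, and the design choices made where the design was genuinely
open.

## Synthetic data: what it emulates, and what it does not

All tests and examples run on synthetic data with planted truth; no
real sequencing, genotyping or insect data ship with the package.

**Transcriptome pair.** `simulate_transcriptome_pair()` builds a
reference EST set and two accession consensus sets.  Accession A equals
the reference; accession B differs at planted SNP positions (default
rate 0.005/nt).  A fraction of contigs receives a near-identical
paralogous copy (default identity 0.99, i.e. within the >98% band that
confounds fragment uniqueness), and a fraction of bases receives a
Phred score drawn from 15--32, below the discovery threshold of 33;
all other bases score 40.  The generator does **not** simulate reads,
alignment, or coverage: the consensus-with-qualities is the contract
boundary, so passing tests say nothing about upstream read mapping or
consensus calling on real data.

**Diversity panel.** `simulate_diversity_panel()` draws subpopulation
allele frequencies from the Balding--Nichols model
(Beta with mean p and concentration (1-F)/F), admixture proportions
from a symmetric Dirichlet (default concentration 0.2, giving mostly
near-discrete membership with a minority of admixed accessions), and
genotypes by drawing **one** allele per accession and doubling it --
the fully inbred limit -- with an independent heterozygous-call
probability (default 0.02, matching a highly homozygous panel whose
mean heterozygous call rate is about 2%) and a missing-call
probability (default 0.01).  Defaults are 96 accessions, 653 markers,
3 subpopulations, F~ST~ 0.25.  Markers land on pseudo-chromosomes 1--9
with about 14% assigned to an unplaced "group 10", mirroring the usual
fraction of assays that cannot be anchored in a draft assembly.  The
generator does not model linkage disequilibrium between markers, so LD
decay can only be exercised with purpose-built block fixtures.

**Alpha design.** `generate_alpha_design()` returns a resolvable
incomplete-block design - every line once per replicate - whose
contractual property is that of the field's alpha designs: no pair of
lines shares a block more than twice.  Randomized allocation with
min-conflict repair was tried first and could not reliably satisfy the
bound at the canonical geometry (96 lines, 10 replicates of 8 blocks
x 12 pots), so the generator uses the classical cyclic construction
instead: an r x k generating array over Z~s~ in which, for every pair
of columns, each difference residue occurs at most twice.  Arrays are
found by randomized depth-first search; the canonical geometry uses a
precomputed, verified array randomized by property-preserving
symmetries (row/column permutation, unit multiplier, per-row additive
shifts).  Every returned design is re-checked by exhaustive pair
enumeration.

**Aphid trial.** Counts come from a latent Gaussian on the square-root
scale, t = mu + QTL + line + replicate + block + error, with
total = round(max(0, t^2 - 0.375)) and the alate (winged) share
binomial given the total.  This makes sqrt(x + 0.375)
variance-stabilizing *by construction*, so the REML analysis is exactly
specified and parameter recovery is testable.  No claim is made that
real aphid counts follow this law; the trial literature does not state
a count distribution, and the latent-square model is a stand-in chosen
for testability.  The intercept is solved so that the expected grand
mean matches a calibration target (default 132.327 aphids/plant); QTL
effects are written on the square-root scale with the difference
between opposite homozygotes equal to the stated effect.  Default
variance components (line 3, replicate 0.2, block 0.3, residual 1.5 on
the sqrt scale) give a plot-basis heritability of 0.6, in the range
reported for insect-count traits on diverse host panels.

## Panel design

Candidate SNPs are positions where both consensus calls are unambiguous
A/C/G/T and differ; N masks a site.  The filters are pure predicates,
so their order does not change the final pass set (tested):

* **Quality**: the lower of the two Phred scores must be at least 33
  (`< 33` fails -- the threshold value itself passes).
* **Fragment**: 150 nt centred on the SNP, 74 left / 75 right (the SNP
  at 1-based offset 75), taken from the accession-A consensus; sites
  too close to a contig end are `edge`.  The even fragment length
  forces an asymmetric split; 74/75 is this package's convention.
* **Uniqueness**: the fragment must align to exactly one reference
  sequence with identity strictly greater than 0.98 over at least 90%
  of its length, both strands searched.  Identity is matches over
  alignment columns of the best local alignment (match +1, mismatch
  -2, gap open 5, gap extend 2 per position).  The 90% coverage rule
  keeps short spurious seeds from qualifying while a 150-nt fragment
  with up to 2 mismatches still does.  Note the strictness boundary:
  3 mismatches in 150 nt is exactly 98.0% and does *not* qualify, so a
  paralog pair whose window differs at 3+ sites legitimately escapes -
  the tests therefore exercise guaranteed rejection with paralogs at
  1 mutation per contig.

Survivors are ranked by decreasing lower Phred score (ties by contig
then position) and the top `panel_size` (default 682) retained.
Internal controls are pairs of panel fragments from different contigs
whose sequences match at >98% identity with swapped SNP alleles; they
are reported as two markers forming one control pair.

The local alignment itself is delegated to Biostrings'
Smith--Waterman (`pairwiseAlignment(type = "local")`); the test suite
cross-checks its scores against an independent plain-R
dynamic-programming oracle on short random pairs.

## Marker diagnostics

* **Allele frequencies** from genotype counts, missing excluded;
  oriented to the major allele.
* **PIC** uses Botstein's formula, biallelic form
  1 - (p^2 + q^2) - 2 p^2 q^2, maximum 0.375 at p = 0.5.
* **HWE**: the exact test enumerates all heterozygote counts
  compatible with the observed allele counts and sums the
  probabilities of outcomes no more probable than the observed one.  A
  permutation estimator (default 10,000 shuffles of the 2N alleles
  into N diploids, add-one smoothed) approximates the same p-value and
  converges to it; the pipeline default reports the exact enumeration.
* **LD r^2** treats homozygotes in the inbred panel as haplotypes:
  heterozygous and missing calls are dropped pairwise and r^2 is the
  squared Pearson correlation of the 0/1 allele codes, identically
  D^2 / (p~A~(1-p~A~) p~B~(1-p~B~)).  Pairs with fewer than two
  complete observations, or monomorphic after dropping, are undefined.
  Distance binning uses same-chromosome pairs only; group-10 markers
  are excluded from all physical-distance summaries.
* **Polymorphism partition** classifies markers by the alleles
  observed per accession group (wild / crop).  Percentages are
  reported over the polymorphic markers and **truncated** (not
  rounded) to two decimals - the truncation convention is what makes
  244/653 print as 37.36.
* **Het/uncertainty filter**: loci with heterozygous, uncertain or
  missing calls in strictly more than 20% of accessions are dropped;
  surviving heterozygous/uncertain calls are recoded missing.

## Population structure

STRUCTURE-style MCMC with correlated allele frequencies is out of
scope.  The `admixture_em()` stand-in maximizes the binomial
likelihood of allele counts under P(allele B) = sum~k~ q~ik~ f~kj~ by
alternating closed-form EM updates of the admixture rows and frequency
columns.  The observed-data log-likelihood is asserted non-decreasing
at every iteration; missing genotypes contribute no terms (they are
mean-imputed only in PCA).  K = 1 is closed-form.  This produces the
two artefacts the pipeline consumes - Q covariate matrices and per-K
log-likelihoods - but makes no claim to reproduce STRUCTURE's
posterior.

`evanno_deltaK()` implements L'(K) = L(K) - L(K-1),
L''(K) = |L'(K+1) - L'(K)|, delta-K = |L''(K)| / sd(K), with the mean
and standard deviation over independent runs per K.  The absolute
value follows Evanno's definition even though the formula is often
quoted without it.  delta-K is reported for interior K only and
dropped where the replicate spread is exactly zero.  With a
deterministic EM the replicate spread comes from random restarts
converging to different local optima; at the true K the optimum is
reliably found (small spread, large curvature), which is exactly what
the delta-K peak rewards.

## Trial analysis

All counts are transformed to t = sqrt(x + 0.375) before analysis;
back-transformation is max(0, m^2 - 0.375).  The model is

t = mu + line + replicate + block(replicate) + error,

fitted by REML via lme4.  Strata absent from the data (or constant)
are dropped; a model with no random terms falls back to least squares.
Which strata the original trial treated as random is not documented,
so both replicate and block are retained as random by default.

* **Line fixed** gives GLS predicted means (equal to raw means on a
  balanced design), their standard errors, the Wald chi-square test of
  line differences (n~lines~ - 1 df; the denominator-df approximations
  of proprietary software are not reproduced), and the **maximum LSD**:
  t~0.975,df~ times the largest standard error of a difference over
  all line pairs, the conservative yardstick for unbalanced designs.
  Residual df are taken as n - p, exact for least squares and a
  large-sample approximation under the mixed fit.
* **Line random** gives variance components and broad-sense
  heritability.  The default is the plot basis,
  h^2 = s^2~line~ / (s^2~line~ + s^2~rep~ + s^2~block~ + s^2~resid~);
  a line-mean basis (s^2~resid~ divided by the mean replication) is
  available as an option since the reporting basis of such trials is
  often unstated.
* Total counts are analyzed as their own trait: summed first, then
  transformed.

## Dual association

The response is the accession-level predicted mean on the square-root
scale (a two-stage analysis), not plant-level data.

**Kruskal--Wallis scan** (`kw_scan`): per marker, the two homozygote
classes are compared (heterozygous and missing calls dropped; classes
smaller than 2 skip the marker) with the tie-corrected H referred to
chi-square with 1 df; all-tied responses give H = 0, p = 1 by
convention.  The significance threshold is 0.005 - stringent because
this scan carries no structure correction.

**Mixed-model scan** (`mm_scan`): y = X beta + u + e with
var(u) = sigma^2~g~ K (VanRaden method 1 kinship: K = ZZ' / (2 sum
p(1-p)), Z = M - 2P, dosage coding 0/1/2 with heterozygote 1 and
missing imputed to the mean) and var(e) = sigma^2~e~ I.  The kinship
is eigendecomposed once and the restricted likelihood profiled down to
the single ratio delta = sigma^2~e~/sigma^2~g~, maximized on a log
grid with local refinement (EMMA).  By default the null-model
components are reused for every marker (P3D); exact per-marker
re-estimation is available.  The SNP coefficient is tested with a GLS
t-test on n - rank(X) df.  Q covariates enter as K - 1 columns - the
rows of Q sum to one, so the full matrix would be collinear with the
intercept; dropping the last column is this package's convention.
With identity kinship and no Q the scan provably reduces to OLS, which
the tests assert to 1e-6.

Hits must pass **both** tests (KW p <= 0.005 and mixed-model
p <= 0.01); `intersect_and_report()` builds per-trait hit lists, their
overlaps, and Manhattan/QQ tables.  No multiplicity adjustment is
applied beyond these fixed thresholds - that is the procedure this
package reproduces, not a recommendation.

## Numerical choices and degenerate inputs

* EM: frequencies clamped to [1e-9, 1-1e-9]; convergence on absolute
  log-likelihood change (default 1e-4); non-convergence returns with a
  warning, never silently.
* EMMA: log-delta grid [-10, 10] with 101 points; an optimum at the
  grid edge warns that the variance ratio is effectively 0 or
  infinite.
* HWE: ties on outcome probability are included using a 1 + 1e-9
  relative tolerance; monomorphic markers return p = 1.
* KW at very small n: the chi-square reference is a continuous
  approximation to a coarse discrete permutation null.  Exhaustive
  enumeration shows it tracks the exact permutation tail probability
  within 0.05 wherever either p is at or below 0.1 (n = 7, 8), but can
  deviate by >0.2 at small H, where permutation p-values saturate
  near 1.  Since the scan only acts on p <= 0.005, the approximation
  is adequate where it matters.
* Alignment tie-breaks follow Biostrings' deterministic choice.
* Percent truncation (not rounding) to 2 decimals everywhere a
  partition percentage is reported.
* All generators take an integer seed and are byte-reproducible under
  it.

## Problem sizes used by the test suite

The suite exercises the study-scale geometry where the property
demands it (96 x 650 panels for structure and association power; a
96-line, 10-replicate alpha design; 200 simulated trials at 4
replicates for heritability recovery) and small constructed fixtures
everywhere an exact hand value is being checked.  These sizes are the
package's choice of a balance between fidelity to the emulated study
and a test suite that runs in minutes.

## Known limitations

* The admixture EM is a maximum-likelihood stand-in; its absolute
  log-likelihoods are not comparable to STRUCTURE's LnP(D), only the
  delta-K machinery on top of them is.
* Marker-level simulation is linkage-free; LD-decay behaviour is
  validated on constructed block fixtures only.
* The latent square-root count model is a modelling convenience; real
  overdispersed counts may violate it, in which case the REML
  assumptions hold only approximately after transformation.
* Indels, multi-allelic markers and read-level artefacts are out of
  scope throughout.
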