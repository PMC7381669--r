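---
title: "Methods: models, parameters and design choices in teapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in teapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`teapop` re-implements, as one tested pipeline, the statistical workflow used
to analyse RNA-seq derived SNP panels of clonally propagated tea collections:
variant QC, likelihood parentage with a resampling consensus, LD and kinship
statistics, a kinship-corrected metabolite association scan with LD-based QTL
clumping, and multi-SNP genotype-class analysis. This vignette documents the
models behind each stage, the tunable parameters and their defaults, and the
design decisions taken where the underlying methodology left choices open.

## The synthetic population generator

Every stage of the pipeline is exercised against simulated data with known
truth, so the generator is first-class, tested code rather than a fixture.
It emulates the salient features of a tea breeding collection:

* **Scale.** 190 founders plus 30 pedigree offspring (~220 accessions) in 5
  subpopulations; 5 chromosomes x 1,000 SNP sites over 2 Mb each.
* **Site frequencies.** Ancestral ALT frequencies are drawn from a symmetric
  Beta(0.55, 0.55) truncated to [0.05, 0.95] — a U-shaped spectrum typical of
  expressed-SNP panels.
* **Structure.** Subpopulation frequencies follow the Balding–Nichols model,
  `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` with `fst = 0.1`; each founder
  haplotype-chromosome descends from a random other subpopulation with
  probability `admixture = 0.1`, giving chromosome-scale admixture tracts.
* **Heterozygosity.** A within-subpopulation inbreeding coefficient
  (`inbreeding = 0.23`) makes a founder chromosome pair autozygous with that
  probability. Together with the frequency spectrum this puts mean per-site
  heterozygosity of the QC-passed panel near 26%, the level reported for real
  tea collections of this kind. These two values were calibrated once,
  analytically then confirmed by simulation, and frozen.
* **Linkage disequilibrium.** Haplotypes are built by a first-order Markov
  process along each chromosome: a latent standard-normal AR(1) chain with
  step correlation `exp(-rate * gap_bp)` is thresholded at `qnorm(p_site)`.
  Marginal allele frequencies are exact, adjacent-site r2 decays
  exponentially with distance, and `recombination_rate = 0` yields perfectly
  linked sites. We chose this latent-Gaussian Markov formulation over a
  finite donor-pool copying model because the copying model's zero-distance
  r2 is bounded by the donor-pool diversity and cannot reproduce the fully
  linked limit. The default rate (5e-5 per bp) puts the half-maximum decay
  distance of the default population near 7 kb, the kilobase-scale decay
  order of magnitude reported for tea subpopulations; it is a calibration to
  that order of magnitude, not a fit.
* **Pedigree.** Each offspring receives one recombinant gamete from an
  in-sample parent and one from a hidden parent simulated fresh from the same
  subpopulation. This makes the number of recoverable parent-offspring pairs
  equal to the number of offspring: with both parents in-sample, single-parent
  assignment could recover at most half of the true edges, which would
  conflate method error with design. Explicit two-in-sample crosses remain
  available through the `crosses` argument.
* **Observation model.** With probability `genotyping_error = 0.01` one
  randomly chosen allele of a call is flipped; calls are masked at
  `missing_rate = 0.02`; depth fields (`DP ~ Poisson(40)`, binomial allele
  split for heterozygotes) and passing-range site annotations are then
  synthesised so the QC cascade has realistic inputs.
* **Phenotypes.** For each trait (named after the eight catechins and gallic
  acid), planted QTLs contribute `effect_size` phenotype-SD per standardised
  dosage unit, a polygenic term is drawn multivariate-normal with covariance
  proportional to the kinship matrix, tissues (young/third/mature leaf)
  receive additive shifts with young leaf highest, and independent noise is
  added. Traits draw their QTLs from a deliberately small shared pool with
  same-sign effects, which reproduces the strong positive inter-compound
  correlations seen in catechin data.

What the generator does **not** emulate: genotype-calling artefacts beyond a
uniform flip error (no allele-specific expression bias, no depth-dependent
error), linkage between chromosomes, crossover interference, selection, or
the historical demography behind real LD. Tests passing on this generator
therefore demonstrate correctness of the statistical machinery under its
stated model, not robustness to every pathology of RNA-seq genotyping.

All randomness flows through explicit integer seeds; one seed reproduces
byte-identical outputs, including the pipeline's JSON summary.

## Variant QC cascade

The six steps run in a fixed order (annotation filters, genotype-level depth
filters, then site-level filters), matching the order such filters are
conventionally listed:

1. Annotation hard filters: remove sites with `QD < 2`, `FS > 60`, `MQ < 40`,
   `MQRankSum < -12.5` or `ReadPosRankSum < -8`. An absent annotation passes:
   callers emit these statistics conditionally, and removing sites for
   missing metadata would silently discard clean homozygous blocks.
2. More than two alleles: removed.
3. Homozygous calls need total supporting depth strictly greater than 10.
   Whether "supporting reads" means total or called-allele depth is
   ambiguous; we default to total depth with `hom_depth = "allele"` as an
   option.
4. Heterozygous calls need each allele's depth strictly greater than 4.
   Failing calls in steps 3–4 are set to missing; the site survives.
5. SNPs within 10 bp of an indel are removed, boundary inclusive (a SNP
   exactly 10 bp away fails; 11 bp passes) — the conservative reading.
6. Sites with missing rate above 0.8 or MAF below 0.05 are removed, with the
   missing rate computed after the depth masking of steps 3–4. The stricter
   0.10 missing-rate threshold used for the analysis marker sets is a
   separate, configurable parameter.

Every input site ends up exactly once as retained or as a removal-log entry
with its failing rules; the cascade is idempotent.

Per-site statistics use the Botstein polymorphic information content; for a
biallelic site `PIC = 1 - p^2 - q^2 - 2 p^2 q^2`, maximal at 0.375. Sites
with every call missing are flagged undefined rather than zeroed.

## Parentage

Single-parent likelihood assignment in the style of Marshall et al.'s
parentage system: for each offspring-candidate pair the LOD is the natural
log of `P(genotypes | candidate is parent) / P(genotypes | unrelated)`,
summed over jointly typed markers, with Mendelian transmission and the
untransmitted allele drawn from population frequencies. Mistyping is modelled
as replacement of the observed genotype by a random Hardy–Weinberg draw with
probability `e` (the documented mistyping model of that system); this keeps
the marginal distribution of an observed genotype at Hardy–Weinberg, so the
unrelated-pair likelihood is unchanged and the LOD stays finite whenever
`e > 0`. With `e = 0` one opposite-homozygote marker excludes the candidate
outright.

Confidence is calibrated by Monte-Carlo simulation of the Delta statistic
(best minus second-best candidate LOD). Simulated offspring are bred from a
fresh Hardy–Weinberg mother; with probability `prop_sampled = 0.5` she is
available among the candidates; loci are typed with probability
`prop_typed = 0.8` and mistyped at `e = 0.01` — the conventional settings for
a collection of ~220 candidate mothers. One fixed panel of unrelated
candidates is shared across simulated offspring (the true mother is fresh per
offspring); this is ~100x cheaper than fresh panels and leaves the Delta null
distribution unchanged in expectation. The critical Delta at a confidence
level is the smallest threshold whose exceedance set is at least that
proportion correct. The full-scale convention is 10,000 simulated offspring;
the acceptance runs use 2,000 per marker set, which bounds the critical-value
Monte-Carlo error well below the Delta separation observed between true and
false pairs at 500 markers.

One empirical note: the critical Delta is *not* monotone increasing as marker
informativeness falls. Less informative markers shrink the entire LOD scale,
and the critical value — which tracks the upper tail of the false-assignment
Delta distribution — shrinks with it. What is monotone is the assignment
success rate at fixed design, and that is the property the tests check.

Assignments are made per marker set (ten random sets of 500 markers with
PIC > 0.35, missing rate <= 10%, MAF > 0.05); a pair is reliable when the
same unordered pair is assigned at the strict (95%) confidence in at least
nine of the ten sets. Pairs are stored unordered because direction is not
identifiable from a single-generation likelihood. Reliable pairs are merged
into family groups as connected components of the pair graph.

## Population genetics

* **r2** is the squared Pearson correlation of ALT-dosage codes over jointly
  non-missing samples (composite LD). Phase is not available from called
  genotypes, so haplotype D' is out of reach; dosage correlation is what
  genotype-mode LD software computes.
* **LD decay** aggregates all intra-chromosomal pairs within 100 kb into
  100 bp bins (defaults mirror the conventional genotype-mode settings:
  site filters MAF >= 0.05, missing <= 0.5). The decay distance is where the
  mean r2 first drops to half its maximum, linearly interpolated between
  flanking bin midpoints; a curve that never crosses reports `> max_dist`
  rather than a number. The half-maximum reference is the global maximum bin
  by default (`reference = "first"` uses the shortest-distance bin; the two
  coincide for monotone curves).
* **Kinship** defaults to the Balding–Nichols-style standardised relationship
  matrix (dosages centred by `2p`, scaled by `sqrt(2p(1-p))`, pairwise-
  complete averaging), the matrix the efficient mixed-model literature calls
  the BN kinship; VanRaden centred GRM and mean IBS are available behind the
  `method` flag. Before use as a covariance the spectrum is floored at zero
  (smallest eigenvalue shifted to at least -1e-8 + tol).
* **PCA** standardises dosages, mean-imputes missing calls, and fixes each
  component's sign by forcing its largest-magnitude loading positive so
  results are deterministic.

## Mixed-model association and QTL clumping

The null model `y = Xb + u + e`, `Var(u) = sg2 K`, `Var(e) = se2 I` is fitted
by REML (the default of the efficient mixed-model tools this follows):
projecting out the fixed effects and decomposing the projected kinship
reduces the restricted likelihood to a 1-D function of `delta = se2/sg2`,
optimised on a log grid (`log delta` in [-12, 12]) refined by golden-section
search; hitting a grid end is flagged as a boundary fit. Pseudo-heritability
is `1/(1 + delta)`.

The scan fixes the variance components from the null model and tests each
site by generalised least squares after whitening with `V^(-1/2)` — the
standard one-decomposition approximation. Missing genotypes are mean-imputed
per site for the test only (never for LD or parentage); monomorphic sites are
reported without a p-value. With an identity kinship the scan reduces exactly
to OLS, which the tests assert at 1e-8.

The genome-wide threshold is `1 / Me`, with the effective marker number Me
estimated per chromosome by the Li–Ji eigenvalue method on the dosage
correlation matrix (`f(x) = I(x >= 1) + (x - floor(x))` summed over
eigenvalues, chromosomes summed). The eigenvalue spectrum is rounded at the
9th decimal before `floor()` so a numerically perfect correlation block
counts exactly 1. This estimator stands in for the external effective-marker
software conventionally used; the count is reported so the induced threshold
is visible, and the conventional printed cutoff (1.05e-5) is carried along
for annotation.

Clumping follows the reported merging rule: leads (p below the threshold) in
ascending p; supports need `p < 0.001`, distance <= 500 kb from the lead and
r2 > 0.1 with the lead; each support joins the first eligible lead (greedy,
single assignment — multiplicity handling is not specified by the rule, and
greedy ascending-p assignment is the deterministic standard); regions need
at least 2 SNPs; the member span is extended by 100 kb each side, floored at
position 1; overlapping extended regions of one trait merge, keeping the
best lead. A lead that fails to form a region stays available as a support
for later leads.

## Genotype-class analysis

Class strings concatenate per-site genotypes over position-ordered candidate
SNPs: homozygotes contribute their base once, heterozygotes render as
`"X/Y"` with the reference allele first (the published strings do not fix an
order; reference-first is deterministic). The published rendering style
concatenates sites without a separator (`"T/CGTT"` = het T/C then G, T, T),
which is the default; a separator argument exists. Classes below 3 samples
are dropped. Phenotype differences across classes use one-way ANOVA and
Tukey HSD; the compact letter display is built from the maximal cliques of
the "not significantly different" graph, which guarantees two classes share
a letter exactly when their Tukey-adjusted p is at or above alpha.
Enrichment of a class in a subpopulation is a two-sided Fisher exact test on
the 2x2 membership table; raw p-values carry the stars (as is conventional
for these displays) with a Benjamini–Hochberg column emitted alongside.
Tissue contrasts reuse the Tukey machinery at alpha = 0.01, and compound
correlation matrices are pairwise-complete Pearson per tissue.

The "mixed linear regression" sometimes used for subpopulation effects on
phenotypes is not specified in detail anywhere we could follow; where needed
it is interpreted as a fixed-effect subpopulation term with the optional
kinship random effect reusing the association machinery.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout (VCF convention).
* Monomorphic sites: skipped by LD pruning (retained, logged), excluded from
  r2 (flagged `NA` with a reason), reported without p in scans.
* All-missing sites get flagged-undefined statistics, never silent zeros;
  all-missing samples are an error naming the sample.
* Exclusion LODs (`-Inf`) are carried through BLAS products as -1e9 and
  mapped back to `-Inf` beyond -1e8; finite LOD sums are orders of magnitude
  smaller, so the encoding cannot collide with a real score.
* Ties in the compact letter display are resolved by ordering cliques by
  their best-ranked member's mean.

## Problem sizes used by the tests and acceptance runs

Unit tests run on populations of 40–220 samples and 50–2,000 sites; the
acceptance suite uses the default study-scale population (220 accessions,
5,000 sites, 30 hidden pairs, ten 500-marker sets with 2,000 simulated
offspring per confidence calibration), a 200 x 2,000 structured null panel
for type-I error, and 50 phenotype replicates at n = 300 for heritability
recovery. These sizes were chosen so the full consensus-parentage analysis,
the calibration property and the null-calibration property are all exercised
end-to-end at the scale the generator's defaults define.

## Known limitations

* The parentage module assigns single parents only; parent-pair likelihoods,
  sibship reconstruction and multigenerational inference are out of scope.
* Me estimation by Li–Ji is an approximation; with far more sites than
  samples the sample correlation spectrum saturates and Me is conservative.
* The mistyping model used for likelihoods (Hardy–Weinberg replacement)
  differs deliberately from the generator's allele-flip error; agreement of
  recovery results across the two is evidence of robustness, not of model
  identity.
* LD decay in the generator is exponential-like by construction; real decay
  curves mix demography and recombination-rate variation the generator does
  not model.
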