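---
title: "Methods: measuring relaxed selection on pollen-specific genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring relaxed selection on pollen-specific genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Genes expressed only in the haploid pollen stage (the male gametophyte)
experience selection differently from genes restricted to diploid
sporophytic tissues. Haploid expression exposes every allele to selection
(no masking by a dominant partner), and pollen competition can add
strong selection of its own — but in a highly selfing plant both forces
are diluted: genome-wide homozygosity removes masking in the sporophyte
too, and few pollen genotypes compete. The pipeline in this package asks,
for a panel of fully homozygous inbred strains plus interspecific
divergence data, whether purifying selection is currently weaker on
pollen-specific genes than on sporophyte-specific genes, and whether that
difference survives control for the genomic covariates that differ
between the two gene classes.

The package implements every stage as a testable unit: expression-based
gene classification, per-strain consequence scoring, site-class
diversity statistics, a gamma distribution-of-fitness-effects (DFE) fit,
counting-method dN/dS over ortholog pairs, and the covariate-controlled
group comparison. A seeded generator produces synthetic data with the
same statistical structure, so the full chain is exercised end to end
without any external download.

# Gene classification

Expression input is a long table of per-gene, per-tissue pairs of a
normalized level and a presence score in [0, 1] (a detection-reliability
measure). A gene counts as present in a tissue only when the presence
score reaches a threshold, 0.9 by default; all lower scores are treated
as zero expression. The two pollen-tube data sets are merged first
(element-wise maximum of level and presence), after which the pollen side
comprises six tissues and the sporophyte side ten. Genes present only on
the pollen side are `pollen_specific`, only on the sporophyte side
`sporophyte_specific`, on both `shared`, on neither `not_expressed`. A
gene's expression level is the maximum level over its present tissues —
the level at which the gene matters most to the phenotype. Shared genes
are classified but excluded from all two-group comparisons, which are
built on exclusive expression. Two finer sporophyte groupings support
tissue-specificity control: genes present in exactly one of the guard
cell, xylem or root-hair sets, and genes present in at least five
sporophytic tissues.

One degenerate case is decided explicitly: a presence score at or above
the threshold with a zero expression level is treated as an input error
rather than silently reconciled, because the two fields would contradict
each other.

# Consequence scoring

Strains are fully homozygous inbred lines, so every call is applied as
such. Per-strain coding sequences are rebuilt from the representative
splice model: SNPs substituted at their CDS-mapped positions, indels
applied left-anchored (VCF convention, first base shared), minus-strand
genes reverse-complemented into transcript orientation. A variant whose
reference allele disagrees with the reference sequence is rejected and
counted, never silently applied.

Two deleterious-allele statistics are computed per gene:

* **Premature stops.** A unique (CDS position, alternative base) pair
  that creates a stop codon before the reference terminal stop when
  applied alone to the reference CDS. Each candidate SNP is evaluated
  alone in the reference codon context, which makes the statistic
  independent of which strains happen to co-carry other SNPs in the same
  codon (such codons are masked in the diversity statistics anyway). A
  change in the terminal stop itself is a stop-loss and is out of scope:
  "premature" is positional. The reported frequency divides the unique
  count by the panel size so that means are comparable across panels;
  the raw count is kept alongside.
* **Frameshifts.** The proportion of strains carrying at least one CDS
  indel whose length change is not a multiple of three. A strain counts
  once however many frameshifts it carries. Indels are scored only here;
  premature-stop scoring uses SNPs only, keeping the two metrics
  non-overlapping.

# Diversity at 0-fold and 4-fold sites

Synonymous and nonsynonymous positions are proxied by 4-fold and 0-fold
degenerate sites of the reference codons (every / no single-base change
preserves the amino acid). Codons containing more than one polymorphic
position in the panel, or any ambiguity code, are fully masked: multiple
hits within a codon make the synonymous/nonsynonymous status of each SNP
context-dependent. Per gene and site class the package reports
Watterson's `theta = S / (a_{n-1} L)` and nucleotide diversity
`pi = sum 2 c (n - c) / (n (n - 1)) / L` with `c` the alternative-allele
count. Both are per site; genes with no usable site in a class get `NA`
with a warning rather than a silent zero.

Site-frequency spectra (SFS) feed the DFE fit. Folded spectra
(minor-allele counts) are the default: no outgroup polarization is
assumed anywhere in the pipeline, and the gamma model below is fitted on
folded data without loss. Sites with a missing call in any strain can be
dropped with `L` adjusted; triallelic sites are excluded and counted.

# The gamma DFE

New nonsynonymous mutations are assigned a gamma-distributed deleterious
scaled effect `S = 4 Ne s` with shape `b` and mean `E[S]` (no beneficial
mass — the all-deleterious "GammaZero" family). Under mutation-selection
balance the population frequency density of a mutation with effect `-S`
is

$$H(x; -S) = \frac{1 - e^{-S(1-x)}}{x(1-x)(1 - e^{-S})},$$

with the neutral limit `1/x`. The expected count of sites at sample
frequency `i` of `n` is `theta L r_i` times the gamma expectation of the
binomial-sampled weight of `H`; synonymous sites use `S = 0`. The
`r_i` are per-frequency-class nuisance multipliers shared by both site
categories (`r_1 = 1`); they absorb demographic and ascertainment
distortions of the spectrum shape, leaving the DFE identified by the
*difference* between the nonsynonymous and synonymous spectra.

Numerics, chosen to be deterministic and testable:

* The frequency integral uses fixed-order Gauss–Legendre (order 160) on
  (0, 1). The binomial kernel removes the `1/x` and `1/(1-x)`
  singularities for every class `1 <= i <= n-1`, so no substitution is
  needed; `H` is evaluated in the overflow-safe form
  `e^{-Sx}(1 - e^{-S(1-x)})/(x(1-x)(1 - e^{-S}))` with the `1/x` branch
  below `S = 1e-8`.
* The gamma expectation uses Gauss–Legendre on the probability scale
  (nodes at gamma quantiles), order 64, which handles the density's
  singularity at zero for shapes below one.
* The Poisson likelihood is profiled: given `(b, E[S])`, the maximizing
  `theta` (from class 1) and `r_i` (class totals) are closed-form, so the
  numerical optimisation is two-dimensional over `(log b, log E[S])`
  (L-BFGS-B, five dispersed starts, box `[0.01, 20] x [1e-3, 1e7]`).
  This profiling is algebraically exact, and it is what makes the
  1000-replicate gene bootstrap affordable.

The fitted gamma is discretised into `Nes` bins — default `[0,2)`,
`[2,10)`, `[10,100)`, `[100,Inf)`, reconciling the conventional
"effectively neutral below 2" and "strongly deleterious above 10"
landmarks — by CDF differences at four times the edges (the internal
scale is `4 Ne s`; the output documents the factor). The adaptive
proportion is
`alpha = 1 - (D_s L_n / (D_n L_s)) E[S / (e^S - 1)]`,
where the expectation over the fitted gamma is the mean relative
fixation probability of a deleterious mutation (1 at `S = 0`, 0 for
strong selection). Confidence intervals come from a percentile bootstrap
that resamples genes with replacement, sums their spectra and divergence
counts, and refits warm-started at the point estimate; it is fully
deterministic under its seed.

# Counting-method dN/dS

Pairwise divergence uses the Nei–Gojobori counting method with
Jukes–Cantor correction rather than a maximum-likelihood codon model:
it is self-contained, fast at desk scale, and checkable against an
exhaustive path-enumeration oracle, while the analysis surface — the
*contrast* between gene classes — does not depend on the absolute
estimator choice. Orthologs are reciprocal best hits (mutual top bit
score, ties broken by identity then subject ID) at a minimum of 30%
identity over 150 aligned amino acids; protein alignments are
back-translated to codon alignments with hard validation. Synonymous
site counts per codon are the per-position fractions of one-step changes
that preserve the amino acid (changes to stops count as nonsynonymous);
observed differences are averaged with equal weight over all minimal
substitution paths, discarding paths through stop codons. Proportions
are corrected with `d = -(3/4) log(1 - 4p/3)`; pairs with `d_S` above 2
(saturation) are excluded with an explicit reason, and `omega` is
reported as `+Inf` when `d_S = 0` with `d_N > 0` so rank tests can
exclude it deliberately.

One counting-method subtlety is documented rather than hidden: two
synonymous codons from a split family (the two serine boxes) can be
separated only by paths whose intermediate steps are nonsynonymous, so a
divergence simulated with `omega = 0` yields an exactly identical
protein yet a tiny positive `d_N` (below 0.002 at `d_S = 0.2`).

# Covariates and the controlled comparison

Six genomic covariates are computed per gene: expression level, GC
content, the within-gene variance of relative synonymous codon usage
(RSCU; codon counts scaled by family size, stop codons excluded, codons
of unused amino acids excluded, single-codon amino acids contributing a
constant 1), gene density (genes per fixed 100-kb window, assigned by
gene start, half-open boundaries), gene length (genomic span) and
average intron length (mean CDS gap, 0 for intronless genes). GC content
is computed on the genomic gene span by default — the same footing as
the length covariates — with the spliced CDS available as an option.

The comparison machinery:

* **Mann–Whitney U**, two-sided, exact where sample sizes permit, with
  Bonferroni correction `min(1, p * family)` over each declared family.
* **Partial Spearman correlations**: correlation of rank-regression
  residuals, `t`-distributed with `n - 2 - k` degrees of freedom.
* **Principal-component regression**: all variables log-transformed
  (additive offset `1e-4` for gene length and intron length, which can
  be zero; a dependent with zeros gets half its smallest positive value,
  recorded in the output), predictors centred and scaled, the dependent
  regressed on all components. Each component's explained share of the
  dependent's variance is its squared correlation with the dependent.
  Predictor significance is a leave-one-out jackknife of the predictor's
  coefficient mapped back through the loadings *summed over all
  components* (at full rank, the regression coefficient on standardised
  logs). The single-component alternative — testing slope x loading of
  only the best component — cannot discard an irrelevant predictor that
  is merely rotated into the informative component by the PCA, which is
  exactly the situation the pruning step exists for; the summed-loading
  definition matches the cited jackknife test's semantics and is
  validated by a constructed-fixture test. Nonsignificant predictors are
  dropped and the model refitted until all survivors are significant;
  the pruning history is kept.
* **ANCOVA**: the log dependent against the best-explaining component
  with the life-stage group as binary covariate. When the slopes differ
  significantly the pooled component axis is split into five equal-count
  bins (rank-based, so the counts are equal within one on any input) and
  the group difference tested per bin with family-size-5 Bonferroni.

# The synthetic-data generator

The generator emulates the structure the analysis assumes, under the
study conditions that are its defaults:

* 80 fully homozygous strains (the size of the polymorphism panel the
  DFE analysis is designed for); 5 chromosomes; genes with 0–4 introns,
  random strand, valid reference CDS.
* Class fractions 9.4% pollen-specific and 33.2% sporophyte-specific of
  expressed genes, 20.7% unexpressed — the observed complement.
* Per-site scaled mutation rate `theta = 0.005`, the magnitude typical
  of *Arabidopsis thaliana* synonymous diversity.
* A gamma DFE with shape 0.3 (a realistic plant-genome shape) and mean
  `4 Ne s` of 2000 for sporophyte-specific genes, relaxed fivefold to
  400 for pollen-specific genes.
* Deleterious-allele injection as separate per-gene Bernoulli processes
  (rates 0.30 pollen / 0.15 sporophyte for both premature stops and
  frameshift indels) with carrier counts drawn `P(k) ~ 1/k` up to
  `n/4`: low-frequency but not strictly singleton, which places the
  per-gene event burden at the order observed in real panels
  (stop-allele frequencies of a few hundredths, frameshift strain
  proportions near 0.02) while keeping the two-to-one class contrast.
* Divergence at branch `d_S = 0.15` with `omega` 0.208 (pollen) and
  0.164 (sporophyte), the observed median rates, via a per-codon
  Gillespie process whose synonymous and nonsynonymous one-step rates
  are `d_S/3` and `omega d_S/3` (changes to stops forbidden).

Allele frequencies are drawn independently per site from the *expected
sample-frequency distribution* — the same weights the estimator uses
(one shared implementation), neutral `1/i` at 4-fold sites, the
gamma-DFE sampling distribution of the gene's class at 0-fold sites.
This deliberate generator/estimator consistency is what makes parameter
recovery a sharp test. Background DFE draws never create a stop codon,
so premature stops are governed solely by the injection process and the
consequence module's effect size is directly controllable.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: linkage and recombination (sites are
independent), coalescent genealogies and demography (spectra are at
mutation–selection–drift equilibrium by construction), selection at
2-fold/3-fold sites (polymorphism is placed only at 0-fold and 4-fold
sites, the only classes the estimators read), sequencing error beyond a
quality-score filter, heterozygosity (strains are ideal inbred lines),
and alignment error in the ortholog pairs.

# Problem sizes used by the test suite

The shipped tests run the DFE recovery at `n = 80`, `L_n = 2x10^6`,
`L_s = 5x10^5` (20 replicates), bootstrap coverage at `B = 200` over 20
datasets of 100 genes, the discrimination experiment at 300 genes per
class with 80 strains, the null calibration over 50 replicate seeds of a
smaller design (80 genes, 30 strains), and the dN/dS recovery on a
10,000-codon alignment. These sizes give the acceptance properties
comfortable statistical room (e.g. the shape recovery's median absolute
error is about 0.006 against a tolerance of 0.05) while the whole suite
stays in the minutes range on one CPU.

# Known limitations

* The premature-stop uniqueness key is (position, alternative base);
  counting unique mutant haplotypes instead would differ when distinct
  strains reach the same stop through different SNP combinations.
* `alpha` inherits the usual caveats of polymorphism-based estimators
  under recent demographic change; the package reports it but the
  synthetic conditions make no claim about its real-data behaviour.
* The Jukes–Cantor correction assumes equal base exchangeabilities; at
  the simulated divergence (`d_S` around 0.15) the induced bias is well
  inside the 15% recovery tolerance, but highly saturated pairs are
  excluded rather than corrected.
* The PCR jackknife's normal approximation is calibrated by simulation
  tests, not derived; with very small gene sets its p-values should be
  read qualitatively.
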