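---
title: "Haplotype-based fine mapping in half-sib designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based fine mapping in half-sib designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsfinemap)
```

## The problem

In a daughter design, genotyped sires are evaluated through their
phenotyped, genotyped daughters. A sire that is heterozygous for a QTL
transmits two haplotype alleles with different effects, and the daughters
inheriting each allele form two half-sib groups whose phenotype difference
estimates the allele contrast. `hsfinemap` implements the full chain from
unphased chip genotypes to candidate causal variants:

1. pedigree verification and record edits (`verify_pedigree`,
   `form_contemporary_groups`, `filter_records`);
2. half-sib phasing of sire haplotypes over predefined haploblocks and
   assignment of each daughter's paternal allele (`phase_sire_blocks`,
   `assign_paternal_allele`, `build_allele_catalog`, `filter_alleles`);
3. a Bayes B fit of allele effects with a genome-wide SNP background
   (`fit_bayesb`), and posterior contrasts per sire
   (`haplotype_contrast`, `segregation_report`);
4. regression imputation of sequence variants onto haplotype fragments and
   the concordance filter (`finemap_block`, `concordant_variants`);
5. gene assignment and over-representation analysis
   (`assign_variants_to_genes`, `run_ora`).

## Model and sampler

The haploblock model is
$y_i = Fb + Hh + \sum_j x_{ij} s_j + e_i$, with contemporary-group effects
and an age regression in $b$ (flat priors), fixed haplotype-allele effects
$h$ for the block under study, and a Bayes B mixture over all other chip
SNPs: $s_j = 0$ with probability $\pi$ and otherwise
$s_j \sim N(0, \sigma_j^2)$ with a locus-specific variance. Throughout,
$\pi = 0.999$, so roughly one SNP in a thousand is in the model at any
iteration; the SNP background absorbs population structure so the allele
contrasts are not confounded by family means.

The sampler (compiled, single-site Gibbs) updates, per iteration: each
fixed effect from its conditional normal; each SNP's inclusion indicator
from the conditional odds given $\pi$, its effect from the conditional
normal when included, and its locus variance from the conjugate scaled
inverse-chi-squared update when included (prior draw otherwise, with
$\nu_s = 4.2$ and a scale derived from a genetic-variance guess split over
the expected number of included SNPs); the residual variance from its
scaled inverse-chi-squared conditional ($\nu_e = 10$) for Gaussian traits.
Binary traits use the liability threshold model: latent liabilities are
redrawn each iteration from normals truncated at 0 on the side dictated by
the observed 0/1 outcome, with the residual variance fixed at 1 and the
threshold at 0 — the standard identification, under which heritabilities
and effects are expressed on the liability scale.

Identifiability choices: the intercept is absorbed into the
contemporary-group effects, and within the fitted block one haplotype
column is dropped as the reference. The reported effect of the reference
allele is 0; all sire contrasts are differences of two allele effects and
are invariant to this choice (a property the test suite checks by
re-expressing the same posterior against a shifted reference).

A sire is declared heterozygous when
$p = \min\{P(\Delta \ge 0), P(\Delta \le 0)\} < \alpha$ with
$\alpha = 0.10$, i.e. when at least 90% of the posterior draws of its
allele contrast $\Delta$ agree in sign. This reads the published threshold
as a posterior tail mass; other constructions (e.g. a calibrated Bayesian
p-value) are conceivable, so the definition is stated here rather than
asserted as the only one. Sires whose two block alleles are identical are
non-segregating by construction, and no multiplicity correction is applied
across sires or blocks.

The full-scale chain protocol is 90,000 iterations with 2,000 burn-in,
keeping every 100th draw (880 retained). The package default is a
desk-scale 6,000/1,000/5 chain (1,000 retained draws), which the
calibration experiments below use; the full protocol is available by
setting `model_config(chain_length = 90000, burn_in = 2000, thin = 100)`.

## Phasing and the allele catalog

`phase_sire_blocks` reconstructs each sire's two block haplotypes from its
own genotype plus the progeny genotypes: homozygous sire loci are forced;
at sire-heterozygous loci a daughter with dosage 0 or 2 pins her paternal
allele, daughters are clustered into the two paternal gametes by majority
vote over already-phased loci, and each remaining locus is phased by the
gamete-weighted vote (greedy in map order, then refinement passes until a
fixed point). Loci with no informative progeny stay `NA` and are skipped
downstream. With error-free genotypes the votes are unanimous, so accuracy
is limited only by informativeness; at 20 daughters per sire the test
suite requires exact recovery of the simulated truth for at least 99% of
sires.

Daughters whose genotype matches neither paternal haplotype are
mismatches; those compatible with both are ambiguous and are excluded — a
conservative choice that may shed more records than a full pedigree
phaser, which could use flanking information to break the tie. Alleles
observed in fewer than three daughters of a sire are dropped (inclusive at
exactly three). In the design matrix `H` the paternal assignment
contributes one copy; a second (maternal) copy is added only when the
dosage residue after removing the paternal haplotype exactly equals a
catalogued allele — an approximation to full population phasing that never
invents alleles.

## Fragment regression and concordance

Haploblocks are partitioned into ~1 Mb fragments anchored at the block
start because whole multi-Mb haplotypes are rarely shared among a small
sequenced panel. For each fragment, distinct phased sub-haplotypes among
the sequenced animals become allele columns, retained when seen on at
least three haplotype copies.

Each variant's alt-dosage vector is regressed, without intercept, on the
allele columns **of the fragment containing the variant**. The restriction
is a structural necessity, not a convenience: for fully resolved diploid
animals the allele dosages of every fragment sum to 2, so columns of
different fragments are exactly collinear in a block-wide design and the
presence/absence pattern would be unidentifiable; within a single fragment
the coefficients are estimable and equal 0 or 1 exactly whenever every
copy of an allele carries the same sequence. For the same reason, animals
carrying a dropped (rare) allele in a fragment are excluded from that
fragment's regressions — their dosage contains a contribution no retained
column can explain.

Verdicts follow the published reliability rule: a coefficient imputes
presence (1) or absence (0) only if it equals that integer to within
`tol = 1e-6` ("exactly", allowing for floating point) and its standard
error is strictly below `1e-4`; intermediate coefficients, inflated
errors, or rank-deficiency flags make the allele's verdict unreliable.
When the residuals vanish identically the standard error is defined as 0.

Concordance assumes a single biallelic QTN per QTL: each segregating
(heterozygous) sequenced sire must carry the variant on exactly one of its
two significant alleles, and any variant whose verdicts make a confidently
non-segregating sequenced sire heterozygous is excluded globally. The
per-sire heterozygosity filter is applied first and the homozygous-sire
exclusion second; per-sire candidate lists are then intersected.

## Enrichment

Variants are assigned to genes by 1-based inclusive containment within the
gene's genomic interval; overlapping genes each receive the variant. The
over-representation p-value is the hypergeometric upper tail
$P(X \ge g)$ for $g$ target genes in a term of size $k$, with $S$ targets
among $N$ analysed genes, accumulated in log space from binomial
coefficients; it matches exact enumeration to below $10^{-12}$ for all
$N \le 30$ and is reported raw (significance at 0.05, no multiplicity
correction). The gene universe defaults to the supplied annotation —
typically the genes overlapping the analysed QTL windows — and is
user-overridable. Gene sets are consumed as GMT files; no online database
retrieval is performed.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults define the study conditions used by the test suite
and the acceptance script:

| knob | default | meaning |
|---|---|---|
| `n_sires`, `progeny_per_sire` | 6, 50 | half-sib families |
| `n_chip_loci`, `block_markers` | 600, 20 | chip density; markers in the 4 Mb haploblock |
| `founder_block_alleles` | 4 | distinct founder haplotype alleles per block |
| `qtn_effect_liability` | 1.0 | QTN allele substitution effect, residual-SD units |
| `polygenic_variance`, `residual_variance` | 0.3, 1.0 | liability-scale variances |
| `hp_threshold` | 1.0 | liability threshold; centres prevalence near 0.5 given the planted QTN |
| `n_sequenced_sires`, `n_sequenced_ancestors` | 6, 20 | the sequenced panel (26 animals) |
| `seq_variants_per_block` | 30 | one planted QTN plus decoys |
| `prop_concordant_decoys` | 0.5 | rest are made discordant to exercise the reliability filter |

Sires and ancestors draw block haplotypes from a small founder pool;
daughters inherit one paternal block haplotype intact (no intra-block
recombination, free recombination elsewhere) and a maternal haplotype from
pool frequencies, so chip dosage is always the sum of two haplotypes.
Founder alleles are forced pairwise-distinct within every 1 Mb marker
segment so that a fragment allele identifies its founder haplotype — the
regime in which the single-QTN concordance logic is exact. The liability
is contemporary-group effect + age regression + QTN dosage effect +
polygenic + residual; the follicle count is a rounded Gaussian floored at
zero (the trait is analysed as continuous, so a Poisson shape is not
needed).

Deliberately not emulated: realistic LD decay and recombination maps,
genotyping error, selection, indels, dam genotypes, and multi-QTN
architectures. Passing tests therefore demonstrate correctness of the
machinery under the stated assumptions — intact paternal transmission and
haplotype-determined variants — not robustness to phase error or allelic
heterogeneity in real data, where the reliability filter is expected to
discard many more variants (as the original NF windows illustrate: poorly
represented alleles simply cannot be fine-mapped).

All randomness flows from one integer seed; the population, phenotype and
panel stages use `seed`, `seed + 1`, `seed + 2` so each stage can be
re-run in isolation.

## Numerical choices and edge cases

* Mendelian verification uses the opposite-homozygote rate over loci where
  both members are non-missing; 0/0 is defined as rate 0 with a warning
  flag, and the 0.1% threshold is strict (`>`), so a rate of exactly 0.001
  keeps the pair.
* Contemporary groups without at least two distinct trait values
  (including singletons) are removed whole; the 3.5 SD age cut uses the
  group-specific SD ($n-1$), computed before any removals.
* Variant QC: site QUAL is inclusive at the threshold; the depth rule is
  per-sample (the published wording does not say which; per-sample is the
  conservative reading), and a call with unknown depth fails it. A variant
  is dropped only when all its calls become missing.
* Missing chip dosages entering the SNP background are imputed at twice
  the allele frequency and centred, for the sampler only; regressions on
  fragment alleles drop missing observations pairwise instead.
* `block_width_mb` rounds to two decimals. One published size (the NF
  window on BTA11) is inconsistent with its own printed bp bounds under
  any two-decimal convention — the bounds give 4.25 Mb against a printed
  4.24 — and the acceptance test records that discrepancy rather than
  special-casing it; the trait-level averages are unaffected.
* Posterior summaries use type-1 (order-statistic) quantiles so the
  reported 90% interval endpoints are actual retained draws.

## Problem sizes

The shipped experiments use: 6 sires x 50 daughters, 600 chip loci and one
4 Mb haploblock for the sampler calibration (20 replicates, chain
6,000/1,000/5); founder-panel-only populations for the 20 imputation
replicates; 100 sires x 20 daughters for the phasing-recovery check; and
1,200 loci for pedigree verification. These sizes were chosen so the whole
suite and the acceptance script each run in about a minute on a single
CPU. At this chain length the detection rate for segregating sires sits
far above its 80% requirement, while the false-positive rate for
non-segregating sires fluctuates around 15% across seeds — consistent
with the ~10% nominal tail probability of the $\alpha = 0.10$ rule plus
Monte Carlo noise in the tail-mass estimate from 1,000 retained draws;
longer chains (the full 90,000-iteration protocol) tighten it.

## Limitations

* Phasing assumes half-sib families with a genotyped (or reliably imputed)
  sire and no recombination within a block; it is not a population-scale
  LD phaser.
* The concordance logic inherits the single-QTN assumption; allelic
  heterogeneity breaks it by design.
* Binary-trait effects are on the liability scale and are not directly
  comparable to observed-scale differences.
* ORA treats gene sets as given; it performs no semantic grouping of
  related terms and no correction across terms.
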