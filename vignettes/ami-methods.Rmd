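---
title: "Measuring assortative mating on local ancestry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring assortative mating on local ancestry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amindex)
library(dplyr)
```

## The question and the statistic

Admixed populations — such as Latin American populations formed by the
mixing of African, European and Native American ancestors — are known to
mate assortatively on genetic ancestry. Because mate choice acts on
phenotypes, and many phenotypes are polygenic with ancestry-variable
expression, a local-ancestry view can reveal *which* traits carry the
assortative signal: if mates match on a trait, the genes underlying that
trait should show an excess of ancestry *homozygosity* (the same ancestry
on both gene copies of an individual) relative to random mating.

`amindex` quantifies this with the **assortative mating index**, a log
odds ratio per gene locus:

$$
\mathrm{AMI} \;=\;
\ln\!\left(
  \frac{obs(\mathrm{hom})/exp(\mathrm{hom})}
       {obs(\mathrm{het})/exp(\mathrm{het})}
\right)
$$

Observed counts classify each fully assigned individual at a gene as
ancestry-homozygous or -heterozygous. Expected counts come from a
**triallelic Hardy–Weinberg model**: the locus ancestry fractions
$(a, e, n)$ of the African, European and Native American labels among the
$2N$ haplotypes act as three allele frequencies, and the trinomial square
$(a+e+n)^2$ gives expected homozygosity $a^2+e^2+n^2$ and heterozygosity
$2ae+2an+2en$, scaled by the $N$ fully assigned individuals. Positive AMI
means excess homozygosity (assortative mating); negative AMI means excess
heterozygosity (disassortative mating, the classic expectation at
HLA/MHC loci).

Gene sets for polygenic phenotypes are analysed jointly: each gene
contributes a 2×2 stratum (rows observed/expected, columns hom/het), and
the set is pooled with the **Mantel–Haenszel fixed-effects estimator**

$$
\widehat{OR}_{MH} = \frac{\sum_g a_g d_g / N_g}{\sum_g b_g c_g / N_g},
$$

with the Robins–Breslow–Greenland variance for the log odds ratio, a
normal-deviate two-sided p-value, and Benjamini–Hochberg q-values over
the declared family of tests (all phenotype × population analyses of a
run). Expected cells are real-valued and used without rounding.

## From segments to genotypes

Local-ancestry callers emit haplotype segments. A gene receives an
ancestry label on one haplotype **iff its interval is fully contained in
a single segment with certainty ≥ `min_certainty`** (default 0.99). A
gene straddling a segment boundary is left unassigned on that haplotype;
cells therefore carry 0, 1 or 2 labels, and only full pairs enter the
statistic. This containment rule is deliberately conservative: segment
boundaries are exactly where ancestry assignment is least reliable. An
alternative would aggregate per-marker posteriors across the gene
(minimum, mean, or majority); we use segment-level certainty with full
containment, and for RFMix v1 input we aggregate optional per-marker
posteriors by the minimum within a segment — the most cautious of the
three.

Genes are then filtered by the **ancestry-genotype threshold**: with
$n_g$ the number of fully assigned individuals at gene $g$, genes with
$n_g > \bar{x} - s$ are retained, where $\bar{x}$ and $s$ are the mean
and standard deviation of the $n_g$ across genes. We read the threshold
as strictly exceeded, with one degenerate-case rule: when $s = 0$ (all
genes equally covered, as in simulations) the strict rule would discard
everything, so `n_g >= mean` applies instead. The per-gene counting
orientation (individuals per gene, not genes per individual) is a
deliberate reading: it keeps the filter aligned with the per-gene 2×2
tables the statistic is built from.

Gene sets (GMT input) are restricted to callable genes, must retain at
least 2 genes, and are pruned for linkage disequilibrium using a
precomputed table of maximal inter-genic SNP r² values: pairs with
r² > 0.1 are processed in decreasing r², dropping the later-listed gene
of any offending pair still present. Keeping the earlier-listed gene is
arbitrary but deterministic and reproducible; pruning is within sets
(each set must be internally independent — cross-set sharing is
legitimate).

## Numerical conventions

* **Zero observed cells.** `ln(0)` is undefined; when a gene has zero
  observed homozygotes or heterozygotes, the Haldane–Anscombe correction
  (+0.5 on all four cells) is applied for the gene-level display value,
  flagged in `ami_corrected`. Mantel–Haenszel pooling itself tolerates
  zero cells and uses the raw counts.
* **Fixed loci.** Genes where one expected cell is 0 (the locus carries a
  single ancestry) have no defined index and are excluded with a logged
  reason.
* **Cohort consistency.** Locus fractions are computed from fully
  assigned individuals only, so observed and expected counts always
  refer to the same cohort; partially assigned cells influence nothing.
* **Empirical p-values** from permutation nulls use the add-one rule,
  $(1 + \#\{|null| \ge |obs|\})/(n_{perm}+1)$, so they are never zero.
* **Distribution comparison.** Observed-vs-expected AMI distributions
  are compared with Welch's t-test by default (the observed distribution
  is visibly wider than the permutation null); Student's test is
  available via `var_equal = TRUE`. When both samples are constant and
  equal the convention $t = 0,\ p = 1$ applies.

## Permutation controls

Two permutation schemes guard the analysis:

1. **Random-mating re-pairing** (`random_mating_null()`): at each gene,
   the haplotype labels of fully assigned individuals are pooled and
   re-paired with replacement into 10,000 virtual diploids; the AMI of
   each virtual cohort against the same Hardy–Weinberg expectations
   forms the expected-AMI distribution, narrow and centred at zero.
   Re-pairing is per gene, from that gene's own label pool, with
   replacement — matching the Hardy–Weinberg ideal and easiest to reason
   about.
2. **Random gene sets** (`random_geneset_null()`): admixed populations
   mate assortatively on ancestry genome-wide, so any gene set inherits
   a baseline homozygosity excess. Pooled log odds ratios of random sets
   of matched size form a null that asks whether a *specific* trait set
   deviates beyond that genome-wide background. The same null supplies
   the reference distribution for the cross-population variance ranking,
   whose dedicated significance test the source framework leaves
   unspecified — the random-set null is our substitution, applied
   two-sided since both concordant and discordant extremes are of
   interest.

## Ancestry drivers

Which ancestry carries the signal is resolved two ways. The **AH
profile** sums, over a set's genes, the relative deviation of observed
from expected homozygote counts separately per ancestry,
$\sum_g (obs_g^{anc} - exp_g^{anc})/exp_g^{anc}$ with
$exp_g^{anc} = f_{anc}(g)^2 N_g$; genes where an ancestry is absent are
skipped for that ancestry. Because the summand is a *relative* deviation
it weights rare ancestries strongly; an absolute-deviation column
(`excess_hom`) and a per-gene mean (`ah_mean`) are emitted alongside for
interpretation, and the per-ancestry absolute deviations always sum to
the total homozygosity excess of the set. The **coefficient of
variation** (sample sd / mean) of per-individual global ancestry
fractions complements AH: assortative mating inflates the population
variance of whatever drives mate choice, so the driving ancestry should
show the highest CV. Raw variance is reported next to the CV.

## The synthetic-population generator

`simulate_admixed_population()` is first-class, tested code — the
validation instrument for everything above. The model, chosen as the
simplest one that exhibits the phenomena the statistic must detect:

* **Founders** are single-ancestry diploids drawn from
  `founder_proportions` (default AFR/EUR/NAT = 0.15/0.55/0.30, a typical
  three-way admixed profile).
* **Admixture phase**: `n_burnin` generations (default 10) of random
  mating homogenize individual admixture proportions. This phase is
  essential: if strong assortment acts on pure founders it simply
  prevents admixture — every locus remains homozygous and the population
  never resembles an admixed cohort.
* **Mate-choice phase**: `n_generations` generations (default 5) in
  which monogamous pairs form by sequential weighted sampling without
  self-mating; a candidate pair's weight is
  $\exp(-\text{strength} \cdot d/\bar{d})$ with $d$ the Euclidean
  distance between ancestry vectors and $\bar{d}$ the generation's mean
  pairwise distance. The normalization makes the preference scale-free:
  a given strength discriminates equally whether ancestry variation is
  wide (recently admixed) or narrow (homogenized). The vector is the
  global ancestry fraction triple, the fraction over a designated trait
  gene set (`assort_on = "gene_subset"`), or a single component
  (`assort_ancestry = "AFR"`) when one ancestry should drive mate
  choice.
* **Reproduction**: constant population size, two offspring per pair
  (odd sizes topped up from random pairs), each offspring gene-haplotype
  drawn uniformly from the corresponding parent's two copies,
  independently across genes (free recombination).

The truth record keeps the full configuration, per-individual global
fractions, and per-generation realized mate-pair ancestry correlations —
the direct check that the strength dial does what it claims.

What the generator does **not** emulate: linkage and recombination maps
(genes are unlinked, whereas real local-ancestry tracts are long and
strongly correlated along chromosomes), mutation, selection, migration
after founding, sex differences in mate preference, and segment-calling
error (simulated certainty is 1). Passing tests on simulated data
therefore validate the statistical machinery — calibration, power,
driver attribution — not robustness to correlated tracts or ancestry
mis-assignment in real genomes. At MHC-like regions with unusual LD the
independence assumptions of the meta-analysis are at their weakest.

## Study conditions used in validation

The packaged checks run at sizes chosen to finish quickly while leaving
the conclusions clear; they are stated here as the package's own
experimental design. Calibration: 200 individuals × 500 genes, random
mating, 100 random 10-gene phenotypes, permutation null with 10,000
virtual diploids. Power: 50 replicates of a 30-gene trait set under
strength-10 trait-restricted assortment, judged against 20 null sets of
the same size. Driver recovery: 15 replicates of 400 individuals × 300
genes with strength-10 assortment on the African component — the larger
cohort is needed because summed relative deviations for a minor ancestry
are noisy in small samples. The bundled four-population demonstration
dataset uses 80 individuals × 300 genes per population with a 3-generation
admixture phase, so the populations retain the broad inter-individual
ancestry variation characteristic of real admixed cohorts.

Two properties of the Mantel–Haenszel test deserve explicit mention.
The "expected" row of each 2×2 is a deterministic function of the same
data as the observed row, while the Robins–Breslow–Greenland variance
treats both rows as independent samples; the standard error is therefore
inflated by almost exactly $\sqrt{2}$ and the test is *conservative* —
its real type-I rate under random mating is well below nominal, and its
power at the detection margin is correspondingly reduced. This is a
property of the method as published, reproduced faithfully here; the
random-gene-set permutation null provides the calibrated alternative
when exact error control matters.

## A worked example

```{r example, eval = FALSE}
fx <- generate_fixture_dataset("fixture", seed = 1)
res <- run_ami(fx$config)

# per-phenotype pooled AMI with family-wide q-values
res$results %>% arrange(q_value)

# which ancestry drives the strongest phenotype in PopB?
fit <- res$fits$PopB
ancestry_homozygosity(
  fit$gene_table %>% filter(gene_id %in% fit$sets$gene_id),
  population_id = "PopB"
)

autoplot(fit)                      # forest plot
glance(fit)                        # one-row summary
```

The command-line wrapper (`inst/cli/ami.R`) exposes the same two entry
points (`run`, `simulate`) for shell pipelines; the R functions remain
the primary interface.
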