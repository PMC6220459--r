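---
title: "Verifying maternity and paternity from SNP-array genotype concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying maternity and paternity from SNP-array genotype concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioconcord)
```

## The model

Trio interpretation of array results assumes the two tested adults are the
proband's biological parents. `trioconcord` checks that assumption using
only the SNP genotypes the array already produces, with a deliberately
simple counting argument rather than likelihood-based kinship estimation.

Consider one proband–parent pairing at a biallelic SNP where **both**
samples are two-copy homozygotes. If the parent is truly a biological
parent, the child must have inherited one of the parent's two (identical)
alleles, so the child's homozygous genotype must contain that allele: an
opposite-homozygote configuration (parent `TT`, child `AA`) is
Mendelian-impossible. For unrelated individuals, by contrast, the two
homozygous genotypes are independent draws from the population, and opposite
homozygotes are common whenever the SNP is polymorphic.

The procedure is therefore:

1. merge the two samples' tables on locus identifier;
2. keep only loci homozygous-in-both — heterozygotes, no-calls and one- or
   three-copy calls (copy-number gains/losses render the genotype
   uninterpretable under the two-copy model) in *either* sample are removed;
3. classify each surviving ("informative") locus as concordant (identical
   call strings) or discordant (anything else), and report
   `proportion_discordant = n_discordant / n_informative`.

A pairing is called a **true-pair** iff the proportion is strictly below the
threshold; a trio is a **true trio** iff both pairings are true-pairs.

### Why the proportion, and why this denominator

The raw discordant count depends on how many loci survive the filter, which
in turn depends on relatedness (related pairs share more homozygous
genotypes) and on specimen quality (no-call and CN-abnormal rates). The
proportion normalises that away. The denominator is the number of
*informative* loci — concordant plus discordant — not the number of merged
loci: classification is only defined for loci that pass the
homozygous-in-both filter, so the proportion is the conditional rate of
Mendelian impossibility given that the locus is scoreable. Under this
convention the expected proportion for an unrelated pair at minor-allele
frequency $q$ (with $p = 1-q$) is

$$\Pr(\text{discordant} \mid \text{informative})
  = \frac{2\,p^2 q^2 \cdot 2}{(p^2+q^2)^2},$$

which equals $1/2$ at $q = 1/2$, while the informative fraction itself is
$(p^2+q^2)^2 = 1/4$. Both closed forms are asserted by the test suite
against simulation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.015 | strict upper bound on the discordant proportion for a true-pair call. True parent–child pairings sit near $10^{-3}$ (assay noise only) and unrelated pairings near $10^{-1}$, so the cut-off sits in the wide empty band between the two regimes. A value *equal* to the threshold is a false-pair: the boundary belongs to the refuting side because a true-pair claim should require strictly better evidence than the cut-off. |
| `caution_band` | `[0.015, 0.05)` | advisory flag only; does not change the verdict. Proportions intermediate between the true-pair and unrelated regimes can arise from close relatives or degraded specimens and deserve manual review. |
| `autosomes_only` | `TRUE` | hemizygous male X genotypes violate the two-copy homozygote model and would register as systematic false discordance in father–son comparisons; X/Y probes are therefore excluded whenever chromosome labels are available. Tables without any chromosome column are scored in full, with a warning. |
| `min_informative` | 1000 | evidence floor (warning only). The platform supplies ~30,000 loci of which a third to a half are typically informative; drastic shrinkage signals an input problem rather than a biological one. |

Decisions on degenerate inputs: a comparison with **zero** informative loci
gets the verdict `uninformative`, never `0/0 = 0` and hence never a silent
true-pair — parentage cannot be asserted on empty evidence. An
`uninformative` member likewise makes the whole trio `uninformative` rather
than false: "false trio" is a clinically loaded claim of non-parentage that
one unusable sample does not justify, and the uninformative verdict forces a
re-test either way. Genotype strings are normalised at parse time
(uppercase; `TA` → `AT`) so heterozygote detection is order-free, and
no-call tokens from different vendor-software versions (`NoCall`, `NC`,
`NA`, empty) collapse to one internal sentinel.

## Cohort cross-matching

The validation design for a cohort of $T$ trios compares every proband with
every parent exactly once: $2T$ matched pairings and $2T(T-1)$ deliberately
mismatched ones ($2T^2$ in total), where "mismatched" means any parent not
from the proband's own trio — a trio's mother and father are never counted
as each other's mismatches. At $T = 10$ this gives 20 matched and 180
mismatched pairings. `cross_match_cohort()` returns both distributions with
median/range summaries; `glance()` reports whether the threshold separates
them perfectly.

## The simulator

No patient genotypes ship with the package, so the simulator supplies
cohorts with the statistical structure the method assumes:

- **Panel**: one shared set of `n_loci = 30000` biallelic SNPs (the
  platform's approximate probe count) on autosomes 1–22, allele pairs drawn
  uniformly from {A,C,G,T}.
- **Founders**: Hardy–Weinberg genotypes, minor-allele dosage
  $\sim \mathrm{Binomial}(2, q)$ with $q \sim U[0.05, 0.5]$ — common,
  polymorphic SNPs, which is what an absence-of-heterozygosity panel is
  designed around.
- **Children**: one allele drawn uniformly from each parent's two,
  independently across loci.
- **Relatives**: a full sibling is a second child of the same couple; a
  half sibling shares one parent with a fresh founder; "unrelated" is a
  fresh founder on the same panel.
- **Noise**, per genotype, mutually exclusive and in priority order:
  no-call (rate 0.005), copy-number-abnormal one- or three-copy call built
  from the individual's true alleles (rate 0.001), miscall replaced
  uniformly by one of the other two two-copy genotypes at that locus (rate
  0.002).

The noise defaults were chosen once so that simulated true-pair proportions
land at the $10^{-3}$ order and unrelated-pair proportions at $10^{-1}$ —
the regimes observed on the real platform — using the simplest symmetric
error model; no calibration to any particular laboratory's values is
attempted or claimed. With these defaults a 10-trio cross-match yields
matched medians around 0.003 and mismatched medians around 0.18.

What the simulator deliberately omits: linkage disequilibrium between loci,
population structure and real-world MAF spectra, mutation and genotyping
batch effects, and the true (unknown, probably asymmetric) error process of
the array software. Passing tests therefore demonstrate the method's
combinatorial and statistical correctness under its own assumptions, not
the false-positive rate any specific laboratory will observe; the
recommendation to validate locally against known pedigrees stands.

### Reproducibility

A cohort is one pseudo-random stream: `config$seed` is applied once, then
draws occur in a documented order (allele frequencies, panel alleles, then
per trio: mother's genotypes, father's genotypes, child's transmissions,
and each member's noise). Identical configs give byte-identical written
cohorts and hence byte-identical downstream reports; `write_cohort()`
records seed and parameters in a manifest sufficient to regenerate the
files exactly.

## Problem sizes in the test suite

The suite validates the cross-match design and threshold separation on a
10-trio, 30,000-locus cohort (200 pairwise comparisons), the Mendelian
zero law on 20 independently seeded noise-free trios at full panel size,
and the closed-form limits at $q = 1/2$ on 30,000 loci, where three
binomial standard errors give tolerances of about 0.017 on the discordance
proportion and 0.008 on the informative fraction. Smaller cohorts
(hundreds to a few thousand loci) back the combinatorial and IO tests.

## Known limitations

- **Close relatives.** The method tests Mendelian compatibility, not
  identity: a full sibling of a parent, or other close relatives, can
  produce intermediate proportions, and a sample swap between the proband
  and a full sibling is undetectable in principle — sibling–parent pairs
  *are* true parent–child pairs. The caution band flags the intermediate
  cases; the sibling blind spot is demonstrated, not patched, by the test
  suite.
- **Which sample is wrong** is not identified; only pair/trio truth values
  are claimed.
- The threshold is an operating point in an empty band between two
  well-separated regimes, not the result of fitting well-defined
  distributions; laboratories with unusual MAF spectra or noise levels
  should re-derive it from local data.
- Uniparental disomy, large absence-of-heterozygosity regions or severe
  aneuploidy shrink the informative set and can shift proportions; the
  evidence-floor warning is the only guard provided.
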