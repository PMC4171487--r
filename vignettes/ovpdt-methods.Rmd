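---
title: "Combined common- and rare-variant association testing in nuclear families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined common- and rare-variant association testing in nuclear families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovpdt)
```

## The problem

Region-based association tests for family sequencing data have mostly been
built around rare variants, down-weighting or ignoring common variants with
modest effects. When a region harbours both kinds of signal — and when some
causal alleles are protective rather than deleterious — a test should (i)
pick out the promising common variants, (ii) find a sensible allele-frequency
cutoff below which rare variants are enriched for function, and (iii) stay
valid under arbitrary population structure. `ovpdt` implements a test with
those three properties for nuclear families (two genotyped parents and one or
more children), together with the simulation machinery needed to study its
operating characteristics.

## The statistic

**Family-level scores.** At each biallelic site, code genotypes as
minor-allele dosage, the minor allele being the less frequent allele among
the parents. A triad (two parents, one affected child) scores
$T = (\text{minor alleles transmitted}) - (\text{not transmitted})
= 2\,g_c - g_f - g_m$, and a discordant sib pair scores
$S = g_{\text{affected}} - g_{\text{unaffected}}$. The family score $D_i$ is
the average of $T$ and $S$ over the family's informative units (a triad is
informative when at least one parent is heterozygous; a sibship when some
affected/unaffected pair differs). The single-variant statistic is
$X = (\sum_i D_i)^2 / \sum_i D_i^2$, chi-square with 1 df under the null of
no linkage or no association, and identical whether the minor allele is
risk-increasing or protective.

**Ordering common variants by parental information.** For common variants
(MAF > 0.05) the genotypic relative risks $r_1 = f_1/f_0$ and $r_2 = f_2/f_0$
are estimated from the parental mating-type distribution alone. Under HWE and
ascertainment on an affected child, four combinations of mating-type
probabilities are free of the allele frequency and depend only on
$(r_1, r_2)$; `grr_theoretical_ratios()` gives their closed forms and the
vignette's companion tests verify them against direct penetrance enumeration.
Every ratio involves a homozygous-minor parent, so estimation generally
succeeds above MAF $\approx 0.1$ and fails below $\approx 0.05$ — precisely
why this route is used only for common variants. Under an additive penetrance
constraint ($r_2 = 2r_1 - 1$), $r_1$ is fitted by a log-scale grid search on
$(0.5, 20)$ minimising the summed absolute distance between theoretical and
estimable observed ratios; a multinomial bootstrap over the six mating-type
cells (B = 1000) gives $\mathrm{var}(\log \hat r_1)$, and the ordering score
is $lr = \log \hat r_1 / \sqrt{\mathrm{var}(\log \hat r_1)}$, set to 0 when
nothing is estimable. Because parents are untouched by transmission
permutations, $lr$ is computed once per region.

**Ordered subset.** Common variants are ranked by $|lr|$ (protective
signals rank as high as risk signals); prefix sums of their $X$ statistics
are scanned, the prefix of size $i$ being referred to a $\chi^2_i$ tail. The
common statistic $C$ is the prefix sum at the minimum tail probability if
that minimum is $\le 0.05$, and 0 otherwise.

**Variable threshold.** For each MAF threshold
$t \in \{0.05, 0.03, 0.01, 0.005\}$ the rare burden is $R_t = \sum X_i$ over
variants with MAF $< t$, and $M_t = R_t + C$ with equal weights.

**Permutation and the maximum statistic.** Permuting transmitted and
non-transmitted parental alleles within a family flips the sign of every one
of its scores, so the permutation null is generated by drawing one ±1 sign
per family per chromosome and recomputing all statistics (denominators are
sign-invariant). Flipping whole chromosomes preserves LD between variants;
flipping all siblings together preserves linkage. Since the four $M_t$ have
different scales, each is standardised by the mean and SD of its own
permuted values; the region statistic is $M = \max_t$ standardised $M_t$,
each permutation is reduced the same way, and
$p = (\#\{M_i > M\} + 1)/(K + 1)$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `common_cut` | 0.05 | MAF above which a variant is "common" (strictly above; exactly 0.05 joins neither set) |
| `thresholds` | 0.05, 0.03, 0.01, 0.005 | variable rare-variant MAF thresholds (strictly below) |
| `gate` | 0.05 | significance gate for the ordered-subset minimum p-value |
| `min_K`, `target_exceedances` | 2000, 36 | adaptive permutation: stop once both are met |
| `max_K` | 10^6 | hard cap on permutations |
| `lr_bootstrap` | 1000 | resamples for `var(log r1)` |

The adaptive rule runs permutations in batches of 1,000; after each batch the
standardisation means/SDs are recomputed from the **entire** permutation
history and exceedances are recounted over that history, which avoids
stopping decisions based on a drifting early estimate of the null. The
exceedance comparison is strict (`>`), so the p-value can never be 0 and the
floor is $1/(K+1)$.

## Numerical choices and degenerate inputs

* Missing genotypes remove the affected unit (triad or pair) at that site
  only; MAF uses whichever parents are present. Mendelian-inconsistent
  sites are zeroed for the offending family with a warning.
* All per-family scores zero (no informative family anywhere): the region is
  flagged untestable and reported with p = 1.
* A threshold with no rare variants keeps $M_t = C$ rather than being
  dropped, so the maximum is always over the same four thresholds.
* Zero permutation SD at a threshold standardises to 0 (uninformative).
* Ordering ties: larger $X$ first, then smaller genomic position; variants
  with $lr = 0$ rank after all others. This makes results invariant to the
  variant order of the input file.
* The bootstrap refits use a hierarchical scan of the same $r_1$ grid
  (coarse stride, then exhaustive refinement around the best few basins);
  it agrees with the exhaustive scan in > 99.9% of random draws in the
  test-suite check, and the observed (non-bootstrap) fit always uses the
  exhaustive scan. Grid ties take the smallest $r_1$.
* With only some ratios estimable the distance sum simply omits the others;
  with none, the variant gets $lr = 0$ and ranks last.

## The simulator

`simulate_cohort()` generates ascertained nuclear-family cohorts:

* **Haplotype pool.** A Kingman coalescent with three demographic epochs
  (recent exponential expansion, a constant bottleneck, a smaller ancient
  size), simulated per region as a Poisson number of recombination segments
  with independent genealogies. Segment intensity comes from standard human
  parameters ($\rho = 4 N_e r L$, $N_e = 10^4$, $r = 1.3\times10^{-8}$/bp);
  the demographic constants were calibrated (see
  `scripts/calibrate_pool.R`) so that 10 kb pools of 10,000 haplotypes
  average ≈198 polymorphic sites with ≈166 below MAF 0.01 (25 kb: ≈512 and
  ≈429) and a density of MAF > 0.05 variants near sequencing-data levels
  (≈1.5–1.8 per kb).
* **Disease model.** Logistic penetrance at 5% prevalence. Rare causal
  variants (class MAF < 0.01) receive
  $\log \mathrm{OR} = (\log 5 / 4)\,|\log_{10} \mathrm{MAF}|$ (pluggable via
  the scenario's `log_or_fun`); common causal variants draw OR ~
  Uniform(1.05, 1.3); protective effects invert the OR. The intercept is
  solved on a Monte-Carlo population of pool-haplotype pairs so realised
  prevalence is 0.05 ± 0.002.
* **Ascertainment.** Parents are random pool haplotype pairs; children
  inherit one whole haplotype per parent (no meiotic recombination at the
  10–25 kb scale); the whole family is redrawn until the structure's
  affection pattern holds exactly (A: one affected child; AUU: one affected
  and two unaffected; AA: two affected).
* **Stratification.** Two-population scenarios draw 700 and 300 families
  from population-specific pools whose site sets are disjoint — a
  deliberately harsh form of stratification (every site is
  population-private), useful for stressing validity.

**What the simulator does not emulate.** Within-segment LD is all-or-none
(sites in one segment share a genealogy; sites in different segments are
independent), so close common variants can be perfect duplicates while LD at
a few kb is weaker than in real data. Sequencing error, missingness and
genotype-quality filtering are absent. Passing operating-characteristic
tests under this generator therefore demonstrates validity of the inference
machinery (the sign-flip null is exact under the within-family permutation
argument regardless of LD or stratification), but power numbers carry the
generator's modelling assumptions — in our checks the aggregate causal
signal runs noticeably stronger than under the reference spectrum those
scenario definitions originally described, so power levels here should be
read as generator-specific rather than portable.

## Study scales

`run_type1()` defaults to 2,000 replicates (permutations capped at 20,000)
and `run_power()` to 250 replicates (capped at 2,000 permutations, a p-value
floor of 1/2001, ample to classify rejection at $\alpha = 0.05$); the full
printed scales (20,000 and 1,000 replicates, permutation cap 10^6) are plain
arguments away. Replicate seeds are derived from the experiment seed, so a
report is reproducible bit-for-bit and independent of execution order.

## A worked example

```{r example}
sc <- ovpdt_scenario("Scen11", n_families = 200)
cohort <- simulate_cohort(sc, seed = 7)
cohort

fit <- ovpdt(cohort, control = ovpdt_control(min_K = 1000, max_K = 5000),
             seed = 1)
fit
```

The row reports the ordered-subset statistic `C` with its selected subset
size, the best rare-variant threshold, the standardised maximum `M`, the
number of permutations `K` the adaptive rule used, and the permutation
p-value.

## Known limitations

* Extended pedigrees and families with missing parents are out of scope; the
  sign-flip argument is exact only for nuclear families.
* The ordered-subset reference distribution treats ranked common variants as
  independent; the permutation corrects the final p-value, but `min_p`
  itself is not a calibrated per-region p-value.
* Relative risks are estimated under HWE and single-affected ascertainment;
  the test's validity does not depend on these (the permutation does not
  touch parents), only the efficiency of the ordering does.
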