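---
title: "Methods: miRNA-targetome variant prioritization and case-control association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-targetome variant prioritization and case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtld)
```

## The problem

Variants in miRNA binding sites of a gene's 3′UTR can change how strongly
the miRNA represses that gene, so they are plausible functional candidates
behind GWAS signals. A study of this kind runs in two stages. First, a
*prioritization* stage turns a GWAS hit list into a short list of
binding-site variants: because a GWAS index variant is rarely the causal
one, each index is expanded to every variant in strong linkage
disequilibrium with it in a phased reference panel, and the resulting
candidate set is intersected with annotated miRNA binding sites and
filtered to genes in pathways of interest (here, inflammatory pathways).
Second, an *association* stage genotypes the surviving variants in a
case-control cohort and tests them under the classical single-locus genetic
models, with haplotype-level analyses for pairs of variants.

`mirtld` implements both stages as composable tibble-in/tibble-out
functions, plus a synthetic-data generator that produces every input with
known ground truth.

## Prioritization

**LD proxy expansion.** For an index variant $i$ and candidate $j$, both in
a phased panel, LD is computed from directly counted haplotype
frequencies. With $p_1, p_2$ the alternate-allele frequencies and $f_{11}$
the alt–alt haplotype frequency,

$$D = f_{11} - p_1 p_2,\qquad
r^2 = \frac{D^2}{p_1(1-p_1)\,p_2(1-p_2)},\qquad
D' = D / D_{\max},$$

where $D_{\max} = \min\{p_1(1-p_2),\,(1-p_1)p_2\}$ when $D>0$ and
$\min\{p_1p_2,\,(1-p_1)(1-p_2)\}$ when $D<0$. A variant is a proxy when
$r^2 \ge$ `r2_threshold` (default 0.6, *inclusive*, matching the plain
reading of an "LD ≥ 0.6" rule) and lies within `proxy_window_bp` (default
1 Mb — no principled window is implied by the method itself, so we use the
conventional proxy-search bound; it is configurable). $r^2$ is the
thresholded measure throughout; $D'$ is reported alongside for block-style
summaries. An index absent from the panel is recorded and skipped, not
fatal. A monomorphic locus leaves all three statistics undefined and the
result is flagged (`defined = FALSE`) rather than propagating `NaN`.

**Targetome intersection.** Coordinates are 0-based half-open internally;
VCF positions are converted on read and write, BED intervals pass through
unchanged. Each binding site $[s, e)$ is extended to
$[s - \mathrm{flank}, e + \mathrm{flank})$ with `flank_nt = 25` by default,
clamped at zero. A variant at exactly `flank_nt` bp from the site edge is
*inside* the flank (the boundary is inclusive: "±25 nt" includes the 25th
nucleotide); placements are classified `in_site` when the position falls in
the unextended site and `flank` otherwise. Overlapping sites each produce
their own interaction — the unit of counting is the (miRNA, site, variant)
triple, not the unique variant — and a variant inside two miRNAs' sites on
the same gene therefore counts twice in per-gene summaries. Strand is
carried for interpretability but does not affect intersection, since
positions are strand-absolute genomic coordinates. The intersection is
computed with `IRanges::findOverlaps`; the test suite holds it equal to an
$O(nm)$ double-loop oracle on random fixtures (1,000 variants × 100 sites).

**Pathway filter.** An interaction survives when its gene belongs to at
least one pathway flagged inflammatory; all matching pathway names and
sources are attached as an annotation rather than duplicating rows. All
inputs must share one genome build; the package treats coordinates as
build-agnostic and performs no liftover.

## Association

**Hardy–Weinberg.** Genotype counts $(n_{\mathrm{AA}}, n_{\mathrm{Aa}},
n_{\mathrm{aa}})$ are tested against $n(\hat p^2, 2\hat p\hat q, \hat q^2)$
by a 1-df chi-square **without continuity correction**. The choice is
deliberate: the uncorrected statistic is what reproduces published
control-group p-values from their genotype counts in the worked
recomputations the acceptance tests pin down (a Yates-corrected version
gives visibly different values). Monomorphic variants are flagged
undefined, mirroring the all-wild-type scenario in which association
analysis is impossible.

**Genetic models.** From case/control genotype counts the package builds
2×2 exposure × status tables for dominant (carriers vs reference
homozygotes), recessive, overdominant, three codominant pairings
(reference genotype listed first, so its row is OR = 1.00), and allelic
(allele counts, a 2n denominator). Crude odds ratios are cross-products
with Woolf intervals, $\exp(\ln\mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$;
a single zero cell triggers the Haldane–Anscombe +0.5 correction (flagged),
and a fully empty margin leaves the OR undefined (flagged). Inverting the
exposure coding maps OR to 1/OR and swaps the interval ends — a property
the tests assert.

**Adjusted models.** Adjusted odds ratios come from logistic regression
fitted by IRLS (`stats::glm`, binomial family) with Wald intervals and
p-values; Wald rather than likelihood-ratio because it matches the
conventional OR (95% CI) reporting format. The default adjustment set is
age, sex, diabetes, family cancer history and smoking (configurable). With
a single binary exposure and no covariates the MLE reproduces the crude
cross-product OR exactly (saturated model), which the tests use as an
identity check. Complete separation is detected (the glm degenerate-fit
warning or |β| > 15) and flagged with no estimate reported; rank-deficient
designs are an error naming the collinear columns. For the allelic model
the adjusted fit uses per-sample additive allele dosage (0/1/2), since an
allele-level 2n table has no per-person covariates: its estimand is a
per-allele odds ratio, the natural covariate-adjusted analogue of the
allelic contrast.

**Two-locus EM.** Unphased genotypes at two loci leave only the double
heterozygote phase-ambiguous. Starting from linkage-equilibrium products of
the observed allele frequencies, the E-step splits the $n_{dh}$ double
heterozygotes between coupling and repulsion in proportion to
$f_{11}f_{00} : f_{10}f_{01}$ and the M-step renormalizes expected gamete
counts. Iteration stops when the largest frequency change is below `tol`
(default 1e-10) or after `max_iter` (default 1000, then
`converged = FALSE` rather than an error). The log-likelihood trace is
stored and must be non-decreasing (asserted in tests). Two degenerate
behaviours are defined, not accidental: with no double heterozygotes the
first iteration lands exactly on the closed-form gamete counts; and when
the two phase assignments tie exactly ($f_{11}f_{00} = f_{10}f_{01}$, e.g.
a sample of only double heterozygotes), the algorithm stays at the
symmetric fixed point and the result carries a `"symmetric likelihood"`
note — deterministic and documented, rather than an arbitrary tie-break.

**Cumulative genotypes.** For a variant pair, joint genotype frequencies
use the complete-case denominator (samples typed at *both* variants; the
per-variant denominators in real genotyping runs differ, so this is the
only coherent choice), and per-group haplotype frequencies come from the
EM. Pairwise group comparisons per class use Pearson chi-square, switching
to Fisher's exact test when any expected count is below 5 — a single
explicit rule in place of ad-hoc mixing. Haplotype-class comparisons scale
EM frequencies to rounded chromosome counts, an approximation flagged here
because EM frequencies are not observed counts.

**The suite.** `run_association_suite()` crosses every variant with every
genetic model and every contrast (case vs control overall and within BMI
strata; obese vs overweight/nonobese pooled and within cases — the default
contrast list is fully user-replaceable, since which groups a study pools
is a design choice, not something the method dictates). BMI classes use
the WHO cutoffs with boundaries mapping upward: 25.0 is overweight, 30.0
is obese, and BMI < 18.5 violates the cohort inclusion rule. Strata below
`min_stratum_size` (default 10) are skipped with a warning. No
multiple-testing correction is applied — significance is reported at
per-test α = 0.05 as in the study design this mirrors — but the number of
tests performed is recorded in the result so a reader can apply their own.

## The synthetic-data generator

The generator emulates three things: a phased reference panel, a genotyped
case-control cohort, and a toy targetome.

*Panel.* Variants are independent Bernoulli columns at MAFs drawn from
`maf_range`; each LD constraint rebuilds the pair's second column by
copy-with-error from the first (copy probability $\sqrt{r^2}$, else a
fresh draw at the parent's MAF), which makes the expected allele
correlation $\sqrt{r^2}$ and hence the expected $r^2$ equal to the target,
with equal MAFs in the pair. This is deliberately not a coalescent
simulation: the methods under test consume only pairwise LD, and the copy
construction gives an analytically tunable target.

*Cohort.* Individuals pair two panel chromosomes drawn with replacement,
so cohort genotypes inherit the panel's LD. Case status is Bernoulli from
a logistic model whose intercept is solved by root-finding so the expected
case fraction hits `case_fraction`; genotype effects enter through their
model encoding (log odds ratios from `effect_spec`) and covariates through
`covariate_coefs`. Covariate distributions default to a middle-aged
clinical cohort shape — age ~ Normal(56, 11), 47% male, 17% diabetes, 23%
family cancer history, 9% smoking, BMI class fractions 27/44/29 — chosen
once for realism and configurable. Missingness is completely at random at
`missing_rate` (default 2%, the order of magnitude of per-variant
genotyping dropout).

Two generator facts matter for interpreting recovery tests. The adjusted
logistic model estimates the *conditional* odds ratio, which is exactly
the planted parameter, so CI coverage is checked against it. The *crude*
odds ratio is a marginal quantity and is attenuated relative to the
conditional one whenever prognostic covariates are in play
(non-collapsibility); large-sample crude-recovery checks therefore run
with null covariate coefficients, where the two coincide.

*Targetome.* Panel variants are cycled through three placements (inside a
site, at exactly the flank boundary, one bp outside it) and three genes
(two on inflammatory pathways, one not); GWAS p-values alternate above and
below the threshold. Each variant carries a truth label saying which
pipeline stage it should survive, so the full cascade can be asserted
end-to-end. The truth labels assume the panel's distinct variants are
pairwise unlinked (no `target_ld` constraints), since a proxy of a passing
index would legitimately re-enter the candidate set.

What passing these tests does *not* show: the generator has no
recombination maps, population structure, genotyping-error model beyond
MCAR missingness, or realistic site/pathway annotation noise, so results
on real data additionally depend on annotation quality and confounding
structure the simulation does not emulate.

## Numerical and testing choices

- EM tolerance 1e-10 on the max frequency change; LD statistics carry a
  `defined` flag instead of NaN; haplotype frequencies are validated to
  sum to 1 within 1e-9.
- The EM's independent oracle is a pure grid maximizer of the multinomial
  likelihood: a 0.01-step scan of the haplotype-frequency simplex followed
  by 1e-3 refinement around the coarse optimum, agreeing with the EM
  within 2e-3 on 20-sample fixtures.
- Exact-test and chi-square routines delegate to `stats::fisher.test` and
  `stats::chisq.test(correct = FALSE)` but are held against a hand-rolled
  hypergeometric enumeration and hand-computed statistics in the tests.
- Problem sizes used by the test and acceptance runs: brute-force
  intersection at 1,000 × 100, proxy scans on 100-variant panels,
  OR recovery at n = 20,000, CI coverage over 200 replicates at n = 2,000,
  HWE calibration over 2,000 replicates at n = 200 (MAF 0.3), null
  association over 500 cohorts of 430. These sizes make the checks sharp
  while keeping a full run in tens of seconds.
- All generation is plain-R RNG under explicit seeds; reruns are
  byte-identical, which the tests assert on written fixture files.

## Known limitations

Only pairwise LD and two-locus haplotypes are implemented — no multi-locus
phasing and no haplotype-block partitioning algorithm; block-style figures
must be built from the pairwise table. The prioritization consumes
pre-fetched annotation files and performs no database queries or liftover.
Adjusted odds ratios on real cohorts depend on individual-level covariates;
nothing in the package can (or tries to) reproduce another study's adjusted
estimates without its subject-level data — the substituted guarantees are
the saturated-model identity, simulation recovery, and CI coverage checks
described above.
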