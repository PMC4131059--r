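---
title: "Collapsing rare variants in nuclear pedigrees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsing rare variants in nuclear pedigrees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r setup}
library(rvpdt)
```

## The problem

Rare variants (minor allele frequency between 0.001 and 0.05) are
individually almost powerless in association tests, yet jointly they can
carry substantial risk for complex disease. Families help twice: a rare
allele segregating in a pedigree is observed several times rather than
once, and transmission-based tests are immune to population
stratification. `rvpdt` implements a family of pedigree disequilibrium
tests (PDT) that aggregate rare units — either the *haplotypes* spanning a
small region, which can tag joint effects of several rare alleles, or the
individual rare *variants* — into a single weighted statistic, and
complements them with single-unit maximum tests and with training-split
tests that learn each unit's direction of effect.

## Transmission units and family scores

A nuclear family is decomposed into

* one **case–parent trio** per affected child whose parents are both
  genotyped, contributing, for unit $k$, the number of transmissions minus
  non-transmissions over the two parental meioses
  ($D_T^{(k)} \in [-2, 2]$), and
* one **discordant sib pair** (DSP) per unordered pair of an affected and
  an unaffected sibling, contributing the difference in copy numbers
  ($D_S^{(k)} \in [-2, 2]$).

Individuals of unknown affection enter no unit. With $n_T$ trios and
$n_S$ DSPs, the family summary is the average
$$D_i^{(k)} = \frac{\sum_j D_{T_j}^{(k)} + \sum_j D_{S_j}^{(k)}}{n_T + n_S},$$
zero (and flagged uninformative) for families without units. Under the
null hypothesis of no association every meiosis is a fair coin and sib
labels are exchangeable, so $E[D_i^{(k)}] = 0$ for any family structure.

## The six statistics

**Collapsing tests (hPDT, vPDT).** Units are weighted by the inverse
binomial standard deviation of their frequency,
$w_k = 1/\sqrt{\lambda\, q_k (1 - q_k)}$ with $\lambda$ the number of
individuals, so rarer units count more. The collapsed family score is
$D_i = \sum_k w_k D_i^{(k)}$ and the statistic
$$Z = \frac{\sum_i D_i}{\sqrt{\sum_i D_i^2}}$$
is asymptotically standard normal under the null; p-values are two-sided.
hPDT collapses all observed haplotypes except the most frequent one
(ties broken towards the lowest catalog index); vPDT collapses exactly
the sites whose estimated MAF falls in the rare window.

**Maximum tests (maxH, maxV).** Each unit gets its own
$Z^{(k)} = \sum_i D_i^{(k)} / \sqrt{\sum_i (D_i^{(k)})^2}$, and the test
statistic is the *signed* maximum $T = \max_k Z^{(k)}$ — a deliberate
one-sided, risk-direction choice (`signed_max = FALSE` switches to
$\max_k |Z^{(k)}|$). P-values come from transmission permutations: each
parental meiosis re-draws its transmitted haplotype with probability 1/2
(in variant mode, independently per site, since single-variant
transmissions are resampled per variant), and each DSP swaps its sib
labels with probability 1/2. The DSP swap is our extension — sib labels
are exchangeable under the null — and is applied in both modes as one
sign per pair. P-values use the add-one rule
$\hat p = (1 + \#\{T_b \ge T\})/(B+1)$, so they are never zero and ties
count as exceedances.

**Pooled permutations.** In a simulation with $R$ replicates of one
design, all $B \times R$ permuted statistics form a joint null sample, and
each replicate's p-value is computed against the pool:
$p_r = (1 + \#\{T_{r'b} \ge T_r\})/(BR + 1)$. With $R = 1000$ and
$B = 10$, ten permutations per replicate buy the resolution of 10,000.

**Training-split tests (hPDT-t, vPDT-t).** A random 30% of the
*families* (families, never individuals, are the independent sampling
units) estimates each unit's $Z^{(k)}_{train}$; units with
$|Z^{(k)}_{train}| > \mu$ keep their frequency weight with the training
sign, all others drop to zero; the collapsed statistic is then evaluated
on the remaining 70%. The default $\mu = 1.04$ is the two-sided normal
critical value at level 0.3, deliberately lax so that more units survive
(1.28 and 1.64 correspond to 0.2 and 0.1). When no unit survives, the
test is degenerate with $p = 1$ — and such replicates count as
non-rejections in power tallies, which is why these tests run
conservative under the null.

## Where unit frequencies come from

Frequencies $q_k$ (and the rare-window eligibility of variants) are
estimated from **founders only** by default. This is a deliberate
validity choice: children's haplotypes are transmitted copies of parental
ones, so frequencies taken over all individuals absorb the very
transmission counts being tested — an over-transmitted haplotype gains
copies through the children, lowers its own weight, and drags the null
distribution of the weighted $Z$ below zero, inflating the type I error
of hPDT (the test suite demonstrates this downward drift directly). With
founder-based estimation the weights are independent of the transmissions
given the founder genotypes, and the empirical null rejection of hPDT and
vPDT is nominal in the package's calibration study. `founders_only = FALSE` restores
the all-individuals estimate for comparison. $\lambda$ remains the total
number of individuals.

## Phase: enumeration and EM over gene flows

Haplotype-mode tests need phase. Phased input (`hap_pat`/`hap_mat`
columns) is used as-is; otherwise `enumerate_phases()` lists every
Mendelian-consistent, recombination-free assignment of haplotype pairs to
the members of each nuclear family (missing sites are enumerated over
both alleles; a cap of 4096 configurations per family guards against
combinatorial blow-up). `em_hap_frequencies()` then treats the
configurations as missing data under random mating: a configuration's
weight is proportional to the product of the current frequencies of its
four founder haplotypes (E-step), and frequencies are re-estimated from
the weighted founder counts (M-step). Only founders enter the frequency
estimates — children are copies. The observed-data log-likelihood is
non-decreasing and iteration stops when no frequency moves by more than
`tol = 1e-6` (at most 500 iterations; non-convergence returns the last
iterate flagged). Family scores are then flow-weighted,
$D_i = \sum_f \mathrm{Weight}^{(f)} D_i^{(f)}$; on fully phased or
unambiguous input this reduces exactly to the plain scores.

## The simulators

Both simulators produce the canonical study family: two parents and
three children, rejection-sampled until exactly two children are affected
and one unaffected (affected listed first), 200 families and hence 1000
individuals per replicate by default. Parental affection is simulated but
not conditioned on; rejection sampling of whole sibships is the simplest
mechanism consistent with the fixed design, and an acceptance probability
below $10^{-4}$ aborts with a diagnostic rather than spinning.

**Haplotype LD design** (`sim_hap_pedigrees()`). Fifteen fixed
10-site haplotypes — four carrying two rare alleles, ten carrying one,
plus the all-major haplotype — with frequencies 0.01 (×14) and 0.86.
The first four sites have MAF 0.03, the rest 0.01; the two-variant
haplotypes induce exactly four site pairs with $R^2 \approx 0.098$ while
all other pairs are negligible (the two largest residual pairs compute to
≈0.00096 from the pool frequencies). Affection follows
$\mathrm{logit}\,P(\text{affected}) = \beta_{k_1} + \beta_{k_2}$ over the
individual's haplotype pair; three built-in β settings cover pure
cancellation at the variant level, mixed effects, and strong
same-direction variant effects.

**Variant-spectrum design** (`sim_variant_pedigrees()`). A stand-in for
forward-evolution output: the site count is drawn from a rounded normal
(mean 22, sd 4.7, at least 5 — emulating a 20 kb region), each MAF from a
truncated $1/f$ density on $[0.001, 0.05]$, and founder haplotypes by
independent per-site Bernoulli draws (linkage equilibrium). A disease
model marks a fraction `d_causal` of sites causal and a fraction `r_risk`
of those risk-increasing; each causal variant carries a population
attributable risk of `par = 0.006`, giving
$GRR_l = 1 + PAR/(f_l(1-PAR))$ so that rarer variants get larger
effects (about 1.6 at MAF 0.01, about 7 at 0.001). We settled on the
per-variant PAR normalisation after checking that splitting one total
PAR across the causal set yields per-site relative risks near 1.04 and
essentially no power at realistic sample sizes, which is incompatible
with the power regime this design is meant to explore; `grr_from_par()`
retains the total-PAR split behind its `n_causal` argument. Penetrance is
multiplicative over causal copies with baseline $f_0 = 0.10$, protective
sites act through $1/GRR$ (symmetric on the log scale), and the product
is capped at 1. The null model sets penetrance to 0.30 flat, keeping
ascertained sibships common.

What the stand-in does *not* emulate: linkage disequilibrium among the
variant sites, the site-frequency spectrum of a specific demographic
history, recombination, or selection. Collapsing-test power is driven by
the aggregate transmission signal and is insensitive to these details,
but single-unit maximum tests and variant-trained tests are sensitive to
how many ultra-rare, large-GRR sites a region contains, so their power
under this generator should be read as ordering information, not as
point predictions for any particular evolutionary scenario.

## Study orchestration and reproducibility

`pdt_study()` derives one sub-seed per replicate from the master seed
up front, so studies are bit-reproducible and method subsets do not
perturb one another's streams within a replicate loop. The maximum tests
store their $B$ permuted statistics per replicate and are assigned pooled
p-values after the loop. Degenerate training-split replicates enter the
tally with $p = 1$. Default problem sizes — 200 families, $R = 1000$
replicates, $B = 10$ permutations — are the package's reference study
conditions; the variant-spectrum power ordering uses $R = 500$.

```{r}
st <- pdt_study(design_haplotype_study(1), R = 1000, B = 10, seed = 1)
tidy(st)
autoplot(st)
```

## Numerical choices and degenerate inputs

* Minor alleles are defined per site by sample frequency, ties broken
  towards the lower allele label; on writing, the minor allele is coded
  `1` so that read–write round-trips are exact.
* Mendelian-impossible child genotypes are set missing with a warning
  (never an abort); families whose genotypes admit no phase configuration
  get an empty flow list; trios whose child haplotype matches neither
  parental haplotype are dropped with a warning.
* Monomorphic units ($q \in \{0, 1\}$) are excluded from weighting;
  all-zero unit columns give $Z^{(k)} = 0$; a test with no units, no
  informative families, or all-zero weights reports a degenerate result
  (statistic 0, $p = 1$) rather than an error.
* Only nuclear families are modelled; multi-generation pedigrees must be
  split by the caller, and the reader rejects families with more than one
  parental couple.

## Known limitations

Quantitative traits, covariates, sex chromosomes and kinship-based
corrections for extended pedigrees are out of scope. The EM phasing
model assumes random mating and no recombination within the tested
region, which is appropriate for the short (tens of kb) regions these
tests target but not for long-range haplotypes. Permutation p-values for
a single dataset need a large `B` (the default 1000 resolves to 1/1001;
use 10,000 or pooled designs for genome-wide thresholds).
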