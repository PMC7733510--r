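---
title: "Scoring donor-microbiota engraftment in HMA animal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring donor-microbiota engraftment in HMA animal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engraftr)
```

## The scoring model

`engraftr` quantifies engraftment of a human donor's gut community in
recipient gnotobiotic animals with a prevalence ladder applied to an ASV
count table. Let $c_{sj}$ be the read count of ASV $j$ in sample $s$, and
let detection mean $c_{sj} \ge k$ with $k$ the detection threshold
(default $k = 1$ read).

1. **Depth QC.** Samples with fewer than 10,500 total reads are removed;
   "fewer than" is strict, so a sample at exactly the threshold survives.
2. **Core donor ASVs.** For donor $d$ with inoculum aliquots
   $A_d$, the core is $\{ j : c_{aj} \ge k \;\forall a \in A_d \}$.
   Requiring presence in *all* aliquots suppresses depth-driven
   composition noise; a failed aliquot simply shrinks $A_d$ (the count
   used is recorded). In practice cores capture almost all inoculum reads
   (`core_read_fraction()` reports the coverage).
3. **Colonizers.** Core ASV $j$ colonizes host group $h$ when it is
   detected in at least one fecal sample of that donor-host group: a
   single read in a single animal on a single day suffices.
4. **Persistent colonizers.** For each scheduled day $t$, the detection
   fraction is
   $f_j(t) = \#\{\text{animals detecting } j\} / \#\{\text{animals sampled at } t\}$.
   A day qualifies when $f_j(t) > 1/2$ (strict: 5 of 10 animals does not
   qualify, 2 of 3 does), and $j$ is persistent when at least 4 of the 7
   scheduled days qualify.
5. **Donor-like maintenance.** For each persistent colonizer and each day,
   the animal counts are tested against the donor aliquots (below);
   an ASV maintained a donor-like abundance when the BH-adjusted p value
   is $\ge \alpha$ (default 0.05) on at least 4 of the 7 days.

Every threshold lives in a single `study_design()` object
(schedule, depth floor, $k$, the 4-of-7 and $>50\%$ rules, $\alpha$), so
sensitivity analyses change one argument, not code.

### Decisions where the design was genuinely open

* **Persistence denominator.** Fractions are computed over animals *with a
  sample on that day*, not animals enrolled: dead animals have no fecal
  sample and should not deflate detection. A day with no samples at all
  contributes nothing, and the 4-day requirement is still out of 7 —
  conservative under missingness (the same convention applies to missing
  test days in maintenance scoring).
* **Presence.** "Found in" means literal non-zero detection at $k=1$; no
  minimum-count or minimum-abundance variant is imposed, but $k$ is
  configurable, and raising it can only shrink cores (anti-monotone, a
  property the tests enforce).
* **Rounding convention.** Reported percentages use half-away-from-zero
  rounding (1 decimal in table-style output, 0 in prose-style;
  `establishment_pct()`), because base R's banker's rounding surprises in
  report tables.
* **Cross-host contingency** supports both the colonizer and the
  persistent-colonizer basis — the same partition logic at a stricter
  threshold.

## The differential-abundance test

The maintenance call needs a per-day, two-group count comparison (3–4
inoculum aliquots vs the animals sampled that day). The package implements
the defensible core of the standard count-model pipeline rather than a
full shrinkage estimator:

* **Normalization** by median-of-ratios size factors: the reference is the
  per-ASV geometric mean over samples (restricted to ASVs positive in all
  samples), and each sample's factor is the *median of the natural-scale
  ratios* count/reference. A `pseudocount = TRUE` escape hatch (+1 to all
  cells) exists for sparse tables with no everywhere-positive ASV.
* **Test** (`nb_wald`): group means $m_1, m_2$ of normalized counts; a
  pooled method-of-moments dispersion
  $\hat\alpha = \max\!\big(\mathrm{df\text{-}weighted\ mean\ of\ }(s_g^2 - m_g)/m_g^2,\ 10^{-8}\big)$;
  Wald statistic
  $z = (\log m_2 - \log m_1) \big/ \sqrt{(1/m_1+\hat\alpha)/n_1 + (1/m_2+\hat\alpha)/n_2}$
  using the negative-binomial variance $\mu + \alpha\mu^2$. Because
  $\hat\alpha$ is estimated from a handful of samples, $z$ is referred to
  a $t$ distribution with $n_1+n_2-2$ degrees of freedom: in null
  simulations at $n_1=n_2=5$ the normal reference rejects at roughly 8–9%
  nominal 5%, while the $t$ reference is calibrated (the test suite checks
  the type-I rate against a 1000-replicate null simulation). This
  small-sample correction is the one deliberate departure from the plain
  normal-reference Wald test.
* **Fold changes** are reported as $\log_2((m_2+0.5)/(m_1+0.5))$; the
  pseudocount is for reporting only and never enters the test, except
  that a group whose mean is exactly zero (but not both) receives a
  $0.5/n_g$ continuity offset to keep the statistic finite. ASVs with
  zero counts in both groups get $p=1$, $\mathrm{lfc}=0$ by convention.
* **Multiplicity.** BH adjustment is applied across the tested ASVs within
  one donor &times; host &times; day comparison — the natural family for a
  per-time-point analysis. Only persistent colonizers are tested (they are
  the only ASVs eligible for the maintenance call). A regression test
  pins this scope, since pooling days changes results.
* **Fallback** (`rank_sum`): Wilcoxon rank-sum on within-sample relative
  abundances, for users who distrust the count model at these group
  sizes. All outputs carry a `test_mode` label.

Exact moderated-shrinkage machinery (dispersion shrinkage toward a trend,
outlier filtering, independent filtering) is intentionally out of scope:
the scientific contribution here is the 4-of-7 maintenance rule, and the
test behind it is labelled and swappable.

## Diversity support

Shannon index (natural log by default; the base is an argument) is
computed on **all** ASVs, not only cores, because alpha diversity is
sensitive to rare taxa. Bray–Curtis operates on relative abundances by
default (raw-count mode available); unweighted UniFrac is presence-based
and computed by branch-incidence classification on the rooted tree
(fraction of subtended branch length unique to one community); on a star
tree with unit branches it reduces to the Jaccard complement, a closed
form the tests exploit. PCoA is classical scaling: negative eigenvalues
(expected for Bray–Curtis) are dropped and counted — never
Cailliez/Lingoes-corrected — and explained proportions are relative to the
positive-eigenvalue total. Beta diversity for establishment figures is
computed on the core-restricted table by default (`beta_on_core`), since
that is the community being tracked; a flag switches to all ASVs.
`distance_to_donor()` summarizes each fecal sample as the mean of its
distances to its donor's aliquots (an all-pairs mode would treat each
sample-aliquot pair as an observation; the per-sample mean avoids
pseudo-replication across aliquots). Group comparisons use the Wilcoxon
rank-sum test, exact when the combined $n \le 10$ and untied.

## The synthetic-study simulator

`simulate_study()` emulates the statistical structure the classifier
assumes, with full ground truth:

* **Donor communities**: `n_asvs` per donor (defaults 26/76/140/134),
  identifiers drawn Zipf-weighted (probability $\propto 1/\mathrm{rank}$)
  from a shared pool of 400 so donors share common taxa — the default
  study yields roughly 25–30 core ASVs shared by the three larger donors.
  Phyla are assigned deterministically over the pool (interleaved so the
  mixture — 60% Firmicutes, 25% Bacteroidetes, 8% Actinobacteriota, 5%
  Proteobacteria, 2% Desulfobacterota — is stable across ranks);
  abundances are normalized log-normal draws with $\sigma = 1.5$, giving
  rank-abundance curves spanning several orders of magnitude.
* **Aliquots**: independent multinomial draws (default 3–4 aliquots at
  40,000 reads).
* **Colonization**: per animal and ASV, an independent Bernoulli with a
  per-phylum probability. Defaults encode the host contrast the package
  is designed to detect: mice {Firmicutes 0.15, Bacteroidetes 0.85,
  Actinobacteriota 0.5, Proteobacteria 0.4, Desulfobacterota 0.4} vs
  piglets {0.75, 0.9, 0.7, 0.6, 0.6}, with 10 mice and 3 piglets per
  donor. Established ASVs take the donor abundance times a log-normal
  distortion ($\sigma = 1$, renormalized within animal) — colonizer
  abundances deviate from the donor, as observed in real transplants.
* **Persistence failure**: between consecutive scheduled days each carried
  ASV is lost with probability 0.05, absorbing (no recolonization) — the
  simplest mechanism that can break the 4-of-7 rule. Animal death is
  modelled as missing samples after a configurable last day.
* **Sequencing**: multinomial reads per (animal, day) at 45,000 (mice) /
  38,000 (piglets); empty communities yield all-zero samples that the
  depth filter removes.
* **Truth labels** record colonization and carriage before sequencing;
  persistence truth applies the same majority rule to carriage. In the
  saturated regime (deep depth, no extinction, no distortion) classifier
  output equals truth exactly for every ASV whose expected per-sample
  count is $\ge 10$ — an acceptance property of the test suite.

**What the simulator does not emulate.** Animals within an isolator are
independent here; real cage-mates exchange microbes (coprophagy), which
concentrates detection fractions near 0 or 1. One consequence is that with
10 independent mice, *group-level* colonization (detection in $\ge 1$
animal) saturates even at low per-animal probabilities, so the simulator
cannot reproduce observed group-level colonization and majority-persistence
rates simultaneously; the defaults favour the qualitative contrasts
(Firmicutes establish and persist far better in piglets; Bacteroidetes in
both). There is no ecology (no interactions, no succession), no taxonomy
below phylum, and no sequence-level error. Passing tests therefore
demonstrate correctness of the scoring rules and recovery of configured
host selectivity — not that the generative model is a faithful portrait of
gnotobiotic colonization dynamics.

## Numerical conventions and degenerate inputs

* Counts must be integers; fractional cells are rejected, not rounded.
* Tables are identifier-keyed and dense: results never depend on row
  order or on which zeros are stored.
* Zero-depth samples error in normalization/diversity and are flagged for
  the depth filter; empty cores warn and report fraction 0.
* Relative-abundance rows sum to 1 within $10^{-9}$; distance matrices are
  symmetric within $10^{-12}$ with zero diagonals.
* All simulator randomness flows from one integer seed
  (`sim_config(seed=)`); repeated runs are bit-identical.

## Problem sizes used by the test suite

The suite validates against independent oracles at sizes chosen to keep a
full run around two minutes: exhaustive enumeration of the persistence
rule for one animal over the 7-day schedule ($2^7$ patterns) plus ~500
randomly sampled multi-animal presence tensors against a brute-force rule
evaluation; BH step-up against a hand-written step-up on vectors of length
$\le 8$; size factors against direct enumeration and an external
median-of-ratios implementation; exact rank-sum p against full permutation
enumeration at $n=3+3$; UniFrac against per-branch classification on small
trees; PCoA against planar round-trips; NB Wald type-I error against a
1000-replicate null simulation; ground-truth recovery on a 4-donor
saturated simulation; and the Firmicutes host-preference ordering across
100 seeded single-donor studies.
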