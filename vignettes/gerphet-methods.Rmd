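---
title: "Models and methods: deleterious-allele dominance and heterosis in a partial diallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: deleterious-allele dominance and heterosis in a partial diallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gerphet)
```

# The scientific problem

Most new mutations are deleterious, and complementation of recessive
deleterious alleles is the oldest genetic explanation of hybrid vigour: an
inbred line is homozygous for its own load, while an F1 between two inbreds
masks whatever load the parents do not share. `gerphet` implements an
analysis chain that tests a sharper version of this idea on a partial
diallel of fully inbred parents: deleterious alleles are identified *a
priori* from evolutionary constraint (GERP scores from a multi-species
alignment; the minor allele at a constrained site is treated as putatively
deleterious), their additive and dominance effects are estimated jointly,
and the estimated dominance is fed back into a haplotype-level genomic
prediction model. If incompletely dominant deleterious alleles drive trait
variation and heterosis, then (i) dominance variance should concentrate in
fitness-related traits, (ii) more constrained alleles should be more
recessive, and (iii) weighting haplotypes by conservation should improve
phenotypic prediction relative to permuted conservation scores.

The package provides every stage as a tested function, plus a synthetic-data
generator that produces diallels with exactly the statistical structure the
analysis assumes, so that each stage can be exercised against ground truth.

# Trial analysis

Plot-level data from a multi-year replicated trial are reduced to one best
linear unbiased estimate (BLUE) per genotype and trait with the mixed model

$$Y_{ijkl} = \mu + \varsigma_i + \delta_{ij} + \beta_{kij} + \alpha_l +
(\varsigma\alpha)_{il} + \varepsilon,$$

with year ($\varsigma_i$) and genotype ($\alpha_l$) fixed, and
replicate-in-year, block-in-replicate and genotype-by-year random
(`fit_blues()`, REML via **lme4**). Broad-sense heritability on an
entry-mean basis is

$$H^2 = \frac{V_G}{V_G + V_{G\times E}/i + V_E/(ij)}$$

with $i$ years and $j$ replicates (`compute_H2()`). Mid-parent heterosis is
$\mathrm{MPH}_{ij} = \hat G_{ij} - \tfrac12(\hat G_i + \hat G_j)$, reported
both absolutely and as a percentage of the mid-parent mean
(`compute_mph()`); general and specific combining abilities follow the
classical definitions (`compute_gca_sca()`). Both conventions of "heterosis"
are supported downstream because figures in this literature usually show
percent MPH while prediction targets are in trait units.

# Per-SNP effects: additive + dominance GBLUP

Hybrid BLUEs are modelled as
$Y_i = \mu + \sum_j X_{ij}\alpha_j + \sum_j W_{ij} d_j + \varepsilon$, with
the centred genotype codes (for 0, 1, 2 copies of the deleterious allele,
whose frequency is $p$)

$$X = \{2p,\; 2p-1,\; 2p-2\}, \qquad
W = \{-2p^2,\; 2p(1-p),\; -2(1-p)^2\}.$$

Both code vectors have zero mean under Hardy–Weinberg proportions — this
requires $p$ to be the frequency of the allele whose copies are counted,
and the package consistently uses the deleterious-allele frequency in the
hybrid sample (configurable). The codes make $\alpha_j$ (substitution
effect) and $d_j$ (dominance deviation) orthogonal at a locus.
`fit_gblup()` estimates $\sigma^2_A$, $\sigma^2_D$, $\sigma^2_E$ by REML
with the realized relationship matrices $G_A = XX'/\sum 2p(1-p)$ and
$G_D = WW'/\sum (2p(1-p))^2$, maximising the REML log-likelihood directly
over log-variances with L-BFGS-B (we found this simpler and as accurate as
average-information iterations at these problem sizes; a grid-search oracle
in the test suite confirms the optimum). Constrained fits with $d = 0$
(complete additivity) or $\alpha = 0$ (complete dominance) are available.

Because the phenotypes are stage-one BLUEs, their error variance is known
from the trial fit (mean squared BLUE standard error); passing it as
`sigma_e` fixes the residual variance in stage two. This matters: with 66
hybrids and rare ascertained alleles the dominance relationship matrix is
strongly diagonal, so a free residual and $\sigma^2_D$ compete, and fixing
the residual at its known value removes a systematic upward bias in the
dominance share that we observed otherwise.

`backsolve_effects()` converts the genomic BLUPs to per-SNP effects
($\hat\alpha = (\sigma^2_A/\sum 2pq)\,X'V^{-1}(y-\mu)$ and likewise
$\hat d$), then derives the additive effect and the degree of dominance
$k = d/a$ of the conserved allele, truncated at $|k| \le 2$. Since
$\hat\alpha$ is the average substitution effect, the additive
(homozygote half-difference) effect follows the classical relation
$a = \alpha + (1-2p)d$; the package also reports the alternative
extraction $a = \alpha - 2p(1-p)d$ (columns `a_printed`, `k_printed`) used
by some GBLUP software output conventions, but its own $k$ is the
classical one — in simulation the classical extraction recovers the sign of
the dominance–conservation relationship markedly better, which is expected
since only it inverts the substitution-effect definition. $k > 0$ means the
conserved allele is dominant (deleterious allele recessive); $k = +1$ is
complete recessivity of the deleterious allele.

Per-SNP variances use the standard single-locus decomposition
$V_{A,j} = 2p(1-p)\hat\alpha^2$, $V_{D,j} = (2p(1-p)\hat d)^2$; regressions
of $|a|$, $d$ and $k$ on the conservation score (`regress_on_gerp()`) are
restricted to SNPs explaining more than the genome-wide mean per-SNP
variance, with an optional removal of the lowest recombination quartile as
a linked-selection robustness check. Control SNP sets matched to the
conserved set's joint allele-frequency (10% bins) by recombination-rate
(quartile) histogram are drawn by `matched_random_sample()`.

# Haplotype blocks and complementation scores

Pairwise identity-by-descent segments between the inbred parents define
haplotype blocks: every segment endpoint, pooled over all pairs, is a
breakpoint, and blocks are the intervals between consecutive breakpoints,
kept if at least 1 kb long (`build_blocks()`; coordinates are 0-based
half-open throughout, with a conversion flag for 1-based interval files).
Since inbred parents transmit a single haplotype, F1 genotypes are
projected exactly from the parents (`project_f1()`). Each block is scored
per hybrid by summing over its positively scored SNPs (`score_blocks()`):

* homozygous conserved: 0,
* homozygous deleterious: $2g$,
* heterozygous: $(1 + k_{het})\,g$,

where $g$ is the SNP's conservation score and $k_{het}$ is 0 (additive
model), $-1$ (dominance model, i.e. full complementation), or the per-SNP
estimate under the incomplete-dominance model. Note the sign bridge: the
GBLUP $k$ is the dominance of the *conserved* allele, so the heterozygote
weight uses $k_{het} = -k$ clamped to $[-1, 1]$ — a fully recessive
deleterious allele ($k = +1$) then scores 0 in the heterozygote, which is
what complementation means, and values outside the clamp would take a
heterozygote outside the $0\ldots2g$ range of the scheme. Missing genotypes
contribute 0 and blocks without positively scored SNPs are excluded.

# Genomic prediction and the permutation null

Block scores enter a BayesC regression
$Y_i = \mu + \sum_j r_j I_{ij} + \varepsilon$ with a spike-and-slab prior
on block effects (`bayesc_fit()`, Gibbs sampling in compiled code on R's
RNG, so runs are reproducible with `set.seed()`). Priors follow
GenSel-style defaults: scaled inverse-$\chi^2$ (df 4) on the slab and
residual variances with scales derived from an *a priori* split of the
phenotypic variance, and the exclusion probability $\pi$ estimated under a
Beta(1, 9) prior unless fixed. The default chain is 4,100 iterations with
100 burn-in — at a few hundred blocks the posterior means are stable well
before that — and the long-chain setting (41,000 / 1,000) is one argument
away.

Prediction accuracy is the Pearson correlation between predicted and
observed values on hold-out sets: random 80/20 splits, 100 by default
(`cross_validate()`), with the split list reusable so that competing models
and nulls share identical training/validation sets. The null model for
"does conservation carry information?" permutes the score track circularly
within consecutive windows of 50,000 SNPs (one whole-track rotation when the
track is shorter), keeping coordinates and the local score distribution
intact while breaking the score-to-site assignment
(`circular_permutation()`, with a genic-only variant). Real and permuted
accuracies are compared per trait by a one-sided paired t-test across the
shared splits, Benjamini–Hochberg adjusted across traits
(`compare_real_vs_permuted()`).

Two more checks close the loop. `gca_model_comparison()` asks whether the
genomic breeding value adds information beyond classical combining
abilities ($Y_{ij} = \mu + GCA_i + GCA_j (+ G_{ij}) + \varepsilon$; F-test
and $\Delta$AIC). A useful exact property surfaced here: additive block
scores decompose into parental sums, so an additive-model breeding value is
*perfectly* collinear with the GCA design — the comparison is only
informative for dominance-aware models, and the collinear case is flagged
rather than treated as an error. Finally `triploid_projection()` projects
unbalanced-composition triploids (AAB/ABB) from the parental haplotypes,
scoring a site with deleterious dosage $x$ in a ploidy-$m$ genotype as
$g\,x\,(1 + k_{del}(m-x)/(m-1))$ — the unique linear-in-$x$ interpolation
that reduces to the diploid $0/(1+k_{del})g/2g$ scheme at $m = 2$. Under
full recessivity a single deleterious copy among three is fully masked, so
AAB and ABB hybrids differ whenever the parents differ, which is the
qualitative pattern that motivates dosage-aware complementation models.

# Mutation-selection balance and the ascertainment control

`equilibrium_frequency()` gives the deterministic equilibrium frequency of
a deleterious allele under recurrent mutation $\mu$ and selection $s$
against the deleterious homozygote, with dominance expressed as $k$ of the
conserved allele: $p = \sqrt{\mu/s}$ for near-complete recessivity
($k > 0.98$) and $p = 2\mu/(s(1-k))$ (equivalently $\mu/(hs)$,
$h = (1-k)/2$) otherwise. Both closed forms are validated in the test suite
against a forward selection–mutation recursion; they are asymptotic
approximations, exact to $10^{-3}$ relative in the rare-allele regime away
from the divergent $k \to 1$ boundary, which is where the tests sample.

`run_msb_experiment()` is the ascertainment control: dominance is drawn
uniformly and *independently* of the conservation score, selection is tied
to the score, equilibrium frequencies are computed, and a panel of 12
inbreds is sampled per site. Because recessive alleles equilibrate at
higher frequencies, they are over-represented among panel-segregating
sites — but equally so at every score, so the regression of $k$ on score
among segregating sites is null. This verifies that a positive
dominance–conservation regression in the real analysis is not an artifact
of small-panel ascertainment.

# The synthetic diallel generator

`simulate_diallel()` generates, under one seed: a conservation-score track
(exponential positive tail with mean decreasing in local recombination
rate, so constrained sites concentrate in low-recombination regions; point
mass at zero plus a small negative tail otherwise; genic flags at a 0.64
fraction), equilibrium allele frequencies via the mutation-selection
machinery, fully inbred parent genotypes, pairwise IBD segments with
genotype identity enforced inside them, true per-SNP effects, exact F1
projections for all 66 crosses, and plot-level phenotypes for a 3-year ×
3-replicate trial with genotypes re-randomized into incomplete blocks every
replicate (a resolvable design, so genotype effects are estimable free of
block confounding).

Key default choices, made once:

* **Ascertainment.** Sites are SNPs: panel carrier counts are drawn from
  the binomial conditioned on polymorphism, mirroring the fact that an
  observed SNP table contains only sites that segregate in the sequenced
  panel. The unconditioned mode (`ascertain = FALSE`) exists for limit
  checks (overwhelming selection then fixes every site for the conserved
  allele).
* **Effective mutation rate** `mu = 1e-4` with `s(g) = 0.005 + 0.012 g`.
  These are not literal per-generation point rates; they are chosen so
  equilibrium frequencies give realistic numbers of segregating sites and a
  declining frequency–score relationship in a 12-line elite panel. The
  selection law rises fast enough in `g` to dominate the
  frequency-increasing effect of the dominance law, keeping the
  frequency–score correlation negative across the score range.
* **Dominance and effect laws** `k(g) = 0.15 + 0.22 g` (Gaussian noise, sd
  0.05, clamped to [0, 1]) and `|a|(g) = 0.25 g` (half-normal noise, sd
  0.03). The magnitudes of these slopes are not published anywhere; they
  are calibrated once so that the qualitative signals (positive
  effect–score and dominance–score relationships) are statistically
  detectable at 5,000 scored sites and 66 hybrids, not for physiological
  realism. The dominance-law clamp deliberately ends at 1, not just below
  it: clamping at the boundary of the partial-dominance equilibrium formula
  would pile sites onto its divergence and flood the panel with
  spuriously common deleterious alleles.
* **Dominance-variance share.** Dominance deviations of the yield-like
  trait are rescaled by one global factor (root search, `d <= a` enforced)
  so that the realized share `var(Wd) / (var(X alpha) + var(Wd))` in the
  simulated hybrid population equals the 0.24 target. The realized-variance
  calibration matters: with all dominance deviations positive and only 12
  founder haplotypes, between-site linkage inflates realized dominance
  variance well above the independent-sites sum, so calibrating on the
  latter would miss the target by a factor of up to two.
* **Heritability.** The target (default 0.7 for yield) is calibrated on the
  genetic variance of the hybrid population, the material every genomic
  analysis in the package models. For a trait with directional dominance
  the inbred–hybrid gap (which equals $\sum_j 2p_jq_jd_j$ and grows with
  the number of segregating sites) inflates the all-entries genetic
  variance, so the all-entries $H^2$ implied by the chosen components is
  higher (~0.9; reported as `H2_implied` in the truth record, and what
  `compute_H2()` recovers on the full trial). Anchoring the noise to the
  all-entries variance instead would make hybrid-level signal collapse
  whenever the gap is large, which is the opposite of how real yield trials
  behave.
* **Heterosis anchor.** The yield intercept is set so hybrids exceed the
  mid-parent mean by a 1.82 ratio in expectation (strong hybrid vigour),
  floored so that every mid-parent value stays several BLUE standard
  errors above zero — percent heterosis is a ratio and explodes otherwise.
  Realized mean percent MPH varies by seed, roughly 60–240%.
* **IBD density** 8% of the genome per pair (mean segment 2 Mb). Per-site,
  pairwise IBD constraints are transitive; groups share the genotype of a
  randomly chosen member (preserving marginal frequencies). The 8% default
  keeps the per-site relatedness graph subcritical — at substantially
  higher densities the 12 parents chain into large groups, the effective
  panel shrinks, and allele-frequency outliers distort the variance
  decomposition.

What the generator does **not** emulate: linkage-disequilibrium decay
within blocks (within a block, parental haplotypes are the only structure),
multi-chromosome genomes (single linear chromosome by default; the block
machinery accepts any chromosome-length table), realistic maize
demography, or the empirical GERP score distribution. Passing tests
therefore show that the estimators recover the generating structure they
assume — not that real resequencing data satisfy those assumptions.

# Numerical choices and degenerate inputs

Variances are floored at $10^{-10}\times$ the phenotypic variance inside
REML; a constant phenotype returns all-zero components rather than an
error. Equilibrium frequencies are clamped to $[0, 0.5]$ (the deleterious
allele is by definition minor) with the clamp count recorded. Monomorphic
sites are kept in tracks but dropped by `encode_ad()`. Heterozygous parent
sites are set to missing in all F1 projections with a warning; missing
genotypes contribute 0 to block scores and are mean-imputed in the GBLUP
codes. Bin-mean regressions of frequency on score are weighted by bin
occupancy — sparsely occupied tail bins otherwise dominate the fit and the
null test is miscalibrated. The `k = d/a` ratio is truncated at $\pm 2$ and
left `NA` where $a = 0$.

# Problem sizes and what the checks run

The test suite exercises the pipeline at 12 parents, 5,000 scored sites
(roughly 1,500 segregating conserved SNPs after ascertainment and IBD
forcing), 66 hybrids and a 3×3 trial, across ten fixed seeds; unit tests
use 400-site configurations. Cross-validation checks use 20 random 80/20
splits against 3 circular shuffles at 4,100 BayesC iterations; the
brute-force block-score oracle runs 1,000 randomized instances. These sizes
are the package's chosen trade-off between statistical resolution and a
test suite that runs in minutes.

# Known limitations

* With 66 hybrids and relationship matrices built from only 12 founder
  haplotypes, the REML likelihood is flat in the additive/dominance split:
  the sampling spread of the fitted dominance share is roughly ±0.1–0.15
  even with the residual variance fixed at its known value, and a known
  share of 0.24 is recovered to ±0.1 only in a majority — not the vast
  majority — of seeds. This is an information limit of the design, not of
  the estimator (fits on noise-free genetic values recover the share in
  10/10 seeds).
* Per-SNP backsolved effects at this design size are heavily shrunk and
  individually noisy (correlations with true per-SNP effects around 0.1);
  only their aggregate regressions on conservation score are informative,
  and the $k$ regression in particular depends on using the classical
  extraction of $a$.
* The gain of observed over permuted conservation scores in
  cross-validation is small (a few accuracy points, mirroring what is
  reported for real data) and at some seeds within noise of zero; the
  paired-design comparison across shared splits is the package's
  recommended inference, and win-counting across small numbers of seeds is
  fragile.
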