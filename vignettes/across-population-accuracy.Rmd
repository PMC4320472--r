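---
title: "Deterministic and empirical accuracy of across-population genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic and empirical accuracy of across-population genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Genomic prediction estimates breeding values of genotyped selection
candidates from a reference population with phenotypes and marker
genotypes. When candidates come from a *different* population than the
reference — another cattle breed, another line, another human
subpopulation — accuracy drops sharply: close family links are absent,
allele frequencies differ, linkage disequilibrium (LD) between markers and
QTL is only conserved at short range, and the allele substitution effects
of the QTL themselves may differ between populations. The correlation
between allele substitution effects across populations acts as a genetic
correlation $r_G$ between the populations and caps what across-population
prediction can achieve.

`xpopacc` implements two deterministic predictors of this accuracy, the
simulation machinery to validate them empirically, and the estimation of
$r_G$ itself:

1. a selection-index formula that predicts the accuracy for each candidate
   from its genomic relationships with the reference individuals;
2. a population-parameter formula that needs only the reference size, the
   heritability, the genetic correlation, and the effective number of
   chromosome segments $M_e$;
3. an empirical pipeline — phenotype simulation, GREML/GBLUP, and the
   correlation of estimated with true breeding values;
4. a bivariate GREML model that estimates $r_G$ by treating the same trait
   in two populations as two traits;
5. a gene-dropping simulator producing multi-population genotype panels
   with a matching pedigree, standing in for real multi-breed data.

# The model

## Genomic relationships with population-specific centering

Relationships are computed from standardized dosages
$x_{ijk} = (g_{ijk} - 2p_{jk}) / \sqrt{2 p_{jk}(1-p_{jk})}$, where
$g_{ijk} \in \{0,1,2\}$ is the dosage of individual $i$ of population $j$
at locus $k$, and $G = XX'/n$ over $n$ loci. The choice of $p_{jk}$
matters:

* **own-population frequencies** (`scheme = "own_population"`): each
  individual is centered with the frequencies of its own population. Each
  population becomes its own base, so cross-population blocks average
  exactly zero and the deterministic theory applies. A covariance is
  defined around the mean of each variable; this scheme is the matrix
  version of that statement.
* **pooled equal-weight frequencies** (`scheme = "pooled_equal_weight"`):
  the unweighted mean frequency over populations (so the largest
  population does not dominate). This is the scheme used in the empirical
  GREML pipeline.

Loci whose standardizing frequency is 0 or 1 cannot be standardized; under
the own-population scheme they are excluded per population, and each block
of the matrix is divided by the number of loci usable for that pair of
populations.

## Selection-index accuracy

Predicting candidate $i$ of population $A$ from reference population $B$
by $\hat a_{A_i} = \mathbf b' \mathbf y_B$ with
$\mathbf b = \mathrm{Var}(\mathbf y_B)^{-1}\,
\mathrm{Cov}(a_{A_i}, \mathbf y_B)$ gives

$$
r_{A_i} \;=\; r_{G_{AB}}\sqrt{\mathbf g'_{A_i,B}
\Bigl[\mathbf G_B + \mathbf R_B\,\sigma^2_{e_B}/\sigma^2_{a_B}\Bigr]^{-1}
\mathbf g_{A_i,B}},
$$

where $\mathbf g_{A_i,B}$ holds the genomic relationships of the candidate
with the reference individuals, $\mathbf G_B$ the relationships within the
reference, and $\mathbf R_B$ the environmental correlation matrix
(identity by default — simulated environments are independent, and no
study we emulate parameterizes it otherwise). `si_accuracy_single()`
evaluates this with a symmetric positive-definite solve; an explicit
inverse is never formed. The derivation uses
$\mathrm{Cov}(\hat a, a) = \mathrm{Var}(\hat a)$, which holds for the
across-population index as well; the test suite asserts this identity
numerically on random systems to $10^{-10}$.

With two reference populations $B$ and $C$ the same logic gives a
$2 \times 2$ block system whose cross block is
$r_{G_{BC}} \mathbf G_{BC}$ (`si_accuracy_multi()`). With an empty second
population it reduces exactly to the single-reference formula, and with
candidates drawn from the reference population itself it reduces to the
classical within-population relationship-based (prediction-error-variance)
accuracy — both reductions are tested.

Accuracy is *exactly proportional* to $r_G$: the correlation enters only
as a multiplicative factor. This is the formula's headline property, and
it means an observed empirical-to-deterministic accuracy ratio estimates
$r_G$ itself.

`si_accuracy_loo()` computes the leave-one-out accuracy for every member
of one population from a single factorization, via the
partitioned-inverse identity
$\mathbf g_i' \mathbf M_{-i}^{-1} \mathbf g_i = H_{ii} - 1/(H^{-1})_{ii}$
on the full system $H = G + (\sigma^2_e/\sigma^2_a) I$.

## Population-parameter accuracy

When each of $M_e$ independently segregating chromosome segments explains
variance $\sigma^2_a / M_e$, the accuracy of genomic prediction is

$$
r_P = r_G \sqrt{\frac{N_p h^2}{N_p h^2 + M_e}},
$$

with reference size $N_p$ and heritability $h^2$ (`pp_accuracy()`). $M_e$
is estimated as the reciprocal of the variance of the deviation of genomic
from pedigree relationships, $M_e = 1/\mathrm{Var}(G_{ij} - A_{ij})$
(`effective_segments()`): over all pairs within the reference for
within-population prediction, and over all reference × candidate pairs for
across-population prediction. The genomic matrix entering $M_e$ must use
own-population frequencies so that unrelated individuals have expected
relationship zero. Sample variances ($N-1$ denominator) are used
throughout; the sources are silent on the denominator and consistency was
preferred.

## The empirical pipeline

Phenotypes are simulated on the panel (below), a GREML model
$y = X\beta + a + e$ with population as fixed effect,
$\mathrm{Var}(a) = G\sigma^2_a$, $\mathrm{Var}(e) = I\sigma^2_e$ is fitted
on the reference by restricted maximum likelihood (`reml_single()`),
candidates are predicted by
$\hat a_{cand} = \hat\sigma^2_a G_{cand,ref} V^{-1}(y - X\hat\beta)$
(`blup_predict()`), and the empirical accuracy is the Pearson correlation
of EBV with true breeding values within each candidate population
(`empirical_accuracy()`).

The G supplied to GREML is, by default, the pooled-frequency matrix with
two adjustments:

* **inbreeding rescaling** `rescale_inbreeding()`:
  $G^* = (1-\bar F_b) G + 2 \bar F_b J$ applied to each within-population
  block, with $\bar F_b$ the population's mean pedigree inbreeding from
  the truncated pedigree. It aligns the base of G (current population)
  with the base of the pedigree matrix A.
* **regression towards A** `regress_to_nrm()`:
  $\hat G = A + b (G^* - A)$ with
  $b = (\mathrm{Var}(G^*-A) - 1/n) / \mathrm{Var}(G^*-A)$, estimated
  separately per bin of pedigree relationship
  ($(0,0.10], (0.10,0.25], (0.25,0.50], (>0.50)$; closed on the right,
  cross-population pairs fall in the first bin) within each population and
  population pair. A finite marker panel measures relationships with
  sampling error $\approx 1/n$; the regression shrinks exactly that
  component. Self-relationships and direct parent–offspring pairs (looked
  up in the pedigree, not inferred from A values) are barely affected by
  locus sampling and are excluded from the estimation and copied from
  $G^*$ unchanged. Degenerate bins (≤ 1 eligible pair) default to
  $b = 1$; estimates are clipped to $[0,1]$ because small panels can
  produce out-of-range values.

Pedigrees are cut at seven generations above the panel
(`truncate_pedigree()`) so that unequal pedigree depths do not create
artificial inbreeding differences between populations, and A is built by
the tabular method (`pedigree_nrm()`).

## Estimating the genetic correlation

`reml_genetic_correlation()` treats the same trait in two populations as
two traits with covariance
$r_G \sigma_{a_A} \sigma_{a_B} \mathbf G_{AB}$ and zero environmental
cross-covariance, population means as fixed effects, the focal
population's components free, and the other population's components fixed
at supplied values (small populations rarely support estimating them).
The optimizer works on $(\log\sigma^2_{a}, \log\sigma^2_{e},
\mathrm{atanh}(r_G/0.999))$, which keeps the correlation in
$(-0.999, 0.999)$ and the variances positive.

**Which G to use here matters at desk scale.** The inbreeding rescaling
acts on within-population blocks only. When pedigree inbreeding is
substantial — our generator's breeding design yields
$\bar F_b \approx 0.2$ after seven pedigree generations at effective size
~50 — rescaling changes the scale of the within-blocks relative to the
cross-block and attenuates $\hat r_G$ by roughly 20%. The package
therefore feeds the correlation model the pooled-frequency G regressed
towards A *without* the inbreeding rescaling. For prediction this choice
is immaterial (a within-population correlation of EBV with TBV is
invariant to those block transformations); in data with low pedigree
inbreeding the two choices coincide.

# Trait simulation

`sample_qtl_effects()` draws, per QTL, one allele substitution effect per
population from a standard multivariate normal with correlation $r_G$
between all population pairs, via the Cholesky factor of the correlation
matrix (a symmetric eigenvalue square root handles the singular case
$r_G = 1$, where all populations must receive identical effects).
QTL are drawn per replicate from a fixed candidate pool
(`partition_candidates()`), so the marker set stays constant across
replicates while QTL vary.

`compute_tbv()` sums effect × dosage over the QTL, each individual using
its own population's effect vector, and rescales the result to mean 0 and
variance 1 *across* populations. The per-population means are kept: they
are real consequences of allele-frequency divergence. Rescaling makes the
genetic variance identical across replicates and QTL counts, so a larger
number of QTL simply means each explains less variance.

`simulate_phenotypes()` draws environmental effects from
$N\bigl(0, (1/h^2 - 1)\,v\bigr)$, where $v$ is the variance of TBV after
subtracting each population's own mean (a single pooled value — the
variance expression is printed once and heritability is assumed equal
across populations). Population means are removed *only* to compute $v$;
phenotypes are $y = \mathrm{TBV} + e$ with the means intact.

The default heritability is 0.95. That is not a biological heritability:
it is the reliability of a deregressed proof of a progeny-tested bull —
`drp_reliability(285, 0.25)` returns exactly 0.95 — and it makes accuracy
differences between scenarios visible at moderate reference sizes.

# The synthetic multi-breed generator

Real multi-breed cattle panels are rarely public, so `synthpop` generates
them (`simulate_multibreed_panel()`):

1. an ancestral pool of 100 diploids with locus frequencies drawn
   Uniform(0.1, 0.9) random-mates for 50 burn-in generations, which builds
   the short-range LD that real breeds share from common ancestry;
2. each population is founded from the pool (50 founders) and drifts
   independently for 20 generations at census ≈ effective size 50,
   creating breed divergence — pairwise $F_{ST} \approx
   1-(1-\tfrac{1}{100})^{20} \approx 0.18$ and cross-breed
   allele-frequency correlations around 0.7–0.8;
3. three final breeding generations use 10 sires each mated to many dams,
   producing the paternal half-sib families typical of dairy cattle; sex
   alternates at birth so the design is always feasible;
4. gametes recombine under Haldane's model (Poisson crossover count with
   mean equal to the map length in Morgan, uniform breakpoints, no
   interference); loci sit on an even grid over three 1-Morgan
   chromosomes.

The pedigree covers the divergence and breeding phases; the burn-in pool
is the unpedigreed base. Divergence and burn-in matings draw parents
multinomially (keeping $N_e$ near census size); only the breeding phase
balances parental contributions, which is the half-sib design itself.

**Marker density is a deliberate choice.** The default is 4000 loci per
chromosome (12 000 total; ~8000 after QC; ~6400 markers after reserving
1500 candidate QTL). The panels we emulate are dense relative to the LD
range (tens of thousands of loci on a few Morgan), and the deterministic
theory relies on markers tagging QTL: at half this density the
marker-based G carries enough locus-sampling noise that the
selection-index accuracy is visibly inflated relative to what any
marker-based predictor can achieve, and the agreement between
deterministic and empirical accuracy degrades. With the default density
the two agree within sampling error, which is the package's central
validation.

What the generator does *not* emulate: mutation, selection during
breeding, coalescent-exact haplotype structure, ascertainment bias of chip
SNPs (all loci come from one frequency distribution, whereas real chips
enrich intermediate frequencies and real QTL are enriched at low
frequencies), and sequence-level features. Passing tests therefore show
that the formulas and pipeline behave as derived on data satisfying their
assumptions — not that real across-breed accuracies will match the
simulated magnitudes.

# Marker quality control

`marker_qc()` removes, in order: loci with pooled minor allele frequency
≤ 0.5% (boundary inclusive), loci with fewer than three observed genotype
classes, and — scanning each chromosome left to right — loci in complete
LD ($r^2 = 1$ within $10^{-12}$) with the nearest retained locus to their
left (the leftmost of such a run is kept, making the scan deterministic).
The first two rules act on the pooled panel; the report reconciles exactly
with the dimension change. Missing genotypes are rejected at input: the
data this package targets are complete post-imputation panels, and
completeness keeps all downstream algebra exact.

# Scenarios and replication

`scenario_spec()` + `run_scenario()` orchestrate the standard designs:
a base (within-population) scenario — leave-one-out for the deterministic
accuracy, k-fold cross-validation (default 20) for the empirical one —
and across-population scenarios with one or two reference populations.
Deterministic accuracies are computed once per panel (they use no
phenotypes); empirical accuracies are averaged over replicates, each with
its own QTL draw, effect draw and noise draw, on seeds derived from the
base seed by fixed offsets (recorded in the report). `fast_cv = TRUE`
estimates variance components on the first fold of a replicate and reuses
them across the remaining folds; the default refits per fold.

# Numerical choices

* Positive-definite solves use Cholesky; if factorization fails and the
  smallest eigenvalue exceeds $-10^{-8}\,\mathrm{tr}(M)/n$, a jitter of
  $10^{-8}$ is added once, otherwise the error reports the smallest
  eigenvalue. Genomic systems with duplicated relatives are near-singular,
  and silent regularization of a genuinely indefinite system would be
  worse than failing.
* Single-trait REML profiles the likelihood through one eigendecomposition
  of the reference G block, making each objective evaluation $O(n)$;
  optimization is bounded quasi-Newton on log-variances with relative
  tolerance $10^{-8}$ and a 200-iteration cap. An identity G is rejected
  (genetic and residual variance would be confounded). The bivariate model
  re-factorizes V per evaluation because its structure changes with
  $r_G$.
* Individual leave-one-out accuracies can exceed 1 slightly for
  individuals whose realized self-relationship $G_{ii}$ exceeds 1: the
  formulas express accuracy on the population-variance scale
  ($\mathrm{Var}(a) = 1$), not relative to the individual's own
  $G_{ii}$. They are reported as computed, not clamped.
* All stochastic steps take explicit seeds and restore the caller's RNG
  state; a fixed configuration reproduces byte-identical panels,
  pedigrees and reports.

# Problem sizes

The test suite validates on a two-population panel of 200 + 80
individuals (7200 loci on three 0.8-Morgan chromosomes, effective size
~40) so the whole suite runs in well under a minute, and on textbook-sized
fixtures with brute-force oracles. The acceptance analyses use the default
generator: 400 reference + 100 candidate individuals, 12 000 loci, 1500
candidate QTL, 100 phenotype replicates for the empirical ratios. These
sizes are the package's desk-scale stand-in for a real design of roughly
1000 + 100–150 individuals and ~26 500 markers.

# Known limitations

* Variance components fed to the deterministic formulas default to the
  simulation truth; with estimated components their sampling error
  propagates into the predicted accuracy.
* The population-parameter formula assumes markers capture all genetic
  variance in the candidates; across populations they do not, so it
  overestimates — on simulated panels here by ~10–20%, on real data
  reportedly more. Scaling its $M_e$ input from a genome subset to the
  whole genome is the user's responsibility.
* Only additive gene action is modeled; dominance and epistasis, which
  are one *cause* of $r_G < 1$, are represented only through the effect
  correlation itself.
* The bivariate correlation model is pairwise; a three-population joint
  model is not implemented.
* Heterogeneous genetic variances across populations are supported in the
  selection-index formulas but not exercised by the default simulation
  (TBV are rescaled to a common variance).
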