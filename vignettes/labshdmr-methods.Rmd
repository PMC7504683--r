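---
title: "Methods: second-order HDMR classification and interaction detection for SNP dosages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: second-order HDMR classification and interaction detection for SNP dosages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labshdmr)
```

## The statistical problem

Case/control SNP data report dosages — minor-allele counts in {0, 1, 2} —
for thousands to millions of loci on hundreds to thousands of samples.
The Bayes rule thresholds the log-likelihood ratio
$L(X) = \log P(y{=}1\mid X) - \log P(y{=}0\mid X)$, but the joint law of
$X$ is never estimable at that dimension. This package approximates
$L$ by its second-order high dimensional model representation (HDMR):
single-locus terms plus pairwise-interaction terms, each a finite table
because the inputs are categorical.

## Exact HDMR for enumerable categorical joints

For an enumerable joint (`categorical_joint`) with pmf $w$ and target
$Z = f(X)$, `hdmr_expand(joint, d)` finds component functions $f_u$,
$|u| \le d$, minimizing $\sum_x w(x)\,(f_0 + \sum_u f_u(x_u) - f(x))^2$
subject to the vanishing conditions: for every $u$, every $i \in u$, and
every value of $x_{u\setminus i}$,
$\sum_{x_i, x_{-u}} f_u(x_u)\, w(x) = 0$. These conditions are exactly
equivalent to hierarchical orthogonality — $f_u$ orthogonal under $w$ to
every function of a strict subset of $u$ — because any function of a
strict subset of $u$ is a function of $x_{u\setminus i}$ for some
$i \in u$. We therefore impose only the vanishing rows and verify the
orthogonality residuals in tests.

**Numerical choices.** All components are solved *simultaneously* as one
equality-constrained weighted least-squares (KKT) system. For dependent
inputs the classical recursion defining each component from
lower-order ones is self-referential, so no iteration is attempted: the
direct solve is exact. The KKT matrix is inverted with the Moore–Penrose
pseudoinverse (`MASS::ginv`), for two reasons: the per-subset constraint
blocks are deliberately redundant (rank $< $ rows), and cells with zero
probability leave some coefficients unidentified — the pseudoinverse
returns the minimum-norm representative and those cells are flagged
`unsupported`. Tolerances used in the test suite: reconstruction and
orthogonality residuals $10^{-8}$, independence-recursion agreement
$10^{-10}$, algebraic identities $10^{-12}$. The product space is capped
at $10^6$ cells by default; this solver is an oracle for small systems,
not a genome-scale tool.

Sobol indices are computed by exact summation:
$S(u) = \mathrm{var}(E(Z\mid X_u))/\mathrm{var}(Z)$ and
$S^c(u) = 1 - \mathrm{var}(E(Z\mid X_{-u}))/\mathrm{var}(Z)$. For the
XOR system with fair independent bits, $S(\{1\}) = 0$ and
$S(\{1,2\}) = 1$, the canonical pure-interaction benchmark.

```{r xor}
j <- categorical_joint(list(x1 = 0:1, x2 = 0:1), rep(0.25, 4), c(0, 1, 1, 0))
e <- hdmr_expand(j, 2)
c(f0 = e$f0, S1 = sobol_indices(j, "x1")$S,
  S12 = sobol_indices(j, c("x1", "x2"))$S)
```

Infinite entries in log-likelihood-ratio tables (one class has mass, the
other none) are propagated as flags and never silently clipped;
`classification_joint` requires an explicit `clip` magnitude before it
will truncate them, since the HDMR least-squares target must be finite.

## Binarization and the OBF filter

Each SNP becomes two indicators: carrier $1\{X \ge 1\}$ and
homozygous-minor $1\{X = 2\}$. This spans dominant, recessive and
additive dose–response shapes with two linear degrees of freedom and
reconstructs the dosage as their sum. Features are ranked by the
Dirichlet-multinomial Bayes factor comparing independent class-specific
category distributions against a shared one, computed in log space to
survive large samples; the posterior association probability uses a
prior $\pi$ that is constant across features and therefore never affects
the ranking ($\pi = 0.05$ by default, configurable). Defaults
$\alpha = (2, 2)$ for binarized features (the uniform prior over the
pair patterns a binarized SNP enters) and $\alpha = (1,1,1)$ for raw
3-category dosage are both available. `D`, the number of retained
features, counts *binarized* features — values in the 900–1250 range are
typical for GWAS-scale inputs.

**Missing data.** Missing genotypes are mode-imputed per SNP before
binarization (`impute_mode`); `binarize` refuses `NA`s so the imputation
step is always explicit. Dosages are taken as minor-allele counts as
given; `polarize_minor` optionally flips SNPs whose coded-allele
frequency exceeds 0.5.

## The Fixed Pattern Test

For a pair of binary features and a fixed pattern $(c_i, c_j)$, the
within-class sample correlations of $1\{X_i{=}c_i\}$ and
$1\{X_j{=}c_j\}$ (the phi coefficient) are Fisher-transformed,
$z_y = \tanh^{-1}\hat\rho_y$, and compared:
$Z = (z_1 - z_0)\big/\sqrt{1/(n_0-3) + 1/(n_1-3)}$, approximately
standard normal under equal correlations. Design choices:

- **Two-sided p-values**: an interaction may strengthen or weaken the
  correlation.
- **Clamping** $|\hat\rho| \ge 1 - 10^{-7}$ before the transform keeps
  p-values positive and the BH family well defined.
- **Family**: all four patterns of each cross-SNP pair are separate
  tests ($4\binom{D}{2}$ candidates); their dependence (the four share
  $|Z|$) is not corrected for. Intra-SNP pairs (carrier with
  homozygous indicator of the same SNP) are excluded — nested
  indicators carry no pairwise information.
- **Degenerate patterns** (constant indicator in either class) are
  reported as `SKIPPED_DEGENERATE` and excluded from the family rather
  than assigned $p = 1$.

BH q-values come from `stats::p.adjust(method = "BH")`; the rejection set
`q <= level` coincides with the literal step-up rule, which the tests
verify against a brute-force implementation.

## The classifier

Training (`labs_fit`) proceeds: impute → binarize → OBF top-`D` →
single-feature risks → pair-pattern risks → blocks → feature vector →
weights.

- **Single risks.** $v^f$ is the larger of
  $|\log(\hat p_{1,1}/\hat p_{1,0})|$ and
  $|\log(\hat p_{0,1}/\hat p_{0,0})|$ over the two category patterns
  ($\hat p_{c,y}$ the Dirichlet posterior mean of $P(X_f{=}c \mid y)$);
  the signed risk takes the sign of the winning log-ratio. Features with
  $|r^f| < T_1$ are dropped from the feature vector. A tie
  $|l_1| = |l_0|$ resolves toward pattern $c = 1$.
- **Pair risks.** For each pattern,
  $r = \log\frac{\hat p_{c_ic_j}(1)}{\hat p_{c_ic_j}(0)}
  - \log\frac{\hat p_{c_i,1}}{\hat p_{c_i,0}}
  - \log\frac{\hat p_{c_j,1}}{\hat p_{c_j,0}}$, so class-conditionally
  independent pairs contribute nothing. Joint pattern probabilities use
  add-one smoothing over the four cells (Dirichlet $\alpha = 1$ each),
  guaranteeing positivity; the slight marginal inconsistency with the
  singles' $\alpha = (2,2)$ is accepted and documented here. Pairs are
  formed over *all* top-`D` features, not only those passing $T_1$ —
  single and pair filtering are parallel stages. Threshold: $|r| \ge
  T_2$, strictly signed (an exactly zero risk joins no block).
- **Blocks.** Retained pairs are grouped by (anchor feature, pattern,
  sign); each pair belongs to the two blocks anchored at either end with
  mirrored pattern. A sample's block value is the fraction of member
  patterns it fires. The block risk is the log-ratio of class means of
  that fraction, stabilized by $\varepsilon_y = 1/(2n_y)$ per class so
  rare blocks cannot produce $\log 0$; blocks with $|r_A| < T_3$ are
  dropped. The per-sample-fraction-then-class-ratio reading of the block
  risk is a deliberate choice and is recorded in the model object.
- **Weights.** The separation objective — maximize the distance between
  the projected class means of $V$ — is linear in $b$ and thus
  unbounded; since any positive rescaling of $b$ leaves the ROC
  unchanged, we fix $\lVert b\rVert_2 = 1$, giving the closed form
  $b^* = (m_1 - m_0)/\lVert m_1 - m_0\rVert$. Degenerate case
  $m_1 = m_0$ raises an explicit "non-informative representation" error.
- **Feature vector.** $V$ stacks raw 0/1 indicator values (not
  risk-weighted — weighting is $b^*$'s job) and block fractions.

Hyperparameters $(D, T_1, T_2, T_3)$ are selected by stratified k-fold
cross-validation (`labs_cv`, default $k = 5$) on mean validation AUC;
ties prefer smaller $D$, then larger thresholds (the simpler model). The
decision threshold $T$ is set afterwards by maximizing Youden's J on the
pooled validation scores. The default grid spans $D \in \{250, 500, 900,
1250\}$, $T_1 \in \{0, 0.25, 0.5\}$, $T_2 \in \{0.8, 1.0, 1.2\}$,
$T_3 \in \{0.5, 0.8\}$.

## What the simulator emulates — and what it does not

`simulate_dataset` generates dosages from a Gaussian-copula haplotype
model: within LD blocks the two latent haplotype draws share an
equicorrelated normal (`ld_rho` on the latent scale) and alleles arise by
thresholding at the MAF quantile, so each SNP is marginally in
Hardy–Weinberg equilibrium. Phenotypes follow a logistic model additive
in the binarized indicators; fixed class sizes come from case/control
sampling of an oversampled pool, which shifts the log-likelihood ratio
only by a constant and so changes no ROC. Planted interactions overwrite
a pair's carrier indicators with draws from the 2×2 joint having the
requested within-class correlations (Fréchet-feasibility checked) and
class-equal marginals; dosages are back-filled with the conditional
Hardy–Weinberg homozygote probability. The default profile — 2000
controls, 1000 cases, 200 SNPs in blocks of 10, 10 causal SNPs with
per-indicator log-odds 0.5 — is a scaled stand-in for a genome-wide
resampling study.

Not emulated: recombination/coalescent haplotype structure, population
stratification, imputation uncertainty, genotyping error, sex
chromosomes. Passing tests on this generator demonstrate correctness of
the algorithms under a clean HWE/LD model, not performance on real
cohorts.

## Study conditions used by the tests and the acceptance script

All simulation-backed checks run at fixed seeds and the following sizes,
chosen once as realistic desk-scale conditions:

- Solver checks: 20 random joints over 3–4 binary variables, full
  support, including 10 independent-input joints for the recursion
  cross-check and a constrained-QP null-space oracle for optimality.
- FPT calibration: 500 samples per class, 5000 independent pairs;
  power: correlations 0 vs 0.4, 300 per class, 1000 replicates.
- Interaction-only classification: three planted pairs with within-class
  carrier correlations −0.4 (controls) and +0.4 (cases), class-equal
  marginals at MAF 0.3, 50 additional noise SNPs, 1000 training and 1000
  test samples per class; the comparator is the first-order additive
  score $\sum_f r^f x_f$ from the same fit.
- Additive benchmark: the default 2000/1000 profile, 900 + 900 training
  samples per split, 10 holdout iterations, compared against the
  generating model's exact log-likelihood-ratio score.

For sign-recovery checks the MAF range is restricted to 0.05–0.15: when
the carrier frequency approaches or exceeds one half, the absence
pattern's log-ratio can legitimately dominate and the signed risk of a
risk-increasing allele flips — a property of the risk definition, not a
bug, and the reason dosage should be coded on the minor allele.

## Known limitations

- The exact solver scales as the product-space size and is intended for
  oracle use on small systems only.
- The four patterns of a pair are dependent tests; BH is applied to the
  full family without a dependence correction.
- Pair risks use add-one smoothing, which for very rare patterns shrinks
  hard toward uniformity; with fewer than ~20 samples per class the
  block stage is effectively inert.
- The weight estimator is the class-mean difference, not a covariance-
  whitened direction; it is robust at small samples but can be
  dominated by a few high-variance block fractions when `D` is large
  and thresholds are loose.
- `read_vcf_dosage` handles biallelic records only and rounds DS values;
  imputation dosage uncertainty is discarded.
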