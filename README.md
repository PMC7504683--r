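# labshdmr

Binary case/control classification and pairwise-interaction detection for
SNP dosage data, treating genotypes as the categorical variables they are.

Genome-wide association data report, per sample and per SNP, the *dosage*
— the minor-allele count, a value in {0, 1, 2}. Predicting a binary
phenotype from such data is hard for standard reasons (many weak markers,
small samples, strong linkage disequilibrium) and for one less standard
reason: most off-the-shelf classifiers treat dosage as a real number,
forcing a homozygous-minor genotype to carry exactly twice the risk of a
heterozygous one, which is wrong for dominant and recessive loci and says
nothing about epistasis. `labshdmr` addresses both problems with the
high dimensional model representation (HDMR) of the log-likelihood ratio.

## The model

Write `L(X) = log P(y=1|X) − log P(y=0|X)` for the log-likelihood ratio of
a genotype vector `X`. HDMR decomposes any such target under the input law
`w` into hierarchically orthogonal component functions,

    L(X) = f_0 + Σ_f f_f(X_f) + Σ_{f<f'} f_{ff'}(X_f, X_{f'}) + ...,

where each `f_u` is orthogonal (under `w`) to every function of a strict
subset of `u`. Truncating at order 2 keeps single-SNP effects and pairwise
interactions — the best second-order approximation in mean square. For
categorical inputs every component is a finite table, and a non-zero
pairwise component of `L` is equivalent to the pair's indicator variables
being differently correlated in cases and controls.

The package implements this programme at three levels:

- **Exact solver** (`hdmr_expand`, `sobol_indices`): for fully enumerable
  joints it computes the constrained least-squares HDMR expansion of any
  target — dependent inputs included — plus total- and main-effect Sobol
  indices. This is the analytic oracle against which the classifier's
  approximations can be measured.
- **Fixed Pattern Test** (`fpt_scan`): for each feature pair and value
  pattern `(c_i, c_j)`, the within-class correlations of the indicators
  `1{X_i=c_i}`, `1{X_j=c_j}` are Fisher-transformed and compared across
  classes with `Z = (z_1 − z_0)/sqrt(1/(n_0−3) + 1/(n_1−3))`, with
  Benjamini–Hochberg FDR control over all `4·C(D,2)` patterns.
- **LABS-HDMR-CO classifier** (`labs_fit`, `labs_predict`): each SNP is
  binarized into carrier (`1{X≥1}`) and homozygous-minor (`1{X=2}`)
  indicators; a Dirichlet-multinomial Bayesian filter (OBF) keeps the top
  `D`; single features and pair patterns are scored by smoothed
  class-probability log-ratios and thresholded (`T1`, `T2`); surviving
  pairs are merged into risk-increasing/-decreasing blocks anchored at
  each feature (threshold `T3` on the block's class log-ratio); the final
  score is `R(x) = b*·V(x)` where `V(x)` stacks retained indicators and
  per-sample block pattern fractions and `b*` is the unit-norm class-mean
  difference. `y_hat = 1{R(x) > T}`.

A Gaussian-copula genotype simulator (`simulate_dataset`) with LD blocks,
Hardy–Weinberg marginals, additive logistic effects and planted
class-dependent pair correlations makes every stage testable without
external data, and exposes the generating model's exact log-likelihood
ratio as a Bayes-optimal reference score.

## Worked example

```r
library(labshdmr)

sim <- simulate_dataset(n0 = 1200, n1 = 800, n_snps = 50, causal = 5,
                        effect_size = 0.8, seed = 42)
sim
#> labs_sim: 1200 controls / 800 cases, 50 SNPs, 5 causal, 0 planted interactions

train <- c(which(sim$labels == 0)[1:800], which(sim$labels == 1)[1:500])
test  <- setdiff(seq_along(sim$labels), train)
dm_tr <- dosage_matrix(sim$dm$values[train, ], rownames(sim$dm$values)[train])
dm_te <- dosage_matrix(sim$dm$values[test, ],  rownames(sim$dm$values)[test])

model <- labs_fit(dm_tr, sim$labels[train], D = 60, T1 = 0.25, T2 = 1, T3 = 0.5)
model
#> labs_model: D=60 features, 20 retained singles, 4 pair patterns, 7 blocks; |V| = 27, T = 0

roc_auc(labs_predict(model, dm_te)$R, sim$labels[test])
#> roc_result: AUC = 0.7619 (554 thresholds)
roc_auc(sim$true_L[test], sim$labels[test])   # Bayes-optimal reference
#> roc_result: AUC = 0.7718 (11 thresholds)

fpt <- fpt_scan(binarize(dm_tr), sim$labels[train], q_level = 0.05)
sum(fpt$significant, na.rm = TRUE)
#> [1] 4
```

The fitted classifier keeps 20 of 60 ranked indicator features, folds 4
surviving pair patterns into 7 blocks, and its held-out AUC (0.76) sits
within a point of the generating model's own score (0.77) — on additive
data the second-order machinery costs essentially nothing. The FPT scan of
all 19,600 cross-SNP patterns flags 4 at 5% FDR; with purely additive
simulated effects these are the expected handful of false discoveries.

Hyperparameters can be selected by stratified cross-validation over a grid
(`labs_cv`), and the evaluation protocol of repeated stratified holdout
splits is available as `repeated_holdout`.

A thin command-line interface over the same functions ships at
`inst/cli/labshdmr` (subcommands `simulate`, `rank`, `fpt`, `train`,
`predict`, `evaluate`).

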