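#' Simulate LD-blocked genotype dosages
#'
#' Gaussian-copula haplotype model: SNPs are laid out in consecutive
#' blocks; within a block the two latent haplotype draws of each sample
#' share an equicorrelated normal (`ld_rho` on the latent scale), and an
#' allele is present when its latent value falls below the MAF quantile.
#' Dosage is the sum of the two haplotype indicators, so each SNP is
#' marginally in Hardy-Weinberg equilibrium at its MAF; realized
#' dosage-scale LD is weaker than `ld_rho` and is a property of the
#' output, not a promise.
#'
#' @param n Number of samples.
#' @param n_snps Number of SNPs.
#' @param maf_range MAF drawn uniformly per SNP from this range.
#' @param ld_block_size SNPs per block (last block may be shorter).
#' @param ld_rho Latent within-block correlation, in `[0, 1)`.
#' @param seed Integer seed (mandatory: outputs are a function of
#'   configuration and seed only).
#' @return A [dosage_matrix()] with attribute `maf` (the drawn MAFs).
#' @export
simulate_genotypes <- function(n, n_snps, maf_range = c(0.05, 0.5),
                               ld_block_size = 10, ld_rho = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1L], maf_range[2L])
  thr <- stats::qnorm(maf)
  block <- rep(seq_len(ceiling(n_snps / ld_block_size)),
               each = ld_block_size)[seq_len(n_snps)]
  dos <- matrix(0L, n, n_snps)
  for (hap in 1:2) {
    z <- matrix(stats::rnorm(n * n_snps), n, n_snps)
    if (ld_rho > 0) {
      shared <- matrix(stats::rnorm(n * max(block)), n, max(block))
      z <- sqrt(ld_rho) * shared[, block, drop = FALSE] +
        sqrt(1 - ld_rho) * z
    }
    dos <- dos + (z < matrix(thr, n, n_snps, byrow = TRUE))
  }
  storage.mode(dos) <- "integer"
  colnames(dos) <- sprintf("snp%d", seq_len(n_snps))
  dm <- dosage_matrix(dos)
  attr(dm, "maf") <- maf
  dm
}

#' Simulate phenotype labels from additive indicator effects
#'
#' Logistic disease model on the binarized indicators:
#' `P(y = 1 | x) = plogis(intercept + sum_f beta_ge1 1{x_f >= 1} +
#' beta_eq2 1{x_f = 2})`. The per-sample linear predictor is the exact
#' log-likelihood ratio of the generative model (up to the constant
#' intercept), and is returned as the Bayes-optimal reference score.
#'
#' @param dm A [dosage_matrix()] without missing values.
#' @param effects Data frame with columns `snp` (id), `beta_ge1`,
#'   `beta_eq2` (log-odds contributions of the carrier and
#'   homozygous-minor indicators).
#' @param intercept Baseline log-odds.
#' @param seed Integer seed.
#' @return List: `labels` (0/1 vector), `true_L` (linear predictor per
#'   sample), `prob` (case probability per sample).
#' @export
simulate_labels_additive <- function(dm, effects, intercept = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is.dosage_matrix(dm))
  v <- dm$values
  idx <- match(effects$snp, colnames(v))
  if (anyNA(idx)) stop("effects reference unknown SNPs: ",
                       paste(effects$snp[is.na(idx)], collapse = ", "))
  eta <- rep(intercept, nrow(v))
  for (k in seq_along(idx)) {
    x <- v[, idx[k]]
    eta <- eta + effects$beta_ge1[k] * (x >= 1L) +
      effects$beta_eq2[k] * (x == 2L)
  }
  prob <- stats::plogis(eta)
  set.seed(seed)
  labels <- stats::rbinom(length(prob), 1L, prob)
  list(labels = labels, true_L = eta, prob = prob)
}

#' Draw a correlated indicator pair for one class
#'
#' Constructs the 2x2 joint of two binary indicators with given marginals
#' and correlation `rho` (so `P(1,1) = p_i p_j + rho sqrt(p_i (1-p_i)
#' p_j (1-p_j))`), checks the Frechet bounds, and samples `n` draws.
#'
#' @param n Number of draws.
#' @param p_i,p_j Marginal probabilities of the two indicators.
#' @param rho Target correlation.
#' @return Integer matrix `n x 2` of 0/1 indicator values. (Uses the
#'   current RNG stream; seed at the caller.)
#' @export
draw_indicator_pair <- function(n, p_i, p_j, rho) {
  p11 <- p_i * p_j + rho * sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
  lo <- max(0, p_i + p_j - 1)
  hi <- min(p_i, p_j)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stop(sprintf(paste0("correlation %g infeasible for marginals ",
                        "(%g, %g): P(1,1)=%g outside Frechet bounds ",
                        "[%g, %g]"), rho, p_i, p_j, p11, lo, hi))
  p11 <- min(max(p11, lo), hi)
  p10 <- p_i - p11; p01 <- p_j - p11; p00 <- 1 - p11 - p10 - p01
  cell <- sample.int(4L, n, replace = TRUE, prob = c(p11, p10, p01, p00))
  cbind(i = as.integer(cell %in% c(1L, 2L)),
        j = as.integer(cell %in% c(1L, 3L)))
}

#' Plant a class-dependent pairwise interaction pattern
#'
#' Overwrites two SNP columns of a case/control dataset so that the
#' carrier indicators `1{X >= 1}` of the pair have within-class
#' correlation `rho0` in controls and `rho1` in cases while keeping the
#' marginals class-equal — the alternative hypothesis of the fixed
#' pattern test, invisible to any single-feature statistic. Dosages are
#' back-filled consistently with the indicator: carriers are homozygous
#' minor with the conditional Hardy-Weinberg probability
#' `p^2 / (1 - (1-p)^2)`.
#'
#' @param dm A [dosage_matrix()].
#' @param labels 0/1 labels aligned with `dm`.
#' @param snp_i,snp_j SNP ids (columns of `dm`) to overwrite.
#' @param rho0,rho1 Target within-class indicator correlations.
#' @param maf MAF used for the pair (carrier probability
#'   `1 - (1 - maf)^2`); default 0.3.
#' @param seed Integer seed.
#' @return The modified `dosage_matrix`.
#' @export
plant_pattern_interaction <- function(dm, labels, snp_i, snp_j,
                                      rho0, rho1, maf = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is.dosage_matrix(dm))
  labels <- check_labels(labels, nrow(dm$values))
  ji <- match(c(snp_i, snp_j), colnames(dm$values))
  if (anyNA(ji)) stop("SNP id not found")
  p_carrier <- 1 - (1 - maf)^2
  p_hom_given_carrier <- maf^2 / p_carrier
  set.seed(seed)
  v <- dm$values
  for (y in c(0L, 1L)) {
    idx <- which(labels == y)
    rho <- if (y == 0L) rho0 else rho1
    ind <- draw_indicator_pair(length(idx), p_carrier, p_carrier, rho)
    for (k in 1:2) {
      hom <- stats::rbinom(length(idx), 1L, p_hom_given_carrier)
      v[idx, ji[k]] <- as.integer(ind[, k] * (1L + hom))
    }
  }
  dosage_matrix(v, rownames(v), dm$snp_meta)
}

#' Simulate a complete case/control dataset
#'
#' The package's stand-in for resampled-haplotype case/control data:
#' LD-blocked dosages under Hardy-Weinberg equilibrium, a logistic
#' additive disease model on a small causal set, fixed class sizes
#' obtained by case/control sampling from a generated pool, and optional
#' planted pairwise-interaction patterns. The default profile (2000
#' controls, 1000 cases, 200 SNPs in blocks of 10, 10 causal SNPs) is a
#' scaled-down emulation of a genome-wide resampling study.
#'
#' @param n0,n1 Number of controls and cases.
#' @param n_snps,maf_range,ld_block_size,ld_rho See
#'   [simulate_genotypes()].
#' @param causal Data frame (`snp`, `beta_ge1`, `beta_eq2`) of additive
#'   effects, or an integer: that many causal SNPs are spread evenly with
#'   effects `beta_ge1 = effect_size`, `beta_eq2 = effect_size` (additive
#'   on the two indicators), alternating sign.
#' @param effect_size Per-indicator log-odds magnitude used when `causal`
#'   is a count (default 0.5).
#' @param intercept Baseline log-odds of disease in the pool.
#' @param interactions Optional data frame (`snp_i`, `snp_j`, `rho0`,
#'   `rho1`, optional `maf`) of planted interaction patterns.
#' @param seed Integer seed.
#' @return List of class `labs_sim`: `dm` ([dosage_matrix()]), `labels`,
#'   `true_L` (exact log-likelihood ratio of the additive model; `NA` for
#'   samples whose interaction columns were overwritten), `causal`,
#'   `interactions`.
#' @export
simulate_dataset <- function(n0 = 2000, n1 = 1000, n_snps = 200,
                             maf_range = c(0.05, 0.5), ld_block_size = 10,
                             ld_rho = 0.3, causal = 10, effect_size = 0.5,
                             intercept = -1, interactions = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  # oversampled pool so both classes reach their quota
  pool_n <- max(4L * (n0 + n1), 2000L)
  dm_pool <- simulate_genotypes(pool_n, n_snps, maf_range, ld_block_size,
                                ld_rho, seed = seeds[1L])
  if (is.numeric(causal) && length(causal) == 1L) {
    k <- as.integer(causal)
    snp_idx <- if (k > 0) unique(round(seq(1, n_snps, length.out = k))) else integer(0)
    causal <- data.frame(
      snp = colnames(dm_pool$values)[snp_idx],
      beta_ge1 = effect_size * rep_len(c(1, -1), length(snp_idx)),
      beta_eq2 = effect_size * rep_len(c(1, -1), length(snp_idx)),
      stringsAsFactors = FALSE)
  }
  sim <- if (nrow(causal) > 0)
    simulate_labels_additive(dm_pool, causal, intercept, seed = seeds[2L])
  else {
    set.seed(seeds[2L])
    list(labels = stats::rbinom(pool_n, 1L, stats::plogis(intercept)),
         true_L = rep(0, pool_n))
  }
  i0 <- which(sim$labels == 0L); i1 <- which(sim$labels == 1L)
  if (length(i0) < n0 || length(i1) < n1)
    stop("pool too small for requested class sizes; adjust intercept")
  take <- c(i0[seq_len(n0)], i1[seq_len(n1)])
  dm <- subset_dm(dm_pool, take)
  labels <- sim$labels[take]
  true_L <- sim$true_L[take]
  if (!is.null(interactions) && nrow(interactions) > 0) {
    set.seed(seeds[3L])
    iseeds <- sample.int(.Machine$integer.max - 1L, nrow(interactions))
    for (r in seq_len(nrow(interactions))) {
      m <- if ("maf" %in% names(interactions)) interactions$maf[r] else 0.3
      dm <- plant_pattern_interaction(
        dm, labels, interactions$snp_i[r], interactions$snp_j[r],
        interactions$rho0[r], interactions$rho1[r], maf = m,
        seed = iseeds[r])
    }
    true_L <- rep(NA_real_, length(labels))  # closed form no longer exact
  }
  structure(list(dm = dm, labels = labels, true_L = true_L,
                 causal = causal, interactions = interactions),
            class = "labs_sim")
}

#' @export
print.labs_sim <- function(x, ...) {
  cat(sprintf("labs_sim: %d controls / %d cases, %d SNPs, %d causal, %d planted interactions\n",
              sum(x$labels == 0L), sum(x$labels == 1L), ncol(x$dm$values),
              nrow(x$causal), if (is.null(x$interactions)) 0L else nrow(x$interactions)))
  invisible(x)
}
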