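#' Binarize a dosage matrix into indicator features
#'
#' Each SNP with dosage in `{0, 1, 2}` is expanded into two binary
#' features: the carrier indicator `1{X >= 1}` (kind `"GE1"`) and the
#' homozygous-minor indicator `1{X = 2}` (kind `"EQ2"`). A dominant SNP is
#' captured by the first, a recessive SNP by the second, and the pair
#' reconstructs the dosage as `GE1 + EQ2`.
#'
#' @param dm A [dosage_matrix()] without missing entries (see
#'   [impute_mode()]).
#' @return An object of class `binarized_matrix`: list with `values`
#'   (binary integer matrix, samples x 2k, columns ordered SNP by SNP with
#'   GE1 before EQ2) and `feature_meta` (data frame: `feature`,
#'   `parent_snp`, `kind`).
#' @export
binarize <- function(dm) {
  stopifnot(is.dosage_matrix(dm))
  v <- dm$values
  if (anyNA(v))
    stop("dosage matrix contains missing entries; impute first (impute_mode)")
  k <- ncol(v)
  out <- matrix(0L, nrow = nrow(v), ncol = 2L * k)
  out[, seq(1L, 2L * k, by = 2L)] <- (v >= 1L) + 0L
  out[, seq(2L, 2L * k, by = 2L)] <- (v == 2L) + 0L
  snp <- colnames(v)
  feat <- as.vector(rbind(paste0(snp, ":GE1"), paste0(snp, ":EQ2")))
  colnames(out) <- feat
  rownames(out) <- rownames(v)
  meta <- data.frame(feature = feat,
                     parent_snp = rep(snp, each = 2L),
                     kind = rep(c("GE1", "EQ2"), times = k),
                     stringsAsFactors = FALSE)
  structure(list(values = out, feature_meta = meta),
            class = "binarized_matrix")
}

#' @export
print.binarized_matrix <- function(x, ...) {
  cat(sprintf("binarized_matrix: %d samples x %d indicator features (%d SNPs)\n",
              nrow(x$values), ncol(x$values), ncol(x$values) / 2L))
  invisible(x)
}

log_multibeta <- function(a) sum(lgamma(a)) - lgamma(sum(a))

#' Dirichlet posterior mean of class-conditional category probabilities
#'
#' For category counts `n_c` observed in one class under a Dirichlet prior
#' `alpha`, the posterior mean of the category probabilities is
#' `(n_c + alpha_c) / (n + sum(alpha))`.
#'
#' @param counts Non-negative integer vector of per-category counts.
#' @param alpha Strictly positive Dirichlet hyperparameter vector, same
#'   length as `counts`.
#' @return Numeric vector of posterior means, summing to 1.
#' @export
obf_posterior_mean <- function(counts, alpha) {
  if (length(alpha) != length(counts))
    stop("alpha length must equal number of categories")
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  (counts + alpha) / (sum(counts) + sum(alpha))
}

#' Bayesian evidence for a class-distributional difference (OBF score)
#'
#' Dirichlet-multinomial Bayes factor comparing independent per-class
#' category distributions against a single shared one:
#' `K = B(alpha + c0) B(alpha + c1) / (B(alpha) B(alpha + c0 + c1))`,
#' with `B` the multivariate beta function, computed in log space. The
#' posterior probability that the feature differs between classes is
#' `pi K / (pi K + 1 - pi)` for prior association probability `pi`.
#'
#' @param counts0,counts1 Per-category counts in class 0 and class 1.
#' @param alpha Dirichlet hyperparameter vector (default `c(2, 2)`, the
#'   uniform prior over the two pair patterns a binarized SNP enters).
#' @param pi Prior probability a feature is disease associated, in (0, 1);
#'   constant across features so it never affects the ranking.
#' @return List with `log_bayes_factor`, `bayes_factor`, `posterior`.
#' @export
obf_score <- function(counts0, counts1, alpha = c(2, 2), pi = 0.05) {
  if (length(counts0) != length(counts1))
    stop("count vectors must have equal length")
  if (length(alpha) != length(counts0))
    stop("alpha length must equal number of categories")
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  if (pi <= 0 || pi >= 1) stop("pi must be in (0, 1)")
  logK <- log_multibeta(alpha + counts0) + log_multibeta(alpha + counts1) -
    log_multibeta(alpha) - log_multibeta(alpha + counts0 + counts1)
  post <- 1 / (1 + exp(log(1 - pi) - log(pi) - logK))
  list(log_bayes_factor = logK, bayes_factor = exp(logK), posterior = post)
}

# Vectorized binary-feature OBF over the columns of a binarized matrix.
# Returns one row per feature: counts, log Bayes factor and the Dirichlet
# posterior means p_hat[c, y] used downstream for risk scoring.
obf_scan_binary <- function(values, labels, alpha = c(2, 2), pi = 0.05) {
  labels <- check_labels(labels, nrow(values))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  ones1 <- colSums(values[labels == 1L, , drop = FALSE])
  ones0 <- colSums(values[labels == 0L, , drop = FALSE])
  a1 <- alpha[1L]; a0 <- alpha[2L]  # alpha[1] pairs with category 1
  lmb <- function(x1, x0) lgamma(x1) + lgamma(x0) - lgamma(x1 + x0)
  logK <- lmb(a1 + ones0, a0 + n0 - ones0) +
    lmb(a1 + ones1, a0 + n1 - ones1) -
    lmb(a1, a0) - lmb(a1 + ones0 + ones1, a0 + (n0 - ones0) + (n1 - ones1))
  s <- sum(alpha)
  data.frame(
    feature = colnames(values),
    log_bayes_factor = logK,
    posterior = 1 / (1 + exp(log(1 - pi) - log(pi) - logK)),
    p1_y1 = (ones1 + a1) / (n1 + s),
    p0_y1 = (n1 - ones1 + a0) / (n1 + s),
    p1_y0 = (ones0 + a1) / (n0 + s),
    p0_y0 = (n0 - ones0 + a0) / (n0 + s),
    stringsAsFactors = FALSE)
}

#' Rank binarized features by OBF evidence
#'
#' Scores every column of a binarized matrix with the Dirichlet-multinomial
#' Bayes factor and returns the ranking (descending log Bayes factor, ties
#' kept in input column order).
#'
#' @param bm A [binarize()]d matrix.
#' @param labels 0/1 phenotype labels, one per sample.
#' @param top Number of top features to retain (`D`); counts binarized
#'   features, so `top = 2 * k` keeps everything. `NULL` ranks all.
#' @param alpha,pi Passed to the per-feature score; see [obf_score()].
#' @return Data frame (one row per retained feature, ranked): `feature`,
#'   `parent_snp`, `kind`, `column` (index into `bm$values`),
#'   `log_bayes_factor`, `posterior`, and posterior mean probabilities
#'   `p1_y1`, `p0_y1`, `p1_y0`, `p0_y0` (`p<c>_y<y>` is P(X = c | class y)).
#' @export
obf_rank <- function(bm, labels, top = NULL, alpha = c(2, 2), pi = 0.05) {
  stopifnot(inherits(bm, "binarized_matrix"))
  res <- obf_scan_binary(bm$values, labels, alpha = alpha, pi = pi)
  res$parent_snp <- bm$feature_meta$parent_snp
  res$kind <- bm$feature_meta$kind
  res$column <- seq_len(nrow(res))
  ord <- order(-res$log_bayes_factor, res$column)
  res <- res[ord, c("feature", "parent_snp", "kind", "column",
                    "log_bayes_factor", "posterior",
                    "p1_y1", "p0_y1", "p1_y0", "p0_y0")]
  rownames(res) <- NULL
  if (!is.null(top)) {
    if (top <= 0) stop("top must be positive")
    if (top > nrow(res)) stop("top exceeds number of binarized features")
    res <- res[seq_len(top), ]
  }
  res
}
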