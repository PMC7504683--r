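#' Sample correlation of two binary indicators (phi coefficient)
#'
#' Pearson correlation of two 0/1 vectors, which for binary data is the
#' phi coefficient of the 2x2 contingency table.
#'
#' @param a,b Binary (0/1) vectors of equal length >= 2.
#' @return Numeric correlation, or `NA` with attribute
#'   `degenerate = TRUE` when either vector is constant.
#' @export
indicator_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 observations")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(structure(NA_real_, degenerate = TRUE))
  stats::cor(a, b)
}

#' Fisher's r-to-z transformation
#'
#' `z = 0.5 log((1 + rho) / (1 - rho)) = atanh(rho)`. Correlations with
#' `|rho| >= 1 - 1e-7` are clamped to `+-(1 - 1e-7)` before the transform
#' (flagged via attribute `clamped`) so downstream p-values stay finite.
#'
#' @param rho Correlation(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) stop("|rho| must be <= 1")
  lim <- 1 - 1e-7
  clamped <- !is.na(rho) & abs(rho) >= lim
  rho[clamped] <- sign(rho[clamped]) * lim
  structure(atanh(rho), clamped = clamped)
}

#' Fixed-pattern two-sample correlation test statistic
#'
#' Tests whether a pair-pattern's within-class indicator correlation
#' differs between classes:
#' `Z = (z1 - z0) / sqrt(1/(n0 - 3) + 1/(n1 - 3))` with `z_y` the Fisher
#' transform of the class-`y` correlation; `Z` is approximately standard
#' normal under the null of equal correlations. Two-sided p-value.
#'
#' @param rho0,rho1 Within-class sample correlations (vectors allowed).
#' @param n0,n1 Class sample sizes, both `> 3`.
#' @return List with `Z` and `p`.
#' @export
fpt_statistic <- function(rho0, rho1, n0, n1) {
  if (n0 <= 3 || n1 <= 3) stop("insufficient class size: need n_y > 3")
  z0 <- as.numeric(fisher_z(rho0))
  z1 <- as.numeric(fisher_z(rho1))
  Z <- (z1 - z0) / sqrt(1 / (n0 - 3) + 1 / (n1 - 3))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Classic step-up procedure: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, reject all tests with `p <= p_(k*)` where `k* = max{k : p_(k)
#' <= k q / m}`. Adjusted q-values are the standard monotone BH values
#' (via [stats::p.adjust()]), and the rejection set equals
#' `q <= q_level`.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA`s allowed; excluded from
#'   the family and never rejected).
#' @param q_level Target false discovery rate.
#' @return List with `q` (adjusted values) and `reject` (logical).
#' @export
benjamini_hochberg <- function(p, q_level = 0.05) {
  if (length(p) == 0L) return(list(q = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= q_level)
}

# correlations between all column pairs of a binary matrix, via crossprod;
# returns list(rho = D x D matrix, constant = logical per column)
phi_matrix <- function(m) {
  n <- nrow(m)
  s <- colSums(m)
  cp <- crossprod(m)                       # n11 counts
  num <- n * cp - tcrossprod(s)
  den <- sqrt(tcrossprod(s * (n - s)))
  rho <- num / den
  constant <- s == 0 | s == n
  rho[constant, ] <- NA
  rho[, constant] <- NA
  list(rho = rho, constant = constant)
}

#' Scan all feature-pair patterns with the Fixed Pattern Test
#'
#' For every unordered pair of binarized features from distinct parent
#' SNPs, and each of the four value patterns `(c_i, c_j)` in `{0,1}^2`,
#' tests whether the within-class correlation of the indicators
#' `1{f_i = c_i}`, `1{f_j = c_j}` differs between classes. Since
#' complementing an indicator only flips the correlation's sign, the four
#' patterns of one pair share `|Z|`; all four are still reported and
#' counted as separate tests in the BH family (`4 * choose(D, 2)`
#' candidates). Patterns involving a constant indicator in either class
#' are reported as `SKIPPED_DEGENERATE` and excluded from the family.
#'
#' @param bm A [binarize()]d matrix, or any 0/1 matrix with column names;
#'   optionally restricted to ranked features first.
#' @param labels 0/1 phenotype labels.
#' @param q_level FDR level for the BH correction (default 0.05).
#' @param features Optional character vector or index of columns to scan
#'   (e.g. top-D ranked features).
#' @return Data frame, one row per (pair, pattern): `feature_i`,
#'   `feature_j`, `c_i`, `c_j`, `rho0`, `rho1`, `Z`, `p`, `q`,
#'   `significant`, `status`.
#' @export
fpt_scan <- function(bm, labels, q_level = 0.05, features = NULL) {
  if (inherits(bm, "binarized_matrix")) {
    values <- bm$values
    parent <- bm$feature_meta$parent_snp
  } else {
    values <- as.matrix(bm)
    if (is.null(colnames(values)))
      colnames(values) <- paste0("f", seq_len(ncol(values)))
    parent <- colnames(values)
  }
  names(parent) <- colnames(values)
  if (!is.null(features)) values <- values[, features, drop = FALSE]
  parent <- parent[colnames(values)]
  labels <- check_labels(labels, nrow(values))
  D <- ncol(values)
  if (D < 2L) stop("need at least 2 features to scan")
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 <= 3 || n1 <= 3) stop("insufficient class size: need n_y > 3")

  ph0 <- phi_matrix(values[labels == 0L, , drop = FALSE])
  ph1 <- phi_matrix(values[labels == 1L, , drop = FALSE])

  ij <- which(upper.tri(matrix(0, D, D)), arr.ind = TRUE)
  keep <- parent[ij[, 1L]] != parent[ij[, 2L]]  # intra-SNP pairs excluded
  ij <- ij[keep, , drop = FALSE]
  rho0_11 <- ph0$rho[ij]
  rho1_11 <- ph1$rho[ij]

  # pattern (c_i, c_j): indicator complementation flips sign per zero
  pat <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  sgn <- c(1, -1, -1, 1)
  np <- nrow(ij)
  res <- data.frame(
    feature_i = rep(colnames(values)[ij[, 1L]], times = 4L),
    feature_j = rep(colnames(values)[ij[, 2L]], times = 4L),
    c_i = rep(pat[, 1L], each = np),
    c_j = rep(pat[, 2L], each = np),
    rho0 = rep(rho0_11, times = 4L) * rep(sgn, each = np),
    rho1 = rep(rho1_11, times = 4L) * rep(sgn, each = np),
    stringsAsFactors = FALSE)
  ok <- !is.na(res$rho0) & !is.na(res$rho1)
  res$Z <- NA_real_; res$p <- NA_real_
  if (any(ok)) {
    st <- fpt_statistic(res$rho0[ok], res$rho1[ok], n0, n1)
    res$Z[ok] <- st$Z
    res$p[ok] <- st$p
  }
  bh <- benjamini_hochberg(res$p, q_level)
  res$q <- bh$q
  res$significant <- bh$reject
  res$status <- ifelse(ok, "TESTED", "SKIPPED_DEGENERATE")
  res
}
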