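#' Single-feature risks from OBF posterior probabilities
#'
#' For each binarized feature the risk magnitude is
#' `v = max(|log(p1_y1 / p1_y0)|, |log(p0_y1 / p0_y0)|)` over the two
#' category patterns, where `p<c>_y<y>` is the Dirichlet posterior mean of
#' `P(X = c | class y)`. The signed risk `r` takes the sign of the
#' log-ratio at the maximizing pattern: positive (risk increasing) when
#' the pattern is more probable in cases than controls. Features with
#' `|r| < T1` are flagged for removal.
#'
#' @param ranked Data frame from [obf_rank()] (needs the `p*_y*` columns).
#' @param T1 Removal threshold on `|r|`.
#' @return `ranked` with columns `v`, `r`, `argmax_c`, `retained` added.
#' @export
compute_feature_risks <- function(ranked, T1 = 0) {
  l1 <- log(ranked$p1_y1 / ranked$p1_y0)
  l0 <- log(ranked$p0_y1 / ranked$p0_y0)
  use1 <- abs(l1) >= abs(l0)
  ranked$v <- pmax(abs(l1), abs(l0))
  ranked$r <- ifelse(use1, l1, l0)
  ranked$argmax_c <- ifelse(use1, 1L, 0L)
  ranked$retained <- abs(ranked$r) >= T1
  ranked
}

#' Pair-pattern risks over selected binarized features
#'
#' For each unordered pair of features from distinct parent SNPs and each
#' value pattern `(c_i, c_j)` in `{0,1}^2`, the pair risk is
#' `r = log(p_pair(1) / p_pair(0)) - log(p_i(c_i,1) / p_i(c_i,0)) -
#' log(p_j(c_j,1) / p_j(c_j,0))`, where `p_pair(y)` is the smoothed joint
#' pattern probability in class `y` (Dirichlet posterior mean with
#' add-one smoothing over the 4 joint cells) and the single-feature terms
#' come from the OBF posteriors. A pair of class-conditionally independent
#' features contributes `r = 0` and so never enters the classifier.
#'
#' @param values 0/1 matrix of the selected features (samples x D),
#'   columns named.
#' @param labels 0/1 labels.
#' @param ranked Risk table from [compute_feature_risks()] aligned to the
#'   columns of `values` (matched by feature name).
#' @param T2 Removal threshold on `|r|`.
#' @return Data frame, one row per retained (pair, pattern): `i`, `j`
#'   (column indices), `feature_i`, `feature_j`, `c_i`, `c_j`, `r`.
#' @export
compute_pair_risks <- function(values, labels, ranked, T2 = 0) {
  labels <- check_labels(labels, nrow(values))
  D <- ncol(values)
  if (D < 2L) return(data.frame(i = integer(0), j = integer(0),
                                feature_i = character(0),
                                feature_j = character(0),
                                c_i = integer(0), c_j = integer(0),
                                r = numeric(0)))
  m <- match(colnames(values), ranked$feature)
  if (anyNA(m)) stop("feature missing from risk table")
  parent <- ranked$parent_snp[m]
  # single-feature log-ratio per pattern c: log(p_c,1 / p_c,0)
  l1 <- log(ranked$p1_y1 / ranked$p1_y0)[m]
  l0 <- log(ranked$p0_y1 / ranked$p0_y0)[m]

  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  pair_logratio <- function(cls_values, n_y) {
    n11 <- crossprod(cls_values)                       # D x D
    s <- colSums(cls_values)
    n10 <- outer(s, rep(1, D)) - n11                   # X_i=1, X_j=0
    n01 <- outer(rep(1, D), s) - n11
    n00 <- n_y - n11 - n10 - n01
    lapply(list(`11` = n11, `10` = n10, `01` = n01, `00` = n00),
           function(nn) log((nn + 1) / (n_y + 4)))
  }
  lp1 <- pair_logratio(values[labels == 1L, , drop = FALSE], n1)
  lp0 <- pair_logratio(values[labels == 0L, , drop = FALSE], n0)

  ij <- which(upper.tri(matrix(0, D, D)), arr.ind = TRUE)
  ij <- ij[parent[ij[, 1L]] != parent[ij[, 2L]], , drop = FALSE]
  pats <- list(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  out <- vector("list", 4L)
  for (k in seq_along(pats)) {
    ci <- pats[[k]][1L]; cj <- pats[[k]][2L]
    key <- paste0(ci, cj)
    li <- if (ci == 1L) l1 else l0
    lj <- if (cj == 1L) l1 else l0
    r <- (lp1[[key]][ij] - lp0[[key]][ij]) - li[ij[, 1L]] - lj[ij[, 2L]]
    out[[k]] <- data.frame(i = ij[, 1L], j = ij[, 2L],
                           c_i = ci, c_j = cj, r = r)
  }
  res <- do.call(rbind, out)
  res$feature_i <- colnames(values)[res$i]
  res$feature_j <- colnames(values)[res$j]
  res <- res[abs(res$r) >= T2 & res$r != 0, ]
  rownames(res) <- NULL
  res[, c("i", "j", "feature_i", "feature_j", "c_i", "c_j", "r")]
}

#' Merge retained feature pairs into anchored blocks
#'
#' For each anchor feature `f` and pattern `(c1, c2)`, the risk-increasing
#' block `P` collects retained pairs with positive risk in which `f` takes
#' `c1` and the partner takes `c2`; the risk-decreasing block `N`
#' collects those with negative risk. Each retained pair therefore
#' belongs to exactly two blocks, anchored at either feature with the
#' mirrored pattern. A sample's block value is the fraction of member
#' pairs whose pattern it exhibits. The block risk is
#' `r_A = log((m1 + e1) / (m0 + e0))` with `m_y` the class-`y` training
#' mean of that fraction and stabilizer `e_y = 1 / (2 n_y)`; blocks with
#' `|r_A| < T3` are dropped.
#'
#' @param pairs Retained pairs from [compute_pair_risks()].
#' @param values 0/1 matrix of the selected features (training samples).
#' @param labels 0/1 labels.
#' @param T3 Removal threshold on `|r_A|`.
#' @return List of blocks; each has `anchor` (column index), `c1`, `c2`,
#'   `polarity` (`"P"`/`"N"`), `partners` (column indices), `r_A`.
#' @export
build_blocks <- function(pairs, values, labels, T3 = 0) {
  labels <- check_labels(labels, nrow(values))
  if (nrow(pairs) == 0L) return(list())
  # each pair joins the block anchored at i with (c_i, c_j) and at j with (c_j, c_i)
  long <- rbind(
    data.frame(anchor = pairs$i, partner = pairs$j,
               c1 = pairs$c_i, c2 = pairs$c_j, r = pairs$r),
    data.frame(anchor = pairs$j, partner = pairs$i,
               c1 = pairs$c_j, c2 = pairs$c_i, r = pairs$r))
  long$polarity <- ifelse(long$r > 0, "P", "N")
  key <- paste(long$anchor, long$c1, long$c2, long$polarity, sep = "|")
  groups <- split(seq_len(nrow(long)), key)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  e1 <- 1 / (2 * n1); e0 <- 1 / (2 * n0)
  is1 <- labels == 1L
  blocks <- list()
  for (g in groups) {
    anchor <- long$anchor[g[1L]]
    c1 <- long$c1[g[1L]]; c2 <- long$c2[g[1L]]
    partners <- long$partner[g]
    ratio <- block_ratio(values, anchor, c1, partners, c2)
    m1 <- mean(ratio[is1]); m0 <- mean(ratio[!is1])
    r_A <- log((m1 + e1) / (m0 + e0))
    if (abs(r_A) >= T3) {
      blocks[[length(blocks) + 1L]] <-
        list(anchor = anchor, c1 = c1, c2 = c2,
             polarity = long$polarity[g[1L]], partners = partners,
             r_A = r_A)
    }
  }
  blocks
}

# per-sample fraction of a block's member pairs whose pattern fires
block_ratio <- function(values, anchor, c1, partners, c2) {
  av <- values[, anchor]
  ia <- if (c1 == 1L) av else 1L - av
  pv <- values[, partners, drop = FALSE]
  if (c2 == 0L) pv <- 1L - pv
  ia * rowMeans(pv)
}

#' Assemble the classifier's feature vector V(x)
#'
#' Concatenates the retained binarized feature values (0/1) with the
#' per-sample pattern fractions of the retained blocks, in the model's
#' fixed layout.
#'
#' @param values 0/1 matrix over the model's selected features (columns
#'   aligned with the training layout).
#' @param feature_cols Column indices of the retained single features.
#' @param blocks Block list from [build_blocks()].
#' @return Numeric matrix, samples x (retained features + blocks).
#' @export
build_feature_matrix <- function(values, feature_cols, blocks) {
  parts <- list()
  if (length(feature_cols))
    parts$features <- values[, feature_cols, drop = FALSE]
  if (length(blocks)) {
    bmat <- vapply(blocks, function(b)
      block_ratio(values, b$anchor, b$c1, b$partners, b$c2),
      numeric(nrow(values)))
    if (!is.matrix(bmat)) bmat <- matrix(bmat, nrow = nrow(values))
    colnames(bmat) <- vapply(blocks, function(b)
      paste0("block:", colnames(values)[b$anchor], ":", b$c1, b$c2,
             ":", b$polarity), character(1))
    parts$blocks <- bmat
  }
  if (!length(parts)) return(matrix(numeric(0), nrow = nrow(values), ncol = 0))
  do.call(cbind, parts)
}

#' Class-mean-difference weights on the unit sphere
#'
#' Maximizes the separation of the projected class means of `V` over unit
#' vectors, whose closed-form solution is the normalized class-mean
#' difference `b* = (m1 - m0) / ||m1 - m0||`. The objective is invariant
#' to translating every `V` by a constant vector, and any positive
#' rescaling of `b` leaves the induced ROC unchanged, so the unit-norm
#' representative is reported.
#'
#' @param V Numeric matrix (samples x components).
#' @param labels 0/1 labels.
#' @return List: `b` (unit-norm weights), `m0`, `m1` (class means).
#' @export
estimate_weights <- function(V, labels) {
  labels <- check_labels(labels, nrow(V))
  m1 <- colMeans(V[labels == 1L, , drop = FALSE])
  m0 <- colMeans(V[labels == 0L, , drop = FALSE])
  diff <- m1 - m0
  nrm <- sqrt(sum(diff^2))
  if (nrm == 0) stop("non-informative representation: identical class means")
  list(b = diff / nrm, m0 = m0, m1 = m1)
}

#' Fit the LABS-HDMR-CO classifier
#'
#' End-to-end training: mode-impute missing dosages, binarize, rank
#' binarized features with the OBF Bayes factor and keep the top `D`,
#' score single-feature risks (threshold `T1`), pair-pattern risks
#' (threshold `T2`, over all top-`D` features), merge retained pairs into
#' anchored blocks (threshold `T3`), assemble `V(x)` from retained
#' features and block fractions, and set the weights to the unit-norm
#' class-mean difference. Prediction scores are `R(x) = b* . V(x)`
#' thresholded at `T`.
#'
#' @param dm Training [dosage_matrix()].
#' @param labels 0/1 labels, one per sample (both classes >= 5).
#' @param D Number of top binarized features kept (defaults to all).
#' @param T1,T2,T3 Risk thresholds for single features, pair patterns and
#'   blocks.
#' @param T Decision threshold on the risk score `R(x)` (default 0; see
#'   [labs_cv()] for data-driven selection).
#' @param alpha,pi OBF hyperparameters; see [obf_score()].
#' @param verbose Log per-stage survivor counts to stderr.
#' @return Object of class `labs_model`.
#' @export
labs_fit <- function(dm, labels, D = NULL, T1 = 0.25, T2 = 1, T3 = 0.5,
                     T = 0, alpha = c(2, 2), pi = 0.05, verbose = FALSE) {
  stopifnot(is.dosage_matrix(dm))
  labels <- check_labels(labels, nrow(dm$values))
  if (min(table(labels)) < 5L) stop("need at least 5 samples per class")
  dm <- impute_mode(dm)
  bm <- binarize(dm)
  if (is.null(D)) D <- ncol(bm$values)
  say <- function(...) if (verbose) message(sprintf(...))
  ranked <- obf_rank(bm, labels, top = D, alpha = alpha, pi = pi)
  say("OBF selection: %d of %d binarized features", nrow(ranked),
      ncol(bm$values))
  risks <- compute_feature_risks(ranked, T1 = T1)
  say("feature risks: %d of %d pass |r| >= T1", sum(risks$retained), nrow(risks))
  sel_values <- bm$values[, ranked$column, drop = FALSE]
  pairs <- compute_pair_risks(sel_values, labels, risks, T2 = T2)
  say("pair risks: %d retained pair patterns", nrow(pairs))
  blocks <- build_blocks(pairs, sel_values, labels, T3 = T3)
  say("blocks: %d retained", length(blocks))
  feature_cols <- which(risks$retained)
  V <- build_feature_matrix(sel_values, feature_cols, blocks)
  if (ncol(V) == 0L)
    stop("non-informative representation: no features or blocks retained")
  wts <- estimate_weights(V, labels)
  structure(list(
    hyper = list(D = D, T1 = T1, T2 = T2, T3 = T3, T = T,
                 alpha = alpha, pi = pi),
    features = ranked$feature,          # selected binarized features, ranked
    risks = risks,
    pairs = pairs,
    blocks = blocks,
    feature_cols = feature_cols,
    layout = colnames(V),
    b = wts$b, m0 = wts$m0, m1 = wts$m1),
    class = "labs_model")
}

#' @export
print.labs_model <- function(x, ...) {
  cat(sprintf(paste0("labs_model: D=%d features, %d retained singles, ",
                     "%d pair patterns, %d blocks; |V| = %d, T = %g\n"),
              length(x$features), length(x$feature_cols), nrow(x$pairs),
              length(x$blocks), length(x$layout), x$hyper$T))
  invisible(x)
}

# binarized values for the model's selected features, from a dosage matrix
model_feature_values <- function(model, dm) {
  stopifnot(is.dosage_matrix(dm))
  dm <- impute_mode(dm)
  bm <- binarize(dm)
  missing <- setdiff(model$features, colnames(bm$values))
  if (length(missing))
    stop("SNPs required by the model are absent: ",
         paste(unique(sub(":(GE1|EQ2)$", "", missing)), collapse = ", "))
  bm$values[, model$features, drop = FALSE]
}

#' Score and label new samples with a fitted model
#'
#' Computes `R(x) = b* . V(x)` and the decision `y_hat = 1{R(x) > T}`.
#'
#' @param model A [labs_fit()] model.
#' @param dm A [dosage_matrix()] containing all SNPs the model uses.
#' @param T Decision threshold; defaults to the model's stored `T`.
#' @return Data frame: `sample_id`, `R`, `y_hat`.
#' @export
labs_predict <- function(model, dm, T = model$hyper$T) {
  stopifnot(inherits(model, "labs_model"))
  values <- model_feature_values(model, dm)
  V <- build_feature_matrix(values, model$feature_cols, model$blocks)
  R <- as.numeric(V %*% model$b)
  data.frame(sample_id = rownames(dm$values), R = R,
             y_hat = as.integer(R > T), stringsAsFactors = FALSE)
}

#' First-order additive risk score
#'
#' Internal comparator: the purely additive score
#' `sum_f r^f x_f` over the model's top-D binarized features, ignoring all
#' pair and block structure. Useful to quantify what the second-order
#' machinery adds on interaction-driven data.
#'
#' @param model A [labs_fit()] model.
#' @param dm A [dosage_matrix()].
#' @return Numeric score vector.
#' @export
additive_score <- function(model, dm) {
  values <- model_feature_values(model, dm)
  as.numeric(values %*% model$risks$r)
}

#' Stratified cross-validation over the hyperparameter grid
#'
#' Stratified k-fold CV selecting `(D, T1, T2, T3)` by mean validation
#' AUC; ties prefer the simpler model (smaller `D`, then larger `T1`,
#' `T2`, `T3`). The final model is refit on the full data and its decision
#' threshold `T` set to maximize Youden's J on the pooled validation
#' scores of the winning grid point.
#'
#' @param dm Training [dosage_matrix()].
#' @param labels 0/1 labels.
#' @param grid Data frame with columns `D`, `T1`, `T2`, `T3` (a default
#'   grid spanning the ranges used for real GWAS data is supplied).
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param ... Further arguments to [labs_fit()].
#' @return List: `model` (refit on all data, with selected `T`), `best`
#'   (winning row), `cv` (grid with `mean_auc` per point).
#' @export
labs_cv <- function(dm, labels, grid = default_grid(), k = 5, seed = 1, ...) {
  labels <- check_labels(labels, nrow(dm$values))
  if (k < 2) stop("k must be >= 2")
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  set.seed(seed)
  folds <- integer(length(labels))
  for (y in c(0L, 1L)) {
    idx <- which(labels == y)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  grid$mean_auc <- NA_real_
  pooled <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- numeric(0)
    sc <- list()
    for (fold in seq_len(k)) {
      tr <- folds != fold
      res <- tryCatch({
        m <- labs_fit(subset_dm(dm, tr), labels[tr],
                      D = grid$D[gi], T1 = grid$T1[gi],
                      T2 = grid$T2[gi], T3 = grid$T3[gi], ...)
        p <- labs_predict(m, subset_dm(dm, !tr))
        list(auc = roc_auc(p$R, labels[!tr])$auc,
             scores = data.frame(R = p$R, y = labels[!tr]))
      }, error = function(e) NULL)
      if (!is.null(res)) {
        aucs <- c(aucs, res$auc)
        sc[[length(sc) + 1L]] <- res$scores
      }
    }
    if (length(aucs) == k) {
      grid$mean_auc[gi] <- mean(aucs)
      pooled[[gi]] <- do.call(rbind, sc)
    }
  }
  if (all(is.na(grid$mean_auc)))
    stop("no grid point produced a model on every fold")
  ord <- order(-grid$mean_auc, grid$D, -grid$T1, -grid$T2, -grid$T3)
  best <- ord[1L]
  ps <- pooled[[best]]
  T_star <- youden_threshold(ps$R, ps$y)
  model <- labs_fit(dm, labels, D = grid$D[best], T1 = grid$T1[best],
                    T2 = grid$T2[best], T3 = grid$T3[best], T = T_star, ...)
  list(model = model, best = grid[best, ], cv = grid)
}

#' Default hyperparameter grid
#'
#' Spans the ranges appropriate for GWAS-scale data, including the values
#' typically selected on real dosage datasets (`D` of 900 or 1250,
#' `T1 = 0.25`, `T2` of 1-1.2, `T3` of 0.5-0.8). `D` counts binarized
#' features.
#'
#' @return Data frame over `D`, `T1`, `T2`, `T3`.
#' @export
default_grid <- function() {
  expand.grid(D = c(250, 500, 900, 1250), T1 = c(0, 0.25, 0.5),
              T2 = c(0.8, 1.0, 1.2), T3 = c(0.5, 0.8),
              KEEP.OUT.ATTRS = FALSE)
}

# threshold maximizing tpr - fpr; midpoint convention between score levels
youden_threshold <- function(scores, labels) {
  o <- order(scores)
  s <- scores[o]; y <- labels[o]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  # candidate cut after position i: predict 1 for scores > s[i]
  tp <- n1 - cumsum(y == 1L)
  fp <- n0 - cumsum(y == 0L)
  j <- tp / n1 - fp / n0
  last <- !duplicated(s, fromLast = TRUE)  # only cuts at level boundaries
  j[!last] <- -Inf
  best <- which.max(c(n1 / n1 - n0 / n0, j))  # leading option: predict all 1
  if (best == 1L) return(min(s) - 1)
  i <- best - 1L
  if (i == length(s)) s[i] + 1 else (s[i] + s[i + 1L]) / 2
}

subset_dm <- function(dm, idx) {
  dosage_matrix(dm$values[idx, , drop = FALSE],
                rownames(dm$values)[idx], dm$snp_meta)
}

#' Write / read a fitted model as structured text
#'
#' JSON serialization that survives a text-only round trip exactly
#' (numbers stored at full precision).
#'
#' @param model A `labs_model`.
#' @param path File path.
#' @return `read_labs_model` returns the restored `labs_model`.
#' @export
write_labs_model <- function(model, path) {
  stopifnot(inherits(model, "labs_model"))
  obj <- unclass(model)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_labs_model
#' @export
read_labs_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$format_version)) stop("not a labs_model file")
  obj$format_version <- NULL
  obj$risks <- as.data.frame(obj$risks, stringsAsFactors = FALSE)
  obj$pairs <- as.data.frame(obj$pairs, stringsAsFactors = FALSE)
  obj$blocks <- lapply(obj$blocks, function(b) {
    b$partners <- as.integer(b$partners)
    b$anchor <- as.integer(b$anchor)
    b
  })
  obj$feature_cols <- as.integer(obj$feature_cols)
  obj$b <- stats::setNames(as.numeric(obj$b), obj$layout)
  obj$m0 <- stats::setNames(as.numeric(obj$m0), obj$layout)
  obj$m1 <- stats::setNames(as.numeric(obj$m1), obj$layout)
  structure(obj, class = "labs_model")
}
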