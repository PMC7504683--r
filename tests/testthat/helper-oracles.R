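# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (recursion, enumeration, pair counting) and
# must stay independent of the package's own code paths.

# HDMR components for *independent* inputs via the classical recursion:
# f_u(x_u) = E[f | X_u = x_u] - sum_{v strictly inside u} f_v(x_v).
# Returns, per subset key "i,j,..." (variable indices), the component value
# expanded to every cell of the full grid.
hdmr_recursion_oracle <- function(joint, d) {
  nv <- length(joint$supports)
  f0 <- sum(joint$w * joint$f)
  subsets <- unlist(lapply(seq_len(d), function(k)
    utils::combn(nv, k, simplify = FALSE)), recursive = FALSE)
  cond_exp <- function(u) {
    key <- interaction(joint$grid[u], drop = FALSE)
    wg <- tapply(joint$w, key, sum)
    fg <- tapply(joint$w * joint$f, key, sum)
    (fg / wg)[as.character(key)]
  }
  cellvals <- list()
  for (u in subsets) {
    v <- cond_exp(u) - f0
    for (vs in subsets) {
      if (length(vs) < length(u) && all(vs %in% u))
        v <- v - cellvals[[paste(vs, collapse = ",")]]
    }
    cellvals[[paste(u, collapse = ",")]] <- as.numeric(v)
  }
  cellvals
}

# expand a fitted hdmr_expansion component to full-grid cell values
component_on_grid <- function(expansion, joint, key) {
  comp <- expansion$components[[key]]
  u <- match(comp$variables, names(joint$supports))
  sel <- joint$grid[u]
  tab <- comp$table
  idx <- rep(1L, nrow(joint$grid))
  mult <- 1L
  for (q in seq_along(u)) {
    idx <- idx + (match(sel[[q]], joint$supports[[u[q]]]) - 1L) * mult
    mult <- mult * length(joint$supports[[u[q]]])
  }
  tab$value[idx]
}

# constrained least-squares by an independent route: re-derive the
# constraint matrix from first principles, parameterize its null space
# (base-R svd) and solve the reduced weighted least-squares problem.
# Returns fitted values and the achieved weighted squared error.
hdmr_nullspace_oracle <- function(joint, d) {
  nv <- length(joint$supports)
  sizes <- lengths(joint$supports)
  grid <- joint$grid
  n_cells <- nrow(grid)
  subsets <- if (d >= 1) unlist(lapply(seq_len(d), function(k)
    utils::combn(nv, k, simplify = FALSE)), recursive = FALSE) else list()
  cols <- list(rep(1, n_cells))
  cons <- list()
  col_subset <- c(0L)
  for (u in subsets) {
    ug <- expand.grid(lapply(u, function(v) joint$supports[[v]]),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    block_cols <- integer(0)
    for (r in seq_len(nrow(ug))) {
      ind <- rep(TRUE, n_cells)
      for (q in seq_along(u)) ind <- ind & (grid[[u[q]]] == ug[r, q])
      cols[[length(cols) + 1L]] <- as.numeric(ind)
      block_cols <- c(block_cols, length(cols))
      col_subset <- c(col_subset, length(cons) + 1L)  # placeholder
    }
    # vanishing constraints: sum over categories of each i in u, per value
    # of the remaining coordinates, weighted by the marginal of w on u
    w_u <- numeric(nrow(ug))
    for (r in seq_len(nrow(ug))) {
      ind <- rep(TRUE, n_cells)
      for (q in seq_along(u)) ind <- ind & (grid[[u[q]]] == ug[r, q])
      w_u[r] <- sum(joint$w[ind])
    }
    for (i in seq_along(u)) {
      rest <- ug[, -i, drop = FALSE]
      rid <- if (ncol(rest) == 0L) rep(1L, nrow(ug)) else
        as.integer(interaction(rest, drop = FALSE))
      for (rv in unique(rid)) {
        row <- numeric(0)
        cons[[length(cons) + 1L]] <- list(cols = block_cols[rid == rv],
                                          vals = w_u[rid == rv])
      }
    }
  }
  A <- do.call(cbind, cols)
  P <- ncol(A)
  C <- matrix(0, length(cons), P)
  for (k in seq_along(cons)) C[k, cons[[k]]$cols] <- cons[[k]]$vals
  # null space of C
  if (nrow(C) > 0) {
    sv <- svd(C, nu = 0, nv = P)
    rank <- sum(sv$d > max(dim(C)) * max(sv$d, 0) * 1e-12)
    Z <- sv$v[, seq(rank + 1L, P), drop = FALSE]
  } else Z <- diag(P)
  B <- A %*% Z
  wts <- joint$w
  M <- crossprod(B, B * wts)
  g <- crossprod(B * wts, joint$f)
  t_hat <- MASS::ginv(M) %*% g
  fitted <- as.numeric(B %*% t_hat)
  list(fitted = fitted,
       error = sum(wts * (fitted - joint$f)^2),
       nullspace = Z, basis = B, A = A)
}

# O(n^2) pair-counting AUC
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# literal BH step-up decisions
bh_step_up_oracle <- function(p, q_level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q_level / m)
  reject <- logical(m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# random fully-supported joint over binary variables
random_binary_joint <- function(n_var, seed) {
  set.seed(seed)
  supports <- setNames(rep(list(0:1), n_var), paste0("x", seq_len(n_var)))
  n_cells <- 2^n_var
  w <- rgamma(n_cells, 1); w <- w / sum(w)
  categorical_joint(supports, w, f = rnorm(n_cells))
}

# random *independent-input* binary joint
random_independent_joint <- function(n_var, seed) {
  set.seed(seed)
  ps <- runif(n_var, 0.2, 0.8)
  supports <- setNames(rep(list(0:1), n_var), paste0("x", seq_len(n_var)))
  grid <- expand.grid(supports)
  w <- rep(1, nrow(grid))
  for (i in seq_len(n_var)) w <- w * ifelse(grid[[i]] == 1, ps[i], 1 - ps[i])
  categorical_joint(supports, w, f = rnorm(nrow(grid)))
}

# weighted squared error of an expansion against its joint
expansion_error <- function(expansion, joint) {
  sum(joint$w * (expansion$fitted - joint$f)^2)
}

# max hierarchical-orthogonality residual (Eq.-3 style): every component
# against every indicator of a strict subset of its variables
max_orthogonality_residual <- function(expansion, joint) {
  res <- 0
  for (key in names(expansion$components)) {
    comp <- expansion$components[[key]]
    u <- comp$variables
    fu <- component_on_grid(expansion, joint, key)
    subs <- unlist(lapply(seq_len(length(u) - 1L), function(k)
      utils::combn(u, k, simplify = FALSE)), recursive = FALSE)
    subs <- c(subs, list(character(0)))  # includes the constant function
    for (v in subs) {
      if (length(v) == 0L) {
        res <- max(res, abs(sum(fu * joint$w)))
      } else {
        vg <- expand.grid(lapply(v, function(nm) joint$supports[[nm]]),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        for (r in seq_len(nrow(vg))) {
          ind <- rep(TRUE, nrow(joint$grid))
          for (q in seq_along(v)) ind <- ind & (joint$grid[[v[q]]] == vg[r, q])
          res <- max(res, abs(sum(fu[ind] * joint$w[ind])))
        }
      }
    }
  }
  res
}

# row-subset of a dosage matrix (mirrors the package-internal helper)
subset_dm_for_test <- function(dm, idx) {
  dosage_matrix(dm$values[idx, , drop = FALSE],
                rownames(dm$values)[idx], dm$snp_meta)
}
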