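#' Enumerable categorical joint distribution with a target function
#'
#' Container for an exactly enumerable system: a finite categorical random
#' vector `X` with pmf `w` over the product space, and a real-valued target
#' `Z = f(X)` defined on the same space. Cells are laid out in
#' [expand.grid()] order (first variable fastest).
#'
#' @param supports Named list; one entry per variable giving its category
#'   values (each a vector of length >= 2, or >= 1).
#' @param w Numeric vector of cell probabilities over the product space
#'   (length `prod(sizes)`); must be non-negative and sum to 1 within
#'   `1e-10`.
#' @param f Numeric vector of target values on the same cells; must be
#'   finite wherever `w > 0`.
#' @param cap Maximum admissible product-space size (default `1e6`).
#' @return Object of class `categorical_joint`: `supports`, `grid` (cell
#'   data frame), `w`, `f`.
#' @export
categorical_joint <- function(supports, w, f, cap = 1e6) {
  if (is.null(names(supports)) || any(names(supports) == ""))
    stop("supports must be a fully named list")
  sizes <- lengths(supports)
  if (any(sizes < 1L)) stop("empty support")
  n_cells <- prod(sizes)
  if (n_cells > cap) stop(sprintf("product space (%g cells) exceeds cap %g",
                                  n_cells, cap))
  if (length(w) != n_cells || length(f) != n_cells)
    stop("w and f must cover the full product space")
  if (any(w < 0)) stop("negative probability in w")
  if (abs(sum(w) - 1) > 1e-10) stop("w does not sum to 1")
  if (any(w > 0 & !is.finite(f)))
    stop("f must be finite on the support of w")
  grid <- expand.grid(supports, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(supports = supports, grid = grid,
                 w = as.numeric(w), f = as.numeric(f)),
            class = "categorical_joint")
}

#' @export
print.categorical_joint <- function(x, ...) {
  cat(sprintf("categorical_joint: %d variables, %d cells, support size %d\n",
              length(x$supports), length(x$w), sum(x$w > 0)))
  invisible(x)
}

#' Log-likelihood-ratio target from two class-conditional pmfs
#'
#' Builds the table `L(x) = log(P(y=1|x) / P(y=0|x)) =
#' log(w1(x) p1) - log(w0(x) p0)` on the shared product space. Cells where
#' exactly one class has mass get `+Inf`/`-Inf` (kept, flagged); cells
#' outside both supports get `NA`.
#'
#' @param w0,w1 Class-conditional cell pmfs (same layout).
#' @param prior Class prior `c(p0, p1)`, summing to 1.
#' @return List: `L` (numeric vector, possibly infinite), `infinite`
#'   (logical flag vector), `excluded` (cells with `w0 = w1 = 0`).
#' @export
loglik_ratio_table <- function(w0, w1, prior = c(0.5, 0.5)) {
  if (length(w0) != length(w1)) stop("w0 and w1 must share a layout")
  if (abs(sum(prior) - 1) > 1e-10) stop("class prior must sum to 1")
  if (any(w0 < 0) || any(w1 < 0)) stop("negative probability")
  L <- log(w1 * prior[2L]) - log(w0 * prior[1L])
  excluded <- w0 == 0 & w1 == 0
  L[excluded] <- NA_real_
  list(L = L, infinite = is.infinite(L), excluded = excluded)
}

#' Joint for binary classification of a categorical vector
#'
#' Convenience wrapper: mixes class-conditional pmfs into the marginal
#' input law `w = p0 w0 + p1 w1` and sets the target to the
#' log-likelihood ratio. Cells where `L` is infinite may be clipped
#' (required for the HDMR least-squares target to be finite).
#'
#' @inheritParams categorical_joint
#' @param w0,w1 Class-conditional cell pmfs over `supports`.
#' @param prior Class prior `c(p0, p1)`.
#' @param clip If finite, infinite `L` values are clipped to `+-clip`;
#'   default `Inf` (no clipping, errors if one-sided zeros occur).
#' @return A [categorical_joint()] whose `f` is `L`, with attributes
#'   `w0`, `w1`, `prior` retained.
#' @export
classification_joint <- function(supports, w0, w1, prior = c(0.5, 0.5),
                                 clip = Inf) {
  lt <- loglik_ratio_table(w0, w1, prior)
  L <- lt$L
  if (any(lt$infinite)) {
    if (!is.finite(clip))
      stop("one-sided zero-probability cells produce infinite L; set clip")
    L[L == Inf] <- clip
    L[L == -Inf] <- -clip
  }
  w <- prior[1L] * w0 + prior[2L] * w1
  L[lt$excluded] <- 0  # zero-weight cells; value immaterial
  joint <- categorical_joint(supports, w, L)
  joint$w0 <- w0
  joint$w1 <- w1
  joint$prior <- prior
  joint
}

all_subsets <- function(n_var, d) {
  out <- list()
  for (k in seq_len(min(d, n_var))) {
    cmb <- utils::combn(n_var, k)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
  }
  out
}

subset_key <- function(u, names) paste(names[u], collapse = ",")

# Index of each cell's restriction to variables u, as an integer in
# 1..prod(sizes[u]) (u's own expand.grid order).
cell_u_index <- function(grid_idx, u, sizes) {
  idx <- grid_idx[, u[1L]]
  if (length(u) > 1L) {
    mult <- 1L
    for (j in seq_along(u)[-1L]) {
      mult <- mult * sizes[u[j - 1L]]
      idx <- idx + (grid_idx[, u[j]] - 1L) * mult
    }
  }
  idx
}

#' Exact HDMR expansion of a categorical joint
#'
#' Computes the order-`d` high dimensional model representation of
#' `Z = f(X)` under the (possibly dependent) input law `w`: the component
#' functions `f_u` over all variable subsets `|u| <= d` minimizing the
#' weighted squared error `sum_x w(x) (f_0 + sum_u f_u(x_u) - f(x))^2`
#' subject to the vanishing conditions — for every component `u`, every
#' `i` in `u` and every fixed value of the remaining coordinates of `u`,
#' the `w`-weighted sum of `f_u` over the categories of `x_i` is zero.
#' These conditions are equivalent to hierarchical orthogonality: each
#' `f_u` is orthogonal under `w` to every function of a strict subset of
#' `u`. All components are solved simultaneously as one
#' equality-constrained least-squares (KKT) system; the Moore-Penrose
#' inverse yields the minimum-norm solution when zero-probability cells
#' leave coefficients unidentified.
#'
#' @param joint A [categorical_joint()].
#' @param d Expansion order, `0 <= d <=` number of variables.
#' @return Object of class `hdmr_expansion`: `order`, `f0`, `components`
#'   (named list keyed by comma-joined variable names; each has `table`
#'   (data frame of category combinations and `value`) and `unsupported`
#'   (flag per row: marginal probability zero)), plus `supports` and the
#'   fitted values `fitted` on the full grid.
#' @export
hdmr_expand <- function(joint, d) {
  stopifnot(inherits(joint, "categorical_joint"))
  n_var <- length(joint$supports)
  if (d < 0 || d > n_var) stop("order d must be between 0 and the number of variables")
  sizes <- lengths(joint$supports)
  vnames <- names(joint$supports)
  n_cells <- length(joint$w)
  grid_idx <- vapply(seq_len(n_var),
                     function(j) match(joint$grid[[j]], joint$supports[[j]]),
                     integer(n_cells))
  if (!is.matrix(grid_idx)) grid_idx <- matrix(grid_idx, nrow = n_cells)

  subsets <- if (d >= 1L) all_subsets(n_var, d) else list()
  # parameter layout: intercept, then per subset its C_u cells
  p_sizes <- vapply(subsets, function(u) prod(sizes[u]), numeric(1))
  offsets <- cumsum(c(1, p_sizes))  # offsets[j]+1 .. offsets[j+1] for subset j
  P <- 1L + sum(p_sizes)

  A <- matrix(0, n_cells, P)
  A[, 1L] <- 1
  for (j in seq_along(subsets)) {
    u <- subsets[[j]]
    ui <- cell_u_index(grid_idx, u, sizes)
    A[cbind(seq_len(n_cells), offsets[j] + ui)] <- 1
  }

  # constraint rows: subset u, drop variable i, one row per value of u \ {i}
  cons <- list()
  for (j in seq_along(subsets)) {
    u <- subsets[[j]]
    ui <- cell_u_index(grid_idx, u, sizes)
    w_u <- as.numeric(tapply(joint$w, ui, sum))  # marginal on C_u
    n_u <- prod(sizes[u])
    # category index within C_u for each of its cells
    ugrid <- expand.grid(lapply(u, function(v) seq_len(sizes[v])),
                         KEEP.OUT.ATTRS = FALSE)
    for (i in seq_along(u)) {
      rest <- ugrid[, -i, drop = FALSE]
      rid <- if (ncol(rest) == 0L) rep(1L, n_u) else
        as.integer(interaction(rest, drop = FALSE))
      for (r in unique(rid)) {
        row <- numeric(P)
        sel <- rid == r
        row[offsets[j] + which(sel)] <- w_u[sel]
        cons[[length(cons) + 1L]] <- row
      }
    }
  }
  C <- if (length(cons)) do.call(rbind, cons) else
    matrix(0, 0, P)

  Aw <- A * joint$w
  H <- crossprod(A, Aw)            # A' W A
  g <- crossprod(Aw, joint$f)      # A' W f
  m <- nrow(C)
  KKT <- rbind(cbind(2 * H, t(C)), cbind(C, matrix(0, m, m)))
  rhs <- c(2 * g, numeric(m))
  sol <- MASS::ginv(KKT) %*% rhs
  q <- sol[seq_len(P)]

  comps <- list()
  for (j in seq_along(subsets)) {
    u <- subsets[[j]]
    ui <- cell_u_index(grid_idx, u, sizes)
    w_u <- as.numeric(tapply(joint$w, ui, sum))
    tab <- expand.grid(joint$supports[u], KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    tab$value <- q[offsets[j] + seq_len(prod(sizes[u]))]
    comps[[subset_key(u, vnames)]] <- list(
      variables = vnames[u], table = tab, unsupported = w_u == 0)
  }
  structure(list(order = d, f0 = q[1L], components = comps,
                 supports = joint$supports,
                 fitted = as.numeric(A %*% q)),
            class = "hdmr_expansion")
}

#' @export
print.hdmr_expansion <- function(x, ...) {
  cat(sprintf("hdmr_expansion: order %d, f0 = %.6g, %d component functions\n",
              x$order, x$f0, length(x$components)))
  invisible(x)
}

#' Evaluate an HDMR expansion at a point
#'
#' Returns `f_0 + sum_u f_u(x_u)` for one category tuple.
#'
#' @param expansion An [hdmr_expand()] result.
#' @param x Named list or vector of category values, one per variable.
#' @return Numeric scalar.
#' @export
hdmr_reconstruct <- function(expansion, x) {
  stopifnot(inherits(expansion, "hdmr_expansion"))
  vnames <- names(expansion$supports)
  if (is.null(names(x))) names(x) <- vnames
  val <- expansion$f0
  for (comp in expansion$components) {
    tab <- comp$table
    sel <- rep(TRUE, nrow(tab))
    for (v in comp$variables) sel <- sel & (tab[[v]] == x[[v]])
    if (sum(sel) != 1L) stop("point not in product space")
    val <- val + tab$value[sel]
  }
  val
}

#' Component variances of an HDMR expansion
#'
#' `w`-weighted variance contribution of each component (its weighted mean
#' square, since components have weighted mean zero).
#'
#' @param expansion An [hdmr_expand()] result.
#' @param joint The [categorical_joint()] it was computed from.
#' @return Named numeric vector of `sum_x w(x) f_u(x_u)^2` per component.
#' @export
hdmr_component_variances <- function(expansion, joint) {
  sizes <- lengths(joint$supports)
  n_cells <- length(joint$w)
  grid_idx <- vapply(seq_along(joint$supports),
                     function(j) match(joint$grid[[j]], joint$supports[[j]]),
                     integer(n_cells))
  if (!is.matrix(grid_idx)) grid_idx <- matrix(grid_idx, nrow = n_cells)
  out <- numeric(0)
  for (key in names(expansion$components)) {
    comp <- expansion$components[[key]]
    u <- match(comp$variables, names(joint$supports))
    ui <- cell_u_index(grid_idx, u, sizes)
    vals <- comp$table$value[ui]
    out[key] <- sum(joint$w * vals^2)
  }
  out
}

#' Sobol sensitivity indices by exact enumeration
#'
#' Total effect `S(u) = var(E(Z|X_u)) / var(Z)` and main effect
#' `S_c(u) = 1 - var(E(Z|X_{-u})) / var(Z)`, both computed by exact
#' summation over the joint.
#'
#' @param joint A [categorical_joint()].
#' @param u Variable subset: names or indices.
#' @return List with `S` (total effect) and `Sc` (main effect).
#' @export
sobol_indices <- function(joint, u) {
  stopifnot(inherits(joint, "categorical_joint"))
  vnames <- names(joint$supports)
  if (is.character(u)) u <- match(u, vnames)
  if (anyNA(u) || length(u) == 0L) stop("unknown variable in u")
  mu <- sum(joint$w * joint$f)
  varZ <- sum(joint$w * (joint$f - mu)^2)
  if (varZ <= 0) stop("constant target: var(Z) = 0")
  var_cond <- function(set) {
    if (length(set) == 0L) return(0)
    key <- interaction(joint$grid[set], drop = FALSE)
    wg <- tapply(joint$w, key, sum)
    fg <- tapply(joint$w * joint$f, key, sum)
    keep <- !is.na(wg) & wg > 0
    cond <- fg[keep] / wg[keep]
    sum(wg[keep] * (cond - mu)^2)
  }
  S <- var_cond(u) / varZ
  Sc <- 1 - var_cond(setdiff(seq_along(vnames), u)) / varZ
  list(S = S, Sc = Sc)
}

#' Pairwise interaction ratio and covariance identity
#'
#' For a 2x2 (or general two-way) class-conditional pmf and a fixed pattern
#' `(c_i, c_j)`, computes `k = P(X_i = c_i, X_j = c_j) /
#' (P(X_i = c_i) P(X_j = c_j))` together with the indicator covariance,
#' and verifies the identity `cov = (k - 1) P_i P_j`.
#'
#' @param pmf Matrix of joint probabilities, rows indexing categories of
#'   the first variable, columns of the second.
#' @param c_i,c_j Pattern categories: dimname value or index.
#' @return List: `k`, `cov`, `P_i`, `P_j`, `identity_gap`
#'   (`cov - (k-1) P_i P_j`, analytically 0), `defined` (FALSE when a
#'   marginal is zero, in which case `k` is `NA`).
#' @export
interaction_ratio <- function(pmf, c_i, c_j) {
  pmf <- as.matrix(pmf)
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-10)
    stop("pmf must be a probability table")
  ri <- if (is.character(c_i)) match(c_i, rownames(pmf)) else c_i
  cj <- if (is.character(c_j)) match(c_j, colnames(pmf)) else c_j
  if (is.na(ri) || is.na(cj)) stop("pattern category not found")
  P_i <- sum(pmf[ri, ]); P_j <- sum(pmf[, cj])
  p_joint <- pmf[ri, cj]
  cov <- p_joint - P_i * P_j
  if (P_i == 0 || P_j == 0)
    return(list(k = NA_real_, cov = cov, P_i = P_i, P_j = P_j,
                identity_gap = NA_real_, defined = FALSE))
  k <- p_joint / (P_i * P_j)
  list(k = k, cov = cov, P_i = P_i, P_j = P_j,
       identity_gap = cov - (k - 1) * P_i * P_j, defined = TRUE)
}
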