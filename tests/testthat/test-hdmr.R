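test_that("single-variable decomposition is exact", {
  j <- categorical_joint(list(x = 0:1), c(0.3, 0.7), c(2, 5))
  e <- hdmr_expand(j, 1)
  expect_equal(e$f0, 0.3 * 2 + 0.7 * 5)
  expect_equal(e$components[["x"]]$table$value, c(2, 5) - e$f0,
               tolerance = 1e-10)
  expect_equal(e$fitted, c(2, 5), tolerance = 1e-10)
})

test_that("XOR decomposes into a pure pairwise component", {
  j <- categorical_joint(list(x1 = 0:1, x2 = 0:1), rep(0.25, 4),
                         c(0, 1, 1, 0))
  e <- hdmr_expand(j, 2)
  expect_equal(e$f0, 0.5, tolerance = 1e-12)
  expect_lt(max(abs(e$components[["x1"]]$table$value)), 1e-12)
  expect_lt(max(abs(e$components[["x2"]]$table$value)), 1e-12)
  tab <- e$components[["x1,x2"]]$table
  expect_equal(tab$value[tab$x1 != tab$x2], c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(tab$value[tab$x1 == tab$x2], c(-0.5, -0.5), tolerance = 1e-12)
  # truncation at order 1 predicts the mean everywhere
  e1 <- hdmr_expand(j, 1)
  expect_equal(e1$fitted, rep(0.5, 4), tolerance = 1e-10)
  expect_equal(hdmr_reconstruct(e1, list(x1 = 1, x2 = 0)), 0.5,
               tolerance = 1e-10)
  # Sobol: no main effect, all variance in the pair
  expect_equal(sobol_indices(j, "x1")$S, 0, tolerance = 1e-12)
  expect_equal(sobol_indices(j, c("x1", "x2"))$S, 1, tolerance = 1e-12)
})

test_that("independent-input components follow the recursion oracle", {
  for (seed in 11:14) {
    nv <- if (seed %% 2) 3L else 4L
    j <- random_independent_joint(nv, seed)
    e <- hdmr_expand(j, nv)
    orc <- hdmr_recursion_oracle(j, nv)
    for (key in names(e$components)) {
      u <- match(e$components[[key]]$variables, names(j$supports))
      expect_equal(component_on_grid(e, j, key),
                   orc[[paste(u, collapse = ",")]], tolerance = 1e-10)
    }
    # variance decomposition at full order for independent inputs
    mu <- sum(j$w * j$f)
    expect_equal(sum(hdmr_component_variances(e, j)),
                 sum(j$w * (j$f - mu)^2), tolerance = 1e-8)
  }
})

test_that("components of dependent joints satisfy hierarchical orthogonality", {
  for (seed in 21:24) {
    j <- random_binary_joint(3 + seed %% 2, seed)
    d <- 2
    e <- hdmr_expand(j, d)
    expect_lt(max_orthogonality_residual(e, j), 1e-8)
    # full order reconstructs f exactly on the support
    ef <- hdmr_expand(j, length(j$supports))
    expect_lt(max(abs(ef$fitted - j$f)[j$w > 0]), 1e-8)
  }
})

test_that("truncated expansion attains the constrained least-squares optimum", {
  for (seed in 31:33) {
    j <- random_binary_joint(3, seed)
    e <- hdmr_expand(j, 2)
    orc <- hdmr_nullspace_oracle(j, 2)
    expect_equal(expansion_error(e, j), orc$error, tolerance = 1e-8)
    # random feasible perturbations never do better
    set.seed(seed)
    for (rep in 1:5) {
      pert <- orc$nullspace %*% rnorm(ncol(orc$nullspace), sd = 0.3)
      alt_fit <- orc$fitted + as.numeric(orc$A %*% pert)
      expect_gte(sum(j$w * (alt_fit - j$f)^2),
                 expansion_error(e, j) - 1e-10)
    }
  }
})

test_that("order-0 expansion is the weighted mean", {
  j <- random_binary_joint(3, 41)
  e <- hdmr_expand(j, 0)
  expect_equal(e$f0, sum(j$w * j$f))
  expect_equal(unique(round(e$fitted, 12)), round(e$f0, 12))
})

test_that("sobol indices flag independence and determinism", {
  # Z depends only on x1: S({x2}) = 0, S({x1}) = 1
  j <- categorical_joint(list(x1 = 0:1, x2 = 0:1),
                         c(0.2, 0.3, 0.2, 0.3), c(1, 5, 1, 5))
  expect_equal(sobol_indices(j, "x2")$S, 0, tolerance = 1e-12)
  expect_equal(sobol_indices(j, "x1")$S, 1, tolerance = 1e-12)
  expect_equal(sobol_indices(j, c("x1", "x2"))$S, 1, tolerance = 1e-12)
  jconst <- categorical_joint(list(x = 0:1), c(0.5, 0.5), c(2, 2))
  expect_error(sobol_indices(jconst, "x"), "constant target")
})

test_that("log-likelihood-ratio tables follow the definition", {
  lt <- loglik_ratio_table(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(lt$L, c(0, 0))
  lt2 <- loglik_ratio_table(c(0.05, 0.95), c(0.2, 0.8))
  expect_equal(lt2$L[1], log(4))
  # swapping classes negates L
  expect_equal(loglik_ratio_table(c(0.2, 0.8), c(0.05, 0.95))$L, -lt2$L)
  # one-sided zeros flagged infinite; shared zeros excluded
  lt3 <- loglik_ratio_table(c(0, 0.5, 0.5, 0), c(0.25, 0.25, 0.5, 0))
  expect_true(lt3$infinite[1])
  expect_true(lt3$excluded[4])
  expect_error(loglik_ratio_table(c(1, 0), c(1, 0), prior = c(0.7, 0.5)),
               "sum to 1")
})

test_that("no-interaction joints have a vanishing pairwise component", {
  # additive L over two dependent-free binary inputs: build class pmfs by
  # exponential tilting so that L(x) = a1 x1 + a2 x2 + const
  p <- c(0.4, 0.6); q <- c(0.45, 0.55)
  w0 <- outer(p, q)
  a1 <- 0.8; a2 <- -0.5
  tilt <- outer(exp(a1 * (0:1)), exp(a2 * (0:1)))
  w1 <- w0 * tilt; w1 <- w1 / sum(w1)
  j <- classification_joint(list(x1 = 0:1, x2 = 0:1),
                            as.numeric(w0), as.numeric(w1))
  e <- hdmr_expand(j, 2)
  expect_lt(max(abs(e$components[["x1,x2"]]$table$value)), 1e-10)
  # conditional-expectation additivity (the no-interaction condition)
  # implies the closed second-order index of the pair equals the sum of
  # singletons' contributions; equivalently L is reproduced at order 1
  e1 <- hdmr_expand(j, 1)
  expect_lt(max(abs(e1$fitted - j$f)), 1e-10)
})

test_that("interaction ratio verifies the covariance identity", {
  # independent pair
  ind <- outer(c(0.3, 0.7), c(0.6, 0.4))
  r <- interaction_ratio(ind, 1, 1)
  expect_equal(r$k, 1)
  expect_equal(r$cov, 0)
  # frozen example: P(1,1)=0.2 with P_i=0.4, P_j=0.25 gives k=2, cov=0.1
  pmf <- matrix(c(0.2, 0.05, 0.2, 0.55), 2, 2,
                dimnames = list(c("1", "0"), c("1", "0")))
  r2 <- interaction_ratio(pmf, "1", "1")
  expect_equal(r2$k, 2)
  expect_equal(r2$cov, 0.1)
  expect_equal(r2$cov, (r2$k - 1) * r2$P_i * r2$P_j)
  # identity holds on random 2x2 pmfs
  set.seed(6)
  for (i in 1:100) {
    w <- rgamma(4, 1); w <- matrix(w / sum(w), 2, 2)
    rr <- interaction_ratio(w, 1, 1)
    expect_lt(abs(rr$identity_gap), 1e-12)
  }
  # zero marginal is flagged undefined
  degen <- matrix(c(0, 0, 0.5, 0.5), 2, 2)
  expect_false(interaction_ratio(degen, 1, 1)$defined)
})

test_that("product-space cap and pmf validation are enforced", {
  expect_error(categorical_joint(list(x = 0:1), c(0.6, 0.6), c(1, 2)),
               "sum to 1")
  expect_error(categorical_joint(setNames(rep(list(0:1), 21),
                                          paste0("x", 1:21)),
                                 rep(1 / 2^21, 2^21), rep(0, 2^21),
                                 cap = 1e6),
               "exceeds cap")
})
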