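# risk table with given posterior probabilities, for closed-form checks
risk_row <- function(p1_y1, p1_y0, feature = "f1", parent = "s1") {
  data.frame(feature = feature, parent_snp = parent, kind = "GE1",
             column = 1L, log_bayes_factor = 0, posterior = 0,
             p1_y1 = p1_y1, p0_y1 = 1 - p1_y1,
             p1_y0 = p1_y0, p0_y0 = 1 - p1_y0,
             stringsAsFactors = FALSE)
}

test_that("feature risks take the larger log-ratio with its sign", {
  # p11=0.3, p10=0.1, p01=0.7, p00=0.9: v = log 3 at c=1, risk increasing
  r <- compute_feature_risks(risk_row(0.3, 0.1), T1 = 0.5)
  expect_equal(r$v, log(3))
  expect_equal(r$r, log(3))
  expect_equal(r$argmax_c, 1L)
  expect_true(r$retained)
  # identical posteriors: zero risk, removed at any positive threshold
  r0 <- compute_feature_risks(risk_row(0.4, 0.4), T1 = 1e-9)
  expect_equal(r0$r, 0)
  expect_false(r0$retained)
  # swapping class labels negates the risk
  rs <- compute_feature_risks(risk_row(0.1, 0.3), T1 = 0)
  expect_equal(rs$r, -log(3))
})

test_that("pair risks vanish for class-wise independent features and match a count oracle", {
  set.seed(12)
  n <- 300
  labels <- rep(0:1, n / 2)
  vals <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.3),
                c = rbinom(n, 1, 0.5))
  ranked <- obf_rank(structure(list(values = vals,
                                    feature_meta = data.frame(
                                      feature = colnames(vals),
                                      parent_snp = colnames(vals),
                                      kind = "GE1")),
                               class = "binarized_matrix"), labels)
  risks <- compute_feature_risks(ranked, T1 = 0)
  vals_o <- vals[, ranked$feature]
  pr <- compute_pair_risks(vals_o, labels, risks, T2 = 0)
  expect_equal(nrow(pr), 4 * choose(3, 2))
  # oracle: recompute each risk from raw counts
  for (row in seq_len(nrow(pr))) {
    i <- pr$i[row]; j <- pr$j[row]; ci <- pr$c_i[row]; cj <- pr$c_j[row]
    lr_pair <- sapply(0:1, function(y) {
      nIn <- sum(vals_o[labels == y, i] == ci & vals_o[labels == y, j] == cj)
      log((nIn + 1) / (sum(labels == y) + 4))
    })
    single <- function(col, cc) {
      m <- match(colnames(vals_o)[col], ranked$feature)
      if (cc == 1) log(ranked$p1_y1[m] / ranked$p1_y0[m])
      else log(ranked$p0_y1[m] / ranked$p0_y0[m])
    }
    expect_equal(pr$r[row],
                 (lr_pair[2] - lr_pair[1]) - single(i, ci) - single(j, cj),
                 tolerance = 1e-12)
  }
  # exchange symmetry of the pair with its pattern
  p12 <- pr[pr$i == 1 & pr$j == 2 & pr$c_i == 1 & pr$c_j == 0, "r"]
  expect_length(p12, 1L)
  # population-level independence: risks concentrate near zero
  expect_lt(max(abs(pr$r)), 0.5)
})

test_that("intra-SNP pairs never produce pair risks", {
  dm <- dosage_matrix(matrix(sample(0:2, 200, replace = TRUE), 100, 2,
                             dimnames = list(NULL, c("s1", "s2"))))
  labels <- rep(0:1, 50)
  bm <- binarize(dm)
  ranked <- obf_rank(bm, labels)
  risks <- compute_feature_risks(ranked, 0)
  pr <- compute_pair_risks(bm$values[, ranked$feature], labels, risks, T2 = 0)
  meta <- setNames(bm$feature_meta$parent_snp, bm$feature_meta$feature)
  expect_true(all(meta[pr$feature_i] != meta[pr$feature_j]))
  expect_equal(nrow(pr), 4 * 4)  # 2x2 cross-SNP feature pairs, 4 patterns
})

test_that("blocks aggregate member pairs and score class ratio of firing", {
  # construct 2 features whose (1,1) pattern fires mostly in cases
  set.seed(13)
  n <- 400
  labels <- rep(0:1, n / 2)
  vals <- cbind(f1 = integer(n), f2 = integer(n), f3 = rbinom(n, 1, 0.5))
  on <- labels == 1 & rbinom(n, 1, 0.8) == 1
  off <- labels == 0 & rbinom(n, 1, 0.2) == 1
  vals[on | off, c("f1", "f2")] <- 1L
  pairs <- data.frame(i = 1L, j = 2L, feature_i = "f1", feature_j = "f2",
                      c_i = 1L, c_j = 1L, r = 2)
  blocks <- build_blocks(pairs, vals, labels, T3 = 0)
  expect_length(blocks, 2L)  # anchored at each member feature
  anchors <- sort(sapply(blocks, `[[`, "anchor"))
  expect_equal(anchors, c(1L, 2L))
  b <- blocks[[1]]
  expect_equal(b$polarity, "P")
  # r_A equals the stabilized log ratio of class means of the firing fraction
  fire <- vals[, 1] * vals[, 2]
  m1 <- mean(fire[labels == 1]); m0 <- mean(fire[labels == 0])
  eps <- 1 / (2 * (n / 2))
  expect_equal(b$r_A, log((m1 + eps) / (m0 + eps)))
  # a block of 4 members firing 2 gives ratio 0.5
  vals4 <- cbind(a = 1L, p1 = 1L, p2 = 1L, p3 = 0L, p4 = 0L)
  V <- build_feature_matrix(rbind(vals4, vals4),
                            integer(0),
                            list(list(anchor = 1L, c1 = 1L, c2 = 1L,
                                      polarity = "P", partners = 2:5,
                                      r_A = 1)))
  expect_equal(unname(V[, 1]), c(0.5, 0.5))
  # empty pair list yields no blocks
  expect_length(build_blocks(pairs[0, ], vals, labels, 0), 0L)
})

test_that("feature vectors concatenate retained features then block ratios", {
  vals <- cbind(f1 = c(1L, 0L), f2 = c(0L, 1L), f3 = c(1L, 1L))
  blocks <- list(list(anchor = 1L, c1 = 1L, c2 = 1L, polarity = "P",
                      partners = c(2L, 3L), r_A = 1))
  V <- build_feature_matrix(vals, c(1L, 2L), blocks)
  expect_equal(dim(V), c(2L, 3L))
  expect_equal(unname(V[1, ]), c(1, 0, 0.5))  # pattern fires on f3 only
  expect_equal(unname(V[2, ]), c(0, 1, 0))    # anchor is 0: ratio 0
})

test_that("weights are the unit-norm class-mean difference", {
  V <- rbind(c(0.8, 0.2), c(0.8, 0.2), c(0.2, 0.2), c(0.2, 0.2))
  labels <- c(1, 1, 0, 0)
  w <- estimate_weights(V, labels)
  expect_equal(unname(w$b), c(1, 0))
  # 1-D case: sign of the mean difference
  w1 <- estimate_weights(cbind(c(0.7, 0.7, 0.3, 0.3)), labels)
  expect_equal(unname(w1$b), 1)
  # translation invariance
  w2 <- estimate_weights(sweep(V, 2, c(5, -3), "+"), labels)
  expect_equal(w2$b, w$b)
  expect_error(estimate_weights(matrix(1, 4, 2), labels),
               "non-informative")
})

test_that("fit records hyperparameters, predicts deterministically, and errors on empty V", {
  sim <- simulate_dataset(n0 = 150, n1 = 150, n_snps = 20, causal = 3,
                          effect_size = 1, ld_rho = 0, seed = 77)
  m <- labs_fit(sim$dm, sim$labels, D = 20, T1 = 0.1, T2 = 1, T3 = 0.5)
  expect_equal(m$hyper$D, 20)
  expect_equal(m$hyper$T2, 1)
  expect_equal(length(m$layout), length(m$b))
  p1 <- labs_predict(m, sim$dm)
  p2 <- labs_predict(m, sim$dm)
  expect_identical(p1, p2)
  expect_identical(p1$y_hat, as.integer(p1$R > m$hyper$T))
  # threshold limits
  expect_true(all(labs_predict(m, sim$dm, T = Inf)$y_hat == 0L))
  expect_true(all(labs_predict(m, sim$dm, T = -Inf)$y_hat == 1L))
  # sample-order invariance of scores
  perm <- rev(seq_along(sim$labels))
  pp <- labs_predict(m, subset_dm_for_test(sim$dm, perm))
  expect_equal(pp$R[match(p1$sample_id, pp$sample_id)], p1$R)
  # impossible thresholds leave nothing in V
  expect_error(labs_fit(sim$dm, sim$labels, T1 = 50, T2 = 50, T3 = 50),
               "non-informative")
  # missing SNPs are reported by name
  dm_small <- dosage_matrix(sim$dm$values[, 1:5],
                            rownames(sim$dm$values), sim$dm$snp_meta[1:5, ])
  expect_error(labs_predict(m, dm_small), "absent")
})

test_that("null data yield chance-level test AUC", {
  sim <- simulate_dataset(n0 = 400, n1 = 400, n_snps = 30, causal = 0,
                          intercept = 0, ld_rho = 0, seed = 88)
  tr <- c(which(sim$labels == 0)[1:250], which(sim$labels == 1)[1:250])
  te <- setdiff(seq_along(sim$labels), tr)
  m <- labs_fit(subset_dm_for_test(sim$dm, tr), sim$labels[tr],
                T1 = 0, T2 = 0.5, T3 = 0)
  auc <- roc_auc(labs_predict(m, subset_dm_for_test(sim$dm, te))$R,
                 sim$labels[te])$auc
  expect_gt(auc, 0.38)
  expect_lt(auc, 0.62)
})

test_that("a risk-increasing planted SNP receives positive risk", {
  pos <- 0L
  for (rep in 1:20) {
    # minor-allele regime: at MAF <= 0.15 the carrier pattern dominates
    # the absence pattern, so the planted risk allele gets r > 0
    sim <- simulate_dataset(n0 = 500, n1 = 500, n_snps = 10, ld_rho = 0,
                            maf_range = c(0.05, 0.15),
                            causal = data.frame(snp = "snp5",
                                                beta_ge1 = 0.8,
                                                beta_eq2 = 0.8),
                            intercept = -0.5, seed = 300 + rep)
    ranked <- obf_rank(binarize(sim$dm), sim$labels)
    risks <- compute_feature_risks(ranked, 0)
    r_ge1 <- risks$r[risks$feature == "snp5:GE1"]
    pos <- pos + (r_ge1 > 0)
  }
  expect_gte(pos / 20, 0.99)
})

test_that("cross-validation selects from the grid and honours tie-breaking", {
  sim <- simulate_dataset(n0 = 120, n1 = 120, n_snps = 15, causal = 3,
                          effect_size = 1.2, ld_rho = 0, seed = 99)
  grid <- expand.grid(D = c(10, 20), T1 = 0.1, T2 = c(1, 2), T3 = 0.5)
  res <- labs_cv(sim$dm, sim$labels, grid = grid, k = 3, seed = 5)
  expect_equal(nrow(res$cv), nrow(grid))
  expect_true(all(c("mean_auc") %in% names(res$cv)))
  expect_true(res$best$D %in% grid$D)
  expect_s3_class(res$model, "labs_model")
  # single-point grid returns that point
  res1 <- labs_cv(sim$dm, sim$labels, k = 3, seed = 5,
                  grid = data.frame(D = 20, T1 = 0.1, T2 = 1, T3 = 0.5))
  expect_equal(res1$best$D, 20)
  expect_error(labs_cv(sim$dm, sim$labels, grid = grid[0, ], k = 3),
               "empty")
  # default grid includes the values selected on real dosage datasets
  dg <- default_grid()
  expect_true(all(c(900, 1250) %in% dg$D))
  expect_true(0.25 %in% dg$T1)
  expect_true(all(c(1, 1.2) %in% dg$T2))
  expect_true(all(c(0.5, 0.8) %in% dg$T3))
})

test_that("models survive a text round trip exactly", {
  sim <- simulate_dataset(n0 = 100, n1 = 100, n_snps = 12, causal = 2,
                          effect_size = 1, ld_rho = 0, seed = 111)
  m <- labs_fit(sim$dm, sim$labels, D = 16, T1 = 0.1, T2 = 0.8, T3 = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_labs_model(m, path)
  m2 <- read_labs_model(path)
  expect_equal(m2$b, m$b)
  expect_equal(m2$hyper$T2, m$hyper$T2)
  p1 <- labs_predict(m, sim$dm)
  p2 <- labs_predict(m2, sim$dm)
  expect_equal(p2$R, p1$R)
})
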