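test_that("concentration chain has the right gamma moments", {
  dag <- fig_dag()
  set.seed(11)
  n <- 2e4
  draws <- replicate(n, sample_concentrations(dag, 5)$alpha)
  ## the child shape sums the parents' values, so the marginal mean of a
  ## node is alpha0 times its number of root-to-node paths: 1 for the root
  ## and layer 1, 2 for layer 2, 6 for node 8
  expected <- c(`1` = 5, `2` = 5, `3` = 5, `4` = 5,
                `5` = 10, `6` = 10, `7` = 10, `8` = 30)
  for (key in rownames(draws)) {
    m <- mean(draws[key, ])
    expect_lt(abs(m - expected[[key]]), 3 * mc_se(draws[key, ]))
  }
  ## root variance is alpha0
  expect_lt(abs(var(draws["1", ]) - 5), 0.2)

  ## child shape is the sum of its parents' values: condition on parents
  ## by construction with a fixed-conc two-parent graph
  dg <- group_dag(cbind(c(1, 1, 2, 3), c(2, 3, 4, 4)))
  set.seed(12)
  kid <- replicate(2e4, {
    conc <- fixed_conc(dg, c(1, 2, 3, 0))
    conc$alpha["4"] <- rgamma(1, shape = sum(conc$alpha[c("2", "3")]), rate = 1)
    conc$alpha[["4"]]
  })
  expect_lt(abs(mean(kid) - 5), 3 * mc_se(kid))
})

test_that("parent-mixture weights are Dirichlet in the parents' concentrations", {
  dg <- group_dag(cbind(c(1, 1, 2, 3), c(2, 3, 4, 4)))
  conc <- fixed_conc(dg, c(1, 2, 3, 5))
  set.seed(13)
  n <- 2e4
  w4 <- t(replicate(n, sample_parent_weights(dg, conc)[["4"]]))
  ## E[pi] = (2, 3)/5
  expect_lt(abs(mean(w4[, 1]) - 0.4), 3 * mc_se(w4[, 1]))
  expect_lt(abs(mean(w4[, 2]) - 0.6), 3 * mc_se(w4[, 2]))
  ## single-parent nodes get weight exactly one; the root has no entry
  pw <- sample_parent_weights(dg, conc)
  expect_equal(unname(pw[["2"]]), 1)
  expect_null(pw[["1"]])
})

test_that("weight-state simplices are exact and obey the tower property", {
  dag <- fig_dag()
  set.seed(14)
  conc <- sample_concentrations(dag, 5)
  w <- sample_weight_state(dag, conc, L = 2)
  expect_equal(sum(w$beta_root), 1, tolerance = 1e-10)
  for (b in w$beta) expect_equal(sum(b), 1, tolerance = 1e-10)
  for (ch in w$nu) for (nu in ch) expect_equal(sum(nu), 1, tolerance = 1e-10)
  expect_true(all(w$beta_root >= 0))

  ## chain root -> a -> b: E[beta_b | beta_root] = beta_root through the
  ## hidden chain (iterated expectations)
  cd <- chain_dag()
  conc2 <- fixed_conc(cd, c(4, 3, 6))
  set.seed(15)
  n <- 4e4
  ws <- sample_weight_state(cd, conc2, L = 4, ndraw = n)
  dev <- ws$beta[["3"]] - ws$beta_root
  for (l in 1:4) expect_lt(abs(mean(dev[, l])), 3 * mc_se(dev[, l]))
})

test_that("tiny Dirichlet shapes stay positive and normalized", {
  set.seed(16)
  x <- rdirichlet(2000, rep(5 / 30, 30))
  expect_true(all(x > 0))
  expect_equal(rowSums(x), rep(1, 2000), tolerance = 1e-10)
  ## moments still correct for symmetric Dir(1/6): E = 1/30
  expect_lt(abs(mean(x[, 1]) - 1 / 30), 3 * mc_se(x[, 1]))
  expect_error(rdirichlet(1, c(1, -1)), "positive")
})

test_that("NIW atoms have inverse-Wishart covariance moments", {
  g0 <- niw_params(c(0, 0), 0.01, diag(2), 2)
  set.seed(17)
  at <- sample_atoms(g0, 10)
  expect_equal(dim(at$means), c(10L, 2L))
  for (l in 1:10) {
    expect_true(all(eigen(at$covs[, , l], symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
  ## E[Sigma] = Psi / (df - d - 1) when df > d + 1
  g1 <- niw_params(c(0, 0), 1, diag(c(2, 3)), 6)
  s11 <- replicate(8000, sample_atoms(g1, 1)$covs[1, 1, 1])
  expect_lt(abs(mean(s11) - 2 / 3), 3 * mc_se(s11))
  ## kappa0 -> large: means pile on mean0
  g2 <- niw_params(c(1, -1), 1e8, diag(2), 6)
  at2 <- sample_atoms(g2, 5)
  expect_lt(max(abs(sweep(at2$means, 2, c(1, -1)))), 1e-2)
  expect_error(niw_params(c(0, 0), 0.01, matrix(c(1, 2, 2, 1), 2), 2),
               "positive-definite")
})

test_that("log joint decomposes over independently computed factors", {
  cd <- chain_dag()
  set.seed(18)
  conc <- sample_concentrations(cd, 5)
  L <- 3
  w <- sample_weight_state(cd, conc, L)
  g0 <- niw_params()
  atoms <- sample_atoms(g0, L)
  x <- matrix(rnorm(8), 4, 2)
  dat <- grouped_data(x, c(1, 1, 2, 3))
  z <- c(1L, 2L, 1L, 3L)

  lp <- log_joint(cd, conc, w, atoms, z, dat, g0)

  ## independent term-by-term computation
  a <- conc$alpha
  cm <- sum(a["2"])  # generation-1 ancestors of node 3 at layer 1
  ref <- dgamma(a[["1"]], 5, 1, log = TRUE) +
    dgamma(a[["2"]], a[["1"]], 1, log = TRUE) +
    dgamma(a[["3"]], a[["2"]], 1, log = TRUE) +
    dirichlet_logpdf(w$beta_root, rep(a[["1"]] / L, L)) +
    dirichlet_logpdf(w$beta[["2"]], a[["2"]] * w$beta_root) +
    dirichlet_logpdf(w$nu[["3"]][[1]], cm * w$beta_root) +
    dirichlet_logpdf(w$beta[["3"]], a[["3"]] * w$nu[["3"]][[1]])
  for (l in 1:L) {
    S <- atoms$covs[, , l]
    ref <- ref + gdpclust:::dinvwishart_log(S, g0$df, g0$Psi) +
      mvn_logpdf(atoms$means[l, ], g0$mean0, S / g0$kappa0)
  }
  bmap <- list(`1` = w$beta_root, `2` = w$beta[["2"]], `3` = w$beta[["3"]])
  for (i in 1:4) {
    gi <- as.character(dat$group[i])
    ref <- ref + log(bmap[[gi]][z[i]]) +
      mvn_logpdf(x[i, ], atoms$means[z[i], ], atoms$covs[, , z[i]])
  }
  expect_equal(lp, ref, tolerance = 1e-8)

  ## prior-only value is finite with no data
  empty <- grouped_data(matrix(numeric(0), 0, 2), integer(0))
  expect_true(is.finite(log_joint(cd, conc, w, atoms, NULL, empty, g0)))

  ## adding one observation changes the value by its two factors
  dat2 <- grouped_data(rbind(x, c(0.3, -0.2)), c(1, 1, 2, 3, 2))
  z2 <- c(z, 2L)
  delta <- log_joint(cd, conc, w, atoms, z2, dat2, g0) - lp
  expect_equal(delta,
               log(w$beta[["2"]][2]) +
                 mvn_logpdf(c(0.3, -0.2), atoms$means[2, ], atoms$covs[, , 2]),
               tolerance = 1e-8)
})

test_that("a Dirichlet mixture of Dirichlets collapses to a single Dirichlet", {
  set.seed(19)
  ## Beta(2,2) mixture of two Dir(1,1): collapsed Dir(2,2)
  out <- collapse_dirichlet_mixture(list(c(1, 1), c(1, 1)), 5e4)
  expect_equal(out$collapsed_alpha, c(2, 2))
  x1 <- out$samples[, 1]
  expect_lt(abs(mean(x1) - 0.5), 3 * mc_se(x1))
  expect_lt(abs(var(x1) - 0.05), 3 * mc_se((x1 - mean(x1))^2))

  ## Dir(2,1) + Dir(1,2) with Dir(3,3) weights -> Dir(3,3)
  out2 <- collapse_dirichlet_mixture(list(c(2, 1), c(1, 2)), 5e4)
  expect_equal(out2$collapsed_alpha, c(3, 3))
  y <- out2$samples[, 1]
  expect_lt(abs(mean(y) - 0.5), 3 * mc_se(y))
  expect_lt(abs(var(y) - 3 * 3 / (36 * 7)), 3 * mc_se((y - mean(y))^2))
  ## Kolmogorov-Smirnov distance to the collapsed Beta marginal
  ks <- suppressWarnings(ks.test(y, pbeta, 3, 3))
  expect_lt(unname(ks$statistic), 0.01)

  ## single component passes through
  out3 <- collapse_dirichlet_mixture(list(c(4, 6)), 1000)
  expect_equal(out3$collapsed_alpha, c(4, 6))
  expect_lt(abs(mean(out3$samples[, 1]) - 0.4), 0.02)
})
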