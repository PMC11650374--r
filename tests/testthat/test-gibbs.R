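test_that("logit-simplex proposals stay on the simplex with exact closure", {
  p <- c(0.2, 0.3, 0.5)
  zero <- salt_propose(p, 2, 0)
  expect_identical(zero$proposal, p)
  expect_identical(zero$log_hastings, 0)
  set.seed(41)
  for (r in 1:200) {
    i <- sample.int(3, 1)
    pr <- salt_propose(p, i, 2)
    expect_equal(sum(pr$proposal), 1, tolerance = 1e-12)
    expect_true(all(pr$proposal > 0))
    p <- pr$proposal
  }
  expect_error(salt_propose(c(0, 1), 1, 1), "degenerate")
})

test_that("Metropolis with the logit-simplex proposal targets a Dirichlet", {
  ## short version of the stationarity check (full length in acceptance)
  set.seed(42)
  target <- c(2, 3, 4)
  x <- rep(1 / 3, 3)
  lt <- function(p) sum((target - 1) * log(p))
  ltc <- lt(x)
  sums <- numeric(3)
  nst <- 6000
  for (s in seq_len(nst)) {
    for (i in 1:3) {
      pr <- salt_propose(x, i, 1.2)
      ltp <- lt(pr$proposal)
      if (log(runif(1)) < ltp - ltc + pr$log_hastings) {
        x <- pr$proposal
        ltc <- ltp
      }
    }
    sums <- sums + x
  }
  expect_lt(max(abs(sums / nst - target / 9)), 0.02)
})

test_that("NIW conjugate updates match the closed-form identities", {
  g0 <- niw_params(c(1, -1), 2, diag(c(1, 2)), 4)
  ## single observation
  y <- c(0.5, 0.2)
  p1 <- niw_posterior(g0, matrix(y, 1))
  expect_equal(p1$mean0, (2 * c(1, -1) + y) / 3)
  expect_equal(p1$kappa0, 3)
  expect_equal(p1$df, 5)
  ## five-point fixture vs brute-force sufficient statistics
  set.seed(43)
  Y <- matrix(rnorm(10), 5, 2)
  p5 <- niw_posterior(g0, Y)
  yb <- colMeans(Y)
  S <- matrix(0, 2, 2)
  for (i in 1:5) S <- S + tcrossprod(Y[i, ] - yb)
  expect_equal(p5$kappa0, 7)
  expect_equal(p5$df, 9)
  expect_equal(p5$mean0, (2 * c(1, -1) + 5 * yb) / 7)
  expect_equal(p5$Psi,
               diag(c(1, 2)) + S + (2 * 5 / 7) * tcrossprod(yb - c(1, -1)))
  ## empty data returns the prior unchanged
  expect_equal(niw_posterior(g0, matrix(numeric(0), 0, 2)), g0)

  ## sampled atoms concentrate on the posterior mean parameter
  dat <- grouped_data(Y, rep(1L, 5))
  set.seed(44)
  mu_draws <- t(replicate(3000, update_atoms(dat, rep(1L, 5), g0, 1)$means[1, ]))
  for (j in 1:2) {
    expect_lt(abs(mean(mu_draws[, j]) - p5$mean0[j]), 4 * mc_se(mu_draws[, j]))
  }
})

test_that("node-weight conditional is the documented Dirichlet", {
  base <- c(0.5, 0.3, 0.2)
  set.seed(45)
  ## counts all zero: prior draw with mean = base
  prior_draws <- t(replicate(8000, update_node_weights(c(0, 0, 0), base, 6)))
  for (l in 1:3) {
    expect_lt(abs(mean(prior_draws[, l]) - base[l]), 3 * mc_se(prior_draws[, l]))
  }
  ## E[beta_l] = (alpha nu_l + c_l) / (alpha + n)
  counts <- c(7, 1, 2)
  post_draws <- t(replicate(8000, update_node_weights(counts, base, 6)))
  expec <- (6 * base + counts) / (6 + 10)
  for (l in 1:3) {
    expect_lt(abs(mean(post_draws[, l]) - expec[l]), 3 * mc_se(post_draws[, l]))
  }
  ## huge counts dominate the prior
  big <- update_node_weights(c(8e5, 1e5, 1e5), base, 6)
  expect_lt(max(abs(big - c(0.8, 0.1, 0.1))), 0.01)
})

test_that("assignment sampling follows the weighted Gaussian posterior", {
  dag <- group_dag(NULL, nodes = 1L)
  L <- 3
  w <- structure(list(L = L, beta_root = c(1, 1e-12, 1e-12) / (1 + 2e-12),
                      nu = list(), beta = list()), class = "gdp_weights")
  atoms <- structure(list(
    means = rbind(c(0, 0), c(0, 0), c(5, 5)),
    covs = array(rep(diag(2), 3), c(2, 2, 3)), L = L, d = 2),
    class = "gdp_atoms")
  dat <- grouped_data(matrix(rnorm(40), 20, 2), rep(1L, 20))
  set.seed(46)
  ## essentially all weight on component 1
  expect_true(all(update_assignments(dat, dag, w, atoms) == 1L))

  ## two identical atoms with equal weight: assignments split 50/50
  w$beta_root <- c(0.5, 0.5, 1e-12) / (1 + 1e-12)
  z <- replicate(300, update_assignments(dat, dag, w, atoms))
  frac1 <- mean(z == 1L)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / length(z)))

  ## three atoms, hand-set weights: frequencies match the softmax of
  ## log-weight + log-density at a fixed point
  w$beta_root <- c(0.2, 0.3, 0.5)
  x0 <- c(2, 2)
  dat1 <- grouped_data(matrix(x0, 1), 1L)
  logf <- vapply(1:3, function(l) {
    -sum((x0 - atoms$means[l, ])^2) / 2 - log(2 * pi)
  }, numeric(1))
  pref <- exp(log(w$beta_root) + logf)
  pref <- pref / sum(pref)
  set.seed(47)
  zs <- replicate(4000, update_assignments(dat1, dag, w, atoms))
  for (l in 1:3) {
    expect_lt(abs(mean(zs == l) - pref[l]), 4 * sqrt(pref[l] / 4000) + 0.01)
  }
})

test_that("root-weight posterior matches an importance-sampling oracle", {
  ## two-node chain (root -> child), child holds counts; conc fixed.
  ## The exact target of the Metropolis block is
  ##   Dir(b; a_r/L) * DirMult(counts; a_c * b)
  dag <- group_dag(cbind(1, 2))
  conc <- fixed_conc(dag, c(4, 3))
  L <- 3
  counts <- list(`2` = c(6L, 2L, 0L))

  ## importance sampling on the same target, proposal = the Dirichlet prior
  set.seed(48)
  n_is <- 2e5
  b <- rdirichlet(n_is, rep(4 / L, L))
  lw <- apply(b, 1, function(bb) {
    a <- 3 * bb
    lgamma(sum(a)) - lgamma(sum(a) + 8) +
      sum(lgamma(a[1:2] + c(6, 2)) - lgamma(a[1:2]))
  })
  wgt <- exp(lw - max(lw))
  is_mean <- colSums(b * wgt) / sum(wgt)
  ess <- sum(wgt)^2 / sum(wgt^2)
  is_se <- sqrt(colSums(wgt * sweep(b, 2, is_mean)^2) / sum(wgt) / ess)

  ## Metropolis block on the same state
  set.seed(49)
  w <- gdpclust:::floor_weights(sample_weight_state(dag, conc, L))
  keep <- matrix(0, 4000, L)
  for (it in seq_len(6000)) {
    hw <- update_hidden_weights(dag, conc, w, root_counts = NULL,
                                scales = 1, counts = counts)
    w <- hw$weights
    if (it > 2000) keep[it - 2000, ] <- w$beta_root
  }
  mh_mean <- colMeans(keep)
  ## MH standard error from batch means
  bm <- rowsum(keep, rep(1:40, each = 100)) / 100
  mh_se <- apply(bm, 2, sd) / sqrt(40)
  for (l in seq_len(L)) {
    expect_lt(abs(mh_mean[l] - is_mean[l]), 3 * sqrt(is_se[l]^2 + mh_se[l]^2))
  }
})

test_that("concentration updates recover their prior without data", {
  dag <- fork_dag(3)
  set.seed(50)
  conc <- sample_concentrations(dag, 5)
  w <- gdpclust:::floor_weights(sample_weight_state(dag, conc, 4))
  draws <- numeric(4000)
  for (it in seq_len(5000)) {
    ## weights redrawn from the prior so the alpha marginal is Gamma(5, 1)
    w <- sample_weight_state(dag, conc, 4)
    cu <- update_concentrations(dag, conc, w, scales = 0.5)
    conc <- cu$conc
    if (it > 1000) draws[it - 1000] <- conc$alpha[["0"]]
  }
  expect_lt(abs(mean(draws) - 5), 0.35)
  expect_gt(cor(sort(draws), qgamma(ppoints(4000), 5, 1)), 0.99)
})

test_that("the blocked sampler keeps exact bookkeeping and reproducibility", {
  dat <- two_blob_data(n_per = 15, sep = 10, seed = 51)
  dag <- group_dag(NULL, nodes = 1L)
  cfg <- sampler_config(n_iter = 41, burn_in = 40, thin = 1, seed = 9)
  fit <- gdp_gibbs(dat, dag, niw_params(), alpha0 = 3, L = 5, config = cfg)
  expect_equal(nrow(fit$z_draws), 1L)
  expect_length(loglik_trace(fit), 1L)

  cfg2 <- sampler_config(n_iter = 120, burn_in = 40, thin = 2, seed = 9,
                         n_chains = 2)
  f1 <- gdp_gibbs(dat, dag, niw_params(), alpha0 = 3, L = 5, config = cfg2)
  f2 <- gdp_gibbs(dat, dag, niw_params(), alpha0 = 3, L = 5, config = cfg2)
  expect_identical(f1$z_draws, f2$z_draws)
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(nrow(f1$z_draws), 2L * 40L)
  ## retained root weights are exact simplices
  expect_equal(rowSums(f1$beta_root_draws), rep(1, 80), tolerance = 1e-10)
  expect_true(all(is.finite(f1$loglik_full)))

  ## a single group with two 10-sd-separated blobs is recovered exactly
  cl <- dahl_estimate(f1)
  expect_equal(adjusted_rand(cl$labels, rep(1:2, each = 15)), 1)

  ## group labels must be observed DAG nodes
  bad <- grouped_data(matrix(rnorm(4), 2), c(1L, 9L))
  expect_error(gdp_gibbs(bad, dag, niw_params(), 3, 5, cfg), "observed DAG")
})

test_that("the log-likelihood trace matches a hand computation", {
  dat <- grouped_data(rbind(c(0, 0), c(1, 1)), c(1L, 1L))
  atoms <- structure(list(means = rbind(c(0, 0), c(2, 2)),
                          covs = array(rep(diag(2), 2), c(2, 2, 2)),
                          L = 2L, d = 2L), class = "gdp_atoms")
  z <- c(1L, 2L)
  ll <- gdpclust:::loglik_given_state(dat, atoms, z)
  hand <- mvn_logpdf(c(0, 0), c(0, 0), diag(2)) +
    mvn_logpdf(c(1, 1), c(2, 2), diag(2))
  expect_equal(ll, hand, tolerance = 1e-10)
})
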