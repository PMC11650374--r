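# Independently coded truncated HDP, used as an oracle for the fork-graph
# special case. Deliberately different algorithm: the direct-assignment
# sampler with group weights integrated out and the global weights updated
# through auxiliary table counts (Antoniak/Bernoulli construction), rather
# than logit-simplex Metropolis.

# prior sampler: global weights Dir(gamma/L), group weights Dir(alpha * beta0)
hdp_prior_weights <- function(n, L, gamma0, alpha_children) {
  beta0 <- t(sapply(seq_len(n), function(i) {
    g <- rgamma(L, shape = gamma0 / L, rate = 1)
    if (all(g == 0)) g[sample.int(L, 1)] <- 1e-300
    g / sum(g)
  }))
  betas <- lapply(alpha_children, function(a) {
    g <- matrix(rgamma(n * L, shape = as.vector(t(a * beta0)), rate = 1),
                n, L, byrow = TRUE)
    g <- pmax(g, 1e-300)
    g / rowSums(g)
  })
  list(beta0 = beta0, betas = betas)
}

# NIW posterior draw for one component (own code, standard identities)
hdp_draw_atom <- function(Y, m0, k0, Psi, nu0) {
  n <- nrow(Y)
  if (n > 0) {
    yb <- colMeans(Y)
    S <- crossprod(sweep(Y, 2, yb))
    kn <- k0 + n
    mn <- (k0 * m0 + n * yb) / kn
    Pn <- Psi + S + k0 * n / kn * tcrossprod(yb - m0)
    nun <- nu0 + n
  } else {
    kn <- k0; mn <- m0; Pn <- Psi; nun <- nu0
  }
  Prec <- stats::rWishart(1, nun, solve(Pn))[, , 1]
  Sig <- solve(Prec)
  Sig <- (Sig + t(Sig)) / 2
  mu <- mn + drop(t(chol(Sig / kn)) %*% rnorm(length(m0)))
  list(mu = mu, Sigma = Sig)
}

# direct-assignment truncated HDP Gibbs; fixed concentrations
# X: pooled matrix, grp: group index 1..J
hdp_direct_gibbs <- function(X, grp, L, gamma0, alpha, m0, k0, Psi, nu0,
                             n_iter, burn_in, thin = 1, seed = 1) {
  set.seed(seed)
  N <- nrow(X)
  J <- max(grp)
  z <- stats::kmeans(X, centers = min(L, nrow(unique(X))), nstart = 5)$cluster
  beta0 <- rep(1 / L, L)
  keep <- NULL
  njl <- function(z) {
    t(vapply(seq_len(J), function(j) tabulate(z[grp == j], nbins = L),
             integer(L)))
  }
  for (it in seq_len(n_iter)) {
    atoms <- lapply(seq_len(L), function(l) {
      hdp_draw_atom(X[z == l, , drop = FALSE], m0, k0, Psi, nu0)
    })
    logf <- sapply(atoms, function(a) {
      R <- chol(a$Sigma)
      v <- forwardsolve(t(R), t(X) - a$mu)
      -0.5 * colSums(v^2) - sum(log(diag(R))) - log(2 * pi)
    })
    # group weights integrated out: P(z_i = l) prop to (n_jl^-i + alpha*beta0_l) f
    for (i in seq_len(N)) {
      cnt <- tabulate(z[grp == grp[i]], nbins = L)
      cnt[z[i]] <- cnt[z[i]] - 1L
      lw <- log(cnt + alpha * beta0) + logf[i, ]
      lw <- lw - max(lw)
      z[i] <- sample.int(L, 1, prob = exp(lw))
    }
    # auxiliary table counts and the conjugate global-weight draw
    counts <- njl(z)
    m <- matrix(0L, J, L)
    for (j in seq_len(J)) for (l in seq_len(L)) {
      n <- counts[j, l]
      if (n > 0) {
        a <- alpha * beta0[l]
        m[j, l] <- sum(runif(n) < a / (a + seq_len(n) - 1))
      }
    }
    g <- rgamma(L, shape = gamma0 / L + colSums(m), rate = 1)
    g <- pmax(g, 1e-300)
    beta0 <- g / sum(g)
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      keep <- rbind(keep, z)
    }
  }
  keep
}
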