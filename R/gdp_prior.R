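#' Normal-inverse-Wishart base measure parameters
#'
#' The conjugate base measure for Gaussian mixture atoms
#' \eqn{(\mu, \Sigma)}: \eqn{\Sigma \sim IW(\nu, \Psi)} and
#' \eqn{\mu \mid \Sigma \sim N(m_0, \Sigma/\kappa_0)}. The default matches a
#' weakly informative choice for standardized 2-D embeddings:
#' \eqn{NIW(0, 0.01, I_2, 2)}.
#'
#' @param mean0 prior mean vector \eqn{m_0}.
#' @param kappa0 positive scalar precision multiplier \eqn{\kappa_0}.
#' @param Psi positive-definite scale matrix \eqn{\Psi}.
#' @param df degrees of freedom \eqn{\nu > d - 1}.
#' @return an object of class `niw_params`.
#' @export
niw_params <- function(mean0 = c(0, 0), kappa0 = 0.01,
                       Psi = diag(length(mean0)), df = length(mean0)) {
  mean0 <- as.numeric(mean0)
  d <- length(mean0)
  Psi <- as.matrix(Psi)
  stopifnot(kappa0 > 0, nrow(Psi) == d, ncol(Psi) == d, df > d - 1)
  if (max(abs(Psi - t(Psi))) > 1e-10) stop("`Psi` must be symmetric")
  ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`Psi` must be positive-definite")
  structure(list(mean0 = mean0, kappa0 = kappa0, Psi = Psi, df = df, d = d),
            class = "niw_params")
}

#' Dirichlet random deviates, safe for very small shapes
#'
#' Draws from Dirichlet distributions whose shapes may be far below 1 (as in
#' the symmetric `Dir(alpha/L)` prior with large truncation `L`). Small
#' shapes are sampled on the log scale via the shape-boost identity
#' \eqn{G_a \overset{d}{=} G_{a+1} U^{1/a}} so that coordinates never
#' underflow to exact zero before normalization; any residual zeros are
#' floored at `1e-300` and the vector renormalized.
#'
#' @param n number of draws.
#' @param alpha shape parameters: a positive vector (recycled across draws)
#'   or an `n x L` matrix giving a different shape vector per draw.
#' @return an `n x L` matrix; rows sum to one.
#' @export
rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == n)
    L <- ncol(alpha)
    a <- as.vector(t(alpha))
  } else {
    L <- length(alpha)
    a <- rep(as.numeric(alpha), n)
  }
  if (any(a < 0) || anyNA(a)) stop("Dirichlet shapes must be strictly positive")
  if (min(a) < 1e-300) a <- pmax(a, 1e-300)  # concentration products can underflow
  lg <- numeric(length(a))
  small <- a < 1
  if (any(small)) {
    as <- a[small]
    lg[small] <- log(stats::rgamma(sum(small), shape = as + 1, rate = 1)) +
      log(stats::runif(sum(small))) / as
  }
  if (any(!small)) {
    lg[!small] <- log(stats::rgamma(sum(!small), shape = a[!small], rate = 1))
  }
  lg <- matrix(lg, nrow = n, byrow = TRUE)
  m <- apply(lg, 1L, max)
  g <- exp(lg - m)
  g[g < 1e-300] <- 1e-300
  g / rowSums(g)
}

## log density of Dirichlet(alpha) at x (both vectors); shapes that have
## underflowed to zero are floored to keep the value defined
ddirichlet_log <- function(x, alpha) {
  if (min(alpha) < 1e-300) alpha <- pmax(alpha, 1e-300)
  sum((alpha - 1) * log(x)) - sum(lgamma(alpha)) + lgamma(sum(alpha))
}

## rows of X ~ N(mean, Sigma); returns vector of log densities
dmvnorm_log <- function(X, mean, Sigma) {
  X <- matrix(X, ncol = length(mean))
  R <- chol(Sigma)
  z <- forwardsolve(t(R), t(X) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * length(mean) * log(2 * pi)
}

## log density of inverse-Wishart(df, Psi) at Sigma
dinvwishart_log <- function(Sigma, df, Psi) {
  d <- nrow(Psi)
  lmvgamma <- (d * (d - 1) / 4) * log(pi) + sum(lgamma((df + 1 - seq_len(d)) / 2))
  ldPsi <- determinant(Psi, logarithm = TRUE)$modulus
  ldS <- determinant(Sigma, logarithm = TRUE)$modulus
  as.numeric((df / 2) * ldPsi - (df * d / 2) * log(2) - lmvgamma -
               ((df + d + 1) / 2) * ldS - 0.5 * sum(diag(Psi %*% solve(Sigma))))
}

dniw_log <- function(mu, Sigma, g0) {
  dinvwishart_log(Sigma, g0$df, g0$Psi) +
    dmvnorm_log(matrix(mu, nrow = 1), g0$mean0, Sigma / g0$kappa0)
}

#' Sample concentration parameters along the DAG
#'
#' The gamma-DAG hyperprior: the root concentration follows
#' `Gamma(alpha0, rate = 1)`; every other node's concentration follows a
#' gamma with unit rate whose shape is the sum of its parents' (sampled)
#' concentrations. Draws proceed in layer order so each shape is available
#' when needed. Under this chain every node's marginal mean equals `alpha0`.
#'
#' @param dag a [group_dag()].
#' @param alpha0 fixed positive shape of the root concentration.
#' @return a list of class `gdp_concentration` with `alpha0` and `alpha`, a
#'   named vector over all nodes (root included) in canonical order.
#' @export
sample_concentrations <- function(dag, alpha0) {
  stopifnot(alpha0 > 0)
  alpha <- stats::setNames(numeric(length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) {
    key <- as.character(v)
    shape <- if (v == dag$root) alpha0 else sum(alpha[as.character(dag$parents[[key]])])
    alpha[key] <- stats::rgamma(1L, shape = shape, rate = 1)
  }
  structure(list(alpha0 = alpha0, alpha = alpha), class = "gdp_concentration")
}

#' Sample the parent-mixture weights
#'
#' Each node's base measure is a convex combination of its parents'
#' measures; the combination weights get a Dirichlet prior whose parameters
#' are the parents' concentrations, so higher-precision parents receive more
#' weight. These weights are integrated out analytically in the sampler (a
#' Dirichlet mixture of Dirichlets collapses to a single Dirichlet) and are
#' exposed here for forward simulation and testing.
#'
#' @param dag a [group_dag()].
#' @param conc a `gdp_concentration`.
#' @return named list: for each node with at least one parent, a named weight
#'   vector over its parents summing to one.
#' @export
sample_parent_weights <- function(dag, conc) {
  out <- list()
  for (v in non_root_nodes(dag)) {
    pa <- dag$parents[[as.character(v)]]
    a <- conc$alpha[as.character(pa)]
    w <- drop(rdirichlet(1L, as.numeric(a)))
    out[[as.character(v)]] <- stats::setNames(w, pa)
  }
  out
}

## concentrations of the hidden weight chain of `node` (layer k >= 2):
## element m-1 (m = 2..k) is the summed concentration of its
## generation-(k-m+1) ancestors, who sit in layer m-1
hidden_chain_conc <- function(dag, conc, node) {
  k <- dag$layer[[as.character(node)]]
  if (k < 2L) return(numeric(0))
  vapply(2:k, function(m) {
    anc <- dag_ancestors(dag, node, generation = k - m + 1L)
    sum(conc$alpha[as.character(anc)])
  }, numeric(1))
}

#' Sample the truncated weight state of the finite GDP representation
#'
#' Draws the full set of mixing weights of the L-component finite
#' representation: root weights `beta_root ~ Dir(alpha_root/L, ...)`; for a
#' node in layer `k >= 2` a chain of hidden simplices
#' `nu^(k,2) ~ Dir(c_2 * beta_root)`, ...,
#' `nu^(k,k) ~ Dir(c_k * nu^(k,k-1))` where `c_m` sums the concentrations of
#' the node's generation-(k-m+1) ancestors; and finally node weights
#' `beta_j ~ Dir(alpha_j * nu^(k,k))` (layer-1 nodes use `beta_root` as base
#' directly). As the truncation level grows this construction converges to
#' the graphical Dirichlet process.
#'
#' @param dag a [group_dag()].
#' @param conc a `gdp_concentration`.
#' @param L truncation level (`>= 2`).
#' @param ndraw number of independent replicate draws. With `ndraw = 1`
#'   (default) simplices are plain vectors; with `ndraw > 1` every stored
#'   simplex becomes an `ndraw x L` matrix (a Monte Carlo convenience: all
#'   replicates share `conc`).
#' @return a list of class `gdp_weights`: `L`, `beta_root`, `nu` (per node,
#'   list of hidden simplices indexed `m = 2..k`), `beta` (per non-root
#'   node).
#' @export
sample_weight_state <- function(dag, conc, L, ndraw = 1L) {
  stopifnot(L >= 2, ndraw >= 1)
  a_root <- conc$alpha[[as.character(dag$root)]]
  beta_root <- rdirichlet(ndraw, rep(a_root / L, L))
  nu <- list()
  beta <- list()
  for (v in non_root_nodes(dag)) {
    key <- as.character(v)
    k <- dag$layer[[key]]
    base <- beta_root
    if (k >= 2L) {
      cm <- hidden_chain_conc(dag, conc, v)
      chain <- vector("list", k - 1L)
      for (m in 2:k) {
        base <- rdirichlet(ndraw, cm[m - 1L] * base)
        chain[[m - 1L]] <- if (ndraw == 1L) drop(base) else base
      }
      names(chain) <- paste0("m", 2:k)
      nu[[key]] <- chain
    }
    b <- rdirichlet(ndraw, conc$alpha[[key]] * base)
    beta[[key]] <- if (ndraw == 1L) drop(b) else b
  }
  structure(list(L = L, beta_root = if (ndraw == 1L) drop(beta_root) else beta_root,
                 nu = nu, beta = beta),
            class = "gdp_weights")
}

#' Sample mixture atoms from the NIW base measure
#'
#' @param g0 a [niw_params()].
#' @param L number of atoms.
#' @return a list of class `gdp_atoms` with `means` (`L x d`) and `covs`
#'   (`d x d x L`).
#' @export
sample_atoms <- function(g0, L) {
  d <- g0$d
  means <- matrix(0, L, d)
  covs <- array(0, c(d, d, L))
  for (l in seq_len(L)) {
    Sigma <- riw(g0$df, g0$Psi)
    covs[, , l] <- Sigma
    means[l, ] <- MASS::mvrnorm(1L, g0$mean0, Sigma / g0$kappa0)
  }
  structure(list(means = means, covs = covs, L = L, d = d), class = "gdp_atoms")
}

## one inverse-Wishart(df, Psi) draw
riw <- function(df, Psi) {
  W <- stats::rWishart(1L, df, solve(Psi))[, , 1L]
  S <- solve(W)
  (S + t(S)) / 2
}

#' Grouped multivariate observations
#'
#' Container pooling all observations with their group labels. Observation
#' order within a group is preserved.
#'
#' @param x numeric matrix (or data frame) of observations, one row each.
#' @param group integer vector of group labels, one per row of `x`.
#' @return a list of class `grouped_data` with pooled matrix `x`, `group`,
#'   sorted unique `groups`, per-group counts `n`, and dimension `d`.
#' @export
grouped_data <- function(x, group) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  group <- as.integer(group)
  stopifnot(length(group) == nrow(x))
  groups <- sort(unique(group))
  n <- stats::setNames(as.integer(table(factor(group, levels = groups))), groups)
  structure(list(x = x, group = group, groups = groups, n = n, d = ncol(x)),
            class = "grouped_data")
}

#' Log joint density of the finite GDP mixture state
#'
#' Sums every factor of the truncated model: the gamma-DAG terms for the
#' concentrations, the Dirichlet terms for root, hidden, and node weights,
#' the NIW density of each atom, and for every observation the categorical
#' weight of its component and its Gaussian likelihood. An observed root
#' contributes its assignment/likelihood terms through `beta_root`.
#'
#' @param dag a [group_dag()].
#' @param conc a `gdp_concentration`.
#' @param weights a `gdp_weights` (single draw).
#' @param atoms a `gdp_atoms`.
#' @param z integer vector of component assignments, pooled in the order of
#'   `data$x` (may be `NULL` when `data` is empty).
#' @param data a [grouped_data()] (groups must be observed DAG nodes).
#' @param g0 a [niw_params()].
#' @return scalar log density.
#' @export
log_joint <- function(dag, conc, weights, atoms, z, data, g0) {
  lp <- log_conc_prior(dag, conc) +
    log_weight_prior(dag, conc, weights)
  for (l in seq_len(atoms$L)) {
    lp <- lp + dniw_log(atoms$means[l, ], atoms$covs[, , l], g0)
  }
  if (!is.null(data) && nrow(data$x) > 0L) {
    stopifnot(length(z) == nrow(data$x))
    bmat <- node_weight_matrix(dag, weights, data$groups)
    gidx <- match(data$group, data$groups)
    lp <- lp + sum(log(bmat[cbind(gidx, z)]))
    for (l in sort(unique(z))) {
      idx <- z == l
      lp <- lp + sum(dmvnorm_log(data$x[idx, , drop = FALSE],
                                 atoms$means[l, ], atoms$covs[, , l]))
    }
  }
  lp
}

## all gamma terms of the concentration chain
log_conc_prior <- function(dag, conc) {
  lp <- 0
  for (v in dag$nodes) {
    key <- as.character(v)
    shape <- if (v == dag$root) conc$alpha0 else
      sum(conc$alpha[as.character(dag$parents[[key]])])
    lp <- lp + stats::dgamma(conc$alpha[[key]], shape = shape, rate = 1, log = TRUE)
  }
  lp
}

## all Dirichlet terms of the weight state given the concentrations
log_weight_prior <- function(dag, conc, weights) {
  L <- weights$L
  a_root <- conc$alpha[[as.character(dag$root)]]
  lp <- ddirichlet_log(weights$beta_root, rep(a_root / L, L))
  for (v in non_root_nodes(dag)) {
    key <- as.character(v)
    k <- dag$layer[[key]]
    base <- weights$beta_root
    if (k >= 2L) {
      cm <- hidden_chain_conc(dag, conc, v)
      for (m in 2:k) {
        nu <- weights$nu[[key]][[m - 1L]]
        lp <- lp + ddirichlet_log(nu, cm[m - 1L] * base)
        base <- nu
      }
    }
    lp <- lp + ddirichlet_log(weights$beta[[key]], conc$alpha[[key]] * base)
  }
  lp
}

## rows: groups (in `groups` order); the weight vector each group's
## assignments are drawn from (beta_root for an observed root)
node_weight_matrix <- function(dag, weights, groups) {
  t(vapply(groups, function(g) {
    if (g == dag$root) weights$beta_root else weights$beta[[as.character(g)]]
  }, numeric(weights$L)))
}

#' Collapse a Dirichlet mixture of Dirichlet vectors
#'
#' If \eqn{X_i \sim Dir(\alpha_i)} independently and
#' \eqn{\pi \sim Dir(\alpha_{1\cdot}, ..., \alpha_{L\cdot})} with
#' \eqn{\alpha_{i\cdot} = \sum_j \alpha_{ij}}, then
#' \eqn{\sum_i \pi_i X_i \sim Dir(\sum_i \alpha_i)}. This collapse is what
#' lets the parent-mixture weights be integrated out of the model; the
#' function draws from the left-hand side and reports the collapsed
#' parameter so the identity can be checked empirically.
#'
#' @param alphas list of positive shape vectors of equal length.
#' @param n number of Monte Carlo draws.
#' @return list with `samples` (`n x k` draws of the mixture) and
#'   `collapsed_alpha` (the parameter of the equivalent single Dirichlet).
#' @export
collapse_dirichlet_mixture <- function(alphas, n) {
  stopifnot(length(alphas) >= 1L)
  k <- length(alphas[[1L]])
  stopifnot(all(vapply(alphas, length, 1L) == k))
  Lc <- length(alphas)
  row_tot <- vapply(alphas, sum, numeric(1))
  if (Lc == 1L) {
    samples <- rdirichlet(n, alphas[[1L]])
  } else {
    pi_mat <- rdirichlet(n, row_tot)
    samples <- matrix(0, n, k)
    for (i in seq_len(Lc)) {
      samples <- samples + pi_mat[, i] * rdirichlet(n, alphas[[i]])
    }
  }
  list(samples = samples, collapsed_alpha = Reduce(`+`, alphas))
}
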