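#' Sampler configuration
#'
#' @param n_iter total sweeps per chain.
#' @param burn_in sweeps discarded before retention (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param n_chains independent chains, pooled after burn-in.
#' @param seed integer seed; each chain uses a distinct substream.
#' @param salt_scale initial per-coordinate scale of the logit-simplex
#'   Metropolis proposals.
#' @param alpha_rw_scale initial log-scale random-walk standard deviation for
#'   concentration updates.
#' @param adapt adapt both proposal scales toward a 0.44 per-coordinate
#'   acceptance rate during burn-in (frozen afterwards so the retained chain
#'   has a fixed kernel).
#' @param init_mode `"kmeans"` (assignments from k-means with `L` centers,
#'   the default) or `"prior"` (assignments drawn from the forward prior).
#' @param update_alpha set `FALSE` to keep the concentration parameters
#'   fixed at their initial values (useful for matched comparisons).
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 2000L, burn_in = 500L, thin = 1L,
                           n_chains = 1L, seed = 1L, salt_scale = 1,
                           alpha_rw_scale = 0.2, adapt = TRUE,
                           init_mode = c("kmeans", "prior"),
                           update_alpha = TRUE) {
  init_mode <- match.arg(init_mode)
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1,
            salt_scale > 0, alpha_rw_scale > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), salt_scale = salt_scale,
                 alpha_rw_scale = alpha_rw_scale, adapt = isTRUE(adapt),
                 init_mode = init_mode, update_alpha = isTRUE(update_alpha)),
            class = "sampler_config")
}

#' Logit-simplex Metropolis proposal for one coordinate
#'
#' Proposes a Gaussian step on the logit of the chosen coordinate and
#' rescales the remaining coordinates proportionally so the vector stays on
#' the simplex. In the coordinates (logit of the chosen entry, relative
#' proportions of the rest) the walk is a symmetric Gaussian, so the exact
#' Metropolis--Hastings correction is the Jacobian ratio of the map back to
#' the simplex: `log p'_i + (L-1) log(1-p'_i) - log p_i - (L-1) log(1-p_i)`.
#'
#' @param current strictly positive simplex vector.
#' @param coord index of the coordinate to move.
#' @param scale standard deviation of the logit-scale step; `0` returns the
#'   current point with zero correction.
#' @return list with `proposal` (simplex vector) and `log_hastings` (the log
#'   correction to add to the target log ratio).
#' @export
salt_propose <- function(current, coord, scale) {
  L <- length(current)
  p <- current[coord]
  if (!(p > 0 && p <= 1)) stop("degenerate simplex coordinate: ", p)
  if (scale == 0) return(list(proposal = current, log_hastings = 0))
  ## keep the logit finite at the floating-point boundary of the simplex
  p <- min(max(p, 1e-300), 1 - 1e-12)
  y2 <- stats::qlogis(p) + stats::rnorm(1L, 0, scale)
  p2 <- min(max(stats::plogis(y2), 1e-300), 1 - 1e-12)
  proposal <- current * ((1 - p2) / (1 - p))
  proposal[coord] <- p2
  proposal <- proposal / sum(proposal)
  log_hastings <- log(p2) + (L - 1) * log1p(-p2) -
    log(p) - (L - 1) * log1p(-p)
  list(proposal = proposal, log_hastings = log_hastings)
}

#' Sample component assignments
#'
#' Each observation's indicator is drawn from the categorical distribution
#' with probability proportional to (its group's component weight) times
#' (the Gaussian density of the observation under the component's atom),
#' computed in log space with Gumbel-max sampling.
#'
#' @param data a [grouped_data()].
#' @param dag the [group_dag()] (identifies the root, whose observations are
#'   weighted by the root simplex).
#' @param weights a `gdp_weights` state.
#' @param atoms a `gdp_atoms` state.
#' @return integer vector of component indices in `1..L`, pooled order.
#' @export
update_assignments <- function(data, dag, weights, atoms) {
  N <- nrow(data$x)
  if (N == 0L) return(integer(0))
  L <- atoms$L
  logdens <- matrix(0, N, L)
  for (l in seq_len(L)) {
    logdens[, l] <- dmvnorm_log(data$x, atoms$means[l, ], atoms$covs[, , l])
  }
  bmat <- node_weight_matrix(dag, weights, data$groups)
  gidx <- match(data$group, data$groups)
  logw <- logdens + log(bmat)[gidx, , drop = FALSE]
  best <- max.col(logw, ties.method = "first")
  if (any(!is.finite(logw[cbind(seq_len(N), best)]))) {
    stop("all component weights vanished for some observation (numeric failure)")
  }
  gum <- -log(-log(matrix(stats::runif(N * L), N, L)))
  max.col(logw + gum, ties.method = "first")
}

#' Conjugate posterior of a normal-inverse-Wishart given data
#'
#' Standard update: `kappa_n = kappa0 + n`, `m_n = (kappa0 m0 + n ybar) /
#' kappa_n`, `df_n = df + n`, `Psi_n = Psi + S + kappa0 n / kappa_n (ybar -
#' m0)(ybar - m0)'` with `S` the centered scatter matrix.
#'
#' @param g0 a [niw_params()].
#' @param Y matrix of observations (rows), possibly empty.
#' @return a [niw_params()] with updated parameters.
#' @export
niw_posterior <- function(g0, Y) {
  Y <- matrix(Y, ncol = g0$d)
  n <- nrow(Y)
  if (n == 0L) return(g0)
  ybar <- colMeans(Y)
  S <- crossprod(sweep(Y, 2L, ybar))
  kap_n <- g0$kappa0 + n
  dev <- ybar - g0$mean0
  niw_params(mean0 = (g0$kappa0 * g0$mean0 + n * ybar) / kap_n,
             kappa0 = kap_n,
             Psi = g0$Psi + S + (g0$kappa0 * n / kap_n) * tcrossprod(dev),
             df = g0$df + n)
}

#' Sample mixture atoms from their conjugate conditional
#'
#' Per component, draws `(mu, Sigma)` from the normal-inverse-Wishart
#' posterior given the observations currently assigned to it, pooled across
#' groups (atoms are global). Components with no assigned observations draw
#' from the prior, which is what lets clusters be born in the blocked
#' sampler.
#'
#' @param data a [grouped_data()].
#' @param z integer assignment vector (pooled order).
#' @param g0 a [niw_params()].
#' @param L number of components.
#' @return a `gdp_atoms` state.
#' @export
update_atoms <- function(data, z, g0, L) {
  d <- g0$d
  means <- matrix(0, L, d)
  covs <- array(0, c(d, d, L))
  for (l in seq_len(L)) {
    post <- if (length(z) > 0L) {
      niw_posterior(g0, data$x[z == l, , drop = FALSE])
    } else g0
    Sigma <- riw(post$df, post$Psi)
    covs[, , l] <- Sigma
    means[l, ] <- MASS::mvrnorm(1L, post$mean0, Sigma / post$kappa0)
  }
  structure(list(means = means, covs = covs, L = L, d = d), class = "gdp_atoms")
}

#' Conjugate update of a node's component weights
#'
#' The node weights have a Dirichlet prior `Dir(alpha_node * base)` and a
#' multinomial likelihood through the assignment counts, so the full
#' conditional is `Dir(alpha_node * base + counts)` -- an exact Gibbs step.
#'
#' @param counts nonnegative integer vector of per-component assignment
#'   counts for the node.
#' @param base the node's top hidden simplex (or the root weights for a
#'   layer-1 node).
#' @param alpha_node the node's concentration.
#' @return a simplex vector.
#' @export
update_node_weights <- function(counts, base, alpha_node) {
  stopifnot(length(counts) == length(base), all(counts >= 0))
  drop(rdirichlet(1L, alpha_node * base + counts))
}

## ---- SALT Metropolis block over root and hidden weights -------------------

## log Dirichlet-multinomial mass of `counts` under concentration vector
## `alpha`: the node-weight simplex integrated out analytically. Evaluating
## this in place of the Dirichlet density of a sampled node simplex keeps
## Metropolis targets free of coordinates that underflow double precision.
lddirmult <- function(counts, alpha) {
  n <- sum(counts)
  if (n == 0) return(0)
  if (min(alpha) < 1e-300) alpha <- pmax(alpha, 1e-300)
  pos <- counts > 0
  lgamma(sum(alpha)) - lgamma(sum(alpha) + n) +
    sum(lgamma(alpha[pos] + counts[pos]) - lgamma(alpha[pos]))
}

zero_counts <- function(counts, key, L) {
  if (!is.null(counts) && !is.null(counts[[key]])) counts[[key]] else rep(0L, L)
}

## full-conditional log target of beta_root, with every leaf node-weight
## simplex collapsed (Dirichlet-multinomial in its assignment counts)
logtarget_root <- function(b, dag, conc, weights, root_counts, counts) {
  L <- weights$L
  lp <- ddirichlet_log(b, rep(conc$alpha[[as.character(dag$root)]] / L, L))
  for (v in non_root_nodes(dag)) {
    key <- as.character(v)
    k <- dag$layer[[key]]
    if (k == 1L) {
      lp <- lp + lddirmult(zero_counts(counts, key, L), conc$alpha[[key]] * b)
    } else {
      c2 <- hidden_chain_conc(dag, conc, v)[1L]
      lp <- lp + ddirichlet_log(weights$nu[[key]][[1L]], c2 * b)
    }
  }
  if (!is.null(root_counts)) lp <- lp + sum(root_counts * log(b))
  lp
}

## full-conditional log target of nu_v^(k,m) (list index m-1), leaf weights
## collapsed
logtarget_nu <- function(u, dag, conc, weights, v, m, cm, counts) {
  key <- as.character(v)
  k <- dag$layer[[key]]
  base <- if (m == 2L) weights$beta_root else weights$nu[[key]][[m - 2L]]
  lp <- ddirichlet_log(u, cm[m - 1L] * base)
  if (m < k) {
    lp + ddirichlet_log(weights$nu[[key]][[m]], cm[m] * u)
  } else {
    lp + lddirmult(zero_counts(counts, key, weights$L), conc$alpha[[key]] * u)
  }
}

## per-coordinate SALT sweep over one simplex given its log target
salt_sweep_simplex <- function(current, logtarget, scale) {
  acc <- 0L
  lt_cur <- logtarget(current)
  L <- length(current)
  for (i in seq_len(L)) {
    prop <- salt_propose(current, i, scale)
    lt_prop <- logtarget(prop$proposal)
    if (isTRUE(log(stats::runif(1L)) < lt_prop - lt_cur + prop$log_hastings)) {
      current <- prop$proposal
      lt_cur <- lt_prop
      acc <- acc + 1L
    }
  }
  list(value = current, accepted = acc, proposed = L)
}

#' Metropolis update of the root and hidden weight simplices
#'
#' The root weights and every hidden simplex are non-conjugate: each appears
#' through its own Dirichlet prior, as the base of other Dirichlet factors,
#' and (for an observed root) through the root group's assignment counts.
#' The leaf node-weight simplices are collapsed out of every target
#' analytically (Dirichlet-multinomial in the per-node assignment counts),
#' which both improves mixing and keeps the targets free of simplex
#' coordinates too small for double precision. Each remaining simplex is
#' updated by per-coordinate logit-simplex Metropolis steps on its full
#' conditional, followed by an independence proposal drawn from its
#' conditional Dirichlet prior and accepted on the ratio of the remaining
#' (downstream) factors; the independence move traverses the ridge on which
#' a simplex and the factors it feeds reinforce each other, where small
#' logit steps mix slowly.
#'
#' @param dag a [group_dag()].
#' @param conc a `gdp_concentration`.
#' @param weights a `gdp_weights` state (single draw).
#' @param root_counts per-component assignment counts of the root group, or
#'   `NULL` when the root is hidden or empty.
#' @param scales named numeric vector of per-simplex proposal scales:
#'   `"root"` plus `"<node>.m<m>"` entries; a single unnamed scalar is
#'   recycled.
#' @param counts named list mapping non-root node labels to per-component
#'   assignment count vectors; `NULL` (no data) drops the collapsed terms.
#' @return list with updated `weights`, and `accepted` / `proposed` counts
#'   per simplex (named as in `scales`; logit-step moves only).
#' @export
update_hidden_weights <- function(dag, conc, weights, root_counts = NULL,
                                  scales = 1, counts = NULL) {
  get_scale <- function(name) {
    if (length(scales) == 1L && is.null(names(scales))) return(scales)
    if (!name %in% names(scales)) stop("missing proposal scale for ", name)
    scales[[name]]
  }
  acc <- integer(0)
  prop <- integer(0)
  L <- weights$L

  root_prior <- function(b) {
    ddirichlet_log(b, rep(conc$alpha[[as.character(dag$root)]] / L, L))
  }
  res <- salt_sweep_simplex(
    weights$beta_root,
    function(b) logtarget_root(b, dag, conc, weights, root_counts, counts),
    get_scale("root"))
  weights$beta_root <- res$value
  acc["root"] <- res$accepted
  prop["root"] <- res$proposed
  ## independence move: propose from the Dir(alpha_root/L) prior
  cand <- floor_simplex(drop(rdirichlet(
    1L, rep(conc$alpha[[as.character(dag$root)]] / L, L))))
  down_new <- logtarget_root(cand, dag, conc, weights, root_counts, counts) -
    root_prior(cand)
  down_old <- logtarget_root(weights$beta_root, dag, conc, weights, root_counts,
                             counts) -
    root_prior(weights$beta_root)
  if (isTRUE(log(stats::runif(1L)) < down_new - down_old)) weights$beta_root <- cand

  for (v in non_root_nodes(dag)) {
    key <- as.character(v)
    k <- dag$layer[[key]]
    if (k < 2L) next
    cm <- hidden_chain_conc(dag, conc, v)
    for (m in 2:k) {
      nm <- paste0(key, ".m", m)
      res <- salt_sweep_simplex(
        weights$nu[[key]][[m - 1L]],
        function(u) logtarget_nu(u, dag, conc, weights, v, m, cm, counts),
        get_scale(nm))
      weights$nu[[key]][[m - 1L]] <- res$value
      acc[nm] <- res$accepted
      prop[nm] <- res$proposed
      ## independence move from the conditional prior Dir(c_m * base)
      base <- if (m == 2L) weights$beta_root else weights$nu[[key]][[m - 2L]]
      cand <- floor_simplex(drop(rdirichlet(1L, cm[m - 1L] * base)))
      pr <- function(u) ddirichlet_log(u, cm[m - 1L] * base)
      cur <- weights$nu[[key]][[m - 1L]]
      d_new <- logtarget_nu(cand, dag, conc, weights, v, m, cm, counts) - pr(cand)
      d_old <- logtarget_nu(cur, dag, conc, weights, v, m, cm, counts) - pr(cur)
      if (isTRUE(log(stats::runif(1L)) < d_new - d_old)) {
        weights$nu[[key]][[m - 1L]] <- cand
      }
    }
  }
  list(weights = weights, accepted = acc, proposed = prop)
}

## ---- concentration updates -------------------------------------------------

## static map: for each non-root node v, the hidden-chain factors of
## descendants whose concentration sums alpha_v
alpha_dependents <- function(dag) {
  dep <- list()
  for (v in non_root_nodes(dag)) {
    kv <- dag$layer[[as.character(v)]]
    m <- kv + 1L
    entries <- list()
    for (j in non_root_nodes(dag)) {
      kj <- dag$layer[[as.character(j)]]
      if (kj < max(2L, m)) next
      anc <- dag_ancestors(dag, j, generation = kj - kv)
      if (!(v %in% anc)) next
      entries[[length(entries) + 1L]] <-
        list(j = as.character(j), m = m, anc = as.character(anc))
    }
    dep[[as.character(v)]] <- entries
  }
  dep
}

## log of every factor that involves alpha_v, evaluated with alpha_v =
## value; leaf node-weight simplices are collapsed (counts terms)
log_alpha_target <- function(dag, conc, weights, v, value, counts = NULL,
                             dep = NULL) {
  key <- as.character(v)
  alpha <- conc$alpha
  alpha[key] <- value
  shape_v <- if (v == dag$root) conc$alpha0 else
    sum(alpha[as.character(dag$parents[[key]])])
  lp <- stats::dgamma(value, shape = shape_v, rate = 1, log = TRUE)
  for (ch in dag$children[[key]]) {
    sh <- sum(alpha[as.character(dag$parents[[as.character(ch)]])])
    lp <- lp + stats::dgamma(alpha[[as.character(ch)]], shape = sh, rate = 1,
                             log = TRUE)
  }
  L <- weights$L
  if (v == dag$root) {
    return(lp + ddirichlet_log(weights$beta_root, rep(value / L, L)))
  }
  kv <- dag$layer[[key]]
  base_top <- if (kv == 1L) weights$beta_root else weights$nu[[key]][[kv - 1L]]
  lp <- lp + lddirmult(zero_counts(counts, key, L), value * base_top)
  ## hidden-chain factors of descendants whose generation-(k'-kv) ancestor
  ## set contains v: their concentration sums alpha_v
  if (is.null(dep)) dep <- alpha_dependents(dag)
  for (e in dep[[key]]) {
    cc <- sum(alpha[e$anc])
    base <- if (e$m == 2L) weights$beta_root else weights$nu[[e$j]][[e$m - 2L]]
    lp <- lp + ddirichlet_log(weights$nu[[e$j]][[e$m - 1L]], cc * base)
  }
  lp
}

#' Metropolis update of the concentration parameters
#'
#' Each concentration (root and per-node) gets a Gaussian random-walk step on
#' the log scale targeting its full conditional: its own gamma prior, the
#' gamma priors of its children (whose shapes sum the parents'
#' concentrations), and every Dirichlet weight factor whose parameter
#' involves it. The random-walk step is followed by an independence proposal
#' from the conditional gamma prior, accepted on the ratio of the remaining
#' factors, which lets a concentration jump off the ridge where it and the
#' simplices it concentrates reinforce each other.
#'
#' @param dag a [group_dag()].
#' @param conc a `gdp_concentration`.
#' @param weights a `gdp_weights` state.
#' @param scales named numeric vector of log-scale step sizes per node
#'   (names = node labels); a single unnamed scalar is recycled.
#' @param counts named list of per-node assignment count vectors (leaf
#'   weights are collapsed into Dirichlet-multinomial terms); `NULL` for no
#'   data.
#' @return list with updated `conc` and `accepted` / `proposed` counts per
#'   node (random-walk moves only).
#' @export
update_concentrations <- function(dag, conc, weights, scales = 0.2,
                                  counts = NULL) {
  acc <- stats::setNames(integer(length(dag$nodes)), dag$nodes)
  dep <- alpha_dependents(dag)
  for (v in dag$nodes) {
    key <- as.character(v)
    sc <- if (length(scales) == 1L && is.null(names(scales))) scales else scales[[key]]
    cur <- conc$alpha[[key]]
    prop <- cur * exp(stats::rnorm(1L, 0, sc))
    delta <- log_alpha_target(dag, conc, weights, v, prop, counts, dep) -
      log_alpha_target(dag, conc, weights, v, cur, counts, dep) +
      log(prop) - log(cur)
    if (isTRUE(log(stats::runif(1L)) < delta)) {
      conc$alpha[key] <- prop
      acc[key] <- 1L
    }
    ## independence move from the conditional gamma prior
    shape_v <- if (v == dag$root) conc$alpha0 else
      sum(conc$alpha[as.character(dag$parents[[key]])])
    cand <- stats::rgamma(1L, shape = shape_v, rate = 1)
    if (cand > 0) {
      down <- function(a) {
        log_alpha_target(dag, conc, weights, v, a, counts, dep) -
          stats::dgamma(a, shape = shape_v, rate = 1, log = TRUE)
      }
      if (isTRUE(log(stats::runif(1L)) < down(cand) - down(conc$alpha[[key]]))) {
        conc$alpha[key] <- cand
      }
    }
  }
  list(conc = conc, accepted = acc,
       proposed = stats::setNames(rep(1L, length(dag$nodes)), dag$nodes))
}

## ---- the blocked Gibbs sampler --------------------------------------------

loglik_given_state <- function(data, atoms, z) {
  if (length(z) == 0L) return(0)
  ll <- 0
  for (l in sort(unique(z))) {
    idx <- z == l
    ll <- ll + sum(dmvnorm_log(data$x[idx, , drop = FALSE],
                               atoms$means[l, ], atoms$covs[, , l]))
  }
  ll
}

## guard against exact zeros (logit proposals and log densities need the
## open simplex); 1e-300 leaves the distribution essentially untouched
floor_simplex <- function(x, eps = 1e-300) {
  x <- pmax(x, eps)
  x / sum(x)
}

floor_weights <- function(weights) {
  weights$beta_root <- floor_simplex(weights$beta_root)
  weights$nu <- lapply(weights$nu, function(ch) lapply(ch, floor_simplex))
  weights$beta <- lapply(weights$beta, floor_simplex)
  weights
}

#' Fit the GDP mixture by Metropolis-within-blocked-Gibbs
#'
#' Posterior sampler for the truncated graphical Dirichlet process mixture.
#' Each sweep updates, in order: atoms (conjugate normal-inverse-Wishart),
#' assignments (categorical), node weights (conjugate Dirichlet), root and
#' hidden weights (per-coordinate logit-simplex Metropolis), and
#' concentrations (log-scale random walk). Chains are run independently from
#' distinct substreams of `config$seed` and pooled after burn-in.
#'
#' @param data a [grouped_data()]; group labels must be observed nodes of
#'   `dag`. Observed nodes without data contribute prior draws only.
#' @param dag a [group_dag()].
#' @param g0 a [niw_params()] base measure.
#' @param alpha0 fixed shape of the root concentration prior.
#' @param L truncation level (`>= 2`).
#' @param config a [sampler_config()].
#' @param init optional named list overriding the default initialization:
#'   `conc` (a `gdp_concentration`, used as-is -- combine with
#'   `update_alpha = FALSE` for fixed-concentration runs), `weights`, `z`.
#' @return object of class `gdp_samples`: retained draws `z_draws`
#'   (draws x N), `beta_root_draws`, `alpha_draws`, `atom_mean_draws`
#'   (draws x L x d), `loglik` (retained), `loglik_full` (n_iter x chains),
#'   `acceptance` rates per Metropolis block, plus `group`, `groups`, `dag`,
#'   `L`, `config`, and the final per-chain states in `final_state`.
#' @export
gdp_gibbs <- function(data, dag, g0 = niw_params(), alpha0 = 5, L = 10L,
                      config = sampler_config(), init = NULL) {
  stopifnot(inherits(data, "grouped_data"), inherits(dag, "group_dag"), L >= 2)
  obs_nodes <- dag$nodes[dag$observed[as.character(dag$nodes)]]
  if (!all(data$groups %in% obs_nodes)) {
    stop("data contain group labels that are not observed DAG nodes")
  }
  N <- nrow(data$x)
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  root_observed <- dag$observed[[as.character(dag$root)]]

  simplex_names <- "root"
  for (v in non_root_nodes(dag)) {
    k <- dag$layer[[as.character(v)]]
    if (k >= 2L) simplex_names <- c(simplex_names, paste0(v, ".m", 2:k))
  }

  all_z <- matrix(NA_integer_, n_keep * config$n_chains, N)
  all_beta_root <- matrix(NA_real_, n_keep * config$n_chains, L)
  all_alpha <- matrix(NA_real_, n_keep * config$n_chains, length(dag$nodes),
                      dimnames = list(NULL, dag$nodes))
  all_means <- array(NA_real_, c(n_keep * config$n_chains, L, data$d))
  all_ll <- numeric(n_keep * config$n_chains)
  ll_full <- matrix(NA_real_, config$n_iter, config$n_chains)
  acc_tot <- NULL
  final_state <- vector("list", config$n_chains)

  for (chain in seq_len(config$n_chains)) {
    set.seed((config$seed + 104729L * (chain - 1L)) %% 2147483647L)

    conc <- if (!is.null(init$conc)) init$conc else
      sample_concentrations(dag, alpha0)
    weights <- if (!is.null(init$weights)) floor_weights(init$weights) else
      floor_weights(sample_weight_state(dag, conc, L))
    if (!is.null(init$z)) {
      z <- as.integer(init$z)
    } else if (N > 0L) {
      if (config$init_mode == "kmeans") {
        centers <- min(L, nrow(unique(data$x)))
        if (centers < 1L) stop("k-means initialization needs data")
        z <- stats::kmeans(data$x, centers = centers, nstart = 5L,
                           iter.max = 50L)$cluster
      } else {
        atoms0 <- sample_atoms(g0, L)
        z <- update_assignments(data, dag, weights, atoms0)
      }
    } else {
      z <- integer(0)
    }
    atoms <- update_atoms(data, z, g0, L)

    salt_scales <- stats::setNames(rep(config$salt_scale, length(simplex_names)),
                                   simplex_names)
    alpha_scales <- stats::setNames(rep(config$alpha_rw_scale, length(dag$nodes)),
                                    dag$nodes)
    salt_acc <- salt_prop <- stats::setNames(numeric(length(simplex_names)),
                                             simplex_names)
    alpha_acc <- alpha_prop <- stats::setNames(numeric(length(dag$nodes)),
                                               dag$nodes)
    batch_salt_acc <- batch_salt_prop <- salt_acc
    batch_alpha_acc <- batch_alpha_prop <- alpha_acc
    batch_no <- 0L

    keep_idx <- 0L
    offset <- (chain - 1L) * n_keep
    gidx <- match(data$group, data$groups)

    count_list <- function(z) {
      if (N == 0L) return(NULL)
      tab <- table(factor(data$group, levels = data$groups),
                   factor(z, levels = seq_len(L)))
      counts <- matrix(as.integer(tab), nrow = length(data$groups))
      out <- lapply(seq_along(data$groups), function(i) counts[i, ])
      names(out) <- data$groups
      out
    }
    counts <- count_list(z)

    for (it in seq_len(config$n_iter)) {
      atoms <- update_atoms(data, z, g0, L)

      ## node weights drawn fresh from their conjugate conditional right
      ## before the assignment step (they are collapsed out of the
      ## Metropolis blocks below)
      for (v in non_root_nodes(dag)) {
        key <- as.character(v)
        k <- dag$layer[[key]]
        base <- if (k == 1L) weights$beta_root else weights$nu[[key]][[k - 1L]]
        cnt <- zero_counts(counts, key, L)
        weights$beta[[key]] <- update_node_weights(cnt, base, conc$alpha[[key]])
      }

      if (N > 0L) z <- update_assignments(data, dag, weights, atoms)
      counts <- count_list(z)

      root_counts <- if (root_observed && dag$root %in% data$groups) {
        counts[[as.character(dag$root)]]
      } else NULL
      hw <- update_hidden_weights(dag, conc, weights, root_counts,
                                  salt_scales, counts)
      weights <- hw$weights
      salt_acc <- salt_acc + hw$accepted
      salt_prop <- salt_prop + hw$proposed
      batch_salt_acc <- batch_salt_acc + hw$accepted
      batch_salt_prop <- batch_salt_prop + hw$proposed

      if (config$update_alpha) {
        cu <- update_concentrations(dag, conc, weights, alpha_scales, counts)
        conc <- cu$conc
        alpha_acc <- alpha_acc + cu$accepted
        alpha_prop <- alpha_prop + cu$proposed
        batch_alpha_acc <- batch_alpha_acc + cu$accepted
        batch_alpha_prop <- batch_alpha_prop + cu$proposed
      }

      ll <- loglik_given_state(data, atoms, z)
      ll_full[it, chain] <- ll

      ## scale adaptation in batches of 50, burn-in only
      if (config$adapt && it <= config$burn_in && it %% 50L == 0L) {
        batch_no <- batch_no + 1L
        gain <- 1 / sqrt(batch_no)
        rate <- ifelse(batch_salt_prop > 0, batch_salt_acc / batch_salt_prop, 0.44)
        salt_scales <- salt_scales * exp(gain * (rate - 0.44))
        salt_scales <- pmin(pmax(salt_scales, 1e-3), 20)
        if (config$update_alpha) {
          arate <- ifelse(batch_alpha_prop > 0,
                          batch_alpha_acc / batch_alpha_prop, 0.44)
          alpha_scales <- alpha_scales * exp(gain * (arate - 0.44))
          alpha_scales <- pmin(pmax(alpha_scales, 1e-3), 20)
        }
        batch_salt_acc[] <- 0; batch_salt_prop[] <- 0
        batch_alpha_acc[] <- 0; batch_alpha_prop[] <- 0
      }

      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0L &&
          keep_idx < n_keep) {
        keep_idx <- keep_idx + 1L
        row <- offset + keep_idx
        if (N > 0L) all_z[row, ] <- z
        all_beta_root[row, ] <- weights$beta_root
        all_alpha[row, ] <- conc$alpha
        all_means[row, , ] <- atoms$means
        all_ll[row] <- ll
      }
    }

    acc_chain <- c(salt_acc / pmax(salt_prop, 1),
                   if (config$update_alpha) alpha_acc / pmax(alpha_prop, 1))
    acc_tot <- if (is.null(acc_tot)) acc_chain / config$n_chains else
      acc_tot + acc_chain / config$n_chains
    final_state[[chain]] <- list(conc = conc, weights = weights,
                                 atoms = atoms, z = z,
                                 salt_scales = salt_scales,
                                 alpha_scales = alpha_scales)
  }

  structure(list(z_draws = all_z, beta_root_draws = all_beta_root,
                 alpha_draws = all_alpha, atom_mean_draws = all_means,
                 loglik = all_ll, loglik_full = ll_full,
                 acceptance = acc_tot, group = data$group,
                 groups = data$groups, dag = dag, L = L, alpha0 = alpha0,
                 g0 = g0, config = config, n_keep = n_keep,
                 final_state = final_state),
            class = "gdp_samples")
}

#' Log-likelihood trace of retained draws
#'
#' The observation log-likelihood (sum of Gaussian log densities under each
#' observation's assigned atom) at every retained posterior draw, pooled
#' across chains. The full per-iteration trace, including burn-in, is in
#' `samples$loglik_full`.
#'
#' @param samples a `gdp_samples`.
#' @return numeric vector, one value per retained draw.
#' @export
loglik_trace <- function(samples) {
  stopifnot(inherits(samples, "gdp_samples"))
  if (length(samples$loglik) == 0L) stop("no retained draws")
  samples$loglik
}

#' @export
print.gdp_samples <- function(x, ...) {
  cat("GDP posterior samples:", nrow(x$z_draws), "retained draws (",
      x$config$n_chains, "chain(s) ),", ncol(x$z_draws),
      "observations, L =", x$L, "\n")
  cat("Mean Metropolis acceptance:",
      round(mean(x$acceptance), 3), "\n")
  invisible(x)
}
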