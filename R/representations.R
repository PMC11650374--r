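#' Truncated stick-breaking weights
#'
#' Draws `L - 1` sticks `Beta(1, alpha)` and forms the usual product
#' weights; the mass left after `L - 1` breaks is assigned to the last
#' coordinate so the result is an exact point on the simplex (the standard
#' truncation-closure convention).
#'
#' @param alpha positive concentration.
#' @param L truncation level (`>= 1`).
#' @return numeric vector of length `L` summing to one.
#' @export
stick_break <- function(alpha, L) {
  stopifnot(alpha > 0, L >= 1)
  if (L == 1L) return(1)
  v <- stats::rbeta(L - 1L, 1, alpha)
  w <- numeric(L)
  rem <- 1
  for (k in seq_len(L - 1L)) {
    w[k] <- v[k] * rem
    rem <- rem * (1 - v[k])
  }
  w[L] <- rem
  w
}

#' Nested-DP concentration chain of a node (hypergraph representation)
#'
#' The measure of a layer-k node can be written as a chain of nested
#' Dirichlet processes anchored at the root measure: the node's own DP with
#' concentration `alpha_j`, then one hidden "hypernode" DP per ancestral
#' generation whose concentration is the *sum* of the concentrations of the
#' corresponding generation's ancestors. The chain is returned in
#' node-to-root order and has length equal to the node's layer.
#'
#' @param dag a [group_dag()].
#' @param conc a `gdp_concentration`.
#' @param node a node in layer `k >= 1`.
#' @return object of class `hypergraph_chain`: list with `node`, `layer`,
#'   and `concentrations` (length-k numeric, `alpha_j` first, the summed
#'   generation-(k-1) ancestor concentration last).
#' @export
hypergraph_chain <- function(dag, conc, node) {
  key <- as.character(node)
  if (!key %in% names(dag$layer)) stop("unknown node: ", node)
  k <- dag$layer[[key]]
  if (k < 1L) stop("the root has no hypergraph chain")
  cc <- numeric(k)
  cc[1L] <- conc$alpha[[key]]
  if (k >= 2L) {
    for (g in seq_len(k - 1L)) {
      anc <- dag_ancestors(dag, node, generation = g)
      cc[g + 1L] <- sum(conc$alpha[as.character(anc)])
    }
  }
  structure(list(node = node, layer = k, concentrations = cc),
            class = "hypergraph_chain")
}

#' Sample node weights through the hypergraph chain
#'
#' The finite-truncation analog of the nested-DP chain: starting from the
#' root weights, each level draws a Dirichlet with parameter
#' `concentration * base`, ending with the node's own concentration. Serves
#' as a cross-validation oracle for [sample_weight_state()] -- the two
#' constructions must agree in distribution.
#'
#' @param chain a [hypergraph_chain()].
#' @param beta_root root weight simplex (length `L` vector), or an
#'   `ndraw x L` matrix of independent root draws.
#' @param ndraw number of replicate draws (must match `nrow(beta_root)` when
#'   a matrix is supplied).
#' @return the node's weight simplex: a length-`L` vector, or an
#'   `ndraw x L` matrix when `ndraw > 1`.
#' @export
sample_weights_via_hypergraph <- function(chain, beta_root, ndraw = 1L) {
  base <- if (is.matrix(beta_root)) beta_root else
    matrix(beta_root, nrow = ndraw, ncol = length(beta_root), byrow = TRUE)
  stopifnot(nrow(base) == ndraw)
  for (cc in rev(chain$concentrations)) {
    base <- rdirichlet(ndraw, cc * base)
  }
  if (ndraw == 1L) drop(base) else base
}

#' Simulate the family-owned restaurant process
#'
#' The predictive (urn) representation of the graphical Dirichlet process
#' with all random measures integrated out. Each group is a restaurant:
#' customers join an occupied table with probability proportional to its
#' occupancy or open a new table with probability proportional to the
#' group's concentration. A new table must fetch its dish through the
#' group's stack of *hyper-restaurants* -- one per ancestral generation,
#' with concentration equal to the summed concentration of that
#' generation's ancestors -- each level again a weighted choice between an
#' existing table (inheriting its dish) and a referral one level closer to
#' the root. New tables at the shared root restaurant order a brand-new dish
#' from the global menu. An observed root seats its own customers directly
#' in the root restaurant (a plain Chinese restaurant over its data).
#'
#' Dishes are opaque integer labels supplied by `labeler` so the simulator
#' is distribution-free over atoms.
#'
#' @param dag a [group_dag()].
#' @param conc a `gdp_concentration`.
#' @param n_customers named vector or list mapping observed node labels to
#'   nonnegative customer counts.
#' @param labeler optional function returning a fresh dish label on each
#'   call; defaults to sequential integers.
#' @return object of class `restaurant_state`: per-node restaurants
#'   (`tables` occupancy counts, `dishes` labels), per-node lists of hyper
#'   levels (node-to-root order), the shared `root` restaurant, per-node
#'   customer-to-dish assignments `dish_of_customer`, and `n_dishes`.
#' @export
restaurant_sim <- function(dag, conc, n_customers, labeler = NULL) {
  counter <- 0L
  if (is.null(labeler)) {
    labeler <- function() {
      counter <<- counter + 1L
      counter
    }
  }
  new_rest <- function() list(tables = integer(0), dishes = integer(0))

  root <- new_rest()
  restaurants <- list()
  hyper <- list()
  dish_of <- list()

  ## seat a customer in restaurant `r` with concentration `a`; `fetch()`
  ## resolves the dish of a newly opened table. Returns list(rest, dish).
  seat <- function(r, a, fetch) {
    tot <- sum(r$tables)
    if (length(r$tables) > 0L &&
        stats::runif(1L) < tot / (tot + a)) {
      t <- sample.int(length(r$tables), 1L, prob = r$tables)
      r$tables[t] <- r$tables[t] + 1L
      return(list(rest = r, dish = r$dishes[t]))
    }
    dish <- fetch()
    r$tables <- c(r$tables, 1L)
    r$dishes <- c(r$dishes, dish)
    list(rest = r, dish = dish)
  }

  seat_at_root <- function() {
    res <- seat(root, conc$alpha[[as.character(dag$root)]],
                fetch = labeler)
    root <<- res$rest
    res$dish
  }

  ## resolve a new-table dish for node `v` through hyper level `i`
  ## (i indexes the node-to-root chain concentrations, positions 2..k)
  fetch_through <- function(v, i, cc) {
    key <- as.character(v)
    if (i > length(cc)) return(seat_at_root())
    res <- seat(hyper[[key]][[i - 1L]], cc[i],
                fetch = function() fetch_through(v, i + 1L, cc))
    hyper[[key]][[i - 1L]] <<- res$rest
    res$dish
  }

  for (v in dag$nodes) {
    key <- as.character(v)
    n <- 0L
    if (!is.null(n_customers[[key]])) n <- as.integer(n_customers[[key]])
    if (n == 0L) next
    if (!dag$observed[[key]]) stop("customers assigned to hidden node ", v)
    dishes <- integer(n)
    if (v == dag$root) {
      for (i in seq_len(n)) dishes[i] <- seat_at_root()
    } else {
      cc <- hypergraph_chain(dag, conc, v)$concentrations
      if (is.null(restaurants[[key]])) restaurants[[key]] <- new_rest()
      if (length(cc) >= 2L && is.null(hyper[[key]])) {
        hyper[[key]] <- replicate(length(cc) - 1L, new_rest(), simplify = FALSE)
      }
      for (i in seq_len(n)) {
        res <- seat(restaurants[[key]], cc[1L],
                    fetch = function() fetch_through(v, 2L, cc))
        restaurants[[key]] <- res$rest
        dishes[i] <- res$dish
      }
    }
    dish_of[[key]] <- dishes
  }

  structure(list(restaurants = restaurants, hyper = hyper, root = root,
                 dish_of_customer = dish_of,
                 n_dishes = length(root$dishes)),
            class = "restaurant_state")
}

#' Prior probability that two groups share a cluster
#'
#' Monte Carlo estimate, under the restaurant representation, that the first
#' customer of each of two groups is served the same dish -- a direct
#' measure of a-priori cluster sharing between groups. Passing the same node
#' twice estimates the probability that that group's first two customers
#' share a dish.
#'
#' @param dag a [group_dag()].
#' @param conc a `gdp_concentration`.
#' @param node_pair length-2 vector of observed node labels.
#' @param n_reps number of simulated restaurant realizations.
#' @return scalar probability in `[0, 1]`.
#' @export
prior_cocluster_probability <- function(dag, conc, node_pair, n_reps) {
  stopifnot(length(node_pair) == 2L, n_reps >= 1L)
  a <- as.character(node_pair[1L])
  b <- as.character(node_pair[2L])
  same_node <- identical(a, b)
  n_cust <- if (same_node) stats::setNames(list(2L), a) else
    stats::setNames(list(1L, 1L), c(a, b))
  hits <- 0L
  for (r in seq_len(n_reps)) {
    st <- restaurant_sim(dag, conc, n_cust)
    d <- if (same_node) st$dish_of_customer[[a]] else
      c(st$dish_of_customer[[a]][1L], st$dish_of_customer[[b]][1L])
    if (d[1L] == d[2L]) hits <- hits + 1L
  }
  hits / n_reps
}
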