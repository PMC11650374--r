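#' Build the layered DAG that links experimental groups
#'
#' Constructs a `group_dag` object from a directed edge list over integer
#' group labels. The graph must be acyclic and *graded*: every edge must
#' connect a node in layer `k - 1` to a node in layer `k`, where the layer of
#' a node is the length of the longest directed path from the root. The
#' layer-wise recursions of the graphical Dirichlet process are defined only
#' for graded DAGs, so non-graded inputs are rejected with an error rather
#' than silently re-interpreted.
#'
#' A DAG with several roots is, by default, augmented with a single *hidden*
#' root that becomes the common parent of all original roots. The hidden node
#' carries no data (`observed = FALSE`) and leaves the Markov blanket of
#' every non-root node unchanged; original roots simply gain the hidden
#' parent.
#'
#' @param edges two-column matrix or data frame of directed edges
#'   `(parent, child)`, or `NULL` for an edgeless graph.
#' @param nodes optional integer vector of node labels; required when some
#'   nodes are isolated. Defaults to the labels appearing in `edges`.
#' @param observed named logical vector mapping node labels to whether the
#'   group carries data. Defaults to `TRUE` for all declared nodes; an
#'   auto-added hidden root is always unobserved.
#' @param auto_augment if `TRUE` (default) a multi-root graph is augmented
#'   with a hidden common parent; if `FALSE` such a graph is an error.
#' @param hidden_id label reserved for the hidden root. Defaults to `0` if
#'   unused, otherwise `min(nodes) - 1`.
#'
#' @return An object of class `group_dag` with components `nodes` (canonical
#'   order: layer, then label), `edges`, `observed`, `layer` (named integer),
#'   `layers` (list of node vectors per layer, element 1 = layer 0), `root`,
#'   `K` (number of non-root layers), `p` (number of non-root nodes), and
#'   precomputed `parents` / `children` adjacency lists keyed by node label.
#'
#' @examples
#' edges <- cbind(c(1, 1, 1, 2, 4, 2, 3, 3, 4, 5, 6, 7),
#'                c(2, 3, 4, 5, 5, 6, 6, 7, 7, 8, 8, 8))
#' dag <- group_dag(edges)
#' dag$layers
#' @export
group_dag <- function(edges, nodes = NULL, observed = NULL,
                      auto_augment = TRUE, hidden_id = NULL) {
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("`edges` must have two columns (parent, child)")
    storage.mode(edges) <- "integer"
  }
  if (is.null(nodes)) nodes <- sort(unique(as.integer(edges)))
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) == 0L) stop("the DAG must contain at least one node")
  if (nrow(edges) > 0L && !all(edges %in% nodes)) {
    stop("edges reference undeclared nodes")
  }
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) {
    edges <- unique(edges)
  }

  parents <- lapply(nodes, function(v) sort(edges[edges[, 2L] == v, 1L]))
  names(parents) <- as.character(nodes)
  roots <- nodes[vapply(parents, length, 1L) == 0L]
  if (length(roots) == 0L) {
    stop(dag_condition("gdp_cycle_error", "directed cycle detected: no root node"))
  }

  if (length(roots) > 1L) {
    if (!auto_augment) {
      stop(dag_condition(
        "gdp_multiroot_error",
        sprintf("DAG has %d roots; enable `auto_augment` to add a hidden common parent",
                length(roots))))
    }
    if (is.null(hidden_id)) hidden_id <- if (0L %in% nodes) min(nodes) - 1L else 0L
    hidden_id <- as.integer(hidden_id)
    if (hidden_id %in% nodes) stop("`hidden_id` collides with an existing node")
    edges <- rbind(cbind(hidden_id, roots), edges)
    if (!is.null(observed)) observed <- c(stats::setNames(FALSE, hidden_id), observed)
    nodes <- sort(c(hidden_id, nodes))
    parents <- lapply(nodes, function(v) sort(edges[edges[, 2L] == v, 1L]))
    names(parents) <- as.character(nodes)
    roots <- hidden_id
    hidden_root_added <- TRUE
  } else {
    hidden_root_added <- FALSE
  }

  children <- lapply(nodes, function(v) sort(edges[edges[, 1L] == v, 2L]))
  names(children) <- as.character(nodes)

  layer <- longest_path_layers(nodes, parents)

  ## gradedness: each edge spans exactly one layer
  if (nrow(edges) > 0L) {
    span <- layer[as.character(edges[, 2L])] - layer[as.character(edges[, 1L])]
    if (any(span != 1L)) {
      bad <- which(span != 1L)[1L]
      stop(dag_condition(
        "gdp_gradedness_error",
        sprintf("edge %d -> %d skips a layer (spans %d); the layered recursions require a graded DAG",
                edges[bad, 1L], edges[bad, 2L], span[bad])))
    }
  }

  if (is.null(observed)) {
    observed <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  } else {
    obs <- stats::setNames(rep(TRUE, length(nodes)), nodes)
    obs[names(observed)] <- as.logical(observed)
    observed <- obs
  }
  if (hidden_root_added) observed[as.character(roots)] <- FALSE

  K <- max(layer)
  layers <- lapply(0:K, function(k) sort(nodes[layer[as.character(nodes)] == k]))
  ord <- order(layer[as.character(nodes)], nodes)
  nodes <- nodes[ord]

  ## precomputed generation-g ancestor sets (queried heavily by the sampler)
  anc <- lapply(nodes, function(v) {
    k <- layer[[as.character(v)]]
    if (k == 0L) return(list())
    out <- vector("list", k)
    cur <- v
    for (g in seq_len(k)) {
      cur <- sort(unique(unlist(parents[as.character(cur)], use.names = FALSE)))
      out[[g]] <- as.integer(cur)
    }
    out
  })
  names(anc) <- as.character(nodes)

  structure(list(
    nodes = nodes, edges = edges, observed = observed[as.character(nodes)],
    layer = layer[as.character(nodes)], layers = layers,
    root = roots, K = K, p = length(nodes) - 1L,
    parents = parents[as.character(nodes)], children = children[as.character(nodes)],
    ancestors = anc
  ), class = "group_dag")
}

## layers as longest directed path from a root; Kahn order doubles as the
## cycle check (a leftover node can never be peeled)
longest_path_layers <- function(nodes, parents) {
  layer <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  remaining <- as.character(nodes)
  repeat {
    ready <- remaining[vapply(remaining, function(v) {
      pa <- as.character(parents[[v]])
      length(pa) == 0L || !anyNA(layer[pa])
    }, TRUE)]
    if (length(ready) == 0L) break
    for (v in ready) {
      pa <- as.character(parents[[v]])
      layer[v] <- if (length(pa) == 0L) 0L else max(layer[pa]) + 1L
    }
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) > 0L) {
    stop(dag_condition(
      "gdp_cycle_error",
      paste("directed cycle detected involving nodes:",
            paste(remaining, collapse = ", "))))
  }
  layer
}

dag_condition <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Augment a multi-root DAG with a hidden common parent
#'
#' A single-root `group_dag` is returned unchanged. Raw multi-root inputs
#' (edge list plus node set) are converted into a valid single-root
#' `group_dag` by adding one hidden node as the parent of every original
#' root; layers shift up by one and the hidden root is flagged unobserved.
#'
#' @param x a `group_dag` (returned as-is) or a two-column edge list.
#' @inheritParams group_dag
#' @return a `group_dag` with a unique root.
#' @export
augment_hidden_root <- function(x, nodes = NULL, observed = NULL,
                                hidden_id = NULL) {
  if (inherits(x, "group_dag")) return(x)
  group_dag(x, nodes = nodes, observed = observed,
            auto_augment = TRUE, hidden_id = hidden_id)
}

#' Generation-l ancestors of a node
#'
#' Returns all nodes reachable from `node` by following exactly `generation`
#' edges backwards. Generation 1 is the parent set; because the DAG is
#' graded, the generation-g ancestors of a layer-k node all sit in layer
#' `k - g`.
#'
#' @param dag a `group_dag`.
#' @param node node label.
#' @param generation integer in `1..layer(node)`.
#' @return sorted integer vector of node labels.
#' @export
dag_ancestors <- function(dag, node, generation) {
  key <- as.character(node)
  if (!key %in% names(dag$layer)) stop("unknown node: ", node)
  k <- dag$layer[[key]]
  if (generation < 1L || generation > k) {
    stop("`generation` must be between 1 and the node's layer (", k, ")")
  }
  if (!is.null(dag$ancestors)) return(dag$ancestors[[key]][[generation]])
  cur <- node
  for (g in seq_len(generation)) {
    cur <- sort(unique(unlist(dag$parents[as.character(cur)], use.names = FALSE)))
  }
  as.integer(cur)
}

#' Markov blanket of a node
#'
#' Parents, children, and co-parents of children (excluding the node itself):
#' the minimal set that renders the node conditionally independent of the
#' rest of the graph.
#'
#' @inheritParams dag_ancestors
#' @return sorted integer vector of node labels (possibly empty).
#' @export
markov_blanket <- function(dag, node) {
  key <- as.character(node)
  if (!key %in% names(dag$layer)) stop("unknown node: ", node)
  ch <- dag$children[[key]]
  copar <- unlist(dag$parents[as.character(ch)], use.names = FALSE)
  out <- sort(unique(c(dag$parents[[key]], ch, copar)))
  as.integer(setdiff(out, node))
}

#' @export
print.group_dag <- function(x, ...) {
  cat("Layered group DAG:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges,", x$K, "non-root layer(s)\n")
  for (k in seq_along(x$layers)) {
    lab <- x$layers[[k]]
    hidden <- !x$observed[as.character(lab)]
    lab <- ifelse(hidden, paste0("(", lab, ")"), as.character(lab))
    cat(sprintf("  layer %d: %s\n", k - 1L, paste(lab, collapse = " ")))
  }
  invisible(x)
}

## canonical topological order (layer, then label), excluding the root
non_root_nodes <- function(dag) dag$nodes[dag$nodes != dag$root]

## the eight-group two-condition factorial DAG used throughout the examples:
## a baseline root, three single-factor groups, three two-factor groups, and
## one three-factor group
#' Eight-group factorial design DAG
#'
#' The layered DAG of the motivating eight-group experiment: group 1 is the
#' baseline root; groups 2--4 each alter one factor; groups 5--7 combine two
#' factors (each with the two corresponding single-factor parents); group 8
#' combines all three.
#'
#' @return a `group_dag` with layers `{1}, {2,3,4}, {5,6,7}, {8}`.
#' @export
eight_group_dag <- function() {
  group_dag(cbind(c(1, 1, 1, 2, 4, 2, 3, 3, 4, 5, 6, 7),
                  c(2, 3, 4, 5, 5, 6, 6, 7, 7, 8, 8, 8)))
}

#' Fork DAG: one root and exchangeable children
#'
#' The special case under which the graphical Dirichlet process reduces to a
#' hierarchical Dirichlet process. With `hidden_root = TRUE` the root carries
#' no data, matching the usual HDP in which the global measure is latent.
#'
#' @param n_children number of child groups.
#' @param hidden_root should the root be unobserved? Default `TRUE`.
#' @param root_id label of the root node (default 0).
#' @return a `group_dag`.
#' @export
fork_dag <- function(n_children, hidden_root = TRUE, root_id = 0L) {
  kids <- seq_len(n_children)
  obs <- stats::setNames(c(!hidden_root, rep(TRUE, n_children)),
                         c(root_id, kids))
  group_dag(cbind(root_id, kids), observed = obs)
}
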