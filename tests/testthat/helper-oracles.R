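# independent brute-force oracles used to validate the package's fast paths

# generation-g ancestors by exhaustive enumeration of reversed paths
brute_ancestors <- function(edges, node, generation) {
  frontier <- node
  for (i in seq_len(generation)) {
    frontier <- unique(unlist(lapply(frontier, function(v) edges[edges[, 2] == v, 1])))
    if (length(frontier) == 0) return(integer(0))
  }
  sort(as.integer(frontier))
}

# pair-counting adjusted Rand index, straight from the definition
pair_count_ari <- function(a, b) {
  n <- length(a)
  s_a <- outer(a, a, "==")[upper.tri(diag(n))]
  s_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(s_a & s_b); n00 <- sum(!s_a & !s_b)
  n10 <- sum(s_a & !s_b); n01 <- sum(!s_a & s_b)
  tot <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - expected) / (maxidx - expected)
}

# O(N^2 * draws) posterior similarity by direct pair counting
brute_psm <- function(Z) {
  N <- ncol(Z)
  psm <- matrix(0, N, N)
  for (d in seq_len(nrow(Z))) psm <- psm + outer(Z[d, ], Z[d, ], "==")
  psm / nrow(Z)
}

# exhaustive least-squares draw selection
brute_dahl <- function(Z, psm = brute_psm(Z)) {
  d2 <- apply(Z, 1, function(z) sum((outer(z, z, "==") - psm)^2))
  which.min(d2)
}

# exact CRP partition probability (EPPF): alpha^B * prod (|b|-1)! / rising(alpha, n)
crp_partition_prob <- function(blocks, alpha, n) {
  rising <- prod(alpha + 0:(n - 1))
  alpha^length(blocks) * prod(factorial(blocks - 1)) / rising
}

# canonical key of the partition induced by a label vector
partition_key <- function(z) {
  paste(match(z, unique(z)), collapse = "")
}

# Dirichlet log density (independent of the package's version)
dirichlet_logpdf <- function(x, a) {
  sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
}

# multivariate normal log density, solve-based (independent implementation)
mvn_logpdf <- function(x, m, S) {
  d <- length(m)
  q <- drop(t(x - m) %*% solve(S) %*% (x - m))
  as.numeric(-0.5 * q - 0.5 * determinant(S, logarithm = TRUE)$modulus -
               d / 2 * log(2 * pi))
}
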