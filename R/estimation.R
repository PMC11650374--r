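#' Posterior similarity matrix
#'
#' Entry (a, b) is the fraction of retained draws in which observations a
#' and b are assigned to the same component. Atoms are global, so labels are
#' comparable across groups and the matrix is computed on the pooled
#' observations.
#'
#' @param samples a `gdp_samples`, or a draws x N integer matrix of
#'   assignments.
#' @return symmetric N x N matrix with unit diagonal.
#' @export
posterior_similarity <- function(samples) {
  Z <- if (inherits(samples, "gdp_samples")) samples$z_draws else as.matrix(samples)
  if (nrow(Z) < 1L) stop("need at least one retained draw")
  D <- nrow(Z)
  N <- ncol(Z)
  psm <- matrix(0, N, N)
  for (l in sort(unique(as.vector(Z)))) {
    B <- Z == l
    psm <- psm + crossprod(B)
  }
  psm <- psm / D
  diag(psm) <- 1
  psm
}

#' Dahl's least-squares clustering estimate
#'
#' Selects, among the retained posterior draws, the partition whose
#' association matrix minimizes the squared Frobenius distance to the
#' posterior similarity matrix. Ties break toward the earliest draw. The
#' criterion is label-free: permuting component labels within a draw does
#' not change its association matrix.
#'
#' @param samples a `gdp_samples`, or a draws x N assignment matrix.
#' @param psm optional precomputed [posterior_similarity()] matrix.
#' @return list of class `gdp_clustering`: `labels` (pooled integer vector,
#'   relabeled to consecutive cluster ids), `raw_labels` (component indices
#'   of the chosen draw), `psm`, `chosen_draw`, and `ls_distance`.
#' @export
dahl_estimate <- function(samples, psm = NULL) {
  Z <- if (inherits(samples, "gdp_samples")) samples$z_draws else as.matrix(samples)
  if (is.null(psm)) psm <- posterior_similarity(Z)
  D <- nrow(Z)
  ## squared distance to the PSM up to a draw-free constant:
  ## sum over co-clustered pairs of (1 - 2 psm)
  M <- 1 - 2 * psm
  score <- numeric(D)
  for (d in seq_len(D)) {
    zd <- Z[d, ]
    for (l in unique(zd)) {
      idx <- which(zd == l)
      score[d] <- score[d] + sum(M[idx, idx])
    }
  }
  best <- which.min(score)
  raw <- Z[best, ]
  list(labels = as.integer(factor(raw, levels = unique(raw))),
       raw_labels = raw, psm = psm, chosen_draw = best,
       ls_distance = score[best] + sum(psm^2)) |>
    structure(class = "gdp_clustering")
}

#' Adjusted Rand index
#'
#' Hubert--Arabie chance-corrected agreement between two partitions of the
#' same items; 1 for identical partitions, around 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  mclust::adjustedRandIndex(a, b)
}

#' Internal clustering validation indices
#'
#' Calinski-Harabasz (between/within variance ratio; higher is better),
#' Davies-Bouldin (mean worst-case cluster overlap; lower is better), and
#' mean silhouette width (higher is better), computed on the pooled
#' observations.
#'
#' @param data a [grouped_data()] or a numeric matrix.
#' @param labels cluster labels, one per pooled observation; at least two
#'   non-empty clusters.
#' @return named list with `calinski_harabasz`, `davies_bouldin`,
#'   `silhouette`.
#' @export
internal_validation <- function(data, labels) {
  X <- if (inherits(data, "grouped_data")) data$x else as.matrix(data)
  labels <- as.integer(factor(labels))
  stopifnot(length(labels) == nrow(X))
  k <- length(unique(labels))
  if (k < 2L) stop("internal validation needs at least two clusters")
  n <- nrow(X)
  centers <- rowsum(X, labels) / as.vector(table(labels))
  grand <- colMeans(X)
  nk <- as.vector(table(labels))
  ssb <- sum(nk * rowSums(sweep(centers, 2L, grand)^2))
  ssw <- sum((X - centers[labels, , drop = FALSE])^2)
  ch <- (ssb / (k - 1)) / (ssw / (n - k))

  ## Davies-Bouldin with mean Euclidean dispersion per cluster
  disp <- vapply(seq_len(k), function(l) {
    mean(sqrt(rowSums(sweep(X[labels == l, , drop = FALSE], 2L, centers[l, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centers))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (disp[i] + disp[j]) / cd[i, j], numeric(1)))
  }, numeric(1)))

  sil <- mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
  list(calinski_harabasz = ch, davies_bouldin = db, silhouette = sil)
}

#' Pooled k-means baseline
#'
#' Reference labeling from k-means on the pooled observations with `k`
#' centers (conventionally set to the truncation level of the GDP fit),
#' deterministic under the given seed.
#'
#' @param data a [grouped_data()] or matrix.
#' @param k number of centers (`<=` number of observations).
#' @param seed integer seed.
#' @return integer label vector.
#' @export
kmeans_baseline <- function(data, k, seed = 1L) {
  X <- if (inherits(data, "grouped_data")) data$x else as.matrix(data)
  stopifnot(k <= nrow(X))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k_eff <- min(k, nrow(unique(X)))
  if (k_eff >= nrow(X)) return(seq_len(nrow(X)))
  stats::kmeans(X, centers = k_eff, nstart = 10L, iter.max = 100L)$cluster
}
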