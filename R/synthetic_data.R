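#' Simulation design for grouped Gaussian-mixture data
#'
#' Describes a grouped dataset drawn from the finite GDP representation:
#' concentrations follow the gamma chain along the DAG, group weights follow
#' the truncated weight chain with truncation equal to the number of true
#' components, assignments are multinomial, and observations are Gaussian
#' with shared component means but group-specific covariances (so sibling
#' groups share clusters through ancestry while differing in local noise).
#'
#' @param dag a [group_dag()].
#' @param sizes named vector of per-group sample sizes (observed nodes).
#' @param alpha0 root concentration shape.
#' @param means_true matrix of true component means (rows).
#' @param covs_true list mapping observed node labels to d x d
#'   positive-definite covariance matrices.
#' @param seed integer seed.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(dag, sizes, alpha0 = 5, means_true, covs_true,
                       seed = 1L) {
  means_true <- as.matrix(means_true)
  obs <- dag$nodes[dag$observed[as.character(dag$nodes)]]
  stopifnot(all(names(sizes) %in% as.character(obs)),
            all(sizes >= 0),
            all(names(covs_true) %in% as.character(obs)))
  structure(list(dag = dag, sizes = sizes, alpha0 = alpha0,
                 n_components_true = nrow(means_true),
                 means_true = means_true, covs_true = covs_true,
                 seed = as.integer(seed), d = ncol(means_true)),
            class = "sim_design")
}

#' Simulate grouped data from the finite GDP
#'
#' Draws concentrations from the gamma chain, group weights from the
#' truncated weight chain (truncation = number of true components), true
#' component indicators from per-group multinomials, and observations from
#' Gaussians with the component's mean and the group's covariance. Returns
#' the full ground truth alongside the data.
#'
#' @param design a [sim_design()].
#' @return list with `data` (a [grouped_data()]), `z_true` (pooled integer
#'   vector), `weights`, `conc`, and the `design`.
#' @export
simulate_grouped_data <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  dag <- design$dag
  conc <- sample_concentrations(dag, design$alpha0)
  weights <- sample_weight_state(dag, conc, L = design$n_components_true)
  groups <- as.integer(names(design$sizes))
  ord <- order(groups)
  groups <- groups[ord]
  sizes <- as.integer(design$sizes)[ord]

  xs <- vector("list", length(groups))
  zs <- vector("list", length(groups))
  glab <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    n <- sizes[i]
    if (n == 0L) {
      xs[[i]] <- matrix(numeric(0), 0L, design$d)
      zs[[i]] <- integer(0)
      glab[[i]] <- integer(0)
      next
    }
    beta_g <- if (g == dag$root) weights$beta_root else
      weights$beta[[as.character(g)]]
    z <- sample.int(design$n_components_true, n, replace = TRUE, prob = beta_g)
    R <- chol(design$covs_true[[as.character(g)]])
    x <- design$means_true[z, , drop = FALSE] +
      matrix(stats::rnorm(n * design$d), n) %*% R
    xs[[i]] <- x
    zs[[i]] <- z
    glab[[i]] <- rep(g, n)
  }
  data <- grouped_data(do.call(rbind, xs), unlist(glab))
  list(data = data, z_true = unlist(zs), weights = weights, conc = conc,
       design = design)
}

## deterministic family of group covariances: rotated anisotropic ellipses
## with mild per-group scale differences
group_covariances <- function(groups, sd_scale = 1) {
  covs <- list()
  for (i in seq_along(groups)) {
    th <- (i - 1) * pi / length(groups)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    s <- sd_scale * (0.8 + 0.1 * ((i - 1) %% 5))
    covs[[as.character(groups[i])]] <- R %*% diag(c(s^2, (0.6 * s)^2)) %*% t(R)
  }
  covs
}

#' Preset simulation designs
#'
#' Ready-made designs on the eight-group factorial DAG with the study's four
#' sample-size profiles (`small`, `moderate`, `large`, `unbalanced`), plus a
#' `hard` variant with weak component separation and a `fork_hdp` design
#' with exchangeable groups under a hidden root. All presets use four true
#' bivariate Gaussian components and `alpha0 = 5`. For the size presets the
#' component means sit at least five within-cluster standard deviations
#' apart (means on a 10-unit grid, unit-scale covariances); the `hard`
#' preset reduces the separation to roughly two standard deviations (3-unit
#' grid, 1.5-scale covariances). Means and covariances are declared package
#' fixtures of the harness, not estimates of any particular dataset.
#'
#' @param name one of `"small"`, `"moderate"`, `"large"`, `"unbalanced"`,
#'   `"hard"`, `"fork_hdp"`.
#' @param seed seed stored in the design.
#' @return a [sim_design()].
#' @export
preset_design <- function(name = c("small", "moderate", "large",
                                   "unbalanced", "hard", "fork_hdp"),
                          seed = 1L) {
  name <- match.arg(name)
  size_rows <- list(
    small      = c(40, 30, 30, 35, 25, 30, 25, 30),
    moderate   = c(80, 70, 70, 75, 83, 88, 92, 88),
    large      = c(150, 160, 180, 170, 155, 175, 185, 145),
    unbalanced = c(350, 30, 40, 45, 25, 25, 35, 35))
  means_easy <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  means_hard <- rbind(c(0, 0), c(3, 0), c(0, 3), c(3, 3))

  if (name == "fork_hdp") {
    dag <- fork_dag(8L, hidden_root = TRUE, root_id = 0L)
    sizes <- stats::setNames(size_rows$small, 1:8)
    return(sim_design(dag, sizes, alpha0 = 5, means_true = means_easy,
                      covs_true = group_covariances(1:8), seed = seed))
  }
  dag <- eight_group_dag()
  if (name == "hard") {
    sizes <- stats::setNames(size_rows$small, 1:8)
    return(sim_design(dag, sizes, alpha0 = 5, means_true = means_hard,
                      covs_true = group_covariances(1:8, sd_scale = 1.5),
                      seed = seed))
  }
  sizes <- stats::setNames(size_rows[[name]], 1:8)
  sim_design(dag, sizes, alpha0 = 5, means_true = means_easy,
             covs_true = group_covariances(1:8), seed = seed)
}
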