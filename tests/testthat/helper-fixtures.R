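# shared fixtures: small DAGs, fixed concentration states, toy datasets

fig_dag <- function() eight_group_dag()

chain_dag <- function() group_dag(cbind(c(1, 2), c(2, 3)))

# fixed concentration state (no sampling) for distributional tests
fixed_conc <- function(dag, values) {
  stopifnot(length(values) == length(dag$nodes))
  structure(list(alpha0 = values[[1L]],
                 alpha = stats::setNames(as.numeric(values), dag$nodes)),
            class = "gdp_concentration")
}

# two well-separated isotropic blobs in one group
two_blob_data <- function(n_per = 20, sep = 10, sd = 1, group = 1L, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per, 0, sd), ncol = 2),
             matrix(rnorm(2 * n_per, sep, sd), ncol = 2))
  grouped_data(x, rep(group, 2 * n_per))
}

# standard error of a Monte Carlo mean
mc_se <- function(x) stats::sd(x) / sqrt(length(x))
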