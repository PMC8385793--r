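# Independent oracles and small fixtures shared across tests.

# Brute-force OLS via the normal equations; independent of the package's
# QR-based residualisation path.
ols_residuals_normal_eq <- function(y, X) {
  D <- cbind(1, as.matrix(X))
  b <- solve(t(D) %*% D, t(D) %*% y)
  as.vector(y - D %*% b)
}

# A small, fast simulation config: low missingness so that complete-case
# samples stay usable at a few thousand children.
tiny_config <- function(n = 2000, ...) {
  cfg <- default_config()
  cfg$n_children <- n
  cfg$missingness$checkup_miss <- c(m4 = 0.05, m7 = 0.2, m10 = 0.1)
  cfg$missingness$asq_miss <- c("6" = 0.03, "12" = 0.05)
  cfg$covariate_missing <- lapply(cfg$covariate_missing, function(x) 0.01)
  cfg$p_missing_basic <- 0
  cfg$p_non_singleton <- 0
  cfg$p_malformation <- 0
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

# Multivariate-normal z-score fixture with the default correlation
# structure, used where only the z stage matters.
random_zscores <- function(n, seed = 1) {
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, 8), Sigma = default_growth_corr())
  colnames(Z) <- paste0("z_", rep(c("length", "weight"), 4), "_",
                        rep(c("birth", "4m", "7m", "10m"), each = 2))
  dplyr::bind_cols(
    tibble::tibble(child_id = sprintf("Z%05d", seq_len(n)),
                   sex = rep_len(c("boy", "girl"), n)),
    tibble::as_tibble(Z))
}
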