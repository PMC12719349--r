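# Monte-Carlo structural-equation simulator used as an independent oracle
# for the analytic expected covariance matrices.  It never touches
# expected_covariance(): twin pairs are simulated factor by factor from the
# generating equations and the empirical covariance is compared entrywise.

# Draw n twin pairs under the structural equations; returns an n x 2k
# matrix over the model's observed variables (twin 1 block first).
simulate_twin_pairs <- function(theta, model_id, zygosity, n, seed = 1L) {
  set.seed(seed)
  r_g <- if (zygosity == "MZ") 1 else 0.5

  # bivariate factor scores with cross-twin correlation r on each factor:
  # [F_1, F_2] ~ N(0, [[S, r S], [r S, S]]) drawn via the conditional
  # decomposition F_2 = r F_1 + sqrt(1 - r^2) * F_new
  draw_pair <- function(S, r) {
    L <- t(chol(S + diag(1e-12, 2)))
    f1 <- L %*% matrix(rnorm(2 * n), 2)
    f2 <- r * f1 + sqrt(1 - r^2) * (L %*% matrix(rnorm(2 * n), 2))
    list(t(f1), t(f2))
  }

  SA <- matrix(c(theta$aX2, theta$covA, theta$covA, theta$aY2), 2, 2)
  SC <- matrix(c(theta$cX2, theta$covC, theta$covC, theta$cY2), 2, 2)
  SE <- matrix(c(theta$eX2, theta$covE, theta$covE, theta$eY2), 2, 2)
  cps <- theta$rf * sqrt(theta$sigma2_ps1 * theta$sigma2_ps2)
  Sps <- matrix(c(theta$sigma2_ps1, cps, cps, theta$sigma2_ps2), 2, 2)

  A <- draw_pair(SA, r_g)
  C <- draw_pair(SC, 1)
  E <- draw_pair(SE, 0)
  PS <- draw_pair(Sps, r_g)   # polygenic scores are additive-genetic

  M <- solve(matrix(c(1, -theta$g1, -theta$g2, 1), 2, 2))  # (I - B)^{-1}
  G <- matrix(c(theta$b1, theta$b2, 0, theta$b3), 2, 2)
  twin <- function(j) {
    u <- A[[j]] + C[[j]] + E[[j]]
    traits <- t(M %*% t(PS[[j]] %*% t(G) + u))
    # unreliable indicators: sqrt(rel) loading plus fresh residual noise
    obs <- cbind(
      sqrt(theta$rel1) * traits[, 1] + sqrt(1 - theta$rel1) * rnorm(n),
      sqrt(theta$rel2) * traits[, 2] + sqrt(1 - theta$rel2) * rnorm(n))
    cbind(PS1 = PS[[j]][, 1], PS2 = PS[[j]][, 2],
          T1 = obs[, 1], T2 = obs[, 2])
  }
  keep <- model_spec(model_id)$observed_vars
  x <- cbind(twin(1)[, keep, drop = FALSE], twin(2)[, keep, drop = FALSE])
  colnames(x) <- c(paste0(keep, "_1"), paste0(keep, "_2"))
  x
}

# Entrywise z-comparison of an analytic covariance against the empirical
# covariance of a Monte-Carlo sample; SE of a Gaussian covariance entry is
# sqrt((s_ii s_jj + s_ij^2) / n).
max_cov_z <- function(sigma, x) {
  emp <- cov(x)
  n <- nrow(x)
  se <- sqrt((tcrossprod(diag(sigma)) + sigma^2) / n)
  se[se < 1e-12] <- 1e-12
  max(abs(emp - sigma) / se)
}

# Random admissible parameter set for a model (used by property tests).
random_theta <- function(model_id, seed) {
  set.seed(seed)
  a <- runif(2, 0.2, 0.5); c_ <- runif(2, 0.1, 0.3)
  e <- 1 - a - c_
  th <- parameter_set(
    g1 = runif(1, 0.05, 0.3),
    g2 = if (model_id == "MR-DoC2") runif(1, 0.05, 0.3) else 0,
    b1 = if (model_id != "DoC") runif(1, 0.1, 0.25) else 0,
    b2 = if (model_id == "MR-DoC") runif(1, 0.1, 0.25) else 0,
    b3 = if (model_id == "MR-DoC2") runif(1, 0.1, 0.25) else 0,
    rf = if (model_id == "MR-DoC2") runif(1, -0.4, 0.5) else 0,
    aX2 = a[1], cX2 = c_[1], eX2 = e[1],
    aY2 = a[2], cY2 = c_[2], eY2 = e[2])
  correlations_to_covariances(th,
    ra = runif(1, -0.3, 0.4), rc = runif(1, -0.3, 0.4),
    re = if (model_id == "MR-DoC2") runif(1, -0.3, 0.4) else NULL)
}

# Independent constrained-minimum search: coarse grid around the starting
# values followed by Nelder-Mead polish of the best grid points.  Shares
# only the discrepancy definition with fit_model(), not the search path.
brute_force_constrained_F <- function(spec, S_mz, S_dz, theta, fix = c(g1 = 0),
                                      step = 0.12, n_polish = 10) {
  free <- setdiff(spec$free, names(fix))
  v0 <- unlist(unclass(theta)[free])
  obj <- function(v) {
    vals <- unclass(theta)
    vals[free] <- as.list(v)
    vals[names(fix)] <- as.list(fix)
    f <- try(suppressWarnings(
      ml_discrepancy(spec, do.call(parameter_set, vals), S_mz, S_dz)),
      silent = TRUE)
    if (inherits(f, "try-error") || !is.finite(f)) 1e9 else f
  }
  gr <- as.matrix(expand.grid(lapply(v0, function(x) x + c(-step, 0, step))))
  vals <- apply(gr, 1, obj)
  best <- Inf
  for (j in order(vals)[seq_len(n_polish)]) {
    o <- optim(gr[j, ], obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Mid-level Table-1-style generating values for each model.
mid_theta <- function(model_id) {
  th <- parameter_set(
    g1 = sqrt(0.02),
    g2 = if (model_id == "MR-DoC2") sqrt(0.02) else 0,
    b1 = if (model_id != "DoC") sqrt(0.025) else 0,
    b2 = if (model_id == "MR-DoC") sqrt(0.03) else 0,
    b3 = if (model_id == "MR-DoC2") sqrt(0.025) else 0,
    rf = if (model_id == "MR-DoC2") 0.2 else 0,
    aX2 = 0.4, cX2 = 0.2, eX2 = 0.4, aY2 = 0.4, cY2 = 0.2, eY2 = 0.4)
  correlations_to_covariances(th, ra = 0.2, rc = 0.2,
    re = if (model_id == "MR-DoC2") 0.2 else NULL)
}
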