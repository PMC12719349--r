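#' Multigroup normal-theory ML discrepancy
#'
#' Maximum-likelihood fit function for covariance-structure models over the
#' two zygosity groups, on the -2lnL-difference scale:
#' \deqn{F(\theta) = \sum_{g \in \{MZ, DZ\}} n_g \left[\ln|\Sigma_g(\theta)|
#'   + \mathrm{tr}\!\left(S_g \Sigma_g(\theta)^{-1}\right) - \ln|S_g|
#'   - 2k\right],}
#' where `S_g` is the group's data covariance (each twin *pair* is one
#' observation, so `n_g` counts pairs) and `Sigma_g(theta)` the model-implied
#' matrix.  `F >= 0` with equality iff the model reproduces both matrices
#' exactly; differences of `F` between nested fits to exact-moment data are
#' likelihood-ratio non-centrality parameters.
#'
#' A model-implied matrix that is not positive definite yields `+Inf` (a
#' step-rejection sentinel, so variance components can roam unbounded
#' during optimization); a non-positive-definite *data* matrix is an error.
#'
#' Because monozygotic twins carry identical polygenic scores, the full MZ
#' covariance matrix of a model with PGS variables is singular (each PGS is
#' duplicated across twins).  The MZ likelihood is therefore evaluated on
#' the non-degenerate vector in which each PGS appears once; the DZ group
#' uses all `2k` variables.  `k` in the formula is the per-group
#' likelihood-vector dimension.
#'
#' @param spec A [model_spec()].
#' @param theta A [parameter_set()] (reliabilities are ignored: fitted
#'   models assume fully reliable indicators).
#' @param S_mz,S_dz Data covariance matrices, as [twin_covariance()] objects.
#' @param n_mz,n_dz Pair counts of the two groups.
#' @return Scalar discrepancy value (possibly `Inf`).
#' @export
ml_discrepancy <- function(spec, theta, S_mz, S_dz, n_mz = 1000, n_dz = 1000) {
  stopifnot(n_mz > 0, n_dz > 0)
  pre <- .prepare_data(spec, list(S_mz, S_dz))
  .ml_discrepancy_fast(spec, theta, pre, c(n_mz, n_dz))
}

.model_labels <- function(spec) {
  c(paste0(spec$observed_vars, "_1"), paste0(spec$observed_vars, "_2"))
}

# Monozygotic twins carry identical polygenic scores, so in the MZ group
# each PGS is a degenerate duplicate of its co-twin's and the full 2k x 2k
# MZ matrix is singular (positive semidefinite only).  The likelihood is
# formed on the non-degenerate MZ vector: each PGS enters once (twin 1's
# copy); the DZ group keeps all 2k variables.
.lik_index <- function(spec, zygosity) {
  labs <- .model_labels(spec)
  if (zygosity == "DZ") return(seq_along(labs))
  drop <- paste0(intersect(c("PS1", "PS2"), spec$observed_vars), "_2")
  which(!(labs %in% drop))
}

# Precompute per-group likelihood-vector index, log|S| and dimension;
# errors on non-PD (reduced) data.
.prepare_data <- function(spec, S_list) {
  labs <- .model_labels(spec)
  zyg <- c("MZ", "DZ")
  lapply(1:2, function(g) {
    S <- S_list[[g]]
    stopifnot(inherits(S, "twinmr_covariance"))
    if (!identical(S$var_labels, labs))
      stop("data covariance variables do not match the ", spec$model_id,
           " model's observed vector (", paste(labs, collapse = ", "), ")")
    idx <- .lik_index(spec, zyg[g])
    Ssub <- S$sigma[idx, idx, drop = FALSE]
    R <- tryCatch(chol(Ssub), error = function(e) NULL)
    if (is.null(R)) stop("data covariance matrix is not positive definite")
    list(S = Ssub, idx = idx, logdet = 2 * sum(log(diag(R))), k2 = length(idx))
  })
}

# Bare-matrix covariance evaluation for the optimizer hot loop: no S3
# wrapping, no structural validation (the caller fixes the template), rel
# forced to 1 upstream.
.expected_sigma <- function(spec, theta, r_g) {
  bl <- .blocks_bare(theta, r_g)
  idx <- spec$var_idx
  w <- bl$within[idx, idx, drop = FALSE]
  x <- bl$cross[idx, idx, drop = FALSE]
  rbind(cbind(w, x), cbind(x, w))
}

.ml_discrepancy_fast <- function(spec, theta, pre, n) {
  r_gs <- c(1, 0.5)
  f <- 0
  for (g in 1:2) {
    if (abs(theta$g1 * theta$g2) >= 1) return(Inf)
    sigma <- .expected_sigma(spec, theta, r_gs[g])
    sigma <- sigma[pre[[g]]$idx, pre[[g]]$idx, drop = FALSE]
    R <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    logdet <- 2 * sum(log(diag(R)))
    trace <- sum(pre[[g]]$S * chol2inv(R))
    f <- f + n[g] * (logdet + trace - pre[[g]]$logdet - pre[[g]]$k2)
  }
  f
}

#' Fit result of a maximum-likelihood model fit
#'
#' @description Returned by [fit_model()].  Fields: `estimates` (a
#' [parameter_set()] with free entries at the ML solution and fixed entries
#' echoed exactly), `minus2lnL` (the ML discrepancy at the solution, on the
#' -2lnL difference scale), `status` (`"converged-clean"`,
#' `"converged-warn"` or `"failed"`), `n_evals` (objective evaluations
#' spent) and `gradient_norm` (max absolute numerical gradient at the
#' solution).  `"converged-clean"` corresponds to an estimation that
#' finished without warnings: the optimizer converged, the implied matrices
#' are positive definite and the scaled gradient norm is below tolerance.
#'
#' @param x A `twinmr_fit`.
#' @param ... Unused.
#' @name twinmr_fit
NULL

#' @export
print.twinmr_fit <- function(x, ...) {
  cat("ML fit (", x$model_id, "): status ", x$status,
      ", -2lnL discrepancy = ", format(x$minus2lnL, digits = 8),
      ", ", x$n_evals, " evaluations, |grad| = ",
      format(x$gradient_norm, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Maximum-likelihood fit of a twin model to MZ/DZ covariance matrices
#'
#' Minimizes [ml_discrepancy()] over the model's free parameters (optionally
#' minus extra constrained ones) with a quasi-Newton optimizer
#' ([stats::nlminb()]), numerically evaluated derivatives, and up to
#' `restarts` seeded jittered restarts if the first pass does not converge
#' cleanly.  Variance components are unbounded (they may go negative);
#' inadmissible implied matrices are rejected through the `+Inf` sentinel.
#'
#' With exact-moment data generated from the same model, starting at the
#' generating values, the fit recovers the generating parameters and a
#' discrepancy of zero to numerical precision.
#'
#' @inheritParams ml_discrepancy
#' @param start A [parameter_set()] of starting values (fixed entries are
#'   overwritten by the model's identification fixes).
#' @param extra_fixed Named list/vector of additional parameters to fix
#'   (e.g. `list(g1 = 0)` for the causal-path likelihood-ratio test); names
#'   must belong to the model's free set.
#' @param restarts Maximum number of jittered restarts.
#' @param seed Integer seed for the restart jitter.
#' @return An object of class `twinmr_fit`; see [twinmr_fit].
#' @export
#' @examples
#' spec <- model_spec("DoC")
#' theta <- parameter_set(g1 = sqrt(0.03), covA = 0.08, covC = 0.04)
#' S_mz <- expected_covariance(spec, theta, "MZ")
#' S_dz <- expected_covariance(spec, theta, "DZ")
#' f <- fit_model(spec, S_mz, S_dz, start = theta)
#' f$minus2lnL   # ~0: exact-data recovery
fit_model <- function(spec, S_mz, S_dz, n_mz = 1000, n_dz = 1000,
                      start, extra_fixed = NULL, restarts = 5, seed = 1L) {
  stopifnot(inherits(spec, "twinmr_model"), inherits(start, "twinmr_parameters"))
  extra_fixed <- as.list(extra_fixed)
  if (length(extra_fixed)) {
    bad <- setdiff(names(extra_fixed), spec$free)
    if (length(bad))
      stop("extra_fixed must be a subset of the free set; not free: ",
           paste(bad, collapse = ", "))
  }
  free <- setdiff(spec$free, names(extra_fixed))
  pre <- .prepare_data(spec, list(S_mz, S_dz))
  n <- c(n_mz, n_dz)

  # template: start values with model fixes and extra constraints imposed
  template <- unclass(start)
  template[names(spec$fixed)] <- as.list(spec$fixed)
  template[names(extra_fixed)] <- extra_fixed
  template$rel1 <- 1
  template$rel2 <- 1

  make_theta <- function(v) {
    template[free] <- as.list(v)
    # bypass constructor checks in the hot loop; admissibility handled by
    # the PD sentinel and the |g1*g2| gate below
    if (abs(template$g1 * template$g2) >= 1) return(NULL)
    structure(template, class = "twinmr_parameters")
  }
  n_evals <- 0L
  objective <- function(v) {
    n_evals <<- n_evals + 1L
    th <- make_theta(v)
    if (is.null(th)) return(1e12)
    f <- .ml_discrepancy_fast(spec, th, pre, n)
    if (!is.finite(f)) 1e12 else f
  }

  v0 <- unlist(template[free])
  # F is on the -2lnL scale of ~2000 pairs: a gradient of 1e-3 is ~5e-7
  # per observation, the floor achievable with finite-difference
  # derivatives at rel.tol 1e-12
  grad_tol <- function(f) 1e-3 * max(1, abs(f))

  best <- NULL
  for (attempt in 0:restarts) {
    v_start <- if (attempt == 0) {
      v0
    } else if (!is.null(best) && is.finite(best$opt$objective) &&
               best$opt$objective < 1e11 && attempt %% 2 == 1) {
      # polish pass: re-enter the optimizer near the best point found
      best$opt$par + .jitter(length(v0), seed + attempt, sd = 1e-4)
    } else {
      v0 + .jitter(length(v0), seed + attempt, sd = 0.05)
    }
    opt <- tryCatch(
      stats::nlminb(v_start, objective,
                    control = list(eval.max = 5000, iter.max = 2000,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    gr <- tryCatch(pracma::grad(objective, opt$par, heps = 1e-6),
                   error = function(e) rep(NA_real_, length(opt$par)))
    gnorm <- if (all(is.finite(gr))) max(abs(gr)) else Inf
    # "without warnings": admissible solution (finite F, PD implied
    # matrices) with a near-zero gradient; nlminb's own code is advisory
    # only (it reports false convergence when started at the optimum)
    clean <- is.finite(opt$objective) && opt$objective < 1e11 &&
      gnorm <= grad_tol(opt$objective)
    cand <- list(opt = opt, gnorm = gnorm, clean = clean)
    if (is.null(best) || opt$objective < best$opt$objective - 1e-10 ||
        (clean && !best$clean &&
         opt$objective <= best$opt$objective + 1e-8))
      best <- cand
    if (best$clean) break
  }

  if (is.null(best) || !is.finite(best$opt$objective) ||
      best$opt$objective >= 1e11) {
    status <- "failed"
    est <- make_theta(v0)
    f_val <- NA_real_
    gnorm <- NA_real_
  } else {
    status <- if (best$clean) "converged-clean" else "converged-warn"
    est <- make_theta(best$opt$par)
    f_val <- best$opt$objective
    gnorm <- best$gnorm
  }

  structure(list(
    model_id = spec$model_id,
    estimates = est,
    free = free,
    minus2lnL = f_val,
    status = status,
    n_evals = n_evals,
    gradient_norm = gnorm), class = "twinmr_fit")
}

# Seeded jitter that leaves the caller's RNG stream untouched.
.jitter <- function(n, seed, sd = 0.05) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  stats::rnorm(n, sd = sd)
}

#' Likelihood-ratio non-centrality parameter for a nested constraint
#'
#' Fits the model twice to exact-moment data — unconstrained, and with the
#' null constraints imposed — and returns the difference in the ML
#' discrepancy, which for exact data equals the non-centrality parameter
#' (NCP) of the likelihood-ratio test of those constraints.  Tiny negative
#' differences from numerical round-off (> -1e-6) are clipped to zero.
#'
#' @inheritParams fit_model
#' @param null_constraints Named list of constrained values defining the
#'   null hypothesis, e.g. `list(g1 = 0)`.
#' @return List with `ncp`, `df` (number of constraints), and the two
#'   `twinmr_fit` objects (`fit_free`, `fit_null`).
#' @export
ncp_for_test <- function(spec, S_mz, S_dz, n_mz = 1000, n_dz = 1000,
                         start, null_constraints, seed = 1L) {
  stopifnot(length(null_constraints) >= 1)
  f1 <- fit_model(spec, S_mz, S_dz, n_mz, n_dz, start = start, seed = seed)
  f0 <- fit_model(spec, S_mz, S_dz, n_mz, n_dz, start = start,
                  extra_fixed = null_constraints, seed = seed + 1L)
  if (f1$status == "failed" || f0$status == "failed")
    stop("fit failed (free: ", f1$status, ", constrained: ", f0$status, ")")
  ncp <- f0$minus2lnL - f1$minus2lnL
  if (ncp < 0 && ncp > -1e-6) ncp <- 0
  list(ncp = ncp, df = length(null_constraints),
       fit_free = f1, fit_null = f0)
}

#' Power of a likelihood-ratio test from its non-centrality parameter
#'
#' Computes `P[chisq(df, ncp) > q]` with `q` the `1 - alpha` quantile of the
#' central chi-square: the asymptotic power of the likelihood-ratio test at
#' type-I error rate `alpha` when the true alternative implies
#' non-centrality `ncp`.
#'
#' @param ncp Non-centrality parameter (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @param alpha Type-I error rate.
#' @return Power in `[alpha, 1]`.
#' @export
#' @examples
#' power_from_ncp(7.849, df = 1)   # ~0.80
power_from_ncp <- function(ncp, df = 1, alpha = 0.05) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  if (any(ncp < -1e-6)) stop("ncp must be nonnegative")
  ncp <- pmax(ncp, 0)
  q <- stats::qchisq(1 - alpha, df)
  out <- stats::pchisq(q, df, ncp = ncp, lower.tail = FALSE)
  # the central case is alpha by construction; return it exactly
  out[ncp == 0] <- alpha
  out
}

#' Serialize a fit result to JSON
#'
#' @param fit A `twinmr_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "twinmr_fit"))
  x <- list(model_id = fit$model_id,
            estimates = unclass(fit$estimates),
            minus2lnL = fit$minus2lnL,
            status = fit$status,
            n_evals = fit$n_evals,
            gradient_norm = fit$gradient_norm)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
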