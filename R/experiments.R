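#' Scenario tags for the bias experiments
#'
#' A bias experiment is defined by a generating model, a fitted model, and
#' a distortion scenario: `"none"` (exact own-structure data),
#' `"meas-error"` (reliabilities 0.9 / 0.7 on exposure / outcome),
#' `"re+0.3"` / `"re-0.3"` (unshared-environment confounding injected into
#' the generating structure while DoC and MR-DoC are still fitted with
#' re = 0).  Cross-model runs (generating MR-DoC2, fitting DoC or MR-DoC)
#' marginalize the generated covariance to the fitted model's observed
#' variables.
#'
#' @param generating_model,fitted_model Model ids.
#' @param scenario One of `"none"`, `"meas-error"`, `"re+0.3"`, `"re-0.3"`.
#' @return The composite scenario tag used in records and summaries.
#' @export
scenario_tag <- function(generating_model, fitted_model, scenario) {
  base <- if (identical(generating_model, fitted_model)) {
    if (scenario == "none") "own-model" else scenario
  } else {
    if (scenario == "none") "mrdoc2-generated"
    else paste0("mrdoc2-generated+", scenario)
  }
  base
}

# distortion parameters used throughout the measurement-error study
.MEAS_REL <- c(rel1 = 0.9, rel2 = 0.7)
.RE_LEVEL <- 0.3

#' Registry of the package's headline experiments
#'
#' Enumerates every (generating model, fitted model, scenario) combination
#' of the bias studies plus the three power-profile experiments, each
#' invocable through [run_bias_experiment()] / [run_power_experiment()]
#' (and the bundled command-line wrapper).
#'
#' @return Data frame with columns `experiment`, `design_id`,
#'   `generating_model`, `fitted_model`, `scenario`, `tag`.
#' @export
experiment_registry <- function() {
  models <- c("DoC", "MR-DoC", "MR-DoC2")
  designs <- c("DoC" = 1L, "MR-DoC" = 2L, "MR-DoC2" = 3L)
  own <- expand.grid(fitted_model = models,
                     scenario = c("meas-error", "re+0.3", "re-0.3"),
                     stringsAsFactors = FALSE)
  own$generating_model <- own$fitted_model
  own$design_id <- designs[own$generating_model]
  cross <- expand.grid(fitted_model = models,
                       scenario = c("none", "meas-error", "re+0.3", "re-0.3"),
                       stringsAsFactors = FALSE)
  cross$generating_model <- "MR-DoC2"
  cross$design_id <- 3L
  cross <- cross[cross$fitted_model != "MR-DoC2" | cross$scenario == "none", ]
  bias <- rbind(own[, c("design_id", "generating_model", "fitted_model", "scenario")],
                cross[, c("design_id", "generating_model", "fitted_model", "scenario")])
  bias$experiment <- "bias"
  power <- data.frame(design_id = unname(designs), generating_model = models,
                      fitted_model = models, scenario = "none",
                      experiment = "power", stringsAsFactors = FALSE)
  out <- rbind(bias, power)
  out$tag <- mapply(scenario_tag, out$generating_model, out$fitted_model,
                    out$scenario)
  rownames(out) <- NULL
  out[, c("experiment", "design_id", "generating_model", "fitted_model",
          "scenario", "tag")]
}

# Starting values for fitting `fitted_spec` to data generated by theta_gen:
# generating values with the fitted model's identification fixes imposed.
.bias_start <- function(fitted_spec, theta_gen) {
  vals <- unclass(theta_gen)
  vals[names(fitted_spec$fixed)] <- as.list(fitted_spec$fixed)
  vals$rel1 <- 1
  vals$rel2 <- 1
  do.call(parameter_set, vals)
}

#' Run one bias experiment over a design grid
#'
#' For every cell: build the generating parameter set, apply the scenario
#' distortion (re injection at the parameter level, measurement error at
#' the covariance level), marginalize if the fitted model is smaller than
#' the generating one, fit the fitted model by maximum likelihood, and
#' record `estimate - true` for every free parameter of the fitted model
#' plus the derived confounding correlations.
#'
#' @param generating_model,fitted_model Model ids; when they differ the
#'   generating model must contain the fitted model's observed variables
#'   (the supported case is generating `"MR-DoC2"`).
#' @param scenario `"none"`, `"meas-error"`, `"re+0.3"` or `"re-0.3"`.
#' @param grid A [build_grid()] for the generating model's design.
#' @param n_mz,n_dz Pair counts per zygosity group.
#' @param seed Base seed for optimizer restarts.
#' @return Data frame of bias records: `cell_id`, `parameter`,
#'   `true_value`, `estimate`, `bias`, `scenario`, `generating_model`,
#'   `fitted_model`, `status`.
#' @export
run_bias_experiment <- function(generating_model, fitted_model,
                                scenario = c("none", "meas-error",
                                             "re+0.3", "re-0.3"),
                                grid, n_mz = 1000, n_dz = 1000, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(grid, "twinmr_grid"))
  if (grid$model != generating_model)
    stop("grid was built for ", grid$model, ", not ", generating_model)
  if (generating_model != fitted_model && generating_model != "MR-DoC2")
    stop("cross-model runs require the generating model to be MR-DoC2")
  gen_spec <- model_spec(generating_model)
  fit_spec <- model_spec(fitted_model)
  tag <- scenario_tag(generating_model, fitted_model, scenario)

  records <- vector("list", nrow(grid$cells))
  n_failed <- 0L
  for (i in seq_len(nrow(grid$cells))) {
    theta_gen <- cell_parameters(grid, i)
    if (scenario == "re+0.3") theta_gen <- inject_re(theta_gen, .RE_LEVEL)
    if (scenario == "re-0.3") theta_gen <- inject_re(theta_gen, -.RE_LEVEL)
    covs <- lapply(c("MZ", "DZ"), function(z)
      expected_covariance(gen_spec, theta_gen, z))
    if (scenario == "meas-error")
      covs <- lapply(covs, add_measurement_error,
                     rel1 = .MEAS_REL[["rel1"]], rel2 = .MEAS_REL[["rel2"]])
    if (generating_model != fitted_model)
      covs <- lapply(covs, marginalize, target = fit_spec)
    start <- .bias_start(fit_spec, theta_gen)
    f <- fit_model(fit_spec, covs[[1]], covs[[2]], n_mz, n_dz,
                   start = start, seed = seed + i)
    ok <- f$status != "failed"
    if (!ok) n_failed <- n_failed + 1L

    pars <- fit_spec$free
    true_vals <- unlist(unclass(theta_gen)[pars])
    est_vals <- if (ok) unlist(unclass(f$estimates)[pars])
                else rep(NA_real_, length(pars))
    rr_true <- component_correlations(theta_gen)
    rr_est <- if (ok) component_correlations(f$estimates)
              else c(ra = NA_real_, rc = NA_real_, re = NA_real_)
    keep_r <- c("ra", "rc", if ("covE" %in% fit_spec$free) "re")
    records[[i]] <- data.frame(
      cell_id = grid$cells$cell_id[i],
      parameter = c(pars, keep_r),
      true_value = c(true_vals, rr_true[keep_r]),
      estimate = c(est_vals, rr_est[keep_r]),
      scenario = tag,
      generating_model = generating_model,
      fitted_model = fitted_model,
      status = f$status,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (n_failed == nrow(grid$cells))
    stop("all cells failed to fit in scenario ", tag)
  out <- do.call(rbind, records)
  out$bias <- out$estimate - out$true_value
  out
}

#' Summarize bias records into a scenario x model x parameter table
#'
#' Mean of per-cell bias over converged cells, with the number of excluded
#' (non-converged) cells reported per stratum.
#'
#' @param records Output of [run_bias_experiment()] (possibly row-bound
#'   over several scenarios).
#' @return Data frame with `scenario`, `fitted_model`, `parameter`,
#'   `mean_bias`, `n_cells`, `n_excluded`.
#' @export
summarize_bias <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  strata <- interaction(records$scenario, records$fitted_model,
                        records$parameter, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(records)), strata), function(idx) {
    r <- records[idx, ]
    good <- r$status != "failed"
    data.frame(scenario = r$scenario[1], fitted_model = r$fitted_model[1],
               parameter = r$parameter[1],
               mean_bias = mean(r$bias[good]),
               n_cells = sum(good), n_excluded = sum(!good),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$scenario, out$fitted_model, out$parameter), ]
}

#' Run the power-profile experiment for one model over its design grid
#'
#' For every cell: compute the exact MZ/DZ covariance matrices, rescale
#' both to correlation matrices, fit the model unconstrained and with
#' `g1 = 0`, record the -2lnL difference as the non-centrality parameter of
#' the 1-df causal-path test, and convert it to power at the given alpha.
#' Starting values for the correlation-scale fits are obtained in closed
#' form with [rescale_parameters()].
#'
#' @param grid A [build_grid()] for the model's design.
#' @param alpha Type-I error rate of the test.
#' @param n_mz,n_dz Pair counts per group.
#' @param standardized Rescale the matrices to correlations before fitting
#'   (the default, as in the power study).
#' @param seed Base seed for optimizer restarts.
#' @return Data frame with the cell's factor values plus `cell_id`, `ncp`,
#'   `power`, `status_free`, `status_null`.
#' @export
run_power_experiment <- function(grid, alpha = 0.05, n_mz = 1000, n_dz = 1000,
                                 standardized = TRUE, seed = 1L) {
  stopifnot(inherits(grid, "twinmr_grid"))
  spec <- model_spec(grid$model)
  cells <- grid$cells
  ncp <- power <- rep(NA_real_, nrow(cells))
  status_free <- status_null <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    theta <- cell_parameters(grid, i)
    S_mz <- expected_covariance(spec, theta, "MZ")
    S_dz <- expected_covariance(spec, theta, "DZ")
    start <- theta
    if (standardized) {
      d <- 1 / sqrt(diag(S_mz$sigma)[seq_along(spec$observed_vars)])
      names(d) <- spec$observed_vars
      start <- rescale_parameters(theta, d)
      S_mz <- standardize(S_mz)
      S_dz <- standardize(S_dz)
    }
    res <- tryCatch(
      ncp_for_test(spec, S_mz, S_dz, n_mz, n_dz, start = start,
                   null_constraints = list(g1 = 0), seed = seed + i),
      error = function(e) NULL)
    if (is.null(res)) {
      status_free[i] <- status_null[i] <- "failed"
      next
    }
    ncp[i] <- res$ncp
    power[i] <- power_from_ncp(res$ncp, df = 1, alpha = alpha)
    status_free[i] <- res$fit_free$status
    status_null[i] <- res$fit_null$status
  }
  cbind(cells, data.frame(ncp = ncp, power = power,
                          status_free = status_free,
                          status_null = status_null,
                          stringsAsFactors = FALSE))
}

#' Regress non-centrality parameters on the design factors
#'
#' Ordinary least squares of the per-cell NCP on the design's factor values
#' (main effects plus intercept).  Predictors are z-scored for coefficient
#' display, which leaves the R-squared unchanged; the reported coefficients
#' are therefore per-standard-deviation effects of each factor on the NCP.
#'
#' @param power_records Output of [run_power_experiment()].
#' @param factor_table Named list of factor levels (from the grid), naming
#'   the predictor columns.
#' @return List with `coefficients` (data frame: `factor`, `coefficient`)
#'   and `r_squared`.
#' @export
regress_ncp <- function(power_records, factor_table) {
  factors <- names(factor_table)
  stopifnot(all(factors %in% names(power_records)))
  ok <- is.finite(power_records$ncp)
  if (sum(ok) < 10 * length(factors))
    stop("need at least 10 records per factor (",
         sum(ok), " usable records, ", length(factors), " factors)")
  X <- scale(as.matrix(power_records[ok, factors, drop = FALSE]))
  dat <- data.frame(ncp = power_records$ncp[ok], X)
  fit <- stats::lm(ncp ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear factor(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  list(coefficients = data.frame(factor = factors,
                                 coefficient = unname(cf[factors]),
                                 stringsAsFactors = FALSE),
       r_squared = summary(fit)$r.squared)
}

#' Fraction of estimations finishing without warnings
#'
#' The "code zero" rate: the proportion of all model fits in a batch of
#' power or bias records whose status is `converged-clean`.
#'
#' @param records Output of [run_power_experiment()] (counts both the free
#'   and the constrained fit per cell) or of [run_bias_experiment()].
#' @return Proportion in `[0, 1]`.
#' @export
convergence_rate <- function(records) {
  if (all(c("status_free", "status_null") %in% names(records))) {
    st <- c(records$status_free, records$status_null)
  } else if ("status" %in% names(records)) {
    # bias records carry one row per parameter; one status per cell
    st <- records$status[!duplicated(records$cell_id)]
  } else stop("records carry no status columns")
  mean(st == "converged-clean")
}
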