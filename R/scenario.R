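#' Distort a twin covariance with phenotypic measurement error
#'
#' Replaces the (latent) traits by unreliable observed indicators: each
#' observed trait loads on its latent trait with coefficient equal to the
#' square root of the reliability and carries residual variance one minus
#' the reliability.  The error is twin-specific and non-transmissible, so at
#' the covariance level every off-diagonal entry involving a trait
#' (within-twin, cross-twin, and trait-PGS) is scaled by `sqrt(rel)` per
#' trait involved, the trait diagonal becomes `rel * var_latent + (1 - rel)`,
#' and all PGS-only entries are untouched.
#'
#' @param cov A [twin_covariance()] of latent-trait structure.
#' @param rel1,rel2 Reliabilities of Trait 1 and Trait 2, in (0, 1].
#' @return A distorted [twin_covariance()].
#' @export
#' @examples
#' spec <- model_spec("DoC")
#' theta <- parameter_set(g1 = sqrt(0.02))
#' add_measurement_error(expected_covariance(spec, theta, "MZ"), 0.9, 0.7)
add_measurement_error <- function(cov, rel1, rel2) {
  stopifnot(inherits(cov, "twinmr_covariance"))
  if (rel1 <= 0 || rel1 > 1) stop("rel1 must lie in (0, 1]")
  if (rel2 <= 0 || rel2 > 1) stop("rel2 must lie in (0, 1]")
  labs <- cov$var_labels
  base <- sub("_[12]$", "", labs)
  lam <- ifelse(base == "T1", sqrt(rel1), ifelse(base == "T2", sqrt(rel2), 1))
  resid <- ifelse(base == "T1", 1 - rel1, ifelse(base == "T2", 1 - rel2, 0))
  sigma <- cov$sigma * tcrossprod(lam)     # scale all trait rows/columns
  diag(sigma) <- diag(sigma) + resid       # twin-specific error variance
  twin_covariance(sigma, cov$zygosity, labs)
}

#' Inject unshared-environment confounding into a parameter set
#'
#' Sets the cross-trait E covariance to the value implied by a target
#' unshared-environment correlation `re`, `covE = re * sqrt(eX2 * eY2)`.
#' Used to generate data in which the usual identification assumption
#' re = 0 of the DoC and MR-DoC models is violated.
#'
#' @param theta A [parameter_set()] with `eX2 * eY2 > 0`.
#' @param re_value Target correlation of the two traits' E factors.
#' @return `theta` with `covE` replaced.
#' @export
inject_re <- function(theta, re_value) {
  stopifnot(inherits(theta, "twinmr_parameters"))
  if (abs(re_value) > 1) stop("|re_value| must be <= 1")
  if (theta$eX2 * theta$eY2 <= 0) stop("re undefined: eX2 * eY2 <= 0")
  update_parameters(theta, covE = re_value * sqrt(theta$eX2 * theta$eY2))
}

#' Marginalize a twin covariance to a smaller model's observed variables
#'
#' Extracts the submatrix over the target model's per-twin observed
#' variables (both twins), preserving the package's variable ordering.
#' This is how DoC or MR-DoC is fitted to data generated under the richer
#' MR-DoC2 structure.
#'
#' @param cov A [twin_covariance()].
#' @param target A [model_spec()] whose `observed_vars` are contained in
#'   `cov`'s variables.
#' @return A [twin_covariance()] of size 2k' x 2k'.
#' @export
marginalize <- function(cov, target) {
  stopifnot(inherits(cov, "twinmr_covariance"), inherits(target, "twinmr_model"))
  want <- c(paste0(target$observed_vars, "_1"), paste0(target$observed_vars, "_2"))
  missing <- setdiff(want, cov$var_labels)
  if (length(missing))
    stop("variable(s) absent from covariance: ", paste(missing, collapse = ", "))
  twin_covariance(cov$sigma[want, want, drop = FALSE], cov$zygosity, want)
}

#' Exact-moment multivariate-normal sample
#'
#' Draws an `n x 2k` Gaussian sample whose column means are exactly zero
#' and whose sample covariance (denominator `n - 1`) exactly equals the
#' requested matrix: a raw Gaussian draw is centered, whitened by the
#' inverse Cholesky factor of its own empirical covariance, and recolored
#' by the Cholesky factor of the target.  Fitting a model to such a sample
#' is likelihood-equivalent to fitting the covariance matrix directly, so
#' likelihood-ratio differences are exact non-centrality parameters.
#'
#' @param cov A positive-definite [twin_covariance()].
#' @param n Number of twin pairs (rows); must exceed the vector dimension.
#' @param seed Integer seed; same seed, same matrix.
#' @return Numeric matrix `n x 2k` with columns labeled as in `cov`.
#' @export
exact_sample <- function(cov, n, seed = 1L) {
  stopifnot(inherits(cov, "twinmr_covariance"))
  p <- ncol(cov$sigma)
  if (n <= p) stop("n must exceed the observed-vector dimension (", p, ")")
  R <- tryCatch(chol(cov$sigma), error = function(e)
    stop("covariance matrix is not positive definite"))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Rz <- chol(stats::cov(Z))
  X <- Z %*% solve(Rz) %*% R
  colnames(X) <- cov$var_labels
  X
}

#' Sample covariance of a raw sample as a twin covariance object
#'
#' Convenience for the raw-data cross-validation path: computes the
#' `n - 1`-denominator sample covariance of a matrix produced by
#' [exact_sample()] and wraps it for [fit_model()].
#'
#' @param x Numeric matrix with labeled columns.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A [twin_covariance()].
#' @export
sample_covariance <- function(x, zygosity = c("MZ", "DZ")) {
  twin_covariance(stats::cov(x), match.arg(zygosity), colnames(x))
}
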