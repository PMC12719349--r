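#' Construct a parameter set for the twin causal models
#'
#' A `twinmr_parameters` object collects every generating (and estimable)
#' quantity of the bivariate twin models: the causal paths between the two
#' traits, the polygenic-score (PGS) instrument paths, the ACE variance
#' components of the trait residuals, their cross-trait covariance
#' components, the PGS variances and correlation, and the reliabilities of
#' the observed trait indicators.
#'
#' All paths are on the standardized-latent-trait scale used throughout the
#' factorial designs: the residual ACE components of each trait sum to 1 in
#' generating cells, so `g1`, `b1`, ... are directly comparable across
#' parameters.
#'
#' @param g1 Causal effect of Trait 1 on Trait 2.
#' @param g2 Causal effect of Trait 2 on Trait 1 (MR-DoC2 only).
#' @param b1 Effect of PGS 1 on Trait 1 (instrument strength for the
#'   exposure).
#' @param b2 Direct horizontal-pleiotropy effect of PGS 1 on Trait 2
#'   (MR-DoC only).
#' @param b3 Effect of PGS 2 on Trait 2 (instrument for the outcome,
#'   MR-DoC2 only).
#' @param rf Correlation between the two polygenic scores within a person.
#' @param sigma2_ps1,sigma2_ps2 Variances of the two polygenic scores.
#' @param aX2,cX2,eX2 Additive-genetic, shared-environment and
#'   unshared-environment variance components of Trait 1's residual.
#' @param aY2,cY2,eY2 The same components for Trait 2's residual.
#' @param covA,covC,covE Cross-trait covariances of the A, C and E factors
#'   (the confounding channels; the derived correlations are `ra`, `rc`,
#'   `re`, see [component_correlations()]).
#' @param rel1,rel2 Reliabilities of the observed Trait 1 / Trait 2
#'   indicators, in (0, 1]; 1 means the trait is measured without error.
#' @return A named list of class `twinmr_parameters`.
#' @seealso [model_spec()], [expected_covariance()], [component_correlations()]
#' @export
#' @examples
#' theta <- parameter_set(g1 = sqrt(0.02), aX2 = 0.4, cX2 = 0.2, eX2 = 0.4,
#'                        aY2 = 0.4, cY2 = 0.2, eY2 = 0.4)
#' component_correlations(theta)
parameter_set <- function(g1 = 0, g2 = 0, b1 = 0, b2 = 0, b3 = 0,
                          rf = 0, sigma2_ps1 = 1, sigma2_ps2 = 1,
                          aX2 = 0.4, cX2 = 0.2, eX2 = 0.4,
                          aY2 = 0.4, cY2 = 0.2, eY2 = 0.4,
                          covA = 0, covC = 0, covE = 0,
                          rel1 = 1, rel2 = 1) {
  theta <- list(g1 = g1, g2 = g2, b1 = b1, b2 = b2, b3 = b3,
                rf = rf, sigma2_ps1 = sigma2_ps1, sigma2_ps2 = sigma2_ps2,
                aX2 = aX2, cX2 = cX2, eX2 = eX2,
                aY2 = aY2, cY2 = cY2, eY2 = eY2,
                covA = covA, covC = covC, covE = covE,
                rel1 = rel1, rel2 = rel2)
  bad <- names(theta)[!vapply(theta, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("parameter(s) not finite scalars: ", paste(bad, collapse = ", "))
  if (abs(g1 * g2) >= 1)
    stop("non-invertible feedback loop: |g1*g2| must be < 1 (g1 = ",
         g1, ", g2 = ", g2, ")")
  if (rel1 <= 0 || rel1 > 1) stop("rel1 must lie in (0, 1]")
  if (rel2 <= 0 || rel2 > 1) stop("rel2 must lie in (0, 1]")
  if (abs(rf) > 1) stop("rf must lie in [-1, 1]")
  structure(theta, class = "twinmr_parameters")
}

#' @export
print.twinmr_parameters <- function(x, ...) {
  cat("Twin-model parameter set\n")
  cat("  causal:     g1 =", signif(x$g1, 4), " g2 =", signif(x$g2, 4), "\n")
  cat("  instrument: b1 =", signif(x$b1, 4), " b2 =", signif(x$b2, 4),
      " b3 =", signif(x$b3, 4), " rf =", signif(x$rf, 4), "\n")
  cat("  ACE (X):   ", signif(x$aX2, 4), signif(x$cX2, 4), signif(x$eX2, 4), "\n")
  cat("  ACE (Y):   ", signif(x$aY2, 4), signif(x$cY2, 4), signif(x$eY2, 4), "\n")
  cat("  cross-cov:  covA =", signif(x$covA, 4), " covC =", signif(x$covC, 4),
      " covE =", signif(x$covE, 4), "\n")
  rr <- component_correlations(x)
  cat("  derived:    ra =", signif(rr["ra"], 4), " rc =", signif(rr["rc"], 4),
      " re =", signif(rr["re"], 4), "\n")
  if (x$rel1 < 1 || x$rel2 < 1)
    cat("  reliability: rel1 =", x$rel1, " rel2 =", x$rel2, "\n")
  invisible(x)
}

#' Update fields of a parameter set
#'
#' Returns a copy of `theta` with the named fields replaced; all constructor
#' checks are re-applied.
#'
#' @param theta A [parameter_set()].
#' @param ... Named scalar replacements.
#' @return A `twinmr_parameters` object.
#' @export
update_parameters <- function(theta, ...) {
  stopifnot(inherits(theta, "twinmr_parameters"))
  repl <- list(...)
  if (length(repl) == 0L) return(theta)
  unknown <- setdiff(names(repl), names(theta))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  vals <- unclass(theta)
  vals[names(repl)] <- repl
  do.call(parameter_set, vals)
}

#' Cross-trait component correlations and their inverse mapping
#'
#' The models are parameterized in variance components: the A, C and E
#' cross-trait channels carry covariances (`covA`, `covC`, `covE`).  The
#' conventional reporting scale is the correlation of each pair of factors,
#' `ra = covA / sqrt(aX2 * aY2)` (likewise `rc`, `re`).
#' `component_correlations()` derives the correlations;
#' `correlations_to_covariances()` inverts the mapping, which is how the
#' factorial design grids (specified in correlations) are converted to
#' generating covariance components.
#'
#' A correlation whose denominator is not strictly positive (a zero or
#' negative component product, which can occur with unbounded estimated
#' components) is returned as `NA` rather than propagating `NaN`.
#'
#' @param theta A [parameter_set()].
#' @return Named numeric vector `c(ra, rc, re)`, entries `NA` when undefined.
#' @export
component_correlations <- function(theta) {
  stopifnot(inherits(theta, "twinmr_parameters"))
  one <- function(cv, v1, v2) {
    p <- v1 * v2
    if (p <= 0) NA_real_ else cv / sqrt(p)
  }
  c(ra = one(theta$covA, theta$aX2, theta$aY2),
    rc = one(theta$covC, theta$cX2, theta$cY2),
    re = one(theta$covE, theta$eX2, theta$eY2))
}

#' @rdname component_correlations
#' @param ra,rc,re Target correlations of the A, C and E factor pairs.
#' @return For `correlations_to_covariances()`: `theta` with `covA`, `covC`,
#'   `covE` set to `r * sqrt(v1 * v2)`.
#' @export
correlations_to_covariances <- function(theta, ra = NULL, rc = NULL, re = NULL) {
  stopifnot(inherits(theta, "twinmr_parameters"))
  upd <- list()
  if (!is.null(ra)) {
    if (theta$aX2 * theta$aY2 <= 0) stop("ra undefined: aX2 * aY2 <= 0")
    upd$covA <- ra * sqrt(theta$aX2 * theta$aY2)
  }
  if (!is.null(rc)) {
    if (theta$cX2 * theta$cY2 <= 0) stop("rc undefined: cX2 * cY2 <= 0")
    upd$covC <- rc * sqrt(theta$cX2 * theta$cY2)
  }
  if (!is.null(re)) {
    if (theta$eX2 * theta$eY2 <= 0) stop("re undefined: eX2 * eY2 <= 0")
    upd$covE <- re * sqrt(theta$eX2 * theta$eY2)
  }
  do.call(update_parameters, c(list(theta), upd))
}
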