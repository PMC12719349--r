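#' Model specifications: DoC, MR-DoC and MR-DoC2
#'
#' Builds the specification of one of the three bivariate twin causal
#' models:
#'
#' * **DoC** — the classical direction-of-causation twin model.  Observed
#'   variables per twin: the two traits.  The causal path `g1` and the A and
#'   C confounding channels (`covA`, `covC`) are free; identification
#'   requires fixing the unshared-environment confounding `covE = 0` (re = 0)
#'   and the reverse path `g2 = 0`.
#' * **MR-DoC** — DoC augmented with one polygenic score instrumenting the
#'   exposure.  Observed per twin: (PS1, T1, T2).  Frees the instrument path
#'   `b1` and the direct horizontal-pleiotropy path `b2`; fixes `re = 0` and
#'   `g2 = 0` for identification.
#' * **MR-DoC2** — two instruments, bidirectional causation.  Observed per
#'   twin: (PS1, PS2, T1, T2).  Frees `g1`, `g2`, `b1`, `b3`, the
#'   instrument correlation `rf`, and all three confounding channels
#'   including `covE`; fixes the direct pleiotropy path `b2 = 0`.
#'
#' All three models estimate the per-trait A, C and E variance components
#' (unbounded, possibly negative) plus the free cross-trait covariance
#' components; correlations `ra`, `rc`, `re` are derived afterwards with
#' [component_correlations()].  Models with observed polygenic scores also
#' estimate the PGS variances.
#'
#' @param model_id One of `"DoC"`, `"MR-DoC"`, `"MR-DoC2"`.
#' @return An object of class `twinmr_model` with elements `model_id`,
#'   `observed_vars` (per-twin variable ordering), `free` (names of
#'   estimated parameters) and `fixed` (named vector of identification
#'   fixes).
#' @export
#' @examples
#' model_spec("MR-DoC2")$free
model_spec <- function(model_id = c("DoC", "MR-DoC", "MR-DoC2")) {
  model_id <- match.arg(model_id)
  base_free <- c("aX2", "cX2", "eX2", "aY2", "cY2", "eY2", "covA", "covC")
  spec <- switch(model_id,
    "DoC" = list(
      observed_vars = c("T1", "T2"),
      free = c("g1", base_free),
      fixed = c(g2 = 0, b1 = 0, b2 = 0, b3 = 0, rf = 0, covE = 0)),
    "MR-DoC" = list(
      observed_vars = c("PS1", "T1", "T2"),
      free = c("g1", "b1", "b2", "sigma2_ps1", base_free),
      fixed = c(g2 = 0, b3 = 0, rf = 0, covE = 0)),
    "MR-DoC2" = list(
      observed_vars = c("PS1", "PS2", "T1", "T2"),
      free = c("g1", "g2", "b1", "b3", "rf", "sigma2_ps1", "sigma2_ps2",
               base_free, "covE"),
      fixed = c(b2 = 0)))
  spec$var_idx <- match(spec$observed_vars, c("PS1", "PS2", "T1", "T2"))
  structure(c(list(model_id = model_id), spec), class = "twinmr_model")
}

#' @export
print.twinmr_model <- function(x, ...) {
  cat(x$model_id, "model:", length(x$observed_vars),
      "observed variables per twin (",
      paste(x$observed_vars, collapse = ", "), ")\n")
  cat("  free: ", paste(x$free, collapse = ", "), "\n")
  cat("  fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Check a parameter set against a model's structural constraints
#'
#' Verifies that the *path* parameters a model fixes for identification
#' (`g2`, `b1`, `b2`, `b3`, `rf`) hold in `theta`.  The cross-trait
#' E covariance `covE` is deliberately not checked: fixing re = 0 is an
#' estimation-time identification constraint, and misspecification studies
#' generate DoC/MR-DoC data with a nonzero `covE` on purpose.
#'
#' @param spec A [model_spec()].
#' @param theta A [parameter_set()].
#' @param strict Also require `covE` to match the model's fix (used when
#'   validating estimation starting values).
#' @return Invisibly `TRUE`; otherwise an error naming the offending
#'   parameter.
#' @export
validate_parameters <- function(spec, theta, strict = FALSE) {
  stopifnot(inherits(spec, "twinmr_model"), inherits(theta, "twinmr_parameters"))
  fixed <- spec$fixed
  check <- setdiff(names(fixed), if (strict) character(0) else "covE")
  for (nm in check) {
    if (abs(theta[[nm]] - fixed[[nm]]) > 1e-12)
      stop("parameter ", nm, " must be fixed at ", fixed[[nm]],
           " for the ", spec$model_id, " model (got ", theta[[nm]], ")")
  }
  if (abs(theta$g1 * theta$g2) >= 1)
    stop("non-invertible feedback loop: |g1*g2| must be < 1")
  invisible(TRUE)
}
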