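#' Twin-pair covariance objects
#'
#' A `twinmr_covariance` holds the expected (or observed) covariance matrix
#' of one zygosity group's ordered observed vector.  The vector stacks the
#' per-twin observed variables, twin 1 first: labels are `<var>_1` then
#' `<var>_2` with the per-twin ordering (PS1, PS2, T1, T2) restricted to the
#' model's variables.
#'
#' @param sigma Symmetric numeric matrix, 2k x 2k.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param var_labels Character vector of column labels (length 2k).
#' @return An object of class `twinmr_covariance`.
#' @export
twin_covariance <- function(sigma, zygosity = c("MZ", "DZ"), var_labels = NULL) {
  zygosity <- match.arg(zygosity)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma) || nrow(sigma) %% 2L != 0L)
    stop("sigma must be square with an even dimension (two twins)")
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("sigma must be symmetric")
  sigma <- (sigma + t(sigma)) / 2
  if (is.null(var_labels)) var_labels <- colnames(sigma)
  if (is.null(var_labels))
    stop("var_labels required when sigma has no column names")
  dimnames(sigma) <- list(var_labels, var_labels)
  structure(list(zygosity = zygosity, sigma = sigma, var_labels = var_labels),
            class = "twinmr_covariance")
}

#' @export
print.twinmr_covariance <- function(x, digits = 4, ...) {
  cat(x$zygosity, "twin-pair covariance (", nrow(x$sigma), "x",
      ncol(x$sigma), ")\n")
  print(round(x$sigma, digits))
  invisible(x)
}

# Reduced-form within/cross-twin blocks over the full (PS1, PS2, T1, T2)
# per-twin vector. r_g is the genetic cross-twin weight (1 MZ, 0.5 DZ);
# C factors cross twins with weight 1, E factors with weight 0; polygenic
# scores follow the genetic rule for both their variances and their rf
# cross-covariance.  Bare (unnamed) matrices: this sits in the optimizer
# hot loop.
.blocks_bare <- function(theta, r_g) {
  d <- 1 - theta$g1 * theta$g2
  if (abs(d) < 1e-12) stop("non-invertible feedback loop: g1*g2 = 1")
  M <- matrix(c(1, theta$g1, theta$g2, 1), 2, 2) / d   # (I - B)^{-1}
  G <- matrix(c(theta$b1, theta$b2, 0, theta$b3), 2, 2) # PS -> trait paths
  sp <- theta$sigma2_ps1 * theta$sigma2_ps2
  cps <- if (sp > 0) theta$rf * sqrt(sp) else 0
  Sps <- matrix(c(theta$sigma2_ps1, cps, cps, theta$sigma2_ps2), 2, 2)
  SA <- matrix(c(theta$aX2, theta$covA, theta$covA, theta$aY2), 2, 2)
  SC <- matrix(c(theta$cX2, theta$covC, theta$covC, theta$cY2), 2, 2)
  SE <- matrix(c(theta$eX2, theta$covE, theta$covE, theta$eY2), 2, 2)

  MG <- M %*% G
  MGS <- MG %*% Sps
  ps_part <- MGS %*% t(MG)                      # instrument contribution
  within_T  <- ps_part + M %*% (SA + SC + SE) %*% t(M)
  cross_T   <- r_g * ps_part + M %*% (r_g * SA + SC) %*% t(M)

  within <- matrix(0, 4, 4)
  within[1:2, 1:2] <- Sps
  within[3:4, 1:2] <- MGS                       # Cov(T', PS) within a twin
  within[1:2, 3:4] <- t(MGS)
  within[3:4, 3:4] <- within_T
  cross <- matrix(0, 4, 4)
  cross[1:2, 1:2] <- r_g * Sps
  cross[3:4, 1:2] <- r_g * MGS                  # Cov(T'_1, PS_2)
  cross[1:2, 3:4] <- r_g * t(MGS)
  cross[3:4, 3:4] <- cross_T
  list(within = within, cross = cross)
}

.twinmr_blocks <- function(theta, r_g) {
  bl <- .blocks_bare(theta, r_g)
  vars <- c("PS1", "PS2", "T1", "T2")
  dimnames(bl$within) <- dimnames(bl$cross) <- list(vars, vars)
  bl
}

#' Expected twin-pair covariance matrix of a model
#'
#' Solves the structural equations of the chosen model in reduced form and
#' returns the exact population covariance matrix of the observed twin-pair
#' vector.  Per twin the latent traits obey
#' \deqn{T_1' = g_2 T_2' + b_1 PS_1 + A_1 + C_1 + E_1,\qquad
#'       T_2' = g_1 T_1' + b_2 PS_1 + b_3 PS_2 + A_2 + C_2 + E_2,}
#' solved by inverting the 2 x 2 causal-coefficient matrix (admissible when
#' `|g1 * g2| < 1`).  Cross-twin covariances follow the classical twin
#' rules: additive-genetic terms (including the polygenic scores) are
#' weighted 1 for MZ and 0.5 for DZ pairs, shared-environment terms 1 for
#' both, unshared-environment terms 0.  Polygenic scores are uncorrelated
#' with the residual A, C, E factors; their effects on the traits run only
#' through `b1`, `b2`, `b3`.
#'
#' When `theta$rel1` or `theta$rel2` is below 1, the observed traits are
#' unreliable indicators of the latent traits: each observed trait loads on
#' its latent trait with coefficient `sqrt(rel)` and carries twin-specific
#' residual variance `1 - rel` (see [add_measurement_error()] for the
#' equivalent covariance-level operation).
#'
#' @param spec A [model_spec()]; selects the observed variables and checks
#'   the structural fixes of `theta`.
#' @param theta A [parameter_set()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A [twin_covariance()] of size 2k x 2k, k the number of observed
#'   variables per twin.
#' @export
#' @examples
#' spec <- model_spec("DoC")
#' theta <- parameter_set(g1 = sqrt(0.02), covA = 0.2 * sqrt(0.4 * 0.4))
#' expected_covariance(spec, theta, "MZ")
expected_covariance <- function(spec, theta, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  validate_parameters(spec, theta)
  r_g <- if (zygosity == "MZ") 1 else 0.5
  bl <- .twinmr_blocks(theta, r_g)
  keep <- spec$observed_vars
  within <- bl$within[keep, keep, drop = FALSE]
  cross  <- bl$cross[keep, keep, drop = FALSE]

  rel <- c(T1 = theta$rel1, T2 = theta$rel2)
  if (any(rel < 1)) {
    lam <- stats::setNames(rep(1, length(keep)), keep)
    resid <- stats::setNames(numeric(length(keep)), keep)
    for (tr in intersect(c("T1", "T2"), keep)) {
      lam[tr] <- sqrt(rel[[tr]])
      resid[tr] <- 1 - rel[[tr]]
    }
    D <- diag(lam, nrow = length(lam))
    within <- D %*% within %*% D + diag(resid, nrow = length(resid))
    cross  <- D %*% cross %*% D       # error is twin-specific: no cross term
    dimnames(within) <- dimnames(cross) <- list(keep, keep)
  }

  sigma <- rbind(cbind(within, cross), cbind(t(cross), within))
  labels <- c(paste0(keep, "_1"), paste0(keep, "_2"))
  twin_covariance(sigma, zygosity, labels)
}

#' Correlation-scale a twin covariance matrix
#'
#' Rescales a covariance matrix to a correlation matrix,
#' \eqn{D^{-1/2} \Sigma D^{-1/2}}, as applied to the expected MZ and DZ
#' matrices before estimation in the power analyses.
#'
#' @param cov A [twin_covariance()].
#' @return A [twin_covariance()] with unit diagonal.
#' @export
standardize <- function(cov) {
  stopifnot(inherits(cov, "twinmr_covariance"))
  d <- diag(cov$sigma)
  if (any(d <= 0)) stop("non-positive diagonal entry; cannot standardize")
  twin_covariance(stats::cov2cor(cov$sigma), cov$zygosity, cov$var_labels)
}

#' Rescale a parameter set under a diagonal change of observed scale
#'
#' If every observed variable `v` is multiplied by `d_v` (the same factor
#' for both twins), the model family is closed: the rescaled data are
#' exactly reproduced by a transformed parameter set.  This supplies exact
#' starting values when fitting to correlation-scaled (standardized)
#' matrices of a fully reliable model.
#'
#' @param theta A [parameter_set()] with `rel1 = rel2 = 1`.
#' @param d Named numeric vector of scale factors; names among
#'   `"PS1", "PS2", "T1", "T2"`, missing entries treated as 1.
#' @return The transformed `twinmr_parameters`.
#' @export
rescale_parameters <- function(theta, d) {
  stopifnot(inherits(theta, "twinmr_parameters"))
  if (theta$rel1 < 1 || theta$rel2 < 1)
    stop("rescaling is exact only for fully reliable traits (rel = 1)")
  g <- function(v) if (v %in% names(d)) d[[v]] else 1
  d1 <- g("T1"); d2 <- g("T2"); p1 <- g("PS1"); p2 <- g("PS2")
  update_parameters(theta,
    g1 = theta$g1 * d2 / d1, g2 = theta$g2 * d1 / d2,
    b1 = theta$b1 * d1 / p1, b2 = theta$b2 * d2 / p1,
    b3 = theta$b3 * d2 / p2,
    sigma2_ps1 = theta$sigma2_ps1 * p1^2,
    sigma2_ps2 = theta$sigma2_ps2 * p2^2,
    aX2 = theta$aX2 * d1^2, cX2 = theta$cX2 * d1^2, eX2 = theta$eX2 * d1^2,
    aY2 = theta$aY2 * d2^2, cY2 = theta$cY2 * d2^2, eY2 = theta$eY2 * d2^2,
    covA = theta$covA * d1 * d2, covC = theta$covC * d1 * d2,
    covE = theta$covE * d1 * d2)
}

#' Write / read a twin covariance as labeled CSV
#'
#' @param cov A [twin_covariance()].
#' @param path File path.
#' @return `write_twin_covariance()` returns `path` invisibly;
#'   `read_twin_covariance()` returns a [twin_covariance()].
#' @param zygosity Zygosity label to attach on read.
#' @export
write_twin_covariance <- function(cov, path) {
  stopifnot(inherits(cov, "twinmr_covariance"))
  utils::write.csv(as.data.frame(cov$sigma), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_twin_covariance
#' @export
read_twin_covariance <- function(path, zygosity = c("MZ", "DZ")) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  twin_covariance(as.matrix(df), match.arg(zygosity), colnames(df))
}
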