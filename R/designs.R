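#' Factor levels of the three factorial simulation designs
#'
#' Design 1 drives the DoC model (7 factors), Design 2 MR-DoC (9 factors),
#' Design 3 MR-DoC2 (12 factors).  Instrument paths take levels
#' `sqrt(0.025), sqrt(0.03), sqrt(0.04)`; causal paths
#' `sqrt(0.02), sqrt(0.03), sqrt(0.04)`; the confounding correlations
#' `ra`, `rc`, `re` take `0.1, 0.2, 0.3`; the instrument correlation `rf`
#' takes `0.1, 0.2, 0.5`; `aX2`, `aY2` take `0.3, 0.4, 0.5` and `cX2`,
#' `cY2` take `0.1, 0.2, 0.3`.  The unshared-environment components are
#' derived per trait as `e = 1 - a - c`.
#'
#' @param design_id 1, 2 or 3.
#' @return Named list of factor levels, in the canonical (slowest-varying
#'   first) order.
#' @export
design_factors <- function(design_id) {
  b_lev <- sqrt(c(0.025, 0.03, 0.04))
  g_lev <- sqrt(c(0.02, 0.03, 0.04))
  r_lev <- c(0.1, 0.2, 0.3)
  rf_lev <- c(0.1, 0.2, 0.5)
  a_lev <- c(0.3, 0.4, 0.5)
  c_lev <- c(0.1, 0.2, 0.3)
  switch(as.character(design_id),
    "1" = list(g1 = g_lev, ra = r_lev, rc = r_lev,
               aX2 = a_lev, aY2 = a_lev, cX2 = c_lev, cY2 = c_lev),
    "2" = list(b1 = b_lev, b2 = b_lev, g1 = g_lev, ra = r_lev, rc = r_lev,
               aX2 = a_lev, aY2 = a_lev, cX2 = c_lev, cY2 = c_lev),
    "3" = list(b1 = b_lev, b3 = b_lev, g1 = g_lev, g2 = g_lev,
               ra = r_lev, rc = r_lev, re = r_lev, rf = rf_lev,
               aX2 = a_lev, aY2 = a_lev, cX2 = c_lev, cY2 = c_lev),
    stop("design_id must be 1, 2 or 3"))
}

#' The model generated by each design
#' @rdname design_factors
#' @export
design_model <- function(design_id) {
  switch(as.character(design_id), "1" = "DoC", "2" = "MR-DoC",
         "3" = "MR-DoC2", stop("design_id must be 1, 2 or 3"))
}

#' Materialize a factorial design grid
#'
#' Enumerates the full Cartesian product of the design's factor levels in
#' deterministic lexicographic order (the first listed factor varies
#' slowest), assigning each cell a stable integer id equal to its position
#' in the full enumeration.  With `subsample_n`, a seeded uniform subsample
#' of cells (without replacement) is returned, ids preserved from the full
#' enumeration.
#'
#' @param design_id 1, 2 or 3 (grids of 3^7 = 2187, 3^9 = 19683 and
#'   3^12 = 531441 cells).
#' @param subsample_n Optional number of cells to keep.
#' @param seed Seed for the subsample draw.
#' @return Object of class `twinmr_grid`: a list with `design_id`, `model`
#'   (generating model id), `factor_table` (list of levels), and `cells`
#'   (data frame of factor values with a `cell_id` column).
#' @export
#' @examples
#' g <- build_grid(1)
#' nrow(g$cells)   # 2187
build_grid <- function(design_id, subsample_n = NULL, seed = 1L) {
  factors <- design_factors(design_id)
  # expand.grid varies the first column fastest; reverse for lexicographic
  cells <- expand.grid(rev(factors), KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, names(factors), drop = FALSE]
  cells$cell_id <- seq_len(nrow(cells))
  if (!is.null(subsample_n)) {
    if (subsample_n > nrow(cells))
      stop("subsample_n exceeds the grid size (", nrow(cells), ")")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    keep <- sort(sample.int(nrow(cells), subsample_n))
    cells <- cells[keep, , drop = FALSE]
    rownames(cells) <- NULL
  }
  structure(list(design_id = design_id, model = design_model(design_id),
                 factor_table = factors, cells = cells),
            class = "twinmr_grid")
}

#' @export
print.twinmr_grid <- function(x, ...) {
  full <- prod(lengths(x$factor_table))
  cat("Design", x$design_id, "grid (", x$model, "):", nrow(x$cells),
      "of", full, "cells,", length(x$factor_table), "factors\n")
  invisible(x)
}

#' Parameter set of one grid cell
#'
#' Converts one row of a design grid into a generating [parameter_set()]:
#' the correlation factors `ra`, `rc` (and `re` in Design 3) are converted
#' to covariance components, `e` components are derived as `1 - a - c`, and
#' parameters absent from the design are fixed at the generating model's
#' values (0 for absent paths; unit PGS variances).
#'
#' @param grid A [build_grid()] result.
#' @param i Row index into `grid$cells` (not a cell id).
#' @return A `twinmr_parameters` object.
#' @export
cell_parameters <- function(grid, i) {
  stopifnot(inherits(grid, "twinmr_grid"))
  row <- grid$cells[i, , drop = FALSE]
  eX2 <- 1 - row$aX2 - row$cX2
  eY2 <- 1 - row$aY2 - row$cY2
  theta <- parameter_set(
    g1 = row$g1,
    g2 = if ("g2" %in% names(row)) row$g2 else 0,
    b1 = if ("b1" %in% names(row)) row$b1 else 0,
    b2 = if ("b2" %in% names(row)) row$b2 else 0,
    b3 = if ("b3" %in% names(row)) row$b3 else 0,
    rf = if ("rf" %in% names(row)) row$rf else 0,
    aX2 = row$aX2, cX2 = row$cX2, eX2 = eX2,
    aY2 = row$aY2, cY2 = row$cY2, eY2 = eY2)
  correlations_to_covariances(theta, ra = row$ra, rc = row$rc,
                              re = if ("re" %in% names(row)) row$re else NULL)
}

#' Export a grid to CSV for audit
#'
#' One row per cell, one column per factor plus the stable `cell_id`.
#'
#' @param grid A [build_grid()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "twinmr_grid"))
  utils::write.csv(grid$cells, path, row.names = FALSE)
  invisible(path)
}
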