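#' Map agreement by Cohen's Kappa
#'
#' Unweighted Kappa over the jointly valid cells of two aligned
#' categorical rasters: \code{kappa = (p_o - p_e) / (1 - p_e)} with
#' \code{p_o} the observed and \code{p_e} the chance (marginal-product)
#' agreement.
#'
#' @param a,b Aligned \code{\link{land_grid}}s of identical dimensions.
#' @param classes Class codes of the confusion matrix (default the eight
#'   standard classes).
#' @return List with \code{confusion} (cell counts, rows = \code{a}),
#'   \code{overall} (p_o), \code{expected} (p_e) and \code{kappa}.
#' @export
kappa_agreement <- function(a, b, classes = landuse_classes()) {
  if (!all(dim(a$values) == dim(b$values))) {
    stop("rasters have mismatched dimensions")
  }
  va <- as.vector(a$values); vb <- as.vector(b$values)
  ok <- !is.na(va) & !is.na(vb)
  conf <- table(factor(va[ok], levels = classes),
                factor(vb[ok], levels = classes))
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  k <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  dimnames(conf) <- list(names(classes), names(classes))
  list(confusion = conf, overall = po, expected = pe, kappa = k)
}

#' Relative error of simulated versus demanded class areas
#'
#' \code{100 (simulated - demand) / demand}, per class, rounded to 2
#' decimals (half away from zero, the printed-table convention); negative
#' when the simulation undershoots demand.
#'
#' @param demand Named per-class demanded areas (hm2), strictly positive.
#' @param simulated Matching simulated areas.
#' @return Named numeric vector of percentages.
#' @export
relative_error <- function(demand, simulated) {
  stopifnot(length(demand) == length(simulated))
  if (any(demand <= 0)) stop("relative error undefined for zero demand")
  round_half_up(100 * (simulated - demand) / demand, 2)
}

#' Transition cross-tabulation between two maps
#'
#' Joint per-cell tabulation of origin versus destination class,
#' converted to areas (hm2). With \code{focus} the table is restricted to
#' one origin class, e.g. AML to show where reclaimed mined land went.
#'
#' @param origin,destination Aligned \code{\link{land_grid}}s.
#' @param focus Optional origin class code or name.
#' @return Matrix of areas (hm2), rows = origin classes, columns =
#'   destination classes.
#' @export
transition_crosstab <- function(origin, destination, focus = NULL) {
  if (!all(dim(origin$values) == dim(destination$values))) {
    stop("rasters have mismatched dimensions")
  }
  cls <- landuse_classes()
  vo <- as.vector(origin$values); vd <- as.vector(destination$values)
  ok <- !is.na(vo) & !is.na(vd)
  tab <- table(factor(vo[ok], levels = cls), factor(vd[ok], levels = cls))
  m <- as.matrix(tab) * cell_area_hm2(origin)
  dimnames(m) <- list(names(cls), names(cls))
  if (!is.null(focus)) {
    if (is.character(focus)) focus <- cls[[focus]]
    m <- m[names(cls)[cls == focus], , drop = FALSE]
  }
  m
}
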