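#' Default conversion elasticities
#'
#' Per-class stability parameters in [0, 1]; 0 = converts freely, 1 =
#' irreversible. Construction land and water are fixed at 1 (stable uses),
#' forest is sticky, AML converts easily (it exists to be reclaimed).
#'
#' @return Named numeric vector over the eight classes.
#' @export
default_elas <- function() {
  c(cultivated = 0.6, garden = 0.6, forest = 0.8, grassland = 0.4,
    construction = 1, aml = 0.2, water = 1, unutilized = 0.3)
}

#' Default allowed-transition matrix
#'
#' Binary 8 x 8 matrix, rows = origin class, columns = destination.
#' All conversions are allowed except: nothing may convert into AML
#' (mined land is only ever consumed by reclamation), and construction
#' land and water only self-transition (stable uses).
#'
#' @return Integer matrix with dimnames over the class names.
#' @export
default_transition_matrix <- function() {
  cls <- names(landuse_classes())
  m <- matrix(1L, 8, 8, dimnames = list(cls, cls))
  m[, "aml"] <- 0L
  m["construction", ] <- 0L
  m["water", ] <- 0L
  diag(m) <- 1L
  m
}

#' Conversion rules for the allocation engine
#'
#' @param elas Named elasticities in [0, 1] (\code{\link{default_elas}}).
#' @param allowed Binary allowed-transition matrix
#'   (\code{\link{default_transition_matrix}}).
#' @return Object of class \code{transition_rules}.
#' @export
transition_rules <- function(elas = default_elas(),
                             allowed = default_transition_matrix()) {
  cls <- names(landuse_classes())
  stopifnot(all(cls %in% names(elas)), all(dim(allowed) == c(8, 8)))
  elas <- elas[cls]
  if (any(elas < 0 | elas > 1)) stop("ELAS values must lie in [0, 1]")
  if (any(diag(allowed) != 1)) {
    stop("transition matrix diagonal must be 1 (self-transitions allowed)")
  }
  aml <- landuse_classes()[["aml"]]
  if (any(allowed[-aml, aml] != 0)) {
    stop("no class may convert into AML")
  }
  protected <- cls[rowSums(allowed) == 1]
  structure(list(elas = elas, allowed = allowed, protected = protected),
            class = "transition_rules")
}

#' Fit a one-vs-rest binomial logit for one land-use class
#'
#' Maximum-likelihood logistic regression of class presence on the driving
#' factors over all valid cells. Quasi-separation (non-convergence or
#' exploding coefficients) is flagged and, when the \pkg{glmnet} package is
#' available, refitted with a weak ridge penalty to keep the coefficients
#' finite.
#'
#' @param grid Base-year \code{\link{land_grid}}.
#' @param factors \code{\link{factor_stack}} aligned with \code{grid}.
#' @param class Integer class code.
#' @return Object of class \code{logit_model}: list with \code{class},
#'   \code{coef} (intercept + one per factor), \code{separated},
#'   \code{converged}.
#' @export
fit_logit <- function(grid, factors, class) {
  v <- as.vector(grid$values)
  ok <- !is.na(v)
  y <- as.integer(v[ok] == class)
  if (length(unique(y)) < 2 || min(tabulate(y + 1L, 2L)) < 2) {
    stop("need at least 2 cells of each outcome for class ", class)
  }
  x <- factor_matrix(factors)[ok, , drop = FALSE]
  dat <- data.frame(y = y, x)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                     family = stats::binomial()))
  coefs <- stats::coef(fit)
  separated <- !fit$converged || any(!is.finite(coefs)) ||
    any(abs(coefs[-1]) > 15)
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                         lambda = 1e-2)
    coefs <- as.numeric(stats::coef(rf))
    names(coefs) <- c("(Intercept)", colnames(x))
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(coefs)))
  structure(list(class = class, coef = coefs, se = se,
                 separated = separated, converged = fit$converged),
            class = "logit_model")
}

#' Fit logit models for several classes
#'
#' @inheritParams fit_logit
#' @param classes Integer class codes (default all eight).
#' @return List of \code{logit_model}s, named by class name.
#' @export
fit_logits <- function(grid, factors, classes = landuse_classes()) {
  models <- lapply(classes, function(k) fit_logit(grid, factors, k))
  names(models) <- names(landuse_classes())[match(classes,
                                                  landuse_classes())]
  models
}

#' Predicted conversion-probability matrix
#'
#' @param models List of \code{logit_model}s (one per class, in class-code
#'   order).
#' @param factors \code{\link{factor_stack}}.
#' @return Cell-by-class matrix of logistic probabilities (all cells,
#'   column-major).
#' @export
predict_probabilities <- function(models, factors) {
  xmat <- cbind(1, factor_matrix(factors))
  p <- vapply(models, function(m) {
    as.numeric(stats::plogis(xmat %*% m$coef))
  }, numeric(nrow(xmat)))
  colnames(p) <- names(models)
  p
}

#' Rank-statistic ROC area
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a
#' randomly chosen presence cell scores above a randomly chosen absence
#' cell, counting ties as 1/2.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) outcomes; both labels must be present.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome labels must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC area of a fitted logit model on a land-use raster
#'
#' @param model A \code{logit_model}.
#' @param grid The \code{\link{land_grid}} providing the observed classes.
#' @param factors \code{\link{factor_stack}} of predictors.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(model, grid, factors) {
  v <- as.vector(grid$values)
  ok <- !is.na(v)
  xmat <- cbind(1, factor_matrix(factors)[ok, , drop = FALSE])
  scores <- as.numeric(xmat %*% model$coef)
  rank_auc(scores, v[ok] == model$class)
}

#' Total conversion probability of a cell for a class
#'
#' Additive combination of the location suitability (logit probability),
#' the class conversion elasticity and the class competition adjustment.
#'
#' @param p Logit probability.
#' @param elas Conversion elasticity (applied by the allocation engine to
#'   the cell's incumbent class only, under the default interpretation).
#' @param iter Iteration (competition) variable.
#' @return Total probability score.
#' @export
tprop <- function(p, elas, iter) p + elas + iter

#' Allocate one yearly demand step over the raster
#'
#' Each valid cell is assigned the allowed class with maximal total
#' probability (logit probability, plus elasticity for the incumbent
#' class, plus the per-class competition variable ITER). ITER is adjusted
#' iteratively -- raised for under-allocated classes, lowered for
#' over-allocated ones -- until every class area is within tolerance of
#' demand. Ties in the total probability break toward the lowest class
#' code, so allocation is fully deterministic.
#'
#' The ITER update is proportional to the relative deficit
#' (\code{eta * (demand - allocated) / demand}); the per-class step is
#' halved whenever the deficit changes sign, which damps the oscillation
#' the argmax competition otherwise produces.
#'
#' @param current \code{\link{land_grid}} at the start of the step.
#' @param demand Named per-class target areas (hm2) summing to the
#'   landscape area.
#' @param rules \code{\link{transition_rules}}.
#' @param probs Cell-by-class probability matrix (all cells, column-major),
#'   e.g. from \code{\link{predict_probabilities}}.
#' @param tolerance Convergence tolerance as a fraction of each class
#'   demand (default 0.005); never tighter than one cell.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @param eta Initial ITER step size.
#' @param elas_mode \code{"incumbent"} adds ELAS only for the cell's
#'   current class (stability bonus); \code{"all"} adds it to every
#'   candidate class.
#' @return The allocated \code{\link{land_grid}}, with attributes
#'   \code{iterations}, \code{iter_values} and \code{deviation_cells}.
#' @export
allocate_step <- function(current, demand, rules, probs,
                          tolerance = 0.005, max_iter = 2000, eta = 0.05,
                          elas_mode = c("incumbent", "all")) {
  elas_mode <- match.arg(elas_mode)
  v <- as.vector(current$values)
  ok <- !is.na(v)
  cur <- as.integer(v[ok])
  n <- length(cur)
  ca <- cell_area_hm2(current)
  cls <- names(landuse_classes())
  demand <- demand[cls]
  if (abs(sum(demand) - n * ca) > 0.5 * ca) {
    stop("demand (", sum(demand), " hm2) does not sum to the landscape area (",
         n * ca, " hm2)")
  }
  dem_cells <- largest_remainder(pmax(demand, 0), n)
  cur_counts <- tabulate(cur, 8L)

  prot <- match(rules$protected, cls)
  bad <- prot[dem_cells[prot] < cur_counts[prot]]
  if (length(bad) > 0) {
    stop("demand for protected class ", paste(cls[bad], collapse = ", "),
         " is below its fixed current area")
  }
  closed <- which(colSums(rules$allowed) - diag(rules$allowed) == 0)
  bad <- closed[dem_cells[closed] > cur_counts[closed]]
  if (length(bad) > 0) {
    stop("demand for ", paste(cls[bad], collapse = ", "),
         " exceeds its current area but no conversions into it are allowed")
  }

  base <- probs[ok, , drop = FALSE]
  if (elas_mode == "incumbent") {
    base[cbind(seq_len(n), cur)] <- base[cbind(seq_len(n), cur)] +
      rules$elas[cur]
  } else {
    base <- sweep(base, 2, rules$elas, "+")
  }
  base[!(rules$allowed[cur, ] == 1)] <- -Inf

  tol_cells <- if (tolerance == 0) rep(0L, 8) else
    pmax(1, floor(tolerance * dem_cells))
  iter_u <- numeric(8)
  eta_u <- rep(eta, 8)
  prev_dev <- rep(NA_real_, 8)
  assign <- cur
  for (it in seq_len(max_iter)) {
    score <- base + rep(iter_u, each = n)
    assign <- max.col(score, ties.method = "first")
    counts <- tabulate(assign, 8L)
    dev <- dem_cells - counts
    if (all(abs(dev) <= tol_cells)) {
      out <- current
      w <- v
      w[ok] <- assign
      out$values <- matrix(w, nrow(current$values), ncol(current$values))
      attr(out, "iterations") <- it
      attr(out, "iter_values") <- iter_u
      attr(out, "deviation_cells") <- stats::setNames(-dev, cls)
      return(out)
    }
    flip <- !is.na(prev_dev) & sign(dev) * sign(prev_dev) < 0
    eta_u[flip] <- pmax(eta_u[flip] * 0.5, 1e-4)
    prev_dev <- dev
    iter_u <- iter_u + eta_u * dev / pmax(dem_cells, 1)
    iter_u <- pmin(pmax(iter_u, -10), 10)
  }
  stop("allocation did not converge within ", max_iter,
       " iterations; residual cell deviations: ",
       paste(sprintf("%s=%d", cls, dem_cells - tabulate(assign, 8L)),
             collapse = ", "))
}

#' Simulate land-use change over a demand trajectory
#'
#' Applies \code{\link{allocate_step}} year by year. The first trajectory
#' row must match the base-map class areas; the returned final map matches
#' the horizon demand within the allocation tolerance.
#'
#' @param base Base-year \code{\link{land_grid}}.
#' @param trajectory Year-by-class demand matrix from
#'   \code{\link{interpolate_demand}}.
#' @param rules \code{\link{transition_rules}}.
#' @param probs Cell-by-class probability matrix (held fixed over the run).
#' @param ... Passed to \code{\link{allocate_step}}.
#' @return List with \code{maps} (one \code{land_grid} per trajectory row,
#'   the first being \code{base}) and \code{diagnostics} (per-year
#'   iteration counts and residuals).
#' @export
simulate_landuse <- function(base, trajectory, rules, probs, ...) {
  yrs <- rownames(trajectory)
  base_areas <- class_areas(base)
  if (any(abs(trajectory[1, names(landuse_classes())] - base_areas) >
          cell_area_hm2(base) / 2)) {
    stop("trajectory must start at the base-year class areas")
  }
  maps <- vector("list", nrow(trajectory))
  maps[[1]] <- base
  diag_rows <- list()
  for (t in 2:nrow(trajectory)) {
    maps[[t]] <- tryCatch(
      allocate_step(maps[[t - 1]], trajectory[t, ], rules, probs, ...),
      error = function(e) {
        stop("allocation failed in year ", yrs[t], ": ",
             conditionMessage(e))
      })
    diag_rows[[t - 1]] <- data.frame(
      year = as.integer(yrs[t]),
      iterations = attr(maps[[t]], "iterations"),
      max_abs_deviation_cells = max(abs(attr(maps[[t]],
                                             "deviation_cells"))))
  }
  names(maps) <- yrs
  list(maps = maps, diagnostics = do.call(rbind, diag_rows))
}
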