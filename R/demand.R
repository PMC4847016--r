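# Decision variables of the demand LP. x1..x8 are the horizon-year areas of
# the eight classes excluding reclaimed AML; x9..x12 are the AML areas
# reclaimed to cultivated, garden, forest and construction land.
lp_var_names <- function() paste0("x", 1:12)

# Which class each reclamation variable feeds (by class code).
reclamation_targets <- function() {
  c(x9 = 1L, x10 = 2L, x11 = 3L, x12 = 5L)
}

lp_constraint <- function(name, coefs, dir, rhs) {
  v <- stats::setNames(numeric(12), lp_var_names())
  v[names(coefs)] <- coefs
  list(name = name, coefs = v, dir = dir, rhs = rhs)
}

#' Build a scenario demand LP
#'
#' Assembles the linear program whose solution is the horizon-year land-use
#' structure. Scenario \code{"niche"} maximizes the total-niche-weighted
#' area, \code{"esv"} maximizes the ESV-weighted area with reclamation to
#' construction forced to zero, and \code{"planning"} needs no LP (use
#' \code{\link{scenario_demand}}).
#'
#' The constraint set: the total-area equality over all twelve variables
#' (reclaimed AML is part of the landscape, so the reclamation variables are
#' included); the total-reclamation requirement, relaxed downward by
#' \code{reclamation_slack} so that suitability caps whose sum falls a
#' rounding step short of the requirement stay feasible; the residual-AML
#' equality; the suitability caps on the reclamation variables; the
#' planning floors; and optional per-class caps (\code{extra_caps}) on the
#' final class areas, without which the objectives would park all free area
#' in the single highest-valued class.
#'
#' Under the ESV objective the printed suitability caps cannot absorb the
#' reclamation requirement once construction is excluded; with
#' \code{relax_forest_cap = TRUE} (default) the forest cap is raised by the
#' construction-suitable area, which meets the laxer forest criteria.
#'
#' @param scenario \code{"niche"} or \code{"esv"}.
#' @param caps Named reclaimable-area caps over \code{\link{target_uses}}
#'   (hm2), e.g. from \code{\link{aggregate_bounds}}.
#' @param constants List with \code{total_area}, \code{reclamation_total},
#'   \code{residual_aml}; see \code{\link{demand_constants}}.
#' @param niches Niche table (\code{\link{niche_table}}).
#' @param esvs ESV table (\code{\link{esv_table}}).
#' @param floors Planning floors (\code{\link{plan_floors}}).
#' @param extra_caps Optional named per-class caps on final areas
#'   (\code{NA} = uncapped).
#' @param reclamation_slack Allowed shortfall (hm2) of total reclamation.
#' @param relax_forest_cap Raise the forest cap by the construction cap
#'   under the ESV objective.
#' @return Object of class \code{lp_problem}.
#' @export
build_lp <- function(scenario = c("niche", "esv"),
                     caps = mls_caps_default(),
                     constants = demand_constants(),
                     niches = niche_table(),
                     esvs = esv_table(),
                     floors = plan_floors(),
                     extra_caps = NULL,
                     reclamation_slack = 0.5,
                     relax_forest_cap = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(all(caps >= 0), all(floors >= 0), reclamation_slack >= 0)
  if (sum(floors) > constants$total_area) {
    stop("planning floors exceed the total landscape area")
  }
  caps <- caps[target_uses()]
  if (scenario == "esv") {
    if (relax_forest_cap) caps[["forest"]] <- caps[["forest"]] +
        caps[["construction"]]
    caps[["construction"]] <- 0
  }

  obj <- stats::setNames(numeric(12), lp_var_names())
  if (scenario == "niche") {
    val <- stats::setNames(niches$total, niches$class)
  } else {
    val <- stats::setNames(esvs$esv, esvs$class)
  }
  obj[paste0("x", 1:8)] <- val[names(landuse_classes())]
  tgt <- reclamation_targets()
  obj[names(tgt)] <- val[names(landuse_classes())[tgt]]
  if (scenario == "esv") obj[["x12"]] <- 0

  cons <- list(
    lp_constraint("total_area",
                  stats::setNames(rep(1, 12), lp_var_names()),
                  "==", constants$total_area),
    lp_constraint("reclamation_upper",
                  stats::setNames(rep(1, 4), paste0("x", 9:12)),
                  "<=", constants$reclamation_total),
    lp_constraint("reclamation_lower",
                  stats::setNames(rep(1, 4), paste0("x", 9:12)),
                  ">=", constants$reclamation_total - reclamation_slack),
    lp_constraint("residual_aml", c(x6 = 1), "==", constants$residual_aml)
  )
  for (i in seq_along(tgt)) {
    use <- names(landuse_classes())[tgt[i]]
    cons[[length(cons) + 1]] <- lp_constraint(
      paste0("mls_cap_", use),
      stats::setNames(1, names(tgt)[i]), "<=", caps[[use]])
  }
  if (scenario == "esv") {
    cons[[length(cons) + 1]] <- lp_constraint("no_construction_reclamation",
                                              c(x12 = 1), "==", 0)
  }
  floor_vars <- c(cultivated = "x1", garden = "x2", forest = "x3",
                  construction = "x5")
  for (cl in names(floors)) {
    co <- stats::setNames(1, floor_vars[[cl]])
    rv <- names(tgt)[tgt == landuse_classes()[[cl]]]
    if (length(rv) == 1) co <- c(co, stats::setNames(1, rv))
    cons[[length(cons) + 1]] <- lp_constraint(paste0("floor_", cl), co,
                                              ">=", floors[[cl]])
  }
  if (!is.null(extra_caps)) {
    for (cl in names(extra_caps)) {
      if (is.na(extra_caps[[cl]])) next
      code <- landuse_classes()[[cl]]
      co <- stats::setNames(1, paste0("x", code))
      rv <- names(tgt)[tgt == code]
      if (length(rv) == 1) co <- c(co, stats::setNames(1, rv))
      cons[[length(cons) + 1]] <- lp_constraint(paste0("cap_", cl), co,
                                                "<=", extra_caps[[cl]])
    }
  }
  structure(list(objective = obj, maximize = TRUE, constraints = cons,
                 scenario = scenario),
            class = "lp_problem")
}

#' @export
print.lp_problem <- function(x, ...) {
  cat(sprintf("<lp_problem> %s objective, %d variables, %d constraints\n",
              x$scenario, length(x$objective), length(x$constraints)))
  invisible(x)
}

check_lp_feasible <- function(lp, x, tol = 1e-6) {
  viol <- character(0)
  for (con in lp$constraints) {
    lhs <- sum(con$coefs * x)
    ok <- switch(con$dir,
                 "<=" = lhs <= con$rhs + tol,
                 ">=" = lhs >= con$rhs - tol,
                 "==" = abs(lhs - con$rhs) <= tol)
    if (!ok) viol <- c(viol, con$name)
  }
  if (any(x < -tol)) viol <- c(viol, "non_negativity")
  viol
}

# Name an obviously conflicting constraint pair when the solver reports
# infeasibility, so the error is actionable.
diagnose_infeasible <- function(lp) {
  caps <- vapply(lp$constraints, function(con) {
    if (grepl("^mls_cap_", con$name)) con$rhs else NA_real_
  }, numeric(1))
  lower <- vapply(lp$constraints, function(con) {
    if (con$name == "reclamation_lower") con$rhs else NA_real_
  }, numeric(1))
  if (any(!is.na(caps)) && any(!is.na(lower)) &&
      sum(caps, na.rm = TRUE) < max(lower, na.rm = TRUE)) {
    return(paste0("suitability caps sum to ", sum(caps, na.rm = TRUE),
                  " hm2, below the required reclamation of ",
                  max(lower, na.rm = TRUE), " hm2 (reclamation_lower)"))
  }
  "constraint set admits no feasible point"
}

#' Solve a demand LP
#'
#' Solves by a two-phase simplex (Bland's rule) and certifies the
#' returned vertex: every constraint is rechecked within \code{tol}.
#' Infeasible and unbounded problems are signalled distinctly.
#'
#' @param lp An \code{lp_problem} from \code{\link{build_lp}}, or a plain
#'   list with elements \code{objective}, \code{maximize},
#'   \code{constraints} in the same layout (useful for toy problems).
#' @param tol Feasibility certification tolerance (hm2).
#' @return List with \code{x} (named solution vector), \code{objective}
#'   value, and \code{class_totals}, the per-class horizon areas (final
#'   class area plus reclamation inflow).
#' @export
solve_lp <- function(lp, tol = 1e-6) {
  nv <- length(lp$objective)
  amat <- do.call(rbind, lapply(lp$constraints,
                                function(c) unname(c$coefs)))
  dirs <- vapply(lp$constraints, function(c) c$dir, character(1))
  rhs <- vapply(lp$constraints, function(c) c$rhs, numeric(1))
  res <- simplex_solve(unname(lp$objective), amat, dirs, rhs,
                       maximize = isTRUE(lp$maximize))
  if (res$status == "infeasible") {
    stop("LP infeasible: ", diagnose_infeasible(lp))
  }
  if (res$status == "unbounded") stop("LP unbounded")
  if (res$status != "optimal") stop("LP did not solve: ", res$status)
  x <- stats::setNames(res$x, names(lp$objective))
  viol <- check_lp_feasible(lp, x, tol)
  if (length(viol) > 0) {
    stop("solver returned an infeasible point; violated: ",
         paste(viol, collapse = ", "))
  }
  out <- list(x = x, objective = res$value)
  if (nv == 12) out$class_totals <- lp_class_totals(x)
  out
}

# Horizon per-class areas: final class area plus its reclamation inflow.
lp_class_totals <- function(x) {
  tot <- x[paste0("x", 1:8)]
  names(tot) <- names(landuse_classes())
  for (i in seq_along(reclamation_targets())) {
    v <- names(reclamation_targets())[i]
    cl <- names(landuse_classes())[reclamation_targets()[i]]
    tot[cl] <- tot[cl] + x[[v]]
  }
  tot
}

#' Horizon-year demand for a reclamation scenario
#'
#' Scenario 1 (\code{"planning"}) returns the areas prescribed by the
#' general land-use plan. Scenarios 2 (\code{"niche"}) and 3 (\code{"esv"})
#' build and solve the corresponding LP, closed by the shipped per-class
#' planning caps (\code{\link{scenario_caps}}) unless \code{extra_caps} is
#' supplied. Demands are rounded to whole hm2 by largest remainder so they
#' sum exactly to the landscape total.
#'
#' @param scenario 1/2/3 or "planning"/"niche"/"esv".
#' @param extra_caps Per-class caps for the LP scenarios (default the
#'   shipped study-landscape caps).
#' @param ... Further arguments passed to \code{\link{build_lp}}.
#' @return Named numeric vector of per-class horizon areas (hm2).
#' @export
scenario_demand <- function(scenario, extra_caps = NULL, ...) {
  key <- scenario_key(scenario)
  if (key == "planning") return(planning_demand())
  if (is.null(extra_caps)) {
    extra_caps <- scenario_caps(if (key == "niche") 2 else 3)
  }
  sol <- solve_lp(build_lp(key, extra_caps = extra_caps, ...))
  tot <- sol$class_totals
  d <- largest_remainder(tot, round(sum(tot)))
  stats::setNames(as.numeric(d), names(tot))
}

scenario_key <- function(scenario) {
  if (is.numeric(scenario)) {
    return(switch(scenario, "planning", "niche", "esv"))
  }
  match.arg(scenario, c("planning", "niche", "esv"))
}

#' Linear demand trajectory between base and horizon year
#'
#' Interpolates per-class areas linearly year by year, then rounds each
#' year to whole cells by largest remainder so every yearly total equals
#' the landscape total exactly.
#'
#' @param base_areas Named per-class areas (hm2) at \code{base_year}.
#' @param target_areas Matching areas at \code{horizon_year}.
#' @param base_year,horizon_year Integer years, increasing.
#' @param cell_area_hm2 Area of one raster cell (hm2); demands are rounded
#'   to whole cells.
#' @param total_slack Tolerated mismatch (hm2) between the two totals.
#' @return Matrix with one row per year (rownames = years) and one column
#'   per class, in hm2.
#' @export
interpolate_demand <- function(base_areas, target_areas,
                               base_year = 2007, horizon_year = 2020,
                               cell_area_hm2 = 1, total_slack = 0.5) {
  stopifnot(horizon_year > base_year,
            length(base_areas) == length(target_areas))
  if (abs(sum(base_areas) - sum(target_areas)) > total_slack) {
    stop("base and target areas differ in total by more than ", total_slack,
         " hm2")
  }
  years <- base_year:horizon_year
  n_cells_total <- round(sum(base_areas) / cell_area_hm2)
  frac <- (years - base_year) / (horizon_year - base_year)
  traj <- t(vapply(frac, function(f) {
    a <- (1 - f) * base_areas + f * target_areas
    largest_remainder(pmax(a, 0), n_cells_total) * cell_area_hm2
  }, numeric(length(base_areas))))
  dimnames(traj) <- list(years, names(base_areas))
  traj
}
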