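test_that("total niche is an exact weighted sum and linear", {
  expect_equal(total_niche(16453, 6250, 10000), 11081.2)
  expect_equal(total_niche(0, 0, 0), 0)
  # linearity in each argument
  expect_equal(total_niche(2 * 16453, 6250, 10000) -
                 total_niche(16453, 6250, 10000), 0.4 * 16453)
  expect_equal(total_niche(1, 0, 0), 0.4)
  expect_equal(total_niche(0, 1, 0), 0.4)
  expect_equal(total_niche(0, 0, 1), 0.2)
  expect_error(total_niche(1, 1, 1, weights = c(0.5, 0.5, 0.5)),
               "sum to 1")
  # vectorized over the full table
  nt <- niche_table()
  expect_equal(nt$total,
               0.4 * nt$natural + 0.4 * nt$economic + 0.2 * nt$social)
})

test_that("garden ESV is the midpoint of its parents", {
  expect_equal(garden_esv(5, 5), 5)
  expect_equal(garden_esv(0, 10), 5)
  expect_equal(esv_table()$esv[esv_table()$class == "garden"],
               garden_esv(3296.98, 11735.57))
})

test_that("the simplex solver matches brute-force vertex enumeration", {
  # hand toy: max x + y, x <= 1, y <= 2
  lp <- list(objective = c(x = 1, y = 1), maximize = TRUE,
             constraints = list(
               list(name = "cx", coefs = c(x = 1, y = 0), dir = "<=",
                    rhs = 1),
               list(name = "cy", coefs = c(x = 0, y = 1), dir = "<=",
                    rhs = 2)))
  sol <- solve_lp(lp)
  expect_equal(unname(sol$x), c(1, 2))
  expect_equal(sol$objective, 3)

  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    m <- sample(2:5, 1)
    A <- matrix(stats::rnorm(m * n), m, n)
    dir <- sample(c("<=", ">=", "=="), m, replace = TRUE,
                  prob = c(0.6, 0.25, 0.15))
    # anchor on a random non-negative feasible point
    x0 <- stats::runif(n, 0, 3)
    slackb <- abs(stats::rnorm(m, 0, 1))
    rhs <- as.numeric(A %*% x0) +
      ifelse(dir == "<=", slackb, ifelse(dir == ">=", -slackb, 0))
    # box constraints keep the problem bounded
    A <- rbind(A, diag(n))
    dir <- c(dir, rep("<=", n))
    rhs <- c(rhs, rep(10, n))
    obj <- stats::rnorm(n)
    cons <- lapply(seq_along(rhs), function(i) {
      list(name = paste0("c", i), coefs = A[i, ], dir = dir[i],
           rhs = rhs[i])
    })
    sol <- solve_lp(list(objective = stats::setNames(obj,
                                                     paste0("v", 1:n)),
                         maximize = TRUE, constraints = cons))
    oracle <- oracle_lp(obj, A, dir, rhs, maximize = TRUE)
    expect_equal(sol$objective, oracle$value, tolerance = 1e-6)
  }
})

test_that("infeasible and unbounded LPs are signalled distinctly", {
  infeas <- list(objective = c(x = 1), maximize = TRUE,
                 constraints = list(
                   list(name = "lo", coefs = c(x = 1), dir = ">=", rhs = 2),
                   list(name = "hi", coefs = c(x = 1), dir = "<=", rhs = 1)))
  expect_error(solve_lp(infeas), "infeasible")
  unb <- list(objective = c(x = 1), maximize = TRUE,
              constraints = list(
                list(name = "lo", coefs = c(x = 1), dir = ">=", rhs = 0)))
  expect_error(solve_lp(unb), "unbounded")
})

test_that("scenario LPs carry the printed structure", {
  niche <- build_lp("niche")
  nm <- vapply(niche$constraints, function(c) c$name, character(1))
  caps <- vapply(niche$constraints[grepl("mls_cap", nm)],
                 function(c) c$rhs, numeric(1))
  expect_equal(unname(caps), c(85.3, 176.1, 1729.0, 1081.5))
  expect_equal(niche$constraints[[1]]$rhs, 46634)
  expect_true(all(niche$constraints[[1]]$coefs == 1)) # x12 conserved too

  esv <- build_lp("esv")
  nm <- vapply(esv$constraints, function(c) c$name, character(1))
  expect_true("no_construction_reclamation" %in% nm)
  expect_equal(esv$objective[["x12"]], 0)
  # forest cap relaxed by the construction-suitable area
  caps <- vapply(esv$constraints[grepl("mls_cap", nm)],
                 function(c) c$rhs, numeric(1))
  expect_equal(unname(caps), c(85.3, 176.1, 1729.0 + 1081.5, 0))
  # without the relaxation the caps cannot absorb the reclamation
  expect_error(solve_lp(build_lp("esv", relax_forest_cap = FALSE)),
               "infeasible.*caps")
})

test_that("the niche optimum drives reclamation variables to their caps", {
  sol <- solve_lp(build_lp("niche", extra_caps = scenario_caps(2)))
  expect_equal(unname(sol$x[c("x9", "x10", "x11")]),
               c(85.3, 176.1, 1729.0))
  # x12 stops where the construction class cap binds
  expect_equal(unname(sol$x["x5"] + sol$x["x12"]), 6689)
  # with only the suitability caps, all four sit at (or within slack of)
  # their caps because the caps sum almost exactly to total reclamation
  sol2 <- solve_lp(build_lp("niche"))
  expect_true(all(abs(sol2$x[c("x9", "x10", "x11", "x12")] -
                        mls_caps_default()) <= 0.5))
  # every returned solution satisfies all constraints (certified)
  expect_silent(solve_lp(build_lp("niche", extra_caps = scenario_caps(2))))
})

test_that("scenario demands match the study demand tables", {
  d1 <- scenario_demand(1)
  expect_equal(unname(d1), c(1656, 1678, 29738, 2643, 6688, 501, 955,
                             2775))
  d2 <- scenario_demand(2)
  expect_equal(unname(d2), c(1656, 1678, 31035, 1692, 6689, 501, 1691,
                             1692))
  d3 <- scenario_demand("esv")
  expect_equal(unname(d3), c(1656, 1678, 32784, 1109, 6688, 501, 1109,
                             1109))
  expect_equal(sum(d1), 46634)
  expect_equal(sum(d2), 46634)
  expect_equal(sum(d3), 46634)
})

test_that("demand trajectories interpolate linearly and conserve area", {
  base <- stats::setNames(c(10, 0), c("a", "b"))
  tr <- interpolate_demand(base, stats::setNames(c(10, 0), c("a", "b")),
                           2000, 2005)
  expect_true(all(tr[, "a"] == 10))
  tr2 <- interpolate_demand(stats::setNames(c(13, 0), c("a", "b")),
                            stats::setNames(c(0, 13), c("a", "b")),
                            2007, 2020)
  expect_equal(unname(diff(tr2[, "b"])), rep(1, 13))

  traj <- interpolate_demand(base_year_areas(), scenario_demand(2))
  expect_equal(unname(rowSums(traj)), rep(46634, 14))
  expect_equal(traj[1, ], base_year_areas())
  expect_equal(traj[14, ], scenario_demand(2))
  expect_error(interpolate_demand(c(a = 10), c(a = 12)), "differ in total")
})
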