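toy_rules <- function(k = 8) transition_rules()

# Build a probability matrix for a toy grid from a per-class score matrix.
toy_probs <- function(score, nr, nc) {
  p <- matrix(0.5, nr * nc, 8)
  p[, seq_len(ncol(score))] <- score
  p
}

test_that("rank AUC matches brute-force pair counting", {
  expect_equal(rank_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(rank_auc(rep(0.3, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  # oracle-computed value for a small mixed case
  expect_equal(rank_auc(c(0.4, 0.3, 0.2, 0.8), c(0, 1, 0, 1)),
               oracle_auc(c(0.4, 0.3, 0.2, 0.8), c(0, 1, 0, 1)))
  expect_equal(oracle_auc(c(0.4, 0.3, 0.2, 0.8), c(0, 1, 0, 1)), 0.75)
  set.seed(5)
  for (rep in 1:10) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE) # plenty of ties
    l <- stats::rbinom(30, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(rank_auc(s, l), oracle_auc(s, l))
  }
  expect_error(rank_auc(c(1, 2), c(1, 1)), "both outcome labels")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  s <- stats::rnorm(500)
  l <- stats::rbinom(500, 1, stats::plogis(s))
  expect_equal(rank_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
})

test_that("separable and null classes give extreme and chance AUC", {
  land <- small_landscape(seed = 55, nr = 100, nc = 100)
  v <- as.vector(land$grid$values)
  # class defined by thresholding one factor: perfectly separable
  x1 <- as.vector(land$factors$layers$X1)
  lab <- as.integer(x1 > 1)
  expect_equal(rank_auc(x1, lab), 1.0)
  # scores independent of the outcome: AUC ~ 0.5 on 10,000 cells
  set.seed(9)
  noise <- stats::rnorm(length(v))
  expect_lt(abs(rank_auc(noise, as.integer(v == 3)) - 0.5), 0.05)
})

test_that("total probability is additive and monotone in ITER", {
  expect_equal(tprop(0.3, 0, 0), 0.3)
  expect_equal(tprop(0.3, 0.5, 0.1), 0.9)
  p <- stats::runif(20)
  expect_true(all(tprop(p, 0.2, 0.3) > tprop(p, 0.2, 0.1)))
})

test_that("transition rule invariants are enforced", {
  expect_error(transition_rules(elas = replace(default_elas(), 1, 1.5)),
               "\\[0, 1\\]")
  bad <- default_transition_matrix()
  diag(bad)[3] <- 0L
  expect_error(transition_rules(allowed = bad), "diagonal")
  bad2 <- default_transition_matrix()
  bad2["forest", "aml"] <- 1L
  expect_error(transition_rules(allowed = bad2), "into AML")
  r <- transition_rules()
  expect_setequal(r$protected, c("construction", "water"))
})

test_that("identity demand with identity rules returns the input map", {
  land <- small_landscape(seed = 77, nr = 20, nc = 20)
  idm <- default_transition_matrix()
  idm[, ] <- 0L; diag(idm) <- 1L
  rules <- transition_rules(allowed = idm)
  probs <- true_probabilities(land)
  out <- allocate_step(land$grid, class_areas(land$grid), rules, probs)
  expect_identical(out$values, land$grid$values)
})

test_that("tiny-grid allocation matches exhaustive search", {
  set.seed(31)
  for (rep in 1:8) {
    nr <- 2; nc <- sample(2:4, 1)
    n <- nr * nc
    k <- sample(2:3, 1)
    cur <- sample.int(k, n, replace = TRUE)
    # open transition rules among the first k classes
    allowed <- default_transition_matrix()
    allowed[seq_len(k), seq_len(k)] <- 1L
    allowed[, 6] <- 0L; diag(allowed) <- 1L
    rules <- transition_rules(allowed = allowed)
    score <- matrix(stats::runif(n * k), n, k)
    dem_cells <- as.integer(largest_remainder(rep(1, k), n))
    demand <- stats::setNames(numeric(8), names(landuse_classes()))
    demand[seq_len(k)] <- dem_cells
    grid <- land_grid(matrix(cur, nr, nc))
    probs <- toy_probs(score, nr, nc)
    out <- allocate_step(grid, demand, rules, probs, tolerance = 0,
                         eta = 0.2, max_iter = 5000)
    got <- as.vector(out$values)
    # oracle maximizes the same base score (prob + incumbent elasticity)
    base <- score
    base[cbind(seq_len(n), cur)] <- base[cbind(seq_len(n), cur)] +
      rules$elas[cur]
    oracle <- oracle_allocation(cur, dem_cells,
                                allowed[seq_len(k), seq_len(k)], base)
    expect_equal(sum(base[cbind(seq_len(n), got)]), oracle$value,
                 tolerance = 1e-9)
    expect_equal(tabulate(got, k), dem_cells)
  }
})

test_that("allocation meets demand within tolerance and respects rules", {
  land <- small_landscape(seed = 13, nr = 50, nc = 50)
  rules <- transition_rules()
  models <- fit_logits(land$grid, land$factors)
  probs <- predict_probabilities(models, land$factors)
  areas <- class_areas(land$grid)
  total <- sum(areas)
  target <- areas + c(50, 10, -80, -40, 90, -60, 20, 10)
  stopifnot(sum(target) == total)
  out <- allocate_step(land$grid, target, rules, probs)
  got <- class_areas(out)
  tol <- pmax(1, floor(0.005 * target))
  expect_true(all(abs(got - target) <= tol))
  # protected cells unchanged; no new AML
  v0 <- as.vector(land$grid$values); v1 <- as.vector(out$values)
  for (cl in c("construction", "water")) {
    code <- landuse_classes()[[cl]]
    expect_true(all(v1[v0 == code] == code))
  }
  aml <- landuse_classes()[["aml"]]
  expect_true(all(which(v1 == aml) %in% which(v0 == aml)))
})

test_that("infeasible demands are rejected up front", {
  land <- small_landscape(seed = 14, nr = 20, nc = 20)
  rules <- transition_rules()
  probs <- true_probabilities(land)
  areas <- class_areas(land$grid)
  bad <- areas
  bad["construction"] <- bad["construction"] - 5
  bad["grassland"] <- bad["grassland"] + 5
  expect_error(allocate_step(land$grid, bad, rules, probs),
               "protected")
  bad2 <- areas
  bad2["aml"] <- bad2["aml"] + 5
  bad2["forest"] <- bad2["forest"] - 5
  expect_error(allocate_step(land$grid, bad2, rules, probs),
               "no conversions into it")
  expect_error(allocate_step(land$grid, areas + 10, rules, probs),
               "does not sum")
})

test_that("a one-step trajectory equals a single allocation step", {
  land <- small_landscape(seed = 15, nr = 30, nc = 30)
  rules <- transition_rules()
  probs <- true_probabilities(land)
  areas <- class_areas(land$grid)
  target <- areas + c(20, 0, -30, -10, 15, -5, 5, 5)
  traj <- rbind(`2007` = areas, `2008` = target)
  sim <- simulate_landuse(land$grid, traj, rules, probs)
  single <- allocate_step(land$grid, target, rules, probs)
  expect_identical(sim$maps[[2]]$values, single$values)
  expect_error(simulate_landuse(land$grid,
                                rbind(`2007` = target, `2008` = target),
                                rules, probs),
               "base-year")
})

test_that("AML is non-increasing along a declining-demand trajectory", {
  land <- small_landscape(seed = 16, nr = 40, nc = 40)
  rules <- transition_rules()
  probs <- true_probabilities(land)
  areas <- class_areas(land$grid)
  target <- areas
  drop <- min(60, areas[["aml"]] - 5)
  target["aml"] <- target["aml"] - drop
  target["forest"] <- target["forest"] + drop
  traj <- interpolate_demand(areas, target, 2007, 2011)
  sim <- simulate_landuse(land$grid, traj, rules, probs)
  aml <- landuse_classes()[["aml"]]
  sets <- lapply(sim$maps, function(g) which(as.vector(g$values) == aml))
  for (t in 2:length(sets)) {
    expect_true(all(sets[[t]] %in% sets[[t - 1]]))
  }
  # determinism of the whole run
  sim2 <- simulate_landuse(land$grid, traj, rules, probs)
  expect_identical(sim$maps[[length(sim$maps)]]$values,
                   sim2$maps[[length(sim2$maps)]]$values)
})
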