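# Run expr with a local RNG state seeded from `seed`, restoring the global
# state afterwards so generator calls never perturb user randomness.
run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Box blur with clipped windows via integral images; two passes approximate
# a Gaussian of scale ~radius.
smooth_field <- function(m, radius, passes = 2) {
  if (radius < 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    ii <- rbind(0, apply(m, 2, cumsum))
    ii <- cbind(0, t(apply(ii, 1, cumsum)))
    r1 <- pmax(1, seq_len(nr) - radius); r2 <- pmin(nr, seq_len(nr) + radius)
    c1 <- pmax(1, seq_len(nc) - radius); c2 <- pmin(nc, seq_len(nc) + radius)
    s <- ii[r2 + 1, c2 + 1, drop = FALSE] - ii[r1, c2 + 1, drop = FALSE] -
      ii[r2 + 1, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
    cnt <- outer(r2 - r1 + 1, c2 - c1 + 1)
    m <- s / cnt
  }
  m
}

standardize <- function(m) {
  s <- stats::sd(as.vector(m))
  if (s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

#' Generator-truth logit coefficients
#'
#' The default data-generating coefficients of the synthetic landscape:
#' one row per land-use class, columns \code{b0} (intercept) and
#' \code{X1..X15}. Signs encode the qualitative driving-factor story of
#' the study system (e.g. cultivated land favours low elevation/slope and
#' high soil organic matter; construction land favours road and town
#' proximity and population density; water hugs the river network).
#' Factors are standardized, so magnitudes are log-odds per standard
#' deviation.
#'
#' @return 8 x 16 numeric matrix.
#' @export
default_true_betas <- function() {
  b <- matrix(0, nrow = 8, ncol = 16,
              dimnames = list(names(landuse_classes()),
                              c("b0", paste0("X", 1:15))))
  b["cultivated", c("b0", "X1", "X2", "X8", "X11")] <-
    c(-2.0, -0.8, -0.8, 0.8, 0.6)
  b["garden", c("b0", "X2", "X7", "X13")] <- c(-2.5, -0.5, -0.6, 0.6)
  b["forest", c("b0", "X1", "X6", "X14", "X15")] <-
    c(0.5, 0.8, 0.5, 0.6, 0.6)
  b["grassland", c("b0", "X1", "X5", "X14")] <- c(-1.5, 0.5, 0.5, -0.5)
  b["construction", c("b0", "X3", "X6", "X9", "X10")] <-
    c(-2.0, -0.9, -0.8, 0.9, 0.5)
  b["aml", c("b0", "X2", "X12")] <- c(-2.5, 0.5, 0.9)
  b["water", c("b0", "X1", "X5")] <- c(-3.0, -0.5, -1.2)
  b["unutilized", c("b0", "X2", "X8", "X9")] <- c(-2.0, 0.5, -0.6, -0.5)
  b
}

#' Configuration of the synthetic landscape generator
#'
#' The defaults emulate the study landscape: a 466 km2 district rasterized
#' at 100 m (one-hectare cells), 46,634 valid cells, the eight base-year
#' class areas as proportions, and 93 abandoned-mine-land patches. The
#' rectangle hosting the cells is 216 x 216; the trailing cells beyond
#' \code{n_cells} (row-major from the south-east corner) are nodata
#' padding.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param n_cells Number of valid cells (\code{NULL} = all); must not
#'   exceed \code{n_rows * n_cols}.
#' @param cell_size Cell edge, meters.
#' @param class_proportions Eight non-negative fractions summing to 1.
#' @param n_aml_patches Target number of AML patch nuclei (>= 1 whenever
#'   the AML proportion is positive).
#' @param clump_scale Spatial autocorrelation length in cells (smoothing
#'   radius of the noise fields).
#' @param clump_weight Weight of the class-specific clumping field in the
#'   assignment utility.
#' @param true_betas 8 x 16 generator-truth coefficient matrix
#'   (\code{\link{default_true_betas}}).
#' @param seed Integer; all generator randomness flows from it.
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_rows = 216, n_cols = 216, n_cells = 46634,
                             cell_size = 100,
                             class_proportions = base_year_areas() /
                               sum(base_year_areas()),
                             n_aml_patches = 93,
                             clump_scale = 4,
                             clump_weight = 1.5,
                             true_betas = default_true_betas(),
                             seed = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0,
            length(class_proportions) == 8, all(class_proportions >= 0),
            is.matrix(true_betas), all(dim(true_betas) == c(8, 16)))
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  if (is.null(n_cells)) n_cells <- n_rows * n_cols
  if (n_cells > n_rows * n_cols) {
    stop("n_cells exceeds the grid size")
  }
  aml_p <- class_proportions[landuse_classes()[["aml"]]]
  if (aml_p > 0 && n_aml_patches < 1) {
    stop("n_aml_patches must be >= 1 when the AML proportion is positive")
  }
  if (n_aml_patches > n_cells) {
    stop("grid too small to host ", n_aml_patches, " AML patches")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, n_cells = n_cells,
                 cell_size = cell_size,
                 class_proportions = class_proportions,
                 n_aml_patches = n_aml_patches, clump_scale = clump_scale,
                 clump_weight = clump_weight, true_betas = true_betas,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Valid-cell mask matrix: TRUE for the first n_cells cells column-major.
config_mask <- function(config) {
  m <- matrix(FALSE, config$n_rows, config$n_cols)
  m[seq_len(config$n_cells)] <- TRUE
  m
}

generate_factors <- function(config) {
  nr <- config$n_rows; nc <- config$n_cols
  rowf <- matrix(seq_len(nr), nr, nc)
  colf <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  layers <- lapply(1:15, function(k) {
    ang <- 2 * pi * (k - 1) / 15
    grad <- cos(ang) * rowf / nr + sin(ang) * colf / nc
    noise <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                          config$clump_scale)
    standardize(0.6 * standardize(grad) + 0.8 * standardize(noise))
  })
  names(layers) <- paste0("X", 1:15)
  factor_stack(layers, cell_size = config$cell_size)
}

# AML clumping field: radial bumps around n_aml_patches nuclei so the AML
# quota condenses into approximately that many compact patches.
aml_bump_field <- function(config, mask) {
  nr <- config$n_rows; nc <- config$n_cols
  valid_idx <- which(mask)
  nuclei <- sample(valid_idx, min(config$n_aml_patches, length(valid_idx)))
  rows <- (nuclei - 1) %% nr + 1
  cols <- (nuclei - 1) %/% nr + 1
  s <- max(config$clump_scale, 2)
  field <- matrix(0, nr, nc)
  rmat <- matrix(seq_len(nr), nr, nc)
  cmat <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_along(nuclei)) {
    d2 <- (rmat - rows[i])^2 + (cmat - cols[i])^2
    field <- pmax(field, exp(-d2 / (2 * s^2)))
  }
  field
}

#' Generate a synthetic base-year landscape
#'
#' Produces a categorical land-use raster, a 15-layer driving-factor stack
#' and an attributed AML patch set with known statistical structure. The
#' driving factors are standardized deterministic gradients plus smoothed
#' noise. Class labels are assigned by a quota-balanced argmax
#' over per-class utilities \code{b0 + X beta} (the generator-truth logit
#' score) plus a class-specific spatially autocorrelated clumping field,
#' so per-class cell counts match the requested proportions to within one
#' cell and a one-vs-rest logit fitted to the output recovers the signs of
#' \code{true_betas}. The AML clumping field concentrates the AML quota
#' around \code{n_aml_patches} nuclei.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return Object of class \code{synthetic_landscape}: list with
#'   \code{grid} (a \code{\link{land_grid}}), \code{factors} (a
#'   \code{\link{factor_stack}}), \code{aml_patches} (see
#'   \code{\link{aml_patch_table}}) and \code{config}.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  run_seeded(config$seed, {
    mask <- config_mask(config)
    factors <- generate_factors(config)
    nr <- config$n_rows; nc <- config$n_cols
    xmat <- cbind(1, factor_matrix(factors))
    util <- xmat %*% t(config$true_betas)
    for (k in 1:8) {
      if (names(landuse_classes())[k] == "aml") {
        clump <- 6 * aml_bump_field(config, mask)
      } else {
        clump <- config$clump_weight *
          standardize(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                                   config$clump_scale))
      }
      util[, k] <- util[, k] + as.vector(clump)
    }
    valid_idx <- which(as.vector(mask))
    quotas <- largest_remainder(config$class_proportions,
                                length(valid_idx))
    labels <- assign_quota_balanced(util[valid_idx, , drop = FALSE],
                                    quotas)
    values <- matrix(NA_real_, nr, nc)
    values[valid_idx] <- labels
    grid <- land_grid(values, cell_size = config$cell_size)
    patches <- aml_patch_table(grid)
    structure(list(grid = grid, factors = factors, aml_patches = patches,
                   config = config),
              class = "synthetic_landscape")
  })
}

# Quota-constrained assignment by balanced argmax: per-class additive
# offsets are adjusted until the argmax occupancy meets the quotas
# (approximately the optimal-transport solution, so each class condenses
# on its best-scoring cells), then a greedy swap repair enforces the
# quotas exactly. Fully deterministic given `util`.
assign_quota_balanced <- function(util, quotas, eta = 0.2,
                                  max_iter = 3000) {
  n <- nrow(util); k <- ncol(util)
  stopifnot(sum(quotas) == n)
  lam <- numeric(k)
  eta_u <- rep(eta, k)
  prev <- rep(NA_real_, k)
  lab <- integer(n)
  for (it in seq_len(max_iter)) {
    sc <- util + rep(lam, each = n)
    lab <- max.col(sc, ties.method = "first")
    dev <- quotas - tabulate(lab, k)
    if (max(abs(dev)) <= pmax(1, quotas %/% 500)[which.max(abs(dev))]) break
    flip <- !is.na(prev) & sign(dev) * sign(prev) < 0
    eta_u[flip] <- pmax(eta_u[flip] * 0.5, 1e-3)
    prev <- dev
    lam <- lam + eta_u * dev / pmax(quotas, 1)
  }
  sc <- util + rep(lam, each = n)
  dev <- quotas - tabulate(lab, k)
  while (any(dev != 0)) {
    u <- which.max(dev)   # most under-allocated class
    o <- which.min(dev)   # most over-allocated class
    cand <- which(lab == o)
    best <- cand[which.max(sc[cand, u] - sc[cand, o])]
    lab[best] <- u
    dev[u] <- dev[u] - 1L
    dev[o] <- dev[o] + 1L
  }
  lab
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("<synthetic_landscape>\n")
  print(x$grid)
  cat(sprintf("  %d AML patches\n", nrow(x$aml_patches$patches)))
  invisible(x)
}

#' Delineate and attribute the AML patches of a land-use raster
#'
#' AML patches are the 8-connected components of the AML class. Each patch
#' receives the seven suitability attributes, sampled uniformly over the
#' grading intervals of the criteria table (numeric intervals first drawn
#' by band, then uniformly within the band) so that all suitability classes
#' occur across a patch set.
#'
#' @param grid A \code{\link{land_grid}}.
#' @return List with \code{patches} (data frame: patch_id, n_cells,
#'   area_hm2 and the seven attributes) and \code{cells} (list of
#'   cell-index vectors, column-major).
#' @export
aml_patch_table <- function(grid) {
  aml_code <- landuse_classes()[["aml"]]
  ps <- delineate_patches(grid, connectivity = 8)
  sel <- ps$patches$class == aml_code
  ids <- ps$patches$patch_id[sel]
  cells <- lapply(ids, function(id) which(as.vector(ps$labels) == id))
  n <- length(ids)
  if (n == 0) {
    return(list(patches = data.frame(), cells = list()))
  }
  sample_bands <- function(bands) {
    pick <- sample.int(length(bands), n, replace = TRUE)
    lo <- vapply(bands, `[`, numeric(1), 1)[pick]
    hi <- vapply(bands, `[`, numeric(1), 2)[pick]
    stats::runif(n, lo, hi)
  }
  patches <- data.frame(
    patch_id = seq_len(n),
    n_cells = ps$patches$n_cells[sel],
    area_hm2 = ps$patches$area_hm2[sel],
    slope = sample_bands(list(c(0, 5), c(5, 10), c(10, 15), c(15, 25))),
    surface = sample(c("loam_sandy_loam", "rock_soil_mixture",
                       "sand_gravel"), n, replace = TRUE),
    som = sample_bands(list(c(0.1, 0.5), c(0.5, 1), c(1, 3))),
    thickness = sample_bands(list(c(5, 10), c(10, 40), c(40, 60),
                                  c(60, 80), c(80, 120))),
    irrigation = sample(c("full", "basic", "none"), n, replace = TRUE),
    road_dist = sample_bands(list(c(0, 2000), c(2000, 4000),
                                  c(4000, 6000), c(6000, 8000))),
    damage = sample(c("light", "moderate", "severe"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(patches = patches, cells = cells)
}

#' Forward-reference ("future truth") map
#'
#' Regenerates the landscape from \code{config} and runs the allocation
#' engine with conversion probabilities computed from the generator-truth
#' coefficients, yielding a reference horizon map against which simulations
#' driven by fitted coefficients can be scored (e.g. by
#' \code{\link{kappa_agreement}}).
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param rules \code{\link{transition_rules}}.
#' @param trajectory Demand trajectory from \code{\link{interpolate_demand}}
#'   whose first row matches the generated base-year areas.
#' @param ... Passed to \code{\link{simulate_landuse}}.
#' @return The horizon-year \code{\link{land_grid}}.
#' @export
forward_reference <- function(config, rules, trajectory, ...) {
  land <- generate_landscape(config)
  probs <- true_probabilities(land)
  sim <- simulate_landuse(land$grid, trajectory, rules, probs, ...)
  sim$maps[[length(sim$maps)]]
}

#' Conversion probabilities from the generator-truth coefficients
#'
#' @param landscape A \code{synthetic_landscape}.
#' @return Cell-by-class matrix of logistic probabilities.
#' @export
true_probabilities <- function(landscape) {
  xmat <- cbind(1, factor_matrix(landscape$factors))
  stats::plogis(xmat %*% t(landscape$config$true_betas))
}

#' Write a synthetic landscape to disk
#'
#' The land-use grid and each driving factor are written as ESRI ASCII
#' grids, the AML patch attributes as CSV.
#'
#' @param landscape A \code{synthetic_landscape}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ascii_grid(landscape$grid, file.path(dir, "landuse.asc"))
  for (nm in names(landscape$factors$layers)) {
    write_ascii_grid(land_grid(landscape$factors$layers[[nm]],
                               cell_size = landscape$factors$cell_size),
                     file.path(dir, paste0(nm, ".asc")))
  }
  utils::write.csv(landscape$aml_patches$patches,
                   file.path(dir, "aml_patches.csv"), row.names = FALSE)
  invisible(dir)
}
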