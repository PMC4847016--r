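# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive, separate code path (recursion, exhaustive
# enumeration, closed forms) kept free of the package's internals.

# Flood-fill connected components by explicit stack traversal.
oracle_components <- function(values, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(NA_integer_, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(values[r, c]) || !is.na(lab[r, c])) next
    nxt <- nxt + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(offs))) {
        rr <- cur[1] + offs[i, 1]; cc <- cur[2] + offs[i, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (is.na(values[rr, cc]) || !is.na(lab[rr, cc])) next
        if (values[rr, cc] != values[cur[1], cur[2]]) next
        lab[rr, cc] <- nxt
        stack[[length(stack) + 1]] <- c(rr, cc)
      }
    }
  }
  lab
}

# Brute-force LP by vertex enumeration: every n-subset of the active
# constraint candidates (constraints as equalities plus x_i = 0 planes)
# defines a candidate vertex; keep feasible ones and return the best.
oracle_lp <- function(obj, A, dir, rhs, maximize = TRUE, tol = 1e-8) {
  n <- length(obj)
  planes <- rbind(A, diag(n))
  prhs <- c(rhs, rep(0, n))
  m <- nrow(planes)
  best <- NULL; best_val <- if (maximize) -Inf else Inf
  for (idx in utils::combn(m, n, simplify = FALSE)) {
    M <- planes[idx, , drop = FALSE]
    if (abs(det(M)) < tol) next
    x <- tryCatch(solve(M, prhs[idx]), error = function(e) NULL)
    if (is.null(x)) next
    lhs <- as.numeric(A %*% x)
    feas <- all(x >= -tol) &&
      all(ifelse(dir == "<=", lhs <= rhs + tol,
                 ifelse(dir == ">=", lhs >= rhs - tol,
                        abs(lhs - rhs) <= tol)))
    if (!feas) next
    val <- sum(obj * x)
    if ((maximize && val > best_val) || (!maximize && val < best_val)) {
      best_val <- val; best <- x
    }
  }
  list(x = best, value = best_val)
}

# Exhaustive-search allocation: enumerate all class assignments meeting
# the per-class cell demand and the allowed-transition rules, maximizing
# the summed base score (probability + incumbent elasticity). Feasible
# only for tiny grids.
oracle_allocation <- function(cur, demand_cells, allowed, base_score) {
  n <- length(cur)
  k <- ncol(base_score)
  best <- NULL; best_val <- -Inf
  recurse <- function(i, assign, left, val) {
    if (i > n) {
      if (all(left == 0) && val > best_val) {
        best_val <<- val; best <<- assign
      }
      return()
    }
    for (cl in seq_len(k)) {
      if (left[cl] == 0 || allowed[cur[i], cl] == 0) next
      left[cl] <- left[cl] - 1L
      recurse(i + 1, c(assign, cl), left, val + base_score[i, cl])
      left[cl] <- left[cl] + 1L
    }
  }
  recurse(1L, integer(0), as.integer(demand_cells), 0)
  list(assign = best, value = best_val)
}

# AUC by explicit concordant/discordant pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Directed 4-neighbor adjacency counts g[i, k] by explicit looping.
oracle_adjacency <- function(values, classes) {
  nr <- nrow(values); nc <- ncol(values)
  m <- length(classes)
  g <- matrix(0, m, m)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(values[r, c])) next
    i <- match(values[r, c], classes)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (is.na(values[rr, cc])) next
      k <- match(values[rr, cc], classes)
      g[i, k] <- g[i, k] + 1
    }
  }
  g
}

# Contagion from first principles via oracle_adjacency.
oracle_contagion <- function(values) {
  cls <- sort(unique(values[!is.na(values)]))
  m <- length(cls)
  if (m < 2) return(100)
  g <- oracle_adjacency(values, cls)
  p <- as.numeric(table(factor(values[!is.na(values)], levels = cls)))
  p <- p / sum(p)
  q <- p * g / pmax(rowSums(g), 1)
  q <- q[q > 0]
  (1 + sum(q * log(q)) / (2 * log(m))) * 100
}

# Pairwise min cell-center distance between same-class patches, brute
# force over all cell pairs.
oracle_patch_distances <- function(values, connectivity = 8,
                                   cell_size = 100) {
  lab <- oracle_components(values, connectivity)
  ids <- sort(unique(lab[!is.na(lab)]))
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    ci <- which(lab == ids[i], arr.ind = TRUE)
    cj <- which(lab == ids[j], arr.ind = TRUE)
    if (values[ci[1, 1], ci[1, 2]] != values[cj[1, 1], cj[1, 2]]) next
    dmin <- Inf
    for (a in seq_len(nrow(ci))) for (b in seq_len(nrow(cj))) {
      d <- sqrt(sum((ci[a, ] - cj[b, ])^2))
      dmin <- min(dmin, d)
    }
    out[[length(out) + 1]] <- data.frame(a = ids[i], b = ids[j],
                                         dist_m = dmin * cell_size)
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# Random categorical raster for property checks.
random_grid <- function(nr, nc, n_classes, cell_size = 100) {
  land_grid(matrix(sample.int(n_classes, nr * nc, replace = TRUE), nr, nc),
            cell_size = cell_size)
}

# Small synthetic landscape shared by several tests.
small_landscape <- function(seed = 42, nr = 50, nc = 50) {
  generate_landscape(synthetic_config(n_rows = nr, n_cols = nc,
                                      n_cells = NULL, n_aml_patches = 8,
                                      seed = seed))
}

# Full nine-metric oracle built only from the helper oracles.
oracle_metrics <- function(grid, connectivity = 8, threshold = NULL) {
  v <- grid$values
  cs <- grid$cell_size
  lab <- oracle_components(v, connectivity)
  ids <- sort(unique(lab[!is.na(lab)]))
  areas <- vapply(ids, function(i) sum(lab == i, na.rm = TRUE),
                  numeric(1)) * cs^2 / 1e4
  n <- length(ids)
  # edges: boundary/nodata sides once, internal class boundaries once
  nr <- nrow(v); nc <- ncol(v)
  estar <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || is.na(v[rr, cc])) {
        estar <- estar + 1
      } else if (v[rr, cc] != v[r, c]) {
        estar <- estar + 0.5
      }
    }
  }
  # contiguity by direct template evaluation
  contig <- vapply(ids, function(i) {
    cells <- which(lab == i, arr.ind = TRUE)
    sc <- 0
    for (j in seq_len(nrow(cells))) {
      r <- cells[j, 1]; c <- cells[j, 2]
      s <- 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !is.na(lab[rr, cc]) && lab[rr, cc] == i) s <- s + 2
      }
      for (d in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !is.na(lab[rr, cc]) && lab[rr, cc] == i) s <- s + 1
      }
      sc <- sc + s
    }
    (sc / nrow(cells) - 1) / 12
  }, numeric(1))
  pd <- oracle_patch_distances(v, connectivity, cs)
  enn <- if (is.null(pd)) NA_real_ else {
    nn <- tapply(c(pd$dist_m, pd$dist_m), c(pd$a, pd$b), min)
    mean(nn)
  }
  if (is.null(threshold)) threshold <- enn
  conn <- if (is.null(pd)) NA_real_ else
    100 * sum(pd$dist_m <= threshold) / nrow(pd)
  vv <- v[!is.na(v)]
  p <- as.numeric(table(vv)) / length(vv)
  m <- length(p)
  shdi_v <- -sum(p * log(p))
  list(mean_patch_size = sum(areas) / n,
       patch_size_cv = if (n < 2) NA_real_ else
         100 * sqrt(mean((areas - mean(areas))^2)) / mean(areas),
       lsi = 0.25 * estar * cs / sqrt(sum(areas) * 1e4),
       contiguity_am = sum(areas * contig) / sum(areas),
       contagion = oracle_contagion(v),
       enn_mn = enn, connectance = conn,
       shdi = shdi_v, shei = if (m < 2) 0 else shdi_v / log(m))
}

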