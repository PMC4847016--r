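# Neighbor index pairs of a nr x nc matrix for the given connectivity:
# two-column matrix of (cell, neighbor) with cell < neighbor, column-major
# indices.
neighbor_pairs <- function(nr, nc, connectivity = 4) {
  id <- matrix(seq_len(nr * nc), nr, nc)
  pairs <- list(
    cbind(as.vector(id[-nr, , drop = FALSE]),
          as.vector(id[-1, , drop = FALSE])),
    cbind(as.vector(id[, -nc, drop = FALSE]),
          as.vector(id[, -1, drop = FALSE]))
  )
  if (connectivity == 8) {
    pairs <- c(pairs, list(
      cbind(as.vector(id[-nr, -nc, drop = FALSE]),
            as.vector(id[-1, -1, drop = FALSE])),
      cbind(as.vector(id[-1, -nc, drop = FALSE]),
            as.vector(id[-nr, -1, drop = FALSE]))
    ))
  }
  do.call(rbind, pairs)
}

#' Delineate patches of a categorical raster
#'
#' Patches are connected components of same-class cells under 4- or
#' 8-neighbor adjacency (default 8, the FRAGSTATS convention). Patch
#' perimeters count cell sides adjacent to a different class, nodata or
#' the landscape boundary.
#'
#' @param grid A \code{\link{land_grid}}.
#' @param connectivity 4 or 8.
#' @return Object of class \code{patch_set}: list with \code{labels}
#'   (patch-id matrix, \code{NA} on nodata), \code{patches} (data frame
#'   with patch_id, class, n_cells, area_hm2, perimeter_m), the landscape
#'   totals \code{total_area_m2} and \code{total_edge_m} (internal class
#'   edges counted once, plus the landscape/nodata boundary), and
#'   \code{cell_size}.
#' @export
delineate_patches <- function(grid, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  v <- as.vector(grid$values)
  if (n_valid_cells(grid) == 0) stop("empty raster: no valid cells")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  np <- neighbor_pairs(nr, nc, connectivity)
  same <- !is.na(v[np[, 1]]) & !is.na(v[np[, 2]]) &
    v[np[, 1]] == v[np[, 2]]
  g <- igraph::graph_from_edgelist(np[same, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  memb[is.na(v)] <- NA
  ids <- sort(unique(memb[!is.na(memb)]))
  relabel <- match(memb, ids)
  labels <- matrix(relabel, nr, nc)

  tab <- tabulate(relabel[!is.na(relabel)], length(ids))
  first_cell <- rep(NA_integer_, length(ids))
  seen <- which(!is.na(relabel))
  first_cell[relabel[seen][!duplicated(relabel[seen])]] <-
    seen[!duplicated(relabel[seen])]
  patch_class <- v[first_cell]

  # 4-neighbor side counts: class-different, nodata or boundary sides.
  np4 <- neighbor_pairs(nr, nc, 4)
  a <- v[np4[, 1]]; b <- v[np4[, 2]]
  la <- relabel[np4[, 1]]; lb <- relabel[np4[, 2]]
  diff_edge <- !is.na(a) & !is.na(b) & a != b
  perim <- numeric(length(ids))
  add_counts <- function(lab) {
    t <- tabulate(lab, length(ids))
    perim <<- perim + t
  }
  add_counts(la[diff_edge])
  add_counts(lb[diff_edge])
  a_na <- !is.na(a) & is.na(b); add_counts(la[a_na])
  b_na <- is.na(a) & !is.na(b); add_counts(lb[b_na])
  # landscape boundary sides
  bcount <- boundary_side_counts(nr, nc, relabel, length(ids))
  perim <- perim + bcount

  cellsz <- grid$cell_size
  internal_once <- sum(diff_edge)
  nodata_edges <- sum(a_na) + sum(b_na)
  boundary_edges <- sum(bcount)
  total_edge_m <- (internal_once + nodata_edges + boundary_edges) * cellsz

  patches <- data.frame(patch_id = seq_along(ids),
                        class = patch_class,
                        n_cells = tab,
                        area_hm2 = tab * cellsz^2 / 1e4,
                        perimeter_m = perim * cellsz)
  structure(list(labels = labels, patches = patches,
                 total_area_m2 = sum(tab) * cellsz^2,
                 total_edge_m = total_edge_m,
                 cell_size = cellsz, connectivity = connectivity),
            class = "patch_set")
}

# Sides of valid cells on the outer rectangle edge, tabulated by patch.
boundary_side_counts <- function(nr, nc, relabel, n_ids) {
  id <- matrix(seq_len(nr * nc), nr, nc)
  edge_cells <- c(id[1, ], id[nr, ], id[, 1], id[, nc])
  lab <- relabel[edge_cells]
  tabulate(lab[!is.na(lab)], n_ids)
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, %d classes, %d-connectivity\n",
              nrow(x$patches), length(unique(x$patches$class)),
              x$connectivity))
  invisible(x)
}

#' Mean patch size
#' @param p A \code{\link{delineate_patches}} result.
#' @return Mean patch area (hm2), total area over patch count.
#' @export
mean_patch_size <- function(p) {
  sum(p$patches$area_hm2) / nrow(p$patches)
}

#' Patch size coefficient of variation
#' @param p A \code{patch_set}; needs at least two patches.
#' @return 100 x population standard deviation / mean of patch areas (%).
#' @export
patch_size_cv <- function(p) {
  a <- p$patches$area_hm2
  if (length(a) < 2) stop("patch size CV needs at least 2 patches")
  m <- mean(a)
  100 * sqrt(mean((a - m)^2)) / m
}

#' Landscape shape index
#'
#' Standardized total edge: \code{0.25 E* / sqrt(A)} with E* the total
#' edge length including the landscape boundary and A the landscape area,
#' in consistent units. A single-class square landscape scores exactly 1.
#'
#' @param p A \code{patch_set}.
#' @return Dimensionless index >= 1 for rectangular landscapes.
#' @export
landscape_shape_index <- function(p) {
  0.25 * p$total_edge_m / sqrt(p$total_area_m2)
}

#' Area-weighted mean patch contiguity index
#'
#' Per patch, each cell is scored with a 3 x 3 template (center 1,
#' orthogonal neighbors 2, diagonal neighbors 1, counting only cells of
#' the same patch); patch contiguity is (mean cell score - 1) / 12, which
#' is 0 for a one-pixel patch and approaches 1 for large solid blocks.
#' The landscape value is the area-weighted mean over patches.
#'
#' @param p A \code{patch_set}.
#' @return Value in [0, 1].
#' @export
contiguity_am <- function(p) {
  lab <- p$labels
  nr <- nrow(lab); nc <- ncol(lab)
  score <- matrix(1, nr, nc)
  shifts <- list(c(1, 0, 2), c(-1, 0, 2), c(0, 1, 2), c(0, -1, 2),
                 c(1, 1, 1), c(1, -1, 1), c(-1, 1, 1), c(-1, -1, 1))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]; w <- s[3]
    r_src <- seq_len(nr) - dr; c_src <- seq_len(nc) - dc
    ok_r <- r_src >= 1 & r_src <= nr; ok_c <- c_src >= 1 & c_src <= nc
    nb <- matrix(NA_integer_, nr, nc)
    nb[ok_r, ok_c] <- lab[r_src[ok_r], c_src[ok_c]]
    same <- !is.na(lab) & !is.na(nb) & lab == nb
    score[same] <- score[same] + w
  }
  ok <- !is.na(lab)
  mean_score <- tapply(score[ok], lab[ok], mean)
  contig <- (mean_score - 1) / 12
  ord <- as.integer(names(contig))
  a <- p$patches$area_hm2[ord]
  sum(a * contig) / sum(a)
}

#' Contagion index
#'
#' Overall clumpiness of the categorical map from class proportions and
#' 4-neighbor cell adjacencies (double-counted; nodata and boundary
#' adjacencies excluded):
#' \code{CONTAG = (1 + sum q ln q / (2 ln m)) * 100} with
#' \code{q_ik = P_i g_ik / sum_k g_ik} over the m classes present.
#' A single-class raster returns 100 by convention.
#'
#' @param grid A \code{\link{land_grid}}.
#' @return Percentage in [0, 100]; 0 only for exactly uniform adjacency
#'   structure, 100 for a single-class map.
#' @export
contagion <- function(grid) {
  v <- as.vector(grid$values)
  cls <- sort(unique(v[!is.na(v)]))
  m <- length(cls)
  if (m < 2) return(100)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  np <- neighbor_pairs(nr, nc, 4)
  a <- v[np[, 1]]; b <- v[np[, 2]]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  ai <- match(a, cls); bi <- match(b, cls)
  g <- matrix(0, m, m)
  # double-count: each adjacency seen from both cells
  for (pair in list(cbind(ai, bi), cbind(bi, ai))) {
    t <- table(factor(pair[, 1], levels = seq_len(m)),
               factor(pair[, 2], levels = seq_len(m)))
    g <- g + as.matrix(t)
  }
  p_i <- tabulate(match(v[!is.na(v)], cls), m) / sum(!is.na(v))
  q <- p_i * g / pmax(rowSums(g), 1)
  q <- q[q > 0]
  # 0 is attained exactly when q is uniform over the m^2 adjacency cells
  # (equal proportions, perfectly balanced adjacencies); clamp rounding
  min(max((1 + sum(q * log(q)) / (2 * log(m))) * 100, 0), 100)
}

# Minimum center-to-center distance (cells) between two coordinate sets.
min_pair_distance <- function(xy1, xy2) {
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  sqrt(min(d2))
}

# All same-class patch pairs with their minimum edge-to-edge distance in
# meters, pruned by bounding-box lower bounds. `cap` skips exact
# evaluation of pairs whose lower bound exceeds it (Inf = none skipped).
patch_distances <- function(p, cap = Inf) {
  lab <- p$labels
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(NA_integer_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb_diff <- function(a) is.na(a) | a != core
  is_b <- !is.na(core) & (nb_diff(pad[1:nr, 2:(nc + 1)]) |
                          nb_diff(pad[3:(nr + 2), 2:(nc + 1)]) |
                          nb_diff(pad[2:(nr + 1), 1:nc]) |
                          nb_diff(pad[2:(nr + 1), 3:(nc + 2)]))
  idx <- which(is_b)
  coords <- cbind((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
  by_patch <- split(seq_along(idx), lab[idx])
  bbox <- t(vapply(by_patch, function(i) {
    c(min(coords[i, 1]), max(coords[i, 1]),
      min(coords[i, 2]), max(coords[i, 2]))
  }, numeric(4)))
  pid <- as.integer(names(by_patch))
  pclass <- p$patches$class[pid]

  out <- list()
  for (cl in unique(pclass)) {
    members <- which(pclass == cl)
    if (length(members) < 2) next
    for (ii in seq_along(members)[-length(members)]) {
      for (jj in seq((ii + 1), length(members))) {
        i <- members[ii]; j <- members[jj]
        dr <- max(0, bbox[i, 1] - bbox[j, 2], bbox[j, 1] - bbox[i, 2])
        dc <- max(0, bbox[i, 3] - bbox[j, 4], bbox[j, 3] - bbox[i, 4])
        lb <- sqrt(dr^2 + dc^2) * p$cell_size
        if (lb > cap) {
          out[[length(out) + 1]] <- data.frame(class = cl, a = pid[i],
                                               b = pid[j], dist_m = NA,
                                               lower_bound_m = lb)
          next
        }
        d <- min_pair_distance(coords[by_patch[[i]], , drop = FALSE],
                               coords[by_patch[[j]], , drop = FALSE]) *
          p$cell_size
        out[[length(out) + 1]] <- data.frame(class = cl, a = pid[i],
                                             b = pid[j], dist_m = d,
                                             lower_bound_m = lb)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(class = integer(0), a = integer(0), b = integer(0),
                      dist_m = numeric(0), lower_bound_m = numeric(0)))
  }
  do.call(rbind, out)
}

#' Mean Euclidean nearest-neighbor distance
#'
#' For each patch whose class has at least one other patch, the distance
#' (m) between the centers of the closest cell pair linking it to its
#' nearest same-class patch; averaged over those patches. Errors when no
#' class has two patches.
#'
#' @param p A \code{patch_set}.
#' @return Mean distance in meters.
#' @export
enn_mn <- function(p) {
  d <- patch_distances(p)
  if (nrow(d) == 0) {
    stop("no class has two or more patches; nearest-neighbor distance ",
         "undefined")
  }
  nn <- tapply(c(d$dist_m, d$dist_m), c(d$a, d$b), min)
  mean(nn)
}

#' Connectance index
#'
#' Percentage of functionally joined same-class patch pairs among all
#' same-class pairs, a pair being joined when its edge-to-edge distance
#' is within \code{threshold} meters.
#'
#' @param p A \code{patch_set}.
#' @param threshold Joining distance in meters (> 0); the package-level
#'   default used by \code{\link{landscape_metrics}} is the landscape
#'   mean nearest-neighbor distance.
#' @return Percentage in [0, 100].
#' @export
connectance <- function(p, threshold) {
  stopifnot(threshold > 0)
  d <- patch_distances(p)
  if (nrow(d) == 0) {
    stop("no class has two or more patches; connectance undefined")
  }
  100 * sum(d$dist_m <= threshold) / nrow(d)
}

#' Shannon's diversity and evenness indices
#'
#' Computed over the area proportions of the classes present:
#' \code{SHDI = -sum P_i ln P_i}; \code{SHEI = SHDI / ln m} (0 for a
#' single-class landscape).
#'
#' @param grid A \code{\link{land_grid}}.
#' @return \code{shdi}: value in nats >= 0; \code{shei}: value in [0, 1].
#' @export
shdi <- function(grid) {
  v <- grid$values[!is.na(grid$values)]
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log(p))
}

#' @rdname shdi
#' @export
shei <- function(grid) {
  v <- grid$values[!is.na(grid$values)]
  m <- length(unique(v))
  if (m < 2) return(0)
  shdi(grid) / log(m)
}

#' Landscape-level metrics report
#'
#' The nine landscape-level pattern metrics for one categorical map:
#' mean patch size, patch-size coefficient of variation, landscape shape
#' index, area-weighted mean patch contiguity, contagion, mean Euclidean
#' nearest-neighbor distance, connectance, Shannon diversity and Shannon
#' evenness. Metrics undefined for the map at hand (e.g. CV with a single
#' patch) are returned as \code{NA}.
#'
#' @param grid A \code{\link{land_grid}}.
#' @param connectivity Patch delineation connectivity (default 8).
#' @param connect_threshold Connectance joining distance (m); default the
#'   landscape mean nearest-neighbor distance.
#' @param map_id Optional identifier stored in the report row.
#' @return One-row data frame.
#' @export
landscape_metrics <- function(grid, connectivity = 8,
                              connect_threshold = NULL, map_id = NA) {
  p <- delineate_patches(grid, connectivity)
  maybe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  enn <- maybe(enn_mn(p))
  if (is.null(connect_threshold)) connect_threshold <- enn
  data.frame(
    map_id = map_id,
    mean_patch_size = mean_patch_size(p),
    patch_size_cv = maybe(patch_size_cv(p)),
    landscape_shape_index = landscape_shape_index(p),
    contiguity_am = contiguity_am(p),
    contagion = contagion(grid),
    enn_mn = enn,
    connectance = if (is.na(enn)) NA_real_ else
      maybe(connectance(p, connect_threshold)),
    shdi = shdi(grid),
    shei = shei(grid)
  )
}
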