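#' Land-use classes used throughout the package
#'
#' The eight first-level land-use categories of the study system, in their
#' fixed coding order. Code 1 = cultivated land, 2 = garden land,
#' 3 = forest land, 4 = grassland, 5 = construction land, 6 = abandoned
#' mine land (AML), 7 = water, 8 = unutilized land.
#'
#' @return Named integer vector of class codes.
#' @export
landuse_classes <- function() {
  c(cultivated = 1L, garden = 2L, forest = 3L, grassland = 4L,
    construction = 5L, aml = 6L, water = 7L, unutilized = 8L)
}

#' Base-year (2007) class areas in hm2
#'
#' Areas of the eight land-use classes in the 466 km2 study landscape at the
#' simulation base year; one raster cell at the default 100 m resolution is
#' one hectare, so these are also cell counts.
#'
#' @return Named numeric vector (hm2), summing to 46634.
#' @export
base_year_areas <- function() {
  stats::setNames(c(831, 1678, 30165, 3686, 2733, 3573, 905, 3063),
                  names(landuse_classes()))
}

#' Categorical land-use raster
#'
#' A thin matrix-backed raster: integer class codes with \code{NA} for
#' nodata, a square cell size in meters and a lower-left origin. Rows run
#' north to south (row 1 is the northern edge), columns west to east.
#'
#' @param values Integer matrix of class codes; \code{NA} marks nodata.
#' @param cell_size Cell edge length in meters (default 100, i.e. 1 hm2
#'   cells).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param nodata Sentinel value used when the grid is written to disk.
#' @return An object of class \code{land_grid}.
#' @export
land_grid <- function(values, cell_size = 100, xll = 0, yll = 0,
                      nodata = -9999) {
  stopifnot(is.matrix(values), cell_size > 0)
  storage.mode(values) <- "double"
  structure(list(values = values, cell_size = cell_size,
                 xll = xll, yll = yll, nodata = nodata),
            class = "land_grid")
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("<land_grid> %d x %d cells, %g m resolution, %d nodata\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              sum(is.na(x$values))))
  tab <- table(x$values)
  if (length(tab) <= 12) print(tab)
  invisible(x)
}

#' @export
dim.land_grid <- function(x) dim(x$values)

#' Cell area in hm2
#' @param grid A \code{land_grid}.
#' @return Scalar hm2 per cell.
#' @export
cell_area_hm2 <- function(grid) grid$cell_size^2 / 1e4

#' Number of valid (non-nodata) cells
#' @param grid A \code{land_grid}.
#' @export
n_valid_cells <- function(grid) sum(!is.na(grid$values))

#' Per-class areas of a land-use raster
#'
#' @param grid A \code{land_grid} of class codes.
#' @param classes Integer codes to tabulate (default the eight standard
#'   classes).
#' @return Named numeric vector of areas in hm2.
#' @export
class_areas <- function(grid, classes = landuse_classes()) {
  v <- grid$values[!is.na(grid$values)]
  counts <- vapply(classes, function(k) sum(v == k), numeric(1))
  counts * cell_area_hm2(grid)
}

#' Read an ESRI ASCII grid
#'
#' Parses the canonical six-line header (\code{ncols}, \code{nrows},
#' \code{xllcorner}, \code{yllcorner}, \code{cellsize},
#' \code{NODATA_value}) followed by \code{nrows} rows of whitespace-separated
#' values, northernmost row first.
#'
#' @param path File path.
#' @return A \code{land_grid} (nodata cells as \code{NA}).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: too few lines")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("missing header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) stop("expected ", hdr$nrows, " data rows")
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  lens <- lengths(rows)
  if (any(lens != hdr$ncols)) stop("ragged row: expected ", hdr$ncols,
                                   " values, got ", lens[lens != hdr$ncols][1])
  m <- do.call(rbind, rows)
  m[m == hdr$nodata_value] <- NA
  land_grid(m, cell_size = hdr$cellsize, xll = hdr$xllcorner,
            yll = hdr$yllcorner, nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' @param grid A \code{land_grid} (or a bare matrix, written with default
#'   georeferencing).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  if (is.matrix(grid)) grid <- land_grid(grid)
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 15,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Stack of co-registered driving-factor rasters
#'
#' @param layers Named list of numeric matrices, all with identical
#'   dimensions; names default to X1..Xn.
#' @param cell_size Cell edge length in meters.
#' @return Object of class \code{factor_stack}.
#' @export
factor_stack <- function(layers, cell_size = 100) {
  stopifnot(is.list(layers), length(layers) >= 1)
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1) stop("factor layers have mismatched dims")
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- paste0("X", seq_along(layers))
  }
  structure(list(layers = layers, cell_size = cell_size),
            class = "factor_stack")
}

#' @export
print.factor_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<factor_stack> %d layers (%s), %d x %d cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              d[1], d[2]))
  invisible(x)
}

#' Flatten a factor stack to a cell-by-factor matrix
#'
#' Cells are taken column-major (R matrix order); use the same ordering as
#' \code{as.vector(grid$values)} when pairing with a land-use raster.
#'
#' @param stack A \code{factor_stack}.
#' @return Numeric matrix, one row per cell, one column per factor.
#' @export
factor_matrix <- function(stack) {
  do.call(cbind, lapply(stack$layers, as.vector))
}

# Round half away from zero at given decimals; base round() ties to even,
# which does not reproduce printed-table rounding (e.g. 7516.275 -> 7516.28).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Apportion `total` integer units to fractional weights by largest remainder.
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (sum(weights) == 0) {
    out <- rep(0L, length(weights))
    return(out)
  }
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
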