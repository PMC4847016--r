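#' Target reclamation uses
#' @return Character vector of the four uses AML may be reclaimed to.
#' @export
target_uses <- function() c("cultivated", "garden", "forest", "construction")

#' Limiting factors of the suitability assessment
#' @return Character vector of the seven factor identifiers.
#' @export
suitability_factors <- function() {
  c("slope", "surface", "som", "thickness", "irrigation", "road_dist",
    "damage")
}

# One criterion row per (factor, interval-or-category, use). `grade` may be
# a single grade ("1".."3", "N") or an ambiguous printed range ("1|2",
# "2|3", "3|N") resolved at grading time.
criterion_rows <- function(factor, kind, level, low, high, grades) {
  data.frame(factor = factor, kind = kind, level = level,
             low = low, high = high, use = target_uses(),
             grade = grades, stringsAsFactors = FALSE)
}

#' Default criteria table for mined-land suitability
#'
#' Grading criteria of the seven limiting factors (slope, surface material
#' composition, soil organic matter, soil layer thickness, irrigation and
#' drainage condition, transport accessibility, land damage conditions)
#' against the four target uses. Grades are 1 (best) to 3 (worst suitable)
#' and N (unsuitable); ambiguous printed grades are kept as ranges such as
#' \code{"3|N"} and resolved by the rule passed to \code{\link{grade_factor}}.
#' Soil layers of 10--20 cm are graded with the 20--40 cm band (the
#' published criteria leave that interval unstated and grade < 10 cm as N).
#'
#' Numeric intervals are left-closed, right-open.
#'
#' @return Data frame with columns factor, kind, level, low, high, use,
#'   grade.
#' @export
default_criteria <- function() {
  rows <- list(
    criterion_rows("slope", "numeric", "", 0, 5, c("1", "1", "1", "1")),
    criterion_rows("slope", "numeric", "", 5, 10, c("2", "2", "2", "2")),
    criterion_rows("slope", "numeric", "", 10, 15, c("3", "2", "2", "3")),
    criterion_rows("slope", "numeric", "", 15, Inf, c("N", "3", "3", "N")),

    criterion_rows("surface", "category", "loam_sandy_loam", NA, NA,
                   c("1", "1", "1", "1")),
    criterion_rows("surface", "category", "rock_soil_mixture", NA, NA,
                   c("N", "2|3", "2|3", "2")),
    criterion_rows("surface", "category", "sand_gravel", NA, NA,
                   c("N", "3", "3", "3")),

    criterion_rows("som", "numeric", "", 1, Inf, c("1|2", "1", "1", "1")),
    criterion_rows("som", "numeric", "", 0.5, 1, c("3", "2|3", "2|3", "2")),
    criterion_rows("som", "numeric", "", 0, 0.5, c("N", "3", "3", "3")),

    criterion_rows("thickness", "numeric", "", 80, Inf,
                   c("1", "1", "1", "1")),
    criterion_rows("thickness", "numeric", "", 60, 80,
                   c("1|2", "2", "2", "2")),
    criterion_rows("thickness", "numeric", "", 40, 60,
                   c("2|3", "2|3", "2|3", "3")),
    criterion_rows("thickness", "numeric", "", 10, 40,
                   c("3|N", "3|N", "3|N", "3|N")),
    criterion_rows("thickness", "numeric", "", 0, 10, c("N", "N", "N", "N")),

    criterion_rows("irrigation", "category", "full", NA, NA,
                   c("1", "1", "1", "1")),
    criterion_rows("irrigation", "category", "basic", NA, NA,
                   c("2", "2", "2", "2")),
    criterion_rows("irrigation", "category", "none", NA, NA,
                   c("N", "3|N", "3|N", "N")),

    criterion_rows("road_dist", "numeric", "", 0, 2000,
                   c("1", "1", "1", "1")),
    criterion_rows("road_dist", "numeric", "", 2000, 4000,
                   c("2", "2", "2", "2")),
    criterion_rows("road_dist", "numeric", "", 4000, 6000,
                   c("3", "3", "3", "3")),
    criterion_rows("road_dist", "numeric", "", 6000, Inf,
                   c("N", "3|N", "3|N", "N")),

    criterion_rows("damage", "category", "light", NA, NA,
                   c("2", "2", "2", "1")),
    criterion_rows("damage", "category", "moderate", NA, NA,
                   c("3", "3", "3", "2")),
    criterion_rows("damage", "category", "severe", NA, NA,
                   c("N", "3|N", "3|N", "3"))
  )
  do.call(rbind, rows)
}

#' Read / write a criteria table as CSV
#'
#' @param path CSV path with the columns of \code{\link{default_criteria}}.
#' @return Criteria data frame.
#' @export
read_criteria <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("factor", "kind", "level", "low", "high", "use", "grade")
  if (!all(need %in% names(d))) {
    stop("criteria CSV must have columns: ", paste(need, collapse = ", "))
  }
  d$level[is.na(d$level)] <- ""
  d
}

#' @rdname read_criteria
#' @param criteria Criteria data frame to write.
#' @export
write_criteria <- function(criteria, path) {
  utils::write.csv(criteria, path, row.names = FALSE)
  invisible(path)
}

# Ordinal grade ranking: 1 best ... 3 worst-suitable, N unsuitable.
grade_rank <- function(grade) {
  match(grade, c("1", "2", "3", "N"))
}

resolve_grade <- function(grade, rule = c("worst", "best")) {
  rule <- match.arg(rule)
  opts <- strsplit(grade, "|", fixed = TRUE)[[1]]
  r <- grade_rank(opts)
  if (anyNA(r)) stop("unknown grade: ", grade)
  opts[if (rule == "worst") which.max(r) else which.min(r)]
}

#' Grade one factor measurement for one target use
#'
#' Looks up the criteria interval (numeric factors, left-closed intervals)
#' or category containing \code{value} and returns its grade. Printed grade
#' ranges such as \code{"3|N"} are resolved by \code{rule}; the default
#' takes the worst printed option, a conservative reading when the
#' secondary discriminant behind the range is unknown.
#'
#' @param value Measurement: numeric for slope (degrees), soil organic
#'   matter (percent), soil layer thickness (cm) and distance to the
#'   nearest road (m); a category label for surface material, irrigation
#'   and damage level.
#' @param factor One of \code{\link{suitability_factors}}.
#' @param use One of \code{\link{target_uses}}.
#' @param criteria Criteria table (default \code{\link{default_criteria}}).
#' @param rule \code{"worst"} or \code{"best"} resolution of ambiguous
#'   grades.
#' @return \code{"1"}, \code{"2"}, \code{"3"} or \code{"N"}.
#' @export
grade_factor <- function(value, factor, use, criteria = default_criteria(),
                         rule = c("worst", "best")) {
  rule <- match.arg(rule)
  rows <- criteria[criteria$factor == factor & criteria$use == use, ,
                   drop = FALSE]
  if (nrow(rows) == 0) stop("no criteria for factor ", factor, ", use ", use)
  if (rows$kind[1] == "numeric") {
    if (!is.numeric(value)) stop(factor, " expects a numeric value")
    hit <- which(value >= rows$low & value < rows$high)
  } else {
    hit <- which(rows$level == as.character(value))
  }
  if (length(hit) == 0) {
    stop("value ", value, " outside all criteria intervals for ", factor)
  }
  resolve_grade(rows$grade[hit[1]], rule)
}

#' Assess one AML patch against all target uses
#'
#' Applies the limit-condition ("cask principle") rule: the unit score is
#' that of its most limiting factor. Among the ordinal grades the worst
#' (largest class number) wins and a single N makes the unit unsuitable
#' for that use.
#'
#' @param attrs Named list or one-row data frame with entries
#'   \code{slope}, \code{surface}, \code{som}, \code{thickness},
#'   \code{irrigation}, \code{road_dist}, \code{damage}.
#' @param criteria Criteria table.
#' @param rule Ambiguity resolution rule, see \code{\link{grade_factor}}.
#' @return Data frame, one row per target use, with columns use, class
#'   (integer 1..3 or NA), category ("suitable"/"unsuitable") and the seven
#'   per-factor grades.
#' @export
assess_patch <- function(attrs, criteria = default_criteria(),
                         rule = c("worst", "best")) {
  rule <- match.arg(rule)
  attrs <- as.list(attrs)
  missing <- setdiff(suitability_factors(), names(attrs))
  if (length(missing) > 0) {
    stop("missing patch attributes: ", paste(missing, collapse = ", "))
  }
  out <- lapply(target_uses(), function(use) {
    g <- vapply(suitability_factors(), function(f) {
      grade_factor(attrs[[f]], f, use, criteria, rule)
    }, character(1))
    worst <- g[which.max(grade_rank(g))]
    suitable <- worst != "N"
    row <- data.frame(use = use,
                      class = if (suitable) as.integer(worst) else NA_integer_,
                      category = if (suitable) "suitable" else "unsuitable",
                      stringsAsFactors = FALSE)
    cbind(row, as.data.frame(as.list(g), stringsAsFactors = FALSE))
  })
  do.call(rbind, out)
}

#' Assess a table of AML patches
#'
#' @param patches Data frame with a \code{patch_id} column and the seven
#'   attribute columns of \code{\link{assess_patch}}.
#' @param criteria,rule See \code{\link{assess_patch}}.
#' @return Long data frame: patch_id x use with class and category.
#' @export
assess_patches <- function(patches, criteria = default_criteria(),
                           rule = c("worst", "best")) {
  rule <- match.arg(rule)
  stopifnot("patch_id" %in% names(patches))
  res <- lapply(seq_len(nrow(patches)), function(i) {
    r <- assess_patch(patches[i, , drop = FALSE], criteria, rule)
    r$patch_id <- patches$patch_id[i]
    r[, c("patch_id", "use", "class", "category")]
  })
  do.call(rbind, res)
}

#' Per-use reclaimable-area upper bounds
#'
#' Sums the areas of the patches suitable for each target use; the sums
#' feed the demand LP as caps on the reclamation variables.
#'
#' @param results Assessment results from \code{\link{assess_patches}}.
#' @param patch_areas Named numeric vector of patch areas (hm2), names
#'   matching \code{patch_id}.
#' @return Named numeric vector of bounds (hm2) over
#'   \code{\link{target_uses}}.
#' @export
aggregate_bounds <- function(results, patch_areas) {
  stopifnot(all(results$patch_id %in% names(patch_areas)))
  vapply(target_uses(), function(use) {
    r <- results[results$use == use & results$category == "suitable", ]
    sum(patch_areas[as.character(r$patch_id)])
  }, numeric(1))
}
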