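#' Private lands and the undeveloped-land rule
#'
#' Private land is what remains of the study area after removing all public
#' and protected land. Its conservation potential is then assessed on a
#' landcover grid: cells in any "developed" class or in "cultivated crops"
#' are excluded, and the rest count as undeveloped private land. Cell
#' membership (both for the private mask and for species-range overlays) is
#' by cell centre, which is unbiased for area in expectation and makes
#' results bit-reproducible.
#'
#' @name private_lands
NULL

#' Undeveloped-land classification rule
#'
#' @param excluded_codes landcover class codes excluded from "undeveloped";
#'   the default is the NLCD-style set: developed open space / low /
#'   medium / high intensity (21-24) and cultivated crops (82).
#' @return an \code{undeveloped_rule}.
#' @export
undeveloped_rule <- function(excluded_codes = c(21L, 22L, 23L, 24L, 82L)) {
  excluded_codes <- as.integer(excluded_codes)
  if (length(excluded_codes) == 0L) stop("excluded_codes must be non-empty")
  structure(list(excluded_codes = excluded_codes),
            class = "undeveloped_rule")
}

#' Derive the private-lands mask
#'
#' @param study_boundary a \code{cgeom}.
#' @param public_and_protected list of \code{cgeom} (all public land,
#'   protected areas and easements); empty list returns the boundary.
#' @return a \code{cgeom}: the boundary minus the union of the inputs.
#' @export
private_mask <- function(study_boundary, public_and_protected) {
  if (length(public_and_protected) == 0L) return(study_boundary)
  cg_difference(study_boundary, cg_union(public_and_protected))
}

#' Undeveloped private-land cells
#'
#' Retains the grid cells whose centre lies inside the private mask and
#' whose landcover code is neither excluded by the rule nor nodata.
#'
#' @param mask a \code{cgeom} (private-lands mask).
#' @param grid a \code{landcover_grid} covering the mask extent.
#' @param rule an \code{undeveloped_rule}.
#' @return a \code{cell_set}: retained cell centres with their common cell
#'   area.
#' @export
undeveloped_private_cells <- function(mask, grid, rule = undeveloped_rule()) {
  codes <- as.integer(names(grid$legend))
  if (!all(rule$excluded_codes %in% codes))
    stop("excluded_codes outside the grid legend: ",
         paste(setdiff(rule$excluded_codes, codes), collapse = ", "))
  bb <- cg_bbox(mask)
  gx0 <- grid$origin[1L]
  gy1 <- grid$origin[2L]
  gx1 <- gx0 + ncol(grid$values) * grid$cell_size
  gy0 <- gy1 - nrow(grid$values) * grid$cell_size
  tol <- grid$cell_size * 1e-6
  if (bb["xmin"] < gx0 - tol || bb["xmax"] > gx1 + tol ||
      bb["ymin"] < gy0 - tol || bb["ymax"] > gy1 + tol) {
    ma <- cg_area(mask)
    cov <- cg_intersection_area(mask, cg_rect(gx0, gy0, gx1, gy1))
    stop(sprintf("grid does not cover the mask: %.2f%% uncovered",
                 100 * (ma - cov) / ma))
  }
  centers <- grid_cell_centers(grid)
  code <- as.vector(grid$values)
  ok <- !(code %in% rule$excluded_codes) & code != grid$nodata
  ok[ok] <- cg_contains(mask, centers[ok, , drop = FALSE])
  structure(list(centers = centers[ok, , drop = FALSE],
                 cell_size = grid$cell_size,
                 cell_area_km2 = grid$cell_size^2 / 1e6),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set: %d cells of %g m, total %.4f km2>\n",
              nrow(x$centers), x$cell_size,
              nrow(x$centers) * x$cell_area_km2))
  invisible(x)
}

#' Total area of a cell set in km2
#' @param cells a \code{cell_set}.
#' @export
cell_set_area <- function(cells) nrow(cells$centers) * cells$cell_area_km2

#' Percent of a species range on undeveloped private land
#'
#' Counts retained cells whose centre falls inside the range geometry.
#'
#' @param range one row of a species-range data.frame (or a list with
#'   \code{geometry} and \code{total_range_km2}).
#' @param cells a \code{cell_set} from
#'   \code{\link{undeveloped_private_cells}}.
#' @return percent of \code{total_range_km2}.
#' @export
range_pct_on_undeveloped_private <- function(range, cells) {
  g <- if (is.data.frame(range)) range$geometry[[1L]] else range$geometry
  total <- if (is.data.frame(range)) range$total_range_km2[1L]
           else range$total_range_km2
  if (nrow(cells$centers) == 0L) return(0)
  bb <- cg_bbox(g)
  pre <- cells$centers[, 1L] >= bb["xmin"] & cells$centers[, 1L] <= bb["xmax"] &
         cells$centers[, 2L] >= bb["ymin"] & cells$centers[, 2L] <= bb["ymax"]
  if (!any(pre)) return(0)
  n_in <- sum(cg_contains(g, cells$centers[pre, , drop = FALSE]))
  100 * n_in * cells$cell_area_km2 / total
}
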