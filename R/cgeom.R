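#' Convex-decomposition multipolygons
#'
#' All geometry in this package is carried as a `cgeom`: a list of convex
#' rings (n x 2 matrices, counter-clockwise) whose interiors are pairwise
#' disjoint and whose union is the region. Simple polygons (with optional
#' holes) enter the representation through ear-clipping triangulation;
#' boolean operations (intersection, difference, union) are closed over it,
#' so overlay areas are exact sums of shoelace areas. Coordinates are metres
#' in the study CRS; areas are reported in km2.
#'
#' @param rings a list of closed or open rings (n x 2 matrices). The first
#'   ring is the outer boundary; subsequent rings are holes (GeoJSON
#'   polygon semantics).
#' @return a `cgeom` object.
#' @export
cg_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  outer <- cpp_triangulate(rings[[1]])
  g <- structure(outer, class = "cgeom")
  if (length(rings) > 1L) {
    for (h in rings[-1L]) {
      hole <- structure(cpp_triangulate(h), class = "cgeom")
      g <- cg_difference(g, hole)
    }
  }
  g
}

#' @rdname cg_polygon
#' @param parts a list of `cgeom` objects or ring lists to combine into one
#'   (possibly multi-part) geometry.
#' @export
cg_multipolygon <- function(parts) {
  pieces <- list()
  for (p in parts) {
    if (!inherits(p, "cgeom")) p <- cg_polygon(p)
    pieces <- c(pieces, unclass(p))
  }
  structure(pieces, class = "cgeom")
}

#' Axis-aligned rectangle geometry
#' @param xmin,ymin,xmax,ymax rectangle corners (metres).
#' @return a `cgeom`.
#' @export
cg_rect <- function(xmin, ymin, xmax, ymax) {
  structure(list(rbind(c(xmin, ymin), c(xmax, ymin),
                       c(xmax, ymax), c(xmin, ymax))),
            class = "cgeom")
}

#' @export
print.cgeom <- function(x, ...) {
  cat(sprintf("<cgeom: %d convex piece%s, %.6g km2>\n",
              length(x), if (length(x) == 1L) "" else "s", cg_area(x)))
  invisible(x)
}

#' Area of a geometry in km2
#' @param g a `cgeom`.
#' @return area in km2.
#' @export
cg_area <- function(g) cpp_cg_area(g) / 1e6

#' Geometry overlay operations
#'
#' Intersection, difference and union of convex-decomposition geometries.
#' Results are again `cgeom` objects; `cg_intersection_area()` returns only
#' the overlap area (km2), short-circuiting once `stop_at_km2` is exceeded.
#'
#' @param a,b `cgeom` objects.
#' @return a `cgeom` (or km2 for `cg_intersection_area`).
#' @export
cg_intersection <- function(a, b)
  structure(cpp_cg_intersection(a, b), class = "cgeom")

#' @rdname cg_intersection
#' @param stop_at_km2 optional early-exit threshold (km2).
#' @export
cg_intersection_area <- function(a, b, stop_at_km2 = -1) {
  stop_at <- if (stop_at_km2 > 0) stop_at_km2 * 1e6 else -1
  cpp_cg_intersection_area(a, b, stop_at) / 1e6
}

#' @rdname cg_intersection
#' @export
cg_difference <- function(a, b)
  structure(cpp_cg_difference(a, b), class = "cgeom")

#' @rdname cg_intersection
#' @param gs a list of `cgeom` objects (for `cg_union`).
#' @export
cg_union <- function(gs) {
  if (inherits(gs, "cgeom")) gs <- list(gs)
  structure(cpp_cg_union_many(gs), class = "cgeom")
}

#' Point-in-geometry test
#' @param g a `cgeom`.
#' @param pts n x 2 matrix of points (metres).
#' @return logical vector; boundary points count as inside.
#' @export
cg_contains <- function(g, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  cpp_points_in_cg(pts, g)
}

#' Bounding box of a geometry
#' @param g a `cgeom`.
#' @return named numeric vector (xmin, ymin, xmax, ymax), metres.
#' @export
cg_bbox <- function(g) {
  xs <- unlist(lapply(g, function(m) m[, 1L]))
  ys <- unlist(lapply(g, function(m) m[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Area-weighted centroid
#' @param g a `cgeom`.
#' @return numeric length-2 (x, y), metres.
#' @export
cg_centroid <- function(g) cpp_cg_centroid(g)

#' Rigid-motion transform
#'
#' Rotates `g` by `theta` radians about `about` (default: its centroid) and
#' then translates so that point lands on `to`. Rigid motions conserve area
#' to floating point.
#'
#' @param g a `cgeom`.
#' @param theta rotation angle, radians.
#' @param to length-2 target point for the rotation centre.
#' @param about length-2 rotation centre; defaults to the centroid.
#' @return the transformed `cgeom`.
#' @export
cg_transform <- function(g, theta = 0, to = NULL, about = NULL) {
  if (is.null(about)) about <- cg_centroid(g)
  if (is.null(to)) to <- about
  structure(cpp_cg_transform(g, theta, about[1L], about[2L], to[1L], to[2L]),
            class = "cgeom")
}

#' @rdname cg_area
#' @export
cg_is_empty <- function(g) length(g) == 0L

# internal: Monte-Carlo area via point sampling (test oracle convenience)
cg_mc_fraction <- function(g, pts) mean(cg_contains(g, pts))

# internal: concatenate geometries KNOWN to have disjoint interiors
# (avoids the disjointification pass of cg_union)
cg_concat <- function(gs) {
  structure(unlist(lapply(gs, unclass), recursive = FALSE), class = "cgeom")
}
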