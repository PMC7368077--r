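#' Study coordinate reference systems
#'
#' Every layer entering the pipeline is expressed in a single planar
#' equal-area CRS with metre units, so that planimetric areas (reported in
#' km2 after division by 1e6) are the quantity analysed. Two identifiers are
#' built in: \code{"local-cartesian-meters"} for synthetic worlds (no
#' geodesy) and \code{"albers-conus"}, a spherical Albers equal-area conic
#' configured for the conterminous USA, used to project geographic
#' (longitude/latitude) input.
#'
#' @param identifier text code of the projection.
#' @param linear_unit unit of the plane; only \code{"m"} is supported.
#' @return a \code{study_crs} object.
#' @export
study_crs <- function(identifier = "local-cartesian-meters",
                      linear_unit = "m") {
  stopifnot(is.character(identifier), length(identifier) == 1L)
  if (!identical(linear_unit, "m"))
    stop("only metre-based planar CRS are supported")
  structure(list(identifier = identifier, linear_unit = linear_unit),
            class = "study_crs")
}

#' @export
print.study_crs <- function(x, ...) {
  cat(sprintf("<study_crs: %s [%s]>\n", x$identifier, x$linear_unit))
  invisible(x)
}

same_crs <- function(a, b) identical(a$identifier, b$identifier)

#' Spherical Albers equal-area conic projection
#'
#' Projects longitude/latitude (degrees) to planar metres. The projection is
#' exactly equal-area on a sphere of radius \code{radius}; defaults follow
#' the usual conterminous-USA parameterization.
#'
#' @param lonlat n x 2 matrix of (longitude, latitude) in degrees.
#' @param lat0,lon0 latitude/longitude of origin (degrees).
#' @param lat1,lat2 standard parallels (degrees).
#' @param radius sphere radius in metres.
#' @return n x 2 matrix of (x, y) in metres.
#' @export
albers_project <- function(lonlat, lat0 = 23, lon0 = -96,
                           lat1 = 29.5, lat2 = 45.5, radius = 6378137) {
  if (is.null(dim(lonlat))) lonlat <- matrix(lonlat, ncol = 2L)
  d2r <- pi / 180
  phi1 <- lat1 * d2r; phi2 <- lat2 * d2r
  phi0 <- lat0 * d2r; lam0 <- lon0 * d2r
  n <- (sin(phi1) + sin(phi2)) / 2
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho <- function(phi) radius * sqrt(C - 2 * n * sin(phi)) / n
  phi <- lonlat[, 2L] * d2r
  lam <- lonlat[, 1L] * d2r
  th <- n * (lam - lam0)
  r <- rho(phi)
  cbind(x = r * sin(th), y = rho(phi0) - r * cos(th))
}

# ---------------------------------------------------------------------------
# vector layers

#' Construct a vector layer
#'
#' A \code{vlayer} bundles a plain attribute data frame with a parallel list
#' of \code{cgeom} geometries and a \code{study_crs}.
#'
#' @param attributes data.frame of feature attributes (one row per feature).
#' @param geometry list of \code{cgeom} objects, same length as rows.
#' @param crs a \code{study_crs}.
#' @return a \code{vlayer}.
#' @export
vlayer <- function(attributes, geometry, crs = study_crs()) {
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  stopifnot(nrow(attributes) == length(geometry))
  structure(list(attributes = attributes, geometry = geometry, crs = crs),
            class = "vlayer")
}

#' @export
print.vlayer <- function(x, ...) {
  cat(sprintf("<vlayer: %d features, attrs [%s], crs %s>\n",
              nrow(x$attributes),
              paste(names(x$attributes), collapse = ", "),
              x$crs$identifier))
  invisible(x)
}

#' @export
length.vlayer <- function(x) nrow(x$attributes)

# ring self-intersection repair: node crossing points, extract simple loops
segment_intersections <- function(ring) {
  n <- nrow(ring)
  hits <- vector("list", n)
  for (i in seq_len(n)) hits[[i]] <- numeric(0)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      a <- ring[i, ]; b <- ring[i %% n + 1L, ]
      c <- ring[j, ]; d <- ring[j %% n + 1L, ]
      r <- b - a; s <- d - c
      den <- r[1L] * s[2L] - r[2L] * s[1L]
      if (abs(den) < 1e-14) next
      t <- ((c[1L] - a[1L]) * s[2L] - (c[2L] - a[2L]) * s[1L]) / den
      u <- ((c[1L] - a[1L]) * r[2L] - (c[2L] - a[2L]) * r[1L]) / den
      if (t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9) {
        hits[[i]] <- c(hits[[i]], t)
        hits[[j]] <- c(hits[[j]], u)
      }
    }
  }
  hits
}

repair_ring <- function(ring) {
  n <- nrow(ring)
  hits <- segment_intersections(ring)
  if (all(lengths(hits) == 0L)) return(NULL)  # already simple
  pts <- list()
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[i %% n + 1L, ]
    pts[[length(pts) + 1L]] <- a
    for (t in sort(hits[[i]]))
      pts[[length(pts) + 1L]] <- a + t * (b - a)
  }
  seqm <- do.call(rbind, pts)
  key <- sprintf("%.4f|%.4f", seqm[, 1L], seqm[, 2L])
  loops <- list()
  path <- integer(0)
  open <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(seqm))) {
    k <- key[i]
    if (!is.null(open[[k]])) {
      j <- open[[k]]
      loop_idx <- path[j:length(path)]
      if (length(loop_idx) >= 3L)
        loops[[length(loops) + 1L]] <- seqm[loop_idx, , drop = FALSE]
      for (kk in key[path[j:length(path)]]) if (kk != k) rm(list = kk, envir = open)
      path <- path[seq_len(j - 1L)]
    }
    path <- c(path, i)
    open[[k]] <- length(path)
  }
  if (length(path) >= 3L)
    loops[[length(loops) + 1L]] <- seqm[path, , drop = FALSE]
  loops
}

ring_simple_area <- function(ring) {
  n <- nrow(ring)
  j <- c(2:n, 1L)
  abs(sum(ring[, 1L] * ring[j, 2L] - ring[j, 1L] * ring[, 2L])) / 2
}

# Build a cgeom from GeoJSON-style rings with validity repair.
# Returns list(geometry=, repaired=logical).
rings_to_cgeom <- function(rings) {
  repaired <- FALSE
  fixed <- list()
  for (r in rings) {
    if (nrow(r) > 1L && all(abs(r[1L, ] - r[nrow(r), ]) < 1e-12))
      r <- r[-nrow(r), , drop = FALSE]
    loops <- repair_ring(r)
    if (is.null(loops)) {
      fixed[[length(fixed) + 1L]] <- list(r)
    } else {
      repaired <- TRUE
      loops <- Filter(function(l) ring_simple_area(l) > 1e-9, loops)
      fixed[[length(fixed) + 1L]] <- loops
    }
  }
  # first ring (possibly split into loops) is outer, rest are holes
  outer <- cg_union(lapply(fixed[[1L]], cg_polygon))
  g <- outer
  if (length(fixed) > 1L) {
    for (holeset in fixed[-1L]) {
      hole <- cg_union(lapply(holeset, cg_polygon))
      g <- cg_difference(g, hole)
    }
  }
  list(geometry = g, repaired = repaired)
}

geojson_coords_to_rings <- function(coords) {
  lapply(coords, function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    m
  })
}

#' Read a vector layer from GeoJSON
#'
#' Reads Polygon/MultiPolygon features, repairs invalid (self-intersecting)
#' rings by noding and loop extraction, drops empty geometries with a
#' warning, and reprojects geographic coordinates into the study CRS via
#' \code{\link{albers_project}}. A legacy \code{crs} member naming a planar
#' identifier is honoured; otherwise coordinates are taken as WGS84
#' longitude/latitude, per the GeoJSON convention.
#'
#' @param path GeoJSON file path.
#' @param required_attrs character vector of attribute names each feature
#'   must carry; a missing one raises a schema error naming it.
#' @param crs target \code{study_crs}; defaults to the file CRS if planar,
#'   else \code{"albers-conus"}.
#' @return a \code{vlayer}.
#' @export
read_vector <- function(path, required_attrs = character(), crs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::read_json(path)
  if (is.null(js$features)) stop("not a GeoJSON FeatureCollection: ", path)
  file_crs_name <- tryCatch(js$crs$properties$name, error = function(e) NULL)
  geographic <- is.null(file_crs_name) ||
    grepl("4326|WGS ?84", file_crs_name, ignore.case = TRUE)
  if (is.null(crs))
    crs <- if (geographic) study_crs("albers-conus") else study_crs(file_crs_name)

  attrs <- list(); geoms <- list(); n_rep <- 0L; n_drop <- 0L
  for (f in js$features) {
    gtype <- f$geometry$type
    polys <- switch(gtype,
      Polygon = list(f$geometry$coordinates),
      MultiPolygon = f$geometry$coordinates,
      stop("unsupported geometry type: ", gtype))
    parts <- list(); repaired <- FALSE
    for (poly in polys) {
      rings <- geojson_coords_to_rings(poly)
      if (geographic) rings <- lapply(rings, albers_project)
      res <- rings_to_cgeom(rings)
      repaired <- repaired || res$repaired
      if (!cg_is_empty(res$geometry))
        parts[[length(parts) + 1L]] <- res$geometry
    }
    if (repaired) n_rep <- n_rep + 1L
    if (length(parts) == 0L) { n_drop <- n_drop + 1L; next }
    g <- cg_multipolygon(parts)
    props <- if (is.null(f$properties)) list() else f$properties
    for (a in required_attrs)
      if (is.null(props[[a]]))
        stop("schema error: feature missing required attribute '", a, "'")
    attrs[[length(attrs) + 1L]] <- props
    geoms[[length(geoms) + 1L]] <- g
  }
  if (n_rep > 0L) warning(n_rep, " feature(s) required geometry repair")
  if (n_drop > 0L) {
    if (length(geoms) == 0L) stop("all features dropped as unrepairable")
    warning(n_drop, " empty/unrepairable feature(s) dropped")
  }
  keys <- unique(unlist(lapply(attrs, names)))
  df <- as.data.frame(
    setNames(lapply(keys, function(k) {
      sapply(attrs, function(a) if (is.null(a[[k]])) NA else a[[k]])
    }), keys), stringsAsFactors = FALSE, optional = TRUE)
  if (length(keys) == 0L) df <- data.frame(row.names = seq_along(geoms))
  vlayer(df, geoms, crs)
}

#' Write a vector layer to GeoJSON
#'
#' Geometries are written as MultiPolygons of their convex pieces; the layer
#' CRS is recorded in a legacy \code{crs} member so a re-read round-trips
#' without reprojection.
#'
#' @param layer a \code{vlayer}.
#' @param path output path.
#' @export
write_vector <- function(layer, path) {
  feats <- lapply(seq_len(nrow(layer$attributes)), function(i) {
    g <- layer$geometry[[i]]
    coords <- lapply(unclass(g), function(m) {
      ring <- rbind(m, m[1L, , drop = FALSE])
      list(lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1L], ring[k, 2L])))
    })
    props <- as.list(layer$attributes[i, , drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  out <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = layer$crs$identifier)),
              features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# landcover grids (ESRI ASCII Grid)

#' Construct a landcover grid
#'
#' @param values integer matrix of class codes; row 1 is the northernmost
#'   row (top of the map).
#' @param origin (x, y) of the top-left corner, metres.
#' @param cell_size cell edge, metres (square cells).
#' @param legend named list/vector mapping code to label.
#' @param nodata integer nodata code.
#' @param crs a \code{study_crs}.
#' @return a \code{landcover_grid}.
#' @export
landcover_grid <- function(values, origin, cell_size, legend,
                           nodata = -9999L, crs = study_crs()) {
  stopifnot(cell_size > 0, nrow(values) >= 1L, ncol(values) >= 1L)
  values <- matrix(as.integer(values), nrow(values), ncol(values))
  codes <- as.integer(names(legend))
  bad <- !(values %in% c(codes, nodata)) & !is.na(values)
  if (any(bad)) {
    warning(sum(bad), " cell(s) with codes outside the legend set to nodata")
    values[bad] <- nodata
  }
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size), legend = legend,
                 nodata = as.integer(nodata), crs = crs),
            class = "landcover_grid")
}

#' @export
print.landcover_grid <- function(x, ...) {
  cat(sprintf("<landcover_grid: %d x %d cells of %g m, %d classes>\n",
              nrow(x$values), ncol(x$values), x$cell_size, length(x$legend)))
  invisible(x)
}

#' Centres of all grid cells
#' @param grid a \code{landcover_grid}.
#' @return n x 2 matrix of cell-centre coordinates (row-major, top row
#'   first), metres.
#' @export
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  xs <- grid$origin[1L] + (seq_len(nc) - 0.5) * cs
  ys <- grid$origin[2L] - (seq_len(nr) - 0.5) * cs
  cbind(rep(xs, each = nr), rep(ys, times = nc))
}

#' Read a categorical landcover raster (ESRI ASCII Grid)
#'
#' @param path path to a .asc file.
#' @param legend named list/vector mapping integer code to label; cells with
#'   codes outside the legend become nodata with a warning.
#' @param crs the \code{study_crs} of the grid; ASCII grids carry no CRS, so
#'   it must be stated explicitly (no silent assumption).
#' @return a \code{landcover_grid}.
#' @export
read_landcover <- function(path, legend, crs) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(crs) || is.null(crs))
    stop("raster has no embedded CRS; pass `crs` explicitly")
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (l in lines) {
    kv <- strsplit(trimws(l), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header: ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = length(hdr), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid size mismatch in ", path)
  if (any(vals != round(vals)))
    stop("format error: non-integer raster band in ", path)
  m <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols,
              byrow = TRUE)
  origin <- c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize)
  landcover_grid(m, origin, hdr$cellsize, legend,
                 nodata = as.integer(nodata), crs = crs)
}

#' Write a landcover grid as ESRI ASCII Grid
#' @param grid a \code{landcover_grid}.
#' @param path output .asc path.
#' @export
write_landcover <- function(grid, path) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.6f", grid$origin[1L]),
    sprintf("yllcorner %.6f", grid$origin[2L] - nr * grid$cell_size),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %d", grid$nodata)), con)
  apply(grid$values, 1L, function(row)
    writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

# ---------------------------------------------------------------------------
# tables

#' Write records to CSV
#'
#' @param rows a data.frame, or a list of same-schema records.
#' @param path output path.
#' @param schema character vector of column names, required when
#'   \code{rows} is empty.
#' @export
write_table <- function(rows, path, schema = NULL) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (length(rows) == 0L) {
    if (is.null(schema)) stop("empty record list and no schema supplied")
    df <- as.data.frame(setNames(rep(list(character(0)), length(schema)),
                                 schema))
  } else {
    keys <- names(rows[[1L]])
    for (r in rows)
      if (!identical(names(r), keys)) stop("records do not share a schema")
    df <- as.data.frame(setNames(
      lapply(keys, function(k) sapply(rows, `[[`, k)), keys),
      stringsAsFactors = FALSE)
  }
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
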