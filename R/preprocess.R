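#' Protected-area selection and preparation
#'
#' The analysis keeps only highly protected areas (GAP status 1 or 2:
#' managed for biodiversity with no extractive uses), removes units smaller
#' than 5 km2 so that trivially small reserves do not over-represent
#' coverage, and splits units spanning several ecoregions into subordinate
#' parts so that each part belongs to exactly one ecoregion — the stratum
#' within which the null model later randomizes. The area filter applies to
#' whole protected areas before splitting; post-split parts may fall below
#' the cutoff.
#'
#' @name preprocess
NULL

SLIVER_KM2 <- 1e-6  # 1 m2: overlay noise floor below which pieces are dropped

#' Convert a vector layer to a protected-area table
#'
#' @param layer a \code{vlayer} with a \code{gap_status} attribute
#'   (integer 1-4) and optionally \code{pa_id}.
#' @return data.frame with pa_id, gap_status, area_km2 and a geometry
#'   list-column.
#' @export
as_protected_areas <- function(layer) {
  at <- layer$attributes
  if (is.null(at$gap_status)) stop("schema error: missing 'gap_status'")
  gs <- as.integer(at$gap_status)
  if (any(is.na(gs)) || any(gs < 1L | gs > 4L))
    stop("schema error: gap_status outside 1-4")
  ids <- if (!is.null(at$pa_id)) as.character(at$pa_id)
         else sprintf("pa%04d", seq_along(layer$geometry))
  out <- data.frame(pa_id = ids, gap_status = gs,
                    area_km2 = vapply(layer$geometry, cg_area, 0),
                    ecoregion_id = rep(NA_character_, length(ids)),
                    stringsAsFactors = FALSE)
  out$geometry <- layer$geometry
  out
}

#' @rdname as_protected_areas
#' @export
as_ecoregions <- function(layer) {
  at <- layer$attributes
  if (is.null(at$ecoregion_id)) stop("schema error: missing 'ecoregion_id'")
  out <- data.frame(ecoregion_id = as.character(at$ecoregion_id),
                    area_km2 = vapply(layer$geometry, cg_area, 0),
                    stringsAsFactors = FALSE)
  out$geometry <- layer$geometry
  out
}

#' Select highly protected areas by GAP status
#'
#' @param pas a \code{vlayer} or protected-area data.frame (see
#'   \code{\link{as_protected_areas}}).
#' @param allowed_gap integer set of GAP statuses to keep; the default
#'   \code{c(1, 2)} keeps land managed for biodiversity.
#' @return the filtered protected-area data.frame.
#' @export
select_protected <- function(pas, allowed_gap = c(1L, 2L)) {
  if (inherits(pas, "vlayer")) pas <- as_protected_areas(pas)
  pas[pas$gap_status %in% as.integer(allowed_gap), , drop = FALSE]
}

#' Remove protected areas below a minimum size
#'
#' Units with area strictly less than \code{min_km2} are removed; a unit of
#' exactly \code{min_km2} is retained.
#'
#' @param pas protected-area data.frame.
#' @param min_km2 minimum area in km2 (default 5).
#' @return the filtered data.frame.
#' @export
filter_min_area <- function(pas, min_km2 = 5) {
  if (min_km2 < 0) stop("min_km2 must be non-negative")
  pas[pas$area_km2 >= min_km2, , drop = FALSE]
}

#' Split protected areas by ecoregion
#'
#' Each unit is intersected with every ecoregion it touches; the parts carry
#' the parent \code{pa_id} plus the owning \code{ecoregion_id}. Parts below
#' the sliver tolerance (1 m2) are dropped; units entirely outside all
#' ecoregions are dropped with a warning.
#'
#' @param pas protected-area data.frame.
#' @param ecoregions ecoregion data.frame (see \code{\link{as_ecoregions}}).
#' @return data.frame of parts, one row per (pa, ecoregion) piece.
#' @export
split_by_ecoregion <- function(pas, ecoregions) {
  rows <- list(); geoms <- list(); lost <- 0L
  for (i in seq_len(nrow(pas))) {
    g <- pas$geometry[[i]]
    bb <- cg_bbox(g)
    hit <- FALSE
    for (j in seq_len(nrow(ecoregions))) {
      eb <- cg_bbox(ecoregions$geometry[[j]])
      if (bb["xmin"] > eb["xmax"] || eb["xmin"] > bb["xmax"] ||
          bb["ymin"] > eb["ymax"] || eb["ymin"] > bb["ymax"]) next
      piece <- cg_intersection(g, ecoregions$geometry[[j]])
      a <- cg_area(piece)
      if (a < SLIVER_KM2) next
      hit <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        pa_id = pas$pa_id[i], gap_status = pas$gap_status[i],
        area_km2 = a, ecoregion_id = ecoregions$ecoregion_id[j],
        stringsAsFactors = FALSE)
      geoms[[length(geoms) + 1L]] <- piece
    }
    if (!hit) lost <- lost + 1L
  }
  if (lost > 0L)
    warning(lost, " protected area(s) outside all ecoregions dropped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pa_id = character(0), gap_status = integer(0),
               area_km2 = numeric(0), ecoregion_id = character(0),
               stringsAsFactors = FALSE)
  out$geometry <- geoms
  out
}

#' Normalize species ranges
#'
#' Dissolves multi-feature species into one multipolygon per
#' \code{species_id}, clips to the study boundary, and sets
#' \code{total_range_km2} — the denominator of every later coverage
#' percentage — from the clipped geometry. Species with zero clipped area
#' are dropped with a warning.
#'
#' @param ranges a \code{vlayer} with \code{species_id} and
#'   \code{tetrapod_class} attributes.
#' @param study_boundary a \code{cgeom}.
#' @return data.frame with species_id, tetrapod_class, total_range_km2 and
#'   a geometry list-column.
#' @export
normalize_ranges <- function(ranges, study_boundary) {
  at <- ranges$attributes
  if (is.null(at$species_id)) stop("schema error: missing 'species_id'")
  if (is.null(at$tetrapod_class))
    stop("schema error: missing 'tetrapod_class'")
  sp <- as.character(at$species_id)
  cls <- as.character(at$tetrapod_class)
  for (s in unique(sp)) {
    if (length(unique(cls[sp == s])) > 1L)
      stop("schema error: species '", s, "' has conflicting tetrapod_class")
  }
  ids <- unique(sp)
  rows <- list(); geoms <- list(); dropped <- 0L
  for (s in ids) {
    parts <- ranges$geometry[sp == s]
    g <- if (length(parts) == 1L) parts[[1L]] else cg_union(parts)
    g <- cg_intersection(g, study_boundary)
    a <- cg_area(g)
    if (a <= 0) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      species_id = s, tetrapod_class = cls[sp == s][1L],
      total_range_km2 = a, stringsAsFactors = FALSE)
    geoms[[length(geoms) + 1L]] <- g
  }
  if (dropped > 0L)
    warning(dropped, " species range(s) outside the study boundary dropped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(0), tetrapod_class = character(0),
               total_range_km2 = numeric(0), stringsAsFactors = FALSE)
  out$geometry <- geoms
  out
}

#' Full protected-area preparation pipeline
#'
#' \code{select_protected} then \code{filter_min_area} then
#' \code{split_by_ecoregion}, in that order.
#'
#' @param pas a \code{vlayer} of protected areas.
#' @param ecoregions ecoregion data.frame.
#' @param allowed_gap,min_km2 see the individual steps.
#' @return data.frame of ecoregion-bounded protected-area parts.
#' @export
prepare_protected <- function(pas, ecoregions, allowed_gap = c(1L, 2L),
                              min_km2 = 5) {
  split_by_ecoregion(
    filter_min_area(select_protected(pas, allowed_gap), min_km2),
    ecoregions)
}
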