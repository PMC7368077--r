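#' Ecoregion-stratified spatial null model for protected-area placement
#'
#' For each ecoregion, the observed number of unique endangered species
#' whose ranges overlap its highly protected areas is compared with a null
#' distribution obtained by re-placing every protected-area part at a
#' random position and orientation within the same ecoregion (a rigid
#' motion: uniform rotation about the part centroid, centroid translated to
#' a uniform point in the ecoregion), many times over. Placed parts may
#' overlap one another — the null deliberately leaves placement
#' unconstrained — which makes the comparison conservative. An ecoregion is
#' classified "better" or "worse" than random only when observed and null
#' mean differ by at least one species.
#'
#' @name null_model
NULL

#' Placement configuration
#'
#' @param n_iterations number of null draws (default 1000).
#' @param seed master integer seed; per-ecoregion substreams are derived
#'   deterministically from (seed, ecoregion_id) so results do not depend
#'   on evaluation order.
#' @param max_tries rejection-sampling attempts per part per draw before
#'   the fallback (clip the best candidate to the ecoregion) fires.
#' @param containment fraction of a part's area that must land inside its
#'   ecoregion for a placement to be accepted; 1 demands full containment.
#' @param overlap_allowed placed parts may overlap (the null model's
#'   stated assumption); kept as a flag for transparency, only TRUE is
#'   implemented.
#' @return a \code{placement_config} object.
#' @export
placement_config <- function(n_iterations = 1000L, seed = 1L,
                             max_tries = 100L, containment = 1.0,
                             overlap_allowed = TRUE) {
  stopifnot(n_iterations >= 1L, containment > 0, containment <= 1,
            max_tries >= 1L, isTRUE(overlap_allowed))
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 max_tries = as.integer(max_tries),
                 containment = containment,
                 overlap_allowed = overlap_allowed),
            class = "placement_config")
}

# deterministic 31-bit substream seed from (master seed, text id); FNV-1a
derive_seed <- function(seed, id) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste0(id, ":", seed))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

#' Count unique species overlapping a set of protected-area parts
#'
#' A species counts once if the area of its range intersected with the
#' union of the parts exceeds \code{epsilon_km2}; edge touches (zero-area
#' intersections) do not count.
#'
#' @param pieces list of \code{cgeom} parts, or a protected-area data.frame.
#' @param ranges species-range data.frame (see
#'   \code{\link{normalize_ranges}}).
#' @param epsilon_km2 minimum overlap area (default 1e-6 km2 = 1 m2).
#' @return integer count.
#' @export
count_species_overlapping <- function(pieces, ranges,
                                      epsilon_km2 = 1e-6) {
  if (is.data.frame(pieces)) pieces <- pieces$geometry
  if (length(pieces) == 0L || nrow(ranges) == 0L) return(0L)
  u <- cg_union(pieces)
  if (cg_is_empty(u)) return(0L)
  eps <- epsilon_km2
  sum(vapply(ranges$geometry, function(g)
    cg_intersection_area(g, u, stop_at_km2 = eps) > eps, NA))
}

#' One random rigid placement of a part within its ecoregion
#'
#' Draws a rotation uniform on [0, 2*pi) about the part centroid and a
#' translation landing the centroid on a uniform point of the ecoregion
#' interior, retrying until the containment requirement is met. After
#' \code{max_tries} failures the best candidate (highest contained
#' fraction) is clipped to the ecoregion and flagged as a fallback.
#' Accepted placements are congruent to the input, so area is conserved to
#' floating point. Draws come from R's RNG: seed beforehand for
#' reproducibility.
#'
#' @param piece a \code{cgeom} (must have positive area).
#' @param ecoregion a \code{cgeom}.
#' @param cfg a \code{placement_config} (only max_tries/containment used).
#' @return list with \code{geometry} (a \code{cgeom}) and \code{fallback}
#'   (logical).
#' @export
random_rigid_placement <- function(piece, ecoregion,
                                   cfg = placement_config()) {
  if (cg_area(piece) <= 0) stop("degenerate (zero-area) piece")
  res <- cpp_place_piece(piece, ecoregion, cfg$max_tries, cfg$containment)
  list(geometry = structure(res$geometry, class = "cgeom"),
       fallback = res$fallback)
}

#' Classify an ecoregion against its null distribution
#'
#' "better" when observed exceeds the null mean by at least \code{delta}
#' species, "worse" when it falls short by at least \code{delta}, otherwise
#' "equal"; the boundary is inclusive.
#'
#' @param observed observed unique-species count.
#' @param null_mean mean of the null counts.
#' @param delta species margin (default 1).
#' @return "better", "worse" or "equal".
#' @export
classify_difference <- function(observed, null_mean, delta = 1) {
  stopifnot(delta > 0)
  d <- observed - null_mean
  ifelse(d >= delta, "better", ifelse(d <= -delta, "worse", "equal"))
}

#' Run the spatial null model
#'
#' @param pieces protected-area parts data.frame (output of
#'   \code{\link{prepare_protected}} / \code{\link{split_by_ecoregion}}),
#'   with an \code{ecoregion_id} per part.
#' @param ranges species-range data.frame.
#' @param ecoregions ecoregion data.frame.
#' @param cfg a \code{placement_config}.
#' @param delta species margin for classification (default 1).
#' @param epsilon_km2 minimum overlap area for a species to count.
#' @return a \code{pa_null_model} object: a results data.frame (one row per
#'   ecoregion containing at least one part) plus the full null count
#'   draws. Ecoregions with no parts are omitted.
#' @export
run_null_model <- function(pieces, ranges, ecoregions,
                           cfg = placement_config(), delta = 1,
                           epsilon_km2 = 1e-6) {
  eco_ids <- ecoregions$ecoregion_id
  rows <- list()
  draws <- list()
  for (eid in eco_ids) {
    sel <- pieces$ecoregion_id == eid
    if (!any(sel)) next
    eg <- ecoregions$geometry[[which(eco_ids == eid)]]
    pg <- pieces$geometry[sel]
    # ranges that could ever intersect a placement: ecoregion bbox grown by
    # the largest part diameter (parts may overhang when containment < 1)
    eb <- cg_bbox(eg)
    grow <- max(vapply(pg, function(g) {
      b <- cg_bbox(g)
      sqrt((b["xmax"] - b["xmin"])^2 + (b["ymax"] - b["ymin"])^2)
    }, 0))
    keep <- vapply(ranges$geometry, function(g) {
      b <- cg_bbox(g)
      b["xmin"] <= eb["xmax"] + grow && eb["xmin"] - grow <= b["xmax"] &&
        b["ymin"] <= eb["ymax"] + grow && eb["ymin"] - grow <= b["ymax"]
    }, NA)
    rg <- lapply(ranges$geometry[keep], unclass)
    set.seed(derive_seed(cfg$seed, eid))
    res <- cpp_null_ecoregion(lapply(pg, unclass), rg, eg,
                              cfg$n_iterations, cfg$max_tries,
                              cfg$containment, epsilon_km2 * 1e6)
    nm <- mean(res$null_counts)
    rows[[length(rows) + 1L]] <- data.frame(
      ecoregion_id = eid,
      observed = res$observed,
      null_mean = nm,
      null_sd = sd(res$null_counts),
      difference = res$observed - nm,
      classification = classify_difference(res$observed, nm, delta),
      fallback_placements = res$fallback_placements,
      stringsAsFactors = FALSE)
    draws[[eid]] <- res$null_counts
  }
  if (length(rows) == 0L)
    stop("no ecoregion contains a protected-area part")
  structure(list(results = do.call(rbind, rows), null_counts = draws,
                 config = cfg, delta = delta),
            class = "pa_null_model")
}

#' @export
print.pa_null_model <- function(x, ...) {
  cat(sprintf(
    "Spatial null model: %d ecoregions, %d iterations, seed %d\n",
    nrow(x$results), x$config$n_iterations, x$config$seed))
  print(x$results[, setdiff(names(x$results), "geometry")], row.names = FALSE)
  invisible(x)
}

#' Summarize a null model run
#'
#' Percentages of ecoregions (among those holding at least one
#' protected-area part) classified better / equal / worse than random.
#'
#' @param object a \code{pa_null_model}.
#' @param ... unused.
#' @return a \code{pa_null_summary} list with \code{n_ecoregions},
#'   \code{pct_better}, \code{pct_equal}, \code{pct_worse}.
#' @export
summary.pa_null_model <- function(object, ...) {
  cl <- object$results$classification
  n <- length(cl)
  out <- list(n_ecoregions = n,
              pct_better = 100 * sum(cl == "better") / n,
              pct_equal = 100 * sum(cl == "equal") / n,
              pct_worse = 100 * sum(cl == "worse") / n)
  class(out) <- "pa_null_summary"
  out
}

#' @export
print.pa_null_summary <- function(x, ...) {
  cat(sprintf(
    "%d ecoregions: %.1f%% better, %.1f%% equal, %.1f%% worse than random\n",
    x$n_ecoregions, x$pct_better, x$pct_equal, x$pct_worse))
  invisible(x)
}

#' @export
plot.pa_null_model <- function(x, ...) {
  d <- x$results$difference
  graphics::hist(d, breaks = "FD",
                 main = "Observed minus null-mean species count",
                 xlab = "difference (species)", ...)
  graphics::abline(v = c(-x$delta, x$delta), lty = 2)
  invisible(x)
}

#' Species-richness grid
#'
#' Counts, for each square pixel, the number of species whose range
#' intersects the pixel by more than \code{epsilon_km2}.
#'
#' @param ranges species-range data.frame.
#' @param pixel_area_km2 pixel area; the default 5 km2 gives pixels of side
#'   sqrt(5) km.
#' @param extent bbox (xmin, ymin, xmax, ymax) in metres; defaults to the
#'   joint bbox of the ranges.
#' @param epsilon_km2 minimum overlap.
#' @return a \code{richness_grid}: integer matrix (row 1 = northern edge)
#'   with origin and cell size attached.
#' @export
richness_grid <- function(ranges, pixel_area_km2 = 5, extent = NULL,
                          epsilon_km2 = 1e-6) {
  stopifnot(pixel_area_km2 > 0)
  if (is.null(extent)) {
    bbs <- lapply(ranges$geometry, cg_bbox)
    extent <- c(min(sapply(bbs, `[`, "xmin")), min(sapply(bbs, `[`, "ymin")),
                max(sapply(bbs, `[`, "xmax")), max(sapply(bbs, `[`, "ymax")))
  }
  side <- sqrt(pixel_area_km2) * 1000
  nx <- max(1L, as.integer(ceiling((extent[3L] - extent[1L]) / side)))
  ny <- max(1L, as.integer(ceiling((extent[4L] - extent[2L]) / side)))
  m <- cpp_richness_grid(lapply(ranges$geometry, unclass),
                         extent[1L], extent[2L], side, nx, ny,
                         epsilon_km2 * 1e6)
  structure(list(values = m,
                 origin = c(extent[1L], extent[2L] + ny * side),
                 cell_size = side),
            class = "richness_grid")
}

#' @export
print.richness_grid <- function(x, ...) {
  cat(sprintf("<richness_grid: %d x %d pixels of %.0f m, max %d species>\n",
              nrow(x$values), ncol(x$values), x$cell_size, max(x$values)))
  invisible(x)
}
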