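#' Tiered land-designation coverage analysis
#'
#' Each species' range is apportioned across an ordered cascade of
#' mutually exclusive land-designation tiers: highly protected land (GAP
#' 1-2), conservation easements, USFS/BLM land, other federal land, state
#' land, undeveloped private land, and remaining (developed or cultivated)
#' private land. Cumulative coverage along the cascade shows the earliest
#' stage at which a species reaches the 30% adequate-protection threshold —
#' the rule-of-thumb fraction of a range that must be protected for
#' persistence in the absence of species-specific viability analysis.
#'
#' @name coverage_tiers
NULL

#' Canonical tier order
#'
#' @return character vector of tier ids, highest precedence first.
#' @export
tier_order <- function() {
  c("PROTECTED_GAP12", "EASEMENT", "USFS_BLM", "OTHER_FEDERAL",
    "STATE", "PRIVATE_UNDEVELOPED", "PRIVATE_OTHER")
}

default_agency_map <- function(agencies) {
  up <- toupper(agencies)
  ifelse(up %in% c("USFS", "BLM"), "USFS_BLM",
         ifelse(up == "STATE", "STATE", "OTHER_FEDERAL"))
}

#' Build the tier map
#'
#' Assigns every location of the study area to the first tier, in canonical
#' order, whose source layer covers it (a USFS parcel inside a GAP-2
#' polygon is PROTECTED_GAP12, an easement over state land is STATE, and so
#' on), which keeps the partition mutually exclusive. Private land is the
#' remainder; it is split into undeveloped and other private land on the
#' landcover grid by the cell-centre rule.
#'
#' @param protected protected-area data.frame (post GAP/area filtering).
#' @param easements a \code{vlayer} of conservation easements (may be
#'   empty).
#' @param public a \code{vlayer} of public lands with an \code{agency}
#'   attribute; agencies USFS and BLM map to the USFS_BLM tier, STATE to
#'   STATE, anything else to OTHER_FEDERAL.
#' @param study_boundary a \code{cgeom}.
#' @param landcover a \code{landcover_grid}, or NULL to leave all private
#'   land in PRIVATE_OTHER.
#' @param rule an \code{undeveloped_rule}.
#' @return a \code{tier_map}: vector geometries for the five upper tiers
#'   and the private mask, plus the undeveloped-private \code{cell_set}.
#' @export
build_tier_map <- function(protected, easements, public, study_boundary,
                           landcover = NULL, rule = undeveloped_rule()) {
  boundary_km2 <- cg_area(study_boundary)
  sources <- list()
  sources$PROTECTED_GAP12 <-
    if (nrow(protected)) cg_union(protected$geometry) else NULL
  sources$EASEMENT <-
    if (length(easements) > 0L) cg_union(easements$geometry) else NULL
  if (length(public) > 0L) {
    tier_of <- default_agency_map(public$attributes$agency)
    for (t in c("USFS_BLM", "OTHER_FEDERAL", "STATE")) {
      sel <- tier_of == t
      sources[[t]] <- if (any(sel)) cg_union(public$geometry[sel]) else NULL
    }
  }
  tiers <- list()
  cum <- NULL
  for (t in c("PROTECTED_GAP12", "EASEMENT", "USFS_BLM",
              "OTHER_FEDERAL", "STATE")) {
    src <- sources[[t]]
    if (is.null(src)) {
      tiers[[t]] <- structure(list(), class = "cgeom")
      next
    }
    g <- cg_intersection(src, study_boundary)
    if (cg_area(src) - cg_area(g) > 1e-6 * boundary_km2)
      warning("layer for tier ", t,
              " extends outside the study boundary; clipped")
    if (!is.null(cum)) g <- cg_difference(g, cum)
    tiers[[t]] <- g
    cum <- if (is.null(cum)) g else cg_union(list(cum, g))
  }
  pmask <- if (is.null(cum)) study_boundary
           else cg_difference(study_boundary, cum)
  cells <- if (!is.null(landcover))
    undeveloped_private_cells(pmask, landcover, rule) else NULL
  structure(list(tiers = tiers, private_mask = pmask,
                 undeveloped_cells = cells,
                 boundary = study_boundary,
                 boundary_km2 = boundary_km2),
            class = "tier_map")
}

#' @export
print.tier_map <- function(x, ...) {
  cat("<tier_map> areas (km2):\n")
  a <- tier_areas(x)
  for (t in names(a)) cat(sprintf("  %-20s %12.4f\n", t, a[[t]]))
  invisible(x)
}

#' Tier areas in km2
#' @param tier_map a \code{tier_map}.
#' @return named numeric vector over the canonical tier order.
#' @export
tier_areas <- function(tier_map) {
  a <- vapply(tier_map$tiers, cg_area, 0)
  priv <- cg_area(tier_map$private_mask)
  undev <- if (!is.null(tier_map$undeveloped_cells))
    cell_set_area(tier_map$undeveloped_cells) else 0
  undev <- min(undev, priv)
  c(a, PRIVATE_UNDEVELOPED = undev, PRIVATE_OTHER = priv - undev)
}

#' Coverage record for one species
#'
#' @param range one-row species-range data.frame.
#' @param tier_map a \code{tier_map}.
#' @param threshold adequacy threshold in percent (default 30).
#' @param inclusive whether exactly \code{threshold} percent counts as
#'   adequate (default TRUE).
#' @return one-row data.frame with per-tier percents (\code{pct_<tier>}),
#'   cumulative percents (\code{cum_<tier>}) and
#'   \code{earliest_adequate_tier}.
#' @export
coverage_for_species <- function(range, tier_map, threshold = 30,
                                 inclusive = TRUE) {
  g <- range$geometry[[1L]]
  total <- range$total_range_km2[1L]
  if (total <= 0) stop("zero-area range: ", range$species_id[1L])
  pct <- vapply(tier_map$tiers, function(t)
    100 * cg_intersection_area(g, t) / total, 0)
  priv_pct <- 100 * cg_intersection_area(g, tier_map$private_mask) / total
  undev_pct <- if (!is.null(tier_map$undeveloped_cells))
    range_pct_on_undeveloped_private(range, tier_map$undeveloped_cells) else 0
  undev_pct <- min(undev_pct, priv_pct)  # raster estimate capped by vector
  pct <- c(pct, PRIVATE_UNDEVELOPED = undev_pct,
           PRIVATE_OTHER = priv_pct - undev_pct)
  pct <- pct[tier_order()]
  cum <- cumsum(pct)
  ok <- if (inclusive) cum >= threshold else cum > threshold
  earliest <- if (any(ok)) tier_order()[which(ok)[1L]] else NA_character_
  out <- data.frame(species_id = range$species_id[1L],
                    tetrapod_class = range$tetrapod_class[1L],
                    stringsAsFactors = FALSE)
  for (t in tier_order()) out[[paste0("pct_", t)]] <- unname(pct[t])
  for (t in tier_order()) out[[paste0("cum_", t)]] <- unname(cum[t])
  out$earliest_adequate_tier <- earliest
  out
}

#' Tiered coverage for a set of species
#'
#' @param ranges species-range data.frame.
#' @param tier_map a \code{tier_map}.
#' @param threshold,inclusive see \code{\link{coverage_for_species}}.
#' @return a \code{tier_coverage} object holding one
#'   \code{\link{coverage_for_species}} record per species.
#' @export
tier_coverage <- function(ranges, tier_map, threshold = 30,
                          inclusive = TRUE) {
  recs <- lapply(seq_len(nrow(ranges)), function(i)
    coverage_for_species(ranges[i, , drop = FALSE], tier_map,
                         threshold, inclusive))
  structure(list(records = do.call(rbind, recs), threshold = threshold,
                 inclusive = inclusive),
            class = "tier_coverage")
}

#' @export
print.tier_coverage <- function(x, ...) {
  cat(sprintf("Tiered coverage: %d species, %g%% threshold\n",
              nrow(x$records), x$threshold))
  n <- vapply(tier_order(), function(t) count_adequate(x, t), 0L)
  for (t in tier_order())
    cat(sprintf("  adequate through %-20s %d\n", t, n[[t]]))
  invisible(x)
}

#' @export
summary.tier_coverage <- function(object, ...) class_summary(object)

#' Count species adequately protected through a tier
#'
#' Number of species whose cumulative coverage at \code{through_tier}
#' reaches the threshold (inclusive by default: exactly the threshold
#' counts).
#'
#' @param coverage a \code{tier_coverage}.
#' @param through_tier a tier id from \code{\link{tier_order}}.
#' @return integer count.
#' @export
count_adequate <- function(coverage, through_tier) {
  if (!through_tier %in% tier_order())
    stop("unknown tier: ", through_tier)
  cum <- coverage$records[[paste0("cum_", through_tier)]]
  th <- coverage$threshold
  sum(if (coverage$inclusive) cum >= th else cum > th)
}

#' Mean per-tier coverage by tetrapod class
#'
#' @param coverage a \code{tier_coverage}.
#' @return data.frame of (tetrapod_class, tier_id, mean_pct).
#' @export
class_summary <- function(coverage) {
  rec <- coverage$records
  out <- list()
  for (cls in sort(unique(rec$tetrapod_class))) {
    sel <- rec$tetrapod_class == cls
    for (t in tier_order()) {
      out[[length(out) + 1L]] <- data.frame(
        tetrapod_class = cls, tier_id = t,
        mean_pct = mean(rec[[paste0("pct_", t)]][sel]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
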