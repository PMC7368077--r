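#' Synthetic-world generator
#'
#' Generates complete, fully seeded synthetic study areas — an ecoregion
#' partition, blob-shaped species ranges, protected areas placed with a
#' controllable bias toward or away from species-rich locations, a tiered
#' land-designation tessellation, and a categorical landcover grid — with
#' exact ground-truth bookkeeping of every species' per-tier coverage. The
#' generator emulates the statistical structure of the real inputs (a
#' PAD-US-like protected-area layer, ECOS-like range maps, NCED/SMA-like
#' tenure layers, an NLCD-like grid) without any external data, so the
#' whole pipeline is testable offline.
#'
#' At \code{bias_beta = 0} protected-area placement goes through the same
#' rigid-placement sampler the null model uses, so the observed layout is
#' by construction one draw from the null distribution — the basis of the
#' calibration property.
#'
#' @name synthetic_data
NULL

#' World configuration
#'
#' Defaults describe the package's standard toy world: a 100 x 100 km
#' extent holding 8 ecoregions, 96 species and 30 protected areas, with
#' 100 m landcover cells — small enough that every pipeline stage runs in
#' seconds. Species richness is deliberately generous: the better/worse
#' classification uses an absolute one-species margin, so sparse worlds
#' cannot express placement bias at all.
#'
#' @param extent_km (width, height) of the rectangular study area, km.
#' @param n_ecoregions number of Voronoi-cell ecoregions.
#' @param n_species number of species ranges.
#' @param range_median_km2,range_log_sd log-normal range-area distribution.
#' @param range_shape blob irregularity in [0, 1]; 0 gives discs.
#' @param range_clustered_frac fraction of species whose range centres
#'   cluster around richness hotspots (endangered-species richness is
#'   strongly spatially clustered in real landscapes); the rest are
#'   uniform.
#' @param n_range_clusters number of hotspot centres, or NULL (default)
#'   for one hotspot per ecoregion (stratified, so every ecoregion holds
#'   local richness structure even in small worlds).
#' @param range_cluster_sd_km Gaussian scatter of clustered range centres
#'   around their hotspot, km.
#' @param n_protected number of protected areas.
#' @param pa_min_per_ecoregion minimum number of protected areas allocated
#'   to each ecoregion (the remainder is allocated proportionally to
#'   area), so every stratum holds an informative protected network.
#' @param pa_median_km2,pa_log_sd log-normal protected-area size
#'   distribution, truncated below at 5 km2 so the generated network
#'   matches the analysed (post-size-filter) network.
#' @param bias_beta placement bias: PA centroids are sampled from a density
#'   proportional to exp(-bias_beta * richness); 0 is the null, positive
#'   repels protected areas from species-rich land, negative attracts.
#' @param tier_proportions named fractions of non-protected land for
#'   EASEMENT, USFS_BLM, OTHER_FEDERAL, STATE and PRIVATE; must sum to 1.
#' @param p_developed,p_crops per-cell probabilities of developed /
#'   cultivated-crops landcover on private land.
#' @param cell_size_m landcover cell edge, metres.
#' @param seed integer seed; (config, seed) fully determines the world.
#' @return a \code{world_config}.
#' @export
world_config <- function(extent_km = c(100, 100),
                         n_ecoregions = 8L,
                         n_species = 96L,
                         range_median_km2 = 80,
                         range_log_sd = 0.8,
                         range_shape = 0.35,
                         range_clustered_frac = 0.9,
                         n_range_clusters = NULL,
                         range_cluster_sd_km = 3.5,
                         n_protected = 30L,
                         pa_min_per_ecoregion = 3L,
                         pa_median_km2 = 12,
                         pa_log_sd = 0.4,
                         bias_beta = 0,
                         tier_proportions = c(EASEMENT = 0.03,
                                              USFS_BLM = 0.15,
                                              OTHER_FEDERAL = 0.10,
                                              STATE = 0.10,
                                              PRIVATE = 0.62),
                         p_developed = 0.10,
                         p_crops = 0.25,
                         cell_size_m = 100,
                         seed = 1L) {
  stopifnot(n_ecoregions >= 1L, n_species >= 1L, n_protected >= 1L,
            range_shape >= 0, range_shape <= 1,
            range_clustered_frac >= 0, range_clustered_frac <= 1,
            is.null(n_range_clusters) || n_range_clusters >= 1L,
            p_developed >= 0, p_crops >= 0, p_developed + p_crops <= 1,
            cell_size_m > 0)
  if (abs(sum(tier_proportions) - 1) > 1e-6)
    stop("tier_proportions must sum to 1")
  need <- c("EASEMENT", "USFS_BLM", "OTHER_FEDERAL", "STATE", "PRIVATE")
  if (!all(need %in% names(tier_proportions)))
    stop("tier_proportions must name ", paste(need, collapse = ", "))
  structure(as.list(environment()), class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<world_config: %g x %g km, %d ecoregions, %d species, ",
    "%d protected areas, bias %g, seed %d>\n"),
    x$extent_km[1L], x$extent_km[2L], x$n_ecoregions, x$n_species,
    x$n_protected, x$bias_beta, x$seed))
  invisible(x)
}

TOY_LEGEND <- c("41" = "forest", "21" = "developed", "82" = "cultivated crops")
TOY_EXCLUDED <- c(21L, 82L)

world_extent <- function(cfg)
  cg_rect(0, 0, cfg$extent_km[1L] * 1000, cfg$extent_km[2L] * 1000)

#' Generate the ecoregion partition
#'
#' A Voronoi partition of the extent around random sites: contiguous,
#' non-overlapping convex regions covering the extent exactly.
#'
#' @param cfg a \code{world_config}.
#' @param sites optional n x 2 matrix of sites (metres) overriding the
#'   random draw, e.g. for symmetric layouts.
#' @return ecoregion data.frame (ecoregion_id, area_km2, geometry).
#' @export
generate_ecoregions <- function(cfg, sites = NULL) {
  W <- cfg$extent_km[1L] * 1000; H <- cfg$extent_km[2L] * 1000
  n <- cfg$n_ecoregions
  if (is.null(sites)) {
    if (n == 1L) sites <- matrix(c(W / 2, H / 2), 1L)
    else sites <- cbind(runif(n, 0, W), runif(n, 0, H))
  }
  cells <- cpp_voronoi(sites, 0, 0, W, H)
  geoms <- lapply(cells, function(m) structure(list(m), class = "cgeom"))
  out <- data.frame(ecoregion_id = sprintf("eco%02d", seq_len(nrow(sites))),
                    area_km2 = vapply(geoms, cg_area, 0),
                    stringsAsFactors = FALSE)
  out$geometry <- geoms
  out
}

# blob: radial harmonic perturbation of a disc; star-shaped, hence simple.
# Scaled radially so the polygon area equals target_km2 exactly.
make_blob <- function(center, target_km2, shape, n_vertices = 36L) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  pert <- rep(0, n_vertices)
  if (shape > 0) {
    for (k in 2:6) {
      pert <- pert + runif(1, -1, 1) / k * cos(k * phi) +
                     runif(1, -1, 1) / k * sin(k * phi)
    }
    pert <- shape * pert
  }
  r <- pmax(0.15, 1 + pert)
  ring <- cbind(center[1L] + r * cos(phi), center[2L] + r * sin(phi))
  g <- cg_polygon(ring)
  scale <- sqrt(target_km2 / cg_area(g))
  ring <- cbind(center[1L] + scale * r * cos(phi),
                center[2L] + scale * r * sin(phi))
  cg_polygon(ring)
}

#' Generate species ranges
#'
#' Blob-shaped ranges with log-normal areas, clipped to the extent;
#' tetrapod classes are assigned round-robin over amphibian, bird, mammal,
#' reptile. A configurable fraction of range centres cluster around shared
#' hotspot locations (a Thomas-process-style pattern), producing the
#' spatially aggregated richness typical of endangered faunas; remaining
#' centres are uniform.
#'
#' @param cfg a \code{world_config}.
#' @param ecoregions ecoregion data.frame; required when hotspots are
#'   stratified per ecoregion (the default).
#' @return species-range data.frame (species_id, tetrapod_class,
#'   total_range_km2, geometry).
#' @export
generate_species_ranges <- function(cfg, ecoregions = NULL) {
  W <- cfg$extent_km[1L] * 1000; H <- cfg$extent_km[2L] * 1000
  boundary <- world_extent(cfg)
  classes <- c("amphibian", "bird", "mammal", "reptile")
  if (is.null(cfg$n_range_clusters)) {
    if (is.null(ecoregions))
      stop("ecoregions needed for stratified hotspots")
    # one hotspot per ecoregion: a uniform point inside it
    hot <- t(vapply(ecoregions$geometry, function(e) {
      bb <- cg_bbox(e)
      repeat {
        p <- c(runif(1, bb["xmin"], bb["xmax"]),
               runif(1, bb["ymin"], bb["ymax"]))
        if (cg_contains(e, p)) return(p)
      }
    }, c(0, 0)))
  } else {
    hot <- cbind(runif(cfg$n_range_clusters, 0, W),
                 runif(cfg$n_range_clusters, 0, H))
  }
  csd <- cfg$range_cluster_sd_km * 1000
  rows <- list(); geoms <- list()
  for (i in seq_len(cfg$n_species)) {
    a <- rlnorm(1, log(cfg$range_median_km2), cfg$range_log_sd)
    if (runif(1) < cfg$range_clustered_frac) {
      k <- sample.int(nrow(hot), 1L)
      repeat {
        ctr <- hot[k, ] + stats::rnorm(2, 0, csd)
        if (ctr[1L] >= 0 && ctr[1L] <= W && ctr[2L] >= 0 && ctr[2L] <= H)
          break
      }
    } else {
      ctr <- c(runif(1, 0, W), runif(1, 0, H))
    }
    g <- cg_intersection(make_blob(ctr, a, cfg$range_shape), boundary)
    area <- cg_area(g)
    rows[[i]] <- data.frame(species_id = sprintf("sp%03d", i),
                            tetrapod_class = classes[(i - 1L) %% 4L + 1L],
                            total_range_km2 = area,
                            stringsAsFactors = FALSE)
    geoms[[i]] <- g
  }
  out <- do.call(rbind, rows)
  out$geometry <- geoms
  out
}

# richness (number of covering ranges) at points
richness_at_points <- function(ranges, pts) {
  r <- rep(0L, nrow(pts))
  for (g in ranges$geometry) {
    bb <- cg_bbox(g)
    pre <- pts[, 1L] >= bb["xmin"] & pts[, 1L] <= bb["xmax"] &
           pts[, 2L] >= bb["ymin"] & pts[, 2L] <= bb["ymax"]
    if (any(pre))
      r[pre] <- r[pre] + as.integer(cg_contains(g, pts[pre, , drop = FALSE]))
  }
  r
}

# largest-remainder allocation of n items proportional to weights, with a
# per-stratum minimum
allocate_counts <- function(n, w, minimum = 0L) {
  k <- length(w)
  minimum <- min(minimum, n %/% k)
  base0 <- rep(as.integer(minimum), k)
  n_left <- n - sum(base0)
  raw <- n_left * w / sum(w)
  base <- floor(raw)
  left <- n_left - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base0 + as.integer(base)
}

#' Place protected areas with controllable richness bias
#'
#' Protected areas are allocated to ecoregions proportionally to area.
#' With \code{bias_beta = 0} each is placed by the null model's own rigid
#' placement sampler (uniform position and orientation within the
#' ecoregion). Otherwise centroids are drawn from a density proportional
#' to exp(-bias_beta * richness) over a fine in-ecoregion lattice (with
#' within-cell jitter), rotation stays uniform, and full containment is
#' enforced by rejection with the same clip-to-ecoregion fallback.
#'
#' @param cfg a \code{world_config}.
#' @param ecoregions ecoregion data.frame.
#' @param ranges species-range data.frame (used for the richness field).
#' @return a \code{vlayer} of protected areas with pa_id and gap_status.
#' @export
place_protected_biased <- function(cfg, ecoregions, ranges) {
  n_eco <- nrow(ecoregions)
  counts <- allocate_counts(cfg$n_protected, ecoregions$area_km2,
                            cfg$pa_min_per_ecoregion)
  pcfg <- placement_config(n_iterations = 1L, seed = cfg$seed)
  attrs <- list(); geoms <- list(); k <- 0L
  for (j in seq_len(n_eco)) {
    if (counts[j] == 0L) next
    eg <- ecoregions$geometry[[j]]
    bb <- cg_bbox(eg)
    lattice <- NULL; weights <- NULL; spacing <- NULL
    if (cfg$bias_beta != 0) {
      nx <- 30L
      spacing <- max((bb["xmax"] - bb["xmin"]) / nx,
                     (bb["ymax"] - bb["ymin"]) / nx)
      xs <- seq(bb["xmin"] + spacing / 2, bb["xmax"], by = spacing)
      ys <- seq(bb["ymin"] + spacing / 2, bb["ymax"], by = spacing)
      lattice <- cbind(rep(xs, times = length(ys)),
                       rep(ys, each = length(xs)))
      lattice <- lattice[cg_contains(eg, lattice), , drop = FALSE]
      rich <- richness_at_points(ranges, lattice)
      w <- exp(-cfg$bias_beta * (rich - min(rich)))
      weights <- w / sum(w)
    }
    for (i in seq_len(counts[j])) {
      k <- k + 1L
      repeat {
        a <- rlnorm(1, log(cfg$pa_median_km2), cfg$pa_log_sd)
        if (a >= 5 && a < 0.9 * ecoregions$area_km2[j]) break
      }
      blob <- make_blob(c(0, 0), a, cfg$range_shape)
      if (cfg$bias_beta == 0) {
        res <- random_rigid_placement(blob, eg, pcfg)
        g <- res$geometry
      } else {
        g <- NULL; best <- NULL; best_frac <- -1
        for (t in seq_len(pcfg$max_tries)) {
          idx <- sample.int(nrow(lattice), 1L, prob = weights)
          pt <- lattice[idx, ] + runif(2, -spacing / 2, spacing / 2)
          cand <- cg_transform(blob, runif(1, 0, 2 * pi), to = pt)
          frac <- cg_intersection_area(cand, eg) / a
          if (frac >= 1 - 1e-9) { g <- cand; break }
          if (frac > best_frac) { best_frac <- frac; best <- cand }
        }
        if (is.null(g)) g <- cg_intersection(best, eg)
      }
      attrs[[k]] <- data.frame(pa_id = sprintf("pa%04d", k),
                               gap_status = sample(1:2, 1L),
                               stringsAsFactors = FALSE)
      geoms[[k]] <- g
    }
  }
  vlayer(do.call(rbind, attrs), geoms, study_crs())
}

#' Assign land tiers and landcover
#'
#' Partitions non-protected land into EASEMENT / USFS_BLM / OTHER_FEDERAL /
#' STATE / private by labelling the cells of a fine Voronoi tessellation to
#' hit the configured tier proportions (largest-deficit-first assignment;
#' tolerance about one tile, i.e. ~2 percentage points), then lays a
#' landcover grid over the extent with developed and cultivated-crops
#' cells at the configured probabilities on private land.
#'
#' @param cfg a \code{world_config}.
#' @param ecoregions ecoregion data.frame (unused beyond the extent; kept
#'   for interface symmetry).
#' @param pas protected-area \code{vlayer} from
#'   \code{\link{place_protected_biased}}.
#' @param ranges species-range data.frame (for truth bookkeeping).
#' @param n_tiles number of tessellation tiles.
#' @return list with \code{easements} and \code{public} vlayers,
#'   \code{landcover} grid, \code{truth} data.frame of exact per-species
#'   tier percents, and the private-land geometry.
#' @export
assign_tiers_and_landcover <- function(cfg, ecoregions, pas, ranges,
                                       n_tiles = 150L) {
  W <- cfg$extent_km[1L] * 1000; H <- cfg$extent_km[2L] * 1000
  boundary <- world_extent(cfg)
  pa_union <- cg_union(pas$geometry)
  nonpa_km2 <- cg_area(boundary) - cg_area(pa_union)

  sites <- cbind(runif(n_tiles, 0, W), runif(n_tiles, 0, H))
  cells <- cpp_voronoi(sites, 0, 0, W, H)
  # each tile: its (convex) Voronoi cell minus the protected network
  tiles <- lapply(cells, function(m)
    cg_difference(structure(list(m), class = "cgeom"), pa_union))
  tile_km2 <- vapply(tiles, cg_area, 0)
  keep <- tile_km2 > 1e-9
  tiles <- tiles[keep]; tile_km2 <- tile_km2[keep]

  prop <- cfg$tier_proportions
  labels <- names(prop)
  target <- prop * nonpa_km2
  got <- setNames(rep(0, length(labels)), labels)
  lab <- character(length(tiles))
  for (i in sample.int(length(tiles))) {
    deficit <- (target - got) / nonpa_km2
    pick <- labels[which.max(deficit)]
    lab[i] <- pick
    got[pick] <- got[pick] + tile_km2[i]
  }

  tier_geom <- list()
  for (t in labels) {
    sel <- lab == t
    tier_geom[[t]] <- if (any(sel)) cg_concat(tiles[sel])  # tiles disjoint
                      else structure(list(), class = "cgeom")
  }

  # layers as the pipeline consumes them
  eas_sel <- which(lab == "EASEMENT")
  easements <- vlayer(
    data.frame(easement_id = sprintf("eas%03d", seq_along(eas_sel)),
               stringsAsFactors = FALSE),
    tiles[eas_sel], study_crs())
  pub_sel <- which(lab %in% c("USFS_BLM", "OTHER_FEDERAL", "STATE"))
  agency_for <- function(l, i) switch(l,
    USFS_BLM = c("USFS", "BLM")[i %% 2L + 1L],
    OTHER_FEDERAL = c("DOD", "BOR")[i %% 2L + 1L],
    STATE = "STATE")
  public <- vlayer(
    data.frame(agency = vapply(seq_along(pub_sel), function(i)
                 agency_for(lab[pub_sel[i]], i), ""),
               stringsAsFactors = FALSE),
    tiles[pub_sel], study_crs())

  # landcover over the extent: private cells draw developed/crops/natural
  cs <- cfg$cell_size_m
  nc <- as.integer(round(W / cs)); nr <- as.integer(round(H / cs))
  grid0 <- landcover_grid(matrix(41L, nr, nc), origin = c(0, H),
                          cell_size = cs, legend = TOY_LEGEND,
                          crs = study_crs())
  centers <- grid_cell_centers(grid0)
  in_private <- cg_contains(tier_geom$PRIVATE, centers)
  code <- rep(41L, nrow(centers))
  npriv <- sum(in_private)
  u <- runif(npriv)
  code[in_private][u < cfg$p_developed] <- 21L
  code[in_private][u >= cfg$p_developed &
                   u < cfg$p_developed + cfg$p_crops] <- 82L
  vals <- matrix(code, nr, nc)  # column-major matches grid_cell_centers
  landcover <- landcover_grid(vals, origin = c(0, H), cell_size = cs,
                              legend = TOY_LEGEND, crs = study_crs())

  # exact truth bookkeeping per species
  cell_km2 <- cs^2 / 1e6
  undev_center <- in_private & code == 41L
  undev_pts <- centers[undev_center, , drop = FALSE]
  truth <- list()
  for (i in seq_len(nrow(ranges))) {
    g <- ranges$geometry[[i]]
    total <- ranges$total_range_km2[i]
    pct <- c(PROTECTED_GAP12 =
               100 * cg_intersection_area(g, pa_union) / total)
    for (t in c("EASEMENT", "USFS_BLM", "OTHER_FEDERAL", "STATE"))
      pct[t] <- 100 * cg_intersection_area(g, tier_geom[[t]]) / total
    priv_pct <- 100 * cg_intersection_area(g, tier_geom$PRIVATE) / total
    bb <- cg_bbox(g)
    pre <- undev_pts[, 1L] >= bb["xmin"] & undev_pts[, 1L] <= bb["xmax"] &
           undev_pts[, 2L] >= bb["ymin"] & undev_pts[, 2L] <= bb["ymax"]
    undev_pct <- if (any(pre))
      100 * sum(cg_contains(g, undev_pts[pre, , drop = FALSE])) *
        cell_km2 / total else 0
    undev_pct <- min(undev_pct, priv_pct)
    pct["PRIVATE_UNDEVELOPED"] <- undev_pct
    pct["PRIVATE_OTHER"] <- priv_pct - undev_pct
    row <- data.frame(species_id = ranges$species_id[i],
                      tetrapod_class = ranges$tetrapod_class[i],
                      total_range_km2 = total, stringsAsFactors = FALSE)
    for (t in tier_order()) row[[paste0("pct_", t)]] <- unname(pct[t])
    truth[[i]] <- row
  }

  list(easements = easements, public = public, landcover = landcover,
       truth = do.call(rbind, truth), private_geom = tier_geom$PRIVATE,
       tier_geoms = tier_geom)
}

#' Generate a complete synthetic world
#'
#' @param cfg a \code{world_config}.
#' @param tiers generate the tier tessellation, landcover grid and truth
#'   table (set FALSE for null-model-only worlds, which are much lighter).
#' @return a \code{synthetic_world}: ecoregions, ranges, protected (vlayer),
#'   boundary, and — when \code{tiers} — easements, public, landcover,
#'   truth.
#' @export
generate_world <- function(cfg = world_config(), tiers = TRUE) {
  set.seed(cfg$seed)
  ecoregions <- generate_ecoregions(cfg)
  ranges <- generate_species_ranges(cfg, ecoregions)
  pas <- place_protected_biased(cfg, ecoregions, ranges)
  world <- list(config = cfg, boundary = world_extent(cfg),
                ecoregions = ecoregions, ranges = ranges, protected = pas)
  if (tiers)
    world <- c(world, assign_tiers_and_landcover(cfg, ecoregions, pas,
                                                 ranges))
  structure(world, class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world: %d ecoregions, %d species, %d protected areas%s>\n",
    nrow(x$ecoregions), nrow(x$ranges), length(x$protected),
    if (!is.null(x$truth)) ", with tier truth" else ""))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Writes the exact formats the pipeline consumes: GeoJSON layers
#' (ecoregions, ranges, protected, easements, public), an ASCII-grid
#' landcover raster, and truth.csv.
#'
#' @param world a \code{synthetic_world}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  crs <- study_crs()
  eco <- world$ecoregions
  write_vector(vlayer(eco[, c("ecoregion_id", "area_km2")],
                      eco$geometry, crs),
               file.path(dir, "ecoregions.geojson"))
  rg <- world$ranges
  write_vector(vlayer(rg[, c("species_id", "tetrapod_class",
                             "total_range_km2")],
                      rg$geometry, crs),
               file.path(dir, "ranges.geojson"))
  write_vector(world$protected, file.path(dir, "protected.geojson"))
  if (!is.null(world$easements)) {
    write_vector(world$easements, file.path(dir, "easements.geojson"))
    write_vector(world$public, file.path(dir, "public.geojson"))
    write_landcover(world$landcover, file.path(dir, "landcover.asc"))
    write_table(world$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}
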