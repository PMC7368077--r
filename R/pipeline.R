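#' Pipeline configuration and orchestration
#'
#' One YAML config file drives the full analysis: preprocessing (GAP and
#' size filters, ecoregion splitting), the spatial null model, the tier
#' map, the coverage cascade and all outputs. All randomness flows from
#' the single config seed.
#'
#' @name cli_reporting
NULL

#' Build a pipeline configuration
#'
#' @param ecoregions,protected,ranges paths to GeoJSON layers (required).
#' @param easements,public optional GeoJSON layer paths.
#' @param landcover optional ASCII-grid raster path.
#' @param out_dir output directory.
#' @param crs CRS identifier for planar inputs.
#' @param legend named landcover legend (code to label).
#' @param excluded_codes landcover codes excluded from "undeveloped".
#' @param n_iterations,seed,max_tries,containment placement settings (see
#'   \code{\link{placement_config}}).
#' @param threshold adequacy threshold, percent in (0, 100].
#' @param min_pa_km2 protected-area size cutoff, km2.
#' @param allowed_gap GAP statuses retained.
#' @param pixel_area_km2 richness-grid pixel area.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(ecoregions, protected, ranges,
                            easements = NULL, public = NULL,
                            landcover = NULL, out_dir = "pipeline_out",
                            crs = "local-cartesian-meters",
                            legend = TOY_LEGEND,
                            excluded_codes = TOY_EXCLUDED,
                            n_iterations = 1000L, seed = 1L,
                            max_tries = 100L, containment = 1.0,
                            threshold = 30, min_pa_km2 = 5,
                            allowed_gap = c(1L, 2L),
                            pixel_area_km2 = 5) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys are \code{\link{pipeline_config}} arguments,
#'   with \code{legend} as a code-to-label map.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$legend)) y$legend <- unlist(y$legend)
  do.call(pipeline_config, y)
}

#' Validate a pipeline configuration
#'
#' @param cfg a \code{pipeline_config}.
#' @return character vector of problems; empty when runnable.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  need <- function(field) {
    p <- cfg[[field]]
    if (is.null(p)) problems <<- c(problems, paste0(field, ": path missing"))
    else if (!file.exists(p))
      problems <<- c(problems, paste0(field, ": file not found (", p, ")"))
  }
  need("ecoregions"); need("protected"); need("ranges")
  for (field in c("easements", "public", "landcover")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p))
      problems <- c(problems, paste0(field, ": file not found (", p, ")"))
  }
  if (is.null(cfg$threshold) || cfg$threshold <= 0 || cfg$threshold > 100)
    problems <- c(problems, "threshold: must be in (0, 100]")
  if (is.null(cfg$n_iterations) || cfg$n_iterations < 1)
    problems <- c(problems, "n_iterations: must be >= 1")
  if (is.null(cfg$containment) || cfg$containment <= 0 ||
      cfg$containment > 1)
    problems <- c(problems, "containment: must be in (0, 1]")
  problems
}

# plain-text checksum: FNV-1a over the serialized config
config_hash <- function(cfg) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste(deparse(cfg[order(names(cfg))]),
                            collapse = ""))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

fmt_num <- function(x) ifelse(is.na(x), NA, signif(x, 10))

#' Run the full pipeline
#'
#' Reads all layers, prepares the protected-area network, runs the spatial
#' null model, builds the tier map, computes the coverage cascade, and
#' writes \code{nullmodel_results.csv}, \code{nullmodel_summary.csv},
#' \code{coverage.csv}, \code{class_summary.csv}, \code{richness.asc} and
#' \code{manifest.json} to the output directory. Re-running with the same
#' config and seed reproduces the CSVs bit-identically.
#'
#' @param cfg a \code{pipeline_config}.
#' @param quiet suppress stage logging.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  problems <- validate_config(cfg)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  stages <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e)))
    stages[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }
  crs <- study_crs(cfg$crs)

  inputs <- tick("read", {
    eco <- as_ecoregions(read_vector(cfg$ecoregions, "ecoregion_id", crs))
    pas <- read_vector(cfg$protected, "gap_status", crs)
    rng <- read_vector(cfg$ranges, c("species_id", "tetrapod_class"), crs)
    eas <- if (!is.null(cfg$easements))
      read_vector(cfg$easements, character(), crs)
      else vlayer(data.frame(), list(), crs)
    pub <- if (!is.null(cfg$public)) read_vector(cfg$public, "agency", crs)
      else vlayer(data.frame(), list(), crs)
    lc <- if (!is.null(cfg$landcover))
      read_landcover(cfg$landcover, cfg$legend, crs) else NULL
    list(eco = eco, pas = pas, rng = rng, eas = eas, pub = pub, lc = lc)
  })

  prep <- tick("preprocess", {
    boundary <- cg_union(inputs$eco$geometry)
    kept <- filter_min_area(
      select_protected(inputs$pas, cfg$allowed_gap), cfg$min_pa_km2)
    pieces <- split_by_ecoregion(kept, inputs$eco)
    ranges <- normalize_ranges(inputs$rng, boundary)
    log_msg("preprocess: %d/%d protected areas kept, %d pieces, %d species",
            nrow(kept), length(inputs$pas), nrow(pieces), nrow(ranges))
    list(boundary = boundary, pieces = pieces, ranges = ranges,
         n_pa_in = length(inputs$pas), n_pa_kept = nrow(kept))
  })

  nm <- tick("null_model", {
    pc <- placement_config(cfg$n_iterations, cfg$seed, cfg$max_tries,
                           cfg$containment)
    run_null_model(prep$pieces, prep$ranges, inputs$eco, pc)
  })
  nm_sum <- summary(nm)
  log_msg("null model: %d ecoregions, %.1f%% better / %.1f%% equal / %.1f%% worse",
          nm_sum$n_ecoregions, nm_sum$pct_better, nm_sum$pct_equal,
          nm_sum$pct_worse)

  cov <- tick("coverage", {
    tm <- build_tier_map(prep$pieces, inputs$eas, inputs$pub,
                         prep$boundary, inputs$lc,
                         undeveloped_rule(cfg$excluded_codes))
    tier_coverage(prep$ranges, tm, threshold = cfg$threshold)
  })

  rich <- tick("richness", {
    bb <- cg_bbox(prep$boundary)
    richness_grid(prep$ranges, cfg$pixel_area_km2,
                  extent = unname(bb[c("xmin", "ymin", "xmax", "ymax")]))
  })

  tick("write", {
    res <- nm$results
    for (col in c("null_mean", "null_sd", "difference"))
      res[[col]] <- fmt_num(res[[col]])
    write_table(res, file.path(cfg$out_dir, "nullmodel_results.csv"))
    write_table(data.frame(n_ecoregions = nm_sum$n_ecoregions,
                           pct_better = fmt_num(nm_sum$pct_better),
                           pct_equal = fmt_num(nm_sum$pct_equal),
                           pct_worse = fmt_num(nm_sum$pct_worse)),
                file.path(cfg$out_dir, "nullmodel_summary.csv"))
    rec <- cov$records
    for (col in names(rec))
      if (is.numeric(rec[[col]])) rec[[col]] <- fmt_num(rec[[col]])
    write_table(rec, file.path(cfg$out_dir, "coverage.csv"))
    cs <- class_summary(cov)
    cs$mean_pct <- fmt_num(cs$mean_pct)
    write_table(cs, file.path(cfg$out_dir, "class_summary.csv"))
    rg <- landcover_grid(rich$values, rich$origin, rich$cell_size,
                         legend = setNames(
                           as.list(paste(0:max(rich$values), "species")),
                           0:max(rich$values)),
                         nodata = -9999L, crs = crs)
    write_landcover(rg, file.path(cfg$out_dir, "richness.asc"))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("protgap")),
    config_hash = config_hash(unclass(cfg)),
    seed = cfg$seed,
    n_protected_input = prep$n_pa_in,
    n_protected_kept = prep$n_pa_kept,
    n_species = nrow(prep$ranges),
    n_ecoregions_modeled = nm_sum$n_ecoregions,
    stages_complete = names(stages),
    stage_seconds = stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("pipeline complete: outputs in %s", cfg$out_dir)
  invisible(manifest)
}
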