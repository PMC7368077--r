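# shared fixtures, built in code and memoised for the session

.fixtures <- new.env(parent = emptyenv())

# the package's default toy world (100 m cells); generated once
default_world <- function() {
  if (is.null(.fixtures$world)) {
    .fixtures$world <- suppressWarnings(generate_world(world_config(seed = 1)))
  }
  .fixtures$world
}

# a lighter world for pipeline smoke tests (coarse cells, fewer species)
light_world <- function() {
  if (is.null(.fixtures$light)) {
    cfg <- world_config(n_species = 24L, cell_size_m = 500, seed = 3)
    .fixtures$light <- suppressWarnings(generate_world(cfg))
  }
  .fixtures$light
}

light_world_dir <- function() {
  if (is.null(.fixtures$light_dir)) {
    d <- file.path(tempdir(), "protgap_light_world")
    write_world(light_world(), d)
    .fixtures$light_dir <- d
  }
  .fixtures$light_dir
}

# rectangle vlayer helper: one feature per row of (xmin, ymin, xmax, ymax)
rect_layer <- function(rects, attrs = NULL) {
  geoms <- lapply(seq_len(nrow(rects)), function(i)
    cg_rect(rects[i, 1L], rects[i, 2L], rects[i, 3L], rects[i, 4L]))
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_along(geoms))
  vlayer(attrs, geoms, study_crs())
}

# analytic overlap area of two axis-aligned rectangles, km2
rect_overlap_km2 <- function(a, b) {
  w <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  h <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  w * h / 1e6
}

# Monte-Carlo area fraction oracle: fraction of uniform points in `frame`
# (bbox vector) falling inside g, with binomial standard error
mc_area_km2 <- function(g, frame, n = 1e5) {
  pts <- cbind(runif(n, frame[1L], frame[3L]), runif(n, frame[2L], frame[4L]))
  inside <- cg_contains(g, pts)
  a_frame <- (frame[3L] - frame[1L]) * (frame[4L] - frame[2L]) / 1e6
  p <- mean(inside)
  list(est = p * a_frame, se = sqrt(p * (1 - p) / n) * a_frame)
}

# symmetric-difference area between two geometries, km2
symdiff_km2 <- function(a, b) {
  cg_area(cg_difference(a, b)) + cg_area(cg_difference(b, a))
}

# protected-area data.frame from explicit geometries
pa_df <- function(geoms, gap_status = NULL, ids = NULL) {
  n <- length(geoms)
  if (is.null(gap_status)) gap_status <- rep(1L, n)
  if (is.null(ids)) ids <- sprintf("pa%03d", seq_len(n))
  out <- data.frame(pa_id = ids, gap_status = as.integer(gap_status),
                    area_km2 = vapply(geoms, cg_area, 0),
                    ecoregion_id = NA_character_, stringsAsFactors = FALSE)
  out$geometry <- geoms
  out
}

# species-range data.frame from explicit geometries
range_df <- function(geoms, ids = NULL, classes = NULL) {
  n <- length(geoms)
  if (is.null(ids)) ids <- sprintf("sp%03d", seq_len(n))
  if (is.null(classes))
    classes <- rep(c("amphibian", "bird", "mammal", "reptile"), length.out = n)
  out <- data.frame(species_id = ids, tetrapod_class = classes,
                    total_range_km2 = vapply(geoms, cg_area, 0),
                    stringsAsFactors = FALSE)
  out$geometry <- geoms
  out
}
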