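planar_feature_json <- function(rings_list, props_list,
                                crs = "local-cartesian-meters") {
  feats <- vapply(seq_along(rings_list), function(i) {
    ring <- rings_list[[i]]
    ring <- rbind(ring, ring[1, ])
    coords <- paste0("[", paste(sprintf("[%f,%f]", ring[, 1], ring[, 2]),
                                collapse = ","), "]")
    props <- props_list[[i]]
    pj <- if (length(props) == 0) "{}" else
      paste0("{", paste(sprintf('"%s": %s', names(props),
        vapply(props, function(v) if (is.character(v))
          sprintf('"%s"', v) else as.character(v), "")), collapse = ","), "}")
    sprintf('{"type":"Feature","properties":%s,"geometry":{"type":"Polygon","coordinates":[%s]}}',
            pj, coords)
  }, "")
  sprintf('{"type":"FeatureCollection","crs":{"type":"name","properties":{"name":"%s"}},"features":[%s]}',
          crs, paste(feats, collapse = ","))
}

test_that("GeoJSON identity read preserves features and attributes", {
  sq <- function(x) rbind(c(x, 0), c(x + 1000, 0), c(x + 1000, 1000),
                          c(x, 1000))
  js <- planar_feature_json(list(sq(0), sq(2000), sq(4000)),
                            list(list(id = "a"), list(id = "b"),
                                 list(id = "c")))
  f <- tempfile(fileext = ".geojson")
  writeLines(js, f)
  lay <- read_vector(f)
  expect_equal(length(lay), 3L)
  expect_equal(lay$attributes$id, c("a", "b", "c"))
  expect_equal(vapply(lay$geometry, cg_area, 0), rep(1, 3))
})

test_that("missing required attribute raises a schema error naming it", {
  js <- planar_feature_json(list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
                            list(list(id = "a")))
  f <- tempfile(fileext = ".geojson")
  writeLines(js, f)
  expect_error(read_vector(f, required_attrs = "gap_status"), "gap_status")
  expect_error(read_vector(tempfile()), "not found")
})

test_that("bow-tie rings are repaired to the sum of their lobes", {
  # self-intersecting square of nominal side 2 km; the two triangular lobes
  # have shoelace area 1 km2 each
  bow <- rbind(c(0, 0), c(2000, 0), c(0, 2000), c(2000, 2000))
  js <- planar_feature_json(list(bow), list(list(id = "x")))
  f <- tempfile(fileext = ".geojson")
  writeLines(js, f)
  expect_warning(lay <- read_vector(f), "repair")
  expect_equal(cg_area(lay$geometry[[1]]), 2, tolerance = 1e-9)
})

test_that("write-then-read round-trips geometry within overlay tolerance", {
  set.seed(11)
  g1 <- protgap:::make_blob(c(5e4, 5e4), 120, 0.5)
  g2 <- cg_union(list(cg_rect(0, 0, 1e4, 1e4), cg_rect(2e4, 0, 3e4, 5e3)))
  lay <- vlayer(data.frame(id = c("a", "b"), v = c(1.5, -2.25)),
                list(g1, g2), study_crs())
  f <- tempfile(fileext = ".geojson")
  write_vector(lay, f)
  back <- read_vector(f, required_attrs = c("id", "v"))
  expect_equal(back$attributes$id, c("a", "b"))
  for (i in 1:2)
    expect_lt(symdiff_km2(lay$geometry[[i]], back$geometry[[i]]), 1e-9)
})

test_that("Albers projection is equal-area against a geodesic oracle", {
  skip_if_not_installed("geosphere")
  # geodesic quadrilateral over the central USA; same sphere radius on
  # both routes
  lon <- c(-105, -100, -100, -105)
  lat <- c(38, 38, 42, 42)
  geo <- geosphere::areaPolygon(cbind(lon, lat), a = 6378137, f = 0) / 1e6
  xy <- albers_project(cbind(lon, lat))
  planar <- cg_area(cg_polygon(xy))
  expect_lt(abs(planar - geo) / geo, 0.001)
})

test_that("ASCII grids round-trip and carry area semantics", {
  set.seed(3)
  vals <- matrix(sample(c(41L, 21L, 82L), 100, replace = TRUE), 10, 10)
  g <- landcover_grid(vals, origin = c(0, 300), cell_size = 30,
                      legend = c("41" = "forest", "21" = "developed",
                                 "82" = "crops"))
  # 100 cells of 30 m: total area 0.09 km2
  expect_equal(nrow(g$values) * ncol(g$values) * g$cell_size^2 / 1e6, 0.09)
  f <- tempfile(fileext = ".asc")
  write_landcover(g, f)
  back <- read_landcover(f, legend = g$legend, crs = study_crs())
  expect_identical(back$values, g$values)
  expect_equal(back$cell_size, 30)
  expect_equal(back$origin, g$origin)
})

test_that("landcover ingestion enforces legend, integer band and CRS", {
  vals <- matrix(41L, 5, 5); vals[2, 2] <- 99L
  expect_warning(
    g <- landcover_grid(vals, c(0, 500), 100, legend = c("41" = "forest")),
    "outside the legend")
  expect_equal(g$values[2, 2], g$nodata)
  f <- tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "NODATA_value -9999", "1.5 2"), f)
  expect_error(read_landcover(f, legend = c("1" = "x"), crs = study_crs()),
               "non-integer")
  expect_error(read_landcover(f, legend = c("1" = "x")), "CRS")
})

test_that("write_table round-trips 100 random records at 6 significant digits", {
  set.seed(8)
  df <- data.frame(species = sprintf("sp%03d", 1:100),
                   pct = signif(runif(100, 0, 100), 8),
                   n = sample.int(1e6, 100))
  f <- tempfile(fileext = ".csv")
  write_table(df, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_identical(back$species, df$species)
  expect_equal(signif(back$pct, 6), signif(df$pct, 6))
  expect_identical(back$n, df$n)
})

test_that("empty record lists need an explicit schema", {
  f <- tempfile(fileext = ".csv")
  write_table(list(), f, schema = c("species", "pct"))
  expect_identical(readLines(f), '"species","pct"')
  expect_error(write_table(list(), tempfile()), "schema")
  # single record -> two-line CSV
  f2 <- tempfile(fileext = ".csv")
  write_table(list(list(species = "A", pct_protected = 13.0)), f2)
  expect_length(readLines(f2), 2L)
})
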