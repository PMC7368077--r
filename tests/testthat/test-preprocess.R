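test_that("GAP selection keeps exactly the allowed statuses", {
  rects <- cbind(0:3 * 2000, 0, 0:3 * 2000 + 1000, 1000)
  lay <- rect_layer(rects, data.frame(gap_status = 1:4))
  kept <- select_protected(lay)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$gap_status, c(1L, 2L))
  expect_equal(nrow(select_protected(lay, allowed_gap = 1:4)), 4L)
  empty <- rect_layer(rects[0, , drop = FALSE],
                      data.frame(gap_status = integer(0)))
  expect_equal(nrow(select_protected(empty)), 0L)
  bad <- rect_layer(rects[1, , drop = FALSE], data.frame(gap_status = 5L))
  expect_error(select_protected(bad), "1-4")
})

test_that("size filter removes strictly-below-minimum units, keeps 5 km2", {
  # areas 4.9, 5.0, 5.1 km2 as 1-km-tall rectangles
  geoms <- list(cg_rect(0, 0, 4900, 1000),
                cg_rect(0, 2000, 5000, 3000),
                cg_rect(0, 4000, 5100, 5000))
  pas <- pa_df(geoms)
  kept <- filter_min_area(pas, 5)
  expect_equal(sort(kept$area_km2), c(5.0, 5.1))
  expect_equal(nrow(filter_min_area(pas, 0)), 3L)
  expect_error(filter_min_area(pas, -1), "non-negative")
})

test_that("size-filter survivors match an independent area scan", {
  set.seed(21)
  dims <- cbind(runif(100, 500, 4000), runif(100, 500, 4000))
  geoms <- lapply(1:100, function(i)
    cg_rect(0, 0, dims[i, 1], dims[i, 2]))
  pas <- pa_df(geoms)
  kept <- filter_min_area(pas, 5)
  oracle <- which(dims[, 1] * dims[, 2] / 1e6 >= 5)  # plain arithmetic
  expect_identical(which(pas$pa_id %in% kept$pa_id), oracle)
})

test_that("ecoregion splitting halves a straddling square and is lossless", {
  eco <- data.frame(ecoregion_id = c("L", "R"), area_km2 = c(50, 50),
                    stringsAsFactors = FALSE)
  eco$geometry <- list(cg_rect(0, 0, 5000, 10000), cg_rect(5000, 0, 10000, 10000))
  pas <- pa_df(list(cg_rect(4000, 4000, 6000, 6000),   # straddles both
                    cg_rect(1000, 1000, 2000, 2000)))  # inside L
  sp <- split_by_ecoregion(pas, eco)
  str1 <- sp[sp$pa_id == "pa001", ]
  expect_equal(nrow(str1), 2L)
  expect_equal(sort(str1$area_km2), c(2, 2))
  expect_setequal(str1$ecoregion_id, c("L", "R"))
  in1 <- sp[sp$pa_id == "pa002", ]
  expect_equal(nrow(in1), 1L)
  expect_equal(in1$area_km2, 1)
  expect_equal(in1$ecoregion_id, "L")
  # a PA outside all ecoregions is dropped with a warning
  out <- pa_df(list(cg_rect(20000, 0, 21000, 1000)))
  expect_warning(res <- split_by_ecoregion(out, eco), "outside")
  expect_equal(nrow(res), 0L)
})

test_that("splitting conserves clipped area against a rectangle oracle", {
  set.seed(31)
  eco_rects <- rbind(c(0, 0, 4000, 10000), c(4000, 0, 7000, 10000),
                     c(7000, 0, 10000, 10000))
  eco <- data.frame(ecoregion_id = c("e1", "e2", "e3"),
                    area_km2 = c(40, 30, 30), stringsAsFactors = FALSE)
  eco$geometry <- lapply(1:3, function(i)
    cg_rect(eco_rects[i, 1], eco_rects[i, 2], eco_rects[i, 3], eco_rects[i, 4]))
  pa_rects <- cbind(runif(20, -1000, 9000), runif(20, 0, 9000), 0, 0)
  pa_rects[, 3] <- pa_rects[, 1] + runif(20, 500, 3000)
  pa_rects[, 4] <- pa_rects[, 2] + runif(20, 500, 3000)
  pas <- pa_df(lapply(1:20, function(i)
    cg_rect(pa_rects[i, 1], pa_rects[i, 2], pa_rects[i, 3], pa_rects[i, 4])))
  sp <- suppressWarnings(split_by_ecoregion(pas, eco))
  for (i in 1:20) {
    expected <- sum(vapply(1:3, function(j)
      rect_overlap_km2(pa_rects[i, ], eco_rects[j, ]), 0))
    got <- sum(sp$area_km2[sp$pa_id == pas$pa_id[i]])
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("range normalization dissolves, clips and sets denominators", {
  boundary <- cg_rect(0, 0, 10000, 10000)
  lay <- rect_layer(rbind(c(0, 0, 1000, 1000), c(3000, 3000, 4000, 4000),
                          c(20000, 0, 21000, 1000)),
                    data.frame(species_id = c("s1", "s1", "s2"),
                               tetrapod_class = c("bird", "bird", "mammal")))
  expect_warning(rg <- normalize_ranges(lay, boundary), "dropped")
  expect_equal(nrow(rg), 1L)        # s2 lies wholly outside
  expect_equal(rg$species_id, "s1") # two disjoint squares dissolve to one
  expect_equal(rg$total_range_km2, 2)
  bad <- rect_layer(rbind(c(0, 0, 1000, 1000), c(2000, 0, 3000, 1000)),
                    data.frame(species_id = c("s1", "s1"),
                               tetrapod_class = c("bird", "mammal")))
  expect_error(normalize_ranges(bad, boundary), "conflicting")
})

test_that("clipped range areas agree with a Monte-Carlo oracle", {
  set.seed(41)
  boundary <- cg_rect(0, 0, 2e4, 2e4)
  geoms <- lapply(1:5, function(i)
    protgap:::make_blob(runif(2, 0, 2e4), runif(1, 30, 150), 0.5))
  lay <- vlayer(data.frame(species_id = sprintf("s%d", 1:5),
                           tetrapod_class = "bird"), geoms, study_crs())
  rg <- normalize_ranges(lay, boundary)
  frame <- c(0, 0, 2e4, 2e4)
  for (i in seq_len(nrow(rg))) {
    mc <- mc_area_km2(rg$geometry[[i]], frame, n = 1e5)
    expect_lt(abs(rg$total_range_km2[i] - mc$est), 3 * mc$se)
  }
})

test_that("the preparation pipeline never increases total protected area", {
  w <- light_world()
  raw <- as_protected_areas(w$protected)
  pieces <- prepare_protected(w$protected, w$ecoregions)
  expect_lte(sum(pieces$area_km2), sum(raw$area_km2) + 1e-9)
  # split conserves: every piece lies in its named ecoregion
  for (i in seq_len(nrow(pieces))) {
    eg <- w$ecoregions$geometry[[
      match(pieces$ecoregion_id[i], w$ecoregions$ecoregion_id)]]
    expect_lt(cg_area(cg_difference(pieces$geometry[[i]], eg)), 1e-6)
  }
})
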