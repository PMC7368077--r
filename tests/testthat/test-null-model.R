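test_that("classification respects the inclusive one-species margin", {
  expect_equal(classify_difference(10, 8.5), "better")
  expect_equal(classify_difference(10, 9.5), "equal")
  expect_equal(classify_difference(7, 8.0), "worse")    # exactly -1.0
  expect_equal(classify_difference(9, 8.0), "better")   # exactly +1.0
  expect_equal(classify_difference(5, 5), "equal")
  expect_error(classify_difference(5, 5, delta = 0))
})

test_that("species counting uses unique species over the piece union", {
  range1 <- cg_rect(0, 0, 5000, 5000)
  ranges <- range_df(list(range1))
  inside <- list(cg_rect(1000, 1000, 2000, 2000))
  expect_equal(count_species_overlapping(inside, ranges), 1L)
  # shared edge only: zero-area intersection does not count
  touching <- list(cg_rect(5000, 0, 6000, 1000))
  expect_equal(count_species_overlapping(touching, ranges), 0L)
  # two pieces inside the same range still count the species once
  two <- list(cg_rect(0, 0, 1000, 1000), cg_rect(3000, 3000, 4000, 4000))
  expect_equal(count_species_overlapping(two, ranges), 1L)
  expect_equal(count_species_overlapping(list(), ranges), 0L)
})

test_that("species counts match a rectangle-arithmetic oracle", {
  set.seed(51)
  for (rep in 1:5) {
    sp_rects <- cbind(runif(20, 0, 8000), runif(20, 0, 8000), 0, 0)
    sp_rects[, 3] <- sp_rects[, 1] + runif(20, 500, 2500)
    sp_rects[, 4] <- sp_rects[, 2] + runif(20, 500, 2500)
    pa_rects <- cbind(runif(5, 0, 8000), runif(5, 0, 8000), 0, 0)
    pa_rects[, 3] <- pa_rects[, 1] + runif(5, 500, 2000)
    pa_rects[, 4] <- pa_rects[, 2] + runif(5, 500, 2000)
    ranges <- range_df(lapply(1:20, function(i)
      cg_rect(sp_rects[i, 1], sp_rects[i, 2], sp_rects[i, 3], sp_rects[i, 4])))
    pieces <- lapply(1:5, function(i)
      cg_rect(pa_rects[i, 1], pa_rects[i, 2], pa_rects[i, 3], pa_rects[i, 4]))
    got <- count_species_overlapping(pieces, ranges)
    # oracle: a species counts when it overlaps any PA by positive area
    oracle <- sum(vapply(1:20, function(i)
      any(vapply(1:5, function(j)
        rect_overlap_km2(sp_rects[i, ], pa_rects[j, ]), 0) > 1e-6), NA))
    expect_equal(got, oracle)
  }
})

test_that("accepted rigid placements conserve area and stay contained", {
  set.seed(61)
  eco <- cg_rect(0, 0, 40000, 40000)
  piece <- protgap:::make_blob(c(0, 0), 20, 0.5)
  a0 <- cg_area(piece)
  cfg <- placement_config(seed = 1)
  for (i in 1:100) {
    res <- random_rigid_placement(piece, eco, cfg)
    expect_false(res$fallback)
    expect_lt(abs(cg_area(res$geometry) - a0) / a0, 1e-9)
    expect_lt(cg_area(cg_difference(res$geometry, eco)), 1e-9)
  }
  expect_error(random_rigid_placement(structure(list(), class = "cgeom"),
                                      eco, cfg), "degenerate")
})

test_that("oversized pieces fall back to a clipped best candidate", {
  set.seed(62)
  eco <- cg_rect(0, 0, 5000, 5000)
  # piece as large as the ecoregion but rotated shapes cannot fit fully
  piece <- cg_polygon(rbind(c(0, 0), c(4900, 0), c(4900, 4900), c(0, 4900)))
  res <- random_rigid_placement(piece, eco, placement_config(max_tries = 20))
  expect_true(res$fallback)
  expect_lt(cg_area(cg_difference(res$geometry, eco)), 1e-9)
})

test_that("saturated and empty ecoregions classify as equal", {
  eco <- data.frame(ecoregion_id = "e1", area_km2 = 100,
                    stringsAsFactors = FALSE)
  eco$geometry <- list(cg_rect(0, 0, 10000, 10000))
  pieces <- pa_df(list(cg_rect(2000, 2000, 3000, 3000)))
  pieces$ecoregion_id <- "e1"
  # the single range covers the whole ecoregion: every draw counts it
  ranges <- range_df(list(cg_rect(0, 0, 10000, 10000)))
  nm <- run_null_model(pieces, ranges, eco, placement_config(50, seed = 2))
  expect_equal(nm$results$observed, 1L)
  expect_true(all(nm$null_counts$e1 == 1L))
  expect_equal(nm$results$classification, "equal")
  # no species at all
  nm0 <- run_null_model(pieces, ranges[0, ], eco,
                        placement_config(50, seed = 2))
  expect_equal(nm0$results$observed, 0L)
  expect_true(all(nm0$null_counts$e1 == 0L))
  expect_equal(nm0$results$classification, "equal")
})

test_that("identical seeds reproduce null counts exactly", {
  w <- light_world()
  pieces <- prepare_protected(w$protected, w$ecoregions)
  a <- run_null_model(pieces, w$ranges, w$ecoregions,
                      placement_config(30, seed = 99))
  b <- run_null_model(pieces, w$ranges, w$ecoregions,
                      placement_config(30, seed = 99))
  expect_identical(a$null_counts, b$null_counts)
  expect_identical(a$results, b$results)
  c <- run_null_model(pieces, w$ranges, w$ecoregions,
                      placement_config(30, seed = 100))
  expect_false(identical(a$null_counts, c$null_counts))
})

test_that("adding a species that intersects nothing changes no counts", {
  w <- light_world()
  pieces <- prepare_protected(w$protected, w$ecoregions)
  a <- run_null_model(pieces, w$ranges, w$ecoregions,
                      placement_config(20, seed = 5))
  far <- range_df(list(cg_rect(5e5, 5e5, 5.1e5, 5.1e5)), ids = "spFAR")
  aug <- rbind(w$ranges, far)
  b <- run_null_model(pieces, aug, w$ecoregions,
                      placement_config(20, seed = 5))
  expect_identical(a$null_counts, b$null_counts)
  expect_identical(a$results$observed, b$results$observed)
})

test_that("null-model summary percentages sum to 100", {
  mk <- function(cls) {
    structure(list(results = data.frame(classification = cls),
                   config = placement_config(1)), class = "pa_null_model")
  }
  s <- summary(mk(c("better", "worse", "worse", "equal")))
  expect_equal(c(s$pct_better, s$pct_equal, s$pct_worse), c(25, 25, 50))
  s2 <- summary(mk(rep("equal", 3)))
  expect_equal(c(s2$pct_better, s2$pct_equal, s2$pct_worse), c(0, 100, 0))
})

test_that("richness grid counts species per pixel", {
  # one species covering the whole extent: every pixel is 1
  ranges <- range_df(list(cg_rect(0, 0, 10000, 10000)))
  rg <- richness_grid(ranges, pixel_area_km2 = 5,
                      extent = c(0, 0, 10000, 10000))
  expect_true(all(rg$values == 1L))
  expect_equal(rg$cell_size, sqrt(5) * 1000)
  # rectangle oracle: per-pixel counts from analytic overlaps
  set.seed(71)
  sp_rects <- cbind(runif(6, 0, 8000), runif(6, 0, 8000), 0, 0)
  sp_rects[, 3] <- sp_rects[, 1] + runif(6, 1000, 4000)
  sp_rects[, 4] <- sp_rects[, 2] + runif(6, 1000, 4000)
  ranges2 <- range_df(lapply(1:6, function(i)
    cg_rect(sp_rects[i, 1], sp_rects[i, 2], sp_rects[i, 3], sp_rects[i, 4])))
  rg2 <- richness_grid(ranges2, pixel_area_km2 = 4,
                       extent = c(0, 0, 10000, 10000))
  side <- 2000
  nx <- ncol(rg2$values); ny <- nrow(rg2$values)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    px <- c((i - 1) * side, (ny - j) * side, i * side, (ny - j + 1) * side)
    oracle <- sum(vapply(1:6, function(s)
      rect_overlap_km2(sp_rects[s, ], px), 0) > 1e-6)
    expect_equal(rg2$values[j, i], oracle)
  }
})
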