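test_that("tier map splits a half/half study area with no overlap", {
  boundary <- cg_rect(0, 0, 10000, 10000)
  protected <- pa_df(list(cg_rect(0, 0, 5000, 10000)))
  public <- rect_layer(rbind(c(5000, 0, 10000, 10000)),
                       data.frame(agency = "USFS"))
  empty <- rect_layer(matrix(numeric(0), 0, 4), data.frame())
  tm <- build_tier_map(protected, empty, public, boundary)
  a <- tier_areas(tm)
  expect_equal(unname(a["PROTECTED_GAP12"]), 50)
  expect_equal(unname(a["USFS_BLM"]), 50)
  expect_equal(unname(a["PRIVATE_OTHER"]), 0, tolerance = 1e-9)
  expect_lt(cg_intersection_area(tm$tiers$PROTECTED_GAP12,
                                 tm$tiers$USFS_BLM), 1e-6)
})

test_that("precedence empties lower tiers under higher ones", {
  boundary <- cg_rect(0, 0, 10000, 10000)
  protected <- pa_df(list(cg_rect(2000, 2000, 8000, 8000)),
                     gap_status = 2L)
  public <- rect_layer(rbind(c(3000, 3000, 6000, 6000)),   # inside GAP-2
                       data.frame(agency = "USFS"))
  empty <- rect_layer(matrix(numeric(0), 0, 4), data.frame())
  tm <- build_tier_map(protected, empty, public, boundary)
  expect_lt(cg_area(tm$tiers$USFS_BLM), 1e-9)
})

test_that("random overlapping layers still partition the study area", {
  set.seed(81)
  boundary <- cg_rect(0, 0, 10000, 10000)
  rand_rects <- function(n, wmax = 4000) {
    r <- cbind(runif(n, 0, 9000), runif(n, 0, 9000), 0, 0)
    r[, 3] <- pmin(10000, r[, 1] + runif(n, 1000, wmax))
    r[, 4] <- pmin(10000, r[, 2] + runif(n, 1000, wmax))
    r
  }
  protected <- pa_df(lapply(1:4, function(i) {
    r <- rand_rects(1); cg_rect(r[1], r[2], r[3], r[4])
  }))
  eas <- rect_layer(rand_rects(3), data.frame(id = 1:3))
  pub <- rect_layer(rand_rects(6),
                    data.frame(agency = rep(c("USFS", "DOD", "STATE"), 2)))
  tm <- build_tier_map(protected, eas, pub, boundary)
  expect_lt(abs(sum(tier_areas(tm)) - 100) / 100, 1e-4)
  # pairwise exclusivity of the vector tiers plus the private mask
  geoms <- c(tm$tiers, list(PRIV = tm$private_mask))
  for (i in seq_along(geoms)) for (j in seq_along(geoms)) {
    if (i < j)
      expect_lt(cg_intersection_area(geoms[[i]], geoms[[j]]), 1e-6)
  }
})

test_that("a fully protected range is adequate at the first tier", {
  boundary <- cg_rect(0, 0, 10000, 10000)
  protected <- pa_df(list(cg_rect(0, 0, 5000, 10000)))
  empty <- rect_layer(matrix(numeric(0), 0, 4), data.frame())
  tm <- build_tier_map(protected, empty, empty, boundary)
  rg <- range_df(list(cg_rect(1000, 1000, 3000, 3000)))
  rec <- coverage_for_species(rg[1, ], tm)
  expect_equal(rec$pct_PROTECTED_GAP12, 100)
  expect_equal(rec$earliest_adequate_tier, "PROTECTED_GAP12")
  expect_equal(rec$cum_PRIVATE_OTHER, 100)
})

test_that("a sparsely protected range can reach adequacy on public land", {
  # 1.9% of the range in highly protected land and 51.4% in other federal
  # land: the cascade crosses 30% at OTHER_FEDERAL
  boundary <- cg_rect(0, 0, 20000, 20000)
  # range: 10 x 10 km = 100 km2
  rg <- range_df(list(cg_rect(0, 0, 10000, 10000)))
  protected <- pa_df(list(cg_rect(0, 0, 1900, 1000)))        # 1.9 km2
  pub <- rect_layer(rbind(c(0, 2000, 10000, 7140)),          # 51.4 km2
                    data.frame(agency = "DOD"))
  empty <- rect_layer(matrix(numeric(0), 0, 4), data.frame())
  tm <- build_tier_map(protected, empty, pub, boundary)
  rec <- coverage_for_species(rg[1, ], tm)
  expect_equal(rec$pct_PROTECTED_GAP12, 1.9, tolerance = 1e-9)
  expect_equal(rec$pct_OTHER_FEDERAL, 51.4, tolerance = 1e-9)
  expect_lt(rec$cum_USFS_BLM, 30)
  expect_gte(rec$cum_OTHER_FEDERAL, 30)
  expect_equal(rec$earliest_adequate_tier, "OTHER_FEDERAL")
})

test_that("exactly 30 percent counts as adequate (inclusive boundary)", {
  boundary <- cg_rect(0, 0, 10000, 10000)
  rg <- range_df(list(cg_rect(0, 0, 10000, 10000)))  # 100 km2
  protected <- pa_df(list(cg_rect(0, 0, 3000, 10000)))  # exactly 30 km2
  empty <- rect_layer(matrix(numeric(0), 0, 4), data.frame())
  tm <- build_tier_map(protected, empty, empty, boundary)
  cov_in <- tier_coverage(rg, tm, threshold = 30, inclusive = TRUE)
  expect_equal(count_adequate(cov_in, "PROTECTED_GAP12"), 1L)
  expect_equal(cov_in$records$earliest_adequate_tier, "PROTECTED_GAP12")
  cov_ex <- tier_coverage(rg, tm, threshold = 30, inclusive = FALSE)
  expect_equal(count_adequate(cov_ex, "PROTECTED_GAP12"), 0L)
  expect_error(count_adequate(cov_in, "NO_SUCH_TIER"), "unknown tier")
})

test_that("cumulative coverage is monotone and adequacy counts cascade", {
  w <- light_world()
  pieces <- prepare_protected(w$protected, w$ecoregions)
  tm <- build_tier_map(pieces, w$easements, w$public, w$boundary,
                       w$landcover, undeveloped_rule(c(21L, 82L)))
  cov <- tier_coverage(w$ranges, tm)
  cums <- as.matrix(cov$records[, paste0("cum_", tier_order())])
  expect_true(all(diff(t(cums)) > -1e-9))
  expect_true(all(abs(cums[, ncol(cums)] - 100) < 0.01))
  counts <- vapply(tier_order(), function(t) count_adequate(cov, t), 0L)
  expect_true(all(diff(counts) >= 0L))
})

test_that("class summary equals an independent group-by mean", {
  boundary <- cg_rect(0, 0, 10000, 10000)
  protected <- pa_df(list(cg_rect(0, 0, 5000, 10000)))
  empty <- rect_layer(matrix(numeric(0), 0, 4), data.frame())
  tm <- build_tier_map(protected, empty, empty, boundary)
  # two birds: one fully inside the protected half, one fully outside
  rg <- range_df(list(cg_rect(0, 0, 2000, 2000),
                      cg_rect(6000, 6000, 8000, 8000)),
                 classes = c("bird", "bird"))
  cov <- tier_coverage(rg, tm)
  cs <- class_summary(cov)
  got <- cs$mean_pct[cs$tetrapod_class == "bird" &
                     cs$tier_id == "PROTECTED_GAP12"]
  expect_equal(got, 50)
  # and against aggregate() on a generated world
  w <- light_world()
  pieces <- prepare_protected(w$protected, w$ecoregions)
  tmw <- build_tier_map(pieces, w$easements, w$public, w$boundary,
                        w$landcover, undeveloped_rule(c(21L, 82L)))
  covw <- tier_coverage(w$ranges, tmw)
  csw <- class_summary(covw)
  for (t in tier_order()) {
    ag <- aggregate(covw$records[[paste0("pct_", t)]],
                    list(covw$records$tetrapod_class), mean)
    for (k in seq_len(nrow(ag)))
      expect_equal(csw$mean_pct[csw$tetrapod_class == ag[k, 1] &
                                csw$tier_id == t], ag[k, 2])
  }
})

test_that("tier percentages agree with a Monte-Carlo point oracle", {
  set.seed(91)
  w <- light_world()
  pieces <- prepare_protected(w$protected, w$ecoregions)
  tm <- build_tier_map(pieces, w$easements, w$public, w$boundary)
  idx <- sample(nrow(w$ranges), 3)
  for (i in idx) {
    rg <- w$ranges[i, , drop = FALSE]
    rec <- coverage_for_species(rg, tm)
    bb <- cg_bbox(rg$geometry[[1]])
    n <- 1e5
    pts <- cbind(runif(n, bb["xmin"], bb["xmax"]),
                 runif(n, bb["ymin"], bb["ymax"]))
    in_range <- cg_contains(rg$geometry[[1]], pts)
    pin <- pts[in_range, , drop = FALSE]
    for (t in c("PROTECTED_GAP12", "USFS_BLM", "STATE")) {
      p <- mean(cg_contains(tm$tiers[[t]], pin))
      se <- sqrt(max(p * (1 - p), 1e-8) / nrow(pin)) * 100
      expect_lt(abs(rec[[paste0("pct_", t)]] - p * 100), 3 * se + 1e-6)
    }
  }
})
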