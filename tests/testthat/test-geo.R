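test_that("Jenks breaks isolate separated clusters and validate input", {
  v <- c(1, 1, 1, 10, 10, 100)
  br <- jenks_breaks(v, 3)
  cls <- findInterval(v, br, left.open = TRUE) + 1
  expect_equal(cls, c(1, 1, 1, 2, 2, 3))

  expect_equal(jenks_breaks(v, 1), numeric(0))
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
})

test_that("Jenks equals the exhaustive-search optimum (spot checks)", {
  set.seed(50)
  for (i in 1:25) {
    n <- sample(5:12, 1); k <- sample(2:4, 1)
    if (k > n) next
    v <- round(stats::runif(n, 0, 100), 1)
    if (length(unique(v)) < k) next
    br <- jenks_breaks(v, k)
    expect_equal(jenks_ss_of_breaks(v, br), oracle_jenks_ss(v, k),
                 tolerance = 1e-9)
  }
})

test_that("classification uses half-open intervals with lower-class ties", {
  r <- tiny_raster(vals = matrix(c(0.1, 0.3, 0.3, 0.5, 0.7, 0.9), 2, 3))
  cm <- classify_suitability(r, c(0.3, 0.7))
  expect_equal(as.vector(cm$classes), c(1, 1, 1, 2, 2, 3))

  r$values[1, 1] <- NA
  cmna <- classify_suitability(r, c(0.3, 0.7))
  expect_true(is.na(cmna$classes[1, 1]))

  expect_error(classify_suitability(r, c(0.7, 0.3)), "increasing")

  # class counts equal histogram counts over the same intervals
  set.seed(51)
  rv <- tiny_raster(nr = 10, nc = 10,
                    vals = matrix(stats::runif(100), 10, 10))
  br <- c(0.33, 0.66)
  cm2 <- classify_suitability(rv, br)
  hist_counts <- as.vector(table(cut(rv$values, c(-Inf, br, Inf))))
  expect_equal(as.vector(table(cm2$classes)), hist_counts)

  # everything below the first break: all unsuitable
  low <- classify_suitability(tiny_raster(vals = matrix(0.01, 2, 2)), c(0.5, 0.9))
  expect_true(all(low$classes == 1))
})

test_that("spherical cell areas conserve the sphere and match closed forms", {
  # 1x1 degree cell at the equator
  eq <- env_raster(matrix(0, 1, 1), 0, 0, 1)
  expect_equal(cell_area_km2(eq), 12363.7, tolerance = 1e-4)

  # full-sphere partition sums to 4 pi R^2
  sphere <- env_raster(matrix(0, 180, 360), -180, -90, 1)
  total <- sum(cell_area_km2(sphere)) * 360
  expect_equal(total, 4 * pi * 6371.0088^2, tolerance = 1e-6)

  # polar cells are smaller than equatorial ones
  band <- env_raster(matrix(0, 180, 1), 0, -90, 1)
  areas <- cell_area_km2(band)
  expect_lt(areas[1], areas[90])
  expect_error(cell_area_km2(env_raster(matrix(0, 2, 2), 0, 89.5, 1)),
               "latitude")
})

test_that("regional summaries count cells where their centers fall", {
  r <- tiny_raster(nr = 4, nc = 4, xll = 0, yll = 0, cs = 1,
                   vals = matrix(c(rep(0.1, 8), rep(0.9, 8)), 4, 4))
  cm <- classify_suitability(r, c(0.3, 0.95), labels = c("unsuitable", "low", "high"))
  regs <- generate_regions(c(xmin = 0, xmax = 4, ymin = 0, ymax = 4), 2, 2)
  rs <- regional_summary(cm, regs)
  # left half (cols 1-2) is class 1, right half class 2; each region holds 4 cells
  areas_by_region <- tapply(rs$area_km2, rs$region_id, sum)
  # east and west regions in the same latitude band hold equal area
  expect_equal(areas_by_region[["SP01"]], areas_by_region[["SP02"]])
  expect_equal(areas_by_region[["SP03"]], areas_by_region[["SP04"]])
  # conservation: totals over regions match the global class areas
  cellA <- rep(cell_area_km2(cm), times = 4)
  global <- tapply(cellA, as.vector(cm$classes), sum)
  totals <- attr(rs, "class_totals")
  expect_equal(unname(totals[["unsuitable"]]), unname(global[["1"]]))
  expect_equal(unname(totals[["low"]]), unname(global[["2"]]))
  expect_equal(unname(totals[["high"]]), 0)

  # single all-covering region reproduces global totals
  one <- region_set("ALL", list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))))
  rs1 <- regional_summary(cm, one)
  expect_equal(sum(rs1$area_km2), sum(cellA))

  # region with no cells: zeros
  far <- region_set(c("A", "B"),
                    list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)),
                         cbind(c(10, 11, 11, 10), c(10, 10, 11, 11))))
  rsf <- regional_summary(cm, far)
  expect_equal(sum(rsf$area_km2[rsf$region_id == "B"]), 0)
})

test_that("per-class area shares are percentages of the classified total", {
  s <- data.frame(region_id = "X", class = c("unsuitable", "low", "high"),
                  area_km2 = c(70, 20, 10))
  sh <- area_shares(s)
  expect_equal(unname(sh), c(70, 20, 10))
  expect_equal(sum(sh), 100)
})

test_that("class centroids are area-weighted cell-center means", {
  r <- tiny_raster(nr = 1, nc = 3, xll = 0, yll = 0, cs = 1,
                   vals = matrix(c(0.9, 0.1, 0.9), 1, 3))
  cm <- classify_suitability(r, c(0.5))
  # single-class single-cell centroid is that cell center
  one <- classify_suitability(tiny_raster(nr = 1, nc = 1, xll = 10, yll = 20,
                                          vals = matrix(0.9, 1, 1)), c(0.5))
  expect_equal(class_centroid(one, 2), c(lon = 10.5, lat = 20.5))
  # two cells symmetric about lon 1.5 (same latitude band: equal areas)
  cen <- class_centroid(cm, 2)
  expect_equal(unname(cen[["lon"]]), 1.5)
  expect_error(class_centroid(cm, 99), "empty")

  # hand-computed weighted mean over rows with different areas
  r2 <- env_raster(matrix(c(0.9, 0.9, 0.9, 0.1), 2, 2), 0, 60, 1)
  cm2 <- classify_suitability(r2, 0.5)
  a <- cell_area_km2(cm2)
  sel <- which(cm2$classes == 2)  # cells (1,1),(2,1),(1,2) col-major
  lons <- c(0.5, 0.5, 1.5); lats <- c(61.5, 60.5, 61.5)
  wts <- a[c(1, 2, 1)]
  expect_equal(class_centroid(cm2, 2),
               c(lon = sum(lons * wts) / sum(wts),
                 lat = sum(lats * wts) / sum(wts)))
})

test_that("centroid shifts use the haversine on the authalic sphere", {
  same <- centroid_shift(c(100, 30), c(100, 30))
  expect_equal(same$distance_km, 0)
  expect_equal(same$direction, "none")

  quarter <- centroid_shift(c(0, 0), c(90, 0))
  expect_equal(quarter$distance_km, 2 * pi * 6371.0088 / 4, tolerance = 1e-6)
  expect_equal(quarter$direction, "eastward")

  a <- centroid_shift(c(97, 33), c(98.2, 32.1))
  b <- centroid_shift(c(98.2, 32.1), c(97, 33))
  expect_equal(a$distance_km, b$distance_km)
  expect_equal(a$direction, "southeastward")
})

test_that("change summaries report absolute and percent differences", {
  s1 <- data.frame(region_id = "X", class = c("unsuitable", "low", "high"),
                   area_km2 = c(100, 100, 0))
  s2 <- data.frame(region_id = "X", class = c("unsuitable", "low", "high"),
                   area_km2 = c(100, 50, 30))
  ch <- change_summary(s1, s2)
  expect_equal(ch$change_pct[ch$class == "unsuitable"], 0)
  expect_equal(ch$change_pct[ch$class == "low"], -50)
  expect_true(is.na(ch$change_pct[ch$class == "high"]))
  expect_equal(ch$change_km2, c(0, -50, 30))

  expect_equal(change_summary(s1, s1)$change_pct[1:2], c(0, 0))
})
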