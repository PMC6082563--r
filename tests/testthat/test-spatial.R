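test_that("hex grid geometry and validation", {
  g <- build_hex_grid(c(0, 0, 1000, 1000), side = 40)
  expect_equal(g$tile_area, 3 * sqrt(3) / 2 * 40^2)
  expect_error(build_hex_grid(c(0, 0, 0, 1000), side = 40), "degenerate")
  expect_error(build_hex_grid(c(0, 0, 100, 100), side = -1), "positive")
  expect_error(build_hex_grid(c(0, 0, 100, 100), side = 0), "positive")
  # tiles jointly cover at least the bbox area, without gross excess
  expect_gte(nrow(g$tiles) * g$tile_area, 1000 * 1000)
})

test_that("tile count matches the area-based expectation", {
  g <- build_hex_grid(c(0, 0, 2000, 2000), side = 40)
  n_exp <- 2000 * 2000 / (3 * sqrt(3) / 2 * 40^2)       # ~962 interior tiles
  # one boundary ring: tiles cut by the perimeter
  ring <- 2 * 2000 / (1.5 * 40) + 2 * 2000 / (sqrt(3) * 40) + 4
  expect_gte(nrow(g$tiles), n_exp)
  expect_lte(nrow(g$tiles), n_exp + 2 * ring)
})

test_that("hex assignment agrees with brute-force nearest-centre search", {
  g <- build_hex_grid(c(0, 0, 1000, 1000), side = 40)
  ev <- gen_uniform_points(10000, c(0, 0, 1000, 1000), seed = 71)
  cv <- assign_points_to_hexes(ev, g)
  expect_s3_class(cv, "count_vector")
  expect_equal(sum(cv$counts), 10000)
  oracle_idx <- nearest_centre_oracle(ev$x, ev$y, g$tiles$cx, g$tiles$cy)
  oracle_counts <- tabulate(oracle_idx, nbins = nrow(g$tiles))
  expect_identical(cv$counts, as.integer(oracle_counts))
})

test_that("hex assignment edge cases and policies", {
  g <- build_hex_grid(c(0, 0, 500, 500), side = 50)
  empty <- assign_points_to_hexes(data.frame(x = numeric(), y = numeric()), g)
  expect_true(all(empty$counts == 0))

  one <- assign_points_to_hexes(
    data.frame(x = g$tiles$cx[5], y = g$tiles$cy[5]), g)
  expect_equal(one$counts[5], 1L)
  expect_equal(sum(one$counts), 1L)

  out <- data.frame(x = c(100, 9999), y = c(100, 9999))
  expect_warning(cv <- assign_points_to_hexes(out, g), "dropped")
  expect_equal(sum(cv$counts), 1L)
  expect_equal(attr(cv, "n_dropped"), 1L)
  expect_error(assign_points_to_hexes(out, g, strict = TRUE), "strict")
})

test_that("translation consistency: shifting points and origin together", {
  bbox <- c(0, 0, 800, 600)
  ev <- gen_uniform_points(2000, bbox, seed = 13)
  g1 <- build_hex_grid(bbox, side = 35)
  shift <- c(12345.6, -987.3)
  g2 <- build_hex_grid(bbox + shift[c(1, 2, 1, 2)], side = 35,
                       origin = g1$origin + shift)
  ev2 <- data.frame(x = ev$x + shift[1], y = ev$y + shift[2])
  expect_identical(assign_points_to_hexes(ev, g1)$counts,
                   assign_points_to_hexes(ev2, g2)$counts)
})

test_that("road segmentation bins kilometre-posts", {
  # 121 km at 500 m -> 242 units
  cv <- segment_road(numeric(), road_length = 121)
  expect_equal(cv$n_units, 242L)
  expect_true(all(cv$counts == 0))

  cv <- segment_road(c(0.1, 0.4, 0.6), road_length = 1)
  expect_equal(cv$counts, c(2L, 1L))

  # half-open [a, b): a post exactly at 0.5 km belongs to segment 2;
  # the road end belongs to the last segment
  cv <- segment_road(c(0.5, 1.0), road_length = 1)
  expect_equal(cv$counts, c(0L, 2L))

  expect_warning(cv <- segment_road(c(0.5, -1, 2), road_length = 1), "dropped")
  expect_equal(sum(cv$counts), 1L)
  expect_error(segment_road(c(-1), road_length = 1, strict = TRUE), "strict")
  expect_error(segment_road(1, road_length = 0), "positive")
})

test_that("count conservation holds on both discretisation paths", {
  set.seed(29)
  for (rep in 1:5) {
    n <- sample(50:500, 1)
    bbox <- c(0, 0, runif(1, 200, 2000), runif(1, 200, 2000))
    ev <- gen_uniform_points(n, bbox)
    g <- build_hex_grid(bbox, side = runif(1, 20, 80))
    expect_equal(sum(assign_points_to_hexes(ev, g)$counts), n)
    len <- runif(1, 5, 100)
    km <- runif(n, 0, len)
    expect_equal(sum(segment_road(km, road_length = len)$counts), n)
  }
})

test_that("CSR test statistics and edge cases", {
  # coincident points: zero NN distance, certain rejection
  ev <- data.frame(x = rep(1, 10), y = rep(1, 10))
  tst <- nearest_neighbour_csr_test(ev, region_area = 1, bbox = c(0, 0, 1, 1),
                                    n_sims = 99, seed = 2)
  expect_equal(tst$R, 0)
  expect_lte(tst$p_value, 0.05)

  expect_error(nearest_neighbour_csr_test(data.frame(x = 1, y = 1)),
               "at least 2")

  # large uniform pattern: ratio near 1 (mild edge-effect inflation)
  ev <- gen_uniform_points(2000, c(0, 0, 1, 1), seed = 8)
  tst <- nearest_neighbour_csr_test(ev, region_area = 1, bbox = c(0, 0, 1, 1),
                                    n_sims = 0)
  expect_gt(tst$R, 0.9)
  expect_lt(tst$R, 1.15)
  expect_identical(tst$null, "normal approximation (Clark-Evans)")
})

test_that("mean NN distance matches the brute-force oracle", {
  set.seed(17)
  for (rep in 1:3) {
    n <- sample(10:60, 1)
    x <- runif(n); y <- runif(n)
    expect_equal(rareconc:::mean_nn_distance(x, y), nn_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("clustered patterns are detected against the MC envelope", {
  set.seed(91)
  cl <- sample(1:2, 100, replace = TRUE)
  ev <- data.frame(x = c(0.25, 0.75)[cl] + rnorm(100, 0, 0.02),
                   y = c(0.25, 0.75)[cl] + rnorm(100, 0, 0.02))
  tst <- nearest_neighbour_csr_test(ev, region_area = 1, bbox = c(0, 0, 1, 1),
                                    n_sims = 99, seed = 5)
  expect_lt(tst$R, 1)
  expect_lte(tst$p_value, 0.05)
  # MC p-value is a valid achievable p: bounded below by 1/(n_sims+1)
  expect_gte(tst$p_value, 1 / 100)
})
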