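# Synthetic-data generator: shapes, populations, swim-up counts, midpieces.

test_that("generated shapes are valid, deterministic, apex-unique", {
  o <- generate_shape(seed = 1)
  v <- outline_verts(o)
  expect_gte(nrow(v), 200)
  expect_gt(spermshape:::signed_area(v), 0)  # counterclockwise
  expect_true(spermshape:::is_simple_polygon(v))
  # determinism
  expect_identical(outline_verts(generate_shape(seed = 1)), v)
  expect_false(identical(outline_verts(generate_shape(seed = 2)), v))
  # exactly one global minimum of the profile, at the planted hook tip
  pr <- angle_profile(o)
  expect_equal(sum(pr$angles == min(pr$angles)), 1)
  expect_lte(min(which.min(pr$angles) - 1, 100 - which.min(pr$angles) + 1), 3)
  # parameter validation
  expect_error(generate_shape(shape_params(body_length = -1)), "positive")
  expect_error(shape_params(area_scale = 0), "area_scale")
})

test_that("vanishing hook gives a smooth ellipse-like outline with no sharp angle", {
  o <- generate_shape(shape_params(hook_length = 1e-9), seed = 1)
  pr <- angle_profile(o)
  expect_gt(min(pr$angles), 100)
})

test_that("population generator: exchangeable WT sexes, planted YQDEL shifts, validation", {
  # null: X and Y identically distributed in WT (KS p > 0.01 nearly always)
  ks_ps <- replicate(60, {
    pop <- generate_population(population_spec("WT", 500, seed = sample.int(1e6, 1)),
                               make_outlines = FALSE)
    with(pop$cells, ks_two_sample(acrosome_curvature[sex == "X"],
                                  acrosome_curvature[sex == "Y"])$p)
  })
  expect_gte(mean(ks_ps > 0.01), 0.95)
  # planted effect: Y curvature mean exceeds X mean
  pop <- generate_population(population_spec(
    "YQDEL", 500, seed = 3, sex_effect = c(acrosome_curvature = 0.44)),
    make_outlines = FALSE)
  mx <- with(pop$cells, tapply(acrosome_curvature, sex, mean))
  expect_gt(mx["Y"], mx["X"])
  # monotonicity: larger sex_effect -> larger Y-vs-X difference
  gaps <- vapply(c(0.1, 0.3, 0.6), function(eff) {
    p <- generate_population(population_spec(
      "YQDEL", 2000, seed = 11, sex_effect = c(acrosome_curvature = eff)),
      make_outlines = FALSE)
    diff(with(p$cells, tapply(acrosome_curvature, sex, mean))[c("X", "Y")])
  }, 0)
  expect_true(all(diff(gaps) > 0))
  expect_error(population_spec("WT", 0), "n_cells")
  expect_error(population_spec("WT", sex_effect = c(bogus = 1)), "unknown shape parameter")
  # determinism of the whole population
  a <- generate_population(population_spec("YQDEL", 20, seed = 9))
  b <- generate_population(population_spec("YQDEL", 20, seed = 9))
  expect_identical(a$cells, b$cells)
  expect_identical(outline_verts(a$outlines[[7]]), outline_verts(b$outlines[[7]]))
})

test_that("rasterization: analytic disc area, determinism, error cases", {
  disc <- circle_outline(r = 5, n = 300, centre = c(6, 6))
  img <- rasterize(disc, pixel_size = 0.1, blur_sd = 0, noise_sd = 0,
                   dims = c(120, 120), seed = 1)
  expect_s3_class(img, "gray_image")
  masks <- segment_nuclei(img, threshold_method = "fixed", threshold = 0.5,
                          min_area = 10, max_area = 1000)
  expect_length(masks, 1)
  area_px <- sum(masks[[1]]) * 0.1^2
  expect_equal(area_px, pi * 25, tolerance = 0.01 * pi * 25)
  # determinism with noise
  i1 <- rasterize(disc, pixel_size = 0.1, noise_sd = 0.05, dims = c(120, 120), seed = 7)
  i2 <- rasterize(disc, pixel_size = 0.1, noise_sd = 0.05, dims = c(120, 120), seed = 7)
  expect_identical(unclass(i1), unclass(i2))
  # blank outline and canvas overflow
  expect_error(rasterize(list(), seed = 1))
  expect_error(rasterize(disc, pixel_size = 0.1, dims = c(50, 50), origin = c(0, 0)),
               "canvas")
})

test_that("round trip segment -> extract_outline recovers the polygon area within 2%", {
  for (s in c(5, 21)) {
    o <- generate_shape(seed = s)
    img <- rasterize(o, pixel_size = 0.1, seed = s)
    masks <- segment_nuclei(img, min_area = 5, max_area = 200)
    expect_length(masks, 1)
    back <- extract_outline(masks[[1]])
    expect_equal(polygon_area(back), polygon_area(o),
                 tolerance = 0.02, info = sprintf("seed %d", s))
  }
})

test_that("swim-up counts: bounds, null centre, planted monotone trend", {
  null_tab <- generate_swimup_counts(swimup_spec(
    n_males = 10, genotypes = "WT", logit_slope_per_fraction = c(WT = 0),
    logit_intercept = 0, male_sd = 0, states = "live", seed = 2))
  ktot <- sum(null_tab$x_count); ntot <- sum(null_tab$x_count + null_tab$y_count)
  expect_lt(abs(ktot / ntot - 0.5), 3 * se_proportion(round(ntot / 2), ntot))
  expect_true(all(null_tab$x_count >= 0 & null_tab$x_count <= 400))
  # structure: one row per male x state x fraction
  tab <- generate_swimup_counts(swimup_spec(n_males = 3, seed = 1))
  expect_equal(nrow(tab), 2 * 3 * 2 * 6)
  # killed rows have no trend; live YQDEL rows climb
  agg <- function(d) tapply(d$x_count / (d$x_count + d$y_count), d$fraction, mean)
  # Monte-Carlo: mean X proportion essentially non-decreasing with slope +0.15
  bad <- replicate(50, {
    t1 <- generate_swimup_counts(swimup_spec(
      n_males = 10, genotypes = "YQDEL",
      logit_slope_per_fraction = c(YQDEL = 0.15),
      states = "live", seed = sample.int(1e6, 1)))
    sum(diff(agg(t1)) < 0)
  })
  expect_true(all(bad <= 1))  # at most one inversion per dataset at these n
  expect_error(swimup_spec(n_males = 0), "must be > 0")
  expect_error(swimup_spec(genotypes = "XX"), "no slope")
})

test_that("midpiece lengths: null KS calibration and planted-shift power", {
  ps <- vapply(1:200, function(s) {
    smp <- generate_midpiece_lengths(400, 400, shift = 0, seed = s)
    ks_two_sample(smp$top, smp$bottom)$p
  }, 0)
  expect_lte(mean(ps < 0.01), 0.035)  # nominal 1% with binomial noise
  hits <- vapply(1:100, function(s) {
    smp <- generate_midpiece_lengths(400, 400, shift = 1.6, sd = 0.8, seed = s)
    ks_two_sample(smp$top, smp$bottom)$p < 0.01
  }, TRUE)
  expect_gt(mean(hits), 0.99)
  expect_error(generate_midpiece_lengths(0, 10), "must be > 0")
})

test_that("generator RNG is isolated from the caller's stream", {
  set.seed(123); before <- .Random.seed
  invisible(generate_shape(seed = 5))
  invisible(generate_swimup_counts(swimup_spec(n_males = 2, seed = 9)))
  expect_identical(.Random.seed, before)
})
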