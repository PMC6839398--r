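# Angle profiles, hook-apex anchoring, and morphometric parameters.

test_that("circle profile equals the inscribed-angle closed form for several windows", {
  circ <- circle_outline(r = 3, n = 600)
  for (f in c(0.02, 0.05, 0.1)) {
    pr <- angle_profile(circ, window_fraction = f, n_index = 100)
    expect_equal(pr$angles, rep(180 - 180 * f, 100), tolerance = 0.5 / 171,
                 info = sprintf("window %.2f", f))
  }
  expect_error(angle_profile(circ, window_fraction = 0.5), "antipode")
})

test_that("square profile: collinear mid-edge 180 deg, symmetric corner 90 deg", {
  sq <- dense_square(s = 4, per_edge = 100)
  pr <- angle_profile(sq, window_fraction = 0.02, n_index = 100)
  # 100 indices over 4 edges: corners at indices 1, 26, 51, 76; mid-edges between
  corners <- pr$angles[c(1, 26, 51, 76)]
  mids <- pr$angles[c(13, 38, 63, 88)]
  expect_equal(corners, rep(90, 4), tolerance = 0.02)
  expect_equal(mids, rep(180, 4), tolerance = 0.02)
})

test_that("profile is invariant to rotation, translation, scaling and stored orientation", {
  o <- generate_shape(seed = 4)
  ref <- angle_profile(o)$angles
  v <- outline_verts(o)
  moved <- outline(sweep(rotate_verts(v, 1.1), 2, c(5, -3), "+") * 2.7)
  expect_equal(angle_profile(moved)$angles, ref, tolerance = 1e-6)
  flipped <- outline(v[nrow(v):1, ])  # reversed input; canonicalized to CCW
  expect_equal(angle_profile(flipped)$angles, ref, tolerance = 1e-6)
})

test_that("signed turning over any closed simple outline sums to 360 degrees", {
  shapes <- list(circle_outline(2), ellipse_outline(3, 1),
                 generate_shape(seed = 1), generate_shape(seed = 9))
  for (o in shapes) {
    v <- outline_verts(smooth_resample(o, 400))
    n <- nrow(v)
    e <- v[c(2:n, 1), ] - v
    ang <- atan2(e[, 2], e[, 1])
    turn <- diff(c(ang, ang[1]))
    turn <- (turn + pi) %% (2 * pi) - pi
    expect_equal(sum(turn) * 180 / pi, 360, tolerance = 1e-6)
  }
})

test_that("hook apex: detection, rotation, ties and no-landmark flagging", {
  o <- generate_shape(seed = 6)
  pr <- detect_hook_apex(angle_profile(o))
  expect_true(pr$anchored)
  expect_equal(which.min(pr$angles), 1L)
  # the generator plants the apex at arc position 0 -> profile index 0
  expect_lte(min(pr$apex, 100 - pr$apex), 3)
  # synthetic rotation of the profile is undone
  raw <- angle_profile(o)
  shifted <- raw
  shifted$angles <- raw$angles[c(38:100, 1:37)]
  re <- detect_hook_apex(shifted)
  expect_equal(re$apex, which.min(shifted$angles) - 1L)
  expect_equal(min(re$angles), re$angles[1])
  expect_error(detect_hook_apex(angle_profile(circle_outline(1))), "no landmark")
})

test_that("apex detection survives rasterization and segmentation", {
  o <- generate_shape(seed = 11)
  img <- rasterize(o, pixel_size = 0.05, seed = 2)
  masks <- segment_nuclei(img, min_area = 5, max_area = 200)
  expect_length(masks, 1)
  oo <- extract_outline(masks[[1]])
  pr <- detect_hook_apex(angle_profile(oo))
  # the planted hook tip (vertex 1 of the generated outline, in physical
  # coordinates) must sit within +/- 3 profile indices of the detected apex
  # tip mapped into the image frame (rasterize shifts by its origin)
  tip <- outline_verts(o)[1, ] - attr(img, "origin")
  v <- outline_verts(oo)
  near <- which.min((v[, 1] - tip[1])^2 + (v[, 2] - tip[2])^2)
  tip_index <- round((near - 1) / nrow(v) * 100)
  delta <- abs(tip_index - pr$apex)
  expect_lte(min(delta, 100 - delta), 3)
})

test_that("morphometric parameters match analytic shapes", {
  circ <- morph_stats(circle_outline(r = 2, n = 720))
  expect_equal(circ$circularity, 1, tolerance = 0.005)
  expect_equal(circ$regularity, 1, tolerance = 0.005)
  sq <- morph_stats(smooth_resample(square_outline(3), 400))
  expect_equal(sq$circularity, pi / 4, tolerance = 0.01)
  ell <- morph_stats(ellipse_outline(a = 4, b = 2, n = 720))
  expect_equal(ell$length / ell$width, 2, tolerance = 0.02)
  expect_equal(ell$regularity, 1, tolerance = 0.02)
  expect_equal(ell$area, pi * 4 * 2, tolerance = 0.01 * pi * 8)
  # circularity <= 1 with equality only for the circle, over a shape battery
  battery <- c(lapply(1:5, function(s) generate_shape(seed = s)),
               list(ellipse_outline(3, 1), smooth_resample(square_outline(2), 200)))
  circs <- vapply(battery, function(o) morph_stats(o)$circularity, 0)
  expect_true(all(circs < 1))
  # self-intersecting input is rejected
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(morph_stats(structure(list(vertices = bowtie), class = "outline")),
               "self-intersecting")
})

test_that("X/Y comparison: null false-positive rate near nominal, planted effect found", {
  pnames <- shape_param_names()
  # null: WT populations, X and Y exchangeable
  flags <- replicate(60, {
    pop <- generate_population(population_spec("WT", 400, seed = sample.int(1e6, 1)),
                               make_outlines = FALSE)
    tab <- compare_xy(pop$cells, parameters = pnames, alpha = 0.01)
    any(tab$flag)
  })
  # familywise alpha 0.01 after Bonferroni: expect almost no flagged datasets
  expect_lte(mean(flags), 0.1)
  # power: planted curvature shift of ~1 SD flags acrosome_curvature
  hits <- replicate(20, {
    pop <- generate_population(population_spec(
      "YQDEL", 400, seed = sample.int(1e6, 1),
      sex_effect = c(acrosome_curvature = 0.35)), make_outlines = FALSE)
    tab <- compare_xy(pop$cells, parameters = pnames, alpha = 0.01)
    tab$flag[tab$parameter == "acrosome_curvature"]
  })
  expect_gte(mean(hits), 0.95)
  # degenerate constant measurements do not crash and give p = 1
  const <- data.frame(genotype = "WT", sex = rep(c("X", "Y"), each = 5), v = 1)
  expect_equal(compare_xy(const, parameters = "v")$p, 1)
  # missing label class errors
  onesex <- data.frame(genotype = "WT", sex = "X", v = rnorm(5))
  expect_error(compare_xy(onesex, parameters = "v"), "both sex labels")
})

test_that("profiles and morphometrics round-trip through the wide CSV", {
  pop <- generate_population(population_spec("WT", 5, seed = 2))
  profs <- lapply(pop$outlines, function(o) detect_hook_apex(angle_profile(o)))
  f <- tempfile(fileext = ".csv")
  write_profiles_csv(profs, pop$cells[, 1:3], f)
  back <- read_profiles_csv(f)
  expect_equal(back$profiles, unname(profile_matrix(pop)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$meta$id, pop$cells$id)
  unlink(f)
})
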