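# Capture/recapture: coordinate pairing, SSIM scoring, one-to-one matching.

make_slide <- function(n = 20, seed = 1, jitter = 0.5, shift = c(0, 0),
                       distort = TRUE) {
  # n nuclei at distinct stage positions; post images are the FISH-swollen
  # versions of the pre images at jittered coordinates
  set.seed(seed)
  centres <- expand.grid(x = seq(0, by = 40, length.out = ceiling(sqrt(n))),
                         y = seq(0, by = 40, length.out = ceiling(sqrt(n))))[1:n, ]
  pre <- list(); post <- list()
  for (i in seq_len(n)) {
    o <- generate_shape(seed = seed * 1000 + i)
    img <- rasterize(o, pixel_size = 0.1, dims = c(130, 130), seed = i)
    pre[[i]] <- captured_image(img, c(centres$x[i], centres$y[i]),
                               phase = "pre", id = sprintf("p%03d", i))
    pimg <- if (distort) fish_distort(img, seed = i + 5000) else unclass(img)
    post[[i]] <- captured_image(gray_image(pimg, 0.1),
                                c(centres$x[i], centres$y[i]) + shift +
                                  runif(2, -jitter, jitter),
                                phase = "post", id = sprintf("q%03d", i))
  }
  list(pre = pre, post = post)
}

test_that("coordinate pairing: exact, translated and empty-radius cases", {
  sl <- make_slide(n = 9, seed = 2, jitter = 0, distort = FALSE)
  cand <- pair_by_coordinates(sl$pre, sl$post, radius = 1)
  expect_equal(nrow(cand), 9)
  expect_true(all(cand$distance == 0))
  # uniform +2 um shift found at distance 2
  sl2 <- make_slide(n = 9, seed = 2, jitter = 0, shift = c(2, 0), distort = FALSE)
  cand2 <- pair_by_coordinates(sl2$pre, sl2$post, radius = 5)
  expect_true(all(abs(cand2$distance[cand2$pre_id == sub("q", "p", cand2$post_id)] - 2) < 1e-9))
  # zero radius with jittered coordinates: empty candidate set
  sl3 <- make_slide(n = 4, seed = 3, jitter = 0.5, distort = FALSE)
  expect_equal(nrow(pair_by_coordinates(sl3$pre, sl3$post, radius = 0)), 0)
  # mixed slides rejected
  bad <- sl$post
  bad[[1]]$slide_id <- "other"
  expect_error(pair_by_coordinates(sl$pre, bad, radius = 1), "mixed slides")
})

test_that("SSIM: identity, negative, noise, symmetry, intensity invariance", {
  img <- unclass(rasterize(generate_shape(seed = 5), pixel_size = 0.1,
                           dims = c(130, 130), seed = 5))
  expect_equal(ssim_score(img, img), 1, tolerance = 1e-9)
  expect_lt(ssim_score(img, 1 - img), 0.2)
  set.seed(8)
  n1 <- matrix(runif(64^2), 64, 64); n2 <- matrix(runif(64^2), 64, 64)
  expect_lt(abs(ssim_score(n1, n2, levels = 1)), 0.1)
  a <- img; b <- fish_distort(img, seed = 1)
  expect_equal(ssim_score(a, b), ssim_score(b, a), tolerance = 1e-12)
  # common affine intensity rescale barely moves the score
  expect_equal(ssim_score(img, pmin(img * 1.05 + 0.01, 1)),
               1, tolerance = 0.05)
  expect_error(ssim_score(img, img[1:50, 1:50]), "dimension mismatch")
})

test_that("greedy assignment is one-to-one, thresholded, and tie-broken by id", {
  cand <- data.frame(pre_id = c("p1", "p1", "p2"),
                     post_id = c("q1", "q2", "q1"),
                     distance = c(1, 1, 1),
                     similarity = c(0.9, 0.8, 0.85))
  m <- assign_matches(cand, min_similarity = 0.5)
  # best pair (p1, q1) blocks both alternatives: greedy leaves one match
  expect_equal(nrow(m), 1)
  expect_equal(m$pre_id, "p1")
  expect_equal(m$post_id, "q1")
  # unattainable threshold
  expect_equal(nrow(assign_matches(cand, min_similarity = 1.01)), 0)
  # equal similarity: lowest pre id wins the shared post image
  tie <- data.frame(pre_id = c("p2", "p1"), post_id = c("q1", "q1"),
                    distance = 0, similarity = 0.7)
  mt <- assign_matches(tie, min_similarity = 0.5)
  expect_equal(mt$pre_id, "p1")
  expect_error(assign_matches(tie[, 1:3]), "scored")
})

test_that("one-to-one-ness holds on adversarial candidate sets", {
  set.seed(13)
  for (rep in 1:20) {
    cand <- data.frame(
      pre_id = sample(sprintf("p%d", 1:6), 30, replace = TRUE),
      post_id = sample(sprintf("q%d", 1:6), 30, replace = TRUE),
      distance = runif(30, 0, 5), similarity = runif(30, -0.2, 1))
    cand <- cand[!duplicated(cand[, 1:2]), ]
    m <- assign_matches(cand, min_similarity = 0.3)
    expect_false(any(duplicated(m$pre_id)))
    expect_false(any(duplicated(m$post_id)))
    expect_true(all(m$similarity >= 0.3))
  }
})

test_that("capture/recapture re-identifies nearly all nuclei despite FISH swelling", {
  sl <- make_slide(n = 25, seed = 6, jitter = 3)
  cand <- pair_by_coordinates(sl$pre, sl$post, radius = 12)
  cand <- score_candidates(cand, sl$pre, sl$post)
  m <- assign_matches(cand, min_similarity = 0.2)
  correct <- sum(sub("p", "", m$pre_id) == sub("q", "", m$post_id))
  expect_gte(correct / 25, 0.95)
})
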