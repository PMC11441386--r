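test_that("binarization uses a strict inequality at the threshold", {
  img <- matrix(c(100L, 150L, 150L, 200L), 2, 2)
  m <- apply_threshold(img, 150)
  expect_identical(as.vector(unclass(m)), c(0L, 0L, 0L, 255L))

  any_img <- make_fixture("noise", c(16, 16), seed = 1)
  expect_true(all(unclass(apply_threshold(any_img, 255)) == 0L))
  expect_true(all(unclass(apply_threshold(any_img, -1)) == 255L))
  expect_true(all(unclass(apply_threshold(any_img, 127.5)) %in% c(0L, 255L)))
})

test_that("mean threshold is the real-valued pixel mean", {
  const <- matrix(77L, 5, 5)
  r <- mean_threshold(const)
  expect_equal(r$value, 77)
  expect_true(all(unclass(apply_threshold(const, r$value)) == 0L))

  expect_equal(mean_threshold(matrix(c(0L, 255L), 1))$value, 127.5)

  ramp <- make_fixture("ramp", c(16, 16))
  expect_equal(mean_threshold(ramp)$value, 127.5)
})

test_that("Otsu's threshold maximizes between-class variance (vs oracle)", {
  img <- matrix(as.integer(c(rep(40, 100), rep(200, 100))), 10, 20)
  r <- otsu_threshold(img)
  expect_gte(r$value, 40); expect_lte(r$value, 199)
  expect_identical(r$value, otsu_oracle(img))
  expect_length(r$objective_curve, 256)
  expect_equal(r$value, (0:255)[which.max(r$objective_curve)])

  bw <- matrix(as.integer(c(rep(0, 30), rep(255, 226))), 16, 16)
  r2 <- otsu_threshold(bw)
  expect_identical(r2$value, otsu_oracle(bw))
  m <- unclass(apply_threshold(bw, r2$value))
  expect_identical(m == 255L, unclass(bw) == 255L)  # exact class separation

  set.seed(31)
  for (i in 1:20) {
    rnd <- matrix(as.integer(sample(0:255, 256, replace = TRUE)), 16, 16)
    expect_identical(otsu_threshold(rnd)$value, otsu_oracle(rnd))
  }

  expect_error(otsu_threshold(matrix(5L, 4, 4)), "distinct")
})

test_that("Otsu agrees with an independent library implementation", {
  for (seed in 1:5) {
    img <- quantize8(smooth_gaussian(
      make_fixture("bimodal", c(32, 32), seed = seed) + 0, 2))
    ours <- otsu_threshold(img)$value
    ref <- EBImage::otsu(EBImage::Image(t(img) / 255), levels = 256) * 255
    expect_lte(abs(ours - ref), 1.5)  # binning grids differ by up to a level
  }
})

test_that("max-edge selector equals the naive 256-iteration loop", {
  const <- matrix(50L, 16, 16)
  r0 <- max_edge_threshold(const)
  expect_identical(r0$value, 0L)                   # all-zero curve, smallest t
  expect_true(all(r0$objective_curve == 0))

  img <- make_fixture("nested_rects", c(64, 64))
  r <- max_edge_threshold(img)
  ref <- naive_max_edge(img)
  expect_identical(r$value, ref$t)
  expect_equal(r$objective_curve, ref$curve)
  expect_equal(r$objective_curve[256], 0)          # t = 255: all black
  expect_equal(max(r$objective_curve),
               r$objective_curve[r$value + 1])
})

test_that("edge-similarity selector equals the naive 256-iteration loop", {
  img <- make_fixture("nested_rects", c(64, 64))
  r <- edge_similarity_threshold(img)
  ref <- naive_edge_similarity(img)
  expect_identical(r$value, ref$t)
  expect_equal(r$objective_curve, ref$curve, tolerance = 1e-9)
  expect_equal(r$objective_curve[256], sqrt(64^2 + 64^2))  # empty Mooney edges

  # a binary image reproduces itself at some threshold: minimal distance 0
  bin <- make_fixture("polarity_pair", c(32, 32), seed = 4)[[1]]
  rb <- edge_similarity_threshold(bin)
  expect_equal(min(rb$objective_curve), 0)

  expect_error(edge_similarity_threshold(matrix(9L, 16, 16)), "empty edge map")
})

test_that("all selectors agree with their oracles on a seeded fixture battery", {
  fixtures <- spatial_test_fixtures(n_per_kind = 3L)
  for (nm in names(fixtures)) {
    q <- fixtures[[nm]]
    expect_identical(otsu_threshold(q)$value, otsu_oracle(q), label = nm)
    expect_identical(max_edge_threshold(q)$value, naive_max_edge(q)$t,
                     label = nm)
    expect_identical(edge_similarity_threshold(q)$value,
                     naive_edge_similarity(q)$t, label = nm)
  }
})

test_that("selected thresholds lie in the image's intensity range", {
  fixtures <- spatial_test_fixtures(n_per_kind = 2L)
  for (q in fixtures) {
    rng <- range(q)
    expect_gte(mean_threshold(q)$value, rng[1])
    expect_lte(mean_threshold(q)$value, rng[2])
    expect_gte(otsu_threshold(q)$value, rng[1])
    expect_lt(otsu_threshold(q)$value, rng[2])  # both classes non-empty
    for (f in list(max_edge_threshold, edge_similarity_threshold)) {
      v <- f(q)$value
      expect_true((v >= rng[1] && v <= rng[2]) || v == 0L)
    }
  }
})

test_that("thresholding is nested: higher thresholds give subset white sets", {
  set.seed(33)
  for (i in 1:25) {
    img <- quantize8(matrix(runif(400, 0, 255), 20, 20))
    ts <- sort(sample(0:254, 2))
    w1 <- unclass(apply_threshold(img, ts[1])) == 255L
    w2 <- unclass(apply_threshold(img, ts[2])) == 255L
    expect_true(all(w2 <= w1))  # white set at t2 subset of white set at t1
  }
})

test_that("the full pipeline composes the stages deterministically", {
  const <- array(rep(matrix(128, 16, 16), 3), c(16, 16, 3))
  out <- generate_mooney(const, sigma = 2, technique = "mean")
  expect_true(all(unclass(out$mooney) == 0L))     # strict > at the mean

  fx <- make_fixture("bimodal", c(32, 32), seed = 7)
  a <- generate_mooney(fx, sigma = 2, technique = "otsu")
  b <- generate_mooney(fx, sigma = 2, technique = "otsu")
  expect_identical(a$mooney, b$mooney)
  expect_identical(a$result$value, b$result$value)

  # compositional consistency: pipeline threshold equals the selector applied
  # to the manually pre-processed image, for each technique
  q <- quantize8(smooth_gaussian(to_grayscale(fx), 2))
  manual <- list(mean = mean_threshold(q)$value,
                 otsu = otsu_threshold(q)$value,
                 max_edge = max_edge_threshold(q)$value,
                 edge_similarity = edge_similarity_threshold(q)$value)
  for (tech in mooney_techniques()) {
    expect_equal(generate_mooney(fx, sigma = 2, technique = tech)$result$value,
                 manual[[tech]], label = tech)
  }
})
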