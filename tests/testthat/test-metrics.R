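test_that("dissimilarity ratio anchors: identical 0, polarity-reversed 1", {
  pair <- make_fixture("polarity_pair", c(32, 32), seed = 9)
  expect_equal(dissimilarity_ratio(pair[[1]], pair[[1]]), 0)
  expect_equal(dissimilarity_ratio(pair[[1]], pair[[2]]), 1)

  a <- matrix(c(0L, 255L, 0L, 255L), 2, 2)
  b <- matrix(c(255L, 0L, 0L, 255L), 2, 2)
  expect_equal(dissimilarity_ratio(a, b), 0.5)    # 2 of 4 pixels differ

  expect_error(dissimilarity_ratio(a, matrix(0L, 3, 3)), "shape")
})

test_that("dissimilarity ratio is a normalized Hamming metric", {
  set.seed(41)
  for (i in 1:50) {
    x <- random_binary_map(8, 8, 0.5)
    y <- random_binary_map(8, 8, 0.5)
    z <- random_binary_map(8, 8, 0.5)
    dxy <- dissimilarity_ratio(x, y)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
    expect_equal(dxy, dissimilarity_ratio(y, x))              # symmetry
    expect_equal(dissimilarity_ratio(x, x), 0)                # identity
    expect_lte(dxy, dissimilarity_ratio(x, z) +
                    dissimilarity_ratio(z, y) + 1e-12)        # triangle
  }
})

test_that("two global thresholds of a non-constant image never fully disagree", {
  set.seed(42)
  for (i in 1:20) {
    img <- quantize8(matrix(runif(256, 0, 255), 16, 16))
    rng <- range(img)
    ts <- sort(sample(seq(rng[1], rng[2] - 1), 2))
    d <- dissimilarity_ratio(apply_threshold(img, ts[1]),
                             apply_threshold(img, ts[2]))
    expect_lt(d, 1)  # nestedness forbids polarity reversal
  }
})

test_that("per-image threshold SD uses the sample denominator", {
  expect_equal(per_image_threshold_sd(c(100, 100, 100, 100)), 0)
  expect_equal(per_image_threshold_sd(c(0, 0, 0, 0)), 0)
  expect_equal(per_image_threshold_sd(c(10, 20, 30, 40)),
               sqrt(500 / 3))  # 12.909944...
  expect_equal(per_image_threshold_sd(c(10, 20, 30, 40), type = "population"),
               sqrt(125))
  expect_error(per_image_threshold_sd(c(1, 2, 3)), "four")
})

test_that("threshold distribution summaries match direct recomputation", {
  tab <- data.frame(source_id = "a", technique = "mean", sigma = 2,
                    threshold = 120)
  s1 <- threshold_distribution_summary(tab)
  expect_equal(s1$mean, 120)
  expect_equal(s1$sd, 0)  # degenerate single-row group, by convention

  tab2 <- data.frame(source_id = c("a", "b"), technique = "otsu", sigma = 2,
                     threshold = c(0, 255))
  expect_equal(threshold_distribution_summary(tab2)$mean, 127.5)

  set.seed(43)
  big <- do.call(rbind, lapply(mooney_techniques(), function(tech) {
    data.frame(source_id = sprintf("img%03d", 1:100), technique = tech,
               sigma = 2, threshold = sample(0:255, 100, replace = TRUE))
  }))
  s <- threshold_distribution_summary(big)
  for (tech in mooney_techniques()) {
    x <- big$threshold[big$technique == tech]
    row <- s[s$technique == tech, ]
    expect_equal(row$n, 100)
    expect_equal(row$mean, mean(x))
    expect_equal(row$sd, sd(x))
    q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
    expect_equal(c(row$q1, row$median, row$q3), q)
    iqr <- q[3] - q[1]
    expect_equal(row$whisker_low, min(x[x >= q[1] - 1.5 * iqr]))
    expect_equal(row$whisker_high, max(x[x <= q[3] + 1.5 * iqr]))
  }
  expect_error(threshold_distribution_summary(big[0, ]), "empty")
})

test_that("pairwise dissimilarity matrix averages over images symmetrically", {
  blank <- matrix(0L, 8, 8)
  full <- matrix(255L, 8, 8)
  same <- lapply(1:3, function(i) {
    setNames(replicate(4, blank, simplify = FALSE), mooney_techniques())
  })
  m0 <- pairwise_dissimilarity_matrix(same)
  expect_true(all(m0 == 0))

  # one image; pair (mean, otsu) differs in 25% of pixels
  v <- blank; v[1:16] <- 255L
  one <- list(img1 = list(mean = blank, otsu = v, max_edge = blank,
                          edge_similarity = blank))
  m1 <- pairwise_dissimilarity_matrix(one)
  expect_equal(m1["mean", "otsu"], 0.25)
  expect_equal(m1, t(m1))
  expect_true(all(diag(m1) == 0))

  # mean over images equals brute-force recomputation
  set.seed(44)
  sets <- lapply(1:10, function(i) {
    setNames(lapply(1:4, function(j) {
      matrix(ifelse(random_binary_map(8, 8, 0.5), 255L, 0L), 8, 8)
    }), mooney_techniques())
  })
  m <- pairwise_dissimilarity_matrix(sets)
  brute <- mean(vapply(sets, function(s) {
    mean(s$mean != s$max_edge)
  }, numeric(1)))
  expect_equal(m["mean", "max_edge"], brute)

  bad <- sets
  bad[[3]] <- bad[[3]][c("mean", "otsu")]
  expect_error(pairwise_dissimilarity_matrix(bad), "missing technique")
})

test_that("difficulty stratification partitions [0, 1] at the stated bounds", {
  p <- c(0.76, 0.75, 0.251, 0.25, 0, 1)
  lab <- difficulty_stratify(p)
  expect_equal(as.character(lab),
               c("easy", "medium", "medium", "difficult", "difficult", "easy"))

  set.seed(45)
  x <- runif(200)
  lab2 <- difficulty_stratify(x)
  expect_false(anyNA(lab2))                        # exhaustive
  expect_equal(sum(table(lab2)), 200L)             # exclusive
  expect_error(difficulty_stratify(c(0.5, 1.2)), "\\[0, 1\\]")
})
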