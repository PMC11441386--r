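# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops and direct definitions only.

# exhaustive between-class variance search over all 256 thresholds
otsu_oracle <- function(img) {
  v <- as.vector(img)
  n <- length(v)
  best <- -Inf
  best_t <- 0L
  for (t in 0:255) {
    black <- v[v <= t]
    white <- v[v > t]
    if (length(black) == 0L || length(white) == 0L) next
    obj <- (length(black) / n) * (length(white) / n) *
      (mean(black) - mean(white))^2
    if (obj > best) {
      best <- obj
      best_t <- t
    }
  }
  best_t
}

# literal 256-iteration reference loop for the max-edge selector
naive_max_edge <- function(img, sigma = 1, low = 0.1, high = 0.2) {
  counts <- numeric(256)
  for (t in 0:255) {
    m <- apply_threshold(img, t)
    counts[t + 1] <- edge_pixel_count(canny_edges(m, sigma = sigma,
                                                  low = low, high = high))
  }
  list(t = (0:255)[which.max(counts)], curve = counts)
}

# literal 256-iteration reference loop for the edge-similarity selector
naive_edge_similarity <- function(img, sigma = 1, low = 0.1, high = 0.2) {
  template <- canny_edges(img, sigma = sigma, low = low, high = high)
  dists <- numeric(256)
  for (t in 0:255) {
    m <- apply_threshold(img, t)
    dists[t + 1] <- brute_hausdorff(template,
                                    canny_edges(m, sigma = sigma,
                                                low = low, high = high))
  }
  list(t = (0:255)[which.min(dists)], curve = dists)
}

# O(|a| * |b|) double loop over edge-pixel coordinates
brute_hausdorff <- function(a, b) {
  pa <- unname(which(a, arr.ind = TRUE))
  pb <- unname(which(b, arr.ind = TRUE))
  if (nrow(pa) == 0L) return(0)
  if (nrow(pb) == 0L) return(sqrt(nrow(a)^2 + ncol(a)^2))
  worst <- 0
  for (i in seq_len(nrow(pa))) {
    nearest <- Inf
    for (j in seq_len(nrow(pb))) {
      d <- sqrt((pa[i, 1] - pb[j, 1])^2 + (pa[i, 2] - pb[j, 2])^2)
      if (d < nearest) nearest <- d
    }
    if (nearest > worst) worst <- nearest
  }
  worst
}

# exhaustive-distance foil search: all pairwise distances, ties by name
brute_foils <- function(concept, table, k) {
  others <- setdiff(rownames(table), concept)
  d <- vapply(others, function(o) {
    sqrt(sum((table[o, ] - table[concept, ])^2))
  }, numeric(1))
  others[order(d, others)][1:k]
}

random_binary_map <- function(h, w, p = 0.1) {
  matrix(stats::runif(h * w) < p, h, w)
}

make_toy_embedding <- function(n, d, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * d, -2, 2), n, d,
              dimnames = list(sprintf("concept_%02d", seq_len(n)),
                              sprintf("dim_%02d", seq_len(d))))
  m
}

# direct (non-separable) 2-D convolution with half-sample mirror padding,
# used to check separability of the Gaussian smoother
conv2_reflect <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  reflect <- function(i, n) {
    p <- (i - 1L) %% (2L * n)
    ifelse(p < n, p + 1L, 2L * n - p)
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + kernel[di + r + 1L, dj + r + 1L] *
            img[reflect(i + di, h), reflect(j + dj, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# small battery of quantized, smoothed fixtures for selector oracle tests
spatial_test_fixtures <- function(n_per_kind = 13L) {
  kinds <- c("bimodal", "nested_rects", "disk", "noise")
  out <- list()
  for (kind in kinds) {
    for (i in seq_len(n_per_kind)) {
      shape <- c(24L + ((i * 3L) %% 25L), 24L + ((i * 5L) %% 17L))
      fx <- make_fixture(kind, shape = shape, seed = i)
      out[[paste0(kind, "_", i)]] <-
        quantize8(smooth_gaussian(fx + 0, sigma = 2))
    }
  }
  out
}
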