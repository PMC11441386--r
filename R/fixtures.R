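#' Deterministic synthetic test images
#'
#' Generates 8-bit grayscale fixtures with the statistical structure the
#' Mooney pipeline assumes, standing in for photographic template images in
#' tests and examples. All randomness comes from R's Mersenne-Twister
#' generator with Inversion normals, seeded explicitly and restored on exit,
#' so the same spec and seed give byte-identical images on every platform.
#'
#' Kinds:
#' \describe{
#'   \item{`ramp`}{linear intensity ramp filling the full 0-255 range; a
#'     16x16 ramp contains every 8-bit value exactly once.}
#'   \item{`bimodal`}{an object blob (centred disk) drawn from
#'     `N(mu1, sd)` on a `N(mu0, sd)` background — a smooth bimodal
#'     intensity scene on which mean and Otsu thresholds are well defined
#'     and distinct.}
#'   \item{`nested_rects`}{three nested rectangles at intensities 60, 120
#'     and 180: known edge geometry for the edge-based selectors.}
#'   \item{`disk`}{a single disk of intensity `fg` on a `bg` background.}
#'   \item{`noise`}{independent uniform noise over 0-255 (high-frequency
#'     content that smoothing must suppress).}
#'   \item{`polarity_pair`}{a binary image and its polarity reverse, as a
#'     two-element list; their dissimilarity ratio is exactly 1 by
#'     construction.}
#' }
#'
#' @param kind fixture kind, see Details.
#' @param shape integer `c(H, W)`, both at least 8.
#' @param seed integer seed controlling all random content.
#' @param mu0,mu1 background/object component means for `bimodal` (defaults
#'   40 and 200 on the 0-255 scale).
#' @param sd noise standard deviation for `bimodal` (default 10).
#' @param radius disk radius in pixels for `disk`/`bimodal`
#'   (default `min(shape) / 4`).
#' @param fg,bg disk foreground/background intensities for `disk`.
#' @return an integer matrix with values in `0:255`, or for
#'   `polarity_pair` a list of two such matrices.
#' @examples
#' img <- make_fixture("bimodal", shape = c(32, 32), seed = 7)
#' range(img)
#' @export
make_fixture <- function(kind = c("ramp", "bimodal", "nested_rects", "disk",
                                  "noise", "polarity_pair"),
                         shape = c(64L, 64L), seed = 1L,
                         mu0 = 40, mu1 = 200, sd = 10,
                         radius = min(shape) / 4, fg = 200, bg = 50) {
  kind <- match.arg(kind)
  if (length(shape) != 2L || any(shape < 8L)) {
    stop("`shape` must be c(H, W) with both dimensions >= 8", call. = FALSE)
  }
  if (any(c(mu0, mu1, fg, bg) < 0) || any(c(mu0, mu1, fg, bg) > 255)) {
    stop("intensity parameters must lie in [0, 255]", call. = FALSE)
  }
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  with_fixture_seed(seed, {
    switch(kind,
      ramp = quantize8(matrix(seq(0, 255, length.out = h * w), h, w)),
      bimodal = {
        obj <- disk_mask(h, w, radius)
        px <- matrix(stats::rnorm(h * w, mu0, sd), h, w)
        px[obj] <- stats::rnorm(sum(obj), mu1, sd)
        quantize8(pmin(pmax(px, 0), 255))
      },
      nested_rects = {
        img <- matrix(60, h, w)
        img[rect_idx(h, 1 / 6), rect_idx(w, 1 / 6)] <- 120
        img[rect_idx(h, 1 / 3), rect_idx(w, 1 / 3)] <- 180
        quantize8(img)
      },
      disk = {
        img <- matrix(bg, h, w)
        img[disk_mask(h, w, radius)] <- fg
        quantize8(img)
      },
      noise = quantize8(matrix(stats::runif(h * w, 0, 255), h, w)),
      polarity_pair = {
        base <- matrix(stats::runif(h * w, 0, 255), h, w)
        sm <- quantize8(smooth_gaussian(base, sigma = 2))
        b <- unclass(apply_threshold(sm, mean(sm)))
        attributes(b) <- attributes(b)["dim"]
        list(b, 255L - b)
      })
  })
}

# evaluate `expr` under a named, explicitly seeded RNG; restore global state
with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

disk_mask <- function(h, w, radius) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  outer(seq_len(h), seq_len(w),
        function(r, c) (r - cy)^2 + (c - cx)^2 <= radius^2)
}

rect_idx <- function(n, margin_frac) {
  lo <- max(1L, floor(n * margin_frac) + 1L)
  hi <- min(n, n - floor(n * margin_frac))
  lo:hi
}

#' Write a battery of fixture images to disk
#'
#' Generates `n` fixtures per kind (PNG, plus both members of each polarity
#' pair) and a CSV manifest of their specs, for use by the command-line
#' pipeline and for visual inspection.
#'
#' @param out_dir output directory (created if missing).
#' @param kinds fixture kinds to generate; defaults to all single-image
#'   kinds.
#' @param n number of fixtures per kind.
#' @param shape image shape `c(H, W)`.
#' @param seed base seed; fixture `i` of each kind uses `seed + i - 1`.
#' @return data frame manifest (one row per written file), invisibly.
#' @export
make_fixture_set <- function(out_dir,
                             kinds = c("ramp", "bimodal", "nested_rects",
                                       "disk", "noise"),
                             n = 5L, shape = c(64L, 64L), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (kind in kinds) {
    for (i in seq_len(n)) {
      s <- seed + i - 1L
      fx <- make_fixture(kind, shape = shape, seed = s)
      if (kind == "polarity_pair") {
        for (m in 1:2) {
          id <- sprintf("%s_%03d_%s", kind, i, c("a", "b")[m])
          f <- file.path(out_dir, paste0(id, ".png"))
          write_gray_png(fx[[m]], f)
          rows[[length(rows) + 1L]] <- data.frame(
            source_id = id, kind = kind, height = shape[1L],
            width = shape[2L], seed = s, file = f)
        }
      } else {
        id <- sprintf("%s_%03d", kind, i)
        f <- file.path(out_dir, paste0(id, ".png"))
        write_gray_png(fx, f)
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = id, kind = kind, height = shape[1L],
          width = shape[2L], seed = s, file = f)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "fixtures.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
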