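#' Convert an RGB image to grayscale luminance
#'
#' Computes a per-pixel weighted sum of the three colour channels. The default
#' weights are the CIE1931 luminance coefficients for sRGB primaries
#' (0.2126, 0.7152, 0.0722), applied directly to the stored 8-bit channel
#' values. Set `gamma_decode = TRUE` to first linearize the channels with the
#' inverse sRGB companding function, compute relative luminance in linear
#' space, and rescale to 0-255; whether the original toolchain decoded gamma
#' is not documented, so both paths are available and the direct path is the
#' default.
#'
#' @param img an `H x W x 3` numeric array of channel intensities on the
#'   0-255 scale, or an `H x W` matrix (already grayscale, returned as-is).
#' @param weights numeric vector of three non-negative channel weights
#'   summing to 1.
#' @param gamma_decode logical; linearize sRGB before the weighted sum.
#' @return an `H x W` numeric matrix of luminance values on the 0-255 scale.
#' @examples
#' rgb <- array(0, c(2, 2, 3)); rgb[, , 1] <- 255
#' to_grayscale(rgb)[1, 1]  # 255 * 0.2126
#' @export
to_grayscale <- function(img, weights = c(0.2126, 0.7152, 0.0722),
                         gamma_decode = FALSE) {
  if (is.matrix(img)) {
    return(img + 0)  # achromatic input maps to itself
  }
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop("`img` must be an H x W x 3 array or an H x W matrix", call. = FALSE)
  }
  if (length(weights) != 3L || any(weights < 0) || any(!is.finite(weights))) {
    stop("`weights` must be three finite non-negative values", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must sum to 1", call. = FALSE)
  }
  hw <- dim(img)[1:2]
  ch <- function(a, k) matrix(a[, , k], hw[1L], hw[2L])
  if (gamma_decode) {
    lin <- srgb_decode(img / 255)
    return(255 * (ch(lin, 1L) * weights[1L] + ch(lin, 2L) * weights[2L] +
                    ch(lin, 3L) * weights[3L]))
  }
  ch(img, 1L) * weights[1L] + ch(img, 2L) * weights[2L] +
    ch(img, 3L) * weights[3L]
}

# inverse sRGB companding, input in [0, 1]
srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' Gaussian smoothing with a truncated separable kernel
#'
#' Convolves the image with a normalized discrete Gaussian, truncated at
#' `truncate` standard deviations (kernel radius `floor(truncate * sigma +
#' 0.5)` pixels). The kernel is a convex combination, so output values never
#' leave the input range and constant images are preserved exactly.
#'
#' @param img numeric matrix (luminance on the 0-255 scale).
#' @param sigma standard deviation of the kernel in pixels; `sigma = 0`
#'   returns the input unchanged.
#' @param truncate kernel cutoff in units of sigma (default 4).
#' @param boundary edge-extension rule: `"reflect"` (mirror about the edge,
#'   the default — avoids darkening at borders, which would bias mean-based
#'   thresholds), `"replicate"` (repeat the edge pixel) or `"circular"`.
#' @return numeric matrix of the same shape.
#' @export
smooth_gaussian <- function(img, sigma, truncate = 4,
                            boundary = c("reflect", "replicate", "circular")) {
  boundary <- match.arg(boundary)
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix", call. = FALSE)
  }
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be a single finite value >= 0", call. = FALSE)
  }
  if (truncate <= 0) stop("`truncate` must be positive", call. = FALSE)
  if (sigma == 0) return(img + 0)
  r <- floor(truncate * sigma + 0.5)
  if (r < 1) return(img + 0)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  convolve_separable(img, k, k, boundary)
}

# separable convolution: 1-D kernel down columns (kr) then across rows (kc);
# kernels are odd-length and centred
convolve_separable <- function(img, kr, kc, boundary) {
  out <- convolve_1d(img, kr, boundary, along = "rows")
  convolve_1d(out, kc, boundary, along = "cols")
}

# correlate each column (along = "rows") or row with an odd centred kernel
convolve_1d <- function(img, k, boundary, along) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(img * k)
  n <- if (along == "rows") nrow(img) else ncol(img)
  idx <- extend_index(n, r, boundary)
  if (along == "rows") {
    pad <- img[idx, , drop = FALSE]
    out <- matrix(0, nrow(img), ncol(img))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    }
  } else {
    pad <- img[, idx, drop = FALSE]
    out <- matrix(0, nrow(img), ncol(img))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[, j:(j + n - 1L), drop = FALSE]
    }
  }
  out
}

# index vector of length n + 2r implementing the boundary extension;
# reflect is half-sample symmetric (edge pixel not repeated across the fold)
extend_index <- function(n, r, boundary) {
  i <- (1L - r):(n + r)
  switch(boundary,
    reflect = {
      p <- (i - 1L) %% (2L * n)
      ifelse(p < n, p + 1L, 2L * n - p)
    },
    replicate = pmin(pmax(i, 1L), n),
    circular = ((i - 1L) %% n) + 1L
  )
}

#' Quantize a luminance image to 8-bit
#'
#' Rounds half away from zero, then clips to `[0, 255]`. Deterministic and
#' platform-independent so that selected thresholds are reproducible
#' bit-exactly; idempotent on already-integer input.
#'
#' @param img numeric matrix with finite values.
#' @return integer matrix with values in `0:255`.
#' @export
quantize8 <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop("`img` contains non-finite values", call. = FALSE)
  }
  q <- sign(img) * floor(abs(img) + 0.5)
  q <- pmin(pmax(q, 0), 255)
  storage.mode(q) <- "integer"
  q
}

#' Read a PNG or JPEG raster
#'
#' @param path file path.
#' @return for colour images an `H x W x 3` array, for grayscale an `H x W`
#'   matrix; values on the 0-255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im) * 255
  nd <- length(dim(a))
  if (nd == 2L) {
    t(a)
  } else if (nd == 3L && dim(a)[3L] >= 3L) {
    aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))  # drop alpha if present
  } else if (nd == 3L && dim(a)[3L] == 2L) {
    t(a[, , 1L])  # gray + alpha
  } else {
    stop("unsupported channel layout in ", path, call. = FALSE)
  }
}

#' Write a grayscale or binary image as single-channel 8-bit PNG
#'
#' @param img numeric matrix on the 0-255 scale (binary Mooney images use
#'   0/255).
#' @param path output file path (`.png`).
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  if (!is.matrix(img)) stop("`img` must be a matrix", call. = FALSE)
  EBImage::writeImage(EBImage::Image(t(img) / 255), path,
                      type = "png", bits.per.sample = 8L)
  invisible(path)
}
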