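#' Canny edge detection
#'
#' Standard Canny pipeline: Gaussian smoothing at `sigma`, Sobel gradients,
#' non-maximum suppression perpendicular to the local gradient orientation,
#' and double-threshold hysteresis with 8-connected linking. The hysteresis
#' thresholds are fractions of the image's gradient-magnitude maximum, so the
#' edge map is invariant to polarity reversal of the input.
#'
#' Non-maximum suppression quantizes the gradient *orientation* (modulo 180
#' degrees) to one of four neighbour axes and keeps a pixel iff its magnitude
#' strictly exceeds one spatial neighbour and is at least that of the other;
#' the asymmetric tie rule thins the symmetric two-pixel plateau of an ideal
#' step edge to a single 1-pixel line while staying polarity-invariant.
#'
#' @param img numeric or logical matrix; grayscale 0-255 values or a binary
#'   Mooney image.
#' @param sigma Gaussian scale of the detector in pixels (default 1).
#' @param low,high hysteresis thresholds as fractions of the gradient
#'   magnitude maximum, `0 <= low <= high <= 1`.
#' @return logical matrix of edge pixels with attribute `sigma_used`.
#' @export
canny_edges <- function(img, sigma = 1, low = 0.1, high = 0.2) {
  if (inherits(img, "mooney_image")) img <- unclass(img)
  if (is.logical(img)) {
    img <- matrix(as.numeric(img) * 255, nrow(img), ncol(img))
  }
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix", call. = FALSE)
  }
  if (min(dim(img)) < 2L) {
    stop("degenerate image shape ", nrow(img), " x ", ncol(img),
         ": Canny edge detection needs at least 2 pixels per axis",
         call. = FALSE)
  }
  if (!(sigma > 0)) stop("`sigma` must be > 0", call. = FALSE)
  if (low < 0 || high > 1 || low > high) {
    stop("need 0 <= low <= high <= 1", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  # centre at mid-scale before filtering: for 8-bit input, polarity reversal
  # then negates the centred image exactly, and negation commutes bit-exactly
  # with the convolutions, so the edge map is identical for reversed input
  sm <- smooth_gaussian(img - 127.5, sigma, truncate = 4,
                        boundary = "reflect")
  # Sobel gradients: derivative [-1, 0, 1] x smoothing [1, 2, 1]
  gx <- convolve_separable(sm, c(1, 2, 1), c(-1, 0, 1), "reflect")
  gy <- convolve_separable(sm, c(-1, 0, 1), c(1, 2, 1), "reflect")
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  out <- matrix(FALSE, h, w)
  if (mmax == 0) {
    attr(out, "sigma_used") <- sigma
    return(out)
  }

  # Gradient orientation quantized (modulo 180 degrees) to 4 neighbour axes.
  # Classified from |gx|, |gy| and sign(gx * gy) only, all of which are exact
  # invariants of gradient negation, so polarity reversal cannot move a pixel
  # across a sector boundary the way a floating-point atan2 difference could.
  t1 <- tan(pi / 8)
  ax <- abs(gx); ay <- abs(gy)
  sector <- matrix(3L, h, w)                 # anti-diagonal axis by default
  sector[ay < t1 * ax] <- 0L                 # horizontal gradient
  sector[ax < t1 * ay] <- 2L                 # vertical gradient
  sector[sector == 3L & gx * gy >= 0] <- 1L  # main-diagonal axis

  # zero-padded magnitude for neighbour lookup
  pm <- matrix(0, h + 2L, w + 2L)
  pm[2:(h + 1L), 2:(w + 1L)] <- mag
  shift <- function(dr, dc) pm[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  # fixed spatial neighbour pairs per sector (minus side, plus side)
  n_minus <- shift(0L, -1L); n_plus <- shift(0L, 1L)        # sector 0
  s1m <- shift(-1L, -1L); s1p <- shift(1L, 1L)              # sector 1
  s2m <- shift(-1L, 0L); s2p <- shift(1L, 0L)               # sector 2
  s3m <- shift(-1L, 1L); s3p <- shift(1L, -1L)              # sector 3
  n_minus[sector == 1L] <- s1m[sector == 1L]
  n_plus[sector == 1L] <- s1p[sector == 1L]
  n_minus[sector == 2L] <- s2m[sector == 2L]
  n_plus[sector == 2L] <- s2p[sector == 2L]
  n_minus[sector == 3L] <- s3m[sector == 3L]
  n_plus[sector == 3L] <- s3p[sector == 3L]
  nms <- mag > n_minus & mag >= n_plus

  weak <- nms & mag >= low * mmax
  strong <- nms & mag >= high * mmax
  out <- hysteresis_link(strong, weak)
  attr(out, "sigma_used") <- sigma
  out
}

# grow the strong set through 8-connected weak pixels (breadth-first)
hysteresis_link <- function(strong, weak) {
  h <- nrow(strong); w <- ncol(strong)
  result <- strong
  frontier <- which(strong)
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  while (length(frontier)) {
    r <- ((frontier - 1L) %% h) + 1L
    cc <- ((frontier - 1L) %/% h) + 1L
    nr <- rep(r, each = 8L) + off_r
    nc <- rep(cc, each = 8L) + off_c
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nb <- unique((nc[ok] - 1L) * h + nr[ok])
    new <- nb[weak[nb] & !result[nb]]
    result[new] <- TRUE
    frontier <- new
  }
  result
}

#' Count edge pixels in an edge map
#'
#' @param em logical matrix as returned by [canny_edges()].
#' @return number of edge (TRUE) pixels.
#' @export
edge_pixel_count <- function(em) {
  if (!is.logical(em)) stop("`em` must be a logical edge map", call. = FALSE)
  sum(em)
}

#' Directed Hausdorff distance between two edge maps
#'
#' The maximum, over edge pixels of `template_edges`, of the Euclidean
#' distance to the nearest edge pixel of `mooney_edges` (pixel coordinates
#' are integer row/column positions). Returns 0 when the template has no edge
#' pixels, and the image diagonal `sqrt(H^2 + W^2)` when the template has
#' edges but `mooney_edges` is empty, so degenerate all-black or all-white
#' candidates are maximally penalized in an argmin search instead of failing.
#'
#' @param template_edges,mooney_edges logical matrices of identical shape.
#' @param symmetric if `TRUE` return the symmetric Hausdorff distance (the
#'   larger of the two directed distances); the default is the directed
#'   distance from template to Mooney edges.
#' @return non-negative distance in pixels.
#' @export
directed_hausdorff <- function(template_edges, mooney_edges,
                               symmetric = FALSE) {
  if (!is.logical(template_edges) || !is.logical(mooney_edges)) {
    stop("edge maps must be logical matrices", call. = FALSE)
  }
  if (!identical(dim(template_edges), dim(mooney_edges))) {
    stop("edge maps must have identical shapes", call. = FALSE)
  }
  d <- hausdorff_one_way(template_edges, mooney_edges)
  if (symmetric) {
    d <- max(d, hausdorff_one_way(mooney_edges, template_edges))
  }
  d
}

hausdorff_one_way <- function(a, b) {
  if (!any(a)) return(0)
  h <- nrow(a); w <- ncol(a)
  if (!any(b)) return(sqrt(h^2 + w^2))
  # exact Euclidean distance transform: distance of every pixel to the
  # nearest TRUE pixel of b (b pixels are the background of the transform)
  dt <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(matrix(as.numeric(!b), h, w)), metric = "euclidean"))
  max(dt[a])
}
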