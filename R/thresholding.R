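#' @title Threshold results
#' @description Constructor for the value object returned by the four
#'   threshold selectors: the selected threshold on the 0-255 scale, the
#'   technique identifier, and (for the search-based selectors) the
#'   per-candidate objective curve over all 256 candidate thresholds.
#' @param technique one of `"mean"`, `"otsu"`, `"max_edge"`,
#'   `"edge_similarity"`.
#' @param value selected threshold in `[0, 255]`.
#' @param objective_curve optional numeric vector of length 256 with the
#'   objective value at every candidate threshold `0:255`.
#' @param source_id identifier of the input image.
#' @return an object of class `threshold_result`.
#' @keywords internal
threshold_result <- function(technique, value, objective_curve = NULL,
                             source_id = NA_character_) {
  stopifnot(technique %in% mooney_techniques(),
            value >= 0, value <= 255,
            is.null(objective_curve) || length(objective_curve) == 256L)
  structure(
    list(technique = technique, value = value,
         objective_curve = objective_curve,
         candidates = if (!is.null(objective_curve)) 0:255 else NULL,
         source_id = source_id),
    class = "threshold_result")
}

#' Names of the supported threshold-selection techniques
#' @return character vector of the four technique identifiers.
#' @export
mooney_techniques <- function() {
  c("mean", "otsu", "max_edge", "edge_similarity")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result>", x$technique, "threshold =",
      format(x$value, digits = 7), "\n")
  if (!is.null(x$objective_curve)) {
    cat("  objective curve over", length(x$objective_curve),
        "candidate thresholds\n")
  }
  if (!is.na(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Binarize an 8-bit image at a threshold
#'
#' Pixels whose intensity strictly exceeds `t` become white (255); pixels at
#' or below `t` become black (0). The strict inequality means `t = 255`
#' yields an all-black image and `t = -1` an all-white one.
#'
#' @param img integer matrix with values in `0:255`.
#' @param t finite threshold (need not be an integer; the mean selector
#'   returns real values).
#' @param technique optional technique label stored on the result.
#' @param source_id optional source identifier stored on the result.
#' @return integer matrix of 0/255 values with class `mooney_image` and
#'   attributes `threshold_used` and `technique`.
#' @export
apply_threshold <- function(img, t, technique = NA_character_,
                            source_id = NA_character_) {
  if (!is.matrix(img)) stop("`img` must be a matrix", call. = FALSE)
  if (length(t) != 1L || !is.finite(t)) {
    stop("`t` must be a single finite value", call. = FALSE)
  }
  m <- matrix(0L, nrow(img), ncol(img))
  m[img > t] <- 255L
  structure(m, class = c("mooney_image", class(m)),
            threshold_used = t, technique = technique,
            source_id = source_id)
}

#' @export
print.mooney_image <- function(x, ...) {
  cat("<mooney_image>", nrow(x), "x", ncol(x), "|",
      round(100 * mean(unclass(x) == 255L), 1), "% white | threshold",
      format(attr(x, "threshold_used"), digits = 7), "\n")
  invisible(x)
}

#' Mean-intensity threshold
#'
#' Baseline non-spatial selector: the threshold is the arithmetic mean of all
#' pixel intensities, kept real-valued (comparison during binarization is
#' against integer pixel values, so rounding would only discard information).
#'
#' @param img integer matrix with values in `0:255`.
#' @param source_id optional source identifier.
#' @return a [`threshold_result`] with `technique = "mean"`.
#' @export
mean_threshold <- function(img, source_id = NA_character_) {
  check_gray8(img)
  threshold_result("mean", mean(img), source_id = source_id)
}

#' Otsu's threshold
#'
#' Non-spatial clustering selector: picks the integer threshold maximizing
#' the between-class variance \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} of
#' the black (intensity \eqn{\le t}) and white (\eqn{> t}) classes, computed
#' from the 256-bin histogram; equivalent to minimizing within-class
#' variance. Ties are broken toward the smallest threshold.
#'
#' @param img integer matrix with values in `0:255` and at least two distinct
#'   intensities.
#' @param source_id optional source identifier.
#' @return a [`threshold_result`] with the 256-entry between-class variance
#'   curve in `objective_curve`.
#' @export
otsu_threshold <- function(img, source_id = NA_character_) {
  check_gray8(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L) {
    stop("Otsu's method needs at least two distinct intensities ",
         "(degenerate histogram)", call. = FALSE)
  }
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts) / n              # weight of class <= t
  m0 <- cumsum(counts * levels)
  mu_total <- m0[256L] / n
  w1 <- 1 - w0
  mu0 <- ifelse(w0 > 0, (m0 / n) / w0, 0)
  mu1 <- ifelse(w1 > 0, (mu_total - m0 / n) / w1, 0)
  curve <- w0 * w1 * (mu0 - mu1)^2
  curve[w0 == 0 | w1 == 0] <- 0
  t_star <- levels[which.max(curve)]   # first max: smallest t wins ties
  threshold_result("otsu", t_star, objective_curve = curve,
                   source_id = source_id)
}

#' Max-edge threshold
#'
#' Spatial selector: every candidate threshold `t` in `0:255` is applied to
#' the image, a Canny edge map of the binarized image is computed, and the
#' threshold producing the largest number of edge pixels is selected (ties
#' toward the smallest threshold). All 256 candidates are enumerated;
#' thresholds that fall between the same two occupied intensity levels
#' produce byte-identical binarizations, so the edge map is evaluated once
#' per distinct binarization and the value shared — every entry of the
#' objective curve equals what a literal 256-iteration loop computes.
#'
#' @param img integer matrix with values in `0:255`.
#' @param sigma,low,high Canny detector parameters, see [canny_edges()].
#' @param source_id optional source identifier.
#' @return a [`threshold_result`] with the 256 edge-pixel counts in
#'   `objective_curve`.
#' @export
max_edge_threshold <- function(img, sigma = 1, low = 0.1, high = 0.2,
                               source_id = NA_character_) {
  check_gray8(img)
  curve <- candidate_objective(img, function(mooney) {
    edge_pixel_count(canny_edges(mooney, sigma = sigma,
                                 low = low, high = high))
  })
  t_star <- (0:255)[which.max(curve)]
  threshold_result("max_edge", t_star, objective_curve = curve,
                   source_id = source_id)
}

#' Edge-similarity threshold
#'
#' Spatial selector: the Canny edge map of the (smoothed, quantized)
#' template image is computed once; every candidate threshold in `0:255` is
#' applied, the binarized image's edge map computed, and the threshold
#' minimizing the directed Hausdorff distance from template edges to Mooney
#' edges is selected (ties toward the smallest threshold). The resulting
#' two-tone image is the one whose edges stay closest to the template's.
#'
#' @param img integer matrix with values in `0:255`; must produce a
#'   non-empty template edge map.
#' @param sigma,low,high Canny detector parameters, see [canny_edges()].
#' @param source_id optional source identifier.
#' @return a [`threshold_result`] with the 256 Hausdorff distances in
#'   `objective_curve`.
#' @export
edge_similarity_threshold <- function(img, sigma = 1, low = 0.1, high = 0.2,
                                      source_id = NA_character_) {
  check_gray8(img)
  template <- canny_edges(img, sigma = sigma, low = low, high = high)
  if (edge_pixel_count(template) == 0L) {
    stop("template image has an empty edge map; the edge-similarity ",
         "objective is undefined", call. = FALSE)
  }
  curve <- candidate_objective(img, function(mooney) {
    directed_hausdorff(template,
                       canny_edges(mooney, sigma = sigma,
                                   low = low, high = high))
  })
  t_star <- (0:255)[which.min(curve)]
  threshold_result("edge_similarity", t_star, objective_curve = curve,
                   source_id = source_id)
}

# Enumerate all 256 candidate thresholds; evaluate `f` on the binarization
# once per distinct binarization (the white set {v > t} only changes when t
# crosses an occupied intensity level) and share the value across the
# candidates in the same run.
candidate_objective <- function(img, f) {
  u <- sort(unique(as.integer(img)))
  group <- findInterval(0:255, u)  # same group <=> identical binarization
  vals <- vapply(unique(group), function(g) {
    t_rep <- (0:255)[match(g, group)]
    f(apply_threshold(img, t_rep))
  }, numeric(1))
  vals[match(group, unique(group))]
}

#' Generate a Mooney image from a template
#'
#' The full two-step pipeline: grayscale conversion (CIE1931 weights),
#' Gaussian smoothing in floating point, 8-bit quantization, threshold
#' selection by the requested technique, and binarization. Deterministic
#' given the inputs and configuration.
#'
#' @param img an `H x W x 3` RGB array or `H x W` grayscale matrix on the
#'   0-255 scale.
#' @param sigma standard deviation of the smoothing kernel in pixels
#'   (2 is the minimum that removes enough noise for the characteristic
#'   Mooney look; 2-6 is the useful range, larger values erase contours).
#' @param technique one of [mooney_techniques()].
#' @param weights grayscale channel weights, see [to_grayscale()].
#' @param truncate,boundary smoothing parameters, see [smooth_gaussian()].
#' @param edge_sigma,edge_low,edge_high Canny parameters for the two spatial
#'   selectors, see [canny_edges()].
#' @param source_id optional source identifier propagated to the results.
#' @return a list with elements `mooney` (the binary image) and `result`
#'   (the [`threshold_result`]).
#' @examples
#' img <- make_fixture("bimodal", shape = c(32, 32), seed = 7)
#' out <- generate_mooney(img, sigma = 2, technique = "otsu")
#' out$result
#' @export
generate_mooney <- function(img, sigma = 2, technique = "mean",
                            weights = c(0.2126, 0.7152, 0.0722),
                            truncate = 4, boundary = "reflect",
                            edge_sigma = 1, edge_low = 0.1, edge_high = 0.2,
                            source_id = NA_character_) {
  technique <- match.arg(technique, mooney_techniques())
  gray <- withCallingHandlers(
    to_grayscale(img, weights = weights),
    error = function(e) stop("grayscale stage: ", conditionMessage(e),
                             call. = FALSE))
  sm <- smooth_gaussian(gray, sigma, truncate = truncate, boundary = boundary)
  q <- quantize8(sm)
  res <- switch(technique,
    mean = mean_threshold(q, source_id = source_id),
    otsu = otsu_threshold(q, source_id = source_id),
    max_edge = max_edge_threshold(q, sigma = edge_sigma, low = edge_low,
                                  high = edge_high, source_id = source_id),
    edge_similarity = edge_similarity_threshold(
      q, sigma = edge_sigma, low = edge_low, high = edge_high,
      source_id = source_id))
  mooney <- apply_threshold(q, res$value, technique = technique,
                            source_id = source_id)
  list(mooney = mooney, result = res)
}

check_gray8 <- function(img) {
  if (!is.matrix(img) || length(img) == 0L) {
    stop("`img` must be a non-empty matrix", call. = FALSE)
  }
  rng <- range(img)
  if (!all(is.finite(rng)) || rng[1L] < 0 || rng[2L] > 255 ||
      any(img != floor(img))) {
    stop("`img` must contain integer values in [0, 255]; apply quantize8() ",
         "first", call. = FALSE)
  }
  invisible(img)
}
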