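#' Dissimilarity ratio between two Mooney images
#'
#' The fraction of pixel positions at which two equal-sized binary images
#' disagree (a normalized Hamming distance). A value of 0 means the images
#' are identical; 1 means they are polarity-reversed versions of each other
#' (every white pixel in one is black in the other).
#'
#' @param a,b binary matrices of identical shape (0/255 Mooney images or
#'   logical matrices).
#' @return a value in `[0, 1]`.
#' @export
dissimilarity_ratio <- function(a, b) {
  a <- as_binary(a); b <- as_binary(b)
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical shapes", call. = FALSE)
  }
  mean(a != b)
}

as_binary <- function(x) {
  if (inherits(x, "mooney_image")) x <- unclass(x)
  if (is.logical(x)) return(x)
  if (!is.matrix(x)) stop("expected a matrix", call. = FALSE)
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 255) | v %in% c(0, 1))) {
    stop("expected a binary image (values 0/255 or logical)", call. = FALSE)
  }
  x > 0
}

#' Standard deviation of the four thresholds selected for one image
#'
#' @param thresholds numeric vector of exactly four thresholds (one per
#'   technique).
#' @param type `"sample"` (denominator n-1, the default) or `"population"`
#'   (denominator n).
#' @return the standard deviation.
#' @export
per_image_threshold_sd <- function(thresholds, type = c("sample", "population")) {
  type <- match.arg(type)
  if (length(thresholds) != 4L) {
    stop("expected exactly four thresholds (one per technique)", call. = FALSE)
  }
  if (any(!is.finite(thresholds))) stop("non-finite threshold", call. = FALSE)
  s <- stats::sd(thresholds)
  if (type == "population") s <- s * sqrt(3 / 4)
  s
}

#' Summarize threshold distributions per technique
#'
#' One summary row per technique: count, mean, standard deviation, quartiles
#' (linear interpolation, `stats::quantile` type 7) and Tukey whisker bounds
#' (the most extreme observations within 1.5 IQR of the box).
#'
#' @param table data frame with columns `source_id`, `technique`, `sigma`,
#'   `threshold` (the manifest written by [run_batch()] has this layout).
#' @return data frame with one row per technique present in `table`.
#' @export
threshold_distribution_summary <- function(table) {
  need <- c("technique", "threshold")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("`table` must contain columns `technique` and `threshold`",
         call. = FALSE)
  }
  if (nrow(table) == 0L) stop("`table` is empty", call. = FALSE)
  groups <- split(table$threshold, table$technique)
  rows <- lapply(names(groups), function(tech) {
    x <- groups[[tech]]
    if (length(x) == 0L) {
      warning("no thresholds for technique ", tech, "; skipped")
      return(NULL)
    }
    q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3L] - q[1L]
    lo <- min(x[x >= q[1L] - 1.5 * iqr])
    hi <- max(x[x <= q[3L] + 1.5 * iqr])
    data.frame(technique = tech, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               q1 = q[1L], median = q[2L], q3 = q[3L],
               whisker_low = lo, whisker_high = hi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean pairwise dissimilarity matrix across techniques
#'
#' For each image, all pairs of its technique variants are compared with
#' [dissimilarity_ratio()]; entries are the unweighted means over images.
#' The result is symmetric with a zero diagonal.
#'
#' @param mooneys list of images; each element is a named list holding the
#'   binary variant produced by each technique (all four techniques present,
#'   common shape within an image).
#' @param techniques technique names defining row/column order; defaults to
#'   the techniques named in the first element.
#' @return a symmetric numeric matrix with technique-labelled dimensions.
#' @export
pairwise_dissimilarity_matrix <- function(mooneys, techniques = NULL) {
  if (length(mooneys) == 0L) stop("`mooneys` is empty", call. = FALSE)
  if (is.null(techniques)) techniques <- names(mooneys[[1L]])
  k <- length(techniques)
  ids <- names(mooneys)
  if (is.null(ids)) ids <- as.character(seq_along(mooneys))
  acc <- matrix(0, k, k, dimnames = list(techniques, techniques))
  for (i in seq_along(mooneys)) {
    var_i <- mooneys[[i]]
    missing <- setdiff(techniques, names(var_i))
    if (length(missing)) {
      stop("image ", ids[i], " is missing technique variant(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (p in seq_len(k - 1L)) {
      for (q in (p + 1L):k) {
        d <- dissimilarity_ratio(var_i[[techniques[p]]],
                                 var_i[[techniques[q]]])
        acc[p, q] <- acc[p, q] + d
        acc[q, p] <- acc[q, p] + d
      }
    }
  }
  acc / length(mooneys)
}

#' Stratify images into difficulty groups by identification accuracy
#'
#' Images whose concept was detected in more than 75% of presentations are
#' "easy"; in more than 25% and up to 75%, "medium"; in 25% or fewer,
#' "difficult". The three groups partition `[0, 1]` exactly.
#'
#' @param p numeric vector of per-image proportions correct in `[0, 1]`.
#' @return factor with levels `easy`, `medium`, `difficult`.
#' @export
difficulty_stratify <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  lab <- ifelse(p > 0.75, "easy", ifelse(p > 0.25, "medium", "difficult"))
  factor(lab, levels = c("easy", "medium", "difficult"))
}
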