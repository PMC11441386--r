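#' The 13 shape-related embedding dimensions
#'
#' Names of the shape-related dimensions of the 49-dimensional THINGS
#' concept embedding used to define the similarity space for foil selection.
#'
#' @return character vector of 13 dimension names.
#' @export
shape_dimensions <- function() {
  c("disc-shaped", "course pattern", "paper-related/text-related",
    "long-thin", "powdery/fine-scale pattern", "spherical",
    "repetitiveness", "flat/patterned", "thin/flat", "stringy",
    "has beams/support", "has grating", "cylindrical/conical")
}

#' Read a concept-embedding table from CSV
#'
#' Expects a header row of dimension names and a first column of concept
#' names; remaining columns are real-valued embedding dimensions.
#'
#' @param path CSV file path.
#' @return numeric matrix with concept row names and dimension column names.
#' @export
read_embedding <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("embedding CSV needs a concept column plus at ",
                          "least one dimension", call. = FALSE)
  concepts <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- concepts
  validate_embedding(m)
  m
}

validate_embedding <- function(m) {
  if (anyDuplicated(rownames(m))) {
    stop("duplicate concept names in embedding", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate dimension names in embedding", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("non-finite embedding values", call. = FALSE)
  invisible(m)
}

#' Project an embedding onto a named subspace
#'
#' Restricts the embedding to the listed dimensions, preserving their listed
#' order. Dimension names are matched case-insensitively (published column
#' labels and the appendix's spellings differ in case); any name that still
#' fails to match is reported in the error.
#'
#' @param table numeric matrix as returned by [read_embedding()].
#' @param subspace character vector of dimension names; defaults to the 13
#'   shape-related dimensions of [shape_dimensions()].
#' @return the projected matrix, columns in `subspace` order.
#' @export
project_shape <- function(table, subspace = shape_dimensions()) {
  validate_embedding(table)
  idx <- match(tolower(subspace), tolower(colnames(table)))
  if (anyNA(idx)) {
    stop("dimension(s) not present in embedding: ",
         paste(subspace[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  table[, idx, drop = FALSE]
}

#' Select shape-similar foil concepts
#'
#' Returns the `k` concepts nearest to the query concept by Euclidean
#' distance in the embedding space (excluding the query itself), ordered by
#' distance with ties broken alphabetically. Applied to the shape-related
#' projection, this yields foil answers that are harder to discriminate from
#' the correct concept than random foils.
#'
#' @param concept query concept name (must be a row of `table`).
#' @param table numeric embedding matrix, typically the output of
#'   [project_shape()].
#' @param k number of foils (default 3).
#' @return character vector of `k` concept names.
#' @export
select_foils <- function(concept, table, k = 3L) {
  validate_embedding(table)
  if (!concept %in% rownames(table)) {
    stop("unknown concept: ", concept, call. = FALSE)
  }
  if (k < 1L || k > nrow(table) - 1L) {
    stop("`k` must be between 1 and the number of other concepts (",
         nrow(table) - 1L, ")", call. = FALSE)
  }
  q <- table[concept, ]
  others <- rownames(table)[rownames(table) != concept]
  d <- sqrt(colSums((t(table[others, , drop = FALSE]) - q)^2))
  others[order(d, others)][seq_len(k)]
}

#' Write a foil table for a set of concepts
#'
#' @param concepts character vector of query concepts.
#' @param table embedding matrix (already projected, if desired).
#' @param path output CSV path; columns `concept`, `foil1` .. `foilk`.
#' @param k number of foils per concept.
#' @return the foil data frame, invisibly.
#' @export
write_foil_table <- function(concepts, table, path, k = 3L) {
  rows <- lapply(concepts, function(cn) {
    f <- select_foils(cn, table, k = k)
    stats::setNames(data.frame(cn, t(f), stringsAsFactors = FALSE),
                    c("concept", paste0("foil", seq_len(k))))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
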