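#' Batch Mooney image generation
#'
#' Runs the full pipeline over a set of template images for every requested
#' (technique, sigma) combination, writing one single-channel 8-bit Mooney
#' PNG per combination plus a CSV manifest. Output files are named
#' `{source_id}__{technique}__s{sigma}.png`; re-running with the same
#' configuration overwrites them deterministically. Unreadable inputs are
#' logged and skipped; the number of skips is recorded on the manifest.
#'
#' @param inputs character vector of PNG/JPEG paths, or a named list of
#'   in-memory images (matrices / RGB arrays on the 0-255 scale).
#' @param out_dir output directory (created if missing).
#' @param techniques subset of [mooney_techniques()] (default: all four).
#' @param sigmas smoothing kernel standard deviations in pixels; the default
#'   `2` matches single-level generation, `c(2, 4, 6)` spans the useful
#'   smoothing range (4 techniques x 3 sigmas = 12 variants per template).
#' @param weights grayscale conversion weights, see [to_grayscale()].
#' @param boundary smoothing boundary mode, see [smooth_gaussian()].
#' @param edge_sigma,edge_low,edge_high Canny parameters for the spatial
#'   selectors.
#' @param verbose emit per-stage progress on stderr.
#' @return data frame manifest with columns `source_id`, `technique`,
#'   `sigma`, `threshold`, `objective_opt`, `file`; attribute `n_skipped`
#'   counts unreadable inputs. Also written to `out_dir/manifest.csv`.
#' @export
run_batch <- function(inputs, out_dir,
                      techniques = mooney_techniques(), sigmas = 2,
                      weights = c(0.2126, 0.7152, 0.0722),
                      boundary = "reflect",
                      edge_sigma = 1, edge_low = 0.1, edge_high = 0.2,
                      verbose = FALSE) {
  if (length(techniques) == 0L || !all(techniques %in% mooney_techniques())) {
    stop("`techniques` must be a non-empty subset of: ",
         paste(mooney_techniques(), collapse = ", "), call. = FALSE)
  }
  if (length(sigmas) == 0L || any(sigmas <= 0)) {
    stop("`sigmas` must be positive", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) if (verbose) message(...)

  if (is.character(inputs)) {
    ids <- sub("\\.[^.]+$", "", basename(inputs))
    getter <- function(i) read_image(inputs[[i]])
  } else if (is.list(inputs)) {
    ids <- names(inputs)
    if (is.null(ids) || any(ids == "")) {
      stop("in-memory `inputs` must be a fully named list", call. = FALSE)
    }
    getter <- function(i) inputs[[i]]
  } else {
    stop("`inputs` must be file paths or a named list of images",
         call. = FALSE)
  }
  if (length(inputs) == 0L) {
    warning("empty input set; nothing to do")
    manifest <- empty_manifest()
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    attr(manifest, "n_skipped") <- 0L
    return(invisible(manifest))
  }

  rows <- list()
  n_skipped <- 0L
  for (i in seq_along(inputs)) {
    id <- ids[[i]]
    img <- tryCatch(getter(i), error = function(e) {
      message("skipping ", id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) { n_skipped <- n_skipped + 1L; next }
    gray <- to_grayscale(img, weights = weights)
    for (sg in sigmas) {
      log_line("[", id, "] smoothing at sigma = ", sg)
      q <- quantize8(smooth_gaussian(gray, sg, boundary = boundary))
      for (tech in techniques) {
        log_line("[", id, "] selecting threshold: ", tech)
        res <- switch(tech,
          mean = mean_threshold(q, source_id = id),
          otsu = otsu_threshold(q, source_id = id),
          max_edge = max_edge_threshold(q, sigma = edge_sigma,
                                        low = edge_low, high = edge_high,
                                        source_id = id),
          edge_similarity = edge_similarity_threshold(
            q, sigma = edge_sigma, low = edge_low, high = edge_high,
            source_id = id))
        mooney <- apply_threshold(q, res$value, technique = tech,
                                  source_id = id)
        fname <- sprintf("%s__%s__s%s.png", id, tech, format(sg))
        fpath <- file.path(out_dir, fname)
        write_gray_png(unclass(mooney), fpath)
        opt <- if (is.null(res$objective_curve)) NA_real_ else {
          if (tech == "edge_similarity") min(res$objective_curve)
          else max(res$objective_curve)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = id, technique = tech, sigma = sg,
          threshold = res$value, objective_opt = opt, file = fname,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else empty_manifest()
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "n_skipped") <- n_skipped
  invisible(manifest)
}

empty_manifest <- function() {
  data.frame(source_id = character(), technique = character(),
             sigma = numeric(), threshold = numeric(),
             objective_opt = numeric(), file = character(),
             stringsAsFactors = FALSE)
}

#' Evaluate a batch of Mooney images
#'
#' Recomputes the image-level statistics from a [run_batch()] output
#' directory: the per-technique threshold distribution summary, the mean
#' per-image standard deviation of the four thresholds, and the mean
#' pairwise dissimilarity matrix between technique variants (per sigma,
#' averaged over images).
#'
#' @param batch_dir directory containing `manifest.csv` and the Mooney PNGs.
#' @param write if `TRUE`, write `threshold_summary.csv`,
#'   `per_image_sd.csv` and `dissimilarity_s{sigma}.csv` into `batch_dir`.
#' @return list with elements `summary` (data frame), `per_image_sd`
#'   (data frame of source_id, sigma, sd), `mean_sd` (scalar), and
#'   `dissimilarity` (named list of matrices, one per sigma).
#' @export
evaluate_batch <- function(batch_dir, write = TRUE) {
  mf <- file.path(batch_dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", batch_dir, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0L) stop("manifest is empty", call. = FALSE)
  summary <- threshold_distribution_summary(manifest)

  sd_rows <- list()
  diss <- list()
  for (sg in unique(manifest$sigma)) {
    sub <- manifest[manifest$sigma == sg, ]
    per_image <- split(sub, sub$source_id)
    complete <- Filter(function(d) {
      all(mooney_techniques() %in% d$technique)
    }, per_image)
    for (id in names(complete)) {
      sd_rows[[length(sd_rows) + 1L]] <- data.frame(
        source_id = id, sigma = sg,
        sd = per_image_threshold_sd(
          complete[[id]]$threshold[match(mooney_techniques(),
                                         complete[[id]]$technique)]))
    }
    if (length(complete)) {
      sets <- lapply(complete, function(d) {
        imgs <- lapply(mooney_techniques(), function(tech) {
          read_image(file.path(batch_dir,
                               d$file[d$technique == tech][1L]))
        })
        stats::setNames(imgs, mooney_techniques())
      })
      diss[[format(sg)]] <- pairwise_dissimilarity_matrix(
        sets, techniques = mooney_techniques())
    }
  }
  per_image_sd <- if (length(sd_rows)) do.call(rbind, sd_rows) else
    data.frame(source_id = character(), sigma = numeric(), sd = numeric())
  out <- list(summary = summary, per_image_sd = per_image_sd,
              mean_sd = if (nrow(per_image_sd)) mean(per_image_sd$sd)
                        else NA_real_,
              dissimilarity = diss)
  if (write) {
    utils::write.csv(summary, file.path(batch_dir, "threshold_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(per_image_sd, file.path(batch_dir, "per_image_sd.csv"),
                     row.names = FALSE)
    for (sg in names(diss)) {
      utils::write.csv(data.frame(technique = rownames(diss[[sg]]),
                                  diss[[sg]], check.names = FALSE),
                       file.path(batch_dir,
                                 sprintf("dissimilarity_s%s.csv", sg)),
                       row.names = FALSE)
    }
  }
  out
}

#' Load a run configuration from a JSON file
#'
#' Recognised keys mirror the arguments of [run_batch()]: `techniques`,
#' `sigmas`, `weights`, `boundary`, `edge_sigma`, `edge_low`, `edge_high`,
#' `seed`. Unknown keys raise an error. Precedence when used from the
#' command line is flags > config file > package defaults.
#'
#' @param path JSON file path.
#' @return named list of configuration values.
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("techniques", "sigmas", "weights", "boundary",
             "edge_sigma", "edge_low", "edge_high", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg
}
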