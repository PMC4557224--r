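# Run configuration and the end-to-end pipeline:
# detect -> field -> colocalization / intersection / sinks.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with the defaults used in the
#' package's reference experiments. All randomness (only the synthetic
#' generator uses any) flows from `seed`.
#'
#' @param mode RBF mode, `"direct"`, `"indirect"` or `"custom"`.
#' @param beta,gamma Shape parameters for `mode = "custom"`.
#' @param pair_threshold Background threshold for [pair_fields()] (0--100).
#' @param pair_rule Background rule for [pair_fields()].
#' @param manders_threshold Threshold for [manders_m1_m2()] (0--100).
#' @param bins Histogram bins over the normalized scale.
#' @param max_dist Stained-classification range, pixels.
#' @param rel_sink_threshold Relative divergence threshold in (0, 1).
#' @param seed Integer seed.
#' @param pixel_size_um Physical pixel size, micrometres (reporting only).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = "direct", beta = NULL, gamma = NULL,
                       pair_threshold = 25, pair_rule = "zero",
                       manders_threshold = 50, bins = 100, max_dist = 5,
                       rel_sink_threshold = 0.3, seed = 1,
                       pixel_size_um = 0.5) {
  params <- rbf_params(mode, beta = beta, gamma = gamma)
  stopifnot(pair_threshold >= 0, pair_threshold <= 100,
            manders_threshold >= 0, manders_threshold <= 100,
            bins >= 2, max_dist >= 0,
            rel_sink_threshold > 0, rel_sink_threshold < 1)
  structure(
    list(params = params, pair_threshold = pair_threshold,
         pair_rule = pair_rule, manders_threshold = manders_threshold,
         bins = as.integer(bins), max_dist = max_dist,
         rel_sink_threshold = rel_sink_threshold, seed = as.integer(seed),
         pixel_size_um = pixel_size_um),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> mode %s (beta %g, gamma %g), pair threshold %g (%s), Manders %g, bins %d, max_dist %g px, sink rel %g, seed %d, %g um/px\n",
    x$params$mode, x$params$beta, x$params$gamma, x$pair_threshold,
    x$pair_rule, x$manders_threshold, x$bins, x$max_dist,
    x$rel_sink_threshold, x$seed, x$pixel_size_um))
  invisible(x)
}

config_snapshot <- function(config) {
  list(mode = config$params$mode, alpha = config$params$alpha,
       beta = config$params$beta, gamma = config$params$gamma,
       pair_threshold = config$pair_threshold, pair_rule = config$pair_rule,
       manders_threshold = config$manders_threshold, bins = config$bins,
       max_dist = config$max_dist,
       rel_sink_threshold = config$rel_sink_threshold, seed = config$seed,
       pixel_size_um = config$pixel_size_um)
}

#' Run the full analysis pipeline on a registered image pair
#'
#' Detects cells in two registered RGB images (or accepts ready-made
#' centroid tables), builds the normalized summation field of the stained
#' population of each image, and runs the requested analyses. The two
#' images must already be registered; the pipeline performs no alignment.
#'
#' @param config A [run_config()].
#' @param image_a,image_b RGB arrays, [make_pseudo_ihc()] results, file
#'   paths, or centroid tibbles (`row`, `col`, `stained`) with a
#'   `source_shape` attribute.
#' @param analyses Subset of `c("coloc", "intersect", "sinks")`.
#' @return An `analysis_report` with the config snapshot and one entry per
#'   analysis. `glance()` flattens it to one row.
#' @export
run_pipeline <- function(config, image_a, image_b,
                         analyses = c("coloc", "intersect", "sinks")) {
  stopifnot(inherits(config, "run_config"))
  analyses <- match.arg(analyses, several.ok = TRUE)
  prep <- function(x) {
    if (is.character(x)) x <- read_image(x)
    if (is.data.frame(x)) {
      shape <- attr(x, "source_shape")
      if (is.null(shape)) abort("centroid table lacks a source_shape attribute")
      list(centroids = x, shape = as.integer(shape))
    } else {
      det <- detect_cells(x, max_dist = config$max_dist)
      list(centroids = det$centroids,
           shape = as.integer(attr(det$centroids, "source_shape")))
    }
  }
  a <- prep(image_a); b <- prep(image_b)
  if (!identical(a$shape, b$shape))
    stop_shape("images must have equal (registered) dimensions")
  stained_pts <- function(p) {
    pts <- dplyr::filter(p$centroids, .data$stained)
    if (nrow(pts) == 0L)
      abort("no stained centroids detected", class = "histofield_empty_error")
    as.matrix(pts[, c("row", "col")])
  }
  fa <- point_field(stained_pts(a), a$shape, config$params)
  fb <- point_field(stained_pts(b), b$shape, config$params)
  results <- list()
  if ("coloc" %in% analyses)
    results$coloc <- coloc_stats(fa, fb, threshold = config$pair_threshold,
                                 rule = config$pair_rule,
                                 manders_threshold = config$manders_threshold)
  if ("intersect" %in% analyses)
    results$intersection <- histogram_intersection(fa, fb, n_bins = config$bins)
  if ("sinks" %in% analyses) {
    ffull_a <- point_field(stained_pts(a), a$shape, config$params, extent = "full")
    results$sinks <- divergence_sinks(ffull_a, config$rel_sink_threshold)
  }
  structure(
    list(config = config_snapshot(config),
         n_centroids = c(a = nrow(a$centroids), b = nrow(b$centroids)),
         n_stained = c(a = sum(a$centroids$stained), b = sum(b$centroids$stained)),
         results = results,
         version = as.character(utils::packageVersion("histofield")),
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  centroids: %d / %d (stained %d / %d)\n",
              x$n_centroids[1], x$n_centroids[2], x$n_stained[1], x$n_stained[2]))
  if (!is.null(x$results$coloc)) print(x$results$coloc)
  if (!is.null(x$results$intersection))
    cat(sprintf("  histogram intersection: %.3f\n", x$results$intersection))
  if (!is.null(x$results$sinks)) print(x$results$sinks)
  invisible(x)
}

#' @method glance analysis_report
#' @export
glance.analysis_report <- function(x, ...) {
  out <- tibble(
    n_centroids_a = x$n_centroids[["a"]], n_centroids_b = x$n_centroids[["b"]],
    n_stained_a = x$n_stained[["a"]], n_stained_b = x$n_stained[["b"]]
  )
  if (!is.null(x$results$coloc))
    out <- dplyr::bind_cols(out, glance(x$results$coloc))
  if (!is.null(x$results$intersection))
    out$intersection <- x$results$intersection
  if (!is.null(x$results$sinks))
    out$n_sinks <- x$results$sinks$n_sinks
  out
}

#' Serialize an analysis report to JSON
#'
#' The JSON body (without the timestamp) is a pure function of inputs and
#' config, so reruns with the same seed are byte-identical up to that
#' field.
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @param timestamp Include the timestamp field (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, timestamp = TRUE) {
  body <- list(
    config = report$config,
    n_centroids = as.list(report$n_centroids),
    n_stained = as.list(report$n_stained),
    version = report$version
  )
  if (timestamp) body$timestamp <- report$timestamp
  r <- report$results
  if (!is.null(r$coloc)) body$coloc <- unclass(glance(r$coloc))
  if (!is.null(r$intersection)) body$intersection <- r$intersection
  if (!is.null(r$sinks))
    body$sinks <- list(n_sinks = r$sinks$n_sinks,
                       centroids = r$sinks$sink_centroids,
                       divergence_threshold = r$sinks$divergence_threshold)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
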