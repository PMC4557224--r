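# Preprocessing of brightfield IHC images: colour deconvolution, nucleus
# segmentation with watershed separation, centroid extraction and
# stained/non-stained classification. The input stack is assumed to be
# registered already; no alignment is attempted here.

#' Separate DAB and hematoxylin densities by colour deconvolution
#'
#' Optical-density unmixing after Ruifrok and Johnston with the standard
#' H-DAB stain matrix: per pixel, OD = -log10(I/255) per RGB channel is
#' projected onto the stain basis. Negative concentrations (off-basis
#' noise) are clipped to zero.
#'
#' @param rgb A `height x width x 3` array with values in 0--255, or a
#'   [make_pseudo_ihc()] result.
#' @return A list of class `channel_pair` with matrices `brown` (DAB) and
#'   `blue` (hematoxylin) of per-pixel stain densities (>= 0).
#' @examples
#' im <- make_pseudo_ihc(128, 128, 3, 5, 0, seed = 1)
#' ch <- colour_deconvolve(im)
#' dim(ch$brown)
#' @export
colour_deconvolve <- function(rgb) {
  if (inherits(rgb, "pseudo_ihc")) rgb <- rgb$pixels
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L))
    abort("input must be an RGB array (height x width x 3)",
          class = "histofield_format_error")
  if (min(rgb) < 0 || max(rgb) > 255)
    abort("RGB values must lie in [0, 255]", class = "histofield_format_error")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  od <- -log10(pmax(matrix(rgb, h * w, 3), 0.5) / 255)
  conc <- od %*% solve(hdab_stain_matrix())   # pixels x stains
  conc[conc < 0] <- 0
  structure(
    list(brown = matrix(conc[, 2], h, w), blue = matrix(conc[, 1], h, w)),
    class = "channel_pair"
  )
}

# Local maxima of a matrix with a minimum separation, greedy by height.
# Ties are resolved by column-major scan order (which.max convention).
find_seeds <- function(x, mask, min_sep = 5) {
  cand <- which(mask & x > 0)
  if (length(cand) == 0L) return(matrix(integer(), 0, 2))
  h <- nrow(x)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  sel <- matrix(numeric(), 0, 2)
  for (p in ord) {
    r <- ((p - 1L) %% h) + 1L; cc <- ((p - 1L) %/% h) + 1L
    if (nrow(sel) > 0 && any((sel[, 1] - r)^2 + (sel[, 2] - cc)^2 < min_sep^2)) next
    # keep only local maxima of x within a 3x3 neighbourhood
    rr <- max(1, r - 1):min(nrow(x), r + 1)
    ccr <- max(1, cc - 1):min(ncol(x), cc + 1)
    if (x[r, cc] < max(x[rr, ccr])) next
    sel <- rbind(sel, c(r, cc))
  }
  sel
}

#' Segment nuclei in a stain density channel
#'
#' Thresholds the channel (Otsu unless a threshold is given), labels
#' 8-connected foreground components, and splits touching blobs by a
#' marker-based watershed on the chamfer distance transform: seeds are
#' distance-transform maxima at least `seed_min_sep` pixels apart, and each
#' foreground pixel is assigned to its nearest seed within its component.
#'
#' @param channel Non-negative matrix (e.g. `colour_deconvolve()$blue`).
#' @param threshold Foreground threshold; `NULL` for Otsu.
#' @param min_size Discard components smaller than this many pixels.
#' @param seed_min_sep Minimum seed separation in pixels.
#' @return Integer label matrix, 0 = background; an all-background channel
#'   yields an all-zero labelling.
#' @export
segment_nuclei <- function(channel, threshold = NULL, min_size = 4,
                           seed_min_sep = 5) {
  stopifnot(is.matrix(channel))
  if (any(!is.finite(channel)) || min(channel) < 0)
    abort("channel must be finite and non-negative")
  if (max(channel) == 0) return(matrix(0L, nrow(channel), ncol(channel)))
  thr <- if (is.null(threshold)) otsu_threshold(channel) else threshold
  mask <- channel > thr
  if (!any(mask)) return(matrix(0L, nrow(channel), ncol(channel)))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) return(matrix(0L, nrow(channel), ncol(channel)))
  mask <- mask & lab %in% keep
  lab <- label_components(mask)

  dt <- chamfer_dt(mask)
  seeds <- find_seeds(dt, mask, min_sep = seed_min_sep)
  if (nrow(seeds) == 0L) return(lab)
  seed_comp <- lab[seeds]
  out <- matrix(0L, nrow(channel), ncol(channel))
  fg <- which(mask, arr.ind = TRUE)
  fg_comp <- lab[mask]
  # nearest seed within the same connected component
  assign_id <- integer(nrow(fg))
  for (comp in unique(fg_comp)) {
    sidx <- which(seed_comp == comp)
    pidx <- which(fg_comp == comp)
    if (length(sidx) == 0L) { assign_id[pidx] <- 0L; next }
    sr <- seeds[sidx, 1]; sc <- seeds[sidx, 2]
    d2 <- outer(fg[pidx, 1], sr, "-")^2 + outer(fg[pidx, 2], sc, "-")^2
    assign_id[pidx] <- sidx[max.col(-d2, ties.method = "first")]
  }
  keeppix <- assign_id > 0L
  out[fg[keeppix, , drop = FALSE]] <- assign_id[keeppix]
  # relabel consecutively
  ids <- sort(unique(out[out > 0]))
  relab <- integer(max(ids)); relab[ids] <- seq_along(ids)
  out[out > 0] <- relab[out[out > 0]]
  out
}

#' Extract one centroid per labelled region
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @return A tibble (`row`, `col`, `stained`) with one row per label at the
#'   rounded mean pixel position; `stained` is initialised to `FALSE`. The
#'   image size is kept in the `source_shape` attribute.
#' @export
extract_centroids <- function(labels) {
  stopifnot(is.matrix(labels))
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    out <- tibble(row = integer(), col = integer(), stained = logical())
  } else {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    rows <- round(tapply(idx[, 1], lab, mean))
    cols <- round(tapply(idx[, 2], lab, mean))
    out <- tibble(row = as.integer(rows), col = as.integer(cols),
                  stained = FALSE)
  }
  attr(out, "source_shape") <- dim(labels)
  out
}

#' Classify centroids as stained by distance to a stained-area mask
#'
#' A centroid is `stained` when its Euclidean distance to the nearest
#' mask-positive pixel is at most `max_dist` pixels (a centroid inside the
#' mask has distance 0). Monotone in `max_dist` by construction.
#'
#' @param centroids Tibble with `row`, `col` (from [extract_centroids()]).
#' @param stained_mask Binary matrix, same size as the source image.
#' @param max_dist Maximum distance in pixels (>= 0); default 5
#'   (about 2.5 micrometres at 0.5 um/px).
#' @return The centroid tibble with `stained` set.
#' @export
classify_stained <- function(centroids, stained_mask, max_dist = 5) {
  stopifnot(is.data.frame(centroids))
  shape <- attr(centroids, "source_shape")
  if (!is.null(shape) && !identical(as.integer(shape), as.integer(dim(stained_mask))))
    stop_shape("stained_mask size does not match the centroid source image")
  if (max_dist < 0) abort("max_dist must be >= 0")
  pos <- which(stained_mask != 0, arr.ind = TRUE)
  out <- centroids
  if (nrow(out) == 0L) return(out)
  if (nrow(pos) == 0L) {
    out$stained <- FALSE
    return(out)
  }
  md2 <- max_dist^2
  out$stained <- vapply(seq_len(nrow(out)), function(i) {
    d2 <- (pos[, 1] - out$row[i])^2 + (pos[, 2] - out$col[i])^2
    min(d2) <= md2
  }, logical(1))
  out
}

#' Full detection chain for one RGB IHC image
#'
#' Colour deconvolution, nucleus segmentation on the combined stain density
#' (all nuclei carry hematoxylin; DAB-only nuclei are also covered by adding
#' the brown density), then stained classification against the
#' Otsu-thresholded brown channel.
#'
#' @param rgb RGB array or [make_pseudo_ihc()] result.
#' @param max_dist Stained-classification range in pixels.
#' @param ... Passed to [segment_nuclei()].
#' @return A list with `centroids` (classified tibble), `labels`,
#'   `stained_mask`, and `channels`.
#' @export
detect_cells <- function(rgb, max_dist = 5, ...) {
  ch <- colour_deconvolve(rgb)
  nuc <- ch$blue + ch$brown
  labels <- segment_nuclei(nuc, ...)
  cents <- extract_centroids(labels)
  brown_thr <- otsu_threshold(ch$brown)
  stained_mask <- (ch$brown > brown_thr) * 1
  cents <- classify_stained(cents, stained_mask, max_dist = max_dist)
  list(centroids = cents, labels = labels, stained_mask = stained_mask,
       channels = ch)
}
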