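# Synthetic test images: binary point patterns, point clusters, and
# pseudo-immunohistochemistry images with ground truth. These stand in for
# scanned slides so that the whole pipeline is testable offline.

#' Binary image with points at given pixel coordinates
#'
#' @param height,width Image size in pixels.
#' @param points Two-column matrix or data frame of (row, col) coordinates,
#'   1-based. Duplicates collapse onto one pixel. May be empty.
#' @return A `height x width` matrix of 0/1.
#' @examples
#' img <- make_point_image(500, 500, cbind(251, 251))
#' sum(img)  # 1
#' @export
make_point_image <- function(height, width, points) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L)
    abort("image dimensions must be >= 1", class = "histofield_dim_error")
  img <- matrix(0, height, width)
  pts <- as.matrix(as.data.frame(points)[, 1:2, drop = FALSE])
  if (nrow(pts) == 0L) return(img)
  storage.mode(pts) <- "double"
  if (any(pts[, 1] < 1 | pts[, 1] > height | pts[, 2] < 1 | pts[, 2] > width))
    stop_coord(sprintf("point coordinates outside the %dx%d image", height, width))
  img[cbind(pts[, 1], pts[, 2])] <- 1
  img
}

#' Coordinates of a small point cluster
#'
#' `pattern = "cross"` places the centre plus up to four axis neighbours at
#' distance `spacing` (a quincunx for `n_points = 5`); `pattern = "line"`
#' places `n_points` along a row, centred. The nearest-neighbour distance of
#' a cross cluster equals `spacing` exactly.
#'
#' @param center `(row, col)` of the cluster centre.
#' @param n_points Number of points (>= 1; at most 5 for `"cross"`).
#' @param spacing Point spacing in pixels.
#' @param pattern `"cross"` or `"line"`.
#' @return Integer matrix of (row, col) coordinates.
#' @export
cluster_points <- function(center, n_points = 5, spacing = 25,
                           pattern = c("cross", "line")) {
  pattern <- match.arg(pattern)
  if (n_points < 1) abort("n_points must be >= 1")
  r <- center[1]; cc <- center[2]; s <- spacing
  pts <- switch(pattern,
    cross = {
      if (n_points > 5) abort("cross pattern supports at most 5 points")
      rbind(c(r, cc), c(r - s, cc), c(r + s, cc), c(r, cc - s), c(r, cc + s))[seq_len(n_points), , drop = FALSE]
    },
    line = {
      offs <- seq_len(n_points) - (n_points + 1) / 2
      cbind(r, cc + offs * s)
    }
  )
  storage.mode(pts) <- "integer"
  colnames(pts) <- c("row", "col")
  pts
}

#' Binary image holding a point cluster
#'
#' @inheritParams cluster_points
#' @inheritParams make_point_image
#' @return A binary matrix with the cluster's pixels set to 1.
#' @examples
#' img <- make_cluster_image(500, 500, c(251, 251), 5, 25)
#' sum(img)  # 5
#' @export
make_cluster_image <- function(height, width, center, n_points = 5,
                               spacing = 25, pattern = c("cross", "line")) {
  pts <- cluster_points(center, n_points, spacing, pattern)
  make_point_image(height, width, pts)
}

# Ruifrok-Johnston H-DAB stain vectors (unit optical-density directions).
# Rows: hematoxylin, DAB, residual (cross product).
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(h / sqrt(sum(h^2)), d / sqrt(sum(d^2)), r / sqrt(sum(r^2)))
  rownames(m) <- c("hematoxylin", "dab", "residual")
  m
}

#' Pseudo-immunohistochemistry image with ground truth
#'
#' Simulates a brightfield H-DAB stained section: round nuclei as blobs of
#' hematoxylin (blue) or DAB plus hematoxylin (brown, "stained"), optional
#' pale-green horizontal bone bands, on a near-white background. Pixel
#' colours are composed through the Beer--Lambert law from the
#' Ruifrok--Johnston H-DAB stain vectors, so [colour_deconvolve()]
#' recovers the generating densities. Blob centres are placed by rejection
#' sampling with a minimum separation of `2 * radius + 2` pixels, at least
#' `radius + 1` from the border and off the bone bands.
#'
#' @param height,width Image size.
#' @param n_stained,n_unstained Number of brown / blue nuclei.
#' @param bone_bands Number of horizontal bone bands (each 24 px high).
#' @param seed Integer seed fixing all randomness; the same arguments and
#'   seed give bit-identical output.
#' @param radius Nucleus radius in pixels.
#' @return A list of class `pseudo_ihc` with elements `pixels` (a
#'   `height x width x 3` array of 0--255 values), `truth` (tibble
#'   `row`, `col`, `stained`), and `bone_mask` (binary matrix).
#' @examples
#' im <- make_pseudo_ihc(256, 256, 5, 10, 1, seed = 7)
#' nrow(im$truth)  # 15
#' @export
make_pseudo_ihc <- function(height, width, n_stained, n_unstained,
                            bone_bands = 0, seed = 1, radius = 5) {
  if (n_stained < 0 || n_unstained < 0 || bone_bands < 0)
    abort("counts must be >= 0")
  height <- as.integer(height); width <- as.integer(width)
  withr::with_seed(as.integer(seed), {
    band_h <- 24L
    bone <- matrix(0, height, width)
    if (bone_bands > 0) {
      # evenly spaced horizontal bands
      centres <- round(seq(0.2, 0.8, length.out = bone_bands) * height)
      for (bc in centres) {
        r0 <- max(1L, bc - band_h %/% 2L); r1 <- min(height, bc + band_h %/% 2L)
        bone[r0:r1, ] <- 1
      }
    }
    n <- n_stained + n_unstained
    centres <- matrix(NA_integer_, 0, 2)
    min_sep2 <- (2 * radius + 2)^2
    tries <- 0L
    while (nrow(centres) < n) {
      tries <- tries + 1L
      if (tries > 200L * max(n, 1L))
        abort("could not place all blobs without overlap",
              class = "histofield_placement_error")
      r <- sample.int(height - 2L * (radius + 1L), 1L) + radius + 1L
      cc <- sample.int(width - 2L * (radius + 1L), 1L) + radius + 1L
      rr0 <- max(1L, r - radius - 1L):min(height, r + radius + 1L)
      if (any(bone[rr0, max(1L, cc - radius - 1L):min(width, cc + radius + 1L)] == 1)) next
      if (nrow(centres) > 0) {
        d2 <- (centres[, 1] - r)^2 + (centres[, 2] - cc)^2
        if (any(d2 < min_sep2)) next
      }
      centres <- rbind(centres, c(r, cc))
    }
    stained <- rep(c(TRUE, FALSE), c(n_stained, n_unstained))
    # per-pixel stain densities
    c_h <- matrix(0.02, height, width)   # faint background haze
    c_d <- matrix(0, height, width)
    if (n > 0) {
      for (i in seq_len(n)) {
        r <- centres[i, 1]; cc <- centres[i, 2]
        rr <- max(1L, r - radius):min(height, r + radius)
        ccr <- max(1L, cc - radius):min(width, cc + radius)
        sub <- expand.grid(rr, ccr)
        inside <- (sub[, 1] - r)^2 + (sub[, 2] - cc)^2 <= radius^2
        px <- as.matrix(sub[inside, ])
        if (stained[i]) {
          c_d[px] <- 1.0
          c_h[px] <- 0.3
        } else {
          c_h[px] <- 1.0
        }
      }
    }
    sm <- hdab_stain_matrix()
    pixels <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      od <- c_h * sm[1, ch] + c_d * sm[2, ch]
      pixels[, , ch] <- round(255 * 10^(-od))
    }
    # bone bands drawn as flat pale green, on top of the background only
    if (bone_bands > 0) {
      bg <- bone == 1
      bone_col <- c(205, 235, 205)
      for (ch in 1:3) {
        plane <- pixels[, , ch]
        plane[bg] <- bone_col[ch]
        pixels[, , ch] <- plane
      }
    }
    truth <- tibble(
      row = if (n > 0) as.integer(centres[, 1]) else integer(),
      col = if (n > 0) as.integer(centres[, 2]) else integer(),
      stained = stained
    )
    structure(list(pixels = pixels, truth = truth, bone_mask = bone),
              class = "pseudo_ihc")
  })
}

#' @export
print.pseudo_ihc <- function(x, ...) {
  cat(sprintf("<pseudo_ihc %dx%d> %d nuclei (%d stained), bone pixels: %d\n",
              dim(x$pixels)[1], dim(x$pixels)[2], nrow(x$truth),
              sum(x$truth$stained), sum(x$bone_mask)))
  invisible(x)
}
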