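# Independent oracles used across the suite. These deliberately avoid the
# package's FFT path: fields are built by direct summation of the RBF
# closed form over every pixel.

# Direct evaluation of the summation field for a set of points.
# extent = "image": truncated like the image-size-kernel convolution
#   (offsets limited to what the centred kernel window covers);
# extent = "full": the untruncated superposition.
brute_force_field <- function(points, shape, params, extent = "image") {
  h <- shape[1]; w <- shape[2]
  out <- matrix(0, h, w)
  cr <- floor(h / 2) + 1L
  cc <- floor(w / 2) + 1L
  for (i in seq_len(nrow(points))) {
    r0 <- points[i, 1]; c0 <- points[i, 2]
    for (r in seq_len(h)) for (cl in seq_len(w)) {
      dx <- cl - c0; dy <- r - r0
      if (extent == "image") {
        # kernel window covers offsets [1 - cr, h - cr] x [1 - cc, w - cc]
        if (dy < 1 - cr || dy > h - cr || dx < 1 - cc || dx > w - cc) next
      }
      out[r, cl] <- out[r, cl] +
        params$alpha * sqrt(1 / (params$beta + params$gamma * dx^2) +
                            1 / (params$beta + params$gamma * dy^2))
    }
  }
  out
}

# Plain-loop histogram binning over [0, 100].
brute_force_histogram <- function(values, n_bins) {
  masses <- numeric(n_bins)
  width <- 100 / n_bins
  for (v in as.numeric(values)) {
    b <- min(floor(v / width) + 1, n_bins)
    masses[b] <- masses[b] + 1
  }
  masses / length(values)
}

# Standard 500x500 test geometry: generic anchor one pixel off the kernel
# centre, moving point along the same row.
anchor_500 <- c(252L, 252L)

pair_point_fields <- function(d, params = rbf_direct(), shape = c(500, 500),
                              anchor = anchor_500) {
  list(
    a = point_field(cbind(anchor[1], anchor[2]), shape, params),
    b = point_field(cbind(anchor[1], anchor[2] + d), shape, params)
  )
}

# Wrap a plain matrix as an un-normalized field (tests of normalization
# and histogram behaviour on synthetic value grids).
new_field_for_test <- function(values, normalized = FALSE) {
  histofield:::new_scalar_field(values, params = rbf_direct(),
                                normalized = normalized, n_sources = 1L)
}
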