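# Internal numerical helpers: FFT convolution, connected components,
# chamfer distance transform, Otsu threshold.

# Zero-padded linear 2-D convolution, cropped so that the kernel's centre
# element (cr, cc) lands on each source pixel ("same"-size output, conv2
# style). Pads to 2/3/5-smooth sizes for the FFT.
conv2d_same <- function(src, ker, cr, cc) {
  h <- nrow(src); w <- ncol(src)
  kh <- nrow(ker); kw <- ncol(ker)
  ph <- stats::nextn(h + kh - 1L, c(2, 3, 5))
  pw <- stats::nextn(w + kw - 1L, c(2, 3, 5))
  ps <- pk <- matrix(0, ph, pw)
  ps[seq_len(h), seq_len(w)] <- src
  pk[seq_len(kh), seq_len(kw)] <- ker
  full <- Re(stats::fft(stats::fft(ps) * stats::fft(pk), inverse = TRUE)) / (ph * pw)
  # full linear result index = src index + ker index - 1
  full[(cr):(cr + h - 1L), (cc):(cc + w - 1L), drop = FALSE]
}

# Brute-force reference for conv2d_same; O(n^2 m^2), tests only but kept in
# the package so oracle and implementation share one crop convention.
conv2d_same_naive <- function(src, ker, cr, cc) {
  h <- nrow(src); w <- ncol(src)
  out <- matrix(0, h, w)
  idx <- which(src != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r0 <- idx[k, 1]; c0 <- idx[k, 2]
    for (r in seq_len(h)) {
      kr <- r - r0 + cr
      if (kr < 1 || kr > nrow(ker)) next
      for (cl in seq_len(w)) {
        kc <- cl - c0 + cc
        if (kc < 1 || kc > ncol(ker)) next
        out[r, cl] <- out[r, cl] + src[r0, c0] * ker[kr, kc]
      }
    }
  }
  out
}

# 8-connected component labelling of a logical matrix. Iterative BFS over
# foreground pixels only; returns an integer matrix (0 = background).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nb <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  current <- 0L
  queue <- integer(length(fg))
  for (s in fg) {
    if (lab[s] != 0L) next
    current <- current + 1L
    lab[s] <- current
    queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% h) + 1L
      for (d in nb) {
        q <- p + d
        if (q < 1L || q > h * w) next
        # guard against wrapping across matrix columns
        qr <- ((q - 1L) %% h) + 1L
        if (abs(qr - r) > 1L) next
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- current
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  lab
}

# Chamfer 3-4 distance transform (divided by 3 to approximate pixels) of a
# logical mask: distance from each TRUE pixel to the nearest FALSE pixel.
# Row sweeps are vectorised; the in-row running min uses the cummin trick
# min_k (v_k + a*(j-k)) = a*j + cummin(v_k - a*k).
chamfer_dt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  big <- 3 * (h + w)
  d <- matrix(0, h, w)
  d[mask] <- big
  run_min <- function(v, a) {
    j <- seq_along(v)
    fwd <- a * j + cummin(v - a * j)
    bwd <- rev(a * j + cummin(rev(v) - a * j))
    pmin(fwd, bwd)
  }
  for (r in seq_len(h)) {        # forward pass
    if (r > 1L) {
      up <- d[r - 1L, ]
      diag <- pmin(c(Inf, up[-w]) + 4, c(up[-1], Inf) + 4)
      d[r, ] <- pmin(d[r, ], up + 3, diag)
    }
    d[r, ] <- run_min(d[r, ], 3)
  }
  for (r in rev(seq_len(h))) {   # backward pass
    if (r < h) {
      dn <- d[r + 1L, ]
      diag <- pmin(c(Inf, dn[-w]) + 4, c(dn[-1], Inf) + 4)
      d[r, ] <- pmin(d[r, ], dn + 3, diag)
    }
    d[r, ] <- run_min(d[r, ], 3)
  }
  d / 3
}

#' Otsu's threshold
#'
#' Parameter-free foreground threshold: maximizes the between-class variance
#' over a 256-bin histogram of the value range. Used to binarize stain
#' density channels (e.g. the DAB channel for the stained-area mask).
#'
#' @param x Numeric matrix or vector.
#' @return The threshold value.
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  idx <- pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + k * (hi - lo) / nb
}

stop_shape <- function(msg) abort(msg, class = "histofield_shape_error")
stop_coord <- function(msg) abort(msg, class = "histofield_coord_error")
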