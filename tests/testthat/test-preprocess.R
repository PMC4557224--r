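test_that("colour deconvolution: white is empty, stain vectors round-trip", {
  white <- array(255, dim = c(2, 2, 3))
  ch <- colour_deconvolve(white)
  expect_lt(max(ch$brown), 1e-6)
  expect_lt(max(ch$blue), 1e-6)

  # a pixel composed from the pure DAB vector unmixes brown-dominant
  sm <- histofield:::hdab_stain_matrix()
  dab_px <- array(round(255 * 10^(-1.0 * sm[2, ])), dim = c(1, 1, 3))
  ch <- colour_deconvolve(dab_px)
  expect_gt(ch$brown[1, 1], ch$blue[1, 1])
  expect_gt(ch$brown[1, 1], 0.8)

  hem_px <- array(round(255 * 10^(-1.0 * sm[1, ])), dim = c(1, 1, 3))
  ch <- colour_deconvolve(hem_px)
  expect_gt(ch$blue[1, 1], ch$brown[1, 1])

  expect_error(colour_deconvolve(matrix(1, 4, 4)),
               class = "histofield_format_error")
})

test_that("thresholded brown channel recovers the stained blob count", {
  im <- make_pseudo_ihc(512, 512, 20, 30, 0, seed = 11)
  ch <- colour_deconvolve(im)
  mask <- ch$brown > otsu_threshold(ch$brown)
  lab <- histofield:::label_components(mask)
  expect_equal(max(lab), 20)
})

test_that("segmentation labels disjoint blobs and splits touching ones", {
  disc <- function(img, r0, c0, rad) {
    for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img)))
      if ((r - r0)^2 + (cc - c0)^2 <= rad^2) img[r, cc] <- 1
    img
  }
  img <- matrix(0, 60, 60)
  img <- disc(img, 15, 15, 6)
  img <- disc(img, 45, 45, 6)
  expect_equal(max(segment_nuclei(img)), 2)

  # overlapping discs, centres 1.2 radii apart -> split by watershed
  img2 <- matrix(0, 60, 60)
  img2 <- disc(img2, 30, 24, 8)
  img2 <- disc(img2, 30, 24 + round(1.2 * 8), 8)
  lab2 <- segment_nuclei(img2)
  expect_equal(max(lab2), 2)

  expect_equal(max(segment_nuclei(matrix(0, 30, 30))), 0)
})

test_that("centroid extraction: symmetric regions and label counts", {
  lab <- matrix(0L, 30, 30)
  lab[10:12, 10:12] <- 1L
  cents <- extract_centroids(lab)
  expect_equal(nrow(cents), 1)
  expect_equal(c(cents$row, cents$col), c(11, 11))
  expect_false(any(cents$stained))

  lab[20:22, 5:6] <- 2L
  lab[2, 25] <- 3L
  expect_equal(nrow(extract_centroids(lab)), 3)
})

test_that("stained classification: distance rule and monotonicity in max_dist", {
  mask <- matrix(0, 50, 50); mask[20:30, 20:30] <- 1
  cents <- tibble::tibble(row = c(25L, 25L, 25L), col = c(25L, 35L, 41L),
                          stained = FALSE)
  attr(cents, "source_shape") <- c(50L, 50L)
  c0 <- classify_stained(cents, mask, max_dist = 0)
  expect_equal(c0$stained, c(TRUE, FALSE, FALSE))
  c5 <- classify_stained(cents, mask, max_dist = 5)
  expect_equal(c5$stained, c(TRUE, TRUE, FALSE))   # 10 px away stays unstained
  c12 <- classify_stained(cents, mask, max_dist = 12)
  expect_equal(c12$stained, c(TRUE, TRUE, TRUE))
  # monotone: stained set grows with max_dist
  for (d in c(0, 2, 6, 12)) {
    lo <- classify_stained(cents, mask, max_dist = d)$stained
    hi <- classify_stained(cents, mask, max_dist = d + 3)$stained
    expect_true(all(hi[lo]))
  }
  bad <- cents; attr(bad, "source_shape") <- c(10L, 10L)
  expect_error(classify_stained(bad, mask), class = "histofield_shape_error")
})

test_that("full detection chain recovers ground truth on pseudo-IHC fixtures", {
  for (seed in c(7, 19)) {
    im <- make_pseudo_ihc(512, 512, 20, 50, 1, seed = seed)
    det <- detect_cells(im, max_dist = 5)
    cents <- det$centroids
    tr <- im$truth
    hits <- 0; flags <- 0
    for (i in seq_len(nrow(tr))) {
      d2 <- (cents$row - tr$row[i])^2 + (cents$col - tr$col[i])^2
      j <- which.min(d2)
      if (d2[j] <= 4) {
        hits <- hits + 1
        if (cents$stained[j] == tr$stained[i]) flags <- flags + 1
      }
    }
    expect_gte(hits / nrow(tr), 0.95)
    expect_equal(flags, hits)   # stained flags exactly reproduced
  }
})
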