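test_that("delta identity: a point at the kernel centre reproduces the kernel", {
  k <- build_kernel(rbf_direct(), 21, 21)
  f <- convolve_sources(cbind(11, 11), k)
  expect_equal(field_values(f), field_values(k), tolerance = 1e-10)
})

test_that("FFT convolution equals direct RBF summation on small grids", {
  p <- rbf_direct()
  withr::with_seed(42, {
    for (sh in list(c(17, 17), c(32, 24), c(9, 31))) {
      pts <- cbind(sample.int(sh[1], 3), sample.int(sh[2], 3))
      f <- point_field(pts, sh, p, normalize = FALSE)
      oracle <- brute_force_field(pts, sh, p, extent = "image")
      expect_equal(field_values(f), oracle, tolerance = 1e-9)
      ffull <- point_field(pts, sh, p, extent = "full", normalize = FALSE)
      oracle_full <- brute_force_field(pts, sh, p, extent = "full")
      expect_equal(field_values(ffull), oracle_full, tolerance = 1e-9)
    }
  })
})

test_that("fields are additive over disjoint source sets (pre-normalization)", {
  sh <- c(64, 64)
  a <- cbind(c(10, 20), c(15, 40))
  b <- cbind(50, 33)
  fa <- point_field(a, sh, normalize = FALSE)
  fb <- point_field(b, sh, normalize = FALSE)
  fab <- point_field(rbind(a, b), sh, normalize = FALSE)
  expect_equal(field_values(fab), field_values(fa) + field_values(fb),
               tolerance = 1e-9)
  expect_equal(fab$n_sources, 3L)
})

test_that("translation equivariance away from borders", {
  sh <- c(80, 80)
  f1 <- point_field(cbind(30, 30), sh, normalize = FALSE)
  f2 <- point_field(cbind(37, 34), sh, normalize = FALSE)
  # compare on an interior window, shifted by (7, 4)
  win <- 20:60
  expect_equal(field_values(f1)[win, win],
               field_values(f2)[win + 7, win + 4], tolerance = 1e-9)
})

test_that("mask convolution treats every positive pixel as a unit source", {
  sh <- c(40, 40)
  mask <- matrix(0, 40, 40); mask[18:22, 10] <- 1
  f <- point_field(mask, sh, normalize = FALSE)
  expect_equal(f$n_sources, 5L)
  pts <- cbind(18:22, 10)
  expect_equal(field_values(f),
               field_values(point_field(pts, sh, normalize = FALSE)),
               tolerance = 1e-10)
})

test_that("full-extent fields are strictly positive; image-extent fields of
           off-centre sources carry a zero strip", {
  sh <- c(50, 50)
  f_full <- point_field(cbind(10, 10), sh, extent = "full", normalize = FALSE)
  expect_gt(min(field_values(f_full)), 0)
  f_img <- point_field(cbind(10, 10), sh, extent = "image", normalize = FALSE)
  expect_equal(min(field_values(f_img)), 0)
})

test_that("normalization maps endpoints, preserves order, is idempotent on [0,100]", {
  withr::with_seed(7, {
    for (i in 1:5) {
      v <- matrix(runif(400, 5, 205), 20, 20)
      f <- new_field_for_test(v)
      fn <- normalize_field(f)
      expect_equal(min(field_values(fn)), 0)
      expect_equal(max(field_values(fn)), 100)
      expect_equal(cor(as.numeric(v), as.numeric(field_values(fn)),
                       method = "spearman"), 1)
    }
  })
  # endpoint mapping at stated values
  v <- matrix(c(5, 100, 150, 205), 2, 2)
  fn <- normalize_field(new_field_for_test(v))
  expect_equal(field_values(fn)[1, 1], 0)
  expect_equal(field_values(fn)[2, 2], 100)
  # canonical range is a fixed point
  fn2 <- normalize_field(fn)
  expect_equal(field_values(fn2), field_values(fn))
})

test_that("degenerate and invalid inputs error cleanly", {
  expect_error(normalize_field(new_field_for_test(matrix(3, 4, 4))),
               class = "histofield_degenerate_error")
  k <- build_kernel(rbf_direct(), 10, 10)
  expect_error(convolve_sources(matrix(0, 10, 10), k),
               class = "histofield_empty_error")
  expect_error(convolve_sources(matrix(1, 12, 12), k),
               class = "histofield_shape_error")
})
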