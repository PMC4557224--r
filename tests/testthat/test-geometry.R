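test_that("field histograms: mass one, brute-force agreement, state checks", {
  f <- pair_point_fields(0, shape = c(500, 500))$a
  h <- field_histogram(f, 100)
  expect_equal(sum(h$masses), 1, tolerance = 1e-9)
  expect_equal(h$masses, brute_force_histogram(field_values(f), 100))

  # one pixel at 100, rest at 0
  v <- matrix(0, 10, 10); v[5, 5] <- 100
  h2 <- field_histogram(new_field_for_test(v, normalized = TRUE), 10)
  expect_equal(h2$masses[1], 99 / 100)
  expect_equal(h2$masses[10], 1 / 100)

  raw <- point_field(cbind(5, 5), c(20, 20), normalize = FALSE)
  expect_error(field_histogram(raw), class = "histofield_state_error")
})

test_that("histogram intersection: identity, symmetry, bounds, bin checks", {
  fp <- pair_point_fields(80, shape = c(300, 300), anchor = c(151, 100))
  expect_equal(histogram_intersection(fp$a, fp$a), 1.0)
  i_ab <- histogram_intersection(fp$a, fp$b)
  expect_equal(i_ab, histogram_intersection(fp$b, fp$a))
  expect_true(i_ab >= 0 && i_ab <= 1)
  expect_lt(i_ab, 1)
  h1 <- field_histogram(fp$a, 50)
  h2 <- field_histogram(fp$b, 100)
  expect_error(histogram_intersection(h1, h2), class = "histofield_bin_error")
})

test_that("intersection profile is monotone non-increasing up to 200 px", {
  prof <- intersection_distance_profile(rbf_direct(), c(10, 25, 50, 100, 150, 200))
  expect_true(all(diff(prof$intersection) <= 0))
  expect_equal(prof$distance, c(10, 25, 50, 100, 150, 200))
  expect_error(
    intersection_distance_profile(rbf_direct(), 300),
    class = "histofield_coord_error"
  )
})

test_that("normalized gradient: unit mean, flat peak, analytic slope", {
  f <- pair_point_fields(0, shape = c(500, 500))$a
  g <- normalized_gradient(f)
  expect_equal(mean(g), 1, tolerance = 1e-9)
  # zero slope at the peak pixel (local maximum, symmetric neighbours)
  peak <- which(field_values(f) == 100, arr.ind = TRUE)[1, ]
  expect_lt(g[peak[1], peak[2]], 1e-6)

  # central differences match the analytic derivative of the kernel within
  # discretization error at a 20 px offset along the axis
  p <- rbf_direct()
  vals <- field_values(point_field(cbind(252, 252), c(500, 500), p,
                                   normalize = FALSE))
  gc <- histofield:::gradient_components(vals)
  d <- 20
  analytic <- -p$alpha * p$gamma * d /
    ((p$beta + p$gamma * d^2)^2 *
       sqrt(1 / (p$beta + p$gamma * d^2) + 1 / p$beta))
  expect_equal(gc$gc[252, 252 + d], analytic, tolerance = 0.02)

  flat <- new_field_for_test(matrix(5, 10, 10), normalized = TRUE)
  expect_error(normalized_gradient(flat), class = "histofield_degenerate_error")
})

test_that("discrete divergence theorem: domain integral equals boundary flux", {
  f <- point_field(cbind(101, 101), c(200, 200), extent = "full")
  div <- field_divergence(f, normalize = FALSE)
  g <- histofield:::gradient_components(field_values(f))
  # summing the difference operator telescopes to a boundary expression:
  # sum_i D(u)_i = 1.5 (u_n - u_1) - 0.5 (u_{n-1} - u_2) per line
  flux_r <- sum(1.5 * (g$gr[nrow(div), ] - g$gr[1, ]) -
                  0.5 * (g$gr[nrow(div) - 1, ] - g$gr[2, ]))
  flux_c <- sum(1.5 * (g$gc[, ncol(div)] - g$gc[, 1]) -
                  0.5 * (g$gc[, ncol(div) - 1] - g$gc[, 2]))
  expect_equal(sum(div), flux_r + flux_c, tolerance = 1e-9)
  # the interior contribution cancels: removing the boundary flux leaves
  # nothing compared with the total unsigned divergence
  expect_lt(abs(sum(div) - (flux_r + flux_c)), 1e-6 * sum(abs(div)))
})

test_that("sink detection: one sink per isolated object, fusion at close spacing", {
  sh <- c(500, 500)
  f1 <- point_field(cbind(251, 251), sh, extent = "full")
  s1 <- divergence_sinks(f1, 0.3)
  expect_equal(s1$n_sinks, 1)
  expect_lt(max(abs(unlist(s1$sink_centroids) - 251)), 3)

  counts <- sapply(c(10, 25, 50, 75, 100, 125), function(sp) {
    f <- point_field(cluster_points(c(251, 251), 5, sp), sh, extent = "full")
    divergence_sinks(f, 0.3)$n_sinks
  })
  expect_true(all(diff(counts) >= 0))      # non-decreasing in spacing
  expect_true(all(counts >= 1 & counts <= 5))

  expect_error(divergence_sinks(f1, 1.5), "rel_threshold")
})

test_that("niche allocation orders objects by proximity to the bone band", {
  sh <- c(300, 300)
  bone <- matrix(0, 300, 300); bone[140:160, ] <- 1
  nf <- point_field(bone, sh)
  offsets <- c(0, 20, 40, 60, 80, 100, 120)
  cells <- lapply(offsets, function(o) point_field(cbind(160 + o, 151), sh))
  na <- niche_allocation(cells, nf, intersection_threshold = 0.7)
  ints <- na$objects$intersection
  expect_true(all(diff(ints) < 0))          # strictly nearer, never lower
  expect_equal(which.max(ints), 1)          # on-band object is the maximum
  expect_true(na$objects$allocated[1])
  expect_false(na$objects$allocated[length(offsets)])

  # several cells along the band at one offset: tight spread
  cells2 <- lapply(seq(40, 260, by = 40),
                   function(cc) point_field(cbind(200, cc), sh))
  na2 <- niche_allocation(cells2, nf)
  expect_lt(na2$sd, 0.1)

  expect_error(niche_allocation(list(), nf), class = "histofield_empty_error")
})
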