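# Uses small images where closed-form checks suffice and the standard
# 500x500 geometry where the distance behaviour of the statistics matters.

test_that("pair_fields rules and retained counts match a brute-force scan", {
  fp <- pair_point_fields(10, shape = c(120, 120), anchor = c(61, 50))
  a <- field_values(fp$a); b <- field_values(fp$b)

  all_pairs <- pair_fields(fp$a, fp$b, threshold = 0, rule = "both-below")
  expect_equal(nrow(all_pairs), length(a))

  same <- pair_fields(fp$a, fp$a, threshold = 25)
  expect_identical(same$a, same$b)

  pb <- pair_fields(fp$a, fp$b, threshold = 25, rule = "both-below")
  expect_equal(attr(pb, "n_retained"), sum(a >= 25 | b >= 25))
  pe <- pair_fields(fp$a, fp$b, threshold = 25, rule = "either-below")
  expect_equal(attr(pe, "n_retained"), sum(a >= 25 & b >= 25))
  pz <- pair_fields(fp$a, fp$b, threshold = 25, rule = "zero")
  expect_equal(attr(pz, "n_retained"), length(a))
  expect_equal(sum(pz$a == 0), sum(a < 25))

  expect_error(pair_fields(fp$a, point_field(cbind(5, 5), c(60, 60))),
               class = "histofield_shape_error")
  expect_error(pair_fields(fp$a, fp$b, threshold = 101, rule = "either-below"),
               class = "histofield_empty_error")
})

test_that("identical fields give perfect correlation and overlap", {
  f <- point_field(cbind(40, 61), c(100, 100))
  p <- pair_fields(f, f, threshold = 25)
  expect_equal(pearson(p), 1.0)
  expect_equal(manders_overlap(p), 1.0)
  m <- manders_m1_m2(f, f, 50)
  expect_equal(m[["m1"]], m[["m2"]])
  expect_gt(m[["m1"]], 0)
  expect_lte(m[["m1"]], 1)
})

test_that("statistics are symmetric in their arguments and bounded", {
  fp <- pair_point_fields(60, shape = c(200, 200), anchor = c(101, 60))
  pab <- pair_fields(fp$a, fp$b)
  pba <- pair_fields(fp$b, fp$a)
  expect_equal(pearson(pab), pearson(pba))
  expect_equal(manders_overlap(pab), manders_overlap(pba))
  mab <- manders_m1_m2(fp$a, fp$b)
  mba <- manders_m1_m2(fp$b, fp$a)
  expect_equal(mab[["m1"]], mba[["m2"]])
  expect_equal(mab[["m2"]], mba[["m1"]])
  expect_true(manders_overlap(pab) >= 0 && manders_overlap(pab) <= 1)
  expect_true(all(mab >= 0 & mab <= 1))
  expect_true(abs(pearson(pab)) <= 1)
})

test_that("field statistics decrease with point separation", {
  ds <- c(10, 25, 50, 100, 150, 200)
  stats <- sapply(ds, function(d) {
    fp <- pair_point_fields(d)
    r <- coloc_stats(fp$a, fp$b)
    c(pcc = r$pcc, moc = r$moc,
      hint = histogram_intersection(fp$a, fp$b))
  })
  expect_true(all(diff(stats["pcc", ]) < 0))
  expect_true(all(diff(stats["moc", ]) < 0))
  expect_true(all(diff(stats["hint", ]) < 0))
})

test_that("binary baseline: exact at distance 0, collapsed at 1 px", {
  a <- make_point_image(500, 500, cbind(252, 252))
  same <- baseline_binary_coloc(a, a)
  expect_equal(same$pcc, 1.0)
  expect_equal(same$moc, 1.0)

  b1 <- make_point_image(500, 500, cbind(252, 253))
  r1 <- baseline_binary_coloc(a, b1)
  expect_equal(r1$moc, 0)                      # disjoint supports
  expect_lt(abs(r1$pcc), 1e-5)                 # -1/(n-1), essentially zero

  b100 <- make_point_image(500, 500, cbind(252, 352))
  expect_equal(baseline_binary_coloc(a, b100)$moc, 0)

  expect_error(baseline_binary_coloc(a, matrix(0, 500, 500)),
               class = "histofield_degenerate_error")
})

test_that("convolved statistics degrade gracefully where the baseline collapses", {
  fp <- pair_point_fields(10)
  expect_gte(coloc_stats(fp$a, fp$b)$pcc, 0.9)
  a <- make_point_image(500, 500, cbind(252, 252))
  b <- make_point_image(500, 500, cbind(252, 253))
  expect_lte(abs(baseline_binary_coloc(a, b)$pcc), 0.05)
})

test_that("degenerate samples raise typed errors", {
  p <- tibble::tibble(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(pearson(p), class = "histofield_degenerate_error")
  z <- tibble::tibble(a = c(0, 0), b = c(1, 2))
  expect_error(manders_overlap(z), class = "histofield_degenerate_error")
})
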