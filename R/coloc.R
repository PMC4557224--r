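# Colocalization statistics between two normalized scalar fields, plus the
# no-convolution baseline on raw binary images.

#' Pair two fields pixel-wise with background handling
#'
#' Linearizes two same-shape normalized fields into paired samples, handling
#' near-zero background densities that would otherwise inflate correlation.
#' Rules:
#' \describe{
#'   \item{`"zero"`}{(default) densities below `threshold` are set to 0;
#'     every pixel is retained. This is the reading of "densities below 25
#'     are excluded" that reproduces the published point-pair correlations.}
#'   \item{`"both-below"`}{drop pixels where *both* fields are below the
#'     threshold; values are kept as-is.}
#'   \item{`"either-below"`}{drop pixels where *either* field is below.}
#'   \item{`"none"`}{keep everything untouched.}
#' }
#'
#' @param a,b Normalized [scalar_field]s of equal shape.
#' @param threshold Density threshold on the 0--100 scale (default 25).
#' @param rule Background rule, see above.
#' @return A `paired_samples` tibble with columns `a` and `b` in row-major
#'   pixel order; attributes record the rule, threshold and retained count.
#' @export
pair_fields <- function(a, b, threshold = 25,
                        rule = c("zero", "both-below", "either-below", "none")) {
  rule <- match.arg(rule)
  stopifnot(inherits(a, "scalar_field"), inherits(b, "scalar_field"))
  if (!identical(dim(a$values), dim(b$values)))
    stop_shape("fields have different shapes")
  if (!a$normalized || !b$normalized)
    warn("pairing un-normalized fields; thresholds assume the 0-100 scale")
  # row-major linearization
  av <- as.numeric(t(a$values)); bv <- as.numeric(t(b$values))
  if (rule == "zero") {
    av[av < threshold] <- 0
    bv[bv < threshold] <- 0
  } else if (rule == "both-below") {
    keep <- av >= threshold | bv >= threshold
    av <- av[keep]; bv <- bv[keep]
  } else if (rule == "either-below") {
    keep <- av >= threshold & bv >= threshold
    av <- av[keep]; bv <- bv[keep]
  }
  if (length(av) == 0L)
    abort("all pixels excluded by the threshold rule",
          class = "histofield_empty_error")
  out <- tibble(a = av, b = bv)
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- rule
  attr(out, "n_retained") <- length(av)
  class(out) <- c("paired_samples", class(out))
  out
}

#' Pearson correlation of paired field samples
#'
#' @param pairs A [pair_fields()] result (or any data frame with `a`, `b`).
#' @return Pearson's product-moment coefficient in \[-1, 1\].
#' @export
pearson <- function(pairs) {
  if (nrow(pairs) < 2L)
    abort("need at least two retained pairs", class = "histofield_empty_error")
  if (sd(pairs$a) == 0 || sd(pairs$b) == 0)
    abort("correlation undefined: zero variance in a field",
          class = "histofield_degenerate_error")
  cor(pairs$a, pairs$b)
}

#' Manders overlap coefficient of paired field samples
#'
#' MOC = sum(a*b) / sqrt(sum(a^2) * sum(b^2)); 1 exactly when the two value
#' vectors are proportional (Cauchy--Schwarz equality).
#'
#' @inheritParams pearson
#' @return MOC in \[0, 1\].
#' @export
manders_overlap <- function(pairs) {
  if (nrow(pairs) < 1L)
    abort("need at least one retained pair", class = "histofield_empty_error")
  sa <- sum(pairs$a^2); sb <- sum(pairs$b^2)
  if (sa == 0 || sb == 0)
    abort("overlap undefined for an all-zero sample",
          class = "histofield_degenerate_error")
  sum(pairs$a * pairs$b) / sqrt(sa * sb)
}

#' Manders split coefficients M1/M2
#'
#' Fraction of each field's total mass that lies where the partner field
#' exceeds the threshold: `m1 = sum(a[b > t]) / sum(a)` and symmetrically
#' for `m2`. With the canonical threshold 50 on normalized fields this is
#' the overlap of the upper half of the density scale.
#'
#' @param a,b Normalized [scalar_field]s of equal shape.
#' @param manders_threshold Partner-field threshold on the 0--100 scale.
#' @return Named numeric vector `c(m1 = ..., m2 = ...)`, both in \[0, 1\].
#' @export
manders_m1_m2 <- function(a, b, manders_threshold = 50) {
  stopifnot(inherits(a, "scalar_field"), inherits(b, "scalar_field"))
  if (!identical(dim(a$values), dim(b$values)))
    stop_shape("fields have different shapes")
  av <- a$values; bv <- b$values
  if (sum(av) == 0 || sum(bv) == 0)
    abort("split coefficients undefined for a zero-mass field",
          class = "histofield_degenerate_error")
  c(m1 = sum(av[bv > manders_threshold]) / sum(av),
    m2 = sum(bv[av > manders_threshold]) / sum(bv))
}

new_coloc_result <- function(pcc, moc, m1, m2, pair_threshold, manders_threshold,
                             n_retained, rule = NA_character_, baseline = FALSE) {
  structure(
    list(pcc = pcc, moc = moc, m1 = m1, m2 = m2,
         pair_threshold = pair_threshold, manders_threshold = manders_threshold,
         n_pixels_retained = n_retained, rule = rule, baseline = baseline),
    class = "coloc_result"
  )
}

#' Colocalization statistics for a pair of fields
#'
#' Computes PCC and MOC on the background-handled pixel pairs (see
#' [pair_fields()]) and the Manders split coefficients M1/M2 on the full
#' normalized fields.
#'
#' @inheritParams pair_fields
#' @param manders_threshold Threshold for [manders_m1_m2()].
#' @return A `coloc_result`; see [tidy.coloc_result()].
#' @examples
#' fa <- point_field(cbind(251, 251), c(100, 100), rbf_direct())
#' fb <- point_field(cbind(251 - 10, 251), c(100, 100), rbf_direct())
#' @export
coloc_stats <- function(a, b, threshold = 25,
                        rule = c("zero", "both-below", "either-below", "none"),
                        manders_threshold = 50) {
  rule <- match.arg(rule)
  pairs <- pair_fields(a, b, threshold = threshold, rule = rule)
  m <- manders_m1_m2(a, b, manders_threshold = manders_threshold)
  new_coloc_result(
    pcc = pearson(pairs), moc = manders_overlap(pairs),
    m1 = m[["m1"]], m2 = m[["m2"]],
    pair_threshold = threshold, manders_threshold = manders_threshold,
    n_retained = attr(pairs, "n_retained"), rule = rule
  )
}

#' Baseline colocalization on raw binary images (no convolution)
#'
#' The conventional pixel-wise analysis applied directly to the binary
#' object images: PCC and MOC over all pixels, no field, no threshold.
#' Useful as the contrast case -- it collapses to zero as soon as two
#' objects are one pixel apart, whereas the field statistics degrade
#' smoothly with distance.
#'
#' @param a,b Binary matrices of equal shape, each with at least one
#'   positive pixel.
#' @return A `coloc_result` with `m1`/`m2` set to `NA`.
#' @export
baseline_binary_coloc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_shape("images have different shapes")
  if (sum(a) == 0 || sum(b) == 0)
    abort("baseline undefined on a blank image",
          class = "histofield_degenerate_error")
  av <- as.numeric(t(a)); bv <- as.numeric(t(b))
  moc <- sum(av * bv) / sqrt(sum(av^2) * sum(bv^2))
  new_coloc_result(pcc = cor(av, bv), moc = moc, m1 = NA_real_, m2 = NA_real_,
                   pair_threshold = NA_real_, manders_threshold = NA_real_,
                   n_retained = length(av), baseline = TRUE)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result%s> PCC = %.2f, MOC = %.2f",
              if (x$baseline) " (binary baseline)" else "", x$pcc, x$moc))
  if (!is.na(x$m1))
    cat(sprintf(", M1 = %.2f, M2 = %.2f", x$m1, x$m2))
  cat(sprintf("  [%d px retained]\n", x$n_pixels_retained))
  invisible(x)
}

#' Tidy a colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return A long tibble with one row per statistic.
#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(
    statistic = c("pcc", "moc", "m1", "m2"),
    value = c(x$pcc, x$moc, x$m1, x$m2)
  )
}

#' One-row summary of a colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return A one-row tibble with statistics, thresholds and pixel counts.
#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(
    pcc = x$pcc, moc = x$moc, m1 = x$m1, m2 = x$m2,
    pair_threshold = x$pair_threshold,
    manders_threshold = x$manders_threshold,
    n_pixels_retained = x$n_pixels_retained,
    rule = x$rule, baseline = x$baseline
  )
}
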