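# File input/output. No TIFF package is assumed: a minimal baseline TIFF
# codec (uncompressed, single image, little-endian) is implemented here,
# covering the three layouts the package writes: 8-bit grayscale, 8-bit
# RGB, and 32-bit float fields. Plain-text PNM (P2/P3) and binary (P5/P6)
# are supported as a fixture-friendly alternative. Lossy compression is
# never used.

tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)

#' Write an image as uncompressed TIFF
#'
#' Accepts an 8-bit grayscale matrix (values 0--255), an RGB array
#' (`height x width x 3`, 0--255), or -- with `float = TRUE` -- a numeric
#' matrix stored as 32-bit IEEE floats (used for scalar fields).
#'
#' @param img Matrix or `h x w x 3` array.
#' @param path Output path.
#' @param float Store a matrix as float32 instead of 8-bit.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, float = FALSE) {
  is_rgb <- is.array(img) && length(dim(img)) == 3L
  h <- dim(img)[1]; w <- dim(img)[2]
  spp <- if (is_rgb) 3L else 1L
  bits <- if (float) 32L else 8L
  photometric <- if (is_rgb) 2L else 1L
  sample_format <- if (float) 3L else 1L
  bytecount <- h * w * spp * (bits %/% 8L)

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(v, size) writeBin(v, con, size = size, endian = "little")
  wb(charToRaw("II"), 1L)
  wb(42L, 2)
  data_offset <- 8L
  ifd_offset <- data_offset + bytecount + (bytecount %% 2L)
  wb(ifd_offset, 4)
  # pixel data: row-major, channels interleaved
  if (is_rgb) {
    px <- aperm(img, c(3, 2, 1))          # channel, col, row -> fastest: channel
    wb(as.integer(round(px)), 1)
  } else if (float) {
    wb(as.numeric(t(img)), 4)
  } else {
    wb(as.integer(round(t(img))), 1)
  }
  if (bytecount %% 2L) wb(0L, 1)

  entries <- list(
    list(256L, tiff_types[["LONG"]], 1L, w),
    list(257L, tiff_types[["LONG"]], 1L, h),
    list(258L, tiff_types[["SHORT"]], spp, NA),   # value or offset, fixed below
    list(259L, tiff_types[["SHORT"]], 1L, 1L),
    list(262L, tiff_types[["SHORT"]], 1L, photometric),
    list(273L, tiff_types[["LONG"]], 1L, data_offset),
    list(277L, tiff_types[["SHORT"]], 1L, spp),
    list(278L, tiff_types[["LONG"]], 1L, h),
    list(279L, tiff_types[["LONG"]], 1L, bytecount),
    list(339L, tiff_types[["SHORT"]], spp, NA)
  )
  n <- length(entries)
  extra_offset <- ifd_offset + 2L + 12L * n + 4L
  extras <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (e[[1]] == 258L) {
      if (spp == 1L) e[[4]] <- bits
      else { e[[4]] <- extra_offset; extras <- c(extras, list(rep(bits, spp)))
             extra_offset <- extra_offset + 2L * spp }
    }
    if (e[[1]] == 339L) {
      if (spp == 1L) e[[4]] <- sample_format
      else { e[[4]] <- extra_offset; extras <- c(extras, list(rep(sample_format, spp)))
             extra_offset <- extra_offset + 2L * spp }
    }
    entries[[i]] <- e
  }
  wb(n, 2)
  for (e in entries) {
    wb(as.integer(e[[1]]), 2); wb(as.integer(e[[2]]), 2); wb(as.integer(e[[3]]), 4)
    if (e[[2]] == tiff_types[["SHORT"]] && e[[3]] == 1L) {
      wb(as.integer(e[[4]]), 2); wb(0L, 2)
    } else {
      wb(as.integer(e[[4]]), 4)
    }
  }
  wb(0L, 4)   # no further IFD
  for (x in extras) wb(as.integer(x), 2)
  invisible(path)
}

#' Read an uncompressed TIFF
#'
#' Supports what [write_tiff()] produces plus 16-bit grayscale and
#' multi-strip layouts. Grayscale images return a matrix (8/16-bit as
#' integers, float32 as numeric); RGB returns a `h x w x 3` array.
#'
#' @param path TIFF file.
#' @return Matrix or array of pixel values.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) abort("truncated TIFF file", class = "histofield_io_error")
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else abort("not a TIFF file", class = "histofield_io_error")
  rd <- function(off, n, size, what = "integer") {
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = size >= 4)
  }
  if (rd(2, 1, 2) != 42L) abort("not a TIFF file", class = "histofield_io_error")
  ifd <- rd(4, 1, 4)
  n <- rd(ifd, 1, 2)
  tags <- list()
  for (i in seq_len(n)) {
    base <- ifd + 2 + (i - 1) * 12
    tag <- rd(base, 1, 2); type <- rd(base + 2, 1, 2); cnt <- rd(base + 4, 1, 4)
    tsize <- c(1L, 1L, 2L, 4L, 8L)[type]
    if (cnt * tsize <= 4) {
      val <- rd(base + 8, cnt, tsize)
    } else {
      off <- rd(base + 8, 1, 4)
      val <- rd(off, cnt, tsize)
    }
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) abort(sprintf("TIFF tag %d missing", tag),
                                  class = "histofield_io_error")
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 1L)[1]
  if (need(259, 1L) != 1L)
    abort("compressed TIFF not supported", class = "histofield_io_error")
  spp <- need(277, 1L)
  fmt <- need(339, 1L)[1]
  offsets <- need(273); counts <- need(279)
  buf <- raw(0)
  for (i in seq_along(offsets))
    buf <- c(buf, raw[(offsets[i] + 1):(offsets[i] + counts[i])])
  npx <- h * w * spp
  vals <- if (fmt == 3L) {
    readBin(buf, "numeric", n = npx, size = bits %/% 8, endian = endian)
  } else {
    readBin(buf, "integer", n = npx, size = bits %/% 8, endian = endian,
            signed = FALSE)
  }
  if (length(vals) < npx)
    abort("truncated TIFF pixel data", class = "histofield_io_error")
  if (spp == 1L) {
    matrix(vals, h, w, byrow = TRUE)
  } else {
    a <- array(vals, dim = c(spp, w, h))
    aperm(a, c(3, 2, 1))
  }
}

#' Write / read portable anymap images
#'
#' Text formats P2 (grayscale) / P3 (RGB) are the default: human-readable
#' and friendly to version control. `read_pnm()` additionally understands
#' the binary forms P5/P6.
#'
#' @param img Matrix (grayscale 0--255) or `h x w x 3` array.
#' @param path File path.
#' @param maxval Maximum pixel value declared in the header.
#' @return `write_pnm()`: the path, invisibly; `read_pnm()`: matrix or
#'   array.
#' @export
write_pnm <- function(img, path, maxval = 255) {
  is_rgb <- is.array(img) && length(dim(img)) == 3L
  h <- dim(img)[1]; w <- dim(img)[2]
  con <- file(path, "w")
  on.exit(close(con))
  if (is_rgb) {
    writeLines(c("P3", paste(w, h), as.character(maxval)), con)
    px <- matrix(aperm(img, c(3, 2, 1)), nrow = 3)
    writeLines(paste(as.integer(round(px[1, ])), as.integer(round(px[2, ])),
                     as.integer(round(px[3, ]))), con)
  } else {
    writeLines(c("P2", paste(w, h), as.character(maxval)), con)
    writeLines(apply(round(img), 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_pnm
#' @export
read_pnm <- function(path) {
  hdr <- readBin(path, "raw", n = 2)
  magic <- rawToChar(hdr)
  if (magic %in% c("P2", "P3")) {
    toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    w <- as.integer(toks[2]); h <- as.integer(toks[3])
    vals <- as.numeric(toks[-(1:4)])
    if (magic == "P2") return(matrix(vals, h, w, byrow = TRUE))
    a <- array(vals, dim = c(3, w, h))
    return(aperm(a, c(3, 2, 1)))
  }
  if (magic %in% c("P5", "P6")) {
    raw <- readBin(path, "raw", n = file.info(path)$size)
    txt <- rawToChar(raw[1:min(100, length(raw))])
    toks <- strsplit(txt, "\\s+")[[1]]
    w <- as.integer(toks[2]); h <- as.integer(toks[3])
    # pixel data starts after the single whitespace following maxval
    hdr_len <- gregexpr(toks[4], txt, fixed = TRUE)[[1]][1] + nchar(toks[4])
    vals <- as.integer(raw[(hdr_len + 1):length(raw)])
    if (magic == "P5") return(matrix(vals, h, w, byrow = TRUE))
    a <- array(vals, dim = c(3, w, h))
    return(aperm(a, c(3, 2, 1)))
  }
  abort(sprintf("unsupported PNM magic '%s'", magic),
        class = "histofield_io_error")
}

#' Read an image file (TIFF or PNM)
#'
#' Dispatches on the file's magic bytes, not its extension.
#'
#' @param path Image file.
#' @return Matrix (grayscale) or `h x w x 3` array (RGB).
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "histofield_io_error")
  magic <- readBin(path, "raw", n = 2)
  if (identical(magic, charToRaw("II")) || identical(magic, charToRaw("MM")))
    return(read_tiff(path))
  if (length(magic) == 2 && magic[1] == charToRaw("P"))
    return(read_pnm(path))
  abort(sprintf("unsupported image format in %s", path),
        class = "histofield_io_error")
}

#' Read a mask image as strict 0/1
#'
#' Any grayscale image is binarized at half its nominal range (so 8-bit
#' 0/255 and 16-bit 0/65535 masks both map to 0/1; an already-binary 0/1
#' image is returned unchanged).
#'
#' @param path Image file.
#' @return Binary matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (!is.matrix(img))
    abort("mask must be single-channel", class = "histofield_io_error")
  hi <- max(img)
  if (hi <= 1) return((img > 0.5) * 1)
  (img > hi / 2) * 1
}

#' Save / load a scalar field with its metadata sidecar
#'
#' The field goes to a 32-bit float TIFF; parameters, normalization state
#' and source count go to a JSON sidecar next to it (same path with a
#' `.json` extension). Reading without the sidecar is an error: a bare
#' value grid is not a field.
#'
#' @param field A [scalar_field].
#' @param path TIFF path.
#' @return `write_field()`: the path, invisibly; `read_field()`: the
#'   restored [scalar_field], bit-identical values.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  write_tiff(field$values, path, float = TRUE)
  meta <- list(
    normalized = field$normalized,
    n_sources = field$n_sources,
    params = if (!is.null(field$params))
      field$params[c("mode", "alpha", "beta", "gamma")]
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")

#' @rdname write_field
#' @export
read_field <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    abort(sprintf("metadata sidecar missing: %s", sp),
          class = "histofield_metadata_error")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  vals <- read_tiff(path)
  params <- if (!is.null(meta$params))
    rbf_params(meta$params$mode, beta = if (meta$params$mode == "custom") meta$params$beta,
               gamma = if (meta$params$mode == "custom") meta$params$gamma,
               alpha = meta$params$alpha)
  new_scalar_field(vals, params = params,
                   normalized = isTRUE(meta$normalized),
                   n_sources = meta$n_sources)
}

#' Write / read centroid tables
#'
#' CSV with header `row,col,stained`, `stained` coded 0/1.
#'
#' @param centroids Tibble with `row`, `col`, `stained`.
#' @param path CSV path.
#' @return `write_centroids()`: path invisibly; `read_centroids()`: tibble.
#' @export
write_centroids <- function(centroids, path) {
  df <- tibble(row = centroids$row, col = centroids$col,
               stained = as.integer(centroids$stained))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    row = readr::col_integer(), col = readr::col_integer(),
    stained = readr::col_integer()))
  tibble(row = df$row, col = df$col, stained = df$stained == 1L)
}
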