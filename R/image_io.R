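#' Read an RGB dermoscopy image
#'
#' Decodes a PNG or JPEG file to an 8-bit RGB array. Grayscale images are
#' replicated to three identical channels; an alpha channel, if present, is
#' dropped with a warning. The file type is detected from its magic bytes,
#' not the extension.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An `H x W x 3` numeric array with values in 0..255, channels
#'   ordered R, G, B.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s': no such file", path))
  magic <- readBin(path, "raw", n = 3L)
  a <- tryCatch({
    if (length(magic) >= 3L && identical(magic[1:2], as.raw(c(0xff, 0xd8))))
      jpeg::readJPEG(path)
    else if (length(magic) >= 3L && identical(magic, as.raw(c(0x89, 0x50, 0x4e))))
      png::readPNG(path)
    else stop("not a PNG or JPEG stream")
  }, error = function(e)
    stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)), call. = FALSE))
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  nch <- dim(a)[3]
  if (nch == 4L || nch == 2L) {
    warning(sprintf("dropping alpha channel in '%s'", path))
    a <- a[, , seq_len(nch - 1L), drop = FALSE]
    nch <- dim(a)[3]
  }
  if (nch == 1L) a <- array(a[, , 1], c(dim(a)[1:2], 3L))
  if (dim(a)[3] != 3L)
    stop(sprintf("cannot read image '%s': unsupported channel count", path))
  round(a * 255)
}

#' Split an RGB image into channel matrices
#'
#' @param img `H x W x 3` numeric array (R, G, B), e.g. from [read_image()]
#'   or [synth_lesion()].
#' @return Named list of three `H x W` matrices `R`, `G`, `B`; restacking
#'   them reproduces the input exactly.
#' @export
split_channels <- function(img) {
  img <- check_rgb(img)
  list(R = img[, , 1], G = img[, , 2], B = img[, , 3])
}

check_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("'img' must be an H x W x 3 array")
  if (any(!is.finite(img)) || min(img) < 0 || max(img) > 255)
    stop("'img' must hold finite intensities in [0, 255]")
  img
}

check_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (any(!is.finite(mask)) || any(mask != round(mask)) || min(mask) < 0)
    stop("mask labels must be non-negative integers")
  labs <- sort(unique(as.vector(mask)))
  if (!identical(as.integer(labs), seq_along(labs) - 1L))
    stop("mask labels must form a contiguous range starting at 0")
  storage.mode(mask) <- "integer"
  mask
}

#' Write / read a label mask as a grayscale PNG
#'
#' Labels `0..K-1` are stored as `K` evenly spaced gray levels so the mask
#' is viewable; [read_mask()] inverts the encoding by ranking the distinct
#' gray values found in the file.
#'
#' @param mask Integer matrix with contiguous labels starting at 0.
#' @param path Output / input PNG path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns an
#'   integer label matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- check_mask(mask)
  k <- max(mask) + 1L
  g <- if (k == 1L) mask * 0 else mask / (k - 1)
  ok <- tryCatch({ png::writePNG(g, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write mask to '%s'", path))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read mask '%s': no such file", path))
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  levs <- sort(unique(as.vector(g)))
  m <- matrix(match(g, levs) - 1L, nrow(g), ncol(g))
  storage.mode(m) <- "integer"
  m
}
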