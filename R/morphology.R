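#' Flat structuring elements
#'
#' Build a flat (binary) structuring element for grayscale morphology.
#' The default shapes are symmetric about their anchor, which sits at the
#' centre of the footprint.
#'
#' @param shape One of `"disk"` (pixels within Euclidean distance `radius` of
#'   the anchor), `"square"` ((2r+1) x (2r+1) block) or `"cross"` (the anchor
#'   row and column).
#' @param radius Radius in pixels (non-negative integer). `radius = 0` gives
#'   the single-pixel identity element.
#' @return An object of class `"struct_el"`: a list with `footprint` (logical
#'   matrix) and `anchor` (row, col of the origin, 1-based).
#' @examples
#' struct_el("disk", 2)      # the default 5x5 disk
#' struct_el("square", 1)    # 3x3 block
#' @export
struct_el <- function(shape = c("disk", "square", "cross"), radius = 2) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 0L)
    stop("'radius' must be a non-negative integer")
  n <- 2L * radius + 1L
  d <- outer(seq_len(n) - radius - 1L, seq_len(n) - radius - 1L,
             function(i, j) sqrt(i^2 + j^2))
  fp <- switch(shape,
    disk   = d <= radius + 1e-9,
    square = matrix(TRUE, n, n),
    cross  = outer(seq_len(n), seq_len(n),
                   function(i, j) i == radius + 1L | j == radius + 1L))
  new_struct_el(fp, c(radius + 1L, radius + 1L))
}

#' @rdname struct_el
#' @param footprint Logical (or 0/1) matrix marking member cells.
#' @param anchor Integer pair (row, col) of the origin inside the footprint.
#' @export
new_struct_el <- function(footprint, anchor = NULL) {
  footprint <- as.matrix(footprint)
  mode(footprint) <- "logical"
  if (!any(footprint)) stop("structuring element must have at least one cell")
  if (is.null(anchor))
    anchor <- as.integer(ceiling(dim(footprint) / 2))
  anchor <- as.integer(anchor)
  if (anchor[1] < 1L || anchor[1] > nrow(footprint) ||
      anchor[2] < 1L || anchor[2] > ncol(footprint))
    stop("anchor must lie inside the footprint")
  structure(list(footprint = footprint, anchor = anchor),
            class = "struct_el")
}

#' @export
print.struct_el <- function(x, ...) {
  cat(sprintf("structuring element: %d x %d footprint, %d active cells, anchor (%d, %d)\n",
              nrow(x$footprint), ncol(x$footprint), sum(x$footprint),
              x$anchor[1], x$anchor[2]))
  invisible(x)
}

# (row, col) offsets of active cells relative to the anchor
se_offsets <- function(se) {
  w <- which(se$footprint, arr.ind = TRUE)
  cbind(w[, 1] - se$anchor[1], w[, 2] - se$anchor[2])
}

reflect_se <- function(se) {
  fp <- se$footprint[nrow(se$footprint):1, ncol(se$footprint):1, drop = FALSE]
  anchor <- c(nrow(fp) - se$anchor[1] + 1L, ncol(fp) - se$anchor[2] + 1L)
  new_struct_el(fp, anchor)
}

# fold out-of-range indices back into 1..n by edge-repeating reflection
fold_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  }
  idx
}

check_channel <- function(P, what = "P") {
  P <- as.matrix(P)
  if (!is.numeric(P) || any(!is.finite(P)))
    stop(sprintf("'%s' must be a finite numeric matrix", what))
  P
}

# shared min/max filter core: reflect-pad, then fold pmin/pmax over offsets
.minmax_filter <- function(P, offs, op) {
  nr <- nrow(P); nc <- ncol(P)
  pr <- max(abs(offs[, 1]), 0L); pc <- max(abs(offs[, 2]), 0L)
  ri <- fold_index((1L - pr):(nr + pr), nr)
  ci <- fold_index((1L - pc):(nc + pc), nc)
  Pp <- P[ri, ci, drop = FALSE]
  out <- NULL
  for (k in seq_len(nrow(offs))) {
    blk <- Pp[(1L + pr + offs[k, 1]):(nr + pr + offs[k, 1]),
              (1L + pc + offs[k, 2]):(nc + pc + offs[k, 2]), drop = FALSE]
    out <- if (is.null(out)) blk else op(out, blk)
  }
  out
}

#' Grayscale morphological operators
#'
#' Flat (min/max filter) grayscale erosion, dilation, closing and
#' morphological gradient over an arbitrary structuring element, with
#' reflect padding at image borders. Erosion takes the minimum of the image
#' over the footprint placed at each pixel; dilation takes the maximum over
#' the reflected footprint, so the usual duality
#' `dilate(P, S) == -erode(-P, reflect(S))` holds exactly. Closing is
#' dilation followed by erosion and fills dark holes smaller than the
#' element; the gradient (dilation minus erosion) highlights intensity
#' edges and is non-negative everywhere.
#'
#' @param P Numeric matrix (one image channel); must be finite.
#' @param se A [struct_el()] structuring element.
#' @return A numeric matrix of the same dimensions as `P`.
#' @examples
#' P <- matrix(0, 5, 5); P[3, 3] <- 1
#' dilate(P, struct_el("square", 1))   # 3x3 plateau of ones
#' mgradient(matrix(2, 4, 4), struct_el("disk", 1))  # all zero
#' @name morphology
NULL

#' @rdname morphology
#' @export
erode <- function(P, se) {
  P <- check_channel(P)
  stopifnot(inherits(se, "struct_el"))
  .minmax_filter(P, se_offsets(se), pmin)
}

#' @rdname morphology
#' @export
dilate <- function(P, se) {
  P <- check_channel(P)
  stopifnot(inherits(se, "struct_el"))
  .minmax_filter(P, -se_offsets(se), pmax)
}

#' @rdname morphology
#' @export
mclose <- function(P, se) {
  erode(dilate(P, se), se)
}

#' @rdname morphology
#' @export
mgradient <- function(P, se) {
  dilate(P, se) - erode(P, se)
}
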