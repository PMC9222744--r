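#' Single-valued neutrosophic entropy
#'
#' The entropy of a neutrosophic point `(t, i, f)` is defined geometrically:
#' in the unit cube, the axis `{t = f, i = 1/2}` is the locus of total
#' uncertainty (fuzziness `|t - f|` and intuitiveness `|i - 1/2|` both
#' vanish). The entropy decreases linearly with the Euclidean distance `d`
#' from that axis,
#'
#' \deqn{E = 1 - \frac{2}{\sqrt{3}}\, d, \qquad
#'       d = \sqrt{\tfrac{(t-f)^2}{2} + \Bigl(\tfrac{1-2i}{2}\Bigr)^2},}
#'
#' so that `E = 1` on the axis and `E = 0` at the crisp cube corners of
#' maximal distance (`d = sqrt(3)/2`, e.g. `(1, 0, 0)`). All points at equal
#' axis distance lie on one *isentropic cylinder* and share one entropy
#' value. All three functions are vectorised over their arguments.
#'
#' @param t,i,f Truth, indeterminacy, falsity memberships in `[0, 1]`
#'   (vectors or matrices of equal shape).
#' @return `axis_distance()`: distances in `[0, sqrt(3)/2]`;
#'   `pixel_entropy()`: entropies in `[0, 1]`.
#' @examples
#' pixel_entropy(0.5, 0.5, 0.5)  # 1: total indeterminacy
#' pixel_entropy(1, 0, 0)        # 0: crisp full membership
#' @export
axis_distance <- function(t, i, f) {
  check_unit(t, i, f)
  sqrt((t - f)^2 / 2 + ((1 - 2 * i) / 2)^2)
}

#' @rdname axis_distance
#' @export
pixel_entropy <- function(t, i, f) {
  check_unit(t, i, f)
  # algebraically 1 - (2/sqrt(3)) * axis_distance; folding the constant into
  # the radicand keeps the anchor values 1 and 0 exact in floating point
  1 - sqrt((2 * (t - f)^2 + (1 - 2 * i)^2) / 3)
}

check_unit <- function(t, i, f) {
  for (v in list(t, i, f))
    if (any(!is.finite(v)) || min(v) < 0 || max(v) > 1)
      stop("neutrosophic components must be finite and in [0, 1]")
  invisible(NULL)
}

#' Neutrosophic-entropy map of a channel triple
#'
#' Evaluates the single-valued neutrosophic entropy at every pixel of an
#' `ns_triple`, preserving the spatial layout. The scalar set entropy (the
#' mean over all pixels) is attached as attribute `"scalar"`.
#'
#' @param ns An `ns_triple` from [to_ns()].
#' @return `H x W` matrix of entropies in `[0, 1]` with attributes
#'   `channel` (the source channel tag) and `scalar` (mean entropy).
#' @export
entropy_map <- function(ns) {
  stopifnot(inherits(ns, "ns_triple"))
  E <- pixel_entropy(ns$T, ns$I, ns$F)
  structure(E, channel = ns$channel, scalar = mean(E))
}
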