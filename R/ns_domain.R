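#' Neutrosophic-set conversion of an image channel
#'
#' Maps one intensity channel into its neutrosophic triple (T, I, F).
#' Truth T is the morphologically closed channel rescaled to `[0, 1]` by its
#' global minimum and maximum; closing removes small dark structures (hairs,
#' specks) before membership is assessed. Falsity is the complement
#' `F = 1 - T`. Indeterminacy I is the absolute morphological gradient,
#' min-max rescaled, so it peaks on intensity edges where membership is
#' genuinely ambiguous.
#'
#' Degenerate channels (constant after the morphological step, so the
#' min-max range is zero) map to the semantically neutral values `T = 0.5`
#' everywhere (hence `F = 0.5`) and `I = 0` everywhere.
#'
#' @param P Numeric channel matrix (finite values).
#' @param se Structuring element from [struct_el()]; default 5x5 disk.
#' @param T Truth matrix in `[0, 1]` (for [to_F()]).
#' @return `to_T()`, `to_F()`, `to_I()` return an `H x W` matrix in `[0, 1]`.
#' @seealso [to_ns()] for whole-image conversion.
#' @export
to_T <- function(P, se = struct_el("disk", 2)) {
  P <- check_channel(P)
  rescale01(mclose(P, se), degenerate = 0.5)
}

#' @rdname to_T
#' @export
to_F <- function(T) {
  T <- check_channel(T, "T")
  if (min(T) < 0 || max(T) > 1) stop("'T' must lie in [0, 1]")
  1 - T
}

#' @rdname to_T
#' @export
to_I <- function(P, se = struct_el("disk", 2)) {
  P <- check_channel(P)
  rescale01(abs(mgradient(P, se)), degenerate = 0)
}

rescale01 <- function(M, degenerate) {
  rng <- range(M)
  if (rng[2] - rng[1] <= 0) {
    M[] <- degenerate
    return(M)
  }
  (M - rng[1]) / (rng[2] - rng[1])
}

#' Convert an RGB image to the neutrosophic-set domain
#'
#' Applies the (T, I, F) conversion to each of the R, G, B channels.
#'
#' @param img `H x W x 3` array in 0..255.
#' @param se Structuring element shared by the closing and gradient steps.
#' @return Named list `R`, `G`, `B` of `ns_triple` objects; each is a list
#'   with matrices `T`, `I`, `F` and a `channel` tag, satisfying
#'   `T + F == 1` elementwise.
#' @export
to_ns <- function(img, se = struct_el("disk", 2)) {
  ch <- split_channels(img)
  out <- lapply(names(ch), function(nm) ns_triple_from_channel(ch[[nm]], nm, se))
  names(out) <- names(ch)
  out
}

ns_triple_from_channel <- function(P, channel, se) {
  T <- to_T(P, se)
  new_ns_triple(T, to_I(P, se), to_F(T), channel)
}

new_ns_triple <- function(T, I, F, channel) {
  stopifnot(identical(dim(T), dim(I)), identical(dim(T), dim(F)))
  if (min(T) < 0 || max(T) > 1 || min(I) < 0 || max(I) > 1 ||
      min(F) < 0 || max(F) > 1)
    stop("neutrosophic memberships must lie in [0, 1]")
  structure(list(T = T, I = I, F = F, channel = channel), class = "ns_triple")
}

#' @export
print.ns_triple <- function(x, ...) {
  cat(sprintf("neutrosophic triple, channel %s: %d x %d; mean T %.3f, mean I %.3f\n",
              x$channel, nrow(x$T), ncol(x$T), mean(x$T), mean(x$I)))
  invisible(x)
}
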