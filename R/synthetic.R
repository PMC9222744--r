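#' Specification of a synthetic dermoscopy lesion
#'
#' Parameter object for the seeded phantom generator. The phantom has three
#' radial regions around `center`: a dark lesion core (inside
#' `inner_radius`), a banded edge annulus over which colour grades smoothly
#' from `core_rgb` to `skin_rgb` (between the radii), and background skin
#' outside. Both radii are modulated by a common low-order harmonic wobble
#' so outlines are irregular, as melanoma outlines are. The colour
#' transition is cubic-smoothstep (hence nonlinear) and channel-dependent:
#' the red channel fades across the whole band, green over its middle, and
#' blue only near the outer edge — emulating the stronger absorption of
#' short wavelengths by melanin, which keeps pigmented tissue dark in the
#' blue channel until pigment has almost vanished.
#'
#' @param H,W Image size in pixels.
#' @param center Lesion centre (row, col); defaults to the image centre.
#' @param inner_radius,outer_radius Core and outer band radii in pixels;
#'   `0 < inner < outer < min(H, W)/2`.
#' @param wobble_amp Relative amplitude of the boundary wobble (0 disables).
#' @param wobble_harmonics Number of harmonics in the wobble.
#' @param core_rgb,skin_rgb Mean colours (0..255) of lesion core and skin.
#' @param noise_sigma Additive Gaussian noise s.d. in intensity units.
#' @param hair_count,bubble_count Number of dark hair strokes / bright
#'   bubble artefacts to overlay.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `"lesion_spec"`.
#' @export
lesion_spec <- function(H = 128, W = 128, center = NULL,
                        inner_radius = 25, outer_radius = 40,
                        wobble_amp = 0.05, wobble_harmonics = 3,
                        core_rgb = c(70, 40, 45), skin_rgb = c(205, 160, 140),
                        noise_sigma = 3, hair_count = 0, bubble_count = 0,
                        seed = 42) {
  if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
  if (!(inner_radius > 0 && inner_radius < outer_radius &&
        outer_radius < min(H, W) / 2))
    stop("need 0 < inner_radius < outer_radius < min(H, W)/2")
  if (any(c(core_rgb, skin_rgb) < 0) || any(c(core_rgb, skin_rgb) > 255))
    stop("colours must lie in [0, 255]")
  if (wobble_amp < 0 || noise_sigma < 0 || hair_count < 0 || bubble_count < 0)
    stop("amplitudes and counts must be non-negative")
  structure(list(H = as.integer(H), W = as.integer(W), center = center,
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 wobble_amp = wobble_amp,
                 wobble_harmonics = as.integer(wobble_harmonics),
                 core_rgb = core_rgb, skin_rgb = skin_rgb,
                 noise_sigma = noise_sigma,
                 hair_count = as.integer(hair_count),
                 bubble_count = as.integer(bubble_count),
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic lesion spec: %d x %d, core radius %g, band to %g,",
                     " wobble %g, noise sd %g, %d hairs, %d bubbles, seed %d\n"),
              x$H, x$W, x$inner_radius, x$outer_radius, x$wobble_amp,
              x$noise_sigma, x$hair_count, x$bubble_count, x$seed))
  invisible(x)
}

# per-channel transition windows over the band coordinate s in [0, 1]
.band_windows <- list(R = c(0, 1), G = c(0.15, 0.9), B = c(0.55, 1))

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic dermoscopy image with ground truth
#'
#' Renders the phantom described by a [lesion_spec()]: wobbled radial
#' geometry, channel-wise smoothstep colour grading across the banded edge,
#' additive Gaussian noise, then optional hair and bubble artefacts. The
#' ground-truth mask is derived from the same wobbled radii, so it is exact.
#'
#' @param spec A [lesion_spec()].
#' @return List with `image` (`H x W x 3` array, 0..255), `truth` (integer
#'   mask: 0 background, 1 banded edge, 2 lesion core) and `spec`.
#' @examples
#' fx <- synth_lesion(lesion_spec(H = 64, W = 64, inner_radius = 12,
#'                                outer_radius = 20, seed = 7))
#' table(fx$truth)
#' @export
synth_lesion <- function(spec = lesion_spec()) {
  stopifnot(inherits(spec, "lesion_spec"))
  with_seed(spec$seed, {
    dy <- outer(seq_len(spec$H) - spec$center[1], rep(1, spec$W))
    dx <- outer(rep(1, spec$H), seq_len(spec$W) - spec$center[2])
    d <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)

    rho <- matrix(1, spec$H, spec$W)
    if (spec$wobble_amp > 0 && spec$wobble_harmonics > 0) {
      a <- stats::rnorm(spec$wobble_harmonics) / seq_len(spec$wobble_harmonics)
      b <- stats::rnorm(spec$wobble_harmonics) / seq_len(spec$wobble_harmonics)
      w <- matrix(0, spec$H, spec$W)
      for (h in seq_len(spec$wobble_harmonics))
        w <- w + a[h] * cos(h * theta) + b[h] * sin(h * theta)
      rho <- 1 + spec$wobble_amp * w / max(abs(w))
    }
    r_in <- spec$inner_radius * rho
    r_out <- spec$outer_radius * rho

    truth <- matrix(0L, spec$H, spec$W)
    truth[d < r_out] <- 1L
    truth[d < r_in] <- 2L

    s <- pmin(pmax((d - r_in) / (r_out - r_in), 0), 1)
    img <- array(0, c(spec$H, spec$W, 3))
    for (c3 in 1:3) {
      win <- .band_windows[[c3]]
      v <- smoothstep((s - win[1]) / (win[2] - win[1]))
      img[, , c3] <- spec$core_rgb[c3] + v * (spec$skin_rgb[c3] - spec$core_rgb[c3])
    }
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
    img <- pmin(pmax(img, 0), 255)
    if (spec$hair_count > 0)
      img <- add_hairs(img, spec$hair_count, seed = NULL)
    if (spec$bubble_count > 0)
      img <- add_bubbles(img, spec$bubble_count, seed = NULL)
    list(image = img, truth = truth, spec = spec)
  })
}

#' Overlay hair and bubble artefacts
#'
#' `add_hairs()` draws dark curved strokes (quadratic Bezier arcs, 1-3 px
#' wide) emulating body hair across the dermoscopy field; `add_bubbles()`
#' adds small bright discs emulating immersion-fluid air bubbles. Both
#' return the image with an attribute (`hair_mask` / `bubble_mask`) marking
#' the touched pixels; with `count = 0` the image is returned unchanged.
#'
#' @param img `H x W x 3` array in 0..255.
#' @param count Number of artefacts.
#' @param seed Optional seed (`NULL` uses the current RNG stream).
#' @return The modified image array.
#' @export
add_hairs <- function(img, count, seed = NULL) {
  img <- check_rgb(img)
  if (count == 0) return(img)
  run <- function() {
    H <- dim(img)[1]; W <- dim(img)[2]
    mask <- matrix(FALSE, H, W)
    for (k in seq_len(count)) {
      p <- matrix(c(stats::runif(3, 1, H), stats::runif(3, 1, W)), 3, 2)
      tt <- seq(0, 1, length.out = 4L * max(H, W))
      br <- (1 - tt)^2 * p[1, 1] + 2 * tt * (1 - tt) * p[2, 1] + tt^2 * p[3, 1]
      bc <- (1 - tt)^2 * p[1, 2] + 2 * tt * (1 - tt) * p[2, 2] + tt^2 * p[3, 2]
      half <- (sample(1:3, 1) - 1) / 2
      shade <- stats::runif(1, 15, 45)
      for (q in seq_along(tt)) {
        rr <- round(br[q] + (-half):half); cc <- round(bc[q] + (-half):half)
        rr <- rr[rr >= 1 & rr <= H]; cc <- cc[cc >= 1 & cc <= W]
        if (length(rr) && length(cc)) {
          mask[rr, cc] <- TRUE
          for (c3 in 1:3) img[rr, cc, c3] <- shade * c(1, 0.85, 0.8)[c3]
        }
      }
    }
    structure(img, hair_mask = mask)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @rdname add_hairs
#' @export
add_bubbles <- function(img, count, seed = NULL) {
  img <- check_rgb(img)
  if (count == 0) return(img)
  run <- function() {
    H <- dim(img)[1]; W <- dim(img)[2]
    mask <- matrix(FALSE, H, W)
    dyx <- function(cy, cx)
      sqrt(outer((seq_len(H) - cy)^2, rep(1, W)) +
           outer(rep(1, H), (seq_len(W) - cx)^2))
    for (k in seq_len(count)) {
      cy <- stats::runif(1, 5, H - 4); cx <- stats::runif(1, 5, W - 4)
      rad <- stats::runif(1, 2, 4)
      inside <- dyx(cy, cx) <= rad
      mask <- mask | inside
      boost <- stats::runif(1, 50, 90)
      for (c3 in 1:3) {
        ch <- img[, , c3]
        ch[inside] <- pmin(ch[inside] + boost, 255)
        img[, , c3] <- ch
      }
    }
    structure(img, bubble_mask = mask)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
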