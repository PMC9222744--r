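#' Hierarchical Gaussian mixture model with an MRF spatial prior
#'
#' Fits, by EM, a K-category mixture to the pixels of a feature image in
#' which each category density is itself a mixture of `r` Gaussians,
#' \deqn{f(x_i) = \sum_{j=1}^{K} \pi_{ij} \sum_{\rho=1}^{r} \eta_{j\rho}\,
#'       G(x_i \mid \mu_{j\rho}, \Sigma_{j\rho}),}
#' with a per-pixel prior \eqn{\pi_{ij}} coupled to the 3x3 pixel
#' neighbourhood through a Markov-random-field term
#' \eqn{g_{ij} = \exp[\beta / (2|N_i|) \sum_{m \in N_i} (z_{mj} + \pi_{mj})]}
#' (neighbourhoods truncated at the image border). Each iteration performs
#' the posterior update \eqn{z_{ij} \propto \pi_{ij} D_{ij}}, recomputes
#' `g`, re-estimates means and variances as posterior-weighted moments, and
#' updates the prior as \eqn{\pi_{ij} \propto z_{ij} + g_{ij}}. Iteration
#' stops when the penalised log-likelihood
#' \eqn{\sum_{ij} z_{ij}(\log\pi_{ij} + \log D_{ij}) +
#'      \sum_{ij} g_{ij}\log\pi_{ij}}
#' increases by less than `tol`.
#'
#' With `beta = 0` every \eqn{g_{ij} = 1} and the spatial coupling
#' disappears; with `r = 1` the category densities are single Gaussians and
#' the updates reduce to the classical mixture form.
#'
#' @param x Numeric matrix (feature image; pixels are the observations) or
#'   vector. A vector is treated as a 1-pixel-high image, so the MRF
#'   neighbourhood degenerates to the two sequence neighbours.
#' @param k Number of categories (>= 1). Default 3: background, banded
#'   edge, lesion core.
#' @param r Sub-Gaussians per category (>= 1). Default 1.
#' @param beta MRF smoothness (>= 0); 0 disables spatial coupling. Default 2.
#' @param tol Stop when the log-likelihood increase falls below this
#'   (default 0.1).
#' @param max_iter Iteration cap (default 100).
#' @param seed Optional integer seed; the fit is deterministic for a given
#'   seed (and, with the default quantile initialisation, even without one).
#' @return An object of class `"hgmm"`: list with elements `mu`, `sigma2`,
#'   `eta` (k x r matrices), `pi`, `z`, `g` (N x k matrices), `labels`
#'   (argmax-posterior label matrix, values 1..k), `loglik` (per-iteration
#'   trace of the penalised objective), `data_loglik` (trace of the
#'   marginal data log-likelihood), `converged`, `iter`, `dims`, `call`.
#' @examples
#' x <- matrix(rnorm(400, rep(c(0, 3), each = 200), 0.5), 20, 20)
#' fit <- hgmm(x, k = 2, beta = 0, seed = 1)
#' coef(fit)$mu
#' table(fit$labels)
#' @export
hgmm <- function(x, k = 3, r = 1, beta = 2, tol = 0.1, max_iter = 100,
                 seed = NULL) {
  cl <- match.call()
  dims <- if (is.matrix(x)) dim(x) else c(1L, length(x))
  xv <- as.numeric(x)
  if (any(!is.finite(xv))) stop("'x' must be finite")
  k <- as.integer(k); r <- as.integer(r)
  if (k < 1L || r < 1L) stop("'k' and 'r' must be positive integers")
  if (length(xv) < k) stop("need at least k pixels")
  if (beta < 0) stop("'beta' must be non-negative")
  if (tol <= 0 || max_iter < 1L) stop("invalid 'tol' or 'max_iter'")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  st <- hgmm_init(xv, k, r)
  ll_trace <- numeric(0); dll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    logD <- hgmm_log_density(xv, st)
    st$z <- hgmm_e_step(st$pi, logD)
    st$g <- hgmm_g(st$z, st$pi, beta, dims)
    ll <- hgmm_loglik(st$z, st$g, st$pi, logD)
    ll_trace <- c(ll_trace, ll)
    dll_trace <- c(dll_trace, hgmm_data_loglik(st$pi, logD))
    if (iter > 1L && ll - ll_trace[iter - 1L] < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    st <- hgmm_m_step(xv, st, logD)
  }
  if (!converged && max_iter > 1L)
    warning("hgmm: EM did not meet the stopping rule within 'max_iter' iterations")

  labels <- matrix(max.col(st$z, ties.method = "first"), dims[1], dims[2])
  structure(list(mu = st$mu, sigma2 = st$sigma2, eta = st$eta,
                 pi = st$pi, z = st$z, g = st$g, labels = labels,
                 loglik = ll_trace, data_loglik = dll_trace,
                 converged = converged, iter = iter, k = k, r = r,
                 beta = beta, dims = dims, x = x, call = cl),
            class = "hgmm")
}

# quantile-spread initialisation: deterministic, brackets the modes
hgmm_init <- function(xv, k, r) {
  n <- length(xv)
  q <- stats::quantile(xv, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  if (anyDuplicated(q)) {
    # heavily tied data (e.g. a large exactly-constant region) can collapse
    # the quantiles onto one value, which would make every component
    # identical forever; spread the starting means over the data range instead
    rng <- range(xv)
    q <- if (rng[1] < rng[2]) seq(rng[1], rng[2], length.out = k + 2L)[-c(1L, k + 2L)]
         else q
  }
  spread <- if (r > 1L) (seq_len(r) - (r + 1) / 2) * max(stats::sd(xv), 1e-6) / (2 * k) else 0
  mu <- outer(q, rep(1, r)) + outer(rep(1, k), spread)
  v0 <- max(stats::var(xv), 1e-8)
  list(mu = mu, sigma2 = matrix(v0, k, r),
       eta = matrix(1 / r, k, r),
       pi = matrix(1 / k, n, k),
       z = matrix(1 / k, n, k), g = matrix(1, n, k))
}

# log of the hierarchical category densities: N x k matrix of log D_ij
hgmm_log_density <- function(xv, st) {
  k <- nrow(st$mu); r <- ncol(st$mu); n <- length(xv)
  logD <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lg <- vapply(seq_len(r), function(rr)
      log(st$eta[j, rr]) +
        stats::dnorm(xv, st$mu[j, rr], sqrt(st$sigma2[j, rr]), log = TRUE),
      numeric(n))
    logD[, j] <- if (r == 1L) lg[, 1] else row_logsumexp(lg)
  }
  logD
}

row_logsumexp <- function(m) {
  mx <- as.numeric(do.call(pmax, asplit(m, 2)))
  mx + log(rowSums(exp(m - mx)))
}

# posterior responsibilities z_ij (rows sum to 1), computed in log space
hgmm_e_step <- function(pi, logD) {
  lw <- log(pmax(pi, .Machine$double.xmin)) + logD
  z <- exp(lw - row_logsumexp(lw))
  z / rowSums(z)
}

# MRF neighbourhood term g_ij over the 8-connected 3x3 window (truncated at
# borders); beta = 0 short-circuits to all ones
hgmm_g <- function(z, pi, beta, dims) {
  if (beta == 0) return(matrix(1, nrow(z), ncol(z)))
  cnt <- neighbor_sum(matrix(1, dims[1], dims[2]))
  g <- matrix(0, nrow(z), ncol(z))
  s <- z + pi
  for (j in seq_len(ncol(z))) {
    ns <- neighbor_sum(matrix(s[, j], dims[1], dims[2]))
    g[, j] <- exp(beta / (2 * cnt) * ns)
  }
  g
}

# sum of the 8 neighbours of every cell, zero-padded (border cells simply
# have fewer neighbours)
neighbor_sum <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(0, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- M
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out + P[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  as.numeric(out)
}

# posterior-weighted moment updates; nested responsibilities when r > 1
hgmm_m_step <- function(xv, st, logD) {
  k <- nrow(st$mu); r <- ncol(st$mu); n <- length(xv)
  nj <- colSums(st$z)
  for (j in seq_len(k)) {
    if (nj[j] < n * 1e-10) {           # empty category: re-seed at the point
      dens <- rowSums(exp(logD))       # the current model explains worst
      i0 <- which.min(dens)
      st$mu[j, ] <- xv[i0]
      st$sigma2[j, ] <- max(stats::var(xv), 1e-8)
      st$eta[j, ] <- 1 / r
      message(sprintf("hgmm: re-seeded empty category %d at x = %.4g", j, xv[i0]))
      next
    }
    if (r == 1L) {
      st$mu[j, 1] <- sum(st$z[, j] * xv) / nj[j]
      st$sigma2[j, 1] <- max(sum(st$z[, j] * (xv - st$mu[j, 1])^2) / nj[j], 1e-8)
    } else {
      ltau <- vapply(seq_len(r), function(rr)
        log(st$eta[j, rr]) +
          stats::dnorm(xv, st$mu[j, rr], sqrt(st$sigma2[j, rr]), log = TRUE),
        numeric(n)) - logD[, j]
      tau <- st$z[, j] * exp(ltau)     # z_ijr, summing over r to z_ij
      w <- colSums(tau)
      ok <- w > n * 1e-12
      st$eta[j, ] <- if (any(ok)) pmax(w, 1e-12) / sum(pmax(w, 1e-12)) else rep(1 / r, r)
      for (rr in seq_len(r)) {
        if (!ok[rr]) next
        st$mu[j, rr] <- sum(tau[, rr] * xv) / w[rr]
        st$sigma2[j, rr] <- max(sum(tau[, rr] * (xv - st$mu[j, rr])^2) / w[rr], 1e-8)
      }
    }
  }
  s <- st$z + st$g
  st$pi <- s / rowSums(s)
  st
}

# penalised objective: sum_ij z_ij (log pi_ij + log D_ij) + sum_ij g_ij log pi_ij
hgmm_loglik <- function(z, g, pi, logD) {
  lp <- log(pmax(pi, .Machine$double.xmin))
  sum(z * (lp + logD)) + sum(g * lp)
}

hgmm_data_loglik <- function(pi, logD) {
  sum(row_logsumexp(log(pmax(pi, .Machine$double.xmin)) + logD))
}

#' @export
print.hgmm <- function(x, ...) {
  cat(sprintf("MRF-regularised hierarchical Gaussian mixture (k = %d, r = %d, beta = %g)\n",
              x$k, x$r, x$beta))
  cat(sprintf("  %d pixels (%d x %d), %d EM iterations, %s\n",
              prod(x$dims), x$dims[1], x$dims[2], x$iter,
              if (x$converged) "converged" else "iteration cap reached"))
  cat("  category means:", paste(sprintf("%.4f", rowSums(x$eta * x$mu)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hgmm <- function(object, ...) {
  mix_mu <- rowSums(object$eta * object$mu)
  tab <- data.frame(category = seq_len(object$k),
                    mean = mix_mu,
                    sd = sqrt(rowSums(object$eta * (object$sigma2 + object$mu^2)) - mix_mu^2),
                    pixels = as.integer(tabulate(object$labels, object$k)),
                    weight = colMeans(object$z))
  structure(list(table = tab, loglik = object$loglik,
                 iter = object$iter, converged = object$converged,
                 k = object$k, r = object$r, beta = object$beta),
            class = "summary.hgmm")
}

#' @export
print.summary.hgmm <- function(x, ...) {
  cat(sprintf("hgmm fit: k = %d, r = %d, beta = %g; %d iterations (%s)\n",
              x$k, x$r, x$beta, x$iter,
              if (x$converged) "converged" else "not converged"))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("final penalised log-likelihood: %.4f\n",
              x$loglik[length(x$loglik)]))
  invisible(x)
}

#' @export
coef.hgmm <- function(object, ...) {
  list(mu = object$mu, sigma2 = object$sigma2, eta = object$eta)
}

#' Posterior prediction for new feature values
#'
#' Evaluates category posteriors for values without spatial context, using
#' the fitted image-average prior per category.
#'
#' @param object An `hgmm` fit.
#' @param newdata Numeric vector of feature values; defaults to the
#'   training pixels.
#' @param type `"class"` (default) for hard labels, `"posterior"` for the
#'   N x k posterior matrix.
#' @param ... Unused.
#' @export
predict.hgmm <- function(object, newdata = NULL,
                         type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    z <- object$z
  } else {
    xv <- as.numeric(newdata)
    st <- list(mu = object$mu, sigma2 = object$sigma2, eta = object$eta)
    prior <- matrix(colMeans(object$pi), length(xv), object$k, byrow = TRUE)
    z <- hgmm_e_step(prior, hgmm_log_density(xv, st))
  }
  if (type == "posterior") z else max.col(z, ties.method = "first")
}

#' @export
fitted.hgmm <- function(object, ...) {
  mix_mu <- rowSums(object$eta * object$mu)
  f <- as.numeric(object$z %*% mix_mu)
  matrix(f, object$dims[1], object$dims[2])
}

#' @export
residuals.hgmm <- function(object, ...) {
  matrix(as.numeric(object$x), object$dims[1], object$dims[2]) - fitted(object)
}

#' Simulate a feature image from a fitted model
#'
#' Draws each pixel from its fitted per-pixel prior over categories, then
#' from the category's Gaussian sub-mixture.
#'
#' @param object An `hgmm` fit.
#' @param nsim Number of images to simulate.
#' @param seed Optional seed, restored on exit as `simulate()` methods do.
#' @param ... Unused.
#' @return A list of `nsim` matrices with the fitted image dimensions.
#' @export
simulate.hgmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- prod(object$dims)
  lapply(seq_len(nsim), function(s) {
    j <- vapply(seq_len(n), function(i)
      sample.int(object$k, 1L, prob = object$pi[i, ]), integer(1))
    rr <- vapply(j, function(jj)
      sample.int(object$r, 1L, prob = object$eta[jj, ]), integer(1))
    x <- stats::rnorm(n, object$mu[cbind(j, rr)], sqrt(object$sigma2[cbind(j, rr)]))
    matrix(x, object$dims[1], object$dims[2])
  })
}

#' @export
plot.hgmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(seq_along(x$loglik), x$loglik, type = "b", pch = 16,
                 xlab = "EM iteration", ylab = "penalised log-likelihood",
                 main = "EM trace")
  xv <- as.numeric(x$x)
  graphics::hist(xv, breaks = 60, freq = FALSE, main = "fitted mixture",
                 xlab = "feature value", col = "grey90", border = "grey70")
  xs <- seq(min(xv), max(xv), length.out = 400)
  w <- colMeans(x$z)
  st <- list(mu = x$mu, sigma2 = x$sigma2, eta = x$eta)
  D <- exp(hgmm_log_density(xs, st))
  graphics::lines(xs, as.numeric(D %*% w), lwd = 2, col = "firebrick")
  invisible(x)
}
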