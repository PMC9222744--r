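test_that("initialisation is deterministic and validated", {
  set.seed(51)
  x <- rnorm(100)
  s1 <- nedsem:::hgmm_init(x, 2L, 1L)
  s2 <- nedsem:::hgmm_init(x, 2L, 1L)
  expect_identical(s1, s2)
  # quantile rule brackets the modes of a bimodal sample
  xb <- c(rnorm(500, -2, 0.3), rnorm(500, 2, 0.3))
  mu <- sort(nedsem:::hgmm_init(xb, 2L, 1L)$mu[, 1])
  expect_lt(mu[1], -1); expect_gt(mu[2], 1)
  expect_error(hgmm(rnorm(4), k = 5), "at least k")
  expect_error(hgmm(c(1, NaN, 3), k = 2), "finite")
  expect_error(hgmm(rnorm(10), k = 2, beta = -1), "non-negative")
})

test_that("the hierarchical density reduces and sums as defined", {
  st <- list(mu = matrix(c(0, 2), 1, 2), sigma2 = matrix(c(1, 4), 1, 2),
             eta = matrix(c(0.3, 0.7), 1, 2))
  x <- seq(-2, 4, by = 0.5)
  D <- exp(nedsem:::hgmm_log_density(x, st))
  # direct-summation oracle over the sub-Gaussians
  expect_equal(D[, 1],
               0.3 * dnorm(x, 0, 1) + 0.7 * dnorm(x, 2, 2), tolerance = 1e-12)
  # r = 1 collapses to the single Gaussian pdf
  st1 <- list(mu = matrix(1.5), sigma2 = matrix(0.25), eta = matrix(1))
  expect_equal(exp(nedsem:::hgmm_log_density(x, st1))[, 1],
               dnorm(x, 1.5, 0.5), tolerance = 1e-12)
  # equal sub-Gaussians with any weights degenerate to one Gaussian
  st2 <- list(mu = matrix(c(1, 1), 1, 2), sigma2 = matrix(c(1, 1), 1, 2),
              eta = matrix(c(0.5, 0.5), 1, 2))
  expect_equal(exp(nedsem:::hgmm_log_density(x, st2))[, 1],
               dnorm(x, 1, 1), tolerance = 1e-12)
})

test_that("the posterior update follows Bayes' rule", {
  # equidistant point between equal-variance means with equal priors
  logD <- log(cbind(dnorm(1, 0, 1), dnorm(1, 2, 1)))
  z <- nedsem:::hgmm_e_step(matrix(0.5, 1, 2), logD)
  expect_equal(as.numeric(z), c(0.5, 0.5))
  # a degenerate prior forces the posterior regardless of densities
  z2 <- nedsem:::hgmm_e_step(matrix(c(1, 0), 1, 2),
                             log(cbind(1e-12, 1)))
  expect_equal(as.numeric(z2), c(1, 0), tolerance = 1e-9)
  # random instance against a plain-loop Bayes oracle
  set.seed(52)
  x <- rnorm(20); pii <- matrix(runif(40), 20, 2); pii <- pii / rowSums(pii)
  mu <- c(-1, 1); s <- c(0.5, 1.5)
  logD <- cbind(dnorm(x, mu[1], s[1], log = TRUE), dnorm(x, mu[2], s[2], log = TRUE))
  z <- nedsem:::hgmm_e_step(pii, logD)
  for (i in 1:20) {
    w <- pii[i, ] * dnorm(x[i], mu, s)
    expect_equal(z[i, ], w / sum(w), tolerance = 1e-12)
  }
  expect_equal(rowSums(z), rep(1, 20), tolerance = 1e-12)
})

test_that("the MRF neighbourhood term honours beta, uniformity and borders", {
  dims <- c(5L, 6L)
  n <- prod(dims)
  z <- matrix(1 / 3, n, 3); pii <- z
  expect_equal(nedsem:::hgmm_g(z, pii, 0, dims), matrix(1, n, 3))
  g <- nedsem:::hgmm_g(z, pii, 1.7, dims)
  # uniform z = pi = 1/K gives g = exp(beta/K) everywhere (the truncated
  # average cancels the neighbour count)
  expect_equal(g, matrix(exp(1.7 / 3), n, 3), tolerance = 1e-12)
  cnt <- nedsem:::neighbor_sum(matrix(1, dims[1], dims[2]))
  cntm <- matrix(cnt, dims[1], dims[2])
  expect_equal(cntm[1, 1], 3)       # corner
  expect_equal(cntm[1, 3], 5)       # edge
  expect_equal(cntm[3, 3], 8)       # interior
})

test_that("moment updates match hard-assignment and weighted oracles", {
  set.seed(53)
  x <- c(rnorm(30, 0, 1), rnorm(30, 5, 1))
  hard <- cbind(rep(c(1, 0), each = 30), rep(c(0, 1), each = 30))
  st <- list(mu = matrix(c(0, 5), 2, 1), sigma2 = matrix(1, 2, 1),
             eta = matrix(1, 2, 1), z = hard, g = matrix(1, 60, 2),
             pi = matrix(0.5, 60, 2))
  logD <- nedsem:::hgmm_log_density(x, st)
  up <- nedsem:::hgmm_m_step(x, st, logD)
  expect_equal(up$mu[1, 1], mean(x[1:30]), tolerance = 1e-12)
  expect_equal(up$mu[2, 1], mean(x[31:60]), tolerance = 1e-12)
  expect_equal(up$sigma2[1, 1], mean((x[1:30] - mean(x[1:30]))^2),
               tolerance = 1e-12)
  expect_equal(rowSums(up$pi), rep(1, 60), tolerance = 1e-12)
  # pi update: (z + g) renormalised
  expect_equal(up$pi, (hard + st$g) / rowSums(hard + st$g), tolerance = 1e-12)
})

test_that("the penalised log-likelihood matches direct summation", {
  set.seed(54)
  n <- 15
  z <- matrix(runif(n * 2), n, 2); z <- z / rowSums(z)
  g <- matrix(runif(n * 2, 0.5, 2), n, 2)
  pii <- matrix(runif(n * 2), n, 2); pii <- pii / rowSums(pii)
  logD <- matrix(rnorm(n * 2), n, 2)
  direct <- 0
  for (i in 1:n) for (j in 1:2)
    direct <- direct + z[i, j] * (log(pii[i, j]) + logD[i, j]) +
      g[i, j] * log(pii[i, j])
  expect_equal(nedsem:::hgmm_loglik(z, g, pii, logD), direct, tolerance = 1e-10)
})

test_that("with beta = 0 the fit reproduces the plain-loop EM trajectory", {
  set.seed(55)
  x <- c(rnorm(150, -1, 0.5), rnorm(150, 2, 0.8))
  tr <- o_em_trace(x, 2, 5)
  for (t in c(2, 5)) {
    f <- suppressWarnings(hgmm(x, k = 2, beta = 0, tol = 1e-12, max_iter = t))
    expect_equal(as.numeric(f$mu), tr[[t]]$mu, tolerance = 1e-6)
    expect_equal(as.numeric(f$sigma2), tr[[t]]$s2, tolerance = 1e-6)
    expect_equal(f$z, tr[[t]]$z, tolerance = 1e-6)
    expect_equal(f$data_loglik[t], tr[[t]]$dll, tolerance = 1e-6)
  }
})

test_that("well-separated regions are recovered up to label permutation", {
  set.seed(56)
  truth <- matrix(rep(c(1, 2), each = 128), 16, 16)
  x <- matrix(c(0, 10)[truth] + rnorm(256, 0, 0.3), 16, 16)
  f <- hgmm(x, k = 2, beta = 0, seed = 1)
  m <- o_best_perm(as.vector(f$labels), as.vector(truth), 2)
  expect_equal(m$acc, 1)
  # k = 1: one label, immediate convergence
  f1 <- hgmm(x, k = 1, beta = 0)
  expect_true(all(f1$labels == 1))
  expect_lte(f1$iter, 2)
})

test_that("relabelling the state permutes the outputs identically", {
  set.seed(57)
  x <- rnorm(50)
  st <- nedsem:::hgmm_init(x, 3L, 1L)
  perm <- c(3L, 1L, 2L)
  stp <- list(mu = st$mu[perm, , drop = FALSE],
              sigma2 = st$sigma2[perm, , drop = FALSE],
              eta = st$eta[perm, , drop = FALSE],
              pi = st$pi[, perm], z = st$z[, perm], g = st$g[, perm])
  z1 <- nedsem:::hgmm_e_step(st$pi, nedsem:::hgmm_log_density(x, st))
  z2 <- nedsem:::hgmm_e_step(stp$pi, nedsem:::hgmm_log_density(x, stp))
  expect_equal(z2, z1[, perm], tolerance = 1e-12)
})

test_that("normalisations hold after a full fit and r > 1 is supported", {
  set.seed(58)
  x <- matrix(c(rnorm(128, 0, 0.5), rnorm(128, 4, 1.5)), 16, 16)
  f <- hgmm(x, k = 2, r = 2, beta = 1, seed = 2)
  expect_equal(rowSums(f$z), rep(1, 256), tolerance = 1e-9)
  expect_equal(rowSums(f$pi), rep(1, 256), tolerance = 1e-9)
  expect_equal(rowSums(f$eta), c(1, 1), tolerance = 1e-9)
  expect_true(all(f$sigma2 > 0))
  expect_identical(dim(f$mu), c(2L, 2L))
})

test_that("fits are deterministic given a seed and expose model methods", {
  set.seed(59)
  x <- matrix(rnorm(256, rep(c(0, 3), each = 128), 0.5), 16, 16)
  f1 <- hgmm(x, k = 2, seed = 7)
  f2 <- hgmm(x, k = 2, seed = 7)
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$mu, f2$mu)
  expect_equal(length(f1$loglik), f1$iter)     # trace recorded every iteration

  expect_output(print(f1), "hierarchical Gaussian mixture")
  s <- summary(f1)
  expect_s3_class(s, "summary.hgmm")
  expect_equal(sum(s$table$pixels), 256L)
  expect_named(coef(f1), c("mu", "sigma2", "eta"))
  p <- predict(f1, c(-0.1, 3.2))
  expect_equal(p[1] != p[2], TRUE)
  post <- predict(f1, c(-0.1, 3.2), type = "posterior")
  expect_equal(rowSums(post), c(1, 1), tolerance = 1e-12)
  sim <- simulate(f1, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_equal(dim(sim[[1]]), dim(x))
  expect_equal(residuals(f1), x - fitted(f1), tolerance = 1e-12)
})

test_that("spatial smoothing removes boundary-hugging speckle", {
  fx <- fixture_speckle()
  f0 <- hgmm(fx$x, k = 2, beta = 0, seed = 1)
  f2 <- hgmm(fx$x, k = 2, beta = 2, seed = 1)
  expect_lt(o_islands(f2$labels), o_islands(f0$labels))
})
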