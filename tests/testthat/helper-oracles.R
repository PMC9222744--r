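# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: plain loops, direct formulas.

# reflect an index into 1..n (edge-repeating reflection, as the filters pad)
o_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# brute-force flat min/max filter; type "min" = erosion over the footprint,
# type "max" = dilation (maximum over the reflected footprint)
o_filter <- function(P, se, type = c("min", "max")) {
  type <- match.arg(type)
  w <- which(se$footprint, arr.ind = TRUE)
  offs <- cbind(w[, 1] - se$anchor[1], w[, 2] - se$anchor[2])
  out <- P
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    vals <- numeric(nrow(offs))
    for (q in seq_len(nrow(offs))) {
      if (type == "min") { r <- i + offs[q, 1]; c <- j + offs[q, 2] }
      else               { r <- i - offs[q, 1]; c <- j - offs[q, 2] }
      vals[q] <- P[o_reflect(r, nrow(P)), o_reflect(c, ncol(P))]
    }
    out[i, j] <- if (type == "min") min(vals) else max(vals)
  }
  out
}

# direct transcription of the entropy closed form
o_entropy <- function(t, i, f)
  1 - (2 * sqrt(3) / 3) * sqrt((t - f)^2 / 2 + (abs(1 - 2 * i) / 2)^2)

# plain-loop EM for the spatially uncoupled model (beta = 0, r = 1): the
# neighbourhood term is identically 1, so pi_ij = (z_ij + 1) / (K + 1).
# Returns the state *at* each iteration (parameters entering the E-step).
o_em_trace <- function(x, k, iters) {
  n <- length(x)
  mu <- as.numeric(stats::quantile(x, (2 * seq_len(k) - 1) / (2 * k)))
  s2 <- rep(stats::var(x), k)
  pii <- matrix(1 / k, n, k)
  tr <- vector("list", iters)
  for (t in seq_len(iters)) {
    z <- matrix(0, n, k); dll <- 0
    for (i in 1:n) {
      w <- numeric(k)
      for (j in 1:k) w[j] <- pii[i, j] * stats::dnorm(x[i], mu[j], sqrt(s2[j]))
      z[i, ] <- w / sum(w)
      dll <- dll + log(sum(w))
    }
    tr[[t]] <- list(mu = mu, s2 = s2, z = z, dll = dll)
    for (j in 1:k) {
      mu[j] <- sum(z[, j] * x) / sum(z[, j])
      s2[j] <- max(sum(z[, j] * (x - mu[j])^2) / sum(z[, j]), 1e-8)
    }
    pii <- (z + 1) / rowSums(z + 1)
  }
  tr
}

# best label permutation (small k): relabel `est` to match `truth`
o_best_perm <- function(est, truth, k) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), , drop = FALSE]
  best <- NULL; best_acc <- -1
  for (i in seq_len(nrow(perms))) {
    acc <- mean(perms[i, ][est] == truth)
    if (acc > best_acc) { best_acc <- acc; best <- perms[i, ] }
  }
  list(perm = best, acc = best_acc)
}

# count isolated label islands: pixels disagreeing with all 8 neighbours
o_islands <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab); cnt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nb <- c(if (i > 1) lab[i - 1, j], if (i < nr) lab[i + 1, j],
            if (j > 1) lab[i, j - 1], if (j < nc) lab[i, j + 1],
            if (i > 1 && j > 1) lab[i - 1, j - 1],
            if (i > 1 && j < nc) lab[i - 1, j + 1],
            if (i < nr && j > 1) lab[i + 1, j - 1],
            if (i < nr && j < nc) lab[i + 1, j + 1])
    if (all(nb != lab[i, j])) cnt <- cnt + 1L
  }
  cnt
}

# the two study fixtures used by end-to-end checks
fixture_default <- function() synth_lesion(lesion_spec())
fixture_noisy <- function()
  synth_lesion(lesion_spec(noise_sigma = 6, hair_count = 8, bubble_count = 4))

# two-region feature image with boundary-hugging speckle on 5% of pixels:
# speckled values land just across the decision midpoint, so a spatially
# blind fit mislabels them while a smoothing prior can recover them
fixture_speckle <- function(H = 64, W = 64, seed = 7) {
  set.seed(seed)
  labs <- matrix(rep(c(1, 2), each = H * W / 2), H, W)
  x <- matrix(c(0.2, 0.8)[labs] + stats::rnorm(H * W, 0, 0.1), H, W)
  sp <- sample(H * W, round(0.05 * H * W))
  x[sp] <- ifelse(labs[sp] == 1,
                  stats::runif(length(sp), 0.52, 0.58),
                  stats::runif(length(sp), 0.42, 0.48))
  list(x = x, labs = labs)
}
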