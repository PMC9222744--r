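test_that("structuring elements are validated and shaped as documented", {
  se <- struct_el("disk", 2)
  expect_equal(dim(se$footprint), c(5L, 5L))
  expect_true(se$footprint[3, 3])
  expect_false(se$footprint[1, 1])          # disk cuts the corners
  expect_equal(sum(struct_el("square", 1)$footprint), 9L)
  expect_equal(sum(struct_el("cross", 1)$footprint), 5L)
  expect_error(new_struct_el(matrix(FALSE, 2, 2)), "at least one")
  expect_error(new_struct_el(matrix(TRUE, 3, 3), c(4, 1)), "anchor")
  expect_error(struct_el("disk", -1), "non-negative")
})

test_that("erosion and dilation match the brute-force min/max oracle", {
  set.seed(101)
  for (se in list(struct_el("square", 1), struct_el("disk", 2),
                  struct_el("cross", 2))) {
    P <- matrix(rnorm(64), 8, 8)
    expect_equal(erode(P, se), o_filter(P, se, "min"), tolerance = 1e-12)
    expect_equal(dilate(P, se), o_filter(P, se, "max"), tolerance = 1e-12)
  }
  # asymmetric footprint exercises the anchored/reflected variants
  se_a <- new_struct_el(rbind(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE)),
                        c(1L, 2L))
  P <- matrix(rnorm(63), 7, 9)
  expect_equal(erode(P, se_a), o_filter(P, se_a, "min"), tolerance = 1e-12)
  expect_equal(dilate(P, se_a), o_filter(P, se_a, "max"), tolerance = 1e-12)
})

test_that("derived point-spread examples behave as hand-computed", {
  se3 <- struct_el("square", 1)
  P <- matrix(0, 5, 5); P[3, 3] <- 1
  expect_equal(erode(P, se3), matrix(0, 5, 5))           # spike eroded away
  D <- dilate(P, se3)
  expect_equal(sum(D), 9)                                # 3x3 plateau
  expect_equal(D[2:4, 2:4], matrix(1, 3, 3))
  # bright plateau with one dark interior pixel: closing raises it back
  Q <- matrix(5, 7, 7); Q[4, 4] <- 0
  expect_equal(mclose(Q, se3), matrix(5, 7, 7))
  # step edge: gradient is 1 on the two columns flanking the step
  S <- matrix(rep(c(0, 0, 0, 1, 1, 1), each = 6), 6, 6)
  G <- mgradient(S, se3)
  expect_equal(unique(G[, 3]), 1)
  expect_equal(unique(G[, 4]), 1)
  expect_equal(unique(as.vector(G[, c(1, 6)])), 0)
})

test_that("morphological algebra holds on random matrices", {
  set.seed(202)
  se <- struct_el("disk", 1)
  for (rep in 1:20) {
    P <- matrix(rnorm(80), 8, 10)
    c1 <- mclose(P, se)
    expect_true(all(dilate(P, se) >= P))                 # dilation extensive
    expect_true(all(erode(P, se) <= P))                  # erosion anti-extensive
    expect_true(all(c1 >= P))                            # closing extensive
    expect_equal(mclose(c1, se), c1, tolerance = 1e-12)  # idempotent
    expect_true(all(mgradient(P, se) >= 0))
    expect_equal(dilate(P, se),
                 -erode(-P, nedsem:::reflect_se(se)), tolerance = 1e-12)
  }
})

test_that("constants are fixed points and single-pixel elements are identities", {
  C <- matrix(3.7, 6, 6)
  se <- struct_el("disk", 2)
  expect_equal(erode(C, se), C)
  expect_equal(dilate(C, se), C)
  expect_equal(mclose(C, se), C)
  expect_equal(mgradient(C, se), matrix(0, 6, 6))
  id <- struct_el("square", 0)
  P <- matrix(rnorm(36), 6, 6)
  expect_equal(erode(P, id), P)
  expect_equal(dilate(P, id), P)
  expect_error(erode(matrix(c(1, NA, 2, 3), 2, 2), se), "finite")
})
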