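test_that("forward stepping reproduces the signal model", {
  h <- 6; w <- 5
  a0 <- matrix(70000, h, w)
  a1 <- matrix(30000, h, w)
  th <- matrix(0, h, w)

  st <- forward_stepping(a0, a1, th, M = 8)
  for (k in 1:8)
    expect_equal(st$frames[, , k],
                 matrix(70000 + 30000 * sin(2 * pi * k / 8), h, w))

  # amplitude-free signal: every frame equals the DC offset
  flat <- forward_stepping(a0, a1 * 0, matrix(runif(h * w), h, w), M = 8)
  for (k in 1:8) expect_equal(flat$frames[, , k], a0)

  # shifting theta by a full period leaves the stack unchanged
  st2 <- forward_stepping(a0, a1, th + 2 * pi, M = 8)
  expect_lt(max(abs(st2$frames - st$frames)), 1e-6)
})

test_that("forward stepping validates its inputs", {
  a <- matrix(1, 4, 4)
  expect_error(forward_stepping(a, matrix(1, 4, 5), a, M = 8),
               "shape mismatch.*a1")
  expect_error(forward_stepping(a, a, matrix(0, 5, 4), M = 8),
               "shape mismatch.*theta")
  expect_error(forward_stepping(a, a, a, M = 2), "M must be at least 3")
  expect_warning(forward_stepping(a, a * 3, a * 0, M = 8),
                 "negative intensities")
  expect_error(stepping_stack(array(1, c(2, 2, 2))), "at least 3")
  expect_error(stepping_stack(array(-1, c(2, 2, 4))), "negative")
})

test_that("the closed-form fit inverts the forward model to 1e-9", {
  set.seed(101)
  for (rep in 1:20) {
    h <- 3; w <- 4
    a0 <- matrix(runif(h * w, 1e3, 1e5), h, w)
    a1 <- a0 * matrix(runif(h * w, 0.05, 0.95), h, w)
    th <- matrix(runif(h * w, -pi, pi - 1e-3), h, w)
    M <- sample(c(3, 5, 8, 12), 1)
    fit <- fit_sinusoid(forward_stepping(a0, a1, th, M = M))
    expect_lt(max(abs(fit$a0 - a0) / a0), 1e-9)
    expect_lt(max(abs(fit$a1 - a1) / a1), 1e-9)
    expect_lt(max(abs(wrap_angle(fit$theta - th))), 1e-9)
  }
})

test_that("the fit agrees with a dense grid-search oracle", {
  k <- 1:8
  y <- 70000 + 30000 * sin(2 * pi * k / 8 + 0.3)
  or <- grid_fit_oracle(y, k, 8)
  st <- stepping_stack(array(rep(y, each = 1), c(1, 1, 8)))
  fit <- fit_sinusoid(st)
  expect_lt(abs(fit$a0[1, 1] - 70000) / 70000, 1e-9)
  expect_lt(abs(fit$a1[1, 1] - 30000) / 30000, 1e-9)
  expect_lt(abs(fit$theta[1, 1] - 0.3), 1e-9)
  # the oracle's grid optimum cannot beat the closed form
  res_fit <- sum((fit$a0[1, 1] + fit$a1[1, 1] *
                    sin(2 * pi * k / 8 + fit$theta[1, 1]) - y)^2)
  expect_lte(res_fit, or$rss + 1e-9)
})

test_that("the closed-form fit is optimal against random perturbations", {
  set.seed(7)
  k <- 1:8
  y <- 50000 + 20000 * sin(2 * pi * k / 8 - 1.1) + rnorm(8, 0, 200)
  fit <- fit_sinusoid(stepping_stack(array(y, c(1, 1, 8))))
  p0 <- c(fit$a0[1, 1], fit$a1[1, 1], fit$theta[1, 1])
  rss0 <- sum((p0[1] + p0[2] * sin(2 * pi * k / 8 + p0[3]) - y)^2)
  n <- 10000
  pert <- cbind(p0[1] + rnorm(n, 0, 300), p0[2] + rnorm(n, 0, 300),
                p0[3] + rnorm(n, 0, 0.05))
  rss <- sapply(seq_len(n), function(i)
    sum((pert[i, 1] + pert[i, 2] * sin(2 * pi * k / 8 + pert[i, 3]) - y)^2))
  expect_true(all(rss0 <= rss + 1e-9))
})

test_that("fit conventions: wrapping, degenerate pixels", {
  h <- 2; w <- 2
  a0 <- matrix(5e4, h, w); a1 <- matrix(2e4, h, w)
  f1 <- fit_sinusoid(forward_stepping(a0, a1, matrix(pi - 1e-6, h, w), M = 8))
  f2 <- fit_sinusoid(forward_stepping(a0, a1, matrix(-pi + 1e-6, h, w), M = 8))
  # thetas sit on opposite sides of the wrap; their angular distance is 2e-6
  expect_lt(max(abs(abs(wrap_angle(f1$theta - f2$theta)) - 2e-6)), 1e-9)
  expect_true(all(f1$theta >= -pi & f1$theta < pi))

  const <- fit_sinusoid(stepping_stack(array(42, c(2, 2, 8))))
  expect_equal(const$a0, matrix(42, 2, 2))
  expect_equal(const$a1, matrix(0, 2, 2), tolerance = 1e-9)

  zero <- fit_sinusoid(stepping_stack(array(0, c(2, 2, 8))))
  expect_equal(zero$a0, matrix(0, 2, 2))
  expect_equal(zero$a1, matrix(0, 2, 2))
  expect_equal(zero$theta, matrix(0, 2, 2))
})

make_fit <- function(a0, a1, theta) {
  structure(list(a0 = as.matrix(a0), a1 = as.matrix(a1),
                 theta = as.matrix(theta)), class = "sinusoid_fit")
}

test_that("contrast extraction follows the channel definitions", {
  f <- make_fit(matrix(70000, 3, 3), matrix(30000, 3, 3), matrix(0.5, 3, 3))
  tri <- extract_contrast(f, f)
  expect_equal(tri$transmission, matrix(1, 3, 3))
  expect_equal(tri$dpci, matrix(0, 3, 3))
  expect_equal(tri$darkfield, matrix(1, 3, 3))

  half <- make_fit(matrix(35000, 3, 3), matrix(15000, 3, 3),
                   matrix(0.5, 3, 3))
  expect_equal(extract_contrast(f, half)$transmission, matrix(0.5, 3, 3))

  shifted <- make_fit(f$a0, f$a1, f$theta + 3 * pi / 2)
  expect_equal(extract_contrast(f, shifted)$dpci, matrix(-pi / 2, 3, 3))
})

test_that("the literal dark-field form is available behind the flag", {
  ref <- make_fit(matrix(70000, 2, 2), matrix(30000, 2, 2), matrix(0, 2, 2))
  sam <- make_fit(matrix(35000, 2, 2), matrix(10000, 2, 2), matrix(0, 2, 2))
  vis <- extract_contrast(ref, sam)$darkfield
  lit <- extract_contrast(ref, sam, darkfield_form = "literal")$darkfield
  expect_equal(vis[1, 1], (10000 / 35000) / (30000 / 70000))
  expect_equal(lit[1, 1], (10000 / 70000) / (35000 / 30000))
})

test_that("contrast is equivariant under a common carrier phase", {
  set.seed(3)
  ref <- make_fit(matrix(runif(12, 5e4, 8e4), 3, 4),
                  matrix(runif(12, 1e4, 3e4), 3, 4),
                  matrix(runif(12, -1, 1), 3, 4))
  sam <- make_fit(ref$a0 * 0.7, ref$a1 * 0.5, ref$theta + 0.2)
  t1 <- extract_contrast(ref, sam)
  cshift <- 1.3
  t2 <- extract_contrast(make_fit(ref$a0, ref$a1, ref$theta + cshift),
                         make_fit(sam$a0, sam$a1, sam$theta + cshift))
  expect_equal(t1$transmission, t2$transmission)
  expect_equal(t1$dpci, t2$dpci, tolerance = 1e-12)
  expect_equal(t1$darkfield, t2$darkfield)
})

test_that("scaling the sample stack scales transmission only", {
  acq <- tiny_acquisition(size = 64)
  s <- 1.7
  scaled <- acq$sam
  scaled$frames <- scaled$frames * s
  t1 <- acq$triplet
  t2 <- extract_contrast(fit_sinusoid(acq$ref), fit_sinusoid(scaled))
  expect_equal(t2$transmission, t1$transmission * s, tolerance = 1e-9)
  expect_equal(t2$dpci, t1$dpci, tolerance = 1e-9)
  expect_equal(t2$darkfield, t1$darkfield, tolerance = 1e-9)
})
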