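test_that("phantom construction pads and normalises as specified", {
  ph <- make_phantom("shepp_logan", size = 256)
  expect_equal(dim(ph$image), c(256, 320))  # 32 px pad left and right
  expect_true(all(ph$image >= 0 & ph$image <= 1))
  expect_true(all(ph$image[, 1:32] == 0) && all(ph$image[, 289:320] == 0))

  tx <- make_phantom("synthetic_texture", size = 64)
  expect_equal(dim(tx$image), c(64, 128))
  expect_error(make_phantom("shepp_logan", size = 32), "at least 64")
  expect_error(make_phantom("user_image"), "requires 'image'")
})

test_that("the empty phantom yields trivial ground truth", {
  ph <- make_phantom("user_image", image = matrix(0, 64, 64))
  expect_equal(ph$gt$dpci_ideal, matrix(0, 64, 128))
  expect_equal(ph$gt$transmission_ideal, matrix(1, 64, 128))
  expect_equal(ph$gt$darkfield_ideal, matrix(1, 64, 128))
})

test_that("carrier phase patterns match their closed forms", {
  ph <- make_phantom("shepp_logan", size = 256)
  # direct evaluation oracle at a handful of coordinates (0-based x, y)
  for (xy in list(c(200, 100), c(0, 0), c(319, 255), c(57, 200))) {
    x <- xy[1]; y <- xy[2]
    expect_equal(ph$theta_pattern[y + 1, x + 1],
                 sqrt((x / 10 - 20)^2 + (-y / 5 + 70)^2) %% (2 * pi))
  }
  # the formula itself, checked off-grid as well
  expect_equal(gipret:::theta_pattern_phantom(200, 350),
               sqrt((200 / 10 - 20)^2 + (-350 / 5 + 70)^2) %% (2 * pi))
  pp <- make_phantom("shepp_logan", size = 64, theta_pattern = "peppers")
  expect_equal(pp$theta_pattern[3, 5],
               sqrt((4 / 40 + 10)^2 + (-2 / 15 + 20)^2) %% (2 * pi))
})

test_that("sample coefficients follow the attenuation/visibility model", {
  img <- matrix(0, 64, 64); img[10, 10] <- 1
  ph <- make_phantom("user_image", image = img)
  cf <- sample_coefficients(ph)
  # air pixel: coefficients equal the reference values
  expect_equal(cf$sam$a0[1, 1], 70000)
  expect_equal(cf$sam$a1[1, 1], 30000)
  expect_equal(cf$sam$theta[1, 1], ph$theta_pattern[1, 1])
  # image = 1 pixel
  expect_equal(cf$sam$a0[10, 42], 70000 * (1 - 0.25^0.7))
  expect_equal(cf$sam$a1[10, 42], 30000 * (1 - (1 / 1.5)^0.5))
  # the sample phase shift is exactly the discrete x-derivative
  expect_equal(cf$sam$theta - ph$theta_pattern, diff_x(ph$image))
})

test_that("noiseless error-free acquisition closes the loop exactly", {
  ph <- make_phantom("shepp_logan", size = 64, eta_range = 0)
  acq <- simulate_acquisition(ph, noisy = FALSE, seed = 5)
  trip <- extract_contrast(fit_sinusoid(acq$ref), fit_sinusoid(acq$sam))
  cf <- sample_coefficients(ph)
  expect_lt(max(abs(trip$dpci - wrap_angle(ph$gt$dpci_ideal))), 1e-6)
  expect_lt(max(abs(trip$transmission - ph$gt$transmission_ideal)), 1e-9)
  expect_lt(max(abs(trip$darkfield - ph$gt$darkfield_ideal)), 1e-9)
  rf <- fit_sinusoid(acq$ref)
  expect_lt(max(abs(rf$a0 - cf$ref$a0) / cf$ref$a0), 1e-9)
})

test_that("identical seeds reproduce the acquisition bit for bit", {
  ph <- make_phantom("shepp_logan", size = 64)
  a1 <- simulate_acquisition(ph, noisy = TRUE, seed = 99)
  a2 <- simulate_acquisition(ph, noisy = TRUE, seed = 99)
  expect_identical(a1$ref$frames, a2$ref$frames)
  expect_identical(a1$sam$frames, a2$sam$frames)
  expect_identical(a1$eta_sam, a2$eta_sam)
})

test_that("Poisson noise has the right mean and variance", {
  ph <- make_phantom("shepp_logan", size = 64, eta_range = 0)
  clean <- simulate_acquisition(ph, noisy = FALSE, seed = 1)$ref$frames[5, 5, 1]
  n <- 200
  draws <- vapply(seq_len(n), function(s)
    simulate_acquisition(ph, noisy = TRUE, seed = s)$ref$frames[5, 5, 1], 0)
  # law of large numbers: the mean sits within 1% of the noise-free value
  expect_lt(abs(mean(draws) - clean) / clean, 0.01)
  # chi-square interval for the variance/mean ratio at 99% confidence
  ratio <- var(draws) / clean
  bounds <- stats::qchisq(c(0.005, 0.995), n - 1) / (n - 1)
  expect_gt(ratio, bounds[1])
  expect_lt(ratio, bounds[2])
})

test_that("stepping error produces a moire residual that shrinks with M", {
  resid <- function(M, seed) {
    ph <- make_phantom("shepp_logan", size = 64, M = M, eta_range = 0.05)
    acq <- simulate_acquisition(ph, noisy = FALSE, seed = seed)
    trip <- extract_contrast(fit_sinusoid(acq$ref), fit_sinusoid(acq$sam))
    sqrt(mean((trip$dpci - wrap_angle(ph$gt$dpci_ideal))^2))
  }
  r8 <- vapply(1:10, function(s) resid(8, s), 0)
  r32 <- vapply(1:10, function(s) resid(32, s), 0)
  expect_true(all(r8 > 0))
  expect_lt(median(r32), median(r8))
})
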