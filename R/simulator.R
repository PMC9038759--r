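#' Shepp-Logan head phantom
#'
#' Rasterises the standard ten-ellipse head phantom (with the
#' high-contrast grey values commonly used for display) on an `n x n`
#' grid over `[-1, 1]^2` and clips to `[0, 1]`. Generated from the ellipse
#' table so the package needs no bundled image data.
#'
#' @param n image side in pixels.
#' @return `n x n` matrix in `[0, 1]`.
#' @export
shepp_logan <- function(n = 256) {
  # columns: additive intensity, semi-axis a (x), b (y), centre x0, y0,
  # rotation phi (degrees)
  E <- matrix(c(
     1.0, 0.69,   0.92,   0,     0,      0,
    -0.8, 0.6624, 0.874,  0,    -0.0184, 0,
    -0.2, 0.11,   0.31,   0.22,  0,    -18,
    -0.2, 0.16,   0.41,  -0.22,  0,     18,
     0.1, 0.21,   0.25,   0,     0.35,   0,
     0.1, 0.046,  0.046,  0,     0.1,    0,
     0.1, 0.046,  0.046,  0,    -0.1,    0,
     0.1, 0.046,  0.023, -0.08, -0.605,  0,
     0.1, 0.023,  0.023,  0,    -0.606,  0,
     0.1, 0.023,  0.046,  0.06, -0.605,  0), ncol = 6, byrow = TRUE)
  xs <- seq(-1, 1, length.out = n)
  ys <- seq(1, -1, length.out = n)  # row 1 is the top of the head
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(E))) {
    phi <- E[i, 6] * pi / 180
    xr <- (X - E[i, 4]) * cos(phi) + (Y - E[i, 5]) * sin(phi)
    yr <- -(X - E[i, 4]) * sin(phi) + (Y - E[i, 5]) * cos(phi)
    inside <- (xr / E[i, 2])^2 + (yr / E[i, 3])^2 <= 1
    img[inside] <- img[inside] + E[i, 1]
  }
  pmin(pmax(img, 0), 1)
}

#' Procedurally generated high-frequency texture phantom
#'
#' A deterministic test image rich in edges and high-frequency content,
#' used where a complex natural scene is wanted without bundling image
#' data: overlapping discs of varying grey level on a smooth background
#' plus a radial chirp. Values lie in `[0, 1]`.
#'
#' @param n image side in pixels.
#' @return `n x n` matrix in `[0, 1]`.
#' @export
synthetic_texture <- function(n = 256) {
  u <- seq(0, 1, length.out = n)
  X <- matrix(u, n, n, byrow = TRUE)
  Y <- matrix(u, n, n)
  img <- 0.25 + 0.15 * sin(2 * pi * 3 * X) * cos(2 * pi * 2 * Y)
  # deterministic disc field (fixed small congruential sequence)
  s <- 12345
  nxt <- function() {
    s <<- (1103515245 * s + 12345) %% 2147483648
    s / 2147483648
  }
  for (i in 1:24) {
    cx <- nxt(); cy <- nxt(); r <- 0.03 + 0.07 * nxt(); v <- nxt()
    d <- (X - cx)^2 + (Y - cy)^2 <= r^2
    img[d] <- 0.2 + 0.75 * v
  }
  rr <- sqrt((X - 0.5)^2 + (Y - 0.5)^2)
  img <- img + 0.08 * sin(2 * pi * 14 * rr^2)
  img <- img - min(img)
  img / max(img)
}

# closed-form reference phase-pattern fields; x is the 0-based column
# index, y the 0-based row index
theta_pattern_phantom <- function(x, y) {
  sqrt((x / 10 - 20)^2 + (-y / 5 + 70)^2) %% (2 * pi)
}

theta_pattern_peppers <- function(x, y) {
  sqrt((x / 40 + 10)^2 + (-y / 15 + 20)^2) %% (2 * pi)
}

#' Build a simulation phantom with ground truth
#'
#' Prepares the sample image and acquisition parameters of the simulation
#' protocol: the base image is zero-padded 32 pixels to the left and
#' right, normalised to `[0, 1]`, and paired with a closed-form reference
#' phase pattern acting as the interferometer carrier. The ground truth
#' holds the padded image (the retrieval target), its discrete
#' x-derivative (the ideal DPCI, see [diff_x()]) and the ideal
#' transmission and dark-field maps implied by the sample-coefficient
#' model of [sample_coefficients()].
#'
#' @param kind `"shepp_logan"`, `"synthetic_texture"` or `"user_image"`.
#' @param size image side in pixels before padding (at least 64).
#' @param image user-supplied matrix when `kind = "user_image"`; values
#'   are rescaled to `[0, 1]`.
#' @param pad_px zero-padding width added to the left and right edges.
#' @param theta_pattern `"phantom"` or `"peppers"`: which closed-form
#'   carrier-phase field to use.
#' @param a0_ref,a1_ref reference DC offset and amplitude in counts.
#' @param M phase-stepping number.
#' @param eta_range half-width of the uniform stepping-error distribution
#'   in step units.
#' @param deriv_scale scale factor between the normalised-image gradient
#'   and the sample phase shift in radians (the units of this coupling are
#'   instrument-specific; 1.0 keeps the shift well within one fringe
#'   period for images normalised to `[0, 1]`).
#' @return object of class `phantom_spec`; element `gt` carries the
#'   ground-truth maps.
#' @export
#' @examples
#' ph <- make_phantom("shepp_logan", size = 64)
#' dim(ph$image)  # 64 x 128: padded 32 px left and right
make_phantom <- function(kind = c("shepp_logan", "synthetic_texture",
                                  "user_image"),
                         size = 256, image = NULL, pad_px = 32,
                         theta_pattern = c("phantom", "peppers"),
                         a0_ref = 70000, a1_ref = 30000, M = 8,
                         eta_range = 0.05, deriv_scale = 1.0) {
  kind <- match.arg(kind)
  theta_pattern <- match.arg(theta_pattern)
  if (kind == "user_image") {
    if (is.null(image)) stop("kind = 'user_image' requires 'image'")
    if (!is.matrix(image) || !is.numeric(image))
      stop("'image' cannot be interpreted as a greyscale matrix")
    base <- image
  } else {
    if (size < 64) stop("size must be at least 64")
    base <- switch(kind, shepp_logan = shepp_logan(size),
                   synthetic_texture = synthetic_texture(size))
  }
  if (a0_ref <= a1_ref || a1_ref <= 0)
    stop("need a0_ref > a1_ref > 0")
  if (eta_range < 0) stop("eta_range must be >= 0")
  base <- base - min(base)
  if (max(base) > 0) base <- base / max(base)
  h <- nrow(base)
  padded <- cbind(matrix(0, h, pad_px), base, matrix(0, h, pad_px))
  w <- ncol(padded)
  xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
  yg <- matrix(0:(h - 1), h, w)
  theta <- switch(theta_pattern,
                  phantom = theta_pattern_phantom(xg, yg),
                  peppers = theta_pattern_peppers(xg, yg))
  dpci_ideal <- deriv_scale * diff_x(padded)
  gt <- list(pci = padded,
             dpci_ideal = dpci_ideal,
             transmission_ideal = 1 - (padded / 4)^0.7,
             darkfield_ideal = (1 - (padded / 1.5)^0.5) /
                               (1 - (padded / 4)^0.7))
  structure(list(image = padded, theta_pattern = theta,
                 pad_px = pad_px, a0_ref = a0_ref, a1_ref = a1_ref,
                 M = as.integer(M), eta_range = eta_range,
                 deriv_scale = deriv_scale, kind = kind, gt = gt),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s, %d x %d (pad %d), M = %d, a0 = %g, a1 = %g, eta +/- %g\n",
              x$kind, nrow(x$image), ncol(x$image), x$pad_px, x$M,
              x$a0_ref, x$a1_ref, x$eta_range))
  invisible(x)
}

#' Sample and reference coefficient maps for a phantom
#'
#' Applies the sample-coefficient model to the normalised phantom image
#' `I`:
#' \deqn{a_{0,sam} = a_{0,ref} (1 - (I/4)^{0.7})}
#' \deqn{a_{1,sam} = a_{1,ref} (1 - (I/1.5)^{0.5})}
#' \deqn{\theta_{sam} = \theta_{pattern} + s \, \partial I / \partial x}
#' The derivative term is the sample-induced phase shift added on top of
#' the carrier pattern shared by both scans, so that the extracted DPCI
#' (`theta_sam - theta_ref`) equals the image derivative; `s` is
#' `deriv_scale` from the phantom.
#'
#' @param spec a `phantom_spec` from [make_phantom()].
#' @return list with elements `ref` and `sam`, each holding matrices
#'   `a0`, `a1`, `theta`.
#' @export
sample_coefficients <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- spec$image
  ref <- list(a0 = matrix(spec$a0_ref, nrow(img), ncol(img)),
              a1 = matrix(spec$a1_ref, nrow(img), ncol(img)),
              theta = spec$theta_pattern)
  sam <- list(a0 = spec$a0_ref * (1 - (img / 4)^0.7),
              a1 = spec$a1_ref * (1 - (img / 1.5)^0.5),
              theta = spec$theta_pattern + spec$gt$dpci_ideal)
  list(ref = ref, sam = sam)
}

#' Simulate a full reference/sample phase-stepping acquisition
#'
#' Generates the 2M frames of a reference scan and a sample scan through
#' the forward stepping model. Each frame receives an independent
#' stepping error `eta_k` drawn uniformly from
#' `[-eta_range, +eta_range]`, independently for the two scans - it is
#' this independence that produces the spatially structured moire
#' residual in the fitted DPCI. With `noisy = TRUE` every frame is
#' replaced by an independent Poisson draw with the noise-free frame as
#' its mean. Fully reproducible from `seed`.
#'
#' @param spec a `phantom_spec`.
#' @param coeffs coefficient maps from [sample_coefficients()]; computed
#'   from `spec` when omitted.
#' @param noisy apply Poisson counting noise?
#' @param seed integer seed; when `NULL` the current RNG stream is used.
#' @return list with `ref` and `sam` stepping stacks and the drawn
#'   per-step errors `eta_ref`, `eta_sam`.
#' @export
simulate_acquisition <- function(spec, coeffs = NULL, noisy = TRUE,
                                 seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(coeffs)) coeffs <- sample_coefficients(spec)
  if (!is.null(seed)) set.seed(seed)
  M <- spec$M
  eta_ref <- runif(M, -spec$eta_range, spec$eta_range)
  eta_sam <- runif(M, -spec$eta_range, spec$eta_range)
  ref <- forward_stepping(coeffs$ref$a0, coeffs$ref$a1, coeffs$ref$theta,
                          M = M, eta = eta_ref, role = "reference")
  sam <- forward_stepping(coeffs$sam$a0, coeffs$sam$a1, coeffs$sam$theta,
                          M = M, eta = eta_sam, role = "sample")
  if (any(ref$frames < 0) || any(sam$frames < 0))
    stop("negative mean intensity encountered before noise")
  if (noisy) {
    ref$frames <- array(rpois(length(ref$frames), ref$frames),
                        dim(ref$frames))
    sam$frames <- array(rpois(length(sam$frames), sam$frames),
                        dim(sam$frames))
  }
  list(ref = ref, sam = sam, eta_ref = eta_ref, eta_sam = eta_sam)
}
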