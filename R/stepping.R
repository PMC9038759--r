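#' Construct a phase-stepping stack
#'
#' A stepping stack holds the M intensity frames recorded while the
#' analyser grating is scanned through one period, together with the step
#' indices `k` entering the sinusoidal signal model and the scan role
#' (reference scan without sample, or sample scan).
#'
#' @param frames numeric array `H x W x M` of non-negative intensities.
#' @param step_indices integer vector of the step numbers `k` (default
#'   `1:M`). Subset fits keep the original indices so the per-frame phases
#'   `2*pi*k/M` are preserved.
#' @param M total number of steps in the full scan; defaults to the number
#'   of frames. Kept separately because a stack may hold a frame subset.
#' @param role `"reference"` or `"sample"`.
#' @return an object of class `stepping_stack`.
#' @export
stepping_stack <- function(frames, step_indices = NULL, M = NULL,
                           role = c("reference", "sample")) {
  role <- match.arg(role)
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L)
    stop("'frames' must be an H x W x M array, got ",
         paste(dim(frames), collapse = " x "))
  n_frames <- dim(frames)[3]
  if (is.null(step_indices)) step_indices <- seq_len(n_frames)
  if (length(step_indices) != n_frames)
    stop("length(step_indices) [", length(step_indices),
         "] does not match the number of frames [", n_frames, "]")
  if (is.null(M)) M <- max(step_indices)
  if (n_frames < 3L)
    stop("at least 3 frames are required (three unknowns per pixel), got ",
         n_frames)
  if (!all(is.finite(frames)))
    stop("frames contain non-finite intensities")
  if (min(frames) < 0)
    stop("frames contain negative intensities")
  structure(list(frames = frames, step_indices = as.integer(step_indices),
                 M = as.integer(M), role = role),
            class = "stepping_stack")
}

#' @export
print.stepping_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stepping_stack> %s scan, %d frame(s) of %d x %d (M = %d)\n",
              x$role, d[3], d[1], d[2], x$M))
  cat("  steps:", paste(x$step_indices, collapse = ", "), "\n")
  invisible(x)
}

#' Forward phase-stepping signal model
#'
#' Evaluates the noise-free stepping sinusoid per pixel and step,
#' `I_k = a0 + a1 * sin(2*pi*(k + eta_k)/M + theta)`,
#' where `eta_k` is a mechanical stepping error in units of one step.
#' Counting noise is deliberately not applied here; it is a separate
#' operation of the simulator (see [simulate_acquisition()]).
#'
#' @param a0 DC-offset map (matrix, counts).
#' @param a1 amplitude map (matrix, counts, must satisfy `0 <= a1 <= a0`
#'   for the intensities to stay non-negative; violations give a warning).
#' @param theta phase map in radians.
#' @param M number of steps; frames are generated for `k = 1:M` unless
#'   `step_indices` says otherwise.
#' @param eta stepping error: a scalar, a length-M vector (one offset per
#'   step) or an `H x W x M` array, in step units. `|eta| < M/2` required.
#' @param step_indices integer step numbers (default `1:M`).
#' @param role passed to [stepping_stack()].
#' @return a `stepping_stack` with `length(step_indices)` frames.
#' @export
#' @examples
#' a0 <- matrix(70000, 8, 8); a1 <- matrix(30000, 8, 8)
#' st <- forward_stepping(a0, a1, theta = matrix(0, 8, 8), M = 8)
#' st$frames[1, 1, 1] == 70000 + 30000 * sin(2 * pi * 1 / 8)
forward_stepping <- function(a0, a1, theta, M, eta = 0,
                             step_indices = seq_len(M),
                             role = c("reference", "sample")) {
  role <- match.arg(role)
  a0 <- as.matrix(a0); a1 <- as.matrix(a1); theta <- as.matrix(theta)
  if (!identical(dim(a0), dim(a1)))
    stop("shape mismatch: a0 is ", paste(dim(a0), collapse = "x"),
         " but a1 is ", paste(dim(a1), collapse = "x"))
  if (!identical(dim(a0), dim(theta)))
    stop("shape mismatch: a0 is ", paste(dim(a0), collapse = "x"),
         " but theta is ", paste(dim(theta), collapse = "x"))
  if (M < 3) stop("M must be at least 3, got ", M)
  n <- length(step_indices)
  if (is.array(eta) && length(dim(eta)) == 3L) {
    if (!identical(dim(eta), c(dim(a0), n)))
      stop("per-pixel eta must be H x W x ", n)
    eta_k <- function(i) eta[, , i]
  } else {
    eta <- rep_len(as.numeric(eta), n)
    eta_k <- function(i) eta[i]
  }
  if (max(abs(if (is.array(eta)) eta else eta)) >= M / 2)
    stop("|eta| must stay below M/2 to remain meaningful within one period")
  if (any(a1 > a0))
    warning("a1 exceeds a0 on some pixels; negative intensities possible")
  frames <- array(0, c(dim(a0), n))
  for (i in seq_len(n)) {
    k <- step_indices[i]
    frames[, , i] <- a0 + a1 * sin(2 * pi * (k + eta_k(i)) / M + theta)
  }
  frames[frames < 0] <- 0
  stepping_stack(frames, step_indices = step_indices, M = M, role = role)
}

#' Closed-form per-pixel sinusoid fit
#'
#' Fits `a0 + a1 * sin(2*pi*k/M + theta)` to every pixel of a stepping
#' stack by linear least squares in the reparameterisation
#' `(a0, a1*cos(theta), a1*sin(theta))`, which makes the harmonic
#' regression exactly linear and the solution closed-form and
#' deterministic. The fit assumes ideal step positions (`eta = 0`): the
#' mechanical stepping error is unknown at analysis time and is absorbed
#' as noise, surfacing downstream as the moire residual that the
#' retrieval methods must remove. The amplitude is normalised to
#' `a1 >= 0` (adding pi to theta where needed) and theta is wrapped to
#' `[-pi, pi)`. An all-zero pixel yields `a0 = a1 = 0`, `theta = 0`.
#'
#' @param stack a `stepping_stack` with at least 3 frames.
#' @return an object of class `sinusoid_fit`: list with `H x W` matrices
#'   `a0`, `a1`, `theta`.
#' @export
fit_sinusoid <- function(stack) {
  stopifnot(inherits(stack, "stepping_stack"))
  d <- dim(stack$frames)
  n <- d[3]
  if (n < 3) stop("at least 3 frames are required for the 3-parameter fit")
  ang <- 2 * pi * stack$step_indices / stack$M
  X <- cbind(1, sin(ang), cos(ang))
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("step phases are degenerate; the sinusoid fit is underdetermined")
  # beta (P x 3) = Y X (X'X)^-1 with Y the P x M pixel matrix
  Y <- matrix(stack$frames, d[1] * d[2], n)
  beta <- Y %*% X %*% solve(XtX)
  a0 <- matrix(beta[, 1], d[1], d[2])
  bc <- beta[, 2]; bs <- beta[, 3]
  a1 <- matrix(sqrt(bc^2 + bs^2), d[1], d[2])
  theta <- matrix(wrap_angle(atan2(bs, bc)), d[1], d[2])
  structure(list(a0 = a0, a1 = a1, theta = theta), class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("<sinusoid_fit> %d x %d; a0 in [%.4g, %.4g], mean visibility %.4g\n",
              nrow(x$a0), ncol(x$a0), min(x$a0), max(x$a0),
              mean(x$a1 / pmax(x$a0, .Machine$double.eps))))
  invisible(x)
}

#' Extract transmission, DPCI and dark-field images from a fit pair
#'
#' Combines the reference-scan and sample-scan sinusoid fits into the
#' three contrast channels: transmission `a0_sam / a0_ref`, differential
#' phase contrast `wrap(theta_sam - theta_ref)`, and dark-field. The
#' dark-field defaults to the conventional visibility ratio
#' `(a1_sam/a0_sam) / (a1_ref/a0_ref)`; `darkfield_form = "literal"`
#' selects the alternative printed ratio
#' `(a1_sam/a0_ref) / (a0_sam/a1_ref)`, which is dimensionally
#' inconsistent with the visibility definition but kept available for
#' comparison.
#'
#' @param ref_fit,sam_fit `sinusoid_fit` objects of equal size.
#' @param darkfield_form `"visibility"` (default) or `"literal"`.
#' @param fill value substituted where a reference-map division by zero
#'   occurs; the number of affected pixels is recorded in the `n_filled`
#'   attribute and reported via a warning.
#' @return object of class `contrast_triplet`: list with matrices
#'   `transmission`, `dpci` (radians in `[-pi, pi)`), `darkfield`.
#' @export
extract_contrast <- function(ref_fit, sam_fit,
                             darkfield_form = c("visibility", "literal"),
                             fill = 0) {
  darkfield_form <- match.arg(darkfield_form)
  stopifnot(inherits(ref_fit, "sinusoid_fit"),
            inherits(sam_fit, "sinusoid_fit"))
  if (!identical(dim(ref_fit$a0), dim(sam_fit$a0)))
    stop("reference and sample fits have different shapes")
  transmission <- sam_fit$a0 / ref_fit$a0
  dpci <- wrap_angle(sam_fit$theta - ref_fit$theta)
  darkfield <- switch(darkfield_form,
    visibility = (sam_fit$a1 / sam_fit$a0) / (ref_fit$a1 / ref_fit$a0),
    literal = (sam_fit$a1 / ref_fit$a0) / (sam_fit$a0 / ref_fit$a1))
  bad <- !is.finite(transmission) | !is.finite(darkfield)
  n_filled <- sum(bad)
  if (n_filled > 0) {
    transmission[!is.finite(transmission)] <- fill
    darkfield[!is.finite(darkfield)] <- fill
    warning(n_filled, " pixel(s) hit a zero reference coefficient; ",
            "filled with ", fill)
  }
  structure(list(transmission = transmission, dpci = dpci,
                 darkfield = darkfield),
            class = "contrast_triplet", n_filled = n_filled)
}

#' @export
print.contrast_triplet <- function(x, ...) {
  cat(sprintf("<contrast_triplet> %d x %d\n", nrow(x$dpci), ncol(x$dpci)))
  cat(sprintf("  transmission in [%.3g, %.3g], dpci in [%.3g, %.3g] rad, darkfield in [%.3g, %.3g]\n",
              min(x$transmission), max(x$transmission),
              min(x$dpci), max(x$dpci), min(x$darkfield), max(x$darkfield)))
  invisible(x)
}
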