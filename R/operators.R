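#' Discrete first-order derivative along x (image columns)
#'
#' Computes the per-row first difference `img[, x] - img[, x - 1]` with a
#' replicate left boundary, so the first column of the result is zero.
#' With this convention [cumsum_x()] is the exact discrete inverse up to
#' the first-column constant, which is what makes one-dimensional phase
#' integration an exact round trip on synthetic data.
#'
#' @param img numeric matrix (rows are image rows y, columns are x).
#' @return matrix of the same dimension.
#' @seealso [cumsum_x()], [diff_y()]
#' @export
#' @examples
#' m <- matrix(1:12, 3, 4)
#' all.equal(cumsum_x(diff_x(m)), m - m[, 1])
diff_x <- function(img) {
  img <- as.matrix(img)
  w <- ncol(img)
  if (w < 2) return(img * 0)
  cbind(0, img[, -1, drop = FALSE] - img[, -w, drop = FALSE])
}

#' Discrete first-order derivative along y (image rows)
#'
#' First difference down the rows with a replicate top boundary (first row
#' of the result is zero). Used as the second component of the anisotropic
#' total-variation operator.
#'
#' @inheritParams diff_x
#' @return matrix of the same dimension.
#' @export
diff_y <- function(img) {
  img <- as.matrix(img)
  h <- nrow(img)
  if (h < 2) return(img * 0)
  rbind(0, img[-1, , drop = FALSE] - img[-h, , drop = FALSE])
}

#' Cumulative sum along x: the discrete inverse of [diff_x()]
#'
#' @inheritParams diff_x
#' @return matrix of per-row cumulative sums.
#' @export
cumsum_x <- function(img) {
  img <- as.matrix(img)
  t(apply(img, 1, cumsum))
}

# adjoint of diff_x: t(D) q, needed by the ADMM normal equations
diff_x_adj <- function(q) {
  q <- as.matrix(q)
  w <- ncol(q)
  if (w < 2) return(q * 0)
  out <- q
  out[, 1] <- 0
  out[, -w] <- out[, -w, drop = FALSE] - q[, -1, drop = FALSE]
  out
}

diff_y_adj <- function(q) {
  q <- as.matrix(q)
  h <- nrow(q)
  if (h < 2) return(q * 0)
  out <- q
  out[1, ] <- 0
  out[-h, ] <- out[-h, , drop = FALSE] - q[-1, , drop = FALSE]
  out
}

#' Wrap angles to the half-open interval [-pi, pi)
#'
#' @param x numeric vector, matrix or array of angles in radians.
#' @return object of the same shape with every value in `[-pi, pi)`.
#' @export
#' @examples
#' wrap_angle(3 * pi / 2)  # -pi/2
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}
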