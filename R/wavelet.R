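# Orthogonal periodized 2-D discrete wavelet transform.
#
# Implemented here because the destriping filter needs direct access to
# the per-level detail sub-bands. Filters are the standard orthonormal
# Daubechies families (sum h = sqrt(2), sum h^2 = 1); with periodic
# boundary handling the analysis operator is orthogonal, so synthesis is
# its exact adjoint and reconstruction is exact to machine precision.

wavelet_filters <- function(name = c("db4", "db2", "haar", "sym4")) {
  name <- match.arg(name)
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
          (4 * sqrt(2)),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114,
            0.030841381835986965, 0.032883011666982945,
            -0.010597401784997278),
    sym4 = c(0.0322231006040427, -0.012603967262037833,
             -0.09921954357684722, 0.29785779560527736,
             0.8037387518059161, 0.49761866763201545,
             -0.02963552764599851, -0.07576571478927333))
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror highpass
  list(h = h, g = g, length = length(h))
}

# one analysis step down the columns of X; returns n/2-row lo and hi parts
dwt_step_cols <- function(X, f) {
  n <- nrow(X)
  if (n %% 2 != 0) stop("dimension must be even for a DWT step, got ", n)
  n2 <- n / 2
  lo <- matrix(0, n2, ncol(X))
  hi <- matrix(0, n2, ncol(X))
  base <- 2 * (seq_len(n2) - 1)
  for (t in seq_len(f$length)) {
    idx <- (base + t - 1) %% n + 1
    lo <- lo + f$h[t] * X[idx, , drop = FALSE]
    hi <- hi + f$g[t] * X[idx, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# adjoint (= inverse, by orthogonality) of dwt_step_cols
idwt_step_cols <- function(lo, hi, f) {
  n2 <- nrow(lo)
  n <- 2 * n2
  X <- matrix(0, n, ncol(lo))
  base <- 2 * (seq_len(n2) - 1)
  for (t in seq_len(f$length)) {
    idx <- (base + t - 1) %% n + 1
    X[idx, ] <- X[idx, ] + f$h[t] * lo + f$g[t] * hi
  }
  X
}

#' Multilevel 2-D discrete wavelet transform (periodized, orthogonal)
#'
#' @param img numeric matrix whose sides are divisible by `2^levels`.
#' @param wavelet filter family name: `"db4"` (default), `"db2"`,
#'   `"haar"` or `"sym4"`.
#' @param levels number of decomposition levels.
#' @return list with the coarse approximation `ll` and per-level detail
#'   bands `detail[[l]]`, each holding `dy` (high-pass along y, low-pass
#'   along x - the band collecting horizontal-stripe energy), `dx`
#'   (low-pass y, high-pass x) and `dxy` (high-pass both).
#' @seealso [idwt2()], [wf_destripe()]
#' @export
dwt2 <- function(img, wavelet = "db4", levels = 1) {
  f <- wavelet_filters(wavelet)
  if (levels < 1) stop("levels must be >= 1")
  d <- dim(img)
  if (any(d %% 2^levels != 0)) {
    feasible <- function(n) {
      ok <- which(n %% 2^(1:30) == 0)
      if (length(ok)) max(ok) else 0L
    }
    stop("image sides (", d[1], " x ", d[2], ") must be divisible by 2^",
         levels, "; maximum feasible level count here: ",
         min(feasible(d[1]), feasible(d[2])))
  }
  detail <- vector("list", levels)
  cur <- img
  for (l in seq_len(levels)) {
    sy <- dwt_step_cols(cur, f)                  # along y (rows)
    lx <- dwt_step_cols(t(sy$lo), f)             # along x of the y-lowpass
    hx <- dwt_step_cols(t(sy$hi), f)             # along x of the y-highpass
    cur <- t(lx$lo)
    detail[[l]] <- list(dy = t(hx$lo), dx = t(lx$hi), dxy = t(hx$hi))
  }
  structure(list(ll = cur, detail = detail, wavelet = wavelet,
                 levels = levels, dim = d), class = "dwt2")
}

#' Inverse of [dwt2()]
#'
#' @param w a `dwt2` decomposition.
#' @return the reconstructed matrix (exact to machine precision).
#' @export
idwt2 <- function(w) {
  stopifnot(inherits(w, "dwt2"))
  f <- wavelet_filters(w$wavelet)
  cur <- w$ll
  for (l in rev(seq_len(w$levels))) {
    dt <- w$detail[[l]]
    ylo <- t(idwt_step_cols(t(cur), t(dt$dx), f))
    yhi <- t(idwt_step_cols(t(dt$dy), t(dt$dxy), f))
    cur <- idwt_step_cols(ylo, yhi, f)
  }
  cur
}
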