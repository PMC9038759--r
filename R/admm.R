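#' Threshold-based air mask
#'
#' Builds the binary prior marking pixels assumed to contain no sample
#' ("air"), where the retrieved phase is constrained towards zero. A
#' pixel is air iff it passes all active tests:
#' transmission >= `t_transmission`, |DPCI| <= `t_dpci` and
#' dark-field >= `t_darkfield`. Any test can be deactivated by passing
#' `NA`; with all three deactivated the mask is empty (all zero), the
#' regime used when the object is larger than the field of view and no
#' air prior exists.
#'
#' @param triplet a `contrast_triplet`.
#' @param t_transmission,t_dpci,t_darkfield thresholds (NA disables).
#' @param opening_radius radius (pixels) of an optional binary
#'   morphological opening that removes isolated speckle from the mask;
#'   0 disables. Requires the EBImage package.
#' @return an `H x W` 0/1 matrix of class `air_mask`.
#' @export
make_mask <- function(triplet, t_transmission = 0.95, t_dpci = 0.1,
                      t_darkfield = 0.8, opening_radius = 0) {
  stopifnot(inherits(triplet, "contrast_triplet"))
  d <- dim(triplet$dpci)
  any_active <- FALSE
  mask <- matrix(TRUE, d[1], d[2])
  if (!is.na(t_transmission)) {
    mask <- mask & (triplet$transmission >= t_transmission)
    any_active <- TRUE
  }
  if (!is.na(t_dpci)) {
    mask <- mask & (abs(triplet$dpci) <= t_dpci)
    any_active <- TRUE
  }
  if (!is.na(t_darkfield)) {
    mask <- mask & (triplet$darkfield >= t_darkfield)
    any_active <- TRUE
  }
  if (!any_active) mask <- matrix(FALSE, d[1], d[2])
  mask <- mask * 1
  if (opening_radius > 0) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("opening_radius > 0 requires the EBImage package")
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    mask <- as.matrix(EBImage::opening(mask, brush)) * 1
  }
  if (any_active && sum(mask) == 0)
    warning("air mask is empty; the mask term will be inactive")
  structure(mask, class = c("air_mask", class(mask)))
}

#' Parameters of the regularised ADMM phase retrieval
#'
#' @param lambda1 weight of the anisotropic total-variation penalty.
#' @param lambda2 weight of the quadratic air-mask (DC-calibration) term.
#' @param c integration-model constant (instrument specific).
#' @param rho ADMM penalty parameter.
#' @param max_iter maximum number of outer iterations.
#' @param tol relative-change stopping threshold on the iterate.
#' @param cg_iter inner conjugate-gradient iterations of the x-update.
#' @return list of class `retrieval_params`.
#' @export
retrieval_params <- function(lambda1 = 0.001, lambda2 = 1, c = 1, rho = 1,
                             max_iter = 200, tol = 1e-5, cg_iter = 15) {
  stopifnot(lambda1 > 0, lambda2 > 0, rho > 0, tol > 0, max_iter >= 1,
            cg_iter >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, c = c, rho = rho,
                 max_iter = max_iter, tol = tol, cg_iter = cg_iter),
            class = "retrieval_params")
}

#' Value of the regularised phase-retrieval objective
#'
#' `||D_x x - dpci||_2^2 + lambda1 * (||D_x x||_1 + ||D_y x||_1)
#'  + lambda2 * ||M x||_2^2`, the unconstrained cost that both the ADMM
#' solver and the network training loss minimise (the network replaces
#' `x` by its output).
#'
#' @param x candidate phase image.
#' @param dpci measured DPCI.
#' @param mask binary air mask (NULL for no mask term).
#' @param lambda1,lambda2 regularisation weights.
#' @return scalar objective value.
#' @export
admm_objective <- function(x, dpci, mask = NULL, lambda1 = 0.001,
                           lambda2 = 1) {
  gx <- diff_x(x)
  obj <- sum((gx - dpci)^2) + lambda1 * (sum(abs(gx)) + sum(abs(diff_y(x))))
  if (!is.null(mask)) obj <- obj + lambda2 * sum((mask * x)^2)
  obj
}

#' ADMM phase retrieval with TV and air-mask regularisation
#'
#' Approximately minimises
#' `||D_x x - dpci||^2 + lambda1 ||TV x||_1 + lambda2 ||M x||^2`
#' by the alternating direction method of multipliers, splitting on the
#' anisotropic TV gradients `z = (D_x x, D_y x)` with scaled duals. The
#' x-update solves the regularised normal equations by warm-started
#' conjugate gradients (the replicate-boundary difference operators are
#' not circulant, so an FFT diagonalisation is not available); the
#' z-update is the soft threshold by `lambda1 / rho`. Iterations start
#' from the direct-integration estimate and stop at `max_iter` or when
#' the relative change of the iterate falls below `tol`.
#'
#' @param dpci DPCI matrix in radians.
#' @param mask optional `air_mask` (or any 0/1 matrix); NULL drops the
#'   mask term.
#' @param params a [retrieval_params()] list.
#' @return object of class `admm_result`: list with the retrieved `pci`,
#'   the per-iteration `objective` trace, `iterations` run and a
#'   `converged` flag.
#' @export
admm_retrieval <- function(dpci, mask = NULL, params = retrieval_params()) {
  dpci <- as.matrix(dpci)
  if (!all(is.finite(dpci))) stop("dpci contains non-finite values")
  if (!is.null(mask)) {
    mask <- as.matrix(mask) * 1
    if (!identical(dim(mask), dim(dpci)))
      stop("mask shape does not match the DPCI")
  }
  l1 <- params$lambda1; l2 <- params$lambda2; rho <- params$rho
  m2 <- if (is.null(mask)) NULL else mask  # mask is already 0/1
  # normal-equation operator: 2 Dx'Dx + 2 l2 M + rho (Dx'Dx + Dy'Dy)
  Aop <- function(v) {
    out <- (2 + rho) * diff_x_adj(diff_x(v)) + rho * diff_y_adj(diff_y(v))
    if (!is.null(m2)) out <- out + 2 * l2 * (m2 * v)
    out
  }
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  x <- direct_integration(dpci, c = params$c, mask = mask)
  zx <- diff_x(x); zy <- diff_y(x)
  ux <- zx * 0; uy <- zy * 0
  obj <- numeric(params$max_iter)
  converged <- FALSE
  iter_run <- 0L
  for (it in seq_len(params$max_iter)) {
    # x-update by CG on the normal equations, warm-started at x
    rhs <- 2 * diff_x_adj(dpci) + rho * (diff_x_adj(zx - ux) +
                                         diff_y_adj(zy - uy))
    r <- rhs - Aop(x)
    p <- r
    rs <- sum(r * r)
    for (cg in seq_len(params$cg_iter)) {
      if (rs < 1e-12) break
      Ap <- Aop(p)
      alpha <- rs / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      rs_new <- sum(r * r)
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
    gx <- diff_x(x); gy <- diff_y(x)
    zx <- soft(gx + ux, l1 / rho)
    zy <- soft(gy + uy, l1 / rho)
    ux <- ux + gx - zx
    uy <- uy + gy - zy
    obj[it] <- admm_objective(x, dpci, mask, l1, l2)
    if (!is.finite(obj[it]))
      stop("non-finite objective at iteration ", it)
    iter_run <- it
    if (it > 1) {
      rel <- sqrt(sum((x - x_prev)^2)) / max(sqrt(sum(x_prev^2)), 1e-12)
      if (rel < params$tol) { converged <- TRUE; break }
    }
    x_prev <- x
  }
  structure(list(pci = x, objective = obj[seq_len(iter_run)],
                 iterations = iter_run, converged = converged,
                 params = params),
            class = "admm_result")
}

#' @export
print.admm_result <- function(x, ...) {
  cat(sprintf("<admm_result> %d x %d, %d iteration(s), %sconverged, final objective %.6g\n",
              nrow(x$pci), ncol(x$pci), x$iterations,
              if (x$converged) "" else "not ", tail(x$objective, 1)))
  invisible(x)
}
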