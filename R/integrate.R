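#' Direct one-dimensional phase integration
#'
#' Retrieves the phase-contrast image by per-row cumulative summation of
#' the DPCI along x, the discrete counterpart of
#' `phi(x, y) = c * integral_0^x dpci(x', y) dx'`. Because every noise or
#' moire contribution accumulates along the integration direction, this
#' estimator produces the characteristic horizontal stripe artifacts that
#' the other retrieval methods are designed to suppress.
#'
#' The integration constant of each row is fixed as follows: when an air
#' mask is supplied, the constant is chosen so the masked (air) pixels of
#' that row average to zero (rows without any air pixel fall back to a
#' zero first column); without a mask the first column is set to zero.
#'
#' @param dpci DPCI matrix in radians.
#' @param c scalar system constant of the integration model (instrument
#'   specific; 1 for all synthetic work).
#' @param mask optional binary air-mask matrix (1 = air).
#' @return matrix with the integrated phase image.
#' @seealso [admm_retrieval()], [wf_destripe()]
#' @export
direct_integration <- function(dpci, c = 1, mask = NULL) {
  dpci <- as.matrix(dpci)
  if (!all(is.finite(dpci))) stop("dpci contains non-finite values")
  pci <- c * cumsum_x(dpci)
  if (is.null(mask)) {
    pci <- pci - pci[, 1]
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(pci)))
      stop("mask shape does not match the DPCI")
    n_air <- rowSums(mask != 0)
    off <- ifelse(n_air > 0,
                  rowSums(pci * (mask != 0)) / pmax(n_air, 1),
                  pci[, 1])
    pci <- pci - off
  }
  pci
}
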