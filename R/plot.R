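#' Display a greyscale image with a chosen window
#'
#' @param img numeric matrix (row 1 is displayed at the top).
#' @param window length-2 display window; values outside are clipped.
#' @param main title.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the clipped image.
#' @export
plot_image <- function(img, window = range(img), main = "", ...) {
  img <- pmin(pmax(as.matrix(img), window[1]), window[2])
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  zlim = window, axes = FALSE, main = main, asp = nrow(img) /
                    ncol(img), ...)
  invisible(img)
}

#' @export
plot.contrast_triplet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  plot_image(x$transmission, main = "transmission")
  plot_image(x$dpci, main = "DPCI [rad]")
  plot_image(x$darkfield, main = "dark-field")
  invisible(x)
}

#' @export
plot.admm_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot_image(x$pci, main = "ADMM phase image")
  graphics::plot(seq_along(x$objective), x$objective, type = "l",
                 log = "y", xlab = "iteration", ylab = "objective",
                 main = "objective trace")
  invisible(x)
}

#' @export
plot.n2n_state <- function(x, ...) {
  h <- x$loss_history
  if (!nrow(h)) {
    message("no training history to plot")
    return(invisible(x))
  }
  it <- seq_len(nrow(h))
  graphics::plot(it, h$total, type = "l", log = "y", xlab = "iteration",
                 ylab = "loss", main = "training loss")
  graphics::lines(it, h$data, col = "grey50")
  graphics::legend("topright", legend = c("total", "data term"),
                   col = c("black", "grey50"), lty = 1, bty = "n")
  invisible(x)
}
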