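#' Architecture of the dual-stream retrieval network
#'
#' Two U-net-style encoder-decoder streams process the conditioning
#' channels (base stream: transmission and dark-field) and the DPCI
#' (detail stream). Each stream has `stream_depth` resolution levels with
#' 3x3 same-padding convolutions and rectified-linear activations;
#' features start at `base_features` and double exactly once per level
#' (stride-2 max pooling down, channel-reducing convolution followed by
#' nearest-neighbour interpolation up, additive skip connections). The
#' stream outputs are added elementwise and passed through
#' `fusion_blocks` convolution blocks, the last of which is the linear
#' 1-channel convolution producing the retrieved phase image.
#'
#' @param stream_depth resolution levels per stream (default 2, i.e. one
#'   pooling stage: features 64 then 128).
#' @param base_features feature count at the first level.
#' @param kernel_size convolution kernel side; only 3 is implemented.
#' @param fusion_blocks convolution blocks after the stream addition,
#'   including the final 1-channel output convolution.
#' @param base_in_channels,detail_in_channels input channel counts.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(stream_depth = 2, base_features = 64,
                         kernel_size = 3, fusion_blocks = 3,
                         base_in_channels = 2, detail_in_channels = 1) {
  if (kernel_size != 3)
    stop("only kernel_size = 3 is implemented")
  stopifnot(stream_depth >= 1, base_features >= 1, fusion_blocks >= 1)
  structure(list(stream_depth = as.integer(stream_depth),
                 base_features = as.integer(base_features),
                 kernel_size = 3L,
                 fusion_blocks = as.integer(fusion_blocks),
                 base_in_channels = as.integer(base_in_channels),
                 detail_in_channels = as.integer(detail_in_channels)),
            class = "network_spec")
}

#' Training schedule and optimiser configuration
#'
#' ADAM with initial learning rate `lr0` decayed per epoch as
#' `lr0 / sqrt(t)` with `t` the epoch number.
#'
#' @param lr0 initial learning rate.
#' @param epochs number of epochs.
#' @param iterations_per_epoch training iterations per epoch.
#' @param lambda1,lambda2 loss weights of the TV and mask terms; set
#'   `lambda2 = 0` when no air prior exists.
#' @param dpci_scale detail-stream input normalisation: the DPCI is
#'   divided by this value (default `pi`, mapping radians into
#'   approximately `[-1, 1]`) before entering the network. The loss is
#'   always evaluated against the unscaled target.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, epochs = 100,
                         iterations_per_epoch = 100, lambda1 = 0.001,
                         lambda2 = 1, dpci_scale = pi) {
  stopifnot(lr0 > 0, epochs >= 1, iterations_per_epoch >= 1,
            lambda1 >= 0, lambda2 >= 0, dpci_scale > 0)
  structure(list(lr0 = lr0, epochs = as.integer(epochs),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 lambda1 = lambda1, lambda2 = lambda2,
                 dpci_scale = dpci_scale),
            class = "train_config")
}

#' Build and initialise the dual-stream network
#'
#' Allocates the network and draws the initial weights (He-scaled normal,
#' zero biases) from R's RNG, so initialisation is reproducible from
#' `seed` and independent of the compiled code's internals.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight initialisation; `NULL` uses
#'   the current RNG stream.
#' @return object of class `n2n_state` holding the network parameters,
#'   an empty loss history and the architecture description. The live
#'   network handle is
#'   cached internally and rebuilt transparently when absent (e.g. after
#'   serialisation).
#' @export
build_network <- function(spec = network_spec(), seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  ptr <- nn_create(spec$stream_depth, spec$base_features,
                   spec$fusion_blocks, spec$base_in_channels,
                   spec$detail_in_channels)
  shapes <- nn_param_shapes(ptr)
  weights <- lapply(shapes, function(s) {
    fan_in <- s$w[1]  # 9 * in_channels
    list(w = matrix(rnorm(prod(s$w), 0, sqrt(2 / fan_in)), s$w[1], s$w[2]),
         b = rep(0, s$b))
  })
  nn_set_weights(ptr, weights)
  env <- new.env(parent = emptyenv())
  env$ptr <- ptr
  structure(list(spec = spec, weights = weights,
                 loss_history = data.frame(), epochs_done = 0L,
                 env = env),
            class = "n2n_state")
}

# live network handle, rebuilding from the stored weights when needed
net_handle <- function(state) {
  env <- state$env
  if (is.null(env)) env <- new.env(parent = emptyenv())
  ok <- !is.null(env$ptr) && nn_valid(env$ptr)
  if (!ok) {
    sp <- state$spec
    env$ptr <- nn_create(sp$stream_depth, sp$base_features,
                         sp$fusion_blocks, sp$base_in_channels,
                         sp$detail_in_channels)
    nn_set_weights(env$ptr, state$weights)
  }
  env$ptr
}

#' Number of trainable parameters
#' @param state an `n2n_state`.
#' @return scalar count of weights and biases.
#' @export
n2n_param_count <- function(state) {
  sum(vapply(state$weights, function(l) length(l$w) + length(l$b), 0))
}

#' @export
print.n2n_state <- function(x, ...) {
  cat(sprintf("<n2n_state> depth %d, %d base features, %d fusion block(s); %d parameters; %d epoch(s) trained\n",
              x$spec$stream_depth, x$spec$base_features,
              x$spec$fusion_blocks, n2n_param_count(x), x$epochs_done))
  invisible(x)
}

#' Physics-informed Noise2Noise training loss
#'
#' `mean((D_x f - target)^2) + lambda1 * (mean(|D_x f|) + mean(|D_y f|))
#'  + lambda2 * mean(mask * f^2)`, the per-pixel-mean form of the
#' retrieval objective with the network output `f` in place of the
#' unknown phase image. The derivative operator is the same discrete
#' [diff_x()] used by the classical solvers, so a network that outputs
#' the exact integral of the target has zero data term.
#'
#' @param f network output (matrix, or array of patches
#'   `H x W x 1 x N`).
#' @param target target DPCI of the same shape.
#' @param mask air-mask patch(es) or NULL (mask term 0).
#' @param lambda1,lambda2 loss weights.
#' @return list with `total`, `data`, `tv` and `mask` components, where
#'   `total = data + lambda1 * tv + lambda2 * mask`.
#' @export
n2n_loss <- function(f, target, mask = NULL, lambda1 = 0.001, lambda2 = 1) {
  per_image <- function(img, fun) {
    if (is.matrix(img)) return(fun(img))
    apply(img, length(dim(img)), function(m) fun(as.matrix(m)))
  }
  as_list <- function(a) {
    if (is.matrix(a)) return(list(a))
    n <- dim(a)[length(dim(a))]
    lapply(seq_len(n), function(i) as.matrix(array(a, dim(a))[, , 1, i]))
  }
  fs <- as_list(f); ts <- as_list(target)
  ms <- if (is.null(mask)) NULL else as_list(mask)
  np <- length(fs[[1]]) * length(fs)
  data_s <- 0; tv_s <- 0; mask_s <- 0
  for (i in seq_along(fs)) {
    gx <- diff_x(fs[[i]])
    gy <- diff_y(fs[[i]])
    data_s <- data_s + sum((gx - ts[[i]])^2)
    tv_s <- tv_s + sum(abs(gx)) + sum(abs(gy))
    if (!is.null(ms)) mask_s <- mask_s + sum(ms[[i]] * fs[[i]]^2)
  }
  data <- data_s / np; tv <- tv_s / np; maskc <- mask_s / np
  list(total = data + lambda1 * tv + lambda2 * maskc,
       data = data, tv = tv, mask = maskc)
}

#' Train the dual-stream network on combination-generated DPCI pairs
#'
#' Runs `epochs x iterations_per_epoch` ADAM steps. Every iteration draws
#' a fresh batch through [draw_training_batch()] (fresh random step
#' subsets each time - pair diversity is maximised by resampling rather
#' than by a frozen dataset), evaluates the physics-informed loss of
#' [n2n_loss()] and updates the parameters at learning rate
#' `lr0 / sqrt(epoch)`. Fully reproducible from `seed`; computation is
#' single-threaded, so reruns are bit-identical.
#'
#' @param acquisitions list of acquisition lists (each with `ref`, `sam`,
#'   `triplet`, optional `mask`); one is sampled per iteration.
#' @param sampler_cfg a [pair_sampler_config()].
#' @param net_spec a [network_spec()].
#' @param cfg a [train_config()].
#' @param seed integer seed covering initialisation and sampling.
#' @param verbose print per-epoch mean losses?
#' @return trained `n2n_state` with a per-iteration `loss_history`
#'   data frame (epoch, iteration, lr, total, data, tv, mask).
#' @export
train_n2n <- function(acquisitions, sampler_cfg, net_spec = network_spec(),
                      cfg = train_config(), seed = 1, verbose = FALSE) {
  if (inherits(acquisitions, "contrast_triplet") ||
      !is.null(acquisitions$ref))
    acquisitions <- list(acquisitions)
  stopifnot(length(acquisitions) >= 1)
  set.seed(seed)
  state <- build_network(net_spec, seed = NULL)  # continue the seeded stream
  ptr <- net_handle(state)
  n_iter <- cfg$epochs * cfg$iterations_per_epoch
  hist <- matrix(0, n_iter, 7,
                 dimnames = list(NULL, c("epoch", "iteration", "lr",
                                         "total", "data", "tv", "mask")))
  h_i <- 0L
  initial_loss <- NULL
  bad_streak <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr0 / sqrt(epoch)
    for (it in seq_len(cfg$iterations_per_epoch)) {
      acq <- acquisitions[[if (length(acquisitions) == 1) 1 else
        sample.int(length(acquisitions), 1)]]
      batch <- draw_training_batch(acq, sampler_cfg)
      loss <- nn_train_step(ptr, batch$base, batch$detail,
                            batch$target, batch$mask,
                            lr, cfg$lambda1, cfg$lambda2, cfg$dpci_scale)
      if (is.null(initial_loss)) initial_loss <- loss[["total"]]
      if (!all(is.finite(loss)))
        stop("non-finite loss at epoch ", epoch, ", iteration ", it)
      bad_streak <- if (loss[["total"]] > 1e3 * initial_loss)
        bad_streak + 1L else 0L
      if (bad_streak >= 50L)
        stop("training diverged (loss > 1000 x initial for 50 iterations)")
      h_i <- h_i + 1L
      hist[h_i, ] <- c(epoch, it, lr, loss[["total"]], loss[["data"]],
                       loss[["tv"]], loss[["mask"]])
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.3g  mean loss %.5g", epoch, lr,
                      mean(hist[(h_i - cfg$iterations_per_epoch + 1):h_i,
                                "total"])))
  }
  state$weights <- nn_get_weights(ptr)
  state$loss_history <- as.data.frame(hist[seq_len(h_i), , drop = FALSE])
  state$epochs_done <- cfg$epochs
  state$train_config <- cfg
  state$sampler_config <- sampler_cfg
  state$seed <- seed
  state
}

# reflect-pad an image so both sides are divisible by 2^(depth-1)
pad_for_net <- function(img, depth) {
  mult <- 2^(depth - 1)
  d <- dim(img)
  target <- ceiling(d / mult) * mult
  py <- target[1] - d[1]; px <- target[2] - d[2]
  if (py > 0) img <- rbind(img, img[d[1]:(d[1] - py + 1), , drop = FALSE])
  if (px > 0) img <- cbind(img, img[, ncol(img):(ncol(img) - px + 1),
                                    drop = FALSE])
  img
}

#' Retrieve the phase image with a trained network
#'
#' Applies the network to the full transmission/dark-field and DPCI
#' images of a contrast triplet. Images that do not fit the network's
#' downsampling factor are reflect-padded and cropped back. When
#' `tile_size` is given and smaller than the image, inference runs on
#' overlapping tiles blended with a smooth cosine window; a tile that
#' covers the whole image reproduces untiled inference exactly.
#'
#' @param state trained `n2n_state`.
#' @param triplet a `contrast_triplet` (full images).
#' @param tile_size optional tile side for tiled inference.
#' @param overlap tile overlap in pixels (default `tile_size / 4`).
#' @return retrieved PCI matrix at the input resolution.
#' @export
predict_pci <- function(state, triplet, tile_size = NULL, overlap = NULL) {
  stopifnot(inherits(state, "n2n_state"),
            inherits(triplet, "contrast_triplet"))
  sc <- if (is.null(state$train_config)) pi else state$train_config$dpci_scale
  run <- function(tr, dk, dp) {
    d <- dim(tr)
    trp <- pad_for_net(tr, state$spec$stream_depth)
    dkp <- pad_for_net(dk, state$spec$stream_depth)
    dpp <- pad_for_net(dp, state$spec$stream_depth)
    base <- array(c(trp, dkp), c(dim(trp), 2))
    detail <- array(dpp / sc, c(dim(dpp), 1))
    out <- nn_predict(net_handle(state), base, detail)
    out[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  }
  tr <- triplet$transmission; dk <- triplet$darkfield; dp <- triplet$dpci
  d <- dim(dp)
  if (is.null(tile_size) || tile_size >= max(d)) {
    return(run(tr, dk, dp))
  }
  if (is.null(overlap)) overlap <- max(8, tile_size %/% 4)
  step <- tile_size - overlap
  starts <- function(n) {
    s <- seq(1, max(n - tile_size + 1, 1), by = step)
    if (tail(s, 1) + tile_size - 1 < n) s <- c(s, n - tile_size + 1)
    unique(pmax(s, 1))
  }
  win1 <- function(n) {
    # smooth cosine ramp over the overlap region
    w <- rep(1, n)
    r <- min(overlap, n %/% 2)
    if (r > 0) {
      ramp <- 0.5 - 0.5 * cos(pi * (seq_len(r)) / (r + 1))
      w[seq_len(r)] <- ramp
      w[n - seq_len(r) + 1] <- ramp
    }
    w
  }
  acc <- matrix(0, d[1], d[2])
  wacc <- matrix(0, d[1], d[2])
  wt <- outer(win1(tile_size), win1(tile_size))
  for (y0 in starts(d[1])) {
    for (x0 in starts(d[2])) {
      ry <- y0:min(y0 + tile_size - 1, d[1])
      rx <- x0:min(x0 + tile_size - 1, d[2])
      out <- run(tr[ry, rx, drop = FALSE], dk[ry, rx, drop = FALSE],
                 dp[ry, rx, drop = FALSE])
      wtile <- wt[seq_along(ry), seq_along(rx), drop = FALSE]
      acc[ry, rx] <- acc[ry, rx] + out * wtile
      wacc[ry, rx] <- wacc[ry, rx] + wtile
    }
  }
  acc / wacc
}
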