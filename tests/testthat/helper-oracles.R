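# Independent oracles used to cross-check the package implementations.
# Everything here is deliberately naive and slow; none of it shares code
# with the functions under test.

# -- brute-force sinusoid fit oracle (one pixel) -----------------------
# coarse-to-fine grid search over (a0, a1, theta) minimising the RSS
grid_fit_oracle <- function(y, k, M, refine = 4) {
  rss <- function(a0, a1, th)
    sum((a0 + a1 * sin(2 * pi * k / M + th) - y)^2)
  a0r <- range(y) + c(-1, 1) * diff(range(y))
  a1r <- c(0, diff(range(y)))
  thr <- c(-pi, pi)
  best <- c(mean(a0r), mean(a1r), 0)
  for (lev in seq_len(refine)) {
    a0s <- seq(a0r[1], a0r[2], length.out = 21)
    a1s <- seq(a1r[1], a1r[2], length.out = 21)
    ths <- seq(thr[1], thr[2], length.out = 41)
    vals <- expand.grid(a0 = a0s, a1 = a1s, th = ths)
    r <- mapply(rss, vals$a0, vals$a1, vals$th)
    best <- unlist(vals[which.min(r), ])
    da0 <- diff(a0r) / 10; da1 <- diff(a1r) / 10; dth <- diff(thr) / 20
    a0r <- best[1] + c(-da0, da0)
    a1r <- pmax(best[2] + c(-da1, da1), 0)
    thr <- best[3] + c(-dth, dth)
  }
  list(a0 = best[1], a1 = best[2], theta = best[3],
       rss = rss(best[1], best[2], best[3]))
}

# -- naive PSNR / SSIM (double loop, straight from the formulas) -------
naive_psnr <- function(x, y, peak = 1) {
  mse <- mean((x - y)^2)
  if (mse == 0) Inf else 10 * log10(peak^2 / mse)
}

naive_ssim <- function(x, y, peak = 1) {
  win <- 11; sig <- 1.5
  half <- (win - 1) / 2
  g <- outer(exp(-((-half):half)^2 / (2 * sig^2)),
             exp(-((-half):half)^2 / (2 * sig^2)))
  g <- g / sum(g)
  c1 <- (0.01 * peak)^2; c2 <- (0.03 * peak)^2
  h <- nrow(x) - win + 1; w <- ncol(x) - win + 1
  vals <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      px <- x[i:(i + win - 1), j:(j + win - 1)]
      py <- y[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(g * px); my <- sum(g * py)
      vx <- sum(g * px^2) - mx^2
      vy <- sum(g * py^2) - my^2
      vxy <- sum(g * px * py) - mx * my
      vals[i, j] <- ((2 * mx * my + c1) * (2 * vxy + c2)) /
                    ((mx^2 + my^2 + c1) * (vx + vy + c2))
    }
  }
  mean(vals)
}

# -- primal-dual (Chambolle-Pock) solver of the retrieval objective ----
# minimises ||Dx x - phi||^2 + l1 (||Dx x||_1 + ||Dy x||_1) + l2 ||M x||^2
# through a completely different splitting than the package's ADMM.
pdhg_solve <- function(phi, mask, l1, l2, iters = 20000, x0 = NULL) {
  h <- nrow(phi); w <- ncol(phi)
  tau <- 1 / sqrt(8); sig <- 1 / sqrt(8)
  x <- if (is.null(x0)) matrix(0, h, w) else x0
  xb <- x
  zx <- matrix(0, h, w); zy <- matrix(0, h, w)
  for (it in seq_len(iters)) {
    # dual ascent with resolvent of F* via Moreau
    vx <- zx + sig * gipret::diff_x(xb)
    vy <- zy + sig * gipret::diff_y(xb)
    # prox of f1(u) = (u - phi)^2 + l1|u| at parameter 1/sig
    den <- sig + 2
    px <- (vx + 2 * phi) / den
    px <- sign(px) * pmax(abs(px) - l1 / den, 0)
    zx <- vx - sig * px
    # prox of f2(u) = l1 |u|
    py <- vy / sig
    py <- sign(py) * pmax(abs(py) - l1 / sig, 0)
    zy <- vy - sig * py
    # primal descent; G(x) = l2 ||M x||^2
    xn <- x - tau * (gipret:::diff_x_adj(zx) + gipret:::diff_y_adj(zy))
    xn <- xn / (1 + 2 * tau * l2 * mask)
    xb <- 2 * xn - x
    x <- xn
  }
  x
}

# -- naive R forward pass of the dual-stream network -------------------
# mirrors the documented architecture with plain loops; weights come in
# the package's layer order and (9*Cin x Cout) layout.
naive_conv3 <- function(A, Wm, b, relu = TRUE) {
  d <- dim(A); H <- d[1]; W <- d[2]; Ci <- d[3]
  Co <- ncol(Wm)
  out <- array(0, c(H, W, Co))
  for (co in seq_len(Co)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Ci)) {
      for (dx in -1:1) for (dy in -1:1) {
        wv <- Wm[((dx + 1) * 3 + (dy + 1)) * Ci + ci, co]
        src <- matrix(0, H, W)
        ys <- max(1, 1 + dy):min(H, H + dy)
        xs <- max(1, 1 + dx):min(W, W + dx)
        src[ys - dy, xs - dx] <- A[ys, xs, ci]
        acc <- acc + wv * src
      }
    }
    out[, , co] <- if (relu) pmax(acc, 0) else acc
  }
  out
}

naive_pool2 <- function(A) {
  d <- dim(A)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (c in seq_len(d[3]))
    for (i in seq_len(d[1] / 2))
      for (j in seq_len(d[2] / 2))
        out[i, j, c] <- max(A[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  out
}

naive_up2 <- function(A) {
  d <- dim(A)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (c in seq_len(d[3]))
    out[, , c] <- A[rep(seq_len(d[1]), each = 2),
                    rep(seq_len(d[2]), each = 2), c]
  out
}

naive_forward <- function(weights, spec, base, detail) {
  li <- 0
  next_layer <- function() {
    li <<- li + 1
    weights[[li]]
  }
  run_stream <- function(X) {
    D <- spec$stream_depth
    enc <- vector("list", D)
    L <- next_layer()
    enc[[1]] <- naive_conv3(X, L$w, L$b)
    cur <- enc[[1]]
    if (D > 1) {
      for (l in 2:D) {
        L <- next_layer()
        enc[[l]] <- naive_conv3(naive_pool2(enc[[l - 1]]), L$w, L$b)
      }
      cur <- enc[[D]]
      for (l in D:2) {
        L <- next_layer()
        cur <- naive_up2(naive_conv3(cur, L$w, L$b)) + enc[[l - 1]]
      }
    }
    cur
  }
  sb <- run_stream(base)
  sd <- run_stream(detail)
  S <- sb + sd
  if (spec$fusion_blocks > 1)
    for (i in seq_len(spec$fusion_blocks - 1)) {
      L <- next_layer()
      S <- naive_conv3(S, L$w, L$b)
    }
  L <- next_layer()
  naive_conv3(S, L$w, L$b, relu = FALSE)[, , 1]
}

# -- small simulated acquisition shared by several tests ---------------
tiny_acquisition <- function(size = 64, noisy = FALSE, seed = 1,
                             eta_range = 0, M = 8) {
  ph <- make_phantom("shepp_logan", size = size, M = M,
                     eta_range = eta_range)
  acq <- simulate_acquisition(ph, noisy = noisy, seed = seed)
  trip <- extract_contrast(fit_sinusoid(acq$ref), fit_sinusoid(acq$sam))
  list(phantom = ph, ref = acq$ref, sam = acq$sam, triplet = trip)
}
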