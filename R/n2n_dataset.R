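#' DPCI from a subset of the phase-stepping frames
#'
#' Fits the stepping sinusoid to a selected subset of the frames of both
#' scans (keeping each frame's true step index `k` in the model phase
#' `2*pi*k/M`, so the angular sampling stays faithful even when it
#' becomes non-uniform) and returns the resulting DPCI. On noiseless data
#' any valid subset reproduces the full-data DPCI; on noisy data each
#' subset gives an independent-noise realisation of the same underlying
#' image, which is exactly what Noise2Noise training pairs require.
#'
#' @param ref,sam `stepping_stack` objects of a common acquisition.
#' @param indices integer step indices (subset of `1:M`, no repeats, at
#'   least 3: fewer frames leave the 3-parameter fit underdetermined).
#' @return DPCI matrix in radians.
#' @export
subset_dpci <- function(ref, sam, indices) {
  stopifnot(inherits(ref, "stepping_stack"), inherits(sam, "stepping_stack"))
  indices <- as.integer(indices)
  if (length(indices) < 3)
    stop("at least 3 steps are needed for the sinusoid fit, got ",
         length(indices))
  if (anyDuplicated(indices))
    stop("step indices must not repeat")
  if (!all(indices %in% ref$step_indices) ||
      !all(indices %in% sam$step_indices))
    stop("requested steps are not present in the stacks")
  pick <- function(st) {
    sel <- match(indices, st$step_indices)
    stepping_stack(st$frames[, , sel, drop = FALSE],
                   step_indices = indices, M = st$M, role = st$role)
  }
  rf <- fit_sinusoid(pick(ref))
  sf <- fit_sinusoid(pick(sam))
  wrap_angle(sf$theta - rf$theta)
}

#' Configuration of the Noise2Noise pair sampler
#'
#' @param M total phase-stepping number of the acquisitions.
#' @param subset_min,subset_max smallest and largest subset size drawn
#'   (defaults: half of M, rounded up, to M).
#' @param patch_size side of the square training patches.
#' @param patches_per_iteration patches drawn per training iteration.
#' @param flip_augment apply random horizontal/vertical flips? A
#'   horizontal mirror negates the DPCI channels (an x-derivative changes
#'   sign under x-reflection), keeping the derivative loss consistent.
#' @return list of class `pair_sampler_config`.
#' @export
pair_sampler_config <- function(M, subset_min = ceiling(M / 2),
                                subset_max = M, patch_size = 64,
                                patches_per_iteration = 64,
                                flip_augment = TRUE) {
  M <- as.integer(M)
  if (!(3 <= subset_min && subset_min <= subset_max && subset_max <= M))
    stop("need 3 <= subset_min <= subset_max <= M")
  if (patch_size < 16) stop("patch_size must be at least 16")
  structure(list(M = M, subset_min = as.integer(subset_min),
                 subset_max = as.integer(subset_max),
                 patch_size = as.integer(patch_size),
                 patches_per_iteration = as.integer(patches_per_iteration),
                 flip_augment = isTRUE(flip_augment)),
            class = "pair_sampler_config")
}

#' Draw one training batch of Noise2Noise DPCI pairs
#'
#' For each call (one training iteration) two step subsets are drawn
#' independently - sizes uniform on `[subset_min, subset_max]`, subsets
#' uniform without replacement - and fitted into an input DPCI and a
#' target DPCI via [subset_dpci()]. The transmission and dark-field
#' conditioning channels come from the full-data fit. From these full
#' images, `patches_per_iteration` square patches are cut at uniformly
#' random positions; each patch optionally receives an independent
#' horizontal and/or vertical flip applied jointly to all channels (with
#' the DPCI sign negated under horizontal mirroring).
#'
#' The input and target subsets may overlap: independence of the draws is
#' what the Noise2Noise zero-mean pairing argument needs, and it keeps
#' small step counts usable.
#'
#' @param acq acquisition list with elements `ref`, `sam`
#'   (`stepping_stack`s), `triplet` (full-data `contrast_triplet`) and
#'   optionally `mask` (an `air_mask`; an all-zero mask is used when
#'   absent, meaning no air prior).
#' @param cfg a [pair_sampler_config()].
#' @return list of arrays ready for the trainer: `base`
#'   (`patch x patch x 2 x n`: transmission and dark-field), `detail` and
#'   `target` (`patch x patch x 1 x n` DPCI patches in radians), `mask`
#'   (`patch x patch x 1 x n`), plus the drawn `subset_input` and
#'   `subset_target`.
#' @export
draw_training_batch <- function(acq, cfg) {
  stopifnot(inherits(cfg, "pair_sampler_config"))
  trip <- acq$triplet
  d <- dim(trip$dpci)
  ps <- cfg$patch_size
  if (any(d < ps))
    stop("image (", d[1], " x ", d[2], ") is smaller than the patch size ",
         ps)
  draw_subset <- function() {
    size <- sample(cfg$subset_min:cfg$subset_max, 1)
    sort(sample(seq_len(cfg$M), size))
  }
  s_in <- draw_subset()
  s_tg <- draw_subset()
  dpci_in <- subset_dpci(acq$ref, acq$sam, s_in)
  dpci_tg <- subset_dpci(acq$ref, acq$sam, s_tg)
  mask <- if (is.null(acq$mask)) matrix(0, d[1], d[2]) else
    as.matrix(acq$mask) * 1
  n <- cfg$patches_per_iteration
  base <- array(0, c(ps, ps, 2, n))
  detail <- array(0, c(ps, ps, 1, n))
  target <- array(0, c(ps, ps, 1, n))
  mask_a <- array(0, c(ps, ps, 1, n))
  for (i in seq_len(n)) {
    y0 <- sample.int(d[1] - ps + 1, 1)
    x0 <- sample.int(d[2] - ps + 1, 1)
    ry <- y0:(y0 + ps - 1)
    rx <- x0:(x0 + ps - 1)
    fh <- cfg$flip_augment && runif(1) < 0.5   # mirror in x
    fv <- cfg$flip_augment && runif(1) < 0.5   # mirror in y
    cut <- function(img, sign_flip = FALSE) {
      p <- img[ry, rx, drop = FALSE]
      if (fh) p <- p[, ps:1, drop = FALSE]
      if (fv) p <- p[ps:1, , drop = FALSE]
      if (sign_flip && fh) p <- -p
      p
    }
    base[, , 1, i] <- cut(trip$transmission)
    base[, , 2, i] <- cut(trip$darkfield)
    detail[, , 1, i] <- cut(dpci_in, sign_flip = TRUE)
    target[, , 1, i] <- cut(dpci_tg, sign_flip = TRUE)
    mask_a[, , 1, i] <- cut(mask)
  }
  list(base = base, detail = detail, target = target, mask = mask_a,
       subset_input = s_in, subset_target = s_tg)
}
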