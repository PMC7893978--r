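#' Generate synthetic grayscale stimuli
#'
#' Three stimulus ensembles in `[0, 1]`: pixelwise uniform white noise;
#' bandpass-filtered noise (radial annulus in the Fourier domain, passband in
#' cycles/pixel); and a mixture of random Gabor patches on a gray background.
#'
#' @param n Number of stimuli (>= 1).
#' @param side Image side length in pixels (>= 16).
#' @param kind `"white_noise"`, `"bandpass_noise"` or `"gabor_patch_mixture"`.
#' @param seed Integer seed.
#' @param passband Radial frequency band (cycles/pixel) for
#'   `"bandpass_noise"`.
#' @return Array `side x side x n` with values in `[0, 1]`.
#' @export
generate_stimuli <- function(n, side = 32L,
                             kind = c("white_noise", "bandpass_noise",
                                      "gabor_patch_mixture"),
                             seed = 1L, passband = c(0.05, 0.25)) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (side < 16) stop("side must be >= 16", call. = FALSE)
  set.seed(seed)
  out <- array(0, c(side, side, n))
  if (kind == "white_noise") {
    out[] <- stats::runif(side * side * n)
  } else if (kind == "bandpass_noise") {
    freqs <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
    rad <- sqrt(outer(freqs^2, freqs^2, "+"))
    keep <- rad >= passband[1] & rad <= passband[2]
    for (i in seq_len(n)) {
      w <- matrix(stats::rnorm(side^2), side, side)
      f <- stats::fft(w) * keep
      img <- Re(stats::fft(f, inverse = TRUE)) / side^2
      rng <- range(img)
      out[, , i] <- (img - rng[1]) / (rng[2] - rng[1])
    }
  } else {
    for (i in seq_len(n)) {
      img <- matrix(0.5, side, side)
      for (p in seq_len(4L)) {
        par <- gabor_params(omega = stats::runif(1, pi / 8, pi / 2),
                            sigma = stats::runif(1, 1.5, 4),
                            phi = stats::runif(1, 0, pi),
                            theta = stats::runif(1, 0, pi))
        sz <- 2L * sample(4:7, 1L) + 1L
        patch <- synthesize_kernel(par, sz, "real") * stats::runif(1, 0.2, 0.5)
        r0 <- sample.int(side - sz + 1L, 1L) - 1L
        c0 <- sample.int(side - sz + 1L, 1L) - 1L
        img[r0 + seq_len(sz), c0 + seq_len(sz)] <-
          img[r0 + seq_len(sz), c0 + seq_len(sz)] + patch
      }
      out[, , i] <- pmin(pmax(img, 0), 1)
    }
  }
  out
}

# Receptive-field center pixels (1-based) that are representable by the
# default layer stack: Gabor-layer output positions whose feature map entries
# survive every downstream strided valid convolution.
stride_aligned_centers <- function(side, gabor_size = 9L, stride = 2L,
                                   conv_size = 3L, n_conv = 2L) {
  sides <- side
  kernels <- c(gabor_size, rep(conv_size, n_conv))
  for (k in kernels) {
    s <- sides[length(sides)]
    if (s < k) break # smaller images support fewer regular layers
    sides <- c(sides, layer_output_size(s, k, stride))
  }
  n_conv <- length(sides) - 2L
  covered <- 0:(sides[length(sides)] - 1L)
  for (l in rev(seq_len(n_conv))) {
    prev <- integer(0)
    for (i in covered) prev <- union(prev, stride * i + 0:(conv_size - 1L))
    covered <- sort(intersect(prev, 0:(sides[l + 1L] - 1L)))
  }
  # Gabor output index i corresponds to input center (gabor_size-1)/2 + stride*i
  (gabor_size - 1L) %/% 2L + stride * covered + 1L
}

#' Sample ground-truth voxel tuning for one synthetic ROI
#'
#' Each voxel gets a localized Gabor receptive field: a center on the
#' stride-aligned grid of the default architecture (so the tuning is exactly
#' representable by the model class), a frequency and orientation from the
#' initialization grid, a random phase, an envelope width from a
#' profile-specific range, and a positive readout weight. The profiles encode
#' the qualitative progression along the ventral stream: `"low"` (early
#' areas) has small envelopes and high frequencies, `"high"` (later areas)
#' large envelopes and low frequencies, with disjoint envelope ranges
#' (low 1-1.8, mid 2.2-3, high 3.4-5 pixels).
#'
#' @param n_voxels Number of voxels (>= 1).
#' @param side Image side length in pixels.
#' @param roi_profile `"low"`, `"mid"` or `"high"`.
#' @param seed Integer seed.
#' @param noise_sd Response noise standard deviation attached to each voxel.
#' @return List of `ground_truth_voxel` objects, each with fields `center`
#'   (row, col), `params` ([gabor_params()]), `weight`, `nonlinearity`
#'   (`"relu"`) and `noise_sd`.
#' @export
sample_ground_truth <- function(n_voxels, side = 32L,
                                roi_profile = c("low", "mid", "high"),
                                seed = 1L, noise_sd = 0) {
  roi_profile <- match.arg(roi_profile)
  if (n_voxels < 1) stop("n_voxels must be >= 1", call. = FALSE)
  grid <- gabor_init_grid()
  ranges <- list(low = c(1, 1.8), mid = c(2.2, 3), high = c(3.4, 5))
  omega_idx <- list(low = 1:2, mid = 2:4, high = 4:5)
  set.seed(seed)
  centers <- stride_aligned_centers(side)
  lapply(seq_len(n_voxels), function(v) {
    structure(list(
      center = c(sample(centers, 1L), sample(centers, 1L)),
      params = gabor_params(
        omega = sample(grid$omega[omega_idx[[roi_profile]]], 1L),
        sigma = stats::runif(1, ranges[[roi_profile]][1], ranges[[roi_profile]][2]),
        phi = stats::runif(1, 0, pi),
        theta = sample(grid$theta, 1L)),
      weight = stats::runif(1, 0.5, 1.5),
      nonlinearity = "relu",
      noise_sd = noise_sd,
      profile = roi_profile),
      class = "ground_truth_voxel")
  })
}

# Noiseless ground-truth responses: ReLU of the weighted real-branch Gabor
# filter response at the voxel's receptive-field center. The filter sees the
# stimulus contrast (pixel value minus the 0.5 mid-gray background), which
# keeps the rule exactly representable: the Gabor layer's channel bias can
# absorb the resulting DC offset.
noiseless_responses <- function(stimuli, voxels, kernel_size = 9L) {
  if (length(dim(stimuli)) == 2L) dim(stimuli) <- c(dim(stimuli), 1L)
  n <- dim(stimuli)[3]
  half <- (kernel_size - 1L) %/% 2L
  out <- matrix(0, n, length(voxels))
  for (v in seq_along(voxels)) {
    vox <- voxels[[v]]
    k <- synthesize_kernel(vox$params, kernel_size, "real")
    rows <- (vox$center[1] - half):(vox$center[1] + half)
    cols <- (vox$center[2] - half):(vox$center[2] + half)
    for (i in seq_len(n)) {
      resp <- vox$weight * sum((stimuli[rows, cols, i] - 0.5) * k)
      out[i, v] <- max(resp, 0)
    }
  }
  out
}

#' Simulate voxel responses to stimuli
#'
#' The noiseless response of a voxel is the rectified, weighted inner product
#' of the stimulus patch at the voxel's receptive-field center with the
#' voxel's Gabor kernel. Each repeat adds i.i.d. Gaussian noise with the
#' voxel's `noise_sd`. Responses are z-scored per voxel (pooling repeats)
#' unless an existing transform is supplied.
#'
#' @param stimuli Array `side x side x n`.
#' @param voxels List from [sample_ground_truth()].
#' @param repeats Number of repeated presentations (>= 1, default 1).
#' @param seed Integer seed for the noise.
#' @param transform Optional list with per-voxel `mean` and `sd` applied
#'   instead of the data's own statistics (used to carry the training-split
#'   transform onto validation data).
#' @return Matrix `n x n_voxels` when `repeats = 1`, otherwise an array
#'   `repeats x n x n_voxels`; the z-scoring transform is attached as
#'   attribute `"transform"`.
#' @export
simulate_responses <- function(stimuli, voxels, repeats = 1L, seed = 1L,
                               transform = NULL) {
  if (length(dim(stimuli)) == 2L) dim(stimuli) <- c(dim(stimuli), 1L)
  n <- dim(stimuli)[3]
  n_vox <- length(voxels)
  base <- noiseless_responses(stimuli, voxels)
  sds <- apply(base, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance noiseless response for voxel(s) ",
         paste(which(sds == 0), collapse = ", "),
         "; use a richer stimulus ensemble", call. = FALSE)
  }
  set.seed(seed)
  resp <- array(0, c(repeats, n, n_vox))
  for (r in seq_len(repeats)) {
    noise <- vapply(voxels, function(v) stats::rnorm(n, 0, v$noise_sd),
                    numeric(n))
    resp[r, , ] <- base + noise
  }
  if (is.null(transform)) {
    mu <- apply(resp, 3L, mean)
    sd_ <- apply(resp, 3L, stats::sd)
    transform <- list(mean = mu, sd = sd_)
  }
  for (v in seq_len(n_vox)) {
    resp[, , v] <- (resp[, , v] - transform$mean[v]) / transform$sd[v]
  }
  out <- if (repeats == 1L) {
    matrix(resp[1L, , ], n, n_vox)
  } else {
    resp
  }
  attr(out, "transform") <- transform
  out
}

#' Generate a complete synthetic encoding dataset
#'
#' Emulates the structure of the fMRI stimulus-response data at reduced
#' scale: grayscale training and validation stimuli, single-presentation
#' training responses and repeated validation presentations, all generated by
#' a known ground-truth Gabor encoding rule with localized receptive fields.
#' Training responses are z-scored per voxel on the training split and the
#' same transform is applied to the validation responses.
#'
#' @param n_train,n_val Numbers of training / validation stimuli
#'   (defaults 400 / 80).
#' @param side Image side (default 32).
#' @param n_voxels Voxels in the ROI (default 20).
#' @param roi_profile Tuning profile, see [sample_ground_truth()].
#' @param stimulus_kind Ensemble, see [generate_stimuli()].
#' @param repeats Validation presentations (default 13).
#' @param noise_sd Response noise standard deviation (default 0: noiseless).
#' @param seed Integer seed; all draws derive from it.
#' @return A `synthetic_dataset`: list with `train_stimuli`,
#'   `train_responses`, `val_stimuli`, `val_responses`
#'   (repeats x n_val x n_voxels), `voxels`, `roi_profile` and a `manifest`
#'   recording every generation parameter.
#' @export
synthetic_dataset <- function(n_train = 400L, n_val = 80L, side = 32L,
                              n_voxels = 20L, roi_profile = "mid",
                              stimulus_kind = "white_noise", repeats = 13L,
                              noise_sd = 0, seed = 1L) {
  train_stimuli <- generate_stimuli(n_train, side, stimulus_kind, seed = seed)
  val_stimuli <- generate_stimuli(n_val, side, stimulus_kind, seed = seed + 1L)
  voxels <- sample_ground_truth(n_voxels, side, roi_profile, seed = seed + 2L,
                                noise_sd = noise_sd)
  train_responses <- simulate_responses(train_stimuli, voxels, repeats = 1L,
                                        seed = seed + 3L)
  tf <- attr(train_responses, "transform")
  val_responses <- simulate_responses(val_stimuli, voxels, repeats = repeats,
                                      seed = seed + 4L, transform = tf)
  structure(list(train_stimuli = train_stimuli,
                 train_responses = train_responses,
                 val_stimuli = val_stimuli,
                 val_responses = val_responses,
                 voxels = voxels,
                 roi_profile = roi_profile,
                 manifest = list(n_train = n_train, n_val = n_val, side = side,
                                 n_voxels = n_voxels, roi_profile = roi_profile,
                                 stimulus_kind = stimulus_kind,
                                 repeats = repeats, noise_sd = noise_sd,
                                 seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic encoding dataset: %d train / %d val stimuli (%dx%d), %d voxels [%s profile], noise sd %.2g, seed %d\n",
              m$n_train, m$n_val, m$side, m$side, m$n_voxels, m$roi_profile,
              m$noise_sd, m$seed))
  invisible(x)
}

#' Construct an encoder that implements a ground-truth rule exactly
#'
#' Wires an `encoding_model` so that each voxel's prediction equals (an
#' affine transform of) its ground-truth response: voxel `v`'s Gabor
#' parameters are placed in real-branch channel `v`, delta kernels route that
#' channel's value at the receptive-field position through the regular
#' convolutional layers, and the fully connected map reads the routed
#' feature. All other fully connected weights are zero. Used as a known
#' fixed point for interpretation and trend machinery.
#'
#' @param voxels List from [sample_ground_truth()].
#' @param side Image side length.
#' @return An `encoding_model` with `n_voxels = length(voxels)`.
#' @export
wire_ground_truth_model <- function(voxels, side = 32L) {
  n_vox <- length(voxels)
  # as many regular layers as the image size supports, up to the default two
  s <- layer_output_size(side, 9L)
  n_conv <- 0L
  while (n_conv < 2L && s >= 3L) {
    s <- layer_output_size(s, 3L)
    n_conv <- n_conv + 1L
  }
  cfg <- model_config(input_size = side, n_voxels = n_vox,
                      conv_filters = rep(64L, n_conv))
  if (n_vox > cfg$kernels_per_branch || n_vox > min(cfg$conv_filters)) {
    stop("too many voxels to wire one channel each", call. = FALSE)
  }
  model <- build_model(cfg, seed = 1L)
  half <- (cfg$gabor_size - 1L) %/% 2L
  for (i in seq_along(model$conv)) model$conv[[i]]$w[] <- 0
  model$fc_w[] <- 0
  model$fc_b[] <- 0
  model$gabor_bias[] <- 0
  h3 <- model$sides[length(model$sides)]
  for (v in seq_len(n_vox)) {
    vox <- voxels[[v]]
    model$bank$real_params[[v]] <- vox$params
    k <- synthesize_kernel(vox$params, cfg$gabor_size, "real")
    model$gabor_bias[v] <- -0.5 * sum(k)
    # Gabor output index (0-based) of the RF center
    i1 <- (vox$center[1] - 1L - half) %/% cfg$stride
    j1 <- (vox$center[2] - 1L - half) %/% cfg$stride
    pos <- c(i1, j1)
    for (l in seq_along(model$conv)) {
      nxt <- pmin(pos %/% cfg$stride,
                  model$sides[l + 2L] - 1L)
      off <- pos - cfg$stride * nxt
      if (any(off < 0 | off >= cfg$conv_size)) {
        stop("receptive-field center not stride-aligned for voxel ", v,
             call. = FALSE)
      }
      model$conv[[l]]$w[off[1] + 1L, off[2] + 1L, v, v] <- 1
      pos <- nxt
    }
    feat <- (v - 1L) * h3 * h3 + pos[2] * h3 + pos[1] + 1L
    model$fc_w[feat, v] <- sqrt(vox$weight)
  }
  model
}
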