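# Shared fixtures: tiny model configurations and an independent loop-based
# guided-backpropagation oracle.

tiny_config <- function(n_voxels = 3L, activation = "relu") {
  model_config(input_size = 8L, n_voxels = n_voxels, kernels_per_branch = 2L,
               gabor_size = 3L, conv_filters = 4L, activation = activation)
}

random_tiny_model <- function(seed, n_voxels = 3L, activation = "relu") {
  m <- build_model(tiny_config(n_voxels, activation), seed = seed)
  # randomize every weight so the oracle sees a generic network
  set.seed(seed + 1000L)
  pars <- gaborenc:::model_parameters(m)
  for (nm in c("gabor_bias", "fc_b")) pars[[nm]] <- rnorm(length(pars[[nm]]), 0, 0.3)
  for (nm in grep("conv|fc_w", names(pars), value = TRUE)) {
    if (is.null(dim(pars[[nm]]))) {
      pars[[nm]] <- rnorm(length(pars[[nm]]), 0, 0.5)
    } else {
      pars[[nm]] <- array(rnorm(length(pars[[nm]]), 0, 0.5), dim(pars[[nm]]))
    }
  }
  gaborenc:::set_model_parameters(m, pars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 8x8 uniform-noise stimuli for the tiny models (below the generator's
# minimum image size)
tiny_stimuli <- function(n, seed) {
  set.seed(seed)
  array(runif(8 * 8 * n), c(8, 8, n))
}

# Plain-loop strided valid convolution of a (H, W, C) feature map with
# kernels (kh, kw, C, Cout); independent of the package's im2col path.
oracle_conv <- function(a, w, b, stride = 2L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  ho <- (dim(a)[1] - kh) %/% stride + 1L
  wo <- (dim(a)[2] - kw) %/% stride + 1L
  z <- array(0, c(ho, wo, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(ho)) {
      for (j in seq_len(wo)) {
        patch <- a[(i - 1L) * stride + seq_len(kh),
                   (j - 1L) * stride + seq_len(kw), , drop = FALSE]
        z[i, j, co] <- sum(patch * array(w[, , , co], dim(w)[1:3])) + b[co]
      }
    }
  }
  z
}

# Guided backpropagation computed recursively layer by layer with explicit
# loops: at each rectification the backward signal keeps only entries where
# both the forward pre-activation and the incoming gradient are positive.
oracle_gbp <- function(model, stimulus, voxel, rule = "guided") {
  cfg <- model$config
  w1 <- gaborenc:::gabor_weight_array(model)
  ws <- c(list(w1), lapply(model$conv, `[[`, "w"))
  bs <- c(list(model$gabor_bias), lapply(model$conv, `[[`, "b"))
  acts <- list()
  a <- array(stimulus, c(cfg$input_size, cfg$input_size, 1L))
  for (l in seq_along(ws)) {
    z <- oracle_conv(a, ws[[l]], bs[[l]], cfg$stride)
    acts[[l]] <- z
    a <- if (cfg$activation == "relu") pmax(z, 0) else z
  }
  g <- array(model$fc_w[, voxel]^2, dim(a))
  for (l in rev(seq_along(ws))) {
    z <- acts[[l]]
    if (cfg$activation == "relu") {
      g <- switch(rule,
                  guided = (z > 0) * (g > 0) * g,
                  backprop = (z > 0) * g,
                  deconv = (g > 0) * g)
    }
    # gradient through the convolution: scatter each output grad onto the
    # input window it read
    in_dim <- if (l == 1L) c(cfg$input_size, cfg$input_size, 1L) else dim(acts[[l - 1L]])
    gin <- array(0, in_dim)
    kh <- dim(ws[[l]])[1]; kw <- dim(ws[[l]])[2]
    for (co in seq_len(dim(g)[3])) {
      for (i in seq_len(dim(g)[1])) {
        for (j in seq_len(dim(g)[2])) {
          ri <- (i - 1L) * cfg$stride + seq_len(kh)
          cj <- (j - 1L) * cfg$stride + seq_len(kw)
          gin[ri, cj, ] <- gin[ri, cj, , drop = FALSE] +
            array(ws[[l]][, , , co], c(kh, kw, dim(gin)[3])) * g[i, j, co]
        }
      }
    }
    g <- gin
  }
  matrix(g, cfg$input_size, cfg$input_size)
}

# Oracle variant that additionally clips negative backward values right after
# the guided mask at every rectification; the guided rule already guarantees
# non-negativity there, so this must be a no-op.
oracle_gbp_clip_negatives <- function(model, stimulus, voxel) {
  cfg <- model$config
  w1 <- gaborenc:::gabor_weight_array(model)
  ws <- c(list(w1), lapply(model$conv, `[[`, "w"))
  bs <- c(list(model$gabor_bias), lapply(model$conv, `[[`, "b"))
  acts <- list()
  a <- array(stimulus, c(cfg$input_size, cfg$input_size, 1L))
  for (l in seq_along(ws)) {
    z <- oracle_conv(a, ws[[l]], bs[[l]], cfg$stride)
    acts[[l]] <- z
    a <- pmax(z, 0)
  }
  g <- array(model$fc_w[, voxel]^2, dim(a))
  for (l in rev(seq_along(ws))) {
    g <- (acts[[l]] > 0) * (g > 0) * g
    g <- pmax(g, 0) # redundant clip: idempotence under test
    in_dim <- if (l == 1L) c(cfg$input_size, cfg$input_size, 1L) else dim(acts[[l - 1L]])
    gin <- array(0, in_dim)
    kh <- dim(ws[[l]])[1]; kw <- dim(ws[[l]])[2]
    for (co in seq_len(dim(g)[3])) {
      for (i in seq_len(dim(g)[1])) {
        for (j in seq_len(dim(g)[2])) {
          ri <- (i - 1L) * cfg$stride + seq_len(kh)
          cj <- (j - 1L) * cfg$stride + seq_len(kw)
          gin[ri, cj, ] <- gin[ri, cj, , drop = FALSE] +
            array(ws[[l]][, , , co], c(kh, kw, dim(gin)[3])) * g[i, j, co]
        }
      }
    }
    g <- gin
  }
  matrix(g, cfg$input_size, cfg$input_size)
}
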