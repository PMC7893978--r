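#' Spatial size of a strided valid-padding convolution output
#'
#' @param input_side Input side length in pixels.
#' @param kernel Kernel side length.
#' @param stride Stride (default 2).
#' @return `floor((input_side - kernel) / stride) + 1`.
#' @export
#' @examples
#' layer_output_size(128, 9) # 60
#' layer_output_size(60, 3)  # 29
layer_output_size <- function(input_side, kernel, stride = 2L) {
  if (input_side < kernel) {
    stop(sprintf("input side %d smaller than kernel %d", input_side, kernel),
         call. = FALSE)
  }
  as.integer((input_side - kernel) %/% stride + 1L)
}

#' Encoding network configuration
#'
#' Defaults reproduce the optimized architecture: one two-way Gabor
#' convolutional layer (64 kernels per branch, 9 x 9), two regular
#' convolutional layers (64 filters, 3 x 3), all with stride 2, valid padding
#' and ReLU activations, followed by one fully connected layer whose
#' effective weights are squares of the stored raw weights.
#'
#' @param input_size Image side length in pixels (square grayscale input).
#' @param n_voxels Number of voxels in the region of interest.
#' @param kernels_per_branch Gabor kernels per branch (real / imaginary).
#' @param gabor_size Odd Gabor kernel side length.
#' @param conv_filters Filters per regular convolutional layer; the vector
#'   length sets the number of regular layers.
#' @param conv_size Kernel side of the regular layers.
#' @param stride Stride shared by every convolutional layer.
#' @param activation `"relu"` (default) or `"identity"` (diagnostic switch
#'   that disables all rectifications).
#' @param omega_scheme Frequency ladder for Gabor initialization, see
#'   [gabor_init_grid()].
#' @return A `model_config` object.
#' @export
model_config <- function(input_size = 128L, n_voxels = 1L,
                         kernels_per_branch = 64L, gabor_size = 9L,
                         conv_filters = c(64L, 64L), conv_size = 3L,
                         stride = 2L,
                         activation = c("relu", "identity"),
                         omega_scheme = c("half_octave", "octave")) {
  activation <- match.arg(activation)
  omega_scheme <- match.arg(omega_scheme)
  if (n_voxels < 1) stop("n_voxels must be >= 1", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 n_voxels = as.integer(n_voxels),
                 kernels_per_branch = as.integer(kernels_per_branch),
                 gabor_size = check_kernel_size(gabor_size),
                 conv_filters = as.integer(conv_filters),
                 conv_size = as.integer(conv_size),
                 stride = as.integer(stride),
                 activation = activation,
                 omega_scheme = omega_scheme),
            class = "model_config")
}

# Side lengths of every feature map, input first. Errors name the offending
# layer when a map underflows the next kernel.
model_layer_sides <- function(config) {
  sides <- config$input_size
  kernels <- c(config$gabor_size, rep(config$conv_size, length(config$conv_filters)))
  names(kernels) <- c("gabor", paste0("conv", seq_along(config$conv_filters) + 1L))
  for (i in seq_along(kernels)) {
    s <- sides[length(sides)]
    if (s < kernels[i]) {
      stop(sprintf("feature map of side %d is smaller than the %dx%d kernel of layer '%s'",
                   s, kernels[i], kernels[i], names(kernels)[i]), call. = FALSE)
    }
    sides <- c(sides, layer_output_size(s, kernels[i], config$stride))
  }
  unname(sides)
}

he_uniform <- function(dim, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dim), -lim, lim), dim)
}

#' Build an encoding model
#'
#' Assembles the network of [model_config()]: Gabor bank initialized on the
#' frequency/orientation grid with uniform envelope widths and phases,
#' He-uniform regular convolution and fully connected raw weights, zero
#' biases. Construction is deterministic given `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `encoding_model`.
#' @export
#' @examples
#' m <- build_model(model_config(input_size = 32, n_voxels = 4,
#'                               kernels_per_branch = 4), seed = 1)
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  sides <- model_layer_sides(config)   # validates the stack
  set.seed(seed)
  bank <- init_gabor_bank(config$kernels_per_branch, config$gabor_size,
                          seed = seed, scheme = config$omega_scheme)
  n_gabor <- 2L * config$kernels_per_branch
  conv <- list()
  c_in <- n_gabor
  for (i in seq_along(config$conv_filters)) {
    c_out <- config$conv_filters[i]
    fan_in <- config$conv_size^2 * c_in
    conv[[i]] <- list(w = he_uniform(c(config$conv_size, config$conv_size, c_in, c_out),
                                     fan_in),
                      b = numeric(c_out))
    c_in <- c_out
  }
  final_side <- sides[length(sides)]
  n_features <- final_side^2 * c_in
  model <- structure(list(config = config,
                          bank = bank,
                          gabor_bias = numeric(n_gabor),
                          conv = conv,
                          fc_w = he_uniform(c(n_features, config$n_voxels), n_features),
                          fc_b = numeric(config$n_voxels),
                          sides = sides,
                          n_features = n_features,
                          mode = "eval"),
                     class = "encoding_model")
  model
}

#' @export
print.encoding_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Gabor encoding model: %dx%d input -> %s -> %d features -> %d voxels\n",
              cfg$input_size, cfg$input_size,
              paste(x$sides[-1], collapse = " -> "),
              x$n_features, cfg$n_voxels))
  cat(sprintf("  parameters: %d\n", model_parameter_count(x)))
  invisible(x)
}

#' Total learnable parameter count
#'
#' Counts the four scalars of every Gabor kernel, all regular convolution
#' weights and biases, and the fully connected raw weights and biases.
#'
#' @param model An `encoding_model`.
#' @return Integer parameter count.
#' @export
model_parameter_count <- function(model) {
  n <- 4L * (length(model$bank$real_params) + length(model$bank$imag_params)) +
    length(model$gabor_bias) +
    length(model$fc_w) + length(model$fc_b)
  for (l in model$conv) n <- n + length(l$w) + length(l$b)
  n
}

# Gabor kernels re-synthesized from the current parameters on every forward
# pass so gradients flow into (omega, sigma, phi, theta).
gabor_weight_array <- function(model) {
  sz <- model$bank$kernel_size
  stack <- render_bank(model$bank)
  array(stack, c(sz, sz, 1L, dim(stack)[3]))
}

apply_activation <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else z
}

# Full forward pass keeping per-layer caches (pre-activations, activations,
# patch matrices) for backpropagation and attribution.
forward_cached <- function(model, stimuli) {
  cfg <- model$config
  d <- dim(stimuli)
  if (length(d) == 2L) d <- c(d, 1L)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop(sprintf("stimuli are %dx%d but the model expects %dx%d",
                 d[1], d[2], cfg$input_size, cfg$input_size), call. = FALSE)
  }
  n <- d[3]
  x <- array(stimuli, c(d[1], d[2], 1L, n))
  layers <- list()
  w1 <- gabor_weight_array(model)
  fw <- conv_forward(x, w1, model$gabor_bias, cfg$stride)
  a <- apply_activation(fw$z, cfg$activation)
  layers[[1]] <- list(z = fw$z, a = a, cols = fw$cols, w = w1, x_dim = dim(x))
  for (i in seq_along(model$conv)) {
    fw <- conv_forward(a, model$conv[[i]]$w, model$conv[[i]]$b, cfg$stride)
    a_new <- apply_activation(fw$z, cfg$activation)
    layers[[i + 1L]] <- list(z = fw$z, a = a_new, cols = fw$cols,
                             w = model$conv[[i]]$w, x_dim = dim(a))
    a <- a_new
  }
  f <- matrix(a, nrow = model$n_features)        # features x batch
  pred <- crossprod(f, model$fc_w^2)             # batch x voxels
  pred <- sweep(pred, 2L, model$fc_b, "+")
  list(pred = pred, f = f, layers = layers, input = x)
}

#' Predict voxel responses for a batch of stimuli
#'
#' Runs the encoder in evaluation mode (no noise injection): strided valid
#' convolutions with rectification, then the squared-weight affine map
#' `r_hat = (w_fc^2)' f + b`.
#'
#' @param model An `encoding_model`.
#' @param stimuli Array `side x side x n` (or a single `side x side` image).
#' @return Numeric matrix `n x n_voxels`.
#' @export
forward_pass <- function(model, stimuli) {
  forward_cached(model, stimuli)$pred
}

#' @export
predict.encoding_model <- function(object, stimuli, ...) {
  forward_pass(object, stimuli)
}

# ---- flat parameter access (training, checkpoints) -------------------------

# Parameters as a flat named list of numeric arrays. Gabor parameters are
# vectors over channels, real branch first.
model_parameters <- function(model) {
  get_par <- function(branch, name) {
    vapply(branch, function(p) p[[name]], numeric(1))
  }
  pars <- list(
    gabor_omega = c(get_par(model$bank$real_params, "omega"),
                    get_par(model$bank$imag_params, "omega")),
    gabor_sigma = c(get_par(model$bank$real_params, "sigma"),
                    get_par(model$bank$imag_params, "sigma")),
    gabor_phi   = c(get_par(model$bank$real_params, "phi"),
                    get_par(model$bank$imag_params, "phi")),
    gabor_theta = c(get_par(model$bank$real_params, "theta"),
                    get_par(model$bank$imag_params, "theta")),
    gabor_bias  = model$gabor_bias,
    fc_w = model$fc_w,
    fc_b = model$fc_b)
  for (i in seq_along(model$conv)) {
    pars[[paste0("conv", i, "_w")]] <- model$conv[[i]]$w
    pars[[paste0("conv", i, "_b")]] <- model$conv[[i]]$b
  }
  pars
}

set_model_parameters <- function(model, pars) {
  kpb <- length(model$bank$real_params)
  for (k in seq_len(kpb)) {
    model$bank$real_params[[k]] <- gabor_params(pars$gabor_omega[k],
                                                pars$gabor_sigma[k],
                                                pars$gabor_phi[k],
                                                pars$gabor_theta[k])
    model$bank$imag_params[[k]] <- gabor_params(pars$gabor_omega[kpb + k],
                                                pars$gabor_sigma[kpb + k],
                                                pars$gabor_phi[kpb + k],
                                                pars$gabor_theta[kpb + k])
  }
  model$gabor_bias <- pars$gabor_bias
  model$fc_w <- pars$fc_w
  model$fc_b <- pars$fc_b
  for (i in seq_along(model$conv)) {
    model$conv[[i]]$w <- pars[[paste0("conv", i, "_w")]]
    model$conv[[i]]$b <- pars[[paste0("conv", i, "_b")]]
  }
  model
}

#' Save / load a model checkpoint
#'
#' Serializes the configuration, every parameter array and optional training
#' metadata to a single file; the round trip restores the model bit-exactly.
#'
#' @param model An `encoding_model`.
#' @param path Checkpoint file path (`.rds`).
#' @param metadata Optional list of training metadata stored alongside.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model` and `metadata`.
#' @export
save_checkpoint <- function(model, path, metadata = list()) {
  stopifnot(inherits(model, "encoding_model"))
  saveRDS(list(config = model$config,
               parameters = model_parameters(model),
               metadata = metadata,
               package_version = as.character(utils::packageVersion("gaborenc"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  model <- build_model(obj$config, seed = 1L)
  model <- set_model_parameters(model, obj$parameters)
  list(model = model, metadata = obj$metadata)
}
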