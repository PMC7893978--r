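#' Sample Pearson correlation between two vectors
#'
#' The voxel-wise prediction accuracy statistic:
#' `rho = cov(a, b) / sqrt(var(a) var(b))`.
#'
#' @param pred,actual Numeric vectors of equal length (>= 2), both
#'   non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
pearson_correlation <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 2) stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(pred, actual)
}

# Column-wise Pearson correlation of two matrices (samples x voxels).
# Constant columns yield NA rather than an error.
colwise_pearson <- function(pred, actual) {
  pc <- sweep(pred, 2L, colMeans(pred))
  ac <- sweep(actual, 2L, colMeans(actual))
  sp <- sqrt(colSums(pc^2))
  sa <- sqrt(colSums(ac^2))
  rho <- colSums(pc * ac) / (sp * sa)
  rho[sp == 0 | sa == 0] <- NA_real_
  rho
}

#' Add Gaussian regularization noise to predicted responses
#'
#' During training, zero-mean Gaussian noise is added element-wise to the
#' predicted responses before the loss; it damps the gradient contribution of
#' voxels whose predictions carry little signal. Draws come from the current
#' RNG state, so runs are reproducible under [set.seed()].
#'
#' @param pred Numeric matrix (batch x voxels).
#' @param noise_sd Noise standard deviation (>= 0, default 1 as used in
#'   training).
#' @return Matrix of the same shape.
#' @export
inject_noise <- function(pred, noise_sd = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(pred)
  pred + array(stats::rnorm(length(pred), 0, noise_sd), dim(pred))
}

# Loss and its gradient with respect to the predictions.
# Loss = -(1/n) sum_m rho_m^3 + gamma * |grand mean of pred|, rho_m over the
# batch dimension. Constant prediction columns contribute rho = 0 (gradient 0)
# with a warning.
correlation_loss_grad <- function(pred, actual, gamma, need_grad = TRUE) {
  n_vox <- ncol(pred)
  n_b <- nrow(pred)
  pc <- sweep(pred, 2L, colMeans(pred))
  ac <- sweep(actual, 2L, colMeans(actual))
  sp <- sqrt(colSums(pc^2))
  sa <- sqrt(colSums(ac^2))
  bad <- sp == 0 | sa == 0
  if (any(bad)) {
    warning(sprintf("%d constant column(s) in the correlation loss; treated as rho = 0",
                    sum(bad)), call. = FALSE)
  }
  denom <- sp * sa
  denom[bad] <- 1
  rho <- colSums(pc * ac) / denom
  rho[bad] <- 0
  gm <- mean(pred)
  loss <- -mean(rho^3) + gamma * abs(gm)
  grad <- NULL
  if (need_grad) {
    # d rho_m / d pred_m = ac/(sp*sa) - rho * pc/sp^2 (columns already centered)
    sp2 <- sp^2
    sp2[bad] <- 1
    drho <- sweep(ac, 2L, denom, "/") -
      sweep(pc, 2L, rho / sp2, "*")
    drho[, bad] <- 0
    grad <- sweep(drho, 2L, -3 * rho^2 / n_vox, "*") +
      gamma * sign(gm) / (n_vox * n_b)
  }
  list(loss = loss, grad = grad, rho = rho)
}

#' Correlation-weighted encoding loss
#'
#' `Loss = -(1/n) sum_m rho_m^3 + gamma * |(1/n) sum_m mean(r_hat_m)|`, where
#' `rho_m` is the Pearson correlation of predicted and actual responses of
#' voxel `m` over the batch and `n` is the number of voxels. Cubing the
#' correlation is the product of the accuracy `rho_m` with a self-adapting
#' voxel weight `rho_m^2`, which concentrates optimization on voxels that are
#' already predictable; the second term penalizes a drifting prediction mean.
#'
#' @param pred,actual Numeric matrices (batch x voxels), batch >= 2.
#' @param gamma Non-negative weight of the mean-magnitude penalty
#'   (default 0.1).
#' @return Scalar loss, bounded below by -1.
#' @export
encoding_loss <- function(pred, actual, gamma = 0.1) {
  if (!all(dim(pred) == dim(actual))) stop("shape mismatch", call. = FALSE)
  if (nrow(pred) < 2) stop("batch size must be >= 2", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  correlation_loss_grad(pred, actual, gamma, need_grad = FALSE)$loss
}

#' Training configuration
#'
#' Optimizer and loop settings. Defaults follow the published training setup:
#' mini-batch size 128, adaptive moment estimation, learning-rate decay
#' coefficient 0.001 (per-epoch multiplicative decay
#' `lr / (1 + 0.001 * epoch)`), unit-variance regularization noise. The decay
#' coefficient can alternatively be applied as optimizer weight decay
#' (`decay_mode = "weight_decay"`).
#'
#' @param batch_size Mini-batch size (>= 2; correlations are computed within
#'   the batch).
#' @param learning_rate Base Adam step size.
#' @param lr_decay Decay coefficient (default 0.001).
#' @param gamma Weight of the mean-magnitude penalty in [encoding_loss()].
#' @param noise_sd Standard deviation of the injected prediction noise.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling shuffling and noise.
#' @param decay_mode `"lr_decay"` (default) or `"weight_decay"`.
#' @return A `training_config` object.
#' @export
training_config <- function(batch_size = 128L, learning_rate = 0.01,
                            lr_decay = 0.001, gamma = 0.1, noise_sd = 1,
                            epochs = 150L, seed = 1L,
                            decay_mode = c("lr_decay", "weight_decay")) {
  decay_mode <- match.arg(decay_mode)
  if (batch_size < 2) stop("batch_size must be >= 2", call. = FALSE)
  vals <- c(learning_rate, lr_decay, gamma, noise_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rates and weights must be finite and non-negative", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 gamma = gamma, noise_sd = noise_sd,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 decay_mode = decay_mode),
            class = "training_config")
}

# Backward pass: gradients of the loss w.r.t. every parameter, given the
# cached forward pass and dLoss/dpred. Gabor kernel gradients are pulled back
# onto (omega, sigma, phi, theta) through the analytic kernel partials.
model_gradients <- function(model, fwd, dpred) {
  cfg <- model$config
  grads <- list()
  grads$fc_w <- 2 * model$fc_w * (fwd$f %*% dpred)
  grads$fc_b <- colSums(dpred)
  da <- array(model$fc_w^2 %*% t(dpred), dim(fwd$layers[[length(fwd$layers)]]$a))
  for (l in rev(seq_along(fwd$layers))) {
    lay <- fwd$layers[[l]]
    dz <- if (cfg$activation == "relu") da * (lay$z > 0) else da
    bw <- conv_backward(dz, lay$x_dim, lay$w, cfg$stride, cols = lay$cols,
                        need_dx = (l > 1L))
    if (l > 1L) {
      grads[[paste0("conv", l - 1L, "_w")]] <- bw$dw
      grads[[paste0("conv", l - 1L, "_b")]] <- bw$db
      da <- bw$dx
    } else {
      grads$gabor_bias <- bw$db
      kpb <- cfg$kernels_per_branch
      n_ch <- 2L * kpb
      gom <- gsi <- gph <- gth <- numeric(n_ch)
      branches <- c(model$bank$real_params, model$bank$imag_params)
      for (k in seq_len(n_ch)) {
        br <- if (k <= kpb) "real" else "imaginary"
        kg <- gabor_kernel_grads(branches[[k]], cfg$gabor_size, br)
        dk <- bw$dw[, , 1L, k]
        gom[k] <- sum(dk * kg$omega)
        gsi[k] <- sum(dk * kg$sigma)
        gph[k] <- sum(dk * kg$phi)
        gth[k] <- sum(dk * kg$theta)
      }
      grads$gabor_omega <- gom
      grads$gabor_sigma <- gsi
      grads$gabor_phi <- gph
      grads$gabor_theta <- gth
    }
  }
  grads
}

#' Fit an encoding model
#'
#' Mini-batch loop implementing the selective feature/voxel optimization:
#' forward pass, Gaussian noise injection on the predictions, the
#' [encoding_loss()], and an adaptive-moment-estimation step on every
#' parameter, including the four scalars of each Gabor kernel. Because the
#' effective fully connected weights are squares of the raw weights, the raw
#' weights receive gradient `2 w * dL/d(w^2)`: their step size scales with
#' their own magnitude, which is the self-adapting feature weighting.
#'
#' @param model An `encoding_model` (its configuration must match the data).
#' @param stimuli Training stimuli, array `side x side x n`.
#' @param responses Training responses, matrix `n x n_voxels`, z-scored per
#'   voxel.
#' @param config A [training_config()].
#' @param val_stimuli,val_responses Optional validation set; when given, the
#'   history tracks mean validation accuracy per epoch.
#' @param verbose Print per-epoch loss (default FALSE).
#' @return List with `model` (trained) and `history` (data frame with one row
#'   per epoch: `epoch`, `loss`, `val_accuracy`; the seed is kept as an
#'   attribute).
#' @export
fit_encoding_model <- function(model, stimuli, responses, config,
                               val_stimuli = NULL, val_responses = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(model, "encoding_model"), inherits(config, "training_config"))
  n <- dim(stimuli)[3]
  if (nrow(responses) != n) {
    stop("responses rows must match the number of stimuli", call. = FALSE)
  }
  if (ncol(responses) != model$config$n_voxels) {
    stop("responses columns must match the model's voxel count", call. = FALSE)
  }
  set.seed(config$seed)
  pars <- model_parameters(model)
  adam_m <- lapply(pars, function(p) p * 0)
  adam_v <- lapply(pars, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    lr <- if (config$decay_mode == "lr_decay") {
      config$learning_rate / (1 + config$lr_decay * (epoch - 1))
    } else {
      config$learning_rate
    }
    idx <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    losses <- numeric(0)
    for (s in starts) {
      b_idx <- idx[s:min(s + config$batch_size - 1L, n)]
      if (length(b_idx) < 2L) next
      fwd <- forward_cached(model, stimuli[, , b_idx, drop = FALSE])
      pred <- inject_noise(fwd$pred, config$noise_sd)
      lg <- correlation_loss_grad(pred, responses[b_idx, , drop = FALSE],
                                  config$gamma)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d, batch starting at %d",
                     epoch, s), call. = FALSE)
      }
      losses <- c(losses, lg$loss)
      grads <- model_gradients(model, fwd, lg$grad)
      step <- step + 1L
      for (nm in names(pars)) {
        g <- grads[[nm]]
        if (config$decay_mode == "weight_decay") g <- g + config$lr_decay * pars[[nm]]
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      model <- set_model_parameters(model, pars)
    }
    val_acc <- NA_real_
    if (!is.null(val_stimuli)) {
      rho <- colwise_pearson(forward_pass(model, val_stimuli), val_responses)
      val_acc <- mean(rho, na.rm = TRUE)
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                         val_accuracy = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f", epoch,
                      mean(losses), val_acc))
    }
  }
  attr(history, "seed") <- config$seed
  list(model = model, history = history)
}

#' Cross-validation fold assignment
#'
#' Random partition of `n_samples` indices into `k` disjoint folds whose
#' sizes differ by at most one.
#'
#' @param n_samples Number of samples (>= k).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` integer vectors partitioning `1:n_samples`.
#' @export
cv_folds <- function(n_samples, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n_samples < k) stop("n_samples must be >= k", call. = FALSE)
  set.seed(seed)
  assign <- sample(rep_len(seq_len(k), n_samples))
  lapply(seq_len(k), function(i) which(assign == i))
}
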