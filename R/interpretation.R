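#' Guided backpropagation from one voxel to the stimulus
#'
#' Backpropagates the predicted response of a single voxel through the
#' network. Through the fully connected map and the convolutions the backward
#' pass is ordinary linear backpropagation; at every rectification the
#' backward signal is masked by both the forward activation being positive
#' and the incoming gradient being positive (`G^l = (f^l > 0) * (G^{l+1} > 0)
#' * G^{l+1}`). When the model was built with `activation = "identity"` no
#' masking occurs and the result is the plain gradient.
#'
#' @param model An `encoding_model`.
#' @param stimulus A single image, matrix `side x side`.
#' @param voxel Voxel index (1-based).
#' @return List with `map` (input-sized gradient matrix) and `trace`, a
#'   per-layer list of forward activations and masked backward gradients.
#' @export
guided_backprop <- function(model, stimulus, voxel) {
  cfg <- model$config
  if (length(voxel) != 1L || voxel < 1 || voxel > cfg$n_voxels) {
    stop("invalid voxel index", call. = FALSE)
  }
  fwd <- forward_cached(model, stimulus)
  g_feat <- model$fc_w[, voxel]^2
  n_layers <- length(fwd$layers)
  g <- array(g_feat, dim(fwd$layers[[n_layers]]$a))
  trace <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    lay <- fwd$layers[[l]]
    if (cfg$activation == "relu") g <- g * (lay$z > 0) * (g > 0)
    trace[[l]] <- list(activation = lay$a, gradient = g)
    g <- conv_backward_input(g, lay$x_dim, lay$w, cfg$stride)
  }
  list(map = matrix(g, cfg$input_size, cfg$input_size), trace = trace)
}

#' Receptive-field estimate for one voxel
#'
#' Averages the absolute guided-backpropagation maps of a stimulus set,
#' thresholds the aggregate at `mask_fraction` of its maximum to obtain a
#' binary receptive-field mask, and summarizes the mask by its size ratio
#' (mask pixels / image pixels) and its attribution-weighted centroid.
#'
#' @param model An `encoding_model`.
#' @param voxel Voxel index.
#' @param stimuli Stimulus array `side x side x n` (n >= 1).
#' @param mask_fraction Mask threshold as a fraction of the aggregate map
#'   maximum (default 0.1).
#' @return An `rf_estimate`: list with `map`, `mask`, `size_ratio`,
#'   `centroid` (row, col in pixels) and `undefined` (TRUE when the aggregate
#'   map is identically zero).
#' @export
estimate_rf <- function(model, voxel, stimuli, mask_fraction = 0.1) {
  if (length(dim(stimuli)) == 2L) dim(stimuli) <- c(dim(stimuli), 1L)
  n <- dim(stimuli)[3]
  map <- 0
  for (i in seq_len(n)) {
    map <- map + abs(guided_backprop(model, stimuli[, , i], voxel)$map)
  }
  map <- map / n
  if (max(map) == 0) {
    return(structure(list(map = map, mask = map > 0, size_ratio = 0,
                          centroid = c(NA_real_, NA_real_), undefined = TRUE),
                     class = "rf_estimate"))
  }
  mask <- map >= mask_fraction * max(map)
  w <- map * mask
  rows <- row(map); cols <- col(map)
  centroid <- c(sum(rows * w), sum(cols * w)) / sum(w)
  structure(list(map = map, mask = mask,
                 size_ratio = sum(mask) / length(mask),
                 centroid = centroid, undefined = FALSE),
            class = "rf_estimate")
}

#' Preferred Gabor kernels of one voxel
#'
#' Scores every first-layer channel by the attribution it carries for the
#' voxel: the mean over stimuli of the summed absolute product of the guided
#' backward gradient and the forward activation at the Gabor layer output
#' (`score = "grad_x_act"`), or of the absolute gradient alone
#' (`score = "gradient"`). Returns the `k` top-scoring kernels with their
#' current parameters.
#'
#' @param model An `encoding_model`.
#' @param voxel Voxel index.
#' @param stimuli Stimulus array `side x side x n`.
#' @param k Number of kernels to return (default 8).
#' @param score Attribution score, `"grad_x_act"` (default) or `"gradient"`.
#' @return A `preferred_kernels` object: list with `voxel`, `kernel` (channel
#'   indices, real branch first), `score` (non-increasing), `branch`, and
#'   `params` (list of [gabor_params()]).
#' @export
preferred_kernels <- function(model, voxel, stimuli, k = 8L,
                              score = c("grad_x_act", "gradient")) {
  score <- match.arg(score)
  n_ch <- 2L * model$config$kernels_per_branch
  if (k > n_ch) stop("k exceeds the number of Gabor kernels", call. = FALSE)
  if (length(dim(stimuli)) == 2L) dim(stimuli) <- c(dim(stimuli), 1L)
  n <- dim(stimuli)[3]
  totals <- numeric(n_ch)
  for (i in seq_len(n)) {
    tr <- guided_backprop(model, stimuli[, , i], voxel)$trace[[1]]
    contrib <- if (score == "grad_x_act") {
      abs(tr$gradient * tr$activation)
    } else {
      abs(tr$gradient)
    }
    totals <- totals + apply(contrib, 3L, sum)
  }
  totals <- totals / n
  top <- order(-totals)[seq_len(k)]
  all_params <- c(model$bank$real_params, model$bank$imag_params)
  structure(list(voxel = voxel, kernel = top, score = totals[top],
                 branch = model$bank$branch[top],
                 params = all_params[top]),
            class = "preferred_kernels")
}

# All S values over the permutation distribution of a sequence (exact null,
# n <= 8). Returns the vector of S statistics of every permutation.
mk_s_permutations <- function(values) {
  n <- length(values)
  perms <- permutations_of(n)
  apply(perms, 1L, function(p) mk_s(values[p]))
}

mk_s <- function(v) {
  n <- length(v)
  s <- 0
  for (i in seq_len(n - 1L)) {
    s <- s + sum(sign(v[(i + 1L):n] - v[i]))
  }
  as.integer(s)
}

# All permutations of 1..n as an (n! x n) matrix, recursively.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep.int(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

#' Mann-Kendall trend test
#'
#' The trend statistic `S = sum_{i<j} sign(v_j - v_i)`. For sequences of
#' length 8 or less the one-sided p-value in the direction of the observed
#' trend is exact, computed by full enumeration of all orderings of the
#' observed values; for longer sequences the normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' @param values Numeric sequence (length >= 3).
#' @return A `trend_result`: list with `s`, `p_value` (one-sided),
#'   `direction` (`"increasing"`, `"decreasing"` or `"none"`), `n` and
#'   `method`.
#' @export
#' @examples
#' mann_kendall(c(1, 2, 3, 4, 5)) # S = 10, p = 1/120
mann_kendall <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  s <- mk_s(values)
  direction <- if (s > 0) "increasing" else if (s < 0) "decreasing" else "none"
  if (n <= 8) {
    s_null <- mk_s_permutations(values)
    p <- if (s >= 0) mean(s_null >= s) else mean(s_null <= s)
    method <- "exact"
  } else {
    tie_tab <- table(values)
    var_s <- (n * (n - 1) * (2 * n + 5) -
                sum(tie_tab * (tie_tab - 1) * (2 * tie_tab + 5))) / 18
    z <- if (s == 0) 0 else (abs(s) - 1) / sqrt(var_s)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  structure(list(s = s, p_value = p, direction = direction, n = n,
                 method = method),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %d (%s), one-sided p = %.4g [%s, n = %d]\n",
              x$s, x$direction, x$p_value, x$method, x$n))
  invisible(x)
}

#' Parameter and receptive-field trends across regions of interest
#'
#' For each ROI (in the anatomical order supplied, e.g. V1, V2, V3, V4, LO)
#' the `top_n` best-predicted voxels are selected from the accuracy report;
#' their preferred Gabor kernels and receptive-field estimates are pooled
#' into per-ROI means of (omega, sigma, phi, theta) and of the RF size ratio,
#' and each mean sequence is tested for a monotone trend with
#' [mann_kendall()].
#'
#' @param models List of `encoding_model`s, one per ROI.
#' @param reports List of matching `accuracy_report`s.
#' @param stimuli_sets A single stimulus array shared by all ROIs, or a list
#'   of arrays, used for the attribution maps.
#' @param roi_labels Character vector of ROI names (defines the trend order).
#' @param top_n Voxels per ROI entering the summary (default 100; all when an
#'   ROI has fewer).
#' @param k Preferred kernels per voxel (default 8).
#' @param mask_fraction Passed to [estimate_rf()].
#' @return A `roi_trend_summary`: list with `means` (data frame: one row per
#'   ROI with mean omega, sigma, phi, theta, rf_ratio) and `trends` (named
#'   list of `trend_result`s for each column).
#' @export
roi_trend_summary <- function(models, reports, stimuli_sets, roi_labels,
                              top_n = 100L, k = 8L, mask_fraction = 0.1) {
  n_roi <- length(models)
  if (n_roi < 2) stop("need at least 2 ROIs", call. = FALSE)
  stopifnot(length(reports) == n_roi, length(roi_labels) == n_roi)
  if (!is.list(stimuli_sets)) stimuli_sets <- rep(list(stimuli_sets), n_roi)
  means <- data.frame(roi = roi_labels, omega = NA_real_, sigma = NA_real_,
                      phi = NA_real_, theta = NA_real_, rf_ratio = NA_real_)
  for (r in seq_len(n_roi)) {
    ranking <- rank_voxels(reports[[r]]$rho)
    vox <- utils::head(ranking$voxel, top_n)
    om <- si <- ph <- th <- numeric(0)
    ratios <- numeric(length(vox))
    for (i in seq_along(vox)) {
      pk <- preferred_kernels(models[[r]], vox[i], stimuli_sets[[r]], k = k)
      om <- c(om, vapply(pk$params, `[[`, numeric(1), "omega"))
      si <- c(si, vapply(pk$params, `[[`, numeric(1), "sigma"))
      ph <- c(ph, vapply(pk$params, `[[`, numeric(1), "phi"))
      th <- c(th, vapply(pk$params, `[[`, numeric(1), "theta"))
      ratios[i] <- estimate_rf(models[[r]], vox[i], stimuli_sets[[r]],
                               mask_fraction = mask_fraction)$size_ratio
    }
    means$omega[r] <- mean(om)
    means$sigma[r] <- mean(si)
    means$phi[r] <- mean(ph)
    means$theta[r] <- mean(th)
    means$rf_ratio[r] <- mean(ratios)
  }
  trends <- lapply(means[, c("omega", "sigma", "phi", "theta", "rf_ratio")],
                   mann_kendall)
  structure(list(means = means, trends = trends), class = "roi_trend_summary")
}

#' @export
print.roi_trend_summary <- function(x, ...) {
  print(x$means)
  for (nm in names(x$trends)) {
    t <- x$trends[[nm]]
    cat(sprintf("  %-8s S = %3d (%s), p = %.4g\n", nm, t$s, t$direction,
                t$p_value))
  }
  invisible(x)
}
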