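#' Parameter set of one Gabor kernel
#'
#' A Gabor kernel is a Gaussian envelope modulated by a sinusoid. Four scalars
#' define it: the spatial frequency `omega` (radians/pixel), the envelope
#' standard deviation `sigma` (pixels), the phase offset `phi` (radians) and
#' the orientation `theta` (radians). At initialization `omega` and `theta`
#' come from a fixed frequency/orientation grid and `sigma`, `phi` from
#' uniform draws; after training all four are unconstrained real numbers.
#'
#' @param omega Spatial frequency in radians per pixel.
#' @param sigma Gaussian envelope standard deviation in pixels (non-zero).
#' @param phi Phase offset in radians.
#' @param theta Orientation in radians.
#' @return An object of class `gabor_params`.
#' @export
#' @examples
#' gabor_params(pi / 2, 1.5, 0, pi / 8)
gabor_params <- function(omega, sigma, phi, theta) {
  for (v in list(omega, sigma, phi, theta)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("gabor parameters must be finite numeric scalars", call. = FALSE)
    }
  }
  if (sigma == 0) stop("sigma must be non-zero", call. = FALSE)
  structure(list(omega = omega, sigma = sigma, phi = phi, theta = theta),
            class = "gabor_params")
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf("Gabor kernel parameters: omega=%.4g sigma=%.4g phi=%.4g theta=%.4g\n",
              x$omega, x$sigma, x$phi, x$theta))
  invisible(x)
}

# Integer coordinate grids centered at 0; x rightward (columns), y downward
# (rows). Returns size x size matrices.
gabor_coords <- function(size) {
  half <- (size - 1L) / 2L
  offs <- seq(-half, half)
  list(x = matrix(offs, size, size, byrow = TRUE),
       y = matrix(offs, size, size))
}

check_kernel_size <- function(size) {
  if (!is.numeric(size) || length(size) != 1L || size != round(size) ||
      size < 3 || size %% 2 == 0) {
    stop("kernel size must be an odd integer >= 3", call. = FALSE)
  }
  as.integer(size)
}

#' Synthesize a Gabor kernel from its parameters
#'
#' Evaluates the real or imaginary branch of the complex Gabor function on an
#' odd-sized integer pixel grid centred at 0. With rotated coordinates
#' `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`,
#' the real branch is `exp(-(x'^2 + y'^2) / (2 sigma^2)) * cos(omega x' + phi)`
#' and the imaginary branch replaces the cosine by a sine.
#'
#' @param params A [gabor_params()] object.
#' @param size Odd kernel side length in pixels (>= 3).
#' @param branch `"real"` or `"imaginary"`.
#' @return A `size` x `size` numeric matrix (rows = y downward, columns = x
#'   rightward).
#' @export
#' @examples
#' k <- synthesize_kernel(gabor_params(pi / 2, 2, 0, 0), size = 9)
#' k[5, 5] # center element: exp(0) * cos(0) = 1
synthesize_kernel <- function(params, size = 9L,
                              branch = c("real", "imaginary")) {
  branch <- match.arg(branch)
  size <- check_kernel_size(size)
  if (params$sigma == 0) stop("sigma must be non-zero", call. = FALSE)
  g <- gabor_coords(size)
  xr <- g$x * cos(params$theta) + g$y * sin(params$theta)
  yr <- -g$x * sin(params$theta) + g$y * cos(params$theta)
  env <- exp(-(xr^2 + yr^2) / (2 * params$sigma^2))
  carrier <- params$omega * xr + params$phi
  if (branch == "real") env * cos(carrier) else env * sin(carrier)
}

# Analytic partial derivatives of the kernel with respect to (omega, sigma,
# phi, theta). The envelope is isotropic, so rotation only enters through the
# carrier: dx'/dtheta = y'. Returns a list of size x size matrices.
gabor_kernel_grads <- function(params, size = 9L,
                               branch = c("real", "imaginary")) {
  branch <- match.arg(branch)
  size <- check_kernel_size(size)
  g <- gabor_coords(size)
  xr <- g$x * cos(params$theta) + g$y * sin(params$theta)
  yr <- -g$x * sin(params$theta) + g$y * cos(params$theta)
  r2 <- xr^2 + yr^2
  env <- exp(-r2 / (2 * params$sigma^2))
  arg <- params$omega * xr + params$phi
  if (branch == "real") {
    carrier <- cos(arg)
    dcarrier <- -sin(arg)
  } else {
    carrier <- sin(arg)
    dcarrier <- cos(arg)
  }
  list(omega = env * dcarrier * xr,
       sigma = env * carrier * r2 / params$sigma^3,
       phi   = env * dcarrier,
       theta = env * dcarrier * params$omega * yr)
}

#' Initialization grid for Gabor frequencies and orientations
#'
#' Five spatial frequencies and eight orientations. Frequencies follow the
#' half-octave geometric ladder `omega_m = (pi/2) * 2^(-m/2)`, `m = 0..4`
#' (`scheme = "half_octave"`); a full-octave alternative
#' `omega_m = (pi/2) * 2^(-m)` is available as `scheme = "octave"`.
#' Orientations are `theta_n = pi/8 * (n - 1)`, `n = 1..8`.
#'
#' @param scheme Frequency ladder: `"half_octave"` (default) or `"octave"`.
#' @return A list with numeric vectors `omega` (length 5) and `theta`
#'   (length 8).
#' @export
gabor_init_grid <- function(scheme = c("half_octave", "octave")) {
  scheme <- match.arg(scheme)
  m <- 0:4
  omega <- if (scheme == "half_octave") (pi / 2) * 2^(-m / 2) else (pi / 2) * 2^(-m)
  list(omega = omega, theta = (pi / 8) * (0:7))
}

#' Initialize a bank of Gabor kernels for the first network layer
#'
#' Builds `kernels_per_branch` real-branch and `kernels_per_branch`
#' imaginary-branch parameter sets. Frequencies and orientations are assigned
#' deterministically from the 5 x 8 initialization grid: kernel `k` (0-based,
#' within a branch) gets grid cell `m = (k mod 40) div 8`,
#' `n = (k mod 40) mod 8`, wrapping for `k >= 40`. Envelope widths are drawn
#' i.i.d. from U(0, 5) and phases from U(0, pi).
#'
#' @param kernels_per_branch Number of kernels per branch (default 64, giving
#'   128 kernels in total).
#' @param size Odd kernel side length in pixels (default 9).
#' @param seed Integer seed making the uniform draws reproducible.
#' @param scheme Frequency ladder passed to [gabor_init_grid()].
#' @return An object of class `gabor_bank`: list with `real_params` and
#'   `imag_params` (lists of [gabor_params()]), `kernel_size`, and `branch`
#'   labels in render order (real branch first).
#' @export
#' @examples
#' bank <- init_gabor_bank(seed = 1)
#' bank$real_params[[1]]$theta # 0, first orientation of the grid
init_gabor_bank <- function(kernels_per_branch = 64L, size = 9L, seed = 1L,
                            scheme = c("half_octave", "octave")) {
  if (!is.numeric(kernels_per_branch) || kernels_per_branch < 1) {
    stop("kernels_per_branch must be >= 1", call. = FALSE)
  }
  kernels_per_branch <- as.integer(kernels_per_branch)
  size <- check_kernel_size(size)
  grid <- gabor_init_grid(scheme)
  set.seed(seed)
  make_branch <- function() {
    lapply(seq_len(kernels_per_branch) - 1L, function(k) {
      cell <- k %% 40L
      m <- cell %/% 8L
      n <- cell %% 8L
      gabor_params(omega = grid$omega[m + 1L],
                   sigma = runif(1, 0, 5),
                   phi   = runif(1, 0, pi),
                   theta = grid$theta[n + 1L])
    })
  }
  real_params <- make_branch()
  imag_params <- make_branch()
  structure(list(real_params = real_params,
                 imag_params = imag_params,
                 kernel_size = size,
                 branch = rep(c("real", "imaginary"), each = kernels_per_branch)),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("Gabor kernel bank: %d real + %d imaginary kernels, %dx%d px\n",
              length(x$real_params), length(x$imag_params),
              x$kernel_size, x$kernel_size))
  invisible(x)
}

#' Render every kernel of a bank
#'
#' Synthesizes all kernels from their current parameters, real branch first
#' then imaginary, in stable index order.
#'
#' @param bank A [init_gabor_bank()] object.
#' @return Numeric array of dimension `size x size x n_kernels`.
#' @export
render_bank <- function(bank) {
  stopifnot(inherits(bank, "gabor_bank"))
  sz <- bank$kernel_size
  n_re <- length(bank$real_params)
  n_im <- length(bank$imag_params)
  out <- array(0, c(sz, sz, n_re + n_im))
  for (i in seq_len(n_re)) {
    out[, , i] <- synthesize_kernel(bank$real_params[[i]], sz, "real")
  }
  for (i in seq_len(n_im)) {
    out[, , n_re + i] <- synthesize_kernel(bank$imag_params[[i]], sz, "imaginary")
  }
  out
}

#' Export a kernel bank as a PNG image grid
#'
#' Arranges the rendered kernels on a rectangular montage (each kernel
#' min-max scaled independently) and writes a grayscale PNG, for visual
#' inspection of what the first layer has learned.
#'
#' @param bank A `gabor_bank`.
#' @param path Output PNG file path.
#' @param ncol Number of montage columns (default 8).
#' @return Invisibly, the montage matrix.
#' @export
export_bank_png <- function(bank, path, ncol = 8L) {
  stack <- render_bank(bank)
  n <- dim(stack)[3]
  sz <- dim(stack)[1]
  nrow <- ceiling(n / ncol)
  pad <- 1L
  canvas <- matrix(1, nrow * (sz + pad) + pad, ncol * (sz + pad) + pad)
  for (i in seq_len(n)) {
    k <- stack[, , i]
    rng <- range(k)
    k <- if (diff(rng) > 0) (k - rng[1]) / diff(rng) else k * 0 + 0.5
    r0 <- ((i - 1) %/% ncol) * (sz + pad) + pad
    c0 <- ((i - 1) %% ncol) * (sz + pad) + pad
    canvas[r0 + seq_len(sz), c0 + seq_len(sz)] <- k
  }
  png::writePNG(canvas, path)
  invisible(canvas)
}
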