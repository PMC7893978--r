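# Thin R wrappers around the C++ patch gather/scatter kernels. Convolutions
# are computed as (kh*kw*Cin x Cout)' %*% patches, so the heavy lifting is a
# BLAS matrix product. Feature maps are arrays (H, W, C, N).

conv_forward <- function(x, w, b, stride = 2L) {
  d <- dim(x)
  kd <- dim(w)
  if (d[3] != kd[3]) stop("channel mismatch between input and kernels", call. = FALSE)
  if (d[1] < kd[1] || d[2] < kd[2]) {
    stop(sprintf("input %dx%d smaller than kernel %dx%d", d[1], d[2], kd[1], kd[2]),
         call. = FALSE)
  }
  ho <- (d[1] - kd[1]) %/% stride + 1L
  wo <- (d[2] - kd[2]) %/% stride + 1L
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], kd[1], kd[2], stride)
  wm <- matrix(w, nrow = kd[1] * kd[2] * kd[3])
  z <- crossprod(wm, cols) + b              # Cout x (ho*wo*N)
  z <- array(z, c(kd[4], ho, wo, d[4]))
  list(z = aperm(z, c(2, 3, 1, 4)), cols = cols)
}

# dz: gradient w.r.t. the pre-activation output (Ho, Wo, Cout, N).
# Returns gradients for input, kernels and biases. `cols` is the patch matrix
# cached by conv_forward (recomputed from x when NULL).
conv_backward <- function(dz, x_dim, w, stride = 2L, cols = NULL, x = NULL,
                          need_dx = TRUE) {
  kd <- dim(w)
  dd <- dim(dz)
  dzm <- matrix(aperm(dz, c(3, 1, 2, 4)), nrow = kd[4])
  if (is.null(cols)) {
    cols <- im2col_cpp(x, x_dim[1], x_dim[2], x_dim[3], x_dim[4],
                       kd[1], kd[2], stride)
  }
  dw <- array(tcrossprod(cols, dzm), kd)
  db <- rowSums(dzm)
  dx <- NULL
  if (need_dx) {
    wm <- matrix(w, nrow = kd[1] * kd[2] * kd[3])
    dcols <- wm %*% dzm
    dx <- col2im_cpp(dcols, x_dim[1], x_dim[2], x_dim[3], x_dim[4],
                     kd[1], kd[2], stride)
  }
  list(dx = dx, dw = dw, db = db)
}

# Input gradient only (used by guided backpropagation).
conv_backward_input <- function(dz, x_dim, w, stride = 2L) {
  kd <- dim(w)
  dzm <- matrix(aperm(dz, c(3, 1, 2, 4)), nrow = kd[4])
  wm <- matrix(w, nrow = kd[1] * kd[2] * kd[3])
  col2im_cpp(wm %*% dzm, x_dim[1], x_dim[2], x_dim[3], x_dim[4],
             kd[1], kd[2], stride)
}
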