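# RNG scoping: every stochastic operation takes an explicit seed and
# restores the caller's RNG state on exit, so pipelines are reproducible
# end to end and seeds never leak between stages.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# derive a stream of child seeds from one master seed (kept < 2^31)
child_seeds <- function(seed, n) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max - 1L, n)
}

# separable 3-D Gaussian convolution along each axis.
# `sigma_vox` is the kernel sd per axis in voxels; sigma 0 = identity.
# Returns the convolution matrices (one per axis) so callers can reuse or
# square them. Kernel is truncated at 3 sd and NOT normalized here.
gaussian_axis_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k
}

# dense n x n convolution matrix for a 1-D kernel with zero padding
conv_matrix <- function(n, kernel) {
  if (length(kernel) == 1L) return(diag(kernel, n))
  h <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- (i - h):(i + h)
    ok <- js >= 1 & js <= n
    K[i, js[ok]] <- kernel[ok]
  }
  K
}

# apply axis convolution matrices (list of 3) to a stack of volumes held as
# a [nx*ny*nz, m] matrix; returns same layout
smooth_stack <- function(X, shape, Ks) {
  m <- ncol(X)
  A <- array(X, dim = c(shape, m))
  # axis 1
  A <- array(Ks[[1]] %*% matrix(A, shape[1]), dim = c(shape, m))
  # axis 2
  A <- aperm(A, c(2, 1, 3, 4))
  A <- array(Ks[[2]] %*% matrix(A, shape[2]), dim = c(shape[2], shape[1], shape[3], m))
  A <- aperm(A, c(2, 1, 3, 4))
  # axis 3
  A <- aperm(A, c(3, 2, 1, 4))
  A <- array(Ks[[3]] %*% matrix(A, shape[3]), dim = c(shape[3], shape[2], shape[1], m))
  A <- aperm(A, c(3, 2, 1, 4))
  matrix(A, prod(shape), m)
}
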