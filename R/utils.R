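# Internal geometry, spectral-basis and labelling helpers shared across stages.

# All voxel coordinates of a 3D grid, as an n x 3 integer matrix in array order.
grid_coords <- function(dim) {
  arrayInd(seq_len(prod(dim)), .dim = dim)
}

# Relative neighbour offsets for 6/18/26-connectivity in 3D.
neighbor_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be 6, 18 or 26.")
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = d == 1,
    "18" = d >= 1 & d <= 2,
    "26" = d >= 1
  )
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array. Returns an integer array,
# 0 for background. Breadth-first flood fill over precomputed offsets; grids in
# this package are small enough that pure R is adequate.
label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  labels <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  off <- neighbor_offsets(connectivity)
  coords <- arrayInd(idx, .dim = dims)
  inmask <- array(FALSE, dims)
  inmask[idx] <- TRUE
  current <- 0L
  for (s in seq_along(idx)) {
    if (labels[idx[s]] != 0L) next
    current <- current + 1L
    queue <- matrix(coords[s, ], nrow = 1)
    labels[idx[s]] <- current
    while (nrow(queue) > 0L) {
      frontier <- matrix(0L, nrow = nrow(queue) * nrow(off), ncol = 3)
      k <- 0L
      for (q in seq_len(nrow(queue))) {
        nb <- sweep(off, 2, queue[q, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
              nb[, 2] >= 1 & nb[, 2] <= dims[2] &
              nb[, 3] >= 1 & nb[, 3] <= dims[3]
        nb <- nb[ok, , drop = FALSE]
        if (nrow(nb) == 0L) next
        lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
        new <- inmask[lin] & labels[lin] == 0L
        if (any(new)) {
          labels[lin[new]] <- current
          take <- nb[new, , drop = FALSE]
          frontier[k + seq_len(nrow(take)), ] <- take
          k <- k + nrow(take)
        }
      }
      queue <- frontier[seq_len(k), , drop = FALSE]
    }
  }
  labels
}

# Real Fourier design for a length-n series sampled every tr_s seconds.
# Returns the basis matrix (n x n, orthogonal columns) and the frequency (Hz)
# attached to each column. Column 1 is the constant; for even n the final
# column is the Nyquist cosine.
fourier_design <- function(n, tr_s) {
  t <- seq_len(n) - 1
  kmax <- floor(n / 2)
  cols <- list(rep(1, n))
  freq <- 0
  for (k in seq_len(kmax)) {
    w <- 2 * pi * k * t / n
    cols[[length(cols) + 1L]] <- cos(w)
    freq <- c(freq, k / (n * tr_s))
    if (!(n %% 2 == 0 && k == kmax)) {
      cols[[length(cols) + 1L]] <- sin(w)
      freq <- c(freq, k / (n * tr_s))
    }
  }
  basis <- do.call(cbind, cols)
  attr(basis, "freq_hz") <- freq
  basis
}

# Band-limited unit-variance latent signal: random weights on the in-band
# Fourier columns. Frequencies strictly inside (band[1], band[2]).
band_limited_signal <- function(n, tr_s, band = c(0.01, 0.08)) {
  basis <- fourier_design(n, tr_s)
  f <- attr(basis, "freq_hz")
  keep <- f > band[1] & f < band[2]
  if (!any(keep)) abort("No Fourier frequencies fall inside the requested band.")
  s <- as.vector(basis[, keep, drop = FALSE] %*% rnorm(sum(keep)))
  s <- s - mean(s)
  s / sd(s)
}

# Derive a reproducible 32-bit sub-seed from a master seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

compact_num <- function(x) format(x, trim = TRUE, scientific = FALSE)
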