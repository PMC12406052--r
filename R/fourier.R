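## Fourier conventions shared by the whole package:
##  * voxel coordinates are centred integers, x in {-floor(Nx/2), ...};
##  * k-space coordinates are normalised cycles/FOV in [-0.5, 0.5);
##  * forward kernel exp(-2*pi*i k.r), no normalisation (so Parseval reads
##    sum|Y|^2 = M * sum|x|^2 on a full Cartesian grid);
##  * adjoint uses the conjugate kernel, inverse = adjoint / M.

#' Circularly shift a vector
#' @keywords internal
circshift <- function(v, s) {
  n <- length(v)
  if (n == 0) return(v)
  s <- ((s %% n) + n) %% n
  if (s == 0) v else c(v[(n - s + 1):n], v[1:(n - s)])
}

#' Apply fftshift/ifftshift along every dimension of a 3D array
#' @keywords internal
shift3 <- function(x, inverse = FALSE) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    c <- if (inverse) ceiling(n / 2) else floor(n / 2)
    circshift(seq_len(n), c)
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Centred 3D DFT (forward, unnormalised)
#'
#' Computes `Y[j] = sum_x f[x] exp(-2 pi i j.x / N)` with both voxel and
#' frequency indices centred (k-space centre at array position
#' `floor(N/2)+1` along each axis).
#'
#' @param x complex (or numeric) 3D array
#' @return complex 3D array of the same shape
#' @export
fft3_centered <- function(x) {
  shift3(fft(shift3(x, inverse = TRUE)), inverse = FALSE)
}

#' Centred 3D inverse DFT (normalised by the grid size)
#'
#' Exact inverse of [fft3_centered()].
#'
#' @param y complex 3D array
#' @return complex 3D array
#' @export
ifft3_centered <- function(y) {
  shift3(fft(shift3(y, inverse = TRUE), inverse = TRUE),
         inverse = FALSE) / length(y)
}

#' Map normalised k coordinates to grid indices, when on-grid
#'
#' @param K N x 3 matrix of normalised coordinates
#' @param dims grid dimensions
#' @param tol on-grid tolerance in grid units
#' @return integer N x 3 matrix of 1-based array indices, or NULL if any
#'   coordinate is off-grid
#' @keywords internal
grid_indices <- function(K, dims, tol = 1e-6) {
  P <- matrix(0L, nrow(K), 3)
  for (ax in 1:3) {
    u <- K[, ax] * dims[ax]
    r <- round(u)
    if (any(abs(u - r) > tol)) return(NULL)
    p <- as.integer(r) + dims[ax] %/% 2 + 1L
    if (any(p < 1L | p > dims[ax])) return(NULL)
    P[, ax] <- p
  }
  P
}

#' Centred DFT along the third (z) axis only
#' @keywords internal
fftz_centered <- function(x, inverse = FALSE) {
  d <- dim(x)
  zshift <- function(a, inv) {
    idx <- circshift(seq_len(d[3]), if (inv) ceiling(d[3] / 2)
                     else floor(d[3] / 2))
    a[, , idx, drop = FALSE]
  }
  a <- aperm(zshift(x, TRUE), c(3, 1, 2))
  dim(a) <- c(d[3], d[1] * d[2])
  Fz <- mvfft(a, inverse = inverse)
  if (inverse) Fz <- Fz / d[3]
  dim(Fz) <- c(d[3], d[1], d[2])
  zshift(aperm(Fz, c(2, 3, 1)), FALSE)
}

#' On-grid kz plane index of a constant-kz sample block, or NA
#' @keywords internal
stacked_plane <- function(K, nz, tol = 1e-9) {
  kz <- K[, 3]
  if (diff(range(kz)) > tol) return(NA_integer_)
  u <- kz[1] * nz
  r <- round(u)
  if (abs(u - r) > 1e-6) return(NA_integer_)
  p <- as.integer(r) + nz %/% 2 + 1L
  if (p < 1L || p > nz) return(NA_integer_)
  p
}

#' Evaluate the forward Fourier transform of an image at k locations
#'
#' Three exact paths, chosen automatically: Cartesian-on-grid locations via
#' the FFT; stacked readouts (constant on-grid kz, off-grid in-plane) via a
#' z-axis FFT followed by a 2D non-uniform DFT of the selected plane; fully
#' non-Cartesian locations via the 3D non-uniform DFT kernel. All paths
#' agree to numerical precision (see the adjoint/dot-product tests).
#'
#' @param img complex 3D array
#' @param K N x 3 matrix of normalised k coordinates
#' @param F_img optional precomputed [fft3_centered()] of `img` (used by the
#'   engines to amortise the FFT over many shots)
#' @return complex vector of N samples
#' @export
fourier_points <- function(img, K, F_img = NULL) {
  dims <- dim(img)
  P <- grid_indices(K, dims)
  if (!is.null(P)) {
    if (is.null(F_img)) F_img <- fft3_centered(img)
    return(F_img[P])
  }
  pz <- stacked_plane(K, dims[3])
  if (!is.na(pz)) {
    plane <- fftz_centered(img + 0i)[, , pz]
    return(ndft_forward_cpp(as.complex(plane),
                            as.integer(c(dims[1], dims[2], 1L)),
                            K[, 1], K[, 2], rep(0, nrow(K))))
  }
  ndft_forward_cpp(as.complex(img), as.integer(dims),
                   K[, 1], K[, 2], K[, 3])
}

#' Adjoint of [fourier_points()]
#'
#' Conjugate-kernel accumulation of samples back onto the grid. On-grid
#' samples are scattered (duplicates accumulate) and passed through the
#' inverse FFT scaled by the grid size; off-grid samples use the exact
#' adjoint non-uniform DFT.
#'
#' @param samples complex vector of N samples
#' @param K N x 3 matrix of normalised k coordinates
#' @param dims grid dimensions
#' @return complex 3D array
#' @export
adjoint_points <- function(samples, K, dims) {
  dims <- as.integer(dims)
  P <- grid_indices(K, dims)
  if (!is.null(P)) {
    grid <- array(0 + 0i, dim = dims)
    lin <- (P[, 3] - 1L) * dims[1] * dims[2] + (P[, 2] - 1L) * dims[1] + P[, 1]
    if (anyDuplicated(lin)) {
      # accumulate duplicates deterministically
      agg <- rowsum(cbind(Re(samples), Im(samples)), lin)
      grid[as.integer(rownames(agg))] <-
        complex(real = agg[, 1], imaginary = agg[, 2])
    } else {
      grid[lin] <- samples
    }
    return(ifft3_centered(grid) * prod(dims))
  }
  pz <- stacked_plane(K, dims[3])
  if (!is.na(pz)) {
    a2 <- ndft_adjoint_cpp(as.complex(samples),
                           as.integer(c(dims[1], dims[2], 1L)),
                           K[, 1], K[, 2], rep(0, length(samples)))
    zg <- (0:(dims[3] - 1)) - dims[3] %/% 2
    phase <- exp(2i * pi * K[1, 3] * zg)
    out <- array(0i, dim = dims)
    for (z in seq_len(dims[3]))
      out[, , z] <- array(a2, dim = dims[1:2]) * phase[z]
    return(out)
  }
  out <- ndft_adjoint_cpp(as.complex(samples), dims, K[, 1], K[, 2], K[, 3])
  array(out, dim = dims)
}

#' Stack all sample coordinates of a pattern
#' @keywords internal
pattern_coords <- function(pattern) {
  do.call(rbind, lapply(pattern$shots, function(s) s$samples))
}

#' Forward transform of an image at all sample locations of a pattern
#'
#' Same semantics as calling [fourier_points()] shot by shot, but the
#' per-image FFT work (full 3D FFT on Cartesian patterns, z-axis FFT on
#' stacked ones) is done once for the whole pattern.
#'
#' @keywords internal
pattern_forward <- function(x, pattern) {
  dims <- dim(x)
  K <- pattern_coords(pattern)
  P <- grid_indices(K, dims)
  if (!is.null(P)) {
    return(fft3_centered(x)[P])
  }
  Fz <- NULL
  out <- vector("list", length(pattern$shots))
  for (i in seq_along(pattern$shots)) {
    Ks <- pattern$shots[[i]]$samples
    pz <- stacked_plane(Ks, dims[3])
    if (!is.na(pz)) {
      if (is.null(Fz)) Fz <- fftz_centered(x + 0i)
      out[[i]] <- ndft_forward_cpp(as.complex(Fz[, , pz]),
                                   as.integer(c(dims[1], dims[2], 1L)),
                                   Ks[, 1], Ks[, 2], rep(0, nrow(Ks)))
    } else {
      out[[i]] <- ndft_forward_cpp(as.complex(x), as.integer(dims),
                                   Ks[, 1], Ks[, 2], Ks[, 3])
    }
  }
  unlist(out)
}

#' Adjoint of [pattern_forward()]
#' @keywords internal
pattern_adjoint <- function(samples, pattern, dims) {
  dims <- as.integer(dims)
  K <- pattern_coords(pattern)
  P <- grid_indices(K, dims)
  if (!is.null(P)) {
    return(adjoint_points(samples, K, dims))
  }
  nper <- vapply(pattern$shots, function(s) nrow(s$samples), integer(1))
  ends <- cumsum(nper)
  starts <- c(1L, head(ends, -1) + 1L)
  G <- array(0i, dim = dims)
  extra <- NULL
  stacked <- FALSE
  for (i in seq_along(pattern$shots)) {
    Ks <- pattern$shots[[i]]$samples
    ys <- samples[starts[i]:ends[i]]
    pz <- stacked_plane(Ks, dims[3])
    if (!is.na(pz)) {
      a2 <- ndft_adjoint_cpp(as.complex(ys),
                             as.integer(c(dims[1], dims[2], 1L)),
                             Ks[, 1], Ks[, 2], rep(0, length(ys)))
      G[, , pz] <- G[, , pz] + array(a2, dim = dims[1:2])
      stacked <- TRUE
    } else {
      a3 <- adjoint_points(ys, Ks, dims)
      extra <- if (is.null(extra)) a3 else extra + a3
    }
  }
  out <- if (stacked) fftz_centered(G, inverse = TRUE) * dims[3]
  else array(0i, dim = dims)
  if (!is.null(extra)) out <- out + extra
  out
}

#' Brute-force discrete Fourier oracle
#'
#' Direct double-sum evaluation of `sum_r f[r] exp(-2 pi i k.r)` used as an
#' independent reference for the engines and the FFT/NUFFT paths. O(N*M) in
#' R; meant for tiny grids only.
#'
#' @param img complex 3D array
#' @param K N x 3 matrix of normalised k coordinates
#' @return complex vector
#' @export
dft_oracle <- function(img, K) {
  dims <- dim(img)
  g <- centered_grids(dims)
  X <- array(rep(g$x, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(g$y, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(g$z, each = dims[1] * dims[2]), dim = dims)
  vapply(seq_len(nrow(K)), function(n) {
    ph <- exp(-2i * pi * (K[n, 1] * X + K[n, 2] * Y + K[n, 3] * Z))
    sum(img * ph)
  }, complex(1))
}
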