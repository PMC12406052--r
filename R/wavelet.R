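## Orthogonal periodized 3D discrete wavelet transform.
##
## The CS reconstruction needs an orthogonal sparsifying transform (the
## proximal step assumes Psi* Psi = I). This file implements the standard
## periodized orthonormal filter-bank DWT; periodization keeps the
## transform exactly orthogonal on any even-length axis (the even-shift
## orthonormality of the filters survives wrap-around), which the test
## suite verifies numerically.

# Orthonormal low-pass decomposition filters (standard published
# Daubechies/Symlet coefficients). High-pass is the quadrature mirror
# g[n] = (-1)^n h[L-1-n].
WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481,
           0.03169508781149298, 0.007607487324917605,
           -0.1432942383508097, -0.061273359067658524,
           0.4813596512583722, 0.7771857517005235,
           0.3644418948353314, -0.05194583810770904,
           -0.027219029917056003, 0.049137179673607506,
           0.003808752013890615, -0.01495225833704823,
           -0.0003029205147213668, 0.0018899503327594609)
)

#' Wavelet transform specification
#'
#' @param family one of `"sym8"` (default), `"db4"`, `"haar"`
#' @param levels decomposition depth; every image dimension must be
#'   divisible by `2^levels`
#' @return an object of class `ksim_wavelet`
#' @export
wavelet_spec <- function(family = "sym8", levels = 3L) {
  if (!family %in% names(WAVELET_FILTERS))
    stop("unknown wavelet family: ", family)
  h <- WAVELET_FILTERS[[family]]
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  structure(list(family = family, levels = as.integer(levels), h = h, g = g),
            class = "ksim_wavelet")
}

## The one-axis analysis operator is materialised as a dense orthogonal
## n x n matrix (rows: even shifts of the periodized low/high-pass
## filters); axis transforms are then single BLAS multiplies. Matrices are
## cached per (n, family).
.wavelet_mat_cache <- new.env(parent = emptyenv())

#' Periodized analysis matrix for axis length n
#' @keywords internal
wavelet_matrix <- function(n, h, g, family) {
  key <- paste0(family, ":", n)
  W <- .wavelet_mat_cache[[key]]
  if (!is.null(W)) return(W)
  if (n %% 2 != 0) stop("axis length must be even for the periodized DWT")
  half <- n / 2
  W <- matrix(0, n, n)
  for (k in seq_len(half)) {
    for (j in seq_along(h)) {
      col <- ((2 * (k - 1) + j - 1) %% n) + 1
      W[k, col] <- W[k, col] + h[j]
      W[half + k, col] <- W[half + k, col] + g[j]
    }
  }
  .wavelet_mat_cache[[key]] <- W
  W
}

#' One analysis step along a given axis (periodized)
#' @keywords internal
dwt_axis <- function(x, h, g, axis, family = "w") {
  d <- dim(x)
  n <- d[axis]
  W <- wavelet_matrix(n, h, g, family)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(x, perm)
  dim(ap) <- c(n, prod(d[-axis]))
  Y <- W %*% ap
  half <- n / 2
  lo <- Y[seq_len(half), , drop = FALSE]
  hi <- Y[half + seq_len(half), , drop = FALSE]
  dim(lo) <- c(half, d[-axis]); dim(hi) <- c(half, d[-axis])
  inv <- order(perm)
  list(lo = aperm(lo, inv), hi = aperm(hi, inv))
}

#' One synthesis step along a given axis (transpose of [dwt_axis()])
#' @keywords internal
idwt_axis <- function(lo, hi, h, g, axis, family = "w") {
  d <- dim(lo)
  half <- d[axis]
  n <- 2 * half
  W <- wavelet_matrix(n, h, g, family)
  perm <- c(axis, setdiff(1:3, axis))
  al <- aperm(lo, perm); dim(al) <- c(half, prod(d[-axis]))
  ah <- aperm(hi, perm); dim(ah) <- c(half, prod(d[-axis]))
  out <- crossprod(W, rbind(al, ah))
  dim(out) <- c(n, d[-axis])
  aperm(out, order(perm))
}

#' Forward 3D wavelet transform
#'
#' Multi-level separable periodized DWT. Detail blocks per level are named
#' by their per-axis band ("d" = detail) in x, y, z order; e.g. `daa` is
#' detail along x, approximation along y and z.
#'
#' @param x real or complex 3D array
#' @param spec a [wavelet_spec()]
#' @return an object of class `ksim_wt` (fields `approx`, `details` — a
#'   list per level of 7 named blocks —, `spec`, `shape`)
#' @export
dwt3 <- function(x, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "ksim_wavelet"))
  d <- dim(x)
  if (any(d %% 2^spec$levels != 0))
    stop("image dimensions must be divisible by 2^levels")
  details <- vector("list", spec$levels)
  a <- x
  for (lev in seq_len(spec$levels)) {
    s1 <- dwt_axis(a, spec$h, spec$g, 1, spec$family)
    s2l <- dwt_axis(s1$lo, spec$h, spec$g, 2, spec$family)
    s2h <- dwt_axis(s1$hi, spec$h, spec$g, 2, spec$family)
    blocks <- list(
      aa = s2l$lo, da = s2h$lo, ad = s2l$hi, dd = s2h$hi)
    out <- list()
    for (nm in names(blocks)) {
      s3 <- dwt_axis(blocks[[nm]], spec$h, spec$g, 3, spec$family)
      out[[paste0(nm, "a")]] <- s3$lo
      out[[paste0(nm, "d")]] <- s3$hi
    }
    a <- out$aaa
    out$aaa <- NULL
    details[[lev]] <- out
  }
  structure(list(approx = a, details = details, spec = spec, shape = d),
            class = "ksim_wt")
}

#' Inverse 3D wavelet transform
#'
#' Exact inverse (= adjoint) of [dwt3()].
#'
#' @param wt a `ksim_wt`
#' @return 3D array of the original shape
#' @export
idwt3 <- function(wt) {
  stopifnot(inherits(wt, "ksim_wt"))
  spec <- wt$spec
  a <- wt$approx
  for (lev in rev(seq_len(spec$levels))) {
    dd <- wt$details[[lev]]
    up <- function(lo, hi) idwt_axis(lo, hi, spec$h, spec$g, 3, spec$family)
    aa <- up(a, dd$aad); da <- up(dd$daa, dd$dad)
    ad <- up(dd$ada, dd$add); ddb <- up(dd$dda, dd$ddd)
    lo <- idwt_axis(aa, ad, spec$h, spec$g, 2, spec$family)
    hi <- idwt_axis(da, ddb, spec$h, spec$g, 2, spec$family)
    a <- idwt_axis(lo, hi, spec$h, spec$g, 1, spec$family)
  }
  a
}

#' All detail coefficients as one vector
#' @param wt a `ksim_wt`
#' @return vector (complex if the input was complex)
#' @export
wt_detail_vec <- function(wt) {
  unlist(lapply(wt$details, function(lv) lapply(lv, as.vector)),
         use.names = FALSE)
}

#' Finest-scale detail coefficients (level 1)
#' @param wt a `ksim_wt`
#' @return vector
#' @export
wt_finest_details <- function(wt) {
  unlist(lapply(wt$details[[1]], as.vector), use.names = FALSE)
}

#' Soft-threshold the detail coefficients
#'
#' Complex magnitude soft-thresholding `c * max(0, 1 - thr/|c|)` applied to
#' every detail block; the approximation band is left untouched (the l1
#' prior models detail sparsity; shrinking the coarse band would bias the
#' overall intensity scale).
#'
#' @param wt a `ksim_wt`
#' @param thr threshold, >= 0
#' @return a `ksim_wt`
#' @export
wt_soft_threshold <- function(wt, thr) {
  if (thr <= 0) return(wt)
  wt$details <- lapply(wt$details, function(lv)
    lapply(lv, function(b) {
      m <- Mod(b)
      f <- ifelse(m > thr, 1 - thr / m, 0)
      b * f
    }))
  wt
}

#' l1 norm of the detail coefficients
#' @param wt a `ksim_wt`
#' @return scalar
#' @export
wt_l1 <- function(wt) sum(Mod(wt_detail_vec(wt)))
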