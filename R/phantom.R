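#' Per-tissue MR parameters
#'
#' A tissue class is described by its proton density and relaxation times;
#' these enter the steady-state gradient-recalled-echo (GRE) signal equation
#' (see [gre_contrast()]) and the per-tissue T2* decay applied during each
#' readout.
#'
#' @param name tissue label (e.g. `"GM"`)
#' @param rho proton density, arbitrary units, >= 0
#' @param T1 longitudinal relaxation time in ms, > 0
#' @param T2s effective transverse relaxation time T2* in ms, > 0
#'   (`Inf` is allowed and means "no decay")
#' @return an object of class `ksim_tissue`
#' @export
tissue_params <- function(name, rho, T1, T2s) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0)
    stop("rho must be a single non-negative number")
  if (!is.numeric(T1) || length(T1) != 1 || T1 <= 0)
    stop("T1 must be strictly positive (ms)")
  if (!is.numeric(T2s) || length(T2s) != 1 || T2s <= 0)
    stop("T2s must be strictly positive (ms)")
  structure(list(name = as.character(name), rho = rho, T1 = T1, T2s = T2s),
            class = "ksim_tissue")
}

#' Default 7T-like tissue parameters
#'
#' White matter, gray matter and cerebrospinal fluid with proton densities
#' and relaxation times typical of 7T brain imaging. These are configuration
#' values, not constants of the model: pass your own list of
#' [tissue_params()] anywhere a tissue set is accepted.
#'
#' @return a named list of `ksim_tissue` objects (WM, GM, CSF)
#' @export
default_tissues <- function() {
  list(
    WM  = tissue_params("WM",  rho = 0.77, T1 = 1330, T2s = 26),
    GM  = tissue_params("GM",  rho = 0.86, T1 = 2000, T2s = 33),
    CSF = tissue_params("CSF", rho = 1.00, T1 = 4000, T2s = 100)
  )
}

#' Steady-state GRE contrast of one tissue
#'
#' Signal of a spoiled gradient-recalled-echo sequence at steady state:
#' \deqn{\mu = \rho \sin\alpha \frac{1 - e^{-TR/T1}}{1 - \cos\alpha\, e^{-TR/T1}} e^{-TE/T2^*}}
#' The flip angle maximising this expression for given TR/T1 is the Ernst
#' angle \eqn{\cos\alpha = e^{-TR/T1}}.
#'
#' @param tissue a [tissue_params()] object
#' @param TR repetition time (ms), > 0
#' @param TE echo time (ms), >= 0
#' @param FA flip angle alpha in degrees, in [0, 90]
#' @return the scalar contrast value
#' @export
gre_contrast <- function(tissue, TR, TE, FA) {
  stopifnot(inherits(tissue, "ksim_tissue"))
  if (!is.finite(TR) || TR <= 0) stop("TR must be > 0")
  if (!is.numeric(TE) || TE < 0) stop("TE must be >= 0")
  if (!is.numeric(FA) || FA < 0 || FA > 90) stop("FA must be in [0, 90] degrees")
  if (tissue$T1 <= 0 || tissue$T2s <= 0) stop("invalid tissue relaxation times")
  a <- FA * pi / 180
  e1 <- exp(-TR / tissue$T1)
  dec <- if (is.infinite(tissue$T2s)) 1 else exp(-TE / tissue$T2s)
  tissue$rho * sin(a) * (1 - e1) / (1 - cos(a) * e1) * dec
}

## --- internal helpers -----------------------------------------------------

#' Separable Gaussian smoothing of a 3D field (FFT-based, circular)
#' @keywords internal
gaussian_smooth3 <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  dims <- dim(vol)
  tf <- lapply(dims, function(n) {
    x <- 0:(n - 1)
    x <- ifelse(x > n / 2, x - n, x)                # circular offsets
    k <- exp(-x^2 / (2 * sigma_vox^2))
    k <- k / sum(k)
    Re(fft(k))  # symmetric kernel -> real transfer function
  })
  G <- outer(outer(tf[[1]], tf[[2]]), tf[[3]])
  dim(G) <- dims
  Re(fft(fft(vol) * G, inverse = TRUE)) / prod(dims)
}

#' Centered voxel coordinate grids (integer offsets from volume centre)
#' @keywords internal
centered_grids <- function(shape) {
  list(
    x = (0:(shape[1] - 1)) - shape[1] %/% 2,
    y = (0:(shape[2] - 1)) - shape[2] %/% 2,
    z = (0:(shape[3] - 1)) - shape[3] %/% 2
  )
}

#' Build a synthetic three-tissue brain-like phantom
#'
#' Three nested, smoothed ellipsoidal shells labelled CSF (outer), GM
#' (middle) and WM (inner core), with fuzzy boundaries obtained by Gaussian
#' smoothing of the binary shells and a seeded low-frequency perturbation of
#' the shell radius so the object is not perfectly symmetric. Deterministic
#' given `(shape, seed)`.
#'
#' @param shape integer grid dimensions (Nx, Ny, Nz), each >= 16
#' @param voxel_size voxel edge length(s) in mm (scalar or length 3)
#' @param seed integer seed for the radius perturbation
#' @param tissues named list of [tissue_params()]; must contain WM, GM, CSF
#' @param smooth_vox smoothing kernel width (voxels) realising the fuzzy
#'   segmentation; default 1
#' @return an object of class `ksim_phantom` with fields `shape`,
#'   `voxel_size`, `tissues`, `fractions` (list of 3D arrays in [0,1] summing
#'   to <= 1 voxel-wise) and `affine`
#' @export
make_synthetic_phantom <- function(shape, voxel_size = 3, seed = 1,
                                   tissues = default_tissues(),
                                   smooth_vox = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("shape must have 3 dimensions, each >= 16")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (!all(c("WM", "GM", "CSF") %in% names(tissues)))
    stop("tissues must be a named list containing WM, GM and CSF")

  g <- centered_grids(shape)
  # normalised ellipsoidal radius: 1 at the head boundary
  ax <- (shape / 2) * c(0.90, 0.95, 0.85)
  R <- sqrt(outer(outer((g$x / ax[1])^2, (g$y / ax[2])^2, "+"),
                  (g$z / ax[3])^2, "+"))
  dim(R) <- shape

  # seeded smooth perturbation of the radius (brain-like asymmetry)
  pert <- with_seed(mix_seed(seed, 7L), {
    p <- array(rnorm(prod(shape)), dim = shape)
    gaussian_smooth3(p, sigma_vox = max(shape) / 8)
  })
  pert <- 0.06 * pert / max(abs(pert))
  R <- R + pert

  wm  <- (R < 0.62) * 1
  gm  <- (R >= 0.62 & R < 0.82) * 1
  csf <- (R >= 0.82 & R < 1.00) * 1

  fr <- lapply(list(WM = wm, GM = gm, CSF = csf), gaussian_smooth3,
               sigma_vox = smooth_vox)
  fr <- lapply(fr, function(w) pmin(pmax(w, 0), 1))
  tot <- fr$WM + fr$GM + fr$CSF
  excess <- pmax(tot, 1)
  fr <- lapply(fr, function(w) w / excess)

  affine <- rbind(cbind(diag(voxel_size),
                        -voxel_size * (shape %/% 2)),
                  c(0, 0, 0, 1))
  structure(list(shape = shape, voxel_size = voxel_size,
                 tissues = tissues[c("WM", "GM", "CSF")],
                 fractions = fr, affine = affine),
            class = "ksim_phantom")
}

#' @export
print.ksim_phantom <- function(x, ...) {
  cat(sprintf("ksim phantom: %dx%dx%d voxels @ %s mm, %d tissues (%s)\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$voxel_size, 3), collapse = "x"),
              length(x$tissues), paste(names(x$tissues), collapse = ", ")))
  invisible(x)
}

#' Validate phantom invariants
#' @keywords internal
validate_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "ksim_phantom"))
  for (w in phantom$fractions) {
    if (!identical(dim(w), as.integer(phantom$shape)))
      stop("fraction field shape mismatch")
    if (any(w < -1e-12) || any(w > 1 + 1e-12))
      stop("fraction field outside [0, 1]")
  }
  tot <- Reduce(`+`, phantom$fractions)
  if (any(tot > 1 + 1e-9)) stop("tissue fractions sum above 1")
  invisible(TRUE)
}

#' Head support mask
#'
#' Voxels containing any tissue (total fraction above `threshold`).
#'
#' @param phantom a `ksim_phantom`
#' @param threshold minimal total tissue fraction; default 1e-3
#' @return logical 3D array
#' @export
head_mask <- function(phantom, threshold = 1e-3) {
  Reduce(`+`, phantom$fractions) > threshold
}

#' Steady-state contrast volume of a phantom
#'
#' Voxel-wise mixture of the per-tissue GRE contrasts:
#' \eqn{\mu(r) = \sum_i w_i(r)\,\mu_i}, the "state of the object" at the
#' reference time `tref = TE`. Linear in the fraction fields.
#'
#' @inheritParams gre_contrast
#' @param phantom a `ksim_phantom`
#' @return an object of class `ksim_contrast` with fields `values` (3D
#'   array), `tref` (ms) and `sequence`
#' @export
contrast_volume <- function(phantom, TR, TE, FA) {
  validate_phantom(phantom)
  mu <- vapply(phantom$tissues, gre_contrast, numeric(1),
               TR = TR, TE = TE, FA = FA)
  vol <- array(0, dim = phantom$shape)
  for (i in seq_along(phantom$tissues))
    vol <- vol + phantom$fractions[[i]] * mu[i]
  structure(list(values = vol, tref = TE,
                 sequence = list(TR = TR, TE = TE, FA = FA)),
            class = "ksim_contrast")
}

#' Analytic ring-of-receivers coil sensitivity profiles
#'
#' Smooth complex coil sensitivity maps for `L` receivers placed at
#' equi-angular positions on a ring around the volume in the x-y plane. The
#' magnitude of each map peaks near its receiver and decays smoothly away
#' from it; the phase varies linearly across the volume (distinct direction
#' per coil). A small uniform floor keeps the root-sum-of-squares strictly
#' positive everywhere. `L = 1` returns the constant field 1 (single-coil
#' convention).
#'
#' @param phantom a `ksim_phantom`
#' @param L number of receive coils, >= 1
#' @param covariance optional L x L Hermitian positive semi-definite coil
#'   noise covariance; defaults to the identity
#' @return an object of class `ksim_coils` with fields `L`, `maps` (list of
#'   L complex 3D arrays) and `covariance`
#' @export
make_coil_profiles <- function(phantom, L, covariance = NULL) {
  stopifnot(inherits(phantom, "ksim_phantom"))
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1")
  if (is.null(covariance)) covariance <- diag(L)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == c(L, L)))
    stop("covariance must be L x L")
  if (max(Mod(covariance - Conj(t(covariance)))) > 1e-10)
    stop("covariance must be Hermitian")
  ev <- eigen(covariance, only.values = TRUE)$values
  if (min(Re(ev)) < -1e-10 * max(abs(ev), 1))
    stop("covariance must be positive semi-definite")

  shape <- phantom$shape
  if (L == 1) {
    maps <- list(array(1 + 0i, dim = shape))
  } else {
    g <- centered_grids(shape)
    X <- array(rep(g$x, times = shape[2] * shape[3]), dim = shape)
    Y <- array(rep(rep(g$y, each = shape[1]), times = shape[3]), dim = shape)
    rad <- 0.65 * max(shape[1:2])
    sig <- 0.55 * max(shape[1:2])
    maps <- vector("list", L)
    for (l in seq_len(L)) {
      phi <- 2 * pi * (l - 1) / L
      cx <- rad * cos(phi); cy <- rad * sin(phi)
      d2 <- (X - cx)^2 + (Y - cy)^2
      mag <- 0.1 + exp(-d2 / (2 * sig^2))
      # smooth linear phase, direction tied to the coil position
      ph <- 0.5 * pi * (X * cos(phi) + Y * sin(phi)) / max(shape[1:2]) + phi
      maps[[l]] <- mag * exp(1i * ph)
    }
  }
  structure(list(L = L, maps = maps, covariance = covariance),
            class = "ksim_coils")
}

#' Define the activation region of interest
#'
#' The ROI is the set of voxels whose gray-matter fraction reaches
#' `gm_threshold` and whose centre lies inside the given ellipsoid (centre
#' and semi-axes in mm, in the phantom's scanner frame where the grid centre
#' is the origin). This mimics a fuzzy gray-matter segmentation intersected
#' with an ellipse placed over a cortical area.
#'
#' @param phantom a `ksim_phantom`
#' @param center ellipsoid centre, mm (length 3)
#' @param semiaxes ellipsoid semi-axes, mm (length 3), all > 0
#' @param gm_threshold minimal gray-matter fraction; default 0.5
#' @return an object of class `ksim_roi` with fields `mask` (logical 3D
#'   array) and `n_active`
#' @export
define_roi <- function(phantom, center, semiaxes, gm_threshold = 0.5) {
  stopifnot(inherits(phantom, "ksim_phantom"))
  if (length(center) != 3 || length(semiaxes) != 3 || any(semiaxes <= 0))
    stop("center and semiaxes must be length-3, semiaxes > 0")
  g <- centered_grids(phantom$shape)
  xs <- g$x * phantom$voxel_size[1]
  ys <- g$y * phantom$voxel_size[2]
  zs <- g$z * phantom$voxel_size[3]
  E <- outer(outer(((xs - center[1]) / semiaxes[1])^2,
                   ((ys - center[2]) / semiaxes[2])^2, "+"),
             ((zs - center[3]) / semiaxes[3])^2, "+")
  dim(E) <- phantom$shape
  inside <- E <= 1
  mask <- inside & (phantom$fractions$GM >= gm_threshold)
  n <- sum(mask)
  if (n == 0) stop("empty ROI: no gray-matter voxel reaches gm_threshold inside the ellipsoid")
  structure(list(mask = mask, n_active = n), class = "ksim_roi")
}

#' Export phantom tissue fractions as NIfTI
#'
#' One float32 file per tissue, named `<prefix>_<tissue>.nii.gz`, with the
#' phantom affine preserved.
#'
#' @param phantom a `ksim_phantom`
#' @param prefix output path prefix
#' @return invisibly, the written file paths
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "ksim_phantom"))
  paths <- character(0)
  for (nm in names(phantom$fractions)) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    w <- phantom$fractions[[nm]]
    attr(w, "pixdim") <- phantom$voxel_size
    RNifti::writeNifti(RNifti::asNifti(w, datatype = "float"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Import phantom tissue fractions from NIfTI files
#'
#' @param files named character vector of NIfTI paths, names are tissue
#'   labels matching `tissues`
#' @param tissues named list of [tissue_params()] for the same labels
#' @return a `ksim_phantom`
#' @export
read_phantom_nifti <- function(files, tissues = default_tissues()) {
  if (is.null(names(files)) || !all(names(files) %in% names(tissues)))
    stop("files must be named with tissue labels present in tissues")
  fr <- lapply(files, function(f) {
    v <- RNifti::readNifti(f)
    # clamp float32 representation jitter back into [0, 1]
    array(pmin(pmax(as.numeric(v), 0), 1), dim = dim(v))
  })
  shape <- dim(fr[[1]])
  if (length(shape) != 3) stop("tissue maps must be 3D")
  for (w in fr) if (!identical(dim(w), shape)) stop("tissue map shapes differ")
  tot <- Reduce(`+`, fr)
  if (max(tot) > 1) fr <- lapply(fr, function(w) w / pmax(tot, 1))
  vox <- RNifti::pixdim(RNifti::readNifti(files[[1]]))[1:3]
  affine <- rbind(cbind(diag(vox), -vox * (shape %/% 2)), c(0, 0, 0, 1))
  ph <- structure(list(shape = as.integer(shape), voxel_size = vox,
                       tissues = tissues[names(files)], fractions = fr,
                       affine = affine),
                  class = "ksim_phantom")
  validate_phantom(ph)
  ph
}
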