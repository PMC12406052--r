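# Shared small fixtures, built once per test session.

fix_env <- new.env(parent = emptyenv())

tiny_phantom <- function() {
  if (is.null(fix_env$ph))
    fix_env$ph <- make_synthetic_phantom(c(16L, 16L, 16L), voxel_size = 3,
                                         seed = 1)
  fix_env$ph
}

tiny_contrast <- function() {
  if (is.null(fix_env$ct))
    fix_env$ct <- contrast_volume(tiny_phantom(), TR = 50, TE = 25, FA = 12)
  fix_env$ct
}

single_coil <- function(phantom = tiny_phantom()) {
  make_coil_profiles(phantom, 1)
}

# uniform single coil on an arbitrary grid (for operator-level tests)
unit_coils <- function(dims) {
  structure(list(L = 1L, maps = list(array(1 + 0i, dim = dims)),
                 covariance = diag(1)),
            class = "ksim_coils")
}

# random complex image
rand_image <- function(dims, seed = 1) {
  set.seed(seed)
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
        dim = dims)
}

# simulate a whole frame with the basic engine
simulate_frame <- function(contrast, coils, pattern, frame_index = 1L) {
  v <- if (inherits(contrast, "ksim_contrast")) contrast$values else contrast
  ys <- lapply(pattern$shots, function(s) simulate_shot_basic(v, coils, s))
  kspace_frame(ys, pattern, frame_index)
}
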