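test_that("phantom energy is a support-mean of squared magnitude", {
  v <- array(0, dim = c(4, 4, 4))
  v[1:2, , ] <- 2
  expect_equal(phantom_energy(v), 4)
  expect_error(phantom_energy(array(0, dim = c(4, 4, 4))), "zero")
  # permutation invariance
  ct <- tiny_contrast()
  e1 <- phantom_energy(ct)
  set.seed(1)
  vp <- array(sample(as.vector(ct$values)), dim = dim(ct$values))
  expect_equal(phantom_energy(vp), e1, tolerance = 1e-12)
  expect_gt(e1, 0)
})

test_that("basic engine matches the brute-force DFT oracle", {
  d <- c(8L, 8L, 8L)
  x <- rand_image(d, seed = 1)
  co <- unit_coils(d)
  set.seed(2)
  K <- matrix(runif(150, -0.5, 0.4999), ncol = 3)
  sh <- make_shot(K, (0:49) * 0.5 - 12.5, grid_shape = d)
  y <- simulate_shot_basic(x, co, sh)
  ref <- dft_oracle(x, K)
  expect_lt(max(Mod(y[1, ] - ref)) / max(Mod(ref)), 1e-6)
  # multi-coil: each row is the transform of the weighted image
  ph <- tiny_phantom()
  co2 <- make_coil_profiles(ph, 2)
  sh2 <- make_shot(K, (0:49) * 0.5 - 12.5, grid_shape = ph$shape)
  ct <- tiny_contrast()
  y2 <- simulate_shot_basic(ct, co2, sh2)
  for (l in 1:2) {
    ref2 <- dft_oracle(co2$maps[[l]] * ct$values, K)
    expect_lt(max(Mod(y2[l, ] - ref2)) / max(Mod(ref2)), 1e-10)
  }
})

test_that("off-resonance interpolators reproduce the phase term", {
  d <- c(8L, 8L, 8L)
  tms <- (0:49) * 0.5 - 12.5
  # zero field: trivial rank-1 exact model
  o0 <- build_off_resonance(array(0, dim = d), tms, P = 1)
  expect_equal(o0$residual, 0)
  expect_true(all(o0$c == 1))
  expect_true(all(o0$b[[1]] == 1))
  # constant field: rank-1 exact with pure phase evolution
  oc <- build_off_resonance(array(20, dim = d), tms, P = 3)
  expect_equal(oc$residual, 0)
  expect_equal(oc$P, 1L)
  expect_equal(as.vector(oc$c), exp(-2i * pi * 20 * tms / 1000),
               tolerance = 1e-12)
  # smooth random map in [-50, 50] Hz over a 25 ms readout, P = 8
  set.seed(5)
  sm <- array(rnorm(prod(d)), dim = d)
  for (i in 1:4) sm <- (sm + aperm(sm, c(2, 3, 1))) / 2
  fm <- 50 * sm / max(abs(sm))
  tms2 <- (0:2499) * 0.01 - 12.5
  o8 <- build_off_resonance(fm, tms2, P = 8)
  expect_lte(o8$residual, 1e-3)
})

test_that("T2* engine reduces to the basic engine and matches brute force", {
  ph <- tiny_phantom()
  ph_inf <- ph
  for (i in seq_along(ph_inf$tissues)) ph_inf$tissues[[i]]$T2s <- Inf
  co <- single_coil()
  sh <- epi_3d(ph$shape, 25)$shots[[5]]
  ct_inf <- contrast_volume(ph_inf, 50, 25, 12)
  y_b <- simulate_shot_basic(ct_inf, co, sh)
  y_t <- simulate_shot_t2s(baseline_state(ph_inf, 50, 25, 12), co, sh)
  expect_lt(max(Mod(y_b - y_t)) / max(Mod(y_b)), 1e-6)
  expect_equal(attr(y_t, "ft_calls"), 3L)  # N_tis * P * L = 3 * 1 * 1

  # single tissue: the decay factor commutes with the transform
  p1 <- ph
  p1$fractions$GM <- array(0, ph$shape); p1$fractions$CSF <- array(0, ph$shape)
  st1 <- baseline_state(p1, 50, 25, 12)
  y1 <- simulate_shot_t2s(st1, co, sh)
  mu_wm <- gre_contrast(ph$tissues$WM, 50, 25, 12)
  yb <- simulate_shot_basic(p1$fractions$WM * mu_wm, co, sh)
  dec <- exp(-sh$times / ph$tissues$WM$T2s)
  expect_equal(y1[1, ], yb[1, ] * dec, tolerance = 1e-10)

  # full extended model vs voxel-sum oracle (two tissues, finite T2*,
  # constant off-resonance handled exactly with P = 1)
  d <- c(8L, 8L, 8L)
  set.seed(3)
  w1 <- array(runif(prod(d)), dim = d)
  w2 <- array(runif(prod(d)), dim = d) * (1 - w1)
  phx <- structure(list(shape = d, voxel_size = c(3, 3, 3),
                        tissues = list(A = tissue_params("A", 1, 1000, 30),
                                       B = tissue_params("B", 0.8, 2000, 80)),
                        fractions = list(A = w1, B = w2), affine = diag(4)),
                   class = "ksim_phantom")
  stx <- baseline_state(phx, 50, 25, 12)
  cox <- structure(list(L = 1L,
                        maps = list(array(exp(1i * runif(prod(d))), dim = d)),
                        covariance = diag(1)), class = "ksim_coils")
  K <- matrix(runif(150, -0.5, 0.4999), ncol = 3)
  tms <- (0:49) * 0.5 - 12.5
  shot <- make_shot(K, tms, grid_shape = d)
  f0 <- 20
  offres <- build_off_resonance(array(f0, dim = d), tms, P = 1)
  y <- simulate_shot_t2s(stx, cox, shot, offres = offres)
  mu <- vapply(phx$tissues, gre_contrast, numeric(1), TR = 50, TE = 25,
               FA = 12)
  ref <- rep(0 + 0i, 50)
  for (n in 1:50) {
    ph_or <- exp(-2i * pi * f0 * tms[n] / 1000)
    acc <- 0 + 0i
    for (i in 1:2) {
      img <- phx$fractions[[i]] * cox$maps[[1]] * ph_or
      acc <- acc + mu[i] * exp(-tms[n] / phx$tissues[[i]]$T2s) *
        dft_oracle(img, K[n, , drop = FALSE])
    }
    ref[n] <- acc
  }
  expect_lt(max(Mod(y[1, ] - ref)) / max(Mod(ref)), 1e-4)
})

test_that("engine is linear in the contrast volume", {
  ph <- tiny_phantom()
  co <- single_coil()
  sh <- epi_3d(ph$shape, 25)$shots[[3]]
  a <- rand_image(ph$shape, seed = 4)
  b <- rand_image(ph$shape, seed = 5)
  ya <- simulate_shot_basic(a, co, sh)
  yb <- simulate_shot_basic(b, co, sh)
  yab <- simulate_shot_basic(a + 2 * b, co, sh)
  expect_equal(yab, ya + 2 * yb, tolerance = 1e-10)
})

test_that("thermal noise is calibrated to energy/snr_in with coil covariance", {
  E <- 0.02
  Sig <- matrix(c(1, 0.5, 0.5, 1), 2)
  ns <- noise_spec(100, E, covariance = Sig, seed = 7)
  y0 <- matrix(0i, 2, 50000)
  yn <- add_noise(y0, ns, 1)
  target <- E / 100
  expect_lt(abs(mean(Mod(yn)^2) - target) / target, 0.03)
  cc <- mean(yn[1, ] * Conj(yn[2, ]))
  expect_lt(Mod(cc - 0.5 * target) / (0.5 * target), 0.05)
  # equal split between real and imaginary parts
  expect_lt(abs(mean(Re(yn[1, ])^2) - target / 2) / (target / 2), 0.05)
  # per-shot seeding: reproducible per shot, different across shots
  expect_identical(add_noise(y0, ns, 3), add_noise(y0, ns, 3))
  expect_false(identical(add_noise(y0, ns, 3), add_noise(y0, ns, 4)))
  # infinite SNR bypasses bit-exactly
  nsi <- noise_spec(Inf, E, seed = 1)
  expect_identical(add_noise(y0, nsi, 1), y0)
  expect_error(noise_spec(0, E), "snr_in")
})

test_that("acquisition streams shots that equal direct engine calls", {
  ph <- tiny_phantom()
  co <- single_coil()
  roi <- define_roi(ph, c(0, -15, 0), c(9, 9, 9))
  par <- block_paradigm(10, 10, 20)
  h <- hemodynamic_signal(par, 50)
  chain <- handler_chain(bold_handler(bold_spec(-1, 25, roi), h))
  pats <- lapply(1:2, function(f) epi_3d(ph$shape, 25, frame_index = f))
  seqp <- list(TR_shot = 50, TE = 25, FA = 12)
  ct <- tiny_contrast()
  ns <- noise_spec(1000, phantom_energy(ct), seed = 11)
  f1 <- tempfile(fileext = ".mrd")
  acq <- run_acquisition(ph, chain, pats, co, seqp, "basic", noise = ns,
                         output = f1)
  expect_equal(acq$n_shots, 32L)
  m <- read_mrd(f1)
  expect_length(m$records, 32)
  # record 5 equals the direct composition handler -> engine -> noise
  gi <- 5L
  st <- apply_handlers(chain, baseline_state(ph, 50, 25, 12), gi,
                       (gi - 1) * 0.05)
  mu <- Reduce(`+`, Map(`*`, st$phantom$fractions, st$mu))
  yd <- add_noise(simulate_shot_basic(mu, co, pats[[1]]$shots[[gi]]), ns, gi)
  expect_lt(max(Mod(m$records[[gi]]$data - yd)) / max(Mod(yd)), 1e-6)
  # reproducibility: identical payload bytes
  f2 <- tempfile(fileext = ".mrd")
  run_acquisition(ph, chain, pats, co, seqp, "basic", noise = ns,
                  output = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # frame regrouping
  frames <- mrd_frames(m)
  expect_length(frames, 2)
  expect_length(frames[[1]]$data, 16)
  unlink(c(f1, f2))
})

test_that("noise calibration survives the container round trip", {
  # measured k-space SNR of a noisy container matches snr_in
  ph <- tiny_phantom()
  co <- single_coil()
  ct <- tiny_contrast()
  pats <- list(epi_3d(ph$shape, 25))
  seqp <- list(TR_shot = 50, TE = 25, FA = 12)
  snr <- 100
  E <- phantom_energy(ct)
  f_clean <- tempfile(fileext = ".mrd")
  f_noisy <- tempfile(fileext = ".mrd")
  run_acquisition(ph, handler_chain(), pats, co, seqp, "basic",
                  noise = NULL, output = f_clean)
  run_acquisition(ph, handler_chain(), pats, co, seqp, "basic",
                  noise = noise_spec(snr, E, seed = 3), output = f_noisy)
  yc <- unlist(lapply(read_mrd(f_clean)$records, function(r) r$data))
  yn <- unlist(lapply(read_mrd(f_noisy)$records, function(r) r$data))
  noise_var <- mean(Mod(yn - yc)^2)
  expect_lt(abs(noise_var - E / snr) / (E / snr), 0.05)
  unlink(c(f_clean, f_noisy))
})
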