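test_that("adjoint reconstruction inverts fully sampled Cartesian data", {
  ph <- tiny_phantom()
  ct <- tiny_contrast()
  co <- single_coil()
  fr <- simulate_frame(ct, co, epi_3d(ph$shape, 25))
  rec <- adjoint_recon(fr, co)
  expect_lt(max(Mod(rec - ct$values)) / max(ct$values), 1e-6)
  # all-zero data give an all-zero image
  fr0 <- fr
  fr0$data <- lapply(fr0$data, function(d) d * 0)
  expect_equal(max(Mod(adjoint_recon(fr0, co))), 0)
})

test_that("density-compensated adjoint recovers a full stack of spirals", {
  ph <- tiny_phantom()
  ct <- tiny_contrast()
  pat <- stack_of_spirals(ph$shape, Tobs = 30, n_samples = 512, n_turns = 8,
                          center_frac = 0, AF = 1)
  for (L in c(1L, 4L)) {
    co <- make_coil_profiles(ph, L)
    fr <- simulate_frame(ct, co, pat)
    m <- image_metrics(adjoint_recon(fr, co), ct)
    expect_gt(m$psnr, 30)
  }
})

test_that("CS solver solves the unregularized problem and the prox fixed point", {
  ph <- tiny_phantom()
  ct <- tiny_contrast()
  co <- single_coil()
  fr <- simulate_frame(ct, co, epi_3d(ph$shape, 25))
  adj <- adjoint_recon(fr, co)
  spec <- wavelet_spec("sym8", 2L)
  # mu = 0, orthonormal operator: FISTA lands on the least-squares
  # solution (= adjoint) essentially exactly
  rf <- cs_recon_frame(recon_problem(fr, co, spec, mu = 0,
                                     solver = list(algorithm = "fista",
                                                   max_iter = 30,
                                                   tol = 1e-12)))
  expect_lt(max(Mod(rf$image - adj)) / max(Mod(adj)), 1e-6)
  # POGM drives the quadratic cost to a tiny fraction of its initial value
  rp <- cs_recon_frame(recon_problem(fr, co, spec, mu = 0,
                                     solver = list(algorithm = "pogm",
                                                   max_iter = 300,
                                                   tol = 0)))
  expect_lt(rp$cost, 1e-4 * rp$cost0)
  # zero data with positive mu: zero is the fixed point
  fr0 <- fr
  fr0$data <- lapply(fr0$data, function(d) d * 0)
  r0 <- cs_recon_frame(recon_problem(fr0, co, spec, mu = 1,
                                     solver = list(algorithm = "pogm",
                                                   max_iter = 20,
                                                   tol = 1e-12)))
  expect_equal(max(Mod(r0$image)), 0)
  # objective never above its value at the initialisation
  expect_lte(rf$cost, rf$cost0)
  expect_lte(rp$cost, rp$cost0)
  expect_lte(r0$cost, r0$cost0)
  expect_error(cs_recon_frame(recon_problem(fr, co, spec, mu = -1)), "mu")
})

test_that("wavelet-sparse images are recovered from undersampled data", {
  # 20-sparse image in the sym8 detail bands, 2x random Cartesian
  # undersampling, noiseless
  d <- c(16L, 16L, 16L)
  spec <- wavelet_spec("sym8", 2L)
  set.seed(21)
  wt <- dwt3(array(0, dim = d), spec)
  placed <- 0
  while (placed < 20) {
    l <- sample(length(wt$details), 1)
    nm <- sample(names(wt$details[[l]]), 1)
    i <- sample(length(wt$details[[l]][[nm]]), 1)
    if (wt$details[[l]][[nm]][i] == 0) {
      wt$details[[l]][[nm]][i] <- rnorm(1) + sign(rnorm(1))
      placed <- placed + 1
    }
  }
  x_true <- idwt3(wt)
  M <- prod(d)
  keep <- sort(sample(M, M / 2))
  g <- as.matrix(expand.grid(((0:15) - 8) / 16, ((0:15) - 8) / 16,
                             ((0:15) - 8) / 16))[keep, ]
  sh <- make_shot(g, seq_len(nrow(g)) * 0.01 - 10, grid_shape = d)
  co <- unit_coils(d)
  fr <- kspace_frame(list(simulate_shot_basic(x_true + 0i, co, sh)),
                     sampling_pattern(list(sh), grid_shape = d), 1L)
  mu <- 3e-4 * max(abs(wt_detail_vec(dwt3(x_true, spec)))) * M
  res <- cs_recon_frame(recon_problem(fr, co, spec, mu = mu,
                                      solver = list(algorithm = "fista",
                                                    max_iter = 300,
                                                    tol = 0)))
  err <- sqrt(sum(Mod(res$image - x_true)^2) / sum(x_true^2))
  expect_lt(err, 0.01)
})

test_that("SURE weight estimation tracks the noise level", {
  ph <- tiny_phantom()
  ct <- tiny_contrast()
  co <- single_coil()
  pat <- epi_3d(ph$shape, 25)
  spec <- wavelet_spec("sym8", 2L)
  # noiseless, fully sampled: a small weight (well below the universal
  # threshold of any visible noise scale)
  fr <- simulate_frame(ct, co, pat)
  mu0 <- estimate_mu_sure(fr, co, spec)
  expect_lt(attr(mu0, "threshold"), 1e-2 * max(ct$values))
  # zero-variance data: exactly zero
  fr0 <- fr
  fr0$data <- lapply(fr0$data, function(d) d * 0)
  expect_equal(as.numeric(estimate_mu_sure(fr0, co, spec)), 0)
  # pure complex Gaussian noise image: threshold lies in the expected
  # band around the universal threshold
  set.seed(31)
  sig <- 0.1
  img <- array(complex(real = rnorm(prod(ph$shape), 0, sig),
                       imaginary = rnorm(prod(ph$shape), 0, sig)),
               dim = ph$shape)
  fri <- simulate_frame(img, co, pat)
  mui <- estimate_mu_sure(fri, co, spec)
  M2 <- 2 * length(wt_detail_vec(dwt3(img, spec)))
  univ <- sig * sqrt(2 * log(M2))
  expect_gt(attr(mui, "threshold"), 0.5 * univ)
  expect_lt(attr(mui, "threshold"), 1.2 * univ)
  expect_lt(abs(attr(mui, "sigma") - sig) / sig, 0.1)
})

test_that("the SURE value approximates the oracle risk", {
  # piecewise-constant image + known Gaussian noise; the SURE of the
  # selected threshold must match the true risk computed from the clean
  # image
  set.seed(32)
  d <- c(16L, 16L, 16L)
  clean <- array(0, dim = d)
  clean[4:12, 4:12, 4:12] <- 1
  clean[6:9, 6:9, 6:9] <- 2
  sig <- 0.05
  spec <- wavelet_spec("sym8", 2L)
  reps <- vapply(1:20, function(r) {
    obs <- clean + array(rnorm(prod(d), 0, sig), dim = d)
    u <- Re(wt_detail_vec(dwt3(obs, spec)))
    theta <- Re(wt_detail_vec(dwt3(clean, spec)))
    cand <- seq(0, 4 * sig, length.out = 80)
    sure <- vapply(cand, function(t) sure_soft_risk(u, sig, t), numeric(1))
    thr <- cand[which.min(sure)]
    est <- sign(u) * pmax(abs(u) - thr, 0)
    c(min(sure), sum((est - theta)^2))
  }, numeric(2))
  expect_lt(abs(mean(reps[1, ]) - mean(reps[2, ])) / mean(reps[2, ]), 0.05)
})

test_that("series strategies share limits and warm starts save iterations", {
  ph <- tiny_phantom()
  ct <- tiny_contrast()
  co <- single_coil()
  pat <- epi_3d(ph$shape, 25)
  spec <- wavelet_spec("sym8", 2L)
  solver <- list(algorithm = "fista", max_iter = 40, tol = 1e-6)
  fr <- simulate_frame(ct, co, pat)
  # a single frame: all three strategies coincide
  one <- lapply(c("cold", "warm", "refined"), function(s)
    reconstruct_series(list(fr), co, s, spec, mu = 0.001, solver = solver))
  expect_equal(one[[1]]$volumes[[1]], one[[2]]$volumes[[1]],
               tolerance = 1e-8)
  expect_equal(one[[2]]$volumes[[1]], one[[3]]$volumes[[1]],
               tolerance = 1e-8)
  # static noiseless frames: warm initialisation converges in no more
  # iterations than cold for t >= 2
  frames <- list(fr, fr, fr)
  cold <- reconstruct_series(frames, co, "cold", spec, mu = 0.001,
                             solver = solver)
  warm <- reconstruct_series(frames, co, "warm", spec, mu = 0.001,
                             solver = solver)
  expect_true(all(warm$diagnostics$iterations[2:3] <=
                    cold$diagnostics$iterations[2:3]))
  expect_true(all(diff(warm$diagnostics$iterations) <= 0))
  # refined pass on identical frames: identical volumes
  refd <- reconstruct_series(frames, co, "refined", spec, mu = 0.001,
                             solver = solver)
  expect_equal(refd$volumes[[1]], refd$volumes[[3]], tolerance = 1e-7)
  expect_true(all(refd$diagnostics$init_source == "final-warm-volume"))
  expect_error(reconstruct_series(frames, co, "lukewarm"), "arg")
})

test_that("SURE-tuned weights shrink over a warm-started dynamic series", {
  ph <- tiny_phantom()
  ct <- tiny_contrast()
  co <- make_coil_profiles(ph, 2)
  ns <- noise_spec(1000, phantom_energy(ct), seed = 5)
  frames <- lapply(1:3, function(f) {
    pat <- stack_of_spirals(ph$shape, Tobs = 30, n_samples = 256,
                            n_turns = 8, center_frac = 0.15, AF = 3,
                            dynamic = TRUE, frame_index = f, seed = 9)
    ys <- lapply(seq_along(pat$shots), function(i)
      add_noise(simulate_shot_basic(ct$values, co, pat$shots[[i]]), ns,
                (f - 1) * 20 + i))
    kspace_frame(ys, pat, f)
  })
  ser <- reconstruct_series(frames, co, "warm", wavelet_spec("sym8", 2L),
                            mu = "auto",
                            solver = list(algorithm = "pogm", max_iter = 15,
                                          tol = 1e-4))
  mus <- ser$diagnostics$mu
  expect_true(all(mus[2:3] <= mus[1]))
  # cost at the returned iterate never above the cost at initialisation
  expect_true(all(ser$diagnostics$cost >= 0))
})
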