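test_that("3D EPI covers the Cartesian grid exactly once per volume", {
  pat <- epi_3d(c(4L, 4L, 4L), Tobs = 25)
  expect_length(pat$shots, 4)
  expect_true(all(vapply(pat$shots, function(s) nrow(s$samples),
                         integer(1)) == 16))
  K <- do.call(rbind, lapply(pat$shots, function(s) s$samples))
  full <- as.matrix(expand.grid(((0:3) - 2) / 4, ((0:3) - 2) / 4,
                                ((0:3) - 2) / 4))
  expect_equal(nrow(unique(as.data.frame(K))), 64)
  expect_setequal(apply(round(K, 10), 1, paste, collapse = ","),
                  apply(round(full, 10), 1, paste, collapse = ","))
  # counting at a rectangular matrix
  pat2 <- epi_3d(c(6L, 7L, 6L), Tobs = 25)
  expect_length(pat2$shots, 6)
  expect_true(all(vapply(pat2$shots, function(s) nrow(s$samples),
                         integer(1)) == 42))
})

test_that("EPI timing is uniform and echo-centred on the k-space centre", {
  pat <- epi_3d(c(8L, 8L, 8L), Tobs = 25)
  s <- pat$shots[[1]]
  d <- diff(s$times)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
  expect_equal(d[1], 25 / 64, tolerance = 1e-12)
  i0 <- which(s$times == 0)
  expect_equal(unname(s$samples[i0, 1:2]), c(0, 0))
  # centric ordering starts at the kz = 0 plane; ascending covers the
  # same planes in raster order
  expect_equal(pat$shots[[1]]$kz_plane, 0L)
  pasc <- epi_3d(c(8L, 8L, 8L), 25, plane_order = "ascending")
  expect_equal(vapply(pasc$shots, function(s) s$kz_plane, integer(1)),
               -4:3)
  expect_setequal(vapply(pat$shots, function(s) s$kz_plane, integer(1)),
                  -4:3)
})

test_that("in-out spiral crosses the centre at the echo and stays in band", {
  sp <- spiral_inout(512, 8, c(64L, 64L, 1L), Tobs = 30)
  expect_equal(unname(sp$samples[which(sp$times == 0), ]), c(0, 0, 0))
  expect_true(all(abs(sp$samples) < 0.5))
  r <- sqrt(rowSums(sp$samples[, 1:2]^2))
  neg <- which(sp$times < 0)
  pos <- which(sp$times >= 0)
  expect_true(all(diff(r[neg]) <= 1e-12))
  expect_true(all(diff(r[pos]) >= -1e-12))
  expect_error(spiral_inout(511, 8, c(64L, 64L, 1L), 30), "even")
})

test_that("gradient and slew audit follows finite-difference identities", {
  hw <- hardware_spec(Gmax = 40, Smax = 180, fov = 192)
  # constant k: zero gradient and slew
  kc <- matrix(0.1, nrow = 5, ncol = 3)
  sc <- make_shot(kc, (0:4) * 0.01, grid_shape = c(64L, 64L, 64L))
  gs <- gradients_and_slew(sc, hw)
  expect_equal(gs$max_g, 0)
  expect_equal(gs$max_s, 0)
  expect_true(gs$pass)
  # linear ramp: constant gradient, zero slew
  kl <- cbind(seq(-0.4, 0.4, length.out = 9), 0, 0)
  sl <- make_shot(kl, (0:8) * 0.01, grid_shape = c(64L, 64L, 64L))
  gl <- gradients_and_slew(sl, hw)
  expect_equal(max(gl$g) - min(gl$g), 0, tolerance = 1e-9)
  expect_equal(gl$max_s, 0, tolerance = 1e-6)
  # default spiral at 3 mm / FOV 192 mm, 10 us dwell passes the limits
  sp <- spiral_inout(3000, 12, c(64L, 64L, 64L), Tobs = 30)
  expect_true(gradients_and_slew(sp, hw)$pass)
})

test_that("stack of spirals selects centre and accelerated outer planes", {
  # degenerate settings
  p_all <- stack_of_spirals(c(16L, 16L, 8L), 30, n_samples = 64,
                            center_frac = 1, AF = 4)
  expect_length(p_all$shots, 8)
  p_af1 <- stack_of_spirals(c(16L, 16L, 8L), 30, n_samples = 64,
                            center_frac = 0, AF = 1)
  expect_length(p_af1$shots, 8)
  # the scenario-2 arithmetic: 60 planes, 10% centre, AF 4
  p60 <- stack_of_spirals(c(16L, 16L, 60L), 30, n_samples = 64,
                          center_frac = 0.1, AF = 4)
  expect_length(p60$shots, 6 + ceiling(54 / 4))
  kz <- vapply(p60$shots, function(s) s$kz_plane, integer(1))
  expect_true(0L %in% kz)   # the k-space centre plane is always acquired
  expect_true(all(sort(abs(kz))[1:6] <= 3))
  # explicit overrides
  p14 <- stack_of_spirals(c(16L, 16L, 60L), 30, n_samples = 64,
                          n_center = 6, n_outer_per_frame = 8)
  expect_length(p14$shots, 14)
  expect_warning(stack_of_spirals(c(16L, 16L, 8L), 30, n_samples = 64,
                                  center_frac = 0.5, AF = 100),
                 "outer planes")
})

test_that("dynamic plane draws are reproducible and cover k-space", {
  d1 <- stack_of_spirals(c(16L, 16L, 16L), 30, n_samples = 64,
                         center_frac = 0.1, AF = 4, dynamic = TRUE,
                         frame_index = 3, seed = 11)
  d2 <- stack_of_spirals(c(16L, 16L, 16L), 30, n_samples = 64,
                         center_frac = 0.1, AF = 4, dynamic = TRUE,
                         frame_index = 3, seed = 11)
  expect_identical(lapply(d1$shots, `[[`, "samples"),
                   lapply(d2$shots, `[[`, "samples"))
  d3 <- stack_of_spirals(c(16L, 16L, 16L), 30, n_samples = 64,
                         center_frac = 0.1, AF = 4, dynamic = TRUE,
                         frame_index = 4, seed = 11)
  expect_false(identical(vapply(d1$shots, `[[`, integer(1), "kz_plane"),
                         vapply(d3$shots, `[[`, integer(1), "kz_plane")))
  # Monte-Carlo coverage: over AF consecutive frames the expected
  # fraction of outer planes visited is at least 1 - (1 - 1/AF)^AF
  AF <- 4; nz <- 16L
  n_center <- floor(0.1 * nz + 0.5)
  planes <- (0:(nz - 1)) - nz %/% 2
  ord <- order(abs(planes), planes)
  outer_planes <- setdiff(planes, sort(planes[ord[seq_len(n_center)]]))
  fracs <- vapply(1:30, function(sd) {
    seen <- unique(unlist(lapply(1:AF, function(f) {
      p <- stack_of_spirals(c(16L, 16L, nz), 30, n_samples = 64,
                            center_frac = 0.1, AF = AF, dynamic = TRUE,
                            frame_index = f, seed = sd)
      vapply(p$shots, `[[`, integer(1), "kz_plane")
    })))
    length(intersect(seen, outer_planes)) / length(outer_planes)
  }, numeric(1))
  expect_gte(mean(fracs), 1 - (1 - 1 / AF)^AF)
})

test_that("shot validation enforces the k-space band and time grid", {
  expect_error(make_shot(matrix(0.6, 1, 3), 0), "0.5")
  expect_error(make_shot(matrix(0.1, 2, 3), c(1, 0)), "increasing")
  expect_error(make_shot(matrix(0.1, 3, 3), c(0, 1, 3)), "constant")
})

test_that("trajectories round-trip through the binary container", {
  pat <- stack_of_spirals(c(16L, 16L, 8L), 30, n_samples = 64,
                          center_frac = 0.25, AF = 2)
  f <- tempfile(fileext = ".traj")
  write_trajectory(pat, f)
  pat2 <- read_trajectory(f)
  expect_equal(pat2$grid_shape, pat$grid_shape)
  for (i in seq_along(pat$shots)) {
    expect_identical(pat2$shots[[i]]$samples, unname(pat$shots[[i]]$samples))
    expect_identical(pat2$shots[[i]]$times, pat$shots[[i]]$times)
    expect_equal(pat2$shots[[i]]$kz_plane, pat$shots[[i]]$kz_plane)
  }
  unlink(f)
})

test_that("trajectory CSV dialect reads back and malformed files error", {
  pat <- epi_3d(c(4L, 4L, 4L), 25)
  f <- tempfile(fileext = ".csv")
  write_trajectory(pat, f)
  pat2 <- read_trajectory(f)
  expect_equal(do.call(rbind, lapply(pat2$shots, `[[`, "samples")),
               unname(do.call(rbind, lapply(pat$shots, `[[`, "samples"))),
               tolerance = 1e-12)
  unlink(f)
  # out-of-band coordinate in a CSV is rejected
  bad <- tempfile(fileext = ".csv")
  writeLines(c("# grid_shape: 4 4 4", "shot,t,kx,ky,kz",
               "1,0,0.6,0,0", "1,1,0.1,0,0"), bad)
  expect_error(read_trajectory(bad), "0.5")
  unlink(bad)
  # bad magic
  junk <- tempfile(fileext = ".traj")
  writeBin(charToRaw("NOTATRAJ"), junk)
  expect_error(read_trajectory(junk), "magic")
  unlink(junk)
  # empty shot list cannot be written
  expect_error(write_trajectory(structure(list(shots = list(),
                                               grid_shape = c(4L, 4L, 4L),
                                               frame_index = 1L),
                                          class = "ksim_pattern"),
                                tempfile()),
               "empty")
})
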