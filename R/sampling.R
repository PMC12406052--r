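#' k-space shot
#'
#' One readout: an ordered list of k-space sample locations with per-sample
#' times relative to the echo centre. Coordinates are normalised cycles/FOV
#' per axis in [-0.5, 0.5); times are uniformly spaced by the dwell time
#' `dt = Tobs / N` and chosen as `t_n = (n - 1 - floor(N/2)) * dt`, so the
#' sample with index `floor(N/2) + 1` is acquired exactly at the echo
#' (t = 0). All generators in this module place the k-space centre on that
#' sample.
#'
#' @param samples N x 3 matrix of normalised k-space coordinates
#' @param times length-N vector of sample times (ms), strictly increasing
#'   with constant spacing
#' @param shot_index integer shot counter within the pattern
#' @param kz_plane optional plane index for stacked readouts (integer,
#'   centred: 0 is the k-space centre plane)
#' @param grid_shape target matrix size (used for hardware audits)
#' @return an object of class `ksim_shot`
#' @export
make_shot <- function(samples, times, shot_index = 1L, kz_plane = NA_integer_,
                      grid_shape = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3) stop("samples must be an N x 3 matrix")
  if (nrow(samples) != length(times)) stop("times length must match samples")
  if (any(samples < -0.5 - 1e-12) || any(samples >= 0.5))
    stop("k-space coordinates must lie in [-0.5, 0.5)")
  d <- diff(times)
  if (length(d) > 0) {
    if (any(d <= 0)) stop("times must be strictly increasing")
    if (diff(range(d)) > 1e-9 * max(abs(d)))
      stop("times must have constant spacing")
  }
  structure(list(samples = samples, times = as.numeric(times),
                 shot_index = as.integer(shot_index),
                 kz_plane = if (length(kz_plane) == 1 && is.na(kz_plane))
                   NA_integer_ else as.integer(kz_plane),
                 grid_shape = grid_shape),
            class = "ksim_shot")
}

#' Echo-centred sample times
#' @keywords internal
shot_times <- function(N, Tobs) {
  dt <- Tobs / N
  ((0:(N - 1)) - N %/% 2) * dt
}

#' Sampling pattern of one frame
#'
#' @param shots list of [make_shot()] objects sharing dwell and grid
#' @param frame_index frame (volume) counter
#' @param grid_shape target matrix size
#' @return an object of class `ksim_pattern`
#' @export
sampling_pattern <- function(shots, frame_index = 1L, grid_shape) {
  if (length(shots) < 1) stop("a pattern needs at least one shot")
  for (s in shots) stopifnot(inherits(s, "ksim_shot"))
  structure(list(shots = shots, frame_index = as.integer(frame_index),
                 grid_shape = as.integer(grid_shape)),
            class = "ksim_pattern")
}

#' @export
print.ksim_pattern <- function(x, ...) {
  n <- vapply(x$shots, function(s) nrow(s$samples), integer(1))
  cat(sprintf("ksim sampling pattern: frame %d, %d shots x %s samples, grid %s\n",
              x$frame_index, length(x$shots),
              paste(unique(n), collapse = "/"),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Fully sampled 3D EPI (plane-per-shot Cartesian readout)
#'
#' One shot per kz plane; within a plane, raster order over ky lines with
#' alternating kx direction (serpentine), phased so that the (kx=0, ky=0)
#' sample of each plane is acquired exactly at the echo centre. Every
#' Cartesian grid point is covered exactly once per volume.
#'
#' Planes are acquired in `"centric"` (centre-out: kz = 0, -1, +1, -2, ...)
#' order by default, so the low spatial frequencies — which set the
#' apparent timing and amplitude of slow signal changes such as the BOLD
#' response — are collected in a short window at the start of each volume
#' instead of being smeared across the whole TR_vol; `"ascending"` raster
#' plane order is available as an option.
#'
#' @param grid_shape matrix size (Nx, Ny, Nz), each >= 2
#' @param Tobs readout window duration per shot, ms
#' @param frame_index frame counter stored in the pattern
#' @param plane_order `"centric"` (default) or `"ascending"`
#' @return a `ksim_pattern` with Nz shots of Nx*Ny samples
#' @export
epi_3d <- function(grid_shape, Tobs, frame_index = 1L,
                   plane_order = c("centric", "ascending")) {
  plane_order <- match.arg(plane_order)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 2))
    stop("grid_shape must have 3 dimensions, each >= 2")
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  kxv <- ((0:(nx - 1)) - nx %/% 2) / nx
  kyv <- ((0:(ny - 1)) - ny %/% 2) / ny
  # time origin on the (kx=0, ky=0) raster position of the serpentine,
  # so the k-space centre of every plane is acquired exactly at the echo
  idx0 <- (ny %/% 2) * nx + nx %/% 2
  times <- ((0:(nx * ny - 1)) - idx0) * (Tobs / (nx * ny))
  # serpentine with the row holding ky=0 forward
  rows <- lapply(0:(ny - 1), function(r) {
    fwd <- ((r - ny %/% 2) %% 2) == 0
    if (fwd) kxv else rev(kxv)
  })
  kx <- unlist(rows)
  ky <- rep(kyv, each = nx)
  planes <- (0:(nz - 1)) - nz %/% 2       # centred kz indices
  if (plane_order == "centric") planes <- planes[order(abs(planes), planes)]
  shots <- vector("list", nz)
  for (i in seq_len(nz)) {
    pz <- planes[i]
    shots[[i]] <- make_shot(cbind(kx, ky, rep(pz / nz, nx * ny)), times,
                            shot_index = i,
                            kz_plane = pz,
                            grid_shape = grid_shape)
  }
  sampling_pattern(shots, frame_index = frame_index, grid_shape = grid_shape)
}

#' In-out Archimedean spiral shot
#'
#' The readout starts at maximal radius, spirals inward to the k-space
#' centre reached exactly at the echo (t = 0), then retraces the
#' point-mirrored arm outward (k(-t) = -k(t)), which keeps the gradient
#' continuous through the centre. Maximal radius is the largest on-grid
#' frequency, (floor(N/2) - 1)/N for the smaller in-plane dimension.
#'
#' @param n_samples even number of samples
#' @param n_turns number of spiral revolutions of one arm
#' @param grid_shape matrix size (Nx, Ny, Nz)
#' @param Tobs readout duration, ms
#' @param kz normalised kz coordinate of the plane (default 0)
#' @param kz_plane integer plane index stored on the shot
#' @param theta0 rotation of the spiral, radians
#' @param shot_index shot counter
#' @return a `ksim_shot`
#' @export
spiral_inout <- function(n_samples, n_turns, grid_shape, Tobs, kz = 0,
                         kz_plane = NA_integer_, theta0 = 0, shot_index = 1L) {
  if (n_samples %% 2 != 0) stop("n_samples must be even")
  grid_shape <- as.integer(grid_shape)
  nmin <- min(grid_shape[1:2])
  kmax <- (nmin %/% 2 - 1) / nmin
  t <- shot_times(n_samples, Tobs)
  u <- pmin(abs(t) / (Tobs / 2), 1)
  r <- kmax * u
  th <- 2 * pi * n_turns * u + theta0
  kx <- r * cos(th); ky <- r * sin(th)
  neg <- t < 0
  kx[neg] <- -kx[neg]; ky[neg] <- -ky[neg]
  make_shot(cbind(kx, ky, rep(kz, n_samples)), t,
            shot_index = shot_index, kz_plane = kz_plane,
            grid_shape = grid_shape)
}

#' Variable-density stack of spirals
#'
#' A 2D spiral per selected kz plane. A fixed set of central planes
#' (`n_center = round(center_frac * nz)`, always containing the kz = 0
#' plane) is acquired in every frame; the remaining outer planes are
#' subsampled by the acceleration factor `AF`: every frame carries
#' `ceiling(n_outer / AF)` outer planes, either the same stride subset in
#' every frame (`dynamic = FALSE`, "scan and repeat") or a fresh seeded
#' uniform draw without replacement per frame (`dynamic = TRUE`). Selected
#' planes are ordered by kz so the centre plane sits mid-frame. Spirals are
#' rotated plane-wise by the golden angle for sampling incoherence.
#'
#' @param grid_shape matrix size (Nx, Ny, Nz)
#' @param Tobs per-shot readout duration, ms
#' @param n_samples samples per spiral (even)
#' @param n_turns spiral revolutions per arm
#' @param center_frac fraction of planes in the always-acquired centre band
#' @param AF acceleration factor on the outer planes, >= 1
#' @param dynamic re-draw the outer planes each frame
#' @param frame_index frame counter (drives the dynamic draw)
#' @param seed master seed for the dynamic draws
#' @param n_center,n_outer_per_frame explicit overrides of the derived plane
#'   counts (scenario tables sometimes fix these directly)
#' @return a `ksim_pattern`
#' @export
stack_of_spirals <- function(grid_shape, Tobs, n_samples = 1024, n_turns = 12,
                             center_frac = 0.1, AF = 4, dynamic = FALSE,
                             frame_index = 1L, seed = 1L,
                             n_center = NULL, n_outer_per_frame = NULL) {
  grid_shape <- as.integer(grid_shape)
  nz <- grid_shape[3]
  if (nz < 1) stop("nz must be >= 1")
  if (center_frac < 0 || center_frac > 1) stop("center_frac must be in [0, 1]")
  if (AF < 1) stop("AF must be >= 1")
  planes <- (0:(nz - 1)) - nz %/% 2     # centred integer kz indices
  if (is.null(n_center)) n_center <- floor(center_frac * nz + 0.5)
  # centre band: the n_center planes closest to kz=0 (kz=0 always included)
  ord <- order(abs(planes), planes)
  center <- sort(planes[ord[seq_len(max(n_center, 0))]])
  if (n_center == 0) center <- integer(0)
  outer_planes <- setdiff(planes, center)
  n_outer <- length(outer_planes)
  if (is.null(n_outer_per_frame)) n_outer_per_frame <- ceiling(n_outer / AF)
  if (n_outer > 0 && AF > n_outer) {
    warning("AF exceeds the number of outer planes; only centre planes acquired")
    sel <- integer(0)
  } else if (n_outer == 0 || n_outer_per_frame == 0) {
    sel <- integer(0)
  } else if (dynamic) {
    sel <- with_seed(mix_seed(seed, frame_index),
                     sort(sample(outer_planes, n_outer_per_frame)))
  } else {
    sel <- outer_planes[seq(1, n_outer, by = max(1, floor(AF)))]
    sel <- sel[seq_len(min(length(sel), n_outer_per_frame))]
  }
  chosen <- sort(unique(c(center, sel)))
  golden <- pi * (3 - sqrt(5))
  shots <- vector("list", length(chosen))
  for (i in seq_along(chosen)) {
    pz <- chosen[i]
    shots[[i]] <- spiral_inout(n_samples, n_turns, grid_shape, Tobs,
                               kz = pz / nz, kz_plane = pz,
                               theta0 = golden * pz, shot_index = i)
  }
  sampling_pattern(shots, frame_index = frame_index, grid_shape = grid_shape)
}

#' Hardware specification for gradient audits
#'
#' @param Gmax maximal gradient magnitude, mT/m
#' @param Smax maximal slew rate, T/m/s
#' @param gamma gyromagnetic ratio, kHz/mT (default 42.576, protons)
#' @param dwell dwell time, ms
#' @param fov field of view per axis, mm (scalar or length 3)
#' @return an object of class `ksim_hw`
#' @export
hardware_spec <- function(Gmax = 40, Smax = 180, gamma = 42.576,
                          dwell = 0.01, fov = 192) {
  if (length(fov) == 1) fov <- rep(fov, 3)
  vals <- c(Gmax, Smax, gamma, dwell, fov)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hardware parameters must be strictly positive")
  structure(list(Gmax = Gmax, Smax = Smax, gamma = gamma, dwell = dwell,
                 fov = fov), class = "ksim_hw")
}

#' Gradient and slew-rate audit of a shot
#'
#' Converts the normalised trajectory to physical k-space (cycles/mm, using
#' the shot's grid and the hardware FOV), then differentiates:
#' `G = (dk/dt) / (gamma * 1e-3)` in mT/m and `S = dG/dt` in T/m/s
#' (finite differences at the shot's sample spacing). The shot passes when
#' both maxima respect the hardware limits.
#'
#' @param shot a `ksim_shot` with at least 3 samples and a `grid_shape`
#' @param hw a [hardware_spec()]
#' @return list with per-interval gradient magnitudes `g` (mT/m), slew
#'   magnitudes `s` (T/m/s), `max_g`, `max_s` and logical `pass`
#' @export
gradients_and_slew <- function(shot, hw) {
  stopifnot(inherits(shot, "ksim_shot"), inherits(hw, "ksim_hw"))
  if (nrow(shot$samples) < 3) stop("need at least 3 samples")
  if (is.null(shot$grid_shape)) stop("shot carries no grid_shape; cannot map to physical units")
  if (is.null(hw$fov) || is.null(hw$dwell)) stop("hardware fov/dwell missing")
  dt <- if (length(shot$times) > 1) diff(shot$times[1:2]) else hw$dwell
  # physical k in cycles/mm: normalised coordinate / voxel size
  vox <- hw$fov / shot$grid_shape
  kp <- sweep(shot$samples, 2, vox, "/")
  dk <- apply(kp, 2, diff) / dt                 # cycles/mm/ms
  Gxyz <- dk / (hw$gamma * 1e-3)                # mT/m
  g <- sqrt(rowSums(Gxyz^2))
  dG <- apply(Gxyz, 2, diff) / dt               # mT/m/ms == T/m/s
  s <- sqrt(rowSums(dG^2))
  list(g = g, s = s, max_g = max(g), max_s = max(s),
       pass = max(g) <= hw$Gmax && max(s) <= hw$Smax)
}

## --- trajectory exchange --------------------------------------------------

#' Write a sampling pattern to a trajectory file
#'
#' Two dialects: a little-endian binary container (magic `KSTRJ01`, a JSON
#' header with grid shape and shot table, then float64 time/coordinate
#' arrays per shot — lossless round trip), and a plain-text CSV for
#' inspection (one row per sample: shot, t, kx, ky, kz; the grid shape in a
#' leading comment line).
#'
#' @param pattern a `ksim_pattern`
#' @param path output path
#' @param format `"bin"` or `"csv"`; default inferred from the extension
#'   (`.csv` -> csv, otherwise binary)
#' @return invisibly, `path`
#' @export
write_trajectory <- function(pattern, path, format = NULL) {
  stopifnot(inherits(pattern, "ksim_pattern"))
  if (length(pattern$shots) == 0) stop("empty shot list")
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bin"
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# grid_shape: %s",
                       paste(pattern$grid_shape, collapse = " ")), con)
    rows <- do.call(rbind, lapply(pattern$shots, function(s)
      data.frame(shot = s$shot_index, t = s$times,
                 kx = s$samples[, 1], ky = s$samples[, 2],
                 kz = s$samples[, 3])))
    write.csv(rows, con, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("KSTRJ01\n"), con)
  hdr <- jsonlite::toJSON(list(
    version = 1L,
    grid_shape = pattern$grid_shape,
    frame_index = pattern$frame_index,
    n_shots = length(pattern$shots),
    samples_per_shot = vapply(pattern$shots,
                              function(s) nrow(s$samples), integer(1))),
    auto_unbox = TRUE)
  hraw <- charToRaw(as.character(hdr))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (s in pattern$shots) {
    kzp <- if (is.na(s$kz_plane)) -2147483647L else as.integer(s$kz_plane)
    writeBin(c(as.integer(s$shot_index), kzp, nrow(s$samples)),
             con, size = 4L, endian = "little")
    writeBin(as.numeric(s$times), con, size = 8L, endian = "little")
    writeBin(as.numeric(s$samples), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a sampling pattern from a trajectory file
#'
#' Accepts both dialects written by [write_trajectory()]; coordinates are
#' validated against the normalised range [-0.5, 0.5).
#'
#' @param path input path
#' @return a `ksim_pattern`
#' @export
read_trajectory <- function(path) {
  is_csv <- grepl("\\.csv$", path, ignore.case = TRUE)
  if (is_csv) {
    first <- readLines(path, n = 1)
    if (!grepl("^# grid_shape:", first))
      stop("malformed trajectory CSV: missing '# grid_shape:' header line")
    grid_shape <- as.integer(strsplit(sub("^# grid_shape:\\s*", "", first),
                                      "\\s+")[[1]])
    rows <- read.csv(path, comment.char = "#")
    need <- c("shot", "t", "kx", "ky", "kz")
    if (!all(need %in% names(rows)))
      stop("malformed trajectory CSV: need columns ", paste(need, collapse = ", "))
    if (nrow(rows) == 0) stop("empty shot list in trajectory file")
    shots <- lapply(sort(unique(rows$shot)), function(si) {
      r <- rows[rows$shot == si, ]
      r <- r[order(r$t), ]
      make_shot(cbind(r$kx, r$ky, r$kz), r$t, shot_index = si,
                grid_shape = grid_shape)
    })
    return(sampling_pattern(shots, grid_shape = grid_shape))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, "KSTRJ01\n"))
    stop("malformed trajectory file: bad magic '", magic, "'")
  hlen <- readBin(con, "integer", 1, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (hdr$n_shots < 1) stop("empty shot list in trajectory file")
  shots <- vector("list", hdr$n_shots)
  for (i in seq_len(hdr$n_shots)) {
    ints <- readBin(con, "integer", 3, size = 4L, endian = "little")
    if (length(ints) < 3)
      stop(sprintf("malformed trajectory file: truncated at shot record %d", i))
    n <- ints[3]
    times <- readBin(con, "numeric", n, size = 8L, endian = "little")
    coords <- matrix(readBin(con, "numeric", 3 * n, size = 8L,
                             endian = "little"), ncol = 3)
    kzp <- if (ints[2] == -2147483647L) NA_integer_ else ints[2]
    shots[[i]] <- make_shot(coords, times, shot_index = ints[1],
                            kz_plane = kzp,
                            grid_shape = as.integer(hdr$grid_shape))
  }
  sampling_pattern(shots,
                   frame_index = if (!is.null(hdr$frame_index)) hdr$frame_index else 1L,
                   grid_shape = as.integer(hdr$grid_shape))
}
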