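## Raw-data container: a reduced ISMRMRD-style dialect.
##
## ISMRMRD stores one acquisition record per readout (counters, a per-sample
## trajectory, interleaved complex float32 data). This writer keeps exactly
## those fields in a self-contained little-endian binary layout so the
## reader needs nothing beyond base R:
##
##   bytes 0-7   magic "KSMRD01\n"
##   int32       JSON header length, then the UTF-8 JSON header
##               (grid shape, voxel size, coil count, frame table,
##               sequence parameters, engine, noise settings)
##   records     repeated until EOF, each:
##     int32 x 5   scan_counter, frame_index, shot_index, kz_plane
##                 (NA -> -2147483647), n_samples
##     int32       L (coil count)
##     float64 x n            sample times (ms)
##     float64 x 3n           trajectory (column-major n x 3)
##     float32 x 2*L*n        data, coil-major, interleaved re/im

MRD_MAGIC <- "KSMRD01\n"
NA_SENTINEL <- -2147483647L

#' Open a raw-data container for writing
#' @param path output path
#' @param header named list serialised as the JSON header
#' @return a writer handle
#' @keywords internal
mrd_open_write <- function(path, header) {
  con <- file(path, "wb")
  writeBin(charToRaw(MRD_MAGIC), con)
  hraw <- charToRaw(as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                                  digits = NA)))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  list(con = con, path = path)
}

#' Append one acquisition record
#' @keywords internal
mrd_write_record <- function(w, scan_counter, frame_index, shot_index,
                             kz_plane, times, traj, data) {
  n <- length(times)
  stopifnot(nrow(traj) == n, ncol(data) == n)
  kzp <- if (is.na(kz_plane)) NA_SENTINEL else as.integer(kz_plane)
  writeBin(as.integer(c(scan_counter, frame_index, shot_index, kzp, n,
                        nrow(data))),
           w$con, size = 4L, endian = "little")
  writeBin(as.numeric(times), w$con, size = 8L, endian = "little")
  writeBin(as.numeric(traj), w$con, size = 8L, endian = "little")
  # interleave re/im per complex value, coil-major: for coil l the n
  # complex samples are written as re1 im1 re2 im2 ...
  buf <- numeric(2 * length(data))
  d <- t(data)                                   # n x L, column = coil
  buf[seq(1, by = 2, length.out = length(d))] <- Re(d)
  buf[seq(2, by = 2, length.out = length(d))] <- Im(d)
  writeBin(buf, w$con, size = 4L, endian = "little")
  invisible(w)
}

#' @keywords internal
mrd_close <- function(w) {
  try(close(w$con), silent = TRUE)
  invisible(w$path)
}

#' Read a raw-data container
#'
#' Parses the reduced ISMRMRD-style dialect written by [run_acquisition()]
#' (layout documented in the package source). Returns the JSON header and
#' the list of acquisition records; use [mrd_frames()] to regroup records
#' into per-frame k-space objects.
#'
#' @param path container path
#' @return list with `header` and `records` (each record: scan_counter,
#'   frame_index, shot_index, kz_plane, times, traj, data as L x n complex)
#' @export
read_mrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(MRD_MAGIC)))
  if (!identical(magic, MRD_MAGIC)) stop("not a ksim raw-data container")
  hlen <- readBin(con, "integer", 1, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  records <- list()
  repeat {
    ints <- readBin(con, "integer", 6, size = 4L, endian = "little")
    if (length(ints) == 0) break
    if (length(ints) < 6) stop("truncated acquisition record")
    n <- ints[5]; L <- ints[6]
    times <- readBin(con, "numeric", n, size = 8L, endian = "little")
    traj <- matrix(readBin(con, "numeric", 3 * n, size = 8L,
                           endian = "little"), ncol = 3)
    buf <- readBin(con, "numeric", 2 * L * n, size = 4L, endian = "little")
    d <- complex(real = buf[seq(1, by = 2, length.out = L * n)],
                 imaginary = buf[seq(2, by = 2, length.out = L * n)])
    data <- t(matrix(d, nrow = n, ncol = L))
    records[[length(records) + 1]] <- list(
      scan_counter = ints[1], frame_index = ints[2], shot_index = ints[3],
      kz_plane = if (ints[4] == NA_SENTINEL) NA_integer_ else ints[4],
      times = times, traj = traj, data = data)
  }
  list(header = header, records = records)
}

#' Regroup container records into per-frame k-space objects
#'
#' @param mrd result of [read_mrd()]
#' @return list of `ksim_frame` objects (fields: `data` — list of L x n
#'   complex matrices, one per shot —, `pattern`, `frame_index`)
#' @export
mrd_frames <- function(mrd) {
  grid_shape <- as.integer(mrd$header$grid_shape)
  fidx <- vapply(mrd$records, function(r) r$frame_index, integer(1))
  lapply(sort(unique(fidx)), function(f) {
    recs <- mrd$records[fidx == f]
    recs <- recs[order(vapply(recs, function(r) r$shot_index, integer(1)))]
    shots <- lapply(recs, function(r)
      make_shot(r$traj, r$times, shot_index = r$shot_index,
                kz_plane = r$kz_plane, grid_shape = grid_shape))
    kspace_frame(data = lapply(recs, function(r) r$data),
                 pattern = sampling_pattern(shots, frame_index = f,
                                            grid_shape = grid_shape),
                 frame_index = f)
  })
}

#' k-space frame
#'
#' Complex samples of all coils and shots forming one volume's sampling
#' pattern.
#'
#' @param data list (one entry per shot) of L x n complex matrices
#' @param pattern the frame's `ksim_pattern`
#' @param frame_index frame counter
#' @return an object of class `ksim_frame`
#' @export
kspace_frame <- function(data, pattern, frame_index = 1L) {
  stopifnot(inherits(pattern, "ksim_pattern"),
            length(data) == length(pattern$shots))
  L <- nrow(data[[1]])
  for (i in seq_along(data)) {
    if (nrow(data[[i]]) != L ||
        ncol(data[[i]]) != nrow(pattern$shots[[i]]$samples))
      stop("data dimensions do not match (L, N_s, N)")
  }
  structure(list(data = data, pattern = pattern,
                 frame_index = as.integer(frame_index), L = L),
            class = "ksim_frame")
}
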