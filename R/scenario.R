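#' Load and normalise a scenario configuration
#'
#' A scenario is one YAML (or list) description of the whole chain:
#' phantom, paradigm, sequence, trajectory, engine, reconstruction,
#' analysis, run. Missing keys take the documented defaults; the normalised
#' configuration round-trips through YAML unchanged.
#'
#' @param config path to a YAML file, or a named list
#' @return an object of class `ksim_config` (a named list)
#' @export
scenario_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    phantom = list(shape = c(32L, 32L, 32L), voxel_size = 3, seed = 1L,
                   smooth_vox = 1),
    roi = list(center = c(0, -30, 0), semiaxes = c(16, 16, 16),
               gm_threshold = 0.5),
    paradigm = list(on_s = 20, off_s = 20),
    bold = list(delta_R2s = -1, exact = FALSE),
    sequence = list(TR_shot = 50, TE = 25, FA = 12, Tobs = 25),
    trajectory = list(kind = "epi"),
    engine = list(kind = "basic", snr_in = Inf, L = 1L),
    recon = list(method = "adjoint", strategy = "cold", mu = "auto",
                 wavelet = list(family = "sym8", levels = 3L),
                 solver = list(algorithm = "pogm", max_iter = 50L,
                               tol = 1e-5)),
    analysis = list(p = 0.001, frame_time = "center"),
    run = list(length_s = 120, seed = 1L)
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$phantom$shape <- as.integer(cfg$phantom$shape)
  if (is.character(cfg$engine$snr_in))   # YAML "inf"/".inf" fallbacks
    cfg$engine$snr_in <- as.numeric(cfg$engine$snr_in)
  stopifnot(cfg$trajectory$kind %in% c("epi", "sos", "import"),
            cfg$engine$kind %in% c("basic", "t2s"),
            cfg$recon$method %in% c("adjoint", "cs"))
  structure(cfg, class = c("ksim_config", "list"))
}

#' Shots per volume implied by a configuration
#' @keywords internal
config_shots_per_frame <- function(config) {
  tr <- config$trajectory
  switch(tr$kind,
    epi = config$phantom$shape[3],
    sos = length(build_frame_pattern(config, frame_index = 1L,
                                     seed = config$run$seed)$shots),
    import = length(read_trajectory(tr$path)$shots))
}

#' Derive the timing of a scenario
#'
#' `n_shots_total = floor(run_length / TR_shot)`; volumes are assembled
#' from `N_s` consecutive shots, so `TR_vol = N_s * TR_shot` and
#' `n_frames = floor(n_shots_total / N_s)` (a trailing remainder of shots
#' is dropped with a warning).
#'
#' @param config a [scenario_config()]
#' @param N_s shots per volume; derived from the trajectory if missing
#' @return list with `n_shots_total`, `n_frames`, `TR_vol` (s), `N_s`
#' @export
derive_timing <- function(config, N_s = NULL) {
  config <- scenario_config(config)
  if (is.null(N_s)) N_s <- config_shots_per_frame(config)
  n_shots_total <- floor(config$run$length_s * 1000 / config$sequence$TR_shot)
  if (N_s > n_shots_total)
    stop("the shot budget is smaller than one volume (N_s > n_shots_total)")
  n_frames <- n_shots_total %/% N_s
  if (n_shots_total %% N_s != 0)
    warning(sprintf("%d trailing shots do not fill a volume and are dropped",
                    n_shots_total %% N_s))
  list(n_shots_total = n_shots_total, n_frames = n_frames,
       TR_vol = N_s * config$sequence$TR_shot / 1000, N_s = N_s)
}

#' Build the sampling pattern of one frame
#' @keywords internal
build_frame_pattern <- function(config, frame_index, seed) {
  tr <- config$trajectory
  shape <- config$phantom$shape
  Tobs <- config$sequence$Tobs
  if (tr$kind == "epi") {
    epi_3d(shape, Tobs, frame_index = frame_index,
           plane_order = tr$plane_order %||% "centric")
  } else if (tr$kind == "sos") {
    stack_of_spirals(shape, Tobs,
                     n_samples = tr$n_samples %||% 1024L,
                     n_turns = tr$n_turns %||% 12,
                     center_frac = tr$center_frac %||% 0.1,
                     AF = tr$AF %||% 4,
                     dynamic = isTRUE(tr$dynamic),
                     frame_index = frame_index, seed = seed,
                     n_center = tr$n_center,
                     n_outer_per_frame = tr$n_outer_per_frame)
  } else {
    p <- read_trajectory(tr$path)
    p$frame_index <- as.integer(frame_index)
    p
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frame timestamps for the GLM regressor
#'
#' `"center"` (default): the acquisition time of the shot crossing the
#' k-space centre plane of each volume — the moment the volume's
#' low-frequency content, hence the voxel time course, is set.
#' `"start"`: the first shot of the volume.
#'
#' @keywords internal
frame_timestamps <- function(patterns, TR_shot, frame_time = "center") {
  N_s <- vapply(patterns, function(p) length(p$shots), integer(1))
  offsets <- cumsum(c(0L, N_s[-length(N_s)]))
  vapply(seq_along(patterns), function(f) {
    idx <- if (frame_time == "start") 1L else {
      kz <- vapply(patterns[[f]]$shots,
                   function(s) if (is.na(s$kz_plane)) NA_integer_
                   else as.integer(s$kz_plane), integer(1))
      ctr <- which(!is.na(kz) & kz == 0L)
      if (length(ctr) > 0) ctr[1] else (N_s[f] + 1L) %/% 2L
    }
    (offsets[f] + idx - 1L) * TR_shot / 1000
  }, numeric(1))
}

#' Run a complete scenario
#'
#' Executes the full chain — phantom, paradigm, sampling, shot-by-shot
#' acquisition to a raw-data container, frame-wise reconstruction, GLM
#' scoring — and writes the artifact bundle to `out_dir`: `run.mrd`,
#' `series.nii.gz` (4D magnitude), `tmap.nii.gz`, `report.json`,
#' `pr_curve.csv` and `manifest.json`. Rerunning with the same
#' configuration and seed reproduces `run.mrd` and `report.json`
#' bit-exactly (all random draws are sub-seeded from the master seed; the
#' manifest carries the wall times and is not expected to be identical).
#'
#' @param config a [scenario_config()] (or path / list)
#' @param seed optional master seed overriding `run$seed`
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with `report`, `series`, `stat`, `roi`,
#'   `config` and the output `paths`
#' @export
run_scenario <- function(config, seed = NULL, out_dir = tempfile("ksim_")) {
  config <- scenario_config(config)
  if (!is.null(seed)) config$run$seed <- as.integer(seed)
  seed <- config$run$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_t <- list(); tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  ## ground truth ------------------------------------------------------
  tissues <- default_tissues()
  if (!is.null(config$tissues)) {
    for (nm in names(config$tissues)) {
      tt <- utils::modifyList(unclass(tissues[[nm]]), config$tissues[[nm]])
      tissues[[nm]] <- tissue_params(nm, tt$rho, tt$T1, tt$T2s)
    }
  }
  phantom <- make_synthetic_phantom(config$phantom$shape,
                                    voxel_size = config$phantom$voxel_size,
                                    seed = config$phantom$seed,
                                    tissues = tissues,
                                    smooth_vox = config$phantom$smooth_vox)
  coils <- make_coil_profiles(phantom, L = config$engine$L,
                              covariance = config$engine$covariance)
  roi <- define_roi(phantom, config$roi$center, config$roi$semiaxes,
                    config$roi$gm_threshold)
  seqp <- config$sequence
  contrast <- contrast_volume(phantom, TR = seqp$TR_shot, TE = seqp$TE,
                              FA = seqp$FA)
  paradigm <- block_paradigm(config$paradigm$on_s, config$paradigm$off_s,
                             config$run$length_s)
  hemo <- hemodynamic_signal(paradigm, TR_shot = seqp$TR_shot)
  bold <- bold_spec(delta_R2s = config$bold$delta_R2s, TE = seqp$TE,
                    roi = roi, exact = isTRUE(config$bold$exact))
  chain <- handler_chain(bold_handler(bold, hemo))
  stage_t$setup <- tic() - t0

  ## acquisition -------------------------------------------------------
  t0 <- tic()
  timing <- derive_timing(config)
  patterns <- lapply(seq_len(timing$n_frames), function(f)
    build_frame_pattern(config, frame_index = f, seed = seed))
  noise <- if (is.finite(config$engine$snr_in)) {
    noise_spec(config$engine$snr_in, phantom_energy(contrast),
               covariance = config$engine$covariance %||% diag(coils$L),
               seed = mix_seed(seed, 1001L))
  } else NULL
  mrd_path <- file.path(out_dir, "run.mrd")
  acq <- run_acquisition(phantom, chain, patterns, coils, sequence = seqp,
                         engine = config$engine$kind, noise = noise,
                         output = mrd_path)
  stage_t$acquisition <- tic() - t0

  ## reconstruction ----------------------------------------------------
  t0 <- tic()
  frames <- mrd_frames(read_mrd(mrd_path))
  if (config$recon$method == "adjoint") {
    vols <- lapply(frames, adjoint_recon, coils = coils)
    diagnostics <- data.frame(frame = seq_along(vols), iterations = 0L,
                              cost = NA_real_, mu = NA_real_,
                              init_source = "adjoint")
    series <- structure(list(volumes = vols, diagnostics = diagnostics,
                             strategy = "adjoint"), class = "ksim_series")
  } else {
    wl <- wavelet_spec(config$recon$wavelet$family,
                       config$recon$wavelet$levels)
    series <- reconstruct_series(frames, coils,
                                 strategy = config$recon$strategy,
                                 wavelet = wl, mu = config$recon$mu,
                                 solver = config$recon$solver)
  }
  stage_t$reconstruction <- tic() - t0

  ## analysis ----------------------------------------------------------
  t0 <- tic()
  ftimes <- frame_timestamps(patterns, seqp$TR_shot,
                             config$analysis$frame_time)
  design <- design_matrix(hemo, ftimes)
  mag <- series_magnitude(series)
  stat <- glm_tstats(mag, design)
  detection <- threshold_map(stat, config$analysis$p)
  support <- head_mask(phantom)
  conf <- confusion_metrics(detection, roi, support = support)
  pr <- pr_curve_auc(stat, roi, support = support)
  tsn <- tsnr(mag, roi, design = design)
  imfirst <- image_metrics(series$volumes[[1]], contrast)
  imlast <- image_metrics(series$volumes[[length(series$volumes)]], contrast)
  report <- list(
    n_shots = acq$n_shots, n_frames = timing$n_frames,
    TR_vol_s = timing$TR_vol, n_roi_voxels = roi$n_active,
    confusion = conf[c("TP", "FP", "TN", "FN")],
    precision = conf$precision, recall = conf$recall, bacc = conf$bacc,
    pr_auc = pr$auc,
    tsnr_roi = tsn$tsnr, tsnr_roi_raw = tsn$tsnr_raw,
    psnr_first = imfirst$psnr, ssim_first = imfirst$ssim,
    psnr_last = imlast$psnr, ssim_last = imlast$ssim)
  stage_t$analysis <- tic() - t0

  ## outputs -----------------------------------------------------------
  paths <- list(mrd = mrd_path,
                series = file.path(out_dir, "series.nii.gz"),
                tmap = file.path(out_dir, "tmap.nii.gz"),
                report = file.path(out_dir, "report.json"),
                pr_curve = file.path(out_dir, "pr_curve.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  attr(mag, "pixdim") <- c(phantom$voxel_size, timing$TR_vol)
  RNifti::writeNifti(RNifti::asNifti(mag, datatype = "float"),
                     paths$series)
  tmap <- stat$tvalues
  attr(tmap, "pixdim") <- phantom$voxel_size
  RNifti::writeNifti(RNifti::asNifti(tmap, datatype = "float"),
                     paths$tmap)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.csv(pr$curve, paths$pr_curve, row.names = FALSE)
  cfg_yaml <- yaml::as.yaml(unclass(config))
  tmp <- tempfile(); writeLines(cfg_yaml, tmp)
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(tmp)),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("ksim")),
                   r_version = R.version.string,
                   stage_seconds = stage_t)
  unlink(tmp)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(report = report, series = series, stat = stat, roi = roi,
                 phantom = phantom, contrast = contrast, config = config,
                 paths = paths))
}
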