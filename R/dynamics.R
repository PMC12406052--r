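#' Block experimental paradigm
#'
#' Alternating rest/task blocks, rest first, truncated at `run_length`.
#' Block amplitudes are 1 by convention.
#'
#' @param on_s task block duration, seconds, > 0
#' @param off_s rest block duration, seconds, > 0
#' @param run_length total run duration, seconds, > 0
#' @return an object of class `ksim_paradigm` with a data frame `events`
#'   (onset, duration, amplitude, trial_type) and `run_length`
#' @export
block_paradigm <- function(on_s, off_s, run_length) {
  if (!is.numeric(run_length) || run_length <= 0) stop("run_length must be > 0")
  if (on_s <= 0 || off_s <= 0) stop("block durations must be > 0")
  onsets <- if (off_s < run_length)
    seq(off_s, run_length, by = on_s + off_s) else numeric(0)
  onsets <- onsets[onsets < run_length]
  n <- length(onsets)
  ev <- data.frame(onset = onsets,
                   duration = pmin(rep(on_s, n), run_length - onsets),
                   amplitude = rep(1, n),
                   trial_type = rep("task", n),
                   stringsAsFactors = FALSE)
  structure(list(events = ev, run_length = run_length),
            class = "ksim_paradigm")
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF (response peak near 5 s, undershoot near 15 s,
#' undershoot ratio 1/6), evaluated at `t` seconds after the impulse. The
#' absolute scale is irrelevant downstream because [hemodynamic_signal()]
#' renormalises the convolved signal.
#'
#' @param t time in seconds (vector)
#' @param peak_delay,undershoot_delay gamma shape parameters (s)
#' @param peak_disp,undershoot_disp gamma dispersions (s)
#' @param undershoot_ratio relative undershoot amplitude
#' @return HRF values, 0 for `t < 0`
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             undershoot_ratio = 1 / 6) {
  h <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      dgamma(t, shape = undershoot_delay / undershoot_disp,
             scale = undershoot_disp)
  h[t < 0] <- 0
  h
}

#' Normalized hemodynamic signal at shot resolution
#'
#' Convolves the paradigm's boxcar with a reference HRF and samples the
#' result every `TR_shot`. The signal is rescaled so that its maximum is
#' exactly 1 (the convention under which the BOLD amplitude parameter is
#' interpreted); an empty paradigm yields the all-zero signal with no
#' rescaling.
#'
#' @param paradigm a [block_paradigm()] (or compatible) object
#' @param TR_shot shot repetition time, ms, > 0
#' @param hrf_kind `"double-gamma"` (default) or a function `f(t_seconds)`
#' @return an object of class `ksim_hemo` with fields `times` (s) and
#'   `values` (dimensionless, max 1)
#' @export
hemodynamic_signal <- function(paradigm, TR_shot, hrf_kind = "double-gamma") {
  stopifnot(inherits(paradigm, "ksim_paradigm"))
  if (TR_shot <= 0) stop("TR_shot must be > 0 (ms)")
  dt <- TR_shot / 1000
  times <- seq(0, paradigm$run_length - dt / 2, by = dt)
  box <- rep(0, length(times))
  for (i in seq_len(nrow(paradigm$events))) {
    e <- paradigm$events[i, ]
    box[times >= e$onset & times < e$onset + e$duration] <-
      box[times >= e$onset & times < e$onset + e$duration] + e$amplitude
  }
  hrf_fun <- if (is.function(hrf_kind)) hrf_kind
  else if (identical(hrf_kind, "double-gamma")) hrf_double_gamma
  else stop("unknown hrf_kind: ", hrf_kind)
  hk <- hrf_fun(seq(0, 32, by = dt))
  v <- convolve(box, rev(hk), type = "open")[seq_along(box)] * dt
  m <- max(v)
  if (m > 0) v <- v / m
  structure(list(times = times, values = v), class = "ksim_hemo")
}

#' BOLD specification
#'
#' The BOLD effect is modeled as a task-locked change `delta_R2s` of the
#' gray-matter transverse relaxation rate inside the ROI, which at echo time
#' `TE` multiplies the gray-matter contrast by the linearized factor
#' `1 - TE * delta_R2s * h(t)` (or by `exp(-TE * delta_R2s * h(t))` when
#' `exact = TRUE`).
#'
#' @param delta_R2s relaxation-rate change, Hz (negative for a signal
#'   increase); default -1
#' @param TE echo time, ms
#' @param roi a [define_roi()] mask
#' @param exact use the exact exponential factor instead of its
#'   linearization; default FALSE
#' @return an object of class `ksim_bold`
#' @export
bold_spec <- function(delta_R2s = -1, TE, roi, exact = FALSE) {
  stopifnot(inherits(roi, "ksim_roi"))
  if (abs(TE / 1000 * delta_R2s) >= 1)
    stop("|TE * delta_R2s| must be < 1 (linearization validity)")
  structure(list(delta_R2s = delta_R2s, TE = TE, roi = roi, exact = exact),
            class = "ksim_bold")
}

#' BOLD-modulated gray-matter contrast
#'
#' \deqn{\mu_{BOLD}(t) = (1 - TE\,\Delta R_2^*\, \tilde h(t))\, \mu_{GM}}
#' with TE in seconds and `delta_R2s` in Hz. With the defaults
#' (`delta_R2s = -1` Hz, TE = 25 ms) the factor at the hemodynamic peak
#' (`h = 1`) is 1.025, i.e. a 2.5% signal increase.
#'
#' @param mu_gm baseline gray-matter contrast (scalar or array)
#' @param bold a [bold_spec()]
#' @param h normalized hemodynamic response value in [-1, 1] (the
#'   normalization fixes the maximum at 1; the post-stimulus undershoot of
#'   a double-gamma response makes h briefly negative)
#' @return the modulated contrast
#' @export
bold_contrast <- function(mu_gm, bold, h) {
  stopifnot(inherits(bold, "ksim_bold"))
  if (any(abs(h) > 1)) stop("|h| must be <= 1 (normalized response)")
  x <- (bold$TE / 1000) * bold$delta_R2s * h
  factor <- if (bold$exact) exp(-x) else 1 - x
  factor * mu_gm
}

#' Create a handler chain
#'
#' Handlers are pure state-update rules applied in order between consecutive
#' shots: each maps `(state, shot_index, time_s)` to a new state, where the
#' state carries the phantom and the current per-tissue contrast fields.
#' Purity (same inputs, same output) is what makes shot-wise streaming and
#' parallel replay possible: the state before any shot is recomputed from
#' the baseline state and the shot's index/time alone.
#'
#' @param ... handler objects (e.g. [bold_handler()])
#' @return an object of class `ksim_chain`
#' @export
handler_chain <- function(...) {
  hs <- list(...)
  for (h in hs) stopifnot(inherits(h, "ksim_handler"))
  structure(list(handlers = hs), class = "ksim_chain")
}

#' BOLD contrast handler
#'
#' Multiplies the gray-matter contrast field inside the ROI by the
#' [bold_contrast()] factor at the shot's time; all other voxels and tissues
#' are untouched. The factor is recomputed from the baseline state at every
#' call (never accumulated), so the handler is pure.
#'
#' @param bold a [bold_spec()]
#' @param hemo a [hemodynamic_signal()] sampled at shot resolution
#' @return a `ksim_handler`
#' @export
bold_handler <- function(bold, hemo) {
  stopifnot(inherits(bold, "ksim_bold"), inherits(hemo, "ksim_hemo"))
  fn <- function(state, shot_index, time_s) {
    idx <- which.min(abs(hemo$times - time_s))
    h <- hemo$values[idx]
    if (h != 0) {
      m <- bold$roi$mask
      state$mu$GM[m] <- bold_contrast(state$mu$GM[m], bold, h)
    }
    state
  }
  structure(list(name = "bold", fn = fn), class = "ksim_handler")
}

#' Baseline acquisition state of a phantom
#'
#' The state carries one contrast field per tissue,
#' \eqn{\mu_i(r)} (initially uniform at the tissue's GRE contrast), plus the
#' phantom itself. Handlers modify the contrast fields; the engines consume
#' \eqn{w_i(r)\mu_i(r)}.
#'
#' @param phantom a `ksim_phantom`
#' @param TR,TE,FA sequence parameters (ms, ms, degrees)
#' @return an object of class `ksim_state`
#' @export
baseline_state <- function(phantom, TR, TE, FA) {
  validate_phantom(phantom)
  mu <- lapply(phantom$tissues, function(ts)
    array(gre_contrast(ts, TR, TE, FA), dim = phantom$shape))
  structure(list(phantom = phantom, mu = mu,
                 sequence = list(TR = TR, TE = TE, FA = FA)),
            class = "ksim_state")
}

#' Apply a handler chain to a state
#'
#' @param chain a [handler_chain()]
#' @param state a [baseline_state()]
#' @param shot_index global shot counter (1-based)
#' @param time_s acquisition time of the shot, seconds
#' @return the updated state
#' @export
apply_handlers <- function(chain, state, shot_index, time_s) {
  stopifnot(inherits(chain, "ksim_chain"), inherits(state, "ksim_state"))
  for (h in chain$handlers) {
    state <- tryCatch(h$fn(state, shot_index, time_s),
                      error = function(e)
                        stop(sprintf("handler '%s' failed at shot %d: %s",
                                     h$name, shot_index, conditionMessage(e))))
  }
  state
}

#' Export a paradigm as a BIDS-style events table
#'
#' Tab-separated table with columns onset, duration, trial_type (seconds).
#'
#' @param paradigm a `ksim_paradigm`
#' @param path output TSV path
#' @export
write_events_tsv <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "ksim_paradigm"))
  ev <- paradigm$events[, c("onset", "duration", "trial_type")]
  write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a paradigm from a BIDS-style events table
#'
#' @param path TSV path with columns onset, duration and optionally
#'   trial_type, amplitude
#' @param run_length total run duration in seconds
#' @return a `ksim_paradigm`
#' @export
read_events_tsv <- function(path, run_length) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset", "duration") %in% names(ev)))
    stop("events table must have onset and duration columns")
  if (is.null(ev$amplitude)) ev$amplitude <- 1
  if (is.null(ev$trial_type)) ev$trial_type <- "task"
  if (any(ev$onset < 0) || any(ev$onset + ev$duration > run_length + 1e-9))
    stop("events fall outside [0, run_length]")
  structure(list(events = ev, run_length = run_length),
            class = "ksim_paradigm")
}
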