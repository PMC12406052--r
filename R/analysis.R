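#' GLM design matrix for a frame series
#'
#' Columns: the task regressor (normalized hemodynamic signal evaluated at
#' the frame timestamps), a constant, and optionally cosine drift
#' regressors. The simulation itself contains no drift, so the default is
#' constant-only.
#'
#' @param hemo a [hemodynamic_signal()]
#' @param frame_times frame timestamps, seconds
#' @param n_drifts number of cosine drift regressors (default 0)
#' @return an object of class `ksim_design` wrapping the T x p matrix
#' @export
design_matrix <- function(hemo, frame_times, n_drifts = 0) {
  stopifnot(inherits(hemo, "ksim_hemo"))
  task <- stats::approx(hemo$times, hemo$values, xout = frame_times,
                        rule = 2)$y
  X <- cbind(task = task, constant = 1)
  if (n_drifts > 0) {
    T_ <- length(frame_times)
    dur <- max(frame_times) - min(frame_times)
    for (k in seq_len(n_drifts))
      X <- cbind(X, cos(pi * k * (frame_times - min(frame_times)) / dur))
    colnames(X) <- c("task", "constant", paste0("drift", seq_len(n_drifts)))
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, frame_times = frame_times), class = "ksim_design")
}

#' Voxel-wise GLM t statistics
#'
#' Ordinary least squares per voxel, with the one-sided Student statistic
#' of the task regressor, `t = beta_task / SE(beta_task)`. Voxels whose
#' temporal standard deviation is below `degenerate_tol` times their mean
#' magnitude are treated as constant (representation-level noise, e.g. the
#' float32 granularity of the raw-data container): they get `t = 0` and are
#' flagged, and are excluded from precision/recall sweeps downstream.
#'
#' @param series 4D numeric array (x, y, z, t) of magnitudes, or a
#'   `ksim_series` (magnitudes are taken)
#' @param design a [design_matrix()]
#' @param degenerate_tol relative temporal-variation floor; default 1e-5
#' @return an object of class `ksim_statmap`: `tvalues` (3D array), `dof`,
#'   `beta` (task coefficients), `baseline` (constant coefficients),
#'   `degenerate` (logical 3D array)
#' @export
glm_tstats <- function(series, design, degenerate_tol = 1e-5) {
  stopifnot(inherits(design, "ksim_design"))
  if (inherits(series, "ksim_series"))
    series <- series_magnitude(series)
  d <- dim(series)
  if (length(d) != 4) stop("series must be a 4D array")
  T_ <- d[4]
  X <- design$X
  p <- ncol(X)
  if (T_ != nrow(X)) stop("frame count does not match the design")
  if (T_ < p + 1) stop("need at least rank+1 frames")
  V <- prod(d[1:3])
  Y <- matrix(series, nrow = V, ncol = T_)     # voxels x time
  Yt <- t(Y)                                   # time x voxels
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  B <- XtXi %*% crossprod(X, Yt)               # p x voxels
  R <- Yt - X %*% B
  dof <- T_ - p
  s2 <- colSums(R^2) / dof
  se <- sqrt(s2 * XtXi["task", "task"])
  tv <- B["task", ] / se
  mu_t <- colMeans(Yt)
  sd_t <- sqrt(colSums((Yt - rep(mu_t, each = T_))^2) / (T_ - 1))
  # relative rule, with the denominator floored at 1e-3 of the volume's
  # peak mean so that near-empty voxels carrying only representation
  # jitter are flagged too
  degen <- sd_t < degenerate_tol * pmax(abs(mu_t), 1e-3 * max(abs(mu_t)))
  tv[degen | !is.finite(tv)] <- 0
  structure(list(tvalues = array(tv, dim = d[1:3]), dof = dof,
                 beta = array(B["task", ], dim = d[1:3]),
                 baseline = array(B["constant", ], dim = d[1:3]),
                 degenerate = array(degen, dim = d[1:3])),
            class = "ksim_statmap")
}

#' Magnitude 4D array of a reconstructed series
#' @param series a `ksim_series`
#' @return 4D numeric array
#' @export
series_magnitude <- function(series) {
  stopifnot(inherits(series, "ksim_series"))
  d <- dim(series$volumes[[1]])
  out <- array(0, dim = c(d, length(series$volumes)))
  for (t in seq_along(series$volumes))
    out[, , , t] <- Mod(series$volumes[[t]])
  out
}

#' Threshold a statistic map at an uncorrected significance level
#'
#' One-sided test of positivity: the detection mask is
#' `t > qt(1 - p, dof)`.
#'
#' @param stat a [glm_tstats()] map
#' @param p significance level in (0, 1); default 0.001
#' @return logical 3D array
#' @export
threshold_map <- function(stat, p = 0.001) {
  stopifnot(inherits(stat, "ksim_statmap"))
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  stat$tvalues > qt(1 - p, df = stat$dof)
}

#' Confusion counts and detection scores
#'
#' Standard confusion matrix of a detection mask against the ground-truth
#' ROI, with precision, recall and balanced accuracy
#' `BACC = (TPR + TNR) / 2`. When nothing is detected (`TP + FP = 0`),
#' precision is reported as 0 with the `no_detection` flag set.
#'
#' @param detection logical 3D array
#' @param truth a `ksim_roi` or logical 3D array
#' @param support optional logical mask restricting the evaluation (e.g.
#'   the head mask); default: all voxels
#' @return list with TP, FP, TN, FN, precision, recall, specificity, bacc,
#'   no_detection
#' @export
confusion_metrics <- function(detection, truth, support = NULL) {
  tm <- if (inherits(truth, "ksim_roi")) truth$mask else truth
  if (!identical(dim(detection), dim(tm))) stop("shape mismatch")
  if (is.null(support)) support <- array(TRUE, dim = dim(tm))
  d <- detection[support]; g <- tm[support]
  TP <- sum(d & g); FP <- sum(d & !g); FN <- sum(!d & g); TN <- sum(!d & !g)
  no_det <- (TP + FP) == 0
  precision <- if (no_det) 0 else TP / (TP + FP)
  recall <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  specificity <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  list(TP = TP, FP = FP, TN = TN, FN = FN, precision = precision,
       recall = recall, specificity = specificity,
       bacc = (recall + specificity) / 2, no_detection = no_det)
}

#' Precision/recall curve and its area under the curve
#'
#' Precision and recall swept over every distinct t-threshold (activation
#' is a rare class, so the PR curve is preferred to the ROC). The AUC is
#' the trapezoid over the recall axis, with the recall = 0 endpoint closed
#' by duplicating the first precision value. Degenerate (flagged) voxels
#' are excluded from the sweep.
#'
#' @param stat a [glm_tstats()] map, or a numeric score array
#' @param truth a `ksim_roi` or logical array
#' @param support optional logical evaluation mask
#' @return list with `curve` (data frame recall/precision/threshold) and
#'   `auc`
#' @export
pr_curve_auc <- function(stat, truth, support = NULL) {
  tm <- if (inherits(truth, "ksim_roi")) truth$mask else truth
  if (inherits(stat, "ksim_statmap")) {
    keep <- !stat$degenerate
    scores <- stat$tvalues
  } else {
    keep <- array(TRUE, dim = dim(stat))
    scores <- stat
  }
  if (!is.null(support)) keep <- keep & support
  s <- as.numeric(scores[keep]); g <- as.logical(tm[keep])
  if (!any(g)) stop("ground truth is empty on the evaluation mask")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; g <- g[o]
  tp <- cumsum(g); fp <- cumsum(!g)
  # one operating point per distinct threshold (predict score >= threshold)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  P <- sum(g)
  recall <- tp / P
  precision <- tp / (tp + fp)
  r <- c(0, recall); pr <- c(precision[1], precision)
  auc <- sum(diff(r) * (head(pr, -1) + tail(pr, -1)) / 2)
  list(curve = data.frame(recall = recall, precision = precision,
                          threshold = thr),
       auc = auc)
}

#' Image quality metrics against the ground-truth contrast
#'
#' PSNR with the reference peak (`20 log10(peak / rmse)`, `Inf` for exact
#' equality) and SSIM with the standard constants (K1 = 0.01, K2 = 0.03,
#' dynamic range = reference peak) on magnitude images, using a separable
#' Gaussian window (sd 1.5 voxels).
#'
#' @param recon 3D array (complex allowed; magnitude is taken)
#' @param reference a [contrast_volume()] or 3D array
#' @return list with `psnr` (dB) and `ssim`
#' @export
image_metrics <- function(recon, reference) {
  ref <- if (inherits(reference, "ksim_contrast")) reference$values
  else reference
  x <- Mod(recon); r <- Mod(ref)
  if (!identical(dim(x), dim(r))) stop("shape mismatch")
  peak <- max(r)
  if (peak == 0) stop("zero reference volume")
  mse <- mean((x - r)^2)
  psnr <- if (mse == 0) Inf else 20 * log10(peak / sqrt(mse))
  w <- function(v) gaussian_smooth3(v, sigma_vox = 1.5)
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  mx <- w(x); mr <- w(r)
  vx <- w(x^2) - mx^2; vr <- w(r^2) - mr^2
  cxr <- w(x * r) - mx * mr
  ssim_map <- ((2 * mx * mr + C1) * (2 * cxr + C2)) /
    ((mx^2 + mr^2 + C1) * (vx + vr + C2))
  list(psnr = psnr, ssim = mean(ssim_map))
}

#' Temporal SNR over a region of interest
#'
#' Voxel-wise temporal mean over temporal standard deviation, averaged over
#' the ROI. When a design is supplied, the fitted task component is
#' regressed out first so genuine activation does not inflate the apparent
#' noise (`tsnr` field); the raw-series value is always reported too
#' (`tsnr_raw`). Voxels with zero temporal variance are flagged and
#' reported as infinite.
#'
#' @param series 4D magnitude array or `ksim_series`
#' @param roi a `ksim_roi` or logical 3D array
#' @param design optional [design_matrix()] for task removal
#' @return list with `tsnr`, `tsnr_raw`, `n_flagged`
#' @export
tsnr <- function(series, roi, design = NULL) {
  if (inherits(series, "ksim_series")) series <- series_magnitude(series)
  m <- if (inherits(roi, "ksim_roi")) roi$mask else roi
  d <- dim(series)
  if (d[4] < 2) stop("need at least 2 frames")
  V <- prod(d[1:3])
  Y <- t(matrix(series, nrow = V))[, as.vector(m), drop = FALSE]  # T x Vroi
  ts_of <- function(M) {
    mu <- colMeans(M)
    s <- apply(M, 2, sd)
    z <- s == 0
    v <- mu / s
    v[z] <- Inf
    list(v = v, flagged = sum(z))
  }
  raw <- ts_of(Y)
  if (!is.null(design)) {
    X <- design$X
    B <- solve(crossprod(X), crossprod(X, Y))
    task_fit <- X[, "task", drop = FALSE] %*% B["task", , drop = FALSE]
    det <- ts_of(Y - task_fit)
  } else det <- raw
  list(tsnr = mean(det$v), tsnr_raw = mean(raw$v),
       n_flagged = det$flagged)
}
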