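#' Remove the linear trend from a run's time series
#'
#' Least-squares removal of intercept and slope from each voxel's time
#' series within a single run, the detrending step applied before pattern
#' extraction. Accepts a numeric vector or a time-by-voxel matrix.
#'
#' @param x numeric vector (time) or matrix (time x voxels).
#' @return residual series of the same shape, with zero least-squares
#'   linear trend.
#' @export
detrend_run <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 3) stop("run too short to detrend: need at least 3 volumes")
  tc <- seq_len(n) - (n + 1) / 2            # centered time, orthogonal to 1
  slope <- crossprod(tc, x) / sum(tc^2)     # 1 x V
  res <- sweep(x, 2, colMeans(x)) - tcrossprod(tc, t(slope))
  if (vec) drop(res) else res
}

#' Detrend and normalize a dataset run by run
#'
#' Applies [detrend_run()] to every voxel within every run, then (by
#' default) z-scores each voxel's residual series within the run. Voxels
#' with zero residual variance are left at zero. This per-voxel, per-run
#' normalization never crosses the train/test boundary of a
#' leave-one-run-out fold, since folds are whole runs.
#'
#' @param ds a `functional_dataset`.
#' @param zscore_voxels z-score each voxel within run after detrending.
#' @return the dataset with preprocessed `data`.
#' @export
preprocess_dataset <- function(ds, zscore_voxels = TRUE) {
  stopifnot(inherits(ds, "functional_dataset"))
  dims <- dim(ds$data)
  m <- matrix(ds$data, prod(dims[1:3]), dims[4])
  for (r in unique(ds$run_index)) {
    cols <- which(ds$run_index == r)
    res <- t(detrend_run(t(m[, cols, drop = FALSE])))
    if (zscore_voxels) {
      sds <- sqrt(rowSums(res^2) / (length(cols) - 1))
      sds[sds == 0] <- 1
      res <- res / sds
    }
    m[, cols] <- res
  }
  ds$data <- array(m, dims)
  ds$preprocessed <- TRUE
  ds
}

#' Map a stimulus onset to the volume used for decoding
#'
#' Under the default `containment` convention, volume `k = 0` is the volume
#' whose acquisition window `[j*TR, (j+1)*TR)` contains the onset (the
#' pre/at-onset volume), and `k >= 1` selects the k-th complete volume
#' beginning after the onset: with TR = 3 s the k-th volume spans roughly
#' `(3(k-1), 3k]` seconds post-onset (up to sub-TR onset jitter), so `k = 2`
#' is the volume acquired about 4-6 s after the stimulus, where the
#' hemodynamic response peaks. The `ceil` convention instead counts volumes
#' from the first acquisition boundary at or after the onset.
#'
#' @param onset seconds from run start (vectorized).
#' @param tr repetition time, seconds.
#' @param k post-stimulus volume index, 0 (pre/at onset) to 6.
#' @param convention onset-to-grid convention, `"containment"` (default) or
#'   `"ceil"`.
#' @return 0-based volume index within the run (integer vector). Indices
#'   are not checked against the run length here; extraction drops trials
#'   whose index falls beyond the run.
#' @export
select_trial_volume <- function(onset, tr, k,
                                convention = c("containment", "ceil")) {
  convention <- match.arg(convention)
  if (!is_count(k, min = 0) || k > 6) stop("k must be an integer in 0..6")
  base <- floor(onset / tr)
  idx <- if (k == 0) base
         else if (convention == "containment") base + k
         else ceiling(onset / tr) + (k - 1)
  as.integer(idx)
}

#' Extract normalized trial patterns from a region of interest
#'
#' For every event, takes the spatial pattern of the (preprocessed) signal
#' across the ROI's voxels at the volume selected by
#' [select_trial_volume()], and standardizes each pattern across voxels
#' (subtract the row mean, divide by the row standard deviation). This
#' per-pattern normalization removes any bulk amplitude difference between
#' conditions, so that classification can only exploit the fine-grained
#' spatial distribution of the response. Trials whose extraction volume
#' falls beyond the end of the run are dropped with a warning, never
#' imputed.
#'
#' @param ds a `functional_dataset`, normally after [preprocess_dataset()].
#' @param events an `event_table`.
#' @param roi binary 3D mask with at least 2 voxels.
#' @param k post-stimulus volume index (default 2, the response peak).
#' @param normalize standardize each trial pattern across voxels
#'   (default TRUE).
#' @param convention passed to [select_trial_volume()].
#' @param roi_name label stored with the result.
#' @return a `trial_patterns` object: list with `x` (trials x voxels
#'   matrix), `condition` (factor), `run` (integer), `voxels` (linear
#'   indices), `k`, `roi` and `dropped` (indices of dropped events).
#' @export
extract_patterns <- function(ds, events, roi, k = 2, normalize = TRUE,
                             convention = c("containment", "ceil"),
                             roi_name = "roi") {
  stopifnot(inherits(ds, "functional_dataset"))
  convention <- match.arg(convention)
  vox <- mask_voxels(roi)
  if (length(vox) < 2) stop("ROI must contain at least 2 voxels")
  nv <- ds$acq$n_volumes_per_run
  dims <- dim(ds$data)
  m <- matrix(ds$data, prod(dims[1:3]), dims[4])
  idx0 <- select_trial_volume(events$onset, ds$acq$tr, k, convention)
  ok <- idx0 >= 0 & idx0 < nv
  if (any(!ok))
    warning(sprintf("dropped %d trial(s) whose extraction volume lies outside the run: %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  keep <- which(ok)
  cols <- (events$run[keep] - 1L) * nv + idx0[keep] + 1L
  x <- t(m[vox, cols, drop = FALSE])
  if (normalize) {
    mu <- rowMeans(x)
    sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
    if (any(sd == 0))
      stop(sprintf("zero-variance pattern for trial(s): %s",
                   paste(keep[sd == 0], collapse = ", ")))
    x <- (x - mu) / sd
  }
  lev <- attr(events, "conditions")
  if (is.null(lev)) lev <- sort(unique(events$condition))
  structure(list(x = x,
                 condition = factor(events$condition[keep], levels = lev),
                 run = as.integer(events$run[keep]),
                 voxels = vox, k = k, roi = roi_name,
                 dropped = which(!ok)),
            class = "trial_patterns")
}

#' @export
print.trial_patterns <- function(x, ...) {
  cat(sprintf("trial_patterns: %d trials x %d voxels (ROI '%s', volume k=%d)\n",
              nrow(x$x), ncol(x$x), x$roi, x$k))
  print(table(condition = x$condition, run = x$run))
  invisible(x)
}

#' Restrict or relabel the conditions of a trial-pattern set
#'
#' Subsets a `trial_patterns` object to the given conditions and optionally
#' maps them onto new labels. Relabelling implements pooled-condition
#' tasks (for example two stimulus locations pooled under one modality
#' label before training); the original sub-condition labels are retained
#' in `$sub_condition` for auditing.
#'
#' @param tp a `trial_patterns` object.
#' @param conditions condition labels to keep, in the desired level order.
#' @param relabel optional named character vector mapping each kept
#'   condition to its pooled label.
#' @return a `trial_patterns` object.
#' @export
subset_patterns <- function(tp, conditions, relabel = NULL) {
  keep <- tp$condition %in% conditions
  out <- tp
  out$x <- tp$x[keep, , drop = FALSE]
  out$run <- tp$run[keep]
  orig <- factor(as.character(tp$condition[keep]), levels = conditions)
  if (!is.null(relabel)) {
    out$condition <- factor(unname(relabel[as.character(orig)]),
                            levels = unique(unname(relabel)))
    out$sub_condition <- orig
  } else {
    out$condition <- orig
  }
  out
}
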