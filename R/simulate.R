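#' Condition-specific multivoxel pattern specification
#'
#' Each condition carries a voxel-weight map (unitless response amplitudes,
#' non-zero only inside regions of interest) describing the fine-grained
#' spatial pattern its events evoke. `effect_size` scales all maps jointly;
#' `effect_size = 0` yields a pure-noise dataset, the null used by the
#' chance-calibration checks.
#'
#' @param maps named list (one element per condition) of 3D numeric arrays
#'   on the functional grid.
#' @param effect_size non-negative global multiplier of the pattern maps.
#' @return an object of class `pattern_spec`.
#' @export
pattern_spec <- function(maps, effect_size = 1) {
  stopifnot(is.list(maps), length(maps) >= 1, !is.null(names(maps)))
  dims <- dim(maps[[1]])
  if (length(dims) != 3) stop("pattern maps must be 3D arrays")
  for (m in maps) if (!identical(dim(m), dims)) stop("pattern maps must share one grid")
  if (!is.numeric(effect_size) || effect_size < 0) stop("effect_size must be >= 0")
  structure(list(maps = maps, effect_size = effect_size, dim = dims),
            class = "pattern_spec")
}

#' Draw random condition patterns inside regions of interest
#'
#' For every condition, a random subset of each ROI's voxels (fraction
#' `sparsity`) receives a Gaussian amplitude (mean 0, sd `amplitude_sd`),
#' mimicking scattered populations of positively and negatively responding
#' voxels; the remaining voxels carry no condition-specific signal.
#'
#' @param rois named list of binary 3D masks on the functional grid.
#' @param conditions character vector of condition labels.
#' @param sparsity fraction of ROI voxels carrying signal, in (0, 1].
#' @param amplitude_sd standard deviation of voxel amplitudes (signal units).
#' @param effect_size passed to [pattern_spec()].
#' @param seed integer seed.
#' @return a `pattern_spec`.
#' @export
random_patterns <- function(rois, conditions, sparsity = 0.5,
                            amplitude_sd = 1, effect_size = 1, seed = 1) {
  stopifnot(is.list(rois), length(rois) >= 1)
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  dims <- dim(rois[[1]])
  with_seed(seed, {
    maps <- lapply(conditions, function(cond) {
      m <- array(0, dims)
      for (roi in rois) {
        vox <- mask_voxels(roi)
        k <- max(1L, ceiling(sparsity * length(vox)))
        sel <- if (k >= length(vox)) vox else sample(vox, k)
        m[sel] <- stats::rnorm(k, sd = amplitude_sd)
      }
      m
    })
    names(maps) <- conditions
    pattern_spec(maps, effect_size = effect_size)
  })
}

#' Noise model for the simulator
#'
#' Additive white Gaussian noise at every voxel plus a per-run, per-voxel
#' linear drift with random slope. All randomness is keyed to `seed`, so
#' identical seeds produce bit-identical datasets.
#'
#' @param white_sd standard deviation of white noise (signal units).
#' @param drift_slope_sd standard deviation of the drift slope
#'   (signal units per volume); drift is linear within each run.
#' @param seed integer seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 1, drift_slope_sd = 0.02, seed = 1) {
  if (white_sd < 0 || drift_slope_sd < 0) stop("noise SDs must be >= 0")
  structure(list(white_sd = white_sd, drift_slope_sd = drift_slope_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate an event-related BOLD dataset
#'
#' Builds a 4D functional dataset by linear superposition: each voxel's time
#' series is the sum over events of that event's condition pattern amplitude
#' times the peak-normalized [hrf()] shifted to the event onset, sampled at
#' volume mid-acquisition times, scaled by `effect_size`, plus linear drift
#' (brain voxels) and white noise (all voxels). Runs are generated
#' independently and concatenated along the fourth dimension.
#'
#' @param events an `event_table` from [generate_design()] or [read_events()].
#' @param patterns a [pattern_spec()].
#' @param noise a [noise_model()].
#' @param acq an [acq_params()].
#' @param masks optional named list of ROI masks; if supplied, every
#'   non-zero pattern voxel must lie inside their union (error otherwise).
#' @param brain_mask optional binary mask; drift is confined to it
#'   (default: whole grid).
#' @param voxel_size voxel edge lengths in mm, recorded as metadata.
#' @return a `functional_dataset`: list with `data` (4D array x,y,z,time),
#'   `run_index` (run id per volume), `acq`, and `voxel_size`.
#' @export
simulate_dataset <- function(events, patterns, noise, acq,
                             masks = NULL, brain_mask = NULL,
                             voxel_size = c(3, 3, 3)) {
  stopifnot(inherits(patterns, "pattern_spec"), inherits(noise, "noise_model"),
            inherits(acq, "acq_params"))
  dims <- patterns$dim
  if (!is.null(masks)) {
    un <- Reduce(`+`, masks) != 0
    for (cond in names(patterns$maps)) {
      bad <- patterns$maps[[cond]] != 0 & !un
      if (any(bad))
        stop(sprintf("pattern/mask mismatch: condition '%s' has %d signal voxels outside the supplied masks",
                     cond, sum(bad)))
    }
  }
  nv <- acq$n_volumes_per_run
  nt <- nv * acq$n_runs
  run_duration <- nv * acq$tr
  if (any(events$onset < 0 | events$onset >= run_duration))
    stop("events do not fit within the runs")
  if (any(!events$run %in% seq_len(acq$n_runs)))
    stop("event run indices exceed n_runs")
  nvox <- prod(dims)
  brain_idx <- if (is.null(brain_mask)) seq_len(nvox) else mask_voxels(brain_mask)

  # signal voxels: union of non-zero pattern support (deterministic part)
  sig_idx <- which(Reduce(`|`, lapply(patterns$maps, function(m) m != 0)))
  t_mid <- (seq_len(nv) - 0.5) * acq$tr  # mid-acquisition time of each volume

  data <- matrix(0, nvox, nt)
  with_seed(noise$seed, {
    for (r in seq_len(acq$n_runs)) {
      cols <- (r - 1L) * nv + seq_len(nv)
      if (noise$white_sd > 0)
        data[, cols] <- matrix(stats::rnorm(nvox * nv, sd = noise$white_sd),
                               nvox, nv)
      if (noise$drift_slope_sd > 0) {
        slopes <- stats::rnorm(length(brain_idx), sd = noise$drift_slope_sd)
        tc <- seq_len(nv) - (nv + 1) / 2
        data[brain_idx, cols] <- data[brain_idx, cols] + outer(slopes, tc)
      }
    }
  })
  if (patterns$effect_size > 0 && length(sig_idx) > 0) {
    amp <- vapply(patterns$maps, function(m) m[sig_idx],
                  numeric(length(sig_idx)))  # voxels x conditions
    if (is.null(dim(amp))) amp <- matrix(amp, nrow = length(sig_idx))
    colnames(amp) <- names(patterns$maps)
    for (r in seq_len(acq$n_runs)) {
      ev_r <- events[events$run == r, , drop = FALSE]
      if (nrow(ev_r) == 0) next
      S <- matrix(0, length(sig_idx), nv)
      for (i in seq_len(nrow(ev_r))) {
        cond <- ev_r$condition[i]
        if (!cond %in% colnames(amp)) next  # condition with no pattern map
        h <- hrf(t_mid - ev_r$onset[i])
        nz <- which(h != 0)
        if (length(nz))
          S[, nz] <- S[, nz] + patterns$effect_size * outer(amp[, cond], h[nz])
      }
      cols <- (r - 1L) * nv + seq_len(nv)
      data[sig_idx, cols] <- data[sig_idx, cols] + S
    }
  }
  structure(list(data = array(data, c(dims, nt)),
                 run_index = rep(seq_len(acq$n_runs), each = nv),
                 acq = acq, voxel_size = voxel_size),
            class = "functional_dataset")
}

#' @export
print.functional_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("functional_dataset: %d x %d x %d grid, %d volumes (%d runs of %d, TR %g s)\n",
              d[1], d[2], d[3], d[4], x$acq$n_runs, x$acq$n_volumes_per_run,
              x$acq$tr))
  invisible(x)
}

#' Out-of-brain control region
#'
#' Randomly selects voxels outside the brain mask; the voxel count equals
#' the rounded mean of the supplied ROI sizes, so decoding from the control
#' region is directly comparable with the real ROIs while, by construction,
#' its voxels carry no stimulus-related signal.
#'
#' @param brain_mask binary 3D mask of the brain.
#' @param roi_masks list of binary ROI masks whose mean size sets the count.
#' @param seed integer seed.
#' @return a binary 3D mask disjoint from `brain_mask`.
#' @export
make_control_roi <- function(brain_mask, roi_masks, seed = 1) {
  stopifnot(length(dim(brain_mask)) == 3, is.list(roi_masks))
  n <- round(mean(vapply(roi_masks, function(m) sum(m != 0), numeric(1))))
  outside <- which(brain_mask == 0)
  if (length(outside) < n)
    stop(sprintf("insufficient out-of-brain voxels: need %d, found %d",
                 n, length(outside)))
  with_seed(seed, {
    sel <- if (n == length(outside)) outside else sample(outside, n)
    m <- array(0L, dim(brain_mask))
    m[sel] <- 1L
    m
  })
}

#' Toy geometry: a synthetic brain with cubic regions of interest
#'
#' A convenience fixture builder: a box-shaped "brain" mask occupying the
#' centre of the grid and three disjoint cubic ROIs inside it (named S1, A1
#' and V1 after the primary sensory cortices they stand in for). Purely
#' synthetic geometry; anatomical atlases are out of scope.
#'
#' @param dim grid dimensions (3 integers); must fit three disjoint cubes.
#' @param roi_side edge length of the cubic ROIs, voxels.
#' @return list with `brain_mask` and `rois` (named list of masks).
#' @export
demo_geometry <- function(dim = c(20, 16, 10), roi_side = 5) {
  stopifnot(length(dim) == 3, roi_side >= 2)
  if (any(dim < c(3 * roi_side + 4, roi_side + 4, roi_side + 4)))
    stop("grid too small for three disjoint ROIs of this size")
  brain <- array(0L, dim)
  brain[2:(dim[1] - 1), 2:(dim[2] - 1), 2:(dim[3] - 1)] <- 1L
  cube <- function(x0) {
    m <- array(0L, dim)
    m[x0 + seq_len(roi_side) - 1, 3:(2 + roi_side), 3:(2 + roi_side)] <- 1L
    m
  }
  starts <- round(seq(2, dim[1] - roi_side, length.out = 3))
  rois <- list(S1 = cube(starts[1]), A1 = cube(starts[2]), V1 = cube(starts[3]))
  list(brain_mask = brain, rois = rois)
}

#' Write / read functional data and masks as NIfTI-1
#'
#' Thin wrappers around RNifti. The dataset writer stores the 4D array with
#' voxel size and TR in `pixdim`; run structure and acquisition parameters
#' are echoed to a JSON sidecar (same path with extension `.json`).
#'
#' @param ds a `functional_dataset`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param mask a binary 3D array.
#' @return the path, invisibly; `read_mask` returns a 3D integer array.
#' @export
write_functional_dataset <- function(ds, path) {
  img <- RNifti::asNifti(ds$data,
                         pixdim = c(ds$voxel_size, ds$acq$tr))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(tr = ds$acq$tr,
                            n_volumes_per_run = ds$acq$n_volumes_per_run,
                            n_runs = ds$acq$n_runs,
                            run_index = ds$run_index,
                            voxel_size = ds$voxel_size),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_functional_dataset
#' @export
read_functional_dataset <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  acq <- acq_params(tr = meta$tr, n_volumes_per_run = meta$n_volumes_per_run,
                    n_runs = meta$n_runs)
  structure(list(data = array(as.numeric(img), dim(img)),
                 run_index = as.integer(meta$run_index),
                 acq = acq, voxel_size = as.numeric(meta$voxel_size)),
            class = "functional_dataset")
}

#' @rdname write_functional_dataset
#' @export
write_mask <- function(mask, path, voxel_size = c(3, 3, 3)) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask != 0), dim(mask)),
                                     pixdim = voxel_size), path)
  invisible(path)
}

#' @rdname write_functional_dataset
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.integer(img != 0), dim(img))
}
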