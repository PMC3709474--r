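#' Sensitivity map from classifier weights
#'
#' A per-voxel map of each voxel's contribution to one binary decoding
#' task: at the subject level the values are the (fold-averaged) linear SVM
#' weights; at the group level they are F-statistics testing the weights
#' against zero across subjects.
#'
#' @param values numeric vector, one value per ROI voxel.
#' @param voxels linear voxel indices on the common grid.
#' @param dim grid dimensions (3 integers).
#' @param task task label.
#' @param level `"subject"` or `"group"`.
#' @return an object of class `sensitivity_map`.
#' @seealso [group_f_map()], [distance_matrix()]
#' @export
sensitivity_map <- function(values, voxels, dim, task = "",
                            level = c("subject", "group")) {
  level <- match.arg(level)
  stopifnot(length(values) == length(voxels), length(dim) == 3)
  structure(list(values = values, voxels = voxels, dim = dim,
                 task = task, level = level),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("sensitivity map [%s, %s level]: %d voxels on a %s grid\n",
              x$task, x$level, length(x$voxels), paste(x$dim, collapse = "x")))
  invisible(x)
}

#' @export
as.array.sensitivity_map <- function(x, ...) {
  a <- array(NA_real_, x$dim)
  a[x$voxels] <- x$values
  a
}

# subject-level map from a two-way decoding result
decoding_map <- function(decoding, tp, dim) {
  stopifnot(inherits(decoding, "mvpa_decoding"), !is.null(decoding$weights))
  sensitivity_map(decoding$weights, tp$voxels, dim, task = decoding$task,
                  level = "subject")
}

#' Critical F value for the group sensitivity-map threshold
#'
#' One-sample F test of the mean against zero has (1, n-1) degrees of
#' freedom; with 14 subjects and alpha = 0.05 the critical value is 4.67.
#'
#' @param n_subjects number of subjects.
#' @param alpha significance level.
#' @return critical value of F(1, n-1).
#' @export
f_threshold <- function(n_subjects, alpha = 0.05) {
  stopifnot(n_subjects >= 2)
  stats::qf(1 - alpha, 1, n_subjects - 1)
}

#' Group-level sensitivity map (F-test against zero)
#'
#' For every voxel, the subjects' weights are tested against zero with a
#' one-sample F test (the squared one-sample t), giving a group-level
#' measure of each voxel's contribution after between-subject variability
#' is taken into account. Voxels where every subject's weight is zero are
#' undefined and excluded (NA, with a warning); voxels with zero
#' between-subject variance but non-zero mean get an infinite F sentinel.
#'
#' @param subject_maps list of subject-level `sensitivity_map`s on the same
#'   voxels, or a subjects-by-voxels matrix.
#' @param alpha significance level for the threshold.
#' @return a group-level `sensitivity_map` of F values, with attributes
#'   `df`, `threshold` (the alpha critical value) and `significant`
#'   (logical per voxel).
#' @export
group_f_map <- function(subject_maps, alpha = 0.05) {
  if (is.list(subject_maps) && inherits(subject_maps[[1]], "sensitivity_map")) {
    vox <- subject_maps[[1]]$voxels
    dm <- subject_maps[[1]]$dim
    task <- subject_maps[[1]]$task
    for (m in subject_maps)
      if (!identical(m$voxels, vox)) stop("subject maps must share a voxel grid")
    W <- do.call(rbind, lapply(subject_maps, `[[`, "values"))
  } else {
    W <- as.matrix(subject_maps)
    vox <- seq_len(ncol(W)); dm <- c(ncol(W), 1L, 1L); task <- ""
  }
  n <- nrow(W)
  if (n < 2) stop("need at least 2 subjects")
  mu <- colMeans(W)
  va <- colSums(sweep(W, 2, mu)^2) / (n - 1)
  f <- (mu / sqrt(va / n))^2
  allzero <- va == 0 & mu == 0
  novar <- va == 0 & mu != 0
  if (any(allzero)) {
    warning(sprintf("%d voxel(s) zero in every subject: F undefined, excluded", sum(allzero)))
    f[allzero] <- NA_real_
  }
  if (any(novar)) {
    warning(sprintf("%d voxel(s) with zero between-subject variance: F = Inf", sum(novar)))
    f[novar] <- Inf
  }
  thr <- f_threshold(n, alpha)
  out <- sensitivity_map(f, vox, dm, task = task, level = "group")
  attr(out, "df") <- c(1, n - 1)
  attr(out, "threshold") <- thr
  attr(out, "significant") <- !is.na(f) & f > thr
  out
}

#' Dissimilarity matrix between group sensitivity maps
#'
#' Pairwise dissimilarity between tasks, defined as 1 - r where r is the
#' Pearson correlation between two group-level maps over their shared
#' voxels (NA voxels excluded pairwise; zero-weight voxels are informative
#' and included). Entries lie in [0, 2]: identical maps give 0, perfectly
#' anticorrelated maps give 2, orthogonal maps give 1.
#'
#' @param group_maps named list of group-level `sensitivity_map`s (or plain
#'   numeric vectors on a common voxel set).
#' @return symmetric task x task matrix of class `map_distance`.
#' @export
distance_matrix <- function(group_maps) {
  stopifnot(is.list(group_maps), length(group_maps) >= 2)
  nm <- names(group_maps)
  if (is.null(nm))
    nm <- vapply(group_maps, function(m)
      if (inherits(m, "sensitivity_map")) m$task else "", character(1))
  vals <- lapply(group_maps, function(m)
    if (inherits(m, "sensitivity_map")) m$values else as.numeric(m))
  ids <- lapply(group_maps, function(m)
    if (inherits(m, "sensitivity_map")) m$voxels else seq_along(m))
  k <- length(vals)
  D <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    shared <- intersect(ids[[i]], ids[[j]])
    if (length(shared) < 3) stop("maps share too few voxels")
    a <- vals[[i]][match(shared, ids[[i]])]
    b <- vals[[j]][match(shared, ids[[j]])]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop(sprintf("constant map ('%s' or '%s'): correlation undefined", nm[i], nm[j]))
    D[i, j] <- D[j, i] <- 1 - stats::cor(a, b)
  }
  class(D) <- c("map_distance", "matrix")
  D
}

#' @export
print.map_distance <- function(x, digits = 3, ...) {
  cat("map dissimilarity (1 - Pearson r):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Univariate GLM betas for a set of voxels
#'
#' Conventional voxel-wise general linear model: one regressor per
#' condition (the event train convolved with the canonical [hrf()],
#' sampled at volume mid-acquisition times) plus a per-run intercept and
#' per-run linear drift term, estimated by ordinary least squares. Used to
#' characterize whether voxels contributing to classification carry
#' positive BOLD responses, negative responses, or a mixture.
#'
#' @param ds a `functional_dataset` (raw, not detrended: the model carries
#'   its own drift columns).
#' @param events an `event_table`.
#' @param mask binary mask of voxels to fit (for example the significant
#'   voxels of a group sensitivity map).
#' @param hrf_args optional list of arguments passed to [hrf()].
#' @return an object of class `beta_summary`: `betas` (voxels x
#'   conditions), `voxels`, the design matrix `X`, and per-condition sign
#'   proportions over {positive, negative, zero}.
#' @export
glm_betas <- function(ds, events, mask, hrf_args = list()) {
  stopifnot(inherits(ds, "functional_dataset"))
  vox <- mask_voxels(mask)
  conds <- attr(events, "conditions")
  if (is.null(conds)) conds <- sort(unique(events$condition))
  nv <- ds$acq$n_volumes_per_run
  nruns <- ds$acq$n_runs
  nt <- nv * nruns
  t_mid <- (seq_len(nv) - 0.5) * ds$acq$tr
  X <- matrix(0, nt, length(conds) + 2 * nruns)
  colnames(X) <- c(conds, paste0("run", seq_len(nruns), "_intercept"),
                   paste0("run", seq_len(nruns), "_drift"))
  for (r in seq_len(nruns)) {
    rows <- (r - 1L) * nv + seq_len(nv)
    ev_r <- events[events$run == r, , drop = FALSE]
    for (i in seq_len(nrow(ev_r))) {
      ci <- match(ev_r$condition[i], conds)
      X[rows, ci] <- X[rows, ci] +
        do.call(hrf, c(list(t_mid - ev_r$onset[i]), hrf_args))
    }
    X[rows, length(conds) + r] <- 1
    X[rows, length(conds) + nruns + r] <- seq_len(nv) - (nv + 1) / 2
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  dims <- dim(ds$data)
  Y <- t(matrix(ds$data, prod(dims[1:3]), dims[4])[vox, , drop = FALSE])
  B <- qr.coef(qrX, Y)                 # coefficients x voxels
  betas <- t(B[seq_along(conds), , drop = FALSE])
  rownames(betas) <- NULL
  colnames(betas) <- conds
  tol <- 1e-8
  signs <- vapply(conds, function(cc) {
    b <- betas[, cc]
    c(positive = mean(b > tol), negative = mean(b < -tol),
      zero = mean(abs(b) <= tol))
  }, numeric(3))
  structure(list(betas = betas, voxels = vox, conditions = conds,
                 X = X, sign_proportions = t(signs)),
            class = "beta_summary")
}

#' @export
print.beta_summary <- function(x, ...) {
  cat(sprintf("GLM beta summary: %d voxels, %d conditions\n",
              nrow(x$betas), length(x$conditions)))
  cat("sign proportions (rows sum to 1):\n")
  print(round(x$sign_proportions, 3))
  invisible(x)
}

#' Write a sensitivity map as NIfTI
#'
#' @param map a `sensitivity_map`.
#' @param path output path.
#' @param voxel_size voxel edge lengths in mm.
#' @export
write_sensitivity_map <- function(map, path, voxel_size = c(3, 3, 3)) {
  a <- as.array(map)
  a[!is.finite(a)] <- 0
  RNifti::writeNifti(RNifti::asNifti(a, pixdim = voxel_size), path)
  invisible(path)
}
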