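#' Study configuration
#'
#' Bundles everything an end-to-end experiment needs: the event-related
#' design, acquisition timing, ROI geometry, simulation parameters,
#' decoding settings and seeds. Two profiles are provided: `"ci"` (6
#' simulated subjects, 1,000 permutations, small ROIs) sized so a full
#' experiment runs in minutes on one CPU, and `"paper"` (14 subjects,
#' 10,000 permutations) matching the scale of the emulated study. All
#' randomness is keyed to `seed`; no wall-clock seeding anywhere.
#'
#' @param profile `"ci"` or `"paper"`.
#' @param design a [design_spec()].
#' @param acq an [acq_params()].
#' @param geometry list with `brain_mask` and named `rois`
#'   (default [demo_geometry()]).
#' @param roi_modality named character vector mapping ROI name to its
#'   principal condition (used to split pertinent from non-pertinent tasks).
#' @param modality_of named character vector mapping each condition to its
#'   modality (required by [run_experiment2()] for pooling).
#' @param n_subjects,n_permutations overrides of the profile defaults.
#' @param effect_size,pattern_sparsity,amplitude_sd simulation signal
#'   parameters (see [random_patterns()]).
#' @param white_sd,drift_slope_sd noise parameters (see [noise_model()]).
#' @param k post-stimulus volume used for decoding (default 2).
#' @param cost SVM regularization constant.
#' @param timecourse_k volume offsets for the time-course analysis, or
#'   NULL to skip it.
#' @param control_roi include an out-of-brain control region.
#' @param seed master integer seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(profile = c("ci", "paper"),
                         design = design_spec(),
                         acq = acq_params(),
                         geometry = demo_geometry(),
                         roi_modality = c(S1 = "touch", A1 = "audition", V1 = "vision"),
                         modality_of = NULL,
                         n_subjects = NULL, n_permutations = NULL,
                         effect_size = 1, pattern_sparsity = 0.5,
                         amplitude_sd = 1, white_sd = 1, drift_slope_sd = 0.02,
                         k = 2, cost = 1, timecourse_k = 0:6,
                         control_roi = TRUE, seed = 1) {
  profile <- match.arg(profile)
  if (is.null(n_subjects)) n_subjects <- if (profile == "ci") 6L else 14L
  if (is.null(n_permutations)) n_permutations <- if (profile == "ci") 1000L else 10000L
  stopifnot(inherits(design, "design_spec"), inherits(acq, "acq_params"),
            is.list(geometry), !is.null(geometry$rois))
  if (!all(names(roi_modality) %in% names(geometry$rois)))
    roi_modality <- roi_modality[names(roi_modality) %in% names(geometry$rois)]
  structure(list(profile = profile, design = design, acq = acq,
                 geometry = geometry, roi_modality = roi_modality,
                 modality_of = modality_of,
                 n_subjects = as.integer(n_subjects),
                 n_permutations = as.integer(n_permutations),
                 effect_size = effect_size, pattern_sparsity = pattern_sparsity,
                 amplitude_sd = amplitude_sd, white_sd = white_sd,
                 drift_slope_sd = drift_slope_sd, k = k, cost = cost,
                 timecourse_k = timecourse_k, control_roi = control_roi,
                 seed = as.integer(seed)),
            class = "study_config")
}

# Simulate one subject under a config and return the preprocessed dataset.
# Each subject gets its own pseudo-random design and its own pattern maps
# (subject-specific spatial patterns with a common design structure).
simulate_subject <- function(config, subject) {
  s_seed <- config$seed + 1000L * subject
  design <- generate_design(config$design, config$acq, seed = s_seed)
  patterns <- random_patterns(config$geometry$rois, config$design$conditions,
                              sparsity = config$pattern_sparsity,
                              amplitude_sd = config$amplitude_sd,
                              effect_size = config$effect_size,
                              seed = s_seed + 1L)
  ds <- simulate_dataset(design, patterns,
                         noise_model(config$white_sd, config$drift_slope_sd,
                                     seed = s_seed + 2L),
                         config$acq, masks = config$geometry$rois,
                         brain_mask = config$geometry$brain_mask)
  list(dataset = preprocess_dataset(ds), events = design, patterns = patterns)
}

.write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the four-modality decoding experiment end-to-end
#'
#' Simulates `n_subjects` datasets under the four-condition event-related
#' design, then, for every ROI: all six two-way leave-one-run-out
#' decodings with group permutation inference, the four-way
#' pairwise-voting classification with its confusion matrix and
#' permutation test, the pertinent-versus-non-pertinent Wilcoxon
#' comparison, group F sensitivity maps and their 1-r distance matrix, an
#' out-of-brain control region run through the same decodings, and a
#' decoding-accuracy time course across post-stimulus volumes. All tables
#' are written as tab-separated text with the configuration (seeds
#' included) echoed to JSON when `out` is given.
#'
#' @param config a [study_config()] whose design has exactly 4 conditions.
#' @param out optional output directory.
#' @return an `experiment_report` (list) with per-subject accuracy tables,
#'   permutation results, confusion matrices, maps and distances.
#' @export
run_experiment1 <- function(config, out = NULL) {
  stopifnot(inherits(config, "study_config"))
  conds <- config$design$conditions
  if (length(conds) != 4) stop("experiment 1 requires exactly 4 conditions")
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  rois <- config$geometry$rois
  if (config$control_roi)
    rois$control <- make_control_roi(config$geometry$brain_mask,
                                     config$geometry$rois,
                                     seed = config$seed + 99L)
  dims <- dim(config$geometry$brain_mask)
  tc_k <- config$timecourse_k

  tp <- list()          # tp[[roi]][[subject]]
  tc_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sim <- simulate_subject(config, s)
    for (rn in names(rois)) {
      tp[[rn]][[s]] <- extract_patterns(sim$dataset, sim$events, rois[[rn]],
                                        k = config$k, roi_name = rn)
      if (!is.null(tc_k) && rn != "control") {
        tc <- timecourse_decoding(sim$dataset, sim$events, rois[[rn]],
                                  pair = pairs[[1]], k_range = tc_k,
                                  cost = config$cost, roi_name = rn)
        tc_rows[[length(tc_rows) + 1L]] <-
          data.frame(subject = s, roi = rn, task = paste(pairs[[1]], collapse = " vs "),
                     k = tc$k, accuracy = tc$accuracy)
      }
    }
  }

  acc_rows <- list(); group_rows <- list(); wilcox <- list()
  perm <- list(); confusion <- list(); fmaps <- list(); dist <- list()
  for (rn in names(rois)) {
    task_acc <- matrix(NA_real_, config$n_subjects, length(pairs))
    maps <- list()
    for (pi in seq_along(pairs)) {
      pair <- pairs[[pi]]
      task <- paste(pair, collapse = " vs ")
      submaps <- vector("list", config$n_subjects)
      for (s in seq_len(config$n_subjects)) {
        dec <- crossvalidate_two_way(tp[[rn]][[s]], pair, cost = config$cost)
        task_acc[s, pi] <- dec$accuracy
        submaps[[s]] <- decoding_map(dec, tp[[rn]][[s]], dims)
        acc_rows[[length(acc_rows) + 1L]] <-
          data.frame(subject = s, roi = rn, task = task,
                     fold = names(dec$fold_accuracy),
                     accuracy = unname(dec$fold_accuracy))
      }
      pt <- permutation_test(tp[[rn]], pair,
                             n_permutations = config$n_permutations,
                             seed = config$seed + 10L, cost = config$cost)
      perm[[rn]][[task]] <- pt
      maps[[task]] <- suppressWarnings(group_f_map(submaps))
      group_rows[[length(group_rows) + 1L]] <-
        data.frame(roi = rn, task = task, accuracy = pt$observed,
                   chance = pt$chance, p_value = pt$p_value, p = pt$p_label)
    }
    # four-way by pairwise voting (random tie-break on a subject-keyed seed)
    conf <- NULL; four_acc <- numeric(config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      dec4 <- with_seed(config$seed + 500L + s,
                        crossvalidate_four_way(tp[[rn]][[s]], cost = config$cost))
      four_acc[s] <- dec4$accuracy
      conf <- if (is.null(conf)) dec4$confusion else conf + dec4$confusion
    }
    confusion[[rn]] <- conf / config$n_subjects   # group-average counts
    pt4 <- permutation_test(tp[[rn]], "multiway",
                            n_permutations = config$n_permutations,
                            seed = config$seed + 20L, cost = config$cost,
                            tie_break = "lowest")
    perm[[rn]][["multiway"]] <- pt4
    group_rows[[length(group_rows) + 1L]] <-
      data.frame(roi = rn, task = "four-way", accuracy = pt4$observed,
                 chance = pt4$chance, p_value = pt4$p_value, p = pt4$p_label)
    fmaps[[rn]] <- maps
    dist[[rn]] <- distance_matrix(maps)
    # pertinent vs non-pertinent (only ROIs with a principal modality)
    if (rn %in% names(config$roi_modality)) {
      pert <- vapply(pairs, function(p) config$roi_modality[[rn]] %in% p, logical(1))
      if (any(pert) && any(!pert)) {
        # saturated accuracies can make every paired difference zero, in
        # which case the comparison is reported as uninformative, not fatal
        wilcox[[rn]] <- tryCatch(
          wilcoxon_paired(rowMeans(task_acc[, pert, drop = FALSE]),
                          rowMeans(task_acc[, !pert, drop = FALSE]),
                          alternative = "greater"),
          error = function(e) structure(
            list(statistic = NA_real_, p_value = NA_real_,
                 n = config$n_subjects, n_informative = 0L,
                 alternative = "greater", note = conditionMessage(e)),
            class = "group_comparison"))
      }
    }
  }

  report <- structure(list(config = config,
                           accuracies = do.call(rbind, acc_rows),
                           group = do.call(rbind, group_rows),
                           permutation = perm, confusion = confusion,
                           wilcoxon = wilcox, fmaps = fmaps, distance = dist,
                           timecourse = if (length(tc_rows)) do.call(rbind, tc_rows)),
                      class = "experiment_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Run the two-locations-per-modality decoding experiment end-to-end
#'
#' The four conditions are two locations in each of two modalities (for
#' example Touch1/Touch2 and Vision1/Vision2). For every ROI the analysis
#' decodes (a) location within each modality and (b) modality with the two
#' locations pooled under a single label before training, each with group
#' permutation inference. Sub-condition identity is retained in the pooled
#' trial sets for auditing.
#'
#' @param config a [study_config()] whose `modality_of` maps each of the 4
#'   conditions to one of 2 modalities, 2 locations each.
#' @param out optional output directory.
#' @return an `experiment_report`.
#' @export
run_experiment2 <- function(config, out = NULL) {
  stopifnot(inherits(config, "study_config"))
  conds <- config$design$conditions
  mo <- config$modality_of
  if (is.null(mo) || !all(conds %in% names(mo)))
    stop("config$modality_of must map every condition to its modality")
  mo <- mo[conds]
  mods <- unique(unname(mo))
  if (length(mods) != 2 || any(table(mo) < 2))
    stop("experiment 2 requires 2 modalities with at least 2 locations each")
  rois <- config$geometry$rois
  if (config$control_roi)
    rois$control <- make_control_roi(config$geometry$brain_mask,
                                     config$geometry$rois,
                                     seed = config$seed + 99L)

  tp <- list()
  for (s in seq_len(config$n_subjects)) {
    sim <- simulate_subject(config, s)
    for (rn in names(rois))
      tp[[rn]][[s]] <- extract_patterns(sim$dataset, sim$events, rois[[rn]],
                                        k = config$k, roi_name = rn)
  }

  acc_rows <- list(); group_rows <- list(); perm <- list()
  for (rn in names(rois)) {
    # within-modality location decoding
    for (m in mods) {
      pair <- conds[mo == m]
      task <- paste(pair, collapse = " vs ")
      for (s in seq_len(config$n_subjects)) {
        dec <- crossvalidate_two_way(tp[[rn]][[s]], pair, cost = config$cost)
        acc_rows[[length(acc_rows) + 1L]] <-
          data.frame(subject = s, roi = rn, task = task,
                     fold = names(dec$fold_accuracy),
                     accuracy = unname(dec$fold_accuracy))
      }
      pt <- permutation_test(tp[[rn]], pair,
                             n_permutations = config$n_permutations,
                             seed = config$seed + 10L, cost = config$cost)
      perm[[rn]][[task]] <- pt
      group_rows[[length(group_rows) + 1L]] <-
        data.frame(roi = rn, task = task, accuracy = pt$observed,
                   chance = pt$chance, p_value = pt$p_value, p = pt$p_label)
    }
    # pooled modality decoding: sub-conditions relabelled before training
    pooled <- lapply(tp[[rn]], subset_patterns, conditions = conds, relabel = mo)
    task <- paste(mods, collapse = " vs ")
    for (s in seq_len(config$n_subjects)) {
      dec <- crossvalidate_two_way(pooled[[s]], mods, cost = config$cost)
      acc_rows[[length(acc_rows) + 1L]] <-
        data.frame(subject = s, roi = rn, task = paste0("pooled: ", task),
                   fold = names(dec$fold_accuracy),
                   accuracy = unname(dec$fold_accuracy))
    }
    pt <- permutation_test(pooled, mods,
                           n_permutations = config$n_permutations,
                           seed = config$seed + 30L, cost = config$cost)
    perm[[rn]][[paste0("pooled: ", task)]] <- pt
    group_rows[[length(group_rows) + 1L]] <-
      data.frame(roi = rn, task = paste0("pooled: ", task),
                 accuracy = pt$observed, chance = pt$chance,
                 p_value = pt$p_value, p = pt$p_label)
  }
  report <- structure(list(config = config,
                           accuracies = do.call(rbind, acc_rows),
                           group = do.call(rbind, group_rows),
                           permutation = perm),
                      class = "experiment_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Write an experiment report to disk
#'
#' Tab-separated tables (per-fold accuracies, group summary, confusion
#' matrices, distance matrices, time course, Wilcoxon comparisons), NIfTI
#' group sensitivity maps, and a JSON echo of the full configuration
#' including all seeds, so a run can be reproduced byte for byte.
#'
#' @param report an `experiment_report`.
#' @param out output directory (created if missing).
#' @return `out`, invisibly.
#' @export
write_report <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(report$accuracies, out, "accuracies.tsv")
  .write_tsv(report$group, out, "group_results.tsv")
  if (!is.null(report$timecourse)) .write_tsv(report$timecourse, out, "timecourse.tsv")
  for (rn in names(report$confusion)) {
    cm <- as.data.frame(report$confusion[[rn]])
    .write_tsv(cbind(guess = rownames(cm), cm), out, sprintf("confusion_%s.tsv", rn))
  }
  for (rn in names(report$distance)) {
    dm <- as.data.frame(unclass(report$distance[[rn]]))
    .write_tsv(cbind(task = rownames(dm), dm), out, sprintf("distance_%s.tsv", rn))
  }
  if (length(report$wilcoxon)) {
    wt <- do.call(rbind, lapply(names(report$wilcoxon), function(rn)
      data.frame(roi = rn, V = report$wilcoxon[[rn]]$statistic,
                 p_value = report$wilcoxon[[rn]]$p_value)))
    .write_tsv(wt, out, "wilcoxon_pertinent.tsv")
  }
  for (rn in names(report$fmaps)) for (task in names(report$fmaps[[rn]])) {
    fn <- sprintf("fmap_%s_%s.nii.gz", rn, gsub("[^A-Za-z0-9]+", "_", task))
    write_sensitivity_map(report$fmaps[[rn]][[task]], file.path(out, fn))
  }
  cfg <- report$config
  cfg$geometry <- lapply(c(list(brain_mask = cfg$geometry$brain_mask), cfg$geometry$rois),
                         function(m) sum(m != 0))
  names(cfg$geometry) <- c("brain_mask_voxels",
                           paste0(names(report$config$geometry$rois), "_voxels"))
  jsonlite::write_json(cfg, file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment report: %d subjects, %d permutations, profile '%s'\n",
              x$config$n_subjects, x$config$n_permutations, x$config$profile))
  print(x$group, row.names = FALSE)
  invisible(x)
}
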