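# A small but complete study configuration: 3 subjects, short runs,
# strong disjoint patterns, few permutations.
.fast_config <- function(conds = c("pain", "touch", "audition", "vision"),
                         effect = 2.5, n_perm = 30, seed = 7, ...) {
  study_config(profile = "ci",
               design = design_spec(conds, 3, 5, 8),
               acq = acq_params(3, 40, 4),
               geometry = tiny_geometry(),
               roi_modality = c(S1 = "touch", A1 = "audition", V1 = "vision"),
               n_subjects = 3, n_permutations = n_perm,
               effect_size = effect, white_sd = 0.8,
               timecourse_k = NULL, seed = seed, ...)
}

# the full four-condition experiment is run once and inspected by several
# tests below
.report_cache <- new.env(parent = emptyenv())
std_report <- function() {
  hit <- get0("r", envir = .report_cache, inherits = FALSE)
  if (is.null(hit)) {
    cfg <- .fast_config()
    cfg$timecourse_k <- 0:3
    hit <- run_experiment1(cfg)
    assign("r", hit, envir = .report_cache)
  }
  hit
}

test_that("the four-condition experiment enumerates six two-way tasks per ROI", {
  rep <- std_report()
  for (rn in c("S1", "A1", "V1", "control")) {
    tasks <- rep$group$task[rep$group$roi == rn]
    expect_length(setdiff(tasks, "four-way"), 6)   # C(4,2) = 6
    expect_true("four-way" %in% tasks)
  }
  expect_error(run_experiment1(study_config(design = design_spec(c("A", "B"), 3, 5, 8),
                                            acq = acq_params(3, 40, 4),
                                            geometry = tiny_geometry(),
                                            n_subjects = 2)),
               "exactly 4 conditions")
})

test_that("strong disjoint patterns decode above the permutation threshold in every task", {
  rep <- std_report()
  real <- rep$group[rep$group$roi != "control", ]
  expect_true(all(real$accuracy > real$chance))
  expect_true(all(real$p_value <= 0.05))
  # out-of-brain control voxels carry no signal by construction
  ctl <- rep$group[rep$group$roi == "control", ]
  expect_true(all(abs(ctl$accuracy - ctl$chance) < 0.18))
  # confusion matrices of real ROIs are diagonal-dominant
  for (rn in c("S1", "A1", "V1"))
    expect_gt(sum(diag(rep$confusion[[rn]])), 0.5 * sum(rep$confusion[[rn]]))
  # pertinent-vs-non-pertinent comparison present for every named ROI
  expect_true(all(c("S1", "A1", "V1") %in% names(rep$wilcoxon)))
  expect_true(all(vapply(rep$wilcoxon, function(w) w$n, 0) == 3))
})

test_that("the time-course table follows the hemodynamic lag", {
  tc <- std_report()$timecourse
  expect_true(all(tc$k %in% 0:3))
  m <- tapply(tc$accuracy, tc$k, mean)
  expect_gt(max(m[c("1", "2", "3")]), m["0"])
})

test_that("experiment reports are byte-reproducible and fully written to disk", {
  cfg <- .fast_config(n_perm = 10)
  cfg$n_subjects <- 2L
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  r1 <- run_experiment1(cfg, out = out1)
  r2 <- run_experiment1(cfg, out = out2)
  expect_identical(r1$group, r2$group)
  expect_identical(r1$accuracies, r2$accuracies)
  for (f in c("accuracies.tsv", "group_results.tsv", "config.json",
              "confusion_S1.tsv", "distance_S1.tsv", "wilcoxon_pertinent.tsv"))
    expect_true(file.exists(file.path(out1, f)))
  expect_identical(readLines(file.path(out1, "group_results.tsv")),
                   readLines(file.path(out2, "group_results.tsv")))
  expect_true(length(list.files(out1, pattern = "^fmap_.*nii")) >= 6)
  # every accuracy row is traceable to (subject, roi, task, fold)
  acc <- r1$accuracies
  expect_named(acc, c("subject", "roi", "task", "fold", "accuracy"))
  expect_false(anyNA(acc))
  expect_equal(anyDuplicated(acc[, c("subject", "roi", "task", "fold")]), 0)
})

test_that("the two-locations experiment decodes location and pooled modality", {
  conds <- c("Touch1", "Touch2", "Vision1", "Vision2")
  cfg <- .fast_config(conds = conds, n_perm = 25,
                      modality_of = c(Touch1 = "Touch", Touch2 = "Touch",
                                      Vision1 = "Vision", Vision2 = "Vision"))
  cfg$roi_modality <- character(0)
  cfg$n_subjects <- 2L
  cfg$control_roi <- FALSE
  rep <- run_experiment2(cfg)
  s1 <- rep$group[rep$group$roi == "S1", ]
  expect_setequal(s1$task, c("Touch1 vs Touch2", "Vision1 vs Vision2",
                             "pooled: Touch vs Vision"))
  expect_true(all(s1$accuracy > 0.5))
  expect_true(all(s1$p_value <= 0.05))
  # degenerate: fewer than 2 locations per modality
  bad <- .fast_config(conds = c("A", "B", "C", "D"),
                      modality_of = c(A = "m1", B = "m2", C = "m2", D = "m2"))
  expect_error(run_experiment2(bad), "2 locations")
  expect_error(run_experiment2(.fast_config()), "modality_of")
})

test_that("pooling detects modality even when locations share a pattern", {
  # identical maps for the two touch locations, distinct for vision:
  # location decoding within touch sits at chance, pooled modality does not
  geo <- tiny_geometry()
  acq <- acq_params(3, 40, 4)
  conds <- c("Touch1", "Touch2", "Vision1", "Vision2")
  ev <- generate_design(design_spec(conds, 3, 5, 8), acq, seed = 3)
  base <- random_patterns(geo$rois, c("t", "v1", "v2"), effect_size = 2.5,
                          seed = 11)
  maps <- list(Touch1 = base$maps$t, Touch2 = base$maps$t,
               Vision1 = base$maps$v1, Vision2 = base$maps$v2)
  ds <- simulate_dataset(ev, pattern_spec(maps, effect_size = 2.5),
                         noise_model(0.8, 0.02, 13), acq,
                         brain_mask = geo$brain_mask)
  tp <- extract_patterns(preprocess_dataset(ds), ev, geo$rois$S1,
                         roi_name = "S1")
  within_touch <- crossvalidate_two_way(tp, c("Touch1", "Touch2"))
  expect_lt(abs(within_touch$accuracy - 0.5), 0.25)
  pooled <- subset_patterns(tp, conds,
                            relabel = c(Touch1 = "Touch", Touch2 = "Touch",
                                        Vision1 = "Vision", Vision2 = "Vision"))
  expect_identical(levels(pooled$condition), c("Touch", "Vision"))
  expect_identical(as.character(pooled$sub_condition[1:3]),
                   as.character(tp$condition[1:3]))  # audit trail retained
  dec <- crossvalidate_two_way(pooled, c("Touch", "Vision"))
  expect_gt(dec$accuracy, 0.8)
})
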