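test_that("the fold plan holds out every run exactly once", {
  runs <- rep(1:4, each = 6)
  plan <- fold_plan(runs)
  expect_length(plan, 4)
  tested <- vapply(plan, `[[`, 0, "test")
  expect_setequal(tested, 1:4)
  for (f in plan) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:4)
  }
  expect_error(fold_plan(rep(1, 5)), "at least 2 runs")
})

test_that("a separable pair is classified perfectly with the boundary at zero", {
  x <- matrix(c(-1, 1), 2, 1)
  fit <- fit_linear_classifier(x, c("A", "B"))
  expect_equal(as.character(predict(fit, x)), c("A", "B"))
  # decision value at the midpoint is (numerically) zero
  expect_lt(abs(predict(fit, matrix(0, 1, 1), type = "decision")), 1e-8)
  expect_error(fit_linear_classifier(x, c("A", "A")), "single class")
  expect_error(fit_linear_classifier(rbind(x, 0), c("A", "B", "C")),
               "more than two")
})

test_that("duplicating every training trial leaves the max-margin rule unchanged", {
  # cleanly separable clusters: no slack is active, so the maximum-margin
  # solution depends only on the support set, not on trial multiplicity
  set.seed(11)
  x <- matrix(rnorm(20 * 5, sd = 0.3), 20, 5)
  y <- rep(c("A", "B"), 10)
  x[y == "A", 1] <- x[y == "A", 1] + 4
  f1 <- fit_linear_classifier(x, y)
  f2 <- fit_linear_classifier(rbind(x, x), c(y, y))
  expect_equal(f2$weights, f1$weights, tolerance = 1e-5)
  expect_equal(f2$bias, f1$bias, tolerance = 1e-5)
})

test_that("the decision rule agrees with an independent SVM implementation", {
  skip_if_not_installed("kernlab")
  set.seed(12)
  for (cost in c(0.1, 1, 10)) {
    x <- matrix(rnorm(30 * 4), 30, 4)
    y <- factor(rep(c("A", "B"), 15))
    x[y == "A", 2] <- x[y == "A", 2] + 1
    ours <- fit_linear_classifier(x, y, cost = cost)
    ref <- kernlab::ksvm(x, y, type = "C-svc", C = cost,
                         kernel = "vanilladot", scaled = FALSE,
                         kpar = list())
    # compare away from the boundary (b is not unique in degenerate cases)
    sure <- abs(predict(ours, x, type = "decision")) > 1e-6
    expect_gt(mean(sure), 0.9)
    expect_equal(as.character(predict(ours, x))[sure],
                 as.character(kernlab::predict(ref, x))[sure])
  }
  # XOR configuration: no linear rule beats 50% training accuracy
  xor_x <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))
  xor_y <- c("A", "A", "B", "B")
  ours <- fit_linear_classifier(xor_x, xor_y)
  ref <- kernlab::ksvm(xor_x, factor(xor_y), type = "C-svc", C = 1,
                       kernel = "vanilladot", scaled = FALSE, kpar = list())
  expect_equal(mean(predict(ours, xor_x) == xor_y), 0.5)
  expect_equal(mean(as.character(kernlab::predict(ref, xor_x)) == xor_y), 0.5)
})

test_that("two-way cross-validation tests every trial once and averages folds", {
  s <- sim_subject(seed = 31, effect = 3, white = 0.5)
  dec <- crossvalidate_two_way(s$tp, c("A", "B"))
  expect_length(dec$fold_accuracy, 4)
  expect_equal(sum(dec$confusion), nrow(s$tp$x))
  expect_equal(colSums(dec$confusion),
               c(A = sum(s$tp$condition == "A"), B = sum(s$tp$condition == "B")),
               ignore_attr = TRUE)
  expect_equal(dec$accuracy, mean(dec$fold_accuracy))
  expect_equal(dec$accuracy, sum(diag(dec$confusion)) / sum(dec$confusion))
  # strong disjoint patterns, low noise: perfectly separable
  expect_equal(dec$accuracy, 1.0)
})

test_that("a condition missing from a run is reported by name", {
  s <- sim_subject(seed = 32)
  tp <- s$tp
  drop <- which(tp$condition == "A" & tp$run == 2)
  tp$x <- tp$x[-drop, ]; tp$condition <- tp$condition[-drop]
  tp$run <- tp$run[-drop]
  expect_error(crossvalidate_two_way(tp, c("A", "B")), "run\\(s\\): 2")
})

test_that("trial order does not affect fold accuracies", {
  s <- sim_subject(seed = 33, effect = 0.6)
  set.seed(1)
  perm <- sample(nrow(s$tp$x))
  tp2 <- s$tp
  tp2$x <- tp2$x[perm, ]; tp2$condition <- tp2$condition[perm]
  tp2$run <- tp2$run[perm]
  a <- crossvalidate_two_way(s$tp, c("A", "B"))
  b <- crossvalidate_two_way(tp2, c("A", "B"))
  expect_equal(sort(a$fold_accuracy), sort(b$fold_accuracy), tolerance = 1e-12)
  expect_equal(a$accuracy, b$accuracy, tolerance = 1e-12)
})

test_that("vote tallying matches a brute-force oracle over all realizable patterns", {
  labels <- c("p", "t", "a", "v")
  pairs <- combn(labels, 2)
  # all 2^6 outcomes of the six pairwise contests
  grid <- expand.grid(rep(list(1:2), 6))
  oracle_counts <- function(votes) {
    cnt <- setNames(numeric(4), labels)
    for (v in votes) cnt[v] <- cnt[v] + 1
    cnt
  }
  for (g in seq_len(nrow(grid))) {
    votes <- vapply(1:6, function(p) pairs[grid[g, p], p], "")
    cnt <- oracle_counts(votes)
    top <- names(cnt)[cnt == max(cnt)]
    # deterministic rule: lowest label index among tied winners
    got <- tally_votes(matrix(votes, 1), labels, tie_break = "lowest")
    expect_identical(as.character(got), labels[labels %in% top][1])
    # random rule always lands inside the tied set
    got_r <- boldmvpa:::with_seed(g, tally_votes(matrix(votes, 1), labels))
    expect_true(as.character(got_r) %in% top)
  }
})

test_that("a label winning all its own contests wins the trial", {
  labels <- c("p", "t", "a", "v")
  # contests: p-t p-a p-v t-a t-v a-v ; 'p' wins its three
  for (rest in list(c("t", "t", "a"), c("a", "v", "v"), c("t", "v", "a"))) {
    votes <- matrix(c("p", "p", "p", rest), 1)
    expect_identical(as.character(tally_votes(votes, labels, "lowest")), "p")
    expect_identical(as.character(tally_votes(votes, labels, "random")), "p")
  }
})

test_that("separable four-condition decoding yields a diagonal confusion matrix", {
  s <- sim_subject(seed = 35, conds = c("p", "t", "a", "v"), n_per = 3,
                   effect = 3, white = 0.4)
  dec <- crossvalidate_four_way(s$tp, tie_break = "lowest")
  expect_equal(dec$accuracy, 1.0)
  expect_equal(sum(diag(dec$confusion)), sum(dec$confusion))
  expect_equal(colSums(dec$confusion), rep(12, 4), ignore_attr = TRUE)
})

test_that("pairwise voting over two conditions reduces to the binary engine", {
  s <- sim_subject(seed = 36, effect = 0.7)
  two <- crossvalidate_two_way(s$tp, c("A", "B"))
  multi <- crossvalidate_four_way(s$tp, tie_break = "lowest")
  expect_equal(multi$accuracy, two$accuracy, tolerance = 1e-12)
  expect_equal(unclass(multi$confusion), unclass(two$confusion))
})

test_that("decoding accuracy traces the hemodynamic response over volumes", {
  s <- sim_subject(seed = 37, effect = 3, white = 0.5, nv = 50,
                   isi_min = 9, isi_max = 12)
  tc <- timecourse_decoding(s$ds, s$events, s$geo$rois$S1, c("A", "B"),
                            k_range = 0:4)
  expect_equal(tc$k, 0:4)
  expect_true(all(tc$accuracy >= 0 & tc$accuracy <= 1))
  # information peaks after the onset, not before it
  expect_gt(max(tc$accuracy[tc$k >= 1]), tc$accuracy[tc$k == 0])
})
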