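test_that("the group F map equals the squared one-sample t, thresholded at F(1, n-1)", {
  set.seed(41)
  n <- 14; V <- 60
  W <- matrix(rnorm(n * V, mean = 0.2, sd = 1), n, V)
  maps <- lapply(seq_len(n), function(s)
    sensitivity_map(W[s, ], seq_len(V), c(V, 1, 1), task = "A vs B"))
  g <- group_f_map(maps)
  # direct-formula oracle: F = t^2 with t = mean / (sd / sqrt(n))
  oracle <- vapply(seq_len(V), function(v) {
    (mean(W[, v]) / (sd(W[, v]) / sqrt(n)))^2
  }, numeric(1))
  expect_equal(g$values, oracle, tolerance = 1e-10)
  expect_equal(attr(g, "df"), c(1, 13))
  # the 5% critical value for 14 subjects, to the printed precision
  expect_equal(round(attr(g, "threshold"), 2), 4.67)
  expect_equal(round(f_threshold(14), 2), 4.67)
  expect_identical(attr(g, "significant"), g$values > attr(g, "threshold"))
  expect_identical(g$level, "group")
})

test_that("degenerate voxels are excluded or flagged, not silently kept", {
  W <- cbind(c(0, 0, 0, 0), c(1, 1, 1, 1), rnorm(4))
  expect_warning(expect_warning(g <- group_f_map(W), "zero in every subject"),
                 "zero between-subject variance")
  expect_true(is.na(g$values[1]))
  expect_identical(g$values[2], Inf)
  expect_false(attr(g, "significant")[1])
  expect_error(group_f_map(W[1, , drop = FALSE]), "at least 2 subjects")
})

test_that("the group F map is invariant to a global rescaling but not per-subject gains", {
  set.seed(42)
  W <- matrix(rnorm(8 * 30, 0.3), 8, 30)
  f0 <- group_f_map(W)$values
  expect_equal(group_f_map(W * 3.7)$values, f0, tolerance = 1e-10)
  scales <- runif(8, 0.5, 2)
  expect_false(isTRUE(all.equal(group_f_map(W * scales)$values, f0)))
})

test_that("map dissimilarity behaves like 1 minus Pearson correlation", {
  set.seed(43)
  v <- rnorm(50)
  m <- function(x, task) sensitivity_map(x, 1:50, c(50, 1, 1), task)
  # orthogonalize a second map against the first
  o <- rnorm(50); o <- residuals(lm(o ~ v)); o <- o - mean(o)
  vc <- v - mean(v)
  D <- distance_matrix(list(self = m(v, "self"), neg = m(-v, "neg"),
                            orth = m(vc + 0 * o, "same"), o = m(o, "orth")))
  expect_equal(unname(diag(unclass(D))), rep(0, 4))
  expect_equal(D["self", "neg"], 2)
  expect_equal(D["self", "orth"], 0, tolerance = 1e-12)
  expect_equal(D["self", "o"], 1, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(D)))
  expect_true(all(unclass(D) >= 0 & unclass(D) <= 2))
  expect_error(distance_matrix(list(a = m(v, "a"), b = m(rep(1, 50), "b"))),
               "constant map")
})

test_that("tasks over disjoint condition pairs have the most dissimilar maps", {
  conds <- c("p", "t", "a", "v")
  pairs <- combn(conds, 2, simplify = FALSE)
  overlap <- function(p, q) length(intersect(p, q)) > 0
  wins <- 0
  for (seed in 1:20) {
    subs <- lapply(1:3, function(s)
      sim_subject(seed = 1000 * seed + s, conds = conds, n_per = 3,
                  effect = 1.2, white = 1)$tp)
    dims <- c(27, 1, 1)
    maps <- lapply(pairs, function(pr) {
      W <- vapply(subs, function(tp)
        crossvalidate_two_way(tp, pr)$weights, numeric(ncol(subs[[1]]$x)))
      sensitivity_map(rowMeans(W), seq_len(nrow(W)), dims,
                      task = paste(pr, collapse = " vs "))
    })
    names(maps) <- vapply(pairs, paste, "", collapse = " vs ")
    D <- unclass(distance_matrix(maps))
    ov <- dj <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      if (overlap(pairs[[i]], pairs[[j]])) ov <- c(ov, D[i, j])
      else dj <- c(dj, D[i, j])
    }
    if (mean(dj) > mean(ov)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("GLM betas recover injected responses and match the normal equations", {
  geo <- tiny_geometry()
  acq <- tiny_acq(nv = 30, runs = 2)
  ev <- generate_design(tiny_design(c("A", "B"), 2, 6, 9), acq, seed = 51)
  # noiseless: one voxel responding 2x to A, one responding -1.5x to B
  mA <- array(0, dim(geo$brain_mask)); mA[3, 3, 3] <- 2
  mB <- array(0, dim(geo$brain_mask)); mB[4, 3, 3] <- -1.5
  ds <- simulate_dataset(ev, pattern_spec(list(A = mA, B = mB)),
                         noise_model(0, 0, 1), acq)
  mask <- array(0L, dim(geo$brain_mask)); mask[c(3, 4), 3, 3] <- 1L
  bs <- glm_betas(ds, ev, mask)
  expect_equal(unname(bs$betas[1, "A"]), 2, tolerance = 1e-8)
  expect_equal(unname(bs$betas[1, "B"]), 0, tolerance = 1e-8)
  expect_equal(unname(bs$betas[2, "B"]), -1.5, tolerance = 1e-8)
  expect_lt(bs$betas[2, "B"], 0)  # negative response keeps its sign
  expect_true(all(abs(rowSums(bs$sign_proportions) - 1) < 1e-12))
  # noisy instance vs pseudoinverse oracle
  ds$data <- ds$data + array(rnorm(length(ds$data), sd = 0.5), dim(ds$data))
  bs2 <- glm_betas(ds, ev, mask)
  X <- bs2$X
  y <- matrix(ds$data, prod(dim(ds$data)[1:3]), dim(ds$data)[4])[mask_voxels(mask)[1], ]
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(bs2$betas[1, ]), unname(oracle[1:2, 1]), tolerance = 1e-10)
})

test_that("rank-deficient GLM designs name the collinear columns", {
  geo <- tiny_geometry()
  acq <- tiny_acq(nv = 20, runs = 2)
  ev <- generate_design(tiny_design(c("A", "B"), 2, 5, 8), acq, seed = 52)
  # a condition with no events yields an all-zero regressor
  ev2 <- structure(ev, conditions = c("A", "B", "ghost"),
                   class = c("event_table", "data.frame"))
  mask <- array(0L, dim(geo$brain_mask)); mask[3:4, 3, 3] <- 1L
  ds <- simulate_dataset(ev, random_patterns(geo$rois, c("A", "B"), seed = 1),
                         noise_model(1, 0, 1), acq)
  expect_error(glm_betas(ds, ev2, mask), "ghost")
})

test_that("sensitivity maps render onto the grid and to NIfTI", {
  m <- sensitivity_map(c(1.5, -2), c(2L, 5L), c(2, 2, 2), task = "A vs B")
  a <- as.array(m)
  expect_equal(a[2, 1, 1], 1.5)
  expect_equal(a[[5]], -2)      # linear index 5
  expect_equal(sum(!is.na(a)), 2)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_sensitivity_map(m, path)
  img <- read_mask(path)
  expect_equal(dim(img), c(2, 2, 2))
})
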