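#' Group-level permutation test of classification accuracy
#'
#' Builds the null distribution of the group-average cross-validated
#' accuracy by repeatedly shuffling condition labels within each run of
#' each subject and re-running the full leave-one-run-out decoding. The
#' within-run, within-subject shuffle preserves run-level exchangeability
#' under leave-one-run-out cross-validation and never mixes labels across
#' subjects (the group structure is preserved). By default labels are
#' permuted in both the training and the testing side of every fold
#' (`scope = "both"`); `scope = "train-only"` permutes the training labels
#' only. The p-value is the fraction of permutations whose group-average
#' accuracy reaches the observed one, reported as "< 1/n" when none does;
#' a conservative (count+1)/(n+1) convention is available.
#'
#' @param subjects a `trial_patterns` object or a list of them (one per
#'   subject), all with the same condition set.
#' @param task a pair of condition labels (two-way decoding) or
#'   `"multiway"` for pairwise-voting classification over all conditions.
#' @param n_permutations number of label permutations (>= 1).
#' @param seed integer seed; identical seeds give identical null samples.
#' @param scope label-permutation scope, `"both"` or `"train-only"`.
#' @param cost SVM regularization constant.
#' @param tie_break vote tie handling for multiway decoding.
#' @param convention p-value convention, `"count"` or `"add-one"`.
#' @return an object of class `perm_test` with the observed group-average
#'   accuracy, per-subject accuracies, the null sample, and the p-value.
#' @export
permutation_test <- function(subjects, task, n_permutations = 1000, seed = 1,
                             scope = c("both", "train-only"), cost = 1,
                             tie_break = c("random", "lowest"),
                             convention = c("count", "add-one")) {
  scope <- match.arg(scope)
  tie_break <- match.arg(tie_break)
  convention <- match.arg(convention)
  if (!is_count(n_permutations)) stop("n_permutations must be >= 1")
  if (inherits(subjects, "trial_patterns")) subjects <- list(subjects)
  multiway <- length(task) == 1 && task %in% c("multiway", "four-way")
  # identical label assignments give identical accuracies whenever the
  # decoder is deterministic, so permuted decodings can be memoized
  memoize <- !multiway || tie_break == "lowest"

  prep <- lapply(subjects, function(tp) {
    stopifnot(inherits(tp, "trial_patterns"))
    sub <- if (multiway) tp else subset_patterns(tp, task)
    .check_runs(sub$condition, sub$run, levels(sub$condition))
    list(x = sub$x, y = sub$condition, run = sub$run,
         run_groups = split(seq_along(sub$run), sub$run))
  })
  acc_of <- function(p, y_train, y_test) {
    if (multiway) mean(.cv_multi(p$x, y_train, p$run, cost, tie_break,
                                 y_test = y_test, want_conf = FALSE)$acc)
    else mean(.cv_two_acc(p$x, y_train, p$run, cost, y_test = y_test))
  }
  observed_subj <- vapply(prep, function(p) acc_of(p, p$y, p$y), numeric(1))
  observed <- mean(observed_subj)

  caches <- lapply(prep, function(p) new.env(parent = emptyenv()))
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      accs <- vapply(seq_along(prep), function(s) {
        p <- prep[[s]]
        yp <- p$y
        for (g in p$run_groups) yp[g] <- p$y[g][sample.int(length(g))]
        y_test <- if (scope == "both") yp else p$y
        if (memoize) {
          key <- paste(as.integer(yp), collapse = ",")
          hit <- get0(key, envir = caches[[s]], inherits = FALSE)
          if (!is.null(hit)) return(hit)
          a <- acc_of(p, yp, y_test)
          assign(key, a, envir = caches[[s]])
          a
        } else acc_of(p, yp, y_test)
      }, numeric(1))
      mean(accs)
    }, numeric(1))
  })
  pp <- perm_p(sum(null >= observed), n_permutations, convention)
  structure(list(observed = observed, per_subject = observed_subj,
                 null = null, n_permutations = n_permutations,
                 p_value = pp$p_value, p_bound = pp$bound, p_label = pp$label,
                 task = if (multiway) "multiway" else paste(task, collapse = " vs "),
                 chance = if (multiway) 1 / nlevels(prep[[1]]$y) else 0.5,
                 scope = scope, seed = seed, convention = convention),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test [%s], %d subject(s), %d permutations (scope: %s)\n",
              x$task, length(x$per_subject), x$n_permutations, x$scope))
  cat(sprintf("  group-average accuracy %.3f (chance %.3f), %s\n",
              x$observed, x$chance, x$p_label))
  invisible(x)
}

#' @export
plot.perm_test <- function(x, breaks = 30, ...) {
  graphics::hist(x$null, breaks = breaks, main = x$task,
                 xlab = "group-average accuracy under permuted labels",
                 xlim = range(c(x$null, x$observed)), ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of per-subject accuracies
#'
#' Compares two matched sets of per-subject values (for example, mean
#' accuracy in pertinent versus non-pertinent classification tasks) with
#' the paired Wilcoxon signed-rank test. For n <= 25 informative pairs the
#' p-value is exact: the null distribution of the signed-rank statistic V
#' over all 2^n sign assignments is built by convolution over the midranks
#' of |differences| (so exactness is retained under tied magnitudes, where
#' the textbook tables do not apply). Larger samples use the normal
#' approximation with the usual tie correction. Zero differences carry no
#' information and are dropped; if all differences are zero an error is
#' raised.
#'
#' @param a,b numeric vectors of equal length (per-subject values).
#' @param alternative `"greater"` (a > b), `"less"` or `"two.sided"`.
#' @return an object of class `group_comparison` with the signed-rank
#'   statistic `V`, the p-value, and the number of informative pairs.
#' @export
wilcoxon_paired <- function(a, b, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  d <- a - b
  if (all(d == 0)) stop("all paired differences are zero: no information")
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null by convolution: each pair contributes its (doubled, so
    # integer-valued under midranks) rank with probability 1/2
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1); f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[seq_len(total + 1 - ri)]
      f <- g / 2
    }
    v2 <- as.integer(round(2 * v))
    p_ge <- sum(f[(v2 + 1):(total + 1)])
    p_le <- sum(f[seq_len(v2 + 1)])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(ties^3 - ties) / 48)
    z <- (v - mu) / sig
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
  }
  structure(list(statistic = v, p_value = p,
                 n = length(a), n_informative = n,
                 alternative = alternative),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("paired Wilcoxon signed-rank: V = %g, n = %d (%d non-zero), %s, P = %.4g\n",
              x$statistic, x$n, x$n_informative, x$alternative, x$p_value))
  invisible(x)
}

#' Rank correlation between saliency differences and accuracies
#'
#' Spearman correlation (midranks for ties) between per-task differences in
#' stimulus saliency ratings and the corresponding classification
#' accuracies, with a seeded permutation p-value: under the null the
#' pairing is random, so one vector is repeatedly permuted and the
#' correlation recomputed. Used as a control that accuracy is not driven
#' by saliency-related amplitude differences.
#'
#' @param saliency_diff,accuracy numeric vectors of equal length >= 4.
#' @param n_permutations number of pairing permutations.
#' @param seed integer seed.
#' @param alternative `"two.sided"` (on |rho|), `"greater"` or `"less"`.
#' @param convention p-value convention (see [permutation_test()]).
#' @return object of class `rank_correlation` with `rho` and `p_value`.
#' @export
saliency_accuracy_correlation <- function(saliency_diff, accuracy,
                                          n_permutations = 10000, seed = 1,
                                          alternative = c("two.sided", "greater", "less"),
                                          convention = c("count", "add-one")) {
  alternative <- match.arg(alternative)
  convention <- match.arg(convention)
  stopifnot(length(saliency_diff) == length(accuracy))
  if (length(accuracy) < 4) stop("need at least 4 pairs")
  if (stats::sd(saliency_diff) == 0 || stats::sd(accuracy) == 0)
    stop("constant input vector: correlation undefined")
  rho <- stats::cor(saliency_diff, accuracy, method = "spearman")
  rs <- rank(saliency_diff)  # ranks fixed; permute the accuracy ranks
  ra <- rank(accuracy)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b)
      stats::cor(rs, ra[sample.int(length(ra))]), numeric(1))
  })
  count <- switch(alternative,
                  two.sided = sum(abs(null) >= abs(rho)),
                  greater = sum(null >= rho),
                  less = sum(null <= rho))
  pp <- perm_p(count, n_permutations, convention)
  structure(list(rho = rho, p_value = pp$p_value, p_bound = pp$bound,
                 p_label = pp$label, n = length(accuracy),
                 n_permutations = n_permutations, alternative = alternative,
                 seed = seed),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, n = %d, %s (%d permutations)\n",
              x$rho, x$n, x$p_label, x$n_permutations))
  invisible(x)
}
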