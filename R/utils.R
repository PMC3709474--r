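# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded operations never perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Permutation p-value under the reporting convention used throughout:
# p = #(null >= observed) / n, reported as "< 1/n" when no permutation
# reaches the observed value; a conservative (count+1)/(n+1) mode exists.
perm_p <- function(count, n, convention = c("count", "add-one")) {
  convention <- match.arg(convention)
  stopifnot(n >= 1, count >= 0, count <= n)
  if (convention == "add-one") {
    p <- (count + 1) / (n + 1)
    return(list(p_value = p, bound = FALSE,
                label = sprintf("P = %.4g", p)))
  }
  if (count == 0) {
    list(p_value = 1 / n, bound = TRUE,
         label = sprintf("P < %.4g", 1 / n))
  } else {
    list(p_value = count / n, bound = FALSE,
         label = sprintf("P = %.4g", count / n))
  }
}

#' Linear voxel indices of a binary mask
#'
#' @param mask 3D array (0/1 or logical).
#' @return integer vector of linear indices into the grid.
#' @export
mask_voxels <- function(mask) {
  stopifnot(length(dim(mask)) == 3)
  which(mask != 0)
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}
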