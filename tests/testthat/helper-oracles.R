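# Independent oracles shared by several test files. These deliberately use
# naive, brute-force computations so they share no code path with the
# package implementation they check.

# All distinct within-run label arrangements of a balanced two-class design
# (each run holds equal numbers of both conditions).
.all_labelings <- function(run, conds) {
  per_run <- lapply(sort(unique(run)), function(r) {
    n <- sum(run == r)
    pos <- combn(n, n / 2, simplify = FALSE)   # positions of the first label
    lapply(pos, function(p) {
      lab <- rep(conds[2], n); lab[p] <- conds[1]; lab
    })
  })
  grids <- expand.grid(lapply(per_run, seq_along))
  lapply(seq_len(nrow(grids)), function(i) {
    unlist(lapply(seq_along(per_run), function(r) per_run[[r]][[grids[i, r]]]))
  })
}

# A voxel survives erosion iff all its face neighbours (or all 26
# neighbours) are inside the mask; the grid boundary counts as outside.
.erode_oracle <- function(mask, connectivity = 6) {
  d <- dim(mask)
  out <- array(0L, d)
  offs <- if (connectivity == 6) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, ]
  }
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (mask[i, j, k] == 0) next
    keep <- TRUE
    for (o in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[o, ]
      if (any(p < 1) || any(p > d) || mask[p[1], p[2], p[3]] == 0) {
        keep <- FALSE; break
      }
    }
    if (keep) out[i, j, k] <- 1L
  }
  out
}
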