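# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs quickly on one CPU.

tiny_acq <- function(nv = 40, runs = 4, tr = 3) acq_params(tr, nv, runs)

tiny_design <- function(conds = c("A", "B"), n_per = 4,
                        isi_min = 5, isi_max = 8, maxc = 2)
  design_spec(conds, n_per, isi_min, isi_max, maxc)

tiny_geometry <- function(dim = c(14, 10, 8), side = 3)
  demo_geometry(dim, side)

# One simulated subject end-to-end: design -> dataset -> preprocessing ->
# trial patterns for one ROI. Returns the intermediate objects too.
sim_subject <- function(seed = 1, conds = c("A", "B"), n_per = 4,
                        effect = 2, white = 1, drift = 0.02,
                        runs = 4, nv = 40, roi = "S1", k = 2,
                        sparsity = 0.5, isi_min = 5, isi_max = 8) {
  acq <- tiny_acq(nv = nv, runs = runs)
  spec <- tiny_design(conds, n_per, isi_min, isi_max)
  geo <- tiny_geometry()
  ev <- generate_design(spec, acq, seed = seed)
  pat <- random_patterns(geo$rois, conds, sparsity = sparsity,
                         effect_size = effect, seed = seed + 1)
  ds <- simulate_dataset(ev, pat, noise_model(white, drift, seed = seed + 2),
                         acq, masks = geo$rois, brain_mask = geo$brain_mask)
  pp <- preprocess_dataset(ds)
  list(tp = extract_patterns(pp, ev, geo$rois[[roi]], k = k, roi_name = roi),
       ds = pp, raw = ds, events = ev, patterns = pat, geo = geo, acq = acq)
}

# Trial patterns drawn directly from white noise (a pattern-level null):
# balanced labels within runs, no structure linking labels to patterns.
null_tp <- function(seed, n_runs = 2, n_per = 3, nvox = 8,
                    conds = c("A", "B")) {
  set.seed(seed)
  run <- rep(seq_len(n_runs), each = n_per * length(conds))
  cond <- unlist(lapply(seq_len(n_runs), function(r)
    sample(rep(conds, n_per))))
  structure(list(x = matrix(rnorm(length(run) * nvox), length(run), nvox),
                 condition = factor(cond, levels = conds),
                 run = run, voxels = seq_len(nvox), k = 2,
                 roi = "null", dropped = integer(0)),
            class = "trial_patterns")
}

# Null-calibration study: replicate pure-noise datasets at the full
# four-modality design, decoded two-way and four-way. Computed once and
# cached (two checks share it).
.null_cal_cache <- new.env(parent = emptyenv())
null_calibration <- function(n_datasets = 50, n_subjects = 6) {
  key <- sprintf("d%d_s%d", n_datasets, n_subjects)
  hit <- get0(key, envir = .null_cal_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  acq <- acq_params(); spec <- design_spec(); geo <- demo_geometry()
  two <- four <- matrix(NA_real_, n_datasets, n_subjects)
  for (i in seq_len(n_datasets)) {
    for (s in seq_len(n_subjects)) {
      sd0 <- i * 1000 + s * 10
      ev <- generate_design(spec, acq, seed = sd0)
      pat <- random_patterns(geo$rois, spec$conditions, effect_size = 0,
                             seed = sd0 + 1)
      ds <- simulate_dataset(ev, pat, noise_model(1, 0.02, seed = sd0 + 2),
                             acq, brain_mask = geo$brain_mask)
      tp <- extract_patterns(preprocess_dataset(ds), ev, geo$rois$S1,
                             k = 2, roi_name = "S1")
      two[i, s] <- crossvalidate_two_way(tp, c("touch", "pain"))$accuracy
      four[i, s] <- boldmvpa:::with_seed(sd0 + 3,
                                         crossvalidate_four_way(tp)$accuracy)
    }
  }
  out <- list(two_way = rowMeans(two), four_way = rowMeans(four),
              n_test_two = 64L * n_subjects, n_test_four = 128L * n_subjects)
  assign(key, out, envir = .null_cal_cache)
  out
}
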