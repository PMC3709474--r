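#' Acquisition parameters
#'
#' Timing of the functional acquisition: repetition time (TR), volumes per
#' run and number of runs. Defaults follow the study design emulated by the
#' simulator: TR = 3 s, 4 runs, and enough volumes per run (212, i.e. 636 s)
#' to hold 32 events at the maximum inter-stimulus interval plus the tail of
#' the hemodynamic response.
#'
#' @param tr seconds per volume, > 0.
#' @param n_volumes_per_run volumes acquired in each run.
#' @param n_runs number of runs; at least 2 (leave-one-run-out
#'   cross-validation needs a held-out run).
#' @return an object of class `acq_params`.
#' @export
acq_params <- function(tr = 3, n_volumes_per_run = 212, n_runs = 4) {
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0) stop("tr must be > 0")
  if (!is_count(n_volumes_per_run)) stop("n_volumes_per_run must be a positive integer")
  if (!is_count(n_runs, min = 2)) stop("n_runs must be an integer >= 2")
  structure(list(tr = tr,
                 n_volumes_per_run = as.integer(n_volumes_per_run),
                 n_runs = as.integer(n_runs)),
            class = "acq_params")
}

#' Event-related design specification
#'
#' Describes one run of a pseudo-random event-related design: condition
#' labels, events per condition per run, the inter-stimulus interval range,
#' and the maximum allowed number of consecutive same-condition events.
#' Defaults reproduce the four-modality design (touch, pain, audition,
#' vision; 8 events each per run; ISI uniform in 10-19 s; never more than 2
#' consecutive events of the same condition).
#'
#' @param conditions character vector of unique condition labels.
#' @param n_per_condition_per_run events per condition in each run.
#' @param isi_min,isi_max inter-stimulus interval bounds, seconds.
#' @param max_consecutive_same largest allowed run-length of a condition.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(conditions = c("touch", "pain", "audition", "vision"),
                        n_per_condition_per_run = 8,
                        isi_min = 10, isi_max = 19,
                        max_consecutive_same = 2) {
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop("condition labels must be unique")
  if (length(conditions) < 1) stop("need at least one condition")
  if (!is_count(n_per_condition_per_run)) stop("n_per_condition_per_run must be a positive integer")
  if (!(isi_min > 0 && isi_max >= isi_min)) stop("require 0 < isi_min <= isi_max")
  if (!is_count(max_consecutive_same)) stop("max_consecutive_same must be >= 1")
  structure(list(conditions = conditions,
                 n_per_condition_per_run = as.integer(n_per_condition_per_run),
                 isi_min = isi_min, isi_max = isi_max,
                 max_consecutive_same = as.integer(max_consecutive_same)),
            class = "design_spec")
}

# Balanced condition sequence obeying the consecutive-run constraint.
# Rejection sampling with a retry cap, then a greedy max-remaining
# construction (pick, among admissible conditions, one with the largest
# remaining count, random tie-break) which succeeds whenever counts are
# balanced and the constraint is satisfiable.
.balanced_sequence <- function(conditions, n_per, max_consec, retries = 200) {
  labs <- rep(conditions, times = n_per)
  if (length(conditions) == 1) {
    if (n_per > max_consec)
      stop(sprintf("constraint unsatisfiable: %d events of a single condition cannot avoid runs longer than %d",
                   n_per, max_consec))
    return(labs)
  }
  for (i in seq_len(retries)) {
    s <- sample(labs)
    if (max(rle(s)$lengths) <= max_consec) return(s)
  }
  remaining <- stats::setNames(rep(n_per, length(conditions)), conditions)
  out <- character(length(labs))
  streak <- 0L; last <- ""
  for (i in seq_along(out)) {
    allowed <- names(remaining)[remaining > 0]
    if (streak >= max_consec) allowed <- setdiff(allowed, last)
    if (length(allowed) == 0)
      stop(sprintf("constraint unsatisfiable: no admissible condition at position %d with max %d consecutive",
                   i, max_consec))
    mx <- max(remaining[allowed])
    cand <- allowed[remaining[allowed] == mx]
    pick <- if (length(cand) == 1) cand else sample(cand, 1)
    out[i] <- pick
    remaining[pick] <- remaining[pick] - 1L
    streak <- if (identical(pick, last)) streak + 1L else 1L
    last <- pick
  }
  out
}

#' Generate a pseudo-random event table
#'
#' Draws, for every run, a balanced condition sequence (equal counts per
#' condition, no more than `max_consecutive_same` consecutive events of one
#' condition) and onsets from independent uniform inter-stimulus intervals
#' on `[isi_min, isi_max]`; the first onset is one ISI from the run start.
#' Infeasible combinations (a run too short to hold all events even at
#' `isi_min`, or an unsatisfiable consecutive constraint) raise an error
#' naming the violated bound. Output is reproducible for a fixed seed.
#'
#' @param spec a [design_spec()].
#' @param acq an [acq_params()].
#' @param seed integer seed for the design randomization.
#' @return an `event_table`: a data.frame with columns `run` (integer),
#'   `onset` (seconds from run start) and `condition`, carrying the
#'   condition set as an attribute.
#' @export
generate_design <- function(spec, acq, seed = 1) {
  stopifnot(inherits(spec, "design_spec"), inherits(acq, "acq_params"))
  n_events <- length(spec$conditions) * spec$n_per_condition_per_run
  run_duration <- acq$n_volumes_per_run * acq$tr
  # last onset is the sum of n_events ISIs; its volume must lie in the run
  if (n_events * spec$isi_min + acq$tr > run_duration)
    stop(sprintf(paste0("run too short: %d events at isi_min = %g s need %g s ",
                        "but the run lasts %g s (%d volumes x %g s)"),
                 n_events, spec$isi_min, n_events * spec$isi_min + acq$tr,
                 run_duration, acq$n_volumes_per_run, acq$tr))
  with_seed(seed, {
    rows <- vector("list", acq$n_runs)
    for (r in seq_len(acq$n_runs)) {
      conds <- .balanced_sequence(spec$conditions, spec$n_per_condition_per_run,
                                  spec$max_consecutive_same)
      onsets <- NULL
      for (i in 1:200) {
        cand <- cumsum(stats::runif(n_events, spec$isi_min, spec$isi_max))
        if (cand[n_events] + acq$tr <= run_duration) { onsets <- cand; break }
      }
      if (is.null(onsets))
        stop(sprintf("run too short: could not place %d events with ISI in [%g, %g] s within %g s",
                     n_events, spec$isi_min, spec$isi_max, run_duration))
      rows[[r]] <- data.frame(run = r, onset = onsets, condition = conds,
                              stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, rows)
    rownames(ev) <- NULL
    structure(ev, conditions = spec$conditions,
              max_consecutive_same = spec$max_consecutive_same,
              class = c("event_table", "data.frame"))
  })
}

#' Read / write event tables
#'
#' Tab-separated text with header `run<TAB>onset<TAB>condition`; onsets in
#' seconds from the start of the run.
#'
#' @param events an `event_table` (or compatible data.frame).
#' @param path file path.
#' @return `read_events` returns an `event_table`; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("run", "onset", "condition") %in% names(events)))
  utils::write.table(events[, c("run", "onset", "condition")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("run", "onset", "condition") %in% names(ev)))
  ev <- ev[order(ev$run, ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, conditions = unique(ev$condition),
            class = c("event_table", "data.frame"))
}
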