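#' Randomized trial sequence with no adjacent condition repeats
#'
#' Draws, independently for each run, a random order of
#' `per_condition_per_run` repetitions of every condition, under the
#' constraint that two consecutive trials within a run never share a
#' condition. Sampling is by rejection: permutations are redrawn until the
#' constraint holds.
#'
#' @param n_runs number of runs (default 10).
#' @param per_condition_per_run trials per condition per run (default 2).
#' @param conditions character vector of condition labels.
#' @param seed optional integer seed; the output is deterministic given it.
#' @param max_tries rejection-sampling cap per run.
#' @return data.frame with columns `run`, `trial` (within-run position) and
#'   `condition`.
#' @examples
#' seq10 <- generate_trial_sequence(seed = 1)
#' nrow(seq10)           # 100 trials
#' table(seq10$condition) # 20 per condition
#' @export
generate_trial_sequence <- function(n_runs = 10, per_condition_per_run = 2,
                                    conditions = CONDITIONS, seed = NULL,
                                    max_tries = 10000) {
  stopifnot(n_runs >= 1, per_condition_per_run >= 1, length(conditions) >= 1)
  n <- per_condition_per_run * length(conditions)
  if (per_condition_per_run > ceiling(n / 2)) {
    stop("no-adjacent-repeat constraint unsatisfiable: one condition occupies ",
         per_condition_per_run, " of ", n, " slots per run")
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- rep(conditions, each = per_condition_per_run)
  runs <- lapply(seq_len(n_runs), function(r) {
    for (k in seq_len(max_tries)) {
      s <- sample(pool)
      if (n == 1 || !any(s[-1] == s[-n])) return(s)
    }
    stop("failed to draw a no-adjacent-repeat sequence for run ", r,
         " in ", max_tries, " tries")
  })
  data.frame(run = rep(seq_len(n_runs), each = n),
             trial = rep(seq_len(n), n_runs),
             condition = unlist(runs),
             stringsAsFactors = FALSE)
}

#' Assign trial timing within fixed-length runs
#'
#' Each run is `n_volumes * tr` seconds long with `pre_s` of baseline before
#' the first story, each trial presenting a story for `story_s` followed
#' immediately by a `probe_s` probe statement, inter-trial intervals drawn
#' from `iti_range`, and `post_s` of baseline after the last probe. Because
#' run length is fixed, the ITIs of a run must sum to
#' `n_volumes*tr - pre_s - post_s - n_trials*(story_s + probe_s)`; draws are
#' taken uniformly on `iti_range` and recentred to that required mean
#' (redrawn until all recentred values stay inside the range), then rounded
#' to the millisecond. Timing that cannot fit the run errors out rather than
#' being truncated.
#'
#' @param sequence data.frame from [generate_trial_sequence()].
#' @param iti_range length-2 numeric, seconds (default `c(9, 11)`).
#' @param story_s,probe_s story and probe durations, seconds.
#' @param pre_s,post_s baseline before first story / after last probe, seconds.
#' @param tr repetition time, seconds.
#' @param n_volumes volumes acquired per run.
#' @param seed optional integer seed.
#' @return object of class `story_design`: list with `events` (one row per
#'   trial: run, trial, trial_index, condition, story_onset, story_duration,
#'   probe_onset, probe_duration; onsets in seconds from run start),
#'   `n_runs`, `n_volumes`, `tr`.
#' @export
assign_timing <- function(sequence, iti_range = c(9, 11), story_s = 10,
                          probe_s = 4, pre_s = 18, post_s = 12, tr = 2,
                          n_volumes = 130, seed = NULL) {
  stopifnot(is.data.frame(sequence),
            all(c("run", "trial", "condition") %in% names(sequence)),
            length(iti_range) == 2, iti_range[1] <= iti_range[2],
            story_s > 0, probe_s >= 0, tr > 0, n_volumes > 0)
  if (!is.null(seed)) set.seed(seed)
  run_len <- n_volumes * tr
  runs <- sort(unique(sequence$run))
  ev <- lapply(runs, function(r) {
    tri <- sequence[sequence$run == r, ]
    tri <- tri[order(tri$trial), ]
    nt <- nrow(tri)
    n_iti <- nt - 1
    target <- run_len - pre_s - post_s - nt * (story_s + probe_s)
    if (target < n_iti * iti_range[1] - 1e-9) {
      stop("timing overruns the run: ", nt, " trials need at least ",
           pre_s + post_s + nt * (story_s + probe_s) + n_iti * iti_range[1],
           " s but the run is ", run_len, " s")
    }
    if (n_iti > 0 && target > n_iti * iti_range[2] + 1e-9) {
      stop("run underfilled: ITIs on [", iti_range[1], ", ", iti_range[2],
           "] s cannot span the ", target, " s between trials of run ", r)
    }
    itis <- numeric(0)
    if (n_iti > 0) {
      mu <- target / n_iti
      for (k in 1:1000) {
        u <- stats::runif(n_iti, iti_range[1], iti_range[2])
        v <- u - mean(u) + mu
        if (all(v >= iti_range[1] - 1e-12 & v <= iti_range[2] + 1e-12)) {
          itis <- round(v, 3)
          break
        }
      }
      if (length(itis) == 0) stop("could not sample ITIs for run ", r)
    }
    onset <- pre_s + c(0, cumsum(story_s + probe_s + itis))
    data.frame(run = r, trial = tri$trial, condition = tri$condition,
               story_onset = round(onset, 3), story_duration = story_s,
               probe_onset = round(onset + story_s, 3),
               probe_duration = probe_s, stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, ev)
  events$trial_index <- seq_len(nrow(events))
  events <- events[, c("run", "trial", "trial_index", "condition",
                       "story_onset", "story_duration", "probe_onset",
                       "probe_duration")]
  structure(list(events = events, n_runs = length(runs),
                 n_volumes = n_volumes, tr = tr),
            class = "story_design")
}

#' Generate a complete per-subject trial schedule
#'
#' Convenience wrapper: [generate_trial_sequence()] followed by
#' [assign_timing()], under one seed.
#'
#' @inheritParams generate_trial_sequence
#' @param ... passed to [assign_timing()].
#' @return a `story_design`.
#' @export
simulate_design <- function(n_runs = 10, per_condition_per_run = 2,
                            conditions = CONDITIONS, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seq <- generate_trial_sequence(n_runs, per_condition_per_run, conditions)
  assign_timing(seq, ...)
}

#' @export
print.story_design <- function(x, ...) {
  cat("story_design:", x$n_runs, "runs x",
      nrow(x$events) / x$n_runs, "trials,", x$n_volumes,
      "volumes/run at TR", x$tr, "s\n")
  cat("conditions:", paste(sort(unique(x$events$condition)), collapse = ", "),
      "\n")
  invisible(x)
}
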