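#' Read and write BIDS-style event tables
#'
#' Events are stored one row per presentation with columns `onset`,
#' `duration` (seconds from run start), `trial_type` (condition label, or
#' `"probe"` for the probe phase), `run` and `trial_index`. A
#' `story_design` writes two rows per trial (story + probe);
#' `read_events_tsv` reassembles the design by pairing them on
#' `trial_index`.
#'
#' @param design a `story_design`.
#' @param path file path of the TSV.
#' @param n_volumes,tr acquisition parameters to attach on read.
#' @return `read_events_tsv` returns a `story_design`.
#' @export
write_events_tsv <- function(design, path) {
  ev <- design$events
  out <- rbind(
    data.frame(onset = ev$story_onset, duration = ev$story_duration,
               trial_type = ev$condition, run = ev$run,
               trial_index = ev$trial_index, stringsAsFactors = FALSE),
    data.frame(onset = ev$probe_onset, duration = ev$probe_duration,
               trial_type = "probe", run = ev$run,
               trial_index = ev$trial_index, stringsAsFactors = FALSE))
  out <- out[order(out$run, out$onset), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path, n_volumes = 130, tr = 2) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "run", "trial_index")
  if (!all(need %in% names(tab))) {
    stop("events TSV must have columns: ", paste(need, collapse = ", "))
  }
  story <- tab[tab$trial_type != "probe", ]
  probe <- tab[tab$trial_type == "probe", ]
  probe <- probe[match(story$trial_index, probe$trial_index), ]
  story <- story[order(story$run, story$onset), ]
  probe <- probe[match(story$trial_index, probe$trial_index), ]
  events <- data.frame(run = story$run,
                       trial = stats::ave(story$onset, story$run,
                                          FUN = seq_along),
                       trial_index = story$trial_index,
                       condition = story$trial_type,
                       story_onset = story$onset,
                       story_duration = story$duration,
                       probe_onset = probe$onset,
                       probe_duration = probe$duration,
                       stringsAsFactors = FALSE)
  structure(list(events = events, n_runs = length(unique(events$run)),
                 n_volumes = n_volumes, tr = tr),
            class = "story_design")
}

#' Read and write motion-parameter tables
#'
#' Six columns per run (three translations, three rotations), one row per
#' volume, tab-separated with a header.
#'
#' @param motion a single run's `n_volumes` x 6 matrix.
#' @param path file path.
#' @return `read_motion_tsv` returns the matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  utils::write.table(motion, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path))
  if (ncol(m) != 6) stop("motion TSV must have 6 columns, found ", ncol(m))
  m
}

#' Read and write eye-tracking sample files
#'
#' Comma-separated samples with columns `time_ms`, `x`, `y`, `pupil`
#' (empty field = missing pupil, i.e. blink); simulated streams also carry
#' `run`, `trial_index` and `condition`, which are preserved when present.
#'
#' @param stream data.frame of samples.
#' @param path file path.
#' @return `read_eye_csv` returns the data.frame with `NA` pupil where the
#'   field was empty.
#' @export
write_eye_csv <- function(stream, path) {
  cols <- intersect(c("run", "trial_index", "condition", "time_ms", "x",
                      "y", "pupil"), names(stream))
  utils::write.csv(stream[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_eye_csv
#' @export
read_eye_csv <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_ms", "x", "y", "pupil") %in% names(s))) {
    stop("eye CSV must have columns time_ms, x, y, pupil")
  }
  s$pupil <- as.numeric(s$pupil)
  s
}

#' Read and write behavioral response tables
#'
#' @param responses data.frame from [simulate_behavior()].
#' @param path file path.
#' @return `read_responses_tsv` returns the data.frame.
#' @export
write_responses_tsv <- function(responses, path) {
  utils::write.table(responses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses_tsv
#' @export
read_responses_tsv <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  r$correct <- as.logical(r$correct)
  r
}

grid_to_nifti <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  spacing <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3))
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
}

grid_from_nifti <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  make_grid(dim(img)[1:3], affine = matrix(as.numeric(aff), 4, 4))
}

#' Write and read BOLD runs as NIfTI-1 volumes
#'
#' One 4D file per run (`<prefix>_run-XX_bold.nii.gz`), with the grid
#' affine in the sform. Reading returns the `bold_sim`-shaped object the
#' GLM consumes (per-run volumes x voxels matrices plus the grid).
#'
#' @param bold a `bold_sim` (or list with `runs` and `grid`).
#' @param dir output directory.
#' @param prefix file-name prefix (e.g. `"sub-01"`).
#' @return `write_bold_nifti` returns the file paths; `read_bold_nifti`
#'   returns the bold object.
#' @export
write_bold_nifti <- function(bold, dir, prefix = "sub-01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_along(bold$runs), function(r) {
    m <- bold$runs[[r]]
    arr <- array(as.vector(t(m)), c(bold$grid$dim, nrow(m)))
    f <- file.path(dir, sprintf("%s_run-%02d_bold.nii.gz", prefix, r))
    RNifti::writeNifti(grid_to_nifti(arr, bold$grid), f)
    f
  }, character(1))
}

#' @rdname write_bold_nifti
#' @param files character vector of per-run NIfTI paths, in run order.
#' @export
read_bold_nifti <- function(files) {
  imgs <- lapply(files, RNifti::readNifti)
  grid <- grid_from_nifti(imgs[[1]])
  runs <- lapply(imgs, function(img) {
    a <- as.array(img)
    t(matrix(a, prod(dim(a)[1:3]), dim(a)[4]))
  })
  structure(list(runs = runs, grid = grid), class = "bold_sim")
}

#' Write a voxel mask as a 0/1 NIfTI volume
#'
#' @param mask a `voxel_mask`.
#' @param path output path.
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(0, mask$grid$dim)
  arr[mask$lin] <- 1
  RNifti::writeNifti(grid_to_nifti(arr, mask$grid), path)
  invisible(path)
}

#' Write and read a beta series (NIfTI + label sidecar)
#'
#' The betas are written as one 4D NIfTI (one volume per trial, whole grid,
#' zero outside the fitted voxels) together with a sidecar TSV of trial
#' labels (`trial_index`, `run`, `condition`).
#'
#' @param beta_series a `beta_series`.
#' @param path_nii NIfTI path; the sidecar replaces the extension with
#'   `_labels.tsv`.
#' @return `read_beta_series` returns the `beta_series`.
#' @export
write_beta_series <- function(beta_series, path_nii) {
  grid <- beta_series$grid
  nt <- nrow(beta_series$betas)
  full <- matrix(0, nt, prod(grid$dim))
  full[, beta_series$voxels] <- beta_series$betas
  arr <- array(as.vector(t(full)), c(grid$dim, nt))
  RNifti::writeNifti(grid_to_nifti(arr, grid), path_nii)
  side <- sub("\\.nii(\\.gz)?$", "_labels.tsv", path_nii)
  utils::write.table(
    data.frame(trial_index = beta_series$trial_index,
               run = beta_series$run,
               condition = beta_series$condition),
    side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path_nii, side))
}

#' @rdname write_beta_series
#' @export
read_beta_series <- function(path_nii) {
  img <- RNifti::readNifti(path_nii)
  grid <- grid_from_nifti(img)
  a <- as.array(img)
  betas <- t(matrix(a, prod(dim(a)[1:3]), dim(a)[4]))
  side <- sub("\\.nii(\\.gz)?$", "_labels.tsv", path_nii)
  lab <- utils::read.delim(side, stringsAsFactors = FALSE)
  structure(list(betas = betas, condition = lab$condition, run = lab$run,
                 trial_index = lab$trial_index,
                 voxels = seq_len(ncol(betas)), grid = grid),
            class = "beta_series")
}
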