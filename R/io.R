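#' Read a gaze recording CSV
#'
#' The native schema has columns `time_ms`, `theta_x_deg`, `theta_y_deg`;
#' empty or `NaN` angle cells mark invalid samples. Metadata is taken from a
#' filename of the form `S<subject>_R<round>_S<session>_<TASK>.csv` when
#' present, or can be passed explicitly. Column-name mapping supports other
#' layouts (e.g. timestamp/x-angle/y-angle exports of 1000 Hz trackers).
#'
#' @param path CSV file path.
#' @param subject,task,round,session Metadata overrides.
#' @param columns Named character vector mapping the native names
#'   (`time_ms`, `theta_x_deg`, `theta_y_deg`) to the file's column names.
#' @param sample_rate Hz; inferred from median time step when `NULL`.
#' @return A [gaze_recording()].
#' @export
read_recording <- function(path, subject = NULL, task = NULL, round = NULL,
                           session = NULL, columns = NULL,
                           sample_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, na.strings = c("", "NA", "NaN"))
  want <- c(time_ms = "time_ms", theta_x_deg = "theta_x_deg",
            theta_y_deg = "theta_y_deg")
  if (!is.null(columns)) want[names(columns)] <- columns
  miss <- setdiff(want, names(dt))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  tm <- dt[[want["time_ms"]]]
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stop(sprintf("%s: non-monotone time at line %d", path, bad[1] + 2L))
  meta <- .parse_recording_name(basename(path))
  if (is.null(sample_rate)) {
    sample_rate <- if (length(tm) > 1) 1000 / stats::median(diff(tm)) else 1000
    sample_rate <- round(sample_rate)
  }
  gaze_recording(dt[[want["theta_x_deg"]]], dt[[want["theta_y_deg"]]],
                 sample_rate = sample_rate, timestamps = tm,
                 subject = subject %||% meta$subject,
                 task = task %||% meta$task,
                 round = round %||% meta$round,
                 session = session %||% meta$session)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_recording_name <- function(nm) {
  m <- regmatches(nm, regexec("^(S[0-9]+)_R([0-9]+)_S([0-9]+)_([A-Z]+)\\.csv$",
                              nm))[[1]]
  if (length(m) == 5)
    list(subject = m[2], round = as.integer(m[3]),
         session = as.integer(m[4]), task = m[5])
  else
    list(subject = NA_character_, round = NA_integer_,
         session = NA_integer_, task = NA_character_)
}

#' Write a gaze recording CSV
#'
#' @param rec A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  data.table::fwrite(data.table::data.table(
    time_ms = rec$timestamps,
    theta_x_deg = rec$theta_x,
    theta_y_deg = rec$theta_y), path)
  invisible(path)
}

#' Read a cohort manifest written by [simulate_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with the manifest contents; `$recordings` is returned as
#'   a data frame with absolute paths.
#' @export
read_manifest <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  man$recordings$path <- file.path(dir, man$recordings$path)
  man
}

#' Cut recordings into fixed-length segments
#'
#' Per recording, the first `usable_s` seconds are retained and cut into
#' `floor(usable_s / segment_s)` non-overlapping segments in temporal
#' order. Recordings shorter than `usable_s` are truncated to the available
#' full segments with a warning.
#'
#' @param recordings Data frame with at least `path`, `subject`, `task`,
#'   `round`, `session`, `duration_s` (e.g. `read_manifest(dir)$recordings`).
#' @param segment_s Segment duration, seconds.
#' @param usable_s Seconds of each recording eligible for segmentation.
#' @return A data frame of segments with `start_s` and `segment_s` columns
#'   appended; one row per segment.
#' @export
segment_recordings <- function(recordings, segment_s, usable_s = 60) {
  if (segment_s > usable_s) stop("segment_s must not exceed usable_s")
  out <- vector("list", nrow(recordings))
  short <- FALSE
  for (i in seq_len(nrow(recordings))) {
    avail <- min(recordings$duration_s[i], usable_s)
    if (avail < usable_s) short <- TRUE
    n_seg <- floor(avail / segment_s + 1e-9)
    if (n_seg < 1) next
    seg <- recordings[rep(i, n_seg), , drop = FALSE]
    seg$start_s <- (seq_len(n_seg) - 1) * segment_s
    seg$segment_s <- segment_s
    out[[i]] <- seg
  }
  if (short)
    warning("some recordings were shorter than usable_s; truncated to full segments")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign subjects to test set and cross-validation folds
#'
#' Test subjects are those matching `test_rule` (by default: present in all
#' of rounds 1..`full_rounds`). The remaining subjects are trimmed from the
#' end to a multiple of `n_folds` and assigned to folds by a seeded shuffle;
#' the test set stays disjoint from every fold. An optional closed-set
#' temporal split of the test subjects' recordings (rounds 1-4 train, 5-6
#' validation, 7-8 test) is included.
#'
#' @param recordings Data frame with `subject` and `round` columns.
#' @param test_rule Function mapping a per-subject data frame to
#'   `TRUE`/`FALSE`, or a character vector of subject ids.
#' @param n_folds Number of cross-validation folds.
#' @param seed Fold-assignment seed.
#' @param full_rounds Rounds a subject must cover under the default rule.
#' @param closed_rounds List with integer vectors `train`, `val`, `test`
#'   for the closed-set temporal split.
#' @return An object of class `dataset_manifest`: `test_subjects`, `folds`
#'   (list of subject vectors), `closed_set` (recording row indices), and
#'   the input recordings.
#' @export
make_splits <- function(recordings, test_rule = NULL, n_folds = 10, seed = 1,
                        full_rounds = 8,
                        closed_rounds = list(train = 1:4, val = 5:6,
                                             test = 7:8)) {
  subjects <- unique(recordings$subject)
  if (is.character(test_rule)) {
    test_subjects <- test_rule
  } else {
    if (is.null(test_rule))
      test_rule <- function(df) all(seq_len(full_rounds) %in% df$round)
    keep <- vapply(subjects, function(s)
      isTRUE(test_rule(recordings[recordings$subject == s, , drop = FALSE])),
      logical(1))
    test_subjects <- subjects[keep]
  }
  if (!length(test_subjects)) stop("test set is empty")
  rest <- setdiff(subjects, test_subjects)
  n_keep <- (length(rest) %/% n_folds) * n_folds
  rest <- rest[seq_len(n_keep)]
  set.seed(seed)
  if (n_keep > 0) {
    shuffled <- sample(rest)
    folds <- split(shuffled, rep(seq_len(n_folds), length.out = n_keep))
    names(folds) <- paste0("fold", seq_len(length(folds)))
  } else folds <- list()

  is_test <- recordings$subject %in% test_subjects
  closed <- lapply(closed_rounds, function(r)
    which(is_test & recordings$round %in% r))
  stopifnot(!any(unlist(folds) %in% test_subjects))
  structure(list(recordings = recordings, test_subjects = test_subjects,
                 folds = folds, closed_set = closed, seed = seed),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("Dataset manifest: %d recordings, %d test subjects, %d folds of %d subjects\n",
              nrow(x$recordings), length(x$test_subjects), length(x$folds),
              length(x$folds[[1]])))
  invisible(x)
}
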