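# Session data model, I/O, trial filtering and design matrices.
#
# A dataset is a tibble with one row per trial and columns
#   unit_id   recording/session identifier (one unit per session)
#   index     0-based trial position within the session
#   signal    signed fraction of extra frames at the signal disparity
#             (positive = the unit's preferred disparity; 0 = no-signal trial)
#   choice    1 = preferred-disparity choice, 0 = null-disparity choice
#   target    correct (or, on no-signal trials, randomly rewarded) target
#   win       1 if the trial was rewarded
#   spikes    spike count over the 2-s stimulus
#   complete  1 if the trial finished with a registered choice
#   frame_hist  list-column: integer counts of frames per disparity level
#               (sums to 192 frames: 2 s at 96 Hz)
#   binned    optional list-column: 20 counts in 100-ms bins (sums to spikes)

FRAMES_PER_TRIAL <- 192L
N_TIME_BINS <- 20L

trial_columns <- c("unit_id", "index", "signal", "choice", "target",
                   "win", "spikes", "complete")

#' Validate a trial table
#'
#' Checks the per-trial invariants: binary coding of `choice`, `target` and
#' `win`; nonnegative integer `spikes`; `win == (choice == target)` on signal
#' trials; strictly increasing trial indices within each session; at least one
#' no-signal trial per session; `sum(binned) == spikes` and
#' `sum(frame_hist) == 192` where those columns are present.
#'
#' @param trials A trial tibble (see [read_sessions()] for the column layout).
#' @return `trials`, invisibly, if all checks pass. Otherwise an error naming
#'   the offending unit and trial.
#' @export
validate_sessions <- function(trials) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_trial <- function(unit, idx, what) {
    stop(sprintf("validation error in unit '%s', trial %s: %s", unit, idx, what),
         call. = FALSE)
  }
  for (col in c("choice", "target", "win", "complete")) {
    ok <- is_binary01(trials[[col]])
    if (!ok) {
      i <- which(!(trials[[col]] %in% c(0, 1) | is.na(trials[[col]])))[1]
      bad_trial(trials$unit_id[i], trials$index[i],
                sprintf("'%s' must be 0 or 1 (got %s)", col, trials[[col]][i]))
    }
  }
  bad_sp <- which(!is.na(trials$spikes) &
                    (trials$spikes < 0 | trials$spikes != round(trials$spikes)))
  if (length(bad_sp) > 0) {
    i <- bad_sp[1]
    bad_trial(trials$unit_id[i], trials$index[i], "'spikes' must be a nonnegative integer")
  }
  sig <- !is.na(trials$signal) & trials$signal != 0 & trials$complete == 1
  bad_win <- which(sig & trials$win != as.integer(trials$choice == trials$target))
  if (length(bad_win) > 0) {
    i <- bad_win[1]
    bad_trial(trials$unit_id[i], trials$index[i],
              "'win' must equal (choice == target) on signal trials")
  }
  if ("frame_hist" %in% names(trials)) {
    sums <- vapply(trials$frame_hist,
                   function(h) if (is.null(h)) NA_real_ else sum(h), numeric(1))
    bad <- which(!is.na(sums) & sums != FRAMES_PER_TRIAL)
    if (length(bad) > 0) {
      i <- bad[1]
      bad_trial(trials$unit_id[i], trials$index[i],
                sprintf("frame_hist sums to %s, expected %d", sums[i], FRAMES_PER_TRIAL))
    }
  }
  if ("binned" %in% names(trials)) {
    sums <- vapply(trials$binned,
                   function(b) if (is.null(b)) NA_real_ else sum(b), numeric(1))
    bad <- which(!is.na(sums) & sums != trials$spikes)
    if (length(bad) > 0) {
      i <- bad[1]
      bad_trial(trials$unit_id[i], trials$index[i], "sum(binned) != spikes")
    }
  }
  per_unit <- split(trials, trials$unit_id)
  for (u in names(per_unit)) {
    idx <- per_unit[[u]]$index
    if (any(diff(idx) <= 0)) {
      bad_trial(u, idx[which(diff(idx) <= 0)[1] + 1], "trial indices must be strictly increasing")
    }
    if (!any(per_unit[[u]]$signal == 0, na.rm = TRUE)) {
      stop(sprintf("validation error in unit '%s': no no-signal trials", u), call. = FALSE)
    }
  }
  invisible(trials)
}

pack_ints <- function(v) {
  if (is.null(v) || length(v) == 0 || all(is.na(v))) return(NA_character_)
  paste(as.integer(v), collapse = "|")
}

unpack_ints <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  out <- suppressWarnings(as.integer(strsplit(s, "|", fixed = TRUE)[[1]]))
  if (anyNA(out)) stop("malformed delimited integer field: ", s, call. = FALSE)
  out
}

#' Write a trial table to disk
#'
#' One row per trial; `frame_hist` and `binned` are serialized as
#' `|`-separated integer subfields (CSV) or JSON arrays.
#'
#' @param trials A validated trial tibble.
#' @param path Output file. Format is taken from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(trials, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  validate_sessions(trials)
  flat <- trials
  flat$frame_hist <- if ("frame_hist" %in% names(trials)) {
    vapply(trials$frame_hist, pack_ints, character(1))
  } else NA_character_
  flat$binned <- if ("binned" %in% names(trials)) {
    vapply(trials$binned, pack_ints, character(1))
  } else NA_character_
  flat <- flat[, c(trial_columns, "frame_hist", "binned")]
  if (format == "csv") {
    readr::write_csv(flat, path, na = "")
  } else {
    recs <- purrr::pmap(flat, function(...) {
      r <- list(...)
      r$frame_hist <- unpack_ints(r$frame_hist %||% NA_character_)
      r$binned <- unpack_ints(r$binned %||% NA_character_)
      r[!vapply(r, is.null, logical(1))]
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trial table from disk
#'
#' Reads the per-trial CSV (or its JSON mirror) written by [write_sessions()]
#' and validates all trial invariants.  Sessions are returned in file order.
#'
#' @param path Path to a `.csv` or `.json` session file.
#' @param format `"csv"` or `"json"`; `"auto"` infers from the extension.
#' @return A trial tibble with list-columns `frame_hist` and `binned`.
#' @export
read_sessions <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    flat <- suppressWarnings(readr::read_csv(
      path, na = "",
      col_types = readr::cols(
        unit_id = readr::col_character(),
        index = readr::col_integer(),
        signal = readr::col_double(),
        choice = readr::col_integer(),
        target = readr::col_integer(),
        win = readr::col_integer(),
        spikes = readr::col_integer(),
        complete = readr::col_integer(),
        frame_hist = readr::col_character(),
        binned = readr::col_character()
      ),
      progress = FALSE
    ))
    prob <- readr::problems(flat)
    if (nrow(prob) > 0) {
      stop(sprintf("parse error in %s, row %d: %s", path, prob$row[1],
                   prob$expected[1]), call. = FALSE)
    }
  } else {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    flat <- purrr::map_dfr(recs, function(r) {
      tibble(
        unit_id = as.character(r$unit_id), index = as.integer(r$index),
        signal = as.numeric(r$signal), choice = as.integer(r$choice),
        target = as.integer(r$target), win = as.integer(r$win),
        spikes = as.integer(r$spikes), complete = as.integer(r$complete),
        frame_hist = pack_ints(unlist(r$frame_hist)),
        binned = pack_ints(unlist(r$binned))
      )
    })
  }
  trials <- flat
  trials$frame_hist <- lapply(flat$frame_hist, unpack_ints)
  if (all(vapply(trials$frame_hist, is.null, logical(1)))) trials$frame_hist <- NULL
  trials$binned <- lapply(flat$binned, unpack_ints)
  if (all(vapply(trials$binned, is.null, logical(1)))) trials$binned <- NULL
  trials <- as_tibble(trials)
  validate_sessions(trials)
  trials
}

# Lagged covariates computed on the *original* trial sequence, before any
# row is dropped, so that row n always refers to physical trial n-1 (and n-2).
add_lagged <- function(trials) {
  trials %>%
    dplyr::group_by(.data$unit_id) %>%
    dplyr::arrange(.data$index, .by_group = TRUE) %>%
    dplyr::mutate(
      choice_prev = dplyr::lag(.data$choice),
      target_prev = dplyr::lag(.data$target),
      win_prev = dplyr::lag(.data$win),
      spikes_prev = dplyr::lag(.data$spikes),
      signal_prev = dplyr::lag(.data$signal),
      choice_prev2 = dplyr::lag(.data$choice, 2),
      target_prev2 = dplyr::lag(.data$target, 2),
      win_prev2 = dplyr::lag(.data$win, 2),
      spikes_prev2 = dplyr::lag(.data$spikes, 2),
      signal_prev2 = dplyr::lag(.data$signal, 2),
      prev_complete = dplyr::lag(.data$complete)
    ) %>%
    dplyr::ungroup()
}

#' Restrict a dataset to analyzable trials
#'
#' Keeps exactly the trials whose immediate predecessor exists and was
#' completed, attaching lagged covariate columns (`choice_prev`, `target_prev`,
#' `win_prev`, `spikes_prev`, `signal_prev`, and their `*2` versions for trial
#' n-2) computed on the original sequence.  Each session also gets a
#' `passes_inclusion` flag: `TRUE` when its remaining no-signal trials contain
#' at least four choices of each sign.  The operation is idempotent.
#'
#' @param trials A trial tibble.
#' @return The filtered tibble, with lag columns and `passes_inclusion`.
#' @export
filter_trials <- function(trials) {
  if (nrow(trials) == 0) stop("empty session", call. = FALSE)
  if (isTRUE(attr(trials, "cp_filtered"))) return(trials)
  out <- add_lagged(trials) %>%
    dplyr::filter(!is.na(.data$prev_complete), .data$prev_complete == 1) %>%
    dplyr::group_by(.data$unit_id) %>%
    dplyr::mutate(
      passes_inclusion =
        sum(.data$signal == 0 & .data$choice == 1, na.rm = TRUE) >= 4 &
        sum(.data$signal == 0 & .data$choice == 0, na.rm = TRUE) >= 4
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"prev_complete")
  attr(out, "cp_filtered") <- TRUE
  out
}

covariate_columns <- c(
  choice = "choice", choice_prev = "choice_prev", target_prev = "target_prev",
  win_prev = "win_prev", signal = "signal", spikes = "spikes",
  spikes_prev = "spikes_prev", choice_prev2 = "choice_prev2",
  target_prev2 = "target_prev2", win_prev2 = "win_prev2",
  spikes_prev2 = "spikes_prev2"
)

#' Build a standardized design matrix for one session
#'
#' Assembles the requested covariate columns (row n uses trial n-1 values for
#' the lagged covariates), optionally replaces the previous spike count by the
#' residual of regressing it on the previous stimulus strength through the
#' origin (removing its stimulus-induced component), and z-scores every column
#' using statistics computed from the training (signal) rows only; test
#' (no-signal) rows are standardized with the same statistics.  Constant
#' columns get scale 1.
#'
#' @param trials Trials of a single session, already passed through
#'   [filter_trials()] (applied automatically otherwise).
#' @param covariates Character vector among `"choice"`, `"choice_prev"`,
#'   `"target_prev"`, `"win_prev"`, `"signal"`, `"spikes"`, `"spikes_prev"`
#'   and the `"*_prev2"` variants.
#' @param target `"choice"` or `"spikes"`: the response column.
#' @param residualize_prev_spikes Regress the stimulus-induced component out
#'   of `spikes_prev` (and `spikes_prev2`) before standardizing.  Default
#'   `TRUE`, matching the treatment of the previous spike count.
#' @return An object of class `cp_design`: list with the standardized matrix
#'   `x`, response `y`, logical `train` (signal trials) and `test` (no-signal
#'   trials) masks, the per-column `center`/`scale`, and the trial `index`.
#' @export
build_design <- function(trials, covariates,
                         target = c("choice", "spikes"),
                         residualize_prev_spikes = TRUE) {
  target <- match.arg(target)
  if (length(unique(trials$unit_id)) != 1) {
    stop("build_design expects trials from a single session", call. = FALSE)
  }
  if (!isTRUE(attr(trials, "cp_filtered")) && !("choice_prev" %in% names(trials))) {
    trials <- filter_trials(trials)
  }
  unknown <- setdiff(covariates, names(covariate_columns))
  if (length(unknown) > 0) {
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(trials)
  cols <- lapply(covariates, function(cv) as.numeric(trials[[covariate_columns[[cv]]]]))
  x <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(x)) x <- matrix(numeric(0), nrow = n, ncol = 0)
  colnames(x) <- covariates
  if (residualize_prev_spikes && "spikes_prev" %in% covariates) {
    x[, "spikes_prev"] <- resid_through_origin(x[, "spikes_prev"],
                                               as.numeric(trials$signal_prev))
  }
  if (residualize_prev_spikes && "spikes_prev2" %in% covariates) {
    x[, "spikes_prev2"] <- resid_through_origin(x[, "spikes_prev2"],
                                                as.numeric(trials$signal_prev2))
  }
  train <- trials$signal != 0
  test <- trials$signal == 0
  if (sum(train) < 2) stop("fewer than 2 training (signal) rows", call. = FALSE)
  std <- if (ncol(x) > 0) standardize_columns(x, train) else
    list(x = x, center = numeric(0), scale = numeric(0))
  y <- if (target == "choice") as.numeric(trials$choice) else as.numeric(trials$spikes)
  structure(
    list(x = std$x, y = y, train = train, test = test,
         center = std$center, scale = std$scale,
         covariates = covariates, target = target,
         index = trials$index, unit_id = trials$unit_id[1]),
    class = "cp_design"
  )
}

#' @export
print.cp_design <- function(x, ...) {
  cat(sprintf("<cp_design> unit %s: %d trials (%d train, %d test), target '%s'\n",
              x$unit_id, length(x$y), sum(x$train), sum(x$test), x$target))
  cat("covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}
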