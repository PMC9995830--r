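#' Game scores: accuracy and recall
#'
#' The game's two end-of-session scores, exactly as shown to players:
#' accuracy is the percentage of marked sheep that were actually lame
#' (precision), recall the percentage of all lame sheep that were marked.
#' Accuracy is `NA` when no sheep was marked (0/0 is left undefined rather
#' than given a convention); recall is `NA` with a warning for the degenerate
#' draw of a flock with no lame sheep.
#'
#' @param marks A [mark_set()].
#' @param flock A `flock_state` or `session_log` providing the per-sheep
#'   `status` ground truth.
#' @return A percentage in `[0, 100]`, or `NA`.
#' @examples
#' flock <- init_flock(behavior_config(p_lame = 1), seed = 1)
#' score_recall(mark_set(1:6, 1:6), flock)   # 6 of 24 lame marked -> 25
#' @export
score_accuracy <- function(marks, flock) {
  status <- truth_status(flock, marks)
  if (!length(marks$sheep_id)) return(NA_real_)
  100 * sum(status[marks$sheep_id] == "lame") / length(marks$sheep_id)
}

#' @rdname score_accuracy
#' @export
score_recall <- function(marks, flock) {
  status <- truth_status(flock, marks)
  n_lame <- sum(status == "lame")
  if (n_lame == 0L) {
    warning("score_recall: flock contains no lame sheep; recall undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * sum(status[marks$sheep_id] == "lame") / n_lame
}

truth_status <- function(flock, marks) {
  status <- flock$status
  ids <- if (!is.null(flock$sheep_id)) flock$sheep_id else seq_along(status)
  if (length(marks$sheep_id) && !all(marks$sheep_id %in% ids)) {
    stop("marks refer to unknown sheep ids", call. = FALSE)
  }
  status
}

#' End-of-session score report
#'
#' Computes the full score panel from a session log: accuracy, recall, time
#' remaining on the in-game clock (0 when the timer expired), and the mark
#' and lame counts. Percentages are stored at full precision; the print
#' method displays them to one decimal place.
#'
#' @param log A `session_log` from [run_session()] or [read_session_log()].
#' @return An object of class `session_score` with fields `accuracy`,
#'   `recall`, `time_remaining`, `n_marked`, `n_lame`.
#' @export
session_report <- function(log) {
  if (is.null(log$status) || is.null(log$marks)) {
    stop("session_report: malformed log (missing status or marks)",
         call. = FALSE)
  }
  structure(
    list(
      accuracy = score_accuracy(log$marks, log),
      recall = suppressWarnings(score_recall(log$marks, log)),
      time_remaining = max(0, log$session_length - log$end_time),
      n_marked = length(log$marks$sheep_id),
      n_lame = sum(log$status == "lame")
    ),
    class = "session_score"
  )
}

#' @export
print.session_score <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", v)
  cat(sprintf(
    "<session_score> accuracy %s, recall %s, %gs remaining (%d marked / %d lame)\n",
    fmt(x$accuracy), fmt(x$recall), x$time_remaining, x$n_marked, x$n_lame))
  invisible(x)
}
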