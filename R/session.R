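#' Create a learner session
#'
#' Tracks a learner's graded attempts: per-level tallies (attempted,
#' correct, wrong, elapsed seconds), which quizzes have been answered at
#' each level (for without-replacement drawing), the current unlocked
#' level, and a full attempt history for auditing.
#'
#' @param student_id identifier string.
#' @param n_levels number of difficulty levels in play (default 3).
#' @return an object of class `session_state`.
#' @export
session_state <- function(student_id, n_levels = 3L) {
  n_levels <- as.integer(n_levels)
  stopifnot(is.character(student_id), length(student_id) == 1L,
            nzchar(student_id), n_levels >= 1L)
  structure(
    list(student_id = student_id,
         n_levels = n_levels,
         current_level = 1L,
         tallies = data.frame(level = seq_len(n_levels), attempted = 0L,
                              correct = 0L, wrong = 0L, elapsed = 0),
         answered = replicate(n_levels, character(), simplify = FALSE),
         history = list()),
    class = "session_state")
}

#' Record a graded attempt in a session
#'
#' Pure update: tallies at the attempt's level are incremented, the quiz id
#' is marked answered at that level, and the attempt is appended to the
#' history. Replaying the same attempt stream always reproduces the same
#' state. Attempting a level above the learner's current unlocked level is
#' an error.
#'
#' @param state a [session_state()].
#' @param attempt an `attempt_result` from [grade_attempt()].
#' @param level the level the quiz was drawn from.
#' @return the updated `session_state`.
#' @export
update_session <- function(state, attempt, level) {
  stopifnot(inherits(state, "session_state"),
            inherits(attempt, "attempt_result"))
  level <- as.integer(level)
  if (level < 1L || level > state$n_levels) stop("level out of range")
  if (level > state$current_level) {
    stop("level ", level, " is locked (current level ",
         state$current_level, ")")
  }
  i <- level
  state$tallies$attempted[i] <- state$tallies$attempted[i] + 1L
  if (isTRUE(attempt$correct)) {
    state$tallies$correct[i] <- state$tallies$correct[i] + 1L
  } else {
    state$tallies$wrong[i] <- state$tallies$wrong[i] + 1L
  }
  state$tallies$elapsed[i] <- state$tallies$elapsed[i] + attempt$elapsed
  state$answered[[i]] <- c(state$answered[[i]], attempt$quiz_id)
  state$history[[length(state$history) + 1L]] <-
    list(type = "attempt", level = level, attempt = attempt)
  state
}

#' Is a learner eligible to advance from a level?
#'
#' Eligibility requires that at least 70% of the quizzes attempted at the
#' level were answered correctly. With no attempts the result is `FALSE`
#' carrying the attribute `no_data = TRUE`, distinguishing "not yet
#' attempted" from "attempted and below threshold".
#'
#' @param state a [session_state()].
#' @param level the level to check.
#' @param threshold required correct fraction (default 0.70).
#' @return a logical scalar, with attribute `no_data` when there are no
#'   attempts at the level.
#' @export
advancement_eligible <- function(state, level, threshold = 0.70) {
  stopifnot(inherits(state, "session_state"))
  level <- as.integer(level)
  if (level < 1L || level > state$n_levels) stop("level out of range")
  att <- state$tallies$attempted[level]
  if (att == 0L) return(structure(FALSE, no_data = TRUE))
  state$tallies$correct[level] / att >= threshold - 1e-9
}

#' Unlock the next level when eligible
#'
#' Raises `current_level` by one if the learner meets the advancement rule
#' at the current level; otherwise the state is unchanged.
#'
#' @param state a [session_state()].
#' @param threshold required correct fraction (default 0.70).
#' @return the (possibly updated) `session_state`.
#' @export
advance_level <- function(state, threshold = 0.70) {
  if (state$current_level < state$n_levels &&
      isTRUE(as.logical(advancement_eligible(state, state$current_level,
                                             threshold)))) {
    state$current_level <- state$current_level + 1L
  }
  state
}

#' Restart a level
#'
#' Zeroes the level's tallies and clears its answered-quiz set, so its
#' quizzes become drawable again; other levels are untouched and the
#' history keeps both the old attempts and a restart audit record.
#'
#' @param state a [session_state()].
#' @param level the level to restart.
#' @return the updated `session_state`.
#' @export
restart_level <- function(state, level) {
  stopifnot(inherits(state, "session_state"))
  level <- as.integer(level)
  if (level < 1L || level > state$n_levels) stop("level out of range")
  state$tallies$attempted[level] <- 0L
  state$tallies$correct[level] <- 0L
  state$tallies$wrong[level] <- 0L
  state$tallies$elapsed[level] <- 0
  state$answered[[level]] <- character()
  state$history[[length(state$history) + 1L]] <-
    list(type = "restart", level = level)
  state
}

#' Progress dashboard for a session
#'
#' Summarizes a session exactly from its tallies: percent correct overall
#' (pooled over levels) and per level, total time spent, per-level correct
#' counts, and advancement eligibility per level. Percentages are 0 when
#' nothing was attempted.
#'
#' @param state a [session_state()].
#' @param threshold advancement threshold passed through to
#'   [advancement_eligible()].
#' @return a `progress_report`: `student_id`, `overall_percent`,
#'   `total_elapsed`, `per_level` (data.frame with `level`, `attempted`,
#'   `correct`, `wrong`, `percent`, `eligible`, `no_data`),
#'   `current_level`.
#' @export
progress_summary <- function(state, threshold = 0.70) {
  stopifnot(inherits(state, "session_state"))
  t <- state$tallies
  pct <- ifelse(t$attempted > 0, 100 * t$correct / t$attempted, 0)
  elig <- logical(nrow(t)); nodata <- logical(nrow(t))
  for (i in seq_len(nrow(t))) {
    e <- advancement_eligible(state, i, threshold)
    elig[i] <- as.logical(e)
    nodata[i] <- isTRUE(attr(e, "no_data"))
  }
  tot_att <- sum(t$attempted)
  structure(
    list(student_id = state$student_id,
         overall_percent = if (tot_att > 0) 100 * sum(t$correct) / tot_att else 0,
         total_elapsed = sum(t$elapsed),
         per_level = data.frame(level = t$level, attempted = t$attempted,
                                correct = t$correct, wrong = t$wrong,
                                percent = pct, eligible = elig,
                                no_data = nodata),
         current_level = state$current_level),
    class = "progress_report")
}

#' @export
print.progress_report <- function(x, ...) {
  cat("Progress for ", x$student_id, " (current level ",
      x$current_level, ")\n", sep = "")
  cat(sprintf("  overall correct: %.1f%%  total time: %.0f s\n",
              x$overall_percent, x$total_elapsed))
  for (i in seq_len(nrow(x$per_level))) {
    r <- x$per_level[i, ]
    cat(sprintf("  level %d: %d/%d correct (%.1f%%)%s\n", r$level,
                r$correct, r$attempted, r$percent,
                if (r$no_data) " [no attempts]"
                else if (r$eligible) " [advance]" else ""))
  }
  invisible(x)
}

#' Rank a cohort of sessions
#'
#' Lexicographic ranking over the dashboard quantities: total correct
#' answers (more is better), then total wrong answers (fewer is better),
#' then total elapsed time (faster is better), with student id as the final
#' deterministic tie-break. Ranks run 1..N.
#'
#' @param sessions a list of [session_state()] objects.
#' @return a data.frame with `rank`, `student_id`, `total_correct`,
#'   `total_wrong`, `total_elapsed`, and one `level<k>_percent` column per
#'   level.
#' @export
rank_students <- function(sessions) {
  stopifnot(all(vapply(sessions, inherits, TRUE, "session_state")))
  if (length(sessions) == 0L) {
    return(data.frame(rank = integer(), student_id = character(),
                      total_correct = integer(), total_wrong = integer(),
                      total_elapsed = numeric()))
  }
  rows <- lapply(sessions, function(s) {
    t <- s$tallies
    pct <- ifelse(t$attempted > 0, 100 * t$correct / t$attempted, 0)
    cbind(data.frame(student_id = s$student_id,
                     total_correct = sum(t$correct),
                     total_wrong = sum(t$wrong),
                     total_elapsed = sum(t$elapsed)),
          as.data.frame(as.list(setNames(pct,
            paste0("level", t$level, "_percent")))))
  }
  )
  df <- do.call(rbind, rows)
  ord <- order(-df$total_correct, df$total_wrong, df$total_elapsed,
               df$student_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  cbind(rank = seq_len(nrow(df)), df)
}

#' Persist or restore a session as JSON
#'
#' @param state a [session_state()].
#' @param path file path.
#' @export
write_session <- function(state, path) {
  payload <- unclass(state)
  payload$history <- lapply(payload$history, function(h) {
    if (!is.null(h$attempt)) h$attempt <- na_to_null(unclass(h$attempt))
    h
  })
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  st <- session_state(raw$student_id, raw$n_levels)
  st$current_level <- as.integer(raw$current_level)
  tl <- raw$tallies
  st$tallies <- data.frame(
    level = vapply(tl, function(r) as.integer(r$level), 0L),
    attempted = vapply(tl, function(r) as.integer(r$attempted), 0L),
    correct = vapply(tl, function(r) as.integer(r$correct), 0L),
    wrong = vapply(tl, function(r) as.integer(r$wrong), 0L),
    elapsed = vapply(tl, function(r) as.numeric(r$elapsed), 0))
  st$answered <- lapply(raw$answered, function(a) as.character(unlist(a)))
  if (length(st$answered) == 0L) {
    st$answered <- replicate(st$n_levels, character(), simplify = FALSE)
  }
  st$history <- lapply(raw$history, function(h) {
    if (!is.null(h$attempt)) {
      at <- h$attempt
      at$answers <- as.character(unlist(at$answers))
      at$first_error_index <- if (is.null(at$first_error_index)) NA_integer_
        else as.integer(at$first_error_index)
      h$attempt <- structure(at, class = "attempt_result")
    }
    h
  })
  st
}
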