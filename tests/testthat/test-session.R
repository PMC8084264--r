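make_attempt <- function(correct, elapsed = 30, id = NULL) {
  structure(list(quiz_id = id %||% paste0("q", sample.int(1e6, 1)),
                 answers = "x", correct = correct,
                 first_error_index = if (correct) NA_integer_ else 1L,
                 elapsed = elapsed, diagnosis = "d"),
            class = "attempt_result")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("session updates accumulate tallies deterministically", {
  s <- session_state("alice", n_levels = 3L)
  s <- update_session(s, make_attempt(TRUE, 30), 1L)
  expect_equal(unlist(s$tallies[1L, c("attempted", "correct", "wrong")]),
               c(attempted = 1L, correct = 1L, wrong = 0L))
  expect_equal(s$tallies$elapsed[1L], 30)
  s <- update_session(s, make_attempt(FALSE, 12), 1L)
  expect_equal(unlist(s$tallies[1L, c("attempted", "correct", "wrong")]),
               c(attempted = 2L, correct = 1L, wrong = 1L))
  expect_equal(s$tallies$elapsed[1L], 42)
  expect_length(s$history, 2L)
  # attempted = correct + wrong at every level
  expect_true(all(s$tallies$attempted ==
                    s$tallies$correct + s$tallies$wrong))

  # replaying an identical stream reproduces the state exactly
  replay <- function() {
    st <- session_state("bob", 2L)
    st <- update_session(st, make_attempt(TRUE, 10, id = "a"), 1L)
    update_session(st, make_attempt(FALSE, 20, id = "b"), 1L)
  }
  expect_identical(replay(), replay())

  # locked levels are rejected
  expect_error(update_session(s, make_attempt(TRUE), 2L), "locked")
  expect_error(update_session(s, make_attempt(TRUE), 9L), "range")
})

test_that("advancement flips exactly at 70% correct", {
  flips <- vapply(0:10, function(k) {
    s <- session_state("s", 2L)
    for (i in seq_len(k)) s <- update_session(s, make_attempt(TRUE), 1L)
    for (i in seq_len(10L - k)) s <- update_session(s, make_attempt(FALSE), 1L)
    as.logical(advancement_eligible(s, 1L))
  }, TRUE)
  expect_identical(flips, c(rep(FALSE, 7L), rep(TRUE, 4L)))
  # first TRUE at exactly k = 7
  expect_equal(which(flips)[1L] - 1L, 7L)
})

test_that("zero attempts give an ineligible result flagged as no-data", {
  s <- session_state("s", 2L)
  e <- advancement_eligible(s, 1L)
  expect_false(as.logical(e))
  expect_true(attr(e, "no_data"))
  # after one attempt the flag disappears
  s <- update_session(s, make_attempt(FALSE), 1L)
  e2 <- advancement_eligible(s, 1L)
  expect_false(as.logical(e2))
  expect_null(attr(e2, "no_data"))
})

test_that("advance_level unlocks the next level only when eligible", {
  s <- session_state("s", 3L)
  for (i in 1:7) s <- update_session(s, make_attempt(TRUE), 1L)
  for (i in 1:3) s <- update_session(s, make_attempt(FALSE), 1L)
  s <- advance_level(s)
  expect_equal(s$current_level, 2L)
  # 2/4 at level 2: stays
  for (i in 1:2) s <- update_session(s, make_attempt(TRUE), 2L)
  for (i in 1:2) s <- update_session(s, make_attempt(FALSE), 2L)
  expect_equal(advance_level(s)$current_level, 2L)
})

test_that("restarting a level clears it (and only it), keeping the audit trail", {
  s <- session_state("s", 2L)
  for (i in 1:6) s <- update_session(s, make_attempt(i <= 5, 10), 1L)
  s <- advance_level(s)
  s <- update_session(s, make_attempt(TRUE, 5), 2L)
  n_hist <- length(s$history)

  s2 <- restart_level(s, 1L)
  expect_equal(unlist(s2$tallies[1L, c("attempted", "correct", "wrong",
                                       "elapsed")]),
               c(attempted = 0L, correct = 0L, wrong = 0L, elapsed = 0))
  expect_equal(s2$answered[[1L]], character())
  # level 2 untouched
  expect_equal(s2$tallies$attempted[2L], 1L)
  # history retains attempts plus a restart record
  expect_length(s2$history, n_hist + 1L)
  expect_equal(s2$history[[n_hist + 1L]]$type, "restart")

  # restarted quizzes become drawable again
  fit <- c45(fig_fibronectin_table(), c45_control(prune = FALSE))
  pool <- assign_levels(build_quizzes(fit), 1L)
  st <- session_state("t", 1L)
  q <- draw_quiz(pool, st$answered[[1L]], level = 1L, seed = 2L)
  st <- update_session(st, grade_attempt(q, vapply(q$questions, `[[`, "",
                                                   "correct")), 1L)
  expect_true(q$quiz_id %in% st$answered[[1L]])
  st <- restart_level(st, 1L)
  expect_false(q$quiz_id %in% st$answered[[1L]])
})

test_that("progress summaries are pure arithmetic over the tallies", {
  s <- session_state("s", 2L)
  p0 <- progress_summary(s)
  expect_equal(p0$overall_percent, 0)
  expect_equal(p0$total_elapsed, 0)

  for (i in 1:7) s <- update_session(s, make_attempt(TRUE, 10), 1L)
  for (i in 1:3) s <- update_session(s, make_attempt(FALSE, 10), 1L)
  p <- progress_summary(s)
  expect_equal(p$per_level$percent[1L], 70)
  expect_true(p$per_level$eligible[1L])

  # pooled percentage: 2/2 at level 1 plus 1/4 at level 2 = 3/6
  s2 <- session_state("t", 2L)
  for (i in 1:2) s2 <- update_session(s2, make_attempt(TRUE, 5), 1L)
  s2 <- advance_level(s2)
  s2 <- update_session(s2, make_attempt(TRUE, 5), 2L)
  for (i in 1:3) s2 <- update_session(s2, make_attempt(FALSE, 5), 2L)
  p2 <- progress_summary(s2)
  expect_equal(p2$overall_percent, 50)
  expect_equal(p2$total_elapsed, 30)
  # same state, same report
  expect_identical(progress_summary(s2), progress_summary(s2))
})

test_that("ranking is lexicographic: corrects, then errors, then time, then id", {
  mk_session <- function(id, correct, wrong, elapsed) {
    s <- session_state(id, 1L)
    for (i in seq_len(correct)) s <- update_session(s, make_attempt(TRUE, 0), 1L)
    for (i in seq_len(wrong)) s <- update_session(s, make_attempt(FALSE, 0), 1L)
    s$tallies$elapsed[1L] <- elapsed
    s
  }
  sessions <- list(
    mk_session("dora", 8L, 1L, 100),
    mk_session("alice", 10L, 5L, 500),
    mk_session("carol", 8L, 1L, 50),
    mk_session("bob", 8L, 3L, 10),
    mk_session("erin", 8L, 1L, 50))
  r <- rank_students(sessions)
  expect_equal(r$student_id, c("alice", "carol", "erin", "dora", "bob"))
  expect_equal(r$rank, 1:5)
  # permutation of the input, stable across repeated calls
  expect_setequal(r$student_id,
                  vapply(sessions, `[[`, "", "student_id"))
  expect_identical(r, rank_students(rev(sessions)))
})

test_that("sessions persist to JSON and back", {
  s <- session_state("alice", 2L)
  s <- update_session(s, make_attempt(TRUE, 30, id = "q1"), 1L)
  s <- update_session(s, make_attempt(FALSE, 10, id = "q2"), 1L)
  f <- withr::local_tempfile(fileext = ".json")
  write_session(s, f)
  back <- read_session(f)
  expect_identical(back$tallies, s$tallies)
  expect_identical(back$answered, s$answered)
  expect_identical(back$current_level, s$current_level)
  expect_equal(length(back$history), length(s$history))
  expect_identical(back$history[[1L]]$attempt$quiz_id, "q1")
})
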