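test_that("paths biject with leaves, in top-down tree order", {
  # degenerate single-leaf tree
  mono <- c45(case_table(data.frame(a = c("x", "y"), dx = c("s", "s")),
                         class_attribute = "dx"))
  p <- enumerate_paths(mono)
  expect_length(p, 1L)
  expect_equal(nrow(p[[1]]$steps), 0L)

  # depth-1 tree with 3 branches
  df <- data.frame(marker = rep(c("m1", "m2", "m3"), each = 2L),
                   dx = rep(c("a", "b", "c"), each = 2L))
  fit <- c45(case_table(df, class_attribute = "dx"),
             c45_control(prune = FALSE))
  p <- enumerate_paths(fit)
  expect_length(p, 3L)
  expect_true(all(vapply(p, function(x) nrow(x$steps) == 1L, TRUE)))
  expect_equal(vapply(p, function(x) x$steps$branch, ""),
               c("m1", "m2", "m3"))

  # the fibronectin-style branch: one step straight to the diagnosis
  fig <- c45(fig_fibronectin_table(), c45_control(prune = FALSE))
  paths <- enumerate_paths(fig)
  hit <- Filter(function(x)
    any(x$steps$attribute == "immunohistochemistry" &
          x$steps$branch == "positive for fibronectin"), paths)
  expect_length(hit, 1L)
  expect_equal(nrow(hit[[1]]$steps), 1L)
  expect_equal(hit[[1]]$diagnosis, "fibronectin glomerulopathy")

  # bijection holds across assorted induced models
  for (seed in c(1L, 14L, 33L)) {
    gt <- sample_ground_truth(n_diagnoses = 9L, n_attributes = 9L,
                              seed = seed)
    fit <- c45(generate_cases(gt, 120L, seed = seed + 50L),
               c45_control(prune = FALSE))
    expect_length(enumerate_paths(fit), n_leaves(fit))
  }
})

test_that("quizzes mirror paths: full-domain options, stable ids, images", {
  fit <- c45(fig_fibronectin_table(), c45_control(prune = FALSE))
  quizzes <- build_quizzes(fit)
  expect_length(quizzes, n_leaves(fit))
  q1 <- quizzes[[1]]
  expect_equal(q1$questions[[1]]$attribute, "immunohistochemistry")
  expect_setequal(q1$questions[[1]]$options,
                  c("negative", "positive for fibronectin"))
  expect_true(all(vapply(quizzes, function(q)
    all(vapply(q$questions, function(qq) qq$correct %in% qq$options, TRUE)),
    TRUE)))

  # deterministic ids across rebuilds
  ids1 <- vapply(quizzes, `[[`, "", "quiz_id")
  ids2 <- vapply(build_quizzes(fit), `[[`, "", "quiz_id")
  expect_identical(ids1, ids2)
  expect_false(anyDuplicated(ids1) > 0)

  # manifest lookups, with a warning for a diagnosis lacking an image
  manifest <- c("fibronectin glomerulopathy" = "fibro.png",
                "iga nephropathy" = "iga.png")
  expect_warning(q <- build_quizzes(fit, manifest), "minimal change")
  img <- vapply(q, `[[`, "", "diagnosis")
  expect_equal(q[[which(img == "fibronectin glomerulopathy")]]$image_ref,
               "fibro.png")
  expect_true(is.na(q[[which(img == "minimal change disease")]]$image_ref))
})

test_that("retraining on new cases regenerates the pool with fresh ids", {
  tab <- fig_fibronectin_table()
  fit1 <- c45(tab, c45_control(prune = FALSE))
  ids1 <- vapply(build_quizzes(fit1), `[[`, "", "quiz_id")

  extra <- data.frame(
    immunohistochemistry = rep("positive for igg", 2L),
    mesangial_hypercellularity = rep("present", 2L),
    diagnosis = rep("membranous nephropathy", 2L))
  df2 <- rbind(as.data.frame(lapply(tab$data, as.character)), extra)
  fit2 <- c45(case_table(df2, class_attribute = "diagnosis"),
              c45_control(prune = FALSE))
  ids2 <- vapply(build_quizzes(fit2), `[[`, "", "quiz_id")
  # the changed region of the tree yields ids absent from the old pool
  expect_true(length(setdiff(ids2, ids1)) > 0L)
})

test_that("levels follow path-length quantiles with near-equal sizes", {
  mk <- function(len) {
    structure(list(quiz_id = paste0("q", len, sample.int(1e6, 1)),
                   questions = rep(list(list(attribute = "a",
                                             options = c("x", "y"),
                                             correct = "x")), len),
                   diagnosis = "d", image_ref = NA_character_,
                   level = NA_integer_), class = "quiz")
  }
  qs <- assign_levels(list(mk(1), mk(1), mk(3), mk(3)), 2L)
  expect_equal(vapply(qs, `[[`, 0L, "level"), c(1L, 1L, 2L, 2L))
  qs <- assign_levels(list(mk(3), mk(1), mk(2)), 3L)
  expect_equal(vapply(qs, `[[`, 0L, "level"), c(3L, 1L, 2L))
  qs <- assign_levels(list(mk(2), mk(2), mk(2)), 1L)
  expect_equal(vapply(qs, `[[`, 0L, "level"), c(1L, 1L, 1L))
  expect_error(assign_levels(list(mk(1)), 2L), "config error")
  # populations differ by at most one
  qs <- assign_levels(lapply(c(1, 1, 2, 2, 3, 3, 4), mk), 3L)
  sizes <- table(vapply(qs, `[[`, 0L, "level"))
  expect_lte(max(sizes) - min(sizes), 1L)
})

test_that("drawing is seeded, without replacement, and exhausts to NULL", {
  fit <- c45(fig_fibronectin_table(), c45_control(prune = FALSE))
  pool <- assign_levels(build_quizzes(fit), 2L)
  lvl1 <- Filter(function(q) q$level == 1L, pool)

  d1 <- draw_quiz(pool, level = 1L, seed = 9L)
  d2 <- draw_quiz(pool, level = 1L, seed = 9L)
  expect_identical(d1$quiz_id, d2$quiz_id)

  # without replacement: excluding drawn ids eventually exhausts the level
  answered <- character()
  drawn <- character()
  repeat {
    q <- draw_quiz(pool, answered = answered, level = 1L, seed = 1L)
    if (is.null(q)) break
    drawn <- c(drawn, q$quiz_id)
    answered <- c(answered, q$quiz_id)
  }
  expect_setequal(drawn, vapply(lvl1, `[[`, "", "quiz_id"))
  expect_null(draw_quiz(pool, answered = answered, level = 1L))

  # single remaining quiz is returned deterministically
  last <- vapply(lvl1, `[[`, "", "quiz_id")[1]
  got <- draw_quiz(pool, answered = setdiff(answered, last), level = 1L)
  expect_identical(got$quiz_id, last)
})

test_that("grading accepts only the exact tree flow", {
  fit <- c45(fig_fibronectin_table(), c45_control(prune = FALSE))
  quizzes <- build_quizzes(fit)
  two <- Filter(function(q) length(q$questions) == 2L, quizzes)[[1]]
  key <- vapply(two$questions, `[[`, "", "correct")

  ok <- grade_attempt(two, key, elapsed = 30)
  expect_true(ok$correct)
  expect_true(is.na(ok$first_error_index))

  wrong_first <- key
  wrong_first[1] <- setdiff(two$questions[[1]]$options, key[1])[1]
  bad <- grade_attempt(two, wrong_first, elapsed = 10)
  expect_false(bad$correct)
  expect_equal(bad$first_error_index, 1L)

  incomplete <- grade_attempt(two, key[1], elapsed = 5)
  expect_false(incomplete$correct)
  expect_equal(incomplete$first_error_index, 2L)

  expect_error(grade_attempt(two, c("not an option", key[2])), "input error")
  expect_error(grade_attempt(two, c(key, key)), "more answers")
})

test_that("training instances reaching a leaf grade as correct answers", {
  for (seed in c(6L, 19L)) {
    gt <- sample_ground_truth(n_diagnoses = 8L, n_attributes = 8L,
                              seed = seed)
    tab <- generate_cases(gt, 100L, seed = seed + 10L)
    fit <- c45(tab, c45_control(prune = FALSE))
    quizzes <- build_quizzes(fit)
    preds <- predict(fit, tab, type = "prediction")
    for (q in quizzes) {
      key <- vapply(q$questions, `[[`, "", "correct")
      # find a training instance whose classification path is this quiz
      qatt <- vapply(q$questions, `[[`, "", "attribute")
      hit <- which(vapply(preds, function(p)
        nrow(p$path) == length(key) &&
          all(p$path$branch == key) &&
          all(p$path$attribute == qatt), TRUE))[1]
      if (is.na(hit)) next  # leaf not reached by training data (pruned el.)
      ans <- vapply(seq_along(key), function(i)
        as.character(tab$data[[q$questions[[i]]$attribute]][hit]), "")
      expect_true(grade_attempt(q, ans)$correct)
    }
  }
})

test_that("quiz pools round-trip through JSON", {
  fit <- c45(fig_fibronectin_table(), c45_control(prune = FALSE))
  pool <- assign_levels(build_quizzes(fit), 2L)
  back <- quizzes_from_json(quizzes_to_json(pool))
  expect_equal(length(back), length(pool))
  expect_identical(vapply(back, `[[`, "", "quiz_id"),
                   vapply(pool, `[[`, "", "quiz_id"))
  expect_identical(back[[1]]$questions, pool[[1]]$questions)
  expect_identical(vapply(back, `[[`, 0L, "level"),
                   vapply(pool, `[[`, 0L, "level"))
})
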