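#' Enumerate root-to-leaf paths of a tree
#'
#' One path per leaf, in depth-first order following each node's branch
#' declaration order. Each path records the ordered (attribute, branch)
#' steps, the leaf's diagnosis, and its per-class support counts. A
#' single-leaf tree yields one path with zero steps.
#'
#' @param model a fitted [c45()] model.
#' @return a list of `tree_path` objects: `steps` (data.frame `attribute`,
#'   `branch`), `diagnosis`, `support`.
#' @export
enumerate_paths <- function(model) {
  stopifnot(inherits(model, "c45"))
  out <- list()
  walk <- function(node, attrs, branches) {
    if (is_leaf(node)) {
      out[[length(out) + 1L]] <<- structure(
        list(steps = data.frame(attribute = attrs, branch = branches),
             diagnosis = node$diagnosis, support = node$support),
        class = "tree_path")
      return()
    }
    for (b in names(node$branches)) {
      walk(node$branches[[b]], c(attrs, node$attribute), c(branches, b))
    }
  }
  walk(model$root, character(), character())
  out
}

path_key <- function(steps, diagnosis) {
  paste(c(paste(steps$attribute, steps$branch, sep = "="), "->", diagnosis),
        collapse = "|")
}

#' Build quizzes from a fitted tree
#'
#' Each root-to-leaf path becomes one quiz: the questions follow the tree
#' top-down, one per split on the path, and the options offered for a
#' question are the attribute's full domain (the learner must weigh every
#' possible finding, not only those branched on). The quiz's answer key is
#' the path's branch labels and its outcome is the leaf diagnosis. Quiz ids
#' are deterministic hashes of the path, so rebuilding from the same tree
#' reproduces the same ids, while retraining on new cases yields a new pool
#' whose ids invalidate stale ones.
#'
#' @param model a fitted [c45()] model.
#' @param image_manifest optional mapping from diagnosis to an image file
#'   name: a named character vector, or a 2-column data.frame (diagnosis,
#'   file). Diagnoses absent from the manifest get no image and one warning
#'   is raised listing them.
#' @return a list of `quiz` objects: `quiz_id`, `questions` (each with
#'   `attribute`, `options`, `correct`), `diagnosis`, `image_ref`, `level`
#'   (`NA` until [assign_levels()]).
#' @export
build_quizzes <- function(model, image_manifest = NULL) {
  manifest <- normalize_manifest(image_manifest)
  paths <- enumerate_paths(model)
  quizzes <- lapply(paths, function(p) {
    questions <- lapply(seq_len(nrow(p$steps)), function(i) {
      a <- p$steps$attribute[i]
      list(attribute = a,
           options = model$schema$attributes[[a]],
           correct = p$steps$branch[i])
    })
    structure(
      list(quiz_id = fnv1a32(path_key(p$steps, p$diagnosis)),
           questions = questions,
           diagnosis = p$diagnosis,
           image_ref = if (p$diagnosis %in% names(manifest))
             unname(manifest[[p$diagnosis]]) else NA_character_,
           level = NA_integer_),
      class = "quiz")
  })
  if (length(manifest)) {
    missing <- setdiff(vapply(quizzes, `[[`, "", "diagnosis"), names(manifest))
    if (length(missing)) {
      warning("no image for diagnosis/diagnoses: ",
              paste(unique(missing), collapse = ", "))
    }
  }
  quizzes
}

normalize_manifest <- function(m) {
  if (is.null(m)) return(character())
  if (is.data.frame(m)) {
    stopifnot(ncol(m) >= 2L)
    return(setNames(as.character(m[[2L]]), as.character(m[[1L]])))
  }
  stopifnot(is.character(m), !is.null(names(m)))
  m
}

#' Read an image manifest
#'
#' Accepts a JSON object (`{"diagnosis": "file.png", ...}`) or a 2-column
#' CSV (diagnosis, file name).
#'
#' @param path file path; format inferred from the extension.
#' @return a named character vector.
#' @export
read_image_manifest <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    return(unlist(x))
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Assign difficulty levels to a quiz pool
#'
#' Difficulty is the quiz's path length (questions asked before the
#' diagnosis): quizzes are ranked by length and cut into `n_levels`
#' contiguous groups of near-equal size (differing by at most one quiz),
#' shorter paths in lower levels. Quizzes of equal length may straddle a
#' boundary when the group sizes require it.
#'
#' @param quizzes a non-empty list of quizzes from [build_quizzes()].
#' @param n_levels number of difficulty levels (default 3).
#' @return the quizzes, in their original order, with `level` set.
#' @export
assign_levels <- function(quizzes, n_levels = 3L) {
  n <- length(quizzes)
  if (n == 0L) stop("config error: empty quiz list")
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("config error: n_levels must be >= 1")
  if (n_levels > n) stop("config error: n_levels (", n_levels,
                         ") exceeds the quiz count (", n, ")")
  len <- vapply(quizzes, function(q) length(q$questions), 0L)
  ord <- order(len, seq_len(n))               # stable
  sizes <- rep(n %/% n_levels, n_levels)
  extra <- n %% n_levels
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lev <- rep(seq_len(n_levels), times = sizes)
  for (i in seq_len(n)) quizzes[[ord[i]]]$level <- lev[i]
  quizzes
}

#' Draw the next quiz for a session
#'
#' Uniform random draw from the unanswered quizzes at the requested level;
#' drawing is without replacement across a session (already answered ids
#' are excluded), and `NULL` signals that the level is exhausted.
#'
#' @param pool a list of levelled quizzes ([assign_levels()]).
#' @param answered character vector of quiz ids already answered this
#'   session.
#' @param level the level to draw from; `NULL` draws from the whole pool.
#' @param seed optional seed for a reproducible draw; `NULL` uses (and
#'   advances) the current RNG stream.
#' @return a `quiz`, or `NULL` when no unanswered quiz remains.
#' @export
draw_quiz <- function(pool, answered = character(), level = NULL,
                      seed = NULL) {
  ids <- vapply(pool, `[[`, "", "quiz_id")
  keep <- !(ids %in% answered)
  if (!is.null(level)) {
    keep <- keep & vapply(pool, function(q)
      identical(as.integer(q$level), as.integer(level)), TRUE)
  }
  cand <- which(keep)
  if (length(cand) == 0L) return(NULL)
  pick <- with_seed(seed, cand[sample.int(length(cand), 1L)])
  pool[[pick]]
}

#' Grade a quiz attempt
#'
#' An attempt is correct only when it reproduces the tree's flow exactly:
#' every question answered, in order, with the path's branch label. Any
#' deviation -- a wrong answer or an unanswered question -- makes the
#' attempt incorrect, and `first_error_index` points (1-based) at the first
#' mismatching or missing position. An answer outside a question's option
#' set is an input error, not a wrong answer.
#'
#' @param quiz a `quiz`.
#' @param answers character vector of chosen options, in question order; may
#'   be shorter than the question list (an incomplete attempt).
#' @param elapsed seconds spent, `>= 0`.
#' @return an `attempt_result`: `quiz_id`, `answers`, `correct`,
#'   `first_error_index` (`NA` when correct), `elapsed`, `diagnosis`.
#' @export
grade_attempt <- function(quiz, answers, elapsed = 0) {
  stopifnot(inherits(quiz, "quiz"), is.numeric(elapsed), elapsed >= 0)
  answers <- as.character(answers)
  nq <- length(quiz$questions)
  if (length(answers) > nq) stop("more answers than questions")
  for (i in seq_along(answers)) {
    if (!(answers[i] %in% quiz$questions[[i]]$options)) {
      stop("input error: answer ", i, " ('", answers[i],
           "') is not among the question's options")
    }
  }
  key <- vapply(quiz$questions, `[[`, "", "correct")
  first_err <- NA_integer_
  for (i in seq_len(nq)) {
    if (i > length(answers) || answers[i] != key[i]) { first_err <- i; break }
  }
  structure(
    list(quiz_id = quiz$quiz_id, answers = answers,
         correct = is.na(first_err), first_error_index = first_err,
         elapsed = as.numeric(elapsed), diagnosis = quiz$diagnosis),
    class = "attempt_result")
}

#' @export
print.quiz <- function(x, ...) {
  cat("Quiz ", x$quiz_id,
      if (!is.na(x$level)) paste0(" (level ", x$level, ")"), "\n", sep = "")
  for (i in seq_along(x$questions)) {
    q <- x$questions[[i]]
    cat("  Q", i, ". ", q$attribute, "? [",
        paste(q$options, collapse = " | "), "]\n", sep = "")
  }
  cat("  Diagnosis: ", x$diagnosis,
      if (!is.na(x$image_ref)) paste0(" (image: ", x$image_ref, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Export or import a quiz pool as JSON
#'
#' @param quizzes a list of quizzes.
#' @return `quizzes_to_json()`: a JSON string; `quizzes_from_json()`: a list
#'   of quizzes.
#' @export
quizzes_to_json <- function(quizzes) {
  jsonlite::toJSON(lapply(quizzes, function(q) na_to_null(unclass(q))),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname quizzes_to_json
#' @param json a JSON string from `quizzes_to_json()`.
#' @export
quizzes_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  lapply(raw, function(q) {
    q$questions <- lapply(q$questions, function(qq) {
      qq$options <- as.character(unlist(qq$options))
      qq
    })
    q$image_ref <- if (is.null(q$image_ref)) NA_character_ else q$image_ref
    q$level <- if (is.null(q$level)) NA_integer_ else as.integer(q$level)
    structure(q, class = "quiz")
  })
}
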