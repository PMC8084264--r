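#' Induction parameters for C4.5-style trees
#'
#' @param purity_threshold fraction in (0, 1]: a node whose majority class
#'   reaches this fraction of its instances becomes a leaf (the user-set
#'   "level of similarity" at which segmentation stops). Default 1, i.e.
#'   split until pure.
#' @param min_instances positive integer: nodes with fewer instances are not
#'   split. Default 2.
#' @param prune logical: apply pessimistic-error pruning after growth.
#'   Default `TRUE`.
#' @param confidence fraction in (0, 1): confidence level of the binomial
#'   upper bound used by the pruning rule. Default 0.25, the customary J48
#'   default.
#' @param seed integer or `NULL`; recorded with the model. Induction itself
#'   is deterministic, the seed only feeds downstream seeded operations.
#' @return an object of class `c45_control`.
#' @export
c45_control <- function(purity_threshold = 1, min_instances = 2L,
                        prune = TRUE, confidence = 0.25, seed = NULL) {
  stopifnot(is.numeric(purity_threshold), length(purity_threshold) == 1L,
            purity_threshold > 0, purity_threshold <= 1)
  stopifnot(is.numeric(min_instances), length(min_instances) == 1L,
            min_instances >= 1)
  stopifnot(is.logical(prune), length(prune) == 1L)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1) {
    stop("`confidence` must lie strictly between 0 and 1")
  }
  structure(list(purity_threshold = purity_threshold,
                 min_instances = as.integer(min_instances),
                 prune = prune, confidence = confidence,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "c45_control")
}

#' Entropy of a class distribution
#'
#' Shannon entropy in bits, `H = -sum(p_i log2 p_i)` over classes with
#' positive count; it measures the impurity of a tree node and bounds the
#' information gain achievable there. `0 <= H <= log2(#classes)`.
#'
#' @param counts non-negative per-class counts with positive sum.
#' @return entropy in bits.
#' @export
class_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be non-negative and non-missing")
  }
  n <- sum(counts)
  if (n <= 0) stop("`counts` must have a positive sum")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Score one attribute as a split candidate
#'
#' Information gain is the drop in class entropy from partitioning the
#' node's instances by the attribute's observed values; split information is
#' the entropy of the partition sizes; the gain ratio is their quotient,
#' defined as 0 when split information is 0 (an attribute constant on the
#' node). Missing attribute values count as the distinct category
#' `"unknown"`.
#'
#' @param table a [case_table()].
#' @param attribute an attribute name.
#' @param subset optional integer indices restricting to a node's instances.
#' @return a list with `attribute`, `information_gain`, `split_information`,
#'   `gain_ratio` (all in bits / dimensionless).
#' @export
split_scores <- function(table, attribute, subset = NULL) {
  stopifnot(attribute %in% attribute_names(table))
  cls <- as.integer(table$data[[table$class_attribute]])
  av <- train_values(table$data[[attribute]])
  if (!is.null(subset)) { cls <- cls[subset]; av <- av[subset] }
  if (length(cls) == 0L) stop("node has no instances")
  score_split(av, cls, nlevels(table$data[[table$class_attribute]]))
}

# attribute column as character with NA folded into an explicit category
train_values <- function(col) {
  v <- as.character(col)
  v[is.na(v)] <- "unknown"
  v
}

score_split <- function(av, cls, n_classes) {
  n <- length(cls)
  h_node <- class_entropy(tabulate(cls, n_classes))
  groups <- split(cls, av)
  sizes <- lengths(groups)
  if (length(groups) < 2L) {
    return(list(information_gain = 0, split_information = 0, gain_ratio = 0))
  }
  h_cond <- sum(vapply(groups, function(g)
    class_entropy(tabulate(g, n_classes)), 0) * sizes) / n
  gain <- max(0, h_node - h_cond)
  si <- class_entropy(sizes)
  gr <- if (si > 0) gain / si else 0
  list(information_gain = gain, split_information = si, gain_ratio = gr)
}

#' Choose the splitting attribute at a node
#'
#' Among candidates with positive information gain, returns the one with the
#' largest gain ratio; ties go to the earlier-declared attribute. Returns
#' `NA` when no candidate has positive gain (the node cannot be usefully
#' split).
#'
#' @param table a [case_table()].
#' @param candidates attribute names not yet used on the path; defaults to
#'   all attributes.
#' @param subset optional node instance indices.
#' @return the chosen attribute name, or `NA_character_`.
#' @export
select_split <- function(table, candidates = attribute_names(table),
                         subset = NULL) {
  # preserve declaration order regardless of how candidates were passed
  candidates <- intersect(attribute_names(table), candidates)
  best <- NA_character_
  best_gr <- -Inf
  tol <- 1e-12
  for (a in candidates) {
    s <- split_scores(table, a, subset)
    if (s$information_gain > tol && s$gain_ratio > best_gr + tol) {
      best <- a
      best_gr <- s$gain_ratio
    }
  }
  best
}

#' Fit a C4.5-style decision tree
#'
#' Recursive divide-and-conquer induction over a categorical case table:
#' at each node the attribute with the best gain ratio (among those with
#' positive information gain and not yet used on the path) is chosen, and
#' one branch is grown per value observed at the node. A node becomes a leaf
#' when its purity reaches `purity_threshold`, when it holds fewer than
#' `min_instances` cases, or when no attribute has positive gain; the leaf
#' predicts the majority diagnosis (ties broken by class declaration
#' order). With pruning enabled, pessimistic-error pruning
#' ([prune_tree()]) is applied before the model is returned.
#'
#' @param x a formula (`diagnosis ~ .`) or a [case_table()].
#' @param ... passed between methods.
#' @param data with the formula interface, a data.frame of categorical
#'   columns.
#' @param control a [c45_control()].
#' @return an object of class `c45`: fields `root` (the nested node
#'   structure), `schema` (attribute domains and class levels), `params`,
#'   `training_size`. Methods: `print`, `summary`, `predict`, `plot`.
#' @examples
#' cases <- data.frame(
#'   immunohistochemistry = c("positive for fibronectin", "negative",
#'                            "negative", "positive for fibronectin"),
#'   mesangial_expansion  = c("present", "present", "absent", "absent"),
#'   diagnosis = c("fibronectin glomerulopathy", "iga nephropathy",
#'                 "minimal change disease", "fibronectin glomerulopathy")
#' )
#' fit <- c45(diagnosis ~ ., data = cases, control = c45_control(prune = FALSE))
#' print(fit)
#' predict(fit, cases)
#' @export
c45 <- function(x, ...) UseMethod("c45")

#' @rdname c45
#' @export
c45.formula <- function(x, data, control = c45_control(), ...) {
  stopifnot(is.data.frame(data))
  cls_var <- all.vars(x[[2L]])
  if (length(cls_var) != 1L) stop("the formula must have a single response")
  rhs <- labels(stats::terms(x, data = data))
  df <- data[, c(rhs, cls_var), drop = FALSE]
  tab <- case_table(df, class_attribute = cls_var)
  c45.case_table(tab, control = control, ...)
}

#' @rdname c45
#' @export
c45.case_table <- function(x, control = c45_control(), ...) {
  if (n_cases(x) < 1L) stop("cannot induce a tree from a table with no instances")
  atts <- attribute_names(x)
  if (length(atts) < 1L) stop("no non-class attributes to split on")
  k <- nlevels(x$data[[x$class_attribute]])
  cls <- as.integer(x$data[[x$class_attribute]])
  avals <- lapply(x$data[atts], train_values)
  doms <- lapply(x$data[atts], levels)
  class_lv <- class_levels(x)

  grow <- function(idx, avail) {
    counts <- tabulate(cls[idx], k)
    names(counts) <- class_lv
    maj <- class_lv[which_max_first(counts)]
    purity <- max(counts) / sum(counts)
    make_leaf <- function() list(type = "leaf", diagnosis = maj,
                                 support = counts, purity = purity)
    if (purity >= control$purity_threshold - 1e-12) return(make_leaf())
    if (length(idx) < control$min_instances) return(make_leaf())
    best <- NA_character_; best_gr <- -Inf
    for (a in avail) {
      s <- score_split(avals[[a]][idx], cls[idx], k)
      if (s$information_gain > 1e-12 && s$gain_ratio > best_gr + 1e-12) {
        best <- a; best_gr <- s$gain_ratio
      }
    }
    if (is.na(best)) return(make_leaf())
    # branches in the attribute's domain order ("unknown" last), observed only
    f <- factor(avals[[best]][idx],
                levels = unique(c(doms[[best]], "unknown")))
    parts <- split(idx, f, drop = TRUE)
    kids <- lapply(parts, grow, avail = setdiff(avail, best))
    list(type = "internal", attribute = best, branches = kids,
         majority = maj, support = counts, purity = purity)
  }

  root <- grow(seq_len(n_cases(x)), atts)
  schema <- list(
    attributes = setNames(lapply(x$data[atts], levels), atts),
    allows_missing = x$allows_missing[atts],
    class_attribute = x$class_attribute,
    class_levels = class_lv
  )
  model <- structure(
    list(root = root, schema = schema, params = control,
         training_size = n_cases(x)),
    class = "c45"
  )
  if (isTRUE(control$prune)) model <- prune_tree(model, control$confidence)
  model
}

is_leaf <- function(node) identical(node$type, "leaf")

#' Classify one case with a fitted tree
#'
#' Walks from the root, following the branch that matches the case's value
#' for each node's split attribute. A missing value, or a value for which
#' the node has no branch, stops the walk: the node's locally trained
#' majority diagnosis is returned with `fallback_used = TRUE`. The returned
#' path records every (attribute, branch) step taken, so a diagnosis reached
#' after one question has a path of length 1.
#'
#' @param model a fitted [c45()] model.
#' @param instance a named list or character vector assigning attribute
#'   values (`NA` for missing); names outside the model's schema are a
#'   schema error.
#' @return an object of class `c45_prediction`: `diagnosis`, `path` (a
#'   data.frame of `attribute`, `branch`), `leaf_support`, `fallback_used`.
#' @export
classify <- function(model, instance) {
  stopifnot(inherits(model, "c45"))
  inst <- as.list(instance)
  unknown <- setdiff(names(inst), names(model$schema$attributes))
  if (length(unknown)) {
    stop("schema error: unknown attribute(s): ", paste(unknown, collapse = ", "))
  }
  node <- model$root
  steps_a <- character(); steps_b <- character()
  fallback <- FALSE
  while (!is_leaf(node)) {
    v <- inst[[node$attribute]]
    v <- if (is.null(v) || length(v) != 1L || is.na(v)) NA_character_ else as.character(v)
    if (is.na(v) || !(v %in% names(node$branches))) {
      fallback <- TRUE
      break
    }
    steps_a <- c(steps_a, node$attribute)
    steps_b <- c(steps_b, v)
    node <- node$branches[[v]]
  }
  diagnosis <- if (is_leaf(node) && !fallback) node$diagnosis else node$majority %||% node$diagnosis
  structure(
    list(diagnosis = diagnosis,
         path = data.frame(attribute = steps_a, branch = steps_b),
         leaf_support = node$support,
         fallback_used = fallback),
    class = "c45_prediction"
  )
}

#' @export
print.c45_prediction <- function(x, ...) {
  cat("Diagnosis:", x$diagnosis,
      if (x$fallback_used) "(majority fallback)" else "", "\n")
  if (nrow(x$path)) {
    for (i in seq_len(nrow(x$path))) {
      cat("  ", x$path$attribute[i], " = ", x$path$branch[i], "\n", sep = "")
    }
  } else cat("  (no attribute consulted)\n")
  invisible(x)
}

#' Predict diagnoses for new cases
#'
#' @param object a fitted [c45()] model.
#' @param newdata a data.frame or [case_table()] of cases.
#' @param type `"class"` for a factor of diagnoses, `"prediction"` for a
#'   list of full [classify()] results with paths and fallback flags.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.c45 <- function(object, newdata, type = c("class", "prediction"), ...) {
  type <- match.arg(type)
  df <- if (inherits(newdata, "case_table")) newdata$data else newdata
  stopifnot(is.data.frame(df))
  keep <- intersect(names(df), names(object$schema$attributes))
  preds <- lapply(seq_len(nrow(df)), function(i) {
    classify(object, lapply(df[i, keep, drop = FALSE], as.character))
  })
  if (type == "prediction") return(preds)
  factor(vapply(preds, `[[`, "", "diagnosis"),
         levels = object$schema$class_levels)
}

n_nodes <- function(node) {
  if (is_leaf(node)) return(1L)
  1L + sum(vapply(node$branches, n_nodes, 0L))
}

n_leaves_node <- function(node) {
  if (is_leaf(node)) return(1L)
  sum(vapply(node$branches, n_leaves_node, 0L))
}

tree_depth <- function(node) {
  if (is_leaf(node)) return(0L)
  1L + max(vapply(node$branches, tree_depth, 0L))
}

#' Tree size accessors
#'
#' @param model a fitted [c45()] model.
#' @return `n_leaves()`: number of leaves; `tree_size()`: total node count.
#' @export
n_leaves <- function(model) n_leaves_node(model$root)

#' @rdname n_leaves
#' @export
tree_size <- function(model) n_nodes(model$root)

#' @export
print.c45 <- function(x, ...) {
  cat("C4.5-style decision tree\n")
  cat("  training instances:", x$training_size,
      " leaves:", n_leaves(x), " depth:", tree_depth(x$root), "\n\n")
  print_node <- function(node, prefix) {
    if (is_leaf(node)) return()
    for (b in names(node$branches)) {
      child <- node$branches[[b]]
      line <- paste0(prefix, node$attribute, " = ", b)
      if (is_leaf(child)) {
        n <- sum(child$support)
        e <- n - max(child$support)
        cat(line, ": ", child$diagnosis, " (", n,
            if (e > 0) paste0("/", e) else "", ")\n", sep = "")
      } else {
        cat(line, "\n", sep = "")
        print_node(child, paste0(prefix, "|   "))
      }
    }
  }
  if (is_leaf(x$root)) {
    cat(": ", x$root$diagnosis, " (", sum(x$root$support), ")\n", sep = "")
  } else print_node(x$root, "")
  invisible(x)
}

#' @export
summary.c45 <- function(object, ...) {
  paths <- enumerate_paths(object)
  res <- list(
    training_size = object$training_size,
    n_leaves = n_leaves(object),
    n_nodes = tree_size(object),
    depth = tree_depth(object$root),
    path_lengths = vapply(paths, function(p) nrow(p$steps), 0L),
    classes = object$schema$class_levels,
    params = object$params
  )
  class(res) <- "summary.c45"
  res
}

#' @export
print.summary.c45 <- function(x, ...) {
  cat("C4.5-style decision tree\n")
  cat("  training instances:", x$training_size, "\n")
  cat("  nodes:", x$n_nodes, " leaves:", x$n_leaves, " depth:", x$depth, "\n")
  cat("  path lengths: ",
      paste(range(x$path_lengths), collapse = "-"),
      " (median ", stats::median(x$path_lengths), ")\n", sep = "")
  cat("  diagnoses:", length(x$classes), "\n")
  cat("  purity threshold:", x$params$purity_threshold,
      " pruning:", x$params$prune,
      if (x$params$prune) paste0(" (confidence ", x$params$confidence, ")"),
      "\n")
  invisible(x)
}

#' Plot a fitted tree
#'
#' Draws the tree top-down with base graphics: internal nodes show the split
#' attribute, edges their branch labels, leaves the predicted diagnosis.
#' Intended for the small trees this domain produces; large trees are better
#' inspected with `print()`.
#'
#' @param x a fitted [c45()] model.
#' @param cex character expansion for node labels.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.c45 <- function(x, cex = 0.8, ...) {
  leaves_x <- 0
  layout <- function(node, depth) {
    if (is_leaf(node)) {
      leaves_x <<- leaves_x + 1
      return(list(x = leaves_x, y = -depth, node = node, kids = list()))
    }
    kids <- lapply(node$branches, layout, depth = depth + 1)
    list(x = mean(vapply(kids, `[[`, 0, "x")), y = -depth, node = node,
         kids = kids)
  }
  tr <- layout(x$root, 0)
  graphics::plot(NA, xlim = c(0.5, max(1, leaves_x) + 0.5),
                 ylim = c(-tree_depth(x$root) - 0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "", ...)
  draw <- function(nd) {
    node <- nd$node
    if (is_leaf(node)) {
      graphics::text(nd$x, nd$y, paste0(node$diagnosis, "\n(",
                                        sum(node$support), ")"),
                     cex = cex, font = 3)
      return()
    }
    graphics::text(nd$x, nd$y, node$attribute, cex = cex, font = 2)
    bl <- names(node$branches)
    for (i in seq_along(nd$kids)) {
      kid <- nd$kids[[i]]
      graphics::segments(nd$x, nd$y - 0.1, kid$x, kid$y + 0.12, col = "grey40")
      graphics::text((nd$x + kid$x) / 2, (nd$y + kid$y) / 2, bl[i],
                     cex = cex * 0.9, col = "grey25")
      draw(kid)
    }
  }
  draw(tr)
  invisible(x)
}
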