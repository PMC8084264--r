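#' Sample a ground-truth diagnostic tree
#'
#' Builds a random but fully specified decision tree to act as the label
#' function in recovery experiments, emulating the shape of a renal-biopsy
#' case collection: ~30 diagnoses separable by ~20 categorical attributes,
#' most of them binary present/absent findings and the rest multi-valued
#' (immunohistochemistry-like patterns). Growth starts from a single leaf
#' and repeatedly splits a random leaf on a random attribute unused on its
#' path (one branch per domain value) until at least `n_diagnoses` leaves
#' exist; each diagnosis is then assigned to at least one leaf and surplus
#' leaves get uniformly drawn diagnoses. Attributes never used by the tree
#' are irrelevant by construction and are reported so tests can verify that
#' induction ignores them.
#'
#' @param n_diagnoses number of distinct diagnoses (default 30).
#' @param n_attributes number of attributes (default 20); must be at least
#'   `ceiling(log2(n_diagnoses))` so a separating tree exists.
#' @param binary_fraction fraction of attributes that are binary
#'   present/absent (default 0.8); the rest have
#'   `multi_valued_domain_size` values.
#' @param multi_valued_domain_size domain size (>= 3) of the non-binary
#'   attributes.
#' @param max_path_depth maximum root-to-leaf depth (default 6).
#' @param seed integer seed; the same seed reproduces the same tree.
#' @return a `ground_truth` object: `model` (a [c45()]-classed tree usable
#'   with [classify()] and [enumerate_paths()]) and `unused_attributes`.
#' @export
sample_ground_truth <- function(n_diagnoses = 30L, n_attributes = 20L,
                                binary_fraction = 0.8,
                                multi_valued_domain_size = 3L,
                                max_path_depth = 6L, seed = NULL) {
  n_diagnoses <- as.integer(n_diagnoses)
  n_attributes <- as.integer(n_attributes)
  stopifnot(n_diagnoses >= 1L, n_attributes >= 1L,
            binary_fraction >= 0, binary_fraction <= 1,
            multi_valued_domain_size >= 3L, max_path_depth >= 1L)
  if (n_attributes < ceiling(log2(max(2L, n_diagnoses)))) {
    stop("n_attributes too small to separate ", n_diagnoses, " diagnoses")
  }
  n_bin <- round(binary_fraction * n_attributes)
  att_names <- sprintf("attr_%02d", seq_len(n_attributes))
  domains <- c(
    replicate(n_bin, c("absent", "present"), simplify = FALSE),
    replicate(n_attributes - n_bin,
              paste0("pattern_", letters[seq_len(multi_valued_domain_size)]),
              simplify = FALSE)
  )
  names(domains) <- att_names
  classes <- sprintf("dx_%02d", seq_len(n_diagnoses))

  with_seed(seed, {
    # grow: leaves are paths (named value lists); split until enough leaves
    leaves <- list(list(path = character(0)))  # named chr vector attr->value
    repeat {
      if (length(leaves) >= n_diagnoses) break
      can <- which(vapply(leaves, function(l) {
        length(l$path) < max_path_depth &&
          length(setdiff(att_names, names(l$path))) > 0L
      }, TRUE))
      if (length(can) == 0L) {
        stop("cannot realize ", n_diagnoses, " leaves within max_path_depth ",
             max_path_depth)
      }
      i <- can[sample.int(length(can), 1L)]
      leaf <- leaves[[i]]
      unused <- setdiff(att_names, names(leaf$path))
      a <- unused[sample.int(length(unused), 1L)]
      kids <- lapply(domains[[a]], function(v) {
        p <- c(leaf$path, setNames(v, a))
        list(path = p)
      })
      leaves <- c(leaves[-i], kids)
    }
    n_leaf <- length(leaves)
    diag_assign <- character(n_leaf)
    firsts <- sample.int(n_leaf, n_diagnoses)
    diag_assign[firsts] <- sample(classes)
    rest <- setdiff(seq_len(n_leaf), firsts)
    if (length(rest)) {
      diag_assign[rest] <- classes[sample.int(n_diagnoses, length(rest),
                                              replace = TRUE)]
    }

    paths <- lapply(seq_len(n_leaf), function(i)
      list(path = leaves[[i]]$path, diagnosis = diag_assign[i]))
    root <- paths_to_node(paths, classes, domains)
    schema <- list(attributes = domains,
                   allows_missing = setNames(rep(TRUE, n_attributes), att_names),
                   class_attribute = "diagnosis",
                   class_levels = classes)
    model <- structure(
      list(root = root, schema = schema, params = c45_control(prune = FALSE),
           training_size = 0L),
      class = "c45")
    used <- unique(unlist(lapply(paths, function(p) names(p$path))))
    structure(list(model = model,
                   unused_attributes = setdiff(att_names, used),
                   seed = seed),
              class = "ground_truth")
  })
}

# Rebuild a nested tree from leaf paths. By construction every path at a
# node continues with the same attribute (each node was split exactly once).
paths_to_node <- function(paths, classes, domains) {
  if (all(vapply(paths, function(p) length(p$path) == 0L, TRUE))) {
    stopifnot(length(paths) == 1L)
    support <- setNames(integer(length(classes)), classes)
    support[paths[[1]]$diagnosis] <- 1L
    return(list(type = "leaf", diagnosis = paths[[1]]$diagnosis,
                support = support, purity = 1))
  }
  a <- names(paths[[1]]$path)[1L]
  by_val <- split(paths, vapply(paths, function(p) unname(p$path[1L]), ""))
  by_val <- by_val[domains[[a]][domains[[a]] %in% names(by_val)]]
  kids <- lapply(by_val, function(grp) {
    grp <- lapply(grp, function(p)
      list(path = p$path[-1L], diagnosis = p$diagnosis))
    paths_to_node(grp, classes, domains)
  })
  support <- Reduce(`+`, lapply(kids, `[[`, "support"))
  list(type = "internal", attribute = a, branches = kids,
       majority = classes[which_max_first(support)],
       support = support, purity = max(support) / sum(support))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth tree: ", n_leaves(x$model), " leaves, ",
      length(x$model$schema$class_levels), " diagnoses, ",
      length(x$model$schema$attributes), " attributes (",
      length(x$unused_attributes), " irrelevant)\n", sep = "")
  invisible(x)
}

#' Generate synthetic case tables from a ground-truth tree
#'
#' Each instance draws a leaf uniformly at random, sets the attributes on
#' the leaf's path to the path's branch values, fills every off-path or
#' irrelevant attribute uniformly from its domain (those carry no class
#' information), and labels the instance with the leaf's diagnosis. Noise
#' is then applied cell-wise: with probability `label_flip_rate` the
#' diagnosis is replaced by a different, uniformly chosen one; with
#' probability `attribute_corruption_rate` an attribute cell is resampled
#' uniformly from its domain; with probability `missing_rate` an attribute
#' cell is blanked. With all rates zero every generated instance is
#' classified by the ground-truth tree to its own label.
#'
#' @param gt a `ground_truth` from [sample_ground_truth()].
#' @param n_instances number of cases to generate.
#' @param label_flip_rate,attribute_corruption_rate,missing_rate noise
#'   rates in `[0, 1)`; defaults 0.
#' @param seed integer seed.
#' @return a [case_table()] whose provenance records the seed and rates.
#' @export
generate_cases <- function(gt, n_instances,
                           label_flip_rate = 0,
                           attribute_corruption_rate = 0,
                           missing_rate = 0, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), n_instances >= 1L)
  rates <- c(label_flip_rate, attribute_corruption_rate, missing_rate)
  stopifnot(all(rates >= 0), all(rates < 1))
  model <- gt$model
  domains <- model$schema$attributes
  att_names <- names(domains)
  classes <- model$schema$class_levels
  paths <- enumerate_paths(model)
  n <- as.integer(n_instances)

  with_seed(seed, {
    cells <- lapply(att_names, function(a) {
      dom <- domains[[a]]
      dom[sample.int(length(dom), n, replace = TRUE)]
    })
    names(cells) <- att_names
    labels <- character(n)
    leaf_pick <- sample.int(length(paths), n, replace = TRUE)
    for (i in seq_len(n)) {
      p <- paths[[leaf_pick[i]]]
      if (nrow(p$steps)) {
        for (s in seq_len(nrow(p$steps))) {
          cells[[p$steps$attribute[s]]][i] <- p$steps$branch[s]
        }
      }
      labels[i] <- p$diagnosis
    }
    if (label_flip_rate > 0) {
      flip <- stats::runif(n) < label_flip_rate
      for (i in which(flip)) {
        others <- setdiff(classes, labels[i])
        labels[i] <- others[sample.int(length(others), 1L)]
      }
    }
    if (attribute_corruption_rate > 0) {
      for (a in att_names) {
        hit <- stats::runif(n) < attribute_corruption_rate
        if (any(hit)) {
          dom <- domains[[a]]
          cells[[a]][hit] <- dom[sample.int(length(dom), sum(hit),
                                            replace = TRUE)]
        }
      }
    }
    if (missing_rate > 0) {
      for (a in att_names) {
        hit <- stats::runif(n) < missing_rate
        cells[[a]][hit] <- NA_character_
      }
    }
    df <- as.data.frame(cells, check.names = FALSE, stringsAsFactors = FALSE)
    df$diagnosis <- labels
    case_table(df, class_attribute = "diagnosis",
               domains = c(domains, list(diagnosis = classes)),
               provenance = sprintf(
                 "synthetic: seed=%s flip=%g corrupt=%g missing=%g",
                 seed %||% "NULL", label_flip_rate,
                 attribute_corruption_rate, missing_rate))
  })
}

#' Agreement between a ground truth and an induced tree
#'
#' Generates `probe_n` fresh noise-free cases from the ground truth and
#' reports the fraction on which the induced model's prediction agrees with
#' the ground truth's. Both models must share the same schema (attribute
#' domains and class levels).
#'
#' @param gt a `ground_truth`.
#' @param induced a fitted [c45()] model trained on cases from `gt`.
#' @param probe_n number of probe cases (default 200).
#' @param seed integer seed for the probes.
#' @return the agreement fraction in `[0, 1]`.
#' @export
recovery_check <- function(gt, induced, probe_n = 200L, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(induced, "c45"))
  if (!identical(gt$model$schema$attributes, induced$schema$attributes) ||
      !identical(gt$model$schema$class_levels, induced$schema$class_levels)) {
    stop("schema mismatch between ground truth and induced model")
  }
  probes <- generate_cases(gt, probe_n, seed = seed)
  truth <- as.character(predict(gt$model, probes))
  pred <- as.character(predict(induced, probes))
  mean(truth == pred)
}
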