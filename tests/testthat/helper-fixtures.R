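# Shared fixtures and independent oracles for the test suite.

# A small renal-biopsy-flavoured table in which the immunohistochemistry
# finding "positive for fibronectin" alone identifies one diagnosis, while
# the remaining cases need a second (histology) attribute.
fig_fibronectin_table <- function() {
  df <- data.frame(
    immunohistochemistry = c(rep("positive for fibronectin", 3L),
                             rep("negative", 6L)),
    mesangial_hypercellularity = c("present", "absent", "present",
                                   rep("present", 3L), rep("absent", 3L)),
    diagnosis = c(rep("fibronectin glomerulopathy", 3L),
                  rep("iga nephropathy", 3L),
                  rep("minimal change disease", 3L)),
    stringsAsFactors = FALSE
  )
  case_table(df, class_attribute = "diagnosis")
}

# Perfectly separable multi-class table: `marker` alone determines the
# diagnosis; the other attributes are uninformative.
separable_table <- function(n_per_class = 10L, n_classes = 5L, seed = 1L) {
  classes <- paste0("class_", seq_len(n_classes))
  marker <- rep(paste0("m", seq_len(n_classes)), each = n_per_class)
  withr::with_seed(seed, {
    df <- data.frame(
      marker = marker,
      noise_a = sample(c("absent", "present"), n_per_class * n_classes,
                       replace = TRUE),
      noise_b = sample(c("low", "mid", "high"), n_per_class * n_classes,
                       replace = TRUE),
      diagnosis = rep(classes, each = n_per_class),
      stringsAsFactors = FALSE
    )
  })
  case_table(df, class_attribute = "diagnosis")
}

# Random tiny table for the oracle-equivalence property.
random_tiny_table <- function(seed) {
  withr::with_seed(seed, {
    n_attr <- sample(2:4, 1L)
    n <- sample(4:12, 1L)
    n_cls <- sample(2:3, 1L)
    cols <- lapply(seq_len(n_attr), function(j) {
      dom <- paste0("v", seq_len(sample(2:3, 1L)))
      factor(sample(dom, n, replace = TRUE), levels = dom)
    })
    names(cols) <- paste0("a", seq_len(n_attr))
    cols$dx <- factor(sample(paste0("c", seq_len(n_cls)), n, replace = TRUE),
                      levels = paste0("c", seq_len(n_cls)))
    case_table(as.data.frame(cols), class_attribute = "dx")
  })
}

# --- Independent brute-force split-selection oracle -------------------------
# Deliberately written against the raw data.frame with plain loops and
# table(), sharing no code with the package's implementation.

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_scores <- function(df, class_col, attr) {
  v <- as.character(df[[attr]])
  v[is.na(v)] <- "unknown"
  y <- as.character(df[[class_col]])
  n <- length(y)
  h <- oracle_entropy(as.vector(table(y)) / n)
  vals <- unique(v)
  if (length(vals) < 2L) {
    return(list(information_gain = 0, split_information = 0, gain_ratio = 0))
  }
  cond <- 0
  wts <- numeric(0)
  for (val in vals) {
    sel <- v == val
    w <- sum(sel) / n
    cond <- cond + w * oracle_entropy(as.vector(table(y[sel])) / sum(sel))
    wts <- c(wts, w)
  }
  gain <- max(0, h - cond)
  si <- oracle_entropy(wts)
  list(information_gain = gain, split_information = si,
       gain_ratio = if (si > 0) gain / si else 0)
}

oracle_select <- function(df, class_col, candidates) {
  best <- NA_character_
  best_gr <- -Inf
  for (a in candidates) {
    s <- oracle_scores(df, class_col, a)
    if (s$information_gain > 1e-12 && s$gain_ratio > best_gr + 1e-12) {
      best <- a
      best_gr <- s$gain_ratio
    }
  }
  best
}

# --- Tree-walk assertions ---------------------------------------------------

walk_paths_ok <- function(node, used = character()) {
  if (identical(node$type, "leaf")) return(TRUE)
  if (node$attribute %in% used) return(FALSE)
  all(vapply(node$branches, walk_paths_ok, TRUE,
             used = c(used, node$attribute)))
}

count_nodes <- function(node) {
  if (identical(node$type, "leaf")) return(1L)
  1L + sum(vapply(node$branches, count_nodes, 0L))
}

resub_accuracy <- function(model, table) {
  mean(as.character(predict(model, table)) ==
         as.character(table$data[[table$class_attribute]]))
}

# Hand-build a c45 model from an explicit node structure (for pruning and
# path tests that need exact support counts).
hand_model <- function(root, attributes, class_levels,
                       class_attribute = "dx") {
  structure(
    list(root = root,
         schema = list(attributes = attributes,
                       allows_missing = setNames(
                         rep(TRUE, length(attributes)), names(attributes)),
                       class_attribute = class_attribute,
                       class_levels = class_levels),
         params = c45_control(prune = FALSE),
         training_size = sum(root$support)),
    class = "c45")
}

leaf_node <- function(support, class_levels) {
  s <- setNames(integer(length(class_levels)), class_levels)
  s[names(support)] <- as.integer(support)
  list(type = "leaf", diagnosis = class_levels[which.max(s)],
       support = s, purity = max(s) / sum(s))
}

internal_node <- function(attribute, branches, class_levels) {
  s <- Reduce(`+`, lapply(branches, `[[`, "support"))
  list(type = "internal", attribute = attribute, branches = branches,
       majority = class_levels[which.max(s)], support = s,
       purity = max(s) / sum(s))
}
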