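#' Pessimistic-error pruning
#'
#' Bottom-up subtree replacement in the C4.5 style: the training error at
#' each node is inflated to the upper limit of a binomial confidence
#' interval, and a subtree is collapsed to a leaf (predicting the node's
#' majority diagnosis) whenever that pessimistic leaf error does not exceed
#' the summed pessimistic errors of its children. The upper limit is the
#' exact binomial (Clopper-Pearson) bound: the error probability `p` at
#' which observing at most `e` errors in `n` cases has probability
#' `confidence`; for `e = 0` this is `1 - confidence^(1/n)`.
#'
#' Pruning never increases the node count, and can only lower (never raise)
#' resubstitution accuracy.
#'
#' @param model a fitted [c45()] model carrying support counts at every
#'   node.
#' @param confidence fraction strictly between 0 and 1; smaller values prune
#'   more aggressively. Default: the confidence recorded in the model's
#'   params (0.25 unless changed).
#' @return the pruned `c45` model.
#' @export
prune_tree <- function(model, confidence = model$params$confidence) {
  stopifnot(inherits(model, "c45"))
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      is.na(confidence) || confidence <= 0 || confidence >= 1) {
    stop("`confidence` must lie strictly between 0 and 1")
  }
  model$root <- strip_pess(prune_node(model$root, confidence))
  model
}

strip_pess <- function(node) {
  attr(node, "pess") <- NULL
  if (!is_leaf(node)) node$branches <- lapply(node$branches, strip_pess)
  node
}

# Upper confidence limit on the error rate after observing e errors in n.
ucb_error_rate <- function(e, n, confidence) {
  if (n <= 0) return(0)
  if (e >= n) return(1)
  if (e < 0) e <- 0
  stats::qbeta(1 - confidence, e + 1, n - e)
}

# Returns the (possibly collapsed) node; attaches the pessimistic error
# estimate (in instance units) as attribute "pess" for the parent's sum.
prune_node <- function(node, confidence) {
  n <- sum(node$support)
  e <- n - max(node$support)
  leaf_est <- n * ucb_error_rate(e, n, confidence)
  if (is_leaf(node)) {
    attr(node, "pess") <- leaf_est
    return(node)
  }
  node$branches <- lapply(node$branches, prune_node, confidence = confidence)
  child_est <- sum(vapply(node$branches, function(k) attr(k, "pess"), 0))
  if (leaf_est <= child_est + 1e-9) {
    leaf <- list(type = "leaf", diagnosis = node$majority,
                 support = node$support,
                 purity = max(node$support) / n)
    attr(leaf, "pess") <- leaf_est
    return(leaf)
  }
  attr(node, "pess") <- child_est
  node
}
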