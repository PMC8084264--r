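#' Serialize and restore tree models as JSON
#'
#' The JSON format is versioned and lossless: schema (attribute domains,
#' class levels), induction parameters, training size and the full node
#' structure with support counts round-trip exactly. Model files written by
#' the training step are the contract consumed by the quiz-building step.
#'
#' @param model a fitted [c45()] model.
#' @return `serialize_tree()`: a JSON string; `deserialize_tree()`: a `c45`
#'   model.
#' @export
serialize_tree <- function(model) {
  stopifnot(inherits(model, "c45"))
  payload <- list(
    format = "nephroquiz-c45",
    version = 1L,
    schema = list(
      attributes = model$schema$attributes,
      allows_missing = as.list(model$schema$allows_missing),
      class_attribute = model$schema$class_attribute,
      class_levels = model$schema$class_levels
    ),
    params = unclass(model$params),
    training_size = model$training_size,
    root = node_to_list(model$root)
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

node_to_list <- function(node) {
  if (is_leaf(node)) {
    list(type = "leaf", diagnosis = node$diagnosis,
         support = as.list(node$support), purity = node$purity)
  } else {
    list(type = "internal", attribute = node$attribute,
         majority = node$majority, support = as.list(node$support),
         purity = node$purity,
         branches = lapply(node$branches, node_to_list))
  }
}

#' @rdname serialize_tree
#' @param json a JSON string produced by `serialize_tree()`.
#' @export
deserialize_tree <- function(json) {
  payload <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = FALSE),
    error = function(e) stop("parse error: invalid tree JSON: ",
                             conditionMessage(e))
  )
  if (!identical(payload$format, "nephroquiz-c45")) {
    stop("parse error: not a serialized tree model")
  }
  if (!identical(as.integer(payload$version), 1L)) {
    stop("parse error: unsupported tree format version: ", payload$version)
  }
  p <- payload$params
  control <- c45_control(purity_threshold = p$purity_threshold,
                         min_instances = p$min_instances,
                         prune = p$prune, confidence = p$confidence,
                         seed = p$seed)
  schema <- list(
    attributes = lapply(payload$schema$attributes,
                        function(d) as.character(unlist(d))),
    allows_missing = vapply(payload$schema$allows_missing, isTRUE, TRUE),
    class_attribute = payload$schema$class_attribute,
    class_levels = as.character(unlist(payload$schema$class_levels))
  )
  structure(
    list(root = list_to_node(payload$root, schema$class_levels),
         schema = schema, params = control,
         training_size = as.integer(payload$training_size)),
    class = "c45"
  )
}

list_to_node <- function(x, class_levels) {
  support <- setNames(as.integer(unlist(x$support)), names(x$support))
  # restore full class order (JSON objects keep keys, but be defensive)
  support <- support[class_levels]
  support[is.na(support)] <- 0L
  names(support) <- class_levels
  # purity is derived from support; recompute it rather than trust the
  # JSON text, so the round trip is bit-exact
  purity <- max(support) / sum(support)
  if (identical(x$type, "leaf")) {
    list(type = "leaf", diagnosis = x$diagnosis, support = support,
         purity = purity)
  } else if (identical(x$type, "internal")) {
    list(type = "internal", attribute = x$attribute,
         branches = lapply(x$branches, list_to_node,
                           class_levels = class_levels),
         majority = x$majority, support = support,
         purity = purity)
  } else stop("parse error: node with unknown type")
}

#' Read or write a tree model file
#'
#' Thin file wrappers around [serialize_tree()] / [deserialize_tree()].
#'
#' @param model a fitted [c45()] model.
#' @param path file path.
#' @export
write_tree <- function(model, path) {
  writeLines(serialize_tree(model), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  deserialize_tree(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
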