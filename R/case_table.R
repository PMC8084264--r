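#' Categorical case tables
#'
#' A `case_table` holds one biopsy report (or any categorical case) per row
#' and one clinicopathological attribute per column, with one distinguished
#' column carrying the diagnosis (the class label). Every column is nominal:
#' each attribute has an ordered domain of category labels, and cells hold a
#' domain label or are missing (`NA`). The diagnosis column is never missing.
#'
#' Internally columns are stored as factors whose levels are the attribute
#' domains, so declaration order of both attributes and domain labels is
#' preserved; that order is observable and used for tie-breaking during tree
#' induction.
#'
#' @param data a data.frame of character or factor columns. Factor columns
#'   keep their level sets as declared domains; character columns get the
#'   sorted set of observed labels as their domain.
#' @param class_attribute name of the diagnosis column. Default: the last
#'   column.
#' @param domains optional named list of character vectors overriding the
#'   domain (in order) of specific columns.
#' @param allows_missing named logical vector; whether each attribute may be
#'   missing. Defaults to `TRUE` for every attribute and `FALSE` for the
#'   class attribute (which can never be missing).
#' @param provenance free-text metadata recorded with the table.
#'
#' @return an object of class `case_table`.
#' @seealso [read_case_table()], [clean_table()], [validate_table()], [c45()]
#' @export
case_table <- function(data, class_attribute = NULL, domains = NULL,
                       allows_missing = NULL, provenance = "") {
  if (!is.data.frame(data)) stop("`data` must be a data.frame")
  nm <- names(data)
  if (anyDuplicated(nm)) {
    stop("schema error: duplicate column names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (ncol(data) < 2L) stop("a case table needs at least one attribute and a class column")
  class_attribute <- class_attribute %||% nm[length(nm)]
  if (!class_attribute %in% nm) {
    stop("schema error: class attribute '", class_attribute, "' not among columns")
  }
  cols <- lapply(nm, function(j) {
    x <- data[[j]]
    if (is.factor(x)) lv <- levels(x)
    else {
      x <- as.character(x)
      lv <- sort(unique(x[!is.na(x)]))
    }
    if (!is.null(domains[[j]])) lv <- as.character(domains[[j]])
    # domains colliding after normalization are allowed at construction (raw
    # spreadsheets do that); validate_table() reports them, clean_table() fixes
    bad <-!is.na(as.character(x)) & !(as.character(x) %in% lv)
    if (any(bad)) {
      stop("domain-violation error: column '", j, "' row ", which(bad)[1L],
           " has value '", as.character(x)[which(bad)[1L]], "' outside its domain")
    }
    factor(as.character(x), levels = lv)
  })
  names(cols) <- nm
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) df <- df[0L, , drop = FALSE]
  am <- setNames(rep(TRUE, length(nm)), nm)
  am[class_attribute] <- FALSE
  if (!is.null(allows_missing)) am[names(allows_missing)] <- allows_missing
  am[class_attribute] <- FALSE
  if (anyNA(df[[class_attribute]]) ) {
    stop("class attribute '", class_attribute, "' contains missing values")
  }
  structure(
    list(data = df, class_attribute = class_attribute,
         allows_missing = am, provenance = as.character(provenance)),
    class = "case_table"
  )
}

#' @export
print.case_table <- function(x, ...) {
  cat("Case table: ", n_cases(x), " instances, ",
      length(attribute_names(x)), " attributes + class '",
      x$class_attribute, "' (", nlevels(x$data[[x$class_attribute]]),
      " diagnoses)\n", sep = "")
  if (nzchar(x$provenance)) cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' Accessors for case tables
#'
#' `n_cases()` counts instances; `attribute_names()` lists the non-class
#' attributes in declaration order; `class_levels()` gives the diagnosis
#' domain; `case_attributes()` tabulates every attribute with its domain and
#' missing policy.
#'
#' @param table a [case_table()].
#' @return see each description.
#' @export
n_cases <- function(table) nrow(table$data)

#' @rdname n_cases
#' @export
attribute_names <- function(table) {
  setdiff(names(table$data), table$class_attribute)
}

#' @rdname n_cases
#' @export
class_levels <- function(table) levels(table$data[[table$class_attribute]])

#' @rdname n_cases
#' @export
case_attributes <- function(table) {
  nm <- names(table$data)
  data.frame(
    name = nm,
    n_levels = vapply(table$data, nlevels, 0L),
    domain = vapply(table$data, function(c) paste(levels(c), collapse = "|"), ""),
    allows_missing = unname(table$allows_missing[nm]),
    is_class = nm == table$class_attribute,
    row.names = NULL
  )
}

#' Validate a case table against its invariants
#'
#' Checks that every assigned value belongs to its attribute's domain, that
#' missing values occur only where allowed, and that the class column is
#' never missing. Factor storage makes out-of-domain values impossible after
#' construction, but tables deserialized or manipulated by hand can still
#' violate the missing-value rules.
#'
#' @param table a [case_table()].
#' @return a data.frame of violations with columns `row`, `column`, `rule`,
#'   `message`; zero rows when the table is valid.
#' @export
validate_table <- function(table) {
  out <- list()
  add <- function(row, column, rule, message) {
    out[[length(out) + 1L]] <<- data.frame(row = row, column = column,
                                           rule = rule, message = message)
  }
  for (j in names(table$data)) {
    x <- table$data[[j]]
    miss <- which(is.na(x))
    if (j == table$class_attribute) {
      for (i in miss) add(i, j, "class-not-missing",
                          "class attribute value is MISSING")
    } else if (!isTRUE(table$allows_missing[[j]])) {
      for (i in miss) add(i, j, "missing-not-allowed",
                          paste0("attribute '", j, "' does not allow MISSING"))
    }
    if (anyDuplicated(norm_label(levels(x)))) {
      add(NA_integer_, j, "domain-distinct",
          "domain labels collide after normalization")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(row = integer(), column = character(),
                      rule = character(), message = character()))
  }
  do.call(rbind, out)
}

#' Clean a case table
#'
#' Automates the safe part of spreadsheet cleanup: category labels are
#' trimmed, internal whitespace collapsed, and case-folded; an optional
#' synonym map rewrites raw labels to canonical ones (applied after
#' normalization, with normalized keys); exact duplicate rows (identical on
#' every attribute including the diagnosis) are dropped, keeping the first
#' occurrence. Domains are rebuilt from the cleaned values. Anything beyond
#' that -- true spelling correction -- must be expressed through
#' `synonym_map`.
#'
#' @param table a [case_table()].
#' @param synonym_map optional named character vector mapping raw labels to
#'   canonical labels, e.g. `c("trichrome +" = "positive")`.
#' @return a list with elements `table` (the cleaned [case_table()]) and
#'   `report` (a `cleaning_report`: `duplicates_removed`,
#'   `values_normalized`, `synonym_merges` with per-pair cell counts).
#' @export
clean_table <- function(table, synonym_map = NULL) {
  df <- table$data
  nm <- names(df)
  syn_keys <- if (is.null(synonym_map)) character() else norm_label(names(synonym_map))
  syn_vals <- if (is.null(synonym_map)) character() else unname(as.character(synonym_map))
  values_normalized <- 0L
  merge_counts <- setNames(integer(length(syn_keys)), syn_keys)

  cleaned <- lapply(nm, function(j) {
    raw <- as.character(df[[j]])
    val <- norm_label(raw)
    values_normalized <<- values_normalized +
      sum(!is.na(raw) & raw != val)
    hit <- !is.na(val) & val %in% syn_keys
    if (any(hit)) {
      idx <- match(val[hit], syn_keys)
      for (k in unique(idx)) {
        merge_counts[k] <<- merge_counts[k] + sum(idx == k)
      }
      val[hit] <- norm_label(syn_vals[idx])
    }
    val
  })
  names(cleaned) <- nm
  cdf <- as.data.frame(cleaned, check.names = FALSE, stringsAsFactors = FALSE)

  # warn on synonym targets that end up absent from every domain
  if (length(syn_keys)) {
    present <- unique(unlist(lapply(cdf, function(x) unique(x[!is.na(x)]))))
    dead <- norm_label(syn_vals)[!(norm_label(syn_vals) %in% present) &
                                   merge_counts == 0L]
    if (length(dead)) {
      warning("synonym_map target(s) absent from any domain: ",
              paste(unique(dead), collapse = ", "))
    }
  }

  dup <- duplicated(cdf)
  duplicates_removed <- sum(dup)
  cdf <- cdf[!dup, , drop = FALSE]
  rownames(cdf) <- NULL

  merges <- data.frame(raw = syn_keys,
                       canonical = norm_label(syn_vals),
                       cells_changed = unname(merge_counts))
  merges <- merges[merges$cells_changed > 0L, , drop = FALSE]
  rownames(merges) <- NULL

  out <- case_table(cdf, class_attribute = table$class_attribute,
                    allows_missing = table$allows_missing,
                    provenance = table$provenance)
  report <- structure(
    list(duplicates_removed = duplicates_removed,
         values_normalized = values_normalized,
         synonym_merges = merges),
    class = "cleaning_report"
  )
  list(table = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  cat("  duplicate rows removed:", x$duplicates_removed, "\n")
  cat("  cell values normalized:", x$values_normalized, "\n")
  if (nrow(x$synonym_merges)) {
    cat("  synonym merges:\n")
    for (i in seq_len(nrow(x$synonym_merges))) {
      cat("    '", x$synonym_merges$raw[i], "' -> '",
          x$synonym_merges$canonical[i], "' (",
          x$synonym_merges$cells_changed[i], " cells)\n", sep = "")
    }
  } else cat("  synonym merges: none\n")
  invisible(x)
}

#' Export a cleaning report as JSON
#'
#' @param report a `cleaning_report` from [clean_table()].
#' @return a JSON string.
#' @export
cleaning_report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
}
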