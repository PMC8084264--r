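#' Read a case table from CSV or ARFF
#'
#' CSV: RFC 4180, UTF-8, first row a header; the class column defaults to
#' the last column and can be overridden by name; attribute domains are the
#' sorted set of observed labels. ARFF: Weka format restricted to nominal
#' attributes; declared domains are kept in declaration order; the last
#' declared attribute is the class. Missing values are an empty cell or
#' `?` on input.
#'
#' @param source a file path or connection.
#' @param format `"csv"` or `"arff"`.
#' @param class_attribute class column name (CSV only; ARFF always uses the
#'   last declared attribute).
#' @return a [case_table()].
#' @export
read_case_table <- function(source, format = c("csv", "arff"),
                            class_attribute = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(source, colClasses = "character", check.names = FALSE,
                      na.strings = c("", "?"), fileEncoding = "UTF-8"),
      error = function(e) stop("parse error reading CSV: ", conditionMessage(e))
    )
    case_table(df, class_attribute = class_attribute)
  } else {
    parsed <- parse_arff(source)
    case_table(parsed$data, class_attribute = names(parsed$data)[ncol(parsed$data)],
               domains = parsed$domains, provenance = parsed$relation)
  }
}

#' Write a case table to CSV or ARFF
#'
#' The round trip `read_case_table(write_case_table(T))` reproduces `T` up
#' to domain ordering; ARFF preserves domain order exactly and writes the
#' class attribute last. Missing values are written as an empty cell (CSV)
#' or `?` (ARFF).
#'
#' @param table a [case_table()].
#' @param file a file path or connection.
#' @param format `"csv"` or `"arff"`.
#' @return `file`, invisibly.
#' @export
write_case_table <- function(table, file, format = c("csv", "arff")) {
  format <- match.arg(format)
  df <- table$data
  if (format == "csv") {
    out <- as.data.frame(lapply(df, as.character), check.names = FALSE,
                         stringsAsFactors = FALSE)
    utils::write.csv(out, file, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    ord <- c(setdiff(names(df), table$class_attribute), table$class_attribute)
    rel <- if (nzchar(table$provenance)) table$provenance else "case_table"
    lines <- c(paste0("@relation ", arff_quote(rel)))
    for (j in ord) {
      lines <- c(lines, paste0(
        "@attribute ", arff_quote(j), " {",
        paste(vapply(levels(df[[j]]), arff_quote, ""), collapse = ","), "}"))
    }
    lines <- c(lines, "@data")
    if (nrow(df) > 0L) {
      cells <- vapply(ord, function(j) {
        v <- as.character(df[[j]])
        ifelse(is.na(v), "?", vapply(v, arff_quote, ""))
      }, character(nrow(df)))
      cells <- matrix(cells, nrow = nrow(df))
      lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
    }
    writeLines(lines, file, useBytes = TRUE)
  }
  invisible(file)
}

arff_quote <- function(x) {
  if (is.na(x)) return("?")
  if (grepl("[ ,{}'\"%\t?]", x) || !nzchar(x)) {
    paste0("'", gsub("'", "\\\\'", x), "'")
  } else x
}

# Minimal ARFF reader for nominal-only relations. Declared domains are kept
# verbatim and in order; data values outside a declared domain are an error
# naming the offending line.
parse_arff <- function(source) {
  lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  relation <- ""
  att_names <- character()
  domains <- list()
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- sub("%.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    low <- tolower(ln)
    if (startsWith(low, "@relation")) {
      relation <- arff_unquote(trimws(substring(ln, 10L)))
    } else if (startsWith(low, "@attribute")) {
      rest <- trimws(substring(ln, 11L))
      m <- regmatches(rest, regexec("^('(?:[^'\\\\]|\\\\.)*'|\"[^\"]*\"|[^ \t{]+)[ \t]*\\{(.*)\\}[ \t]*$", rest))[[1]]
      if (length(m) != 3L) {
        stop("parse error at line ", i,
             ": only nominal @attribute declarations are supported: ", ln)
      }
      att_names <- c(att_names, arff_unquote(m[2]))
      domains[[length(domains) + 1L]] <- vapply(split_arff_row(m[3]),
                                                arff_unquote, "")
    } else if (startsWith(low, "@data")) {
      data_start <- i + 1L
      break
    } else {
      stop("parse error at line ", i, ": unexpected content: ", ln)
    }
  }
  if (is.na(data_start)) stop("parse error: no @data section")
  if (length(att_names) < 2L) stop("parse error: fewer than 2 attributes declared")
  if (anyDuplicated(att_names)) {
    stop("schema error: duplicate attribute names: ",
         paste(unique(att_names[duplicated(att_names)]), collapse = ", "))
  }
  names(domains) <- att_names
  rows <- list()
  for (i in seq(data_start, length.out = max(0L, length(lines) - data_start + 1L))) {
    ln <- sub("%.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    vals <- vapply(split_arff_row(trimws(ln)), arff_unquote, "")
    if (length(vals) != length(att_names)) {
      stop("parse error at line ", i, ": expected ", length(att_names),
           " values, got ", length(vals))
    }
    vals[vals == "?"] <- NA_character_
    for (k in seq_along(vals)) {
      if (!is.na(vals[k]) && !(vals[k] %in% domains[[k]])) {
        stop("domain-violation error at line ", i, ": value '", vals[k],
             "' not in the declared domain of '", att_names[k], "'")
      }
    }
    rows[[length(rows) + 1L]] <- vals
  }
  df <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    as.data.frame(setNames(rep(list(character()), length(att_names)), att_names),
                  check.names = FALSE)
  }
  names(df) <- att_names
  list(relation = relation, domains = domains, data = df)
}

# Split a comma-separated ARFF row or domain body on commas outside single
# quotes; tokens keep their quotes for arff_unquote() to strip.
split_arff_row <- function(s) {
  out <- character()
  buf <- character()
  in_q <- FALSE
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_q && ch == "\\" && i < length(chars)) {
      buf <- c(buf, ch, chars[i + 1L]); i <- i + 2L; next
    }
    if (ch == "'") in_q <- !in_q
    if (ch == "," && !in_q) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character()
    } else buf <- c(buf, ch)
    i <- i + 1L
  }
  c(out, paste(buf, collapse = ""))
}

arff_unquote <- function(x) {
  x <- trimws(x)
  if (grepl("^'.*'$", x)) x <- gsub("\\\\'", "'", substring(x, 2L, nchar(x) - 1L))
  else if (grepl('^".*"$', x)) x <- substring(x, 2L, nchar(x) - 1L)
  x
}
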