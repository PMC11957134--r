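#' Parse a GATK-style hard-filter expression
#'
#' Parses an OR-combined filter expression such as
#' `"QD < 2.0 || FS > 60.0 || MQ < 40.0"` into an ordered clause table.
#' A record failing any clause is removed.  Printing the parsed object
#' with [format_hard_filters()] round-trips to the normalized string.
#'
#' @param expression filter string: clauses `metric op threshold` joined
#'   by `||`, with op one of `<`, `>`, `<=`, `>=`.  Unicode minus signs
#'   are normalized to ASCII.
#' @return object of class `hard_filter_expression`: data.frame with
#'   `metric`, `op`, `threshold`.
#' @export
parse_hard_filters <- function(expression) {
  expr <- gsub("−", "-", expression)
  clauses <- strsplit(expr, "\\|\\|")[[1]]
  clauses <- trimws(clauses)
  if (length(clauses) == 0 || any(clauses == ""))
    stop("empty clause in filter expression")
  pat <- "^([A-Za-z_][A-Za-z0-9_.]*)\\s*(<=|>=|<|>)\\s*(-?[0-9]+\\.?[0-9]*)$"
  out <- lapply(seq_along(clauses), function(i) {
    m <- regmatches(clauses[i], regexec(pat, clauses[i]))[[1]]
    if (length(m) != 4)
      stop("cannot parse clause ", i, ": '", clauses[i], "'")
    data.frame(metric = m[2], op = m[3], threshold = as.numeric(m[4]),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("hard_filter_expression",
                                           "data.frame"))
}

#' Format a parsed hard-filter expression back to its string form
#' @param filters a `hard_filter_expression`.
#' @return character scalar.
#' @export
format_hard_filters <- function(filters) {
  num <- vapply(filters$threshold, function(x) {
    s <- format(x, trim = TRUE, scientific = FALSE)
    if (!grepl("\\.", s)) s <- paste0(s, ".0")
    s
  }, "")
  paste(paste(filters$metric, filters$op, num), collapse = " || ")
}

#' Apply hard filters to variant records
#'
#' A record is removed iff any clause is true for it.  Clauses referring
#' to a metric the records do not expose (missing column, or NA value) are
#' not applied to those records; skipped metrics are reported in the
#' `skipped_metrics` attribute.
#'
#' @param records data.frame of variant records with metric columns.
#' @param filters a `hard_filter_expression` or its string form.
#' @return the surviving records, with attributes `n_removed` and
#'   `skipped_metrics`.
#' @export
apply_hard_filters <- function(records, filters) {
  if (is.character(filters)) filters <- parse_hard_filters(filters)
  fail <- rep(FALSE, nrow(records))
  skipped <- character(0)
  for (i in seq_len(nrow(filters))) {
    metric <- filters$metric[i]
    if (!metric %in% names(records)) {
      skipped <- c(skipped, metric)
      next
    }
    x <- records[[metric]]
    hit <- switch(filters$op[i],
                  "<" = x < filters$threshold[i],
                  ">" = x > filters$threshold[i],
                  "<=" = x <= filters$threshold[i],
                  ">=" = x >= filters$threshold[i])
    hit[is.na(hit)] <- FALSE
    fail <- fail | hit
  }
  out <- records[!fail, , drop = FALSE]
  attr(out, "n_removed") <- sum(fail)
  attr(out, "skipped_metrics") <- unique(skipped)
  out
}
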