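#' Parse a 13-character multi-axial annotation code
#'
#' Annotation codes follow the mono-hierarchical multi-axial IRMA layout
#' `TTTT-DDD-AAA-BBB`: a 4-character technical axis (imaging modality), and
#' 3-character directional (orientation), anatomical (body region) and
#' biological (organ system) axes. Both the hyphenated 16-character form and
#' the raw 13-character form are accepted; the canonical textual form is
#' always hyphenated.
#'
#' @param text A single annotation string, with or without hyphens.
#' @return An object of class `irma_code` with fields `technical`,
#'   `directional`, `anatomical` and `biological`.
#' @export
#' @examples
#' code <- parse_irma_code("1121-127-732-500")
#' code$anatomical
#' format(code)
parse_irma_code <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    stop("annotation code must be a single character string")
  n <- nchar(text)
  if (n == 16) {
    hy <- which(strsplit(text, "")[[1]] == "-")
    if (!identical(hy, c(5L, 9L, 13L)))
      stop(sprintf(
        "malformed code '%s': hyphens must sit at positions 5, 9 and 13 (found at %s)",
        text, paste(if (length(hy)) hy else "none", collapse = ", ")))
    raw <- gsub("-", "", text, fixed = TRUE)
  } else if (n == 13) {
    if (grepl("-", text, fixed = TRUE))
      stop(sprintf("malformed code '%s': 13-character form must not contain hyphens", text))
    raw <- text
  } else {
    stop(sprintf(
      "malformed code '%s': expected 13 characters (or 16 with hyphens), got %d",
      text, n))
  }
  bad <- regexpr("[^0-9a-z]", raw)
  if (bad > 0)
    stop(sprintf("malformed code '%s': illegal character '%s' at axis position %d (allowed: 0-9, a-z)",
                 text, substr(raw, bad, bad), as.integer(bad)))
  structure(
    list(technical   = substr(raw, 1, 4),
         directional = substr(raw, 5, 7),
         anatomical  = substr(raw, 8, 10),
         biological  = substr(raw, 11, 13)),
    class = "irma_code")
}

#' @export
format.irma_code <- function(x, ...) {
  paste(x$technical, x$directional, x$anatomical, x$biological, sep = "-")
}

#' @export
print.irma_code <- function(x, ...) {
  cat("<irma_code>", format(x), "\n")
  cat("  T (technical):  ", x$technical, "\n")
  cat("  D (directional):", x$directional, "\n")
  cat("  A (anatomical): ", x$anatomical, "\n")
  cat("  B (biological): ", x$biological, "\n")
  invisible(x)
}

#' The five classification schemes
#'
#' Evaluation uses five schemes: the four single axes `T`, `D`, `A`, `B` and
#' the full joined code `IRMA`.
#'
#' @return Character vector of scheme identifiers.
#' @export
scheme_ids <- function() c("T", "D", "A", "B", "IRMA")

#' Project an annotation code onto a classification scheme
#'
#' @param code An `irma_code` object or a single code string.
#' @param scheme One of `"T"`, `"D"`, `"A"`, `"B"`, `"IRMA"`.
#' @return The class label: 4 characters for `T`, 3 for `D`/`A`/`B`, and the
#'   16-character canonical code for `IRMA`.
#' @export
#' @examples
#' project_to_scheme(parse_irma_code("1121-127-732-500"), "A")
project_to_scheme <- function(code, scheme) {
  if (is.character(code)) code <- parse_irma_code(code)
  if (!inherits(code, "irma_code")) stop("`code` must be an irma_code or a string")
  scheme <- match.arg(scheme, scheme_ids())
  switch(scheme,
         T = code$technical,
         D = code$directional,
         A = code$anatomical,
         B = code$biological,
         IRMA = format(code))
}

# vectorized projection of validated canonical 16-char codes
project_codes <- function(codes, scheme) {
  scheme <- match.arg(scheme, scheme_ids())
  switch(scheme,
         T = substr(codes, 1, 4),
         D = substr(codes, 6, 8),
         A = substr(codes, 10, 12),
         B = substr(codes, 14, 16),
         IRMA = codes)
}

#' Enumerate the distinct classes of a label table under a scheme
#'
#' The class universe is always derived from the data at hand (class counts
#' reported for the reference corpus are themselves empirical), so unseen
#' labels in a test table are surfaced by the classifier rather than silently
#' merged in here.
#'
#' @param table A label table (see [read_label_table()]).
#' @param scheme Scheme identifier.
#' @return Sorted character vector of distinct class labels.
#' @export
enumerate_classes <- function(table, scheme) {
  table <- validate_label_table(table)
  if (nrow(table) == 0) stop("label table is empty")
  sort(unique(project_codes(table$irma_code, scheme)))
}

#' Decode an axis value into human-readable text
#'
#' The full axis terminology is not bundled; a user-supplied dictionary maps
#' axis values to descriptions. A small excerpt covering a handful of common
#' values ships with the package under `inst/extdata/` for testing and
#' examples.
#'
#' @param axis_value Axis code string (e.g. `"732"`).
#' @param axis One of `"T"`, `"D"`, `"A"`, `"B"`.
#' @param dictionary Either a named character vector or the path of a
#'   tab-separated file with columns `axis_value<TAB>description`.
#' @return The description, or an `"<unknown ...>"` marker if absent.
#' @export
#' @examples
#' dict <- system.file("extdata", "a-codes.tsv", package = "radannot")
#' decode_axis_label("732", "A", dict)
decode_axis_label <- function(axis_value, axis, dictionary) {
  axis <- match.arg(axis, c("T", "D", "A", "B"))
  if (is.character(dictionary) && length(dictionary) == 1 && is.null(names(dictionary))) {
    dictionary <- read_axis_dictionary(dictionary)
  }
  if (!is.character(dictionary))
    stop("`dictionary` must be a named character vector or a TSV file path")
  if (axis_value %in% names(dictionary)) unname(dictionary[[axis_value]])
  else sprintf("<unknown %s-axis code %s>", axis, axis_value)
}

#' @rdname decode_axis_label
#' @param path Path of a two-column tab-separated dictionary file.
#' @export
read_axis_dictionary <- function(path) {
  if (!file.exists(path)) stop(sprintf("dictionary file not found: %s", path))
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop(sprintf("dictionary '%s' must have two tab-separated columns", path))
  stats::setNames(tab[[2]], tab[[1]])
}

#' Read and write label tables
#'
#' A label table is a `data.frame` with columns `image_id` (unique file name)
#' and `irma_code` (validated annotation code, stored in canonical hyphenated
#' form). Extra columns (e.g. a `split` flag) are preserved.
#'
#' @param path CSV file with header `image_id,irma_code`.
#' @return A validated label table.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("label table not found: %s", path))
  tab <- utils::read.csv(path, colClasses = "character")
  validate_label_table(tab)
}

#' @rdname read_label_table
#' @param table Label table to validate or write.
#' @export
write_label_table <- function(table, path) {
  table <- validate_label_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_label_table
#' @export
validate_label_table <- function(table) {
  if (!is.data.frame(table) || !all(c("image_id", "irma_code") %in% names(table)))
    stop("a label table needs columns `image_id` and `irma_code`")
  if (anyDuplicated(table$image_id))
    stop(sprintf("duplicate image_id in label table: %s",
                 table$image_id[anyDuplicated(table$image_id)]))
  table$irma_code <- vapply(table$irma_code,
                            function(s) format(parse_irma_code(s)),
                            character(1), USE.NAMES = FALSE)
  table
}
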