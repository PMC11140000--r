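# The keyword vocabulary behind the functional classifier: an ordered
# list of classes, each with an ordered list of case-insensitive
# whole-word keywords/phrases scanned against homology-hit descriptions.
# The shipped default has 25 classes (the two similarity-defined classes,
# "unknown conserved" and "unknown", carry no keywords and are assigned
# by rule).

#' Load a class vocabulary
#'
#' Plain-text key-value format, one class per line in priority order:
#' `class label: keyword, keyword, ...`. The special line
#' `@uninformative: term, ...` sets the uninformative-description terms.
#' Classes with no keywords (here `unknown conserved` and `unknown`) are
#' rule-assigned. A keyword occurring in two classes is an error naming
#' both.
#'
#' @param path Path to the vocabulary file; defaults to the shipped
#'   25-class vocabulary.
#' @return A list of class `"vocabulary"`: `classes` (ordered labels),
#'   `keywords` (named list of ordered keyword vectors),
#'   `uninformative_terms`.
#' @export
load_vocabulary <- function(path = default_vocabulary_path()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  uninf <- c("hypothetical", "uncharacterized", "unknown", "unnamed",
             "predicted protein")
  classes <- character()
  keywords <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) stop("malformed vocabulary line: ", ln)
    label <- trimws(sub(":.*$", "", ln))
    rest <- trimws(sub("^[^:]*:", "", ln))
    kws <- if (nzchar(rest)) trimws(strsplit(rest, ",")[[1]]) else character()
    if (label == "@uninformative") { uninf <- kws; next }
    if (label %in% classes) stop("duplicate class label: ", label)
    classes <- c(classes, label)
    keywords[[label]] <- tolower(kws)
  }
  all_kw <- unlist(keywords, use.names = FALSE)
  if (anyDuplicated(all_kw)) {
    dup <- all_kw[duplicated(all_kw)][1]
    owners <- names(keywords)[vapply(keywords, function(k) dup %in% k, TRUE)]
    stop("keyword '", dup, "' appears in two classes: ",
         paste(owners, collapse = " and "))
  }
  structure(list(classes = classes, keywords = keywords,
                 uninformative_terms = tolower(uninf)),
            class = "vocabulary")
}

#' @rdname load_vocabulary
#' @param vocab A `"vocabulary"` object.
#' @export
write_vocabulary <- function(vocab, path) {
  lines <- c(
    paste0("@uninformative: ", paste(vocab$uninformative_terms, collapse = ", ")),
    vapply(vocab$classes, function(cl)
      paste0(cl, ": ", paste(vocab$keywords[[cl]], collapse = ", ")), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname load_vocabulary
#' @export
default_vocabulary_path <- function() {
  system.file("extdata", "vocabulary.txt", package = "sialoshift",
              mustWork = TRUE)
}

# First whole-word, case-insensitive keyword match in a description.
# Returns NULL or list(class, keyword, offset) with the smallest
# character offset; ties at equal offset resolve to the class (then
# keyword) earlier in the vocabulary order.
first_keyword_match <- function(desc, vocab) {
  best <- NULL
  for (cl in vocab$classes) {
    for (kw in vocab$keywords[[cl]]) {
      pos <- regexpr(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw),
                            "\\b"),
                     desc, ignore.case = TRUE, perl = TRUE)
      if (pos > 0 && (is.null(best) || pos < best$offset))
        best <- list(class = cl, keyword = kw, offset = as.integer(pos))
    }
  }
  best
}
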