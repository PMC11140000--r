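#' Read a FASTA file
#'
#' Wraps Biostrings' FASTA reader and returns one row per record with the
#' id (first whitespace-delimited token of the header), the remaining
#' description, and the uppercased sequence.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE))
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA header at line ", nonblank[1],
         ": first record does not start with '>'")
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  data.frame(id = ids, desc = descs,
             seq = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `id` (plus a space and `desc`
#' when the description is non-empty), one sequence per record.
#'
#' @param records A data.frame with columns `id`, `seq` and optionally
#'   `desc`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else ""
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a count table
#'
#' TSV with a first column of CDS ids and one column per library. Every
#' library in the header must appear in the design, counts must be
#' non-negative integers, and missing cells are an error (no silent
#' zero-filling).
#'
#' @param path Path to the TSV.
#' @param design A `"study_design"` table; the header is validated
#'   against its `library_id`s.
#' @return An integer matrix, CDS in rows, libraries in columns.
#' @export
read_counts <- function(path, design) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table needs an id column plus libraries")
  libs <- colnames(tab)[-1]
  unknown <- setdiff(libs, design$library_id)
  if (length(unknown))
    stop("library id not in design: ", paste(unknown, collapse = ", "))
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicate CDS id in count table")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(m))) stop("missing count cells are not allowed")
  if (!is.numeric(m)) stop("non-numeric counts")
  if (any(m < 0)) stop("negative counts are not allowed")
  if (any(m != round(m))) stop("non-integer counts are not allowed")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_counts
#' @param counts Integer matrix of counts (CDS x libraries).
#' @export
write_counts <- function(counts, path) {
  tab <- data.frame(cds_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Generic TSV writers used by the CLI for reports.
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S "), ...)
}
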