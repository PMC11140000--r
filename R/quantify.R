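# TPM quantification and the replicate-consistent expression filter.

#' Compute transcripts per million
#'
#' Per library, `rate_i = count_i / length_i(kb)` and
#' `tpm_i = rate_i / sum(rate) * 1e6`. An all-zero library yields an
#' all-zero TPM column and a message.
#'
#' @param counts Integer matrix (CDS x libraries).
#' @param lengths Numeric vector of CDS lengths in nucleotides, in row
#'   order (or named by CDS id).
#' @return A list of class `"expression_matrix"` with elements `counts`,
#'   `lengths`, `tpm`.
#' @export
#' @examples
#' m <- matrix(c(10L, 30L), 2, 1, dimnames = list(c("a", "b"), "lib1"))
#' compute_tpm(m, c(a = 1000, b = 3000))$tpm
compute_tpm <- function(counts, lengths) {
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop("CDS lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / (lengths / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    log_msg("all-zero library column(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  structure(list(counts = counts, lengths = lengths, tpm = tpm),
            class = "expression_matrix")
}

#' Replicate-consistent expression filter
#'
#' Keeps a CDS iff there is at least one biological group — a
#' (stage, group) cell of the design — in which its TPM is at least
#' `min_tpm` in every replicate. The comparison is inclusive, so a CDS at
#' exactly the threshold in all replicates of one cell passes.
#'
#' @param expr An `"expression_matrix"` from [compute_tpm()], or a TPM
#'   matrix.
#' @param design A `"study_design"` table covering all columns.
#' @param min_tpm Threshold (default 5).
#' @return Character vector of kept CDS ids.
#' @export
filter_expressed <- function(expr, design, min_tpm = 5) {
  tpm <- if (inherits(expr, "expression_matrix")) expr$tpm else expr
  missing <- setdiff(colnames(tpm), design$library_id)
  if (length(missing))
    stop("libraries absent from design: ", paste(missing, collapse = ", "))
  cell <- paste(design$stage, design$group, sep = ".")
  names(cell) <- design$library_id
  keep <- rep(FALSE, nrow(tpm))
  for (cl in unique(cell)) {
    libs <- intersect(names(cell)[cell == cl], colnames(tpm))
    if (!length(libs)) next
    sub <- tpm[, libs, drop = FALSE]
    keep <- keep | apply(sub >= min_tpm, 1, all)
  }
  rownames(tpm)[keep]
}
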