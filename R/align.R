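# Local protein alignment against a tagged reference proteome. Stands in
# for a BLASTp search: full dynamic programming (no heuristic seeding),
# BLOSUM62, affine gaps (opening 11, extension 1; a length-L gap costs
# opening + L * extension, the BLAST convention).

AA_ALPHABET_STD <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                     "F","P","S","T","W","Y","V","X")

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$mat <- e$BLOSUM62
    }
    env$mat
  }
})

check_protein <- function(p, what = "sequence") {
  if (!nzchar(p)) stop("empty protein ", what)
  bad <- setdiff(strsplit(p, "")[[1]], AA_ALPHABET_STD)
  if (length(bad))
    stop("unknown residue '", bad[1], "' in protein ", what)
  invisible(p)
}

encode_protein <- function(p, alphabet) {
  match(strsplit(p, "")[[1]], alphabet) - 1L
}

# Parse "<free text> taxon=<tag>|db=<rank>" description lines.
parse_proteome_tags <- function(desc) {
  taxon <- ifelse(grepl("taxon=", desc),
                  sub(".*taxon=([^|[:space:]]+).*", "\\1", desc), NA_character_)
  db <- ifelse(grepl("db=", desc),
               suppressWarnings(as.integer(sub(".*db=([0-9]+).*", "\\1", desc))),
               NA_integer_)
  list(taxon = taxon, db_rank = db)
}

hit_columns <- function() {
  data.frame(query_id = character(), subject_id = character(),
             subject_description = character(), subject_length = integer(),
             subject_start = integer(), subject_end = integer(),
             query_start = integer(), query_end = integer(),
             score = numeric(), identity = numeric(),
             subject_coverage = numeric(), db_rank = integer(),
             taxon = character(), stringsAsFactors = FALSE)
}

#' Optimal local alignment of two proteins
#'
#' Affine-gap Smith-Waterman via Biostrings, BLOSUM62 by default. Returns
#' `NULL` when the optimal score is below `score_min`. Intervals in the
#' returned hit are 0-based half-open; `subject_coverage` is the aligned
#' subject span divided by the subject length.
#'
#' @param query,subject Protein sequences (standard 20 letters plus X).
#' @param score_min Minimum score for a reportable hit.
#' @param gap_open,gap_extend Affine gap parameters.
#' @param query_id,subject_id,subject_desc Identifiers carried into the
#'   hit row.
#' @return A one-row `data.frame` (see [search_all()] for columns) or
#'   `NULL`.
#' @export
align_local <- function(query, subject, score_min = 50,
                        gap_open = 11, gap_extend = 1,
                        query_id = "query", subject_id = "subject",
                        subject_desc = "") {
  check_protein(query, "query")
  check_protein(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc < score_min) return(NULL)
  qs <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  qe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa)) - 1L
  se <- Biostrings::end(Biostrings::subject(pa))
  cols <- nchar(as.character(Biostrings::pattern(pa)))
  tags <- parse_proteome_tags(subject_desc)
  data.frame(query_id = query_id, subject_id = subject_id,
             subject_description = subject_desc,
             subject_length = nchar(subject),
             subject_start = ss, subject_end = se,
             query_start = qs, query_end = qe,
             score = sc,
             identity = Biostrings::nmatch(pa) / cols,
             subject_coverage = (se - ss) / nchar(subject),
             db_rank = tags$db_rank, taxon = tags$taxon,
             stringsAsFactors = FALSE)
}

#' Search query proteins against a tagged proteome
#'
#' Every query is aligned against every proteome entry by full local DP
#' (a score-only pass locates candidate pairs; detailed alignments are
#' then recomputed for pairs at or above `score_min`). Hits are ranked by
#' score (descending), then database rank (ascending), subject length
#' (descending), and subject id — a total order, so the ranking is
#' deterministic.
#'
#' @param queries A data.frame with columns `id` and `seq` (protein).
#' @param proteome A data.frame with columns `id`, `desc`, `seq`;
#'   descriptions carry `taxon=<tag>|db=<rank>` tags.
#' @param params A [pipeline_params()] list (uses `homology_score_min`).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A `data.frame` of ranked hits with columns `query_id`,
#'   `subject_id`, `subject_description`, `subject_length`,
#'   `subject_start`, `subject_end`, `query_start`, `query_end`, `score`,
#'   `identity`, `subject_coverage`, `db_rank`, `taxon`, `rank`.
#' @export
search_all <- function(queries, proteome, params = pipeline_params(),
                       gap_open = 11, gap_extend = 1) {
  out <- hit_columns()
  out$rank <- integer()
  if (nrow(queries) == 0L || nrow(proteome) == 0L) return(out)
  mat <- blosum62()
  alpha <- rownames(mat)
  subs_enc <- lapply(proteome$seq, encode_protein, alphabet = alpha)
  smat <- mat[, , drop = FALSE]
  storage.mode(smat) <- "integer"
  res <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    q <- queries$seq[qi]
    check_protein(q, paste0("query ", queries$id[qi]))
    scores <- cpp_sw_score_many(encode_protein(q, alpha), subs_enc,
                                smat, gap_open, gap_extend)
    cand <- which(scores >= params$homology_score_min)
    if (!length(cand)) next
    rows <- lapply(cand, function(si) {
      align_local(q, proteome$seq[si], score_min = params$homology_score_min,
                  gap_open = gap_open, gap_extend = gap_extend,
                  query_id = queries$id[qi], subject_id = proteome$id[si],
                  subject_desc = proteome$desc[si])
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) res[[qi]] <- do.call(rbind, rows)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(out)
  hits <- do.call(rbind, res)
  ord <- order(hits$query_id, -hits$score, hits$db_rank,
               -hits$subject_length, hits$subject_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                          FUN = seq_along)
  rownames(hits) <- NULL
  hits
}
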