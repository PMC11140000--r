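# Functional classification: scan the ordered keyword vocabulary against
# homology-hit descriptions, in hit-rank order.

#' Classify one CDS from its ranked hits
#'
#' Rules, in order: (1) no hits at all — class `"unknown"` (no or low
#' similarity to deposited sequences); (2) walk the hits in rank order
#' and, in the first description containing any vocabulary keyword,
#' assign the class of the keyword at the smallest character offset (ties
#' at equal offset resolve to the class earlier in the vocabulary order);
#' (3) hits present but no keyword in any description — class
#' `"unknown conserved"` (similar only to sequences of unknown function,
#' e.g. "hypothetical protein" entries).
#'
#' @param cds_id CDS identifier carried into the result.
#' @param ranked_hits Hits for this CDS's ORF, best first (as from
#'   [search_all()]); `NULL` or empty for no hits.
#' @param vocab A `"vocabulary"` from [load_vocabulary()].
#' @return A one-row `data.frame`: `cds_id`, `class_label`,
#'   `matched_keyword`, `source_subject`, `source_db_rank`.
#' @export
classify_cds <- function(cds_id, ranked_hits, vocab = load_vocabulary()) {
  res <- function(label, kw = NA_character_, subj = NA_character_,
                  rank = NA_integer_)
    data.frame(cds_id = cds_id, class_label = label, matched_keyword = kw,
               source_subject = subj, source_db_rank = rank,
               stringsAsFactors = FALSE)
  if (is.null(ranked_hits) || nrow(ranked_hits) == 0L)
    return(res("unknown"))
  for (i in seq_len(nrow(ranked_hits))) {
    m <- first_keyword_match(ranked_hits$subject_description[i], vocab)
    if (!is.null(m))
      return(res(m$class, m$keyword, ranked_hits$subject_id[i],
                 ranked_hits$db_rank[i]))
  }
  res("unknown conserved")
}

#' Classify every CDS in a table
#'
#' @param cds CDS table from [extract_cds()] (uses `cds_id`, `query_id`).
#' @param hits Ranked hit table from [search_all()].
#' @param vocab A `"vocabulary"`.
#' @return A `data.frame`, one row per CDS (see [classify_cds()]).
#' @export
classify_all <- function(cds, hits, vocab = load_vocabulary()) {
  hit_split <- if (!is.null(hits) && nrow(hits))
    split(hits, hits$query_id) else list()
  rows <- lapply(seq_len(nrow(cds)), function(i)
    classify_cds(cds$cds_id[i], hit_split[[cds$query_id[i]]], vocab))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- classify_cds(character(0), NULL, vocab)[0, ]
  out
}
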