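# Redundancy consolidation: greedy incremental clustering of CDS
# nucleotide sequences at >= 95% identity, one representative per
# cluster.

CLUSTER_MATCH <- 1L
CLUSTER_MISMATCH <- -2L
CLUSTER_GAP_OPEN <- 4L
CLUSTER_GAP_EXT <- 2L

DNA_ALPHA <- c("A", "C", "G", "T", "N")

encode_dna <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], DNA_ALPHA)
  idx[is.na(idx)] <- 5L   # any other ambiguity code behaves like N
  idx - 1L
}

#' Pairwise nucleotide identity (glocal)
#'
#' Identity of the optimal global alignment of the shorter sequence
#' within the longer (free end gaps on the longer only): matching columns
#' divided by alignment columns over the shorter sequence's aligned
#' extent. The denominator convention lets a fragment be absorbed by a
#' full-length representative.
#'
#' @param a,b Nucleotide sequences.
#' @return A list with `identity`, `matches`, `columns`, `score`.
#' @export
pair_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  v <- cpp_glocal_identity(encode_dna(a), encode_dna(b),
                           CLUSTER_MATCH, CLUSTER_MISMATCH,
                           CLUSTER_GAP_OPEN, CLUSTER_GAP_EXT)
  list(score = v[1], matches = v[2], columns = v[3], identity = v[4])
}

#' Greedy incremental clustering at an identity threshold
#'
#' Sequences are sorted by length (descending; ties by id) and processed
#' in order: each sequence joins the first existing cluster whose
#' representative aligns at identity at least `threshold` (first fit),
#' otherwise it founds a new cluster. The representative of a cluster is
#' therefore its longest member (ties by lexicographically smallest id),
#' and the deterministic sort makes the result invariant to input order.
#'
#' @param sequences A data.frame with columns `id`, `seq` (nucleotide
#'   CDS), or a named character vector.
#' @param threshold Identity threshold in (0, 1]; default 0.95.
#' @return A `data.frame` with one row per member: `representative_id`,
#'   `member_id`, `identity` (of member to representative).
#' @export
cluster_greedy <- function(sequences, threshold = 0.95) {
  if (is.character(sequences))
    sequences <- data.frame(id = names(sequences), seq = unname(sequences),
                            stringsAsFactors = FALSE)
  if (!nrow(sequences))
    return(data.frame(representative_id = character(),
                      member_id = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  if (anyDuplicated(sequences$id)) stop("duplicate sequence ids")
  ord <- order(-nchar(sequences$seq), sequences$id, method = "radix")
  sq <- sequences[ord, , drop = FALSE]
  enc <- lapply(sq$seq, encode_dna)
  res <- cpp_cluster_greedy(enc, threshold, CLUSTER_MATCH, CLUSTER_MISMATCH,
                            CLUSTER_GAP_OPEN, CLUSTER_GAP_EXT)
  out <- data.frame(representative_id = sq$id[res$assign],
                    member_id = sq$id,
                    identity = res$identity,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster representatives
#'
#' @param clusters Output of [cluster_greedy()].
#' @return Character vector of representative ids (founding order).
#' @export
cluster_representatives <- function(clusters) {
  unique(clusters$representative_id)
}
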