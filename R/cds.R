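# CDS extraction: two evidence routes. Homology route — the best database
# hit must cover at least 70% of the matched protein and the ORF must be
# at least 100 nt. Signal route — among methionine-initiated sub-ORFs of
# at least 40 aa whose translation the signal-peptide heuristic accepts,
# the most 5' methionine sets the start.

# Kyte-Doolittle hydropathy index.
KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
        E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
        M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
        Y = -1.3, V = 4.2, X = 0)

SMALL_RESIDUES <- c("A", "G", "S", "C", "T", "V")

#' Signal-peptide heuristic
#'
#' A rule-based stand-in for an external signal-peptide predictor,
#' modelling the canonical tripartite architecture. A protein is called
#' positive iff (all positions 1-based):
#' \itemize{
#'   \item n-region: at least one K or R among residues 2-6;
#'   \item h-region: a window of >= 7 consecutive residues within
#'     positions 6-25 with mean Kyte-Doolittle hydropathy > 1.6;
#'   \item c-region: a position p in 12-40 whose residues at p-3 and p-1
#'     are small (A, G, S, C, T, V); the smallest such p is the reported
#'     cleavage index (the first residue of the mature protein).
#' }
#' Proteins not starting with methionine are automatic negatives. The
#' score is the best h-region window mean.
#'
#' @param protein Protein sequence.
#' @return A list with `is_positive`, `cleavage_index` (1-based, `NA`
#'   when negative), and `score`.
#' @export
predict_signal_peptide <- function(protein) {
  neg <- list(is_positive = FALSE, cleavage_index = NA_integer_,
              score = -Inf)
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n < 12L || aa[1] != "M") return(neg)
  # n-region
  if (!any(aa[2:min(6L, n)] %in% c("K", "R"))) return(neg)
  # h-region
  hi <- min(25L, n)
  best <- -Inf
  if (hi - 6L + 1L >= 7L) {
    kd <- KD[aa[6:hi]]
    nn <- length(kd)
    cs <- cumsum(c(0, kd))
    for (len in 7:nn) {
      for (s in 1:(nn - len + 1L)) {
        m <- (cs[s + len] - cs[s]) / len
        if (m > best) best <- m
      }
    }
  }
  if (!(best > 1.6)) return(neg)
  # c-region
  for (p in 12:min(40L, n)) {
    if (aa[p - 3L] %in% SMALL_RESIDUES && aa[p - 1L] %in% SMALL_RESIDUES)
      return(list(is_positive = TRUE, cleavage_index = as.integer(p),
                  score = best))
  }
  neg
}

# Map an amino-acid interval [aa_start, aa_end) of an ORF to
# forward-strand nucleotide coordinates.
orf_aa_to_nt <- function(orf_start, orf_end, strand, aa_start, aa_end) {
  if (strand == "+") c(orf_start + 3L * aa_start, orf_start + 3L * aa_end)
  else c(orf_end - 3L * aa_end, orf_end - 3L * aa_start)
}

#' Call a CDS from homology evidence
#'
#' Accepts an ORF iff its best hit's subject coverage is at least
#' `min_coverage_fraction` ("at least 70% of a matching protein") and the
#' ORF spans at least `min_orf_nt` nucleotides. The CDS is the ORF
#' trimmed to the aligned query span, extended 5' to the nearest upstream
#' in-frame methionine when one exists.
#'
#' @param orf A one-row ORF data.frame (from [find_orfs()]).
#' @param hits Ranked hits for this ORF's translation (best first).
#' @param params A [pipeline_params()] list.
#' @return A list describing the CDS, or `NULL`.
#' @export
call_cds_by_homology <- function(orf, hits, params = pipeline_params()) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  best <- hits[1L, ]
  if (best$subject_coverage < params$min_coverage_fraction) return(NULL)
  if (orf$end - orf$start < params$min_orf_nt) return(NULL)
  mets <- orf$met_positions[[1]]
  qs <- best$query_start
  up <- mets[mets <= qs]
  aa_start <- if (length(up)) max(up) else qs
  aa_end <- best$query_end
  nt <- orf_aa_to_nt(orf$start, orf$end, orf$strand, aa_start, aa_end)
  list(transcript_id = orf$transcript_id, start = nt[1], end = nt[2],
       strand = orf$strand, aa_start = aa_start,
       protein = substr(orf$protein, aa_start + 1L, aa_end),
       evidence = "homology", best_hit = best,
       signal = NULL)
}

#' Refine a CDS start by the signal-peptide route
#'
#' Among methionine-initiated sub-ORFs of at least `min_signal_orf_aa`
#' amino acids whose translation the heuristic accepts, the most 5'
#' methionine is selected as the start; the CDS runs to the ORF end.
#'
#' @inheritParams call_cds_by_homology
#' @param predictor Signal-peptide predictor: a function taking a protein
#'   and returning a list like [predict_signal_peptide()]'s. Supplying a
#'   different function plugs in external predictions.
#' @return A list describing the CDS (evidence `"signal"`), or `NULL`.
#' @export
refine_start <- function(orf, params = pipeline_params(),
                         predictor = predict_signal_peptide) {
  mets <- sort(orf$met_positions[[1]])
  len_aa <- nchar(orf$protein)
  for (m in mets) {
    if (len_aa - m < params$min_signal_orf_aa) break
    prot <- substr(orf$protein, m + 1L, len_aa)
    call <- predictor(prot)
    if (call$is_positive) {
      nt <- orf_aa_to_nt(orf$start, orf$end, orf$strand, m, len_aa)
      return(list(transcript_id = orf$transcript_id,
                  start = nt[1], end = nt[2], strand = orf$strand,
                  aa_start = m,
                  protein = prot, evidence = "signal", best_hit = NULL,
                  signal = call))
    }
  }
  NULL
}

# Enumerate ORFs for a set of transcripts, assigning stable query ids
# <transcript>.o<k>.
enumerate_orfs <- function(transcripts, params = pipeline_params()) {
  min_len <- min(params$min_orf_nt, 3L * params$min_signal_orf_aa)
  orfs <- lapply(seq_len(nrow(transcripts)), function(i) {
    o <- find_orfs(transcripts$seq[i], min_len_nt = min_len,
                   id = transcripts$id[i])
    if (nrow(o)) o$query_id <- sprintf("%s.o%d", transcripts$id[i],
                                       seq_len(nrow(o)))
    o
  })
  do.call(rbind, orfs)
}

#' Extract CDS records from transcripts
#'
#' Runs both evidence routes over every ORF of every transcript. When
#' both routes accept the same ORF the most 5' of the two candidate
#' methionine starts is selected (the signal-peptide mapping can only
#' extend a start upstream, never truncate one), the record carries
#' evidence `"both"`, and the homology best hit is retained.
#'
#' @param transcripts A data.frame with columns `id`, `seq`.
#' @param hits Ranked hit table from [search_all()] over the ORF
#'   translations (query ids `<transcript>.o<k>`).
#' @param params A [pipeline_params()] list.
#' @param predictor Signal-peptide predictor (see [refine_start()]).
#' @return A `data.frame` of CDS records: `cds_id`, `transcript_id`,
#'   `query_id`, `start`, `end`, `strand`, `protein`, `nt_seq`,
#'   `evidence`, best-hit columns, signal columns, `contaminant`.
#' @export
extract_cds <- function(transcripts, hits, params = pipeline_params(),
                        predictor = predict_signal_peptide) {
  orfs <- enumerate_orfs(transcripts, params)
  rows <- list()
  hit_split <- if (!is.null(hits) && nrow(hits))
    split(hits, hits$query_id) else list()
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    h <- hit_split[[orf$query_id]]
    hom <- call_cds_by_homology(orf, h, params)
    sig <- refine_start(orf, params, predictor)
    rec <- if (!is.null(sig) && !is.null(hom)) {
      r <- if (sig$aa_start <= hom$aa_start) sig else hom
      r$evidence <- "both"
      r$best_hit <- hom$best_hit
      r$signal <- sig$signal
      r
    } else if (!is.null(sig)) sig else hom
    if (is.null(rec)) next
    tx_seq <- transcripts$seq[transcripts$id == orf$transcript_id]
    nt <- substr(tx_seq, rec$start + 1L, rec$end)
    if (rec$strand == "-") nt <- revcomp(nt)
    bh <- rec$best_hit
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = rec$transcript_id, query_id = orf$query_id,
      start = rec$start, end = rec$end, strand = rec$strand,
      protein = rec$protein, nt_seq = nt, evidence = rec$evidence,
      hit_subject = if (!is.null(bh)) bh$subject_id else NA_character_,
      hit_score = if (!is.null(bh)) bh$score else NA_real_,
      hit_coverage = if (!is.null(bh)) bh$subject_coverage else NA_real_,
      hit_taxon = if (!is.null(bh)) bh$taxon else NA_character_,
      hit_db_rank = if (!is.null(bh)) bh$db_rank else NA_integer_,
      signal_positive = !is.null(rec$signal),
      signal_cleavage = if (!is.null(rec$signal)) rec$signal$cleavage_index
                        else NA_integer_,
      signal_score = if (!is.null(rec$signal)) rec$signal$score else NA_real_,
      contaminant = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(transcript_id = character(), query_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      protein = character(), nt_seq = character(),
                      evidence = character(), hit_subject = character(),
                      hit_score = numeric(), hit_coverage = numeric(),
                      hit_taxon = character(), hit_db_rank = integer(),
                      signal_positive = logical(), signal_cleavage = integer(),
                      signal_score = numeric(), contaminant = logical(),
                      stringsAsFactors = FALSE)
    out$cds_id <- character()
    return(out)
  }
  cds <- do.call(rbind, rows)
  k <- stats::ave(seq_len(nrow(cds)), cds$transcript_id, FUN = seq_along)
  cds$cds_id <- sprintf("%s.c%d", cds$transcript_id, k)
  rownames(cds) <- NULL
  cds[, c("cds_id", setdiff(names(cds), "cds_id"))]
}

#' Select one primary CDS per transcript
#'
#' Short spurious ORFs (reading-frame shadows of a real coding region,
#' or chance signal-heuristic positives) can satisfy an evidence route;
#' downstream quantification keys counts by transcript, so the pipeline
#' carries a single coding call per transcript: the longest CDS, ties
#' broken by evidence (`both` > `homology` > `signal`), then best-hit
#' score, then leftmost start.
#'
#' @param cds CDS table from [extract_cds()].
#' @return The subset of `cds` with one row per transcript.
#' @export
select_primary_cds <- function(cds) {
  if (!nrow(cds)) return(cds)
  ev_rank <- c(both = 1L, homology = 2L, signal = 3L)
  ord <- order(cds$transcript_id, -(cds$end - cds$start),
               ev_rank[cds$evidence], -ifelse(is.na(cds$hit_score), 0,
                                              cds$hit_score),
               cds$start, method = "radix")
  s <- cds[ord, , drop = FALSE]
  out <- s[!duplicated(s$transcript_id), , drop = FALSE]
  out[order(out$transcript_id), , drop = FALSE]
}

#' Flag contaminant CDS
#'
#' A CDS is a contaminant iff its best hit's taxon is in
#' `contaminant_taxa` and no non-contaminant hit scores within
#' `contaminant_margin_bits` of the best hit (ambiguous cases are kept).
#' Hit-less CDS are kept — they become the "unknown" class downstream.
#'
#' @param cds CDS table from [extract_cds()].
#' @param hits Ranked hit table from [search_all()].
#' @param params A [pipeline_params()] list.
#' @return The CDS table with the `contaminant` column filled in.
#' @export
flag_contaminants <- function(cds, hits, params = pipeline_params()) {
  if (!nrow(cds)) return(cds)
  hit_split <- if (!is.null(hits) && nrow(hits))
    split(hits, hits$query_id) else list()
  flag <- logical(nrow(cds))
  for (i in seq_len(nrow(cds))) {
    h <- hit_split[[cds$query_id[i]]]
    if (is.null(h) || !nrow(h)) next
    best <- h[1L, ]
    if (!best$taxon %in% params$contaminant_taxa) next
    clean <- !(h$taxon %in% params$contaminant_taxa) &
      h$score >= best$score - params$contaminant_margin_bits
    flag[i] <- !any(clean)
  }
  cds$contaminant <- flag
  cds
}
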