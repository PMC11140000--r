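# Six-frame ORF enumeration. Intervals are 0-based, half-open, on the
# transcript's forward strand; minus-strand ORFs keep forward coordinates
# plus a strand flag.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Translate a vector of codons; codons containing anything outside ACGT
# (N in particular) yield NA, stop codons yield "*".
translate_codons <- function(codons) {
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa
}

#' Find open reading frames in all six frames
#'
#' ORFs are stop-to-stop stretches (sequence ends count as boundaries) in
#' each of the six reading frames, translated with the standard genetic
#' code. Codons containing an ambiguous base (N) are not translated and
#' split the frame at that codon. Only ORFs of at least `min_len_nt`
#' nucleotides are returned — by default 100 nt, the minimum the
#' coding-region extraction considers.
#'
#' @param seq Nucleotide sequence (character scalar over A, C, G, T, N).
#' @param min_len_nt Minimum ORF length in nucleotides.
#' @param id Transcript id recorded in the output.
#' @return A `data.frame` with one row per ORF: `transcript_id`, `strand`
#'   (`"+"`/`"-"`), `frame` (0-2, on the reading strand), `start`, `end`
#'   (forward-strand, 0-based, half-open), `protein`, and a list-column
#'   `met_positions` of 0-based amino-acid offsets of methionines.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_len_nt = 6)
find_orfs <- function(seq, min_len_nt = 100L, id = "transcript") {
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  if (L >= 3L) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      for (frame in 0:2) {
        ncod <- (L - frame) %/% 3L
        if (ncod < 1L) next
        starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
        codons <- substring(s, starts, starts + 2L)
        aa <- translate_codons(codons)
        # boundaries: stop codons and untranslatable codons
        boundary <- is.na(aa) | aa == "*"
        runs <- rle(!boundary)
        pos <- cumsum(c(1L, runs$lengths))
        for (k in seq_along(runs$lengths)) {
          if (!runs$values[k]) next
          c0 <- pos[k] - 1L              # 0-based codon start
          nc <- runs$lengths[k]
          if (3L * nc < min_len_nt) next
          s0 <- frame + 3L * c0          # on reading strand
          e0 <- s0 + 3L * nc
          if (strand == "+") { fs <- s0; fe <- e0 } else { fs <- L - e0; fe <- L - s0 }
          prot <- paste(aa[(c0 + 1L):(c0 + nc)], collapse = "")
          mets <- which(aa[(c0 + 1L):(c0 + nc)] == "M") - 1L
          out[[length(out) + 1L]] <- data.frame(
            transcript_id = id, strand = strand, frame = frame,
            start = fs, end = fe, protein = prot,
            met_positions = I(list(as.integer(mets))),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      protein = character(),
                      met_positions = I(list()), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Translate the forward-strand interval [start, end) on the given strand;
# used to verify that recorded CDS intervals reproduce their proteins.
translate_interval <- function(seq, start, end, strand) {
  sub <- substr(toupper(seq), start + 1L, end)
  if (strand == "-") sub <- revcomp(sub)
  n <- nchar(sub) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  paste(translate_codons(substring(sub, starts, starts + 2L)), collapse = "")
}
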