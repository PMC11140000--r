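#' Pipeline parameters
#'
#' Bundles every threshold the pipeline applies, with the defaults used
#' throughout: a coding region must sit in an open reading frame of at
#' least 100 nucleotides and its best database hit must cover at least 70%
#' of the matching protein; the signal-peptide route considers
#' methionine-initiated ORFs of at least 40 amino acids; near-identical
#' coding sequences are consolidated at 95% nucleotide identity; only CDS
#' with TPM >= 5 in all replicates of at least one biological group are
#' analysed; and differential expression requires |log2 fold change| >= 2
#' at FDR < 0.05.
#'
#' @param min_orf_nt Minimum ORF length in nucleotides for the homology
#'   route.
#' @param min_coverage_fraction Minimum fraction of the matched database
#'   protein that the alignment must cover.
#' @param min_signal_orf_aa Minimum length (amino acids) of a
#'   methionine-initiated ORF submitted to the signal-peptide heuristic.
#' @param cluster_identity Nucleotide identity threshold for redundancy
#'   consolidation, in (0, 1].
#' @param min_tpm Expression filter threshold (TPM), applied per replicate
#'   within a biological group.
#' @param lfc_threshold Absolute log2 fold-change threshold for calling
#'   differential expression (inclusive).
#' @param fdr_threshold FDR threshold (strict) for calling differential
#'   expression.
#' @param contaminant_taxa Character vector of taxon tags treated as
#'   contaminant sources.
#' @param contaminant_margin_bits Score margin: a CDS whose best hit is a
#'   contaminant taxon is kept if any non-contaminant hit scores within
#'   this margin of the best.
#' @param homology_score_min Minimum local-alignment score for a hit to be
#'   reported. The default (60 raw BLOSUM62 units, ~28 bits) sits above
#'   the chance-alignment ceiling for searches of a few hundred proteins
#'   of a few hundred residues.
#' @param rng_seed Integer seed used by stochastic stages.
#'
#' @return A list of class `"pipeline_params"`.
#' @export
#' @examples
#' p <- pipeline_params()
#' p$min_coverage_fraction
pipeline_params <- function(min_orf_nt = 100,
                            min_coverage_fraction = 0.70,
                            min_signal_orf_aa = 40,
                            cluster_identity = 0.95,
                            min_tpm = 5.0,
                            lfc_threshold = 2.0,
                            fdr_threshold = 0.05,
                            contaminant_taxa = c("vertebrate", "bacteria"),
                            contaminant_margin_bits = 10,
                            homology_score_min = 60,
                            rng_seed = 1L) {
  stopifnot(
    min_orf_nt > 0, min_signal_orf_aa > 0, min_tpm > 0,
    lfc_threshold > 0, fdr_threshold > 0, homology_score_min > 0,
    contaminant_margin_bits >= 0,
    min_coverage_fraction > 0, min_coverage_fraction <= 1,
    cluster_identity > 0, cluster_identity <= 1
  )
  structure(
    list(
      min_orf_nt = as.integer(min_orf_nt),
      min_coverage_fraction = min_coverage_fraction,
      min_signal_orf_aa = as.integer(min_signal_orf_aa),
      cluster_identity = cluster_identity,
      min_tpm = min_tpm,
      lfc_threshold = lfc_threshold,
      fdr_threshold = fdr_threshold,
      contaminant_taxa = contaminant_taxa,
      contaminant_margin_bits = contaminant_margin_bits,
      homology_score_min = homology_score_min,
      rng_seed = as.integer(rng_seed)
    ),
    class = "pipeline_params"
  )
}

#' Read pipeline parameters from a key-value file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments
#' allowed. Unknown keys are an error. `contaminant_taxa` is
#' comma-separated.
#'
#' @param path Path to the configuration file.
#' @return A `"pipeline_params"` list.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed parameter line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  defaults <- pipeline_params()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  args <- as.list(defaults)
  for (i in seq_along(keys)) {
    args[[keys[i]]] <-
      if (keys[i] == "contaminant_taxa") trimws(strsplit(vals[i], ",")[[1]])
      else as.numeric(vals[i])
  }
  do.call(pipeline_params, args)
}
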