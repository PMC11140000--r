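mk_orf <- function(protein, start = 0L, strand = "+", id = "t1") {
  data.frame(transcript_id = id, strand = strand, frame = 0L,
             start = start, end = start + 3L * nchar(protein),
             protein = protein,
             met_positions = I(list(
               as.integer(which(strsplit(protein, "")[[1]] == "M") - 1L))),
             stringsAsFactors = FALSE)
}

mk_hit <- function(subject_length, subject_start, subject_end,
                   query_start, query_end, score = 500,
                   taxon = "tick", db_rank = 1L, subject_id = "s1",
                   desc = "some protein") {
  data.frame(query_id = "q", subject_id = subject_id,
             subject_description = desc, subject_length = subject_length,
             subject_start = subject_start, subject_end = subject_end,
             query_start = query_start, query_end = query_end,
             score = score, identity = 0.9,
             subject_coverage = (subject_end - subject_start) / subject_length,
             db_rank = db_rank, taxon = taxon, stringsAsFactors = FALSE)
}

test_that("the signal heuristic applies its three-region rule", {
  p <- paste0("MKKLLLLLLLLLASA", strrep("E", 40))
  call <- predict_signal_peptide(p)
  expect_true(call$is_positive)
  # smallest admissible cleavage has the A-S-A small residues at -3/-1
  expect_equal(call$cleavage_index, 16L)
  expect_gt(call$score, 1.6)

  expect_false(predict_signal_peptide(paste0("M", strrep("D", 50)))$is_positive)
  expect_false(predict_signal_peptide(paste0("KK", strrep("L", 40)))$is_positive)
  # no charged n-region residue
  expect_false(predict_signal_peptide(
    paste0("MQQQQ", strrep("L", 15), "ASA", strrep("E", 30)))$is_positive)
})

test_that("homology coverage threshold is inclusive at exactly 70%", {
  orf <- mk_orf(paste0("M", random_aa_str(69)))  # 210 nt
  params <- pipeline_params()
  at <- call_cds_by_homology(orf, mk_hit(100, 30L, 100L, 0L, 70L), params)
  expect_false(is.null(at))
  expect_equal(at$evidence, "homology")
  below <- call_cds_by_homology(orf, mk_hit(100, 65L, 100L, 0L, 35L), params)
  expect_null(below)
  expect_null(call_cds_by_homology(orf, NULL, params))
  # ORF below 100 nt is rejected even at full coverage
  short <- mk_orf(paste0("M", random_aa_str(31)))  # 96 nt
  expect_null(call_cds_by_homology(short, mk_hit(32, 0L, 32L, 0L, 32L), params))
})

test_that("homology CDS starts extend 5' to the nearest upstream in-frame Met", {
  withr::local_seed(41)
  body <- random_aa_str(60)
  body <- gsub("M", "L", body)
  protein <- paste0("AAA", "M", body, "M", body)  # Mets at aa 3 and 64
  orf <- mk_orf(protein)
  params <- pipeline_params()
  # query span starts downstream of both Mets: nearest upstream is aa 64
  r <- call_cds_by_homology(orf, mk_hit(80, 0L, 80L, 70L, 124L), params)
  expect_equal(r$start, 3L * 64L)
  expect_equal(r$end, 3L * 124L)
  # query span starting at 0: no upstream Met, start at the span itself
  r0 <- call_cds_by_homology(orf, mk_hit(80, 0L, 80L, 0L, 124L), params)
  expect_equal(r0$start, 0L)
})

test_that("start refinement picks the most 5' signal-positive methionine", {
  sig <- "MKKLLLLLLLLLASA"
  mature <- gsub("M", "I", random_aa_str(50))
  protein <- paste0(sig, mature, sig, mature)
  orf <- mk_orf(protein)
  r <- refine_start(orf, pipeline_params())
  expect_equal(r$aa_start, 0L)
  expect_equal(r$evidence, "signal")
  expect_true(startsWith(r$protein, "M"))
  expect_gte(nchar(r$protein), 40L)

  # minimum sub-ORF length is 40 aa: a 39-aa signal protein is rejected
  short <- mk_orf(paste0(sig, strrep("E", 24)))  # 39 aa total
  expect_null(refine_start(short, pipeline_params()))
  expect_equal(pipeline_params()$min_signal_orf_aa, 40L)

  # no signal-positive sub-ORF -> nothing from this route
  neg <- mk_orf(paste0("M", strrep("D", 60)))
  expect_null(refine_start(neg, pipeline_params()))
})

test_that("minus-strand coordinates map back to the forward strand", {
  withr::local_seed(43)
  protein <- paste0("M", gsub("M", "K", random_aa_str(40)))
  cds <- sialoshift:::back_translate(protein)
  fwd <- paste0("TAA", cds, "TAA")
  seq <- sialoshift:::revcomp(fwd)
  orfs <- find_orfs(seq, min_len_nt = 60)
  minus <- orfs[orfs$strand == "-" & orfs$protein == protein, ]
  expect_equal(nrow(minus), 1L)
  expect_equal(sialoshift:::translate_interval(seq, minus$start, minus$end, "-"),
               protein)
})

test_that("contaminant flagging uses best-hit taxon with a score margin", {
  params <- pipeline_params()
  cds <- data.frame(cds_id = "c1", query_id = "q", contaminant = FALSE,
                    stringsAsFactors = FALSE)
  vert <- mk_hit(100, 0L, 100L, 0L, 100L, score = 200, taxon = "vertebrate")
  tick195 <- mk_hit(100, 0L, 100L, 0L, 100L, score = 195, taxon = "tick",
                    subject_id = "s2")
  tick150 <- mk_hit(100, 0L, 100L, 0L, 100L, score = 150, taxon = "tick",
                    subject_id = "s3")

  expect_true(flag_contaminants(cds, vert, params)$contaminant)
  # ambiguous: a tick hit within 10 score units of the best
  expect_false(flag_contaminants(cds, rbind(vert, tick195),
                                 params)$contaminant)
  # tick hit outside the margin does not rescue
  expect_true(flag_contaminants(cds, rbind(vert, tick150),
                                params)$contaminant)
  # no hits at all: kept
  expect_false(flag_contaminants(cds, vert[0, ], params)$contaminant)
  # best hit is tick: kept regardless
  expect_false(flag_contaminants(
    cds, rbind(tick195, mk_hit(100, 0, 100, 0, 100, score = 190,
                               taxon = "vertebrate", subject_id = "s4")),
    params)$contaminant)
})
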