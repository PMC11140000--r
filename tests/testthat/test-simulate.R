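test_that("generation is deterministic under a fixed seed", {
  sim <- sim_params(transcripts_per_class = 2, rng_seed = 9)
  p1 <- generate_reference_proteome(sim)
  p2 <- generate_reference_proteome(sim)
  expect_identical(p1, p2)
  t1 <- generate_transcripts(sim, p1)
  t2 <- generate_transcripts(sim, p1)
  expect_identical(t1, t2)
  design <- build_design()
  c1 <- generate_counts(t1$truth, design, sim)
  c2 <- generate_counts(t1$truth, design, sim)
  expect_identical(c1, c2)
})

test_that("informative proteome descriptions resolve to exactly their class", {
  vocab <- load_vocabulary()
  sim <- sim_params(transcripts_per_class = 3, rng_seed = 13)
  prot <- generate_reference_proteome(sim, vocab)
  inf <- prot[prot$role == "informative", ]
  got <- vapply(seq_len(nrow(inf)), function(i)
    sialoshift:::first_keyword_match(inf$desc[i], vocab)$class, "")
  expect_equal(got, inf$class)
  # hypothetical pool carries no keywords at all
  hyp <- prot[prot$role == "hypothetical", ]
  expect_true(all(vapply(hyp$desc, function(d)
    is.null(sialoshift:::first_keyword_match(d, vocab)), TRUE)))
  # tags parse
  tags <- sialoshift:::parse_proteome_tags(prot$desc)
  expect_false(any(is.na(tags$db_rank)))
  expect_true(all(tags$taxon[prot$role == "contaminant"] %in%
                    c("vertebrate", "bacteria")))
})

test_that("role fractions and vocabulary limits are respected", {
  sim0 <- sim_params(transcripts_per_class = 2,
                     fraction_unknown_conserved = 0, rng_seed = 3)
  prot <- generate_reference_proteome(sim0)
  expect_equal(sum(prot$role == "hypothetical"), 0L)
  expect_error(generate_reference_proteome(sim_params(n_classes = 40)),
               "exceeds the vocabulary")
})

test_that("planted CDS intervals translate back to the recorded protein", {
  s <- small_study()
  for (i in seq_len(nrow(s$truth))) {
    tr <- s$transcripts$seq[s$transcripts$id == s$truth$transcript_id[i]]
    expect_equal(
      sialoshift:::translate_interval(tr, s$truth$cds_start[i],
                                      s$truth$cds_end[i], s$truth$strand[i]),
      s$truth$protein[i])
  }
})

test_that("with no mutation every planted protein's best hit is its source at full identity", {
  sim <- sim_params(transcripts_per_class = 2, mutation_rate = 0,
                    rng_seed = 21)
  s <- simulate_study(sim)
  withdb <- s$truth[!is.na(s$truth$source_protein), ]
  queries <- data.frame(id = withdb$transcript_id, seq = withdb$protein,
                        stringsAsFactors = FALSE)
  hits <- search_all(queries, s$proteome, pipeline_params())
  best <- hits[hits$rank == 1L, ]
  best <- best[match(withdb$transcript_id, best$query_id), ]
  expect_equal(best$subject_id, withdb$source_protein)
  expect_equal(best$identity, rep(1, nrow(withdb)))
  expect_equal(best$subject_coverage, rep(1, nrow(withdb)))
})

test_that("planted signal peptides are accepted by the built-in predictor", {
  sim <- sim_params(transcripts_per_class = 2, fraction_signal_peptide = 1,
                    rng_seed = 33)
  s <- simulate_study(sim)
  tick <- s$truth[!s$truth$contaminant, ]
  expect_true(all(tick$signal_peptide))
  calls <- vapply(tick$protein,
                  function(p) predict_signal_peptide(p)$is_positive, TRUE)
  expect_gte(mean(calls), 0.9)
})

test_that("flat transcripts carry zero planted log2 fold change everywhere", {
  s <- small_study()
  lfc_cols <- grep("^lfc_", names(s$truth), value = TRUE)
  flat <- s$truth[s$truth$shape == "flat", lfc_cols]
  expect_true(all(flat == 0))
  # planted fold defaults give |log2FC| = 4 on modulated contrasts
  u <- s$truth[s$truth$shape == "U_shape", ]
  if (nrow(u)) expect_true(all(u$lfc_UF_FED6h == -4))
  ind <- s$truth[s$truth$shape == "induced", ]
  expect_true(all(ind$lfc_UF_FED6h == 4) && all(ind$lfc_UF_FED5d == 0))
})

test_that("phi = 0 with unit size factors gives Poisson counts around the planted means", {
  sim <- sim_params(transcripts_per_class = 2, phi = 0,
                    lib_size_range = c(1, 1), rng_seed = 49)
  s <- simulate_study(sim)
  counts <- s$counts
  groups <- unique(s$design$group)
  z <- c()
  for (g in groups) {
    libs <- s$design$library_id[s$design$group == g]
    for (i in seq_len(nrow(s$truth))) {
      mult <- sialoshift:::profile_multipliers(s$truth$shape[i], groups,
                                               sim$profile_fold)[g]
      mu <- s$truth$baseline[i] * sim$depth_scale * mult
      se <- sqrt(mu / length(libs))
      z <- c(z, (mean(counts[i, libs]) - mu) / se)
    }
  }
  expect_gte(mean(abs(z) <= 3), 0.99)
  expect_error(generate_counts(s$truth, s$design, sim_params(phi = -1)))
})

test_that("the written study files round-trip through the readers", {
  dir <- withr::local_tempdir()
  s <- simulate_study(sim_params(transcripts_per_class = 2, rng_seed = 5),
                      out_dir = dir)
  tx <- read_fasta(s$paths["transcripts"])
  expect_equal(tx$id, s$transcripts$id)
  expect_equal(tx$seq, s$transcripts$seq)
  counts <- read_counts(s$paths["counts"], s$design)
  expect_identical(counts, structure(s$counts, lib_size_factors = NULL))
  d <- read_design(s$paths["design"])
  expect_equal(d$library_id, s$design$library_id)
})
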