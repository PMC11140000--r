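# Synthetic study generator: a tagged reference proteome, transcripts
# with planted CDS / signal peptides / contaminants, and NB counts that
# follow the three temporal transcriptional profiles (unfed-high with a
# drastic drop at 6 h and recovery by day 5; blood-meal-induced; and a
# late switch confined to day 5), plus a ground-truth table keyed by
# transcript.

#' Simulation parameters
#'
#' Defaults describe the desk-scale study the test-suite exercises:
#' 25 classes x 20 transcripts (~500 planted CDS) plus contaminants,
#' across the 45-library design. Profile fold changes default to 16
#' (planted |log2FC| = 4), comfortably past the |log2FC| >= 2 calling
#' threshold.
#'
#' @param n_classes Number of functional classes (including `unknown`
#'   and `unknown conserved`); must not exceed the vocabulary.
#' @param transcripts_per_class Planted transcripts per class.
#' @param fraction_unknown Fraction of transcripts with no database
#'   relative (class `unknown`; always signal-peptide-bearing, since the
#'   signal route is their only extraction evidence).
#' @param fraction_unknown_conserved Fraction whose only database
#'   relatives are "hypothetical protein" entries.
#' @param fraction_contaminant Fraction of additional transcripts derived
#'   from vertebrate/bacterial proteins.
#' @param fraction_signal_peptide Fraction of informative-class proteins
#'   carrying a signal peptide.
#' @param mean_cds_aa Mean mature-protein length (aa; sd 25, min 50).
#' @param utr_len_range Range of UTR lengths (nt).
#' @param phi Negative-binomial dispersion (variance = mu + phi mu^2).
#' @param mutation_rate Per-residue substitution rate between a planted
#'   protein and its database source.
#' @param baseline_ranges Per-shape baseline abundance ranges (TPM-like
#'   units), sampled log-uniformly.
#' @param profile_fold Fold change applied by the profile shapes.
#' @param modulated_fraction Fraction of each database-backed class's
#'   members that follow the class's temporal shape; the remainder are
#'   flat. Keeps per-contrast differential expression a minority of the
#'   transcriptome, the regime the study reports (roughly 5-10% of CDS
#'   modulated per pairwise comparison), while class-level percent
#'   profiles still shift. `unknown`-class transcripts are all induced.
#' @param depth_scale Expected counts per baseline unit at library size
#'   factor 1.
#' @param lib_size_range Range of per-library size factors.
#' @param rng_seed Integer seed.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_classes = 25,
                       transcripts_per_class = 20,
                       fraction_unknown = 0.04,
                       fraction_unknown_conserved = 0.04,
                       fraction_contaminant = 0.08,
                       fraction_signal_peptide = 0.25,
                       mean_cds_aa = 120,
                       utr_len_range = c(30, 150),
                       phi = 0.1,
                       mutation_rate = 0.02,
                       baseline_ranges = list(
                         U_shape = c(100, 3000),
                         induced = c(50, 1500),
                         late_switch = c(100, 3000),
                         flat = c(10, 1000)),
                       profile_fold = 16,
                       modulated_fraction = 0.3,
                       depth_scale = 0.25,
                       lib_size_range = c(0.7, 1.3),
                       rng_seed = 101L) {
  fr <- c(fraction_unknown, fraction_unknown_conserved, fraction_contaminant,
          fraction_signal_peptide, modulated_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1), phi >= 0, mutation_rate >= 0,
            mutation_rate < 1, n_classes >= 3, transcripts_per_class >= 1,
            profile_fold > 1, depth_scale > 0)
  if (utr_len_range[1] > utr_len_range[2] || utr_len_range[1] < 0)
    stop("inconsistent utr_len_range")
  structure(as.list(environment())[names(formals(sim_params))],
            class = "sim_params")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")

# Natural amino-acid background frequencies (Robinson & Robinson). Random
# proteins drawn uniformly over the alphabet overweight rare high-scoring
# residues (W, C) and inflate BLOSUM62 chance-alignment scores far above
# standard search statistics; sampling at natural composition keeps the
# noise floor where a raw-score cutoff expects it.
AA_FREQ <- c(A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
             Q = 0.0426, E = 0.0629, G = 0.0738, H = 0.0219, I = 0.0514,
             L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
             S = 0.0712, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)

# aa -> synonymous codons (standard code, stops excluded)
CODONS_BY_AA <- split(names(Biostrings::GENETIC_CODE),
                      unname(Biostrings::GENETIC_CODE))

random_protein <- function(len)
  paste(sample(AA20, len, TRUE, prob = AA_FREQ), collapse = "")

random_dna <- function(len) paste(sample(c("A","C","G","T"), len, TRUE),
                                  collapse = "")

# Tripartite signal peptide: charged n-region, hydrophobic h-region of
# variable length and mixed composition, small-residue c-region.
# Accepted by predict_signal_peptide with cleavage at nchar(sig) + 1.
# Composition and length are randomized per peptide: planted signal
# peptides must not align to each other at a reportable score, or every
# signal-bearing protein hits every other one on its export tag alone.
random_signal_peptide <- function() {
  n_reg <- sample(c("A", "G", "P", "S", "T", "N", "Q", "L", "V"), 4L, TRUE)
  n_reg[sample.int(4L, 1L)] <- sample(c("K", "R"), 1L)
  h_len <- sample(8:12, 1L)
  h_reg <- sample(c("L", "I", "V", "F", "A", "M"), h_len, TRUE,
                  prob = c(0.35, 0.15, 0.20, 0.10, 0.10, 0.10))
  c_reg <- c(sample(c("A", "G", "S", "T"), 1L),
             sample(c("N", "Q", "E", "K", "H", "S", "A", "L"), 1L),
             sample(c("A", "G", "S", "T"), 1L))
  paste(c("M", n_reg, h_reg, c_reg), collapse = "")
}

# Uniform-random synonymous codons keep nucleotide identity between
# unrelated back-translations low, so clustering stays clean.
back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- CODONS_BY_AA[[a]]
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
}

mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aa <- strsplit(protein, "")[[1]]
  hit <- which(runif(length(aa)) < rate)
  hit <- hit[hit > 1L]  # keep the initiator methionine
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  paste(aa, collapse = "")
}

VERTEBRATE_DESCS <- c("hemoglobin subunit alpha", "serum albumin",
                      "hemoglobin subunit beta", "keratin type I",
                      "fibrinogen alpha chain", "ovalbumin-related protein")
BACTERIA_DESCS <- c("outer membrane protein A", "penicillin-binding protein",
                    "flagellar hook protein", "cell division protein FtsZ",
                    "chaperonin GroEL", "DNA gyrase subunit B")
HYPOTHETICAL_DESCS <- c("hypothetical protein", "uncharacterized protein",
                        "unnamed protein product", "predicted protein")
DESC_TEMPLATES <- c("putative %s", "%s precursor", "%s, partial",
                    "probable %s isoform X1")

informative_classes <- function(sim, vocab) {
  inf <- setdiff(vocab$classes, c("unknown", "unknown conserved"))
  need <- sim$n_classes - 2L
  if (need > length(inf))
    stop("n_classes exceeds the vocabulary (", length(inf),
         " informative classes available)")
  inf[seq_len(need)]
}

sim_counts_per_role <- function(sim) {
  n_total <- sim$n_classes * sim$transcripts_per_class
  list(n_total = n_total,
       n_unknown = round(sim$fraction_unknown * n_total),
       n_unknown_conserved = round(sim$fraction_unknown_conserved * n_total),
       n_contaminant = round(sim$fraction_contaminant * n_total))
}

#' Generate a tagged reference proteome
#'
#' For every informative class, `transcripts_per_class` proteins whose
#' description carries one of that class's keywords (so the classifier
#' resolves it to exactly that class); a pool of uninformative
#' "hypothetical protein" entries; and contaminant proteins tagged
#' `taxon=vertebrate` or `taxon=bacteria`. Descriptions end with
#' `taxon=<tag>|db=<rank>` (db 1 = tick, 2 = hypothetical pool,
#' 3 = vertebrate, 4 = bacteria).
#'
#' @param sim A [sim_params()] list.
#' @param vocab A `"vocabulary"`; defaults to the shipped one.
#' @return A `data.frame` with FASTA columns `id`, `desc`, `seq` plus
#'   bookkeeping columns `class`, `role`, `has_signal`, `cleavage`.
#' @export
generate_reference_proteome <- function(sim = sim_params(),
                                        vocab = load_vocabulary()) {
  with_seed(sim$rng_seed, {
    classes <- informative_classes(sim, vocab)
    nn <- sim_counts_per_role(sim)
    rows <- list()
    add <- function(desc, seq, class, role, has_signal, cleavage) {
      rows[[length(rows) + 1L]] <<- data.frame(
        desc = desc, seq = seq, class = class, role = role,
        has_signal = has_signal, cleavage = cleavage,
        stringsAsFactors = FALSE)
    }
    for (cl in classes) {
      kws <- vocab$keywords[[cl]]
      for (k in seq_len(sim$transcripts_per_class)) {
        len <- max(50L, round(rnorm(1, sim$mean_cds_aa, 25)))
        has_sig <- runif(1) < sim$fraction_signal_peptide
        sig <- if (has_sig) random_signal_peptide() else ""
        seq <- paste0(sig, "M", random_protein(len - 1L))
        kw <- kws[((k - 1L) %% length(kws)) + 1L]
        desc <- sprintf(sample(DESC_TEMPLATES, 1L), kw)
        m <- first_keyword_match(desc, vocab)
        if (is.null(m) || m$class != cl) desc <- paste("putative", kw)
        add(paste0(desc, " taxon=tick|db=1"), seq, cl, "informative",
            has_sig, if (has_sig) nchar(sig) + 1L else NA_integer_)
      }
    }
    for (k in seq_len(nn$n_unknown_conserved)) {
      len <- max(50L, round(rnorm(1, sim$mean_cds_aa, 25)))
      has_sig <- runif(1) < sim$fraction_signal_peptide
      sig <- if (has_sig) random_signal_peptide() else ""
      add(paste0(HYPOTHETICAL_DESCS[((k - 1L) %% length(HYPOTHETICAL_DESCS)) + 1L],
                 " taxon=tick|db=2"),
          paste0(sig, "M", random_protein(len - 1L)),
          "unknown conserved", "hypothetical", has_sig,
          if (has_sig) nchar(sig) + 1L else NA_integer_)
    }
    for (k in seq_len(nn$n_contaminant)) {
      len <- max(50L, round(rnorm(1, sim$mean_cds_aa, 25)))
      vert <- k %% 2L == 1L
      desc <- if (vert) VERTEBRATE_DESCS[((k - 1L) %/% 2L) %% length(VERTEBRATE_DESCS) + 1L]
              else BACTERIA_DESCS[((k - 1L) %/% 2L) %% length(BACTERIA_DESCS) + 1L]
      add(paste0(desc, if (vert) " taxon=vertebrate|db=3" else " taxon=bacteria|db=4"),
          paste0("M", random_protein(len - 1L)),
          NA_character_, "contaminant", FALSE, NA_integer_)
    }
    out <- do.call(rbind, rows)
    out$id <- sprintf("prot_%04d", seq_len(nrow(out)))
    out[, c("id", "desc", "seq", "class", "role", "has_signal", "cleavage")]
  })
}

profile_shapes <- c("U_shape", "induced", "late_switch", "flat")

# Per-group mean multipliers for a profile shape over the feeding groups.
profile_multipliers <- function(shape, groups, fold) {
  if (shape == "flat") return(setNames(rep(1, length(groups)), groups))
  std <- c("UF", "FED6h", "FED12h", "FED24h", "FED5d")
  if (!all(std %in% groups))
    stop("non-flat profiles need the standard feeding groups")
  m <- switch(shape,
    U_shape     = c(UF = 1, FED6h = 1 / fold, FED12h = 1 / fold,
                    FED24h = 1 / fold, FED5d = 1),
    induced     = c(UF = 1, FED6h = fold, FED12h = fold,
                    FED24h = fold, FED5d = 1),
    late_switch = c(UF = 1 / fold, FED6h = 1 / fold, FED12h = 1 / fold,
                    FED24h = 1 / fold, FED5d = 1),
    stop("unknown profile shape: ", shape))
  out <- setNames(rep(1, length(groups)), groups)
  out[names(m)] <- m
  out
}

#' Pairwise feeding-group contrasts
#'
#' The pairwise comparisons computed within each stage: consecutive
#' timepoints plus unfed vs day 5.
#' @return A 2-column character matrix (`A`, `B`).
#' @export
de_contrasts <- function() {
  cbind(A = c("UF", "FED6h", "FED12h", "FED24h", "UF"),
        B = c("FED6h", "FED12h", "FED24h", "FED5d", "FED5d"))
}

#' Generate transcripts and ground truth
#'
#' Every database-backed transcript embeds a CDS back-translated from a
#' mutated copy of its source protein, flanked by random UTRs, on a
#' random strand; each UTR abuts the CDS with an in-frame stop codon, so
#' the planted reading frame is stop-bounded on both sides. `unknown`
#' transcripts carry a signal-peptide-bearing protein with no database
#' relative.
#'
#' @param sim A [sim_params()] list.
#' @param proteome From [generate_reference_proteome()] (same vocabulary
#'   and seed family).
#' @return A list: `transcripts` (data.frame `id`, `desc`, `seq`) and
#'   `truth` (one row per transcript: class, shape, contaminant flag and
#'   taxon, signal call, CDS interval and strand, encoded protein, source
#'   protein, baseline abundance, planted log2FC per contrast, and the NB
#'   dispersion used).
#' @export
generate_transcripts <- function(sim = sim_params(),
                                 proteome = generate_reference_proteome(sim)) {
  with_seed(sim$rng_seed + 1L, {
    nn <- sim_counts_per_role(sim)
    specs <- list()
    for (i in seq_len(nrow(proteome))) {
      p <- proteome[i, ]
      specs[[length(specs) + 1L]] <- list(
        protein = mutate_protein(p$seq, sim$mutation_rate),
        class = if (p$role == "contaminant") NA_character_ else p$class,
        role = p$role, source = p$id,
        taxon = if (p$role == "contaminant")
          parse_proteome_tags(p$desc)$taxon else "tick",
        has_signal = p$has_signal, cleavage = p$cleavage)
    }
    for (k in seq_len(nn$n_unknown)) {
      len <- max(50L, round(rnorm(1, sim$mean_cds_aa, 25)))
      sig <- random_signal_peptide()
      specs[[length(specs) + 1L]] <- list(
        protein = paste0(sig, "M", random_protein(len - 1L)),
        class = "unknown", role = "unknown", source = NA_character_,
        taxon = "tick", has_signal = TRUE, cleavage = nchar(sig) + 1L)
    }
    tx_rows <- list()
    truth_rows <- list()
    contrasts <- de_contrasts()
    groups <- c("UF", "FED6h", "FED12h", "FED24h", "FED5d")
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      id <- sprintf("tx_%04d", i)
      cds <- back_translate(sp$protein)
      u5 <- random_dna(sample(sim$utr_len_range[1]:sim$utr_len_range[2], 1L))
      u3 <- random_dna(sample(sim$utr_len_range[1]:sim$utr_len_range[2], 1L))
      fwd <- paste0(u5, "TAA", cds, "TAA", u3)
      start <- nchar(u5) + 3L
      end <- start + nchar(cds)
      strand <- sample(c("+", "-"), 1L)
      seq <- fwd
      if (strand == "-") {
        L <- nchar(fwd)
        seq <- revcomp(fwd)
        tmp <- start
        start <- L - end
        end <- L - tmp
      }
      # the late-fed core: salivary-secretory classes transcribed almost
      # exclusively at day 5, preparing the next blood meal
      late_classes <- c("secreted", "metalloprotease", "protease inhibitor",
                        "lipocalin", "mucin")
      class_shape <- if (sp$role == "unknown") "induced"
        else if (sp$role == "contaminant") "flat"
        else if (!is.na(sp$class) && sp$class %in% late_classes) "late_switch"
        else "U_shape"
      shape <- if (class_shape %in% c("flat", "induced")) class_shape
        else if (runif(1) < sim$modulated_fraction) class_shape else "flat"
      rng <- sim$baseline_ranges[[shape]]
      baseline <- exp(runif(1, log(rng[1]), log(rng[2])))
      mult <- profile_multipliers(shape, groups, sim$profile_fold)
      lfc <- log2(mult[contrasts[, "B"]] / mult[contrasts[, "A"]])
      names(lfc) <- paste0("lfc_", contrasts[, "A"], "_", contrasts[, "B"])
      tx_rows[[i]] <- data.frame(id = id, desc = "", seq = seq,
                                 stringsAsFactors = FALSE)
      truth_rows[[i]] <- cbind(
        data.frame(transcript_id = id, class = sp$class, role = sp$role,
                   shape = shape, class_shape = class_shape,
                   contaminant = sp$role == "contaminant",
                   taxon = sp$taxon, signal_peptide = sp$has_signal,
                   cleavage_index = sp$cleavage,
                   cds_start = start, cds_end = end, strand = strand,
                   protein = sp$protein, source_protein = sp$source,
                   baseline = baseline, phi = sim$phi,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(lfc)))
    }
    list(transcripts = do.call(rbind, tx_rows),
         truth = do.call(rbind, truth_rows))
  })
}

#' Generate a count matrix from planted profiles
#'
#' Counts are negative-binomial, `NB(mean = mu_gl * s_l, dispersion =
#' phi)`, with library size factors `s_l` drawn uniformly from
#' `lib_size_range` and `mu_gl = baseline x profile multiplier x
#' depth_scale`. With `phi = 0` the draws are Poisson.
#'
#' @param truth Ground-truth table from [generate_transcripts()].
#' @param design A `"study_design"` table.
#' @param sim A [sim_params()] list.
#' @return Integer matrix, transcripts x libraries.
#' @export
generate_counts <- function(truth, design, sim = sim_params()) {
  if (sim$phi < 0) stop("phi must be >= 0")
  validate_design(design)
  with_seed(sim$rng_seed + 2L, {
    libs <- design$library_id
    s_l <- runif(length(libs), sim$lib_size_range[1], sim$lib_size_range[2])
    counts <- matrix(0L, nrow(truth), length(libs),
                     dimnames = list(truth$transcript_id, libs))
    groups <- unique(design$group)
    for (g in seq_len(nrow(truth))) {
      mult <- profile_multipliers(truth$shape[g], groups, sim$profile_fold)
      mu <- truth$baseline[g] * sim$depth_scale * mult[design$group] * s_l
      counts[g, ] <- as.integer(
        if (sim$phi == 0) rpois(length(mu), mu)
        else rnbinom(length(mu), mu = mu, size = 1 / sim$phi))
    }
    attr(counts, "lib_size_factors") <- setNames(s_l, libs)
    counts
  })
}

#' Run the full synthetic-study generator
#'
#' @param sim A [sim_params()] list.
#' @param design A `"study_design"`; defaults to the 45-library layout.
#' @param vocab A `"vocabulary"`.
#' @param out_dir Optional directory; when given, writes
#'   `transcripts.fasta`, `proteome.fasta`, `counts.tsv`, `design.tsv`,
#'   `truth.tsv` and returns their paths in the result.
#' @return A list: `proteome`, `transcripts`, `truth`, `counts`,
#'   `design` (+ `paths` when written).
#' @export
simulate_study <- function(sim = sim_params(), design = build_design(),
                           vocab = load_vocabulary(), out_dir = NULL) {
  proteome <- generate_reference_proteome(sim, vocab)
  tx <- generate_transcripts(sim, proteome)
  counts <- generate_counts(tx$truth, design, sim)
  out <- list(proteome = proteome, transcripts = tx$transcripts,
              truth = tx$truth, counts = counts, design = design)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      transcripts = file.path(out_dir, "transcripts.fasta"),
      proteome = file.path(out_dir, "proteome.fasta"),
      counts = file.path(out_dir, "counts.tsv"),
      design = file.path(out_dir, "design.tsv"),
      truth = file.path(out_dir, "truth.tsv"))
    write_fasta(tx$transcripts, paths["transcripts"])
    write_fasta(proteome, paths["proteome"])
    write_counts(counts, paths["counts"])
    write_design(design, paths["design"])
    write_tsv(tx$truth, paths["truth"])
    out$paths <- paths
  }
  out
}
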