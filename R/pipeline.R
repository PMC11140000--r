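# End-to-end orchestration: ORF enumeration and homology search, CDS
# extraction, redundancy consolidation, contaminant removal, TPM
# filtering, classification, differential expression, and profile
# summaries — plus recovery metrics against a simulation's ground truth.

#' Run the full pipeline
#'
#' @param transcripts Data frame `id`, `seq` (assembled transcripts).
#' @param proteome Data frame `id`, `desc`, `seq` (tagged reference
#'   proteins).
#' @param counts Integer matrix; rows keyed by CDS id or by transcript id
#'   (each CDS then inherits its transcript's row).
#' @param design A `"study_design"`.
#' @param params A [pipeline_params()] list.
#' @param vocab A `"vocabulary"`.
#' @param hits Optional precomputed hit table (as from [search_all()]);
#'   computed when `NULL`.
#' @return A list with elements `hits`, `cds` (all extracted records,
#'   contaminants flagged), `clusters`, `representatives`, `expr`
#'   (expression matrix over kept representatives), `kept_ids`,
#'   `classification`, `de`, `profiles`, `heatmap` (orders + z matrix),
#'   `mds` (per stage, with silhouettes of the unfed / early-fed /
#'   late-fed grouping).
#' @export
run_pipeline <- function(transcripts, proteome, counts, design,
                         params = pipeline_params(),
                         vocab = load_vocabulary(), hits = NULL) {
  validate_design(design)
  if (is.null(hits)) {
    orfs <- enumerate_orfs(transcripts, params)
    queries <- data.frame(id = orfs$query_id, seq = orfs$protein,
                          stringsAsFactors = FALSE)
    log_msg("homology search: ", nrow(queries), " ORF queries vs ",
            nrow(proteome), " proteins")
    hits <- search_all(queries, proteome, params)
  }
  cds_all <- extract_cds(transcripts, hits, params)
  cds <- select_primary_cds(cds_all)
  log_msg("extracted ", nrow(cds_all), " CDS from ", nrow(transcripts),
          " transcripts; ", nrow(cds), " primary")
  cds <- flag_contaminants(cds, hits, params)

  clusters <- cluster_greedy(
    data.frame(id = cds$cds_id, seq = cds$nt_seq, stringsAsFactors = FALSE),
    params$cluster_identity)
  reps <- cluster_representatives(clusters)
  cdr <- cds[match(reps, cds$cds_id), , drop = FALSE]
  log_msg(length(reps), " representatives after clustering; ",
          sum(cdr$contaminant), " contaminant(s) removed")
  cdr <- cdr[!cdr$contaminant, , drop = FALSE]

  key <- if (all(cdr$cds_id %in% rownames(counts))) cdr$cds_id
         else cdr$transcript_id
  missing <- setdiff(key, rownames(counts))
  if (length(missing))
    stop("no counts for: ", paste(missing[1:3], collapse = ", "))
  cmat <- counts[key, design$library_id, drop = FALSE]
  rownames(cmat) <- cdr$cds_id
  expr <- compute_tpm(cmat, setNames(nchar(cdr$nt_seq), cdr$cds_id))
  kept <- filter_expressed(expr, design, params$min_tpm)
  log_msg(length(kept), " CDS pass TPM >= ", params$min_tpm,
          " in all replicates of one group")
  tpm_kept <- expr$tpm[kept, , drop = FALSE]
  counts_kept <- expr$counts[kept, , drop = FALSE]

  classification <- classify_all(cdr[match(kept, cdr$cds_id), ], hits, vocab)
  de <- run_de(counts_kept, design, params)
  profiles <- class_percent_tpm(tpm_kept, classification, design)

  z <- zscore_rows(tpm_kept)
  heatmap <- c(cluster_heatmap(z), list(z = z))

  profile_group <- function(g)
    c(UF = "unfed", FED6h = "early", FED12h = "early", FED24h = "early",
      FED5d = "late")[g]
  mds <- lapply(setNames(nm = unique(design$stage)), function(st) {
    dsub <- design[design$stage == st, ]
    m <- mds_samples(tpm_kept[, dsub$library_id, drop = FALSE], dsub)
    cl <- profile_group(m$group)
    list(coords = m,
         silhouette = if (all(!is.na(cl)))
           silhouette_mean(as.matrix(m[, c("dim1", "dim2")]), cl)
         else NA_real_)
  })

  list(hits = hits, cds = cds, clusters = clusters,
       representatives = reps, expr = expr, kept_ids = kept,
       classification = classification, de = de, profiles = profiles,
       heatmap = heatmap, mds = mds, params = params)
}

#' Recovery metrics against planted ground truth
#'
#' Scores a pipeline result against the generator's truth table, over
#' the planted transcripts:
#' \itemize{
#'   \item `class_recovery` — fraction of non-contaminant transcripts
#'     whose kept CDS is assigned the true class (unextracted or
#'     unkept transcripts count as misses);
#'   \item `contaminant_recovery` — fraction of all transcripts whose
#'     contaminant flag matches truth;
#'   \item `interval_recovery` — fraction of non-contaminant transcripts
#'     with an extracted CDS whose interval and strand equal the planted
#'     ones exactly;
#'   \item `de_recall_lfc4` — fraction of (transcript, stage, contrast)
#'     cases with planted |log2FC| = 4 and mean TPM >= 50 in the
#'     contrast's libraries that are called significant.
#' }
#'
#' @param pipe Result of [run_pipeline()].
#' @param simdata Result of [simulate_study()].
#' @return Named list of metrics.
#' @export
evaluate_against_truth <- function(pipe, simdata) {
  truth <- simdata$truth
  cds <- pipe$cds
  # main CDS per transcript: the one overlapping the planted interval
  main <- lapply(seq_len(nrow(truth)), function(i) {
    sub <- cds[cds$transcript_id == truth$transcript_id[i] &
                 cds$strand == truth$strand[i], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    ov <- pmin(sub$end, truth$cds_end[i]) - pmax(sub$start, truth$cds_start[i])
    sub[which.max(ov), , drop = FALSE]
  })

  nonc <- !truth$contaminant
  cls <- setNames(pipe$classification$class_label, pipe$classification$cds_id)
  rep_of <- setNames(pipe$clusters$representative_id, pipe$clusters$member_id)
  class_ok <- vapply(which(nonc), function(i) {
    m <- main[[i]]
    if (is.null(m)) return(FALSE)
    r <- rep_of[[m$cds_id]]
    !is.null(r) && !is.na(cls[r]) && cls[r] == truth$class[i]
  }, TRUE)

  contam_pred <- vapply(seq_len(nrow(truth)), function(i) {
    m <- main[[i]]
    !is.null(m) && m$contaminant
  }, TRUE)
  contam_ok <- contam_pred == truth$contaminant

  interval_ok <- vapply(which(nonc), function(i) {
    m <- main[[i]]
    !is.null(m) && m$start == truth$cds_start[i] && m$end == truth$cds_end[i]
  }, TRUE)

  # DE recall on planted |log2FC| = 4 at mean TPM >= 50
  de <- pipe$de
  tpm <- pipe$expr$tpm
  design <- simdata$design
  contrasts <- de_contrasts()
  cases <- 0L; hits <- 0L
  for (i in which(nonc)) {
    m <- main[[i]]
    if (is.null(m)) next
    r <- rep_of[[m$cds_id]]
    if (is.null(r) || !(r %in% rownames(tpm))) next
    for (k in seq_len(nrow(contrasts))) {
      lfc <- truth[[paste0("lfc_", contrasts[k, "A"], "_",
                           contrasts[k, "B"])]][i]
      if (is.na(lfc) || abs(lfc) != 4) next
      for (st in unique(design$stage)) {
        libs <- design$library_id[design$stage == st &
                                    design$group %in% contrasts[k, ]]
        if (mean(tpm[r, libs]) < 50) next
        row <- de[de$cds_id == r & de$stage == st &
                    de$contrast == paste0(contrasts[k, "A"], "_vs_",
                                          contrasts[k, "B"]), ]
        if (!nrow(row)) next
        cases <- cases + 1L
        if (row$significant) hits <- hits + 1L
      }
    }
  }

  # planted temporal patterns at class level
  prof <- pipe$profiles$profile
  stages <- unique(design$stage)
  get_pct <- function(cl, st, g) {
    v <- prof$mean_percent[prof$class_label == cl & prof$stage == st &
                             prof$group == g]
    if (length(v)) v else NA_real_
  }
  unknown_ratio <- vapply(stages, function(st)
    get_pct("unknown", st, "FED6h") / get_pct("unknown", st, "UF"), 0)
  u_classes <- unique(truth$class[!is.na(truth$class_shape) &
                                    truth$class_shape == "U_shape" &
                                    !is.na(truth$class)])
  u_checks <- c()
  for (st in stages) for (cl in intersect(u_classes, prof$class_label)) {
    uf <- get_pct(cl, st, "UF"); f6 <- get_pct(cl, st, "FED6h")
    f5 <- get_pct(cl, st, "FED5d")
    u_checks <- c(u_checks, uf > f6 && f5 > f6)
  }

  list(class_recovery = mean(class_ok),
       contaminant_recovery = mean(contam_ok),
       interval_recovery = mean(interval_ok),
       de_recall_lfc4 = if (cases) hits / cases else NA_real_,
       de_recall_cases = cases,
       unknown_induction_min_ratio = min(unknown_ratio),
       u_shape_class_fraction = mean(u_checks),
       min_silhouette = min(vapply(pipe$mds, `[[`, 0, "silhouette")),
       n_transcripts = nrow(truth),
       n_kept = length(pipe$kept_ids))
}

#' Type-I error of the exact test under a null simulation
#'
#' Simulates flat (no-effect) NB counts for a two-group, three-replicate
#' design at the given dispersion, runs the test with the pipeline's
#' dispersion estimator, and returns the fraction of CDS with p < 0.05,
#' averaged over `n_runs` simulations.
#'
#' @param n_cds CDS per run.
#' @param phi True NB dispersion of the simulated counts.
#' @param n_runs Number of replicate simulations.
#' @param seed RNG seed.
#' @return List with `type1` (mean fraction p < 0.05) and `per_run`.
#' @export
null_type1_error <- function(n_cds = 2000, phi = 0.1, n_runs = 20,
                             seed = 7L) {
  design <- build_design(stages = "s1", groups = c("A", "B"),
                         replicates_per_cell = 3L)
  per_run <- vapply(seq_len(n_runs), function(r) {
    sim <- sim_params(phi = phi, rng_seed = seed + 1000L * r)
    truth <- data.frame(
      transcript_id = sprintf("g%04d", seq_len(n_cds)),
      shape = "flat",
      baseline = with_seed(seed + r, exp(runif(n_cds, log(10), log(1000)))),
      stringsAsFactors = FALSE)
    counts <- generate_counts(truth, design, sim)
    f <- norm_factors(counts)
    phi_hat <- estimate_dispersion(counts, design)
    ga <- design$library_id[design$group == "A"]
    gb <- design$library_id[design$group == "B"]
    p <- vapply(seq_len(n_cds), function(i)
      exact_nb_test(counts[i, ga], counts[i, gb], phi_hat,
                    f[c(ga, gb)])$p_value, 0)
    mean(p < 0.05)
  }, 0)
  list(type1 = mean(per_run), per_run = per_run)
}
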