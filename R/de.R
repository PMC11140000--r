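# Differential expression between feeding groups: trimmed-mean
# normalization factors, method-of-moments common dispersion, and an
# exact conditional negative-binomial test. Significance follows the
# study thresholds: |log2FC| >= 2 and FDR < 0.05.

#' Trimmed-mean normalization factors
#'
#' Effective library-size factors against the library of median depth:
#' CDS zero in either library are dropped, the 30% tails of the raw
#' log2-ratios and the 5% tails of mean log2-abundance are trimmed, and
#' the factor is the precision-weighted mean of the remaining log-ratios,
#' exponentiated. Factors are rescaled to geometric mean 1, so they
#' absorb depth differences (a library with exactly doubled counts gets
#' twice the factor).
#'
#' @param counts Integer matrix (CDS x libraries), >= 2 libraries.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
norm_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least two libraries")
  depth <- colSums(counts)
  if (any(depth == 0)) stop("library with all-zero counts: ",
                            colnames(counts)[which(depth == 0)[1]])
  ref <- which.min(abs(depth - median(depth)))
  cr <- counts[, ref]
  f <- vapply(seq_len(ncol(counts)), function(l) {
    if (l == ref) return(1)
    cl <- counts[, l]
    use <- cl > 0 & cr > 0
    if (!any(use)) return(1)
    lr <- log2(cl[use] / cr[use])
    ab <- 0.5 * (log2(cl[use]) + log2(cr[use]))
    qlr <- quantile(lr, c(0.3, 0.7), names = FALSE)
    qab <- quantile(ab, c(0.05, 0.95), names = FALSE)
    keep <- lr >= qlr[1] & lr <= qlr[2] & ab >= qab[1] & ab <= qab[2]
    if (!any(keep)) keep <- rep(TRUE, length(lr))
    w <- 1 / (1 / cl[use][keep] + 1 / cr[use][keep])
    2^weighted.mean(lr[keep], w)
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Method-of-moments common dispersion
#'
#' Per CDS, `phi_g = max(0, (s^2 - mu) / mu^2)` on
#' factor-normalized counts, averaged over the design's replicate cells;
#' the common dispersion is the median of `phi_g` over CDS with overall
#' normalized mean > 5 (all CDS when none qualify). Returns 0 when every
#' per-CDS estimate is 0.
#'
#' @param counts Integer matrix (CDS x libraries).
#' @param design A `"study_design"` covering the columns; cells need
#'   >= 2 replicates.
#' @return Common dispersion estimate (scalar, >= 0).
#' @export
estimate_dispersion <- function(counts, design) {
  f <- norm_factors(counts)
  norm <- sweep(counts, 2, f[colnames(counts)], "/")
  cell <- paste(design$stage, design$group, sep = ".")
  names(cell) <- design$library_id
  cells <- split(colnames(counts), cell[colnames(counts)])
  cells <- cells[lengths(cells) >= 2L]
  if (!length(cells)) stop("need >= 2 replicates per cell")
  phi_g <- rep(0, nrow(counts))
  nused <- rep(0L, nrow(counts))
  acc <- rep(0, nrow(counts))
  for (libs in cells) {
    sub <- norm[, libs, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    ok <- mu > 0
    acc[ok] <- acc[ok] + (v[ok] - mu[ok]) / mu[ok]^2
    nused[ok] <- nused[ok] + 1L
  }
  has <- nused > 0
  phi_g[has] <- pmax(0, acc[has] / nused[has])
  mu_all <- rowMeans(norm)
  pool <- phi_g[mu_all > 5]
  if (!length(pool)) pool <- phi_g
  max(0, median(pool))
}

#' Exact conditional negative-binomial test for one CDS
#'
#' Counts are scaled to the common effective library size (dividing by
#' the factors, which have geometric mean 1) and rounded; the group sums
#' `a`, `b` are modelled as `NB(n_A mu, phi / n_A)` and
#' `NB(n_B mu, phi / n_B)` with `mu` estimated from the total. The
#' two-sided p-value conditions on `T = a + b`: the probabilities of all
#' splits of `T` no more likely than the observed one are summed and
#' normalized. With `phi = 0` this is the exact conditional binomial
#' (Poisson-limit) test. The log2 fold change (B over A) uses normalized
#' group means with a prior count of 0.125.
#'
#' @param counts_a,counts_b Integer count vectors for the two groups.
#' @param phi Common dispersion (>= 0).
#' @param factors Optional effective-size factors, in the order
#'   `c(counts_a, counts_b)` (defaults to all 1).
#' @return A list with `log2FC` and `p_value`.
#' @export
exact_nb_test <- function(counts_a, counts_b, phi = 0, factors = NULL) {
  if (phi < 0) stop("phi must be >= 0")
  n_a <- length(counts_a)
  n_b <- length(counts_b)
  if (is.null(factors)) factors <- rep(1, n_a + n_b)
  sa <- counts_a / factors[seq_len(n_a)]
  sb <- counts_b / factors[n_a + seq_len(n_b)]
  lfc <- log2((mean(sb) + 0.125) / (mean(sa) + 0.125))
  a <- sum(round(sa))
  b <- sum(round(sb))
  tt <- a + b
  if (tt == 0) return(list(log2FC = 0, p_value = 1))
  mu <- tt / (n_a + n_b)
  x <- 0:tt
  lp <- if (phi == 0)
    dpois(x, n_a * mu, log = TRUE) + dpois(tt - x, n_b * mu, log = TRUE)
  else
    dnbinom(x, mu = n_a * mu, size = n_a / phi, log = TRUE) +
      dnbinom(tt - x, mu = n_b * mu, size = n_b / phi, log = TRUE)
  m <- max(lp)
  pr <- exp(lp - m)
  obs <- lp[a + 1L]
  p <- sum(pr[lp <= obs + 1e-9]) / sum(pr)
  list(log2FC = lfc, p_value = min(1, p))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (via `stats::p.adjust`), with input
#' validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag significant results
#'
#' Significant iff `|log2FC| >= lfc_threshold` (inclusive) and
#' `q_value < fdr_threshold`; direction is the fold-change sign for
#' significant results, `"ns"` otherwise.
#'
#' @param results Data frame with columns `log2FC`, `q_value`.
#' @param lfc_threshold,fdr_threshold Calling thresholds.
#' @return `results` with columns `significant`, `direction` added.
#' @export
call_de <- function(results, lfc_threshold = 2, fdr_threshold = 0.05) {
  sig <- abs(results$log2FC) >= lfc_threshold &
    results$q_value < fdr_threshold
  results$significant <- sig
  results$direction <- ifelse(!sig, "ns",
                              ifelse(results$log2FC > 0, "up", "down"))
  results
}

#' Pairwise differential expression across feeding groups
#'
#' Within each stage: effective-size factors and a common dispersion are
#' estimated from that stage's libraries, then every contrast of
#' [de_contrasts()] is tested per CDS with [exact_nb_test()], BH-adjusted
#' within the contrast, and flagged by [call_de()].
#'
#' @param counts Integer matrix (CDS x libraries).
#' @param design A `"study_design"` covering the columns.
#' @param params A [pipeline_params()] list.
#' @param phi Optional fixed dispersion (estimated per stage when
#'   `NULL`).
#' @return A `data.frame`: `cds_id`, `stage`, `contrast`, `log2FC`,
#'   `p_value`, `q_value`, `significant`, `direction`, `neg_log10_q`.
#' @export
run_de <- function(counts, design, params = pipeline_params(), phi = NULL) {
  out <- list()
  contrasts <- de_contrasts()
  for (st in unique(design$stage)) {
    dsub <- design[design$stage == st, ]
    libs <- intersect(dsub$library_id, colnames(counts))
    sub <- counts[, libs, drop = FALSE]
    f <- norm_factors(sub)
    phi_s <- if (is.null(phi)) estimate_dispersion(sub, dsub) else phi
    for (k in seq_len(nrow(contrasts))) {
      ga <- dsub$library_id[dsub$group == contrasts[k, "A"]]
      gb <- dsub$library_id[dsub$group == contrasts[k, "B"]]
      if (!length(ga) || !length(gb)) next
      res <- t(vapply(seq_len(nrow(sub)), function(i) {
        r <- exact_nb_test(sub[i, ga], sub[i, gb], phi_s, f[c(ga, gb)])
        c(r$log2FC, r$p_value)
      }, c(0, 0)))
      df <- data.frame(cds_id = rownames(sub), stage = st,
                       contrast = paste0(contrasts[k, "A"], "_vs_",
                                         contrasts[k, "B"]),
                       log2FC = res[, 1], p_value = res[, 2],
                       stringsAsFactors = FALSE)
      df$q_value <- bh_fdr(df$p_value)
      df <- call_de(df, params$lfc_threshold, params$fdr_threshold)
      df$neg_log10_q <- -log10(pmax(df$q_value, 1e-300))
      out[[length(out) + 1L]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
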