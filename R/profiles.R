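# Class-level temporal profiles, Z-score heatmap ordering, and classical
# MDS of libraries.

#' Class-level percent-TPM profiles
#'
#' Per library, a class's percent TPM is the summed TPM of its members
#' over 1e6, times 100 — so the classes partition 100% in every library.
#' Profiles are the mean and standard deviation across the replicates of
#' each (stage, group) cell.
#'
#' @param expr An `"expression_matrix"` or TPM matrix (kept CDS only).
#' @param classification From [classify_all()]; every row of the matrix
#'   must be classified.
#' @param design A `"study_design"` covering the columns.
#' @return A list: `per_library` (class x library percent matrix) and
#'   `profile` (long data.frame: `class_label`, `stage`, `group`,
#'   `mean_percent`, `sd_percent`).
#' @export
class_percent_tpm <- function(expr, classification, design) {
  tpm <- if (inherits(expr, "expression_matrix")) expr$tpm else expr
  cls <- setNames(classification$class_label, classification$cds_id)
  if (!all(rownames(tpm) %in% names(cls)))
    stop("unclassified CDS: ",
         paste(setdiff(rownames(tpm), names(cls))[1:3], collapse = ", "))
  labels <- cls[rownames(tpm)]
  per_lib <- rowsum(tpm, labels) / 1e6 * 100
  cellsplit <- split(design$library_id,
                     list(design$stage, design$group), sep = "\t")
  rows <- list()
  for (nm in names(cellsplit)) {
    libs <- intersect(cellsplit[[nm]], colnames(per_lib))
    if (!length(libs)) next
    sg <- strsplit(nm, "\t")[[1]]
    sub <- per_lib[, libs, drop = FALSE]
    rows[[nm]] <- data.frame(
      class_label = rownames(per_lib), stage = sg[1], group = sg[2],
      mean_percent = rowMeans(sub),
      sd_percent = apply(sub, 1, sd),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  list(per_library = per_lib, profile = profile)
}

#' Row-wise Z-scores
#'
#' Centres and scales each row by its mean and sample (n-1) standard
#' deviation; constant rows become all zeros.
#'
#' @param mat Numeric matrix (e.g. TPM of kept CDS).
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  z <- (mat - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Hierarchical clustering orders for a heatmap
#'
#' Average-linkage agglomerative clustering with Euclidean distance on
#' rows and on columns. Inputs are pre-sorted by id so the leaf order is
#' deterministic and invariant to input permutation.
#'
#' @param values Numeric matrix with row and column names.
#' @return A list: `row_order`, `col_order` (id vectors).
#' @export
cluster_heatmap <- function(values) {
  values <- values[order(rownames(values)), order(colnames(values)),
                   drop = FALSE]
  ro <- if (nrow(values) > 2L)
    rownames(values)[hclust(dist(values), method = "average")$order]
  else rownames(values)
  co <- if (ncol(values) > 2L)
    colnames(values)[hclust(dist(t(values)), method = "average")$order]
  else colnames(values)
  list(row_order = ro, col_order = co)
}

# Leading-fold-change distance between two libraries: root-mean-square
# of the top_n largest absolute log2 ratios of (TPM + 0.5).
lfc_distance_matrix <- function(tpm, top_n = 500L) {
  lt <- log2(tpm + 0.5)
  n <- ncol(lt)
  top_n <- min(top_n, nrow(lt))
  D <- matrix(0, n, n, dimnames = list(colnames(lt), colnames(lt)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- abs(lt[, i] - lt[, j])
      top <- sort(d, decreasing = TRUE)[seq_len(top_n)]
      D[i, j] <- D[j, i] <- sqrt(mean(top^2))
    }
  }
  D
}

#' Classical MDS of libraries
#'
#' Pairwise distances are leading-fold-change style: per library pair,
#' the root mean square of the `top_n` largest absolute log2 ratios of
#' TPM + 0.5. Classical (Torgerson) scaling returns the first two
#' principal coordinates; each axis is oriented so its
#' largest-magnitude coordinate is positive.
#'
#' @param expr An `"expression_matrix"` or TPM matrix (kept CDS only).
#' @param design A `"study_design"`.
#' @param top_n Number of leading ratios per pair (default 500).
#' @return A `data.frame`: `library_id`, `stage`, `group`, `dim1`,
#'   `dim2`.
#' @export
mds_samples <- function(expr, design, top_n = 500L) {
  tpm <- if (inherits(expr, "expression_matrix")) expr$tpm else expr
  if (ncol(tpm) < 3L) stop("MDS needs at least 3 libraries")
  D <- lfc_distance_matrix(tpm, top_n)
  pts <- cmdscale(stats::as.dist(D), k = 2)
  for (ax in 1:2) {
    i <- which.max(abs(pts[, ax]))
    if (pts[i, ax] < 0) pts[, ax] <- -pts[, ax]
  }
  idx <- match(rownames(pts), design$library_id)
  data.frame(library_id = rownames(pts),
             stage = design$stage[idx], group = design$group[idx],
             dim1 = pts[, 1], dim2 = pts[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean silhouette width
#'
#' Small self-contained silhouette: per point, `(b - a) / max(a, b)`
#' with `a` the mean within-cluster distance and `b` the smallest mean
#' distance to another cluster; singleton clusters score 0.
#'
#' @param coords Numeric matrix of point coordinates (rows = points).
#' @param labels Cluster labels, one per row.
#' @return Mean silhouette width.
#' @export
silhouette_mean <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  labels <- as.character(labels)
  s <- vapply(seq_len(nrow(D)), function(i) {
    own <- labels == labels[i]
    if (sum(own) < 2L) return(0)
    a <- mean(D[i, own & seq_len(nrow(D)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
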