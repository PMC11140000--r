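#' Build a study design table
#'
#' Enumerates libraries for a full factorial of developmental stages,
#' feeding groups, and biological replicates, in deterministic
#' stage-major order. The study layout modelled here is three immature
#' stages (larva and two nymphal stages) sampled unfed (UF) and at 6 h,
#' 12 h, 24 h, and 5 days after a blood meal, with three biological
#' replicates per cell — 45 libraries in total.
#'
#' Library ids follow `"<stage>_<group>_r<k>"`.
#'
#' @param stages Ordered character vector of stage labels.
#' @param groups Ordered character vector of feeding-group labels.
#' @param replicates_per_cell Number of biological replicates per
#'   (stage, group) cell.
#' @return A `data.frame` of class `"study_design"` with columns
#'   `library_id`, `stage`, `group`, `replicate`; the ordered label sets
#'   are kept as attributes `stages`, `groups`, `replicates_per_cell`.
#' @export
#' @examples
#' d <- build_design()
#' nrow(d)  # 45
build_design <- function(stages = c("larva", "nymph1", "nymph2"),
                         groups = c("UF", "FED6h", "FED12h", "FED24h", "FED5d"),
                         replicates_per_cell = 3L) {
  stopifnot(length(stages) >= 1, length(groups) >= 1, replicates_per_cell >= 1)
  if (anyDuplicated(stages)) stop("duplicate stage labels")
  if (anyDuplicated(groups)) stop("duplicate group labels")
  reps <- seq_len(replicates_per_cell)
  tab <- expand.grid(replicate = reps, group = groups, stage = stages,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tab <- tab[, c("stage", "group", "replicate")]
  tab$library_id <- sprintf("%s_%s_r%d", tab$stage, tab$group, tab$replicate)
  tab <- tab[, c("library_id", "stage", "group", "replicate")]
  rownames(tab) <- NULL
  structure(tab,
            stages = as.character(stages),
            groups = as.character(groups),
            replicates_per_cell = as.integer(replicates_per_cell),
            class = c("study_design", "data.frame"))
}

# Validate a design table: unique ids, balanced cells, declared group set.
validate_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("library_id", "stage", "group", "replicate") %in% names(design)))
  if (anyDuplicated(design$library_id)) stop("duplicate library ids in design")
  rpc <- attr(design, "replicates_per_cell")
  if (is.null(rpc)) rpc <- max(design$replicate)
  cells <- table(design$stage, design$group)
  if (any(cells != rpc))
    stop("design is unbalanced: every (stage, group) cell needs ",
         rpc, " replicates")
  grp <- attr(design, "groups")
  if (!is.null(grp) && !setequal(grp, unique(design$group)))
    stop("group label set does not match the declared groups")
  invisible(design)
}

#' Write / read a design table as TSV
#'
#' @param design A `"study_design"` table.
#' @param path File path.
#' @return `read_design` returns a `"study_design"` data.frame.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stages <- unique(tab$stage)
  groups <- unique(tab$group)
  out <- structure(tab,
                   stages = stages, groups = groups,
                   replicates_per_cell = as.integer(max(tab$replicate)),
                   class = c("study_design", "data.frame"))
  validate_design(out)
  out
}
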