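mk_design2 <- function() build_design(stages = "s1", groups = c("UF", "FED6h"),
                                      replicates_per_cell = 2)

test_that("class percentages partition 100% per library", {
  design <- mk_design2()
  tpm <- matrix(c(2e5, 3e5, 5e5), 3, 4,
                dimnames = list(c("a", "b", "c"), design$library_id))
  onecls <- data.frame(cds_id = c("a", "b", "c"),
                       class_label = "mucin", stringsAsFactors = FALSE)
  p1 <- class_percent_tpm(tpm, onecls, design)
  expect_equal(unname(p1$per_library["mucin", ]), rep(100, 4))
  expect_equal(p1$profile$sd_percent, rep(0, nrow(p1$profile)))

  twocls <- data.frame(cds_id = c("a", "b", "c"),
                       class_label = c("mucin", "mucin", "lipocalin"),
                       stringsAsFactors = FALSE)
  p2 <- class_percent_tpm(tpm, twocls, design)
  expect_equal(unname(colSums(p2$per_library)), rep(100, 4), tolerance = 1e-9)
  expect_equal(unname(p2$per_library["lipocalin", 1]), 50)

  expect_error(class_percent_tpm(tpm, twocls[1:2, ], design), "unclassified")
})

test_that("row Z-scores have zero mean and unit sample deviation, constants excepted", {
  m <- rbind(x = c(1, 2, 3), y = c(5, 5, 5))
  z <- zscore_rows(m)
  expect_equal(unname(z["x", ]), c(-1, 0, 1))
  expect_equal(unname(z["y", ]), c(0, 0, 0))
  withr::local_seed(113)
  m2 <- matrix(rnorm(50, sd = 4), 5, 10,
               dimnames = list(letters[1:5], NULL))
  z2 <- zscore_rows(m2)
  expect_equal(unname(rowMeans(z2)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 5), tolerance = 1e-12)
})

test_that("heatmap clustering puts identical columns adjacent and ignores input order", {
  withr::local_seed(127)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("r%02d", 1:10), sprintf("c%d", 1:6)))
  m[, 4] <- m[, 2]  # identical pair
  ord <- cluster_heatmap(m)
  pos <- match(c("c2", "c4"), ord$col_order)
  expect_equal(abs(diff(pos)), 1L)

  perm <- m[sample(nrow(m)), sample(ncol(m))]
  ord2 <- cluster_heatmap(perm)
  expect_equal(ord2$row_order, ord$row_order)
  expect_equal(ord2$col_order, ord$col_order)
})

test_that("identical libraries sit at zero leading-fold-change distance", {
  tpm <- matrix(c(10, 20, 10, 20, 40, 80), 2, 3,
                dimnames = list(c("a", "b"), c("l1", "l2", "l3")))
  D <- sialoshift:::lfc_distance_matrix(tpm, top_n = 2)
  expect_equal(D["l1", "l2"], 0)
  expect_gt(D["l1", "l3"], 0)
})

test_that("classical MDS reproduces an exactly embeddable 4-library geometry", {
  # two free rows make the log-TPM profiles a planar configuration
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(3, 4))
  n_pad <- 48
  lt <- rbind(t(pts), matrix(5, n_pad, 4))
  tpm <- 2^lt - 0.5
  dimnames(tpm) <- list(sprintf("g%02d", 1:50), sprintf("s1_g_r%d", 1:4))
  design <- data.frame(library_id = colnames(tpm), stage = "s1",
                       group = "g", replicate = 1:4,
                       stringsAsFactors = FALSE)
  m <- mds_samples(tpm, design, top_n = 50)
  got <- as.matrix(dist(m[, c("dim1", "dim2")]))
  # expected distances: RMS over all 50 rows of the log ratios
  want <- as.matrix(dist(pts)) / sqrt(50)
  expect_equal(unname(got), unname(want), tolerance = 1e-9)
  # eigen-decomposition oracle agrees up to axis sign
  D <- sialoshift:::lfc_distance_matrix(tpm, 50)
  oc <- oracle_cmds(D)
  expect_equal(unname(as.matrix(dist(oc))), unname(want), tolerance = 1e-9)
  # sign convention: each axis's largest-magnitude coordinate is positive
  for (ax in c("dim1", "dim2")) {
    v <- m[[ax]]
    expect_gte(v[which.max(abs(v))], 0)
  }
  expect_error(mds_samples(tpm[, 1:2], design[1:2, ]), "3 libraries")
})

test_that("MDS coordinates are invariant to library relabeling up to sign", {
  withr::local_seed(131)
  design <- mk_design2()
  tpm <- matrix(exp(rnorm(80, 4)), 20, 4,
                dimnames = list(sprintf("g%02d", 1:20), design$library_id))
  m1 <- mds_samples(tpm, design, top_n = 10)
  tpm2 <- tpm
  colnames(tpm2) <- paste0("x_", colnames(tpm))
  design2 <- design
  design2$library_id <- paste0("x_", design$library_id)
  m2 <- mds_samples(tpm2, design2, top_n = 10)
  expect_equal(abs(m2$dim1), abs(m1$dim1), tolerance = 1e-9)
  expect_equal(abs(m2$dim2), abs(m1$dim2), tolerance = 1e-9)
})

test_that("the internal silhouette agrees with the cluster package", {
  withr::local_seed(137)
  coords <- rbind(matrix(rnorm(20, 0), 10, 2),
                  matrix(rnorm(20, 4), 10, 2),
                  matrix(rnorm(10, c(8, 0)), 5, 2))
  labels <- rep(c("a", "b", "c"), c(10, 10, 5))
  got <- silhouette_mean(coords, labels)
  ref <- mean(cluster::silhouette(as.integer(factor(labels)),
                                  dist(coords))[, "sil_width"])
  expect_equal(got, ref, tolerance = 1e-12)
})
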