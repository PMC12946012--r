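make_fm <- function(mat, ids = sprintf("c%02d", seq_len(nrow(mat)))) {
  df <- tibble::as_tibble(as.data.frame(mat))
  df <- dplyr::mutate(df, cell_id = ids, .before = 1)
  build_feature_matrix(df, registry = setdiff(names(df), "cell_id"))
}

test_that("duplicated prototypes embed as two tight, well-separated groups", {
  proto <- rbind(matrix(0.1, 5, 6), matrix(0.9, 5, 6))
  set.seed(1)
  proto <- proto + matrix(rnorm(60, 0, 0.01), 10, 6)
  fm <- make_fm(proto)
  emb <- embed_cells(fm, seed = 42)
  g <- rep(1:2, each = 5)
  centers <- rbind(colMeans(emb[g == 1, c("umap1", "umap2")]),
                   colMeans(emb[g == 2, c("umap1", "umap2")]))
  within <- max(sqrt(rowSums((as.matrix(emb[, c("umap1", "umap2")]) -
                                centers[g, ])^2)))
  between <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  expect_lt(within, between)
})

test_that("embedding is deterministic given the seed and errors on too few cells", {
  feats <- small_cohort_features()
  fm <- build_feature_matrix(feats)
  e1 <- embed_cells(fm, seed = 42)
  e2 <- embed_cells(fm, seed = 42)
  expect_identical(e1$umap1, e2$umap1)
  expect_identical(e1$umap2, e2$umap2)
  tiny <- make_fm(matrix(runif(12), 3, 4))
  expect_error(embed_cells(tiny, seed = 1), "n_neighbors")
})

test_that("two points split into one cluster each with zero within-cluster SSE", {
  emb <- structure(tibble::tibble(cell_id = c("a", "b"),
                                  umap1 = c(0, 3), umap2 = c(0, 4)),
                   class = c("umap_embedding", "tbl_df", "tbl", "data.frame"))
  cl <- cluster_cells(emb, k = 2, seed = 1)
  expect_equal(sort(cl$cluster), 1:2)
  expect_equal(attr(cl, "tot_withinss"), 0)
  expect_error(cluster_cells(emb, k = 3), "fewer points")
})

test_that("k-means on small point sets matches the exhaustive minimum-SSE partition", {
  # 4 points at square corners plus random configurations
  sets <- list(matrix(c(0, 0, 0, 1, 10, 0, 10, 1), 4, 2, byrow = TRUE))
  set.seed(8)
  for (n in c(6, 8)) sets <- c(sets, list(matrix(rnorm(2 * n), n, 2)))
  for (pts in sets) {
    emb <- structure(tibble::tibble(cell_id = as.character(seq_len(nrow(pts))),
                                    umap1 = pts[, 1], umap2 = pts[, 2]),
                     class = c("umap_embedding", "tbl_df", "tbl",
                               "data.frame"))
    cl <- cluster_cells(emb, k = 2, seed = 1, nstart = 50)
    brute <- kmeans_brute_force(pts)
    same <- all(cl$cluster == brute$assignment) ||
      all(cl$cluster == 3L - brute$assignment)
    expect_true(same)
  }
})

test_that("clusters recover the true classes and the FS label goes to narrow spikes", {
  feats <- small_cohort_features()
  fm <- build_feature_matrix(feats)
  res <- classify_cells(fm, seed = 42)
  expect_gte(mean(res$label == feats$cell_class), 0.9)
  expect_gt(attr(res, "mean_silhouette"), 0.5)
  expect_true(attr(res, "validated"))
  meds <- attr(res, "cluster_medians")
  fs_cluster <- unique(res$cluster[res$label == "FS"])
  expect_equal(which.min(meds), fs_cluster)
})

test_that("label assignment ignores cluster index permutations and applies the tie rule", {
  feats <- small_cohort_features()
  fm <- build_feature_matrix(feats)
  emb <- embed_cells(fm, seed = 42)
  cl <- cluster_cells(emb, k = 2, seed = 42)
  lab <- assign_labels(cl, fm)
  swapped <- cl
  swapped$cluster <- 3L - cl$cluster
  attr(swapped, "k") <- attr(cl, "k")
  lab2 <- assign_labels(swapped, fm)
  expect_identical(lab$label, lab2$label)

  # equal half-width medians: larger upstroke wins FS
  f <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                      ap_halfwidth = c(0.3, 0.3, 0.3, 0.3),
                      max_upstroke = c(850, 850, 460, 460),
                      x = c(0, 0.1, 0.9, 1))
  fm2 <- make_fm(cbind(x1 = f$x, x2 = f$x), ids = f$cell_id)
  fm2$raw$ap_halfwidth <- f$ap_halfwidth
  fm2$raw$max_upstroke <- f$max_upstroke
  cl2 <- structure(tibble::tibble(cell_id = f$cell_id,
                                  umap1 = c(0, 0.1, 5, 5.1),
                                  umap2 = 0, cluster = c(1L, 1L, 2L, 2L),
                                  silhouette = 1),
                   class = c("cluster_result", "tbl_df", "tbl", "data.frame"),
                   k = 2, mean_silhouette = 1)
  lab3 <- assign_labels(cl2, fm2)
  expect_equal(unique(lab3$label[lab3$cluster == 1L]), "FS")
})

test_that("group comparison handles identical, disjoint and tiny groups", {
  x <- c(1, 2, 3, 4, 5)
  f <- tibble::tibble(cell_id = sprintf("c%d", 1:10),
                      ap_halfwidth = c(x, x))
  lab <- tibble::tibble(cell_id = f$cell_id,
                        label = rep(c("FS", "nonFS"), each = 5))
  cmp <- compare_groups(f, lab, which = "ap_halfwidth")
  expect_equal(cmp$p_value, 1, tolerance = 1e-9)

  # disjoint supports, n = 5 vs 5: exact two-sided p = 2 / choose(10, 5)
  f2 <- tibble::tibble(cell_id = f$cell_id,
                       ap_halfwidth = c(1:5, 11:15) + 0.1)
  cmp2 <- compare_groups(f2, lab, which = "ap_halfwidth")
  expect_equal(cmp2$p_value, 2 / choose(10, 5), tolerance = 1e-9)
  expect_equal(cmp2$p_value,
               mw_enumerate_p(f2$ap_halfwidth[1:5], f2$ap_halfwidth[6:10]),
               tolerance = 1e-9)

  f3 <- tibble::tibble(cell_id = c("a", "b", "c"), ap_halfwidth = c(1, 2, 3))
  lab3 <- tibble::tibble(cell_id = f3$cell_id,
                         label = c("FS", "nonFS", "nonFS"))
  cmp3 <- compare_groups(f3, lab3, which = "ap_halfwidth")
  expect_false(cmp3$available)
  expect_true(is.na(cmp3$p_value))
})

test_that("the Mann-Whitney implementation matches exact enumeration for small groups", {
  set.seed(99)
  for (nx in c(3, 5, 8)) {
    for (ny in c(3, 6, 8)) {
      x <- rnorm(nx); y <- rnorm(ny, 0.5)
      expect_equal(mann_whitney(x, y)$p_value, mw_enumerate_p(x, y),
                   tolerance = 1e-9,
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("simulated FS vs non-FS half-widths differ significantly", {
  feats <- small_cohort_features()
  cmp <- compare_groups(feats, feats$cell_class, which = "ap_halfwidth")
  expect_lt(cmp$p_value, 0.05)
})
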