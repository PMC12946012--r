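#' Embed the scaled feature matrix in two dimensions with UMAP
#'
#' Uses the hyperparameters established for this kind of dataset density:
#' 4 neighbors, minimum distance 0.2, Euclidean metric. Fully reproducible
#' given the seed (single-threaded stochastic gradient descent).
#'
#' The layout optimizer runs with a conservative learning rate: with only 4
#' neighbors the fuzzy graph of a small cohort is sparse, and aggressive
#' stochastic gradient steps can tear a weakly connected cell group into
#' separate islands, which the downstream 2-means partition would then cut
#' instead of the class boundary. A small learning rate preserves the
#' global arrangement of the spectral initialization while still resolving
#' local structure.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param seed integer seed for the stochastic embedding.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param learning_rate SGD learning rate of the layout optimization.
#' @return A tibble of class `umap_embedding` with `cell_id`, `umap1`,
#'   `umap2`; hyperparameters and seed stored as attributes.
#' @export
embed_cells <- function(fm, seed = 42, n_neighbors = 4, min_dist = 0.2,
                        learning_rate = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- as.matrix(fm$scaled[, -1])
  if (nrow(x) < n_neighbors + 1)
    stop(sprintf(paste("%d cells is too few for %d neighbors;",
                       "reduce n_neighbors to at most %d"),
                 nrow(x), n_neighbors, nrow(x) - 1), call. = FALSE)
  set.seed(as.integer(seed))
  coords <- uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                       metric = "euclidean", n_threads = 1,
                       n_sgd_threads = 1, learning_rate = learning_rate,
                       verbose = FALSE)
  out <- tibble::tibble(cell_id = fm$scaled$cell_id,
                        umap1 = coords[, 1], umap2 = coords[, 2])
  structure(out, class = c("umap_embedding", class(out)),
            seed = seed, n_neighbors = n_neighbors, min_dist = min_dist)
}

#' Cluster the 2-D embedding with k-means
#'
#' k-means with multiple restarts on the UMAP coordinates, plus silhouette
#' validation on the same coordinates.
#'
#' @param embedding an [embed_cells()] result.
#' @param k number of clusters (2 a priori for the FS / non-FS split).
#' @param seed integer seed for the restarts.
#' @param nstart k-means restarts.
#' @return A tibble of class `cluster_result`: `cell_id`, `umap1`, `umap2`,
#'   `cluster`, `silhouette`; attributes `mean_silhouette`, `k`, `seed`,
#'   `centers`, `tot_withinss`.
#' @export
cluster_cells <- function(embedding, k = 2, seed = 42, nstart = 25) {
  coords <- as.matrix(embedding[, c("umap1", "umap2")])
  if (nrow(coords) < k) stop("fewer points than clusters", call. = FALSE)
  set.seed(as.integer(seed))
  km <- if (nrow(coords) == k) {
    list(cluster = seq_len(k), centers = coords, tot.withinss = 0)
  } else kmeans(coords, centers = k, nstart = nstart)
  sil <- if (k >= 2 && nrow(coords) > k) {
    s <- cluster::silhouette(km$cluster, stats::dist(coords))
    s[, "sil_width"]
  } else rep(NA_real_, nrow(coords))
  out <- tibble::tibble(cell_id = embedding$cell_id,
                        umap1 = coords[, 1], umap2 = coords[, 2],
                        cluster = km$cluster, silhouette = sil)
  structure(out, class = c("cluster_result", class(out)),
            mean_silhouette = mean(sil), k = k, seed = seed,
            centers = km$centers, tot_withinss = km$tot.withinss)
}

#' Assign FS / non-FS labels to clusters
#'
#' The cluster with the smaller median raw AP half-width is labelled FS;
#' ties are broken by the larger median maximal upstroke. Labels are
#' invariant to permutations of the cluster indices.
#'
#' @param result a [cluster_cells()] result (k = 2).
#' @param fm the [build_feature_matrix()] the clustering is based on (raw
#'   half-widths are used).
#' @return The result tibble with a `label` column (`"FS"` / `"nonFS"`),
#'   class `interneuron_classification`; cluster half-width medians stored
#'   in attribute `cluster_medians`.
#' @export
assign_labels <- function(result, fm) {
  stopifnot(inherits(result, "cluster_result"),
            inherits(fm, "feature_matrix"))
  if (attr(result, "k") != 2)
    stop("FS / non-FS labelling requires exactly 2 clusters", call. = FALSE)
  hw <- fm$raw$ap_halfwidth[match(result$cell_id, fm$raw$cell_id)]
  up <- fm$raw$max_upstroke[match(result$cell_id, fm$raw$cell_id)]
  meds <- vapply(1:2, function(cl) {
    v <- hw[result$cluster == cl]
    if (all(is.na(v)))
      stop("cluster ", cl, " has no AP half-width values", call. = FALSE)
    median(v, na.rm = TRUE)
  }, 1)
  fs_cluster <- if (meds[1] == meds[2]) {
    ups <- vapply(1:2, function(cl)
      median(up[result$cluster == cl], na.rm = TRUE), 1)
    which.max(ups)
  } else which.min(meds)
  out <- dplyr::mutate(result,
                       label = ifelse(.data$cluster == fs_cluster,
                                      "FS", "nonFS"))
  attrs <- attributes(result)
  for (a in c("mean_silhouette", "k", "seed", "centers", "tot_withinss"))
    attr(out, a) <- attrs[[a]]
  attr(out, "cluster_medians") <- meds
  class(out) <- c("interneuron_classification",
                  setdiff(class(out), "cluster_result"))
  out
}

#' Classify interneurons from the feature matrix
#'
#' UMAP embedding, k-means (k = 2), silhouette validation and FS / non-FS
#' labelling in one call. A mean silhouette below `silhouette_flag` marks
#' the partition as unvalidated (`validated` attribute), without changing
#' the labels.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param seed seed used for both the embedding and the clustering.
#' @param silhouette_flag minimum mean silhouette for a validated partition.
#' @param diagnostics if `TRUE`, also computes mean silhouettes for
#'   k = 2..5 (attribute `silhouette_by_k`), for reporting only.
#' @return An `interneuron_classification` tibble; see [assign_labels()].
#' @examples
#' \donttest{
#' coh <- simulate_step_cohort(10, seed = 1)
#' fm <- build_feature_matrix(extract_cohort_features(coh))
#' classify_cells(fm, seed = 42)
#' }
#' @export
classify_cells <- function(fm, seed = 42, silhouette_flag = 0.25,
                           diagnostics = FALSE) {
  emb <- embed_cells(fm, seed = seed)
  cl <- cluster_cells(emb, k = 2, seed = seed)
  out <- assign_labels(cl, fm)
  attr(out, "validated") <- isTRUE(attr(out, "mean_silhouette") >=
                                     silhouette_flag)
  if (diagnostics) {
    ks <- 2:min(5, nrow(emb) - 1)
    attr(out, "silhouette_by_k") <- setNames(vapply(ks, function(k)
      attr(cluster_cells(emb, k = k, seed = seed), "mean_silhouette"), 1),
      paste0("k", ks))
  }
  out
}

#' Per-feature FS vs non-FS group comparison
#'
#' Group mean and SD per label plus a two-sided Mann-Whitney p-value for
#' each requested feature (the core feature panel by default). Groups with
#' fewer than 2 cells are flagged unavailable.
#'
#' @param features raw feature tibble (e.g. from
#'   [extract_cohort_features()], or `fm$raw`).
#' @param labels tibble with `cell_id` and `label` (e.g. a
#'   classification result), or a character vector aligned with `features`.
#' @param which character vector of feature columns to compare.
#' @return A tibble: `feature`, per-group `n`/`mean`/`sd`, `p_value`,
#'   `available`.
#' @export
compare_groups <- function(features, labels,
                           which = .mandatory_features) {
  lab <- if (is.character(labels)) labels
         else labels$label[match(features$cell_id, labels$cell_id)]
  stopifnot(length(lab) == nrow(features))
  groups <- sort(unique(lab))
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)
  purrr::map(which, function(f) {
    x <- features[[f]][lab == groups[1]]
    y <- features[[f]][lab == groups[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    ok <- length(x) >= 2 && length(y) >= 2
    tibble::tibble(
      feature = f,
      group1 = groups[1], n1 = length(x), mean1 = mean(x), sd1 = sd(x),
      group2 = groups[2], n2 = length(y), mean2 = mean(y), sd2 = sd(y),
      p_value = if (ok) mann_whitney(x, y)$p_value else NA_real_,
      available = ok)
  }) |> purrr::list_rbind()
}
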