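#' @exportS3Method generics::tidy
tidy.interneuron_classification <- function(x, ...) {
  tibble::as_tibble(x)[, c("cell_id", "cluster", "label", "silhouette",
                           "umap1", "umap2")]
}

#' @exportS3Method generics::glance
glance.interneuron_classification <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x),
                 n_fs = sum(x$label == "FS"),
                 n_nonfs = sum(x$label == "nonFS"),
                 mean_silhouette = attr(x, "mean_silhouette"),
                 validated = isTRUE(attr(x, "validated")),
                 seed = attr(x, "seed"))
}

#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("cell_id", "cluster", "silhouette",
                           "umap1", "umap2")]
}

#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"),
                 mean_silhouette = attr(x, "mean_silhouette"),
                 tot_withinss = attr(x, "tot_withinss"),
                 seed = attr(x, "seed"))
}

#' @exportS3Method generics::tidy
tidy.feature_matrix <- function(x, ...) {
  tidyr::pivot_longer(x$raw, -"cell_id", names_to = "feature",
                      values_to = "value") |>
    dplyr::left_join(
      tidyr::pivot_longer(x$scaled, -"cell_id", names_to = "feature",
                          values_to = "scaled"),
      by = c("cell_id", "feature"))
}

#' @exportS3Method generics::glance
glance.feature_matrix <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$raw),
                 n_features = ncol(x$raw) - 1L,
                 n_constant = sum(x$bounds$constant),
                 n_imputed = sum(x$flags$reason == "imputed_median"))
}

#' @exportS3Method generics::glance
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$classification),
    mean_silhouette = attr(x$classification, "mean_silhouette"),
    n_connections = nrow(x$connections),
    n_intrinsic = if (is.null(x$intrinsic$cells)) 0L
                  else nrow(x$intrinsic$cells),
    seed = x$config$seed)
}
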