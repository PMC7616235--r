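#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Clone-to-cluster assignment as a tibble
#' @param x a `traj_clusters` object.
#' @param ... unused.
#' @return Tibble with `clone_id` and `cluster`.
#' @exportS3Method generics::tidy
#' @export
tidy.traj_clusters <- function(x, ...) x$assignment

#' One-row summary of a clustering result
#' @param x a `traj_clusters` object.
#' @param ... unused.
#' @return Tibble: selected `K`, its mean silhouette, clone and outlier
#'   counts.
#' @exportS3Method generics::glance
#' @export
glance.traj_clusters <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    mean_silhouette = x$silhouette_by_k$mean_silhouette[
      x$silhouette_by_k$k == x$K],
    n_clones = nrow(x$assignment),
    n_outliers = length(x$excluded_outliers)
  )
}
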