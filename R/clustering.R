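.cluster_result <- function(assignment, centers, weights, cutoff, algorithm) {
  # order clusters by descending weighted population, ties by center index
  pops <- vapply(seq_along(centers),
                 function(k) sum(weights[assignment == k]), numeric(1))
  ord <- order(-pops, centers)
  relabel <- match(seq_along(centers), ord)
  structure(
    list(assignment = relabel[assignment], centers = centers[ord],
         populations = pops[ord], cutoff = cutoff, algorithm = algorithm,
         n_clusters = length(centers)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", x$algorithm, ", cutoff ", x$cutoff, " nm: ",
      x$n_clusters, " clusters\n", sep = "")
  top <- utils::head(x$populations, 8)
  cat("  top populations:", paste(sprintf("%.3f", top), collapse = " "), "\n")
  invisible(x)
}

#' GROMOS (Daura) conformational clustering
#'
#' Repeatedly takes the structure with the most neighbours within the RMSD
#' cutoff as a cluster center and removes it together with its neighbours,
#' until no structure remains. Neighbour counting uses plain frame counts
#' (or resampling multiplicities via `counts`), as in the original
#' algorithm; statistical weights enter only the reported populations.
#' Ties between candidate centers are broken by the lowest frame index,
#' making the partition deterministic. The neighbour criterion is strict
#' (`d < cutoff`).
#'
#' @param mat symmetric pairwise RMSD matrix (nm), e.g. from
#'   [rmsd_matrix()].
#' @param cutoff neighbour cutoff in nm.
#' @param weights optional per-frame weights for the populations
#'   (default uniform, or proportional to `counts` when given).
#' @param counts optional integer multiplicities per frame (bootstrap
#'   resamples); equivalent to clustering the matrix with each frame
#'   duplicated `counts[i]` times.
#' @return A `cluster_result`: per-frame `assignment` (cluster 1 has the
#'   largest weighted population), `centers` (frame indices),
#'   `populations` (sum to 1), `cutoff`, `algorithm`.
#' @export
gromos_cluster <- function(mat, cutoff = 0.15, weights = NULL,
                           counts = NULL) {
  n <- nrow(mat)
  if (is.null(n) || n == 0) stop("empty RMSD matrix")
  stopifnot(cutoff > 0)
  counts <- counts %||% rep(1, n)
  w <- if (is.null(weights)) counts / sum(counts) else .as_weights(weights, n)
  adj <- mat < cutoff            # includes self (diagonal is 0)
  active <- rep(TRUE, n)
  assignment <- integer(n)
  centers <- integer(0)
  k <- 0
  while (any(active)) {
    nb <- as.vector(adj[, active, drop = FALSE] %*% counts[active])
    nb[!active] <- -1
    center <- which.max(nb)      # ties -> lowest index
    members <- which(active & adj[, center])
    k <- k + 1
    assignment[members] <- k
    centers[k] <- center
    active[members] <- FALSE
  }
  .cluster_result(assignment, centers, w, cutoff, "gromos")
}

#' Agglomerative average-linkage clustering of conformations
#'
#' Builds the average-linkage dendrogram of the RMSD matrix
#' (`stats::hclust`) and cuts it at height `cutoff`. The center of each
#' cluster is the member minimising the summed intra-cluster distance.
#'
#' @inheritParams gromos_cluster
#' @return A `cluster_result`.
#' @export
hierarchical_cluster <- function(mat, cutoff, weights = NULL) {
  n <- nrow(mat)
  if (is.null(n) || n == 0) stop("empty RMSD matrix")
  stopifnot(cutoff > 0)
  w <- .as_weights(weights, n)
  if (n == 1) {
    return(.cluster_result(1L, 1L, w, cutoff, "hierarchical"))
  }
  hc <- hclust(as.dist(mat), method = "average")
  assignment <- cutree(hc, h = cutoff)
  centers <- vapply(seq_len(max(assignment)), function(k) {
    members <- which(assignment == k)
    members[which.min(rowSums(mat[members, members, drop = FALSE]))]
  }, integer(1))
  .cluster_result(as.integer(assignment), centers, w, cutoff,
                  "hierarchical")
}

#' Number of clusters as a function of the RMSD cutoff
#'
#' @param mat pairwise RMSD matrix.
#' @param cutoffs positive cutoffs in nm (sorted ascending).
#' @param algorithm `"gromos"` or `"hierarchical"`.
#' @param weights optional weights (populations only).
#' @return data.frame with columns `cutoff` and `n_clusters`.
#' @export
cluster_count_curve <- function(mat, cutoffs, algorithm = c("gromos",
                                "hierarchical"), weights = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(all(cutoffs > 0), !is.unsorted(cutoffs))
  f <- if (algorithm == "gromos") gromos_cluster else hierarchical_cluster
  data.frame(
    cutoff = cutoffs,
    n_clusters = vapply(cutoffs, function(cc) f(mat, cc, weights)$n_clusters,
                        integer(1))
  )
}

#' Write a clustering result as an assignment table plus JSON summary
#' @param result a `cluster_result`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return the two paths, invisibly.
#' @export
write_cluster_result <- function(result, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  write.table(data.frame(frame = seq_along(result$assignment),
                         cluster = result$assignment),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(algorithm = result$algorithm, cutoff = result$cutoff,
         n_clusters = result$n_clusters, populations = result$populations,
         centers = result$centers),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv, js))
}
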