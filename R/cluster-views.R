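## Clustering of modules and indicators by the similarity of their
## activation patterns, reduced (cluster-averaged) activation maps, and
## root-mean-square distances between indicator clusters.

#' Cluster modules or indicators by activation pattern
#'
#' Average-linkage hierarchical clustering on `1 - r` Pearson distances
#' between the activation vectors, cut either at a correlation height
#' (`cor_cutoff`, so items in one cluster correlate at least that much at
#' the merge level) or into a requested number of clusters `k`.
#' Constant vectors have no defined correlation; they are assigned the
#' maximal distance 2 to everything and end up in singleton clusters.
#'
#' @param profile an [activation_matrix()].
#' @param axis `"modules"` (rows) or `"indicators"` (columns).
#' @param cor_cutoff minimum correlation within a cluster (tree cut at
#'   height `1 - cor_cutoff`), default 0.90.  Ignored when `k` is given.
#' @param k optional number of clusters (overrides `cor_cutoff`).
#' @return Object of class `activation_clustering` with fields
#'   `assignments` (named integer vector), `hclust`, `axis`,
#'   `mean_intra_cor` (per-cluster mean pairwise correlation; `NA` for
#'   singletons).
#' @export
cluster_by_activation <- function(profile, axis = c("modules", "indicators"),
                                  cor_cutoff = 0.90, k = NULL) {
  axis <- match.arg(axis)
  vecs <- if (axis == "modules") unclass(profile) else t(unclass(profile))
  if (nrow(vecs) < 2) stop("need at least 2 items to cluster")
  sds <- apply(vecs, 1L, stats::sd)
  sds[is.na(sds)] <- 0
  if (any(sds == 0))
    warning("constant activation vector(s) assigned maximal distance: ",
            paste(rownames(vecs)[sds == 0], collapse = ", "))
  cm <- suppressWarnings(stats::cor(t(vecs)))
  cm[is.na(cm)] <- -1          # constant vectors: distance 1 - (-1) = 2
  diag(cm) <- 1
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  assignments <- if (is.null(k)) {
    stats::cutree(hc, h = 1 - cor_cutoff)
  } else {
    stats::cutree(hc, k = k)
  }
  mean_intra <- vapply(sort(unique(assignments)), function(cl) {
    items <- names(assignments)[assignments == cl]
    if (length(items) < 2) return(NA_real_)
    sub <- cm[items, items]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(mean_intra) <- sort(unique(assignments))
  structure(list(assignments = assignments, hclust = hc, axis = axis,
                 mean_intra_cor = mean_intra),
            class = "activation_clustering")
}

#' @export
print.activation_clustering <- function(x, ...) {
  cat(sprintf("activation_clustering of %d %s into %d clusters\n",
              length(x$assignments), x$axis, length(unique(x$assignments))))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Reduced activation map over module and indicator clusters
#'
#' Each entry is the mean activation over the modules of one module
#' cluster and the indicators of one indicator cluster.
#'
#' @param profile an [activation_matrix()].
#' @param module_clusters,indicator_clusters named integer vectors (or
#'   `activation_clustering` objects) assigning profile rows / columns to
#'   clusters.
#' @return Module-cluster x indicator-cluster numeric matrix.
#' @export
reduced_activation <- function(profile, module_clusters, indicator_clusters) {
  mc <- cluster_vector(module_clusters, rownames(profile), "module")
  ic <- cluster_vector(indicator_clusters, colnames(profile), "indicator")
  mcl <- sort(unique(mc)); icl <- sort(unique(ic))
  out <- matrix(NA_real_, length(mcl), length(icl),
                dimnames = list(paste0("MC", mcl), paste0("IC", icl)))
  for (a in seq_along(mcl)) for (b in seq_along(icl)) {
    rows <- names(mc)[mc == mcl[a]]
    cols <- names(ic)[ic == icl[b]]
    out[a, b] <- mean(profile[rows, cols])
  }
  out
}

cluster_vector <- function(x, expected_ids, what) {
  if (inherits(x, "activation_clustering")) x <- x$assignments
  if (is.null(names(x))) stop(sprintf("%s clusters must be named", what))
  if (!setequal(names(x), expected_ids))
    stop(sprintf("%s cluster assignment does not cover the profile axis",
                 what))
  if (!length(x)) stop(sprintf("empty %s clustering", what))
  x
}

#' Root-mean-square distances between indicator clusters
#'
#' For every pair of indicator-cluster columns of a reduced activation
#' map: the square root of the mean squared difference over module
#' clusters.
#'
#' @param map a [reduced_activation()] matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
rms_cluster_distance <- function(map) {
  if (ncol(map) < 2) stop("need at least 2 indicator clusters")
  n <- ncol(map)
  d <- matrix(0, n, n, dimnames = list(colnames(map), colnames(map)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- sqrt(mean((map[, i] - map[, j])^2))
  }
  d
}

#' Correlation between injury indicators and activity classes
#'
#' Pearson correlation between each injury indicator's module-activation
#' vector and each structure-activity class's vector (both are columns of
#' the same profile).  Constant vectors yield `NA`.
#'
#' @param profile an [activation_matrix()] whose columns include both id
#'   sets.
#' @param indicator_ids,class_ids column ids of the profile.
#' @return indicator x class correlation matrix.
#' @export
indicator_class_correlation <- function(profile, indicator_ids, class_ids) {
  missing_ids <- setdiff(c(indicator_ids, class_ids), colnames(profile))
  if (length(missing_ids))
    stop("ids absent from profile: ", paste(missing_ids, collapse = ", "))
  suppressWarnings(
    stats::cor(unclass(profile)[, indicator_ids, drop = FALSE],
               unclass(profile)[, class_ids, drop = FALSE]))
}
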