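## Preprocessing: replicate-averaged log ratios, gene-level filters, and the
## global Z-score transform that every downstream stage consumes.
##
## Matrices are plain numeric matrices with gene ids as rownames and
## condition ids as colnames; the Z-score matrix additionally carries the
## attribute `zscore = TRUE` set by zscore_transform().

#' Construct an expression set
#'
#' Bundles a gene x sample matrix of log2 expression values with a sample map
#' assigning each sample (column) to a condition and a treatment/control role.
#'
#' @param values numeric gene x sample matrix of log2 expression; rownames are
#'   gene ids, colnames are sample ids.
#' @param sample_map data.frame with columns `sample_id`, `condition_id`,
#'   `role` (`"treatment"` or `"control"`); one row per column of `values`.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(values, sample_map) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values)) stop("expression values contain missing entries")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique gene ids as rownames")
  req <- c("sample_id", "condition_id", "role")
  if (!all(req %in% names(sample_map)))
    stop("`sample_map` needs columns sample_id, condition_id, role")
  sample_map <- as.data.frame(sample_map, stringsAsFactors = FALSE)
  if (!setequal(colnames(values), sample_map$sample_id))
    stop("sample ids in `values` and `sample_map` disagree")
  if (!all(sample_map$role %in% c("treatment", "control")))
    stop("`role` must be 'treatment' or 'control'")
  sample_map <- sample_map[match(colnames(values), sample_map$sample_id), ]
  ## every condition needs both roles
  tab <- table(factor(sample_map$condition_id),
               factor(sample_map$role, levels = c("treatment", "control")))
  bad <- rownames(tab)[tab[, "treatment"] == 0 | tab[, "control"] == 0]
  if (length(bad))
    stop(sprintf("condition '%s' lacks treatment or control samples", bad[1]))
  structure(list(values = values, sample_map = sample_map),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples over %d conditions\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_map$condition_id))))
  invisible(x)
}

#' Compute per-condition log ratios
#'
#' For each gene and condition, the log ratio is the mean log2 expression over
#' treatment replicates minus the mean over control replicates.
#'
#' @param expr an [expression_set()].
#' @return Numeric gene x condition log-ratio matrix.
#' @export
compute_log_ratios <- function(expr) {
  stopifnot(inherits(expr, "expression_set"))
  map <- expr$sample_map
  conds <- unique(map$condition_id)
  lr <- matrix(0, nrow(expr$values), length(conds),
               dimnames = list(rownames(expr$values), conds))
  for (cond in conds) {
    trt <- map$sample_id[map$condition_id == cond & map$role == "treatment"]
    ctl <- map$sample_id[map$condition_id == cond & map$role == "control"]
    tm <- rowMeans(expr$values[, trt, drop = FALSE])
    cm <- rowMeans(expr$values[, ctl, drop = FALSE])
    lr[, cond] <- tm - cm
  }
  lr
}

#' Drop the low-variance half of the genes
#'
#' Retains the ceiling(n/2) genes with the highest row variance across
#' conditions, preserving input order of the retained genes.
#'
#' @param m gene x condition log-ratio matrix.
#' @return The filtered matrix.
#' @export
filter_low_variance <- function(m) {
  check_named_matrix(m, "m")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 genes and 2 conditions")
  v <- apply(m, 1L, stats::var)
  keep_n <- ceiling(nrow(m) / 2)
  if (length(unique(v)) == 1L) {
    warning("all gene variances tied; retaining the first ",
            keep_n, " genes by input order")
    return(m[seq_len(keep_n), , drop = FALSE])
  }
  ## highest-variance genes, ties resolved toward earlier rows
  ord <- order(v, decreasing = TRUE)
  keep <- sort(ord[seq_len(keep_n)])
  m[keep, , drop = FALSE]
}

#' Filter genes by present-call fraction
#'
#' Retains genes whose fraction of conditions with an all-replicate
#' "Present" call is at least `min_frac` (boundary inclusive).
#'
#' @param m gene x condition log-ratio matrix.
#' @param mask logical (or 0/1) matrix of the same shape and dimnames;
#'   `TRUE` means every replicate of that condition had a Present call.
#' @param min_frac minimum fraction of present conditions, default 0.25.
#' @return The filtered matrix.
#' @export
filter_present_calls <- function(m, mask, min_frac = 0.25) {
  check_named_matrix(m, "m")
  if (!identical(dim(m), dim(mask)))
    stop("mask shape does not match matrix")
  if (!identical(rownames(m), rownames(mask))) {
    bad <- rownames(mask)[rownames(m) != rownames(mask)][1]
    stop(sprintf("mask gene ids do not match matrix (first mismatch: '%s')",
                 bad))
  }
  if (!identical(colnames(m), colnames(mask))) {
    bad <- colnames(mask)[colnames(m) != colnames(mask)][1]
    stop(sprintf("mask condition ids do not match matrix (first mismatch: '%s')",
                 bad))
  }
  frac <- rowMeans(mask != 0)
  m[frac >= min_frac, , drop = FALSE]
}

#' Global Z-score transform of a log-ratio matrix
#'
#' Standardizes every entry against the grand mean and grand standard
#' deviation taken over all matrix entries (population convention, divide by
#' N), so the output has global mean 0 and global standard deviation 1.
#'
#' @param m gene x condition log-ratio matrix.
#' @return The Z-score matrix (attribute `zscore = TRUE`).
#' @export
zscore_transform <- function(m) {
  check_named_matrix(m, "m")
  if (length(m) < 2L) stop("matrix must have more than one entry")
  mu <- mean(m)
  sigma <- pop_sd(m)
  if (sigma == 0) stop("degenerate matrix: zero global standard deviation")
  z <- (m - mu) / sigma
  attr(z, "zscore") <- TRUE
  z
}

#' Preprocess a log-ratio matrix
#'
#' Applies the present-call and low-variance filters (order configurable)
#' followed by the global Z-score transform.
#'
#' @param m gene x condition log-ratio matrix.
#' @param mask optional present-call mask; when `NULL` the present-call
#'   filter is skipped.
#' @param order filter order, `"present_first"` (default) or
#'   `"variance_first"`.
#' @param min_frac present-call fraction threshold passed on.
#' @return The filtered Z-score matrix.
#' @export
preprocess_matrix <- function(m, mask = NULL,
                              order = c("present_first", "variance_first"),
                              min_frac = 0.25) {
  order <- match.arg(order)
  if (!is.null(mask) && order == "present_first") {
    m <- filter_present_calls(m, mask, min_frac)
  }
  m <- filter_low_variance(m)
  if (!is.null(mask) && order == "variance_first") {
    mask <- mask[rownames(m), colnames(m), drop = FALSE]
    m <- filter_present_calls(m, mask, min_frac)
  }
  zscore_transform(m)
}
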