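## Module evaluation against binary injury indicators: activation scores,
## specificity, intra-module gene correlation, per-gene activation, and
## center-gene selection.  Indicator labels are a condition x indicator
## matrix with entries +1 (abnormal finding recorded) or 0; indicators
## without a positive condition are dropped from all averages.

#' Activation of a single gene for an injury indicator
#'
#' The mean Z-score of the gene over the indicator's positive conditions.
#'
#' @param gene gene id.
#' @param z gene x condition Z-score matrix.
#' @param labels condition x indicator 0/1 matrix.
#' @param indicator indicator id.
#' @return Scalar activation.
#' @export
gene_activation <- function(gene, z, labels, indicator) {
  pos <- intersect(positive_conditions(labels, indicator), colnames(z))
  if (!length(pos))
    stop(sprintf("indicator '%s' has no positive conditions", indicator))
  if (!gene %in% rownames(z)) stop(sprintf("unknown gene '%s'", gene))
  mean(z[gene, pos])
}

#' Activation of a module for an injury indicator
#'
#' The mean Z-score over all member genes and all positive conditions of
#' the indicator; equivalently the mean of the member genes'
#' [gene_activation()] values.  By convention, absolute activations above
#' 1.5 mark a significant module-indicator association.
#'
#' @param module a `coexpression_module`, [gene_set()], or character vector
#'   of gene ids.
#' @param z gene x condition Z-score matrix.
#' @param labels condition x indicator 0/1 matrix.
#' @param indicator indicator id.
#' @return Scalar activation.
#' @export
module_activation <- function(module, z, labels, indicator) {
  genes <- module_genes(module)
  if (!all(genes %in% rownames(z)))
    stop("module contains genes absent from the matrix")
  pos <- intersect(positive_conditions(labels, indicator), colnames(z))
  if (!length(pos))
    stop(sprintf("indicator '%s' has no positive conditions", indicator))
  mean(z[genes, pos, drop = FALSE])
}

module_genes <- function(module) {
  if (inherits(module, "coexpression_module")) return(module$genes)
  if (inherits(module, "gene_set")) return(module$genes)
  as.character(module)
}

module_label <- function(module, fallback) {
  if (inherits(module, "coexpression_module")) return(module$module_id)
  if (inherits(module, "gene_set")) return(module$name)
  fallback
}

#' Activation profile of many modules against all indicators
#'
#' @param modules list of modules (or an `isa_result`).
#' @param z gene x condition Z-score matrix.
#' @param labels condition x indicator 0/1 matrix.
#' @param a_thresh significance convention carried as an attribute,
#'   default 1.5.
#' @return Module x indicator matrix of activations, class
#'   `activation_profile`.  Indicators with no positive condition are
#'   omitted with a warning.
#' @export
activation_matrix <- function(modules, z, labels, a_thresh = 1.5) {
  if (inherits(modules, "isa_result")) modules <- modules$modules
  if (!length(modules)) stop("need at least one module")
  inds <- scoreable_indicators(labels)
  dropped <- setdiff(colnames(labels), inds)
  if (length(dropped))
    warning("indicator(s) without positive conditions omitted: ",
            paste(dropped, collapse = ", "))
  if (!length(inds)) stop("no scoreable indicator")
  ids <- vapply(seq_along(modules),
                function(i) module_label(modules[[i]], sprintf("m%03d", i)),
                character(1))
  A <- matrix(NA_real_, length(modules), length(inds),
              dimnames = list(ids, inds))
  for (i in seq_along(modules)) for (p in inds) {
    A[i, p] <- module_activation(modules[[i]], z, labels, p)
  }
  structure(A, a_thresh = a_thresh, class = c("activation_profile", "matrix"))
}

#' @export
print.activation_profile <- function(x, ...) {
  cat(sprintf("activation_profile: %d modules x %d indicators (|A| > %g deemed significant)\n",
              nrow(x), ncol(x), attr(x, "a_thresh")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], digits = 3)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more modules\n", nrow(x) - 6L))
  invisible(x)
}

#' Specificity of one module to one indicator
#'
#' The mean absolute difference between the module's activation for the
#' indicator and its activation for every other indicator.
#'
#' @param profile an [activation_matrix()].
#' @param module module id (row).
#' @param indicator indicator id (column).
#' @return Scalar specificity (>= 0).
#' @export
module_specificity <- function(profile, module, indicator) {
  if (ncol(profile) < 2) stop("need at least 2 indicators")
  a <- profile[module, ]
  mean(abs(a[indicator] - a[setdiff(colnames(profile), indicator)]))
}

#' Global specificity and intra-module correlation report
#'
#' Per-(module, indicator) specificity `S`, per-indicator maxima `S_max`,
#' and the global specificity `S_plus` (mean of the per-indicator maxima).
#' When `z`, `labels`, and `modules` are supplied the analogous
#' intra-module correlation quantities `R`, `R_max`, `R_plus` are included.
#'
#' @param profile an [activation_matrix()].
#' @param modules optional list of modules matching the profile rows.
#' @param z optional Z-score matrix (required for the correlation part).
#' @param labels optional label matrix (required for the correlation part).
#' @return Object of class `specificity_report` with fields `S` (matrix),
#'   `S_max`, `S_plus`, and when computable `R`, `R_max`, `R_plus`.
#' @export
global_specificity <- function(profile, modules = NULL, z = NULL,
                               labels = NULL) {
  if (ncol(profile) < 2) stop("need at least 2 indicators")
  S <- profile
  for (m in rownames(profile)) for (p in colnames(profile)) {
    S[m, p] <- module_specificity(profile, m, p)
  }
  S <- unclass(S)
  S_max <- apply(S, 2L, max)
  out <- list(S = S, S_max = S_max, S_plus = mean(S_max))
  if (!is.null(modules) && !is.null(z) && !is.null(labels)) {
    if (inherits(modules, "isa_result")) modules <- modules$modules
    R <- matrix(NA_real_, nrow(profile), ncol(profile),
                dimnames = dimnames(profile))
    for (i in seq_along(modules)) for (p in colnames(profile)) {
      R[i, p] <- intra_module_correlation(modules[[i]], z, labels, p)
    }
    R_max <- apply(R, 2L, max, na.rm = TRUE)
    out$R <- R
    out$R_max <- R_max
    out$R_plus <- mean(R_max[is.finite(R_max)])
  }
  structure(out, class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("specificity_report: S+ = %.3f", x$S_plus))
  if (!is.null(x$R_plus)) cat(sprintf(", R+ = %.3f", x$R_plus))
  cat("\n")
  invisible(x)
}

#' Intra-module gene correlation for an indicator
#'
#' The mean Pearson correlation over unordered member-gene pairs
#' (self-pairs excluded), computed across the indicator's positive
#' conditions.  Pairs involving a zero-variance gene are skipped; `NA` is
#' returned when no pair is computable.
#'
#' @inheritParams module_activation
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
intra_module_correlation <- function(module, z, labels, indicator) {
  genes <- module_genes(module)
  if (length(genes) < 2) stop("module needs at least 2 genes")
  pos <- intersect(positive_conditions(labels, indicator), colnames(z))
  if (length(pos) < 2) return(NA_real_)
  sub <- z[genes, pos, drop = FALSE]
  keep <- apply(sub, 1L, stats::sd) > 0
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < 2) return(NA_real_)
  cm <- stats::cor(t(sub))
  mean(cm[upper.tri(cm)])
}

#' Center gene of a module for an indicator
#'
#' The member gene with the largest Pearson-correlation sum to its fellow
#' members (self term included as 1), subject to the reselection rule: a
#' candidate whose mean Z over positive conditions falls below the module
#' mean is discarded and the next-ranked candidate is tried.  Ties are
#' broken by gene-id order.
#'
#' @inheritParams module_activation
#' @param span conditions over which the correlations' means and standard
#'   deviations are computed: `"positive"` (default, the indicator's
#'   positive conditions) or `"all"` (all conditions, with the correlation
#'   sum still accumulated over positive conditions).
#' @return Object of class `center_gene_result` with fields `module_id`,
#'   `indicator`, `gene`, `corr_sum`, `depth` (0 = first-ranked candidate
#'   accepted).
#' @export
center_gene <- function(module, z, labels, indicator,
                        span = c("positive", "all")) {
  span <- match.arg(span)
  genes <- module_genes(module)
  if (length(genes) < 2) stop("module needs at least 2 genes")
  pos <- intersect(positive_conditions(labels, indicator), colnames(z))
  if (length(pos) < 2)
    stop(sprintf("indicator '%s' has fewer than 2 positive conditions",
                 indicator))
  sub_pos <- z[genes, pos, drop = FALSE]
  if (span == "positive") {
    cm <- suppressWarnings(stats::cor(t(sub_pos)))
  } else {
    ## standardize each gene over all conditions, then accumulate the
    ## correlation sum over the positive conditions only
    full <- z[genes, , drop = FALSE]
    mu <- rowMeans(full)
    sigma <- apply(full, 1L, pop_sd)
    std <- (sub_pos - mu) / sigma
    cm <- tcrossprod(std) / length(pos)
  }
  diag(cm) <- 1
  cm[is.na(cm)] <- 0
  corr_sum <- rowSums(cm)
  gene_means <- rowMeans(sub_pos)
  module_mean <- mean(gene_means)
  ord <- order(-corr_sum, genes)
  for (depth in seq_along(ord) - 1L) {
    g <- ord[depth + 1L]
    if (gene_means[g] >= module_mean) {
      return(structure(list(module_id = module_label(module, "module"),
                            indicator = indicator,
                            gene = genes[g],
                            corr_sum = unname(corr_sum[g]),
                            depth = depth),
                       class = "center_gene_result"))
    }
  }
  stop(sprintf("module '%s' is sign-incoherent for indicator '%s': no gene reaches the module mean",
               module_label(module, "module"), indicator))
}

#' @export
print.center_gene_result <- function(x, ...) {
  cat(sprintf("center gene of %s for %s: %s (C = %.3f, reselection depth %d)\n",
              x$module_id, x$indicator, x$gene, x$corr_sum, x$depth))
  invisible(x)
}
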