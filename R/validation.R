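## External validation of signature panels: fold-change correlation
## between an internal and an external log-ratio matrix, and classical
## (Torgerson) multidimensional scaling of external conditions restricted
## to the panel genes.

#' Fold-change correlation of a signature panel across two datasets
#'
#' For each panel gene present in both matrices: the mean log ratio over
#' the named internal condition set versus the mean log ratio over the
#' external condition set; the report is the Pearson correlation over the
#' matched genes.
#'
#' @param panel a `signature_panel`, [gene_set()], or character vector of
#'   gene ids.
#' @param internal_lr,external_lr gene x condition log-ratio matrices.
#' @param internal_conditions,external_conditions condition ids defining
#'   the fold-change averages on each side (default: all columns).
#' @return Object of class `validation_report` with fields `panel_name`,
#'   `r`, `n_matched`, `fold_changes` (data.frame `gene_id`, `internal`,
#'   `external`), `unmatched` (gene ids absent from either matrix).
#' @export
signature_fc_correlation <- function(panel, internal_lr,
                                     external_lr,
                                     internal_conditions = colnames(internal_lr),
                                     external_conditions = colnames(external_lr)) {
  genes <- panel_gene_ids(panel)
  matched <- genes[genes %in% rownames(internal_lr) &
                   genes %in% rownames(external_lr)]
  unmatched <- setdiff(genes, matched)
  if (length(matched) < 3)
    stop(sprintf("only %d panel genes present in both matrices (need >= 3)",
                 length(matched)))
  fc_int <- rowMeans(internal_lr[matched, internal_conditions, drop = FALSE])
  fc_ext <- rowMeans(external_lr[matched, external_conditions, drop = FALSE])
  structure(list(panel_name = panel_label(panel),
                 r = stats::cor(fc_int, fc_ext),
                 n_matched = length(matched),
                 fold_changes = data.frame(gene_id = matched,
                                           internal = unname(fc_int),
                                           external = unname(fc_ext),
                                           stringsAsFactors = FALSE),
                 unmatched = unmatched),
            class = "validation_report")
}

panel_gene_ids <- function(panel) {
  if (inherits(panel, "signature_panel")) return(unique(panel$entries$gene_id))
  if (inherits(panel, "gene_set")) return(panel$genes)
  unique(as.character(panel))
}

panel_label <- function(panel) {
  if (inherits(panel, "signature_panel")) return(panel$name)
  if (inherits(panel, "gene_set")) return(panel$name)
  "panel"
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report for '%s': r = %.3f over %d matched genes (%d unmatched)\n",
              x$panel_name, x$r, x$n_matched, length(x$unmatched)))
  invisible(x)
}

#' Classical MDS of external conditions on a signature panel
#'
#' Torgerson scaling (double-centered squared Euclidean distances, top-2
#' eigenvectors scaled by the square root of their eigenvalues) of the
#' condition vectors restricted to the panel genes, with a silhouette
#' score of the supplied grouping on the embedding as the separation
#' measure.
#'
#' @param external_lr gene x condition log-ratio matrix.
#' @param panel a `signature_panel`, [gene_set()], or character vector.
#' @param group_labels named character/factor vector assigning each
#'   condition to a group (e.g. toxic / non-toxic).
#' @param average_by optional named vector mapping condition ids to a
#'   chemical; when given, replicate exposures are averaged per chemical
#'   before scaling.
#' @return Object of class `mds_projection` with fields `coordinates`
#'   (condition x dim matrix), `eigenvalues`, `silhouette` (mean
#'   silhouette width; `NA` with a single group), `groups`.
#' @export
mds_projection <- function(external_lr, panel, group_labels,
                           average_by = NULL) {
  genes <- intersect(panel_gene_ids(panel), rownames(external_lr))
  if (length(genes) < 2) stop("fewer than 2 panel genes present")
  sub <- external_lr[genes, , drop = FALSE]
  if (!is.null(average_by)) {
    chem_of <- average_by[colnames(sub)]
    chems <- unique(unname(chem_of))
    avg <- vapply(chems, function(ch) {
      rowMeans(sub[, chem_of == ch, drop = FALSE])
    }, numeric(nrow(sub)))
    rownames(avg) <- rownames(sub)
    group_labels <- vapply(chems, function(ch) {
      g <- unique(as.character(group_labels[colnames(sub)[chem_of == ch]]))
      if (length(g) != 1)
        stop(sprintf("group labels differ within chemical '%s'", ch))
      g
    }, character(1))
    sub <- avg
  }
  if (ncol(sub) < 3) stop("need at least 3 conditions")
  d <- stats::dist(t(sub))
  fit <- stats::cmdscale(d, k = min(2L, ncol(sub) - 1L), eig = TRUE)
  coords <- fit$points
  ## drop numerically null dimensions (eigenvalue ~ 0 relative to the top)
  ev <- fit$eig[seq_len(ncol(coords))]
  keep_dim <- ev > max(fit$eig) * 1e-8
  coords <- coords[, keep_dim, drop = FALSE]
  if (ncol(coords) < 2) {
    warning("fewer than 2 informative eigenvalues; embedding in ",
            ncol(coords), " dimension(s)")
  }
  groups <- as.factor(group_labels[rownames(coords)])
  sil <- NA_real_
  if (nlevels(droplevels(groups)) >= 2) {
    sw <- cluster::silhouette(as.integer(droplevels(groups)),
                              stats::dist(coords))
    sil <- mean(sw[, "sil_width"])
  }
  structure(list(coordinates = coords, eigenvalues = fit$eig,
                 silhouette = sil, groups = groups),
            class = "mds_projection")
}

#' @export
print.mds_projection <- function(x, ...) {
  cat(sprintf("mds_projection: %d conditions in %d dimension(s), silhouette = %.3f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$silhouette))
  invisible(x)
}

#' @export
plot.mds_projection <- function(x, ...) {
  co <- x$coordinates
  if (ncol(co) < 2) co <- cbind(co, 0)
  plot(co[, 1], co[, 2], pch = as.integer(x$groups),
       col = as.integer(x$groups),
       xlab = "MDS 1", ylab = "MDS 2", ...)
  graphics::legend("topright", legend = levels(x$groups),
                   pch = seq_len(nlevels(x$groups)),
                   col = seq_len(nlevels(x$groups)))
  invisible(x)
}
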