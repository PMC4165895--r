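## Signature-panel construction: per-module gene panels, per-indicator
## center-gene panels, and the general injury panel pooling center genes
## over all indicators.

new_panel <- function(name, entries) {
  structure(list(name = name, entries = entries), class = "signature_panel")
}

empty_panel_entries <- function() {
  data.frame(gene_id = character(0), source_module = character(0),
             indicator = character(0), activation = numeric(0),
             direction = character(0), center_gene = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.signature_panel <- function(x, ...) {
  cat(sprintf("signature_panel '%s': %d genes (%d entries)\n", x$name,
              length(unique(x$entries$gene_id)), nrow(x$entries)))
  if (nrow(x$entries)) print(utils::head(x$entries, 10), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.signature_panel <- function(x, ...) x$entries

#' Write a signature panel as annotated TSV
#' @param panel a `signature_panel`.
#' @param path file path.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Module-based gene signature
#'
#' Member genes whose absolute per-gene activation exceeds `a_thresh` for
#' at least one of the requested indicators, annotated per qualifying
#' indicator with the signed activation.
#'
#' @param module a `coexpression_module` or [gene_set()].
#' @param z gene x condition Z-score matrix.
#' @param labels condition x indicator 0/1 matrix.
#' @param indicators indicator ids to scan.
#' @param a_thresh per-gene activation threshold, default 1.5.
#' @return A `signature_panel` (possibly empty).
#' @export
module_signature <- function(module, z, labels, indicators, a_thresh = 1.5) {
  genes <- module_genes(module)
  rows <- list()
  for (g in genes) for (p in indicators) {
    a <- gene_activation(g, z, labels, p)
    if (abs(a) > a_thresh) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, source_module = module_label(module, "module"),
        indicator = p, activation = a,
        direction = if (a > 0) "up" else "down",
        center_gene = FALSE, stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else empty_panel_entries()
  new_panel(paste0("module_signature_", module_label(module, "module")),
            entries)
}

#' Indicator-based center-gene signature
#'
#' For every module whose absolute activation for the indicator exceeds
#' `a_thresh`, the module's center gene enters the panel with the module's
#' direction; a center gene shared by several modules collapses to one
#' entry listing all source modules.
#'
#' @param modules list of `coexpression_module` objects (or an
#'   `isa_result`).
#' @param profile an [activation_matrix()] covering the modules.
#' @param z gene x condition Z-score matrix.
#' @param labels condition x indicator 0/1 matrix.
#' @param indicator indicator id.
#' @param a_thresh module activation threshold, default 1.5.
#' @return A `signature_panel`; `source_module` lists recruiting modules
#'   separated by `","` after collapsing duplicates.
#' @export
indicator_signature <- function(modules, profile, z, labels, indicator,
                                a_thresh = 1.5) {
  if (inherits(modules, "isa_result")) modules <- modules$modules
  rows <- list()
  for (i in seq_along(modules)) {
    id <- module_label(modules[[i]], sprintf("m%03d", i))
    a <- profile[id, indicator]
    if (abs(a) <= a_thresh) next
    cg <- tryCatch(center_gene(modules[[i]], z, labels, indicator),
                   error = function(e) {
                     warning(sprintf("module '%s' skipped: %s", id,
                                     conditionMessage(e)))
                     NULL
                   })
    if (is.null(cg)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = cg$gene, source_module = id, indicator = indicator,
      activation = unname(a), direction = if (a > 0) "up" else "down",
      center_gene = TRUE, stringsAsFactors = FALSE)
  }
  entries <- if (length(rows)) do.call(rbind, rows) else empty_panel_entries()
  ## collapse duplicate center genes to one entry listing all modules
  if (nrow(entries)) {
    split_rows <- split(entries, entries$gene_id)
    entries <- do.call(rbind, lapply(split_rows, function(df) {
      out <- df[1, , drop = FALSE]
      out$source_module <- paste(sort(unique(df$source_module)),
                                 collapse = ",")
      out$activation <- mean(df$activation)
      out
    }))
    rownames(entries) <- NULL
  }
  new_panel(paste0("indicator_signature_", indicator), entries)
}

#' General injury signature
#'
#' Union over all scoreable indicators of the per-indicator center-gene
#' panels; each entry keeps the (module, indicator) pair that recruited
#' it, so a gene recruited several times appears once per recruitment.
#'
#' @inheritParams indicator_signature
#' @param per_module when `TRUE`, deduplicate to at most one entry per
#'   source module (any-indicator mode); default `FALSE` keeps every
#'   (module, indicator) recruitment.
#' @return A `signature_panel`.
#' @export
general_injury_signature <- function(modules, profile, z, labels,
                                     a_thresh = 1.5, per_module = FALSE) {
  inds <- intersect(scoreable_indicators(labels), colnames(profile))
  if (!length(inds)) stop("no scoreable indicator")
  parts <- lapply(inds, function(p) {
    indicator_signature(modules, profile, z, labels, p, a_thresh)$entries
  })
  entries <- do.call(rbind, parts)
  if (is.null(entries) || !nrow(entries)) entries <- empty_panel_entries()
  if (per_module && nrow(entries)) {
    ## keep the strongest recruitment per source module
    ord <- order(entries$source_module, -abs(entries$activation))
    entries <- entries[ord, , drop = FALSE]
    entries <- entries[!duplicated(entries$source_module), , drop = FALSE]
  }
  rownames(entries) <- NULL
  new_panel("general_injury_signature", entries)
}
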