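## Readers and writers for the plain-text interchange formats used by the
## pipeline: matrix TSV, sample-map TSV, present-call mask TSV, indicator
## label TSV, GMT gene sets, PPI edge lists, ortholog maps, and module JSON.

#' Read a gene x condition matrix from TSV
#'
#' First column `gene_id`, remaining columns one per condition, tab separated.
#'
#' @param path file path.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be `gene_id`")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  check_named_matrix(m, basename(path))
  m
}

#' Write a gene x condition matrix as TSV
#' @param m matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample map TSV (`sample_id condition_id role`)
#' @param path file path.
#' @return data.frame with the three columns.
#' @export
read_sample_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition_id", "role")
  if (!all(req %in% names(df)))
    stop("sample map needs columns sample_id, condition_id, role")
  df
}

#' Read a present-call mask TSV (same layout as the matrix, entries 0/1)
#' @param path file path.
#' @return Logical matrix.
#' @export
read_mask_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  if (!all(m %in% c(0, 1))) stop("mask entries must be 0 or 1")
  m == 1
}

#' Read indicator labels from TSV
#'
#' Layout: first column `condition_id`, one column per indicator, entries
#' +1 (abnormal finding recorded) or 0.
#'
#' @param path file path.
#' @return Integer condition x indicator matrix.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "condition_id") stop("first column must be `condition_id`")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$condition_id
  if (!all(m %in% c(0L, 1L))) stop("label entries must be 0 or 1")
  m
}

#' Write indicator labels as TSV
#' @param labels condition x indicator matrix of 0/1.
#' @param path file path.
#' @export
write_labels_tsv <- function(labels, path) {
  df <- data.frame(condition_id = rownames(labels), labels, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line — name, description, then tab-separated gene ids.
#'
#' @param path file path.
#' @param source source tag attached to each set (default `"GMT"`).
#' @return List of [gene_set()] objects.
#' @export
read_gmt <- function(path, source = "GMT") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_set(parts[1], unique(parts[-(1:2)]), source = source)
  })
  out
}

#' Write gene sets to a GMT file
#' @param sets list of [gene_set()] objects (or a `signature_panel`).
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "signature_panel")) {
    sets <- list(gene_set(sets$name, sets$entries$gene_id, source = "PANEL"))
  }
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$source, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected PPI edge list TSV (`gene_a gene_b` per line)
#'
#' Self-loops and duplicate edges (in either orientation) are dropped.
#'
#' @param path file path.
#' @return A `ppi_network` object (see [ppi_network()]).
#' @export
read_ppi_edges <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_a", "gene_b"))
  ppi_network(df$gene_a, df$gene_b)
}

#' Read an ortholog map TSV (`source_id target_id`)
#' @param path file path.
#' @return Named character vector, source id -> target id.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("source_id", "target_id"))
  stats::setNames(df$target_id, df$source_id)
}

#' Translate gene ids of gene sets through an ortholog map
#'
#' Ids absent from the map are dropped; empty sets are removed.
#'
#' @param sets list of [gene_set()] objects.
#' @param map named character vector from [read_ortholog_map()].
#' @return Translated list of gene sets.
#' @export
apply_ortholog_map <- function(sets, map) {
  out <- lapply(sets, function(s) {
    g <- unique(unname(map[s$genes[s$genes %in% names(map)]]))
    if (!length(g)) return(NULL)
    gene_set(s$name, g, source = s$source)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Serialize co-expression modules to JSON
#' @param modules list of `coexpression_module` objects.
#' @param path file path.
#' @export
write_modules_json <- function(modules, path) {
  payload <- lapply(modules, function(m) {
    list(module_id = m$module_id,
         genes = m$genes, gene_scores = m$gene_scores,
         conditions = m$conditions, condition_scores = m$condition_scores,
         provenance = m$provenance)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read co-expression modules from JSON written by [write_modules_json()]
#' @param path file path.
#' @return List of `coexpression_module` objects.
#' @export
read_modules_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    new_module(module_id = p$module_id,
               genes = unlist(p$genes),
               gene_scores = unlist(p$gene_scores),
               conditions = unlist(p$conditions),
               condition_scores = unlist(p$condition_scores),
               provenance = lapply(p$provenance, identity))
  })
}
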