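## Pathway over-representation of module genes: one-sided hypergeometric
## (Fisher's exact) test with Bonferroni correction and three admission
## filters — the module must be significantly activated for some
## indicator, the corrected p must clear the significance level, and the
## module-pathway overlap must reach a minimum gene count.

#' One-sided over-representation p-value
#'
#' Hypergeometric upper tail `P(X >= k)` for drawing `k` pathway genes in a
#' module of size `n` from a universe of `N` genes containing `K` pathway
#' genes.
#'
#' @param module_genes,pathway_genes,universe_genes character vectors of
#'   gene ids; module and pathway are intersected with the universe.
#' @return Raw p-value in `(0, 1]`.
#' @export
fisher_overrep <- function(module_genes, pathway_genes, universe_genes) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) < 2) stop("universe must contain >= 2 genes")
  m <- intersect(unique(module_genes), universe_genes)
  p <- intersect(unique(pathway_genes), universe_genes)
  if (!length(m) || !length(p)) {
    warning("empty module or pathway after restriction to universe; p = 1")
    return(1)
  }
  k <- length(intersect(m, p))
  N <- length(universe_genes); K <- length(p); n <- length(m)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Map modules to pathways with the three admission filters
#'
#' Tests every (module, pathway) pair with [fisher_overrep()] and emits a
#' row per (module, pathway, indicator) only when 1) the module's absolute
#' activation for the indicator exceeds `a_thresh`, 2) the
#' Bonferroni-corrected p (multiplier = number of (module, pathway) tests
#' performed) is below `p_thresh`, and 3) the module-pathway overlap has at
#' least `min_hits` genes.  Direction records the sign of the triggering
#' activation.
#'
#' @param modules list of `coexpression_module` objects (or an
#'   `isa_result`).
#' @param pathways list of [gene_set()] objects.
#' @param profile an [activation_matrix()] covering the modules.
#' @param universe_genes character vector, the gene universe for the test
#'   (typically all genes surviving preprocessing).
#' @param a_thresh activation filter, default 1.5.
#' @param p_thresh Bonferroni-corrected p filter, default 0.05.
#' @param min_hits overlap floor, default 6.
#' @return data.frame with columns `module_id`, `pathway`, `indicator`,
#'   `direction` (`"up"`/`"down"`), `activation`, `overlap`, `module_size`,
#'   `pathway_size`, `universe_size`, `p_raw`, `p_bonferroni`.
#' @export
pathway_module_map <- function(modules, pathways, profile, universe_genes,
                               a_thresh = 1.5, p_thresh = 0.05,
                               min_hits = 6) {
  if (inherits(modules, "isa_result")) modules <- modules$modules
  universe_genes <- unique(universe_genes)
  ids <- vapply(seq_along(modules),
                function(i) module_label(modules[[i]], sprintf("m%03d", i)),
                character(1))
  if (!all(ids %in% rownames(profile)))
    stop("profile does not cover all modules")
  n_tests <- length(modules) * length(pathways)
  rows <- list()
  for (i in seq_along(modules)) {
    mg <- intersect(module_genes(modules[[i]]), universe_genes)
    acts <- profile[ids[i], ]
    hits <- colnames(profile)[abs(acts) > a_thresh]
    if (!length(hits)) next                       # filter 1
    for (pw in pathways) {
      pg <- intersect(pw$genes, universe_genes)
      k <- length(intersect(mg, pg))
      if (k < min_hits) next                      # filter 3
      p_raw <- fisher_overrep(mg, pg, universe_genes)
      p_bonf <- min(1, p_raw * n_tests)
      if (p_bonf >= p_thresh) next                # filter 2
      for (ind in hits) {
        rows[[length(rows) + 1L]] <- data.frame(
          module_id = ids[i], pathway = pw$name, indicator = ind,
          direction = if (acts[ind] > 0) "up" else "down",
          activation = unname(acts[ind]),
          overlap = k, module_size = length(mg), pathway_size = length(pg),
          universe_size = length(universe_genes),
          p_raw = p_raw, p_bonferroni = p_bonf,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(module_id = character(0), pathway = character(0),
                      indicator = character(0), direction = character(0),
                      activation = numeric(0), overlap = integer(0),
                      module_size = integer(0), pathway_size = integer(0),
                      universe_size = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
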