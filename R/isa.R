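## The iterative signature algorithm (ISA).  Starting from a seed gene set,
## conditions are scored by the mean Z of the current genes, outlier
## conditions are kept, genes are re-scored as the weighted mean of their Z
## over the kept conditions, outlier genes are kept, and the loop repeats
## until the gene and condition sets stabilize.  Converged modules are
## deduplicated (pairwise gene-score correlation) and filtered against a
## random-starter robustness null.

#' ISA tuning parameters
#'
#' @param t_c condition threshold in standard deviations, default 1.8.
#' @param t_g gene threshold in standard deviations, default 3.5.
#' @param convergence_tol maximum symmetric-difference fraction between
#'   successive gene (and condition) sets that still counts as converged,
#'   default 0.01.
#' @param max_iter iteration cap, default 100; exceeding it returns no
#'   module.
#' @param min_genes smallest admissible module, default 5.  Iteration
#'   trajectories that shrink below this are discarded: a near-singleton
#'   gene set is a stable fixed point of the scoring loop on any matrix
#'   (one extreme gene selects its own extreme conditions) but carries no
#'   co-expression information.
#' @param cor_limit gene-score correlation above which two modules are
#'   considered redundant, default 0.9.
#' @param robustness_runs random starters used to build the robustness
#'   null, default 20.
#' @param robustness_size genes per random starter, default 100.
#' @return Object of class `isa_params`.
#' @export
isa_params <- function(t_c = 1.8, t_g = 3.5, convergence_tol = 0.01,
                       max_iter = 100, min_genes = 5, cor_limit = 0.9,
                       robustness_runs = 20, robustness_size = 100) {
  stopifnot(t_c > 0, t_g > 0, convergence_tol > 0, convergence_tol < 1,
            max_iter >= 1, min_genes >= 1, cor_limit > 0, cor_limit <= 1)
  structure(list(t_c = t_c, t_g = t_g, convergence_tol = convergence_tol,
                 max_iter = max_iter, min_genes = min_genes,
                 cor_limit = cor_limit,
                 robustness_runs = robustness_runs,
                 robustness_size = robustness_size),
            class = "isa_params")
}

new_module <- function(module_id, genes, gene_scores, conditions,
                       condition_scores, provenance) {
  structure(list(module_id = module_id,
                 genes = genes, gene_scores = gene_scores,
                 conditions = conditions,
                 condition_scores = condition_scores,
                 provenance = provenance),
            class = "coexpression_module")
}

#' @export
print.coexpression_module <- function(x, ...) {
  cat(sprintf("coexpression_module '%s': %d genes x %d conditions\n",
              x$module_id, length(x$genes), length(x$conditions)))
  cat(sprintf("  starter: %s (%d iterations)\n",
              x$provenance$starter, x$provenance$iterations))
  invisible(x)
}

#' Score conditions against a gene set
#'
#' Each condition scores the mean Z of the member genes; conditions whose
#' score lies more than `t_c` standard deviations from the mean score across
#' all conditions are relevant.  Thresholding is two-sided, so relevant
#' conditions carry signed scores.
#'
#' @param genes a [gene_set()] or character vector of gene ids.
#' @param z gene x condition Z-score matrix.
#' @param t_c threshold in standard deviations.
#' @return Named numeric vector of signed scores for the relevant
#'   conditions (possibly empty; attribute `degenerate = TRUE` when the
#'   score spread was zero).
#' @export
score_conditions <- function(genes, z, t_c = 1.8) {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- intersect(genes, rownames(z))
  if (!length(genes)) stop("no member gene is present in the matrix")
  sc <- colMeans(z[genes, , drop = FALSE])
  sigma <- stats::sd(sc)
  if (is.na(sigma) || sigma == 0) {
    out <- numeric(0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  keep <- abs(sc - mean(sc)) > t_c * sigma
  sc[keep]
}

#' Score genes against weighted relevant conditions
#'
#' Each gene scores the weighted mean of its Z values over the relevant
#' conditions, with the signed condition scores as weights (normalized by
#' the sum of their absolute values so scores stay on the Z scale); genes
#' more than `t_g` standard deviations from the mean score are relevant.
#'
#' @param condition_scores named numeric vector of signed condition scores
#'   (output of [score_conditions()]).
#' @param z gene x condition Z-score matrix.
#' @param t_g threshold in standard deviations.
#' @return Named numeric vector of signed scores for the relevant genes.
#' @export
score_genes <- function(condition_scores, z, t_g = 3.5) {
  if (!length(condition_scores)) stop("no relevant conditions supplied")
  if (all(condition_scores == 0)) stop("all condition scores are zero")
  conds <- names(condition_scores)
  w <- condition_scores / sum(abs(condition_scores))
  sg <- drop(z[, conds, drop = FALSE] %*% w)
  sigma <- stats::sd(sg)
  if (is.na(sigma) || sigma == 0) return(sg[0])
  keep <- abs(sg - mean(sg)) > t_g * sigma
  sg[keep]
}

## Symmetric-difference fraction between two id sets, relative to the union.
set_change <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(0)
  length(setdiff(u, intersect(a, b))) / length(u)
}

#' Iterate ISA from one starter set to a converged module
#'
#' Alternates [score_conditions()] and [score_genes()], feeding the relevant
#' genes back as the next round's gene set, until both the gene set and the
#' condition set change by at most `convergence_tol` (symmetric-difference
#' fraction of the union) in an iteration.
#'
#' @param starter a [gene_set()].
#' @param z gene x condition Z-score matrix.
#' @param params an [isa_params()].
#' @return A `coexpression_module`, or `NULL` when either set empties or
#'   `max_iter` is reached without convergence.
#' @export
isa_iterate <- function(starter, z, params = isa_params()) {
  stopifnot(inherits(starter, "gene_set"), inherits(params, "isa_params"))
  genes <- intersect(starter$genes, rownames(z))
  if (!length(genes)) return(NULL)
  sg <- NULL
  for (iter in seq_len(params$max_iter)) {
    sc <- score_conditions(genes, z, params$t_c)
    if (!length(sc)) return(NULL)
    sg_new <- score_genes(sc, z, params$t_g)
    if (length(sg_new) < params$min_genes) return(NULL)
    genes_new <- names(sg_new)
    converged <- set_change(genes, genes_new) <= params$convergence_tol
    if (!is.null(sg)) {
      converged <- converged &&
        set_change(names(attr(sg, "sc")), names(sc)) <= params$convergence_tol
    }
    attr(sg_new, "sc") <- sc
    if (converged) {
      ord <- order(genes_new)
      cord <- order(names(sc))
      return(new_module(
        module_id = starter$name,
        genes = genes_new[ord], gene_scores = unname(sg_new)[ord],
        conditions = names(sc)[cord], condition_scores = unname(sc)[cord],
        provenance = list(starter = starter$name, iterations = iter)))
    }
    genes <- genes_new
    sg <- sg_new
  }
  NULL
}

#' Module robustness statistic
#'
#' `sqrt(sum over module cells of |gene score x condition score|)`; large
#' for big modules with strong coherent signal.
#'
#' @param module a `coexpression_module`.
#' @return Non-negative scalar.
#' @export
module_robustness <- function(module) {
  sqrt(sum(abs(outer(module$gene_scores, module$condition_scores))))
}

## Full-length gene-score vector over the matrix gene universe, zeros
## outside the module.
full_gene_score <- function(module, gene_universe) {
  v <- stats::setNames(numeric(length(gene_universe)), gene_universe)
  v[module$genes] <- module$gene_scores
  v
}

#' Prune redundant modules
#'
#' Greedy scan in descending robustness order: a module is dropped when the
#' Pearson correlation between its full-length gene-score vector (zeros
#' outside the module) and that of any already-retained module exceeds
#' `cor_limit`.
#'
#' @param modules list of `coexpression_module` objects.
#' @param gene_universe character vector of all gene ids in the working
#'   matrix.
#' @param cor_limit redundancy threshold, default 0.9.
#' @return The retained modules (pairwise correlation <= `cor_limit`).
#' @export
prune_unique <- function(modules, gene_universe, cor_limit = 0.9) {
  if (length(modules) <= 1L) return(modules)
  rob <- vapply(modules, module_robustness, numeric(1))
  ids <- vapply(modules, `[[`, character(1), "module_id")
  ord <- order(-rob, ids)
  kept <- list()
  kept_vecs <- NULL
  for (i in ord) {
    v <- full_gene_score(modules[[i]], gene_universe)
    if (is.null(kept_vecs)) {
      kept <- c(kept, modules[i]); kept_vecs <- cbind(v)
      next
    }
    r <- suppressWarnings(stats::cor(v, kept_vecs))
    r[is.na(r)] <- 0
    if (all(abs(r) <= cor_limit)) {
      kept <- c(kept, modules[i]); kept_vecs <- cbind(kept_vecs, v)
    }
  }
  kept[order(match(vapply(kept, `[[`, character(1), "module_id"), ids))]
}

#' Filter modules against a random-starter robustness null
#'
#' Builds a signal-free null by permuting the entries of the matrix
#' (destroying any gene-condition block structure while keeping the value
#' distribution), runs [isa_iterate()] from `robustness_runs` random
#' starter sets on that null, and takes the largest robustness among the
#' modules those starters converge to as the threshold.  Modules strictly
#' above the threshold are retained; when no null starter converges all
#' modules pass.
#'
#' @param modules list of `coexpression_module` objects.
#' @param z gene x condition Z-score matrix.
#' @param params an [isa_params()].
#' @param seed integer seed for the permutation and the random starters.
#' @return The retained modules, with the threshold attached as attribute
#'   `robustness_threshold`.
#' @export
filter_robust <- function(modules, z, params = isa_params(), seed = 1) {
  if (params$robustness_runs < 10) stop("`robustness_runs` must be >= 10")
  if (!length(modules)) return(modules)
  size <- min(params$robustness_size, nrow(z))
  z_null <- with_seed(seed, {
    zn <- matrix(sample(as.numeric(z)), nrow(z), ncol(z),
                 dimnames = dimnames(z))
    zn
  })
  null_starters <- random_gene_sets(rownames(z), params$robustness_runs,
                                    size = size, seed = seed + 1)
  null_rob <- vapply(null_starters, function(s) {
    m <- isa_iterate(s, z_null, params)
    if (is.null(m)) NA_real_ else module_robustness(m)
  }, numeric(1))
  threshold <- if (all(is.na(null_rob))) 0 else max(null_rob, na.rm = TRUE)
  keep <- vapply(modules, function(m) module_robustness(m) > threshold,
                 logical(1))
  out <- modules[keep]
  attr(out, "robustness_threshold") <- threshold
  out
}

#' Run the full ISA pipeline over a collection of starters
#'
#' Applies [isa_iterate()] to every starter, deduplicates with
#' [prune_unique()], and filters with [filter_robust()].  A saturation
#' curve records, for growing prefixes of the starter list, how many
#' mutually non-redundant modules had been found — the analog of a
#' module-count versus starter-count plot.
#'
#' @param starters list of [gene_set()] objects.
#' @param z gene x condition Z-score matrix.
#' @param params an [isa_params()].
#' @param seed integer seed (robustness null).
#' @return Object of class `isa_result` with fields `modules`, `curve`
#'   (data.frame `n_starters`, `n_modules`), `params`, and
#'   `robustness_threshold`.
#' @export
run_isa <- function(starters, z, params = isa_params(), seed = 1) {
  if (!length(starters)) stop("need at least one starter")
  check_named_matrix(z, "z")
  universe <- rownames(z)
  converged <- list()
  ## running greedy-unique count for the saturation curve (input order, so
  ## the curve is non-decreasing by construction)
  curve_n <- integer(length(starters))
  uniq_vecs <- NULL
  n_uniq <- 0L
  for (i in seq_along(starters)) {
    m <- isa_iterate(starters[[i]], z, params)
    if (!is.null(m)) {
      converged <- c(converged, list(m))
      v <- full_gene_score(m, universe)
      is_new <- TRUE
      if (!is.null(uniq_vecs)) {
        r <- suppressWarnings(stats::cor(v, uniq_vecs))
        r[is.na(r)] <- 0
        is_new <- all(abs(r) <= params$cor_limit)
      }
      if (is_new) {
        uniq_vecs <- if (is.null(uniq_vecs)) cbind(v) else cbind(uniq_vecs, v)
        n_uniq <- n_uniq + 1L
      }
    }
    curve_n[i] <- n_uniq
  }
  unique_mods <- prune_unique(converged, universe, params$cor_limit)
  robust <- filter_robust(unique_mods, z, params, seed = seed)
  threshold <- attr(robust, "robustness_threshold")
  attr(robust, "robustness_threshold") <- NULL
  ## re-id modules in a stable order
  modules <- robust[order(vapply(robust, `[[`, character(1), "module_id"))]
  for (i in seq_along(modules)) {
    modules[[i]]$module_id <- sprintf("M%03d", i)
  }
  structure(list(modules = modules,
                 curve = data.frame(n_starters = seq_along(starters),
                                    n_modules = curve_n),
                 params = params,
                 robustness_threshold = threshold),
            class = "isa_result")
}

#' @export
print.isa_result <- function(x, ...) {
  cat(sprintf("isa_result: %d modules (t_c = %g, t_g = %g)\n",
              length(x$modules), x$params$t_c, x$params$t_g))
  if (length(x$modules)) {
    sizes <- vapply(x$modules, function(m) length(m$genes), numeric(1))
    cat(sprintf("  gene-set sizes: min %d / mean %.1f / max %d\n",
                min(sizes), mean(sizes), max(sizes)))
  }
  cat(sprintf("  robustness threshold: %.3f\n", x$robustness_threshold))
  invisible(x)
}

#' @export
summary.isa_result <- function(object, ...) {
  mods <- object$modules
  df <- data.frame(
    module_id = vapply(mods, `[[`, character(1), "module_id"),
    n_genes = vapply(mods, function(m) length(m$genes), integer(1)),
    n_conditions = vapply(mods, function(m) length(m$conditions), integer(1)),
    robustness = vapply(mods, module_robustness, numeric(1)),
    starter = vapply(mods, function(m) m$provenance$starter, character(1)),
    iterations = vapply(mods, function(m) m$provenance$iterations,
                        integer(1)),
    stringsAsFactors = FALSE)
  structure(list(table = df, n_starters = nrow(object$curve),
                 robustness_threshold = object$robustness_threshold),
            class = "summary.isa_result")
}

#' @export
print.summary.isa_result <- function(x, ...) {
  cat(sprintf("ISA run over %d starters -> %d modules (null threshold %.3f)\n",
              x$n_starters, nrow(x$table), x$robustness_threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot the module saturation curve
#'
#' Number of mutually non-redundant modules as a function of the number of
#' starter gene sets consumed.
#'
#' @param x an `isa_result`.
#' @param ... passed to [plot()].
#' @export
plot.isa_result <- function(x, ...) {
  plot(x$curve$n_starters, x$curve$n_modules, type = "s",
       xlab = "number of starter gene sets",
       ylab = "number of unique modules", ...)
  invisible(x)
}
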