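## Planted-module synthetic data: a log-ratio-like matrix with Gaussian
## background and co-expressed gene blocks active over condition subsets,
## indicator labels tied to those condition subsets, plus matched PPI
## networks, pathway gene sets, and external validation matrices with a
## controlled fold-change correlation.  Every generator is a pure function
## of (design, seed).

#' Describe a planted-module design
#'
#' The default design — 2,000 genes x 300 conditions carrying 8 disjoint
#' planted modules of 30 genes x 25 conditions at mean signal 3 against
#' unit-variance background — mirrors, at desk scale, a liver
#' toxicogenomics Z-score matrix in which module signal sits about three
#' background standard deviations out.
#'
#' @param n_genes,n_conditions matrix dimensions.
#' @param n_modules number of planted modules.
#' @param module_genes,module_conditions block dimensions per module.
#' @param mu mean absolute signal inside a block (log-ratio scale, before
#'   the global Z transform), default 3.
#' @param block_sd within-block standard deviation, default 1.
#' @param background_sd background standard deviation, default 1.
#' @param amplitude_sd spread of the per-condition response amplitude
#'   shared by all genes of a block (each block condition carries the
#'   signal `mu` scaled by its own Normal(1, amplitude_sd) draw), default
#'   0.3.  This shared amplitude is what makes block genes co-expressed —
#'   positively correlated across the block conditions — rather than
#'   merely mean-shifted.
#' @param signs per-module sign pattern (+1/-1 recycled), default
#'   alternating.
#' @param label_noise probability that an indicator label is flipped,
#'   default 0.
#' @return Object of class `planted_design`.
#' @export
planted_design <- function(n_genes = 2000, n_conditions = 300,
                           n_modules = 8, module_genes = 30,
                           module_conditions = 25, mu = 3,
                           block_sd = 1, background_sd = 1,
                           amplitude_sd = 0.3,
                           signs = NULL, label_noise = 0) {
  stopifnot(mu >= 0, block_sd > 0, background_sd > 0, amplitude_sd >= 0,
            n_modules * module_genes <= n_genes,
            n_modules * module_conditions <= n_conditions,
            label_noise >= 0, label_noise <= 1)
  if (is.null(signs)) signs <- rep_len(c(1, -1), n_modules)
  signs <- rep_len(sign(signs), n_modules)
  structure(list(n_genes = n_genes, n_conditions = n_conditions,
                 n_modules = n_modules, module_genes = module_genes,
                 module_conditions = module_conditions, mu = mu,
                 block_sd = block_sd, background_sd = background_sd,
                 amplitude_sd = amplitude_sd,
                 signs = signs, label_noise = label_noise),
            class = "planted_design")
}

#' @export
print.planted_design <- function(x, ...) {
  cat(sprintf(
    "planted_design: %d x %d matrix, %d modules of %d genes x %d conditions (mu = %g)\n",
    x$n_genes, x$n_conditions, x$n_modules, x$module_genes,
    x$module_conditions, x$mu))
  invisible(x)
}

#' Generate a planted-module log-ratio matrix with indicator labels
#'
#' Background entries are Normal(0, background_sd); block entries are
#' Normal(sign * mu * a_c, block_sd), where `a_c ~ Normal(1, amplitude_sd)`
#' is a per-condition response amplitude shared by the whole block (the
#' source of within-block co-expression).  Each module gets one indicator
#' whose positive conditions are exactly the module's condition block,
#' with optional symmetric label flip noise.
#'
#' @param design a [planted_design()].
#' @param seed integer seed.
#' @return List with elements `lr` (gene x condition matrix), `labels`
#'   (condition x indicator 0/1 matrix), `truth` (ground truth: per-module
#'   gene/condition ids, signs, linked indicator, and the generator
#'   parameters).
#' @export
generate_matrix <- function(design, seed = 1) {
  stopifnot(inherits(design, "planted_design"))
  d <- design
  gene_ids <- sprintf("g%04d", seq_len(d$n_genes))
  cond_ids <- sprintf("c%04d", seq_len(d$n_conditions))
  with_seed(seed, {
    lr <- matrix(stats::rnorm(d$n_genes * d$n_conditions, 0, d$background_sd),
                 d$n_genes, d$n_conditions,
                 dimnames = list(gene_ids, cond_ids))
    modules <- vector("list", d$n_modules)
    labels <- matrix(0L, d$n_conditions, d$n_modules,
                     dimnames = list(cond_ids,
                                     sprintf("ind%02d", seq_len(d$n_modules))))
    for (k in seq_len(d$n_modules)) {
      g_idx <- ((k - 1) * d$module_genes + 1):(k * d$module_genes)
      c_idx <- ((k - 1) * d$module_conditions + 1):(k * d$module_conditions)
      amp <- stats::rnorm(length(c_idx), 1, d$amplitude_sd)
      block_means <- matrix(d$signs[k] * d$mu * amp, length(g_idx),
                            length(c_idx), byrow = TRUE)
      lr[g_idx, c_idx] <- block_means +
        stats::rnorm(length(g_idx) * length(c_idx), 0, d$block_sd)
      labels[c_idx, k] <- 1L
      modules[[k]] <- list(genes = gene_ids[g_idx],
                           conditions = cond_ids[c_idx],
                           sign = d$signs[k],
                           indicator = colnames(labels)[k])
    }
    if (d$label_noise > 0) {
      flips <- matrix(stats::runif(length(labels)) < d$label_noise,
                      nrow(labels), ncol(labels))
      labels <- ifelse(flips, 1L - labels, labels)
      storage.mode(labels) <- "integer"
      dimnames(labels) <- list(cond_ids,
                               sprintf("ind%02d", seq_len(d$n_modules)))
    }
    list(lr = lr, labels = labels,
         truth = list(modules = modules, design = d, seed = seed))
  })
}

#' Generate a PPI network matched to a planted design
#'
#' Every planted module contributes a hub (its first block gene) wired to
#' all other block genes, so the hub's ego network recovers the block;
#' random background edges are layered on top.
#'
#' @param truth ground truth from [generate_matrix()].
#' @param n_background_edges random extra edges, default 200.
#' @param seed integer seed.
#' @return A [ppi_network()].
#' @export
generate_ppi <- function(truth, n_background_edges = 200, seed = 1) {
  gene_ids <- sprintf("g%04d", seq_len(truth$design$n_genes))
  a <- character(0); b <- character(0)
  for (m in truth$modules) {
    hub <- m$genes[1]
    a <- c(a, rep(hub, length(m$genes) - 1))
    b <- c(b, m$genes[-1])
  }
  if (n_background_edges > 0) {
    bg <- with_seed(seed, {
      cbind(sample(gene_ids, n_background_edges, replace = TRUE),
            sample(gene_ids, n_background_edges, replace = TRUE))
    })
    a <- c(a, bg[, 1]); b <- c(b, bg[, 2])
  }
  ppi_network(a, b)
}

#' Generate pathway gene sets matched to a planted design
#'
#' One pathway per planted module — the full gene block plus random
#' distractor genes, guaranteeing a block-sized overlap well above the
#' enrichment filter floor — plus `n_decoy` purely random decoy pathways.
#'
#' @param truth ground truth from [generate_matrix()].
#' @param n_decoy number of decoy pathways, default 10.
#' @param decoy_size genes per decoy (also the distractor count for the
#'   planted pathways), default 40.
#' @param seed integer seed.
#' @return List of [gene_set()] objects; planted pathways are named
#'   `"pathway_<indicator>"`, decoys `"decoy<k>"`.
#' @export
generate_pathways <- function(truth, n_decoy = 10, decoy_size = 40,
                              seed = 1) {
  gene_ids <- sprintf("g%04d", seq_len(truth$design$n_genes))
  with_seed(seed, {
    planted <- lapply(truth$modules, function(m) {
      extras <- sample(setdiff(gene_ids, m$genes),
                       min(decoy_size, length(gene_ids) - length(m$genes)))
      gene_set(paste0("pathway_", m$indicator), c(m$genes, extras),
               source = "GMT")
    })
    decoys <- lapply(seq_len(n_decoy), function(k) {
      gene_set(sprintf("decoy%02d", k), sample(gene_ids, decoy_size),
               source = "GMT")
    })
    c(planted, decoys)
  })
}

#' Generate an external validation matrix with controlled correlation
#'
#' The external per-gene mean fold-changes are Gaussian mixtures of the
#' internal panel-gene fold-changes and independent noise, with the mixing
#' weight chosen so the population correlation equals `target_r`; genes
#' outside the panel are pure noise.  With `groups = TRUE` the conditions
#' split into two groups carrying opposite panel-gene offsets, for MDS
#' separation tests.
#'
#' @param internal_lr gene x condition internal log-ratio matrix.
#' @param panel_genes character vector of panel gene ids.
#' @param target_r target Pearson correlation in `(-1, 1)`.
#' @param n_conditions external condition count, default 6.
#' @param condition_noise_sd per-condition replicate noise around each
#'   gene's mean, expressed as a fraction of the internal fold-change
#'   spread (so the delivered gene-mean correlation stays at `target_r`),
#'   default 0.2.
#' @param groups when `TRUE`, add a two-group offset structure; group
#'   membership is returned in the `"groups"` attribute.
#' @param group_offset panel-gene offset magnitude separating the two
#'   groups, default 3.
#' @param seed integer seed.
#' @return Gene x condition external log-ratio matrix (attribute
#'   `"groups"`: named group vector when `groups = TRUE`).
#' @export
generate_external <- function(internal_lr, panel_genes, target_r = 0.9,
                              n_conditions = 6, condition_noise_sd = 0.2,
                              groups = FALSE, group_offset = 3, seed = 1) {
  if (abs(target_r) > 1)
    stop("`target_r` must lie in [-1, 1]")
  panel_genes <- intersect(panel_genes, rownames(internal_lr))
  if (!length(panel_genes)) stop("no panel gene present in `internal_lr`")
  fc_int <- rowMeans(internal_lr[panel_genes, , drop = FALSE])
  s <- stats::sd(fc_int)
  if (s == 0) stop("internal panel fold-changes are constant")
  cond_ids <- sprintf("x%03d", seq_len(n_conditions))
  with_seed(seed, {
    noise <- stats::rnorm(length(panel_genes), 0, s)
    fc_ext <- target_r * (fc_int - mean(fc_int)) +
      sqrt(1 - target_r^2) * noise + mean(fc_int)
    ext <- matrix(stats::rnorm(nrow(internal_lr) * n_conditions, 0,
                               condition_noise_sd * s),
                  nrow(internal_lr), n_conditions,
                  dimnames = list(rownames(internal_lr), cond_ids))
    ext[panel_genes, ] <- ext[panel_genes, ] + fc_ext
    if (groups) {
      grp <- rep(c("A", "B"), c(ceiling(n_conditions / 2),
                                floor(n_conditions / 2)))
      names(grp) <- cond_ids
      offset <- ifelse(grp == "A", group_offset / 2, -group_offset / 2)
      ext[panel_genes, ] <- sweep(ext[panel_genes, , drop = FALSE], 2L,
                                  offset, `+`)
      attr(ext, "groups") <- grp
    }
    ext
  })
}
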