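## Seed gene sets fed to the iterative signature algorithm, and the
## comparison gene-set families: hierarchical-clustering (HC) sets, PPI ego
## networks with permutation scoring, maximum-average-Z (MAZ) sets, and
## random sets.  SVM-style precomputed sets enter through read_gmt().

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene ids (deduplicated, must be
#'   non-empty).
#' @param source provenance tag, one of `"HC"`, `"PPI"`, `"SVM"`, `"MAZ"`,
#'   `"RAND"`, `"STARTER"`, `"GMT"`, `"PANEL"`.
#' @return Object of class `gene_set` with fields `name`, `genes`, `source`.
#' @export
gene_set <- function(name, genes, source = "STARTER") {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set must be non-empty")
  structure(list(name = as.character(name), genes = genes,
                 source = as.character(source)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' [%s]: %d genes\n", x$name, x$source,
              length(x$genes)))
  invisible(x)
}

#' Construct an undirected PPI network
#'
#' Self-loops and duplicate edges (either orientation) are removed.
#'
#' @param gene_a,gene_b character vectors of equal length, one edge per
#'   position.
#' @return Object of class `ppi_network` with fields `edges` (two-column
#'   character matrix) and `adjacency` (named list of neighbor vectors).
#' @export
ppi_network <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  stopifnot(length(gene_a) == length(gene_b))
  keep <- gene_a != gene_b
  a <- pmin(gene_a[keep], gene_b[keep])
  b <- pmax(gene_a[keep], gene_b[keep])
  key <- paste(a, b, sep = "\r")
  dedup <- !duplicated(key)
  edges <- cbind(gene_a = a[dedup], gene_b = b[dedup])
  nodes <- sort(unique(c(edges)))
  adjacency <- lapply(stats::setNames(nodes, nodes), function(n) {
    sort(unique(c(edges[edges[, 1] == n, 2], edges[edges[, 2] == n, 1])))
  })
  structure(list(edges = edges, adjacency = adjacency), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$adjacency), nrow(x$edges)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Hierarchical-clustering seed sets

## Recursive "hybrid" cut of an hclust tree: a node is split when it is too
## large, or when the gap between its merge height and its children's heights
## marks two well-separated subclusters both big enough to stand alone.
cut_tree_dynamic <- function(hc, min_size, max_size, gap_frac = 0.25) {
  n <- length(hc$order)
  node_members <- function(k) {
    ## k < 0: leaf -k; k > 0: merge row k
    if (k < 0) return(-k)
    c(node_members(hc$merge[k, 1]), node_members(hc$merge[k, 2]))
  }
  node_height <- function(k) if (k < 0) 0 else hc$height[k]
  out <- list()
  recurse <- function(k) {
    members <- node_members(k)
    if (length(members) < min_size) return(invisible(NULL))
    split_node <- FALSE
    if (k > 0) {
      kids <- hc$merge[k, ]
      sizes <- c(length(node_members(kids[1])), length(node_members(kids[2])))
      h <- hc$height[k]
      gap <- h - max(node_height(kids[1]), node_height(kids[2]))
      if (length(members) > max_size) split_node <- TRUE
      else if (all(sizes >= min_size) && h > 0 && gap > gap_frac * h)
        split_node <- TRUE
    }
    if (split_node) {
      recurse(hc$merge[k, 1]); recurse(hc$merge[k, 2])
    } else if (length(members) <= max_size) {
      out[[length(out) + 1L]] <<- members
    }
    invisible(NULL)
  }
  recurse(nrow(hc$merge))
  out
}

#' Hierarchical-clustering gene sets
#'
#' Clusters the gene dimension with average linkage on `1 - r` Pearson
#' distances and extracts clusters with a recursive hybrid tree cut that
#' honors a minimum and maximum cluster size.
#'
#' @param z gene x condition Z-score (or log-ratio) matrix.
#' @param min_size minimum cluster size, default 16.
#' @param max_size maximum cluster size, default 100.
#' @return List of [gene_set()] objects with source `"HC"`.
#' @export
hclust_gene_sets <- function(z, min_size = 16, max_size = 100) {
  check_named_matrix(z, "z")
  v <- apply(z, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) excluded from clustering")
    z <- z[v > 0, , drop = FALSE]
  }
  if (nrow(z) < min_size) {
    warning("fewer genes than `min_size`; no clusters returned")
    return(list())
  }
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  idx_sets <- cut_tree_dynamic(hc, min_size, max_size)
  out <- vector("list", length(idx_sets))
  for (i in seq_along(idx_sets)) {
    out[[i]] <- gene_set(sprintf("HC%03d", i),
                         rownames(z)[sort(idx_sets[[i]])], source = "HC")
  }
  out
}

## ---------------------------------------------------------------------------
## PPI ego-network sets and permutation scoring

#' PPI ego-network gene sets
#'
#' One set per node with degree >= 1: the node plus its direct interaction
#' partners.
#'
#' @param net a [ppi_network()].
#' @return List of [gene_set()] objects with source `"PPI"`, named after the
#'   ego node.
#' @export
ppi_gene_sets <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (!length(net$adjacency)) stop("empty PPI network")
  lapply(names(net$adjacency), function(n) {
    gene_set(n, c(n, net$adjacency[[n]]), source = "PPI")
  })
}

## Counts of up-/down-regulated member genes for a given positive-condition
## set: a gene counts as up (down) when its mean Z over the positive
## conditions exceeds +reg_threshold (falls below -reg_threshold).
count_regulated <- function(member_mean_z, reg_threshold) {
  c(up = sum(member_mean_z > reg_threshold),
    down = sum(member_mean_z < -reg_threshold))
}

#' Permutation Z-scores for PPI gene sets against an injury indicator
#'
#' For each set, counts member genes up-/down-regulated over the indicator's
#' positive conditions and standardizes those counts against `n_perm`
#' permutations of which conditions carry the positive label (label count
#' preserved).
#'
#' @param sets list of [gene_set()] objects.
#' @param z gene x condition Z-score matrix.
#' @param labels condition x indicator 0/1 matrix.
#' @param indicator indicator (column) id to score against.
#' @param n_perm number of label permutations (>= 100).
#' @param reg_threshold mean-Z magnitude that counts a gene as regulated,
#'   default 1.
#' @param seed integer seed for the permutation stream.
#' @return data.frame with columns `set_name`, `n_up`, `n_down`, `z_up`,
#'   `z_down`, `degenerate` (TRUE when a permutation sd was zero and the z
#'   was recorded as 0).
#' @export
score_ppi_gene_sets <- function(sets, z, labels, indicator, n_perm = 1e4,
                                reg_threshold = 1.0, seed = 1) {
  check_named_matrix(z, "z")
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  pos <- positive_conditions(labels, indicator)
  pos <- intersect(pos, colnames(z))
  if (!length(pos)) stop(sprintf("indicator '%s' has no positive conditions",
                                 indicator))
  n_pos <- length(pos)
  conds <- colnames(z)
  member_idx <- lapply(sets, function(s) {
    idx <- match(intersect(s$genes, rownames(z)), rownames(z))
    idx
  })
  observed <- t(vapply(seq_along(sets), function(i) {
    mz <- rowMeans(z[member_idx[[i]], pos, drop = FALSE])
    count_regulated(mz, reg_threshold)
  }, numeric(2)))
  perm_counts <- with_seed(seed, {
    up <- matrix(0, n_perm, length(sets))
    down <- matrix(0, n_perm, length(sets))
    for (p in seq_len(n_perm)) {
      perm_pos <- sample(conds, n_pos)
      for (i in seq_along(sets)) {
        mz <- rowMeans(z[member_idx[[i]], perm_pos, drop = FALSE])
        ct <- count_regulated(mz, reg_threshold)
        up[p, i] <- ct["up"]; down[p, i] <- ct["down"]
      }
    }
    list(up = up, down = down)
  })
  zify <- function(obs, perm) {
    mu <- mean(perm); sigma <- stats::sd(perm)
    if (is.na(sigma) || sigma == 0) return(c(0, TRUE))
    c((obs - mu) / sigma, FALSE)
  }
  res <- lapply(seq_along(sets), function(i) {
    zu <- zify(observed[i, "up"], perm_counts$up[, i])
    zd <- zify(observed[i, "down"], perm_counts$down[, i])
    data.frame(set_name = sets[[i]]$name,
               n_up = observed[i, "up"], n_down = observed[i, "down"],
               z_up = zu[1], z_down = zd[1],
               degenerate = as.logical(zu[2] || zd[2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Null significance thresholds for PPI set scores
#'
#' Repeats the permutation scoring on fully randomized labels `n_runs`
#' times, collects the most extreme positive `z_up` and most extreme
#' negative `z_down` per run, and returns the `percentile`-th entries of the
#' sorted extremes (5th most extreme of 100 by default, an estimated
#' maximum false-positive rate of 5%).
#'
#' @inheritParams score_ppi_gene_sets
#' @param n_runs number of randomized-label runs (>= 20), default 100.
#' @param percentile which sorted extreme to report, default 5.
#' @return Named numeric vector `c(up_threshold=, down_threshold=)`.
#' @export
ppi_significance_threshold <- function(sets, z, labels, indicator,
                                       n_perm = 1000, n_runs = 100,
                                       percentile = 5, seed = 1) {
  if (n_runs < 20) stop("`n_runs` must be at least 20")
  pos <- positive_conditions(labels, indicator)
  n_pos <- length(intersect(pos, colnames(z)))
  run_seeds <- with_seed(seed, sample.int(2^30, n_runs + 1))
  max_up <- numeric(n_runs); min_down <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    rand_labels <- labels
    rand_labels[, indicator] <- 0L
    rand_pos <- with_seed(run_seeds[r], sample(colnames(z), n_pos))
    rand_labels[rand_pos, indicator] <- 1L
    sc <- score_ppi_gene_sets(sets, z, rand_labels, indicator,
                              n_perm = n_perm, seed = run_seeds[n_runs + 1])
    max_up[r] <- max(sc$z_up)
    min_down[r] <- min(sc$z_down)
  }
  c(up_threshold = sort(max_up, decreasing = TRUE)[percentile],
    down_threshold = sort(min_down)[percentile])
}

## ---------------------------------------------------------------------------
## MAZ and random sets, starter expansion

#' Maximum-average-Z gene sets
#'
#' One set per scoreable indicator: the top `size` genes ranked by mean
#' absolute Z-score over that indicator's positive conditions, ties broken
#' by gene-id order.
#'
#' @param z gene x condition Z-score matrix.
#' @param labels condition x indicator 0/1 matrix.
#' @param size genes per set, default 50.
#' @return List of [gene_set()] objects with source `"MAZ"`, named after the
#'   indicator.
#' @export
maz_gene_sets <- function(z, labels, size = 50) {
  check_named_matrix(z, "z")
  inds <- scoreable_indicators(labels)
  if (!length(inds)) stop("no indicator has a positive condition")
  lapply(inds, function(p) {
    pos <- intersect(positive_conditions(labels, p), colnames(z))
    mz <- rowMeans(abs(z[, pos, drop = FALSE]))
    ord <- order(-mz, rownames(z))
    gene_set(paste0("MAZ_", p),
             rownames(z)[ord[seq_len(min(size, nrow(z)))]], source = "MAZ")
  })
}

#' Random gene sets
#'
#' @param gene_ids universe of gene ids.
#' @param n_sets number of sets.
#' @param size genes per set (uniform, without replacement), default 100.
#' @param seed integer seed.
#' @return List of [gene_set()] objects with source `"RAND"`.
#' @export
random_gene_sets <- function(gene_ids, n_sets, size = 100, seed = 1) {
  gene_ids <- unique(as.character(gene_ids))
  if (size > length(gene_ids)) stop("`size` exceeds number of genes")
  with_seed(seed, lapply(seq_len(n_sets), function(i) {
    gene_set(sprintf("RAND%04d", i), sample(gene_ids, size), source = "RAND")
  }))
}

#' Expand starter sets with random genes
#'
#' For every seed set, emits the seed itself plus `n_copies` variants each
#' augmented with `n_random` distinct random genes not already in the seed.
#'
#' @param seeds list of [gene_set()] objects.
#' @param gene_ids universe of gene ids to draw the padding from.
#' @param n_random random genes added per variant, default 100.
#' @param n_copies augmented variants per seed.
#' @param seed integer seed.
#' @return List of length `length(seeds) * (1 + n_copies)`.
#' @export
expand_starters <- function(seeds, gene_ids, n_random = 100, n_copies = 1,
                            seed = 1) {
  if (n_copies < 0) stop("`n_copies` must be >= 0")
  gene_ids <- unique(as.character(gene_ids))
  with_seed(seed, {
    out <- list()
    for (s in seeds) {
      out[[length(out) + 1L]] <- s
      pool <- setdiff(gene_ids, s$genes)
      for (k in seq_len(n_copies)) {
        take <- n_random
        if (length(pool) < n_random) {
          warning(sprintf(
            "only %d genes available outside seed '%s'; using all of them",
            length(pool), s$name))
          take <- length(pool)
        }
        extra <- sample(pool, take)
        out[[length(out) + 1L]] <-
          gene_set(sprintf("%s+rand%d", s$name, k), c(s$genes, extra),
                   source = "STARTER")
      }
    }
    out
  })
}
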