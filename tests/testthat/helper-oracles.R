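## Independent brute-force oracles used to check the implementation.
## Every oracle is written as the most direct rendering of the formula it
## checks, independent of the package's code paths.

## Random gene x condition matrix with dimnames.
rand_matrix <- function(n_genes, n_conds, seed, sd = 1, mean = 0) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_conds, mean, sd), n_genes, n_conds,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(n_conds))))
}

## Labels matrix with one indicator positive on the given condition ids.
labels_for <- function(cond_ids, positive, indicator = "ind1") {
  m <- matrix(0L, length(cond_ids), 1L,
              dimnames = list(cond_ids, indicator))
  m[positive, 1] <- 1L
  m
}

## Per-cell Z-score oracle (population sd).
oracle_zscore <- function(m) {
  mu <- mean(m)
  sigma <- sqrt(mean((m - mu)^2))
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- (m[i, j] - mu) / sigma
  }
  out
}

## Double-loop module activation oracle.
oracle_activation <- function(genes, z, pos_conditions) {
  total <- 0
  for (g in genes) for (cc in pos_conditions) total <- total + z[g, cc]
  total / (length(genes) * length(pos_conditions))
}

## Triple-loop specificity oracle: S for one (module row, indicator) of an
## activation profile.
oracle_specificity <- function(profile, m, p) {
  others <- setdiff(colnames(profile), p)
  total <- 0
  for (q in others) total <- total + abs(profile[m, p] - profile[m, q])
  total / length(others)
}

## Pairwise-loop intra-module correlation oracle.
oracle_intra_cor <- function(genes, z, pos_conditions) {
  vals <- c()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j <= i) next
      vals <- c(vals, cor(z[genes[i], pos_conditions],
                          z[genes[j], pos_conditions]))
    }
  }
  mean(vals)
}

## Brute-force center-gene oracle: correlation sum (self term = 1) over
## positive conditions, candidates in decreasing order, first whose mean Z
## over positive conditions reaches the module mean.
oracle_center_gene <- function(genes, z, pos_conditions) {
  C <- numeric(length(genes))
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      C[i] <- C[i] + if (i == j) 1 else
        cor(z[genes[i], pos_conditions], z[genes[j], pos_conditions])
    }
  }
  gene_means <- vapply(genes, function(g) mean(z[g, pos_conditions]),
                       numeric(1))
  module_mean <- mean(gene_means)
  ord <- order(-C, genes)
  for (depth in seq_along(ord) - 1L) {
    i <- ord[depth + 1L]
    if (gene_means[i] >= module_mean) {
      return(list(gene = genes[i], corr_sum = C[i], depth = depth))
    }
  }
  NULL
}

## Exhaustive hypergeometric upper-tail oracle P(X >= k).
oracle_hyper_tail <- function(N, K, n, k) {
  total <- 0
  for (j in seq(k, min(n, K))) {
    total <- total + choose(K, j) * choose(N - K, n - j)
  }
  total / choose(N, n)
}

## Brute-force average-linkage agglomeration on a dissimilarity matrix:
## repeatedly merge the closest pair of clusters, with inter-cluster
## distance the arithmetic mean of all original cross-pair
## dissimilarities.  Returns merge heights and a function cutting into a
## partition at a given height.
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- c()
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        dist_ab <- mean(d[clusters[[a]], clusters[[b]]])
        if (dist_ab < best_d) { best_d <- dist_ab; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1L]] <-
      list(members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
           height = best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  cut_at <- function(h) {
    cl <- as.list(seq_len(n))
    for (m in merges) {
      if (m$height > h) break
      hit <- which(vapply(cl, function(x) any(x %in% m$members), logical(1)))
      cl[[hit[1]]] <- sort(unique(unlist(cl[hit])))
      cl <- cl[-hit[-1]]
    }
    part <- integer(n)
    for (i in seq_along(cl)) part[cl[[i]]] <- i
    part
  }
  list(heights = sort(heights), cut_at = cut_at)
}

## TRUE when two cluster labelings describe the same partition.
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, numeric(1)))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, numeric(1)))]))
}

## Jaccard index between two gene-id sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

## Best Jaccard of each planted module against a list of recovered modules.
planted_jaccards <- function(truth, modules) {
  vapply(truth$modules, function(tm) {
    if (!length(modules)) return(0)
    max(vapply(modules, function(m) jaccard(m$genes, tm$genes), numeric(1)))
  }, numeric(1))
}

## Small planted design used across test files: same block-to-background
## proportions as the default design (so the default ISA thresholds still
## separate signal from noise after variance filtering), at a fraction of
## the size.
small_design <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 1000, n_conditions = 200, n_modules = 4,
         module_genes = 25, module_conditions = 20, mu = 3),
    list(...))
  do.call(planted_design, args)
}
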