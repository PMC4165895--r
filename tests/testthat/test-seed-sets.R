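test_that("anti-correlated blocks are split into exactly two HC sets", {
  set.seed(2)
  v <- rnorm(40)
  m <- rbind(matrix(rep(v, each = 20), 20, byrow = FALSE) +
               matrix(rnorm(800, 0, 1e-3), 20),
             matrix(rep(-v, each = 20), 20, byrow = FALSE) +
               matrix(rnorm(800, 0, 1e-3), 20))
  dimnames(m) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:40))
  sets <- hclust_gene_sets(m, min_size = 16, max_size = 100)
  expect_length(sets, 2)
  blocks <- lapply(sets, function(s) sort(s$genes))
  expect_true(identical(blocks[[1]], sprintf("g%02d", 1:20)) ||
              identical(blocks[[2]], sprintf("g%02d", 1:20)))
  expect_setequal(unlist(blocks), sprintf("g%02d", 1:40))
})

test_that("too few genes yields an empty HC list with a warning", {
  m <- rand_matrix(5, 10, seed = 1)
  expect_warning(sets <- hclust_gene_sets(m, min_size = 16), "min_size")
  expect_length(sets, 0)
})

test_that("every HC set respects the size contract", {
  sim <- generate_matrix(small_design(), seed = 3)
  z <- preprocess_matrix(sim$lr)
  sets <- hclust_gene_sets(z, min_size = 16, max_size = 100)
  sizes <- vapply(sets, function(s) length(s$genes), integer(1))
  expect_true(all(sizes >= 16 & sizes <= 100))
})

test_that("PPI ego sets are the node plus its direct partners", {
  net <- ppi_network(c("c", "c", "c", "x"), c("a", "b", "d", "x"))
  sets <- ppi_gene_sets(net)
  by_name <- setNames(sets, vapply(sets, `[[`, character(1), "name"))
  expect_setequal(by_name[["c"]]$genes, c("c", "a", "b", "d"))
  expect_setequal(by_name[["a"]]$genes, c("a", "c"))
  ## self-loop x-x dropped, so x is isolated and emits no set
  expect_false("x" %in% names(by_name))
  ## union of ego sets = non-isolated nodes
  expect_setequal(unique(unlist(lapply(sets, `[[`, "genes"))),
                  c("a", "b", "c", "d"))
})

test_that("PPI ego sets match an igraph adjacency oracle on a random graph", {
  skip_if_not_installed("igraph")
  set.seed(17)
  n <- 25
  edges <- cbind(sample(letters[1:n], 40, TRUE), sample(letters[1:n], 40, TRUE))
  net <- ppi_network(edges[, 1], edges[, 2])
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  sets <- ppi_gene_sets(net)
  for (s in sets) {
    nb <- igraph::neighbors(g, s$name)$name
    expect_setequal(s$genes, union(s$name, nb))
  }
})

test_that("PPI set scoring finds a planted direction and respects thresholds", {
  z <- rand_matrix(20, 20, seed = 5)
  z[1:6, 1:3] <- z[1:6, 1:3] + 3       # genes g001-g006 up on c001-c003
  labels <- labels_for(colnames(z), paste0("c00", 1:3))
  set <- gene_set("planted", rownames(z)[1:6])
  sc <- score_ppi_gene_sets(list(set), z, labels, "ind1",
                            n_perm = 500, seed = 2)
  expect_equal(sc$n_up, 6)
  expect_gt(sc$z_up, 2)
  ## an infinite regulation threshold counts nothing
  sc_inf <- score_ppi_gene_sets(list(set), z, labels, "ind1",
                                n_perm = 100, reg_threshold = Inf, seed = 2)
  expect_equal(sc_inf$n_up + sc_inf$n_down, 0)
})

test_that("degenerate permutations flag the z-score as zero", {
  z <- rand_matrix(4, 1, seed = 8)
  labels <- labels_for(colnames(z), colnames(z)[1])
  sc <- score_ppi_gene_sets(list(gene_set("s", rownames(z)[1:2])), z,
                            labels, "ind1", n_perm = 100, seed = 1)
  expect_true(sc$degenerate)
  expect_identical(sc$z_up, 0)
})

test_that("sampled permutation z-scores approach the exhaustive enumeration", {
  z <- rand_matrix(10, 6, seed = 13)
  z[1:5, 1:2] <- z[1:5, 1:2] + 2
  labels <- labels_for(colnames(z), colnames(z)[1:2])
  set <- gene_set("s", rownames(z)[1:5])
  ## exhaustive oracle over all choose(6,2)=15 label placements
  placements <- combn(colnames(z), 2)
  counts <- apply(placements, 2, function(pos) {
    mz <- rowMeans(z[set$genes, pos, drop = FALSE])
    sum(mz > 1)
  })
  obs <- sum(rowMeans(z[set$genes, colnames(z)[1:2]]) > 1)
  oracle_z <- (obs - mean(counts)) / sqrt(mean((counts - mean(counts))^2))
  sc <- score_ppi_gene_sets(list(set), z, labels, "ind1",
                            n_perm = 20000, seed = 4)
  expect_equal(sc$z_up, oracle_z, tolerance = 0.05)
})

test_that("null thresholds have sane signs and are the 5th sorted extreme", {
  z <- rand_matrix(30, 12, seed = 19)
  labels <- labels_for(colnames(z), colnames(z)[1:3])
  sets <- lapply(1:4, function(i)
    gene_set(paste0("s", i), rownames(z)[((i - 1) * 5 + 1):(i * 5)]))
  thr <- ppi_significance_threshold(sets, z, labels, "ind1",
                                    n_perm = 200, n_runs = 20,
                                    percentile = 5, seed = 3)
  expect_gt(thr[["up_threshold"]], 0)
  expect_lt(thr[["down_threshold"]], 0)
})

test_that("MAZ sets rank genes by mean |Z| over positive conditions", {
  sim <- generate_matrix(small_design(), seed = 9)
  z <- zscore_transform(sim$lr)
  sets <- maz_gene_sets(z, sim$labels, size = 30)
  expect_length(sets, 4)
  ## the top set for each indicator contains its planted block
  for (k in 1:4) {
    tm <- sim$truth$modules[[k]]
    s <- sets[[match(paste0("MAZ_", tm$indicator),
                     vapply(sets, `[[`, character(1), "name"))]]
    expect_gte(length(intersect(s$genes, tm$genes)), 18)
    ## sort-oracle on an independently computed mean-|Z| vector
    pos <- tm$conditions
    mz <- rowMeans(abs(z[, pos]))
    oracle <- names(sort(mz, decreasing = TRUE))[1:30]
    ## allow tie reordering at the boundary
    expect_gte(length(intersect(s$genes, oracle)), 29)
  }
  ## size >= n_genes returns everything
  all_sets <- maz_gene_sets(z, sim$labels, size = nrow(z) + 5)
  expect_length(all_sets[[1]]$genes, nrow(z))
})

test_that("random sets are reproducible, sized, and frequency-uniform", {
  ids <- sprintf("g%03d", 1:100)
  a <- random_gene_sets(ids, 5, size = 10, seed = 42)
  b <- random_gene_sets(ids, 5, size = 10, seed = 42)
  expect_identical(lapply(a, `[[`, "genes"), lapply(b, `[[`, "genes"))
  expect_error(random_gene_sets(ids, 1, size = 101), "exceeds")
  full <- random_gene_sets(ids, 2, size = 100, seed = 1)
  expect_setequal(full[[1]]$genes, ids)
  ## inclusion frequency ~ Binomial(n_sets, size/n_genes); the per-gene
  ## 3-sd band is widened to 4 sd because the check takes a max over all
  ## 100 genes
  many <- random_gene_sets(ids, 2000, size = 10, seed = 7)
  freq <- table(factor(unlist(lapply(many, `[[`, "genes")), levels = ids))
  p <- 0.1
  bound <- 4 * sqrt(2000 * p * (1 - p))
  expect_true(all(abs(freq - 2000 * p) <= bound))
})

test_that("starter expansion adds the requested number of fresh genes", {
  ids <- sprintf("g%03d", 1:200)
  seeds <- list(gene_set("seed1", ids[1:30]))
  expect_identical(expand_starters(seeds, ids, n_copies = 0), seeds)
  out <- expand_starters(seeds, ids, n_random = 100, n_copies = 2, seed = 3)
  expect_length(out, 3)
  expect_length(out[[2]]$genes, 130)
  expect_length(intersect(out[[2]]$genes, ids[1:30]), 30)
  out2 <- expand_starters(seeds, ids, n_random = 100, n_copies = 2, seed = 3)
  expect_identical(lapply(out, `[[`, "genes"), lapply(out2, `[[`, "genes"))
  ## too-small pool: augment with all remaining, warn
  expect_warning(
    short <- expand_starters(list(gene_set("s", ids[1:150])), ids,
                             n_random = 100, n_copies = 1, seed = 1),
    "available")
  expect_length(short[[2]]$genes, 200)
})
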