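eval_fixture <- function(seed = 42) {
  sim <- generate_matrix(small_design(), seed = seed)
  z <- preprocess_matrix(sim$lr)
  modules <- lapply(sim$truth$modules, function(tm)
    isa_iterate(gene_set(tm$indicator, tm$genes), z))
  list(sim = sim, z = z, modules = modules)
}

test_that("module activation equals the double-loop oracle and constant blocks", {
  z <- rand_matrix(12, 9, seed = 2)
  labels <- labels_for(colnames(z), colnames(z)[c(2, 5, 8)])
  genes <- rownames(z)[3:7]
  expect_equal(module_activation(genes, z, labels, "ind1"),
               oracle_activation(genes, z, colnames(z)[c(2, 5, 8)]))
  ## constant block
  zc <- z; zc[genes, colnames(z)[c(2, 5, 8)]] <- 4.2
  expect_equal(module_activation(genes, zc, labels, "ind1"), 4.2)
  ## single gene, single positive condition
  l1 <- labels_for(colnames(z), "c004")
  expect_equal(module_activation(rownames(z)[1], z, l1, "ind1"),
               z["g001", "c004"])
  ## unscoreable indicator errors by name
  l0 <- labels_for(colnames(z), character(0), indicator = "empty_ind")
  expect_error(module_activation(genes, z, l0, "empty_ind"), "empty_ind")
})

test_that("gene activation is the positive-condition mean and averages to the module activation", {
  z <- rand_matrix(20, 15, seed = 4)
  pos <- colnames(z)[c(1, 4, 9, 12)]
  labels <- labels_for(colnames(z), pos)
  g <- rownames(z)[5]
  expect_equal(gene_activation(g, z, labels, "ind1"), mean(z[g, pos]))
  ## module activation = mean of member gene activations (exact identity)
  genes <- rownames(z)[2:11]
  ga <- vapply(genes, gene_activation, numeric(1), z = z, labels = labels,
               indicator = "ind1")
  expect_equal(module_activation(genes, z, labels, "ind1"), mean(ga),
               tolerance = 1e-12)
})

test_that("the activation matrix stacks per-pair calls and flags planted links", {
  fx <- eval_fixture()
  prof <- activation_matrix(fx$modules, fx$z, fx$sim$labels)
  expect_identical(dim(prof), c(4L, 4L))
  for (i in 1:4) for (p in colnames(prof)) {
    expect_equal(prof[i, p],
                 module_activation(fx$modules[[i]], fx$z, fx$sim$labels, p))
  }
  ## planted module vs linked indicator: strong; vs unlinked: near zero
  for (i in 1:4) {
    linked <- fx$sim$truth$modules[[i]]$indicator
    expect_gt(abs(prof[fx$modules[[i]]$module_id, linked]), 1.5)
    others <- setdiff(colnames(prof), linked)
    expect_true(all(abs(prof[fx$modules[[i]]$module_id, others]) < 0.5))
  }
})

test_that("specificity matches the loop oracle and its invariances", {
  set.seed(6)
  prof <- structure(matrix(rnorm(15), 3, 5,
                           dimnames = list(paste0("m", 1:3),
                                           paste0("p", 1:5))),
                    class = c("activation_profile", "matrix"), a_thresh = 1.5)
  for (m in rownames(prof)) for (p in colnames(prof)) {
    expect_equal(module_specificity(prof, m, p), oracle_specificity(prof, m, p))
  }
  rep_ <- global_specificity(prof)
  expect_equal(rep_$S_plus, mean(apply(rep_$S, 2, max)))
  ## two indicators with activations {3, 0}: S = 3 on both sides
  p2 <- structure(matrix(c(3, 0), 1, 2,
                         dimnames = list("m1", c("a", "b"))),
                  class = c("activation_profile", "matrix"))
  expect_equal(module_specificity(p2, "m1", "a"), 3)
  expect_equal(module_specificity(p2, "m1", "b"), 3)
  ## constant activation row has zero specificity everywhere
  pc <- structure(matrix(1.7, 2, 4,
                         dimnames = list(c("m1", "m2"), paste0("p", 1:4))),
                  class = c("activation_profile", "matrix"))
  expect_true(all(global_specificity(pc)$S == 0))
  ## translation invariance: adding a constant to a row changes nothing
  shifted <- prof; shifted["m2", ] <- shifted["m2", ] + 11
  expect_equal(global_specificity(shifted)$S["m2", ],
               rep_$S["m2", ])
})

test_that("intra-module correlation handles identical, opposite and random genes", {
  z <- rand_matrix(10, 12, seed = 8)
  pos <- colnames(z)[1:6]
  labels <- labels_for(colnames(z), pos)
  z["g002", ] <- z["g001", ]
  expect_equal(intra_module_correlation(c("g001", "g002"), z, labels, "ind1"),
               1)
  z["g003", ] <- -z["g001", ]
  expect_equal(intra_module_correlation(c("g001", "g003"), z, labels, "ind1"),
               -1)
  genes <- rownames(z)[4:10]
  expect_equal(intra_module_correlation(genes, z, labels, "ind1"),
               oracle_intra_cor(genes, z, pos))
  ## fewer than 2 positive conditions: undefined
  l1 <- labels_for(colnames(z), "c001")
  expect_true(is.na(intra_module_correlation(genes, z, l1, "ind1")))
})

test_that("center genes match the brute-force rule on small modules", {
  set.seed(14)
  for (rep_i in 1:5) {
    z <- rand_matrix(20, 30, seed = 100 + rep_i)
    pos <- sample(colnames(z), 8)
    labels <- labels_for(colnames(z), pos)
    genes <- sample(rownames(z), 12)
    got <- center_gene(gene_set("m", genes), z, labels, "ind1")
    want <- oracle_center_gene(sort(unique(genes)), z, pos)
    expect_identical(got$gene, want$gene)
    expect_equal(got$corr_sum, want$corr_sum)
    expect_identical(got$depth, want$depth)
  }
})

test_that("center gene selection applies the reselection rule and input-order invariance", {
  ## construct: two tightly correlated low genes and one high gene
  z <- matrix(0, 3, 10, dimnames = list(c("low1", "low2", "high"),
                                        paste0("c", 1:10)))
  set.seed(9)
  base <- sin(seq_len(10))
  z["low1", ] <- base - 2
  z["low2", ] <- base + rnorm(10, 0, 0.01) - 2
  z["high", ] <- -base + 4            # anti-correlated but high
  labels <- labels_for(colnames(z), colnames(z))
  got <- center_gene(gene_set("m", rownames(z)), z, labels, "ind1")
  ## top correlation-sum genes are low1/low2, both below the module mean
  expect_identical(got$gene, "high")
  expect_identical(got$depth, 2L)
  got2 <- center_gene(gene_set("m", rev(rownames(z))), z, labels, "ind1")
  expect_identical(got2$gene, got$gene)
})

test_that("center-gene preconditions are enforced", {
  z <- rand_matrix(5, 6, seed = 3)
  l1 <- labels_for(colnames(z), "c001")
  expect_error(center_gene(gene_set("m", rownames(z)), z, l1, "ind1"),
               "positive conditions")
  labels <- labels_for(colnames(z), colnames(z)[1:3])
  expect_error(center_gene(gene_set("m", rownames(z)[1]), z, labels, "ind1"),
               "2 genes")
})

test_that("global specificity and correlation of planted modules beat random sets", {
  fx <- eval_fixture(seed = 77)
  prof <- activation_matrix(fx$modules, fx$z, fx$sim$labels)
  rep_mod <- global_specificity(prof, fx$modules, fx$z, fx$sim$labels)
  sizes <- vapply(fx$modules, function(m) length(m$genes), integer(1))
  rand <- lapply(seq_along(sizes), function(i)
    random_gene_sets(rownames(fx$z), 1, size = sizes[i],
                     seed = 500 + i)[[1]])
  prof_rand <- activation_matrix(rand, fx$z, fx$sim$labels)
  rep_rand <- global_specificity(prof_rand, rand, fx$z, fx$sim$labels)
  expect_gt(rep_mod$S_plus, rep_rand$S_plus)
  expect_gt(rep_mod$R_plus, rep_rand$R_plus)
})
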