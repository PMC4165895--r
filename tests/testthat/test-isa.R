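make_planted_z <- function(seed = 42, design = small_design()) {
  sim <- generate_matrix(design, seed = seed)
  list(z = preprocess_matrix(sim$lr), sim = sim)
}

test_that("condition scoring selects outliers and matches the direct formula", {
  ## single outlier condition
  z <- matrix(0, 5, 100, dimnames = list(paste0("g", 1:5), paste0("c", 1:100)))
  z <- z + matrix(rnorm(500, 0, 0.01), 5, 100)
  z[, "c7"] <- 10
  sel <- score_conditions(rownames(z), z, t_c = 1.8)
  expect_identical(names(sel), "c7")

  ## all-identical scores: degenerate, empty
  zc <- matrix(1, 4, 6, dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  sel2 <- score_conditions(rownames(zc), zc, t_c = 1.8)
  expect_length(sel2, 0)
  expect_true(isTRUE(attr(sel2, "degenerate")))

  ## random case against the direct formula
  zr <- rand_matrix(200, 50, seed = 6)
  genes <- rownames(zr)[1:40]
  sel3 <- score_conditions(genes, zr, t_c = 1.5)
  sc <- colMeans(zr[genes, ])
  oracle <- sc[abs(sc - mean(sc)) > 1.5 * sd(sc)]
  expect_equal(sel3, oracle)
})

test_that("gene scoring collapses to the Z column for a single condition", {
  z <- rand_matrix(30, 10, seed = 3)
  sc <- setNames(1, "c004")
  sg_all <- drop(z[, "c004"])
  sel <- score_genes(sc, z, t_g = 1)
  oracle <- sg_all[abs(sg_all - mean(sg_all)) > 1 * sd(sg_all)]
  expect_equal(sel, oracle)
})

test_that("gene scoring matches the weighted-mean formula on a random case", {
  z <- rand_matrix(100, 20, seed = 8)
  sc <- setNames(c(2.5, -1.5, 3), c("c002", "c007", "c013"))
  sel <- score_genes(sc, z, t_g = 1.2)
  sg <- (z[, "c002"] * 2.5 + z[, "c007"] * -1.5 + z[, "c013"] * 3) / 7
  oracle <- sg[abs(sg - mean(sg)) > 1.2 * sd(sg)]
  expect_equal(sel, oracle)
  expect_error(score_genes(setNames(numeric(0), character(0)), z), "relevant")
  expect_error(score_genes(setNames(c(0, 0), c("c001", "c002")), z), "zero")
})

test_that("a planted starter converges to the planted module", {
  pl <- make_planted_z(seed = 42)
  tm <- pl$sim$truth$modules[[1]]
  mod <- isa_iterate(gene_set("truth1", tm$genes), pl$z)
  expect_false(is.null(mod))
  expect_gte(jaccard(mod$genes, tm$genes), 0.8)
  expect_lte(mod$provenance$iterations, 2)
  ## fixed point: re-feeding the module reproduces it
  again <- isa_iterate(gene_set("refeed", mod$genes), pl$z)
  expect_identical(again$genes, mod$genes)
  expect_identical(again$conditions, mod$conditions)
})

test_that("background starters on pure noise do not yield modules", {
  noise <- make_planted_z(seed = 5, design = small_design(mu = 0))
  starters <- random_gene_sets(rownames(noise$z), 5, size = 50, seed = 2)
  mods <- lapply(starters, isa_iterate, z = noise$z)
  rob <- vapply(mods[!vapply(mods, is.null, logical(1))],
                module_robustness, numeric(1))
  ## nothing spurious should rival a planted module's robustness (~40 at
  ## this design size)
  expect_true(all(rob < 20))
})

test_that("flipping the matrix sign preserves modules and negates condition scores", {
  pl <- make_planted_z(seed = 10)
  tm <- pl$sim$truth$modules[[2]]
  mod <- isa_iterate(gene_set("s", tm$genes), pl$z)
  mod_flip <- isa_iterate(gene_set("s", tm$genes), -pl$z)
  expect_identical(mod_flip$genes, mod$genes)
  expect_identical(mod_flip$conditions, mod$conditions)
  expect_equal(mod_flip$condition_scores, -mod$condition_scores)
  ## gene scores are sign-invariant: the weights flip with the matrix
  expect_equal(mod_flip$gene_scores, mod$gene_scores)
})

test_that("pruning drops duplicates and nested near-copies, keeps disjoint modules", {
  pl <- make_planted_z(seed = 11)
  m1 <- isa_iterate(gene_set("a", pl$sim$truth$modules[[1]]$genes), pl$z)
  m2 <- isa_iterate(gene_set("b", pl$sim$truth$modules[[2]]$genes), pl$z)
  universe <- rownames(pl$z)
  kept <- prune_unique(list(m1, m1, m2), universe, cor_limit = 0.9)
  expect_length(kept, 2)
  kept_ids <- vapply(kept, `[[`, character(1), "module_id")
  expect_setequal(kept_ids, c(m1$module_id, m2$module_id))

  ## nested pair: module vs the same module with a few extra weak genes
  m1_sub <- m1
  m1_sub$genes <- m1$genes[1:(length(m1$genes) - 2)]
  m1_sub$gene_scores <- m1$gene_scores[1:(length(m1$genes) - 2)]
  kept2 <- prune_unique(list(m1, m1_sub), universe, cor_limit = 0.9)
  expect_length(kept2, 1)
  expect_identical(kept2[[1]]$module_id, m1$module_id)  # more robust wins
})

test_that("robustness filtering keeps planted modules and rejects noise", {
  pl <- make_planted_z(seed = 12)
  mods <- lapply(pl$sim$truth$modules[1:2], function(tm)
    isa_iterate(gene_set(tm$indicator, tm$genes), pl$z))
  out <- filter_robust(mods, pl$z, seed = 4)
  expect_length(out, 2)
  expect_length(filter_robust(list(), pl$z, seed = 4), 0)

  noise <- make_planted_z(seed = 6, design = small_design(mu = 0))
  sn <- c(hclust_gene_sets(noise$z),
          random_gene_sets(rownames(noise$z), 10, size = 50, seed = 3))
  fit <- run_isa(sn, noise$z, seed = 9)
  expect_length(fit$modules, 0)
})

test_that("run_isa recovers planted modules with a monotone saturation curve", {
  pl <- make_planted_z(seed = 21)
  starters <- c(hclust_gene_sets(pl$z),
                random_gene_sets(rownames(pl$z), 10, size = 50, seed = 5))
  fit <- run_isa(starters, pl$z, seed = 7)
  jac <- planted_jaccards(pl$sim$truth, fit$modules)
  expect_gte(sum(jac >= 0.8), 3)
  expect_true(all(diff(fit$curve$n_modules) >= 0))

  ## duplicated starters add no modules
  fit2 <- run_isa(c(starters, starters), pl$z, seed = 7)
  expect_identical(lapply(fit2$modules, `[[`, "genes"),
                   lapply(fit$modules, `[[`, "genes"))

  ## exact planted starters recover exactly the planted modules
  truth_starters <- lapply(pl$sim$truth$modules, function(tm)
    gene_set(tm$indicator, tm$genes))
  fit3 <- run_isa(truth_starters, pl$z, seed = 7)
  expect_length(fit3$modules, length(truth_starters))

  ## determinism under a fixed seed
  fit4 <- run_isa(starters, pl$z, seed = 7)
  expect_identical(fit4$modules, fit$modules)

  ## classed result with methods
  expect_s3_class(fit, "isa_result")
  expect_output(print(fit), "modules")
  smry <- summary(fit)
  expect_s3_class(smry, "summary.isa_result")
  expect_identical(nrow(smry$table), length(fit$modules))
})

test_that("one extra iteration changes a returned module by at most the tolerance", {
  pl <- make_planted_z(seed = 30)
  for (k in 1:2) {
    tm <- pl$sim$truth$modules[[k]]
    mod <- isa_iterate(gene_set(tm$indicator, tm$genes), pl$z)
    sc <- score_conditions(mod$genes, pl$z, 1.8)
    sg <- score_genes(sc, pl$z, 3.5)
    change <- length(setdiff(union(mod$genes, names(sg)),
                             intersect(mod$genes, names(sg)))) /
      length(union(mod$genes, names(sg)))
    expect_lte(change, 0.01)
  }
})
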