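test_that("Weir-Cockerham theta matches a literal transcription oracle", {
  # toy 2-pop case: pop1 = 5 AA + 5 Aa, pop2 = 2 Aa + 8 aa
  g <- matrix(c(rep(2, 5), rep(1, 5), rep(1, 2), rep(0, 8)), ncol = 1)
  pop <- rep(c("A", "B"), each = 10)
  comp <- wc_components(g, pop)
  orc <- wc_oracle(g, pop)
  expect_equal(comp$a, orc$a, tolerance = 1e-12)
  expect_equal(comp$b, orc$b, tolerance = 1e-12)
  expect_equal(comp$c, orc$c, tolerance = 1e-12)

  # random multi-population data, with missingness
  set.seed(11)
  g2 <- matrix(rbinom(30 * 40, 2, runif(40, 0.05, 0.95)), 30, 40)
  g2[sample(length(g2), 60)] <- NA
  pop2 <- rep(c("A", "B", "C"), each = 10)
  comp2 <- wc_components(g2, pop2)
  orc2 <- wc_oracle(g2, pop2)
  expect_equal(comp2$a, orc2$a, tolerance = 1e-10)
  expect_equal(comp2$b, orc2$b, tolerance = 1e-10)
  expect_equal(comp2$c, orc2$c, tolerance = 1e-10)

  # fixed differences at every locus: theta = 1
  gf <- cbind(c(rep(2, 6), rep(0, 6)), c(rep(0, 6), rep(2, 6)))
  expect_equal(wc_theta(toy_dataset(gf, pop = rep(c("A", "B"), each = 6)))$theta, 1)

  # identical population tables: theta <= 0
  gi <- rbind(matrix(c(0, 1, 2, 1), 4, 5), matrix(c(0, 1, 2, 1), 4, 5))
  expect_lte(wc_theta(toy_dataset(gi, pop = rep(c("A", "B"), each = 4)))$theta, 0)
})

test_that("permutation test is calibrated under the null and powerful under drift", {
  sim <- cached_sim(seed = 53, n_tags = 200, pops_per_lineage = 1,
                    sample_sizes = 20, admixture_events = list())
  ds <- sim$dataset
  null_ds <- ds[ds$inds$pop == "L1P1", ]
  null_ds$inds$pop <- rep(c("A", "B"), each = 10)
  ps <- vapply(1:10, function(s)
    fst_permutation_test(null_ds, "A", "B", n_perm = 199, seed = s)$p_value,
    numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)

  # fixed-difference populations reach the +1-corrected floor
  gf <- cbind(c(rep(2, 10), rep(0, 10)), c(rep(0, 10), rep(2, 10)))
  dsf <- toy_dataset(gf, pop = rep(c("A", "B"), each = 10))
  f <- fst_permutation_test(dsf, "A", "B", n_perm = 499, seed = 1)
  expect_equal(f$p_value, 1 / 500)

  # simulated F_between = 0.05, n = 30, ~1,000 SNPs: p below the Bonferroni level
  simp <- cached_sim(seed = 54, n_tags = 200, F_between = 0.05,
                     F_within = 0.02, pops_per_lineage = 1,
                     sample_sizes = 30, admixture_events = list())
  fp <- fst_permutation_test(simp$dataset, "L1P1", "L2P1", n_perm = 10000,
                             seed = 9)
  expect_lt(fp$p_value, 0.0001)
  expect_true(fp$significant)
})

test_that("Nei's D_A and its boundary values", {
  expect_equal(nei_da(1, 1), 0)
  expect_equal(nei_da(1, 0.5), 1 - sqrt(0.5))
  expect_equal(nei_da(c(1, 1, 0), c(0, 0, 1)), 1)
  expect_error(nei_da(NA_real_, NA_real_), "no shared loci")
  # symmetry and zero diagonal on simulated frequencies
  sim <- cached_sim(seed = 51, n_tags = 60, pops_per_lineage = 2,
                    sample_sizes = 6)
  D <- da_matrix(sim$dataset)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("neighbour joining recovers topology with bootstrap support", {
  # additive 4-taxon distances: the unique unrooted topology ab|cd, checked
  # against exhaustive four-point evaluation
  Dm <- matrix(c(0, 5, 9, 10, 5, 0, 10, 11, 9, 10, 0, 7, 10, 11, 7, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  splits <- list(c("a", "b"), c("a", "c"), c("a", "d"))
  fp <- vapply(splits, function(s) {
    o <- setdiff(letters[1:4], s)
    Dm[s[1], s[2]] + Dm[o[1], o[2]]
  }, numeric(1))
  expect_equal(which.min(fp), 1L)        # four-point criterion picks ab|cd
  tr <- ape::nj(as.dist(Dm))
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))

  # duplicated population: sister pair with 100% support
  sim <- cached_sim(seed = 9, n_tags = 1000, pops_per_lineage = 2,
                    sample_sizes = 30, admixture_events = list())
  ds <- sim$dataset
  dup <- ds$inds$pop %in% c("L1P1", "L1P2")
  ds_dup <- ds
  # make L1P2 a literal copy of L1P1
  rows1 <- which(ds$inds$pop == "L1P1")
  rows2 <- which(ds$inds$pop == "L1P2")
  ds_dup$geno[rows2, ] <- ds$geno[rows1, ]
  nj1 <- nj_bootstrap(ds_dup, n_boot = 100, seed = 2)
  tr1 <- nj1$tree
  sis <- ape::is.monophyletic(ape::root(tr1, "L2P2"), c("L1P1", "L1P2"))
  expect_true(sis)
  edge_d <- cophenetic(tr1)["L1P1", "L1P2"]
  expect_lt(edge_d, 1e-8)

  # two-lineage scenario: the lineages form two clades with >= 95% support
  nj2 <- nj_bootstrap(ds, n_boot = 200, seed = 3)
  l1 <- grep("^L1", rownames(da_matrix(ds)), value = TRUE)
  tr2 <- ape::root(nj2$tree, "L2P1", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(tr2, l1))
  # support of the lineage bipartition, located via the partition table
  pp <- ape::prop.part(nj2$tree)
  labs <- attr(pp, "labels")
  k <- which(vapply(pp, function(s)
    setequal(labs[s], l1) || setequal(labs[s], setdiff(labs, l1)),
    logical(1)))
  expect_length(k, 1)
  expect_gte(nj2$support[k], 95)
})

test_that("AMOVA reproduces nested-ANOVA oracles and printed arithmetic", {
  # percent reconstruction from variance components
  expect_equal(round(variance_percents(c(54.08, 67.26, 1605.17)), 2),
               c(3.13, 3.90, 92.97))

  # 2 groups x 2 pops x 10 individuals vs the brute-force distance ANOVA
  set.seed(13)
  g <- matrix(rbinom(40 * 25, 2, runif(25, 0.1, 0.9)), 40, 25)
  pop <- rep(paste0("p", 1:4), each = 10)
  grp <- stats::setNames(c("G1", "G1", "G2", "G2"), paste0("p", 1:4))
  am <- amova_components(g, pop, grp)
  bf <- amova_oracle(g, pop, grp)
  expect_equal(unname(am$SSQ), unname(bf), tolerance = 1e-9)
  expect_equal(sum(am$df), 2 * 40 - 1)
  expect_equal(sum(am$percent), 100, tolerance = 1e-6)

  # identical populations: among components ~ 0, within ~ 100%
  gi <- do.call(rbind, rep(list(matrix(rbinom(10 * 25, 2, 0.4), 10, 25)), 4))
  ami <- amova_components(gi, pop, grp)
  expect_lt(abs(ami$percent[1]), 2)
  expect_gt(ami$percent[3], 98)

  # grouping taken from the dataset's population map
  sim <- cached_sim(seed = 9, n_tags = 1000, pops_per_lineage = 2,
                    sample_sizes = 30, admixture_events = list())
  am2 <- amova(sim$dataset)
  expect_equal(sum(am2$df), 2 * nrow(sim$dataset$geno) - 1)
  expect_gt(am2$percent[1], 0)      # lineage stratum carries variation
})

test_that("two-level AMOVA reduction equals the multilocus theta path", {
  sim <- cached_sim(seed = 51, n_tags = 60, pops_per_lineage = 2,
                    sample_sizes = 6)
  ds <- sim$dataset
  sub <- ds[ds$inds$pop %in% c("L1P1", "L2P2"), ]
  th <- wc_theta(sub)$theta
  am <- amova_components(sub$geno, sub$inds$id,
                         stats::setNames(sub$inds$pop, sub$inds$id))
  expect_equal(am$Var[1] / sum(am$Var), th, tolerance = 1e-9)
})

test_that("within-lineage differentiation stays below between-lineage", {
  for (seed in 1:5) {
    sim <- cached_sim(seed = seed, n_tags = 400, pops_per_lineage = 2,
                      sample_sizes = 12, admixture_events = list())
    pw <- pairwise_fst(sim$dataset)
    l <- sim$truth$config$lineage_of_pop[rownames(pw$theta)]
    between <- mean(pw$theta[outer(l, l, "!=") & upper.tri(pw$theta)])
    within <- mean(pw$theta[outer(l, l, "==") & upper.tri(pw$theta)])
    expect_lt(within, between)
  }
})
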