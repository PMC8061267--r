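mh_from_codes <- function(a1, a2, haplotypes) {
  n <- nrow(a1); L <- ncol(a1)
  microhap_data(a1, a2,
                tags = data.frame(tag = paste0("t", seq_len(L)),
                                  chrom = "chr1", pos = seq_len(L) * 1000),
                haplotypes = haplotypes,
                inds = data.frame(id = paste0("i", seq_len(n)), pop = "p1"))
}

test_that("painting follows the nearest-haplotype rule", {
  # 3 individuals, 1 tag: i=(00,00), j=(00,01), k=(11,11)
  a1 <- matrix(c(0L, 0L, 2L), 3, 1)
  a2 <- matrix(c(0L, 1L, 2L), 3, 1)
  cm <- paint_coancestry(mh_from_codes(a1, a2, list(c("00", "01", "11"))))
  expect_equal(cm$M["i1", "i2"], 2)
  expect_equal(cm$M["i1", "i3"], 0)
  # j's alleles: "00" nearest i (distance 0 via i's 00); "01" ties i and...
  # i carries 00 (d=1), k carries 11 (d=1): split equally
  expect_equal(cm$M["i2", "i1"], 1 + 0.5)
  expect_equal(cm$M["i2", "i3"], 0.5)
  expect_equal(diag(cm$M), c(i1 = 0, i2 = 0, i3 = 0))

  # private shared haplotype: the full unit goes to the unique carrier
  a1b <- matrix(c(3L, 3L, 0L, 1L), 4, 1)
  a2b <- matrix(c(3L, 3L, 0L, 2L), 4, 1)
  haps <- list(c("0000", "1100", "0011", "1111"))
  cmb <- paint_coancestry(mh_from_codes(a1b, a2b, haps))
  expect_equal(cmb$M["i1", "i2"], 2)   # both of i1's 1111 alleles find i2

  # identical individuals: every unit splits equally, M[i,j] = 2L/(n-1)
  a1c <- matrix(0L, 4, 3); a2c <- matrix(0L, 4, 3)
  cmc <- paint_coancestry(mh_from_codes(a1c, a2c,
                                        rep(list("0"), 3)))
  off <- cmc$M[row(cmc$M) != col(cmc$M)]
  expect_true(all(abs(off - 2 * 3 / 3) < 1e-12))
})

test_that("painting conserves mass and is invariant to tag order", {
  sim <- cached_sim(seed = 41, n_tags = 150, pops_per_lineage = 2,
                    sample_sizes = 8)
  mh <- build_microhaplotypes(sim$dataset)
  cm <- paint_coancestry(mh)
  expect_lt(max(abs(rowSums(cm$M) - 2 * cm$loci_used)), 1e-6)
  # shuffle tags
  set.seed(17)
  perm <- sample(ncol(mh$a1))
  mh2 <- microhap_data(mh$a1[, perm], mh$a2[, perm], mh$tags[perm, ],
                       mh$haplotypes[perm], mh$inds)
  cm2 <- paint_coancestry(mh2)
  expect_equal(cm$M, cm2$M, tolerance = 1e-12)
})

test_that("group summaries expose the intra/inter basin contrast", {
  sim <- cached_sim(seed = 45, n_tags = 2500, F_within = 0.05,
                    sample_sizes = 15, admixture_events = list())
  mh <- build_microhaplotypes(sim$dataset)
  cm <- paint_coancestry(mh)
  lin <- sim$truth$config$lineage_of_pop
  gs <- coancestry_group_stats(cm, basin_of_pop = lin)
  expect_equal(nrow(gs$intra_pop), 8)
  expect_false(any(is.na(gs$intra_pop$mean_coancestry)))
  intra <- unlist(gs$sets[grep("^intra", names(gs$sets))])
  expect_gt(mean(intra), mean(gs$sets$inter))
  hsd <- tukey_hsd(gs$sets, alpha = 0.001)
  expect_true(any(hsd$significant))
  # singleton population reports a missing intra mean
  one <- cm
  one$inds$pop[1] <- "solo"
  gs1 <- coancestry_group_stats(one, basin_of_pop = c(lin, solo = "L1"))
  expect_true(is.na(gs1$intra_pop$mean_coancestry[gs1$intra_pop$pop == "solo"]))
})

test_that("Tukey HSD matches the reference implementation", {
  set.seed(18)
  gr <- list(a = rnorm(8), b = rnorm(10, 0.5), c = rnorm(6, 1))
  th <- tukey_hsd(gr, alpha = 0.05)
  df <- data.frame(y = unlist(gr),
                   g = rep(names(gr), vapply(gr, length, 1L)))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, df))$g
  key <- paste(th$group2, th$group1, sep = "-")
  expect_equal(th$p, unname(ref[key, "p adj"]), tolerance = 1e-6)
  expect_equal(abs(th$diff), unname(abs(ref[key, "diff"])), tolerance = 1e-12)

  # two groups: q = |t| * sqrt(2) against the pooled t-test
  g2 <- list(a = rnorm(7), b = rnorm(9, 0.8))
  th2 <- tukey_hsd(g2)
  tt <- stats::t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(th2$q, unname(abs(tt$statistic)) * sqrt(2), tolerance = 1e-9)

  # null calibration at alpha = 0.001
  flags <- vapply(1:200, function(s) {
    set.seed(s)
    any(tukey_hsd(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)),
                  alpha = 0.001)$significant)
  }, logical(1))
  expect_gte(mean(!flags), 0.99)

  # degenerate zero-variance groups compare means exactly
  thz <- tukey_hsd(list(a = c(1, 1), b = c(1, 1), c = c(2, 2)))
  expect_equal(thz$p[thz$group1 == "a" & thz$group2 == "b"], 1)
  expect_equal(thz$p[thz$group2 == "c"], c(0, 0))
})

test_that("co-ancestry clustering recovers simulated structure", {
  sim <- cached_sim(seed = 45, n_tags = 2500, F_within = 0.05,
                    sample_sizes = 15, admixture_events = list())
  mh <- build_microhaplotypes(sim$dataset)
  cm <- paint_coancestry(mh)
  tr <- cluster_coancestry(cm)
  lin <- substr(mh$inds$pop, 1, 2)
  k2 <- stats::cutree(tr$hclust, 2)
  agree <- max(mean((k2 == 1) == (lin == "L1")),
               mean((k2 == 2) == (lin == "L1")))
  expect_gte(agree, 0.95)
  kp <- stats::cutree(tr$hclust, 8)
  expect_gte(adjusted_rand(table(kp, mh$inds$pop)), 0.7)
  # identical individuals: valid binary tree with equal merge heights
  a1 <- matrix(0L, 5, 2); a2 <- matrix(0L, 5, 2)
  cmi <- paint_coancestry(mh_from_codes(a1, a2, rep(list("0"), 2)))
  tri <- cluster_coancestry(cmi)
  expect_lt(diff(range(tri$hclust$height)), 1e-12)
  expect_equal(length(tri$tree$tip.label), 5)
})

test_that("supervised EM recovers ancestry proportions", {
  # panels with many near-fixed differences: pure individuals assign cleanly
  # and synthetic F1s land at one half
  set.seed(19)
  L <- 1000
  panels <- cbind(A = runif(L, 0.01, 0.1), B = runif(L, 0.9, 0.99))
  hap_from <- function(p, n = 5)
    matrix(rbinom(n * L, 1, rep(p, each = n)), n, L)
  pureA <- toy_dataset(hap_from(panels[, "A"]) + hap_from(panels[, "A"]))
  emp <- supervised_ancestry_em(pureA, panels)
  expect_true(all(emp$Q[, "A"] >= 0.99))
  f1 <- toy_dataset(hap_from(panels[, "A"]) + hap_from(panels[, "B"]))
  emf <- supervised_ancestry_em(f1, panels)
  expect_lt(max(abs(emf$Q[, "A"] - 0.5)), 0.05)

  # stocked-population mean source ancestry ~ 0.31, matching the truth
  sim <- cached_sim(seed = 1)
  ds <- sim$dataset
  pan <- t(sim$truth$pop_freqs[c("L1P1", "L2P1"), ])
  emr <- supervised_ancestry_em(ds[ds$inds$pop == "L1P1", ], pan)
  truth <- mean(sim$truth$ancestry[ds$inds$pop == "L1P1", "L2"])
  expect_lt(abs(mean(emr$Q[, 2]) - truth), 0.05)
  expect_lt(abs(mean(emr$Q[, 2]) - 0.31), 0.05)

  # log-likelihood is non-decreasing along every trace
  expect_true(all(vapply(emr$trace,
                         function(tr) all(diff(tr) > -1e-8), logical(1))))

  # no admixture: >= 0.95 native ancestry everywhere, with panels estimated
  # from the labelled lineage samples (the supervised reference choice)
  sim0 <- cached_sim(seed = 9, n_tags = 1000, pops_per_lineage = 2,
                     sample_sizes = 30, admixture_events = list())
  ds0 <- sim0$dataset
  lin <- substr(ds0$inds$pop, 1, 2)
  pan0 <- cbind(L1 = colMeans(ds0$geno[lin == "L1", ]) / 2,
                L2 = colMeans(ds0$geno[lin == "L2", ]) / 2)
  for (pp in unique(ds0$inds$pop)) {
    em0 <- supervised_ancestry_em(ds0[ds0$inds$pop == pp, ][1:10, ], pan0)
    expect_gte(mean(em0$Q[, substr(pp, 1, 2)]), 0.95)
  }
  # non-overlapping loci error
  expect_error(supervised_ancestry_em(pureA, panels[1:10, , drop = FALSE]),
               "loci")
})
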