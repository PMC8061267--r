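test_that("missingness/MAC filter drops exactly the right rows and columns", {
  # complete matrix with healthy MACs is untouched
  set.seed(2)
  g <- matrix(rbinom(8 * 6, 2, 0.5), 8, 6)
  while (any(snp_mac(toy_dataset(g)) < 3))
    g <- matrix(rbinom(8 * 6, 2, 0.5), 8, 6)
  ds <- toy_dataset(g)
  expect_identical(filter_missingness(ds)$geno, ds$geno)

  # 6x8: one individual half-missing, one singleton SNP
  g2 <- matrix(rbinom(6 * 8, 2, 0.45), 6, 8)
  g2[g2 == 0] <- 1                      # keep MACs comfortably high
  g2[2, 1:4] <- NA                      # individual 2: 50% missing
  g2[, 8] <- c(0, 0, 0, 0, 0, 1)        # SNP 8: minor-allele count 1
  out <- filter_missingness(toy_dataset(g2))
  expect_identical(out$inds$id, paste0("i", c(1, 3:6)))
  expect_identical(out$loci$tag, paste0("t", 1:7))
  rep <- attr(out, "filter_report")
  expect_equal(rep$individuals_dropped, 1)
  expect_equal(rep$snps_dropped_mac, 1)

  # individual pass precedes SNP pass: t1's MAC falls from 3 to 2 once the
  # half-missing individual i2 is dropped
  g3 <- rbind(c(1, 1, 2, 1, 1, 1),
              c(1, 1, NA, NA, NA, 1),   # genotype rate exactly 0.5
              c(1, 0, 1, 1, 1, 1),
              c(0, 1, 1, 2, 1, 0),
              c(0, 1, 1, 1, 2, 1),
              c(0, 0, 1, 1, 1, 0))
  out3 <- filter_missingness(toy_dataset(g3), ind_rate = 0.5, snp_rate = 0.5)
  expect_false("i2" %in% out3$inds$id)
  expect_false("t1" %in% out3$loci$tag) # MAC 2 after i2 leaves
  expect_setequal(out3$loci$tag, paste0("t", 2:6))

  # idempotent on its own output
  expect_identical(filter_missingness(out)$geno, out$geno)

  # everything filtered is an explicit error
  g4 <- matrix(NA_integer_, 3, 3)
  expect_error(filter_missingness(toy_dataset(g4)), "all individuals")
})

test_that("HDplot statistics follow the read-balance z formula", {
  # 4 heterozygotes with balanced (10,10) reads: H = 4/n, D = 0
  g <- matrix(c(1, 1, 1, 1, 0, 2, 0, 2, 0, 2), 10, 1)
  refm <- matrix(10L, 10, 1); altm <- matrix(10L, 10, 1)
  ds <- toy_dataset(g)
  hd <- hdplot(read_counts(refm, altm), ds)
  expect_equal(hd$stats$H, 4 / 10)
  expect_equal(hd$stats$D, 0)
  expect_length(hd$flagged_tags, 0)

  # 5 hets at (18,2): D = (90-10)/sqrt(100) = 8 -> flagged
  g2 <- matrix(c(rep(1, 5), rep(0, 6)), 11, 1)
  hd2 <- hdplot(read_counts(matrix(18L, 11, 1), matrix(2L, 11, 1)),
                toy_dataset(g2))
  expect_equal(hd2$stats$D, 8)
  expect_identical(hd2$flagged_tags, "t1")

  # all individuals heterozygous: H = 1 > 0.5 -> flagged
  g3 <- matrix(1L, 8, 1)
  hd3 <- hdplot(read_counts(matrix(9L, 8, 1), matrix(11L, 8, 1)),
                toy_dataset(g3))
  expect_equal(hd3$stats$H, 1)
  expect_identical(hd3$flagged_tags, "t1")

  # no heterozygote: D undefined, SNP passes the D criterion
  g4 <- matrix(c(0, 0, 2, 2), 4, 1)
  hd4 <- hdplot(read_counts(matrix(5L, 4, 1), matrix(5L, 4, 1)),
                toy_dataset(g4))
  expect_true(is.na(hd4$stats$D))
  expect_length(hd4$flagged_tags, 0)

  # a flag on one SNP removes the whole tag
  g5 <- cbind(matrix(1L, 8, 1), matrix(c(0, 1, 1, 0, 0, 0, 2, 2), 8, 1))
  ds5 <- toy_dataset(g5, tag = c("tA", "tA"))
  hd5 <- hdplot(read_counts(matrix(10L, 8, 2), matrix(10L, 8, 2)), ds5)
  expect_identical(hd5$flagged_tags, "tA")
  expect_equal(ncol(drop_flagged_tags(ds5, hd5$flagged_tags)$geno), 0)
})

test_that("one SNP per tag: highest MAF wins, first on ties", {
  # MAFs 0.10 / 0.30 / 0.30 within one tag: index 2 (first of the tie) wins
  n <- 10
  make_col <- function(mac) c(rep(1, mac), rep(0, n - mac))
  g <- cbind(make_col(2), make_col(6), make_col(6))
  ds <- toy_dataset(g, tag = rep("tagA", 3))
  out <- select_one_snp_per_tag(ds)
  expect_equal(out$loci$snp_idx, 2)

  # single-SNP tag is its own selection
  ds1 <- toy_dataset(matrix(c(0, 1, 1, 2), 4, 1))
  expect_identical(select_one_snp_per_tag(ds1)$geno, ds1$geno)

  # 20-tag set: one SNP per tag, and each winner's MAF is tag-maximal
  set.seed(4)
  tags <- rep(paste0("g", sprintf("%02d", 1:20)), each = 3)
  g20 <- matrix(rbinom(12 * 60, 2, runif(60, 0.1, 0.5)), 12, 60, byrow = TRUE)
  ds20 <- toy_dataset(g20, tag = tags)
  out20 <- select_one_snp_per_tag(ds20)
  expect_equal(ncol(out20$geno), 20)
  expect_setequal(unique(out20$loci$tag), unique(tags))
  maf_all <- snp_maf(ds20)
  maf_win <- snp_maf(out20)
  for (tg in unique(tags))
    expect_gte(maf_win[out20$loci$tag == tg] + 1e-12,
               max(maf_all[ds20$loci$tag == tg]))
})

test_that("F_IS filter removes heterozygote-deficit loci and bloated tags", {
  # all-homozygous with both alleles present: F_IS = 1 -> removed
  g <- cbind(c(0, 0, 2, 2, 0, 2),          # F_IS = 1
             c(1, 1, 0, 2, 1, 1))          # near-HWE -> retained
  ds <- toy_dataset(g)
  fis <- locus_fis(ds)
  expect_equal(unname(fis[1]), 1)
  expect_lt(abs(fis[2]), 0.35)
  out <- filter_fis(ds)
  expect_identical(out$loci$tag, "t2")

  # microhaplotype tag with 11 alleles is removed regardless of F_IS
  # (all individuals heterozygous, so F_IS alone would keep it)
  n <- 12
  a1 <- matrix(c(0:10, 0L), n, 1)
  a2 <- matrix(c(1:10, 0L, 1L), n, 1)
  mh <- microhap_data(a1, a2,
                      tags = data.frame(tag = "tX", chrom = "chr1", pos = 1),
                      haplotypes = list(sprintf("%02d", 0:10)),
                      inds = data.frame(id = paste0("i", 1:n), pop = "p"))
  expect_equal(ncol(filter_fis(mh)$a1), 0)
  expect_equal(ncol(filter_fis(mh, max_alleles = 11)$a1), 1)
})

test_that("microhaplotypes concatenate phased alleles per tag", {
  # one-SNP tag: microhap alleles coincide with SNP alleles
  h1 <- matrix(c(0L, 1L, 0L), 3, 1)
  h2 <- matrix(c(1L, 1L, 0L), 3, 1)
  mh1 <- build_microhaplotypes(toy_phased(h1, h2))
  expect_equal(mh1$tags$n_alleles, 2)
  expect_identical(mh1$haplotypes[[1]], c("0", "1"))

  # two phased SNPs, individual 0|1 and 1|0: alleles "01" and "10"
  h1 <- matrix(c(0L, 1L), 1, 2)
  h2 <- matrix(c(1L, 0L), 1, 2)
  mh2 <- build_microhaplotypes(toy_phased(h1, h2, tag = c("tA", "tA")))
  expect_identical(mh2$haplotypes[[1]], c("01", "10"))
  expect_equal(mh2$tags$n_alleles, 2)
  expect_false(mh2$a1[1, 1] == mh2$a2[1, 1])

  # three individuals sharing haplotypes {00, 01}: two alleles, dense codes
  h1 <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L))
  h2 <- rbind(c(0L, 1L), c(0L, 0L), c(0L, 1L))
  mh3 <- build_microhaplotypes(toy_phased(h1, h2, tag = c("tA", "tA")))
  expect_equal(mh3$tags$n_alleles, 2)
  expect_setequal(unique(c(mh3$a1[, 1], mh3$a2[, 1])), c(0L, 1L))

  # a missing genotype makes the haplotype missing
  h1 <- rbind(c(0L, NA), c(1L, 1L))
  h2 <- rbind(c(0L, 0L), c(1L, 1L))
  mh4 <- build_microhaplotypes(toy_phased(h1, h2, tag = c("tA", "tA")))
  expect_true(is.na(mh4$a1[1, 1]))
  expect_false(is.na(mh4$a2[1, 1]))

  # unphased data is an error
  expect_error(build_microhaplotypes(toy_dataset(matrix(1L, 2, 2))),
               "phase")
})

test_that("HDplot separates simulated paralogs from clean tags", {
  # detection on a 10%-paralog dataset
  sim <- cached_sim(seed = 12, n_tags = 1000, paralog_fraction = 0.1,
                    pops_per_lineage = 2, sample_sizes = 15)
  rc <- simulate_read_counts(sim$dataset, sim$truth, 40, seed = 13)
  ds <- sim$dataset; ds$geno <- rc$geno_obs
  hd <- hdplot(rc$counts, ds)
  truth <- sim$truth$paralog
  flagged <- names(truth) %in% hd$flagged_tags
  expect_gte(mean(flagged[truth]), 0.8)
  # false-flag rate on paralog-free data
  sim0 <- cached_sim(seed = 21, n_tags = 1000, paralog_fraction = 0)
  rc0 <- simulate_read_counts(sim0$dataset, sim0$truth, 40, seed = 22)
  ds0 <- sim0$dataset; ds0$geno <- rc0$geno_obs
  hd0 <- hdplot(rc0$counts, ds0)
  expect_lt(length(hd0$flagged_tags) / 1000, 0.02)
})

test_that("microhaplotype allele counts are bounded by the data", {
  sim <- cached_sim(seed = 51, n_tags = 60, pops_per_lineage = 2,
                    sample_sizes = 6)
  mh <- build_microhaplotypes(sim$dataset)
  n <- nrow(mh$a1)
  expect_true(all(mh$tags$n_alleles <= 2 * n))
  expect_true(all(mh$tags$n_alleles >= 1))
})
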