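# shared fixture builders; everything is generated in code at test time

# minimal geno_data from a dose matrix
toy_dataset <- function(geno, pop = NULL, chrom = NULL, tag = NULL,
                        pos = NULL, hap1 = NULL, hap2 = NULL) {
  n <- nrow(geno); L <- ncol(geno)
  if (is.null(pop)) pop <- rep("p1", n)
  if (is.null(tag)) tag <- paste0("t", seq_len(L))
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000
  snp_idx <- stats::ave(seq_len(L), tag, FUN = seq_along)
  geno_data(geno,
            loci = data.frame(chrom = chrom, pos = pos, tag = tag,
                              snp_idx = snp_idx),
            inds = data.frame(id = paste0("i", seq_len(n)), pop = pop),
            hap1 = hap1, hap2 = hap2)
}

# phased toy dataset: haplotype matrices given, doses derived
toy_phased <- function(hap1, hap2, ...) {
  toy_dataset(hap1 + hap2, hap1 = hap1, hap2 = hap2, ...)
}

# small two-lineage scenario cached per option set (sims are deterministic)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.sim_cache[[key]])) {
    cfg <- scenario_config(...)
    .sim_cache[[key]] <- simulate_metapopulation(cfg)
  }
  .sim_cache[[key]]
}

# second, literal transcription of the 1984 variance-component equations,
# one locus at a time (the independent oracle for wc_components)
wc_oracle <- function(geno, pop) {
  pops <- unique(pop)
  r <- length(pops)
  out <- vapply(seq_len(ncol(geno)), function(l) {
    x <- geno[, l]
    ok <- !is.na(x)
    ni <- vapply(pops, function(p) sum(ok & pop == p), numeric(1))
    if (any(ni == 0)) return(c(0, 0, 0))
    pi <- vapply(pops, function(p) mean(x[ok & pop == p]) / 2, numeric(1))
    hi <- vapply(pops, function(p) mean(x[ok & pop == p] == 1), numeric(1))
    nbar <- mean(ni)
    if (nbar <= 1) return(c(0, 0, 0))
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) return(c(0, 0, 0))
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    c(a, b, cc)
  }, numeric(3))
  list(a = out[1, ], b = out[2, ], c = out[3, ])
}

# brute-force gene-copy AMOVA from an explicit mismatch distance matrix
amova_oracle <- function(geno, pop, group_of_pop) {
  cp <- matrix(NA_real_, 2 * nrow(geno), ncol(geno))
  cp[seq(1, nrow(cp), 2), ] <- (geno >= 1) * 1
  cp[seq(2, nrow(cp), 2), ] <- (geno == 2) * 1
  cpop <- rep(pop, each = 2)
  cgrp <- unname(group_of_pop[cpop])
  D <- as.matrix(stats::dist(cp, method = "manhattan"))
  ss <- function(idx) sum(D[idx, idx]) / (2 * length(idx))
  SSt <- ss(seq_len(nrow(cp)))
  SSwp <- sum(vapply(unique(cpop), function(p) ss(which(cpop == p)), 1))
  SSwg <- sum(vapply(unique(cgrp), function(g) ss(which(cgrp == g)), 1))
  c(SS_a = SSt - SSwg, SS_b = SSwg - SSwp, SS_w = SSwp)
}

# ideal Wright-Fisher population sampled after several generations of drift;
# the forward-simulation oracle for the LD Ne estimator
wf_sample <- function(seed, N = 100, L = 2000, S = 50, gens = 6) {
  set.seed(seed)
  p0 <- stats::runif(L, 0.1, 0.9)
  h1 <- matrix(stats::rbinom(N * L, 1, rep(p0, each = N)), N, L)
  h2 <- matrix(stats::rbinom(N * L, 1, rep(p0, each = N)), N, L)
  for (g in seq_len(gens)) {
    gam <- function() {
      pidx <- sample.int(N, N, replace = TRUE)
      pick <- matrix(stats::runif(N * L) < 0.5, N, L)
      ifelse(pick, h1[pidx, ], h2[pidx, ])
    }
    nh1 <- gam(); nh2 <- gam()
    h1 <- nh1; h2 <- nh2
  }
  keep <- sample.int(N, S)
  toy_dataset(h1[keep, ] + h2[keep, ],
              chrom = paste0("chr", rep(1:24, length.out = L)))
}

adjusted_rand <- function(tab) {
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  e <- b * cc / choose(sum(tab), 2)
  (a - e) / ((b + cc) / 2 - e)
}
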