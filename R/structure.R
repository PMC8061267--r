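#' Weir-Cockerham variance components per locus
#'
#' Per-locus among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) components for unequal sample sizes,
#' following the 1984 moment estimators with no random-mating assumption.
#' Loci where any population has no genotype, or with fewer than two copies
#' on average, are masked to zero in all three components (they drop out of
#' the ratio of sums).
#'
#' @param geno dose matrix (individuals x loci, 0/1/2/NA).
#' @param pop factor/character of population labels, one per row.
#' @return list of numeric vectors `a`, `b`, `c` (length = loci) and logical
#'   `used`.
#' @keywords internal
wc_components <- function(geno, pop) {
  pop <- factor(pop)
  r <- nlevels(pop)
  stopifnot(r >= 2)
  X0 <- geno; X0[is.na(X0)] <- 0L
  Mi <- (!is.na(geno)) * 1L
  Het <- (geno == 1L) * 1L; Het[is.na(Het)] <- 0L
  Z <- stats::model.matrix(~ pop - 1)              # inds x r
  Ni <- t(Z) %*% Mi                                 # r x L genotyped counts
  Ai <- t(Z) %*% X0                                 # alt-allele dose sums
  Hi <- t(Z) %*% Het                                # het counts
  if (any(rowSums(Ni) == 0)) stop("a population has no data at every locus")
  ok <- colSums(Ni > 0) == r
  nbar <- colSums(Ni) / r
  nc <- (r * nbar - colSums(Ni^2) / (r * nbar)) / (r - 1)
  P <- Ai / (2 * pmax(Ni, 1))
  pbar <- colSums(Ni * P) / (r * nbar)
  s2 <- colSums(Ni * (P - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(Hi) / (r * nbar)
  ok <- ok & nbar > 1 & nc > 0
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  list(a = a, b = b, c = cc, used = ok & (a + b + cc) != 0)
}

#' Multilocus Weir-Cockerham theta
#'
#' `theta = sum(a) / sum(a + b + c)` over loci with a non-zero denominator;
#' may be negative when among-population variance is absent.
#'
#' @param ds a [geno_data].
#' @param grouping optional vector of labels per individual (defaults to the
#'   population map); pass two population names in `pops` for a pairwise
#'   estimate.
#' @param pops optional subset of populations.
#' @return list of class `fst_result`: `theta`, per-locus `a`, `b`, `c`,
#'   `n_loci_used`.
#' @export
wc_theta <- function(ds, grouping = NULL, pops = NULL) {
  if (!is.null(pops)) ds <- ds[ds$inds$pop %in% pops, ]
  if (is.null(grouping)) grouping <- ds$inds$pop
  comp <- wc_components(ds$geno, grouping)
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom == 0) stop("no locus with non-zero total variance")
  structure(list(theta = sum(comp$a) / denom, a = comp$a, b = comp$b,
                 c = comp$c, n_loci_used = sum(comp$used)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Weir-Cockerham theta =", signif(x$theta, 5),
      "over", x$n_loci_used, "loci\n")
  if (!is.null(x$p_value))
    cat("permutation p =", signif(x$p_value, 4),
        "(", x$n_perm, "permutations )\n")
  invisible(x)
}

# theta for many label assignments at once: Z is inds x B 0/1 membership of
# group A; returns length-B thetas (pairwise case, r = 2)
theta_pair_batch <- function(X0, Mi, Het, Z) {
  r <- 2
  NA_ <- crossprod(Z, Mi)                 # B x L
  AA <- crossprod(Z, X0)
  HA <- crossprod(Z, Het)
  NB <- rep(colSums(Mi), each = nrow(NA_)) - NA_
  AB <- rep(colSums(X0), each = nrow(NA_)) - AA
  HB <- rep(colSums(Het), each = nrow(NA_)) - HA
  ok <- NA_ > 0 & NB > 0
  nbar <- (NA_ + NB) / 2
  nc <- (2 * nbar - (NA_^2 + NB^2) / (2 * nbar))
  pA <- AA / (2 * pmax(NA_, 1)); pB <- AB / (2 * pmax(NB, 1))
  pbar <- (NA_ * pA + NB * pB) / (2 * nbar)
  s2 <- (NA_ * (pA - pbar)^2 + NB * (pB - pbar)^2) / nbar
  hbar <- (HA + HB) / (2 * nbar)
  ok <- ok & nbar > 1 & nc > 0
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  rowSums(a) / rowSums(a + b + cc)
}

#' Permutation test for pairwise F_ST
#'
#' Individuals (genotype rows) are permuted between the two population
#' labels, preserving sample sizes; the p-value carries the +1 correction:
#' `p = (1 + #[theta_perm >= theta_obs]) / (1 + n_perm)`.
#'
#' @param ds a [geno_data].
#' @param popA,popB the two population labels.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param alpha significance level reported alongside (the study-scale
#'   Bonferroni level 0.0001 by default).
#' @return `fst_result` with `p_value`, `n_perm`, `significant` added.
#' @export
fst_permutation_test <- function(ds, popA, popB, n_perm = 10000, seed = 1L,
                                 alpha = 0.0001) {
  sub <- ds[ds$inds$pop %in% c(popA, popB), ]
  n <- nrow(sub$geno)
  if (n < 4) stop("need at least 4 pooled individuals")
  obs <- wc_theta(sub, pops = NULL)
  set.seed(as.integer(seed))
  X0 <- sub$geno; X0[is.na(X0)] <- 0L
  Mi <- (!is.na(sub$geno)) * 1L
  Het <- (sub$geno == 1L) * 1L; Het[is.na(Het)] <- 0L
  nA <- sum(sub$inds$pop == popA)
  chunk <- 500L
  exceed <- 0L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    Z <- vapply(seq_len(b), function(k) {
      z <- numeric(n); z[sample.int(n, nA)] <- 1; z
    }, numeric(n))
    th <- theta_pair_batch(X0, Mi, Het, Z)
    exceed <- exceed + sum(th >= obs$theta)
    done <- done + b
  }
  obs$p_value <- (1 + exceed) / (1 + n_perm)
  obs$n_perm <- n_perm
  obs$alpha <- alpha
  obs$significant <- obs$p_value < alpha
  obs
}

#' Pairwise F_ST matrix with permutation significance
#'
#' @param ds a [geno_data].
#' @param n_perm permutations per pair (0 to skip testing).
#' @param seed integer seed.
#' @param alpha Bonferroni-corrected significance level.
#' @return list: `theta` (symmetric matrix), `p` (matrix or NULL),
#'   `significant` (logical matrix).
#' @export
pairwise_fst <- function(ds, n_perm = 0, seed = 1L, alpha = 0.0001) {
  pops <- sort(unique(ds$inds$pop))
  k <- length(pops)
  th <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (n_perm > 0) {
      f <- fst_permutation_test(ds, pops[i], pops[j], n_perm,
                                seed = seed + i * k + j, alpha = alpha)
      pv[i, j] <- pv[j, i] <- f$p_value
    } else {
      f <- wc_theta(ds, pops = c(pops[i], pops[j]))
    }
    th[i, j] <- th[j, i] <- f$theta
  }
  list(theta = th, p = if (n_perm > 0) pv,
       significant = if (n_perm > 0) pv < alpha)
}

#' Nei's D_A genetic distance
#'
#' `D_A = 1 - (1/L) sum_loci sum_alleles sqrt(x_a y_a)`.
#'
#' @param freqsA,freqsB allele frequencies over shared loci: either numeric
#'   vectors of alternate-allele frequencies (biallelic loci) or lists of
#'   per-locus frequency vectors (multiallelic).
#' @return The distance (scalar in `[0, 1]`).
#' @export
nei_da <- function(freqsA, freqsB) {
  1 - mean(locus_sqrt_overlap(freqsA, freqsB))
}

locus_sqrt_overlap <- function(freqsA, freqsB) {
  if (is.numeric(freqsA)) {
    stopifnot(length(freqsA) == length(freqsB))
    ok <- !is.na(freqsA) & !is.na(freqsB)
    if (!any(ok)) stop("no shared loci with defined frequencies")
    sqrt(freqsA[ok] * freqsB[ok]) + sqrt((1 - freqsA[ok]) * (1 - freqsB[ok]))
  } else {
    stopifnot(length(freqsA) == length(freqsB))
    if (!length(freqsA)) stop("no shared loci with defined frequencies")
    vapply(seq_along(freqsA), function(l)
      sum(sqrt(freqsA[[l]] * freqsB[[l]])), numeric(1))
  }
}

#' Population D_A distance matrix
#'
#' @param ds a [geno_data].
#' @param freq optional precomputed populations x SNPs frequency matrix.
#' @return symmetric distance matrix.
#' @export
da_matrix <- function(ds, freq = NULL) {
  if (is.null(freq)) freq <- pop_freq_table(ds)
  k <- nrow(freq)
  D <- matrix(0, k, k, dimnames = list(rownames(freq), rownames(freq)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    D[i, j] <- D[j, i] <- nei_da(freq[i, ], freq[j, ])
  D
}

#' Neighbour-joining dendrogram with locus bootstraps
#'
#' Saitou-Nei neighbour joining on the population D_A matrix; bootstrap
#' replicates resample loci with replacement -- whole RAD tags when tags
#' carry several SNPs, so that intra-tag linkage is not pseudo-replicated --
#' and node support is the percentage of replicate trees containing each
#' bipartition.
#'
#' @param ds a [geno_data].
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return list of class `tree_result`: `tree` (ape `phylo`, unrooted),
#'   `support` (percent per internal node), `newick` (character).
#' @export
nj_bootstrap <- function(ds, n_boot = 10000, seed = 1L) {
  pops <- sort(unique(ds$inds$pop))
  if (length(pops) < 4) stop("need at least 4 populations")
  freq <- pop_freq_table(ds)
  D <- da_matrix(ds, freq)
  tree <- ape::nj(as.dist(D))
  set.seed(as.integer(seed))
  tags <- ds$loci$tag
  utags <- unique(tags)
  by_tag <- length(utags) < length(tags)
  units <- if (by_tag) split(seq_along(tags), factor(tags, levels = utags))
           else as.list(seq_along(tags))
  boots <- vector("list", n_boot)
  for (bb in seq_len(n_boot)) {
    pick <- sample.int(length(units), replace = TRUE)
    cols <- unlist(units[pick], use.names = FALSE)
    boots[[bb]] <- ape::nj(as.dist(da_matrix(NULL, freq[, cols, drop = FALSE])))
  }
  cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / n_boot
  tree$node.label <- round(support, 1)
  structure(list(tree = tree, support = support,
                 newick = ape::write.tree(tree)),
            class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat("<tree_result>", length(x$tree$tip.label), "tips; newick:\n ",
      x$newick, "\n")
  invisible(x)
}

#' Hierarchical analysis of molecular variance
#'
#' Gene-copy-level nested ANOVA under the allele-mismatch distance: sums of
#' squares for among-groups, among-populations-within-groups and
#' within-populations strata, variance components by equating mean squares
#' to their expectations with unequal-size coefficients, and percent of
#' total variation (negative components reported as-is). Degrees of freedom
#' follow the gene-copy nesting: `G - 1`, `P - G`, `2N - P`. Loci with
#' missing genotypes contribute sums of squares from their observed copies
#' only.
#'
#' @param ds a [geno_data].
#' @param group_of_pop named vector mapping each population to a group; or
#'   `NULL` to use the `group` column of the population map.
#' @return data.frame of class `amova_result` with rows Among groups /
#'   Among populations within groups / Within populations and columns `df`,
#'   `SSQ`, `Var`, `percent`.
#' @export
amova <- function(ds, group_of_pop = NULL) {
  if (is.null(group_of_pop)) {
    u <- unique(ds$inds[, c("pop", "group")])
    group_of_pop <- stats::setNames(u$group, u$pop)
  }
  pop <- as.character(ds$inds$pop)
  if (any(!pop %in% names(group_of_pop)))
    stop("every population must be assigned to exactly one group")
  res <- amova_components(ds$geno, pop, group_of_pop)
  singles <- table(group_of_pop[unique(pop)])
  if (any(singles == 1))
    attr(res, "note") <- paste("single-population group(s):",
                               paste(names(singles)[singles == 1],
                                     collapse = ", "))
  res
}

# gene-copy nested ANOVA; geno rows = units carrying 2 copies each
amova_components <- function(geno, pop, group_of_pop) {
  pop <- factor(pop)
  grp <- factor(group_of_pop[as.character(levels(pop))])
  P <- nlevels(pop)
  G <- nlevels(grp)
  stopifnot(G >= 2)
  Z <- stats::model.matrix(~ pop - 1)
  Ni <- 2 * crossprod(Z, (!is.na(geno)) * 1L)     # P x L gene copies
  X0 <- geno; X0[is.na(X0)] <- 0L
  Ai <- crossprod(Z, X0)                           # P x L alt copies
  # per-locus per-pop SS (0/1 indicator == mismatch distance SS)
  ss_pop <- Ai - Ai^2 / pmax(Ni, 1)
  gi <- as.integer(grp)
  Ag <- rowsum(Ai, gi); Ng <- rowsum(Ni, gi)
  ss_grp <- Ag - Ag^2 / pmax(Ng, 1)
  At <- colSums(Ai); Nt <- colSums(Ni)
  ss_tot <- At - At^2 / pmax(Nt, 1)
  SS_w <- sum(ss_pop)
  SS_b <- sum(ss_grp) - SS_w
  SS_a <- sum(ss_tot) - sum(ss_grp)
  # sizes from the design (complete-data gene copies)
  n_p <- 2 * as.vector(table(pop))
  N <- sum(n_p)
  N_g <- as.vector(rowsum(n_p, gi))
  sum_np2_g <- as.vector(rowsum(n_p^2, gi))
  df <- c(G - 1, P - G, N - P)
  n1 <- (N - sum(sum_np2_g / N_g)) / (P - G)
  n2 <- (sum(sum_np2_g / N_g) - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  MS <- c(SS_a, SS_b, SS_w) / df
  s_c <- MS[3]
  s_b <- (MS[2] - s_c) / n1
  s_a <- (MS[1] - s_c - n2 * s_b) / n3
  comp <- c(s_a, s_b, s_c)
  out <- data.frame(
    stratum = c("Among groups", "Among populations within groups",
                "Within populations"),
    df = df, SSQ = c(SS_a, SS_b, SS_w), Var = comp,
    percent = variance_percents(comp))
  class(out) <- c("amova_result", "data.frame")
  out
}

#' Percent of total variation from variance components
#'
#' @param components numeric vector of variance components.
#' @return percentages summing to 100.
#' @export
variance_percents <- function(components) {
  100 * components / sum(components)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (allele-mismatch distance, gene-copy nesting)\n")
  df <- as.data.frame(x)
  df$SSQ <- round(df$SSQ, 2); df$Var <- round(df$Var, 4)
  df$percent <- round(df$percent, 2)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "note"))) cat("note:", attr(x, "note"), "\n")
  if (any(x$Var < 0))
    cat("note: negative variance component(s) reported as-is\n")
  invisible(x)
}
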