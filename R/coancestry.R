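#' Microhaplotype co-ancestry painting
#'
#' For every recipient individual and every tag it is genotyped at, each of
#' its two haplotype alleles donates one unit of co-ancestry to the
#' other genotyped individual(s) whose closest haplotype (minimal Hamming
#' distance over the tag's SNP columns, taking the better of their two
#' alleles) attains the minimum; ties split the unit equally. Rows therefore
#' conserve mass: row i sums to twice the number of tags used by i. Tags are
#' processed in genomic-position order (painting is a sum over tags, so the
#' matrix itself is order-invariant).
#'
#' @param mh a [microhap_data] with at least 3 individuals.
#' @return list of class `coancestry_matrix`: `M` (individuals x
#'   individuals, zero diagonal, not necessarily symmetric), `loci_used`
#'   (per-individual tag count), `excluded` (ids genotyped at zero tags).
#' @export
paint_coancestry <- function(mh) {
  n <- nrow(mh$a1)
  stopifnot(n >= 3)
  ord <- order(mh$tags$chrom, mh$tags$pos, method = "radix")
  ids <- mh$inds$id
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  loci_used <- integer(n)
  for (j in ord) {
    a1 <- mh$a1[, j]; a2 <- mh$a2[, j]
    gen <- which(!is.na(a1) & !is.na(a2))
    if (length(gen) < 2) next
    hap <- mh$haplotypes[[j]]
    hm <- hamming_matrix(hap)
    A1 <- a1[gen] + 1L; A2 <- a2[gen] + 1L
    # recipient allele (rows) vs donor individual (cols): best of the donor's
    # two alleles; self excluded
    for (A in list(A1, A2)) {
      D <- pmin(hm[A, A1, drop = FALSE], hm[A, A2, drop = FALSE])
      diag(D) <- Inf
      rmin <- apply(D, 1, min)
      W <- (D == rmin) * 1
      W <- W / rowSums(W)
      M[gen, gen] <- M[gen, gen] + W
    }
    loci_used[gen] <- loci_used[gen] + 1L
  }
  excluded <- ids[loci_used == 0]
  if (length(excluded))
    warning("individual(s) genotyped at zero tags excluded from painting: ",
            paste(excluded, collapse = ", "))
  structure(list(M = M, loci_used = stats::setNames(loci_used, ids),
                 excluded = excluded, inds = mh$inds),
            class = "coancestry_matrix")
}

hamming_matrix <- function(haps) {
  k <- length(haps)
  s <- strsplit(haps, "")
  H <- matrix(0L, k, k)
  if (k > 1)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      H[i, j] <- H[j, i] <- sum(s[[i]] != s[[j]])
  H
}

#' @export
print.coancestry_matrix <- function(x, ...) {
  cat("<coancestry_matrix>", nrow(x$M), "individuals; mean off-diagonal",
      signif(mean(x$M[row(x$M) != col(x$M)]), 4), "\n")
  invisible(x)
}

#' Group-level co-ancestry summaries
#'
#' Per-population mean intra-population co-ancestry (average of `M[i, j]`
#' over ordered pairs within the population; `NA` for singleton
#' populations), and -- for a focal set of basins -- the pairwise score sets
#' for intra-basin (same basin, different population) and inter-basin
#' comparisons, ready for a Tukey HSD contrast.
#'
#' @param cm a [paint_coancestry()] result.
#' @param basin_of_pop named vector mapping populations to basins; `NULL`
#'   uses the `drainage` column of the individual table.
#' @param basins optional subset of basins to contrast (default: all).
#' @return list: `intra_pop` (data.frame `pop`, `mean_coancestry`, `n`),
#'   `sets` (named list of numeric vectors: one `intra_<basin>` per basin
#'   and one `inter`).
#' @export
coancestry_group_stats <- function(cm, basin_of_pop = NULL, basins = NULL) {
  M <- cm$M
  pop <- cm$inds$pop
  if (is.null(basin_of_pop)) {
    u <- unique(cm$inds[, c("pop", "drainage")])
    basin_of_pop <- stats::setNames(u$drainage, u$pop)
  }
  pops <- sort(unique(pop))
  intra <- data.frame(pop = pops, mean_coancestry = NA_real_,
                      n = as.vector(table(factor(pop, pops))))
  off <- row(M) != col(M)
  for (k in seq_along(pops)) {
    sel <- pop == pops[k]
    if (sum(sel) < 2) next
    sub <- M[sel, sel, drop = FALSE]
    intra$mean_coancestry[k] <- mean(sub[row(sub) != col(sub)])
  }
  basin <- unname(basin_of_pop[pop])
  if (is.null(basins)) basins <- sort(unique(basin))
  inb <- basin %in% basins
  sets <- list()
  for (bs in basins) {
    sel <- which(basin == bs)
    if (length(sel) < 2) next
    pp <- pop[sel]
    sub <- M[sel, sel, drop = FALSE]
    pick <- outer(pp, pp, "!=")            # same basin, different population
    if (any(pick)) sets[[paste0("intra_", bs)]] <- sub[pick]
  }
  ii <- which(inb)
  pickx <- outer(basin[ii], basin[ii], "!=")
  if (any(pickx)) sets$inter <- M[ii, ii][pickx]
  list(intra_pop = intra, sets = sets)
}

#' Tukey's honestly-significant-difference test
#'
#' One-way ANOVA mean square error across the groups, pairwise studentized
#' range statistics with the Tukey-Kramer adjustment for unequal group
#' sizes, and p-values from the studentized range distribution.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha significance level for the flags (default 0.001).
#' @return data.frame: `group1`, `group2`, `diff`, `q`, `p`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.001) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  n <- vapply(groups, length, 1L)
  m <- vapply(groups, mean, 1)
  N <- sum(n)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1)) / (N - k)
  df <- N - k
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff <- m[j] - m[i]
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))   # Tukey-Kramer
    if (se == 0) {                                 # zero variance everywhere
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    c(diff = unname(diff), q = unname(q), p = unname(p))
  })
  out <- data.frame(group1 = names(groups)[pairs[1, ]],
                    group2 = names(groups)[pairs[2, ]],
                    diff = res["diff", ], q = res["q", ], p = res["p", ])
  out$significant <- out$p < alpha
  out
}

#' Average-linkage clustering of the co-ancestry matrix
#'
#' The painting matrix is symmetrized, converted to a dissimilarity by
#' max-minus, and clustered by average-linkage agglomeration; a stand-in for
#' full MCMC population-configuration inference when only the tree over
#' individuals is needed.
#'
#' @param cm a [paint_coancestry()] result (or a plain matrix).
#' @return list of class `coancestry_tree`: `hclust`, `tree` (ape phylo),
#'   `newick`.
#' @export
cluster_coancestry <- function(cm) {
  M <- if (inherits(cm, "coancestry_matrix")) cm$M else as.matrix(cm)
  S <- (M + t(M)) / 2
  D <- max(S) - S
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  tr <- ape::as.phylo(hc)
  structure(list(hclust = hc, tree = tr, newick = ape::write.tree(tr)),
            class = "coancestry_tree")
}

#' @export
print.coancestry_tree <- function(x, ...) {
  cat("<coancestry_tree>", length(x$tree$tip.label), "individuals\n")
  invisible(x)
}

#' Supervised ancestry proportions by EM
#'
#' Maximizes `sum_loci log sum_k q_k P(allele | panel k)` per individual,
#' treating each of the two gene copies at a locus as an independent draw
#' from a mixture of the K reference panels: the E step assigns each copy to
#' panels in proportion to `q_k p_k` (alternate copy) or `q_k (1-p_k)`
#' (reference copy), the M step averages the responsibilities. Convergence
#' when `max |dq| < tol` or after `max_iter` iterations; the log-likelihood
#' is non-decreasing and is returned per iteration.
#'
#' @param ds a [geno_data] of target individuals.
#' @param panels loci x K matrix of panel alternate-allele frequencies
#'   (rownames optional; row order must match `ds` loci).
#' @param tol convergence tolerance on max absolute change in q.
#' @param max_iter iteration cap.
#' @return list of class `ancestry_result`: `Q` (individuals x K, rows sum
#'   to 1), `loglik` (final value per individual), `n_iter`, `trace` (one
#'   per-iteration log-likelihood vector per individual).
#' @export
supervised_ancestry_em <- function(ds, panels, tol = 1e-6, max_iter = 500) {
  panels <- as.matrix(panels)
  K <- ncol(panels)
  stopifnot(K >= 2)
  if (nrow(panels) != ncol(ds$geno))
    stop("panels must cover the dataset's loci")
  eps <- 1e-6
  pk <- pmin(pmax(panels, eps), 1 - eps)
  n <- nrow(ds$geno)
  Q <- matrix(1 / K, n, K,
              dimnames = list(ds$inds$id, colnames(panels)))
  ll <- numeric(n)
  iters <- integer(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    g <- ds$geno[i, ]
    ok <- !is.na(g)
    if (!any(ok)) stop("individual ", ds$inds$id[i],
                       " shares no genotyped loci with the panels")
    # per-copy allele observations: n_alt copies carry alt, n_ref carry ref
    alt_copies <- g[ok]
    ref_copies <- 2 - alt_copies
    P <- pk[ok, , drop = FALSE]
    q <- rep(1 / K, K)
    tr <- numeric(0)
    for (it in seq_len(max_iter)) {
      fa <- P %*% diag(q, K)               # loci x K: q_k p_k
      fr <- (1 - P) %*% diag(q, K)
      sa <- rowSums(fa); sr <- rowSums(fr)
      llv <- sum(alt_copies * log(sa) + ref_copies * log(sr))
      tr <- c(tr, llv)
      resp <- colSums(fa / sa * alt_copies) + colSums(fr / sr * ref_copies)
      q_new <- resp / sum(resp)
      if (max(abs(q_new - q)) < tol) { q <- q_new; break }
      q <- q_new
    }
    Q[i, ] <- q
    ll[i] <- tr[length(tr)]
    iters[i] <- length(tr)
    traces[[i]] <- tr
  }
  structure(list(Q = Q, loglik = ll, n_iter = iters, trace = traces),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat("<ancestry_result>", nrow(x$Q), "individuals x", ncol(x$Q),
      "sources; mean q:\n")
  print(round(colMeans(x$Q), 4))
  invisible(x)
}

#' Allele-frequency reference panels from labelled populations
#'
#' @param ds a [geno_data].
#' @param pops populations to use as panels.
#' @return loci x K matrix of alternate-allele frequencies.
#' @export
reference_panels <- function(ds, pops) {
  out <- vapply(pops, function(pp) snp_freq(ds, pp), numeric(ncol(ds$geno)))
  colnames(out) <- pops
  out
}

#' Heatmap of the co-ancestry matrix
#'
#' Individuals ordered by the average-linkage dendrogram.
#'
#' @param x a [coancestry_matrix].
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.coancestry_matrix <- function(x, ...) {
  ord <- cluster_coancestry(x)$hclust$order
  S <- ((x$M + t(x$M)) / 2)[ord, ord]
  graphics::image(seq_len(nrow(S)), seq_len(ncol(S)), S,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "", axes = FALSE, ...)
  invisible(x)
}
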