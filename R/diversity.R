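#' Per-population genetic diversity statistics
#'
#' Per locus: observed heterozygosity `Ho = n_het / n`, unbiased expected
#' heterozygosity `He = (2n/(2n-1)) (1 - sum p^2)`, and rarefied allelic
#' richness `A_r = sum_a [1 - choose(N - N_a, g) / choose(N, g)]` with `N`
#' gene copies of which `N_a` carry allele `a`, at a standard rarefaction
#' size of `g` gene copies. `F_IS` is the multilocus ratio of means,
#' `1 - mean(Ho) / mean(He)`, over polymorphic loci. Headline `Ho`/`He`
#' averages include all loci with at least one genotype; averages restricted
#' to polymorphic loci are also returned.
#'
#' @param ds a [geno_data].
#' @param population population label (one of `ds$inds$pop`).
#' @param rarefaction_g rarefaction size in gene copies; defaults to the
#'   smallest per-locus gene-copy count in this population. An error asks
#'   for a smaller `g` if any locus has fewer than `g` copies.
#' @return A list of class `diversity_stats`: `Ho`, `He`, `Ar`, `Fis`,
#'   `n_loci`, `g`, plus `Ho_poly`/`He_poly` (polymorphic-only averages).
#' @export
pop_diversity <- function(ds, population, rarefaction_g = NULL) {
  g0 <- pop_rows(ds, population)
  n <- colSums(!is.na(g0))
  use <- n >= 2
  if (!any(use)) stop("no locus with at least two genotyped individuals")
  g0 <- g0[, use, drop = FALSE]
  n <- n[use]
  p <- colMeans(g0, na.rm = TRUE) / 2
  ho <- colSums(g0 == 1L, na.rm = TRUE) / n
  he <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
  if (is.null(rarefaction_g)) rarefaction_g <- min(2 * n)
  if (rarefaction_g > min(2 * n))
    stop("rarefaction_g exceeds the gene copies at some locus; ",
         "use g <= ", min(2 * n))
  N <- 2 * n
  alt <- round(p * N)
  ar <- rarefied_richness(alt, N - alt, rarefaction_g)
  poly <- he > 0
  fis <- if (any(poly)) 1 - mean(ho[poly]) / mean(he[poly]) else NA_real_
  structure(list(
    Ho = mean(ho), He = mean(he), Ar = mean(ar), Fis = fis,
    Ho_poly = if (any(poly)) mean(ho[poly]) else NA_real_,
    He_poly = if (any(poly)) mean(he[poly]) else NA_real_,
    n_loci = length(n), g = rarefaction_g,
    per_locus = data.frame(Ho = ho, He = he, Ar = ar)),
    class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("Ho = ", signif(x$Ho, 4), "  He = ", signif(x$He, 4),
      "  Ar = ", signif(x$Ar, 4), " (g = ", x$g, ")  Fis = ",
      signif(x$Fis, 4), "  [", x$n_loci, " loci]\n", sep = "")
  invisible(x)
}

# expected allele count in a rarefied draw of g copies, biallelic
rarefied_richness <- function(n_alt, n_ref, g) {
  N <- n_alt + n_ref
  miss_alt <- exp(lchoose(N - n_alt, g) - lchoose(N, g))
  miss_ref <- exp(lchoose(N - n_ref, g) - lchoose(N, g))
  miss_alt[n_alt == 0] <- 1
  miss_ref[n_ref == 0] <- 1
  (1 - miss_alt) + (1 - miss_ref)
}

#' Effective size from drift-attributable squared correlation
#'
#' The closed form for unlinked loci,
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2)) / (2 r2)`; `Inf` when the drift signal
#' `r2` is zero or negative (no detectable drift disequilibrium).
#'
#' @param r2_drift mean squared correlation after subtracting the sampling
#'   expectation.
#' @return Effective population size (possibly `Inf`).
#' @export
ne_from_r2drift <- function(r2_drift) {
  if (r2_drift <= 0) return(Inf)
  disc <- max(0, 1 / 9 - 2.76 * r2_drift)
  (1 / 3 + sqrt(disc)) / (2 * r2_drift)
}

#' Diversity table for every population
#'
#' @param ds a [geno_data].
#' @param rarefaction_g shared rarefaction size; defaults to the smallest
#'   per-locus gene-copy count across populations.
#' @return data.frame, one row per population, columns `pop`, `n`, `Ho`,
#'   `He`, `Ar`, `Fis`.
#' @export
diversity_table <- function(ds, rarefaction_g = NULL) {
  pops <- sort(unique(ds$inds$pop))
  if (is.null(rarefaction_g)) {
    rarefaction_g <- min(vapply(pops, function(pp) {
      g <- pop_rows(ds, pp)
      min(2 * colSums(!is.na(g)))
    }, numeric(1)))
  }
  rows <- lapply(pops, function(pp) {
    d <- pop_diversity(ds, pp, rarefaction_g)
    data.frame(pop = pp, n = sum(ds$inds$pop == pp), Ho = d$Ho, He = d$He,
               Ar = d$Ar, Fis = d$Fis)
  })
  do.call(rbind, rows)
}

#' Effective population size from inter-chromosomal linkage disequilibrium
#'
#' The bias-corrected LD method: for every pair of SNPs on different
#' chromosomes, Burrows' composite disequilibrium is estimated from genotype
#' doses as `Delta = cov(x, y) / 2` (sample covariance, denominator S-1) and
#' squared correlation `r2 = Delta^2 / (p(1-p) q(1-q))`. Loci with minor
#' allele frequency below `pcrit` are excluded. The mean `r2` (weighted by
#' pairwise sample size) is corrected for sampling:
#' `r2_drift = r2 - 1/S - 3.19/S^2` for S >= 30 (or
#' `r2 - 0.0018 - 0.907/S - 4.44/S^2` for smaller S), and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2_drift)) / (2 r2_drift)`, infinite when
#' `r2_drift <= 0`. The parametric 95% CI treats the number of pairs as
#' chi-squared degrees of freedom for `r2`.
#'
#' @param ds a [geno_data] whose loci carry chromosome labels.
#' @param population population label.
#' @param pcrit minor-allele-frequency screen (default 0.05).
#' @param max_loci cap on the number of SNPs used (random subset, reproducible
#'   via `sub_seed`); keeps the pairwise computation tractable.
#' @param sub_seed seed for the locus subsample.
#' @return A list of class `ne_estimate`: `r2_mean`, `S`, `Ne`, `CI`
#'   (length-2), `n_pairs`, `n_loci`. `Ne` is `Inf` (printed "Infinite") when
#'   the drift signal is at or below the sampling expectation.
#' @export
ld_ne <- function(ds, population, pcrit = 0.05, max_loci = 2000,
                  sub_seed = 1L) {
  g <- pop_rows(ds, population)
  chrom <- ds$loci$chrom
  if (length(unique(chrom)) < 2)
    stop("at least two chromosomes are required for inter-chromosomal pairs")
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & pmin(p, 1 - p) >= pcrit &
    colSums(!is.na(g)) == nrow(g)   # complete genotypes keep S per-pair equal
  if (sum(keep) < 2) stop("no qualifying locus pairs")
  g <- g[, keep, drop = FALSE]
  chrom <- chrom[keep]
  if (ncol(g) > max_loci) {
    set.seed(as.integer(sub_seed))
    j <- sort(sample.int(ncol(g), max_loci))
    g <- g[, j, drop = FALSE]
    chrom <- chrom[j]
  }
  S <- nrow(g)
  if (S < 10) stop("sample size below 10")
  x <- scale(g, center = TRUE, scale = FALSE)
  C <- crossprod(x) / (S - 1)          # covariance of doses
  p <- colMeans(g) / 2
  v <- p * (1 - p)
  r2 <- (C / 2)^2 / outer(v, v)
  inter <- outer(chrom, chrom, "!=")
  ut <- upper.tri(r2)
  sel <- ut & inter
  if (!any(sel)) stop("no qualifying locus pairs")
  r2_mean <- mean(r2[sel])
  n_pairs <- sum(sel)
  exp_s <- if (S >= 30) 1 / S + 3.19 / S^2 else
    0.0018 + 0.907 / S + 4.44 / S^2
  est <- function(r2m) ne_from_r2drift(r2m - exp_s)
  ne <- est(r2_mean)
  df <- n_pairs
  lo_r2 <- r2_mean * df / stats::qchisq(0.025, df, lower.tail = FALSE)
  hi_r2 <- r2_mean * df / stats::qchisq(0.975, df, lower.tail = FALSE)
  ci <- sort(c(est(lo_r2), est(hi_r2)))
  structure(list(r2_mean = r2_mean, S = S, Ne = ne, CI = ci,
                 n_pairs = n_pairs, n_loci = ncol(g), pcrit = pcrit),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "Infinite" else format(round(v, 1))
  cat("Ne = ", fmt(x$Ne), "  95% CI [", fmt(x$CI[1]), ", ", fmt(x$CI[2]),
      "]\n  mean r2 = ", signif(x$r2_mean, 5), " over ", x$n_pairs,
      " inter-chromosomal pairs (", x$n_loci, " loci, S = ", x$S, ")\n",
      sep = "")
  invisible(x)
}
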