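#' Filter individuals and SNPs on genotype rate and minor-allele count
#'
#' One pass in narrative order: individuals with a genotype rate at or below
#' `ind_rate` are dropped first; SNP rates and minor-allele counts are then
#' recomputed on the surviving individuals, and SNPs with a rate at or below
#' `snp_rate` or a minor-allele count below `mac` are dropped. The pass is
#' idempotent on complete data and is not iterated to convergence.
#'
#' @param ds a [geno_data].
#' @param ind_rate minimum (exclusive) fraction of SNPs genotyped per
#'   retained individual.
#' @param snp_rate minimum (exclusive) fraction of individuals genotyped per
#'   retained SNP.
#' @param mac minimum (inclusive) minor-allele count per retained SNP.
#' @return The filtered [geno_data]; attribute `"filter_report"` holds the
#'   counts dropped at each step.
#' @export
filter_missingness <- function(ds, ind_rate = 0.8, snp_rate = 0.8, mac = 3) {
  stopifnot(nrow(ds$geno) > 0, ncol(ds$geno) > 0)
  gr_ind <- rowMeans(!is.na(ds$geno))
  keep_ind <- gr_ind > ind_rate
  if (!any(keep_ind))
    stop("all individuals removed by the genotype-rate filter")
  ds2 <- ds[keep_ind, ]
  gr_snp <- colMeans(!is.na(ds2$geno))
  mac_snp <- snp_mac(ds2)
  keep_snp <- gr_snp > snp_rate & mac_snp >= mac
  out <- ds2[, keep_snp]
  attr(out, "filter_report") <- list(
    individuals_dropped = sum(!keep_ind),
    snps_dropped_rate = sum(gr_snp <= snp_rate),
    snps_dropped_mac = sum(gr_snp > snp_rate & mac_snp < mac),
    individuals_kept = sum(keep_ind), snps_kept = sum(keep_snp))
  out
}

#' HDplot paralog statistics and tag flags
#'
#' For every SNP, `H` is the proportion of genotyped individuals that are
#' heterozygous and `D` is the z-score of the pooled heterozygote read
#' balance, `D = (sum(ref) - sum(alt)) / sqrt(sum(ref) + sum(alt))` over
#' heterozygous individuals -- the binomial(1/2) standardized deviate. A
#' collapsed duplicate inflates `H` and drives `|D|` away from 0, so a tag is
#' flagged as a putative duplicate when any of its SNPs has `H > max_h` or
#' `|D| > max_d`. SNPs with no heterozygote (or no heterozygote reads) have
#' undefined `D` and pass the `D` criterion by convention.
#'
#' @param counts a [read_counts] aligned with `ds`.
#' @param ds a [geno_data].
#' @param max_h heterozygosity threshold (default 0.5).
#' @param max_d absolute read-ratio deviation threshold (default 7).
#' @return A list: `stats` (data.frame per SNP: `tag`, `H`, `D`, `flag_snp`)
#'   and `flagged_tags` (character vector of putative duplicate tags).
#' @export
hdplot <- function(counts, ds, max_h = 0.5, max_d = 7) {
  stopifnot(inherits(counts, "read_counts"),
            all(dim(counts$ref) == dim(ds$geno)))
  het <- !is.na(ds$geno) & ds$geno == 1L
  n_het <- colSums(het)
  n_gen <- colSums(!is.na(ds$geno))
  H <- ifelse(n_gen > 0, n_het / n_gen, NA_real_)
  refh <- colSums(counts$ref * het)
  alth <- colSums(counts$alt * het)
  tot <- refh + alth
  D <- ifelse(n_het > 0 & tot > 0, (refh - alth) / sqrt(tot), NA_real_)
  flag_snp <- (H > max_h) | (!is.na(D) & abs(D) > max_d)
  flag_snp[is.na(flag_snp)] <- FALSE
  st <- data.frame(tag = ds$loci$tag, H = H, D = D, flag_snp = flag_snp)
  flagged <- unique(st$tag[st$flag_snp])
  list(stats = st, flagged_tags = flagged)
}

#' Drop putative duplicate tags flagged by HDplot
#'
#' @param ds a [geno_data].
#' @param flagged_tags tags to remove (all their SNPs are dropped: collapsed
#'   duplication is a tag-level artifact).
#' @return The filtered [geno_data].
#' @export
drop_flagged_tags <- function(ds, flagged_tags) {
  ds[, !(ds$loci$tag %in% flagged_tags)]
}

#' Keep the highest-MAF SNP of each tag
#'
#' Exactly one SNP per tag survives: the SNP with the highest minor allele
#' frequency; when two or more SNPs of a tag tie, the first (lowest
#' within-tag index) is taken.
#'
#' @param ds a [geno_data].
#' @return A [geno_data] with one SNP per tag.
#' @export
select_one_snp_per_tag <- function(ds) {
  maf <- snp_maf(ds)
  ord <- order(ds$loci$tag, -maf, ds$loci$snp_idx, method = "radix")
  keep <- ord[!duplicated(ds$loci$tag[ord])]
  ds[, sort(keep)]
}

#' Per-locus inbreeding coefficient over all individuals
#'
#' `F_IS = 1 - Ho/He` with the small-sample unbiased gene diversity
#' `He = (2n/(2n-1)) * (1 - sum p^2)`; `NA` for monomorphic loci (He = 0).
#'
#' @param ds a [geno_data].
#' @return Numeric vector, one value per SNP.
#' @export
locus_fis <- function(ds) {
  n <- colSums(!is.na(ds$geno))
  p <- snp_freq(ds)
  he <- (2 * n / pmax(2 * n - 1, 1)) * (1 - p^2 - (1 - p)^2)
  ho <- colSums(ds$geno == 1L, na.rm = TRUE) / n
  unname(ifelse(he > 0, 1 - ho / he, NA_real_))
}

#' Remove loci with excess homozygosity (and over-split microhaplotypes)
#'
#' Loci whose global `F_IS` exceeds `max_fis` are removed. On microhaplotype
#' data, tags with more than `max_alleles` observed haplotype alleles are
#' additionally removed regardless of `F_IS`.
#'
#' @param x a [geno_data] or [microhap_data].
#' @param max_fis maximum retained `F_IS` (default 0.5).
#' @param max_alleles maximum retained allele count for microhaplotype tags
#'   (default 10).
#' @return The filtered object, same class as `x`.
#' @export
filter_fis <- function(x, max_fis = 0.5, max_alleles = 10) {
  if (inherits(x, "geno_data")) {
    fis <- locus_fis(x)
    return(x[, !(!is.na(fis) & fis > max_fis)])
  }
  stopifnot(inherits(x, "microhap_data"))
  fis <- microhap_fis(x)
  keep <- x$tags$n_alleles <= max_alleles & !(!is.na(fis) & fis > max_fis)
  microhap_data(x$a1[, keep, drop = FALSE], x$a2[, keep, drop = FALSE],
                x$tags[keep, , drop = FALSE], x$haplotypes[keep], x$inds)
}

#' Per-tag inbreeding coefficient of a microhaplotype dataset
#'
#' @param mh a [microhap_data].
#' @return Numeric vector, one multiallelic `F_IS` per tag (`NA` where
#'   monomorphic).
#' @export
microhap_fis <- function(mh) {
  vapply(seq_len(ncol(mh$a1)), function(j) {
    a1 <- mh$a1[, j]; a2 <- mh$a2[, j]
    ok <- !is.na(a1) & !is.na(a2)
    n <- sum(ok)
    if (n == 0) return(NA_real_)
    tab <- table(c(a1[ok], a2[ok]))
    p <- tab / (2 * n)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    if (he <= 0) return(NA_real_)
    ho <- mean(a1[ok] != a2[ok])
    1 - ho / he
  }, numeric(1))
}

#' Assemble microhaplotypes from phased SNP genotypes
#'
#' For every tag, each individual's two haplotypes are the concatenation of
#' its phased alleles at the whitelisted SNPs of that tag; a haplotype with
#' any missing genotype is missing. Haplotype alleles are coded densely, in
#' order of first observation (scanning individuals in order, first haplotype
#' then second). The whitelist is the set of individuals and SNPs surviving
#' the missingness and HDplot filters -- before the one-SNP-per-tag
#' selection, which applies only to the single-SNP branch.
#'
#' @param ds a phased [geno_data] (already reduced to whitelisted
#'   individuals and SNPs).
#' @return A [microhap_data] with one multiallelic marker per tag, positioned
#'   at the tag's first SNP.
#' @export
build_microhaplotypes <- function(ds) {
  if (is.null(ds$hap1)) stop("phase matrices are required to build microhaplotypes")
  tags <- unique(ds$loci$tag)
  idx <- split(seq_len(ncol(ds$geno)), factor(ds$loci$tag, levels = tags))
  n_ind <- nrow(ds$geno)
  a1 <- a2 <- matrix(NA_integer_, n_ind, length(tags))
  haplos <- vector("list", length(tags))
  for (k in seq_along(tags)) {
    j <- idx[[k]]
    h1 <- ds$hap1[, j, drop = FALSE]
    h2 <- ds$hap2[, j, drop = FALSE]
    s1 <- apply(h1, 1, paste0, collapse = "")
    s2 <- apply(h2, 1, paste0, collapse = "")
    s1[rowSums(is.na(h1)) > 0] <- NA
    s2[rowSums(is.na(h2)) > 0] <- NA
    # codes in order of first observation over (ind1 hap1, ind1 hap2, ...)
    inter <- as.vector(rbind(s1, s2))
    lev <- unique(inter[!is.na(inter)])
    a1[, k] <- match(s1, lev) - 1L
    a2[, k] <- match(s2, lev) - 1L
    haplos[[k]] <- lev
  }
  first <- !duplicated(ds$loci$tag)
  tag_tab <- data.frame(tag = ds$loci$tag[first],
                        chrom = ds$loci$chrom[first],
                        pos = ds$loci$pos[first])
  tag_tab <- tag_tab[match(tags, tag_tab$tag), ]
  microhap_data(a1, a2, tag_tab, haplos, ds$inds)
}

#' Run the full genotype-filtering branch pair
#'
#' Applies the narrative filter order: individuals and SNPs on genotype rate
#' and minor-allele count, HDplot tag flags, then branch A (one SNP per tag
#' followed by the `F_IS` filter) and branch B (microhaplotype assembly from
#' the whitelist, followed by the allele-count and `F_IS` filters).
#'
#' @param ds a phased [geno_data].
#' @param counts a [read_counts] aligned with `ds` (before filtering).
#' @param ind_rate,snp_rate,mac see [filter_missingness()].
#' @param max_h,max_d see [hdplot()].
#' @param max_fis,max_alleles see [filter_fis()].
#' @return A list: `snp` (single-SNP [geno_data]), `microhap`
#'   ([microhap_data]), `whitelist` (the post-HDplot [geno_data]), and
#'   `report` (counts at every step).
#' @export
filter_pipeline <- function(ds, counts, ind_rate = 0.8, snp_rate = 0.8,
                            mac = 3, max_h = 0.5, max_d = 7, max_fis = 0.5,
                            max_alleles = 10) {
  ds1 <- filter_missingness(ds, ind_rate, snp_rate, mac)
  rep1 <- attr(ds1, "filter_report")
  keep_i <- match(ds1$inds$id, ds$inds$id)
  keep_j <- match(paste0(ds1$loci$tag, "_", ds1$loci$snp_idx),
                  paste0(ds$loci$tag, "_", ds$loci$snp_idx))
  cnt1 <- read_counts(counts$ref[keep_i, keep_j, drop = FALSE],
                      counts$alt[keep_i, keep_j, drop = FALSE])
  hd <- hdplot(cnt1, ds1, max_h, max_d)
  ds2 <- drop_flagged_tags(ds1, hd$flagged_tags)
  snp <- filter_fis(select_one_snp_per_tag(ds2), max_fis)
  mh <- filter_fis(build_microhaplotypes(ds2), max_fis, max_alleles)
  list(snp = snp, microhap = mh, whitelist = ds2,
       report = c(rep1, list(
         tags_flagged_hdplot = length(hd$flagged_tags),
         snps_after_hdplot = ncol(ds2$geno),
         snps_final = ncol(snp$geno),
         microhap_tags_final = ncol(mh$a1))))
}
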