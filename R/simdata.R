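#' Scenario configuration for the synthetic metapopulation generator
#'
#' Describes a stocked metapopulation: two (or more) deeply diverged glacial
#' lineages, populations nested in drainages within lineages, RAD tags
#' carrying 1-10 phased SNPs spread over a multi-chromosome map, stocking
#' admixture pulses into recipient populations, and a minority of collapsed
#' paralogous tags. Defaults emulate the study system the package targets:
#' two lineages at pairwise differentiation ~0.07 between and ~0.04 within,
#' and one heavy historical stocking event in which 2/3 of the recipient
#' population are hybrids carrying on average 46% source ancestry (population
#' mean source ancestry ~0.31).
#'
#' @param n_lineages number of deeply diverged lineages.
#' @param pops_per_lineage populations per lineage.
#' @param drainages_per_lineage drainages per lineage; populations are
#'   assigned to drainages round-robin and drainages are spatial blocks.
#' @param n_tags number of RAD tags.
#' @param snps_per_tag integer range (length-2) of SNPs per tag, within 1-10.
#' @param n_chromosomes chromosome count of the reference map.
#' @param chrom_length chromosome length in bp.
#' @param F_between target realized pairwise differentiation (Weir-Cockerham
#'   theta scale) between populations of different lineages.
#' @param F_within target realized pairwise differentiation within a lineage.
#' @param admixture_events list of stocking events, each a list with fields
#'   `recipient` (population label), `source` (population label), `p_adm`
#'   (per-haplotype source probability among hybrids) and
#'   `fraction_pure_native` (fraction of the recipient left untouched).
#' @param sample_sizes individuals sampled per population (scalar or named by
#'   population).
#' @param mean_depth mean sequencing depth (reads per SNP per individual).
#' @param paralog_fraction fraction of tags simulated as collapsed duplicates.
#' @param seed integer random seed; all randomness flows from it.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_lineages = 2, pops_per_lineage = 4,
                            drainages_per_lineage = 2,
                            n_tags = 1000, snps_per_tag = c(1, 10),
                            n_chromosomes = 24, chrom_length = 1.7e6,
                            F_between = 0.07, F_within = 0.04,
                            admixture_events = list(
                              list(recipient = "L1P1", source = "L2P1",
                                   p_adm = 0.46, fraction_pure_native = 1 / 3)),
                            sample_sizes = 30, mean_depth = 40,
                            paralog_fraction = 0.05, seed = 1L) {
  stopifnot(n_lineages >= 1, pops_per_lineage >= 1, n_tags >= 1,
            n_chromosomes >= 1, chrom_length > 0)
  if (length(snps_per_tag) == 1) snps_per_tag <- rep(snps_per_tag, 2)
  if (snps_per_tag[1] < 1 || snps_per_tag[2] > 10 ||
      snps_per_tag[1] > snps_per_tag[2])
    stop("snps_per_tag must be an increasing range within 1-10")
  if (!(F_between >= 0 && F_between < 1 && F_within >= 0 &&
        F_within <= F_between) || (F_between > 0 && F_within == F_between))
    stop("require 0 <= F_within < F_between < 1 (both may be 0: no drift)")
  if (paralog_fraction < 0 || paralog_fraction > 1)
    stop("paralog_fraction must be in [0,1]")
  if (any(sample_sizes < 2)) stop("sample sizes must be at least 2")
  pops <- as.vector(t(outer(seq_len(n_lineages), seq_len(pops_per_lineage),
                            function(l, p) paste0("L", l, "P", p))))
  lineage_of_pop <- rep(paste0("L", seq_len(n_lineages)),
                        each = pops_per_lineage)
  names(lineage_of_pop) <- pops
  dr <- paste0(rep(paste0("L", seq_len(n_lineages)), each = pops_per_lineage),
               "D", rep_len(rep(seq_len(drainages_per_lineage),
                                length.out = pops_per_lineage), length(pops)))
  drainage_of_pop <- stats::setNames(dr, pops)
  for (ev in admixture_events) {
    stopifnot(ev$recipient %in% pops, ev$source %in% pops,
              ev$p_adm >= 0, ev$p_adm <= 1,
              ev$fraction_pure_native >= 0, ev$fraction_pure_native <= 1)
  }
  if (length(sample_sizes) == 1)
    sample_sizes <- stats::setNames(rep(sample_sizes, length(pops)), pops)
  structure(list(
    n_lineages = n_lineages, pops_per_lineage = pops_per_lineage,
    pops = pops, lineage_of_pop = lineage_of_pop,
    drainage_of_pop = drainage_of_pop,
    n_tags = n_tags, snps_per_tag = snps_per_tag,
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    F_between = F_between, F_within = F_within,
    admixture_events = admixture_events, sample_sizes = sample_sizes,
    mean_depth = mean_depth, paralog_fraction = paralog_fraction,
    seed = as.integer(seed)), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$n_lineages, " lineages x ", x$pops_per_lineage,
      " pops, ", x$n_tags, " tags on ", x$n_chromosomes, " chromosomes\n",
      "  F_between=", x$F_between, " F_within=", x$F_within,
      " paralog_fraction=", x$paralog_fraction,
      " events=", length(x$admixture_events), " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

bn_draw <- function(p, F) {
  # Balding-Nichols beta draw around ancestral frequency p with parameter F
  if (F <= 0) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  stats::rbeta(length(p), a, b)
}

#' Simulate a stocked metapopulation with known ground truth
#'
#' Allele frequencies are drawn by nested Balding-Nichols beta sampling:
#' lineage frequencies around a uniform ancestral frequency, population
#' frequencies around their lineage frequency with parameter `F_within`. The
#' lineage-level beta parameter is `(F_between - F_within) / (1 - F_within)`
#' so that the two drift layers compound to the configured pairwise
#' between-lineage differentiation. Individuals are Hardy-Weinberg diploids
#' with phased haplotypes; stocking events convert a fraction of the
#' recipient population into hybrids whose per-tag haplotypes descend from
#' the source population with probability `p_adm`.
#'
#' @param config a [scenario_config].
#' @return A list with `dataset` (phased [geno_data]) and `truth` (class
#'   `truth_record`): per-individual realized ancestry fractions per lineage
#'   source, per-population per-locus simulated allele frequencies, per-tag
#'   paralog flags, per-population planar coordinates, and the hidden second
#'   genotype of collapsed paralog tags (used by [simulate_read_counts()]).
#' @export
simulate_metapopulation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  cfg <- config
  n_snps_tag <- sample(seq(cfg$snps_per_tag[1], cfg$snps_per_tag[2]),
                       cfg$n_tags, replace = TRUE)
  n_snp <- sum(n_snps_tag)
  tag_ids <- paste0("tag", formatC(seq_len(cfg$n_tags), width = 6, flag = "0"))

  # place tags uniformly on the chromosome map; SNPs of a tag within 140 bp
  tag_chrom <- sample.int(cfg$n_chromosomes, cfg$n_tags, replace = TRUE)
  tag_start <- floor(stats::runif(cfg$n_tags, 1, cfg$chrom_length - 200))
  loci <- data.frame(
    chrom = paste0("chr", rep(tag_chrom, n_snps_tag)),
    pos = rep(tag_start, n_snps_tag) +
      unlist(lapply(n_snps_tag, function(k) sort(sample.int(140, k)))),
    tag = rep(tag_ids, n_snps_tag),
    snp_idx = unlist(lapply(n_snps_tag, seq_len)))
  ord <- order(rep(tag_chrom, n_snps_tag), loci$pos,
               method = "radix")
  # keep tag blocks contiguous: order tags by (chrom, start)
  tag_ord <- order(tag_chrom, tag_start, method = "radix")
  snp_of_tag <- split(seq_len(n_snp), rep(seq_len(cfg$n_tags), n_snps_tag))
  ord <- unlist(snp_of_tag[tag_ord], use.names = FALSE)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL

  # nested allele frequencies
  F_l <- (cfg$F_between - cfg$F_within) / (1 - cfg$F_within)
  # ancestral spectrum: neutral-like 1/x minor-allele frequency per TAG.
  # SNPs of one RAD tag share a genealogy, so both their ancestral frequency
  # and their drift are modelled at the tag level (one Balding-Nichols draw
  # per tag per lineage/population), plus a small per-SNP logit jitter --
  # shared across populations -- for mutation-age differences. This matches
  # RAD-survey heterozygosity (~0.17), keeps mid-frequency loci rare, and
  # gives a tag's SNPs properly correlated HDplot statistics.
  x0 <- 0.01
  x_tag <- x0 * (0.5 / x0)^stats::runif(cfg$n_tags)
  minor_tag <- stats::runif(cfg$n_tags) < 0.5
  p_anc_tag <- pmin(pmax(ifelse(minor_tag, x_tag, 1 - x_tag), 0.005), 0.995)
  lineages <- paste0("L", seq_len(cfg$n_lineages))
  p_lin_tag <- vapply(lineages, function(l) bn_draw(p_anc_tag, F_l),
                      numeric(cfg$n_tags))
  p_pop_tag <- vapply(cfg$pops, function(pp) {
    bn_draw(p_lin_tag[, cfg$lineage_of_pop[[pp]]], cfg$F_within)
  }, numeric(cfg$n_tags))
  eps <- stats::rnorm(n_snp, 0, 0.15)
  expand <- function(ptab) {
    m <- apply(ptab, 2, function(v)
      stats::plogis(stats::qlogis(rep(v, n_snps_tag)) + eps))
    matrix(m, nrow = n_snp, dimnames = list(NULL, colnames(ptab)))
  }
  p_pop <- expand(matrix(p_pop_tag, nrow = cfg$n_tags,
                         dimnames = list(NULL, cfg$pops)))[ord, , drop = FALSE]
  p_lin <- expand(p_lin_tag)[ord, , drop = FALSE]

  n_ind <- sum(cfg$sample_sizes)
  ind_pop <- rep(cfg$pops, cfg$sample_sizes[cfg$pops])
  ids <- paste0(ind_pop, "_", unlist(lapply(cfg$sample_sizes[cfg$pops], seq_len)))
  tag_index <- match(loci$tag, tag_ids[tag_ord])   # 1..n_tags in map order
  n_tags <- cfg$n_tags
  # gamete haplotypes by a common-uniform threshold per tag: allele at SNP s
  # is (u < p_s), one u per gamete per tag, so a tag's SNPs are in complete
  # LD (|D'| = 1) -- the no-recombination limit appropriate for a 140-bp tag
  draw_gametes <- function(rows, pr) {
    U <- matrix(stats::runif(length(rows) * n_tags), length(rows), n_tags)
    (U[, tag_index, drop = FALSE] <
       matrix(pr, length(rows), n_snp, byrow = TRUE)) * 1L
  }
  hap1 <- matrix(0L, n_ind, n_snp)
  hap2 <- matrix(0L, n_ind, n_snp)
  for (pp in cfg$pops) {
    rows <- which(ind_pop == pp)
    pr <- p_pop[, pp]
    hap1[rows, ] <- draw_gametes(rows, pr)
    hap2[rows, ] <- draw_gametes(rows, pr)
  }

  # ancestry bookkeeping: fraction of haplotype draws from each lineage
  anc_counts <- matrix(0, n_ind, cfg$n_lineages,
                       dimnames = list(ids, lineages))
  for (i in seq_len(n_ind)) {
    anc_counts[i, cfg$lineage_of_pop[[ind_pop[i]]]] <- 2 * n_tags
  }

  # stocking admixture pulses: hybrid individuals redraw, per tag and per
  # haplotype, from the source population with probability p_adm
  for (ev in cfg$admixture_events) {
    rows <- which(ind_pop == ev$recipient)
    n_hyb <- round(length(rows) * (1 - ev$fraction_pure_native))
    if (n_hyb == 0) next
    hyb <- rows[seq_len(n_hyb)]
    src_lin <- cfg$lineage_of_pop[[ev$source]]
    rec_lin <- cfg$lineage_of_pop[[ev$recipient]]
    p_src <- p_pop[, ev$source]
    for (i in hyb) {
      for (h in 1:2) {
        from_src <- stats::rbinom(n_tags, 1L, ev$p_adm) == 1L
        take <- from_src[tag_index]
        u_t <- stats::runif(n_tags)[tag_index]
        draw <- (u_t[take] < p_src[take]) * 1L
        if (h == 1) hap1[i, take] <- draw else hap2[i, take] <- draw
        k <- sum(from_src)
        anc_counts[i, src_lin] <- anc_counts[i, src_lin] + k
        anc_counts[i, rec_lin] <- anc_counts[i, rec_lin] - k
      }
    }
  }
  geno <- hap1 + hap2

  # paralog tags: an independent hidden duplicate copy whose reads collapse
  # onto the visible tag
  paralog <- stats::runif(n_tags) < cfg$paralog_fraction
  names(paralog) <- tag_ids[tag_ord]
  dup_hap1 <- dup_hap2 <- NULL
  dup_cols <- which(paralog[loci$tag])
  if (length(dup_cols)) {
    p_dup <- stats::runif(length(dup_cols), 0.2, 0.8)
    dup_tag <- tag_index[dup_cols]
    dup_draw <- function() {
      U <- matrix(stats::runif(n_ind * n_tags), n_ind, n_tags)
      (U[, dup_tag, drop = FALSE] <
         matrix(p_dup, n_ind, length(dup_cols), byrow = TRUE)) * 1L
    }
    dup_hap1 <- dup_draw()
    dup_hap2 <- dup_draw()
  }

  # planar coordinates: lineages far apart, drainages as blocks, jitter pops
  drn <- unique(unname(cfg$drainage_of_pop))
  dr_center <- stats::setNames(vector("list", length(drn)), drn)
  for (k in seq_along(drn)) {
    lin_idx <- as.integer(sub("^L(\\d+)D.*", "\\1", drn[k]))
    d_idx <- as.integer(sub(".*D(\\d+)$", "\\1", drn[k]))
    dr_center[[k]] <- c(x = 10 * lin_idx + 2.5 * d_idx, y = 2.5 * d_idx)
  }
  coords <- data.frame(pop = cfg$pops,
                       x = NA_real_, y = NA_real_)
  for (r in seq_len(nrow(coords))) {
    ctr <- dr_center[[cfg$drainage_of_pop[[coords$pop[r]]]]]
    coords$x[r] <- ctr["x"] + stats::runif(1, -1, 1)
    coords$y[r] <- ctr["y"] + stats::runif(1, -1, 1)
  }

  inds <- data.frame(id = ids, pop = ind_pop,
                     drainage = unname(cfg$drainage_of_pop[ind_pop]),
                     group = unname(cfg$lineage_of_pop[ind_pop]))
  ds <- geno_data(geno, loci, inds, hap1, hap2, coords)
  truth <- structure(list(
    ancestry = anc_counts / (2 * n_tags),
    pop_freqs = t(p_pop),            # populations x SNPs, map order
    lineage_freqs = t(p_lin),
    paralog = paralog,
    dup_hap1 = dup_hap1, dup_hap2 = dup_hap2, dup_cols = dup_cols,
    coords = coords, config = cfg), class = "truth_record")
  list(dataset = ds, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record> ", nrow(x$ancestry), " individuals, ",
      ncol(x$pop_freqs), " SNPs, ", sum(x$paralog), "/",
      length(x$paralog), " paralog tags\n", sep = "")
  invisible(x)
}

#' Simulate allele-specific read counts
#'
#' Depth per individual per SNP is Poisson(`mean_depth`). At clean loci a
#' heterozygote's reference reads are Binomial(depth, 1/2). At collapsed
#' paralog tags the reads of the visible copy and of a hidden duplicate copy
#' (independent genotype, off-centre allele frequency) are merged, which
#' produces both excess apparent heterozygosity and a skewed heterozygote
#' allele balance -- the two HDplot axes.
#'
#' @param dataset phased [geno_data] from [simulate_metapopulation()].
#' @param truth matching `truth_record`.
#' @param mean_depth mean reads per SNP per individual (> 0).
#' @param seed integer seed.
#' @return A list: `counts` ([read_counts]), and `geno_obs` -- the genotype
#'   matrix as it would be called from the merged reads (paralog sites show
#'   the union of the two copies' alleles).
#' @export
simulate_read_counts <- function(dataset, truth, mean_depth = 40, seed = 1L) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  set.seed(as.integer(seed))
  n_ind <- nrow(dataset$geno)
  n_snp <- ncol(dataset$geno)
  # per-copy depth so that paralog sites get double coverage when merged
  dp1 <- matrix(stats::rpois(n_ind * n_snp, mean_depth / 2), n_ind, n_snp)
  dp2 <- matrix(stats::rpois(n_ind * n_snp, mean_depth / 2), n_ind, n_snp)
  alt_frac <- (dataset$hap1 + dataset$hap2) / 2
  alt1 <- matrix(stats::rbinom(n_ind * n_snp, as.vector(dp1),
                               as.vector(alt_frac)), n_ind, n_snp)
  alt2 <- matrix(stats::rbinom(n_ind * n_snp, as.vector(dp2),
                               as.vector(alt_frac)), n_ind, n_snp)
  dp <- dp1 + dp2
  alt <- alt1 + alt2
  geno_obs <- dataset$geno
  if (length(truth$dup_cols)) {
    j <- truth$dup_cols
    dose_dup <- truth$dup_hap1 + truth$dup_hap2
    alt_dup <- matrix(stats::rbinom(n_ind * length(j), as.vector(dp2[, j]),
                                    as.vector(dose_dup / 2)),
                      n_ind, length(j))
    alt[, j] <- alt1[, j] + alt_dup
    merged <- dataset$geno[, j, drop = FALSE] + dose_dup
    geno_obs[, j] <- ifelse(merged == 0L, 0L, ifelse(merged == 4L, 2L, 1L))
  }
  list(counts = read_counts(dp - alt, alt), geno_obs = geno_obs)
}

#' Export a simulated dataset to standard files
#'
#' Writes a phased VCF 4.2 (GT with `|`; AD when read counts are given; the
#' RAD-tag id in the `TID` INFO key), a population map
#' (individual / population / drainage / state-level group, tab-separated),
#' a per-population coordinates table, and the truth record as JSON. The
#' files round-trip losslessly through [read_dataset_vcf()].
#'
#' @param dataset a phased [geno_data].
#' @param truth matching `truth_record` (optional; `NULL` to skip).
#' @param outdir writable output directory (created if absent).
#' @param counts optional [read_counts] to emit as the AD field.
#' @return Invisibly, the named vector of file paths written.
#' @export
export_dataset <- function(dataset, truth, outdir, counts = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  paths <- c(vcf = file.path(outdir, "genotypes.vcf.gz"),
             popmap = file.path(outdir, "popmap.tsv"),
             coords = file.path(outdir, "coords.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_dataset_vcf(dataset, paths[["vcf"]], counts = counts)
  utils::write.table(dataset$inds, paths[["popmap"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$coords))
    utils::write.table(dataset$coords, paths[["coords"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(list(
      ancestry = as.data.frame(truth$ancestry),
      ancestry_ids = rownames(truth$ancestry),
      paralog = as.list(truth$paralog),
      coords = truth$coords), paths[["truth"]], digits = NA, auto_unbox = TRUE)
  }
  invisible(paths)
}
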