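#' Genotype dataset container
#'
#' An individuals-by-SNP diploid genotype matrix with locus metadata and a
#' population map, the common currency of the filtering and structure
#' analyses. Genotypes are alternate-allele doses (0, 1, 2) with `NA` for
#' missing; when the data are phased, two haplotype matrices (0/1 alternate
#' indicator per gene copy) are carried alongside.
#'
#' @param geno integer matrix, individuals x SNPs, values 0/1/2/NA.
#' @param loci data.frame with one row per SNP: `chrom`, `pos` (1-based),
#'   `tag` (RAD-tag id), `snp_idx` (within-tag index, 1-based), and optionally
#'   `ref`/`alt` allele characters.
#' @param inds data.frame with one row per individual: `id`, `pop`, and
#'   optionally `drainage` and `group` (state-level grouping).
#' @param hap1,hap2 optional phase matrices (same shape as `geno`, 0/1/NA);
#'   `hap1 + hap2` must equal `geno` wherever non-missing.
#' @param coords optional data.frame of per-population planar coordinates
#'   (`pop`, `x`, `y`).
#'
#' @return An object of class `geno_data`.
#' @export
geno_data <- function(geno, loci, inds, hap1 = NULL, hap2 = NULL,
                      coords = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(nrow(loci) == ncol(geno), nrow(inds) == nrow(geno))
  req <- c("chrom", "pos", "tag", "snp_idx")
  if (!all(req %in% names(loci)))
    stop("loci must have columns: ", paste(req, collapse = ", "))
  if (!all(c("id", "pop") %in% names(inds)))
    stop("inds must have columns id, pop")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype doses must be 0, 1, 2 or NA")
  if (!is.null(hap1)) {
    stopifnot(!is.null(hap2), dim(hap1) == dim(geno), dim(hap2) == dim(geno))
    storage.mode(hap1) <- "integer"
    storage.mode(hap2) <- "integer"
  }
  rownames(geno) <- inds$id
  if (ncol(geno))
    colnames(geno) <- paste0(loci$tag, "_", loci$snp_idx)
  structure(
    list(geno = geno, loci = as.data.frame(loci), inds = as.data.frame(inds),
         hap1 = hap1, hap2 = hap2, coords = coords),
    class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat("<geno_data> ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " SNPs (", length(unique(x$loci$tag)), " RAD tags, ",
      length(unique(x$loci$chrom)), " chromosomes)\n", sep = "")
  cat("  populations:", paste(levels(factor(x$inds$pop)), collapse = ", "),
      "\n")
  cat("  phased:", !is.null(x$hap1),
      " missing: ", round(100 * mean(is.na(x$geno)), 2), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.geno_data <- function(object, ...) {
  out <- list(
    n_ind = nrow(object$geno), n_snp = ncol(object$geno),
    n_tag = length(unique(object$loci$tag)),
    n_pop = length(unique(object$inds$pop)),
    missing_rate = mean(is.na(object$geno)),
    maf = unname(stats::quantile(snp_maf(object), na.rm = TRUE)))
  class(out) <- "summary.geno_data"
  out
}

#' @export
print.summary.geno_data <- function(x, ...) {
  cat("geno_data:", x$n_ind, "individuals,", x$n_snp, "SNPs,",
      x$n_tag, "tags,", x$n_pop, "populations\n")
  cat("missing rate:", signif(x$missing_rate, 3), "\n")
  cat("MAF quartiles:", paste(signif(x$maf, 3), collapse = " "), "\n")
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x a [geno_data] object.
#' @param i individual index (logical, integer or id character vector).
#' @param j SNP index.
#' @param ... unused.
#' @export
`[.geno_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(i)) i <- match(i, x$inds$id)
  geno_data(x$geno[i, j, drop = FALSE],
            x$loci[j, , drop = FALSE],
            x$inds[i, , drop = FALSE],
            if (!is.null(x$hap1)) x$hap1[i, j, drop = FALSE],
            if (!is.null(x$hap2)) x$hap2[i, j, drop = FALSE],
            x$coords)
}

#' Per-SNP allele frequencies and counts
#'
#' @param ds a [geno_data] object.
#' @param pop optional population label; default pools all individuals.
#' @return `snp_freq`: alternate-allele frequency per SNP (`NA` where no
#'   genotypes). `snp_maf`: minor-allele frequency. `snp_mac`: minor-allele
#'   count. `pop_freq_table`: populations x SNPs matrix of alternate-allele
#'   frequencies.
#' @export
snp_freq <- function(ds, pop = NULL) {
  g <- pop_rows(ds, pop)
  colMeans(g, na.rm = TRUE) / 2
}

#' @rdname snp_freq
#' @export
snp_maf <- function(ds, pop = NULL) {
  p <- snp_freq(ds, pop)
  pmin(p, 1 - p)
}

#' @rdname snp_freq
#' @export
snp_mac <- function(ds, pop = NULL) {
  g <- pop_rows(ds, pop)
  alt <- colSums(g, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(g))
  pmin(alt, tot - alt)
}

#' @rdname snp_freq
#' @export
pop_freq_table <- function(ds) {
  pops <- sort(unique(ds$inds$pop))
  out <- t(vapply(pops, function(p) snp_freq(ds, p), numeric(ncol(ds$geno))))
  rownames(out) <- pops
  out
}

pop_rows <- function(ds, pop = NULL) {
  if (is.null(pop)) return(ds$geno)
  keep <- ds$inds$pop %in% pop
  if (!any(keep)) stop("no individuals in population ", paste(pop, collapse = ","))
  ds$geno[keep, , drop = FALSE]
}

#' Microhaplotype dataset container
#'
#' Multiallelic haplotype genotypes, one marker per RAD tag: each individual
#' carries two integer allele codes per tag (dense 0-based codes in order of
#' first observation), with the underlying haplotype strings retained.
#'
#' @param a1,a2 integer matrices, individuals x tags, allele codes (NA for a
#'   missing haplotype).
#' @param tags data.frame per tag: `tag`, `chrom`, `pos`, `n_alleles`.
#' @param haplotypes list (one element per tag) of character vectors giving
#'   the haplotype string for each allele code (code k = element k + 1).
#' @param inds individual table as in [geno_data].
#' @return An object of class `microhap_data`.
#' @export
microhap_data <- function(a1, a2, tags, haplotypes, inds) {
  stopifnot(dim(a1) == dim(a2), ncol(a1) == nrow(tags),
            nrow(a1) == nrow(inds), length(haplotypes) == nrow(tags))
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  tags$n_alleles <- vapply(haplotypes, length, integer(1))
  structure(list(a1 = a1, a2 = a2, tags = as.data.frame(tags),
                 haplotypes = haplotypes, inds = as.data.frame(inds)),
            class = "microhap_data")
}

#' @export
print.microhap_data <- function(x, ...) {
  cat("<microhap_data> ", nrow(x$a1), " individuals x ", ncol(x$a1),
      " RAD-tag markers\n", sep = "")
  cat("  alleles per tag: median ", stats::median(x$tags$n_alleles),
      " (max ", max(x$tags$n_alleles), ")\n", sep = "")
  invisible(x)
}

#' Read-count table container
#'
#' Per-individual, per-SNP reference and alternate read counts; the input to
#' HDplot paralog detection.
#'
#' @param ref,alt integer matrices, individuals x SNPs.
#' @return An object of class `read_counts`.
#' @export
read_counts <- function(ref, alt) {
  stopifnot(dim(ref) == dim(alt))
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  structure(list(ref = ref, alt = alt), class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat("<read_counts> ", nrow(x$ref), " individuals x ", ncol(x$ref),
      " SNPs, mean depth ",
      round(mean(x$ref + x$alt), 1), "\n", sep = "")
  invisible(x)
}
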