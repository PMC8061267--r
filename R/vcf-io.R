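#' Write a genotype dataset as VCF 4.2
#'
#' Phased genotypes are written as `GT` with the `|` separator, allele-read
#' depths as `AD` when a [read_counts] table is supplied, and the RAD-tag id
#' as the `TID` INFO key so that records of one tag can be regrouped.
#'
#' @param ds a [geno_data]; must be phased.
#' @param path output path (`.vcf.gz`).
#' @param counts optional [read_counts] aligned with `ds`.
#' @return Invisibly, `path`.
#' @export
write_dataset_vcf <- function(ds, path, counts = NULL) {
  if (is.null(ds$hap1)) stop("dataset must be phased to export a phased VCF")
  n_snp <- ncol(ds$geno)
  ref <- if ("ref" %in% names(ds$loci)) ds$loci$ref else rep("A", n_snp)
  alt <- if ("alt" %in% names(ds$loci)) ds$loci$alt else rep("T", n_snp)
  fix <- cbind(CHROM = as.character(ds$loci$chrom),
               POS = as.character(ds$loci$pos),
               ID = paste0(ds$loci$tag, "_", ds$loci$snp_idx),
               REF = ref, ALT = alt, QUAL = ".", FILTER = "PASS",
               INFO = paste0("TID=", ds$loci$tag))
  gt_chr <- matrix(".|.", n_snp, nrow(ds$geno))
  h1 <- t(ds$hap1); h2 <- t(ds$hap2)
  ok <- !is.na(h1) & !is.na(h2)
  gt_chr[ok] <- paste0(h1[ok], "|", h2[ok])
  if (!is.null(counts)) {
    ad <- matrix(paste0(t(counts$ref), ",", t(counts$alt)), n_snp,
                 nrow(ds$geno))
    gt_chr <- matrix(paste0(gt_chr, ":", ad), n_snp, nrow(ds$geno))
    fmt <- "GT:AD"
  } else fmt <- "GT"
  gt <- cbind(FORMAT = fmt, gt_chr)
  colnames(gt) <- c("FORMAT", ds$inds$id)
  meta <- c("##fileformat=VCFv4.2",
            "##source=stockscan",
            "##INFO=<ID=TID,Number=1,Type=String,Description=\"RAD tag id\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            if (!is.null(counts))
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">")
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a genotype dataset from VCF plus a population map
#'
#' The inverse of [write_dataset_vcf()] / [export_dataset()]: parses `GT`
#' (phase retained when the `|` separator is used throughout), `AD` when
#' present, and recovers RAD-tag grouping from the `TID` INFO key (falling
#' back to one tag per record).
#'
#' @param vcf_path path to a VCF (optionally gzipped).
#' @param popmap_path path to a tab-separated population map with columns
#'   `id`, `pop` and optionally `drainage`, `group`; or `NULL`, in which case
#'   all individuals are placed in population "pop1".
#' @param coords_path optional tab-separated coordinates table (`pop`, `x`,
#'   `y`).
#' @return A list with `dataset` ([geno_data]) and `counts` ([read_counts] or
#'   `NULL`).
#' @export
read_dataset_vcf <- function(vcf_path, popmap_path = NULL,
                             coords_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  tid <- vcfR::extract.info(v, element = "TID")
  if (all(is.na(tid))) tid <- paste0("tag", seq_len(nrow(gt)))
  snp_idx <- stats::ave(seq_along(tid), tid, FUN = seq_along)
  loci <- data.frame(chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                     tag = tid, snp_idx = snp_idx,
                     ref = vcfR::getREF(v), alt = vcfR::getALT(v))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  phased <- all(substr(gt[!is.na(gt)], 2, 2) == "|")
  h1 <- t(matrix(suppressWarnings(as.integer(a1)), nrow(gt), ncol(gt)))
  h2 <- t(matrix(suppressWarnings(as.integer(a2)), nrow(gt), ncol(gt)))
  geno <- h1 + h2
  inds <- if (is.null(popmap_path)) {
    data.frame(id = ids, pop = "pop1")
  } else {
    pm <- utils::read.table(popmap_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    pm[match(ids, pm$id), , drop = FALSE]
  }
  coords <- if (!is.null(coords_path)) {
    utils::read.table(coords_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  counts <- NULL
  if ("AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(v, element = "AD")
    refc <- t(matrix(as.integer(sub(",.*", "", ad)), nrow(gt), ncol(gt)))
    altc <- t(matrix(as.integer(sub(".*,", "", ad)), nrow(gt), ncol(gt)))
    counts <- read_counts(refc, altc)
  }
  ds <- geno_data(geno, loci, inds,
                  hap1 = if (phased) h1, hap2 = if (phased) h2,
                  coords = coords)
  list(dataset = ds, counts = counts)
}
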