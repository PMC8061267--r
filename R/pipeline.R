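#' Default pipeline configuration
#'
#' Stage toggles and every stage parameter, initialized to the workflow's
#' standard values: 80%/80% genotype-rate filters with minor-allele count 3,
#' HDplot thresholds H > 0.5 / |D| > 7, 10,000 F_ST permutations
#' (Bonferroni alpha 0.0001), 10,000 dendrogram bootstraps, 500-kb windows
#' with 100-kb steps and 1000/10,000 bootstrap replicates gated at the
#' 90th / called at the 99th percentile, N_e p-crit 0.05, Tukey alpha
#' 0.001, and 3 Monmonier runs with a 5% threshold relaxation. Override any
#' element before passing the config to [run_pipeline()].
#'
#' @param seed master integer seed; each stage derives its own stream.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, filter = TRUE, diversity = TRUE,
                  structure = TRUE, boundaries = TRUE, coancestry = TRUE,
                  scan = TRUE),
    scenario = list(),                  # overrides for scenario_config()
    filter = list(ind_rate = 0.8, snp_rate = 0.8, mac = 3, max_h = 0.5,
                  max_d = 7, max_fis = 0.5, max_alleles = 10),
    diversity = list(pcrit = 0.05, max_loci = 2000),
    structure = list(n_perm = 10000, n_boot = 10000, alpha = 0.0001),
    boundaries = list(n_runs = 3, relax = TRUE, threshold_relax = 0.05),
    coancestry = list(alpha = 0.001),
    scan = list(window = 500000, step = 100000, reps1 = 1000, reps2 = 10000,
                gate = 90, call = 99, min_loci = 2)),
    class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config a `run_config`.
#' @return `read_run_config` returns a `run_config` (defaults filled in for
#'   absent elements); `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  u <- yaml::read_yaml(path)
  cfg <- default_run_config(if (!is.null(u$seed)) u$seed else 1L)
  for (nm in intersect(names(u), names(cfg))) {
    if (is.list(cfg[[nm]])) {
      for (k in names(u[[nm]])) cfg[[nm]][[k]] <- u[[nm]][[k]]
    } else cfg[[nm]] <- u[[nm]]
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_line <- function(...) message("[stockscan] ", ...)

#' Run the full analysis pipeline
#'
#' Simulate (or load) a dataset, then run filtering, diversity, structure,
#' boundary detection, co-ancestry and the genome scan in dependency order.
#' Every stage writes its artifact under `outdir` and logs one line with its
#' input/output dimensions; a manifest JSON records the package version, the
#' seed, all parameter values and artifact checksums.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param outdir output directory.
#' @param dataset,counts optional pre-loaded inputs; required when the
#'   simulate stage is disabled.
#' @param truth optional truth record to carry into the manifest inputs.
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir,
                         dataset = NULL, counts = NULL, truth = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  st <- config$stages

  if (isTRUE(st$simulate)) {
    scen <- do.call(scenario_config, c(config$scenario,
                                       list(seed = config$seed)))
    sim <- simulate_metapopulation(scen)
    dataset <- sim$dataset; truth <- sim$truth
    rc <- simulate_read_counts(dataset, truth, scen$mean_depth,
                               seed = config$seed + 1L)
    counts <- rc$counts
    dataset$geno <- rc$geno_obs          # genotypes as called from reads
    export_dataset(dataset, truth, outdir, counts)
    log_line("simulate: ", nrow(dataset$geno), " individuals x ",
             ncol(dataset$geno), " SNPs (",
             sum(truth$paralog), " paralog tags)")
    res$scenario <- scen; res$truth <- truth
  }
  if (is.null(dataset)) stop("no dataset: enable the simulate stage or pass one")
  res$dataset <- dataset

  if (isTRUE(st$filter)) {
    if (is.null(counts)) stop("filtering requires read counts for HDplot")
    fp <- do.call(filter_pipeline, c(list(dataset, counts), config$filter))
    res$filtered <- fp
    jsonlite::write_json(fp$report, file.path(outdir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line("filter: ", fp$report$individuals_kept, " individuals, ",
             fp$report$snps_final, " SNPs, ",
             fp$report$microhap_tags_final, " microhap tags retained")
    snp_ds <- fp$snp; mh <- fp$microhap
  } else {
    if (mean(is.na(dataset$geno)) > 0)
      warning("filtering disabled on data with missing genotypes; ",
              "downstream statistics use pairwise-complete loci")
    snp_ds <- dataset
    mh <- if (!is.null(dataset$hap1)) build_microhaplotypes(dataset)
  }

  if (isTRUE(st$diversity)) {
    dt <- diversity_table(snp_ds)
    ne_rows <- lapply(sort(unique(snp_ds$inds$pop)), function(pp) {
      ne <- tryCatch(ld_ne(snp_ds, pp, pcrit = config$diversity$pcrit,
                           max_loci = config$diversity$max_loci,
                           sub_seed = config$seed + 2L),
                     error = function(e) NULL)
      data.frame(pop = pp,
                 Ne = if (is.null(ne)) NA else ne$Ne,
                 Ne_lo = if (is.null(ne)) NA else ne$CI[1],
                 Ne_hi = if (is.null(ne)) NA else ne$CI[2])
    })
    dt <- merge(dt, do.call(rbind, ne_rows), by = "pop")
    utils::write.table(dt, file.path(outdir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_line("diversity: ", nrow(dt), " populations")
    res$diversity <- dt
  }

  if (isTRUE(st$structure)) {
    pw <- pairwise_fst(snp_ds, n_perm = config$structure$n_perm,
                       seed = config$seed + 3L,
                       alpha = config$structure$alpha)
    utils::write.table(round(pw$theta, 4),
                       file.path(outdir, "fst_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    am <- amova(snp_ds)
    utils::write.table(as.data.frame(am), file.path(outdir, "amova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nj <- nj_bootstrap(snp_ds, n_boot = config$structure$n_boot,
                       seed = config$seed + 4L)
    writeLines(nj$newick, file.path(outdir, "nj_tree.nwk"))
    log_line("structure: mean pairwise theta ",
             signif(mean(pw$theta[upper.tri(pw$theta)]), 3))
    res$fst <- pw; res$amova <- am; res$tree <- nj
  }

  if (isTRUE(st$boundaries) && !is.null(snp_ds$coords)) {
    ed <- edwards_matrix(snp_ds)
    sc <- pcoa_first_axis(ed)
    net <- population_network(snp_ds$coords, sc$scaled)
    net <- monmonier(net, n_runs = config$boundaries$n_runs,
                     relax = config$boundaries$relax,
                     threshold_relax = config$boundaries$threshold_relax)
    bd <- net$boundaries
    jsonlite::write_json(
      list(threshold = net$threshold, converged_run = net$converged_run,
           boundaries = bd), file.path(outdir, "boundaries.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(bd)) {
      bd_out <- bd
      bd_out$from <- net$pops[bd$from]; bd_out$to <- net$pops[bd$to]
      utils::write.table(bd_out, file.path(outdir, "boundary_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log_line("boundaries: ", if (is.null(bd)) 0 else nrow(bd),
             " crossed edges in ",
             if (is.null(bd)) 0 else length(unique(bd$run)), " run(s)")
    res$network <- net
  }

  if (isTRUE(st$coancestry) && !is.null(mh)) {
    cm <- paint_coancestry(mh)
    utils::write.csv(round(cm$M, 4), file.path(outdir, "coancestry.csv"))
    gs <- coancestry_group_stats(cm)
    utils::write.table(gs$intra_pop,
                       file.path(outdir, "coancestry_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(gs$sets) >= 2) {
      res$coancestry_hsd <- tukey_hsd(gs$sets,
                                      alpha = config$coancestry$alpha)
    }
    tr <- cluster_coancestry(cm)
    writeLines(tr$newick, file.path(outdir, "coancestry_tree.nwk"))
    log_line("coancestry: ", nrow(cm$M), " individuals painted over ",
             ncol(mh$a1), " tags")
    res$coancestry <- cm; res$coancestry_stats <- gs
    res$coancestry_tree <- tr
  }

  if (isTRUE(st$scan)) {
    sc <- config$scan
    scan <- genome_scan(snp_ds, window = sc$window, step = sc$step,
                        reps1 = sc$reps1, reps2 = sc$reps2, gate = sc$gate,
                        call = sc$call, min_loci = sc$min_loci,
                        seed = config$seed + 5L)
    utils::write.table(scan$windows, file.path(outdir, "scan_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(scan$regions))
      write_regions_bed(scan$regions, file.path(outdir, "scan_regions.bed"))
    log_line("scan: ", sum(scan$windows$significant),
             " significant windows, ", nrow(scan$regions), " region(s)")
    res$scan <- scan
  }

  arts <- list.files(outdir, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest <- list(
    package = "stockscan",
    version = as.character(utils::packageVersion("stockscan")),
    seed = config$seed,
    parameters = unclass(config),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(arts)),
                                        basename(arts))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Bundled regional walleye survey tables
#'
#' Printed summary tables from a 23-population RAD-seq survey of midwestern
#' walleye (Wisconsin, Minnesota, and one border water), shipped as
#' plain-text example data: per-population sample sizes, diversity and N_e
#' estimates, mean intra-population co-ancestry and hierarchical grouping
#' (`walleye_survey`); the pairwise F_ST matrix (`walleye_fst_matrix`); and
#' the three hierarchical AMOVA tables (`walleye_amova_table`). They carry
#' the package's reporting arithmetic in tests and the acceptance script.
#'
#' @return `walleye_survey`: data.frame, one row per population.
#'   `walleye_fst_matrix`: symmetric 23 x 23 matrix (diagonal 0).
#'   `walleye_amova_table`: data.frame with `analysis`, `stratum`, `df`,
#'   `SSQ`, `Var`.
#' @export
walleye_survey <- function() {
  utils::read.table(system.file("extdata", "walleye_survey.tsv",
                                package = "stockscan"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname walleye_survey
#' @export
walleye_fst_matrix <- function() {
  d <- utils::read.table(system.file("extdata", "walleye_pairwise_fst.tsv",
                                     package = "stockscan"),
                         header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(d)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- 0
  m
}

#' @rdname walleye_survey
#' @export
walleye_amova_table <- function() {
  utils::read.table(system.file("extdata", "walleye_amova.tsv",
                                package = "stockscan"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
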