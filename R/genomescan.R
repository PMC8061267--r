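#' Per-locus multi-population differentiation
#'
#' Weir-Cockerham theta per SNP, `a / (a + b + c)`; loci with an undefined
#' or zero denominator are dropped and counted.
#'
#' @param ds a [geno_data].
#' @param populations optional subset of populations (default: all).
#' @return data.frame of class `locus_diff`: `chrom`, `pos`, `theta`;
#'   attribute `"n_dropped"` gives the undefined-locus count.
#' @export
per_locus_theta <- function(ds, populations = NULL) {
  if (!is.null(populations)) ds <- ds[ds$inds$pop %in% populations, ]
  comp <- wc_components(ds$geno, ds$inds$pop)
  denom <- comp$a + comp$b + comp$c
  keep <- comp$used & denom > 0
  out <- data.frame(chrom = ds$loci$chrom[keep], pos = ds$loci$pos[keep],
                    theta = comp$a[keep] / denom[keep])
  out <- out[order(out$chrom, out$pos, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("locus_diff", "data.frame")
  out
}

#' Gaussian-kernel smoothed window statistics
#'
#' Windows of `window` bp are tiled per chromosome from coordinate 1 with a
#' `step`-bp shift (half-open intervals `[start, end)`, so a boundary locus
#' belongs to the lower window only). Within a window, locus differentiation
#' is weighted by a Gaussian kernel on the distance to the window centre,
#' `w = exp(-d^2 / (2 sigma^2))`; the plain (unweighted) mean is kept
#' alongside, since the bootstrap null compares plain means. Empty windows
#' are emitted with `n_loci = 0`.
#'
#' @param records a [per_locus_theta()] data.frame (sorted by chrom, pos).
#' @param window window size in bp (default 500000).
#' @param step window shift in bp (default 100000; must not exceed
#'   `window`).
#' @param sigma kernel standard deviation in bp (default `window / 4`, so
#'   +-2 sigma spans the window).
#' @return data.frame of class `window_stats`: `chrom`, `start`, `end`,
#'   `center`, `n_loci`, `wmean_theta`, `mean_theta`.
#' @export
kernel_windows <- function(records, window = 500000, step = 100000,
                           sigma = window / 4) {
  if (window < step) stop("window must be at least step (gaps otherwise)")
  out <- lapply(split(records, records$chrom), function(rc) {
    rc <- rc[order(rc$pos), ]
    maxp <- max(rc$pos)
    starts <- seq(1, max(1, maxp), by = step)
    starts <- starts[starts <= maxp]          # windows beyond the last locus
    ends <- starts + window
    n <- length(starts)
    wm <- pm <- rep(NA_real_, n)
    nl <- integer(n)
    for (k in seq_len(n)) {
      inw <- rc$pos >= starts[k] & rc$pos < ends[k]
      nl[k] <- sum(inw)
      if (nl[k] > 0) {
        ctr <- starts[k] + window / 2
        w <- exp(-(rc$pos[inw] - ctr)^2 / (2 * sigma^2))
        wm[k] <- sum(w * rc$theta[inw]) / sum(w)
        pm[k] <- mean(rc$theta[inw])
      }
    }
    data.frame(chrom = rc$chrom[1], start = starts, end = ends,
               center = starts + window / 2, n_loci = nl,
               wmean_theta = wm, mean_theta = pm)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Two-stage bootstrap significance for windows
#'
#' For a window holding `n` loci, `n` loci are drawn uniformly without
#' replacement from the genome-wide pool and their plain mean
#' differentiation computed, `reps1` times; windows whose plain mean exceeds
#' the empirical `gate`-th percentile are re-tested with fresh `reps2`
#' draws. A window is significant when its plain mean exceeds the `call`-th
#' percentile of the second-stage distribution and it holds at least
#' `min_loci` loci.
#'
#' @param windows a [kernel_windows()] data.frame.
#' @param records the genome-wide [per_locus_theta()] pool.
#' @param reps1,reps2 first/second-stage replicates (1000 / 10000).
#' @param gate,call escalation and calling percentiles (90 / 99).
#' @param min_loci minimum locus count for a significant call (default 2).
#' @param seed integer seed.
#' @return `windows` with `percentile`, `stage` and `significant` columns
#'   filled (percentile from the last stage reached; `NA` for empty
#'   windows).
#' @export
bootstrap_significance <- function(windows, records, reps1 = 1000,
                                   reps2 = 10000, gate = 90, call = 99,
                                   min_loci = 2, seed = 1L) {
  set.seed(as.integer(seed))
  pool <- records$theta
  npool <- length(pool)
  windows$percentile <- NA_real_
  windows$stage <- NA_integer_
  windows$significant <- FALSE
  boot_means <- function(n, reps) {
    if (n > npool) {
      warning("window holds more loci than the pool; sampling with replacement")
      idx <- matrix(sample.int(npool, n * reps, replace = TRUE), reps, n)
    } else if (n == 1) {
      idx <- matrix(sample.int(npool, reps, replace = TRUE), reps, 1)
    } else {
      # vectorized without-replacement draws: rejection on duplicate rows
      # (with-replacement rows conditioned on distinctness are exact
      # without-replacement samples)
      idx <- matrix(sample.int(npool, n * reps, replace = TRUE), reps, n)
      tix <- t(idx)
      srt <- matrix(tix[order(col(tix), tix)], n, reps)
      bad <- which(colSums(srt[-1, , drop = FALSE] ==
                             srt[-n, , drop = FALSE]) > 0)
      for (r in bad) idx[r, ] <- sample.int(npool, n)
    }
    rowMeans(matrix(pool[idx], nrow(idx), ncol(idx)))
  }
  for (k in which(windows$n_loci >= 1)) {
    n <- windows$n_loci[k]
    obs <- windows$mean_theta[k]
    b1 <- boot_means(n, reps1)
    windows$stage[k] <- reps1
    if (obs > stats::quantile(b1, gate / 100, names = FALSE)) {
      b2 <- boot_means(n, reps2)
      windows$stage[k] <- reps2
      windows$percentile[k] <- 100 * mean(b2 < obs)
      windows$significant[k] <-
        obs > stats::quantile(b2, call / 100, names = FALSE) && n >= min_loci
    } else {
      windows$percentile[k] <- 100 * mean(b1 < obs)
    }
  }
  windows
}

#' Merge contiguous significant windows into regions
#'
#' Maximal runs of overlapping or book-ended significant windows on one
#' chromosome are merged; region bounds are the minimum start and maximum
#' end.
#'
#' @param windows a flagged [bootstrap_significance()] data.frame.
#' @return data.frame: `chrom`, `start`, `end`, `n_windows`,
#'   `n_distinct_loci` (locus count of the merged span, taken from the
#'   member windows' unique positions when `records` is supplied).
#' @param records optional locus records to count distinct loci per region.
#' @export
merge_regions <- function(windows, records = NULL) {
  sig <- windows[windows$significant %in% TRUE, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      n_distinct_loci = integer()))
  sig <- sig[order(sig$chrom, sig$start, method = "radix"), ]
  out <- NULL
  cur <- sig[1, c("chrom", "start", "end")]
  nwin <- 1L
  flush <- function(cur, nwin) {
    nd <- if (is.null(records)) NA_integer_ else
      sum(records$chrom == cur$chrom & records$pos >= cur$start &
            records$pos < cur$end)
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               n_windows = nwin, n_distinct_loci = nd)
  }
  if (nrow(sig) > 1) for (k in seq(2, nrow(sig))) {
    if (sig$chrom[k] == cur$chrom && sig$start[k] <= cur$end) {
      cur$end <- max(cur$end, sig$end[k])
      nwin <- nwin + 1L
    } else {
      out <- rbind(out, flush(cur, nwin))
      cur <- sig[k, c("chrom", "start", "end")]
      nwin <- 1L
    }
  }
  out <- rbind(out, flush(cur, nwin))
  rownames(out) <- NULL
  out
}

#' Windowed differentiation genome scan
#'
#' Convenience wrapper: per-locus theta, kernel windows, two-stage bootstrap
#' and region merging in one call.
#'
#' @inheritParams per_locus_theta
#' @inheritParams kernel_windows
#' @inheritParams bootstrap_significance
#' @return list of class `genome_scan`: `records`, `windows`, `regions`.
#' @export
genome_scan <- function(ds, populations = NULL, window = 500000,
                        step = 100000, sigma = window / 4, reps1 = 1000,
                        reps2 = 10000, gate = 90, call = 99, min_loci = 2,
                        seed = 1L) {
  rec <- per_locus_theta(ds, populations)
  win <- kernel_windows(rec, window, step, sigma)
  win <- bootstrap_significance(win, rec, reps1, reps2, gate, call,
                                min_loci, seed)
  structure(list(records = rec, windows = win,
                 regions = merge_regions(win, rec)),
            class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  cat("<genome_scan>", nrow(x$records), "loci,", nrow(x$windows),
      "windows,", sum(x$windows$significant), "significant,",
      nrow(x$regions), "merged region(s)\n")
  invisible(x)
}

#' Write merged regions as BED
#'
#' Internal 1-based half-open coordinates are converted to BED's 0-based
#' half-open convention.
#'
#' @param regions a [merge_regions()] data.frame.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start - 1),
                    end = as.integer(regions$end - 1),
                    name = paste0("region", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Manhattan-style plot of the windowed scan
#'
#' Per-locus theta as points along the concatenated chromosomes, smoothed
#' window means as a line, significant windows highlighted.
#'
#' @param x a [genome_scan] result.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.genome_scan <- function(x, ...) {
  rec <- x$records
  chroms <- unique(rec$chrom)
  offs <- stats::setNames(cumsum(c(0, vapply(chroms, function(ch)
    max(rec$pos[rec$chrom == ch]), numeric(1))))[seq_along(chroms)], chroms)
  gx <- rec$pos + offs[rec$chrom]
  plot(gx, rec$theta, pch = 16, cex = 0.3,
       col = c("grey40", "grey70")[1 + match(rec$chrom, chroms) %% 2],
       xlab = "genome position", ylab = expression(theta), ...)
  win <- x$windows[x$windows$n_loci > 0, ]
  wx <- win$center + offs[win$chrom]
  graphics::lines(wx[order(wx)], win$wmean_theta[order(wx)], col = "steelblue")
  sig <- win[win$significant, ]
  if (nrow(sig))
    graphics::segments(sig$start + offs[sig$chrom], max(rec$theta),
                       sig$end + offs[sig$chrom], max(rec$theta),
                       col = "red", lwd = 3)
  invisible(x)
}
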