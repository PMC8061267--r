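#' Edwards' angular (Euclidean) genetic distance
#'
#' `D = sqrt(1 - (1/L) sum_loci sum_alleles sqrt(x_a y_a))` -- the square
#' root of the D_A complement, a Euclidean embedding-friendly distance.
#'
#' @inheritParams nei_da
#' @return scalar distance in `[0, 1]`.
#' @export
edwards_distance <- function(freqsA, freqsB) {
  sqrt(max(0, 1 - mean(locus_sqrt_overlap(freqsA, freqsB))))
}

#' Edwards distance matrix over populations
#'
#' @param ds a [geno_data].
#' @param freq optional precomputed populations x SNPs frequency matrix.
#' @return symmetric matrix.
#' @export
edwards_matrix <- function(ds, freq = NULL) {
  if (is.null(freq)) freq <- pop_freq_table(ds)
  k <- nrow(freq)
  D <- matrix(0, k, k, dimnames = list(rownames(freq), rownames(freq)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    D[i, j] <- D[j, i] <- edwards_distance(freq[i, ], freq[j, ])
  D
}

#' Distances rescaled on the first principal coordinate
#'
#' Classical PCoA (double-centred squared distances, eigendecomposition);
#' only the axis-1 scores are retained, so the rescaled distance between two
#' populations is the absolute difference of their first-axis scores. This
#' suppresses the off-axis noise that can mask major boundaries.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return list: `scaled` (distance matrix `|s_i - s_j|`), `scores`
#'   (axis-1 coordinates), `eigenvalues`.
#' @export
pcoa_first_axis <- function(D) {
  D <- as.matrix(D)
  stopifnot(isSymmetric(unname(D)), all(abs(diag(D)) < 1e-12))
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (e$values[1] <= 1e-12)
    stop("degenerate configuration: first eigenvalue is not positive")
  s <- e$vectors[, 1] * sqrt(e$values[1])
  scaled <- abs(outer(s, s, "-"))
  dimnames(scaled) <- dimnames(D)
  list(scaled = scaled, scores = stats::setNames(s, rownames(D)),
       eigenvalues = e$values)
}

#' Delaunay triangulation of planar points
#'
#' Incremental Bowyer-Watson triangulation; used to define the neighbour
#' network of sampled populations.
#'
#' @param xy two-column matrix of coordinates.
#' @return list: `edges` (two-column index matrix, i < j), `triangles`
#'   (three-column index matrix).
#' @export
delaunay <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  stopifnot(n >= 3, ncol(xy) == 2)
  # super-triangle enclosing all points
  span <- max(apply(xy, 2, function(v) diff(range(v))), 1e-9)
  cx <- mean(range(xy[, 1])); cy <- mean(range(xy[, 2]))
  big <- 50 * span
  pts <- rbind(xy, c(cx - big, cy - big), c(cx + big, cy - big),
               c(cx, cy + big))
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- matrix(c(s1, s2, s3), 1, 3)
  circum_ok <- function(tri, p) {
    # TRUE when p lies inside the circumcircle of tri
    ax <- pts[tri[1], 1]; ay <- pts[tri[1], 2]
    bx <- pts[tri[2], 1]; by <- pts[tri[2], 2]
    cx2 <- pts[tri[3], 1]; cy2 <- pts[tri[3], 2]
    d <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    if (abs(d) < 1e-12) return(FALSE)
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / d
    rr <- (ax - ux)^2 + (ay - uy)^2
    (p[1] - ux)^2 + (p[2] - uy)^2 < rr - 1e-12
  }
  for (ip in seq_len(n)) {
    p <- pts[ip, ]
    bad <- which(apply(tris, 1, circum_ok, p = p))
    if (!length(bad)) { # numerical fallback: attach to nearest triangle
      bad <- 1L
    }
    # polygon hole boundary = edges of bad triangles not shared twice
    ed <- do.call(rbind, lapply(bad, function(t) {
      tr <- tris[t, ]
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(ed[, 1], ed[, 2])
    keep <- !(key %in% key[duplicated(key)])
    poly <- ed[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    tris <- rbind(tris, cbind(poly, ip))
  }
  tris <- tris[!apply(tris, 1, function(tr) any(tr > n)), , drop = FALSE]
  tris <- t(apply(tris, 1, sort))
  ed <- rbind(tris[, c(1, 2), drop = FALSE], tris[, c(2, 3), drop = FALSE],
              tris[, c(1, 3), drop = FALSE])
  ed <- unique(ed)
  ed <- ed[order(ed[, 1], ed[, 2]), , drop = FALSE]
  list(edges = ed, triangles = tris)
}

#' Build the population connectivity network
#'
#' Delaunay triangulation of population coordinates, with each edge weighted
#' by a (PCoA-rescaled) genetic distance.
#'
#' @param coords data.frame `pop`, `x`, `y`.
#' @param scaled_D symmetric genetic-distance matrix with matching labels.
#' @return list of class `pop_network`: `pops`, `xy`, `edges` (data.frame
#'   `from`, `to`, `dist`), `triangles`.
#' @export
population_network <- function(coords, scaled_D) {
  pops <- coords$pop
  stopifnot(all(pops %in% rownames(scaled_D)))
  xy <- as.matrix(coords[, c("x", "y")])
  tri <- delaunay(xy)
  ed <- data.frame(from = tri$edges[, 1], to = tri$edges[, 2])
  ed$dist <- scaled_D[cbind(match(pops[ed$from], rownames(scaled_D)),
                            match(pops[ed$to], colnames(scaled_D)))]
  structure(list(pops = pops, xy = xy, edges = ed,
                 triangles = tri$triangles), class = "pop_network")
}

#' @export
print.pop_network <- function(x, ...) {
  cat("<pop_network>", length(x$pops), "populations,", nrow(x$edges),
      "Delaunay edges\n")
  if (!is.null(x$boundaries))
    cat("  boundaries:", length(unique(x$boundaries$run)), "run(s),",
        nrow(x$boundaries), "crossed edges\n")
  invisible(x)
}

#' Monmonier maximum-difference boundary detection
#'
#' Each run seeds at the largest not-yet-crossed edge distance above the
#' threshold and extends in both directions through the triangulation dual:
#' from the triangle just entered, the admissible neighbouring edge of
#' maximal distance (uncrossed, above threshold) is crossed next, until the
#' hull, an already-crossed edge, or no admissible edge stops the extension.
#' The default threshold is the third quartile of the network's edge
#' distances. An optional relaxation pass lowers the threshold by
#' `threshold_relax` and appends further runs, probing shallower structure.
#'
#' @param network a [population_network()].
#' @param n_runs number of boundary runs (default 3).
#' @param threshold minimum edge distance enterable into a boundary; default
#'   `quantile(dist, 0.75)`.
#' @param relax if `TRUE`, rerun with threshold reduced by `threshold_relax`
#'   after the main runs.
#' @param threshold_relax relative threshold reduction for the relax pass
#'   (default 0.05).
#' @return The network with `boundaries` (data.frame `run`, `step`, `from`,
#'   `to`, `dist`), `threshold`, and `converged_run` (the run index at which
#'   no seed edge remained above threshold, or `NA`).
#' @export
monmonier <- function(network, n_runs = 3, threshold = NULL, relax = FALSE,
                      threshold_relax = 0.05) {
  ed <- network$edges
  if (is.null(threshold))
    threshold <- unname(stats::quantile(ed$dist, 0.75, type = 7))
  tris <- network$triangles
  m <- nrow(ed)
  ekey <- paste(ed$from, ed$to)
  edge_id <- function(i, j) match(paste(pmin(i, j), pmax(i, j)), ekey)
  # triangle membership of each edge
  tri_edges <- cbind(edge_id(tris[, 1], tris[, 2]),
                     edge_id(tris[, 2], tris[, 3]),
                     edge_id(tris[, 1], tris[, 3]))
  adj <- lapply(seq_len(m), function(e) which(rowSums(tri_edges == e) > 0))
  crossed <- logical(m)
  out <- NULL
  converged <- NA_integer_
  run_pass <- function(n_runs, threshold, run_offset) {
    for (run in seq_len(n_runs)) {
      cand <- which(!crossed & ed$dist > threshold)
      if (!length(cand)) {
        if (is.na(converged)) converged <<- run + run_offset
        break
      }
      seed <- cand[order(-ed$dist[cand], cand)][1]
      crossed[seed] <<- TRUE
      path <- data.frame(run = run + run_offset, step = 0L,
                         from = ed$from[seed], to = ed$to[seed],
                         dist = ed$dist[seed])
      # extend into each adjacent triangle of the seed edge
      for (t0 in adj[[seed]]) {
        cur_tri <- t0
        prev_edge <- seed
        step <- 0L
        repeat {
          ee <- setdiff(tri_edges[cur_tri, ], prev_edge)
          ok <- ee[!crossed[ee] & ed$dist[ee] > threshold]
          if (!length(ok)) break
          nxt <- ok[order(-ed$dist[ok], ok)][1]
          crossed[nxt] <<- TRUE
          step <- step + 1L
          path <- rbind(path, data.frame(run = run + run_offset,
                                         step = step, from = ed$from[nxt],
                                         to = ed$to[nxt],
                                         dist = ed$dist[nxt]))
          nxt_tri <- setdiff(adj[[nxt]], cur_tri)
          if (!length(nxt_tri)) break       # hull reached
          cur_tri <- nxt_tri[1]
          prev_edge <- nxt
        }
      }
      out <<- rbind(out, path)
    }
  }
  run_pass(n_runs, threshold, 0L)
  if (relax) run_pass(n_runs, threshold * (1 - threshold_relax),
                      if (is.null(out)) 0L else max(out$run))
  if (is.null(out))
    warning("no edge distance above the threshold; zero boundaries")
  network$boundaries <- out
  network$threshold <- threshold
  network$converged_run <- converged
  network
}

#' Plot the connectivity network and its boundaries
#'
#' Populations at their coordinates, Delaunay edges in grey, crossed edges
#' highlighted with line width decreasing in run rank.
#'
#' @param x a [pop_network] (after [monmonier()] for boundaries).
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.pop_network <- function(x, ...) {
  plot(x$xy, type = "n", xlab = "x", ylab = "y", asp = 1, ...)
  graphics::segments(x$xy[x$edges$from, 1], x$xy[x$edges$from, 2],
                     x$xy[x$edges$to, 1], x$xy[x$edges$to, 2], col = "grey70")
  if (!is.null(x$boundaries)) {
    b <- x$boundaries
    graphics::segments(x$xy[b$from, 1], x$xy[b$from, 2],
                       x$xy[b$to, 1], x$xy[b$to, 2],
                       col = "red", lwd = 4 / b$run)
  }
  graphics::points(x$xy, pch = 21, bg = "white")
  graphics::text(x$xy, labels = x$pops, pos = 3, cex = 0.7)
  invisible(x)
}
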