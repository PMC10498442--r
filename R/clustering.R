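#' Cluster trajectory frames on a precomputed RMSD matrix
#'
#' Four methods are offered under the names used by common trajectory
#' tools.  `kmeans` runs as PAM-style k-medoids directly on the distance
#' matrix (centroid k-means is ill-defined on an RMSD metric without
#' iterative re-alignment); `hierarchical` is average-linkage
#' agglomeration cut at `k`; `dbscan` is standard density clustering on
#' the distances; `dpeaks` is the cutoff-kernel density-peaks variant
#' (local density rho within `eps`, separation delta to the nearest
#' denser frame, top-k rho*delta picks).  The representative of every
#' cluster is its medoid frame.
#'
#' @param d Symmetric F x F distance matrix (see [rmsd_matrix()]).
#' @param method One of `"kmeans"`, `"hierarchical"`, `"dbscan"`,
#'   `"dpeaks"`.
#' @param k Cluster count for kmeans/hierarchical/dpeaks (default 10).
#' @param eps Neighborhood radius (Angstrom) for dbscan and the dpeaks
#'   density cutoff; defaults to half the median off-diagonal distance.
#' @param min_pts dbscan core-point threshold (default 4).
#' @param seed Seed for the k-medoids initialization (default 2023).
#' @return Object of class `clusterresult`: `labels` (1..K per frame),
#'   `representatives` (frame index per cluster), `sizes`, `method`;
#'   `energies` and `ranking` stay `NULL` until [rank_clusters()].
#' @export
cluster_frames <- function(d, method = c("kmeans", "hierarchical",
                                         "dbscan", "dpeaks"),
                           k = 10L, eps = NULL, min_pts = 4L,
                           seed = 2023L) {
  method <- match.arg(method)
  d <- as.matrix(d)
  f <- nrow(d)
  if (f != ncol(d)) stop("distance matrix must be square")
  if (method %in% c("kmeans", "hierarchical", "dpeaks") && k > f)
    stop("k = ", k, " exceeds the number of frames (", f, ")")
  if (is.null(eps)) {
    off <- d[upper.tri(d)]
    eps <- if (length(off)) stats::median(off) / 2 else 1
  }
  km <- NULL
  labels <- switch(method,
    kmeans = {
      km <- .kmedoids(d, k, seed)
      km$labels
    },
    hierarchical = stats::cutree(stats::hclust(stats::as.dist(d),
                                               method = "average"), k = k),
    dbscan = .dbscan_labels(d, eps, min_pts),
    dpeaks = .dpeaks_labels(d, k, eps))
  labels <- match(labels, sort(unique(labels[labels > 0L])))
  labels[is.na(labels)] <- 0L  # dbscan noise stays 0
  ks <- max(labels)
  if (ks == 0L)
    stop("no clusters found; try a larger eps")
  reps <- vapply(seq_len(ks), function(c_) {
    mem <- which(labels == c_)
    mem[which.min(rowSums(d[mem, mem, drop = FALSE]))]
  }, 1L)
  structure(list(labels = labels, representatives = reps,
                 sizes = as.integer(table(factor(labels[labels > 0L],
                                                 levels = seq_len(ks)))),
                 method = method, energies = NULL, ranking = NULL,
                 objective_trace = if (!is.null(km)) km$objective),
            class = "clusterresult")
}

#' @export
print.clusterresult <- function(x, ...) {
  cat(sprintf("<clusterresult> %s: %d clusters over %d frames\n",
              x$method, length(x$representatives), length(x$labels)))
  if (!is.null(x$ranking)) {
    cat("  rank cluster  frames  rep  dE(kcal/mol)\n")
    for (r in seq_along(x$ranking)) {
      c_ <- x$ranking[r]
      cat(sprintf("  %4d %7d %7d %4d %13.3f\n", r, c_, x$sizes[c_],
                  x$representatives[c_], x$rel_energies[c_]))
    }
  }
  invisible(x)
}

# PAM-style k-medoids on a distance matrix: seeded greedy (k-means++-like)
# initialization, then alternating assignment / medoid-update sweeps whose
# objective never increases, followed by convergence.
.kmedoids <- function(d, k, seed) {
  f <- nrow(d)
  rs <- .seeded_rng(seed)
  meds <- rs$int(1L, f)
  while (length(meds) < k) {
    dm <- apply(d[, meds, drop = FALSE], 1L, min)
    cand <- which.max(dm)  # farthest-point seeding, deterministic
    meds <- c(meds, cand)
  }
  obj_hist <- numeric(0)
  for (it in 1:100) {
    labels <- apply(d[, meds, drop = FALSE], 1L, which.min)
    new_meds <- vapply(seq_len(k), function(c_) {
      mem <- which(labels == c_)
      if (!length(mem)) return(meds[c_])
      mem[which.min(rowSums(d[mem, mem, drop = FALSE]))]
    }, 1L)
    obj <- sum(d[cbind(seq_len(f), new_meds[labels])])
    obj_hist <- c(obj_hist, obj)
    if (identical(new_meds, meds)) break
    meds <- new_meds
  }
  labels <- apply(d[, meds, drop = FALSE], 1L, which.min)
  list(labels = labels, medoids = meds, objective = obj_hist)
}

.dbscan_labels <- function(d, eps, min_pts) {
  f <- nrow(d)
  nbrs <- lapply(seq_len(f), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, 1L) >= min_pts
  labels <- rep(0L, f)
  c_ <- 0L
  for (i in seq_len(f)) {
    if (labels[i] != 0L || !core[i]) next
    c_ <- c_ + 1L
    queue <- i
    labels[i] <- c_
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      if (core[p]) {
        for (q in nbrs[[p]]) {
          if (labels[q] == 0L) {
            labels[q] <- c_
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

.dpeaks_labels <- function(d, k, eps) {
  f <- nrow(d)
  rho <- rowSums(d <= eps) - 1L  # cutoff kernel
  delta <- numeric(f)
  for (i in seq_len(f)) {
    denser <- which(rho > rho[i] | (rho == rho[i] & seq_len(f) < i))
    delta[i] <- if (length(denser)) min(d[i, denser]) else max(d[i, ])
  }
  gamma <- rho * delta
  centers <- order(gamma, decreasing = TRUE)[seq_len(k)]
  labels <- rep(NA_integer_, f)
  labels[centers] <- seq_len(k)
  # assign remaining frames in decreasing density to the label of their
  # nearest denser neighbor
  ord <- order(rho, decreasing = TRUE)
  for (i in ord) {
    if (!is.na(labels[i])) next
    denser <- which(rho > rho[i] | (rho == rho[i] & seq_len(f) < i))
    labels[i] <- labels[denser[which.min(d[i, denser])]]
  }
  labels
}

#' Rank clusters by single-point energy
#'
#' Sorts clusters ascending by the supplied per-cluster energies; ties are
#' broken by population (larger first), then by cluster id.  Relative
#' energies are reported with the minimum at zero.
#'
#' @param c A [cluster_frames()] result.
#' @param energies Numeric vector, one energy (kcal/mol) per cluster, in
#'   cluster-id order (e.g. single-point energies of the representative
#'   frames), or a two-column table `cluster id, energy` as read by
#'   [read_energy_table()].
#' @return The cluster result with `energies`, `rel_energies` and
#'   `ranking` filled in.
#' @export
rank_clusters <- function(c, energies) {
  kc <- length(c$representatives)
  if (is.matrix(energies)) energies <- as.data.frame(energies)
  if (is.data.frame(energies)) {
    e <- numeric(kc)
    e[as.integer(energies[[1L]])] <- as.numeric(energies[[2L]])
    energies <- e
  }
  if (length(energies) != kc)
    stop("need one energy per cluster (", kc, "), got ", length(energies))
  ord <- order(energies, -c$sizes, seq_len(kc))
  c$energies <- energies
  c$rel_energies <- energies - min(energies)
  c$ranking <- ord
  c
}

#' Read a whitespace-delimited cluster-energy table
#'
#' Two columns: cluster id, energy (kcal/mol).  Comment lines start
#' with `#`.
#'
#' @param x Path or text.
#' @return Data frame with columns `cluster`, `energy`.
#' @export
read_energy_table <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"),
                             as.numeric))
  data.frame(cluster = as.integer(m[, 1L]), energy = m[, 2L])
}

#' Write cluster representatives and the ranked summary
#'
#' @param t The aligned [trajectory()] the clustering was computed on.
#' @param c A ranked [cluster_frames()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the written summary table (tsv); one xyz
#'   file per representative is written alongside it.
#' @export
write_cluster_report <- function(t, c, dir) {
  if (is.null(c$ranking)) stop("rank the clusters first")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (c_ in seq_along(c$representatives)) {
    s <- t$topology
    s$coords <- matrix(t$frames[c$representatives[c_], , ], ncol = 3L)
    s$comment <- sprintf("cluster %d representative (frame %d)", c_,
                         c$representatives[c_])
    write_xyz(s, file.path(dir, sprintf("cluster_%02d.xyz", c_)))
  }
  tab <- data.frame(rank = seq_along(c$ranking), cluster = c$ranking,
                    frames = c$sizes[c$ranking],
                    representative = c$representatives[c$ranking],
                    energy = c$energies[c$ranking],
                    rel_energy = c$rel_energies[c$ranking])
  path <- file.path(dir, "clusters_ranked.tsv")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
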