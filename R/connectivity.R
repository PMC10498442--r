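#' Perceive bonds by the scaled-radius distance rule
#'
#' Two atoms are considered bonded when their distance is strictly smaller
#' than `factor` times the sum of their van der Waals radii.  Pairs where
#' neither atom is a metal enter the adjacency list; pairs involving at
#' least one metal that pass the distance test are recorded separately as
#' metal contacts and never enter the adjacency list, so fragmentation
#' treats the metal center as disconnected from its ligands.  Metal-metal
#' passing pairs are also kept in the contact list so polymetallic systems
#' lose no information.
#'
#' @param s An `xyzmol` structure.
#' @param factor Dimensionless scale on the radius sum (default 0.6).
#' @param table Element table providing radii and metal flags.
#' @return An object of class `bondgraph` with fields `n_atoms`,
#'   `adjacency` (two-column matrix of atom index pairs, i < j) and
#'   `metal_contacts` (two-column matrix, metal index first).
#' @export
detect_bonds <- function(s, factor = 0.6, table = element_table()) {
  if (factor <= 0) stop("factor must be positive")
  n <- n_atoms(s)
  radii <- element_vdw(s$elements, table)
  metal <- element_is_metal(s$elements, table)
  adjacency <- matrix(integer(0), 0L, 2L)
  contacts <- matrix(integer(0), 0L, 2L)
  if (n > 1L) {
    d <- as.matrix(stats::dist(s$coords))
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    if (any(d[pairs] < 1e-8))
      stop("degenerate geometry: atoms ",
           paste(pairs[which(d[pairs] < 1e-8)[1L], ], collapse = " and "),
           " have identical coordinates")
    thr <- factor * outer(radii, radii, "+")
    hit <- pairs[d[pairs] < thr[pairs], , drop = FALSE]
    if (nrow(hit)) {
      i <- hit[, 1L]; j <- hit[, 2L]
      m1 <- metal[i]; m2 <- metal[j]
      keep <- !m1 & !m2
      adjacency <- cbind(i[keep], j[keep])
      cm <- which(m1 | m2)
      if (length(cm)) {
        # metal index first; metal-metal pairs keep file order
        a <- i[cm]; b <- j[cm]
        swap <- !metal[a] & metal[b]
        tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
        contacts <- cbind(a, b)
      }
    }
  }
  dimnames(adjacency) <- NULL
  dimnames(contacts) <- NULL
  structure(list(n_atoms = n, adjacency = adjacency,
                 metal_contacts = contacts, is_metal = metal),
            class = "bondgraph")
}

#' @export
print.bondgraph <- function(x, ...) {
  cat(sprintf("<bondgraph> %d atoms, %d bonds, %d metal contacts\n",
              x$n_atoms, nrow(x$adjacency), nrow(x$metal_contacts)))
  invisible(x)
}

#' Fragment container
#'
#' @param fragments List of disjoint integer atom-index vectors that
#'   together partition `1:n_atoms`.
#' @param n_atoms Total number of atoms.
#' @param charges Optional per-fragment integer charges (e).
#' @param labels Optional fragment labels.
#' @return An object of class `fragset`.
#' @export
fragment_set <- function(fragments, n_atoms, charges = NULL, labels = NULL) {
  all_idx <- sort(unlist(fragments))
  if (!identical(as.integer(all_idx), seq_len(n_atoms)))
    stop("fragments must partition atoms 1..", n_atoms, " exactly")
  if (is.null(labels)) labels <- sprintf("F%02d", seq_along(fragments))
  structure(list(fragments = lapply(fragments, as.integer),
                 n_atoms = as.integer(n_atoms),
                 charges = charges, labels = labels),
            class = "fragset")
}

#' @export
print.fragset <- function(x, ...) {
  cat(sprintf("<fragset> %d fragments over %d atoms\n",
              length(x$fragments), x$n_atoms))
  for (f in seq_along(x$fragments)) {
    ch <- if (is.null(x$charges)) "?" else sprintf("%+d", x$charges[f])
    cat(sprintf("  %s: %d atoms, charge %s\n", x$labels[f],
                length(x$fragments[[f]]), ch))
  }
  invisible(x)
}

#' Enumerate fragments by depth-first search
#'
#' Connected components of the non-metal adjacency graph, found with an
#' iterative (explicit-stack) depth-first search so deep chains cannot hit
#' recursion limits.  Metal contacts are ignored, so every metal atom
#' becomes a singleton fragment.  Fragments are ordered by their smallest
#' contained atom index; charges are left unset.
#'
#' @param g A `bondgraph`.
#' @return A [fragment_set()] with `charges = NULL`.
#' @export
find_fragments <- function(g) {
  n <- g$n_atoms
  nbr <- vector("list", n)
  if (nrow(g$adjacency)) {
    for (r in seq_len(nrow(g$adjacency))) {
      i <- g$adjacency[r, 1L]; j <- g$adjacency[r, 2L]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  comp <- integer(n)
  k <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    k <- k + 1L
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- k
      todo <- nbr[[v]][comp[nbr[[v]]] == 0L]
      if (length(todo)) stack <- c(stack, todo)
    }
  }
  frags <- split(seq_len(n), comp)
  frags <- frags[order(vapply(frags, min, 1L))]
  names(frags) <- NULL
  fragment_set(frags, n)
}

#' Attach user-supplied fragment charges
#'
#' @param frags A [fragment_set()].
#' @param charges Integer vector, one total charge (e) per fragment.
#' @param total Integer total system charge the fragment charges must sum to.
#' @return The fragment set with charges stored.
#' @export
assign_fragment_charges <- function(frags, charges, total) {
  if (length(charges) != length(frags$fragments))
    stop("need one charge per fragment (", length(frags$fragments),
         "), got ", length(charges))
  if (sum(charges) != total)
    stop("fragment charges sum to ", sum(charges),
         " but the total system charge is ", total)
  frags$charges <- as.integer(charges)
  frags
}
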