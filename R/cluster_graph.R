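#' Construct a cluster graph from an edge-weight matrix
#'
#' A cluster graph holds the fragments covering one target position as
#' vertices, with undirected edges weighted by pairwise Calpha-RMSD. The
#' object caches the total edge weight `W`, the per-vertex incident weight
#' `w(v)` and the per-vertex degree, so that outlier rejection can probe and
#' perform removals in time linear in the removed vertex's adjacency.
#'
#' Most users build cluster graphs from a fragment library with
#' [build_cluster()]; this constructor takes an explicit weight matrix and is
#' useful for simulation and testing.
#'
#' @param weights Square symmetric numeric matrix; `weights[u, v]` is the
#'   edge weight in Angstrom, `NA` where `u` and `v` are not connected. The
#'   diagonal is ignored.
#' @param ids Character vertex identifiers (default: row names of `weights`,
#'   or `"v1"`, `"v2"`, ...).
#' @param position 1-based target residue index the cluster belongs to.
#' @param fragments Optional list of [fragment()] objects, parallel to `ids`.
#' @return An object of class `cluster_graph`: a list with elements
#'   `position`, `ids`, `fragments`, `weights`, `total_weight`,
#'   `incident_weight`, `degree`, `n_edges`.
#' @seealso [build_cluster()], [shrink_cluster()]
#' @export
#' @examples
#' w <- matrix(NA, 3, 3); w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 2
#' g <- cluster_graph(w)
#' average_rmsd(g)  # 1.5
cluster_graph <- function(weights, ids = NULL, position = NA_integer_,
                          fragments = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop("cluster_graph: weight matrix must be square")
  if (is.null(ids)) {
    ids <- rownames(weights)
    if (is.null(ids)) ids <- if (n) paste0("v", seq_len(n)) else character()
  }
  ids <- as.character(ids)
  if (length(ids) != n) stop("cluster_graph: ids do not match matrix size")
  if (anyDuplicated(ids)) stop("cluster_graph: duplicate vertex ids")
  if (n) {
    diag(weights) <- NA_real_
    if (any(abs(weights - t(weights)) > 1e-9, na.rm = TRUE) ||
        any(is.na(weights) != is.na(t(weights)))) {
      stop("cluster_graph: weight matrix must be symmetric")
    }
    if (any(weights < 0, na.rm = TRUE)) {
      stop("cluster_graph: negative edge weights")
    }
  }
  dimnames(weights) <- list(ids, ids)
  if (!is.null(fragments) && length(fragments) != n) {
    stop("cluster_graph: fragments do not match matrix size")
  }
  g <- structure(list(position = as.integer(position), ids = ids,
                      fragments = fragments, weights = weights),
                 class = "cluster_graph")
  refresh_caches(g)
}

# recompute W, w(v), degree and |E| from the weight matrix
refresh_caches <- function(g) {
  w <- g$weights
  n <- nrow(w)
  if (n == 0L) {
    g$incident_weight <- setNames(numeric(), character())
    g$degree <- setNames(integer(), character())
    g$total_weight <- 0
    g$n_edges <- 0L
    return(g)
  }
  g$incident_weight <- setNames(rowSums(w, na.rm = TRUE), g$ids)
  g$degree <- setNames(as.integer(rowSums(!is.na(w))), g$ids)
  g$total_weight <- sum(w[upper.tri(w)], na.rm = TRUE)
  g$n_edges <- as.integer(sum(!is.na(w[upper.tri(w)])))
  g
}

#' Number of vertices in a cluster graph
#' @param g A [cluster_graph()].
#' @return Integer vertex count.
#' @export
n_vertices <- function(g) length(g$ids)

#' @export
print.cluster_graph <- function(x, ...) {
  avg <- average_rmsd(x)
  cat(sprintf("cluster graph at position %s: %d vertices, %d edges%s\n",
              ifelse(is.na(x$position), "?", x$position),
              n_vertices(x), x$n_edges,
              if (is.na(avg)) "" else sprintf(", avg RMSD %.3f A", avg)))
  invisible(x)
}

# resolve a vertex given as id or index to an index; error when absent
resolve_vertex <- function(g, v) {
  if (is.character(v)) {
    i <- match(v, g$ids)
    if (is.na(i)) stop(sprintf("vertex '%s' not in graph", v))
  } else {
    i <- as.integer(v)
    if (is.na(i) || i < 1L || i > n_vertices(g)) {
      stop(sprintf("vertex index %s out of range", v))
    }
  }
  i
}

#' Pairwise fragment RMSD matrix for a library
#'
#' Computes [fragment_rmsd()] for every pair of fragments whose query
#' intervals overlap by at least `overlap_min` residues; other entries are
#' `NA`. Computing this once and passing it to [build_cluster()] or
#' [predict_target()] avoids recomputing superpositions for every position.
#'
#' @param library List of valid [fragment()] objects.
#' @param overlap_min Minimum overlap in residues (default 6).
#' @return Symmetric numeric matrix with fragment ids as dimnames and `NA`
#'   diagonal.
#' @export
pairwise_rmsd <- function(library, overlap_min = 6) {
  n <- length(library)
  ids <- vapply(library, function(f) f$id, character(1))
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        fragment_rmsd(library[[i]], library[[j]], overlap_min)
    }
  }
  m
}

#' Build the cluster graph for one target position
#'
#' Collects every fragment whose query interval contains `position` and
#' connects each pair overlapping by at least `overlap_min` residues with an
#' edge weighted by their pairwise Calpha-RMSD.
#'
#' @param library List of valid [fragment()] objects.
#' @param position 1-based target residue index.
#' @param overlap_min Minimum overlap in residues (default 6).
#' @param rmsd_matrix Optional precomputed [pairwise_rmsd()] matrix for the
#'   whole library (indexed by fragment id).
#' @return A [cluster_graph()]; empty (0 vertices) when no fragment covers
#'   the position.
#' @export
build_cluster <- function(library, position, overlap_min = 6,
                          rmsd_matrix = NULL) {
  stopifnot(length(position) == 1L, position >= 1)
  keep <- vapply(library, fragment_covers, logical(1), position = position)
  frags <- library[keep]
  ids <- vapply(frags, function(f) f$id, character(1))
  if (anyDuplicated(ids)) stop("build_cluster: duplicate fragment ids")
  n <- length(frags)
  if (!is.null(rmsd_matrix)) {
    w <- rmsd_matrix[ids, ids, drop = FALSE]
  } else {
    w <- pairwise_rmsd(frags, overlap_min)
  }
  cluster_graph(w, ids = ids, position = position, fragments = frags)
}

#' Average RMSD over the edges of a cluster graph
#'
#' The stability statistic of the outlier-rejection algorithm: the mean edge
#' weight `W / |E|`, i.e. the average Calpha-RMSD between all adjacent
#' fragment pairs. A cluster is stable when this value falls below the
#' critical threshold (1.5 Angstrom by default).
#'
#' @param g A [cluster_graph()].
#' @return Mean edge weight in Angstrom, or `NA_real_` for an edgeless graph.
#' @export
average_rmsd <- function(g) {
  if (g$n_edges == 0L) return(NA_real_)
  g$total_weight / g$n_edges
}

#' Average RMSD that would result from removing one vertex
#'
#' Greedy probe of the outlier-rejection algorithm: using the cached sums,
#' the average RMSD after excluding vertex `v` is
#' `(W - w(v)) / (|E| - degree(v))` without modifying the graph.
#'
#' @param g A [cluster_graph()].
#' @param v Vertex id (character) or index.
#' @return Resulting average RMSD in Angstrom, or `NA_real_` when the removal
#'   would leave the graph edgeless.
#' @export
probe_removal <- function(g, v) {
  i <- resolve_vertex(g, v)
  e_left <- g$n_edges - g$degree[[i]]
  if (e_left <= 0L) return(NA_real_)
  (g$total_weight - g$incident_weight[[i]]) / e_left
}

#' Remove a vertex from a cluster graph
#'
#' Deletes the vertex and its incident edges, updating the cached total
#' weight, incident weights and degrees incrementally (work proportional to
#' the removed vertex's adjacency, not the graph size).
#'
#' @param g A [cluster_graph()].
#' @param v Vertex id (character) or index.
#' @return The reduced [cluster_graph()].
#' @export
remove_vertex <- function(g, v) {
  i <- resolve_vertex(g, v)
  nb <- which(!is.na(g$weights[i, ]))
  g$total_weight <- g$total_weight - g$incident_weight[[i]]
  g$n_edges <- g$n_edges - g$degree[[i]]
  g$incident_weight[nb] <- g$incident_weight[nb] - g$weights[i, nb]
  g$degree[nb] <- g$degree[nb] - 1L
  g$weights <- g$weights[-i, -i, drop = FALSE]
  g$ids <- g$ids[-i]
  g$incident_weight <- g$incident_weight[-i]
  g$degree <- g$degree[-i]
  if (!is.null(g$fragments)) g$fragments <- g$fragments[-i]
  g
}
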