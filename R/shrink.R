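#' Greedy outlier rejection on a fragment cluster (ShrinkCluster)
#'
#' Iteratively removes the vertex whose exclusion produces the largest drop
#' in the cluster's average pairwise Calpha-RMSD, until the average falls
#' below the stability threshold. On every iteration each vertex is probed
#' with [probe_removal()]; the vertex with the minimal resulting average is
#' deleted. If no single removal strictly decreases the current average the
#' cluster cannot shrink further and is reported *diverging* — a
#' heterogeneous aggregate of false-positive fragments whose position stays
#' unassigned. A cluster that starts with fewer than two vertices or no
#' edges is reported *empty* (stability is defined over edges).
#'
#' A removal that would leave the graph edgeless has an undefined resulting
#' average and is never taken; consequently a 2-vertex cluster above
#' threshold is diverging. Ties between candidate removals (equal resulting
#' average within `1e-12`) are broken toward the vertex with the larger
#' incident weight, then the lexicographically smallest id, so runs are
#' reproducible.
#'
#' @param g A [cluster_graph()].
#' @param threshold Stability threshold in Angstrom (strict `<`; default
#'   1.5).
#' @param tol Numeric tolerance for "strictly decreases" and for probe ties
#'   (default 1e-12).
#' @return An object of class `filter_result`: list with
#'   \describe{
#'     \item{status}{`"stable"`, `"diverging"` or `"empty"`.}
#'     \item{surviving}{Character ids of the vertices left in the graph.}
#'     \item{removed}{data.frame with columns `id` and `avg_after` (average
#'       RMSD immediately after that removal), in removal order.}
#'     \item{final_avg_rmsd}{Average RMSD of the final graph (`NA` when
#'       edgeless).}
#'     \item{graph}{The filtered [cluster_graph()].}
#'   }
#' @export
#' @examples
#' w <- matrix(0.5, 4, 4); diag(w) <- NA
#' shrink_cluster(cluster_graph(w))$status  # already stable
shrink_cluster <- function(g, threshold = 1.5, tol = 1e-12) {
  stopifnot(inherits(g, "cluster_graph"), threshold > 0)
  removed_ids <- character()
  removed_avg <- numeric()
  finish <- function(status) {
    structure(list(status = status,
                   surviving = g$ids,
                   removed = data.frame(id = removed_ids,
                                        avg_after = removed_avg,
                                        stringsAsFactors = FALSE),
                   final_avg_rmsd = average_rmsd(g),
                   graph = g),
              class = "filter_result")
  }
  if (n_vertices(g) < 2L || g$n_edges == 0L) return(finish("empty"))
  repeat {
    avg <- average_rmsd(g)
    if (avg < threshold) return(finish("stable"))
    n <- n_vertices(g)
    probes <- vapply(seq_len(n), function(i) probe_removal(g, i), numeric(1))
    cand <- which(!is.na(probes) & (avg - probes) > tol)
    if (!length(cand)) return(finish("diverging"))
    best <- cand[probes[cand] <= min(probes[cand]) + tol]
    if (length(best) > 1L) {
      wv <- g$incident_weight[best]
      best <- best[wv >= max(wv) - tol]
      if (length(best) > 1L) {
        best <- best[order(g$ids[best])]
      }
    }
    pick <- best[[1L]]
    removed_ids <- c(removed_ids, g$ids[[pick]])
    g <- remove_vertex(g, pick)
    removed_avg <- c(removed_avg, average_rmsd(g))
    # unreachable in principle (candidate removals keep >= 1 edge), kept as
    # a guard against numerically degenerate inputs
    if (n_vertices(g) < 2L || g$n_edges == 0L) return(finish("empty"))
  }
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter result: %s; %d surviving, %d removed%s\n",
              x$status, length(x$surviving), nrow(x$removed),
              if (is.na(x$final_avg_rmsd)) ""
              else sprintf(", final avg RMSD %.3f A", x$final_avg_rmsd)))
  invisible(x)
}
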