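#' Structural consistency of a filtered cluster
#'
#' Fraction of the cluster's edges whose weight (pairwise Calpha-RMSD) does
#' not exceed the critical threshold — the proportion of structurally
#' similar fragment pairs among all connected pairs. Edges of weight exactly
#' equal to the threshold count as similar.
#'
#' @param g A [cluster_graph()], normally the filtered (stable) cluster.
#' @param threshold Similarity threshold in Angstrom (default 1.5).
#' @return Fraction in \[0, 1\].
#' @export
consistency <- function(g, threshold = 1.5) {
  stopifnot(inherits(g, "cluster_graph"))
  if (g$n_edges == 0L) {
    stop("consistency is undefined for an edgeless cluster")
  }
  ut <- g$weights[upper.tri(g$weights)]
  sum(ut <= threshold, na.rm = TRUE) / g$n_edges
}

#' Recurrence of a filtered cluster
#'
#' The number of fragments (vertices) in the cluster — a proxy for the
#' abundance of the local motif in a non-redundant structure database.
#'
#' @param g A [cluster_graph()].
#' @return Non-negative integer vertex count.
#' @export
recurrence <- function(g) {
  stopifnot(inherits(g, "cluster_graph"))
  n_vertices(g)
}

#' Confidence score of a position assignment
#'
#' Combines the structural consistency `c` and recurrence `r` of the filtered
#' cluster as `k = c * log10(r)`. The logarithmic recurrence term is a
#' weighting factor for the consistency: it equals exactly 1 at `r = 10`
#' (where confidence is determined entirely by consistency), up-weights
#' abundant motifs (`r > 10`) and severely penalizes rare ones (`r < 10`).
#' A value of 0.8 or higher indicates a reliable local structure prediction;
#' 1.5 or higher a credible one (e.g. 75% consistency at 100 instances).
#'
#' @param c Consistency fraction in \[0, 1\]. Vectorized.
#' @param r Recurrence (non-negative integer). `r = 0` yields confidence 0
#'   (unassignable position). Vectorized.
#' @return Non-negative confidence score(s).
#' @export
#' @examples
#' confidence(0.75, 100)  # 1.5
#' confidence(1.0, 10)    # 1.0
confidence <- function(c, r) {
  stopifnot(is.numeric(c), is.numeric(r))
  if (any(c < 0 | c > 1, na.rm = TRUE)) {
    stop("confidence: consistency must lie in [0, 1]")
  }
  if (any(r < 0, na.rm = TRUE)) stop("confidence: recurrence must be >= 0")
  ifelse(r < 1, 0, c * log10(r))
}

#' Centroid (representative fragment) of a stable cluster
#'
#' The representative fragment is the vertex with the minimum average RMSD
#' to its adjacent vertices, `w(v) / degree(v)`. Because the number of edges
#' per vertex varies, only vertices connected to a significant number of
#' cluster elements are considered: degree at least
#' `ceiling(min_degree_fraction * (|V| - 1))` (and at least 1 — isolated
#' vertices are never eligible). Ties are broken toward the smaller incident
#' weight `w(v)`, then the lexicographically smallest id.
#'
#' @param g A stable, filtered [cluster_graph()].
#' @param min_degree_fraction Eligibility fraction (default 0.5).
#' @return The centroid [fragment()] (when the graph carries fragments) or
#'   its id, with attribute `"centroid_id"`; `NULL` when no vertex is
#'   eligible.
#' @export
centroid <- function(g, min_degree_fraction = 0.5) {
  stopifnot(inherits(g, "cluster_graph"))
  n <- n_vertices(g)
  if (n == 0L) return(NULL)
  min_deg <- max(1L, as.integer(ceiling(min_degree_fraction * (n - 1L))))
  elig <- which(g$degree >= min_deg)
  if (!length(elig)) return(NULL)
  avg_w <- g$incident_weight[elig] / g$degree[elig]
  tol <- 1e-12
  best <- elig[avg_w <= min(avg_w) + tol]
  if (length(best) > 1L) {
    wv <- g$incident_weight[best]
    best <- best[wv <= min(wv) + tol]
    if (length(best) > 1L) best <- best[order(g$ids[best])]
  }
  i <- best[[1L]]
  out <- if (!is.null(g$fragments)) g$fragments[[i]] else g$ids[[i]]
  attr(out, "centroid_id") <- g$ids[[i]]
  out
}
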