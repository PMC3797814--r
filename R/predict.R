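empty_assignment <- function(position) {
  data.frame(position = as.integer(position),
             status = "empty",
             recurrence = 0L,
             consistency = NA_real_,
             confidence = 0,
             reliable = FALSE,
             centroid_id = NA_character_,
             phi = NA_real_,
             psi = NA_real_,
             stringsAsFactors = FALSE)
}

#' Predict the local structure of one target position
#'
#' Runs the full per-position pipeline: build the cluster of covering
#' fragments ([build_cluster()]), filter it by greedy outlier rejection
#' ([shrink_cluster()]) and — if the cluster reaches stability — compute
#' recurrence, consistency, the confidence score and the centroid fragment,
#' whose (phi, psi) torsion pair at this position becomes the prediction.
#' Diverging and empty clusters yield an unassigned position (confidence 0,
#' no centroid): a low-precision region.
#'
#' @param library List of valid [fragment()] objects.
#' @param position 1-based target residue index.
#' @param config A [frag_config()].
#' @param rmsd_matrix Optional precomputed [pairwise_rmsd()] matrix.
#' @return One-row data.frame with columns `position`, `status`,
#'   `recurrence`, `consistency`, `confidence`, `reliable`, `centroid_id`,
#'   `phi`, `psi`. For a stable cluster `recurrence`/`consistency` describe
#'   the filtered cluster; for a diverging cluster `recurrence` counts the
#'   survivors at termination and confidence is 0.
#' @export
predict_position <- function(library, position, config = frag_config(),
                             rmsd_matrix = NULL) {
  stopifnot(inherits(config, "frag_config"))
  g <- build_cluster(library, position, overlap_min = config$overlap_min,
                     rmsd_matrix = rmsd_matrix)
  res <- shrink_cluster(g, threshold = config$threshold)
  out <- empty_assignment(position)
  out$status <- res$status
  out$recurrence <- n_vertices(res$graph)
  if (res$status != "stable") return(out)
  r <- recurrence(res$graph)
  c_val <- consistency(res$graph, threshold = config$threshold)
  out$consistency <- c_val
  out$confidence <- confidence(c_val, r)
  cen <- centroid(res$graph,
                  min_degree_fraction = config$min_degree_fraction)
  if (is.null(cen)) return(out)
  out$centroid_id <- attr(cen, "centroid_id")
  offset <- position - cen$query_start + 1L
  out$phi <- cen$torsions[offset, "phi"]
  out$psi <- cen$torsions[offset, "psi"]
  out$reliable <- out$confidence >= config$reliable_cutoff
  out
}

#' Predict local structure along a whole target sequence
#'
#' Applies [predict_position()] to every residue `1..target_length`,
#' computing the pairwise fragment RMSD matrix once and reusing it across
#' positions. Positions whose confidence reaches the reliable cutoff
#' (default 0.8) and that carry a centroid prediction are flagged reliable.
#'
#' @param library List of valid [fragment()] objects.
#' @param target_length Number of residues in the target sequence.
#' @param config A [frag_config()].
#' @return A data.frame of class `frag_prediction`, one row per residue,
#'   with the columns of [predict_position()].
#' @export
#' @examples
#' sc <- generate_scenario(scenario_spec(seed = 7))
#' pred <- predict_target(sc$library, sc$spec$target_length)
#' summary(pred)
predict_target <- function(library, target_length, config = frag_config()) {
  stopifnot(target_length >= 1)
  assert_library(library)
  m <- pairwise_rmsd(library, overlap_min = config$overlap_min)
  rows <- lapply(seq_len(target_length), function(i) {
    predict_position(library, i, config = config, rmsd_matrix = m)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("frag_prediction", "data.frame")
  out
}

#' @export
summary.frag_prediction <- function(object, ...) {
  st <- table(factor(object$status, levels = c("stable", "diverging",
                                               "empty")))
  cat(sprintf("confrag prediction over %d residues\n", nrow(object)))
  cat(sprintf("  stable: %d, diverging: %d, empty: %d\n",
              st[["stable"]], st[["diverging"]], st[["empty"]]))
  cat(sprintf("  assigned (phi,psi): %d; reliable (confidence >= %.2f): %d\n",
              sum(!is.na(object$phi)),
              attr(object, "config")$reliable_cutoff %||% 0.8,
              sum(object$reliable)))
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a confidence profile
#'
#' Confidence score along the target sequence, with the reliable cutoff
#' drawn as a horizontal line and unassigned positions marked at zero.
#'
#' @param x A `frag_prediction` from [predict_target()].
#' @param reliable_cutoff Cutoff line to draw (default from the prediction's
#'   configuration).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.frag_prediction <- function(x, reliable_cutoff = NULL, ...) {
  cut <- reliable_cutoff %||%
    (attr(x, "config")$reliable_cutoff %||% 0.8)
  plot(x$position, x$confidence, type = "h", lwd = 2,
       col = ifelse(x$reliable, "forestgreen", "grey50"),
       xlab = "target position", ylab = "confidence", ...)
  abline(h = cut, lty = 2, col = "firebrick")
  invisible(x)
}
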