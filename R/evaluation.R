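#' Wraparound absolute angular error
#'
#' Torsion angles live on a circle: the absolute difference between two
#' angles in (-180, 180] is taken modulo 360 so the error itself stays in
#' \[0, 180\] — `|d|` if `|d| <= 180`, else `360 - |d|`.
#'
#' @param predicted,experimental Angles in degrees in (-180, 180].
#'   Vectorized; `NA` propagates.
#' @return Absolute angular error(s) in degrees in \[0, 180\].
#' @export
#' @examples
#' angular_error(170, -170)  # 20
angular_error <- function(predicted, experimental) {
  bad <- function(x) any(!is.na(x) & (x <= -180 | x > 180))
  if (bad(predicted) || bad(experimental)) {
    stop("angular_error: angles must lie in (-180, 180]")
  }
  d <- abs(predicted - experimental)
  ifelse(d > 180, 360 - d, d)
}

# coerce native objects / data.frames to a reference torsion data.frame
as_reference <- function(reference) {
  if (is.list(reference) && !is.data.frame(reference) &&
      !is.null(reference$torsions)) {
    data.frame(position = seq_len(nrow(reference$torsions)),
               phi = reference$torsions[, "phi"],
               psi = reference$torsions[, "psi"])
  } else {
    stopifnot(is.data.frame(reference),
              all(c("position", "phi", "psi") %in% names(reference)))
    reference
  }
}

#' Mean absolute torsion angle error above a confidence cutoff
#'
#' Computes the MAE of predicted phi and psi against the experimental
#' reference over all residues whose confidence is at least `cutoff` and
#' where both the prediction and the reference angle are defined. Residues
#' with undefined native angles (chain termini, missing density) are
#' excluded from the denominators.
#'
#' @param predictions data.frame with columns `position`, `phi`, `psi`,
#'   `confidence` (e.g. a [predict_target()] result).
#' @param reference Native reference: data.frame with `position`, `phi`,
#'   `psi`, or a native structure object carrying `$torsions`.
#' @param cutoff Confidence cutoff (inclusive, `>=`; default 0).
#' @return List with `mae_phi`, `mae_psi` (degrees; `NA` when no residue
#'   qualifies), `n_phi`, `n_psi` (residue counts entering each mean) and
#'   `n` (residues passing the confidence cutoff with a defined prediction).
#' @export
evaluate_mae <- function(predictions, reference, cutoff = 0) {
  ref <- as_reference(reference)
  i <- match(predictions$position, ref$position)
  conf_ok <- !is.na(predictions$confidence) &
    predictions$confidence >= cutoff
  phi_ok <- conf_ok & !is.na(predictions$phi) & !is.na(ref$phi[i])
  psi_ok <- conf_ok & !is.na(predictions$psi) & !is.na(ref$psi[i])
  e_phi <- angular_error(predictions$phi[phi_ok], ref$phi[i][phi_ok])
  e_psi <- angular_error(predictions$psi[psi_ok], ref$psi[i][psi_ok])
  list(mae_phi = if (length(e_phi)) mean(e_phi) else NA_real_,
       mae_psi = if (length(e_psi)) mean(e_psi) else NA_real_,
       n_phi = length(e_phi),
       n_psi = length(e_psi),
       n = sum(conf_ok & (!is.na(predictions$phi) | !is.na(predictions$psi))))
}

#' MAE across several targets, pooled or averaged per protein
#'
#' @param predictions_list,reference_list Parallel lists of per-target
#'   predictions and references (see [evaluate_mae()]).
#' @param cutoff Confidence cutoff (inclusive).
#' @param aggregate `"pooled"` pools all qualifying residues across targets
#'   into one mean; `"per_protein"` averages the per-target MAEs (targets
#'   with no qualifying residue are dropped).
#' @return As [evaluate_mae()].
#' @export
evaluate_mae_multi <- function(predictions_list, reference_list, cutoff = 0,
                               aggregate = c("pooled", "per_protein")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(predictions_list) == length(reference_list))
  per <- Map(evaluate_mae, predictions_list, reference_list,
             MoreArgs = list(cutoff = cutoff))
  n_phi <- vapply(per, `[[`, numeric(1), "n_phi")
  n_psi <- vapply(per, `[[`, numeric(1), "n_psi")
  mphi <- vapply(per, `[[`, numeric(1), "mae_phi")
  mpsi <- vapply(per, `[[`, numeric(1), "mae_psi")
  agg <- function(m, n) {
    if (aggregate == "pooled") {
      if (sum(n) == 0L) NA_real_ else sum(m * n, na.rm = TRUE) / sum(n)
    } else {
      if (all(n == 0L)) NA_real_ else mean(m[n > 0])
    }
  }
  list(mae_phi = agg(mphi, n_phi), mae_psi = agg(mpsi, n_psi),
       n_phi = sum(n_phi), n_psi = sum(n_psi),
       n = sum(vapply(per, `[[`, numeric(1), "n")))
}

#' MAE at increasing confidence cutoffs
#'
#' One [evaluate_mae()] row per cutoff; residue counts are non-increasing
#' along an ascending cutoff sequence, and on libraries whose errors
#' anti-correlate with confidence the MAE decreases as low-confidence
#' regions are discarded.
#'
#' @inheritParams evaluate_mae
#' @param cutoffs Ascending numeric vector of confidence cutoffs.
#' @return data.frame with columns `cutoff`, `n_phi`, `n_psi`, `mae_phi`,
#'   `mae_psi`.
#' @export
cutoff_curve <- function(predictions, reference, cutoffs = seq(0, 1.5, 0.1)) {
  stopifnot(!is.unsorted(cutoffs))
  rows <- lapply(cutoffs, function(k) {
    r <- evaluate_mae(predictions, reference, cutoff = k)
    data.frame(cutoff = k, n_phi = r$n_phi, n_psi = r$n_psi,
               mae_phi = r$mae_phi, mae_psi = r$mae_psi)
  })
  do.call(rbind, rows)
}

# full-length native RMSD for every fragment; NA when native coordinates are
# missing inside the fragment's interval
fragment_native_rmsd <- function(library, native_ca) {
  vapply(library, function(f) {
    if (f$query_end > nrow(native_ca)) return(NA_real_)
    nat <- native_ca[f$query_start:f$query_end, , drop = FALSE]
    if (any(!is.finite(nat))) return(NA_real_)
    kabsch(f$ca_trace, nat)$rmsd
  }, numeric(1))
}

#' Local precision and coverage of a fragment library
#'
#' A fragment is a *compatible* (positive) hit when its Calpha-RMSD to the
#' native structure, computed by superposition over its entire query
#' interval, is below the threshold. Local precision at a residue is the
#' fraction of compatible fragments among all fragments covering it;
#' coverage is the fraction of target residues covered by at least one
#' compatible fragment. Fragments spanning residues with missing native
#' coordinates are skipped and counted in `n_skipped`.
#'
#' @param library List of valid [fragment()] objects.
#' @param native_ca Numeric target-length x 3 matrix of native Calpha
#'   coordinates (rows may contain `NA` for missing residues).
#' @param threshold Compatibility threshold in Angstrom (strict `<`;
#'   default 1.5).
#' @return List with `precision` (per-residue fraction, `NA` where no
#'   fragment covers), `coverage` (scalar fraction), `compatible` (logical
#'   per fragment, `NA` = skipped) and `n_skipped`.
#' @export
local_precision_coverage <- function(library, native_ca, threshold = 1.5) {
  native_ca <- as.matrix(native_ca)
  L <- nrow(native_ca)
  rms <- fragment_native_rmsd(library, native_ca)
  compatible <- rms < threshold
  n_cover <- integer(L)
  n_compat <- integer(L)
  for (k in seq_along(library)) {
    if (is.na(compatible[k])) next
    span <- library[[k]]$query_start:library[[k]]$query_end
    span <- span[span >= 1 & span <= L]
    n_cover[span] <- n_cover[span] + 1L
    if (compatible[k]) n_compat[span] <- n_compat[span] + 1L
  }
  precision <- ifelse(n_cover > 0L, n_compat / n_cover, NA_real_)
  list(precision = precision,
       coverage = mean(n_compat > 0L),
       compatible = compatible,
       n_skipped = sum(is.na(compatible)))
}

#' Optimal-centroid baseline prediction
#'
#' Lower-bound oracle for centroid selection: at every covered position the
#' covering fragment with the smallest full-length native Calpha-RMSD is
#' picked and its torsion pair at that position reported. The MAE of this
#' baseline is the best any centroid-selection rule could achieve on the
#' same library.
#'
#' @inheritParams local_precision_coverage
#' @param target_length Number of target residues (default: rows of
#'   `native_ca`).
#' @return data.frame with columns `position`, `centroid_id`, `phi`, `psi`,
#'   `rmsd`, `confidence` (set to `Inf` so the baseline survives any
#'   cutoff); `NA` rows where no fragment covers the position.
#' @export
optimal_centroid_baseline <- function(library, native_ca,
                                      target_length = nrow(native_ca)) {
  native_ca <- as.matrix(native_ca)
  rms <- fragment_native_rmsd(library, native_ca)
  out <- data.frame(position = seq_len(target_length),
                    centroid_id = NA_character_,
                    phi = NA_real_, psi = NA_real_,
                    rmsd = NA_real_, confidence = Inf,
                    stringsAsFactors = FALSE)
  for (i in seq_len(target_length)) {
    cov <- which(vapply(library, fragment_covers, logical(1), position = i) &
                   !is.na(rms))
    if (!length(cov)) next
    best <- cov[which.min(rms[cov])]
    f <- library[[best]]
    off <- i - f$query_start + 1L
    out$centroid_id[i] <- f$id
    out$phi[i] <- f$torsions[off, "phi"]
    out$psi[i] <- f$torsions[off, "psi"]
    out$rmsd[i] <- rms[best]
  }
  out
}

#' Full evaluation report for a prediction
#'
#' Bundles the confidence-stratified MAE curve, the per-position error table
#' and (when the library and native trace are supplied) local precision and
#' coverage of the library.
#'
#' @inheritParams evaluate_mae
#' @param cutoffs Ascending confidence cutoffs for the MAE curve.
#' @param library Optional fragment library for precision/coverage.
#' @param native_ca Optional native Calpha trace (required with `library`).
#' @param threshold Compatibility threshold in Angstrom.
#' @return Object of class `evaluation_report`: list with `per_cutoff`,
#'   `per_position`, and optionally `precision`, `coverage`.
#' @export
evaluate_predictions <- function(predictions, reference,
                                 cutoffs = seq(0, 1.5, 0.1),
                                 library = NULL, native_ca = NULL,
                                 threshold = 1.5) {
  ref <- as_reference(reference)
  i <- match(predictions$position, ref$position)
  per_pos <- data.frame(
    position = predictions$position,
    confidence = predictions$confidence,
    phi_pred = predictions$phi, psi_pred = predictions$psi,
    phi_nat = ref$phi[i], psi_nat = ref$psi[i])
  ok_phi <- !is.na(per_pos$phi_pred) & !is.na(per_pos$phi_nat)
  ok_psi <- !is.na(per_pos$psi_pred) & !is.na(per_pos$psi_nat)
  per_pos$err_phi <- NA_real_
  per_pos$err_psi <- NA_real_
  per_pos$err_phi[ok_phi] <- angular_error(per_pos$phi_pred[ok_phi],
                                           per_pos$phi_nat[ok_phi])
  per_pos$err_psi[ok_psi] <- angular_error(per_pos$psi_pred[ok_psi],
                                           per_pos$psi_nat[ok_psi])
  out <- list(per_cutoff = cutoff_curve(predictions, ref, cutoffs),
              per_position = per_pos)
  if (!is.null(library) && !is.null(native_ca)) {
    pc <- local_precision_coverage(library, native_ca, threshold)
    out$per_position$precision <- pc$precision[per_pos$position]
    out$precision <- pc$precision
    out$coverage <- pc$coverage
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  r0 <- x$per_cutoff[1L, ]
  cat("confrag evaluation report\n")
  cat(sprintf("  MAE at cutoff %.2f: phi %.2f deg (n=%d), psi %.2f deg (n=%d)\n",
              r0$cutoff, r0$mae_phi, r0$n_phi, r0$mae_psi, r0$n_psi))
  if (!is.null(x$coverage)) {
    cat(sprintf("  library coverage: %.3f\n", x$coverage))
  }
  cat(sprintf("  cutoffs evaluated: %s\n",
              paste(format(x$per_cutoff$cutoff), collapse = ", ")))
  invisible(x)
}
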