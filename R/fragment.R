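#' Construct a fragment
#'
#' A fragment is one variable-length structural motif (6-21 residues)
#' detected for a window of the target sequence. It carries the 1-based
#' inclusive query interval it was matched to, one (phi, psi) torsion pair
#' per residue in degrees, and the Calpha backbone trace in Angstrom.
#'
#' @param id Opaque fragment identifier (unique within a library).
#' @param source_id Source structure + chain identifier (e.g. `"1abcA"`).
#' @param query_start,query_end 1-based inclusive residue interval on the
#'   target sequence.
#' @param torsions Numeric matrix (or data.frame) with one row per residue
#'   and columns phi, psi, in degrees. Angles are wrapped into (-180, 180]
#'   on ingest (`normalize = TRUE`); -180 becomes +180.
#' @param ca_trace Numeric matrix with one row per residue and columns
#'   x, y, z (Angstrom).
#' @param normalize Wrap torsion angles into (-180, 180]? Default `TRUE`.
#' @return An object of class `fragment`.
#' @seealso [validate_fragment()]
#' @export
#' @examples
#' f <- fragment("f1", "1abcA", 3, 10,
#'               cbind(phi = rep(-57, 8), psi = rep(-47, 8)),
#'               matrix(rnorm(24), ncol = 3))
#' fragment_length(f)
fragment <- function(id, source_id, query_start, query_end, torsions,
                     ca_trace, normalize = TRUE) {
  torsions <- as.matrix(torsions)
  storage.mode(torsions) <- "double"
  colnames(torsions) <- c("phi", "psi")
  ca_trace <- as.matrix(ca_trace)
  storage.mode(ca_trace) <- "double"
  colnames(ca_trace) <- c("x", "y", "z")
  if (normalize) torsions[] <- normalize_angle(torsions)
  structure(list(id = as.character(id),
                 source_id = as.character(source_id),
                 query_start = as.integer(query_start),
                 query_end = as.integer(query_end),
                 torsions = torsions,
                 ca_trace = ca_trace),
            class = "fragment")
}

#' Fragment length in residues
#'
#' @param f A [fragment()].
#' @return Integer number of residues spanned by the query interval.
#' @export
fragment_length <- function(f) f$query_end - f$query_start + 1L

#' Does a fragment cover a target position?
#'
#' @param f A [fragment()].
#' @param position 1-based target residue index.
#' @return Logical.
#' @export
fragment_covers <- function(f, position) {
  f$query_start <= position && position <= f$query_end
}

#' Validate a fragment against the library invariants
#'
#' Checks the structural invariants of the fragment model: the query interval,
#' torsion list and Calpha trace must all describe the same number of
#' residues; the length must lie in the admissible 6-21 residue range of
#' variable-length fragment detection; all torsion angles must be finite and
#' within (-180, 180]; all coordinates must be finite (missing Calpha atoms
#' invalidate a fragment rather than being imputed).
#'
#' @param f A [fragment()].
#' @return Character vector of violation descriptions; empty if the fragment
#'   is valid.
#' @export
#' @examples
#' f <- fragment("f1", "srcA", 1, 5, cbind(rep(0, 5), rep(0, 5)),
#'               matrix(0, 5, 3))
#' validate_fragment(f)  # too short
validate_fragment <- function(f) {
  v <- character()
  if (!inherits(f, "fragment")) return("not a fragment object")
  n <- f$query_end - f$query_start + 1L
  if (is.na(n) || n < 1L) {
    return(sprintf("query interval [%s, %s] is empty or undefined",
                   f$query_start, f$query_end))
  }
  if (nrow(f$torsions) != n) {
    v <- c(v, sprintf(
      "torsions: %d rows but query interval [%d, %d] spans %d residues",
      nrow(f$torsions), f$query_start, f$query_end, n))
  }
  if (nrow(f$ca_trace) != n) {
    v <- c(v, sprintf(
      "ca_trace: %d rows but query interval [%d, %d] spans %d residues",
      nrow(f$ca_trace), f$query_start, f$query_end, n))
  }
  if (nrow(f$torsions) != nrow(f$ca_trace)) {
    v <- c(v, sprintf("length mismatch: %d torsion pairs vs %d Calpha points",
                      nrow(f$torsions), nrow(f$ca_trace)))
  }
  if (n < 6L) v <- c(v, sprintf("length %d < 6", n))
  if (n > 21L) v <- c(v, sprintf("length %d > 21", n))
  ang <- f$torsions
  if (any(!is.finite(ang))) {
    v <- c(v, "torsions: non-finite angle values")
  } else if (any(ang <= -180 | ang > 180)) {
    v <- c(v, "torsions: angle outside (-180, 180]")
  }
  if (any(!is.finite(f$ca_trace))) {
    v <- c(v, "ca_trace: missing or non-finite Calpha coordinates")
  }
  v
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("fragment %s (source %s): query [%d, %d], %d residues\n",
              x$id, x$source_id, x$query_start, x$query_end,
              fragment_length(x)))
  invisible(x)
}

# stop() unless every fragment in a library is valid
assert_library <- function(library) {
  stopifnot(is.list(library))
  for (f in library) {
    v <- validate_fragment(f)
    if (length(v)) {
      stop(sprintf("invalid fragment '%s': %s",
                   if (is.list(f)) f$id else "?", paste(v, collapse = "; ")))
    }
  }
  invisible(library)
}
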