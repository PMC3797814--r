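cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Computes the proper rotation and translation that superpose `coords_a`
#' onto `coords_b` with minimal root-mean-square deviation, via singular
#' value decomposition of the covariance matrix with reflection correction,
#' so the returned rotation always has determinant +1.
#'
#' @param coords_a,coords_b Numeric matrices of matching dimension
#'   (n x 3, n >= 3): paired 3-D points in Angstrom.
#' @return An object of class `superposition`: a list with `rotation`
#'   (3 x 3 proper rotation matrix), `translation` (length-3 vector) and
#'   `rmsd` (Angstrom). A point `x` from `coords_a` maps to
#'   `rotation %*% x + translation`.
#' @export
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch(a, a)$rmsd  # 0
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (!is.numeric(a) || !is.numeric(b) || ncol(a) != 3L || ncol(b) != 3L) {
    stop("kabsch: inputs must be numeric n x 3 matrices")
  }
  if (nrow(a) != nrow(b)) stop("kabsch: point sets differ in length")
  if (nrow(a) < 3L) stop("kabsch: need at least 3 points")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("kabsch: non-finite coordinates")
  }
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  h <- crossprod(a0, b0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cb - rot %*% ca),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Pairwise Calpha-RMSD between two fragments
#'
#' Edge weight of the cluster graph. Residues are paired by target-sequence
#' index over the intersection of the two query intervals, and the minimal
#' RMSD over all rigid transforms is computed by [kabsch()] superposition of
#' the paired Calpha atoms. When the intervals overlap by fewer than
#' `overlap_min` residues the RMSD is not a meaningful divergence measure
#' and `NA` is returned (no edge).
#'
#' @param f1,f2 Valid [fragment()] objects.
#' @param overlap_min Minimum overlap in residues (default 6).
#' @return RMSD in Angstrom, or `NA_real_` when the overlap is too short.
#' @export
fragment_rmsd <- function(f1, f2, overlap_min = 6) {
  qs <- max(f1$query_start, f2$query_start)
  qe <- min(f1$query_end, f2$query_end)
  if (qe - qs + 1L < overlap_min) return(NA_real_)
  i1 <- (qs - f1$query_start + 1L):(qe - f1$query_start + 1L)
  i2 <- (qs - f2$query_start + 1L):(qe - f2$query_start + 1L)
  kabsch(f1$ca_trace[i1, , drop = FALSE],
         f2$ca_trace[i2, , drop = FALSE])$rmsd
}

#' Signed torsion (dihedral) angle of four points
#'
#' Standard IUPAC convention: 0 degrees for the cis (eclipsed) arrangement,
#' sign by the right-hand rule looking along p2 -> p3, result in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # trans: 180
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    stop("dihedral: undefined angle (collinear or coincident points)")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2 / nb2)
  normalize_angle(atan2(y, x) * 180 / pi)
}
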