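# idealized backbone geometry (Angstrom / degrees)
.bb <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            omega = 180)

# canonical region torsions
.region_torsions <- list(helix = c(phi = -57, psi = -47),
                         strand = c(phi = -120, psi = 120))

# NeRF atom placement: D such that |CD| = r, angle(B,C,D) = theta and
# dihedral(A,B,C,D) = chi (degrees)
place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# build an idealized N-CA-C backbone realizing the given per-residue
# (phi, psi) torsions; virtual C0 / N_{L+1} atoms make phi_1 and psi_L
# well defined. Returns a list of n/ca/c coordinate matrices.
build_backbone <- function(torsions) {
  L <- nrow(torsions)
  n_at <- matrix(NA_real_, L, 3)
  ca_at <- matrix(NA_real_, L, 3)
  c_at <- matrix(NA_real_, L, 3)
  c0 <- c(0, 0, 0)
  n_at[1, ] <- c(.bb$b_c_n, 0, 0)
  ang <- (180 - .bb$a_c_n_ca) * pi / 180
  ca_at[1, ] <- n_at[1, ] + .bb$b_n_ca * c(cos(ang), sin(ang), 0)
  prev_c <- c0
  for (i in seq_len(L)) {
    c_at[i, ] <- place_atom(prev_c, n_at[i, ], ca_at[i, ],
                            .bb$b_ca_c, .bb$a_n_ca_c, torsions[i, "phi"])
    nxt_n <- place_atom(n_at[i, ], ca_at[i, ], c_at[i, ],
                        .bb$b_c_n, .bb$a_ca_c_n, torsions[i, "psi"])
    if (i < L) {
      n_at[i + 1, ] <- nxt_n
      ca_at[i + 1, ] <- place_atom(ca_at[i, ], c_at[i, ], nxt_n,
                                   .bb$b_n_ca, .bb$a_c_n_ca, .bb$omega)
      prev_c <- c_at[i, ]
    }
  }
  list(n = n_at, ca = ca_at, c = c_at)
}

#' Specify a synthetic target scenario
#'
#' Describes a synthetic target protein as an alternating pattern of
#' conserved secondary-structure elements (helix, strand) connected by
#' highly variable coil linkers, together with the fragment library that a
#' remote-homology fragment detector would produce for it: each conserved
#' region is covered by a planted cluster of true fragments (excised from
#' the jittered native backbone) plus a tunable fraction of outliers excised
#' from decoy conformations; coil regions receive only outliers.
#'
#' @param regions data.frame with columns `kind` (`"helix"`, `"strand"` or
#'   `"coil"`) and `length` (residues). Default: helix 14 / coil 10 /
#'   strand 14.
#' @param recurrence Per-region fragment count: for conserved regions the
#'   number of planted true fragments, for coil regions the number of
#'   decoys. Default `c(25, 10, 25)`.
#' @param trace_noise_sd Gaussian jitter (Angstrom, per coordinate) applied
#'   to the Calpha trace of true fragments; default 0.5.
#' @param outlier_rate Fraction of each conserved region's fragments drawn
#'   from decoy conformations; default 0.2.
#' @param fragment_length_range Admissible fragment lengths; default
#'   `c(6, 21)`.
#' @param seed Integer seed; the whole scenario is deterministic given the
#'   spec.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(regions = data.frame(
                            kind = c("helix", "coil", "strand"),
                            length = c(14L, 10L, 14L)),
                          recurrence = c(25L, 10L, 25L),
                          trace_noise_sd = 0.5,
                          outlier_rate = 0.2,
                          fragment_length_range = c(6L, 21L),
                          seed = 1L) {
  stopifnot(is.data.frame(regions),
            all(c("kind", "length") %in% names(regions)),
            all(regions$kind %in% c("helix", "strand", "coil")),
            all(regions$length >= 1),
            length(recurrence) == nrow(regions),
            all(recurrence >= 0),
            outlier_rate >= 0, outlier_rate < 1,
            trace_noise_sd >= 0,
            fragment_length_range[1] >= 6,
            fragment_length_range[2] <= 21)
  structure(list(regions = regions,
                 recurrence = as.integer(recurrence),
                 trace_noise_sd = trace_noise_sd,
                 outlier_rate = outlier_rate,
                 fragment_length_range = as.integer(fragment_length_range),
                 seed = as.integer(seed),
                 target_length = as.integer(sum(regions$length))),
            class = "scenario_spec")
}

# region index bounds: list of c(start, end) per region
region_bounds <- function(spec) {
  ends <- cumsum(spec$regions$length)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(s, e) c(s, e), starts, ends)
}

# sample per-residue torsions for the spec's regions; coil torsions are
# drawn from a broad left-half Ramachandran band: phi ~ U(-180, -30),
# psi ~ U(-180, 180)
sample_torsions <- function(spec) {
  L <- spec$target_length
  tor <- matrix(NA_real_, L, 2, dimnames = list(NULL, c("phi", "psi")))
  for (j in seq_len(nrow(spec$regions))) {
    b <- region_bounds(spec)[[j]]
    idx <- b[1]:b[2]
    kind <- spec$regions$kind[j]
    if (kind == "coil") {
      tor[idx, "phi"] <- runif(length(idx), -180, -30)
      tor[idx, "psi"] <- runif(length(idx), -180, 180)
    } else {
      tor[idx, "phi"] <- .region_torsions[[kind]]["phi"]
      tor[idx, "psi"] <- .region_torsions[[kind]]["psi"]
    }
  }
  tor[] <- normalize_angle(tor)
  tor
}

#' Generate the native structure of a scenario
#'
#' Samples per-residue (phi, psi) torsions from the canonical values of each
#' region (helix -57/-47, strand -120/+120, coil from a broad distribution)
#' and reconstructs an idealized Cartesian backbone realizing them exactly,
#' so that recomputing dihedrals from the coordinates recovers the
#' generating torsions.
#'
#' @param spec A [scenario_spec()].
#' @return Object of class `native_structure`: list with `torsions`
#'   (L x 2), `ca` (L x 3), `backbone` (N/CA/C matrices), `regions` and
#'   `region_of` (per-residue region kind).
#' @export
generate_native <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  tor <- sample_torsions(spec)
  bb <- build_backbone(tor)
  region_of <- rep(spec$regions$kind, spec$regions$length)
  structure(list(torsions = tor, ca = bb$ca, backbone = bb,
                 regions = spec$regions, region_of = region_of),
            class = "native_structure")
}

# excise a fragment from a backbone's Calpha trace + torsion table
excise <- function(id, source_id, start, end, torsions, ca, noise_sd = 0) {
  span <- start:end
  tr <- ca[span, , drop = FALSE]
  if (noise_sd > 0) tr <- tr + rnorm(length(tr), sd = noise_sd)
  fragment(id, source_id, start, end,
           torsions[span, , drop = FALSE], tr)
}

# sample one element (safe for length-1 vectors)
resample1 <- function(x) x[sample.int(length(x), 1L)]

# random fragment interval inside region [a, b], constrained to cover the
# region's central residue so every planted fragment joins that position's
# cluster
sample_interval <- function(a, b, len_range) {
  reg_len <- b - a + 1L
  center <- (a + b) %/% 2L
  len <- resample1(seq(len_range[1], min(len_range[2], reg_len)))
  start <- resample1(max(a, center - len + 1L):min(center, b - len + 1L))
  c(start, start + len - 1L)
}

#' Generate the fragment library of a scenario
#'
#' For each conserved region, plants `recurrence[j]` true fragments excised
#' at random offsets and lengths from the native backbone, with Gaussian
#' jitter on the Calpha coordinates, plus outliers (fraction `outlier_rate`
#' of the region's fragments) excised from decoy backbones rebuilt from
#' independently permuted per-residue torsions — which puts their RMSD to
#' the native in a realistic several-Angstrom band. Coil regions receive
#' only decoys, emulating low-precision zones. Every fragment carries a
#' hidden `"planted"` attribute (`"true"` or `"outlier"`) for test
#' assertions only; the attribute never influences the pipeline and is not
#' serialized.
#'
#' @param spec A [scenario_spec()].
#' @param native The matching [generate_native()] result.
#' @return List of [fragment()] objects.
#' @export
generate_library <- function(spec, native) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(native, "native_structure"))
  set.seed(spec$seed + 1L)
  bounds <- region_bounds(spec)
  lib <- list()
  k <- 0L
  add <- function(f, label) {
    attr(f, "planted") <- label
    lib[[length(lib) + 1L]] <<- f
  }
  decoy_fragment <- function(a, b) {
    perm <- sample(spec$target_length)
    dec_tor <- native$torsions[perm, , drop = FALSE]
    dec_bb <- build_backbone(dec_tor)
    iv <- sample_interval(a, b, spec$fragment_length_range)
    k <<- k + 1L
    excise(sprintf("frag%04d", k), sprintf("d%03dX", k),
           iv[1], iv[2], dec_tor, dec_bb$ca)
  }
  for (j in seq_len(nrow(spec$regions))) {
    a <- bounds[[j]][1]
    b <- bounds[[j]][2]
    if (b - a + 1L < spec$fragment_length_range[1]) next
    kind <- spec$regions$kind[j]
    if (kind == "coil") {
      for (t in seq_len(spec$recurrence[j])) add(decoy_fragment(a, b),
                                                 "outlier")
      next
    }
    n_true <- spec$recurrence[j]
    for (t in seq_len(n_true)) {
      iv <- sample_interval(a, b, spec$fragment_length_range)
      k <- k + 1L
      add(excise(sprintf("frag%04d", k), sprintf("s%03dA", k),
                 iv[1], iv[2], native$torsions, native$ca,
                 noise_sd = spec$trace_noise_sd), "true")
    }
    n_out <- round(n_true * spec$outlier_rate / (1 - spec$outlier_rate))
    for (t in seq_len(n_out)) add(decoy_fragment(a, b), "outlier")
  }
  lib
}

#' Generate a complete scenario
#'
#' Convenience wrapper running [generate_native()] and [generate_library()].
#'
#' @param spec A [scenario_spec()].
#' @return List with `spec`, `native`, `library`.
#' @export
#' @examples
#' sc <- generate_scenario(scenario_spec(seed = 42))
#' length(sc$library)
generate_scenario <- function(spec) {
  native <- generate_native(spec)
  list(spec = spec, native = native, library = generate_library(spec, native))
}
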