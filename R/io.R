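#' @name library-format
#' @title Fragment library file dialect
#' @description
#' Libraries are stored one record per fragment, either as TSV or as a JSON
#' mirror of the same schema (chosen by file extension, `.tsv`/`.txt` vs
#' `.json`). TSV columns: `id`, `source_id`, `query_start`, `query_end`
#' (1-based inclusive target residue interval), `n_res` (record length,
#' for validation), `phi`, `psi` (per-residue torsion angles in degrees,
#' `;`-joined), `ca_x`, `ca_y`, `ca_z` (per-residue Calpha coordinates in
#' Angstrom, `;`-joined). Floats are printed with 6 decimals; writers are
#' deterministic (same library, byte-identical file). The JSON form is an
#' array of objects with the same field names, `phi`/`psi`/`ca_x`/`ca_y`/
#' `ca_z` as numeric arrays.
NULL

fmt6 <- function(x) sprintf("%.6f", x)

join6 <- function(x) paste(fmt6(x), collapse = ";")

parse_num_list <- function(s, what, line) {
  out <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
  if (length(out) == 0L || anyNA(out)) {
    stop(sprintf("parse error at line %d: malformed %s block", line, what))
  }
  out
}

lib_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
}

lib_columns <- c("id", "source_id", "query_start", "query_end", "n_res",
                 "phi", "psi", "ca_x", "ca_y", "ca_z")

#' Write a fragment library
#'
#' Serializes fragments in the documented library dialect (see
#' [library-format]); the format is chosen by the file extension (`.json`
#' for the JSON mirror, TSV otherwise). Output is deterministic.
#'
#' @param library List of [fragment()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fragment_library <- function(library, path) {
  recs <- lapply(library, function(f) {
    list(id = f$id, source_id = f$source_id,
         query_start = f$query_start, query_end = f$query_end,
         n_res = fragment_length(f),
         phi = round(unname(f$torsions[, "phi"]), 6),
         psi = round(unname(f$torsions[, "psi"]), 6),
         ca_x = round(unname(f$ca_trace[, "x"]), 6),
         ca_y = round(unname(f$ca_trace[, "y"]), 6),
         ca_z = round(unname(f$ca_trace[, "z"]), 6))
  })
  if (lib_format(path) == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
  } else {
    lines <- vapply(recs, function(r) {
      paste(r$id, r$source_id, r$query_start, r$query_end, r$n_res,
            join6(r$phi), join6(r$psi),
            join6(r$ca_x), join6(r$ca_y), join6(r$ca_z), sep = "\t")
    }, character(1))
    writeLines(c(paste(lib_columns, collapse = "\t"), lines), path)
  }
  invisible(path)
}

# apply strict/lenient invariant policy to a parsed fragment
ingest_fragment <- function(f, mode, where) {
  v <- validate_fragment(f)
  if (length(v)) {
    if (mode == "strict") {
      stop(sprintf("invalid fragment record '%s' (%s): %s",
                   f$id, where, paste(v, collapse = "; ")))
    }
    attr(f, "violations") <- v
    warning(sprintf("fragment '%s' (%s) kept with violations: %s",
                    f$id, where, paste(v, collapse = "; ")),
            call. = FALSE)
  }
  f
}

#' Read a fragment library
#'
#' Parses the documented library dialect (see [library-format]). In
#' `strict` mode any fragment violating the model invariants (length
#' outside 6-21 residues, array length mismatch, out-of-range angles)
#' aborts with an error naming the record; in `lenient` mode such fragments
#' are kept, flagged with a `"violations"` attribute, and reported as
#' warnings. Torsion angles are wrapped into (-180, 180] on ingest.
#'
#' @param path Library file (TSV or JSON).
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return List of [fragment()] objects.
#' @export
read_fragment_library <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  if (lib_format(path) == "json") {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    return(lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      need <- setdiff(lib_columns, "n_res")
      if (!all(need %in% names(r))) {
        stop(sprintf("parse error in record %d: missing fields", i))
      }
      if (!is.null(r$n_res) &&
          (length(r$phi) != r$n_res || length(r$ca_x) != r$n_res)) {
        stop(sprintf("parse error in record %d ('%s'): n_res mismatch",
                     i, r$id))
      }
      f <- fragment(r$id, r$source_id, r$query_start, r$query_end,
                    cbind(phi = as.numeric(r$phi), psi = as.numeric(r$psi)),
                    cbind(x = as.numeric(r$ca_x), y = as.numeric(r$ca_y),
                          z = as.numeric(r$ca_z)))
      ingest_fragment(f, mode, sprintf("record %d", i))
    }))
  }
  lines <- readLines(path)
  if (!length(lines)) stop("parse error: empty library file")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, lib_columns)) {
    stop("parse error at line 1: unexpected header")
  }
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(k) {
    ln <- k + 1L
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(lib_columns)) {
      stop(sprintf("parse error at line %d: %d fields, expected %d",
                   ln, length(fields), length(lib_columns)))
    }
    qs <- suppressWarnings(as.integer(fields[3]))
    qe <- suppressWarnings(as.integer(fields[4]))
    n_res <- suppressWarnings(as.integer(fields[5]))
    if (anyNA(c(qs, qe, n_res))) {
      stop(sprintf("parse error at line %d: non-integer interval", ln))
    }
    phi <- parse_num_list(fields[6], "phi", ln)
    psi <- parse_num_list(fields[7], "psi", ln)
    x <- parse_num_list(fields[8], "ca_x", ln)
    y <- parse_num_list(fields[9], "ca_y", ln)
    z <- parse_num_list(fields[10], "ca_z", ln)
    if (length(phi) != n_res || length(psi) != n_res ||
        length(x) != n_res || length(y) != n_res || length(z) != n_res) {
      stop(sprintf("parse error at line %d ('%s'): n_res mismatch",
                   ln, fields[1]))
    }
    f <- fragment(fields[1], fields[2], qs, qe,
                  cbind(phi = phi, psi = psi), cbind(x = x, y = y, z = z))
    ingest_fragment(f, mode, sprintf("line %d", ln))
  })
}

#' Write a native reference
#'
#' TSV with columns `position`, `phi`, `psi`, `ca_x`, `ca_y`, `ca_z`
#' (angles in degrees, coordinates in Angstrom, `NA` for undefined values,
#' floats with 6 decimals, deterministic output).
#'
#' @param native A `native_structure`/`native_reference` object (anything
#'   with `$torsions` and `$ca`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_native_reference <- function(native, path) {
  L <- nrow(native$ca)
  fmt_na <- function(x) ifelse(is.na(x), "NA", fmt6(x))
  lines <- vapply(seq_len(L), function(i) {
    paste(i,
          fmt_na(native$torsions[i, "phi"]), fmt_na(native$torsions[i, "psi"]),
          fmt_na(native$ca[i, 1]), fmt_na(native$ca[i, 2]),
          fmt_na(native$ca[i, 3]), sep = "\t")
  }, character(1))
  writeLines(c("position\tphi\tpsi\tca_x\tca_y\tca_z", lines), path)
  invisible(path)
}

# assemble a native_reference from per-residue N/CA/C coordinate matrices
backbone_to_reference <- function(n_at, ca_at, c_at, chain_ok) {
  L <- nrow(ca_at)
  tor <- matrix(NA_real_, L, 2, dimnames = list(NULL, c("phi", "psi")))
  has <- function(m, i) i >= 1 && i <= L && all(is.finite(m[i, ]))
  linked <- function(i) {
    # peptide bond C(i) - N(i+1) must exist and be of bonded length
    has(c_at, i) && has(n_at, i + 1) &&
      sqrt(sum((c_at[i, ] - n_at[i + 1, ])^2)) < 2.0
  }
  for (i in seq_len(L)) {
    if (has(n_at, i) && has(ca_at, i) && has(c_at, i)) {
      if (i > 1 && linked(i - 1)) {
        tor[i, "phi"] <- dihedral(c_at[i - 1, ], n_at[i, ], ca_at[i, ],
                                  c_at[i, ])
      }
      if (i < L && linked(i) && has(n_at, i + 1)) {
        tor[i, "psi"] <- dihedral(n_at[i, ], ca_at[i, ], c_at[i, ],
                                  n_at[i + 1, ])
      }
    }
  }
  structure(list(torsions = tor, ca = ca_at, chain = chain_ok),
            class = c("native_reference"))
}

#' Read a native reference (TSV or PDB)
#'
#' Reads either the package's reference TSV (see
#' [write_native_reference()]) or a PDB-format coordinate file. For PDB
#' input the backbone N/CA/C atoms of the selected chain are extracted
#' (via \pkg{bio3d}) and (phi, psi) torsions are computed with
#' [dihedral()]; residues with missing backbone atoms or flanking a chain
#' break get undefined angles. Residues are renumbered 1..L in chain order.
#'
#' @param path Input file; `.pdb`/`.ent` selects PDB parsing.
#' @param chain Chain identifier; required when the PDB file contains more
#'   than one chain.
#' @return Object of class `native_reference`: list with `torsions`
#'   (L x 2, degrees, `NA` where undefined) and `ca` (L x 3, `NA` rows for
#'   missing Calpha atoms).
#' @export
read_native_reference <- function(path, chain = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom[pdb$atom$type == "ATOM", ]
    chains <- unique(at$chain)
    if (is.null(chain)) {
      if (length(chains) > 1L) {
        stop(sprintf(
          "file contains chains %s: an explicit `chain` is required",
          paste(chains, collapse = ", ")))
      }
      chain <- chains[[1]]
    }
    at <- at[at$chain == chain, ]
    if (!nrow(at)) stop(sprintf("chain '%s' not found", chain))
    resno <- sort(unique(at$resno))
    L <- length(resno)
    grab <- function(elety) {
      m <- matrix(NA_real_, L, 3)
      sel <- at[at$elety == elety, ]
      i <- match(sel$resno, resno)
      first <- !duplicated(i)
      m[i[first], ] <- as.matrix(sel[first, c("x", "y", "z")])
      m
    }
    return(backbone_to_reference(grab("N"), grab("CA"), grab("C"), chain))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "phi", "psi", "ca_x", "ca_y", "ca_z")
  if (!all(need %in% names(df))) {
    stop("parse error: native reference TSV lacks required columns")
  }
  df <- df[order(df$position), ]
  structure(list(torsions = cbind(phi = as.numeric(df$phi),
                                  psi = as.numeric(df$psi)),
                 ca = cbind(x = as.numeric(df$ca_x),
                            y = as.numeric(df$ca_y),
                            z = as.numeric(df$ca_z))),
            class = "native_reference")
}

#' Write per-position assignments
#'
#' TSV with one row per target residue: `position`, `status`, `recurrence`,
#' `consistency`, `confidence`, `reliable`, `centroid_id`, `phi`, `psi`.
#' Floats carry 6 decimals, absent values the explicit sentinel `NA`;
#' output is deterministic.
#'
#' @param assignments A [predict_target()] result (or any data.frame with
#'   those columns).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(assignments, path) {
  cols <- c("position", "status", "recurrence", "consistency", "confidence",
            "reliable", "centroid_id", "phi", "psi")
  stopifnot(all(cols %in% names(assignments)))
  fmt_na <- function(x) ifelse(is.na(x), "NA", fmt6(x))
  chr_na <- function(x) ifelse(is.na(x), "NA", as.character(x))
  lines <- vapply(seq_len(nrow(assignments)), function(i) {
    a <- assignments[i, ]
    paste(a$position, a$status, a$recurrence, fmt_na(a$consistency),
          fmt_na(a$confidence), tolower(a$reliable), chr_na(a$centroid_id),
          fmt_na(a$phi), fmt_na(a$psi), sep = "\t")
  }, character(1))
  writeLines(c(paste(cols, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read per-position assignments written by [write_assignments()]
#'
#' @param path Assignments TSV.
#' @return data.frame with the [predict_position()] columns.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$position <- as.integer(df$position)
  df$recurrence <- as.integer(df$recurrence)
  df$reliable <- df$reliable == "true"
  df$centroid_id <- as.character(df$centroid_id)
  df
}

#' Write an evaluation report
#'
#' Emits the confidence-cutoff MAE curve (one row per cutoff: `cutoff`,
#' `n_phi`, `n_psi`, `mae_phi`, `mae_psi`) and the per-position table
#' (`position`, `confidence`, `phi_pred`, `psi_pred`, `phi_nat`, `psi_nat`,
#' `err_phi`, `err_psi` and, when available, `precision`) as TSV files.
#' Schema version 1; deterministic output.
#'
#' @param report An [evaluate_predictions()] result.
#' @param curve_path Output path for the per-cutoff table.
#' @param positions_path Optional output path for the per-position table.
#' @return Invisibly, `curve_path`.
#' @export
write_evaluation_report <- function(report, curve_path,
                                    positions_path = NULL) {
  write_tsv_num <- function(df, path) {
    fmt_cell <- function(x) {
      if (is.numeric(x)) ifelse(is.na(x), "NA", fmt6(x)) else
        ifelse(is.na(x), "NA", as.character(x))
    }
    cells <- vapply(df, fmt_cell, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- apply(cells, 1L, paste, collapse = "\t")
    writeLines(c(paste(names(df), collapse = "\t"), lines), path)
  }
  write_tsv_num(report$per_cutoff, curve_path)
  if (!is.null(positions_path)) {
    write_tsv_num(report$per_position, positions_path)
  }
  invisible(curve_path)
}
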