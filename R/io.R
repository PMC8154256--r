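# Readers and writers: cpptraj-style dihedral tables, CSV, JSON entropy
# tables, and B-factor projection onto PDB files.

parse_series_name <- function(nm) {
  # "phi:12", "phi_12", "phi 12" -> base "phi", residue 12
  m <- regmatches(nm, regexec("^(.*?)[:_ ]?([0-9]+)$", nm))[[1L]]
  if (length(m) == 3L && nzchar(m[2L]))
    list(dihedral = m[2L], residue_index = as.integer(m[3L]))
  else
    list(dihedral = nm, residue_index = NA_integer_)
}

#' Read a dihedral-angle time-series table
#'
#' Reads per-frame dihedral angles as written by trajectory-analysis tools.
#' The `"cpptraj"` dialect is a whitespace-delimited table whose first line
#' is a '#'-prefixed header naming the columns and whose first column is
#' the frame index; `"csv"` is comma-separated with a plain header. Angle
#' columns become series; residue indices are parsed from trailing digits
#' in names such as `"phi:12"` or `"phi_12"`. Angles are wrapped into
#' \[-180, 180) on ingestion.
#'
#' @param path File path.
#' @param dialect `"cpptraj"` or `"csv"`.
#' @return A long tibble of class `dihedral_tbl` with columns `frame`,
#'   `name` (full column name), `dihedral` (base name), `residue_index`,
#'   `residue_name` (NA; tables do not carry it), `angle`. The source path
#'   is kept in the `"source_path"` attribute.
#' @export
read_dihedral_table <- function(path, dialect = c("cpptraj", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))

  if (dialect == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(df) == 0L) abort(sprintf("'%s' has a header but no data rows.", path))
    header <- names(df)
    mat <- as.matrix(df)
    if (!is.numeric(mat)) {
      bad <- which(apply(mat, 2L, function(cc) any(is.na(suppressWarnings(as.numeric(cc))))))
      abort(sprintf("non-numeric cells in '%s' (column '%s').", path, header[bad[1L]]))
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) abort(sprintf("'%s' is empty.", path))
    if (!startsWith(trimws(lines[1L]), "#"))
      abort(sprintf("'%s': cpptraj tables start with a '#'-prefixed header line.", path))
    header <- strsplit(trimws(sub("^\\s*#\\s*", "", lines[1L])), "\\s+")[[1L]]
    body <- lines[-1L]
    if (length(body) == 0L) abort(sprintf("'%s' has a header but no data rows.", path))
    parts <- strsplit(trimws(body), "\\s+")
    nf <- lengths(parts)
    if (any(nf != length(header))) {
      bad <- which(nf != length(header))[1L]
      abort(sprintf("'%s': line %d has %d fields, header has %d.",
                    path, bad + 1L, nf[bad], length(header)))
    }
    num <- suppressWarnings(as.numeric(unlist(parts)))
    if (any(is.na(num))) {
      bad <- ceiling(which(is.na(num))[1L] / length(header))
      abort(sprintf("'%s': non-numeric cell at line %d.", path, bad + 1L))
    }
    mat <- matrix(num, ncol = length(header), byrow = TRUE)
  }

  frame <- as.integer(mat[, 1L])
  if (ncol(mat) < 2L) abort(sprintf("'%s' has no angle columns.", path))
  series_names <- header[-1L]

  out <- lapply(seq_along(series_names), function(j) {
    info <- parse_series_name(series_names[j])
    tibble(frame = frame,
           name = series_names[j],
           dihedral = info$dihedral,
           residue_index = info$residue_index,
           residue_name = NA_character_,
           angle = wrap_degrees(mat[, j + 1L]))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("dihedral_tbl", class(out))
  attr(out, "source_path") <- path
  out
}

#' Write residuewise entropies to CSV or JSON
#'
#' Deterministic column order: `residue_index`, `residue_name`, one column
#' per dihedral name, then `combined`. JSON values survive a round trip
#' through [jsonlite::fromJSON()] at full precision.
#'
#' @param results A [residuewise_entropy()] tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default: inferred from the file
#'   extension, falling back to csv).
#' @return `path`, invisibly.
#' @export
write_entropy_table <- function(results, path, format = NULL) {
  if (!is.data.frame(results)) abort("`results` must be a data frame.")
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  format <- match.arg(format, c("csv", "json"))
  lead <- intersect(c("residue_index", "residue_name"), names(results))
  rest <- setdiff(names(results), c(lead, "combined"))
  ordered <- results[, c(lead, rest,
                         intersect("combined", names(results)))]
  if (format == "csv") {
    readr::write_csv(ordered, path, progress = FALSE)
  } else {
    jsonlite::write_json(ordered, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Project residuewise entropies onto a PDB B-factor column
#'
#' Writes a copy of the PDB in which every ATOM/HETATM record's B-factor
#' field (columns 61-66, two decimals) is replaced by its residue's
#' combined entropy, clamped to \[0, 999.99\] (the field width). Residues
#' without a result get 0.00. All other records and columns are preserved
#' byte for byte.
#'
#' @param results A [residuewise_entropy()] tibble (needs `residue_index`
#'   and `combined`).
#' @param pdb_in Input PDB path.
#' @param pdb_out Output PDB path.
#' @return `pdb_out`, invisibly.
#' @export
project_to_bfactor <- function(results, pdb_in, pdb_out) {
  if (!is.data.frame(results) ||
      !all(c("residue_index", "combined") %in% names(results)))
    abort("`results` needs columns `residue_index` and `combined`.")
  if (!file.exists(pdb_in)) abort(sprintf("PDB '%s' does not exist.", pdb_in))

  lines <- readLines(pdb_in, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) abort(sprintf("'%s' contains no ATOM/HETATM records.", pdb_in))

  resseq <- rep(NA_integer_, length(lines))
  raw <- trimws(substr(lines[is_atom], 23L, 26L))
  parsed <- suppressWarnings(as.integer(raw))
  if (any(is.na(parsed))) {
    bad <- which(is_atom)[which(is.na(parsed))[1L]]
    abort(sprintf("malformed ATOM record at line %d of '%s' (residue number '%s').",
                  bad, pdb_in, raw[which(is.na(parsed))[1L]]))
  }
  resseq[is_atom] <- parsed

  if (!any(parsed %in% results$residue_index))
    abort("no residue numbers overlap between the PDB and the results.")

  lookup <- results$combined[match(parsed, results$residue_index)]
  lookup[is.na(lookup)] <- 0
  if (any(lookup > 999.99 | lookup < 0)) {
    warn("entropy values outside [0, 999.99] clamped to the B-factor field width.")
    lookup <- pmin(pmax(lookup, 0), 999.99)
  }

  atom_lines <- lines[is_atom]
  short <- nchar(atom_lines) < 66L
  atom_lines[short] <- formatC(atom_lines[short], width = 66L, flag = "-")
  substr(atom_lines, 61L, 66L) <- sprintf("%6.2f", lookup)
  lines[is_atom] <- atom_lines

  writeLines(lines, pdb_out)
  invisible(pdb_out)
}
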