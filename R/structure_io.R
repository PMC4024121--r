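# PDB parsing is delegated to bio3d; the selection rules applied on top
# (first model, first-listed altLoc, first chain carrying the marker atom,
# HETATM dropped) are implemented here.

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

new_calpha_trace <- function(structure_id, chain_id, residues) {
  stopifnot(is.data.frame(residues), nrow(residues) >= 1L)
  structure(list(structure_id = structure_id,
                 chain_id = chain_id,
                 residues = residues),
            class = "calpha_trace")
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts one coordinate per residue from the ATOM records of a PDB file.
#' Selection rules: only the first model is read (records after the first
#' `ENDMDL` are discarded); for residues with alternate locations only the
#' first-listed altLoc is kept; when `chain` is not given, the first chain in
#' file order that contains the marker atom is used; HETATM records are
#' ignored.
#'
#' @param pdb Path to a PDB file, or PDB content given directly as a single
#'   string (with embedded newlines) or a character vector of lines.
#' @param chain Single chain identifier.  `NULL` (default) selects the first
#'   chain containing the marker atom.
#' @param structure_id Label stored on the trace; defaults to the file base
#'   name (or `"structure"` for literal text input).
#' @param atom_name Backbone atom used as the residue position.  `"CA"`
#'   (default) is standard; any backbone atom (e.g. `"N"`, `"C"`, `"O"`)
#'   serves equally well as a residue marker.
#' @return A `calpha_trace` object: a list with elements `structure_id`,
#'   `chain_id` and `residues`, the latter a data frame with columns
#'   `res_seq` (PDB residue number), `icode` (insertion code, `""` if none),
#'   `aa` (one-letter amino acid, `"X"` if not translatable) and `x`, `y`,
#'   `z` coordinates in Angstrom.
#' @seealso [trace_sequence()], [write_trace_pdb()]
#' @export
read_calpha_trace <- function(pdb, chain = NULL, structure_id = NULL,
                              atom_name = "CA") {
  if (is.character(pdb) && length(pdb) == 1L && !grepl("\n", pdb) &&
      file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(structure_id))
      structure_id <- sub("\\.(pdb|ent)$", "", basename(pdb),
                          ignore.case = TRUE)
  } else {
    lines <- if (length(pdb) > 1L) pdb else strsplit(pdb, "\n",
                                                     fixed = TRUE)[[1L]]
    if (is.null(structure_id)) structure_id <- "structure"
  }

  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]

  # validate coordinate columns of relevant ATOM records before handing off
  is_marker <- startsWith(lines, "ATOM") &
    trimws(substr(lines, 13L, 16L)) == atom_name
  for (ln in which(is_marker)) {
    for (cols in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
      fld <- trimws(substr(lines[ln], cols[1L], cols[2L]))
      if (is.na(suppressWarnings(as.numeric(fld))))
        stop("malformed ATOM coordinate columns on line ", ln, ": ",
             lines[ln], call. = FALSE)
    }
  }
  if (!any(is_marker))
    stop("no ", atom_name, " ATOM records found in input", call. = FALSE)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  at <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                        verbose = FALSE)$atom

  at <- at[at$type == "ATOM" & at$elety == atom_name, , drop = FALSE]
  at$chain[is.na(at$chain)] <- ""
  at$insert[is.na(at$insert)] <- ""

  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at))
    stop("empty chain: no ", atom_name, " atoms in chain '", chain, "'",
         call. = FALSE)

  # one coordinate per residue: first-listed altLoc wins
  key <- paste(at$resno, at$insert, sep = "\r")
  at <- at[!duplicated(key), , drop = FALSE]

  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | !aa %in% c(STANDARD_AA, "X")] <- "X"

  residues <- data.frame(res_seq = as.integer(at$resno),
                         icode = as.character(at$insert),
                         aa = aa,
                         x = at$x, y = at$y, z = at$z,
                         stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  new_calpha_trace(structure_id, chain, residues)
}

#' @export
print.calpha_trace <- function(x, ...) {
  r <- x$residues
  cat(sprintf("C-alpha trace '%s' chain '%s': %d residues (res_seq %d..%d)\n",
              x$structure_id, x$chain_id, nrow(r),
              r$res_seq[1L], r$res_seq[nrow(r)]))
  invisible(x)
}

#' One-letter sequence of a C-alpha trace
#'
#' @param trace A [read_calpha_trace()] object.
#' @return Single string; residues in stored (file) order, unknowns as `"X"`.
#' @export
trace_sequence <- function(trace) {
  stopifnot(inherits(trace, "calpha_trace"))
  paste(trace$residues$aa, collapse = "")
}

#' Coordinate matrix of a trace
#'
#' @param trace A `calpha_trace`.
#' @return Numeric matrix with one row per residue and columns x, y, z.
#' @export
trace_coords <- function(trace) {
  stopifnot(inherits(trace, "calpha_trace"))
  as.matrix(trace$residues[, c("x", "y", "z")])
}

#' Write a trace as minimal PDB ATOM records
#'
#' Emits one fixed-width ATOM record per residue (PDB v3.3 columns), so that
#' synthetic traces can be consumed by the same readers as real structures.
#'
#' @param trace A `calpha_trace`.
#' @param path Output file; when `NULL` the lines are returned invisibly
#'   instead of written.
#' @param atom_name Atom name to write (default `"CA"`).
#' @return Invisibly, the character vector of lines.
#' @export
write_trace_pdb <- function(trace, path = NULL, atom_name = "CA") {
  stopifnot(inherits(trace, "calpha_trace"))
  r <- trace$residues
  res3 <- suppressWarnings(bio3d::aa123(r$aa))
  res3[is.na(res3)] <- "UNK"
  icode <- ifelse(r$icode == "", " ", r$icode)
  an <- formatC(atom_name, width = -3)  # left-justified in cols 14-16
  lines <- sprintf("ATOM  %5d  %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
                   seq_len(nrow(r)), an, res3,
                   substr(trace$chain_id, 1L, 1L),
                   r$res_seq, icode, r$x, r$y, r$z)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
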