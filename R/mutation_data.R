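# Mutation tables emulate a COSMIC-style extract: one row per observed
# mutation per sample, with the somatic-status vocabulary used there.

MUTATION_COLUMNS <- c("sample_id", "protein_id", "position", "ref_aa",
                      "alt_aa", "mutation_class", "somatic_status")

#' Default somatic-status whitelist
#'
#' The two COSMIC status strings retained by default when filtering.
#' @export
default_somatic_status <- function() {
  c("Confirmed somatic variant",
    "Reported in another cancer sample as somatic")
}

#' Read a mutation table
#'
#' Reads a tab-delimited mutation table with (at least) the columns
#' `sample_id`, `protein_id`, `position`, `ref_aa`, `alt_aa`,
#' `mutation_class`, `somatic_status`.  Extra columns are ignored.
#'
#' @param tsv Path to a TSV file, or the content itself as a single string /
#'   character vector of lines.
#' @return Data frame of mutation records with integer `position`.
#' @export
read_mutation_table <- function(tsv) {
  if (is.character(tsv) && length(tsv) == 1L && !grepl("\n", tsv) &&
      file.exists(tsv)) {
    df <- utils::read.delim(tsv, stringsAsFactors = FALSE,
                            check.names = FALSE)
  } else {
    txt <- if (length(tsv) > 1L) paste(tsv, collapse = "\n") else tsv
    df <- utils::read.delim(text = txt, stringsAsFactors = FALSE,
                            check.names = FALSE)
  }
  missing_cols <- setdiff(MUTATION_COLUMNS, names(df))
  if (length(missing_cols))
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pos <- suppressWarnings(as.integer(as.character(df$position)))
  bad <- which(is.na(pos) |
                 as.character(pos) != trimws(as.character(df$position)))
  if (length(bad))
    stop("non-integer residue position '", df$position[bad[1L]],
         "' in row ", bad[1L], " (line ", bad[1L] + 1L, ")", call. = FALSE)
  df$position <- pos
  df[, MUTATION_COLUMNS, drop = FALSE]
}

#' Filter mutation records to somatic missense events
#'
#' Keeps missense records whose somatic status is in the whitelist and drops
#' exact duplicates of (sample, protein, position, ref, alt), so a mutation
#' reported twice for the same sample is counted once.
#'
#' @param records Data frame from [read_mutation_table()].
#' @param allowed_status Character vector of retained status strings
#'   (exact, case-sensitive match).
#' @return Filtered data frame (possibly empty).
#' @export
filter_mutations <- function(records,
                             allowed_status = default_somatic_status()) {
  keep <- records$mutation_class == "missense" &
    records$somatic_status %in% allowed_status
  out <- records[keep, , drop = FALSE]
  key <- do.call(paste, c(out[c("sample_id", "protein_id", "position",
                                "ref_aa", "alt_aa")], sep = "\r"))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_mutation_counts <- function(counts, n_total, n_samples) {
  structure(list(counts = counts, n_total = n_total, n_samples = n_samples),
            class = "mutation_counts")
}

#' Collapse mutation records into per-residue counts
#'
#' Pools mutations over samples: the count at a canonical position is the
#' number of retained records there, regardless of how they are distributed
#' across samples.
#'
#' @param records Filtered mutation records.
#' @param protein_id Restrict to this protein; default uses all records.
#' @return A `mutation_counts` object: `counts` is a named integer vector
#'   (names are canonical positions), `n_total` the total mutation count and
#'   `n_samples` the number of distinct contributing samples.
#' @export
collapse_counts <- function(records, protein_id = NULL) {
  if (!is.null(protein_id))
    records <- records[records$protein_id == protein_id, , drop = FALSE]
  if (!nrow(records))
    return(new_mutation_counts(integer(0), 0L, 0L))
  tab <- table(records$position)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  # order by numeric position
  counts <- counts[order(as.integer(names(counts)))]
  new_mutation_counts(counts, sum(counts),
                      length(unique(records$sample_id)))
}

#' @export
print.mutation_counts <- function(x, ...) {
  cat(sprintf("mutation counts: n = %d mutations on %d residues over %d samples\n",
              x$n_total, length(x$counts), x$n_samples))
  invisible(x)
}
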