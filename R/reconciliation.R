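# Numbering reconciliation: structure residues (PDB numbering, possibly with
# gaps and insertion codes) are mapped onto canonical 1..L positions either by
# global pairwise alignment of the ATOM-derived sequence against a canonical
# sequence, or by trusting the PDB numbering directly.

new_residue_map <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (is.unsorted(pairs$canonical_pos, strictly = TRUE))
    stop("canonical positions must be strictly increasing along the structure",
         call. = FALSE)
  structure(list(pairs = pairs, n_effective = nrow(pairs)),
            class = "residue_map")
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("residue map: %d residues mapped (canonical %d..%d)\n",
              x$n_effective, min(x$pairs$canonical_pos),
              max(x$pairs$canonical_pos)))
  invisible(x)
}

#' Map a structure sequence onto a canonical sequence by global alignment
#'
#' Performs a Needleman-Wunsch global alignment (via
#' [Biostrings::pairwiseAlignment()]) and converts each aligned non-gap
#' column into one (structure index, canonical position) pair.  Mismatch
#' columns are mapped only when both letters are standard amino acids; gap
#' columns are never mapped.
#'
#' @param structure_seq One-letter sequence of the residues with coordinates
#'   (see [trace_sequence()]).
#' @param canonical_seq One-letter canonical protein sequence.
#' @param match,mismatch,gap_open,gap_extend Alignment scores; defaults are a
#'   standard protein global-alignment parameterization (match 2, mismatch
#'   -1, gap opening -2, gap extension -0.5; penalties passed as positive
#'   numbers to Biostrings).
#' @param min_identity Minimum fraction of identical residues over aligned
#'   (both non-gap) columns; below it the alignment is rejected as
#'   unreliable.
#' @param trace Optional `calpha_trace` supplying `res_seq`/`icode` keys for
#'   the structure side.
#' @return A `residue_map`: `pairs` is a data frame with columns
#'   `structure_index`, `res_seq`, `icode`, `canonical_pos`; `n_effective`
#'   the number of mapped residues.
#' @export
align_canonical <- function(structure_seq, canonical_seq,
                            match = 2, mismatch = -1,
                            gap_open = 2, gap_extend = 0.5,
                            min_identity = 0.3, trace = NULL) {
  stopifnot(nchar(structure_seq) >= 1L, nchar(canonical_seq) >= 1L)
  alpha <- LETTERS
  submat <- matrix(mismatch, length(alpha), length(alpha),
                   dimnames = list(alpha, alpha))
  diag(submat) <- match
  pa <- Biostrings::pairwiseAlignment(structure_seq, canonical_seq,
                                      type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]

  non_gap <- ap != "-" & as_ != "-"
  ident <- sum(ap == as_ & non_gap) / max(1L, sum(non_gap))
  if (ident < min_identity)
    stop("unreliable alignment: ", sprintf("%.1f%%", 100 * ident),
         " identity over aligned columns (threshold ",
         sprintf("%.0f%%", 100 * min_identity), ")", call. = FALSE)

  spos <- cumsum(ap != "-")
  cpos <- cumsum(as_ != "-")
  keep <- non_gap & (ap == as_ | (ap %in% STANDARD_AA & as_ %in% STANDARD_AA))
  pairs <- data.frame(structure_index = spos[keep],
                      res_seq = NA_integer_,
                      icode = NA_character_,
                      canonical_pos = cpos[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(trace)) {
    pairs$res_seq <- trace$residues$res_seq[pairs$structure_index]
    pairs$icode <- trace$residues$icode[pairs$structure_index]
  }
  rownames(pairs) <- NULL
  new_residue_map(pairs)
}

#' Map a trace onto a canonical sequence
#'
#' Convenience wrapper: aligns [trace_sequence()] of `trace` against
#' `canonical_seq` and carries the trace's residue keys into the map.
#'
#' @inheritParams align_canonical
#' @param trace A `calpha_trace`.
#' @param ... Passed to [align_canonical()].
#' @export
map_trace_to_canonical <- function(trace, canonical_seq, ...) {
  align_canonical(trace_sequence(trace), canonical_seq, ..., trace = trace)
}

#' Use PDB numbering directly as canonical positions
#'
#' Trusts the structure's residue numbering as the canonical numbering.
#' Refuses traces with non-positive residue numbers, insertion codes or
#' non-increasing numbering, which require [align_canonical()] instead.
#'
#' @param trace A `calpha_trace`.
#' @return A `residue_map`.
#' @export
direct_numbering_map <- function(trace) {
  stopifnot(inherits(trace, "calpha_trace"))
  r <- trace$residues
  if (any(r$res_seq <= 0L))
    stop("non-positive residue numbers present; use align_canonical()",
         call. = FALSE)
  if (any(r$icode != ""))
    stop("insertion codes present; use align_canonical()", call. = FALSE)
  if (is.unsorted(r$res_seq, strictly = TRUE))
    stop("residue numbering not strictly increasing; use align_canonical()",
         call. = FALSE)
  new_residue_map(data.frame(structure_index = seq_len(nrow(r)),
                             res_seq = r$res_seq,
                             icode = r$icode,
                             canonical_pos = r$res_seq,
                             stringsAsFactors = FALSE))
}

insufficient_mutations <- function(n_total) {
  stop(errorCondition(
    paste0("insufficient mutations after restriction to mapped residues (n = ",
           n_total, "); structure dropped"),
    n_total = n_total,
    class = c("tspclust_insufficient_mutations", "tspclust_error")))
}

#' Restrict mutation counts to residues with coordinates
#'
#' Drops counts at canonical positions not covered by the map and re-indexes
#' the survivors to 1..N in structure order, N being the number of mapped
#' residues.  The re-indexed scale is the coordinate system on which the
#' uniform null of the clustering test lives.
#'
#' @param counts A `mutation_counts` on canonical positions.
#' @param map A `residue_map`.
#' @return List with elements `counts` (re-indexed `mutation_counts`) and `N`
#'   (number of mapped residues).  Signals a condition of class
#'   `tspclust_insufficient_mutations` when at most one mutation survives.
#' @export
restrict_counts <- function(counts, map) {
  stopifnot(inherits(counts, "mutation_counts"), inherits(map, "residue_map"))
  cp <- map$pairs$canonical_pos
  pos <- as.integer(names(counts$counts))
  keep <- pos %in% cp
  new_idx <- match(pos[keep], cp)       # structure-order index 1..N
  kept <- counts$counts[keep]
  names(kept) <- new_idx
  kept <- kept[order(new_idx)]
  n_total <- sum(kept)
  if (n_total <= 1L) insufficient_mutations(n_total)
  list(counts = new_mutation_counts(kept, n_total, counts$n_samples),
       N = map$n_effective)
}
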