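# Central fitting-style interface: run the whole per-structure analysis
# (reconcile -> restrict -> linearize -> scan -> adjust -> unmap) and return
# one classed object.

#' Detect mutation clusters on a protein structure
#'
#' Runs the full structure-aware clustering analysis for one structure/chain:
#' reconciles structure and canonical numbering, restricts the mutation
#' counts to residues with coordinates, linearizes the residue graph with
#' each requested insertion heuristic, scans all order-statistic pairs with
#' the Beta test, applies the within-structure Bonferroni and structure-level
#' adjustments, and maps the clusters back to canonical residue numbers.
#'
#' @param trace A `calpha_trace` (see [read_calpha_trace()] or the fixture
#'   generators).
#' @param mutations Mutation records ([read_mutation_table()] layout), or a
#'   ready-made `mutation_counts` object on canonical positions.
#' @param canonical_seq Optional canonical sequence; when given, numbering is
#'   reconciled by global alignment, otherwise the PDB numbering is used
#'   directly.
#' @param protein_id Restrict mutation records to this protein.
#' @param methods Insertion heuristics to run (default all three).
#' @param alpha Nominal significance level.
#' @param span_convention See [pair_cluster_pvalue()].
#' @param structure_multiplier Structure-level p* factor
#'   (see [structure_level_adjust()]).
#' @param allowed_status Somatic-status whitelist for filtering.
#' @param include_identity Also scan the identity (sequence-order) path for
#'   comparison with the purely linear test.
#' @return A `mutclust` object: list with the cluster table (`clusters`),
#'   the per-method `paths` and Kendall tau `rearrangement`, the residue
#'   `map`, restricted `counts`, `n`, `N` and the call parameters.
#' @examples
#' tr <- make_contact_domains(60, list(c(8, 52, 6)), seed = 1)
#' mut <- plant_mutations(c(`8` = 3, `52` = 2), n_samples = 5)
#' fit <- mutation_clusters(tr, mut)
#' print(fit)
#' head(summary(fit))
#' @export
mutation_clusters <- function(trace, mutations, canonical_seq = NULL,
                              protein_id = NULL,
                              methods = c("cheapest", "nearest", "farthest"),
                              alpha = 0.05,
                              span_convention = c("inclusive", "exclusive"),
                              structure_multiplier = 1,
                              allowed_status = default_somatic_status(),
                              include_identity = FALSE) {
  span_convention <- match.arg(span_convention)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(trace, "calpha_trace"), length(methods) >= 1L,
            alpha > 0, alpha < 1)

  if (inherits(mutations, "mutation_counts")) {
    counts <- mutations
  } else {
    recs <- filter_mutations(mutations, allowed_status)
    if (is.null(protein_id) && length(unique(recs$protein_id)) == 1L)
      protein_id <- recs$protein_id[1L]
    counts <- collapse_counts(recs, protein_id)
  }

  map <- if (is.null(canonical_seq)) direct_numbering_map(trace)
         else map_trace_to_canonical(trace, canonical_seq)
  restr <- restrict_counts(counts, map)

  co <- trace_coords(trace)[map$pairs$structure_index, , drop = FALSE]
  D <- suppressWarnings(distance_matrix(co))

  run_methods <- c(methods, if (include_identity) "identity")
  paths <- list()
  tau <- integer(0)
  clusters <- NULL
  for (m in run_methods) {
    path <- if (m == "identity") identity_path(restr$N)
            else hamiltonian_path(D, m)
    os <- order_statistics(restr$counts, path)
    scan <- all_pairs_scan(os, span_convention)
    ends <- t(vapply(seq_len(nrow(scan)), function(r) {
      u <- unmap_cluster(scan[r, ], path, map, os)
      c(u$start_residue, u$end_residue)
    }, integer(2L)))
    scan$start_residue <- ends[, 1L]
    scan$end_residue <- ends[, 2L]
    scan$n_mut <- scan$k - scan$i + 1L
    scan$p_star <- structure_level_adjust(scan$p_bonf, structure_multiplier)
    scan <- cbind(structure_id = trace$structure_id, method = m, scan,
                  stringsAsFactors = FALSE)
    clusters <- rbind(clusters, scan)
    paths[[m]] <- path
    tau[m] <- kendall_tau_distance(path)
  }
  rownames(clusters) <- NULL

  structure(list(structure_id = trace$structure_id,
                 protein_id = protein_id,
                 chain_id = trace$chain_id,
                 clusters = clusters,
                 paths = paths,
                 rearrangement = tau,
                 map = map,
                 counts = restr$counts,
                 n = restr$counts$n_total,
                 N = restr$N,
                 methods = methods,
                 alpha = alpha,
                 span_convention = span_convention,
                 structure_multiplier = structure_multiplier),
            class = "mutclust")
}

#' @export
print.mutclust <- function(x, ...) {
  cat(sprintf("Mutation cluster scan of '%s' (chain %s)\n", x$structure_id,
              x$chain_id))
  cat(sprintf("  n = %d mutations on N = %d mapped residues; methods: %s\n",
              x$n, x$N, paste(x$methods, collapse = ", ")))
  sig <- x$clusters[x$clusters$p_bonf <= x$alpha, , drop = FALSE]
  cat(sprintf("  %d of %d pairwise tests significant at alpha = %g (Bonferroni)\n",
              nrow(sig), nrow(x$clusters), x$alpha))
  if (nrow(sig)) {
    b <- sig[which.min(sig$p_bonf), ]
    cat(sprintf("  best cluster: residues %d-%d (%s), p_bonf = %.3g\n",
                b$start_residue, b$end_residue, b$method, b$p_bonf))
  }
  invisible(x)
}

#' Summarize a mutation cluster scan
#'
#' @param object A `mutclust` object.
#' @param significant_only Keep only clusters with `p_bonf <= alpha`.
#' @param ... Unused.
#' @return The cluster table sorted by `p_bonf`, invisibly printed.
#' @export
summary.mutclust <- function(object, significant_only = FALSE, ...) {
  cl <- object$clusters
  if (significant_only)
    cl <- cl[cl$p_bonf <= object$alpha, , drop = FALSE]
  cl <- cl[order(cl$p_bonf, cl$method), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

#' Rearrangement diagnostic plot
#'
#' Plots path position against sequence position for one insertion method;
#' the identity diagonal corresponds to no rearrangement, and the Kendall
#' tau distance is shown in the title.
#'
#' @param x A `mutclust` object.
#' @param method Which stored path to plot (default the first).
#' @param ... Passed to [plot()].
#' @export
plot.mutclust <- function(x, method = NULL, ...) {
  if (is.null(method)) method <- names(x$paths)[1L]
  path <- x$paths[[method]]
  if (is.null(path)) stop("no stored path for method '", method, "'",
                          call. = FALSE)
  pos <- match(seq_len(path$n), path$sequence)
  plot(seq_len(path$n), pos, xlab = "sequence position (mapped residues)",
       ylab = "path position",
       main = sprintf("%s: %s insertion, Kendall tau = %d",
                      x$structure_id, method, x$rearrangement[[method]]),
       pch = 20, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
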