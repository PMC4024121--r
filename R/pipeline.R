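# Batch orchestration: run the per-structure scan over many structures,
# apply the across-structure significance machinery, and write tabular
# outputs.  Per-structure failures are logged, never fatal.

#' Run the clustering pipeline over a batch of structures
#'
#' For every configured structure x insertion method: parse the PDB,
#' reconcile numbering, restrict mutations, linearize, scan, adjust and
#' unmap.  Results are written as TSV tables; structures that fail (e.g.
#' fewer than two mapped mutations) are recorded in a dropped-structures
#' log with the reason.
#'
#' @param config A list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{structures}{list of entries with `pdb` (path), optional
#'       `chain`, optional `fasta` (canonical sequence for alignment-based
#'       numbering; omitted means direct PDB numbering), optional
#'       `protein_id`, optional `id`.}
#'     \item{mutations}{path to the mutation TSV.}
#'     \item{methods}{subset of cheapest/nearest/farthest (default all).}
#'     \item{alpha}{nominal level (default 0.05).}
#'     \item{span_convention}{inclusive (default) or exclusive.}
#'     \item{structure_multiplier}{explicit p* factor; default
#'       `max(1, s(s-1)/2)` with `s` the number of configured structures of
#'       the same protein.}
#'     \item{k_total}{total tests for the rFDR threshold; default
#'       `length(methods) * number of structures`.}
#'     \item{round_down}{floor the threshold to 3 decimals (default TRUE).}
#'     \item{allowed_status}{somatic-status whitelist.}
#'     \item{out_dir}{output directory (created if needed).}
#'   }
#' @return Invisibly, a list with the combined `clusters` table, the
#'   `diagnostics` (Kendall tau per structure x method), `dropped` log,
#'   `threshold` and `best_method` summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$structures),
            !is.null(config$mutations), !is.null(config$out_dir))
  methods <- config$methods %||% c("cheapest", "nearest", "farthest")
  alpha <- config$alpha %||% 0.05
  span <- config$span_convention %||% "inclusive"
  round_down <- config$round_down %||% TRUE
  allowed <- config$allowed_status %||% default_somatic_status()
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- read_mutation_table(config$mutations)

  entries <- config$structures
  prot_of <- vapply(entries, function(e) e$protein_id %||% NA_character_,
                    character(1L))
  n_struct <- length(entries)
  default_mult <- function(p) {
    s <- if (is.na(p)) n_struct else sum(prot_of == p, na.rm = TRUE)
    max(1, s * (s - 1) / 2)
  }
  k_total <- config$k_total %||% (length(methods) * n_struct)

  clusters <- NULL
  diagnostics <- NULL
  dropped <- NULL
  path_orders <- NULL
  for (e in entries) {
    sid <- e$id %||% sub("\\.(pdb|ent)$", "", basename(e$pdb),
                         ignore.case = TRUE)
    res <- tryCatch({
      trace <- read_calpha_trace(e$pdb, chain = e$chain,
                                 structure_id = sid)
      canonical <- if (!is.null(e$fasta)) read_fasta_sequence(e$fasta)
      mult <- config$structure_multiplier %||%
        default_mult(e$protein_id %||% NA_character_)
      mutation_clusters(trace, records, canonical_seq = canonical,
                        protein_id = e$protein_id, methods = methods,
                        alpha = alpha, span_convention = span,
                        structure_multiplier = mult,
                        allowed_status = allowed)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      dropped <- rbind(dropped,
                       data.frame(structure_id = sid,
                                  reason = conditionMessage(res),
                                  stringsAsFactors = FALSE))
      next
    }
    clusters <- rbind(clusters, res$clusters)
    diagnostics <- rbind(diagnostics,
                         data.frame(structure_id = sid,
                                    method = names(res$rearrangement),
                                    kendall_tau = unname(res$rearrangement),
                                    n_mutations = res$n,
                                    n_residues = res$N,
                                    stringsAsFactors = FALSE))
    for (m in names(res$paths)) {
      po <- path_order_table(res$paths[[m]])
      path_orders <- rbind(path_orders,
                           cbind(structure_id = sid, method = m, po,
                                 stringsAsFactors = FALSE))
    }
  }
  if (!is.null(path_orders))
    utils::write.table(path_orders, file.path(out_dir, "path_orders.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- NULL
  if (!is.null(clusters)) {
    sel <- significant_clusters(clusters, alpha = alpha, k_total = k_total,
                                round_down = round_down)
    sig <- sel
    utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sel$significant,
                       file.path(out_dir, "significant_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sel$best_method,
                       file.path(out_dir, "best_method.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(diagnostics))
    utils::write.table(diagnostics, file.path(out_dir, "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(dropped))
    dropped <- data.frame(structure_id = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  utils::write.table(dropped, file.path(out_dir, "dropped.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config_used.yaml"))

  invisible(list(clusters = clusters, diagnostics = diagnostics,
                 dropped = dropped,
                 threshold = if (!is.null(sig)) sig$threshold,
                 best_method = if (!is.null(sig)) sig$best_method))
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA file; only the first record is used.
#' @return Single sequence string.
#' @export
read_fasta_sequence <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path, call. = FALSE)
  as.character(ss[[1L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
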