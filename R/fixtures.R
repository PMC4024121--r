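# Synthetic fixtures: ideal-helix traces, multi-domain folds in which
# sequence-distant residues are spatial neighbors, planted mutation tables,
# and the close/far path-separation validation test.

helix_coords <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  # constants chosen to reproduce the canonical ~3.8 A Calpha-Calpha step
  i <- seq_len(n) - 1L
  th <- i * twist * pi / 180
  cbind(x = radius * cos(th), y = radius * sin(th), z = rise * i)
}

#' Ideal alpha-helix C-alpha trace
#'
#' Residues on an ideal helix (radius 2.3 A, rise 1.5 A per residue, 100
#' degrees per residue), numbered 1..n, all alanine.
#'
#' @param n_residues Number of residues (>= 2).
#' @param structure_id,chain Labels for the trace.
#' @return A `calpha_trace`.
#' @export
make_helix <- function(n_residues, structure_id = "helix", chain = "A") {
  stopifnot(n_residues >= 2L)
  xyz <- helix_coords(n_residues)
  new_calpha_trace(structure_id, chain,
                   data.frame(res_seq = seq_len(n_residues), icode = "",
                              aa = "A", x = xyz[, 1L], y = xyz[, 2L],
                              z = xyz[, 3L], stringsAsFactors = FALSE))
}

#' Multi-domain trace with prescribed spatial contacts
#'
#' Builds a fold in which requested residue pairs that are far apart in
#' sequence are spatial neighbors.  For each contact pair (a, b) the
#' intervening segment a+1..b-1 is excised onto its own helical axis placed
#' `region_gap` Angstrom away, while the remaining residues continue along
#' the main helix -- so residues a and b become consecutive on the main
#' helix (about 3.8 A apart) even though |b - a| is large in sequence.
#' Small seeded Gaussian jitter is added to every coordinate.
#'
#' @param n_residues Total residues.
#' @param contact_pairs Data frame (or coercible matrix/list of triples)
#'   with columns `res_a`, `res_b`, `target` giving the required maximum
#'   Euclidean distance (Angstrom) between the pair.  `NULL` gives a plain
#'   helix.
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @param region_gap Lateral offset between domain axes (Angstrom).
#' @param jitter_sd Standard deviation of the coordinate jitter (Angstrom).
#' @param structure_id,chain Labels.
#' @return A `calpha_trace`; errors if a contact cannot be satisfied.
#' @export
make_contact_domains <- function(n_residues, contact_pairs = NULL, seed = 1L,
                                 region_gap = 30, jitter_sd = 0.15,
                                 structure_id = NULL, chain = "A") {
  if (is.null(structure_id))
    structure_id <- sprintf("domains_s%d", seed)
  if (is.null(contact_pairs) ||
      (is.data.frame(contact_pairs) && !nrow(contact_pairs))) {
    tr <- make_helix(n_residues, structure_id, chain)
    return(tr)
  }
  if (is.list(contact_pairs) && !is.data.frame(contact_pairs))
    contact_pairs <- do.call(rbind, lapply(contact_pairs, function(p)
      data.frame(res_a = p[1L], res_b = p[2L], target = p[3L])))
  cp <- contact_pairs[order(contact_pairs$res_a), , drop = FALSE]
  stopifnot(all(cp$res_a >= 1L), all(cp$res_b <= n_residues),
            all(cp$res_b > cp$res_a), all(cp$target > 0))

  blocks <- lapply(seq_len(nrow(cp)), function(j) {
    a <- cp$res_a[j]; b <- cp$res_b[j]
    if (b - a < 2L) integer(0) else (a + 1L):(b - 1L)
  })
  if (anyDuplicated(unlist(blocks)))
    stop("unsatisfiable contacts: excised segments overlap", call. = FALSE)
  if (any(cp$target < 4.2))
    stop("unsatisfiable contacts: targets below the ~3.8 A backbone step",
         call. = FALSE)

  main <- setdiff(seq_len(n_residues), unlist(blocks))
  xyz <- matrix(NA_real_, n_residues, 3L)
  xyz[main, ] <- helix_coords(length(main))
  for (j in seq_along(blocks)) {
    blk <- blocks[[j]]
    if (!length(blk)) next
    loc <- helix_coords(length(blk))
    loc[, 1L] <- loc[, 1L] + region_gap * j   # own axis, offset in x
    xyz[blk, ] <- loc
  }

  set.seed(seed)
  xyz <- xyz + matrix(stats::rnorm(3L * n_residues, sd = jitter_sd),
                      n_residues, 3L)

  d_ab <- sqrt(rowSums((xyz[cp$res_a, , drop = FALSE] -
                          xyz[cp$res_b, , drop = FALSE])^2))
  if (any(d_ab > cp$target))
    stop("unsatisfiable contacts: achieved distance exceeds target",
         call. = FALSE)

  new_calpha_trace(structure_id, chain,
                   data.frame(res_seq = seq_len(n_residues), icode = "",
                              aa = "A", x = xyz[, 1L], y = xyz[, 2L],
                              z = xyz[, 3L], stringsAsFactors = FALSE))
}

#' Plant mutations at chosen residues
#'
#' Emits whitelisted somatic missense records realizing the requested
#' per-position counts, distributed round-robin across samples.
#'
#' @param positions_and_counts Named vector: names are canonical positions,
#'   values the number of mutations to plant there.
#' @param n_samples Number of samples to spread the records over.
#' @param protein_id Protein label for the records.
#' @return Data frame in the [read_mutation_table()] layout.
#' @export
plant_mutations <- function(positions_and_counts, n_samples = 1L,
                            protein_id = "PROT") {
  if (!length(positions_and_counts)) {
    out <- data.frame(sample_id = character(0), protein_id = character(0),
                      position = integer(0), ref_aa = character(0),
                      alt_aa = character(0), mutation_class = character(0),
                      somatic_status = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  stopifnot(all(positions_and_counts >= 1))
  pos <- rep(as.integer(names(positions_and_counts)),
             as.integer(positions_and_counts))
  data.frame(sample_id = paste0("S", rep_len(seq_len(n_samples),
                                             length(pos))),
             protein_id = protein_id,
             position = pos,
             ref_aa = "A",
             alt_aa = "V",
             mutation_class = "missense",
             somatic_status = default_somatic_status()[1L],
             stringsAsFactors = FALSE)
}

#' Close/far path-separation test
#'
#' Validates that a linearization keeps spatially close residues closer
#' along the path than spatially distant ones.  For each trace, residues are
#' sampled, all their pairs are classified as close (Euclidean distance
#' below `close_thr`) or far (above `far_thr`), and the mean path rank
#' separation of each class is recorded; the per-structure means are then
#' compared with a one-sided Welch t-test of far > close.
#'
#' @param traces List of `calpha_trace` objects (>= 2).
#' @param method Insertion method for the path.
#' @param close_thr,far_thr Distance thresholds in Angstrom
#'   (`close_thr < far_thr`; e.g. 5/25, 10/30, 15/35, 20/40).
#' @param n_residues Residues sampled per structure (without replacement).
#' @param seed Seed for the residue sampling.
#' @return A `close_far` list: `mean_close`, `mean_far`, `t_statistic`,
#'   `p_value`, thresholds, `n_structures` and the per-structure means.
#' @export
close_far_test <- function(traces, method = c("cheapest", "nearest",
                                              "farthest"),
                           close_thr = 5, far_thr = 25, n_residues = 40,
                           seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(traces) >= 2L)
  if (close_thr >= far_thr)
    stop("close_thr must be smaller than far_thr", call. = FALSE)
  set.seed(seed)
  cbar <- fbar <- numeric(0)
  ids <- character(0)
  for (tr in traces) {
    co <- trace_coords(tr)
    N <- nrow(co)
    D <- suppressWarnings(distance_matrix(co))
    path <- hamiltonian_path(D, method)
    pos <- match(seq_len(N), path$sequence)
    res <- sort(sample.int(N, min(n_residues, N)))
    pr <- utils::combn(res, 2L)
    dd <- D[cbind(pr[1L, ], pr[2L, ])]
    sep <- abs(pos[pr[1L, ]] - pos[pr[2L, ]])
    cl <- dd < close_thr
    fa <- dd > far_thr
    if (!any(cl) || !any(fa)) {
      warning("structure '", tr$structure_id,
              "' has no qualifying close or far pairs; skipped")
      next
    }
    cbar <- c(cbar, mean(sep[cl]))
    fbar <- c(fbar, mean(sep[fa]))
    ids <- c(ids, tr$structure_id)
  }
  if (length(cbar) < 2L)
    stop("fewer than two structures with qualifying pairs", call. = FALSE)
  tt <- stats::t.test(fbar, cbar, alternative = "greater",
                      var.equal = FALSE)
  structure(list(mean_close = mean(cbar), mean_far = mean(fbar),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 close_threshold = close_thr, far_threshold = far_thr,
                 method = method, n_structures = length(cbar),
                 per_structure = data.frame(structure_id = ids,
                                            mean_close = cbar,
                                            mean_far = fbar)),
            class = "close_far")
}

#' @export
print.close_far <- function(x, ...) {
  cat(sprintf(paste0("close/far path separation (%s, <%g A vs >%g A, %d ",
                     "structures):\n  mean close = %.2f, mean far = %.2f, ",
                     "t = %.2f, one-sided p = %.3g\n"),
              x$method, x$close_threshold, x$far_threshold, x$n_structures,
              x$mean_close, x$mean_far, x$t_statistic, x$p_value))
  invisible(x)
}
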