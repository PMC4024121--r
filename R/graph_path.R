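# Linearization of the residue graph.  The protein is a complete Euclidean
# graph on its residues; a Hamiltonian path approximating the shortest walk
# through the folded structure is built with classical TSP insertion
# heuristics via the zero-distance dummy-vertex reduction.  Exhaustive
# enumerators for small instances serve as independent oracles.

#' Pairwise Euclidean distance matrix of residue coordinates
#'
#' @param coords Numeric matrix, one row per residue, columns x/y/z (any
#'   dimension >= 1 is accepted).
#' @return Symmetric matrix of distances in the units of `coords`.
#' @export
distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least two points", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  if (any(d[upper.tri(d)] == 0))
    warning("duplicate coordinates: zero off-diagonal distances present")
  d
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square", call. = FALSE)
  if (any(D < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-9))
    stop("distance matrix is not symmetric", call. = FALSE)
  invisible(D)
}

tour_length <- function(D, order) {
  nxt <- c(order[-1L], order[1L])
  sum(D[cbind(order, nxt)])
}

path_length <- function(D, sequence) {
  if (length(sequence) < 2L) return(0)
  sum(D[cbind(sequence[-length(sequence)], sequence[-1L])])
}

# extreme real (non-dummy) edge; ties: smallest i, then smallest j
extreme_edge <- function(D, real, what = c("min", "max")) {
  what <- match.arg(what)
  E <- D[real, real, drop = FALSE]
  diag(E) <- if (what == "min") Inf else -Inf
  m <- if (what == "min") min(E) else max(E)
  idx <- which(E == m, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  real[c(idx[1L, 1L], idx[1L, 2L])]
}

new_path_order <- function(sequence, method) {
  structure(list(sequence = as.integer(sequence),
                 method = method,
                 n = length(sequence)),
            class = "path_order")
}

#' @export
print.path_order <- function(x, ...) {
  cat(sprintf("Hamiltonian path (%s) over %d residues\n", x$method, x$n))
  invisible(x)
}

#' Construct a TSP tour by an insertion heuristic
#'
#' Grows a cyclic tour by repeatedly inserting one vertex at the position of
#' minimal tour-length increase.  The vertex inserted next is chosen by the
#' rule: *cheapest* -- the (vertex, edge) pair with the smallest length
#' increase; *nearest* -- the unvisited vertex closest to the tour;
#' *farthest* -- the unvisited vertex whose distance to the tour is largest.
#' Cheapest and nearest start from the globally shortest edge, farthest from
#' the globally longest.  Ties are broken toward the lowest vertex index and
#' then the earliest insertion position, making the construction
#' deterministic.
#'
#' @param D Symmetric nonnegative distance matrix.
#' @param method One of `"cheapest"`, `"nearest"`, `"farthest"`.
#' @param dummy Internal: index of a zero-distance dummy vertex used by the
#'   Hamiltonian-path reduction.  The dummy is inserted right after tour
#'   initialization and excluded from the vertex-selection distances (it is
#'   at distance zero from everything, which would otherwise degenerate the
#'   nearest/farthest selection rules).
#' @return A `tsp_tour`: list with `order` (cyclic vertex sequence),
#'   `length` (total tour length) and `method`.
#' @export
insertion_tour <- function(D, method = c("cheapest", "nearest", "farthest"),
                           dummy = NULL) {
  method <- match.arg(method)
  check_distance_matrix(D)
  N <- nrow(D)
  canonical <- function(ord) {
    i1 <- match(1L, ord)
    ord <- ord[c(i1:length(ord), seq_len(i1 - 1L))]
    if (length(ord) > 2L && ord[2L] > ord[length(ord)])
      ord <- c(ord[1L], rev(ord[-1L]))
    ord
  }
  if (N == 1L)
    return(structure(list(order = 1L, length = 0, method = method),
                     class = "tsp_tour"))
  if (N == 2L)
    return(structure(list(order = 1:2, length = 2 * D[1L, 2L],
                          method = method), class = "tsp_tour"))

  real <- setdiff(seq_len(N), dummy)
  tour <- extreme_edge(D, real,
                       what = if (method == "farthest") "max" else "min")
  unvisited <- sort(setdiff(real, tour))

  insert_at <- function(tour, k) {
    a <- tour
    b <- tour[c(seq_along(tour)[-1L], 1L)]
    inc <- D[k, a] + D[k, b] - D[cbind(a, b)]
    pos <- which.min(inc)                       # earliest position on ties
    append(tour, k, after = pos)
  }

  if (!is.null(dummy)) tour <- insert_at(tour, dummy)

  while (length(unvisited)) {
    if (method == "cheapest") {
      a <- tour
      b <- tour[c(seq_along(tour)[-1L], 1L)]
      el <- D[cbind(a, b)]
      inc <- D[unvisited, a, drop = FALSE] + D[unvisited, b, drop = FALSE] -
        matrix(el, nrow = length(unvisited), ncol = length(a), byrow = TRUE)
      m <- min(inc)
      idx <- which(inc == m, arr.ind = TRUE)
      idx <- idx[order(unvisited[idx[, 1L]], idx[, 2L]), , drop = FALSE]
      k <- unvisited[idx[1L, 1L]]
      tour <- append(tour, k, after = idx[1L, 2L])
    } else {
      sel <- setdiff(tour, dummy)
      dmin <- apply(D[unvisited, sel, drop = FALSE], 1L, min)
      k <- if (method == "nearest") unvisited[which.min(dmin)]
           else unvisited[which.max(dmin)]     # unvisited sorted: lowest wins
      tour <- insert_at(tour, k)
    }
    unvisited <- setdiff(unvisited, k)
  }

  ord <- canonical(tour)
  structure(list(order = ord, length = tour_length(D, ord), method = method),
            class = "tsp_tour")
}

#' @export
print.tsp_tour <- function(x, ...) {
  cat(sprintf("TSP tour (%s): %d vertices, length %.3f\n",
              x$method, length(x$order), x$length))
  invisible(x)
}

#' Hamiltonian path through the residue graph
#'
#' Reduces the shortest-Hamiltonian-path problem to a TSP by augmenting the
#' distance matrix with a dummy vertex at distance zero to every residue,
#' running [insertion_tour()] on the augmented instance, and cutting the
#' cycle at the dummy.  The path is canonically oriented with the endpoint
#' of smaller structure index first.
#'
#' @inheritParams insertion_tour
#' @return A `path_order`: list with `sequence` (the residue at each path
#'   position), `method` and `n`.
#' @export
hamiltonian_path <- function(D, method = c("cheapest", "nearest",
                                           "farthest")) {
  method <- match.arg(method)
  check_distance_matrix(D)
  N <- nrow(D)
  if (N < 2L) stop("need at least two residues", call. = FALSE)
  if (N == 2L) return(new_path_order(1:2, method))
  Daug <- rbind(cbind(D, 0), 0)
  tour <- insertion_tour(Daug, method, dummy = N + 1L)
  ord <- tour$order
  pos <- match(N + 1L, ord)
  seqn <- ord[c(seq_len(length(ord))[-seq_len(pos)], seq_len(pos - 1L))]
  if (seqn[1L] > seqn[length(seqn)]) seqn <- rev(seqn)
  new_path_order(seqn, method)
}

#' Identity (sequence-order) path
#'
#' The linear ordering used by the purely sequence-based clustering test:
#' residues in chain order.
#'
#' @param n Number of residues.
#' @export
identity_path <- function(n) new_path_order(seq_len(n), "identity")

# all permutations of 1..n as an n! x n integer matrix (iterative insertion)
all_permutations <- function(n) {
  P <- matrix(1L, 1L, 1L)
  if (n == 1L) return(P)
  for (k in 2:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- ((pos - 1L) * m + 1L):(pos * m)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L),
                                                      drop = FALSE]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1L):k] <- P[, pos:(k - 1L), drop = FALSE]
    }
    P <- out
  }
  P
}

#' Exact shortest Hamiltonian path by exhaustive enumeration
#'
#' Enumerates all N!/2 orientation-deduplicated vertex sequences and returns
#' the shortest.  Intended as a small-instance oracle; refuses N > 10.
#'
#' @param D Symmetric nonnegative distance matrix, N <= 10.
#' @return A `path_order` with method `"brute_force"`.
#' @export
brute_force_shortest_path <- function(D) {
  check_distance_matrix(D)
  N <- nrow(D)
  if (N > 10L) stop("brute-force enumeration refused for N > 10",
                    call. = FALSE)
  if (N < 2L) stop("need at least two residues", call. = FALSE)
  P <- all_permutations(N)
  P <- P[P[, 1L] < P[, N], , drop = FALSE]    # halve by orientation
  len <- numeric(nrow(P))
  for (j in seq_len(N - 1L))
    len <- len + D[cbind(P[, j], P[, j + 1L])]
  new_path_order(P[which.min(len), ], "brute_force")
}

#' Exact shortest TSP tour by exhaustive enumeration
#'
#' Fixes vertex 1 first and enumerates the (N-1)!/2 distinct cyclic orders.
#'
#' @param D Symmetric nonnegative distance matrix, N <= 10.
#' @return A `tsp_tour` with method `"brute_force"`.
#' @export
brute_force_shortest_tour <- function(D) {
  check_distance_matrix(D)
  N <- nrow(D)
  if (N > 10L) stop("brute-force enumeration refused for N > 10",
                    call. = FALSE)
  if (N < 3L) {
    ord <- seq_len(N)
    return(structure(list(order = ord, length = tour_length(D, ord),
                          method = "brute_force"), class = "tsp_tour"))
  }
  P <- all_permutations(N - 1L) + 1L
  P <- P[P[, 1L] < P[, N - 1L], , drop = FALSE]  # direction dedup
  P <- cbind(1L, P)
  len <- numeric(nrow(P))
  for (j in seq_len(N))
    len <- len + D[cbind(P[, j], P[, (j %% N) + 1L])]
  best <- which.min(len)
  structure(list(order = P[best, ], length = len[best],
                 method = "brute_force"), class = "tsp_tour")
}

#' Kendall tau distance of a path from sequence order
#'
#' Number of discordant residue pairs between the path ordering and the
#' identity ordering 1..N, i.e. the bubble-sort swap count needed to restore
#' chain order.  Measures how much the linearization rearranged the protein.
#'
#' @param path A `path_order`.
#' @return Nonnegative integer.
#' @export
kendall_tau_distance <- function(path) {
  s <- path$sequence
  n <- length(s)
  if (n < 2L) return(0L)
  sum(vapply(seq_len(n - 1L),
             function(i) sum(s[i] > s[(i + 1L):n]), integer(1L)))
}

#' Rank separation of two residues along a path
#'
#' @param path A `path_order`.
#' @param i,j Residue indices (structure order).
#' @return `|position(i) - position(j)|` along the path.
#' @export
path_separation <- function(path, i, j) {
  pi_ <- match(i, path$sequence)
  pj <- match(j, path$sequence)
  if (anyNA(c(pi_, pj)))
    stop("residue not on path: ", paste(c(i, j)[is.na(c(pi_, pj))],
                                        collapse = ", "), call. = FALSE)
  abs(pi_ - pj)
}

#' Export a path order as a two-column table
#'
#' @param path A `path_order`.
#' @param file Optional TSV destination.
#' @return Data frame with columns `residue` (structure index) and
#'   `path_position`.
#' @export
path_order_table <- function(path, file = NULL) {
  df <- data.frame(residue = path$sequence,
                   path_position = seq_along(path$sequence))
  df <- df[order(df$residue), ]
  rownames(df) <- NULL
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
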