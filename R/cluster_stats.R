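# Order-statistic clustering test in path coordinates.  Pooling mutations
# over samples gives order statistics X(1) <= ... <= X(n) on the N analyzed
# residues; under the uniform null the scaled gap between X(i) and X(k) is
# approximately Beta(k-i, i+n-k+1), giving a closed-form pairwise cluster
# p-value.  All n(n-1)/2 pairs are tested and Bonferroni-adjusted.

new_order_stats <- function(x, n, N) {
  structure(list(x = as.integer(x), n = n, N = N), class = "order_stats")
}

#' Order statistics of mutation positions along a path
#'
#' Each mutated residue contributes `count` copies of its path position;
#' the pooled positions are sorted ascending.
#'
#' @param counts `mutation_counts` whose positions are structure-order
#'   indices 1..N (i.e. after [restrict_counts()]).
#' @param path A `path_order` over the same N residues.
#' @return An `order_stats` object with elements `x` (sorted positions with
#'   multiplicity), `n` (total mutations) and `N` (residues analyzed).
#' @export
order_statistics <- function(counts, path) {
  stopifnot(inherits(counts, "mutation_counts"),
            inherits(path, "path_order"))
  if (counts$n_total < 2L) insufficient_mutations(counts$n_total)
  idx <- as.integer(names(counts$counts))
  pos <- match(idx, path$sequence)
  if (anyNA(pos))
    stop("mutation at residue index not on the path: ",
         paste(idx[is.na(pos)], collapse = ", "), call. = FALSE)
  x <- sort(rep(pos, counts$counts))
  new_order_stats(x, counts$n_total, path$n)
}

#' @export
print.order_stats <- function(x, ...) {
  cat(sprintf("order statistics: n = %d mutations on N = %d residues\n",
              x$n, x$N))
  invisible(x)
}

#' Closed-form pairwise cluster p-value
#'
#' Probability, under positions i.i.d. uniform on the N residues, that the
#' scaled gap between the i-th and k-th order statistics is at most the
#' observed one: `pbeta(c, k - i, i + n - k + 1)` with
#' `c = (xk - xi + 1)/N` under the `"inclusive"` span convention (default)
#' or `c = (xk - xi)/N` under `"exclusive"`.  The inclusive convention keeps
#' recurrent single-residue hotspots (xi = xk) testable with a finite
#' p-value; the exclusive one is the literal limiting form.
#'
#' @param i,k Order-statistic indices, `1 <= i < k <= n`.
#' @param xi,xk Path positions `X(i) <= X(k)`.
#' @param n Total mutations.
#' @param N Residues analyzed.
#' @param span_convention `"inclusive"` or `"exclusive"`.
#' @return Probability in \[0, 1\].  Vectorized over `i`, `k`, `xi`, `xk`.
#' @export
pair_cluster_pvalue <- function(i, k, xi, xk, n, N,
                                span_convention = c("inclusive",
                                                    "exclusive")) {
  span_convention <- match.arg(span_convention)
  if (any(i < 1L) || any(k <= i) || any(k > n))
    stop("need 1 <= i < k <= n", call. = FALSE)
  if (any(xi < 1L) || any(xk < xi) || any(xk > N))
    stop("need 1 <= xi <= xk <= N", call. = FALSE)
  off <- if (span_convention == "inclusive") 1L else 0L
  cc <- (xk - xi + off) / N
  stats::pbeta(pmin(cc, 1), k - i, i + n - k + 1)
}

#' Number of pairwise cluster tests
#'
#' @param n Total mutations (n >= 2).
#' @return `n(n-1)/2`, the Bonferroni factor for the within-structure scan.
#' @export
bonferroni_factor <- function(n) {
  stopifnot(n >= 2)
  as.integer(round(n * (n - 1) / 2))
}

#' Scan all order-statistic pairs for clustering
#'
#' Computes the Beta p-value for every index pair `i < k` and applies the
#' within-structure Bonferroni correction over the n(n-1)/2 tests.
#'
#' @param os An `order_stats` object.
#' @param span_convention See [pair_cluster_pvalue()].
#' @return Data frame with one row per pair: `i`, `k`, `xi`, `xk`, `span_c`,
#'   `p_raw`, `p_bonf`.
#' @export
all_pairs_scan <- function(os, span_convention = c("inclusive",
                                                   "exclusive")) {
  span_convention <- match.arg(span_convention)
  stopifnot(inherits(os, "order_stats"))
  n <- os$n
  if (n < 2L) insufficient_mutations(n)
  pr <- utils::combn(n, 2L)
  i <- pr[1L, ]
  k <- pr[2L, ]
  xi <- os$x[i]
  xk <- os$x[k]
  off <- if (span_convention == "inclusive") 1L else 0L
  p_raw <- pair_cluster_pvalue(i, k, xi, xk, n, os$N, span_convention)
  nb <- bonferroni_factor(n)
  data.frame(i = i, k = k, xi = xi, xk = xk,
             span_c = pmin((xk - xi + off) / os$N, 1),
             p_raw = p_raw,
             p_bonf = pmin(1, p_raw * nb))
}

#' Monte-Carlo oracle for the pairwise cluster p-value
#'
#' Estimates the null probability directly by simulation: draw n positions
#' uniformly on 1..N (with replacement by default), sort, and record how
#' often the scaled (i,k) gap is at most `c_obs`.  Used to validate the Beta
#' approximation; independent of [pair_cluster_pvalue()].
#'
#' @param i,k Order-statistic indices.
#' @param c_obs Observed scaled span.
#' @param n,N Mutation and residue totals.
#' @param reps Number of Monte-Carlo replicates (>= 1000).
#' @param seed Optional seed applied via `set.seed()`.
#' @param span_convention See [pair_cluster_pvalue()].
#' @param replace Sample residues with replacement (i.i.d. uniform null,
#'   default) or without, for sensitivity checks.
#' @return List with `estimate`, `se` (binomial standard error) and `reps`.
#' @export
mc_cluster_pvalue_oracle <- function(i, k, c_obs, n, N, reps = 1e5,
                                     seed = NULL,
                                     span_convention = c("inclusive",
                                                         "exclusive"),
                                     replace = TRUE) {
  span_convention <- match.arg(span_convention)
  stopifnot(reps >= 1000, i >= 1, k > i, k <= n)
  if (!is.null(seed)) set.seed(seed)
  off <- if (span_convention == "inclusive") 1L else 0L
  if (replace) {
    X <- matrix(sample.int(N, reps * n, replace = TRUE), nrow = reps)
  } else {
    stopifnot(n <= N)
    X <- t(vapply(seq_len(reps),
                  function(r) sample.int(N, n, replace = FALSE),
                  integer(n)))
  }
  Xs <- t(apply(X, 1L, sort))
  hit <- (Xs[, k] - Xs[, i] + off) / N <= c_obs
  p <- mean(hit)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Map a path-space cluster back to original residue numbers
#'
#' Translates a scan row (path positions `xi`, `xk`) into canonical residue
#' numbers via the path and the residue map, together with the mutated
#' residues it contains.
#'
#' @param rc One row of an [all_pairs_scan()] data frame (or any list with
#'   `xi`, `xk`).
#' @param path The `path_order` used for the scan.
#' @param map The `residue_map` restricting the analysis.
#' @param os Optional `order_stats`; when given, the mutated residues within
#'   the cluster are reported as `members`.
#' @return List with `start_residue`, `end_residue` (canonical numbering,
#'   ordered) and `members` (sorted canonical residues of the clustered
#'   mutations, `NULL` without `os`).
#' @export
unmap_cluster <- function(rc, path, map, os = NULL) {
  canon <- map$pairs$canonical_pos
  si <- path$sequence[rc$xi]
  sk <- path$sequence[rc$xk]
  ends <- sort(c(canon[si], canon[sk]))
  members <- NULL
  if (!is.null(os)) {
    inside <- unique(os$x[os$x >= rc$xi & os$x <= rc$xk])
    members <- sort(canon[path$sequence[inside]])
  }
  list(start_residue = ends[1L], end_residue = ends[2L], members = members)
}
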