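test_that("distance matrix is Euclidean, isometry-invariant, warns on duplicates", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))
  D <- distance_matrix(co)
  expect_equal(D[1, 3], 5)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
  shifted <- sweep(co, 2, c(10, -4, 2), "+")
  expect_equal(distance_matrix(shifted), D)
  expect_warning(distance_matrix(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
                 "duplicate")
  expect_error(distance_matrix(rbind(c(0, 0, 0))), "at least two")
})

test_that("insertion tours: unique 3-cycle, colinear case, input validation", {
  D <- distance_matrix(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  for (m in c("cheapest", "nearest", "farthest")) {
    t3 <- insertion_tour(D, m)
    expect_equal(t3$length, 12)         # perimeter of the 3-4-5 triangle
    expect_setequal(t3$order, 1:3)
  }
  Dc <- distance_matrix(cbind(c(0, 1, 2, 10), 0, 0))
  for (m in c("cheapest", "nearest", "farthest"))
    expect_equal(insertion_tour(Dc, m)$length, 20)   # twice the span

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(insertion_tour(bad), "not symmetric")
  expect_error(insertion_tour(-D), "negative")
})

test_that("every insertion tour is a valid cycle with consistent length", {
  set.seed(101)
  for (rep in 1:25) {
    N <- sample(4:12, 1)
    D <- suppressWarnings(distance_matrix(cbind(runif(N), runif(N), runif(N))))
    for (m in c("cheapest", "nearest", "farthest")) {
      t <- insertion_tour(D, m)
      expect_setequal(t$order, seq_len(N))
      nxt <- c(t$order[-1], t$order[1])
      expect_equal(t$length, sum(D[cbind(t$order, nxt)]), tolerance = 1e-9)
    }
  }
})

test_that("cheapest and nearest insertion respect the 2x optimal-tour bound", {
  set.seed(202)
  for (rep in 1:30) {
    N <- sample(5:9, 1)
    D <- suppressWarnings(distance_matrix(cbind(runif(N), runif(N), 0)))
    opt <- brute_force_shortest_tour(D)$length
    for (m in c("cheapest", "nearest"))
      expect_lte(insertion_tour(D, m)$length, 2 * opt + 1e-9)
  }
})

test_that("Hamiltonian path handles colinear, tiny and relabeled instances", {
  Dc <- distance_matrix(cbind(c(0, 1, 2, 10), 0, 0))
  for (m in c("cheapest", "nearest", "farthest")) {
    p <- hamiltonian_path(Dc, m)
    expect_equal(p$sequence, 1:4)
    expect_equal(path_len(Dc, p$sequence), 10)
  }
  expect_equal(hamiltonian_path(matrix(c(0, 2, 2, 0), 2), "cheapest")$sequence,
               1:2)

  # reversing input coordinate order relabels but keeps the geometric path
  set.seed(7)
  co <- cbind(runif(8), runif(8), 0)
  D1 <- distance_matrix(co)
  D2 <- distance_matrix(co[8:1, ])
  for (m in c("cheapest", "nearest", "farthest")) {
    s1 <- hamiltonian_path(D1, m)$sequence
    s2 <- 9L - hamiltonian_path(D2, m)$sequence     # undo the relabeling
    e1 <- apply(cbind(s1[-8], s1[-1]), 1, function(e) paste(sort(e), collapse = "-"))
    e2 <- apply(cbind(s2[-8], s2[-1]), 1, function(e) paste(sort(e), collapse = "-"))
    expect_setequal(e1, e2)
  }
})

test_that("path edge sum equals the augmented tour length (free dummy edges)", {
  set.seed(17)
  for (rep in 1:10) {
    N <- sample(4:9, 1)
    D <- suppressWarnings(distance_matrix(cbind(runif(N), runif(N), 0)))
    Daug <- rbind(cbind(D, 0), 0)
    for (m in c("cheapest", "nearest", "farthest")) {
      p <- hamiltonian_path(D, m)
      taug <- insertion_tour(Daug, m, dummy = N + 1L)
      expect_equal(path_len(D, p$sequence), taug$length, tolerance = 1e-9)
    }
  }
})

test_that("brute-force path oracle: geometry-forced cases", {
  Dc <- distance_matrix(cbind(c(0, 4, 1, 9, 2), 0, 0))
  expect_equal(brute_force_shortest_path(Dc)$sequence, c(1, 3, 5, 2, 4))
  Dt <- distance_matrix(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  p <- brute_force_shortest_path(Dt)
  expect_equal(path_len(Dt, p$sequence), 7)     # drops the length-5 edge
  expect_error(brute_force_shortest_path(diag(0, 11)), "N > 10")
})

test_that("heuristics match the brute-force path on easy random instances", {
  set.seed(303)
  agree <- 0
  for (rep in 1:15) {
    N <- sample(5:7, 1)
    D <- suppressWarnings(distance_matrix(cbind(runif(N), runif(N), 0)))
    opt <- path_len(D, brute_force_shortest_path(D)$sequence)
    got <- min(vapply(c("cheapest", "nearest", "farthest"), function(m)
      path_len(D, hamiltonian_path(D, m)$sequence), numeric(1)))
    expect_gte(got, opt - 1e-9)       # never better than the oracle
    if (got <= opt + 1e-9) agree <- agree + 1
  }
  expect_gte(agree, 12)               # heuristics usually exact at this size
})

test_that("Kendall tau distance counts discordant pairs", {
  expect_equal(kendall_tau_distance(identity_path(10)), 0L)
  rev3 <- identity_path(3); rev3$sequence <- 3:1
  expect_equal(kendall_tau_distance(rev3), 3L)
  sw <- identity_path(3); sw$sequence <- c(2L, 1L, 3L)
  expect_equal(kendall_tau_distance(sw), 1L)
})

test_that("path separation is rank distance along the path", {
  p <- identity_path(10)
  expect_equal(path_separation(p, 4, 5), 1L)
  expect_equal(path_separation(p, 7, 7), 0L)
  expect_equal(path_separation(p, 1, 10), 9L)
  expect_error(path_separation(p, 1, 11), "not on path")
})
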