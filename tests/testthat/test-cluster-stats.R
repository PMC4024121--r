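test_that("order statistics pool counts into sorted path positions", {
  cnt <- counts_from_map(c(`5` = 2, `9` = 1))
  os <- order_statistics(cnt, identity_path(10))
  expect_equal(os$x, c(5L, 5L, 9L))
  expect_equal(os$n, 3L)
  expect_equal(os$N, 10L)

  # path placing residue 9 at position 2 and residue 5 at position 7
  p <- identity_path(10)
  p$sequence <- c(1L, 9L, 2L, 3L, 4L, 6L, 5L, 7L, 8L, 10L)
  expect_equal(order_statistics(cnt, p)$x, c(2L, 7L, 7L))

  expect_error(order_statistics(counts_from_map(c(`3` = 1)),
                                identity_path(10)),
               class = "tspclust_insufficient_mutations")
})

test_that("Beta p-value matches closed forms and handles both conventions", {
  # n=2: Beta(1,2) CDF(0.5) = 1 - (1-c)^2 = 0.75
  expect_equal(pair_cluster_pvalue(1, 2, 1, 6, 2, 10, "exclusive"), 0.75)
  # n=3, i=1, k=3: Beta(2,2) CDF(c) = 3c^2 - 2c^3 = 0.028 at c = 0.1
  expect_equal(pair_cluster_pvalue(1, 3, 3, 4, 3, 10, "exclusive"), 0.028)
  # full support
  expect_equal(pair_cluster_pvalue(1, 4, 1, 100, 4, 100, "inclusive"), 1)
  # inclusive gives a finite p for a recurrent single-residue hotspot
  p_same <- pair_cluster_pvalue(1, 2, 50, 50, 5, 100, "inclusive")
  expect_gt(p_same, 0)
  expect_equal(pair_cluster_pvalue(1, 2, 50, 50, 5, 100, "exclusive"), 0)

  expect_error(pair_cluster_pvalue(2, 2, 1, 5, 3, 10), "i < k")
  expect_error(pair_cluster_pvalue(1, 2, 5, 3, 2, 10), "xi <= xk")
})

test_that("p-value is monotone in span and in enclosed mutation count", {
  n <- 8; N <- 200
  cs <- seq(5, 100, by = 5)
  p_by_c <- pair_cluster_pvalue(1, 4, 1, 1 + cs, n, N)
  expect_true(all(diff(p_by_c) >= 0))
  # same span, growing k-i: more mutations inside => smaller p
  p_by_k <- vapply(3:8, function(k)
    pair_cluster_pvalue(1, k, 10, 40, n, N), numeric(1))
  expect_true(all(diff(p_by_k) < 0))
})

test_that("the all-pairs scan enumerates n(n-1)/2 Bonferroni-adjusted tests", {
  os <- order_statistics(counts_from_map(c(`5` = 2, `9` = 1)),
                         identity_path(100))
  sc <- all_pairs_scan(os)
  expect_equal(nrow(sc), 3L)
  expect_equal(bonferroni_factor(2), 1L)
  expect_equal(bonferroni_factor(5), 10L)
  expect_equal(bonferroni_factor(60), 1770L)
  # closed forms for X = (5, 5, 9) on N = 100 under the inclusive span:
  # the tied pair has the smallest span but the triple (1,3) the smallest p
  tied <- sc$i == 1 & sc$k == 2
  expect_equal(sc$span_c[tied], 1 / 100)
  expect_equal(sc$p_raw[tied], 1 - 0.99^3)            # Beta(1,3) at 0.01
  full <- sc$i == 1 & sc$k == 3
  expect_equal(sc$p_raw[full], 3 * 0.05^2 - 2 * 0.05^3)  # Beta(2,2) at 0.05
  expect_equal(which.min(sc$p_raw), which(full))
  expect_equal(sc$p_bonf, pmin(1, sc$p_raw * 3))

  # capping at 1 for weak signals
  wide <- order_statistics(counts_from_map(c(`1` = 1, `5` = 1, `9` = 1)),
                           identity_path(10))
  expect_equal(max(all_pairs_scan(wide)$p_bonf), 1)
})

test_that("Monte-Carlo oracle agrees with the Beta form and scales correctly", {
  mc <- mc_cluster_pvalue_oracle(1, 3, (20 + 0.5) / 100, 3, 100,
                                 reps = 1e5, seed = 9,
                                 span_convention = "exclusive")
  beta <- pbeta(0.205, 2, 2)
  expect_lt(abs(mc$estimate - beta), 4 * mc$se)

  sure <- mc_cluster_pvalue_oracle(1, 2, 1, 4, 50, reps = 1000, seed = 1)
  expect_equal(sure$estimate, 1)

  # binomial SE scaling: se = sqrt(p(1-p)/reps)
  expect_equal(mc$se, sqrt(mc$estimate * (1 - mc$estimate) / 1e5))

  # without-replacement variant still concentrates near the Beta value
  mc2 <- mc_cluster_pvalue_oracle(1, 3, 0.205, 3, 100, reps = 2e4, seed = 4,
                                  span_convention = "exclusive",
                                  replace = FALSE)
  expect_lt(abs(mc2$estimate - beta), 6 * max(mc2$se, 1e-4))
})

test_that("p-values are invariant under path reversal", {
  set.seed(55)
  cnt <- counts_from_map(c(`3` = 2, `11` = 1, `17` = 3))
  p <- identity_path(20); p$sequence <- sample(20)
  pr <- p; pr$sequence <- rev(p$sequence)
  s1 <- all_pairs_scan(order_statistics(cnt, p))
  s2 <- all_pairs_scan(order_statistics(cnt, pr))
  expect_equal(sort(s1$p_raw), sort(s2$p_raw), tolerance = 1e-12)
})

test_that("under the uniform null the structure-level FP rate is controlled", {
  set.seed(77)
  fp <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    pos <- table(sample.int(150, 8, replace = TRUE))
    cnt <- counts_from_map(setNames(as.integer(pos), names(pos)))
    sc <- all_pairs_scan(order_statistics(cnt, identity_path(150)))
    if (min(sc$p_bonf) <= 0.05) fp <- fp + 1
  }
  expect_lte(fp / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("clusters unmap to canonical residue numbers and members", {
  map <- direct_numbering_map(make_helix(100))
  cnt <- counts_from_map(c(`5` = 1, `7` = 1, `9` = 1))
  os <- order_statistics(cnt, identity_path(100))
  sc <- all_pairs_scan(os)
  u <- unmap_cluster(sc[sc$i == 1 & sc$k == 3, ], identity_path(100), map, os)
  expect_equal(u$start_residue, 5)
  expect_equal(u$end_residue, 9)
  expect_equal(u$members, c(5, 7, 9))

  # a path making canonical residues 12 and 61 adjacent reports "12-61"
  p <- identity_path(100)
  p$sequence <- c(12L, 61L, setdiff(1:100, c(12L, 61L)))
  cnt2 <- counts_from_map(c(`12` = 1, `61` = 1))
  os2 <- order_statistics(cnt2, p)
  expect_equal(os2$x, c(1L, 2L))
  u2 <- unmap_cluster(list(xi = 1L, xk = 2L), p, map, os2)
  expect_equal(c(u2$start_residue, u2$end_residue), c(12, 61))

  # recurrent hotspot: single-position cluster has start == end
  cnt3 <- counts_from_map(c(`42` = 2))
  os3 <- order_statistics(cnt3, identity_path(100))
  sc3 <- all_pairs_scan(os3)
  u3 <- unmap_cluster(sc3[1, ], identity_path(100), map, os3)
  expect_equal(u3$start_residue, u3$end_residue)
})
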